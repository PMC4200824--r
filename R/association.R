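# Q+K mixed-model single-SNP association: Ritland marker-based kinship,
# restricted-maximum-likelihood variance components via one eigendecomposition
# of K (EMMA-style), Wald F tests, positive-FDR q-values, variance explained,
# gene-action decomposition and subset validation.

#' Construct a genotype table
#'
#' @param mat n individuals x m SNPs matrix of minor-allele dosages
#'   \{0, 1, 2\} with `NA` for missing; rownames = individual ids,
#'   colnames = SNP ids.
#' @param positions optional bp positions per SNP.
#' @param region optional region label per SNP.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(mat, positions = NULL, region = NULL) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1, 2) | is.na(mat))) {
    stop_user("genotypes must be coded 0/1/2 or NA")
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("ind", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("snp", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat))) stop_user("duplicate individual ids")
  structure(list(mat = mat,
                 positions = positions %||% rep(NA_real_, ncol(mat)),
                 region = region %||% rep(NA_character_, ncol(mat))),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$mat), ncol(x$mat), 100 * mean(is.na(x$mat))))
  invisible(x)
}

# --- kinship ----------------------------------------------------------------

#' Ritland marker-based kinship matrix
#'
#' The Ritland (1996) correlation estimator of pairwise relatedness from
#' codominant markers, with allele frequencies estimated from the same
#' panel. Per biallelic locus with minor-allele frequency `p`, the pairwise
#' estimate is `(P_i P_j / p + (1-P_i)(1-P_j) / (1-p) - 1)` with `P`
#' half-dosages; multilocus estimates are ratios of sums over loci (each
#' biallelic locus contributing unit weight). Negative pairwise estimates
#' are truncated to 0 and the matrix is conditioned to positive
#' semidefiniteness by clipping negative eigenvalues at 0.
#'
#' @param G a [genotype_table()] (missing genotypes ignored per locus pair).
#' @param truncate_negative truncate negative off-diagonal estimates to 0
#'   (default TRUE).
#' @return an n x n symmetric PSD matrix of class `matrix` with individual
#'   ids as dimnames.
#' @export
ritland_kinship <- function(G, truncate_negative = TRUE) {
  X <- G$mat
  mono <- apply(X, 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    is.na(p) || p <= 0 || p >= 1
  })
  X <- X[, !mono, drop = FALSE]
  if (ncol(X) < 10L) stop_user("need >= 10 polymorphic SNPs for kinship")
  n <- nrow(X)
  P <- X / 2                      # frequency of minor allele in individual
  p <- colMeans(P, na.rm = TRUE)  # panel allele frequencies
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  obs <- !is.na(P)
  P0 <- P
  P0[!obs] <- 0
  Q0 <- 1 - P
  Q0[!obs] <- 0
  for (l in seq_len(ncol(X))) {
    o <- obs[, l]
    contrib <- outer(P0[, l], P0[, l]) / p[l] +
      outer(Q0[, l], Q0[, l]) / (1 - p[l]) - outer(o, o)
    num <- num + contrib * outer(o, o)
    den <- den + outer(o, o)  # one allele-class degree of freedom per locus
  }
  K <- num / den
  if (truncate_negative) {
    diag_save <- diag(K)
    K[K < 0] <- 0
    diag(K) <- pmax(diag_save, 0)
  }
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(G$mat), rownames(G$mat))
  K
}

# --- REML mixed model -------------------------------------------------------

#' Eigendecomposition of a kinship matrix for repeated REML fits
#'
#' @param K symmetric PSD kinship matrix.
#' @return list with `values` and `vectors` (as [eigen()]).
#' @export
kinship_eigen <- function(K) {
  if (max(abs(K - t(K))) > 1e-9) stop_user("kinship matrix must be symmetric")
  eigen(K, symmetric = TRUE)
}

# Restricted log-likelihood of the rotated model at ratio delta, plus the
# GLS fit. Rotation: K = U D U', y* = U'y, X* = U'X, Var(y*) propto D+delta.
.reml_at_delta <- function(delta, ys, Xs, d) {
  n <- length(ys)
  p <- ncol(Xs)
  w <- 1 / (d + delta)
  Xw <- Xs * sqrt(w)
  yw <- ys * sqrt(w)
  qr_ <- qr(Xw)
  if (qr_$rank < p) return(list(ll = -Inf, singular = TRUE))
  beta <- qr.coef(qr_, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  sigma_a2 <- rss / (n - p)
  XtWX <- crossprod(Xw)
  ll <- -0.5 * ((n - p) * log(2 * pi * sigma_a2) + sum(log(d + delta)) +
                  determinant(XtWX, logarithm = TRUE)$modulus[1] +
                  (n - p))
  list(ll = as.numeric(ll), beta = as.numeric(beta), rss = rss,
       sigma_a2 = sigma_a2, XtWX = XtWX, singular = FALSE)
}

#' REML fit of the Q+K mixed model for one fixed-effect design
#'
#' Model `y = X b + u + e` with `Var(u) = sigma_a^2 K`,
#' `Var(e) = sigma_e^2 I`. The variance ratio `delta = sigma_e^2/sigma_a^2`
#' is profiled by restricted maximum likelihood on a 60-point grid over
#' `log(delta) in [-10, 10]` followed by golden-section refinement; fixed
#' effects are then estimated by generalised least squares and each
#' coefficient is tested with a Wald F (1, n-p) test. With `K = I` the fit
#' collapses exactly to ordinary least squares.
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix including the intercept.
#' @param eig [kinship_eigen()] of K (so many SNPs can reuse one
#'   decomposition).
#' @return list with `beta`, `se`, `F`, `p` (per coefficient), `delta`,
#'   `sigma_a2`, `sigma_e2`, `rss` (weighted RSS on the rotated scale),
#'   `loglik`, `df_resid`, plus the rotated quantities needed by
#'   [variance_explained()].
#' @export
reml_fit <- function(y, X, eig) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(eig$vectors) == n)
  ys <- crossprod(eig$vectors, y)[, 1]
  Xs <- crossprod(eig$vectors, X)
  d <- pmax(eig$values, 0)
  grid <- exp(seq(-10, 10, length.out = 60))
  lls <- vapply(grid, function(dl) .reml_at_delta(dl, ys, Xs, d)$ll, 0)
  if (all(!is.finite(lls))) {
    return(structure(list(singular = TRUE), class = "reml_fit"))
  }
  k <- which.max(lls)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(function(dl) .reml_at_delta(dl, ys, Xs, d)$ll,
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- if (opt$objective >= lls[k]) opt$maximum else grid[k]
  fit <- .reml_at_delta(delta, ys, Xs, d)
  if (isTRUE(fit$singular)) {
    return(structure(list(singular = TRUE), class = "reml_fit"))
  }
  p <- ncol(X)
  covb <- fit$sigma_a2 * solve(fit$XtWX)
  se <- sqrt(diag(covb))
  Fst <- (fit$beta / se)^2
  pv <- stats::pf(Fst, 1, n - p, lower.tail = FALSE)
  names(fit$beta) <- names(se) <- names(Fst) <- names(pv) <- colnames(X)
  structure(list(beta = fit$beta, se = se, F = Fst, p = pv, delta = delta,
                 sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_a2 * delta,
                 rss = fit$rss, loglik = fit$ll, df_resid = n - p,
                 ys = ys, Xs = Xs, d = d, singular = FALSE,
                 grid_ll = lls, grid = grid),
            class = "reml_fit")
}

#' Percentage of phenotypic variance explained by one term
#'
#' `100 * (RSS_reduced - RSS_full) / TSS` on the rotated, variance-weighted
#' scale of the full fit (both models evaluated at the full model's delta),
#' clipped at 0.
#'
#' @param fit a [reml_fit()] of the full model.
#' @param drop column index (or name) of the term to remove.
#' @return percentage in `[0, 100]`.
#' @export
variance_explained <- function(fit, drop) {
  w <- 1 / (fit$d + fit$delta)
  Xw <- fit$Xs * sqrt(w)
  yw <- fit$ys * sqrt(w)
  if (is.character(drop)) drop <- match(drop, colnames(fit$Xs))
  rss_full <- fit$rss
  Xr <- Xw[, -drop, drop = FALSE]
  rss_red <- sum(stats::lm.fit(Xr, yw)$residuals^2)
  # TSS about the weighted mean on the same scale
  ones_w <- sqrt(w)
  mu_w <- sum(ones_w * yw) / sum(ones_w^2)
  tss <- sum((yw - mu_w * ones_w)^2)
  max(0, 100 * (rss_red - rss_full) / tss)
}

#' Storey positive-FDR q-values
#'
#' The null proportion `pi0` is estimated on the lambda grid
#' `0.05, 0.10, ..., 0.95` with a cubic smoothing spline evaluated at the
#' largest lambda; for fewer than 100 p-values the single-point estimate at
#' `lambda = 0.5` is used. `q_i = min_{p_j >= p_i} pi0 * m * p_j / rank(p_j)`,
#' monotone in p. With `pi0 = 1` this reduces exactly to Benjamini-Hochberg.
#'
#' @param p p-values in `(0, 1]`.
#' @param pi0 optional fixed null proportion (overrides estimation).
#' @return q-values in the order of `p`, with `pi0` as an attribute.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (any(p <= 0 | p > 1 | is.na(p))) stop_user("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- min(1, mean(p > 0.5) / 0.5)
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
    if (pi0 <= 0) pi0 <- 1e-8
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, pi0 * m * p[o] / (m:1))
  q <- cummin(q)[ro]
  structure(q, pi0 = pi0)
}

# --- gene action ------------------------------------------------------------

#' Gene-action mode from |d/a|
#'
#' `|d/a| <= 0.50` codominant (additive); `0.50 < |d/a| < 1.25` partial to
#' full dominance; `|d/a| >= 1.25` over/underdominance.
#'
#' @param d_over_a signed dominance/additive ratio (NA -> `"undefined"`).
#' @return character mode label.
#' @export
gene_action_mode <- function(d_over_a) {
  vapply(d_over_a, function(x) {
    if (is.na(x)) return("undefined")
    ax <- abs(x)
    if (ax <= 0.50) "codominant"
    else if (ax < 1.25) "dominant"
    else "overdominant"
  }, "")
}

#' Gene-action decomposition from genotypic class means
#'
#' `2a = |G_BB - G_bb|`; `d = G_Bb - (G_BB + G_bb)/2`; the ratio uses the
#' unsigned additive span, `d/a = d / (2a/2)`, so it carries the sign of
#' the dominance deviation and is invariant to which allele is labelled B;
#' `2a/s_p` scales the additive span by the trait standard deviation; the
#' additive allele effect is `a_add = p_B G_BB + p_b G_Bb - G` (with
#' respect to the minor allele B).
#'
#' @param G_BB,G_Bb,G_bb trait means of the minor-homozygote, heterozygote
#'   and major-homozygote classes (`NA` for an unobserved class).
#' @param p_B minor-allele frequency.
#' @param s_p phenotypic standard deviation of the trait.
#' @param G overall trait mean.
#' @return list with `two_a`, `d`, `d_over_a`, `two_a_over_sp`, `a_add`,
#'   `mode`. With an unobserved class or `a = 0` the ratio and mode are
#'   `"undefined"`.
#' @export
gene_action <- function(G_BB, G_Bb, G_bb, p_B, s_p, G) {
  if (anyNA(c(G_BB, G_Bb, G_bb))) {
    return(list(two_a = NA_real_, d = NA_real_, d_over_a = NA_real_,
                two_a_over_sp = NA_real_, a_add = NA_real_,
                mode = "undefined"))
  }
  two_a <- abs(G_BB - G_bb)
  d <- G_Bb - 0.5 * (G_BB + G_bb)
  d_over_a <- if (two_a == 0) NA_real_ else d / (two_a / 2)
  list(two_a = two_a, d = d, d_over_a = d_over_a,
       two_a_over_sp = two_a / s_p,
       a_add = p_B * G_BB + (1 - p_B) * G_Bb - G,
       mode = gene_action_mode(d_over_a))
}

# --- association scan -------------------------------------------------------

# Impute per-SNP mean for missing dosages; drop SNPs with > max_missing
# missingness or monomorphic after imputation. Returns the numeric matrix
# and the kept column indices.
impute_genotypes <- function(G, max_missing = 0.2) {
  X <- G$mat
  miss <- colMeans(is.na(X))
  keep <- which(miss <= max_missing)
  X <- X[, keep, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  poly <- apply(X, 2, function(g) stats::var(g) > 0)
  list(X = X[, poly, drop = FALSE], kept = keep[poly],
       n_imputed = sum(is.na(G$mat[, keep[poly], drop = FALSE])))
}

#' Single-SNP Q+K mixed-model association scan
#'
#' Each SNP enters additively (0/1/2 minor-allele dosage, per-SNP mean
#' imputation of missing calls) as a fixed effect alongside the intercept
#' and the structure covariates Q (one column dropped against the
#' intercept); the polygenic background is a random effect with covariance
#' `sigma_a^2 K`. Variance components are re-profiled per SNP, the SNP
#' coefficient is Wald-F tested, variance explained is the weighted
#' RSS-difference on the rotated scale, and q-values are computed across
#' the scan. Genotypic class means are raw per-class trait means.
#'
#' @param G a [genotype_table()].
#' @param y named numeric phenotype vector (names = individual ids) or a
#'   plain vector aligned with `G`.
#' @param Q n x k structure membership matrix (rows sum to 1), or NULL.
#' @param K kinship matrix; default [ritland_kinship()] of `G`.
#' @param trait trait name for the output table.
#' @param max_missing per-SNP missingness ceiling before dropping (0.2).
#' @return data frame of class `assoc_scan`: one row per tested SNP with
#'   `snp`, `trait`, `beta`, `se`, `F`, `p`, `q`, `r2_percent`, `delta`,
#'   `sigma_a2`, `sigma_e2`, class means/counts and minor-allele frequency.
#' @export
assoc_scan <- function(G, y, Q = NULL, K = ritland_kinship(G),
                       trait = "trait", max_missing = 0.2) {
  ids <- rownames(G$mat)
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y))) stop_user("phenotype ids do not cover genotypes")
    y <- y[ids]
  }
  ok <- !is.na(y)
  y <- y[ok]
  Gm <- genotype_table(G$mat[ok, , drop = FALSE],
                       positions = G$positions, region = G$region)
  if (!is.null(Q)) Q <- as.matrix(Q)[ok, , drop = FALSE]
  K <- K[ok, ok]
  imp <- impute_genotypes(Gm, max_missing)
  eig <- kinship_eigen(K)
  Xbase <- cbind(intercept = 1)
  if (!is.null(Q) && ncol(Q) > 1) {
    Xbase <- cbind(intercept = 1, Q[, -ncol(Q), drop = FALSE])
  }
  n <- length(y)
  rows <- lapply(seq_len(ncol(imp$X)), function(j) {
    snp <- imp$X[, j]
    X <- cbind(Xbase, snp = snp)
    fit <- reml_fit(y, X, eig)
    if (isTRUE(fit$singular)) return(NULL)
    r2p <- variance_explained(fit, ncol(X))
    raw <- Gm$mat[, imp$kept[j]]
    cls <- function(v) if (length(v)) mean(y[!is.na(raw) & raw == v]) else NA
    nn <- function(v) sum(raw == v, na.rm = TRUE)
    data.frame(snp = colnames(Gm$mat)[imp$kept[j]], trait = trait,
               position = Gm$positions[imp$kept[j]],
               region = Gm$region[imp$kept[j]],
               beta = unname(fit$beta["snp"]), se = unname(fit$se["snp"]),
               F = unname(fit$F["snp"]), p = unname(fit$p["snp"]),
               r2_percent = r2p, delta = fit$delta,
               sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
               freq_b = mean(snp) / 2,
               mean_bb = cls(0), mean_Bb = cls(1), mean_BB = cls(2),
               n_bb = nn(0), n_Bb = nn(1), n_BB = nn(2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) stop_user("no testable SNPs")
  res$q <- as.numeric(storey_qvalues(pmin(pmax(res$p, 1e-300), 1)))
  class(res) <- c("assoc_scan", "data.frame")
  attr(res, "n") <- n
  res
}

#' Gene-action table for an association scan
#'
#' Applies [gene_action()] to the raw genotypic class means of each scanned
#' SNP.
#'
#' @param scan an [assoc_scan()] result.
#' @param y the phenotype vector used in the scan (for `s_p` and `G`).
#' @return data frame with one gene-action row per SNP.
#' @export
gene_action_table <- function(scan, y) {
  y <- y[!is.na(y)]
  s_p <- stats::sd(y)
  Gbar <- mean(y)
  rows <- lapply(seq_len(nrow(scan)), function(i) {
    ga <- gene_action(scan$mean_BB[i], scan$mean_Bb[i], scan$mean_bb[i],
                      scan$freq_b[i], s_p, Gbar)
    data.frame(snp = scan$snp[i], trait = scan$trait[i],
               two_a = ga$two_a, d = ga$d, d_over_a = ga$d_over_a,
               two_a_over_sp = ga$two_a_over_sp, freq_b = scan$freq_b[i],
               a_add = ga$a_add, mode = ga$mode, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subset validation of association results
#'
#' Reruns the full scan independently inside each subset (kinship re-derived
#' and Q re-subset per subset); a marker-trait pair is "validated" when its
#' p-value is <= `alpha` in at least one subset.
#'
#' @param G,y,Q as in [assoc_scan()].
#' @param subsets factor/character of subset labels per individual.
#' @param alpha per-subset significance level (default 0.05).
#' @param min_n subsets smaller than this are skipped with a warning (30).
#' @param trait trait name.
#' @return list with `per_subset` (named list of scan tables) and
#'   `validated` (data frame: snp, n_subsets_significant, validated).
#' @export
subset_validation <- function(G, y, Q = NULL, subsets, alpha = 0.05,
                              min_n = 30, trait = "trait") {
  labs <- unique(as.character(subsets))
  per <- list()
  for (s in labs) {
    idx <- which(subsets == s)
    if (length(idx) < min_n) {
      warning(sprintf("subset '%s' below size floor (%d < %d); skipped",
                      s, length(idx), min_n))
      next
    }
    Gs <- genotype_table(G$mat[idx, , drop = FALSE],
                         positions = G$positions, region = G$region)
    Qs <- if (is.null(Q)) NULL else {
      q <- as.matrix(Q)[idx, , drop = FALSE]
      q <- q[, colSums(q) > 0, drop = FALSE]
      q / rowSums(q)
    }
    if (!is.null(Qs) && ncol(Qs) < 2) Qs <- NULL
    per[[s]] <- tryCatch(
      assoc_scan(Gs, y[idx], Qs, trait = trait),
      error = function(e) {
        warning(sprintf("subset '%s' scan failed: %s", s, conditionMessage(e)))
        NULL
      })
  }
  per <- per[!vapply(per, is.null, NA)]
  snps <- unique(unlist(lapply(per, function(t) t$snp)))
  hits <- vapply(snps, function(sn) {
    sum(vapply(per, function(t) {
      any(t$snp == sn & t$p <= alpha)
    }, NA))
  }, 0L)
  list(per_subset = per,
       validated = data.frame(snp = snps, n_subsets_significant = hits,
                              validated = hits >= 1L,
                              stringsAsFactors = FALSE))
}
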