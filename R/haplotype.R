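# EM haplotype-frequency estimation from unphased genotypes and haplotype
# trend regression (HTR) on sliding marker windows. Haplotypes within a
# window are enumerated explicitly (window width is capped at 8 markers),
# individuals missing any window genotype are excluded from that window,
# and rare haplotypes are pooled - never silently dropped - so expected
# dosages always sum to 2 per individual.

#' Sliding marker windows
#'
#' Windows `[i, i + width)` over the genotyped-marker index (not bp).
#'
#' @param m number of markers.
#' @param width window width (>= 2, default 3).
#' @param step step between window starts (default 1).
#' @return list of integer vectors of 1-based marker indices.
#' @export
sliding_windows <- function(m, width = 3, step = 1) {
  stopifnot(width >= 2, width <= m, step >= 1)
  starts <- seq.int(1L, m - width + 1L, by = step)
  lapply(starts, function(s) seq.int(s, s + width - 1L))
}

# Haplotypes over w biallelic markers encoded as integers 0..2^w - 1
# (bit k = allele at marker k). Enumerate the compatible ordered pairs for
# a multilocus genotype vector g (0/1/2).
# string position k is marker k (left to right in window order)
.hap_string <- function(code, w) {
  paste(as.integer(intToBits(code))[seq_len(w)], collapse = "")
}

.compatible_pairs <- function(g) {
  w <- length(g)
  het <- which(g == 1L)
  base <- sum((g == 2L) * 2^(seq_len(w) - 1L))
  if (length(het) == 0L) {
    return(matrix(c(base, base), ncol = 2))
  }
  # assign each het marker's minor allele to haplotype 1 or 2
  combos <- as.matrix(expand.grid(rep(list(0:1), length(het))))
  bits <- 2^(het - 1L)
  h1 <- base + combos %*% bits
  h2 <- base + (1 - combos) %*% bits
  unique(cbind(pmin(h1, h2), pmax(h1, h2)))
}

#' EM haplotype-frequency estimation for one marker window
#'
#' Standard EM over phase configurations of unphased biallelic genotypes.
#' The deterministic start is the product of marker allele frequencies;
#' iteration stops when the log-likelihood gain drops below `tol` or after
#' `max_iter` iterations. Monomorphic markers are retained (their
#' haplotypes simply collapse) with a warning.
#'
#' @param geno n x w matrix of 0/1/2 dosages (rows = individuals). Rows
#'   with any `NA` are excluded (complete-case per window).
#' @param tol log-likelihood convergence tolerance (1e-8).
#' @param max_iter iteration cap (1000).
#' @param start optional start frequencies (length `2^w`, summing to 1).
#' @return object of class `hap_freqs`: list with `haplotypes` (strings,
#'   e.g. "010"), `freq`, `loglik` (final), `loglik_trace`, `dosage`
#'   (n_complete x 2^w expected haplotype dosages, rows sum to 2),
#'   `individuals` (row indices of `geno` used), `n_iter`.
#' @export
em_haplotypes <- function(geno, tol = 1e-8, max_iter = 1000, start = NULL) {
  geno <- as.matrix(geno)
  w <- ncol(geno)
  if (w > 8L) stop_user("window too wide for enumeration (max 8 markers)")
  used <- which(stats::complete.cases(geno))
  if (length(used) == 0L) stop_user("no complete-case individuals in window")
  g <- geno[used, , drop = FALSE]
  if (any(colSums(g) %in% c(0L, 2L * nrow(g)))) {
    warning("monomorphic marker in window; haplotypes collapse")
  }
  H <- 2L^w
  pairs <- lapply(seq_len(nrow(g)), function(i) .compatible_pairs(g[i, ]))
  # start: product of allele frequencies
  if (is.null(start)) {
    p <- colMeans(g) / 2
    f <- vapply(0:(H - 1L), function(h) {
      bits <- as.integer(intToBits(h))[seq_len(w)]
      prod(ifelse(bits == 1L, p, 1 - p))
    }, 0)
  } else {
    stopifnot(length(start) == H, abs(sum(start) - 1) < 1e-6)
    f <- start
  }
  f <- pmax(f, 0)
  f <- f / sum(f)
  n <- nrow(g)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(H)
    ll <- 0
    for (i in seq_len(n)) {
      pr <- pairs[[i]]
      wgt <- f[pr[, 1] + 1L] * f[pr[, 2] + 1L] *
        ifelse(pr[, 1] != pr[, 2], 2, 1)
      tot <- sum(wgt)
      if (tot <= 0) {
        wgt <- rep(1 / nrow(pr), nrow(pr))
        tot <- 1
        ll <- ll + log(.Machine$double.xmin)
      } else {
        ll <- ll + log(tot)
        wgt <- wgt / tot
      }
      for (r in seq_len(nrow(pr))) {
        counts[pr[r, 1] + 1L] <- counts[pr[r, 1] + 1L] + wgt[r]
        counts[pr[r, 2] + 1L] <- counts[pr[r, 2] + 1L] + wgt[r]
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (iter >= max_iter || (is.finite(ll_old) && ll - ll_old < tol)) {
      f <- counts / (2 * n)
      break
    }
    ll_old <- ll
    f <- counts / (2 * n)
  }
  # expected per-individual dosages at the final frequencies
  dosage <- matrix(0, n, H)
  for (i in seq_len(n)) {
    pr <- pairs[[i]]
    wgt <- f[pr[, 1] + 1L] * f[pr[, 2] + 1L] *
      ifelse(pr[, 1] != pr[, 2], 2, 1)
    if (sum(wgt) <= 0) wgt <- rep(1, nrow(pr))
    wgt <- wgt / sum(wgt)
    for (r in seq_len(nrow(pr))) {
      dosage[i, pr[r, 1] + 1L] <- dosage[i, pr[r, 1] + 1L] + wgt[r]
      dosage[i, pr[r, 2] + 1L] <- dosage[i, pr[r, 2] + 1L] + wgt[r]
    }
  }
  haps <- vapply(0:(H - 1L), .hap_string, "", w = w)
  colnames(dosage) <- haps
  structure(list(haplotypes = haps, freq = stats::setNames(f, haps),
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, dosage = dosage,
                 individuals = used, n_iter = iter),
            class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  common <- x$freq[x$freq > 0.01]
  cat(sprintf("hap_freqs: %d markers, %d individuals, %d EM iterations\n",
              nchar(x$haplotypes[1]), nrow(x$dosage), x$n_iter))
  print(round(sort(common, decreasing = TRUE), 4))
  invisible(x)
}

#' Haplotype trend regression for one window
#'
#' Regresses the phenotype on expected dosages of the common haplotypes
#' (frequency strictly greater than `min_freq`); rare haplotypes are pooled
#' into one column, and one column is dropped for identifiability. The
#' overall haplotype effect is F-tested against the intercept-only model,
#' each retained haplotype gets a per-haplotype t-test, and an overall
#' permutation p-value is computed from seeded phenotype shuffles with the
#' add-one estimator.
#'
#' @param y phenotype values for the window's complete-case individuals.
#' @param hf an [em_haplotypes()] result (its `dosage` rows must align with
#'   `y`).
#' @param min_freq common-haplotype frequency floor (strict >, default 0.05).
#' @param n_perm permutation count (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @return object of class `htr_result`: `p_overall` (analytic F),
#'   `p_perm`, `r2_percent`, and `per_haplotype` (haplotype, frequency,
#'   trait mean, t, p).
#' @export
htr_test <- function(y, hf, min_freq = 0.05, n_perm = 1000, seed = 1) {
  D <- hf$dosage
  stopifnot(length(y) == nrow(D))
  common <- which(hf$freq > min_freq)
  if (length(common) < 2L) {
    return(structure(list(skipped = TRUE,
                          reason = "fewer than 2 common haplotypes"),
                     class = "htr_result"))
  }
  rare <- setdiff(seq_along(hf$freq), common)
  X <- D[, common, drop = FALSE]
  if (length(rare)) {
    pooled <- rowSums(D[, rare, drop = FALSE])
    if (any(pooled > 0)) X <- cbind(X, pooled_rare = pooled)
  }
  # drop the most frequent column into the intercept
  ref <- which.max(hf$freq[common])
  Xd <- X[, -ref, drop = FALSE]
  dat <- data.frame(y = y, Xd, check.names = FALSE)
  full <- stats::lm(y ~ ., data = dat)
  null <- stats::lm(y ~ 1, data = dat)
  an <- stats::anova(null, full)
  F_obs <- an$F[2]
  p_overall <- an$`Pr(>F)`[2]
  r2_percent <- 100 * summary(full)$r.squared
  # per-haplotype single-dosage regressions (marginal trend tests)
  per <- do.call(rbind, lapply(common, function(h) {
    d <- D[, h]
    fit <- stats::lm(y ~ d)
    sm <- summary(fit)$coefficients
    tv <- if (nrow(sm) > 1) sm[2, 3] else NA_real_
    pv <- if (nrow(sm) > 1) sm[2, 4] else NA_real_
    data.frame(haplotype = hf$haplotypes[h], frequency = unname(hf$freq[h]),
               mean = if (sum(d) > 0) sum(y * d) / sum(d) else NA_real_,
               t = tv, p = pv, stringsAsFactors = FALSE)
  }))
  # permutation F via a fixed QR projection (design never changes)
  set.seed(seed)
  n <- length(y)
  Xfull <- cbind(1, Xd)
  Qmat <- qr.Q(qr(Xfull))
  k <- qr(Xfull)$rank - 1L
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    tss <- sum((yp - mean(yp))^2)
    fit_ss <- sum(crossprod(Qmat, yp)^2) - n * mean(yp)^2
    rss <- tss - fit_ss
    Fp <- (fit_ss / k) / (rss / (n - k - 1L))
    if (!is.na(Fp) && Fp >= F_obs - 1e-12) exceed <- exceed + 1L
  }
  p_perm <- (1 + exceed) / (1 + n_perm)
  structure(list(skipped = FALSE, F = F_obs, p_overall = p_overall,
                 p_perm = p_perm, r2_percent = r2_percent,
                 per_haplotype = per, n = length(y)),
            class = "htr_result")
}

#' @export
print.htr_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("htr_result: skipped -", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("HTR: overall F p = %.4g (perm p = %.4g), r2 = %.2f%%\n",
              x$p_overall, x$p_perm, x$r2_percent))
  print(x$per_haplotype, row.names = FALSE)
  invisible(x)
}

#' Sliding-window haplotype trend regression scan
#'
#' Runs [em_haplotypes()] + [htr_test()] on every window; permutation
#' streams are seeded per window from the global seed plus the window index
#' so results do not depend on evaluation order.
#'
#' @param G a [genotype_table()].
#' @param y phenotype vector aligned with `G` (NA allowed; complete cases
#'   per window).
#' @param width window width in markers (default 3).
#' @param step window step (default 1).
#' @param min_freq common-haplotype floor (default 0.05).
#' @param n_perm permutations per window (default 1000).
#' @param seed global seed.
#' @param trait trait name for the output.
#' @return long data frame: one row per common haplotype per testable
#'   window, with overall and per-haplotype statistics.
#' @export
htr_scan <- function(G, y, width = 3, step = 1, min_freq = 0.05,
                     n_perm = 1000, seed = 1, trait = "trait") {
  wins <- sliding_windows(ncol(G$mat), width, step)
  out <- list()
  for (wi in seq_along(wins)) {
    win <- wins[[wi]]
    geno <- G$mat[, win, drop = FALSE]
    ok <- stats::complete.cases(geno) & !is.na(y)
    if (sum(ok) < 10L) next
    hf <- em_haplotypes(geno[ok, , drop = FALSE])
    res <- htr_test(y[ok][hf$individuals], hf, min_freq = min_freq,
                    n_perm = n_perm, seed = derive_seed(seed, wi))
    if (isTRUE(res$skipped)) next
    ph <- res$per_haplotype
    ph$window <- paste(colnames(G$mat)[win], collapse = "-")
    ph$trait <- trait
    ph$p_overall <- res$p_overall
    ph$p_perm <- res$p_perm
    ph$r2_percent <- res$r2_percent
    out[[length(out) + 1L]] <- ph
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[, c("trait", "window", "p_overall", "p_perm", "r2_percent",
          "haplotype", "frequency", "mean", "t", "p")]
}
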