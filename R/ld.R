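# Pairwise linkage disequilibrium on haplotype-level data, permutation
# significance, Hill-Weir decay fitting and a simplified D'-threshold block
# finder. LD here is always computed from phased (haplotype) 0/1 matrices;
# composite genotype LD is out of scope.

#' Construct a haplotype matrix
#'
#' @param mat n_hap x m matrix over \{0, 1\} (0 = major, 1 = minor allele).
#' @param positions strictly increasing bp offsets, one per column.
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(mat, positions) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1))) stop_user("haplotype entries must be 0/1")
  if (length(positions) != ncol(mat)) {
    stop_user("need one position per column")
  }
  if (any(diff(positions) <= 0)) {
    stop_user("positions must be strictly increasing")
  }
  structure(list(mat = mat, positions = as.numeric(positions)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d sites (%.0f-%.0f bp)\n",
              nrow(x$mat), ncol(x$mat), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Extract a haplotype matrix from an alignment
#'
#' Biallelic segregating columns (after indel masking) become 0/1 sites with
#' 1 coding the minor allele; column offsets become bp positions.
#'
#' @param aln an [aligned_seqs()] object.
#' @param min_maf drop sites with minor-allele frequency below this.
#' @return a [haplotype_matrix()].
#' @export
haplotypes_from_alignment <- function(aln, min_maf = 0) {
  mask <- mask_indels(aln)
  keep <- integer(0)
  cols <- list()
  for (j in which(mask)) {
    col <- aln$mat[, j]
    if (any(col == "N")) next
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) != 2L) next
    maf <- tab[2] / sum(tab)
    if (maf < min_maf || maf == 0) next
    keep <- c(keep, j)
    cols[[length(cols) + 1L]] <- as.integer(col == names(tab)[2])
  }
  if (length(keep) < 2L) stop_user("fewer than 2 usable biallelic sites")
  haplotype_matrix(do.call(cbind, cols), positions = keep)
}

#' Pairwise LD between two sites
#'
#' From haplotype counts: `D = p_AB - p_A p_B`,
#' `r^2 = D^2 / (p_A p_a p_B p_b)`, and `D' = D / D_max` with the standard
#' bounds. Both sites must be polymorphic.
#'
#' @param hap a [haplotype_matrix()].
#' @param i,j 1-based site indices.
#' @return a list: `i`, `j`, `distance` (bp), `D`, `Dprime`, `r_squared`.
#' @export
pair_ld <- function(hap, i, j) {
  x <- hap$mat[, i]
  y <- hap$mat[, j]
  pA <- mean(x)
  pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop_user("LD undefined at a monomorphic site")
  }
  pAB <- mean(x * y)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dp <- if (Dmax == 0) 0 else D / Dmax
  list(i = i, j = j, distance = abs(hap$positions[j] - hap$positions[i]),
       D = D, Dprime = Dp, r_squared = r2)
}

#' All pairwise LD records
#'
#' @param hap a [haplotype_matrix()].
#' @return data frame of [pair_ld()] records for every site pair `i < j`.
#' @export
ld_pairs <- function(hap) {
  m <- ncol(hap$mat)
  idx <- utils::combn(m, 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    p <- pair_ld(hap, idx[1, k], idx[2, k])
    data.frame(i = p$i, j = p$j, distance = p$distance, D = p$D,
               Dprime = p$Dprime, r_squared = p$r_squared)
  })
  do.call(rbind, rows)
}

#' Permutation p-value for a site pair's r^2
#'
#' One site's alleles are shuffled across haplotypes; the add-one estimator
#' `p = (1 + #\{r^2_perm >= r^2_obs\}) / (1 + n_perm)` avoids zero p-values.
#'
#' @param hap a [haplotype_matrix()].
#' @param i,j site indices.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return the permutation p-value, with the observed `r^2` as attribute.
#' @export
ld_permutation_p <- function(hap, i, j, n_perm = 1e5, seed) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  x <- hap$mat[, i]
  y <- hap$mat[, j]
  n <- length(x)
  obs <- pair_ld(hap, i, j)$r_squared
  # r^2 is a monotone function of |sum(x*y) - n pA pB|; precompute margins
  pA <- mean(x); pB <- mean(y)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2_perm <- vapply(seq_len(n_perm), function(k) {
    xp <- x[sample.int(n)]
    (mean(xp * y) - pA * pB)^2 / denom
  }, 0)
  p <- (1 + sum(r2_perm >= obs - 1e-12)) / (1 + n_perm)
  structure(p, r_squared = obs)
}

#' Hill-Weir drift expectation of r^2
#'
#' `E[r^2]` as a function of `C = rho * d` for sample size `n`:
#' `[(10+C)/((2+C)(11+C))] * [1 + ((3+C)(12+12C+C^2))/(n(2+C)(11+C))]`.
#' Monotone non-increasing in `C` for the relevant range.
#'
#' @param C recombination-scaled distance `rho * d`, `C >= 0`.
#' @param n sample size used in the expectation.
#' @return expected r^2.
#' @export
hill_weir_r2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir decay curve to observed pairwise r^2
#'
#' Least-squares fit of `E[r^2](rho * distance)` over `rho >= 0`, via a
#' deterministic log-spaced multi-start grid followed by local
#' golden-section refinement.
#'
#' @param pairs data frame with columns `distance` and `r_squared`
#'   (e.g. from [ld_pairs()]).
#' @param n sample size (number of haplotypes) used in the expectation.
#' @param threshold r^2 level whose crossing distance is reported
#'   (default 0.1).
#' @return an object of class `ld_decay_fit`: list with `rho`, `n`, `rss`,
#'   `threshold`, `crossing_bp` (NA with reason if the curve never reaches
#'   the threshold within 10x the maximum observed distance).
#' @export
fit_ld_decay <- function(pairs, n, threshold = 0.1) {
  if (nrow(pairs) < 10L) stop_user("need at least 10 pairs to fit decay")
  if (length(unique(pairs$distance)) < 2L) {
    stop_user("decay unidentifiable: all pairs at a single distance")
  }
  d <- pairs$distance
  r2 <- pairs$r_squared
  sse <- function(rho) sum((r2 - hill_weir_r2(rho * d, n))^2)
  grid <- c(0, 10^seq(-8, 1, length.out = 120))
  vals <- vapply(grid, sse, 0)
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  if (lo == hi) hi <- lo + 1e-8
  opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-12)
  rho <- max(0, opt$minimum)
  if (sse(rho) > vals[k]) rho <- grid[k]
  fit <- structure(list(rho = rho, n = n, rss = sse(rho),
                        threshold = threshold, model = "hill_weir"),
                   class = "ld_decay_fit")
  fit$crossing_bp <- ld_decay_distance(fit, threshold,
                                       d_max = 10 * max(d))
  fit
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("Hill-Weir LD decay fit: rho = %.6g /bp (n = %d, RSS = %.4g)\n",
              x$rho, x$n, x$rss))
  if (is.na(x$crossing_bp)) {
    cat(sprintf("  E[r^2] stays above %.3g within range\n", x$threshold))
  } else {
    cat(sprintf("  E[r^2] reaches %.3g at ~%d bp\n", x$threshold,
                round(x$crossing_bp)))
  }
  invisible(x)
}

#' Distance at which the fitted decay curve reaches a threshold
#'
#' Smallest distance `d` with `E[r^2](rho * d) <= threshold`, found by
#' bisection to within 1 bp on `[1, d_max]`.
#'
#' @param fit an `ld_decay_fit` (or a list with `rho` and `n`).
#' @param threshold r^2 level.
#' @param d_max search upper bound in bp.
#' @return distance in bp, or flagged `NA` (`"beyond range"`) if the curve
#'   does not cross within `[1, d_max]`.
#' @export
ld_decay_distance <- function(fit, threshold = 0.1, d_max = 1e6) {
  f <- function(d) hill_weir_r2(fit$rho * d, fit$n)
  if (f(1) <= threshold) return(1)
  if (f(d_max) > threshold) {
    return(structure(NA_real_, undefined = TRUE, reason = "beyond range"))
  }
  lo <- 1
  hi <- d_max
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (f(mid) <= threshold) hi <- mid else lo <- mid
  }
  hi
}

#' Simplified haplotype-block finder
#'
#' Deliberately simpler than Haploview's Gabriel confidence-interval method:
#' markers are scanned left to right and a block is extended while every
#' adjacent within-block pair has `|D'| >= dprime_min`. Blocks of at least
#' 2 markers are reported.
#'
#' @param hap a [haplotype_matrix()].
#' @param dprime_min adjacent-pair `|D'|` threshold (default 0.8).
#' @return a list of integer vectors of marker indices, one per block.
#' @export
find_ld_blocks <- function(hap, dprime_min = 0.8) {
  m <- ncol(hap$mat)
  if (m < 2L) stop_user("need at least 2 markers")
  adj <- vapply(seq_len(m - 1L), function(i) {
    abs(pair_ld(hap, i, i + 1L)$Dprime)
  }, 0)
  blocks <- list()
  start <- 1L
  for (i in seq_len(m - 1L)) {
    if (adj[i] < dprime_min) {
      if (i > start) blocks[[length(blocks) + 1L]] <- start:i
      start <- i + 1L
    }
  }
  if (m > start) blocks[[length(blocks) + 1L]] <- start:m
  blocks
}
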