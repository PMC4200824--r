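test_that("pairwise LD matches the correlation identity and boundary cases", {
  # identical columns -> r2 = 1, |D'| = 1
  m <- cbind(c(0, 0, 1, 1, 0, 1), c(0, 0, 1, 1, 0, 1))
  h <- haplotype_matrix(m, c(10, 200))
  p <- pair_ld(h, 1, 2)
  expect_equal(p$r_squared, 1)
  expect_equal(abs(p$Dprime), 1)
  expect_equal(p$distance, 190)
  # exact 2x2 balance -> D = 0, r2 = 0
  bal <- cbind(rep(c(0, 1), each = 50), rep(c(0, 1), times = 50))
  p0 <- pair_ld(haplotype_matrix(bal, c(1, 2)), 1, 2)
  expect_equal(p0$D, 0)
  expect_equal(p0$r_squared, 0)
  # r2 equals squared Pearson correlation (property over random matrices)
  set.seed(91)
  for (r in 1:10) {
    m <- cbind(rbinom(30, 1, 0.4), rbinom(30, 1, 0.6))
    if (var(m[, 1]) == 0 || var(m[, 2]) == 0) next
    h <- haplotype_matrix(m, c(5, 105))
    expect_equal(pair_ld(h, 1, 2)$r_squared, cor(m[, 1], m[, 2])^2,
                 tolerance = 1e-12)
  }
  # monomorphic site errors
  expect_error(pair_ld(haplotype_matrix(cbind(rep(0, 5), c(0, 1, 0, 1, 0)),
                                        c(1, 2)), 1, 2), "monomorphic")
})

test_that("r2 and |D'| are invariant to allele relabelling", {
  set.seed(92)
  m <- cbind(rbinom(40, 1, 0.3), rbinom(40, 1, 0.5))
  h1 <- haplotype_matrix(m, c(0, 500))
  h2 <- haplotype_matrix(cbind(1 - m[, 1], m[, 2]), c(0, 500))
  h3 <- haplotype_matrix(cbind(m[, 1], 1 - m[, 2]), c(0, 500))
  p1 <- pair_ld(h1, 1, 2); p2 <- pair_ld(h2, 1, 2); p3 <- pair_ld(h3, 1, 2)
  expect_equal(p1$r_squared, p2$r_squared, tolerance = 1e-12)
  expect_equal(p1$r_squared, p3$r_squared, tolerance = 1e-12)
  expect_equal(abs(p1$Dprime), abs(p2$Dprime), tolerance = 1e-12)
  expect_equal(abs(p1$Dprime), abs(p3$Dprime), tolerance = 1e-12)
})

test_that("permutation p-values are seeded, bounded and sane", {
  set.seed(93)
  m <- cbind(rbinom(20, 1, 0.5), rbinom(20, 1, 0.5))
  while (var(m[, 1]) == 0 || var(m[, 2]) == 0 ||
         cor(m[, 1], m[, 2])^2 > 0.2) {
    m <- cbind(rbinom(20, 1, 0.5), rbinom(20, 1, 0.5))
  }
  h <- haplotype_matrix(m, c(0, 100))
  p1 <- ld_permutation_p(h, 1, 2, n_perm = 500, seed = 7)
  p2 <- ld_permutation_p(h, 1, 2, n_perm = 500, seed = 7)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_gte(as.numeric(p1), 1 / 501)
  # identical columns with balanced MAF: p tiny
  ident <- cbind(rep(c(0, 1), each = 10), rep(c(0, 1), each = 10))
  hi <- haplotype_matrix(ident, c(0, 100))
  expect_lte(as.numeric(ld_permutation_p(hi, 1, 2, n_perm = 2000, seed = 8)),
             0.01)
})

test_that("Hill-Weir fitting recovers rho exactly on noiseless curves", {
  d <- seq(50, 3000, by = 50)
  for (rho in c(0.001, 0.01, 0.05)) {
    fake <- data.frame(distance = d, r_squared = hill_weir_r2(rho * d, 43))
    fit <- fit_ld_decay(fake, 43)
    expect_lt(abs(fit$rho - rho), 1e-6)
  }
  # fitted curve monotone non-increasing
  curve <- hill_weir_r2(0.01 * seq(1, 5000), 43)
  expect_true(all(diff(curve) <= 1e-12))
  # unidentifiable: single distance
  expect_error(fit_ld_decay(data.frame(distance = rep(100, 12),
                                       r_squared = runif(12)), 43),
               "unidentifiable")
})

test_that("threshold-crossing distance matches a dense grid scan", {
  fit <- list(rho = 0.005, n = 43)
  thr <- 0.1
  bp <- ld_decay_distance(fit, thr, d_max = 1e5)
  dgrid <- seq(1, 1e5, by = 1)
  oracle <- dgrid[which(hill_weir_r2(fit$rho * dgrid, fit$n) <= thr)[1]]
  expect_lte(abs(bp - oracle), 1)
  # self-consistency: threshold at the curve value of d = 500
  thr500 <- hill_weir_r2(fit$rho * 500, fit$n)
  expect_lte(abs(ld_decay_distance(fit, thr500, d_max = 1e5) - 500), 1)
  # threshold above the curve at d = 1 -> returns 1
  expect_equal(ld_decay_distance(fit, 0.9), 1)
  # curve never crossing -> flagged, not a number
  out <- ld_decay_distance(list(rho = 1e-9, n = 43), 0.1, d_max = 100)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "beyond range")
})

test_that("decay crossing distance is ordered by the simulated switch rate", {
  cross <- vapply(c(0.0002, 0.005), function(rate) {
    sim <- sim_ld_haplotypes(8, rate, 100, positions = seq(0, 2400, by = 40),
                             seed = 31)
    fit <- fit_ld_decay(ld_pairs(sim$hap), n = 100)
    as.numeric(fit$crossing_bp)
  }, 0)
  expect_gt(cross[1], cross[2])
})

test_that("block finding equals brute-force application of the adjacency rule", {
  # all pairs in perfect LD -> one block spanning all markers
  base <- rep(c(0, 1), each = 10)
  h <- haplotype_matrix(cbind(base, base, base, base), c(1, 2, 3, 4) * 100)
  expect_equal(find_ld_blocks(h), list(1:4))
  # brute force on simulated panels
  for (seed in c(101, 102, 103)) {
    sim <- sim_ld_haplotypes(4, 0.002, 60,
                             positions = seq(0, 900, by = 100), seed = seed)
    hap <- sim$hap
    m <- ncol(hap$mat)
    adj <- vapply(seq_len(m - 1), function(i) {
      abs(pair_ld(hap, i, i + 1)$Dprime)
    }, 0)
    runs <- rle(adj >= 0.8)
    expected <- list()
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      if (runs$values[k]) {
        expected[[length(expected) + 1L]] <- pos:(pos + runs$lengths[k])
      }
      pos <- pos + runs$lengths[k]
    }
    expect_equal(find_ld_blocks(hap), expected)
  }
})
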