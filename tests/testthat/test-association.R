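test_that("Ritland kinship ranks duplicated individuals above the panel mean", {
  set.seed(201)
  sim <- sim_structured_genotypes(1, 0, p_anc = runif(200, 0.2, 0.8),
                                  n_per = 40, seed = 201)
  mat <- sim$G$mat
  mat[2, ] <- mat[1, ]  # individual 2 duplicates individual 1
  K <- ritland_kinship(genotype_table(mat))
  off <- K[upper.tri(K)]
  expect_gt(K[1, 2], mean(off))
  expect_gt(K[1, 2], 0.3)
  # symmetry and PSD conditioning
  expect_lt(max(abs(K - t(K))), 1e-9)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # diagonal dominates the off-diagonal mean
  expect_gt(mean(diag(K)), mean(off))
})

test_that("panmictic individuals have near-zero mean kinship as markers grow", {
  sim <- sim_structured_genotypes(1, 0, p_anc = runif(500, 0.2, 0.8),
                                  n_per = 30, seed = 202)
  K <- ritland_kinship(sim$G, truncate_negative = FALSE)
  expect_lt(abs(mean(K[upper.tri(K)])), 0.02)
  expect_error(ritland_kinship(genotype_table(matrix(0, 10, 12))),
               "polymorphic")
})

test_that("REML collapses to ordinary least squares when K = I and Q absent", {
  set.seed(203)
  n <- 100
  snp <- rbinom(n, 2, 0.4)
  y <- 0.3 * snp + rnorm(n)
  fit <- reml_fit(y, cbind(intercept = 1, snp = snp), kinship_eigen(diag(n)))
  ols <- summary(lm(y ~ snp))
  expect_equal(unname(fit$p["snp"]), ols$coefficients[2, 4], tolerance = 1e-6)
  expect_equal(unname(fit$beta["snp"]), ols$coefficients[2, 1],
               tolerance = 1e-9)
  # optimiser sanity: restricted likelihood at the optimum beats every grid point
  expect_true(all(fit$loglik >= fit$grid_ll - 1e-6))
  # variance explained equals lm R^2 in the collapsed model
  expect_equal(variance_explained(fit, 2), 100 * ols$r.squared,
               tolerance = 1e-6)
})

test_that("variance explained is 0 for a null SNP and ~100% for a pure signal", {
  set.seed(204)
  n <- 80
  snp <- rbinom(n, 2, 0.5)
  eig <- kinship_eigen(diag(n))
  y_null <- rnorm(n)
  f0 <- reml_fit(y_null, cbind(1, snp = snp), eig)
  expect_lt(variance_explained(f0, 2), 6)
  y_pure <- 2 * snp
  f1 <- reml_fit(y_pure + rnorm(n, 0, 1e-4), cbind(1, snp = snp), eig)
  expect_gt(variance_explained(f1, 2), 99.9)
})

test_that("q-values are monotone, bounded, and reduce to BH at pi0 = 1", {
  set.seed(205)
  p <- c(runif(300), rbeta(60, 0.1, 1))
  p <- pmin(pmax(p, 1e-12), 1)
  q <- storey_qvalues(p)
  expect_true(all(q <= 1 & q >= 0))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_lte(attr(q, "pi0"), 1)
  # pi0 = 1 gives exactly Benjamini-Hochberg
  expect_equal(as.numeric(storey_qvalues(p, pi0 = 1)),
               p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(as.numeric(storey_qvalues(rep(1, 20))), rep(1, 20))
  expect_error(storey_qvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("positive-FDR correction controls realized FDR in a mixture", {
  set.seed(206)
  fdrs <- vapply(1:40, function(r) {
    m <- 2000
    is_null <- runif(m) < 0.8
    p <- ifelse(is_null, runif(m), rbeta(m, 0.1, 1))
    p <- pmin(pmax(p, 1e-300), 1)
    q <- storey_qvalues(p)
    disc <- q <= 0.05
    if (!any(disc)) return(0)
    sum(disc & is_null) / sum(disc)
  }, 0)
  expect_lte(mean(fdrs), 0.08)
})

test_that("gene action reproduces the published worked examples", {
  # microfiber angle, dominant: means 20.96 (CC), 17.59 (CT), 17.26 (TT)
  ga <- gene_action(G_BB = 17.26, G_Bb = 17.59, G_bb = 20.96,
                    p_B = 0.479, s_p = 4.53, G = 19.0)
  expect_equal(ga$two_a, 3.70, tolerance = 1e-9)
  expect_equal(ga$d, -1.52, tolerance = 1e-9)
  expect_gt(abs(ga$d_over_a), 0.50)
  expect_lt(abs(ga$d_over_a), 1.25)
  expect_equal(ga$mode, "dominant")
  # lignin, overdominant: heterozygote exceeds both homozygotes
  ga2 <- gene_action(G_BB = 17.92, G_Bb = 21.02, G_bb = 18.09,
                     p_B = 0.482, s_p = 2.51, G = 19.5)
  expect_equal(ga2$mode, "overdominant")
  expect_gte(abs(ga2$d_over_a), 1.25)
  # exact midpoint heterozygote -> codominant
  ga3 <- gene_action(10, 12.5, 15, 0.3, 2, 12)
  expect_equal(ga3$d, 0)
  expect_equal(ga3$mode, "codominant")
  # undefined cases
  expect_equal(gene_action(NA, 1, 2, 0.5, 1, 1)$mode, "undefined")
  expect_equal(gene_action(5, 7, 5, 0.5, 1, 5)$mode, "undefined")
})

test_that("gene action is equivariant under allele relabelling", {
  set.seed(207)
  for (r in 1:6) {
    m <- sort(rnorm(3, 10, 2))
    mBB <- m[sample(3, 1)]; rest <- setdiff(m, mBB)
    mBb <- rest[1]; mbb <- rest[2]
    pB <- runif(1, 0.1, 0.5)
    G <- runif(1, 9, 11)
    a1 <- gene_action(mBB, mBb, mbb, pB, 2, G)
    a2 <- gene_action(mbb, mBb, mBB, 1 - pB, 2, G)
    expect_equal(a1$two_a, a2$two_a, tolerance = 1e-12)
    expect_equal(a1$d, a2$d, tolerance = 1e-12)
    expect_equal(abs(a1$d_over_a), abs(a2$d_over_a), tolerance = 1e-12)
    expect_equal(a1$mode, a2$mode)
  }
})

test_that("association scan finds a strong simulated effect with sane q-values", {
  sc <- structured_scenario(n_snp = 50, n_per = 120, effect = 0.5, seed = 208)
  res <- assoc_scan(sc$G, sc$y, Q = sc$Q, K = sc$K, trait = "height")
  expect_s3_class(res, "assoc_scan")
  top <- res$snp[which.min(res$p)]
  expect_equal(top, "snp0001")
  expect_true(all(res$p > 0 & res$p <= 1))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_gt(res$r2_percent[res$snp == "snp0001"], 1)
  # genotype class means are raw means
  raw <- sc$G$mat[, 1]
  y <- sc$y
  expect_equal(res$mean_BB[res$snp == "snp0001"],
               mean(y[raw == 2], na.rm = TRUE), tolerance = 1e-9)
})

test_that("missing genotypes are mean-imputed and high-missingness SNPs dropped", {
  sc <- structured_scenario(n_snp = 30, n_per = 80, effect = 0, seed = 209)
  mat <- sc$G$mat
  mat[1:20, 2] <- NA          # 12.5% missing -> kept, imputed
  mat[1:100, 3] <- NA         # 62.5% missing -> dropped
  G2 <- genotype_table(mat)
  res <- assoc_scan(G2, sc$y, Q = sc$Q, K = sc$K)
  expect_false("snp0003" %in% res$snp)
  expect_true("snp0002" %in% res$snp)
})

test_that("subset validation reruns per subset and flags p <= 0.05 hits", {
  sc <- structured_scenario(n_snp = 40, n_per = 150, effect = 0.6, seed = 210)
  subsets <- rep(c("A", "B"), length.out = nrow(sc$G$mat))
  val <- subset_validation(sc$G, sc$y, sc$Q, subsets, trait = "t")
  expect_named(val, c("per_subset", "validated"))
  expect_equal(sort(names(val$per_subset)), c("A", "B"))
  expect_true(val$validated$validated[val$validated$snp == "snp0001"])
  # a subset below the floor is skipped with a warning
  small <- c(rep("A", nrow(sc$G$mat) - 5), rep("tiny", 5))
  expect_warning(subset_validation(sc$G, sc$y, sc$Q, small), "floor")
})
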