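test_that("pi equals the exhaustive all-pairs oracle on random alignments", {
  for (seed in 1:8) {
    n <- sample(3:8, 1)
    L <- sample(10:50, 1)
    aln <- rand_aln(n, L, seed = 100 + seed)
    expect_equal(as.numeric(nuc_diversity(aln)),
                 oracle_pi(aln, seq_len(L)), tolerance = 1e-12)
  }
  # two identical sequences
  a <- aligned_seqs(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC"))
  expect_equal(as.numeric(nuc_diversity(a)), 0)
  # one mismatch in 10 columns
  b <- aligned_seqs(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAT"))
  expect_equal(as.numeric(nuc_diversity(b)), 0.1)
})

test_that("statistics are invariant to sequence order and n=2 forces pi = theta_w", {
  aln <- rand_aln(6, 40, seed = 21)
  perm <- aligned_seqs(aln$mat[sample(6), , drop = FALSE])
  expect_equal(as.numeric(nuc_diversity(perm)), as.numeric(nuc_diversity(aln)))
  expect_equal(segregating_sites(perm)$S, segregating_sites(aln)$S)
  expect_equal(count_singletons(perm), count_singletons(aln))

  two <- rand_aln(2, 60, seed = 22)
  seg <- segregating_sites(two)
  expect_equal(as.numeric(nuc_diversity(two)),
               as.numeric(watterson_theta(seg$S, 2, 60)))
})

test_that("segregating-site scan matches a direct per-column recount", {
  sim <- sim_coalescent_haplotypes(20, 0.02, 500, seed = 31)
  seg <- segregating_sites(sim$aln)
  brute <- sum(vapply(seq_len(500), function(j) {
    col <- sim$aln$mat[, j]
    length(unique(col[col != "N"])) >= 2
  }, NA))
  expect_equal(seg$S, brute)
  # monomorphic alignment
  mono <- aligned_seqs(matrix("A", 4, 10))
  expect_equal(segregating_sites(mono)$S, 0)
  # one biallelic column
  m <- matrix("A", 4, 6); m[3:4, 2] <- "G"
  expect_equal(segregating_sites(aligned_seqs(m))$S, 1)
})

test_that("watterson theta uses the harmonic denominator", {
  expect_equal(as.numeric(watterson_theta(3, 2, 100)), 0.03)
  expect_equal(as.numeric(watterson_theta(0, 10, 100)), 0)
  expect_equal(as.numeric(watterson_theta(25, 10, 1000)),
               25 / (sum(1 / (1:9)) * 1000))
  expect_error(watterson_theta(3, 1, 100), "n >= 2")
})

test_that("Tajima's D matches longhand constants and flags S = 0", {
  # longhand constants for n = 4
  n <- 4; S <- 3
  a1 <- 1 + 1/2 + 1/3
  a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_total <- 2.1
  expected <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(as.numeric(tajima_d(S, n, pi_total)), expected,
               tolerance = 1e-12)
  # numerator zero -> D = 0
  expect_equal(as.numeric(tajima_d(S, n, S / a1)), 0)
  # undefined flags, not zeros
  expect_true(is.na(tajima_d(0, 10, 0)))
  expect_true(isTRUE(attr(tajima_d(0, 10, 0), "undefined")))
  expect_true(is.na(tajima_d(3, 3, 1)))
})

test_that("Fu and Li's D* has the singleton sign convention and longhand value", {
  # every variant a singleton in a 20-row alignment -> D* < 0
  m <- matrix("A", 20, 30)
  for (j in 1:8) m[j, j] <- "G"
  aln <- aligned_seqs(m)
  seg <- segregating_sites(aln)
  d_star <- fu_li_d_star(seg$S, 20, count_singletons(aln, seg = seg))
  expect_lt(as.numeric(d_star), 0)
  # no singletons (all intermediate) -> D* > 0
  m2 <- matrix("A", 20, 30)
  for (j in 1:6) m2[1:10, j] <- "G"
  aln2 <- aligned_seqs(m2)
  seg2 <- segregating_sites(aln2)
  expect_equal(count_singletons(aln2, seg = seg2), 0)
  expect_gt(as.numeric(fu_li_d_star(seg2$S, 20, 0)), 0)
  # longhand constants for n = 6
  n <- 6; S <- 5; eta_s <- 2
  a <- sum(1 / (1:5))
  b <- sum(1 / (1:5)^2)
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v <- ((n / (n - 1))^2 * b + a^2 * dn -
          2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  u <- (n / (n - 1)) * (a - n / (n - 1)) - v
  expected <- ((n / (n - 1)) * S - a * eta_s) / sqrt(u * S + v * S^2)
  expect_equal(as.numeric(fu_li_d_star(S, n, eta_s)), expected,
               tolerance = 1e-12)
  expect_true(is.na(fu_li_d_star(0, 10, 0)))
})

test_that("Nei-Gojobori site counts conserve 3 sites per codon", {
  # ATG (Met) has no synonymous change; TTT (Phe) has exactly 1/3
  a <- aligned_seqs(c(s1 = "ATGTTT", s2 = "ATGTTT"))
  ng <- ng_site_counts(a, 0:5)
  expect_equal(ng$syn_sites + ng$nonsyn_sites, 6, tolerance = 1e-9)
  expect_equal(ng$per_codon_syn[1], 0)
  expect_equal(ng$per_codon_syn[2], 1 / 3, tolerance = 1e-12)
  # conservation on a random coding stretch (property)
  set.seed(41)
  for (r in 1:5) {
    aln <- rand_aln(4, 30, seed = 400 + r)
    ng <- suppressWarnings(ng_site_counts(aln, 0:29))
    expect_equal(ng$syn_sites + ng$nonsyn_sites, 3 * ng$n_codons,
                 tolerance = 1e-9)
  }
})

test_that("mutation classification follows the majority-background codon", {
  # GAA -> GAG (Glu/Glu): synonymous at 3rd position
  a <- aligned_seqs(c(s1 = "GAA", s2 = "GAG", s3 = "GAA", s4 = "GAA"))
  expect_equal(classify_mutation(a, 0:2, 2), "synonymous")
  # GCA -> CCA (Ala -> Pro): nonsynonymous at 1st position
  b <- aligned_seqs(c(s1 = "GCA", s2 = "CCA", s3 = "GCA", s4 = "GCA"))
  expect_equal(classify_mutation(b, 0:2, 0), "nonsynonymous")
  # TAT -> CAT (Tyr -> His): nonsynonymous
  c_ <- aligned_seqs(c(s1 = "TAT", s2 = "CAT", s3 = "TAT", s4 = "TAT"))
  expect_equal(classify_mutation(c_, 0:2, 0), "nonsynonymous")
  # premature stop: TAT -> TAA
  d_ <- aligned_seqs(c(s1 = "TAT", s2 = "TAA", s3 = "TAT", s4 = "TAT"))
  expect_equal(classify_mutation(d_, 0:2, 2), "nonsense")
})

test_that("common-SNP filter is a strict inequality", {
  maf <- c(0.05, 0.10, 0.11, 0.5, 0.099999)
  keep <- common_snps(maf, 0.10)
  expect_equal(keep, c(3L, 4L))
  # brute force on a synthetic panel
  sim <- sim_coalescent_haplotypes(30, 0.01, 400, seed = 51)
  seg <- segregating_sites(sim$aln)
  segcols <- which(seg$segregating)
  maf2 <- vapply(segcols, function(j) {
    cnt <- seg$counts[, j]
    sort(cnt[cnt > 0], decreasing = TRUE)[2] / sum(cnt)
  }, 0)
  maf2 <- pmin(maf2, 0.5)
  expect_equal(common_snps(maf2, 0.1), which(maf2 > 0.1))
})

test_that("per-region summaries agree with single-interval calls", {
  sim <- sim_coalescent_haplotypes(12, 0.015, 300, seed = 61)
  regions <- region_map(start = c(0, 60, 150, 240), end = c(60, 150, 240, 300),
                        label = c("utr5", "ex1", "int1", "utr3"),
                        kind = c("five_prime_utr", "exon", "intron",
                                 "three_prime_utr"),
                        frame = c(NA, 0, NA, NA))
  tab <- diversity_by_region(sim$aln, regions)
  total <- tab[tab$region == "Total", ]
  seg <- segregating_sites(sim$aln)
  expect_equal(total$S, seg$S)
  expect_equal(total$pi, as.numeric(nuc_diversity(sim$aln)), tolerance = 1e-12)
  expect_equal(total$percent_polymorphism, 100 * seg$S / 300)
  expect_equal(total$theta_w,
               as.numeric(watterson_theta(seg$S, 12, 300)), tolerance = 1e-12)
  # exon sub-rows conserve fractional sites over the clean (non-stop) codons
  syn <- tab[tab$region == "ex1_synonymous", ]
  non <- tab[tab$region == "ex1_nonsynonymous", ]
  ng <- suppressWarnings(ng_site_counts(sim$aln, 60:149))
  expect_equal(syn$L_eff + non$L_eff, 3 * ng$n_codons, tolerance = 1e-9)
  expect_lte(syn$L_eff + non$L_eff, 90)
})

test_that("population reports match per-group recomputation", {
  sim <- sim_coalescent_haplotypes(12, 0.02, 300, seed = 71)
  regions <- region_map(start = c(0, 90), end = c(90, 300),
                        label = c("int1", "ex1"),
                        kind = c("intron", "exon"), frame = c(NA, 0))
  groups <- rep(c("north", "south", "west"), each = 4)
  rep_ <- diversity_by_population(sim$aln, groups, regions)
  expect_equal(nrow(rep_), 4)
  # each group's pi_tot equals a direct subset computation
  for (g in c("north", "south", "west")) {
    sub <- aligned_seqs(sim$aln$mat[groups == g, , drop = FALSE])
    expect_equal(rep_$pi_tot[rep_$population == g],
                 as.numeric(nuc_diversity(sub)), tolerance = 1e-12)
  }
  # single group == global report
  one <- diversity_by_population(sim$aln, rep("all", 12), regions)
  expect_equal(one$pi_tot[1], one$pi_tot[2])
  expect_equal(one$tajima_d[1], one$tajima_d[2])
  # identical sequences -> all pi zero
  same <- aligned_seqs(matrix(rep(sim$aln$mat[1, ], each = 6), nrow = 6))
  rep0 <- diversity_by_population(same, rep(c("a", "b"), each = 3), regions)
  expect_true(all(rep0$pi_tot == 0))
  # small groups get flagged neutrality tests
  expect_true(all(is.na(rep0$tajima_d[rep0$population != "Total"])))
})
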