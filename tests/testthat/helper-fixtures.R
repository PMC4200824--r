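# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

# random alignment over ACGT (optionally with gaps/N sprinkled in)
rand_aln <- function(n, L, seed, p_gap = 0, p_n = 0) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                       prob = c(0.35, 0.25, 0.25, 0.15)), n, L)
  if (p_gap > 0) mat[stats::runif(n * L) < p_gap] <- "-"
  if (p_n > 0) mat[stats::runif(n * L) < p_n] <- "N"
  aligned_seqs(mat)
}

# brute-force pi: mean over all sequence pairs of per-site mismatch
# proportion across retained columns
oracle_pi <- function(aln, cols) {
  n <- nrow(aln$mat)
  pairs <- utils::combn(n, 2)
  vals <- apply(pairs, 2, function(p) {
    a <- aln$mat[p[1], cols]
    b <- aln$mat[p[2], cols]
    ok <- a != "N" & b != "N"
    sum(a[ok] != b[ok])
  })
  # matches the column-wise estimator only when no N present; tests use
  # N-free alignments for this oracle
  mean(vals) / length(cols)
}

# phased haplotype sample with LD structure; returns list(geno, realized)
phased_sample <- function(n_ind, seed, width = 3) {
  sim <- sim_ld_haplotypes(6, 0.001, 2 * n_ind,
                           positions = seq(0, 1050, by = 150), seed = seed)
  stopifnot(ncol(sim$hap$mat) >= width)
  H <- sim$hap$mat[, seq_len(width), drop = FALSE]
  key <- apply(H, 1, paste, collapse = "")
  realized <- table(key) / nrow(H)
  geno <- H[seq(1, 2 * n_ind, 2), ] + H[seq(2, 2 * n_ind, 2), ]
  list(geno = geno, realized = realized)
}

# small structured association scenario
structured_scenario <- function(n_snp = 60, n_per = 150, effect = 0,
                                seed = 1) {
  set.seed(seed)
  sim <- sim_structured_genotypes(2, 0.15,
                                  p_anc = stats::runif(n_snp, 0.2, 0.8),
                                  n_per = n_per, seed = seed)
  eff <- if (effect != 0) data.frame(snp = 1, a = effect, d = 0) else NULL
  K <- ritland_kinship(sim$G)
  ph <- sim_phenotypes(sim$G, Q = sim$Q, K = K, effects = eff,
                       sigma_a2 = 0.3, sigma_e2 = 0.7,
                       upsilon = c(0, 0.8), seed = seed + 5000)
  list(G = sim$G, Q = sim$Q, K = K, y = ph$y, labels = sim$truth$labels)
}
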