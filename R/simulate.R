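# Seeded generators for every input the pipeline consumes: neutral
# coalescent haplotype panels (diversity calibration), a founder copying
# model (distance-dependent LD), Balding-Nichols structured genotypes
# (population stratification), and mixed-model phenotypes mirroring the
# fitted Q+K model. Each generator returns the data plus a `truth` list
# sufficient to score parameter-recovery tests without re-simulation.

#' Neutral coalescent haplotype panel (infinite sites, no recombination)
#'
#' Simulates a single-locus Kingman coalescent: with `k` active lineages the
#' waiting time to the next coalescence is exponential with rate
#' `k(k-1)/2`; mutations fall on branches as a Poisson process with rate
#' `theta/2` per site, placed on distinct integer positions (infinite-sites;
#' an error is raised if the mutation count exceeds `L`). With `theta = 0`
#' all sequences are identical. `E[S] = theta * L * a_n`.
#'
#' @param n_hap number of haplotypes (>= 2).
#' @param theta population mutation rate per site (4Nu).
#' @param L locus length in bp.
#' @param seed RNG seed (mandatory).
#' @return list with `aln` (an [aligned_seqs()]), and `truth`: `S`,
#'   `positions` (0-based), `derived` (list of carrier index vectors),
#'   `tree_length` (coalescent units).
#' @export
sim_coalescent_haplotypes <- function(n_hap, theta, L, seed) {
  stopifnot(n_hap >= 2, theta >= 0, L >= 1)
  set.seed(seed)
  members <- as.list(seq_len(n_hap))   # active lineages
  acc <- numeric(n_hap)                # branch length accrued per lineage
  branch_members <- list()
  branch_len <- numeric(0)
  k <- n_hap
  while (k > 1L) {
    t <- stats::rexp(1, rate = k * (k - 1) / 2)
    acc <- acc + t
    pair <- sort(sample.int(k, 2))
    for (x in pair) {
      branch_members[[length(branch_members) + 1L]] <- members[[x]]
      branch_len <- c(branch_len, acc[x])
    }
    merged <- c(members[[pair[1]]], members[[pair[2]]])
    members <- members[-pair]
    acc <- acc[-pair]
    members[[length(members) + 1L]] <- merged
    acc <- c(acc, 0)
    k <- k - 1L
  }
  total_len <- sum(branch_len)
  n_mut <- stats::rpois(1, theta / 2 * L * total_len)
  if (n_mut > L) {
    stop_user("mutation count %d exceeds locus length %d (theta too high)",
              n_mut, L)
  }
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(anc, each = n_hap), nrow = n_hap)
  positions <- integer(0)
  derived <- list()
  if (n_mut > 0) {
    positions <- sort(sample.int(L, n_mut))  # distinct sites
    br <- sample.int(length(branch_len), n_mut, replace = TRUE,
                     prob = branch_len)
    for (m in seq_len(n_mut)) {
      carriers <- branch_members[[br[m]]]
      alt <- sample(setdiff(c("A", "C", "G", "T"), anc[positions[m]]), 1)
      mat[carriers, positions[m]] <- alt
      derived[[m]] <- carriers
    }
  }
  aln <- aligned_seqs(mat, ids = sprintf("hap%02d", seq_len(n_hap)))
  list(aln = aln,
       truth = list(S = length(unique(positions)), positions = positions - 1L,
                    derived = derived, tree_length = total_len,
                    theta = theta, L = L, n_hap = n_hap, seed = seed))
}

#' Copying-model haplotypes with distance-dependent LD
#'
#' Each output haplotype copies one founder and switches to a uniformly
#' chosen founder between adjacent sites with probability
#' `1 - exp(-rate * distance)`. Switch rate 0 reproduces founders exactly;
#' a high rate decorrelates sites, so pairwise r^2 decays with distance.
#'
#' @param founders founder haplotype matrix (f x m of 0/1), or an integer
#'   count: that many founders are drawn with per-site allele-1 frequencies
#'   uniform on (0.2, 0.8).
#' @param rate per-bp switch rate (>= 0).
#' @param n_hap number of output haplotypes.
#' @param positions strictly increasing bp positions (length m; required
#'   when `founders` is a count, otherwise defaults to 1..m spacing 100 bp).
#' @param seed RNG seed.
#' @return list with `hap` (a [haplotype_matrix()]) and `truth` (founders,
#'   rate, copied founder paths).
#' @export
sim_ld_haplotypes <- function(founders, rate, n_hap, positions = NULL, seed) {
  set.seed(seed)
  if (is.matrix(founders)) {
    Fm <- founders
  } else {
    stopifnot(founders >= 2, !is.null(positions))
    m <- length(positions)
    pf <- stats::runif(m, 0.2, 0.8)
    Fm <- matrix(stats::rbinom(founders * m, 1, rep(pf, each = founders)),
                 nrow = founders)
  }
  nf <- nrow(Fm)
  m <- ncol(Fm)
  positions <- positions %||% (seq_len(m) * 100)
  p_switch <- 1 - exp(-rate * diff(positions))
  mat <- matrix(0L, n_hap, m)
  paths <- matrix(0L, n_hap, m)
  for (i in seq_len(n_hap)) {
    src <- sample.int(nf, 1)
    mat[i, 1] <- Fm[src, 1]
    paths[i, 1] <- src
    for (j in 2:m) {
      if (stats::runif(1) < p_switch[j - 1]) src <- sample.int(nf, 1)
      mat[i, j] <- Fm[src, j]
      paths[i, j] <- src
    }
  }
  # keep only sites polymorphic in the sample (monomorphic sites carry no LD)
  poly <- apply(mat, 2, function(x) length(unique(x)) == 2L)
  if (sum(poly) < 2L) stop_user("fewer than 2 polymorphic sites simulated")
  list(hap = haplotype_matrix(mat[, poly, drop = FALSE], positions[poly]),
       truth = list(founders = Fm, rate = rate, paths = paths,
                    kept_sites = which(poly), seed = seed))
}

#' Balding-Nichols structured genotypes
#'
#' Subpopulation allele frequencies are drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around ancestral frequencies `p`
#' (`F = 0` reproduces `p` exactly); genotypes are Hardy-Weinberg within
#' subpopulations. Q is the exact membership-indicator matrix.
#'
#' @param k number of subpopulations.
#' @param F divergence parameter in `[0, 1)`.
#' @param p_anc ancestral allele frequencies in (0,1), one per SNP.
#' @param n_per individuals per subpopulation (scalar or length-k vector).
#' @param seed RNG seed.
#' @return list with `G` (a [genotype_table()]), `Q` (n x k indicator
#'   matrix), and `truth` (subpop labels and per-subpop frequencies).
#' @export
sim_structured_genotypes <- function(k, F, p_anc, n_per, seed) {
  stopifnot(k >= 1, F >= 0, F < 1, all(p_anc > 0 & p_anc < 1))
  set.seed(seed)
  n_per <- rep_len(n_per, k)
  m <- length(p_anc)
  freqs <- matrix(0, k, m)
  for (s in seq_len(k)) {
    freqs[s, ] <- if (F == 0) p_anc else {
      stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
  }
  # guard the degenerate Beta draws
  freqs <- pmin(pmax(freqs, 1e-9), 1 - 1e-9)
  labels <- rep(seq_len(k), n_per)
  n <- length(labels)
  mat <- matrix(0L, n, m)
  for (s in seq_len(k)) {
    idx <- which(labels == s)
    mat[idx, ] <- matrix(
      stats::rbinom(length(idx) * m, 2, rep(freqs[s, ], each = length(idx))),
      nrow = length(idx))
  }
  rownames(mat) <- sprintf("ind%04d", seq_len(n))
  colnames(mat) <- sprintf("snp%04d", seq_len(m))
  Q <- matrix(0, n, k)
  Q[cbind(seq_len(n), labels)] <- 1
  rownames(Q) <- rownames(mat)
  colnames(Q) <- sprintf("pop%d", seq_len(k))
  list(G = genotype_table(mat), Q = Q,
       truth = list(labels = labels, subpop_freqs = freqs, F = F,
                    p_anc = p_anc, seed = seed))
}

#' Mixed-model phenotypes with per-SNP additive and dominance effects
#'
#' `y = mu + Q v + sum_j (a_j dosage_j + d_j het_j) + u + e` with the
#' polygenic term `u ~ N(0, sigma_a2 K)` and `e ~ N(0, sigma_e2 I)` - the
#' generative mirror of the model the association stage fits.
#'
#' @param G a [genotype_table()].
#' @param Q structure matrix or NULL.
#' @param K kinship matrix (PSD; NULL for no polygenic term).
#' @param effects data frame with columns `snp` (index or name), `a`
#'   (additive per-allele effect) and `d` (dominance deviation); NULL for
#'   no causal SNPs.
#' @param sigma_a2,sigma_e2 variance components.
#' @param mu intercept; `upsilon` per-subpopulation effects (length
#'   `ncol(Q)`).
#' @param seed RNG seed.
#' @return list with `y` (named vector) and `truth` (all inputs plus the
#'   drawn `u`).
#' @export
sim_phenotypes <- function(G, Q = NULL, K = NULL, effects = NULL,
                           sigma_a2 = 0, sigma_e2 = 1, mu = 0,
                           upsilon = NULL, seed) {
  set.seed(seed)
  n <- nrow(G$mat)
  y <- rep(mu, n)
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    upsilon <- upsilon %||% rep(0, ncol(Q))
    y <- y + as.numeric(Q %*% upsilon)
  }
  if (!is.null(effects) && nrow(effects)) {
    for (r in seq_len(nrow(effects))) {
      j <- effects$snp[r]
      if (is.character(j)) j <- match(j, colnames(G$mat))
      dos <- G$mat[, j]
      dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      het <- as.numeric(dos == 1)
      y <- y + effects$a[r] * dos + effects$d[r] * het
    }
  }
  u <- rep(0, n)
  if (sigma_a2 > 0) {
    if (is.null(K)) stop_user("sigma_a2 > 0 needs a kinship matrix")
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-6 * max(abs(e$values))) {
      stop_user("kinship matrix is not positive semidefinite")
    }
    u <- as.numeric(e$vectors %*% (sqrt(pmax(e$values, 0) * sigma_a2) *
                                     stats::rnorm(n)))
    y <- y + u
  }
  eps <- stats::rnorm(n, 0, sqrt(sigma_e2))
  y <- y + eps
  names(y) <- rownames(G$mat)
  list(y = y,
       truth = list(mu = mu, upsilon = upsilon, effects = effects,
                    sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, u = u,
                    seed = seed))
}

#' Weir-Cockerham F_ST over biallelic SNPs
#'
#' Multi-locus theta estimate: per-SNP variance components a (among
#' subpopulations), b (among individuals within) and c (within individuals)
#' are summed over loci, `F_ST = sum(a) / sum(a + b + c)`.
#'
#' @param G a [genotype_table()].
#' @param labels subpopulation labels per individual.
#' @return the multilocus estimate.
#' @export
fst_weir_cockerham <- function(G, labels) {
  labels <- as.factor(labels)
  r <- nlevels(labels)
  stopifnot(r >= 2)
  A <- B <- C <- 0
  for (j in seq_len(ncol(G$mat))) {
    g <- G$mat[, j]
    ok <- !is.na(g)
    gs <- split(g[ok], labels[ok])
    ni <- vapply(gs, length, 0)
    if (any(ni < 2) || length(gs) < 2) next
    pi_ <- vapply(gs, function(x) mean(x) / 2, 0)
    hi <- vapply(gs, function(x) mean(x == 1), 0)
    nbar <- mean(ni)
    nt <- sum(ni)
    nc <- (nt - sum(ni^2) / nt) / (r - 1)
    pbar <- sum(ni * pi_) / nt
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / nt
    if (pbar <= 0 || pbar >= 1) next
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a
    B <- B + b
    C <- C + cc
  }
  A / (A + B + C)
}
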