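# Nucleotide diversity and neutrality statistics on an aligned haplotype
# panel, with Nei-Gojobori synonymous/non-synonymous partitioning of coding
# regions. Columns containing a gap in any sequence are excluded everywhere
# (see mask_indels); 'N' bases are excluded pair-wise at the column level.

# --- genetic code -----------------------------------------------------------

# 64-codon lookup built once from the standard nuclear code.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- sort(as.vector(outer(as.vector(outer(bases, bases, paste0)),
                                 bases, paste0)))
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(tolower(cd), "")[[1]])
  }, "")
  names(aa) <- codons
  aa
})

codon_aa <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(.codon_table[codon])
}

# --- site classification ----------------------------------------------------

#' Segregating-site scan
#'
#' A retained column is segregating iff it carries at least two distinct
#' non-`N` bases; multiallelic columns count once toward `S`.
#'
#' @param aln an [aligned_seqs()] object.
#' @param mask logical column mask (default [mask_indels()]).
#' @return a list: `segregating` (logical per column, `FALSE` for masked
#'   columns), `S`, `counts` (5 x L matrix of per-column base counts over
#'   A, C, G, T, `-`; `N` excluded), and `n_allN` (count of retained
#'   columns that were all-`N` and excluded).
#' @export
segregating_sites <- function(aln, mask = mask_indels(aln)) {
  cnt <- .base_counts(aln)
  nz <- colSums(cnt > 0L)
  n_nonN <- colSums(cnt)
  seg <- mask & nz >= 2L
  list(segregating = seg, S = sum(seg), counts = cnt,
       n_allN = sum(mask & n_nonN == 0L))
}

# 5 x L matrix of per-column counts of A, C, G, T, '-' (N dropped).
.base_counts <- function(aln) {
  out <- vapply(c("A", "C", "G", "T", "-"),
                function(b) colSums(aln$mat == b),
                numeric(aln$L))
  t(out)
}

# Per-column mean pairwise differences over an index set of columns.
.pi_by_column <- function(aln, cols, counts = NULL) {
  if (length(cols) == 0L) return(numeric(0))
  cnt <- (counts %||% .base_counts(aln))[, cols, drop = FALSE]
  nc <- colSums(cnt)
  num <- nc * (nc - 1) - colSums(cnt * (cnt - 1))
  ifelse(nc < 2, 0, num / (nc * (nc - 1)))
}

#' Nucleotide diversity (pi)
#'
#' Average proportion of differing sites over all `C(n,2)` sequence pairs,
#' computed per column and divided by the effective (retained) length.
#'
#' @param aln an [aligned_seqs()] object.
#' @param mask logical column mask (default [mask_indels()]).
#' @param interval optional `c(start, end)` 0-based half-open interval;
#'   default whole alignment.
#' @return per-site pi, with attributes `L_eff` and `pi_total` (the mean
#'   pairwise difference count, i.e. pi before dividing by `L_eff`). If no
#'   columns are retained an undefined-flagged `NA` is returned.
#' @export
nuc_diversity <- function(aln, mask = mask_indels(aln), interval = NULL) {
  interval <- interval %||% c(0L, aln$L)
  cols <- which(mask & seq_len(aln$L) > interval[1] &
                  seq_len(aln$L) <= interval[2])
  L_eff <- length(cols)
  if (L_eff == 0L) return(undefined_stat("no retained columns in interval"))
  pi_total <- sum(.pi_by_column(aln, cols))
  structure(pi_total / L_eff, L_eff = L_eff, pi_total = pi_total)
}

#' Watterson's theta per site
#'
#' `theta_w = S / (a_n * L_eff)` with `a_n = sum(1/i, i = 1..n-1)`.
#'
#' @param S number of segregating sites.
#' @param n number of sequences (`n >= 2`).
#' @param L_eff effective length in bp (fractional values allowed for
#'   synonymous/non-synonymous site counts).
#' @return per-site theta.
#' @export
watterson_theta <- function(S, n, L_eff) {
  if (n < 2) stop_user("watterson_theta needs n >= 2")
  if (L_eff <= 0) return(undefined_stat("L_eff = 0"))
  S / (harmonic_a(n) * L_eff)
}

#' Tajima's D
#'
#' Normalised difference between the pairwise estimate of theta (`pi_total`,
#' the per-gene mean pairwise difference count, not per site) and the
#' segregating-sites estimate `S/a_n`, with the 1989 variance constants.
#'
#' @param S segregating sites; `D` is undefined (flagged `NA`) when `S = 0`.
#' @param n number of sequences, `n >= 4`.
#' @param pi_total mean pairwise difference count over the whole region.
#' @return the D statistic.
#' @export
tajima_d <- function(S, n, pi_total) {
  if (n < 4) return(undefined_stat("n < 4"))
  if (S == 0) return(undefined_stat("S = 0"))
  a1 <- harmonic_a(n)
  a2 <- harmonic_b(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D* (outgroup-free)
#'
#' Contrasts the total number of segregating sites with the number of
#' singletons (variants carried by exactly one sequence). An excess of
#' singletons drives D* negative.
#'
#' @param S segregating sites; undefined (flagged `NA`) when `S = 0`.
#' @param n number of sequences, `n >= 4`.
#' @param singletons count of singleton variants.
#' @return the D* statistic.
#' @export
fu_li_d_star <- function(S, n, singletons) {
  if (n < 4) return(undefined_stat("n < 4"))
  if (S == 0) return(undefined_stat("S = 0"))
  a <- harmonic_a(n)
  b <- harmonic_b(n)
  a1 <- a + 1 / n  # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * a1 - 3) / (n - 2) - 1 / n)
  v <- ((n / (n - 1))^2 * b + a^2 * dn -
          2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  u <- (n / (n - 1)) * (a - n / (n - 1)) - v
  ((n / (n - 1)) * S - a * singletons) / sqrt(u * S + v * S^2)
}

#' Count singleton variants in an alignment
#'
#' A singleton is an allele observed in exactly one sequence at a retained
#' segregating column (each such allele counts once).
#'
#' @inheritParams segregating_sites
#' @param seg optional precomputed [segregating_sites()] result.
#' @return integer count.
#' @export
count_singletons <- function(aln, mask = mask_indels(aln),
                             seg = segregating_sites(aln, mask)) {
  segcols <- which(seg$segregating)
  if (!length(segcols)) return(0L)
  sum(seg$counts[, segcols, drop = FALSE] == 1L)
}

# --- Nei-Gojobori synonymous / non-synonymous machinery ---------------------

# Fractional synonymous site count of one codon: for each position, the
# fraction of the 3 single-base changes that preserve the amino acid.
# Changes creating a stop are counted as non-synonymous; codons that are
# themselves stops (or contain non-ACGT) return NA and are skipped upstream.
.codon_syn_sites <- function(codon) {
  aa0 <- codon_aa(codon)
  if (is.na(aa0) || aa0 == "*") return(NA_real_)
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      if (codon_aa(paste(mut, collapse = "")) == aa0) syn <- syn + 1 / 3
    }
  }
  syn
}

# Synonymous/non-synonymous differences between two codons, averaging over
# all shortest mutational pathways (Nei-Gojobori 1986 pathway rule).
# Pathways passing through a stop codon are discarded; if every pathway hits
# a stop the codon pair is skipped (NA).
.codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(p1 != p2)
  perms <- switch(length(diff_pos),
                  list(diff_pos),
                  list(diff_pos, rev(diff_pos)),
                  {
                    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
                    lapply(idx, function(i) diff_pos[i])
                  })
  acc <- c(syn = 0, nonsyn = 0)
  n_ok <- 0L
  for (path in perms) {
    cur <- p1
    steps <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (pos in path) {
      aa_from <- codon_aa(paste(cur, collapse = ""))
      cur[pos] <- p2[pos]
      aa_to <- codon_aa(paste(cur, collapse = ""))
      if (is.na(aa_from) || is.na(aa_to) || aa_to == "*" || aa_from == "*") {
        ok <- FALSE
        break
      }
      if (aa_from == aa_to) steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
    }
    if (ok) {
      acc <- acc + steps
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) return(c(syn = NA_real_, nonsyn = NA_real_))
  acc / n_ok
}

# Split a vector of alignment columns into codon triplets.
.codon_strings <- function(mat_rows, cols) {
  ncod <- length(cols) %/% 3L
  lapply(seq_len(ncod), function(k) {
    idx <- cols[(3 * k - 2):(3 * k)]
    apply(mat_rows[, idx, drop = FALSE], 1, paste, collapse = "")
  })
}

#' Nei-Gojobori fractional synonymous and non-synonymous site counts
#'
#' Each codon position contributes the fraction of its three possible
#' single-base changes that are synonymous; counts are averaged over all
#' sequences in the panel, so `syn + nonsyn = 3 * codons` exactly for clean
#' codons. Codons containing a gap, `N` or a stop are skipped (with a
#' warning for internal stops).
#'
#' @param aln an [aligned_seqs()] object.
#' @param cols 0-based alignment columns of the concatenated complete codons
#'   (see exons of a [region_map()]); length must be a multiple of 3.
#' @return list with `syn_sites`, `nonsyn_sites`, `n_codons` (clean codons
#'   averaged over sequences) and `syn_weight` (per-column synonymous
#'   fraction averaged over sequences, for site bookkeeping).
#' @export
ng_site_counts <- function(aln, cols) {
  cols <- as.integer(cols) + 1L  # to R indexing
  if (length(cols) %% 3L != 0L) stop_user("coding columns must come in codons")
  codons <- .codon_strings(aln$mat, cols)
  n <- nrow(aln$mat)
  syn_w <- matrix(NA_real_, nrow = length(codons), ncol = 1)
  syn_tot <- 0
  codon_tot <- 0
  stops <- 0L
  per_codon_syn <- numeric(length(codons))
  for (k in seq_along(codons)) {
    vals <- vapply(codons[[k]], function(cd) {
      if (grepl("[^ACGT]", cd)) return(NA_real_)
      if (codon_aa(cd) == "*") return(-1)  # sentinel: stop codon
      .codon_syn_sites(cd)
    }, 0)
    if (any(vals == -1, na.rm = TRUE)) stops <- stops + 1L
    vals[!is.na(vals) & vals == -1] <- NA_real_
    ok <- !is.na(vals)
    if (any(ok)) {
      syn_tot <- syn_tot + sum(vals[ok]) / n
      codon_tot <- codon_tot + sum(ok) / n
      per_codon_syn[k] <- mean(vals[ok])
    } else {
      per_codon_syn[k] <- NA_real_
    }
  }
  if (stops > 0L) warning(sprintf("%d codon(s) with an internal stop skipped",
                                  stops))
  list(syn_sites = syn_tot, nonsyn_sites = 3 * codon_tot - syn_tot,
       n_codons = codon_tot, per_codon_syn = per_codon_syn)
}

#' Pairwise Nei-Gojobori synonymous and non-synonymous diversity
#'
#' For every sequence pair, synonymous and non-synonymous differences are
#' counted codon-by-codon (pathway-averaged for codons differing at more
#' than one position) and divided by the pair's mean synonymous and
#' non-synonymous site counts; `pi_syn`/`pi_nonsyn` are the averages over
#' all pairs. Codons containing gaps or `N` in either sequence are skipped
#' for that pair.
#'
#' @inheritParams ng_site_counts
#' @return list with `pi_syn`, `pi_nonsyn`, `syn_sites`, `nonsyn_sites`
#'   (panel-average site counts), and total difference counts.
#' @export
ng_pairwise_diversity <- function(aln, cols) {
  sites <- ng_site_counts(aln, cols)
  cols1 <- as.integer(cols) + 1L
  codons <- .codon_strings(aln$mat, cols1)
  n <- nrow(aln$mat)
  pairs <- utils::combn(n, 2)
  syn_rates <- nonsyn_rates <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sd <- nd <- 0
    ss <- ns <- 0
    for (k in seq_along(codons)) {
      c1 <- codons[[k]][i]; c2 <- codons[[k]][j]
      if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
      s1 <- .codon_syn_sites(c1); s2 <- .codon_syn_sites(c2)
      if (is.na(s1) || is.na(s2)) next
      d <- .codon_pair_diffs(c1, c2)
      if (anyNA(d)) next
      sd <- sd + d[["syn"]]; nd <- nd + d[["nonsyn"]]
      pair_syn <- (s1 + s2) / 2
      ss <- ss + pair_syn
      ns <- ns + 3 - pair_syn
    }
    syn_rates[p] <- if (ss > 0) sd / ss else 0
    nonsyn_rates[p] <- if (ns > 0) nd / ns else 0
  }
  list(pi_syn = mean(syn_rates), pi_nonsyn = mean(nonsyn_rates),
       syn_sites = sites$syn_sites, nonsyn_sites = sites$nonsyn_sites,
       n_codons = sites$n_codons)
}

#' Classify a segregating coding site as synonymous or non-synonymous
#'
#' The alternate allele is substituted into the majority-background codon.
#' When another position of the codon is also segregating with tied allele
#' counts, the site is classified against each tied background; if the
#' classes disagree the site is reported `"mixed"`. Changes creating a
#' premature stop are reported as `"nonsense"`.
#'
#' @param aln an [aligned_seqs()] object.
#' @param cols 0-based coding columns (complete codons, transcript order).
#' @param site 0-based alignment column of the segregating site (must be one
#'   of `cols`).
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`,
#'   `"mixed"`, or `"ambiguous"` (no majority background).
#' @export
classify_mutation <- function(aln, cols, site) {
  pos_in_cds <- match(site, cols)
  if (is.na(pos_in_cds)) stop_user("site %d is not a coding column", site)
  codon_idx <- (pos_in_cds - 1L) %/% 3L
  codon_cols <- cols[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)] + 1L
  within <- pos_in_cds - codon_idx * 3L  # 1..3
  site_col <- aln$mat[, site + 1L]
  site_col <- site_col[!site_col %in% c("N", "-")]
  cnt <- sort(table(site_col), decreasing = TRUE)
  if (length(cnt) < 2L) stop_user("site %d is not segregating", site)
  major <- names(cnt)[1]
  alts <- names(cnt)[-1]

  # majority backgrounds at the other two codon positions (ties -> several)
  bg_opts <- lapply(setdiff(1:3, within), function(w) {
    col <- aln$mat[, codon_cols[w]]
    col <- col[!col %in% c("N", "-")]
    tab <- table(col)
    names(tab)[tab == max(tab)]
  })
  grids <- expand.grid(bg_opts[[1]], bg_opts[[2]], stringsAsFactors = FALSE)
  others <- setdiff(1:3, within)

  classes <- character(0)
  for (g in seq_len(nrow(grids))) {
    codon <- character(3)
    codon[others] <- as.character(grids[g, ])
    codon[within] <- major
    from <- paste(codon, collapse = "")
    for (alt in alts) {
      codon[within] <- alt
      to <- paste(codon, collapse = "")
      aa_from <- codon_aa(from)
      aa_to <- codon_aa(to)
      if (is.na(aa_from) || is.na(aa_to)) next
      classes <- c(classes,
                   if (aa_to == "*" && aa_from != "*") "nonsense"
                   else if (aa_from == aa_to) "synonymous"
                   else "nonsynonymous")
    }
  }
  if (length(classes) == 0L) return("ambiguous")
  u <- unique(classes)
  if (length(u) == 1L) u else "mixed"
}

# --- region and population summaries ----------------------------------------

# One summary row given a set of retained 0-based columns.
.summary_for_cols <- function(aln, cols0, label) {
  cols <- cols0 + 1L
  L_eff <- length(cols)
  if (L_eff == 0L) {
    return(data.frame(region = label, L_eff = 0, S = NA_integer_,
                      percent_polymorphism = NA_real_, pi = NA_real_,
                      theta_w = NA_real_, stringsAsFactors = FALSE))
  }
  cnt <- .base_counts(aln)
  S <- sum(colSums(cnt[, cols, drop = FALSE] > 0L) >= 2L)
  pi_cols <- sum(.pi_by_column(aln, cols, counts = cnt)) / L_eff
  data.frame(region = label, L_eff = L_eff, S = S,
             percent_polymorphism = 100 * S / L_eff, pi = pi_cols,
             theta_w = as.numeric(watterson_theta(S, nrow(aln$mat), L_eff)),
             stringsAsFactors = FALSE)
}

#' Per-region diversity summary table
#'
#' One row per annotated region, with Synonymous / Non-synonymous sub-rows
#' for each exon and for the concatenated exon total, plus a whole-gene
#' Total row. Indel columns are excluded throughout; synonymous and
#' non-synonymous rows use fractional Nei-Gojobori site counts as their
#' effective lengths.
#'
#' @param aln an [aligned_seqs()] object.
#' @param regions a [region_map()].
#' @return a data frame with columns `region`, `L_eff`, `S`,
#'   `percent_polymorphism`, `pi`, `theta_w`.
#' @export
diversity_by_region <- function(aln, regions) {
  mask <- mask_indels(aln)
  keep0 <- which(mask) - 1L
  n <- nrow(aln$mat)

  syn_rows <- function(cols0, prefix) {
    # complete codons among retained columns only
    cc <- cols0[cols0 %in% keep0]
    # codon structure must come from the full exon concatenation; a codon is
    # usable only if all three of its columns are retained
    full <- cols0
    ncod <- length(full) %/% 3L
    use <- unlist(lapply(seq_len(ncod), function(k) {
      idx <- full[(3 * k - 2):(3 * k)]
      if (all(idx %in% keep0)) idx else NULL
    }))
    if (length(use) == 0L) {
      return(data.frame(region = paste0(prefix, c("synonymous", "nonsynonymous")),
                        L_eff = 0, S = NA, percent_polymorphism = NA,
                        pi = NA, theta_w = NA, stringsAsFactors = FALSE))
    }
    ngd <- ng_pairwise_diversity(aln, use)
    # classify segregating coding sites
    seg_cols <- use[vapply(use + 1L, function(j) {
      col <- aln$mat[, j]
      length(unique(col[col != "N"])) >= 2L
    }, NA)]
    cls <- vapply(seg_cols, function(s) classify_mutation(aln, use, s), "")
    S_syn <- sum(cls == "synonymous")
    S_non <- sum(cls %in% c("nonsynonymous", "nonsense", "mixed"))
    rbind(
      data.frame(region = paste0(prefix, "synonymous"),
                 L_eff = ngd$syn_sites, S = S_syn,
                 percent_polymorphism = 100 * S_syn / ngd$syn_sites,
                 pi = ngd$pi_syn,
                 theta_w = as.numeric(watterson_theta(S_syn, n, ngd$syn_sites)),
                 stringsAsFactors = FALSE),
      data.frame(region = paste0(prefix, "nonsynonymous"),
                 L_eff = ngd$nonsyn_sites, S = S_non,
                 percent_polymorphism = 100 * S_non / ngd$nonsyn_sites,
                 pi = ngd$pi_nonsyn,
                 theta_w = as.numeric(watterson_theta(S_non, n, ngd$nonsyn_sites)),
                 stringsAsFactors = FALSE))
  }

  out <- list()
  cds <- exon_codon_columns(regions)
  for (r in seq_len(nrow(regions))) {
    cols0 <- seq.int(regions$start[r], regions$end[r] - 1L)
    cols0 <- cols0[cols0 %in% keep0]
    out[[length(out) + 1L]] <-
      .summary_for_cols(aln, cols0, regions$label[r])
    if (regions$kind[r] == "exon") {
      ex_cols <- intersect(cds$cols,
                           seq.int(regions$start[r], regions$end[r] - 1L))
      out[[length(out) + 1L]] <-
        syn_rows(ex_cols, paste0(regions$label[r], "_"))
    }
  }
  out[[length(out) + 1L]] <- .summary_for_cols(aln, keep0, "Total")
  if (length(cds$cols)) {
    out[[length(out) + 1L]] <- syn_rows(cds$cols, "Total_")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Common-variant filter by minor allele frequency
#'
#' Retains sites with MAF strictly greater than the threshold (a site at
#' exactly the threshold is excluded).
#'
#' @param maf numeric vector of minor-allele frequencies in `[0, 0.5]`.
#' @param threshold frequency cutoff (default 0.10).
#' @return integer indices of retained sites.
#' @export
common_snps <- function(maf, threshold = 0.10) {
  stopifnot(all(maf >= 0 & maf <= 0.5 + 1e-12))
  which(maf > threshold)
}

#' Per-population diversity and neutrality report
#'
#' Computes, for each group of sequences and for the pooled panel:
#' `pi_tot` (all retained sites), `pi_sil` (noncoding plus synonymous,
#' site-weighted), `pi_s`, `pi_n` (Nei-Gojobori pairwise), Tajima's D and
#' Fu and Li's D*. Neutrality tests are flagged undefined for groups with
#' fewer than 4 sequences or no segregating sites.
#'
#' @param aln an [aligned_seqs()] object.
#' @param groups character/factor of group labels, one per sequence.
#' @param regions a [region_map()] (needed for the silent/coding partition).
#' @return a data frame, one row per group plus a `Total` row.
#' @export
diversity_by_population <- function(aln, groups, regions) {
  stopifnot(length(groups) == nrow(aln$mat))
  cds <- exon_codon_columns(regions)
  labels <- c(as.list(unique(as.character(groups))), list("Total"))
  rows <- lapply(labels, function(g) {
    idx <- if (identical(g, "Total")) seq_len(nrow(aln$mat))
           else which(groups == g)
    sub <- aligned_seqs(aln$mat[idx, , drop = FALSE], ids = aln$ids[idx])
    mask <- mask_indels(sub)
    keep0 <- which(mask) - 1L
    n <- length(idx)
    pi_all <- nuc_diversity(sub, mask)
    seg <- segregating_sites(sub, mask)
    # coding columns retained as whole codons
    full <- cds$cols
    ncod <- length(full) %/% 3L
    use <- unlist(lapply(seq_len(ncod), function(k) {
      ix <- full[(3 * k - 2):(3 * k)]
      if (all(ix %in% keep0)) ix else NULL
    }))
    if (length(use)) {
      ngd <- ng_pairwise_diversity(sub, use)
      # silent = noncoding columns + synonymous fraction of coding columns
      noncod <- setdiff(keep0, use)
      pi_noncod_total <- sum(.pi_by_column(sub, noncod + 1L))
      sil_sites <- length(noncod) + ngd$syn_sites
      pi_sil <- (pi_noncod_total + ngd$pi_syn * ngd$syn_sites) / sil_sites
      pi_s <- ngd$pi_syn
      pi_n <- ngd$pi_nonsyn
    } else {
      pi_sil <- as.numeric(pi_all)
      pi_s <- NA_real_
      pi_n <- NA_real_
    }
    D <- if (n >= 4 && seg$S > 0) {
      tajima_d(seg$S, n, attr(pi_all, "pi_total"))
    } else undefined_stat("n < 4 or S = 0")
    Dstar <- if (n >= 4 && seg$S > 0) {
      fu_li_d_star(seg$S, n, count_singletons(sub, mask, seg))
    } else undefined_stat("n < 4 or S = 0")
    data.frame(population = if (identical(g, "Total")) "Total" else g,
               n = n, S = seg$S, pi_tot = as.numeric(pi_all),
               pi_sil = pi_sil, pi_s = pi_s, pi_n = pi_n,
               tajima_d = as.numeric(D), fu_li_d_star = as.numeric(Dstar),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
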