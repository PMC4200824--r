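# Umbrella runner tying the stages into the candidate-gene workflow:
# diversity -> LD -> association (+ FDR, gene action) -> haplotype scan ->
# subset validation, with a JSON run manifest recording every decision.

#' Run the full candidate-gene analysis pipeline
#'
#' Stages execute in order, each consuming the previous stage's outputs; a
#' single global seed governs all stochastic steps (permutation streams are
#' derived from it per stage). Any stage failure aborts with the stage name.
#'
#' @param config a list (or path to a JSON/flat key=value file) with
#'   entries: `alignment` (FASTA path), `regions` (TSV path), `groups`
#'   (optional TSV path: id, group), `genotypes`, `phenotypes`, `structure`
#'   (paths; TSV), `kinship` (optional path), `subsets` (optional TSV path:
#'   id, subset), `traits` (optional character vector; default all),
#'   `ld_threshold` (default 0.1), `ld_n_perm` (default 1000),
#'   `htr_width` (default 3), `htr_n_perm` (default 1000),
#'   `min_hap_freq` (default 0.05), `fdr` (default 0.05).
#' @param seed global RNG seed.
#' @param out output directory (created if absent).
#' @return invisibly, a list of the per-stage results; files and
#'   `manifest.json` are written under `out`.
#' @export
pipeline_run <- function(config, seed = 1, out) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("candgene")),
                   seed = seed, config = config, stages = list())
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out)
      stop_user("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  if (!is.null(config$alignment)) {
    aln <- stage("load_alignment", read_alignment(config$alignment))
    regions <- stage("load_regions",
                     read_regions(config$regions, L_aln = aln$L))
    div <- stage("diversity", diversity_by_region(aln, regions))
    write_diversity_table(div, file.path(out, "diversity_by_region.tsv"))
    results$diversity <- div
    if (!is.null(config$groups)) {
      grp <- utils::read.delim(config$groups, stringsAsFactors = FALSE)
      groups <- grp[[2]][match(aln$ids, grp[[1]])]
      pop <- stage("population_diversity",
                   diversity_by_population(aln, groups, regions))
      utils::write.table(format_numeric(pop, 5),
                         file.path(out, "diversity_by_population.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$population_diversity <- pop
    }
    hap <- stage("ld_haplotypes", haplotypes_from_alignment(aln))
    pairs <- stage("ld_pairs", ld_pairs(hap))
    utils::write.table(format_numeric(pairs, 6),
                       file.path(out, "ld_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- stage("ld_decay",
                 fit_ld_decay(pairs, n = nrow(hap$mat),
                              threshold = config$ld_threshold %||% 0.1))
    jsonlite::write_json(
      list(model = fit$model, rho = fit$rho, n = fit$n, rss = fit$rss,
           threshold = fit$threshold,
           crossing_bp = if (is.na(fit$crossing_bp)) "beyond range"
                         else fit$crossing_bp),
      file.path(out, "ld_decay.json"), auto_unbox = TRUE, digits = NA)
    results$ld <- list(pairs = pairs, fit = fit,
                       blocks = find_ld_blocks(hap))
  }

  if (!is.null(config$genotypes)) {
    G <- stage("load_genotypes", read_genotypes(config$genotypes))
    phen <- stage("load_phenotypes", read_phenotypes(config$phenotypes))
    if (!any(rownames(G$mat) %in% rownames(phen))) {
      stop_user("no overlap between genotype and phenotype ids")
    }
    Q <- if (!is.null(config$structure)) {
      stage("load_structure", read_structure(config$structure))
    } else NULL
    K <- if (!is.null(config$kinship)) {
      stage("load_kinship", read_kinship(config$kinship))
    } else stage("kinship", ritland_kinship(G))
    write_kinship(round(K, 6), file.path(out, "kinship.tsv"))
    traits <- config$traits %||% names(phen)
    scans <- list()
    gact <- list()
    haps <- list()
    for (tr in traits) {
      y <- stats::setNames(phen[[tr]], rownames(phen))[rownames(G$mat)]
      sc <- stage(paste0("assoc_", tr),
                  assoc_scan(G, y, Q = Q[rownames(G$mat), , drop = FALSE],
                             K = K, trait = tr))
      scans[[tr]] <- sc
      gact[[tr]] <- gene_action_table(sc, y)
      ht <- stage(paste0("htr_", tr),
                  htr_scan(G, y, width = config$htr_width %||% 3,
                           min_freq = config$min_hap_freq %||% 0.05,
                           n_perm = config$htr_n_perm %||% 1000,
                           seed = derive_seed(seed, match(tr, traits)),
                           trait = tr))
      if (!is.null(ht)) haps[[tr]] <- ht
    }
    assoc <- do.call(rbind, scans)
    write_assoc_table(assoc, file.path(out, "association.tsv"))
    utils::write.table(format_numeric(do.call(rbind, gact), 4),
                       file.path(out, "gene_action.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(haps)) {
      utils::write.table(format_numeric(do.call(rbind, haps), 4),
                         file.path(out, "haplotype_associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results$association <- assoc
    results$gene_action <- do.call(rbind, gact)
    results$haplotypes <- if (length(haps)) do.call(rbind, haps) else NULL
    if (!is.null(config$subsets)) {
      sub <- utils::read.delim(config$subsets, stringsAsFactors = FALSE)
      labels <- sub[[2]][match(rownames(G$mat), sub[[1]])]
      y1 <- stats::setNames(phen[[traits[1]]], rownames(phen))[rownames(G$mat)]
      val <- stage("subset_validation",
                   subset_validation(G, y1, Q, labels, trait = traits[1]))
      utils::write.table(val$validated,
                         file.path(out, "subset_validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$subset_validation <- val
    }
  }
  write_manifest(manifest, out)
  invisible(results)
}

# flat key=value config reader (or JSON if the file starts with '{')
read_config <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) && grepl("^\\s*\\{", first)) {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), ""))
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

format_numeric <- function(df, digits) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  }
  df
}

#' Write a per-region diversity table in display precision
#'
#' Percent polymorphism to 2 decimals; pi and theta to 5. A full-precision
#' JSON sidecar is written next to the TSV.
#'
#' @param div a [diversity_by_region()] table; @param path output TSV.
#' @export
write_diversity_table <- function(div, path) {
  disp <- div
  disp$percent_polymorphism <- round(disp$percent_polymorphism, 2)
  disp$pi <- round(disp$pi, 5)
  disp$theta_w <- round(disp$theta_w, 5)
  disp$L_eff <- round(disp$L_eff, 2)
  utils::write.table(disp, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  jsonlite::write_json(div, sub("\\.tsv$", ".json", path), digits = NA,
                       na = "null")
  invisible(path)
}

#' Write an association scan in display precision
#' @param assoc an [assoc_scan()] table; @param path output TSV.
#' @export
write_assoc_table <- function(assoc, path) {
  disp <- format_numeric(as.data.frame(assoc), 6)
  utils::write.table(disp, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  jsonlite::write_json(as.data.frame(assoc), sub("\\.tsv$", ".json", path),
                       digits = NA, na = "null")
  invisible(path)
}
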