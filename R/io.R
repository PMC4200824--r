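# Readers and writers for the pipeline's standard formats. TSV dialect:
# tab-separated, UTF-8, header row, '.'/'NA' for missing. VCF coordinates
# are 1-based (standard) and converted to the internal 0-based convention
# in this one reader.

#' Read a genotype table (TSV matrix or VCF)
#'
#' TSV: header row of SNP ids, first column of individual ids, cells in
#' \{0, 1, 2\} counting minor alleles, '.'/'NA' missing. VCF v4.2 (via the
#' vcfR package): biallelic records only (multi-allelic records are skipped
#' with a warning), GT fields converted to minor-allele dosage.
#'
#' @param path input file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", "."), check.names = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop_user("duplicate individual ids in %s", path)
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- ids
    return(genotype_table(mat))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_user("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt) & alt != "." & nchar(alt) > 0
  if (any(!biallelic)) {
    warning(sprintf("%d multi-allelic/invalid record(s) skipped",
                    sum(!biallelic)))
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  })
  mat <- t(dos)
  # recode to minor-allele dosage per SNP
  for (j in seq_len(ncol(mat))) {
    p <- mean(mat[, j], na.rm = TRUE) / 2
    if (!is.na(p) && p > 0.5) mat[, j] <- 2 - mat[, j]
  }
  pos <- as.numeric(vcfR::getPOS(v)) - 1  # to 0-based
  genotype_table(mat, positions = pos)
}

#' Write a genotype table as TSV
#' @param G a [genotype_table()]; @param path output file.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(id = rownames(G$mat), G$mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with an `id` column and one numeric column per trait; '.'/'NA'
#' missing. Non-numeric trait cells raise an error naming the cell.
#'
#' @param path input file.
#' @return data frame with rownames = ids and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "."), check.names = FALSE)
  if (nrow(df) == 0L) stop_user("phenotype file has no data rows: %s", path)
  ids <- as.character(df[[1]])
  out <- df[, -1, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    v <- out[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(suppress))
      if (length(bad)) {
        stop_user("non-numeric phenotype at row %d, column '%s'",
                  bad[1], names(out)[j])
      }
      out[[j]] <- suppress
    }
  }
  rownames(out) <- ids
  out
}

#' Write a phenotype table
#' @param y named vector or data frame of traits; @param path output file.
#' @export
write_phenotypes <- function(y, path) {
  df <- if (is.data.frame(y)) data.frame(id = rownames(y), y, check.names = FALSE)
        else data.frame(id = names(y), trait = as.numeric(y))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a population-structure membership matrix Q
#'
#' TSV with an `id` column and k membership columns. Rows must sum to 1;
#' deviations up to `tol` are renormalised with a warning, larger ones are
#' an error.
#'
#' @param path input file.
#' @param tol renormalisation tolerance (default 0.05).
#' @return numeric matrix with rownames = ids.
#' @export
read_structure <- function(path, tol = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  Q <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(Q) <- "double"
  rs <- rowSums(Q)
  off <- abs(rs - 1)
  if (any(off > tol)) {
    stop_user("Q row %d sums to %.3f (tolerance %.2f)",
              which.max(off), rs[which.max(off)], tol)
  }
  if (any(off > 1e-6)) {
    warning("Q rows renormalised to sum to 1")
    Q <- Q / rs
  }
  rownames(Q) <- ids
  Q
}

#' Write a Q matrix
#' @param Q membership matrix with rownames; @param path output file.
#' @export
write_structure <- function(Q, path) {
  df <- data.frame(id = rownames(Q), Q, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a precomputed kinship matrix (square TSV with id row/column)
#' @param path input file.
#' @return symmetric numeric matrix.
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  K <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(K) <- "double"
  dimnames(K) <- list(ids, ids)
  if (max(abs(K - t(K))) > 1e-6) stop_user("kinship matrix is not symmetric")
  (K + t(K)) / 2
}

#' Write a kinship matrix
#' @param K square matrix with dimnames; @param path output file.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a haplotype matrix + positions as TSV
#' @param hap a [haplotype_matrix()]; @param path output file.
#' @export
write_haplotypes <- function(hap, path) {
  df <- data.frame(haplotype = seq_len(nrow(hap$mat)), hap$mat)
  names(df)[-1] <- paste0("pos", hap$positions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a haplotype matrix written by [write_haplotypes()]
#' @param path input file.
#' @return a [haplotype_matrix()].
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  pos <- as.numeric(sub("^pos", "", names(df)[-1]))
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  haplotype_matrix(mat, pos)
}
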