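# Aligned haplotype panels: construction, FASTA I/O, indel masking and the
# region annotation used to partition a candidate gene into UTR/exon/intron.

VALID_BASES <- c("A", "C", "G", "T", "-", "N")

#' Construct an aligned sequence panel
#'
#' Rows are haplotypes: one record per sequenced allele, so the sample size
#' `n` used by all diversity statistics is the number of rows.
#'
#' @param seqs character vector of equal-length sequences over `A,C,G,T,-,N`
#'   (case-insensitive), or a character matrix with one row per sequence.
#' @param ids unique sequence identifiers; defaults to names of `seqs`.
#' @return an object of class `aligned_seqs`: a list with elements `ids`,
#'   `mat` (n x L character matrix) and `L` (alignment length).
#' @export
aligned_seqs <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    ids <- ids %||% rownames(seqs) %||% paste0("seq", seq_len(nrow(seqs)))
  } else {
    ids <- ids %||% names(seqs) %||% paste0("seq", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[1])[1]
      stop_user("ragged alignment: record %d ('%s') has length %d, expected %d",
                bad, ids[bad], lens[bad], lens[1])
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (nrow(mat) < 2L) stop_user("an alignment needs at least 2 sequences")
  if (anyDuplicated(ids)) stop_user("sequence identifiers must be unique")
  bad <- setdiff(unique(as.vector(mat)), VALID_BASES)
  if (length(bad)) stop_user("invalid alignment characters: %s",
                             paste(bad, collapse = ", "))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, L = ncol(mat)), class = "aligned_seqs")
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat(sprintf("aligned_seqs: %d sequences x %d columns\n", nrow(x$mat), x$L))
  invisible(x)
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param path FASTA file; all records must have the same length.
#' @return an [aligned_seqs()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_user("alignment file not found: %s", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop_user("empty or unparseable FASTA file: %s", path))
  if (length(recs) == 0L) stop_user("empty FASTA file: %s", path)
  aligned_seqs(vapply(recs, as.character, ""), ids = names(recs))
}

#' Write an alignment to FASTA
#'
#' @param aln an [aligned_seqs()] object.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(apply(aln$mat, 1, paste, collapse = "")),
                      names = aln$ids, file.out = path, nbchar = 70)
  invisible(path)
}

#' Indel mask: drop every column that contains a gap in any sequence
#'
#' The strictest reading of excluding indel regions from diversity
#' calculations: a single `-` anywhere removes the whole column.
#'
#' @param aln an [aligned_seqs()] object.
#' @return logical vector of length `L`; `TRUE` = column retained. The number
#'   of excluded columns is attached as attribute `n_excluded`.
#' @export
mask_indels <- function(aln) {
  keep <- colSums(aln$mat == "-") == 0L
  structure(keep, n_excluded = sum(!keep))
}

#' Gene-region annotation map
#'
#' @param start,end 0-based half-open interval bounds within the alignment.
#' @param label region names (e.g. `"exon1"`).
#' @param kind one of `five_prime_utr`, `exon`, `intron`, `three_prime_utr`.
#' @param frame reading-frame offset for exons (0, 1 or 2): number of bases
#'   of the region that complete the previous exon's trailing codon. `NA`
#'   for non-exon regions.
#' @param L_aln alignment length for bounds checking (optional).
#' @return a `region_map` data frame sorted by `start`.
#' @export
region_map <- function(start, end, label, kind, frame = NA_integer_,
                       L_aln = NULL) {
  kinds <- c("five_prime_utr", "exon", "intron", "three_prime_utr")
  if (!all(kind %in% kinds)) {
    stop_user("region kind must be one of: %s", paste(kinds, collapse = ", "))
  }
  df <- data.frame(label = label, kind = kind, start = as.integer(start),
                   end = as.integer(end),
                   frame = rep_len(as.integer(frame), length(start)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop_user("regions must satisfy 0 <= start < end")
  }
  if (!is.null(L_aln) && any(df$end > L_aln)) {
    stop_user("region extends past the alignment (L = %d)", L_aln)
  }
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
    stop_user("regions overlap")
  }
  class(df) <- c("region_map", "data.frame")
  df
}

#' Read a region map from a BED-like TSV
#'
#' Columns: `start`, `end` (0-based half-open), `label`, `kind`, `frame`.
#'
#' @param path TSV file with a header row.
#' @param L_aln optional alignment length for bounds checking.
#' @return a [region_map()].
#' @export
read_regions <- function(path, L_aln = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "label", "kind")
  if (!all(need %in% names(df))) {
    stop_user("region file must have columns: %s", paste(need, collapse = ", "))
  }
  if (is.null(df$frame)) df$frame <- NA_integer_
  region_map(df$start, df$end, df$label, df$kind, df$frame, L_aln = L_aln)
}

#' Concatenated exon columns forming complete codons
#'
#' Exon intervals are concatenated in transcript order; the 0-based
#' alignment columns of all complete codons are returned, with the count of
#' trailing bases that do not complete a codon (flagged, dropped).
#'
#' @param regions a [region_map()].
#' @return list with `cols` (0-based columns, multiple of 3) and `trailing`.
#' @export
exon_codon_columns <- function(regions) {
  ex <- regions[regions$kind == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) return(list(cols = integer(0), trailing = 0L))
  cols <- unlist(Map(function(s, e) seq.int(s, e - 1L), ex$start, ex$end))
  trailing <- length(cols) %% 3L
  if (trailing) cols <- cols[seq_len(length(cols) - trailing)]
  list(cols = cols, trailing = trailing)
}
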