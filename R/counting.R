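## Genotype counting from amplicon reads: anchored offset extraction with a
## targeted-base quality filter.

#' Sample sheet for a selection experiment
#'
#' @param sample Unique sample identifiers.
#' @param replicate Positive replicate indices.
#' @param selection `"pre"` (without kanamycin) or `"post"` (with).
#' @param temperature `"30"` or `"37"` (recycled).
#' @param fastq,fastq2 Optional FASTQ path(s) per sample.
#' @return A validated data frame.
#' @export
sample_sheet <- function(sample, replicate, selection, temperature = "30",
                         fastq = NA_character_, fastq2 = NA_character_) {
  out <- data.frame(sample = as.character(sample),
                    replicate = as.integer(replicate),
                    selection = as.character(selection),
                    temperature = as.character(temperature),
                    fastq = fastq, fastq2 = fastq2)
  if (anyDuplicated(out$sample)) stop("duplicate sample ids in sample sheet")
  if (any(out$replicate < 1L)) stop("replicate indices must be positive")
  if (!all(out$selection %in% c("pre", "post"))) {
    stop("selection must be 'pre' or 'post'")
  }
  out
}

#' Count genotypes in an amplicon FASTQ
#'
#' Reads are anchored by an exact or 1-mismatch match of the 5' constant
#' region at the read start; the eight variable bases are then extracted at
#' fixed offsets. A read is discarded if any targeted base is `N` or has
#' Phred quality below `qmin`. Backbone (non-targeted) bases are not
#' filtered. No indel tolerance: variants are substitutions only.
#'
#' @param fastq Path to a FASTQ(.gz) file of forward reads.
#' @param anchor 5' constant region expected at the read start.
#' @param offsets 1-based positions of the variable bases in the read
#'   (default [amplicon_offsets()]).
#' @param qmin Minimum Phred quality at targeted bases (default 30).
#' @param max_anchor_mismatch Allowed mismatches in the anchor (default 1).
#' @param min_anchor_rate Warn if the fraction of anchored reads falls below
#'   this floor (default 0.5).
#' @return Named integer vector of genotype counts (canonical
#'   `"LLLL-RRRR"` names), with a `qc` attribute: reads seen / anchored /
#'   passed.
#' @export
parse_amplicons <- function(fastq, anchor = AMPLICON_ANCHOR_5P,
                            offsets = amplicon_offsets(), qmin = 30L,
                            max_anchor_mismatch = 1L, min_anchor_rate = 0.5) {
  ## quality coercions drop metadata columns; those warnings are expected
  reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  seqs <- suppressWarnings(as.character(reads))
  quals <- suppressWarnings(as.character(Biostrings::quality(reads)))
  n_seen <- length(seqs)
  if (n_seen == 0L) {
    out <- integer(0)
    attr(out, "qc") <- c(seen = 0L, anchored = 0L, passed = 0L)
    return(out)
  }
  ## anchor match with <= max_anchor_mismatch substitutions at the read start
  alen <- nchar(anchor)
  head_m <- matrix(unlist(strsplit(substr(seqs, 1L, alen), ""),
                          use.names = FALSE), ncol = alen, byrow = TRUE)
  amm <- rowSums(head_m != matrix(strsplit(anchor, "")[[1L]],
                                  nrow(head_m), alen, byrow = TRUE))
  anchored <- amm <= max_anchor_mismatch & nchar(seqs) >= max(offsets)
  if (mean(anchored) < min_anchor_rate) {
    warning(sprintf("anchor-match rate %.1f%% below floor %.1f%% in %s",
                    100 * mean(anchored), 100 * min_anchor_rate, fastq))
  }
  seqs <- seqs[anchored]
  quals <- quals[anchored]
  ## extract targeted bases and their qualities
  base_m <- vapply(offsets, function(o) substr(seqs, o, o),
                   character(length(seqs)))
  qual_m <- vapply(offsets, function(o) {
    utf8ToInt_v(substr(quals, o, o)) - 33L
  }, integer(length(seqs)))
  if (length(seqs) == 1L) {
    base_m <- matrix(base_m, nrow = 1L)
    qual_m <- matrix(qual_m, nrow = 1L)
  }
  valid <- matrix(base_m %in% c("A", "C", "G", "T"), nrow(base_m))
  ok <- rowSums(qual_m < qmin) == 0L & rowSums(!valid) == 0L
  gts <- apply(base_m[ok, , drop = FALSE], 1L, paste0, collapse = "")
  tab <- table(gts)
  out <- stats::setNames(as.integer(tab), gt_format(names(tab)))
  attr(out, "qc") <- c(seen = n_seen, anchored = length(seqs),
                       passed = as.integer(sum(ok)))
  out
}

## internal: vectorised utf8ToInt for single characters
utf8ToInt_v <- function(x) {
  out <- integer(length(x))
  nz <- nchar(x) > 0L
  out[nz] <- vapply(x[nz], function(ch) utf8ToInt(ch)[1L], integer(1L))
  out[!nz] <- -1L
  out
}

#' Assemble per-sample counts into a count table
#'
#' @param columns Named list of per-sample count vectors (as returned by
#'   [parse_amplicons()]), names matching `sheet$sample`.
#' @param sheet [sample_sheet()].
#' @param genotypes Genotype universe for the rows (default: union of
#'   observed genotypes; pass [enumerate_genotypes()] for the complete
#'   space). Missing genotypes are zero-filled.
#' @return Integer matrix (genotype x sample) with a `sheet` attribute and
#'   per-sample totals as attribute `totals`.
#' @export
assemble_count_table <- function(columns, sheet, genotypes = NULL) {
  if (anyDuplicated(names(columns))) stop("duplicate sample ids")
  if (!all(sheet$sample %in% names(columns))) {
    stop("columns missing for sample(s): ",
         paste(setdiff(sheet$sample, names(columns)), collapse = ", "))
  }
  if (is.null(genotypes)) {
    genotypes <- sort(unique(unlist(lapply(columns, names))))
  }
  genotypes <- gt_format(genotypes)
  mat <- vapply(sheet$sample, function(s) {
    col <- columns[[s]]
    if (sum(col) == 0L) {
      warning("sample ", s, " has zero reads")
    }
    v <- integer(length(genotypes))
    idx <- match(names(col), genotypes)
    keep <- !is.na(idx)
    v[idx[keep]] <- as.integer(col[keep])
    v
  }, integer(length(genotypes)))
  rownames(mat) <- genotypes
  attr(mat, "sheet") <- sheet
  attr(mat, "totals") <- colSums(mat)
  mat
}
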