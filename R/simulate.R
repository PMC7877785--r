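## Simulation of the pooled selection experiment: library skew, selection,
## replicates and sequencing, emitting count tables and optional FASTQ.

#' Configuration of a simulated selection experiment
#'
#' @param seed Integer master seed; every random draw of the simulation
#'   derives from it.
#' @param n_replicates Number of biological replicates (default 6, as in the
#'   experiment).
#' @param depth Sequencing reads per sample (default 2e6).
#' @param lambda Library-skew rate per mutation in `(0, 1]`: pre-selection
#'   sampling weights are proportional to `lambda^d`, so the mutagenesis
#'   library is enriched for genotypes close to the master (default 0.1;
#'   the expected read share at distance d is `C(8,d) (3 lambda)^d /
#'   (1 + 3 lambda)^8`).
#' @param phi Negative-binomial overdispersion: per-replicate genotype
#'   weights are multiplied by Gamma(1/phi, scale = phi) deviates
#'   (mean 1, variance phi) before multinomial sampling; 0 = pure
#'   multinomial.
#' @param params Two-state model parameters ([two_state_params()]).
#' @param temperature `"30C"` or `"37C"`.
#' @param read_len Read length for FASTQ output (default 100).
#' @param error_rate Per-base substitution error rate for FASTQ output.
#' @param qual Phred quality character written for every base.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_replicates = 6L, depth = 2e6,
                       lambda = 0.1, phi = 0, params = two_state_params(),
                       temperature = "30C", read_len = 100L,
                       error_rate = 0, qual = "F") {
  stopifnot(lambda > 0, lambda <= 1, depth > 0, n_replicates >= 1, phi >= 0,
            error_rate >= 0, error_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

## internal: one multinomial draw with optional gamma-multinomial
## overdispersion
draw_counts <- function(depth, weights, phi) {
  p <- weights
  if (phi > 0) {
    p <- p * stats::rgamma(length(p), shape = 1 / phi, scale = phi)
  }
  if (sum(p) <= 0) stop("all sampling weights are zero")
  as.integer(stats::rmultinom(1L, size = depth, prob = p / sum(p)))
}

#' Simulate the pre-selection library
#'
#' Draws per-replicate pre-selection counts with sampling weights
#' `lambda^d(g)`, emulating the Hamming-decay skew of the mutagenesis
#' library around the master genotype.
#'
#' @param config [sim_config()].
#' @param genotypes Character vector (default: the full 4^8 space).
#' @return Integer matrix (genotype x replicate) with rownames set to the
#'   canonical genotype form; each column sums to `depth`.
#' @export
simulate_library <- function(config, genotypes = enumerate_genotypes()) {
  d <- hamming(genotypes)
  wts <- config$lambda^d
  set.seed(config$seed)
  out <- vapply(seq_len(config$n_replicates), function(r) {
    draw_counts(config$depth, wts, config$phi)
  }, integer(length(genotypes)))
  rownames(out) <- gt_format(genotypes)
  colnames(out) <- paste0("rep", seq_len(config$n_replicates))
  out
}

#' Simulate one round of selection
#'
#' Resamples each replicate with weights proportional to
#' `n_pre(g) * w(g)`: fitness-weighted survival of the pre-selection pool,
#' re-sequenced at `depth`.
#'
#' @param pre Pre-selection count matrix from [simulate_library()].
#' @param truth A [true_landscape()] (or any data frame with `genotype` and
#'   `w` columns covering the rows of `pre`).
#' @param config [sim_config()].
#' @return Integer matrix like `pre`.
#' @export
simulate_selection <- function(pre, truth, config) {
  idx <- match(rownames(pre), truth$genotype)
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " genotype(s) in the count table are missing from ",
         "the true landscape")
  }
  w <- truth$w[idx]
  set.seed(config$seed + 1L)
  out <- vapply(seq_len(ncol(pre)), function(r) {
    draw_counts(config$depth, pre[, r] * w, config$phi)
  }, integer(nrow(pre)))
  dimnames(out) <- dimnames(pre)
  out
}

#' Simulate a complete selection experiment
#'
#' Generates the ground-truth landscape, the pre-selection library and the
#' post-selection pools for one temperature, and assembles them into a
#' genotype x sample count matrix plus sample sheet (columns
#' `repN_pre` = without kanamycin, `repN_post` = with kanamycin).
#'
#' @param config [sim_config()].
#' @param genotypes Character vector (default: the full 4^8 space).
#' @param truth Optional pre-computed [true_landscape()]; by default built
#'   from `config$params`, `config$temperature`, and genotype noise seeded
#'   from `config$seed` when `params$sigma > 0`.
#' @param noise Draw lognormal genotype noise (`sigma`) for the truth?
#'   Default `TRUE`; set `FALSE` for a noise-free landscape regardless of
#'   `sigma`.
#' @return List with `counts` (integer matrix), `sheet`
#'   ([sample_sheet()] data frame), `truth`, and `config`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                genotypes = enumerate_genotypes(),
                                truth = NULL, noise = TRUE) {
  if (is.null(truth)) {
    truth <- true_landscape(
      genotypes, config$params, config$temperature,
      seed = if (noise && config$params$sigma > 0) config$seed + 2L else NULL
    )
  }
  pre <- simulate_library(config, genotypes)
  post <- simulate_selection(pre, truth, config)
  counts <- cbind(pre, post)
  reps <- seq_len(config$n_replicates)
  colnames(counts) <- c(paste0("rep", reps, "_pre"),
                        paste0("rep", reps, "_post"))
  sheet <- sample_sheet(
    sample = colnames(counts),
    replicate = rep(reps, 2L),
    selection = rep(c("pre", "post"), each = config$n_replicates),
    temperature = sub("C", "", config$temperature)
  )
  list(counts = counts, sheet = sheet, truth = truth, config = config)
}

## Amplicon layout: the sequenced fragment spans a 5' constant region, the
## N2..N5 block, the constant 12-nt loop, the N18..N21 block, and a 3'
## constant region. The 5' anchor and the (reverse-complemented) 3' end are
## the primer-adjacent constant regions of the real amplicon; the middle of
## the 3' constant region is a synthetic filler (the real internal sequence
## plays no role in genotype calling).
AMPLICON_ANCHOR_5P <- "GGGGATGATGTTAAGGCTATTGGTGTTTATGGCTCTCT"  # 38 nt
AMPLICON_LOOP <- "AGCAATATTACG"                                  # 12 nt
AMPLICON_FILLER_SYNTH <- paste0(                                 # 68 nt, synthetic
  "TGACCTGAAGCTATCGGATCACTGTAGCCTTAGGACTT",
  "CAGTTGACGCATTGCAGGTCCTAAGATCGA")
AMPLICON_TAIL_RC <- paste0(  # reverse complement of the reverse-read anchor
  "GGAGGGAAAAGTTATCAGGCATGCACTGGTAGCTAGTCTTTAAACCAATAGATTGCATCGGTTTAAAAGGCAAGACCG")

revcomp <- function(x) chartr("ACGT", "TGCA", vapply(
  strsplit(x, ""), function(b) paste(rev(b), collapse = ""), character(1)))

#' Full amplicon sequence of a genotype
#'
#' @param g Character vector of genotypes.
#' @return Character vector of 204-nt amplicon sequences.
#' @export
amplicon_sequence <- function(g) {
  bare <- gt_parse(g)
  paste0(AMPLICON_ANCHOR_5P, substr(bare, 1L, 4L), AMPLICON_LOOP,
         substr(bare, 5L, 8L), AMPLICON_FILLER_SYNTH, AMPLICON_TAIL_RC)
}

#' Offsets of the eight variable bases in the forward read
#'
#' 1-based positions of N2..N5 and N18..N21 in a forward read that starts at
#' the first base of the 5' constant region.
#'
#' @return Integer vector of length 8.
#' @export
amplicon_offsets <- function() {
  a <- nchar(AMPLICON_ANCHOR_5P)
  c(a + 1:4, a + 4L + nchar(AMPLICON_LOOP) + 1:4)
}

#' Write simulated amplicon reads as FASTQ
#'
#' Emits one forward read (and optionally its reverse mate) per counted
#' molecule, gzip-compressed. At `error_rate = 0` counting the output with
#' [parse_amplicons()] reproduces the input counts exactly.
#'
#' @param counts Named integer vector (genotype -> count) or a single-column
#'   slice of a count matrix.
#' @param file Output path for the forward reads (`.fastq.gz` recommended).
#' @param config [sim_config()]; `read_len`, `error_rate`, `qual` and `seed`
#'   are used.
#' @param file2 Optional path for reverse reads (reverse complement of the
#'   amplicon 3' end; does not cover the variable sites).
#' @return Invisibly, the number of reads written.
#' @export
write_amplicon_fastq <- function(counts, file, config = sim_config(),
                                 file2 = NULL) {
  counts <- counts[counts > 0]
  g <- rep(names(counts), counts)
  set.seed(config$seed + 3L)
  g <- g[sample.int(length(g))]  # shuffle read order
  fwd <- substr(amplicon_sequence(g), 1L, config$read_len)
  if (config$error_rate > 0) {
    fwd <- inject_errors(fwd, config$error_rate)
  }
  qual <- strrep(config$qual, config$read_len)
  ids <- paste0("@sim_read_", seq_along(fwd))
  con <- gzfile(file, "wb")
  writeLines(paste(ids, fwd, "+", qual, sep = "\n"), con)
  close(con)
  if (!is.null(file2)) {
    amp <- amplicon_sequence(g)
    rev <- substr(revcomp(amp), 1L, config$read_len)
    if (config$error_rate > 0) rev <- inject_errors(rev, config$error_rate)
    con <- gzfile(file2, "wb")
    writeLines(paste(ids, rev, "+", qual, sep = "\n"), con)
    close(con)
  }
  invisible(length(fwd))
}

## internal: iid per-base substitution errors on a character vector of reads
inject_errors <- function(reads, rate) {
  n <- length(reads)
  len <- nchar(reads[1L])
  m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
              nrow = n, byrow = TRUE)
  hit <- which(matrix(stats::runif(n * len) < rate, n, len))
  if (length(hit)) {
    cur <- m[hit]
    sub <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1L))
    m[hit] <- sub
  }
  apply(m, 1L, paste0, collapse = "")
}
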