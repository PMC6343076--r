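#' Simulate per-window genome coverage carrying a replication signal
#'
#' In a replicating population, read-start density decreases from the origin
#' of replication (genome fraction x = 0) to the terminus (x = 1) as
#' `2^(log2(true_irep) * (1 - x))`. The number of read starts per window is
#' Poisson with that gradient as its mean, scaled so that the mean per-base
#' depth equals `mean_coverage` (a window of `window` bp at depth C holds
#' about `C * window / read_length` read starts); reported coverage is the
#' per-window mean depth.
#'
#' @param genome_truth a [GenomeTruth-class]; `window` must divide
#'   `genome_length` into at least 50 windows.
#' @return data frame with `window_index`, `x` (window-centre genome
#'   fraction) and `coverage` (mean per-base depth).
#' @examples
#' gt <- genomeTruth(true_irep = 2, mean_coverage = 20)
#' cov <- simulateGenomeCoverage(gt)
#' head(cov)
#' @export
simulateGenomeCoverage <- function(genome_truth) {
  stopifnot(is(genome_truth, "GenomeTruth"))
  validObject(genome_truth)
  gl <- genome_truth@genome_length
  w <- genome_truth@window
  if (gl %% w != 0L)
    stop("window must divide genome_length cleanly")
  n <- gl %/% w
  if (n < 50L) stop("window too large: fewer than 50 windows")
  set.seed(genome_truth@seed)
  x <- (seq_len(n) - 0.5) / n
  expected <- 2^(log2(genome_truth@true_irep) * (1 - x))
  if (genome_truth@mean_coverage == 0) {
    cov <- rep(0, n)
  } else {
    reads_per_window <- genome_truth@mean_coverage * w /
      genome_truth@read_length
    lambda <- expected * reads_per_window / mean(expected)
    cov <- rpois(n, lambda) * genome_truth@read_length / w
  }
  data.frame(window_index = seq_len(n), x = x, coverage = cov)
}

#' Simulate per-ORF transcript read counts
#'
#' Read counts are multinomial with probabilities proportional to
#' `orf_weights * orf_lengths` (length-proportional sampling, so that TPM
#' normalization recovers the configured weights).
#'
#' @param genome_truth a [GenomeTruth-class] with non-empty `orf_lengths`
#'   and `orf_weights`.
#' @param total_reads total transcript reads to distribute (>= 0).
#' @param seed integer seed (defaults to the truth object's seed).
#' @return data frame with `orf_id`, `length` and `count`.
#' @export
simulateOrfTranscripts <- function(genome_truth, total_reads, seed = NULL) {
  stopifnot(is(genome_truth, "GenomeTruth"), total_reads >= 0)
  if (length(genome_truth@orf_lengths) == 0L)
    stop("genome_truth carries no ORFs")
  if (is.null(seed)) seed <- genome_truth@seed
  set.seed(as.integer(seed))
  w <- genome_truth@orf_weights * genome_truth@orf_lengths
  counts <- if (total_reads > 0)
    as.integer(rmultinom(1L, total_reads, w / sum(w)))
  else rep(0L, length(w))
  data.frame(orf_id = sprintf("orf%04d", seq_along(w)),
             length = genome_truth@orf_lengths, count = counts)
}
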