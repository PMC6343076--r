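#' Genome relative abundance from contig coverage
#'
#' Raw value per genome is the length-weighted mean contig coverage divided
#' by the total metagenome reads; with `normalize = TRUE` (default) values
#' are rescaled to sum to 1 across the sample's genomes, so the
#' transcription/abundance ratio is a fraction-over-fraction comparable to
#' the amplicon side.
#'
#' @param contigs data frame with `genome_id`, `length`, `mean_coverage`
#'   (one row per contig).
#' @param total_reads total reads in the metagenome (> 0).
#' @param normalize rescale across genomes (default TRUE).
#' @return data frame with `genome_id`, `raw_abundance`, `rel_abundance`.
#' @export
genomeRelativeAbundance <- function(contigs, total_reads, normalize = TRUE) {
  stopifnot(all(c("genome_id", "length", "mean_coverage") %in%
                  names(contigs)),
            all(contigs$length > 0), all(contigs$mean_coverage >= 0))
  if (total_reads <= 0) stop("total metagenome reads must be > 0")
  lw <- tapply(contigs$length * contigs$mean_coverage, contigs$genome_id,
               sum) / tapply(contigs$length, contigs$genome_id, sum)
  raw <- lw / total_reads
  out <- data.frame(genome_id = names(raw), raw_abundance = as.numeric(raw))
  out$rel_abundance <- if (normalize) out$raw_abundance /
    sum(out$raw_abundance) else out$raw_abundance
  out
}

#' Transcripts per million (TPM)
#'
#' `rate_i = count_i / (length_i / 1000)`;
#' `TPM_i = 1e6 * rate_i / sum(rate)`. Sums to one million by construction.
#'
#' @param orfs data frame with `orf_id`, `length` (bp) and `count`.
#' @return the input with a `tpm` column appended.
#' @export
orfTPM <- function(orfs) {
  stopifnot(all(c("orf_id", "length", "count") %in% names(orfs)),
            all(orfs$length >= 1), all(orfs$count >= 0))
  rate <- orfs$count / (orfs$length / 1000)
  if (sum(rate) == 0) stop("no mapped transcript reads (sum of rates is 0)")
  orfs$tpm <- 1e6 * rate / sum(rate)
  orfs
}

#' Genome relative transcription from summed TPM
#'
#' Sums the TPM of each genome's ORFs and divides by 1e6. ORFs not assigned
#' to any genome (`genome_id` NA) contribute to the TPM denominator but to
#' no genome, so the fractions sum to at most 1.
#'
#' @param tpm_table output of [orfTPM()] plus a `genome_id` column (NA for
#'   unbinned ORFs); each ORF may belong to at most one genome.
#' @return data frame with `genome_id` and `rel_transcription`.
#' @export
genomeRelativeTranscription <- function(tpm_table) {
  stopifnot(all(c("orf_id", "tpm", "genome_id") %in% names(tpm_table)))
  dup <- tpm_table$orf_id[duplicated(tpm_table$orf_id)]
  if (length(dup))
    stop("ORF claimed more than once: ", paste(unique(dup), collapse = ", "))
  binned <- tpm_table[!is.na(tpm_table$genome_id), ]
  frac <- tapply(binned$tpm, binned$genome_id, sum) / 1e6
  data.frame(genome_id = names(frac), rel_transcription = as.numeric(frac))
}

#' Transcription/abundance ratio per genome
#'
#' The genome-side analog of the rRNA/rDNA ratio. Genomes with zero
#' abundance but positive transcription are flagged (the genome analog of
#' phantom taxa) and excluded from ratio statistics.
#'
#' @param activity data frame with `genome_id`, `rel_abundance`,
#'   `rel_transcription`.
#' @return the input with `ratio` and logical `flagged` columns appended.
#' @export
transcriptionAbundanceRatio <- function(activity) {
  stopifnot(all(c("genome_id", "rel_abundance", "rel_transcription") %in%
                  names(activity)))
  flagged <- activity$rel_abundance == 0 & activity$rel_transcription > 0
  ratio <- ifelse(activity$rel_abundance > 0,
                  activity$rel_transcription / activity$rel_abundance,
                  NA_real_)
  activity$ratio <- ratio
  activity$flagged <- flagged
  activity
}

#' iRep replication-rate estimate from coverage windows
#'
#' Discards zero-coverage windows, sorts the remaining window coverages and
#' assigns each a normalized rank in `[0, 1]`, trims `trim_fraction` of the
#' windows from each end (ranks keep their pre-trim values, so the fit is
#' evaluated over the full `[0, 1]` range), and fits ordinary least squares
#' to `log2(coverage)` against rank. iRep is `2^(fit(1) - fit(0)) =
#' 2^slope`; all-equal coverages return exactly 1.
#'
#' @param coverage numeric vector of per-window coverages (or the data
#'   frame from [simulateGenomeCoverage()]).
#' @param trim_fraction fraction trimmed from each end after sorting
#'   (default 0.05).
#' @param min_windows minimum surviving windows (default 50).
#' @return list with `irep`, `r_squared`, `slope`, `n_windows`.
#' @export
irepEstimate <- function(coverage, trim_fraction = 0.05, min_windows = 50) {
  if (is.data.frame(coverage)) coverage <- coverage$coverage
  cov <- coverage[coverage > 0]
  if (length(cov) < min_windows)
    stop("fewer than ", min_windows, " non-zero coverage windows")
  cov <- sort(cov)
  x <- seq(0, 1, length.out = length(cov))
  n_trim <- floor(trim_fraction * length(cov))
  if (n_trim > 0) {
    keep <- (n_trim + 1):(length(cov) - n_trim)
    cov <- cov[keep]
    x <- x[keep]
  }
  n <- length(cov)
  if (diff(range(cov)) == 0)
    return(list(irep = 1, r_squared = NA_real_, slope = 0, n_windows = n))
  y <- log2(cov)
  fit <- lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(irep = 2^coef(fit)[["x"]],
       r_squared = r2,
       slope = coef(fit)[["x"]], n_windows = n)
}

#' iRep versus abundance pattern
#'
#' Pearson correlation between iRep and the transcription/abundance ratio,
#' plus counts of actively replicating genomes (iRep above
#' `irep_threshold`) above and below the relative-abundance threshold --
#' the high-replication-but-rare pattern.
#'
#' @param activity data frame with `genome_id`, `rel_abundance`, `ratio`,
#'   `irep`; >= 3 genomes with both metrics.
#' @param abundance_threshold relative abundance cut (default 0.01).
#' @param irep_threshold iRep above which a genome counts as actively
#'   replicating (default 1.5).
#' @return list with `rho`, `p_value` (NA when iRep is constant) and
#'   `quadrants` (high-iRep rare / high-iRep abundant counts).
#' @export
irepAbundancePattern <- function(activity, abundance_threshold = 0.01,
                                 irep_threshold = 1.5) {
  stopifnot(all(c("rel_abundance", "ratio", "irep") %in% names(activity)))
  ok <- complete.cases(activity[, c("irep", "ratio")])
  if (sum(ok) < 3) stop("fewer than 3 genomes with both metrics")
  a <- activity[ok, ]
  if (sd(a$irep) == 0 || sd(a$ratio) == 0) {
    rho <- NA_real_; pv <- NA_real_
  } else {
    ct <- cor.test(a$irep, a$ratio, method = "pearson")
    rho <- unname(ct$estimate); pv <- ct$p.value
  }
  high <- a$irep > irep_threshold
  list(rho = rho, p_value = pv,
       quadrants = c(
         high_irep_rare = sum(high & a$rel_abundance < abundance_threshold),
         high_irep_abundant =
           sum(high & a$rel_abundance >= abundance_threshold)))
}
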