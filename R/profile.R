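#' Build a paired rDNA/rRNA activity profile for one sample
#'
#' For every unit detected in either pool of the sample, computes the read
#' counts, the relative abundances over mapped reads per pool, the
#' rRNA/rDNA ratio, and the presence class: `shared` (both pools),
#' `phantom` (rRNA only; ratio undefined), or `dna_only` (rDNA only;
#' ratio 0, the dormant/dead signal). Units absent from both pools are
#' omitted.
#'
#' @param x a [UnitCountTable-class] containing columns `sample|rDNA` and
#'   `sample|rRNA`.
#' @param sample sample name.
#' @return data frame with one row per detected unit: `unit_id`,
#'   `rdna_count`, `rrna_count`, `rel_rdna`, `rel_rrna`, `ratio`,
#'   `presence_class`; the sample name is attached as an attribute.
#' @examples
#' ## see vignette("activity-ratios") for a full pipeline example
#' @export
buildPairedProfile <- function(x, sample) {
  stopifnot(is(x, "UnitCountTable"))
  dcol <- paste0(sample, "|rDNA")
  rcol <- paste0(sample, "|rRNA")
  if (!all(c(dcol, rcol) %in% colnames(x)))
    stop("sample '", sample, "' does not have both pools in the table")
  counts <- unitCounts(x)
  d <- counts[, dcol]
  r <- counts[, rcol]
  if (sum(d) == 0 || sum(r) == 0)
    stop("sample '", sample, "' has a pool with zero mapped reads")
  keep <- d > 0 | r > 0
  d <- d[keep]; r <- r[keep]
  rel_d <- d / sum(counts[, dcol])
  rel_r <- r / sum(counts[, rcol])
  class <- ifelse(d > 0 & r > 0, "shared",
                  ifelse(d == 0, "phantom", "dna_only"))
  ratio <- ifelse(class == "phantom", NA_real_,
                  ifelse(class == "dna_only", 0, rel_r / rel_d))
  out <- data.frame(unit_id = rownames(counts)[keep],
                    rdna_count = as.integer(d), rrna_count = as.integer(r),
                    rel_rdna = rel_d, rel_rrna = rel_r, ratio = ratio,
                    presence_class = class, row.names = NULL)
  attr(out, "sample") <- sample
  attr(out, "method") <- unitMethod(x)
  out
}

.as_profile_list <- function(profiles) {
  if (is.data.frame(profiles)) list(profiles) else profiles
}

#' Overlap summary: shared, phantom and DNA-only units
#'
#' Counts units in each presence class and the fraction of each pool's
#' mapped reads falling in each class; with several profiles, also reports
#' the cross-sample aggregate phantom unit proportion (the headline
#' phantom-rate comparison between unit-formation methods).
#'
#' @param profiles one profile from [buildPairedProfile()] or a list of
#'   them.
#' @return list with `per_sample` (data frame: n_shared, n_phantom,
#'   n_dna_only, read fractions per pool and class) and
#'   `aggregate_phantom_fraction` (phantom units / detected units pooled
#'   over samples).
#' @export
overlapSummary <- function(profiles) {
  profiles <- .as_profile_list(profiles)
  rows <- lapply(profiles, function(p) {
    cls <- factor(p$presence_class,
                  levels = c("shared", "phantom", "dna_only"))
    nn <- table(cls)
    rd <- tapply(p$rel_rdna, cls, sum, default = 0)
    rr <- tapply(p$rel_rrna, cls, sum, default = 0)
    data.frame(sample = attr(p, "sample") %||% NA_character_,
               n_shared = as.integer(nn["shared"]),
               n_phantom = as.integer(nn["phantom"]),
               n_dna_only = as.integer(nn["dna_only"]),
               rdna_frac_shared = rd[["shared"]],
               rdna_frac_dna_only = rd[["dna_only"]],
               rrna_frac_shared = rr[["shared"]],
               rrna_frac_phantom = rr[["phantom"]])
  })
  per_sample <- do.call(rbind, rows)
  list(per_sample = per_sample,
       aggregate_phantom_fraction =
         sum(per_sample$n_phantom) /
         sum(per_sample$n_shared + per_sample$n_phantom +
             per_sample$n_dna_only))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative production and its cumulative curve by abundance rank
#'
#' Production of a unit is its relative contribution to the sample's total
#' rRNA (`rel_rrna`); for genomes, its relative transcription. The
#' cumulative curve orders units by decreasing relative rDNA abundance
#' (phantom units, with zero rDNA, rank last) and accumulates production.
#'
#' @param x a profile from [buildPairedProfile()], or a genome activity
#'   data frame with `rel_abundance` and `rel_transcription` columns.
#' @param k top-k summary size (default 10).
#' @return data frame ordered by abundance rank with `unit_id`,
#'   `abundance`, `production` and `cumulative`;
#'   `attr(, "top_k_fraction")` is the production captured by the `k` most
#'   abundant units.
#' @export
relativeProduction <- function(x, k = 10) {
  stopifnot(is.data.frame(x), nrow(x) >= 1)
  if ("rel_rrna" %in% names(x)) {
    ab <- x$rel_rdna; pr <- x$rel_rrna; id <- x$unit_id
  } else if ("rel_transcription" %in% names(x)) {
    ab <- x$rel_abundance; pr <- x$rel_transcription; id <- x$genome_id
  } else stop("unrecognized input columns")
  ord <- order(-ab, id)
  out <- data.frame(unit_id = id[ord], abundance = ab[ord],
                    production = pr[ord],
                    cumulative = cumsum(pr[ord]) / sum(pr))
  attr(out, "top_k_fraction") <- out$cumulative[min(k, nrow(out))]
  out
}

#' Log-log correlation between rRNA and rDNA relative abundances
#'
#' Pearson correlation of `log10(rel_rrna)` against `log10(rel_rdna)` over
#' shared units (zeros are excluded by the restriction to shared units),
#' with the two-sided p-value from the t transform.
#'
#' @param profile a profile from [buildPairedProfile()].
#' @return list with `rho`, `p_value` and `n`.
#' @export
logLogCorrelation <- function(profile) {
  sh <- profile[profile$presence_class == "shared", ]
  if (nrow(sh) < 3) stop("fewer than 3 shared units")
  ct <- cor.test(log10(sh$rel_rrna), log10(sh$rel_rdna),
                 method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(sh))
}

#' Rare-but-active quadrant summary
#'
#' Splits shared units by a relative-abundance threshold (default 1%) and a
#' ratio threshold (default 1), and reports the fraction of active
#' (ratio > threshold) units that are rare (abundance < threshold) -- the
#' headline pattern that the most active taxa tend to be the least
#' abundant.
#'
#' @param profile a profile from [buildPairedProfile()].
#' @param abundance_threshold relative rDNA abundance cut (default 0.01).
#' @param ratio_threshold rRNA/rDNA ratio cut (default 1.0).
#' @return list with quadrant counts (`rare_active`, `abundant_active`,
#'   `rare_inactive`, `abundant_inactive`) and `fraction_rare_among_active`
#'   (NA when no unit is active).
#' @export
rareActiveSummary <- function(profile, abundance_threshold = 0.01,
                              ratio_threshold = 1.0) {
  sh <- profile[profile$presence_class == "shared", ]
  rare <- sh$rel_rdna < abundance_threshold
  active <- sh$ratio > ratio_threshold
  counts <- c(rare_active = sum(rare & active),
              abundant_active = sum(!rare & active),
              rare_inactive = sum(rare & !active),
              abundant_inactive = sum(!rare & !active))
  frac <- if (sum(active) == 0) NA_real_
          else counts[["rare_active"]] / sum(active)
  c(as.list(counts), list(fraction_rare_among_active = frac))
}

#' Pooled rRNA/rDNA ratio distribution statistics
#'
#' Pools units with a defined ratio over samples and reports mean, SD,
#' range and the fraction of ratios below 1, both excluding and including
#' `dna_only` units (which carry ratio 0). Phantom units (undefined ratio)
#' are excluded and counted separately.
#'
#' @param profiles one profile or a list of profiles.
#' @return data frame with rows `shared_only` and `with_dna_only`; columns
#'   `mean`, `sd`, `min`, `max`, `fraction_below_1`, `n`;
#'   `attr(, "n_phantom")` counts excluded phantom units.
#' @export
ratioDistributionStats <- function(profiles) {
  profiles <- .as_profile_list(profiles)
  all <- do.call(rbind, lapply(profiles, function(p)
    p[, c("ratio", "presence_class")]))
  phantom <- sum(all$presence_class == "phantom")
  stats_of <- function(r) data.frame(
    mean = mean(r), sd = if (length(r) > 1) sd(r) else 0,
    min = min(r), max = max(r),
    fraction_below_1 = mean(r < 1), n = length(r))
  sh <- all$ratio[all$presence_class == "shared"]
  wd <- all$ratio[all$presence_class != "phantom"]
  out <- rbind(shared_only = stats_of(sh), with_dna_only = stats_of(wd))
  attr(out, "n_phantom") <- phantom
  out
}
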