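#' Construct a [UnitCountTable-class] from a plain count matrix
#'
#' Column names must follow the `"sample|pool"` convention with pool one of
#' `rDNA`, `rRNA` or `control`.
#'
#' @param counts non-negative integer matrix, units x sample/pool columns,
#'   with unit ids as row names.
#' @param representatives optional representative sequences (named by unit
#'   id, or in row order).
#' @param method `"OTU"` or `"ZOTU"`.
#' @param unassigned optional per-column unassigned read counts.
#' @return a [UnitCountTable-class].
#' @examples
#' m <- matrix(c(90, 10, 0, 50, 25, 25), ncol = 2,
#'             dimnames = list(paste0("u", 1:3), c("S1|rDNA", "S1|rRNA")))
#' unitCountTable(m)
#' @export
unitCountTable <- function(counts, representatives = NULL,
                           method = c("ZOTU", "OTU"), unassigned = NULL) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (is.null(representatives))
    representatives <- setNames(rep("", nrow(counts)), rownames(counts))
  if (is.null(names(representatives)))
    names(representatives) <- rownames(counts)
  if (is.null(unassigned))
    unassigned <- setNames(integer(ncol(counts)), colnames(counts))
  units <- new("TaxonUnitSet", method = method, unit_ids = rownames(counts),
               representatives = Biostrings::DNAStringSet(
                 as.character(representatives)),
               sizes = as.integer(rowSums(counts)),
               total_sizes = as.integer(rowSums(counts)),
               members = rep(list(NULL), nrow(counts)))
  .unit_count_table(counts, units, unassigned)
}

#' Read a unit count table from TSV
#'
#' Inverse of [writeCountTable()]: first column `unit_id`, remaining
#' columns named `sample|pool`.
#'
#' @param path file path.
#' @param method `"OTU"` or `"ZOTU"`.
#' @return a [UnitCountTable-class].
#' @export
readCountTable <- function(path, method = c("ZOTU", "OTU")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  unitCountTable(m, method = match.arg(method))
}

#' Sample paired read sets for several samples of one community
#'
#' Draws `n_samples` independent paired (rDNA, rRNA) read sets from the
#' same community, quality-filters them, and returns the named list
#' expected by [dereplicate()] and [mapReadsToUnits()]. Per-sample seeds
#' are derived deterministically from `base_seed`.
#'
#' @param community a [TrueCommunity-class].
#' @param scenario the [SimScenario-class] providing depths and error
#'   rates.
#' @param n_samples number of samples (default 5).
#' @param base_seed integer seed root (default `scenario@seed`).
#' @return named list of filtered read sets (`"S<i>|rDNA"`,
#'   `"S<i>|rRNA"`).
#' @export
simulatePairedReadSets <- function(community, scenario, n_samples = 5,
                                   base_seed = NULL) {
  if (is.null(base_seed)) base_seed <- scenario@seed
  min_len <- min(230, scenario@seq_len)
  reads <- list()
  for (s in seq_len(n_samples)) {
    reads[[sprintf("S%d|rDNA", s)]] <- qualityFilter(
      sampleAmpliconReads(community, scenario, "rDNA",
                          seed = base_seed + 1000L * s + 1L),
      min_len = min_len)
    reads[[sprintf("S%d|rRNA", s)]] <- qualityFilter(
      sampleAmpliconReads(community, scenario, "rRNA",
                          seed = base_seed + 1000L * s + 2L),
      min_len = min_len)
  }
  reads
}

#' Run the paired-pool pipeline from a community to activity profiles
#'
#' Convenience wrapper chaining [sampleAmpliconReads()], [qualityFilter()],
#' [dereplicate()], unit formation ([denoiseZOTUs()] or [clusterOTUs()]),
#' [mapReadsToUnits()] and [buildPairedProfile()] for a single sample with
#' both pools.
#'
#' @param community a [TrueCommunity-class].
#' @param scenario the [SimScenario-class] used to sample reads.
#' @param method `"ZOTU"` or `"OTU"`.
#' @param sample sample name (default `"S1"`).
#' @param minsize minimum abundance for unit formation (default 8).
#' @return list with `profile`, `units`, `table`, `uniques` and the
#'   filtered read sets.
#' @export
runActivityPipeline <- function(community, scenario,
                                method = c("ZOTU", "OTU"),
                                sample = "S1", minsize = 8) {
  method <- match.arg(method)
  reads <- list(
    qualityFilter(sampleAmpliconReads(community, scenario, "rDNA"),
                  min_len = min(230, scenario@seq_len)),
    qualityFilter(sampleAmpliconReads(community, scenario, "rRNA"),
                  min_len = min(230, scenario@seq_len)))
  names(reads) <- paste0(sample, c("|rDNA", "|rRNA"))
  uniques <- dereplicate(reads)
  units <- if (method == "ZOTU") denoiseZOTUs(uniques, minsize = minsize)
           else clusterOTUs(uniques, minsize = minsize)
  tab <- mapReadsToUnits(reads, units)
  list(profile = buildPairedProfile(tab, sample), units = units,
       table = tab, uniques = uniques, reads = reads)
}
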