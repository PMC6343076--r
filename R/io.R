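#' Read and write amplicon FASTQ (Phred+33)
#'
#' Thin wrappers over Biostrings keeping qualities attached.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path file path.
#' @return `readAmpliconFastq` returns a `QualityScaledDNAStringSet`;
#'   `writeAmpliconFastq` returns the path invisibly.
#' @name fastq-io
NULL

#' @rdname fastq-io
#' @export
writeAmpliconFastq <- function(reads, path) {
  S4Vectors::mcols(reads) <- NULL
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' @rdname fastq-io
#' @export
readAmpliconFastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Write unit representatives as FASTA
#'
#' Headers follow the `>unitID;size=N` convention with the unit total size.
#'
#' @param units a [TaxonUnitSet-class].
#' @param path file path.
#' @export
writeUnitFasta <- function(units, path) {
  reps <- unitRepresentatives(units)
  names(reps) <- sprintf("%s;size=%d", unitIds(units),
                         unname(unitTotalSizes(units)))
  Biostrings::writeXStringSet(reps, path)
  invisible(path)
}

#' Write / read a unit count table as TSV
#'
#' The table is units x sample/pool columns (column names `sample|pool`); a
#' sidecar `<path>.mapping.tsv` records per-column unassigned reads.
#'
#' @param x a [UnitCountTable-class].
#' @param path file path.
#' @export
writeCountTable <- function(x, path) {
  counts <- unitCounts(x)
  df <- data.frame(unit_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ua <- unassignedReads(x)
  utils::write.table(
    data.frame(column = names(ua), mapped = colSums(counts),
               unassigned = as.integer(ua)),
    paste0(path, ".mapping.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth community tables
#'
#' Emits a TSV of `taxon_id`, `abundance`, `activity`, `copy_number`, the
#' reference FASTA, and the true tree in newick.
#'
#' @param community a [TrueCommunity-class].
#' @param prefix path prefix; files `<prefix>.truth.tsv`,
#'   `<prefix>.refs.fasta` and `<prefix>.tree.nwk` are written.
#' @export
writeCommunityTruth <- function(community, prefix) {
  utils::write.table(
    data.frame(taxon_id = taxonIds(community),
               abundance = unname(abundances(community)),
               activity = unname(activities(community)),
               copy_number = unname(copyNumbers(community))),
    paste0(prefix, ".truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  Biostrings::writeXStringSet(references(community),
                              paste0(prefix, ".refs.fasta"))
  ape::write.tree(trueTree(community), paste0(prefix, ".tree.nwk"))
  invisible(prefix)
}

#' Read / write a simulation scenario as YAML
#'
#' @param scenario a [SimScenario-class].
#' @param path file path.
#' @return `readScenario` returns a validated [SimScenario-class].
#' @name scenario-io
NULL

#' @rdname scenario-io
#' @export
writeScenario <- function(scenario, path) {
  stopifnot(is(scenario, "SimScenario"))
  fields <- c("n_taxa", "seq_len", "mean_divergence", "abundance_sigma",
              "activity_model", "activity_sigma", "depth_rdna",
              "depth_rrna", "sub_error_rate", "rt_error_rate",
              "indel_rate", "phred_quality", "seed")
  vals <- lapply(fields, function(f) slot(scenario, f))
  names(vals) <- fields
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname scenario-io
#' @export
readScenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simScenario, vals)
}

#' Write a square distance matrix as TSV
#'
#' @param D symmetric matrix with sample ids as dimnames.
#' @param path file path.
#' @export
writeDistanceMatrix <- function(D, path) {
  D <- as.matrix(D)
  utils::write.table(data.frame(sample = rownames(D), D,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
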