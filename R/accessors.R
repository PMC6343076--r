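#' @name accessors
#' @title Accessors for RiboRatio classes
#' @param x an object.
#' @param object an object (for `show`).
#' @description Small accessor layer so downstream code never touches slots.
NULL

#' @rdname accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))
#' @rdname accessors
#' @export
setMethod("taxonIds", "TrueCommunity", function(x) x@taxon_ids)

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "TrueCommunity",
          function(x) setNames(x@abundances, x@taxon_ids))

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))
#' @rdname accessors
#' @export
setMethod("activities", "TrueCommunity",
          function(x) setNames(x@activities, x@taxon_ids))

#' @rdname accessors
#' @export
setGeneric("copyNumbers", function(x) standardGeneric("copyNumbers"))
#' @rdname accessors
#' @export
setMethod("copyNumbers", "TrueCommunity",
          function(x) setNames(x@copy_numbers, x@taxon_ids))

#' @rdname accessors
#' @export
setGeneric("references", function(x) standardGeneric("references"))
#' @rdname accessors
#' @export
setMethod("references", "TrueCommunity", function(x) x@references)

#' @rdname accessors
#' @export
setGeneric("trueTree", function(x) standardGeneric("trueTree"))
#' @rdname accessors
#' @export
setMethod("trueTree", "TrueCommunity", function(x) x@tree)

#' @rdname accessors
#' @export
setGeneric("uniqueSeqs", function(x) standardGeneric("uniqueSeqs"))
#' @rdname accessors
#' @export
setMethod("uniqueSeqs", "UniqueSequences", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("uniqueSizes", function(x) standardGeneric("uniqueSizes"))
#' @rdname accessors
#' @export
setMethod("uniqueSizes", "UniqueSequences",
          function(x) setNames(x@sizes, x@sequences))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "UniqueSequences", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("unitMethod", function(x) standardGeneric("unitMethod"))
#' @rdname accessors
#' @export
setMethod("unitMethod", "TaxonUnitSet", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("unitMethod", "UnitCountTable",
          function(x) S4Vectors::metadata(x)$method)

#' @rdname accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))
#' @rdname accessors
#' @export
setMethod("unitIds", "TaxonUnitSet", function(x) x@unit_ids)
#' @rdname accessors
#' @export
setMethod("unitIds", "UnitCountTable", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("unitRepresentatives",
           function(x) standardGeneric("unitRepresentatives"))
#' @rdname accessors
#' @export
setMethod("unitRepresentatives", "TaxonUnitSet", function(x) x@representatives)

#' @rdname accessors
#' @export
setGeneric("unitSizes", function(x) standardGeneric("unitSizes"))
#' @rdname accessors
#' @export
setMethod("unitSizes", "TaxonUnitSet",
          function(x) setNames(x@sizes, x@unit_ids))

#' @rdname accessors
#' @export
setGeneric("unitTotalSizes", function(x) standardGeneric("unitTotalSizes"))
#' @rdname accessors
#' @export
setMethod("unitTotalSizes", "TaxonUnitSet",
          function(x) setNames(x@total_sizes, x@unit_ids))

#' @rdname accessors
#' @export
setGeneric("unitMembers", function(x) standardGeneric("unitMembers"))
#' @rdname accessors
#' @export
setMethod("unitMembers", "TaxonUnitSet",
          function(x) setNames(x@members, x@unit_ids))

#' @rdname accessors
#' @export
setGeneric("unitCounts", function(x) standardGeneric("unitCounts"))
#' @rdname accessors
#' @export
setMethod("unitCounts", "UnitCountTable",
          function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("unassignedReads", function(x) standardGeneric("unassignedReads"))
#' @rdname accessors
#' @export
setMethod("unassignedReads", "UnitCountTable",
          function(x) S4Vectors::metadata(x)$unassigned)

#' @rdname accessors
#' @export
setMethod("show", "SimScenario", function(object) {
  cat("SimScenario:", object@n_taxa, "taxa,", object@seq_len, "bp,",
      "model", object@activity_model, "\n")
  cat("  depths rDNA/rRNA:", object@depth_rdna, "/", object@depth_rrna,
      " sub/rt error:", signif(object@sub_error_rate, 3), "/",
      signif(object@rt_error_rate, 3), " seed:", object@seed, "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "TrueCommunity", function(object) {
  cat("TrueCommunity with", length(object@taxon_ids), "taxa\n")
  cat("  abundance range:", signif(range(object@abundances), 3), "\n")
  cat("  activity range:", signif(range(object@activities), 3), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "UniqueSequences", function(object) {
  cat("UniqueSequences:", length(object@sequences), "uniques,",
      sum(object@sizes), "reads,", ncol(object@provenance), "columns\n")
})

#' @rdname accessors
#' @export
setMethod("show", "TaxonUnitSet", function(object) {
  cat("TaxonUnitSet (", object@method, "): ", length(object@unit_ids),
      " units, total size ", sum(object@total_sizes), "\n", sep = "")
})
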