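setOldClass("phylo")

#' Simulation scenario for a paired rDNA/rRNA amplicon experiment
#'
#' Parameter container for the synthetic-community generator. The defaults
#' describe a moderately uneven community of 150 taxa sequenced at 5e4 reads
#' per pool with error rates matching published estimates for Taq polymerase
#' (~1/20,000 per base, the mid-range of 1/10,000--1/50,000) and reverse
#' transcriptase (~1/15,000 per base, applied to rRNA reads on top of the
#' PCR/sequencing rate).
#'
#' @slot n_taxa number of taxa in the community (>= 2).
#' @slot seq_len reference/amplicon length in bases (>= 150).
#' @slot mean_divergence target mean pairwise divergence of the reference
#'   sequences (substitutions per site, in `[0, 0.3)`).
#' @slot abundance_sigma lognormal sigma of cell abundances.
#' @slot activity_model `"independent"` or `"kill_the_winner"` (activity
#'   anti-ranked against abundance).
#' @slot activity_sigma lognormal sigma of per-cell ribosomal amplification
#'   factors.
#' @slot depth_rdna,depth_rrna read depth per pool (>= 0).
#' @slot sub_error_rate per-base substitution error rate applied to every
#'   read (PCR + sequencing), in `[0, 0.1]`.
#' @slot rt_error_rate additional per-base rate applied to rRNA reads only
#'   (reverse transcription), in `[0, 0.1]`.
#' @slot indel_rate per-base indel rate (default 0; substitution-only model).
#' @slot phred_quality constant Phred score written to simulated FASTQ.
#' @slot seed integer seed fixing all stochastic output bit-for-bit.
#' @seealso [simScenario()], [simulateCommunity()]
#' @export
setClass("SimScenario", representation(
  n_taxa = "integer", seq_len = "integer", mean_divergence = "numeric",
  abundance_sigma = "numeric", activity_model = "character",
  activity_sigma = "numeric", depth_rdna = "integer", depth_rrna = "integer",
  sub_error_rate = "numeric", rt_error_rate = "numeric",
  indel_rate = "numeric", phred_quality = "integer", seed = "integer"))

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@n_taxa < 2L) msg <- c(msg, "n_taxa must be >= 2")
  if (object@seq_len < 150L) msg <- c(msg, "seq_len must be >= 150")
  if (object@mean_divergence < 0 || object@mean_divergence >= 0.3)
    msg <- c(msg, "mean_divergence must be in [0, 0.3)")
  if (!object@activity_model %in% c("independent", "kill_the_winner"))
    msg <- c(msg, "activity_model must be 'independent' or 'kill_the_winner'")
  for (s in c("sub_error_rate", "rt_error_rate", "indel_rate")) {
    v <- slot(object, s)
    if (v < 0 || v > 0.1) msg <- c(msg, paste(s, "must be in [0, 0.1]"))
  }
  if (object@abundance_sigma < 0 || object@activity_sigma < 0)
    msg <- c(msg, "sigmas must be >= 0")
  if (object@depth_rdna < 0L || object@depth_rrna < 0L)
    msg <- c(msg, "depths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimScenario-class]
#'
#' @param n_taxa,seq_len,mean_divergence,abundance_sigma,activity_model
#'   see the class documentation.
#' @param activity_sigma,depth_rdna,depth_rrna,sub_error_rate,rt_error_rate
#'   see the class documentation.
#' @param indel_rate,phred_quality,seed see the class documentation.
#' @return a validated `SimScenario`.
#' @examples
#' sc <- simScenario(n_taxa = 20, depth_rdna = 1000, depth_rrna = 1000)
#' sc
#' @export
simScenario <- function(n_taxa = 150, seq_len = 250, mean_divergence = 0.05,
                        abundance_sigma = 1.5,
                        activity_model = c("independent", "kill_the_winner"),
                        activity_sigma = 1.0,
                        depth_rdna = 50000, depth_rrna = 50000,
                        sub_error_rate = 1 / 20000,
                        rt_error_rate = 1 / 15000,
                        indel_rate = 0, phred_quality = 30, seed = 1) {
  activity_model <- match.arg(activity_model)
  new("SimScenario", n_taxa = as.integer(n_taxa),
      seq_len = as.integer(seq_len), mean_divergence = mean_divergence,
      abundance_sigma = abundance_sigma, activity_model = activity_model,
      activity_sigma = activity_sigma, depth_rdna = as.integer(depth_rdna),
      depth_rrna = as.integer(depth_rrna), sub_error_rate = sub_error_rate,
      rt_error_rate = rt_error_rate, indel_rate = indel_rate,
      phred_quality = as.integer(phred_quality), seed = as.integer(seed))
}

#' Ground-truth community
#'
#' Holds the latent state of a simulated community: cell abundances `p_t`,
#' per-cell ribosomal amplification factors `a_t`, 16S copy numbers `c_t`,
#' one reference sequence per taxon, and the true rooted phylogeny.
#'
#' @slot taxon_ids character identifiers, one per taxon.
#' @slot abundances probability vector `p_t` (sums to 1).
#' @slot activities positive vector `a_t`.
#' @slot copy_numbers positive integer vector `c_t` (default all 1).
#' @slot references [Biostrings::DNAStringSet] named by taxon id, pairwise
#'   distinct.
#' @slot tree rooted `phylo` with tip labels equal to the taxon ids.
#' @seealso [simulateCommunity()], [expectedPoolFractions()]
#' @export
setClass("TrueCommunity", representation(
  taxon_ids = "character", abundances = "numeric", activities = "numeric",
  copy_numbers = "integer", references = "DNAStringSet", tree = "phylo"))

setValidity("TrueCommunity", function(object) {
  msg <- character()
  n <- length(object@taxon_ids)
  if (length(object@abundances) != n || length(object@activities) != n ||
      length(object@copy_numbers) != n || length(object@references) != n)
    msg <- c(msg, "field lengths disagree")
  if (abs(sum(object@abundances) - 1) > 1e-12)
    msg <- c(msg, "abundances must sum to 1")
  if (any(object@activities <= 0)) msg <- c(msg, "activities must be > 0")
  if (any(object@copy_numbers < 1L)) msg <- c(msg, "copy_numbers must be >= 1")
  if (anyDuplicated(as.character(object@references)))
    msg <- c(msg, "reference sequences must be pairwise distinct")
  if (!setequal(object@tree$tip.label, object@taxon_ids) ||
      length(object@tree$tip.label) != n)
    msg <- c(msg, "tree tips must match taxon_ids exactly")
  if (length(msg)) msg else TRUE
})

#' Genome-level ground truth for coverage and transcription simulation
#'
#' @slot genome_length genome length in bp.
#' @slot window non-overlapping coverage window size in bp; must divide
#'   `genome_length` into at least 50 windows.
#' @slot true_irep true origin-to-terminus read-density ratio (>= 1).
#' @slot mean_coverage mean per-window coverage.
#' @slot read_length read length in bp used to convert between read counts
#'   and per-base depth (default 250).
#' @slot orf_lengths ORF lengths in bp (each >= 100).
#' @slot orf_weights transcription propensities (normalizable).
#' @slot seed integer seed.
#' @seealso [simulateGenomeCoverage()], [simulateOrfTranscripts()]
#' @export
setClass("GenomeTruth", representation(
  genome_length = "integer", window = "integer", true_irep = "numeric",
  mean_coverage = "numeric", read_length = "integer",
  orf_lengths = "integer", orf_weights = "numeric", seed = "integer"))

setValidity("GenomeTruth", function(object) {
  msg <- character()
  if (object@true_irep < 1) msg <- c(msg, "true_irep must be >= 1")
  if (object@mean_coverage < 0) msg <- c(msg, "mean_coverage must be >= 0")
  if (length(object@orf_lengths) && any(object@orf_lengths < 100L))
    msg <- c(msg, "orf_lengths must be >= 100")
  if (length(object@orf_weights) &&
      (any(object@orf_weights < 0) || sum(object@orf_weights) <= 0))
    msg <- c(msg, "orf_weights must be non-negative with positive sum")
  if (length(object@orf_weights) != length(object@orf_lengths))
    msg <- c(msg, "orf_weights and orf_lengths lengths disagree")
  if (length(msg)) msg else TRUE
})

#' Construct a [GenomeTruth-class]
#'
#' @param genome_length,window,true_irep,mean_coverage,read_length,orf_lengths,orf_weights,seed
#'   see the class documentation.
#' @return a validated `GenomeTruth`.
#' @export
genomeTruth <- function(genome_length = 2e6, window = 5000, true_irep = 1.5,
                        mean_coverage = 20, read_length = 250,
                        orf_lengths = integer(),
                        orf_weights = numeric(), seed = 1) {
  new("GenomeTruth", genome_length = as.integer(genome_length),
      window = as.integer(window), true_irep = true_irep,
      mean_coverage = mean_coverage, read_length = as.integer(read_length),
      orf_lengths = as.integer(orf_lengths),
      orf_weights = as.numeric(orf_weights), seed = as.integer(seed))
}

#' Dereplicated unique sequences with per-sample/pool provenance
#'
#' @slot sequences unique read sequences, sorted by decreasing pooled size,
#'   ties broken lexicographically.
#' @slot sizes pooled read count per unique sequence.
#' @slot provenance integer matrix (uniques x sample/pool columns); row sums
#'   equal `sizes`.
#' @seealso [dereplicate()]
#' @export
setClass("UniqueSequences", representation(
  sequences = "character", sizes = "integer", provenance = "matrix"))

setValidity("UniqueSequences", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@sizes) ||
      nrow(object@provenance) != length(object@sizes))
    msg <- c(msg, "field lengths disagree")
  if (any(object@sizes < 1L)) msg <- c(msg, "sizes must be >= 1")
  if (length(object@sizes) &&
      !all(rowSums(object@provenance) == object@sizes))
    msg <- c(msg, "sizes must equal provenance row sums")
  if (is.unsorted(rev(object@sizes)))
    msg <- c(msg, "uniques must be sorted by decreasing size")
  if (length(msg)) msg else TRUE
})

#' A set of taxonomic units (OTUs or ZOTUs)
#'
#' @slot method `"OTU"` or `"ZOTU"`.
#' @slot unit_ids unique identifiers.
#' @slot representatives [Biostrings::DNAStringSet] named by unit id; each
#'   representative is the most abundant member sequence of its unit.
#' @slot sizes founding unique-sequence size per unit.
#' @slot total_sizes pooled size including merged/member uniques.
#' @slot members list (per unit) of data frames with member `sequence` and
#'   `size`.
#' @seealso [clusterOTUs()], [denoiseZOTUs()]
#' @export
setClass("TaxonUnitSet", representation(
  method = "character", unit_ids = "character",
  representatives = "DNAStringSet", sizes = "integer",
  total_sizes = "integer", members = "list"))

setValidity("TaxonUnitSet", function(object) {
  msg <- character()
  if (!object@method %in% c("OTU", "ZOTU"))
    msg <- c(msg, "method must be 'OTU' or 'ZOTU'")
  if (anyDuplicated(object@unit_ids)) msg <- c(msg, "unit_ids must be unique")
  n <- length(object@unit_ids)
  if (length(object@representatives) != n || length(object@sizes) != n ||
      length(object@total_sizes) != n || length(object@members) != n)
    msg <- c(msg, "field lengths disagree")
  if (length(msg)) msg else TRUE
})

#' Per-unit read counts over (sample, pool) columns
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] with a
#' `counts` assay (units x sample/pool columns), `colData` columns `sample`
#' and `pool` (`"rDNA"`/`"rRNA"`), the unit representative sequence in
#' `rowData`, and per-column unassigned-read diagnostics in `metadata`.
#'
#' @seealso [mapReadsToUnits()], [removeContaminants()],
#'   [buildPairedProfile()]
#' @export
setClass("UnitCountTable", contains = "SummarizedExperiment")

setValidity("UnitCountTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must carry a 'counts' assay")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "counts must be >= 0")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample", "pool") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'sample' and 'pool'")
  else if (!all(cd$pool %in% c("rDNA", "rRNA", "control")))
    msg <- c(msg, "pool must be one of rDNA, rRNA, control")
  if (length(msg)) msg else TRUE
})
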