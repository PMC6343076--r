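#' Expected-error quality filter
#'
#' Retains reads with length >= `min_len` and expected number of errors
#' `sum(10^(-Q/10)) <= max_expected_error` over the Phred qualities
#' (the fastq_filter rule). Order is preserved and the retained
#' fraction is attached as an attribute.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (Phred+33).
#' @param min_len minimum read length (default 230).
#' @param max_expected_error maximum expected errors per read (default 1.0).
#' @return the retained reads, with `attr(, "retained_fraction")`.
#' @examples
#' sc <- simScenario(n_taxa = 5, depth_rdna = 50, depth_rrna = 50,
#'                   seq_len = 250)
#' com <- simulateCommunity(sc)
#' fq <- qualityFilter(sampleAmpliconReads(com, sc, "rDNA"))
#' attr(fq, "retained_fraction")
#' @export
qualityFilter <- function(reads, min_len = 230, max_expected_error = 1.0) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  if (length(reads) == 0L) {
    out <- reads
    attr(out, "retained_fraction") <- NA_real_
    return(out)
  }
  ## expected errors per unique quality string (simulated and real runs
  ## repeat quality strings heavily; this avoids a per-read decode)
  qs <- as.character(Biostrings::quality(reads))
  uq <- unique(qs)
  ee_uq <- vapply(uq, function(s) sum(10^(-(utf8ToInt(s) - 33L) / 10)),
                  numeric(1))
  ee <- ee_uq[match(qs, uq)]
  keep <- Biostrings::width(reads) >= min_len & ee <= max_expected_error
  out <- reads[keep]
  attr(out, "retained_fraction") <- mean(keep)
  out
}

.as_char_reads <- function(x) {
  if (is.character(x)) x else as.character(x)
}

#' Dereplicate reads into unique sequences with provenance
#'
#' Pools reads across all (sample, pool) read sets, collapses exact
#' full-length duplicates, and sorts by decreasing pooled size with ties
#' broken lexicographically by sequence. Per-column counts are preserved as
#' provenance.
#'
#' @param read_sets a named list of read sets (names `"sample|pool"`, e.g.
#'   `"S1|rDNA"`), each a `QualityScaledDNAStringSet`, `DNAStringSet` or
#'   character vector; or a single read set (treated as one column
#'   `"S1|rDNA"`).
#' @return a [UniqueSequences-class].
#' @export
dereplicate <- function(read_sets) {
  if (!is.list(read_sets)) read_sets <- list(`S1|rDNA` = read_sets)
  stopifnot(length(read_sets) >= 1, !is.null(names(read_sets)))
  cols <- lapply(read_sets, .as_char_reads)
  all_seq <- unlist(cols, use.names = FALSE)
  if (length(all_seq) == 0L)
    return(new("UniqueSequences", sequences = character(),
               sizes = integer(),
               provenance = matrix(0L, 0, length(cols),
                                   dimnames = list(NULL, names(cols)))))
  uniq <- unique(all_seq)
  prov <- vapply(cols, function(s)
    as.integer(table(factor(s, levels = uniq))), integer(length(uniq)))
  prov <- matrix(prov, nrow = length(uniq),
                 dimnames = list(NULL, names(cols)))
  sizes <- as.integer(rowSums(prov))
  ord <- order(-sizes, uniq)
  new("UniqueSequences", sequences = uniq[ord], sizes = sizes[ord],
      provenance = prov[ord, , drop = FALSE])
}

#' Greedy 97% identity OTU clustering
#'
#' Scans dereplicated uniques in decreasing-abundance order. A unique joins
#' the best existing centroid with identity >= `identity_threshold`
#' (best = highest identity; ties to the centroid with the larger founding
#' size, then the earlier centroid). Otherwise it founds a new centroid if
#' its size >= `minsize`; smaller uniques are discarded from centroid
#' formation (they can still be recruited by [mapReadsToUnits()]).
#' Centroids are pairwise below the threshold by construction.
#'
#' @param uniques a [UniqueSequences-class] as emitted by [dereplicate()].
#' @param identity_threshold minimum identity to join a centroid
#'   (default 0.97).
#' @param minsize minimum unique size to found a centroid (default 8).
#' @return a [TaxonUnitSet-class] with `method = "OTU"`.
#' @export
clusterOTUs <- function(uniques, identity_threshold = 0.97, minsize = 8) {
  stopifnot(is(uniques, "UniqueSequences"))
  seqs <- uniques@sequences
  sizes <- uniques@sizes
  assignment <- greedy_cluster_cpp(seqs, sizes, identity_threshold,
                                   as.integer(minsize))
  n_cent <- max(assignment, 0L)
  founders <- match(seq_len(n_cent), assignment)  # creator of each centroid
  members <- lapply(seq_len(n_cent), function(k) {
    idx <- which(assignment == k)
    data.frame(sequence = seqs[idx], size = sizes[idx])
  })
  .make_unit_set("OTU", seqs[founders], sizes[founders], members)
}

#' Abundance-skew single-nucleotide denoising (ZOTUs)
#'
#' Implements the frequency-based denoiser: uniques below `minsize` are
#' removed first; the rest are scanned in decreasing-size order, and a
#' unique `u` is merged into an already-accepted centroid `c` when
#' `size(u)/size(c) <= beta(d) = 1 / 2^(alpha * d + 1)` with
#' `d = levenshtein(u, c) >= 1`. Among qualifying centroids the one with
#' the smallest `d` wins (ties to the largest centroid, then the earliest).
#' A unique that merges nowhere becomes a new centroid; each centroid's
#' representative is its own sequence.
#'
#' @param uniques a [UniqueSequences-class].
#' @param alpha skew steepness (default 2, the published preset).
#' @param minsize minimum pooled unique size (default 8).
#' @return a [TaxonUnitSet-class] with `method = "ZOTU"`.
#' @export
denoiseZOTUs <- function(uniques, alpha = 2.0, minsize = 8) {
  stopifnot(is(uniques, "UniqueSequences"))
  keep <- uniques@sizes >= minsize
  seqs <- uniques@sequences[keep]
  sizes <- uniques@sizes[keep]
  cent_seq <- character()
  cent_size <- integer()
  members <- list()
  for (i in seq_along(seqs)) {
    hit <- 0L
    if (length(cent_seq)) {
      d <- as.integer(utils::adist(seqs[i], cent_seq))
      skew <- sizes[i] / cent_size
      ok <- which(d >= 1L & skew <= 1 / 2^(alpha * d + 1))
      if (length(ok)) {
        best <- ok[d[ok] == min(d[ok])]
        if (length(best) > 1L)
          best <- best[cent_size[best] == max(cent_size[best])]
        hit <- best[1L]
      }
    }
    if (hit > 0L) {
      members[[hit]] <- rbind(members[[hit]],
                              data.frame(sequence = seqs[i],
                                         size = sizes[i]))
    } else {
      cent_seq <- c(cent_seq, seqs[i])
      cent_size <- c(cent_size, sizes[i])
      members[[length(cent_seq)]] <-
        data.frame(sequence = seqs[i], size = sizes[i])
    }
  }
  .make_unit_set("ZOTU", cent_seq, cent_size, members)
}

.make_unit_set <- function(method, cent_seq, cent_size, members) {
  n <- length(cent_seq)
  ids <- sprintf("%s%04d", method, seq_len(n))
  reps <- Biostrings::DNAStringSet(setNames(cent_seq, ids))
  totals <- if (n) vapply(members, function(m) sum(m$size), numeric(1))
            else numeric()
  new("TaxonUnitSet", method = method, unit_ids = ids,
      representatives = reps, sizes = as.integer(cent_size),
      total_sizes = as.integer(totals), members = members)
}

#' Map filtered reads to taxonomic units
#'
#' Assigns each read to the best-identity unit representative meeting
#' `min_identity` (ties to the unit with the larger total size, then the
#' earlier unit). Reads failing the threshold are counted as unassigned.
#' The conventional thresholds are 0.97 for OTUs and 1.0 for ZOTUs (the
#' default is chosen from the unit method).
#'
#' @param read_sets named list of read sets (names `"sample|pool"`), or one
#'   read set (treated as column `"S1|rDNA"`).
#' @param units a [TaxonUnitSet-class]; must be non-empty.
#' @param min_identity minimum identity; default 1.0 for ZOTUs, 0.97 for
#'   OTUs.
#' @return a [UnitCountTable-class]; unassigned read counts per column are
#'   in `unassignedReads()`.
#' @export
mapReadsToUnits <- function(read_sets, units, min_identity = NULL) {
  stopifnot(is(units, "TaxonUnitSet"))
  if (length(units@unit_ids) == 0L) stop("unit list is empty")
  if (is.null(min_identity))
    min_identity <- if (units@method == "ZOTU") 1.0 else 0.97
  if (!is.list(read_sets)) read_sets <- list(`S1|rDNA` = read_sets)
  reps <- as.character(units@representatives)
  totals <- units@total_sizes
  nuni <- length(reps)
  counts <- matrix(0L, nrow = nuni, ncol = length(read_sets),
                   dimnames = list(units@unit_ids, names(read_sets)))
  unassigned <- setNames(integer(length(read_sets)), names(read_sets))
  for (ci in seq_along(read_sets)) {
    seqs <- .as_char_reads(read_sets[[ci]])
    if (!length(seqs)) next
    tab <- table(seqs)
    uq <- names(tab)
    nq <- as.integer(tab)
    if (min_identity >= 1) {
      hit <- match(uq, reps)
      hit[is.na(hit)] <- 0L
    } else {
      hit <- best_hit_batch(uq, reps, as.numeric(totals), min_identity)
    }
    assigned <- hit > 0L
    if (any(assigned)) {
      agg <- tapply(nq[assigned], hit[assigned], sum)
      counts[as.integer(names(agg)), ci] <- as.integer(agg)
    }
    unassigned[ci] <- sum(nq[!assigned])
  }
  .unit_count_table(counts, units, unassigned)
}

.unit_count_table <- function(counts, units, unassigned,
                              contaminants = character()) {
  keys <- strsplit(colnames(counts), "|", fixed = TRUE)
  cd <- S4Vectors::DataFrame(
    sample = vapply(keys, `[`, character(1), 1L),
    pool = vapply(keys, `[`, character(1), 2L),
    row.names = colnames(counts))
  rd <- S4Vectors::DataFrame(
    representative = as.character(units@representatives)[
      match(rownames(counts), units@unit_ids)],
    row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd,
    metadata = list(method = units@method, unassigned = unassigned,
                    contaminants = contaminants))
  new("UnitCountTable", se)
}

#' Remove likely contaminant units using negative controls
#'
#' A unit's relative abundance is computed within each negative-control
#' column (a control with zero mapped reads contributes 0) and averaged
#' across controls; units strictly above `threshold` on average are removed
#' from every column. Removed unit ids are recorded in
#' `metadata(x)$contaminants`.
#'
#' @param x a [UnitCountTable-class].
#' @param control_columns column names of the negative controls (>= 1).
#' @param threshold mean relative abundance above which a unit is dropped
#'   (default 0.05; the rule is strictly greater).
#' @return the filtered [UnitCountTable-class].
#' @export
removeContaminants <- function(x, control_columns, threshold = 0.05) {
  stopifnot(is(x, "UnitCountTable"), length(control_columns) >= 1)
  if (!all(control_columns %in% colnames(x)))
    stop("unknown control columns: ",
         paste(setdiff(control_columns, colnames(x)), collapse = ", "))
  cc <- unitCounts(x)[, control_columns, drop = FALSE]
  rel <- apply(cc, 2L, function(v) {
    s <- sum(v)
    if (s == 0) rep(0, length(v)) else v / s
  })
  mean_rel <- rowMeans(matrix(rel, nrow = nrow(cc)))
  drop <- mean_rel > threshold
  out <- x[!drop, ]
  md <- S4Vectors::metadata(out)
  md$contaminants <- c(md$contaminants, rownames(x)[drop])
  S4Vectors::metadata(out) <- md
  out
}

#' Map ZOTUs onto OTU representatives
#'
#' Assigns each ZOTU representative to the best-identity OTU representative
#' at/above `identity_threshold`, or marks it unmapped; per-OTU recruit
#' counts are attached.
#'
#' @param zotus,otus [TaxonUnitSet-class] objects from the same corpus.
#' @param identity_threshold minimum identity (default 0.97).
#' @return data frame with `zotu_id`, `otu_id` (NA when unmapped) and
#'   `identity`; `attr(, "recruits")` holds per-OTU recruit counts.
#' @export
crossMapUnits <- function(zotus, otus, identity_threshold = 0.97) {
  stopifnot(is(zotus, "TaxonUnitSet"), is(otus, "TaxonUnitSet"))
  reps <- as.character(otus@representatives)
  res <- lapply(as.character(zotus@representatives), function(s) {
    idents <- .identities_vs(s, reps, identity_threshold)
    hit <- .best_hit(idents, otus@total_sizes, identity_threshold)
    c(hit = hit, ident = if (hit > 0) idents[hit] else NA_real_)
  })
  hit <- vapply(res, `[[`, numeric(1), "hit")
  out <- data.frame(
    zotu_id = zotus@unit_ids,
    otu_id = ifelse(hit > 0, otus@unit_ids[pmax(hit, 1L)], NA_character_),
    identity = vapply(res, `[[`, numeric(1), "ident"))
  recruits <- table(factor(out$otu_id, levels = otus@unit_ids))
  attr(out, "recruits") <- setNames(as.integer(recruits), otus@unit_ids)
  out
}
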