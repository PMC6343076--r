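BASES <- c("A", "C", "G", "T")

#' Simulate 16S-like reference sequences on a random phylogeny
#'
#' Evolves a random root sequence down a random bifurcating tree. Branch
#' lengths are rescaled so the mean pairwise patristic distance between tips
#' equals `mean_divergence` (expected substitutions per site); each branch
#' then receives a Binomial(`seq_len`, branch length) number of point
#' substitutions at uniformly chosen sites, always to a different base.
#' Because sites can be hit repeatedly, observed divergence saturates
#' following the usual Jukes-Cantor-like curve.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seq_len sequence length (>= 150 for amplicon realism; shorter is
#'   accepted for toys down to 50).
#' @param mean_divergence target mean pairwise patristic distance, `[0, 0.3)`.
#' @param seed integer seed; regenerates bit-identical output.
#' @param min_taxon_dist minimum pairwise substitution (Hamming) distance
#'   between references
#'   (default 8). Taxa are modelled as well-separated lineages --
#'   strain-level microdiversity within a taxon is out of scope -- so tips
#'   that land closer than this (short cherries) have their terminal
#'   branches re-evolved with at least `min_taxon_dist` substitutions until
#'   the whole set is separated. Realized mean divergence can therefore sit
#'   slightly above the target.
#' @return list with `references` ([Biostrings::DNAStringSet] named
#'   `t001, ...`) and `tree` (rooted `phylo`).
#' @details If conflicting sequences cannot be separated (zero-length
#'   terminal branches, as forced by `mean_divergence = 0`), the function
#'   stops with a distinctness error after 100 resampling attempts.
#' @examples
#' ref <- simulateReferences(5, 200, 0.05, seed = 1)
#' ref$references
#' @export
simulateReferences <- function(n_taxa, seq_len, mean_divergence, seed = 1,
                               min_taxon_dist = 8L) {
  stopifnot(n_taxa >= 2, seq_len >= 50,
            mean_divergence >= 0, mean_divergence < 0.3)
  set.seed(as.integer(seed))
  ids <- sprintf("t%03d", seq_len(n_taxa))
  tree <- ape::rtree(n_taxa, tip.label = ids)
  patr <- ape::cophenetic.phylo(tree)
  mp <- mean(patr[upper.tri(patr)])
  tree$edge.length <- tree$edge.length * (mean_divergence / mp)
  patr <- patr * (mean_divergence / mp)

  n_nodes <- n_taxa + tree$Nnode
  root <- n_taxa + 1L
  seqs <- matrix(NA_integer_, nrow = n_nodes, ncol = seq_len)
  seqs[root, ] <- sample.int(4L, seq_len, replace = TRUE)
  evolve <- function(parent_seq, blen, min_sub = 0L) {
    nsub <- rbinom(1L, seq_len, min(blen, 1))
    if (blen > 0) nsub <- max(nsub, min_sub)
    child <- parent_seq
    if (nsub > 0L) {
      pos <- sample.int(seq_len, nsub, replace = TRUE)
      for (p in pos) child[p] <- sample(setdiff(1:4, child[p]), 1L)
    }
    child
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (k in seq_len(nrow(edges)))
    seqs[edges[k, 2L], ] <- evolve(seqs[edges[k, 1L], ], elen[k])

  term_edge <- match(seq_len(n_taxa), tree$edge[, 2L])
  tip_char <- function() apply(seqs[seq_len(n_taxa), , drop = FALSE], 1L,
                               function(v) paste(BASES[v], collapse = ""))
  conflicts <- function(out) {
    # separation is measured in substitution (Hamming) space, which is
    # where the evolution model operates; computed by one-hot crossproduct
    chars <- matrix(unlist(strsplit(out, "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = length(out), byrow = TRUE)
    agree <- matrix(0, length(out), length(out))
    for (b in BASES) agree <- agree + tcrossprod(chars == b)
    mism <- seq_len - agree
    bad <- which(mism < min_taxon_dist & upper.tri(mism), arr.ind = TRUE)
    unique(c(bad[, 2L], which(duplicated(out))))
  }
  out <- tip_char()
  attempts <- 0L
  repeat {
    bad <- conflicts(out)
    if (!length(bad)) break
    attempts <- attempts + 1L
    if (attempts > 100L)
      stop("cannot produce distinct reference sequences: divergence too low")
    for (tip in bad) {
      e <- term_edge[tip]
      seqs[tip, ] <- evolve(seqs[tree$edge[e, 1L], ], tree$edge.length[e],
                            min_sub = min_taxon_dist)
    }
    out <- tip_char()
  }
  refs <- Biostrings::DNAStringSet(setNames(out, ids))
  list(references = refs, tree = tree)
}

#' Simulate a ground-truth community from a scenario
#'
#' Draws cell abundances `p_t` from a lognormal(0, `abundance_sigma`)
#' (normalized to sum 1) and activity factors `a_t` from a lognormal(0,
#' `activity_sigma`). Under the `kill_the_winner` model the activity draws
#' are re-assigned anti-ranked against abundance (most abundant taxon gets
#' the smallest activity), giving Spearman(p, a) = -1 on distinct draws.
#'
#' @param scenario a [SimScenario-class].
#' @return a [TrueCommunity-class] with 16S copy numbers all 1.
#' @examples
#' com <- simulateCommunity(simScenario(n_taxa = 10, seed = 7))
#' sum(abundances(com))
#' @export
simulateCommunity <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  validObject(scenario)
  ref <- simulateReferences(scenario@n_taxa, scenario@seq_len,
                            scenario@mean_divergence, seed = scenario@seed)
  set.seed(scenario@seed + 1L)
  n <- scenario@n_taxa
  p <- rlnorm(n, 0, scenario@abundance_sigma)
  p <- p / sum(p)
  a <- rlnorm(n, 0, scenario@activity_sigma)
  if (scenario@activity_model == "kill_the_winner")
    a <- sort(a, decreasing = TRUE)[rank(p, ties.method = "first")]
  new("TrueCommunity", taxon_ids = names(ref$references),
      abundances = p, activities = a,
      copy_numbers = rep(1L, n), references = ref$references,
      tree = ref$tree)
}

#' Expected read fractions of each taxon in a pool
#'
#' The rDNA pool samples gene copies, so taxon fractions are proportional to
#' `p_t * c_t`; the rRNA pool samples transcripts, proportional to
#' `p_t * c_t * a_t`. The per-taxon ratio of rRNA to rDNA fraction is
#' therefore `a_t / (sum(p c a) / sum(p c))` -- the quantity the rRNA/rDNA
#' estimator recovers up to that community-wide constant.
#'
#' @param community a [TrueCommunity-class].
#' @param pool `"rDNA"` or `"rRNA"`.
#' @return named probability vector over taxa (sums to 1).
#' @export
expectedPoolFractions <- function(community, pool = c("rDNA", "rRNA")) {
  pool <- match.arg(pool)
  w <- community@abundances * community@copy_numbers
  if (pool == "rRNA") w <- w * community@activities
  setNames(w / sum(w), community@taxon_ids)
}

## Apply per-base substitutions (and optional indels) to a character vector
## of reads; errors always change the base.
.mutate_reads <- function(seqs, sub_rate, indel_rate = 0) {
  if (sub_rate <= 0 && indel_rate <= 0) return(seqs)
  L <- nchar(seqs)
  nsub <- rbinom(length(seqs), L, sub_rate)
  for (i in which(nsub > 0L)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(s), nsub[i])
    for (p in pos) s[p] <- sample(setdiff(BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  if (indel_rate > 0) {
    nind <- rbinom(length(seqs), L, indel_rate)
    for (i in which(nind > 0L)) {
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (k in seq_len(nind[i])) {
        p <- sample.int(length(s), 1L)
        if (runif(1) < 0.5 && length(s) > 1L) s <- s[-p]
        else s <- append(s, sample(BASES, 1L), after = p)
      }
      seqs[i] <- paste(s, collapse = "")
    }
  }
  seqs
}

.constant_quality <- function(widths, q) {
  uw <- unique(widths)
  qstr <- setNames(strrep(rawToChar(as.raw(q + 33L)), uw), uw)
  Biostrings::PhredQuality(unname(qstr[as.character(widths)]))
}

#' Sample single-end amplicon reads from a community pool
#'
#' Draws each read's taxon of origin multinomially from
#' [expectedPoolFractions()], copies the reference, and applies independent
#' per-base substitution errors at `sub_error_rate` (plus `rt_error_rate`
#' for the rRNA pool, emulating reverse transcription). Reads carry a
#' constant Phred quality and a truth label in the header after the reserved
#' `;truth=` delimiter; downstream analysis code never reads the label.
#'
#' @param community a [TrueCommunity-class].
#' @param scenario the [SimScenario-class] providing depths, error rates and
#'   quality.
#' @param pool `"rDNA"` or `"rRNA"`.
#' @param seed integer seed; defaults to `scenario@seed` offset by pool so
#'   the two pools of one scenario are independent but reproducible.
#' @return a [Biostrings::QualityScaledDNAStringSet] (possibly empty).
#' @examples
#' sc <- simScenario(n_taxa = 5, depth_rdna = 100, depth_rrna = 100)
#' com <- simulateCommunity(sc)
#' rds <- sampleAmpliconReads(com, sc, "rDNA")
#' length(rds)
#' @export
sampleAmpliconReads <- function(community, scenario,
                                pool = c("rDNA", "rRNA"), seed = NULL) {
  pool <- match.arg(pool)
  stopifnot(is(community, "TrueCommunity"), is(scenario, "SimScenario"))
  depth <- if (pool == "rDNA") scenario@depth_rdna else scenario@depth_rrna
  if (is.null(seed))
    seed <- scenario@seed + if (pool == "rDNA") 101L else 202L
  set.seed(as.integer(seed))
  if (depth == 0L) {
    empty <- Biostrings::DNAStringSet()
    return(Biostrings::QualityScaledDNAStringSet(
      empty, Biostrings::PhredQuality(character())))
  }
  fr <- expectedPoolFractions(community, pool)
  idx <- sample.int(length(fr), depth, replace = TRUE, prob = fr)
  seqs <- as.character(community@references)[idx]
  rate <- scenario@sub_error_rate +
    if (pool == "rRNA") scenario@rt_error_rate else 0
  seqs <- .mutate_reads(seqs, rate, scenario@indel_rate)
  names(seqs) <- sprintf("%s_r%06d;truth=%s", pool, seq_len(depth),
                         community@taxon_ids[idx])
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    .constant_quality(nchar(seqs), scenario@phred_quality))
}

#' Simulate a negative-control (blank extraction) read set
#'
#' Reads are drawn from the supplied contaminant references at the given
#' proportions with no sequencing error, to exercise the >5%-in-controls
#' contaminant filter.
#'
#' @param contaminant_refs [Biostrings::DNAStringSet] (or named character)
#'   of contaminant sequences, length >= 1.
#' @param depth number of control reads.
#' @param seed integer seed.
#' @param proportions sampling proportions (default equal).
#' @param phred_quality constant quality score (default 30).
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
simulateNegativeControl <- function(contaminant_refs, depth, seed = 1,
                                    proportions = NULL, phred_quality = 30) {
  refs <- as.character(contaminant_refs)
  stopifnot(length(refs) >= 1, depth >= 0)
  if (is.null(names(refs))) names(refs) <- sprintf("c%03d", seq_along(refs))
  if (is.null(proportions)) proportions <- rep(1, length(refs))
  stopifnot(length(proportions) == length(refs))
  set.seed(as.integer(seed))
  idx <- if (depth > 0)
    sample.int(length(refs), depth, replace = TRUE, prob = proportions)
  else integer()
  seqs <- setNames(refs[idx],
                   sprintf("ctl_r%06d;truth=%s", seq_len(depth),
                           names(refs)[idx]))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    .constant_quality(nchar(seqs), phred_quality))
}

#' Extract truth labels from simulated read headers
#'
#' Test/validation helper: recovers the taxon of origin recorded after the
#' reserved `;truth=` delimiter. Analysis functions never call this.
#'
#' @param reads a read set produced by the simulator.
#' @return character vector of taxon ids.
#' @export
truthLabels <- function(reads) {
  sub("^.*;truth=", "", names(reads))
}
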