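#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i, base))` over positive entries; base 2 (bits) by
#' default, natural log by flag.
#'
#' @param x non-negative count or abundance vector with at least one
#'   positive entry.
#' @param base logarithm base (default 2).
#' @return Shannon index.
#' @examples
#' shannonIndex(rep(1, 16))  # 4 bits
#' @export
shannonIndex <- function(x, base = 2) {
  x <- x[x > 0]
  if (length(x) == 0) stop("all-zero abundance vector")
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity (root-inclusive)
#'
#' Sum of the branch lengths of the minimal subtree connecting the observed
#' tips and the root. The root-inclusive convention counts the path from
#' the root even for a single observed tip.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param observed_tips tip labels present in the sample (non-empty).
#' @return total branch length of the spanning subtree.
#' @export
faithPD <- function(tree, observed_tips) {
  stopifnot(inherits(tree, "phylo"), length(observed_tips) >= 1)
  unknown <- setdiff(observed_tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label: ", paste(unknown, collapse = ", "))
  ntip <- length(tree$tip.label)
  has_obs <- logical(ntip + tree$Nnode)
  has_obs[match(observed_tips, tree$tip.label)] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge)))
    if (has_obs[po$edge[k, 2L]]) has_obs[po$edge[k, 1L]] <- TRUE
  sum(po$edge.length[has_obs[po$edge[, 2L]]])
}

#' Rarefaction-normalized alpha diversity
#'
#' Subsamples each sample column without replacement to a common depth,
#' computes the metric, and averages over `n_reps` draws (the standard
#' subsample-and-average normalization protocol).
#'
#' @param counts integer matrix, units x samples.
#' @param metric `"richness"`, `"shannon"` or `"pd"`.
#' @param depth rarefaction depth; every included column total must be >=
#'   depth.
#' @param n_reps number of random subsamples to average (default 10).
#' @param seed integer seed fixing the draws.
#' @param tree rooted `phylo` over unit ids (required for `metric = "pd"`).
#' @param base Shannon log base (default 2).
#' @return named per-sample vector of averaged metric values.
#' @export
rarefyMeanAlpha <- function(counts, metric = c("richness", "shannon", "pd"),
                            depth, n_reps = 10, seed = 1, tree = NULL,
                            base = 2) {
  metric <- match.arg(metric)
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  bad <- tot < depth
  if (any(bad))
    stop("column totals below depth: ",
         paste(colnames(counts)[bad], collapse = ", "))
  if (metric == "pd" && is.null(tree)) stop("metric 'pd' requires a tree")
  set.seed(as.integer(seed))
  one <- function(v) {
    vapply(seq_len(ncol(v)), function(j) {
      col <- v[, j]
      switch(metric,
             richness = sum(col > 0),
             shannon = shannonIndex(col, base = base),
             pd = faithPD(tree, rownames(counts)[col > 0]))
    }, numeric(1))
  }
  acc <- matrix(0, nrow = ncol(counts), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    ## rrarefy warns when the smallest positive count exceeds 1; for unit
    ## count tables that is routine, not a data problem.
    sub <- withCallingHandlers(
      t(vegan::rrarefy(t(counts), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    acc[, r] <- one(sub)
  }
  setNames(rowMeans(acc), colnames(counts))
}

#' Build a tree over unit representatives
#'
#' Pairwise distances are one minus the cosine similarity of k-mer count
#' profiles; the tree is built by neighbor joining, midpoint rooted, and
#' negative NJ branch lengths are clamped to zero. Intended as a default
#' substrate for PD and UniFrac when no curated tree is supplied; any
#' user-provided rooted newick can be used instead.
#'
#' @param representatives a named [Biostrings::DNAStringSet] or named
#'   character vector (>= 2 sequences, unique ids).
#' @param k k-mer size (default 6).
#' @return a rooted `phylo` with tip labels equal to the sequence names.
#' @export
buildUnitTree <- function(representatives, k = 6) {
  ids <- names(representatives)
  seqs <- Biostrings::DNAStringSet(setNames(as.character(representatives),
                                            ids))
  if (is.null(ids) || anyDuplicated(ids))
    stop("representatives must carry unique ids")
  n <- length(seqs)
  stopifnot(n >= 2)
  prof <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  norm <- sqrt(rowSums(prof^2))
  cosine <- tcrossprod(prof / norm)
  D <- 1 - cosine
  D[D < 0] <- 0
  diag(D) <- 0
  dimnames(D) <- list(names(seqs), names(seqs))
  if (n == 2L) {
    d <- D[1, 2]
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                        names(seqs)[1], d / 2,
                                        names(seqs)[2], d / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr <- phangorn::midpoint(tr)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## Per-edge descendant totals of a sample abundance vector.
.edge_descendant_sums <- function(tree, v) {
  ntip <- length(tree$tip.label)
  acc <- numeric(ntip + tree$Nnode)
  acc[seq_len(ntip)] <- v
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge)))
    acc[po$edge[k, 1L]] <- acc[po$edge[k, 1L]] + acc[po$edge[k, 2L]]
  list(edge_sum = acc[po$edge[, 2L]], edge_len = po$edge.length)
}

.tip_vector <- function(tree, x) {
  bad <- setdiff(names(x), tree$tip.label)
  if (length(bad))
    stop("tip present in sample but absent from tree: ",
         paste(bad, collapse = ", "))
  v <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
  v[names(x)] <- x
  v
}

#' UniFrac distance between two samples
#'
#' Unweighted UniFrac is the fraction of branch length unique to either
#' sample: `sum(l * |Ia - Ib|) / sum(l * max(Ia, Ib))` over branches with
#' presence indicators `I`. Weighted UniFrac (non-normalized by default) is
#' `sum(l * |A - B|)` where `A`, `B` are the fractions of each sample's
#' reads descending from the branch; `normalized = TRUE` divides by
#' `sum(l * (A + B))`.
#'
#' @param tree rooted `phylo` whose tips cover the observed units.
#' @param a,b named abundance vectors over tree tips.
#' @param weighted logical; abundance-weighted variant (default FALSE).
#' @param normalized logical; normalize the weighted variant
#'   (default FALSE).
#' @return the distance (unweighted always in `[0, 1]`).
#' @export
uniFrac <- function(tree, a, b, weighted = FALSE, normalized = FALSE) {
  va <- .tip_vector(tree, a)
  vb <- .tip_vector(tree, b)
  ea <- .edge_descendant_sums(tree, va)
  eb <- .edge_descendant_sums(tree, vb)
  l <- ea$edge_len
  if (!weighted) {
    Ia <- ea$edge_sum > 0
    Ib <- eb$edge_sum > 0
    denom <- sum(l * pmax(Ia, Ib))
    if (denom == 0) return(0)
    sum(l * abs(Ia - Ib)) / denom
  } else {
    A <- ea$edge_sum / sum(va)
    B <- eb$edge_sum / sum(vb)
    d <- sum(l * abs(A - B))
    if (normalized) d / sum(l * (A + B)) else d
  }
}

#' All-pairs UniFrac distance matrix
#'
#' @param tree rooted `phylo`.
#' @param counts units x samples matrix with unit ids as row names.
#' @param weighted,normalized passed to [uniFrac()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
uniFracMatrix <- function(tree, counts, weighted = FALSE,
                          normalized = FALSE) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  D <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    D[i, j] <- D[j, i] <- uniFrac(tree, counts[, i], counts[, j],
                                  weighted = weighted,
                                  normalized = normalized)
  }
  D
}

#' Principal-coordinate analysis of a distance matrix
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition.
#' Axes are ordered by eigenvalue; the proportion of variance per axis is
#' the eigenvalue over the sum of positive eigenvalues. Negative
#' eigenvalues are reported, not corrected.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param tol symmetry tolerance (default 1e-8).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing) and `proportion_explained` (per positive axis).
#' @export
pcoaAxes <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > tol))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values), 1) * 1e-12
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  dimnames(coords) <- list(rownames(D),
                           if (ncol(coords)) paste0("PCo",
                                                    seq_len(ncol(coords))))
  prop <- if (any(pos)) e$values[pos] / sum(e$values[pos]) else numeric()
  list(coordinates = coords, eigenvalues = e$values,
       proportion_explained = prop)
}

#' PERMANOVA on a distance matrix
#'
#' Distance-based pseudo-F with free permutation of sample labels, computed
#' with [vegan::adonis2()]; the p-value uses the add-one convention
#' `(1 + #{F* >= F}) / (1 + n_permutations)` and is never exactly zero.
#'
#' @param D symmetric distance matrix (or `dist`).
#' @param groups group labels, one per sample; >= 2 groups.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed fixing the permutation stream.
#' @return list with `pseudo_F`, `p_value`, `n_permutations`, `groups`.
#' @export
permanovaTest <- function(D, groups, n_permutations = 999, seed = 1) {
  d <- stats::as.dist(D)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) >= 2,
            length(groups) == attr(d, "Size"),
            length(groups) >= nlevels(groups) + 1)
  set.seed(as.integer(seed))
  df <- data.frame(g = groups)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_permutations)
  list(pseudo_F = fit$F[1], p_value = fit$`Pr(>F)`[1],
       n_permutations = n_permutations, groups = levels(groups))
}
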