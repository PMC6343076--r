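# Independent reference implementations used to validate the package's
# primitives. Deliberately naive: recursion + memoisation, explicit edge
# enumeration, no shared code with the implementations under test.

# Unit-cost edit distance by the textbook recursion.
oracle_levenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- min(rec(i - 1, j) + 1,
               rec(i, j - 1) + 1,
               rec(i - 1, j - 1) + (av[i] != bv[j]))
    memo[[key]] <- res
    res
  }
  rec(length(av), length(bv))
}

# Overlap-alignment identity oracle: enumerate every split into a free
# prefix skip (on one string), a fully penalized global middle, and a free
# suffix skip (on one string); the middle is scored by a memoised recursion
# maximizing (score, matches) with match +1, mismatch -1, gap -1.
# identity = matches / (2 * matches - score) of the lexicographic optimum.
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  global_best <- function(ai, aj, bi, bj) {
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j) { # best (score, match) aligning a[i..aj] vs b[j..bj]
      if (i > aj && j > bj) return(c(0, 0))
      key <- paste(i, j)
      if (!is.null(memo[[key]])) return(memo[[key]])
      cand <- list()
      if (i <= aj && j <= bj) {
        m <- rec(i + 1, j + 1)
        eq <- av[i] == bv[j]
        cand <- c(cand, list(c(m[1] + if (eq) 1 else -1,
                               m[2] + if (eq) 1 else 0)))
      }
      if (i <= aj) { m <- rec(i + 1, j); cand <- c(cand, list(c(m[1] - 1, m[2]))) }
      if (j <= bj) { m <- rec(i, j + 1); cand <- c(cand, list(c(m[1] - 1, m[2]))) }
      best <- cand[[1]]
      for (cc in cand)
        if (cc[1] > best[1] || (cc[1] == best[1] && cc[2] > best[2]))
          best <- cc
      memo[[key]] <- best
      best
    }
    rec(ai, bi)
  }
  best <- c(0, 0) # empty overlap
  for (s in 0:la) for (t in 0:lb) {
    if (s > 0 && t > 0) next
    for (u in 0:(la - s)) for (v in 0:(lb - t)) {
      if (u > 0 && v > 0) next
      m <- global_best(s + 1, la - u, t + 1, lb - v)
      if (m[1] > best[1] || (m[1] == best[1] && m[2] > best[2]))
        best <- m
    }
  }
  cols <- 2 * best[2] - best[1]
  if (cols <= 0) 0 else best[2] / cols
}

# Faith's PD oracle: explicit union of tip-to-root edge sets.
oracle_faith_pd <- function(tree, tips) {
  edge_ids <- integer()
  for (tip in match(tips, tree$tip.label)) {
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      edge_ids <- union(edge_ids, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edge_ids])
}

# Squared Procrustes residual after centering and optimal rotation
# (no scaling; PCoA on Euclidean input preserves scale).
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  R <- s$u %*% t(s$v)
  sum((Xc - Yc %*% R)^2)
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""),
    character(1))
}
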