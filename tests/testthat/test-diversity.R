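test_that("Shannon index matches closed forms", {
  expect_equal(shannonIndex(rep(1, 16)), 4.0)
  expect_equal(shannonIndex(c(0, 0, 7)), 0)
  expect_equal(shannonIndex(c(3, 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(shannonIndex(c(3, 1)), 0.8113, tolerance = 1e-4)
  # zero-count units change nothing; uniform is maximal
  expect_equal(shannonIndex(c(5, 5, 0)), shannonIndex(c(5, 5)))
  expect_gt(shannonIndex(rep(2, 8)), shannonIndex(c(9, 1, 2, 2, 1, 1)))
  # natural-log flag
  expect_equal(shannonIndex(rep(1, 4), base = exp(1)), log(4))
  expect_error(shannonIndex(c(0, 0)), "zero")
})

test_that("Faith's PD equals the edge-union oracle and is monotone", {
  set.seed(21)
  tree <- ape::rtree(10)
  # all tips span the whole tree
  expect_equal(faithPD(tree, tree$tip.label), sum(tree$edge.length))
  # single tip is its root path
  expect_equal(faithPD(tree, tree$tip.label[3]),
               oracle_faith_pd(tree, tree$tip.label[3]))
  # random subsets match the explicit union of tip-to-root edge sets
  for (k in 1:10) {
    tips <- sample(tree$tip.label, sample(1:10, 1))
    expect_equal(faithPD(tree, tips), oracle_faith_pd(tree, tips))
  }
  # monotone in added tips
  t5 <- sample(tree$tip.label, 5)
  extra <- setdiff(tree$tip.label, t5)[1]
  expect_gte(faithPD(tree, c(t5, extra)), faithPD(tree, t5))
  expect_error(faithPD(tree, "nope"), "nope")
})

test_that("Faith's PD agrees with picante's root-inclusive convention", {
  skip_if_not_installed("picante")
  set.seed(33)
  tree <- ape::rtree(12)
  for (k in 1:5) {
    tips <- sample(tree$tip.label, sample(2:12, 1))
    comm <- matrix(as.integer(tree$tip.label %in% tips), nrow = 1,
                   dimnames = list("s", tree$tip.label))
    expect_equal(faithPD(tree, tips),
                 suppressWarnings(
                   picante::pd(comm, tree, include.root = TRUE))$PD)
  }
})

test_that("rarefied alpha diversity matches the hypergeometric expectation", {
  # toy column (100, 1) at depth 50: richness expectation
  # 1 + (1 - C(100,50)/C(101,50)) = 1 + 50/101
  cnt <- matrix(c(100L, 1L), ncol = 1,
                dimnames = list(c("u1", "u2"), "S1|rDNA"))
  est <- rarefyMeanAlpha(cnt, "richness", depth = 50, n_reps = 10000,
                         seed = 2)
  expect_equal(unname(est), 1 + 50 / 101, tolerance = 0.01)
  # depth equal to the column total reproduces the plain metric exactly
  full <- rarefyMeanAlpha(cnt, "richness", depth = 101, n_reps = 5, seed = 1)
  expect_equal(unname(full), 2)
  sh <- rarefyMeanAlpha(cnt, "shannon", depth = 101, n_reps = 3, seed = 1)
  expect_equal(unname(sh), shannonIndex(c(100, 1)))
  # rarefied richness never exceeds full richness
  m <- matrix(rpois(30, 20) + 1L, nrow = 6,
              dimnames = list(paste0("u", 1:6), paste0("S", 1:5, "|rDNA")))
  rich <- rarefyMeanAlpha(m, "richness", depth = 20, n_reps = 10, seed = 4)
  expect_true(all(rich <= 6))
  # under-depth columns are reported by name
  expect_error(rarefyMeanAlpha(cnt, "richness", depth = 1000), "S1")
})

test_that("unit trees recover structure from k-mer distances", {
  # identical sequences give a zero-length cherry
  two <- setNames(rep(strrep("ACGT", 50), 2), c("a", "b"))
  tr2 <- buildUnitTree(two)
  expect_equal(sum(tr2$edge.length), 0)
  expect_setequal(tr2$tip.label, c("a", "b"))
  # three sequences: NJ topology with non-negative lengths
  set.seed(9)
  three <- setNames(random_dna(3, 300), c("a", "b", "c"))
  tr3 <- buildUnitTree(three)
  expect_true(ape::is.rooted(tr3))
  expect_true(all(tr3$edge.length >= 0))
  expect_error(buildUnitTree(setNames(random_dna(2, 100), c("a", "a"))),
               "unique")
  # simulator references: the k-mer NJ tree gets closer to the truth as
  # divergence grows (Robinson-Foulds distance to the true topology)
  rf <- vapply(c(0.02, 0.15), function(dv) {
    r <- simulateReferences(12, 400, dv, seed = 6)
    est <- buildUnitTree(r$references)
    ape::dist.topo(ape::unroot(est), ape::unroot(r$tree))
  }, numeric(1))
  expect_lte(rf[2], rf[1])
})

test_that("UniFrac matches hand enumeration on a printed 4-tip tree", {
  # ((A:1,B:2):1,(C:3,D:1):2); with per-branch lengths as printed
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  a <- c(A = 4, B = 0, C = 0, D = 4)
  b <- c(A = 0, B = 2, C = 2, D = 0)
  # unweighted by hand: shared branches are the two internals (1 and 2);
  # unique branches A(1), B(2), C(3), D(1) all differ between samples
  # numerator = 1+2+3+1 = 7, denominator = 7 + internals (1+2) = 10
  expect_equal(uniFrac(tree, a, b, weighted = FALSE), 7 / 10)
  # weighted by hand: A: l1*|0.5-0|, B: 2*|0-0.5|, C: 3*|0-0.5|,
  # D: 1*|0.5-0|, int1: 1*|0.5-0.5|, int2: 2*|0.5-0.5|
  expect_equal(uniFrac(tree, a, b, weighted = TRUE),
               1 * 0.5 + 2 * 0.5 + 3 * 0.5 + 1 * 0.5)
  # identity and symmetry
  expect_equal(uniFrac(tree, a, a, weighted = FALSE), 0)
  expect_equal(uniFrac(tree, a, a, weighted = TRUE), 0)
  expect_equal(uniFrac(tree, a, b), uniFrac(tree, b, a))
  # disjoint tip sets meeting only at the root
  l <- c(A = 1, B = 1, C = 0, D = 0)
  r <- c(A = 0, B = 0, C = 1, D = 1)
  expect_equal(uniFrac(tree, l, r, weighted = FALSE), 1)
  expect_error(uniFrac(tree, c(Z = 1), b), "Z")
})

test_that("unweighted UniFrac agrees with picante on random communities", {
  skip_if_not_installed("picante")
  set.seed(41)
  tree <- ape::rtree(8)
  comm <- matrix(rbinom(24, 5, 0.5), nrow = 3,
                 dimnames = list(paste0("s", 1:3), tree$tip.label))
  ours <- uniFracMatrix(tree, t(comm), weighted = FALSE)
  theirs <- as.matrix(picante::unifrac(comm, tree))
  expect_equal(unname(ours), unname(theirs[rownames(ours), rownames(ours)]),
               tolerance = 1e-10)
})

test_that("PCoA recovers geometry and reports variance shares", {
  # two samples at distance d sit at +/- d/2
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoaAxes(D2)
  expect_equal(sort(unname(p2$coordinates[, 1])), c(-1.5, 1.5))
  expect_equal(p2$proportion_explained, 1)
  # Euclidean distances from known planar points are reproduced exactly
  set.seed(14)
  X <- matrix(rnorm(20), ncol = 2)
  D <- as.matrix(dist(X))
  p <- pcoaAxes(D)
  expect_lt(procrustes_error(X, p$coordinates[, 1:2]), 1e-8)
  # all-zero matrix: no positive eigenvalues
  D0 <- matrix(0, 3, 3)
  expect_true(all(abs(pcoaAxes(D0)$eigenvalues) < 1e-12))
  # asymmetry is rejected
  Dbad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoaAxes(Dbad), "symmetric")
})

test_that("PERMANOVA pseudo-F matches a hand-computed decomposition", {
  # 4 samples, 2 groups; within-group distances 1, across 5
  D <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, 4)
  g <- c("x", "x", "y", "y")
  # SS_total = sum d^2 / n = (2*1 + 4*25 + ... ) hand-computed below
  ss_total <- sum(D[upper.tri(D)]^2) / 4
  ss_within <- (1^2) / 2 + (1^2) / 2
  ss_between <- ss_total - ss_within
  f_hand <- (ss_between / 1) / (ss_within / 2)
  res <- permanovaTest(D, g, n_permutations = 99, seed = 1)
  expect_equal(res$pseudo_F, f_hand)
  expect_gte(res$p_value, 1 / 100)
})

test_that("tight well-separated clusters reach ceiling significance", {
  # two clusters of 10 far apart: only 2/C(20,10) label arrangements
  # reproduce the partition, so the add-one p hits its floor
  set.seed(8)
  X <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
             matrix(rnorm(20, 50, 0.01), ncol = 2))
  D <- as.matrix(dist(X))
  res <- permanovaTest(D, rep(c("a", "b"), each = 10),
                       n_permutations = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200)
})

test_that("PERMANOVA p-values are calibrated under the null", {
  set.seed(19)
  pvals <- vapply(1:60, function(i) {
    X <- matrix(rnorm(24), ncol = 3)
    D <- as.matrix(dist(X))
    permanovaTest(D, rep(c("a", "b"), each = 4),
                  n_permutations = 199, seed = i)$p_value
  }, numeric(1))
  # roughly uniform: mean near 0.5, no mass collapse at the extremes
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_lt(mean(pvals <= 0.05), 0.2)
})
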