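test_that("quality filter enforces length and expected error", {
  s250 <- strrep("A", 250)
  s230 <- strrep("A", 230)
  s229 <- strrep("A", 229)
  # 250 bases at Q20: EE = 250 * 0.01 = 2.5 -> discarded
  r1 <- make_reads(c(a = s250), q = 20)
  # 229 bases at Q40: fails the length rule
  r2 <- make_reads(c(b = s229), q = 40)
  # 230 bases at Q30: EE = 0.23 -> retained
  r3 <- make_reads(c(c = s230), q = 30)
  all3 <- c(r1, r2, r3)
  kept <- qualityFilter(all3)
  expect_identical(names(kept), "c")
  expect_equal(attr(kept, "retained_fraction"), 1 / 3)
  # mixed per-base qualities: EE is summed per base
  mixed <- make_read_q(s230, c(rep(40, 220), rep(10, 10)))  # EE ~ 1.02
  expect_length(qualityFilter(mixed), 0)
})

test_that("dereplication pools counts with deterministic ordering", {
  s1 <- strrep("ACGT", 60)
  s2 <- strrep("TGCA", 60)
  reads <- list(`S1|rDNA` = make_reads(c(s1, s1, s2)),
                `S1|rRNA` = make_reads(c(s1, s2, s2, s2)))
  uq <- dereplicate(reads)
  expect_identical(unname(uniqueSizes(uq)), c(4L, 3L))
  expect_identical(uniqueSeqs(uq)[1], s2)  # size 4 beats size 3
  expect_identical(unname(provenance(uq)[, "S1|rDNA"]), c(1L, 2L))
  # ties break lexicographically by sequence
  tie <- dereplicate(list(`S1|rDNA` = make_reads(c(s1, s2))))
  expect_identical(uniqueSeqs(tie), sort(c(s1, s2)))
  # sizes sum to the read count on random input
  set.seed(1)
  rnd <- make_reads(sample(random_dna(5, 250), 40, replace = TRUE))
  expect_equal(sum(uniqueSizes(dereplicate(rnd))), 40)
})

test_that("greedy clustering joins by identity and respects minsize", {
  base <- random_dna(1, 100)
  near <- mutate_at(base, c(10, 60))        # identity 0.98
  far <- mutate_at(base, c(5, 25, 45, 65, 85))  # identity 0.95
  # 0.98 pair merges into one OTU led by the bigger unique
  uq1 <- dereplicate(make_reads(c(rep(base, 50), rep(near, 20))))
  otus1 <- clusterOTUs(uq1)
  expect_length(unitIds(otus1), 1)
  expect_identical(as.character(unitRepresentatives(otus1)[[1]]), base)
  expect_equal(unname(unitTotalSizes(otus1)), 70)
  # 0.95 pair stays apart
  uq2 <- dereplicate(make_reads(c(rep(base, 50), rep(far, 20))))
  otus2 <- clusterOTUs(uq2)
  expect_length(unitIds(otus2), 2)
  # identity between centroids is below the threshold by construction
  expect_lt(pairwiseIdentity(
    as.character(unitRepresentatives(otus2)[[1]]),
    as.character(unitRepresentatives(otus2)[[2]])), 0.97)
  # small uniques cannot found centroids but still join existing ones
  uq3 <- dereplicate(make_reads(c(rep(base, 50), rep(near, 3), rep(far, 3))))
  otus3 <- clusterOTUs(uq3)
  expect_length(unitIds(otus3), 1)
  expect_equal(unname(unitTotalSizes(otus3)), 53)  # far (0.95) discarded
  # empty input gives an empty unit set
  expect_length(unitIds(clusterOTUs(dereplicate(make_reads(character())))),
                0)
})

test_that("denoiser merges by the abundance-skew rule", {
  base <- random_dna(1, 200)
  v1 <- mutate_at(base, 7)     # d = 1
  # beta(1) = 1/2^3 = 0.125: size 100 vs 1000 merges (skew 0.1)
  uq <- dereplicate(make_reads(c(rep(base, 1000), rep(v1, 100))))
  z <- denoiseZOTUs(uq)
  expect_length(unitIds(z), 1)
  expect_equal(unname(unitTotalSizes(z)), 1100)
  # size 200 vs 1000 does not (skew 0.2 > 0.125): two ZOTUs
  uq2 <- dereplicate(make_reads(c(rep(base, 1000), rep(v1, 200))))
  z2 <- denoiseZOTUs(uq2)
  expect_length(unitIds(z2), 2)
  # each centroid's representative is its own sequence
  expect_setequal(as.character(unitRepresentatives(z2)), c(base, v1))
  # uniques under minsize are removed before denoising
  v2 <- mutate_at(base, c(30, 90))
  uq3 <- dereplicate(make_reads(c(rep(base, 1000), rep(v2, 7))))
  z3 <- denoiseZOTUs(uq3)
  expect_length(unitIds(z3), 1)
  expect_equal(unname(unitTotalSizes(z3)), 1000)
})

test_that("denoiser picks the closest qualifying centroid", {
  base <- random_dna(1, 200)
  other <- mutate_at(base, c(20, 40, 60, 80))  # d = 4 from base
  v <- mutate_at(base, 20)  # d = 1 from base, d = 3 from other
  uq <- dereplicate(make_reads(c(rep(base, 5000), rep(other, 4000),
                                 rep(v, 30))))
  z <- denoiseZOTUs(uq)
  expect_length(unitIds(z), 2)
  mem <- unitMembers(z)
  base_unit <- which(vapply(
    as.character(unitRepresentatives(z)), identical, logical(1), base))
  expect_true(v %in% mem[[base_unit]]$sequence)
})

test_that("denoising is invariant to input read order", {
  set.seed(3)
  base <- random_dna(1, 150)
  reads <- c(rep(base, 400), rep(mutate_at(base, 5), 20),
             rep(random_dna(1, 150), 50))
  z1 <- denoiseZOTUs(dereplicate(make_reads(reads)))
  z2 <- denoiseZOTUs(dereplicate(make_reads(sample(reads))))
  expect_identical(as.character(unitRepresentatives(z1)),
                   as.character(unitRepresentatives(z2)))
  expect_identical(unitTotalSizes(z1), unitTotalSizes(z2))
})

test_that("read mapping honors thresholds and reports unassigned reads", {
  base <- random_dna(1, 250)
  far <- random_dna(1, 250)
  uq <- dereplicate(make_reads(c(rep(base, 20), rep(far, 10))))
  zot <- denoiseZOTUs(uq, minsize = 8)
  one_off <- mutate_at(base, 125)
  rs <- list(`S1|rDNA` = make_reads(c(base, one_off)))
  # ZOTUs map at 100%: the mutated read is unassigned
  tz <- mapReadsToUnits(rs, zot)
  expect_equal(sum(unitCounts(tz)), 1)
  expect_equal(unname(unassignedReads(tz)), 1L)
  # the same read maps to an OTU at 0.996 >= 0.97
  ot <- clusterOTUs(uq, minsize = 8)
  to <- mapReadsToUnits(rs, ot)
  expect_equal(unname(unassignedReads(to)), 0L)
  expect_equal(sum(unitCounts(to)[, 1]), 2)
  expect_error(mapReadsToUnits(rs, denoiseZOTUs(dereplicate(
    make_reads(character())))), "empty")
})

test_that("every mapped read meets its method identity threshold", {
  sc <- small_scenario(n_taxa = 10, depth_rdna = 800, depth_rrna = 800,
                       sub_error_rate = 0.002, seed = 17)
  com <- simulateCommunity(sc)
  pipe <- runActivityPipeline(com, sc, "OTU")
  reps <- as.character(unitRepresentatives(pipe$units))
  counts <- unitCounts(pipe$table)
  # spot-check by re-alignment: every read of 30 random assigned uniques
  set.seed(1)
  seqs <- as.character(pipe$reads[[1]])
  tab <- table(seqs)
  for (s in sample(names(tab), min(30, length(tab)))) {
    idents <- vapply(reps, function(r) pairwiseIdentity(s, r), numeric(1))
    assigned <- any(idents >= 0.97)
    # reads the mapper assigned must clear the threshold; column sums
    # plus unassigned must account for all reads
    if (!assigned) expect_lt(max(idents), 0.97)
  }
  expect_equal(sum(counts[, 1]) + unassignedReads(pipe$table)[[1]],
               length(seqs))
})

test_that("contaminant removal applies the strict >5 percent mean rule", {
  # u1: 6% of control reads on average -> removed everywhere;
  # u2: absent from controls -> retained; u3: the dominant kit contaminant
  m <- matrix(c(60L, 0L, 940L,
                60L, 0L, 940L,
                100L, 100L, 100L,
                100L, 100L, 100L),
              ncol = 4,
              dimnames = list(c("u1", "u2", "u3"),
                              c("N1|control", "N2|control",
                                "S1|rDNA", "S1|rRNA")))
  tab <- unitCountTable(m)
  out <- removeContaminants(tab, c("N1|control", "N2|control"))
  expect_identical(rownames(out), "u2")
  expect_setequal(S4Vectors::metadata(out)$contaminants, c("u1", "u3"))
  # column totals never increase
  expect_true(all(colSums(unitCounts(out)) <= colSums(unitCounts(tab))))
  # exactly 5.0% is retained (rule is strictly greater)
  m2 <- m; m2[1, 1:2] <- 50L; m2[3, 1:2] <- 950L
  out2 <- removeContaminants(unitCountTable(m2),
                             c("N1|control", "N2|control"))
  expect_true("u1" %in% rownames(out2))
  # a zero-read control contributes zero to the average: mean(0, 6%) = 3%
  m3 <- m; m3[, 1] <- 0L
  out3 <- removeContaminants(unitCountTable(m3),
                             c("N1|control", "N2|control"))
  expect_true("u1" %in% rownames(out3))
})

test_that("ZOTU to OTU cross-mapping follows clustering membership", {
  sc <- small_scenario(n_taxa = 15, depth_rdna = 3000, depth_rrna = 3000,
                       seed = 23)
  com <- simulateCommunity(sc)
  reads <- list(
    `S1|rDNA` = qualityFilter(sampleAmpliconReads(com, sc, "rDNA")),
    `S1|rRNA` = qualityFilter(sampleAmpliconReads(com, sc, "rRNA")))
  uq <- dereplicate(reads)
  zot <- denoiseZOTUs(uq)
  ot <- clusterOTUs(uq)
  cm <- crossMapUnits(zot, ot)
  # a ZOTU identical to an OTU representative maps to it
  reps_o <- as.character(unitRepresentatives(ot))
  reps_z <- as.character(unitRepresentatives(zot))
  shared <- which(reps_z %in% reps_o)
  expect_true(length(shared) > 0)
  for (i in shared)
    expect_identical(
      unname(reps_o[match(cm$otu_id[i], unitIds(ot))]),
      unname(reps_z[i]))
  # every ZOTU whose sequence joined an OTU during clustering maps back to
  # that OTU
  mem <- unitMembers(ot)
  for (oi in seq_along(mem)) {
    for (s in mem[[oi]]$sequence) {
      zi <- match(s, reps_z)
      if (!is.na(zi))
        expect_identical(cm$otu_id[zi], unitIds(ot)[oi])
    }
  }
  expect_equal(sum(attr(cm, "recruits")), sum(!is.na(cm$otu_id)))
  # a ZOTU below 97% to every OTU representative stays unmapped
  lone <- denoiseZOTUs(dereplicate(make_reads(rep(random_dna(1, 250), 10))))
  cm2 <- crossMapUnits(lone, ot)
  expect_true(is.na(cm2$otu_id[1]))
})

test_that("zero-error pipelines recover exactly the true references", {
  sc <- small_scenario(n_taxa = 25, depth_rdna = 4000, depth_rrna = 4000,
                       seed = 31)
  com <- simulateCommunity(sc)
  reads <- list(
    `S1|rDNA` = qualityFilter(sampleAmpliconReads(com, sc, "rDNA")),
    `S1|rRNA` = qualityFilter(sampleAmpliconReads(com, sc, "rRNA")))
  uq <- dereplicate(reads)
  zot <- denoiseZOTUs(uq)
  truth_counts <- table(factor(c(truthLabels(reads[[1]]),
                                 truthLabels(reads[[2]])),
                               levels = taxonIds(com)))
  expected <- unname(as.character(references(com))[truth_counts >= 8])
  expect_setequal(unname(as.character(unitRepresentatives(zot))), expected)
})
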