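test_that("generator honours the empty, probability-one and determinism contracts", {
  empty <- simulateTranscripts(simConfig(seed = 1, nTranscripts = 0))
  expect_length(empty$transcripts, 0L)
  expect_identical(nrow(empty$truth), 0L)

  allTails <- simulateTranscripts(simConfig(seed = 1, nTranscripts = 50,
                                            polyAProb = 1))
  expect_true(all(allTails$truth$tailLength >= 5))

  a <- simulateTranscripts(simConfig(seed = 42, nTranscripts = 40))
  b <- simulateTranscripts(simConfig(seed = 42, nTranscripts = 40))
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  expect_identical(a$truth, b$truth)
  c_ <- simulateTranscripts(simConfig(seed = 43, nTranscripts = 40))
  expect_false(identical(as.character(a$transcripts),
                         as.character(c_$transcripts)))
})

test_that("invalid generator configurations name the offending field", {
  expect_error(simConfig(polyAProb = 1.5), "polyAProb")
  expect_error(simConfig(lengthRange = c(0, 10)), "lengthRange")
  expect_error(simConfig(tierMix = c(gold = 1, silver = 0, bronze = 0.5,
                                     untiered = 0)), "tierMix")
})

test_that("planted tails clip back to the core and vector plants purge", {
  cfg <- simConfig(seed = 19, nTranscripts = 120, polyAProb = 0.5,
                   vectorProb = 0.3)
  sim <- simulateTranscripts(cfg)
  clipped <- clipPolyAT(sim$transcripts)
  ## cores are tail-free by construction, so clipping recovers them exactly
  expect_identical(unname(Biostrings::width(clipped)),
                   sim$truth$coreLength)
  ## planted decoy segment sits at the recorded interval
  withVec <- sim$truth[!is.na(sim$truth$vectorStart), ]
  expect_gt(nrow(withVec), 0)
  ## categories recomputed from the match table agree with the plant
  m <- sim$vectorMatches
  cat_ <- categorizeVectorMatch(m$score, m$start, m$end,
                                Biostrings::width(clipped)[match(
                                  m$id, names(clipped))])
  expect_identical(unname(cat_),
                   sim$truth$vectorCategory[match(m$id, sim$truth$id)])
  kept <- purgeContaminated(clipped, m)
  shouldPurge <- sim$truth$id[sim$truth$vectorCategory %in%
                                c("Strong", "Moderate")]
  expect_identical(names(kept), setdiff(sim$truth$id, shouldPurge))
})

test_that("tier classifier round-trips the generated alignment table", {
  cfg <- simConfig(seed = 7, nTranscripts = 200)
  sim <- simulateTranscripts(cfg)
  hits <- simulateAlignments(sim$truth, cfg)
  res <- tierTable(hits, allIds = sim$truth$id)
  expect_identical(res$labels$tier[match(sim$truth$id, res$labels$id)],
                   sim$truth$tier)
  ## untiered-only truth may produce an empty table
  cfgU <- simConfig(seed = 3, nTranscripts = 10,
                    tierMix = c(gold = 0, silver = 0, bronze = 0,
                                untiered = 1))
  simU <- simulateTranscripts(cfgU)
  hitsU <- simulateAlignments(simU$truth, cfgU)
  resU <- tierTable(hitsU, allIds = simU$truth$id)
  expect_true(all(resU$labels$tier == "untiered"))
  ## gold transcripts shorter than the gold floor are rejected
  cfgBad <- simConfig(seed = 5, nTranscripts = 20, lengthRange = c(150, 250),
                      tierMix = c(gold = 1, silver = 0, bronze = 0,
                                  untiered = 0))
  simBad <- simulateTranscripts(cfgBad)
  expect_error(simulateAlignments(simBad$truth, cfgBad), "inconsistent")
})

test_that("family caller round-trips the generated top-HSP table", {
  cfg <- simConfig(seed = 11, nTranscripts = 200)
  sim <- simulateTranscripts(cfg)
  fh <- simulateFamilyHits(sim$truth, cfg, label = "GST")
  calls <- callFamily(fh, label = "GST")
  expect_identical(calls$member[match(sim$truth$id, calls$id)],
                   sim$truth$familyMember)
})

test_that("counts realise planted fold-changes and zero patterns", {
  de <- data.frame(index = c(5L, 10L, 15L),
                   fold = c(4, 4, 0.25),
                   contrast = c("female:male", "4th:2nd", "adults:nymphs"))
  cfg <- simConfig(seed = 23, nTranscripts = 150, deSpec = de,
                   zeroExprFrac = 0.05, meanDepth = 500)
  sim <- simulateTranscripts(cfg)
  cnt <- simulateCounts(sim$truth, cfg)
  tpm <- computeTpm(cnt$se)
  pooled <- poolGroups(cnt$se)$tpm
  expect_lt(abs(log2FoldChange(tpm[5, "female"], tpm[5, "male"]) - 2), 0.5)
  expect_lt(abs(log2FoldChange(tpm[10, "4th"], tpm[10, "2nd"]) - 2), 0.5)
  expect_lt(abs(log2FoldChange(pooled[15, "adults"],
                               pooled[15, "nymphs"]) + 2), 0.5)
  ## planted zeros are exact
  counts <- SummarizedExperiment::assay(cnt$se, "counts")
  for (j in seq_len(nrow(cnt$zeroPattern))) {
    i <- cnt$zeroPattern$index[j]
    cols <- switch(cnt$zeroPattern$pattern[j],
                   both_fm_zero = c("female", "male"),
                   female_zero = "female", male_zero = "male")
    expect_true(all(counts[i, cols] == 0))
  }
  ## zeroExprFrac = 0: no zero counts anywhere at this depth
  cfg0 <- simConfig(seed = 29, nTranscripts = 100, zeroExprFrac = 0,
                    meanDepth = 500)
  sim0 <- simulateTranscripts(cfg0)
  cnt0 <- simulateCounts(sim0$truth, cfg0)
  expect_true(all(SummarizedExperiment::assay(cnt0$se, "counts") > 0))
  ## determinism
  cnt0b <- simulateCounts(sim0$truth, cfg0)
  expect_identical(SummarizedExperiment::assay(cnt0$se, "counts"),
                   SummarizedExperiment::assay(cnt0b$se, "counts"))
})

test_that("toy ontology construction guarantees hold and map is well-formed", {
  ont <- simulateOntology(nPerAspect = 15, depth = 3, seed = 2)
  g <- ont$graph
  expect_identical(sort(unique(ontologyTerms(g)$aspect)),
                   sort(c("biological_process", "cellular_component",
                          "molecular_function")))
  ## brute-force path enumeration finds a root for every non-root term
  for (term in setdiff(ontologyTerms(g)$id, aspectRoots(g))) {
    root <- aspectRoots(g)[[ontologyTerms(g)$aspect[
      match(term, ontologyTerms(g)$id)]]]
    expect_gt(length(oraclePenultimate(term, g@parents, root)), 0)
  }
  ## depth = 1: every non-root term is a direct child of its root
  flat <- simulateOntology(nPerAspect = 6, depth = 1, seed = 2)$graph
  nonroot <- setdiff(ontologyTerms(flat)$id, aspectRoots(flat))
  expect_true(all(vapply(flat@parents[nonroot],
                         function(p) p %in% aspectRoots(flat), logical(1))))
  expect_true(all(ont$map$go %in% ontologyTerms(g)$id))
})

test_that("fixture files are byte-identical across reruns of one config", {
  cfg <- simConfig(seed = 31, nTranscripts = 30)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  f1 <- writeFixtures(cfg, d1)
  f2 <- writeFixtures(cfg, d2)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), info = k)
})
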