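diamond <- function() {
  ontologyGraph(
    terms = data.frame(id = c("R", "a", "b", "t"),
                       name = c("root", "a", "b", "t"),
                       aspect = "molecular_function"),
    parents = list(R = character(), a = "R", b = "R", t = c("a", "b")))
}

test_that("penultimate-ancestor resolution handles the degenerate cases", {
  g <- diamond()
  expect_identical(resolveGoSlim("a", g), "a")       # child of root: itself
  expect_identical(resolveGoSlim("t", g), c("a", "b"))  # both diamond arms
  expect_error(resolveGoSlim("R", g), "root")
  expect_error(resolveGoSlim("zz", g), "unknown")
})

test_that("slim resolution agrees with exhaustive path enumeration", {
  set.seed(77)
  for (rep in 1:20) {
    g <- randomOntology(sample(5:50, 1))
    root <- unname(aspectRoots(g))
    for (term in setdiff(ontologyTerms(g)$id, root)) {
      got <- resolveGoSlim(term, g)
      want <- oraclePenultimate(term, g@parents, root)
      expect_identical(got, want, info = term)
      ## never empty, always direct children of the root
      expect_gt(length(got), 0)
      expect_true(all(vapply(got, function(u) root %in% g@parents[[u]],
                             logical(1))))
    }
  }
})

test_that("ontology validity rejects cycles and cross-aspect edges", {
  expect_error(ontologyGraph(
    terms = data.frame(id = c("R", "a", "b"), name = c("r", "a", "b"),
                       aspect = "molecular_function"),
    parents = list(R = character(), a = c("R", "b"), b = "a"),
    roots = c(molecular_function = "R")), "acyclic")
  expect_error(ontologyGraph(
    terms = data.frame(id = c("R1", "R2", "a"), name = c("r1", "r2", "a"),
                       aspect = c("molecular_function", "biological_process",
                                  "molecular_function")),
    parents = list(R1 = character(), R2 = character(), a = "R2")),
    "cross aspects")
})

test_that("OBO subset round-trips and drops obsolete terms with a warning", {
  sim <- simulateOntology(nPerAspect = 8, depth = 3, seed = 4)
  f <- tempfile(fileext = ".obo")
  writeObo(sim$graph, f)
  g2 <- readObo(f)
  expect_identical(ontologyTerms(g2), ontologyTerms(sim$graph))
  expect_identical(g2@parents, sim$graph@parents)
  ## append an obsolete stanza: dropped with a warning
  cat("[Term]\nid: GO:9999999\nname: gone\nnamespace: molecular_function\n",
      "is_obsolete: true\n", sep = "", file = f, append = TRUE)
  expect_warning(g3 <- readObo(f), "obsolete")
  expect_false("GO:9999999" %in% ontologyTerms(g3)$id)
})

test_that("pfam2go mapping strips versions and joins like a brute force", {
  a <- data.frame(id = c("t1", "t1", "t2", "t3"),
                  pfam = c("PF00067.20", "PF00001", "PF00067", "PF99999"))
  m <- data.frame(pfam = c("PF00067", "PF00067", "PF00001"),
                  go = c("GO:1", "GO:2", "GO:3"))
  got <- mapPfamToGo(a, m)
  ## brute-force join on version-stripped accessions
  want <- unique(do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    hit <- m$go[m$pfam == sub("\\.\\d+$", "", a$pfam[i])]
    if (!length(hit)) NULL else data.frame(id = a$id[i], go = hit)
  })))
  want <- want[order(want$id, want$go), ]
  expect_identical(unname(as.matrix(got)), unname(as.matrix(want)))
  ## transcript with no Pfams contributes nothing
  expect_identical(nrow(mapPfamToGo(a[0, ], m)), 0L)
})

test_that("distinct-term counts per aspect match set sizes, full and slim", {
  sim <- simulateOntology(nPerAspect = 12, depth = 3, seed = 6)
  g <- sim$graph
  tm <- ontologyTerms(g)
  nonroot <- tm[!tm$id %in% aspectRoots(g), ]
  set.seed(8)
  pairs <- data.frame(id = paste0("t", sample(5, 30, TRUE)),
                      go = sample(nonroot$id, 30, TRUE))
  res <- countDistinctTerms(pairs, g)
  aspOf <- stats::setNames(tm$aspect, tm$id)
  for (a in unique(tm$aspect)) {
    inAspect <- unique(pairs$go[aspOf[pairs$go] == a])
    expect_identical(unname(res$full[a]), length(inAspect))
    slimSet <- unique(unlist(lapply(inAspect, resolveGoSlim, g = g)))
    expect_identical(unname(res$slim[a]),
                     length(slimSet[aspOf[slimSet] == a]))
    ## slim is a projection: never more distinct terms than full
    expect_lte(res$slim[a], res$full[a])
  }
  z <- countDistinctTerms(pairs[0, ], g)
  expect_true(all(z$full == 0) && all(z$slim == 0))
})

test_that("slim assignment table is order-independent", {
  sim <- simulateOntology(nPerAspect = 10, depth = 2, seed = 12)
  tm <- ontologyTerms(sim$graph)
  nonroot <- tm$id[!tm$id %in% aspectRoots(sim$graph)]
  set.seed(2)
  pairs <- data.frame(id = paste0("t", sample(4, 20, TRUE)),
                      go = sample(nonroot, 20, TRUE))
  a1 <- slimAssignments(pairs, sim$graph)
  a2 <- slimAssignments(pairs[sample(nrow(pairs)), ], sim$graph)
  rownames(a1) <- rownames(a2) <- NULL
  expect_identical(a1, a2)
})

test_that("Pfam abundance table ranks by count then accession", {
  a <- data.frame(id = c("t1", "t2", "t3", "t4", "t1"),
                  pfam = c("PF2", "PF2", "PF2", "PF1", "PF1"))
  tab <- tabulatePfam(a, topK = 1)
  expect_identical(tab$pfam, "PF2")
  expect_identical(tab$count, 3L)
  full <- tabulatePfam(a, topK = 10)
  expect_identical(full$pfam, c("PF2", "PF1"))
  ## duplicate (transcript, pfam) rows count once
  expect_identical(full$count, c(3L, 2L))
  expect_error(tabulatePfam(a, topK = -1), "nonnegative")
})
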