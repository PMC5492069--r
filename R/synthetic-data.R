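## Small bundled decoy "vector" sequences planted as contamination; stand-ins
## for cloning-vector fragments so fixtures need no external database.
.vectorDecoys <- c(
  dec1 = "GGCCGCTCTAGAACTAGTGGATCCCCCGGGCTGCAGGAATTCGATATCAAGCTTATCGAT",
  dec2 = "CTAAATTGTAAGCGTTAATATTTTGTTAAAATTCGCGTTAAATTTTTGTTAAATCAGCTC",
  dec3 = "GTGTGGAATTGTGAGCGGATAACAATTTCACACAGGAAACAGCTATGACCATGATTACGC")

.randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate assembled transcripts with ground truth
#'
#' Generates random transcript sequences emulating a de novo assembly's
#' post-processing inputs: a fraction carry a residual 3' poly-A or 5'
#' poly-T tail (recorded length >= 5), a fraction carry a planted vector
#' segment from a small bundled decoy set (recorded 0-based half-open
#' interval on the tail-free core), and every transcript is assigned a
#' ground-truth homology tier and gene-family flag for round-trip testing.
#' Core sequences start with C and end with G, so a core never extends a
#' planted tail and tail clipping recovers the core exactly.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return List with \code{transcripts} (named
#'   \code{\link[Biostrings]{DNAStringSet}}), \code{truth} (one data.frame
#'   row per transcript: tier, family flag, tail and vector plants, Pfam
#'   accessions) and \code{vectorMatches} (vector-screen-style match
#'   data.frame on core coordinates).
#' @examples
#' sim <- simulateTranscripts(simConfig(seed = 7, nTranscripts = 20))
#' head(sim$truth)
#' @export
simulateTranscripts <- function(cfg) {
  methods::validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nTranscripts
  if (n == 0L) {
    empty <- Biostrings::DNAStringSet()
    return(list(transcripts = empty,
                truth = data.frame(id = character(), coreLength = integer(),
                                   tier = character(), familyMember = logical(),
                                   tailLength = integer(), tailEnd = character(),
                                   vectorStart = integer(), vectorEnd = integer(),
                                   vectorCategory = character(),
                                   pfams = character()),
                vectorMatches = data.frame(id = character(), score = integer(),
                                           start = integer(), end = integer())))
  }
  ids <- sprintf("PUT%05d", seq_len(n))
  coreLen <- sample(seq(cfg@lengthRange[1], cfg@lengthRange[2]), n,
                    replace = TRUE)
  cores <- vapply(coreLen, function(L)
    paste0("C", .randSeq(L - 2L), "G"), character(1))

  ## plant vector segments inside the core (internal coordinates)
  hasVec <- stats::runif(n) < cfg@vectorProb
  vecStart <- vecEnd <- rep(NA_integer_, n)
  vecCat <- rep("None", n)
  score <- c(Strong = 35L, Moderate = 27L, Weak = 23L)
  matches <- list()
  for (i in which(hasVec)) {
    decoy <- .vectorDecoys[[sample(length(.vectorDecoys), 1L)]]
    seg <- substr(decoy, 1L, sample(30:60, 1L))
    maxStart <- coreLen[i] - nchar(seg) - 30L
    if (maxStart < 31L) { hasVec[i] <- FALSE; next }
    s0 <- sample(30:maxStart, 1L)  # 0-based, internal (>= terminal window)
    substr(cores[i], s0 + 1L, s0 + nchar(seg)) <- seg
    vecStart[i] <- s0
    vecEnd[i] <- s0 + nchar(seg)
    vecCat[i] <- sample(names(score), 1L)
    matches[[length(matches) + 1L]] <- data.frame(
      id = ids[i], score = score[[vecCat[i]]], start = s0,
      end = s0 + nchar(seg))
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(id = character(), score = integer(), start = integer(),
               end = integer())

  ## residual poly-A/T tails outside the core
  hasTail <- stats::runif(n) < cfg@polyAProb
  tailLen <- ifelse(hasTail, sample(5:30, n, replace = TRUE), 0L)
  tailEnd <- ifelse(hasTail, sample(c("3A", "5T"), n, replace = TRUE), "")
  seqs <- cores
  threeP <- hasTail & tailEnd == "3A"
  fiveP <- hasTail & tailEnd == "5T"
  seqs[threeP] <- paste0(cores[threeP], strrep("A", tailLen[threeP]))
  seqs[fiveP] <- paste0(strrep("T", tailLen[fiveP]), cores[fiveP])

  tier <- sample(names(cfg@tierMix), n, replace = TRUE, prob = cfg@tierMix)
  familyMember <- stats::runif(n) < 0.2
  pfams <- vapply(seq_len(n), function(i) {
    k <- sample(0:2, 1L)
    if (k == 0L) "" else
      paste(sprintf("PF9%04d", sample(10L, k)), collapse = ",")
  }, character(1))

  transcripts <- Biostrings::DNAStringSet(seqs)
  names(transcripts) <- ids
  truth <- data.frame(
    id = ids, coreLength = coreLen, tier = tier,
    familyMember = familyMember,
    tailLength = as.integer(tailLen), tailEnd = tailEnd,
    vectorStart = vecStart, vectorEnd = vecEnd, vectorCategory = vecCat,
    pfams = pfams, stringsAsFactors = FALSE)
  list(transcripts = transcripts, truth = truth, vectorMatches = matches)
}

#' Simulate a protein-alignment table matching a truth table
#'
#' Engineers one alignment summary per tiered transcript that satisfies
#' exactly its true tier's rule and fails all stricter tiers; untiered
#' transcripts receive either no hit or a hit failing the bronze coverage
#' floor. A random subset of tiered transcripts additionally receives a
#' low-bitscore decoy hit to exercise best-hit selection.
#'
#' @param truth Truth data.frame from \code{\link{simulateTranscripts}}.
#' @param cfg The \code{\link{simConfig}} used to generate it.
#' @return data.frame in the \code{\link{readAlignmentTable}} dialect.
#' @export
simulateAlignments <- function(truth, cfg) {
  set.seed(cfg@seed + 1L)
  t <- tierThresholds()
  short <- truth$tier == "gold" & truth$coreLength < t@goldMinQueryNt
  if (any(short))
    stop("tier mix inconsistent with truth: gold transcript(s) shorter ",
         "than ", t@goldMinQueryNt, " nt")
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tier <- truth$tier[i]
    qlen <- truth$coreLength[i]
    row <- switch(tier,
      gold = data.frame(slen = 100, length = 95, positive = 90, n_hsps = 1L),
      silver = data.frame(slen = 100, length = 80, positive = 70,
                          n_hsps = 2L),
      bronze = data.frame(slen = 100, length = 50, positive = 40,
                          n_hsps = 1L),
      untiered = if (stats::runif(1) < 0.5) NULL else
        data.frame(slen = 100, length = 20, positive = 10, n_hsps = 1L))
    if (is.null(row)) next
    row <- cbind(data.frame(qseqid = truth$id[i], qlen = qlen,
                            sseqid = sprintf("SUBJ%05d", i)),
                 row,
                 data.frame(bitscore = round(stats::runif(1, 200, 300), 1)))
    rows[[length(rows) + 1L]] <- row
    if (tier != "untiered" && stats::runif(1) < 0.2)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = truth$id[i], qlen = qlen,
        sseqid = sprintf("DECOY%05d", i), slen = 100, length = 20,
        positive = 10, n_hsps = 1L, bitscore = 50)
  }
  if (!length(rows))
    return(data.frame(qseqid = character(), qlen = numeric(),
                      sseqid = character(), slen = numeric(),
                      length = numeric(), positive = numeric(),
                      n_hsps = integer(), bitscore = numeric()))
  out <- do.call(rbind, rows)
  cols <- c("qseqid", "qlen", "sseqid", "slen", "length", "positive",
            "bitscore", "n_hsps")
  out[, cols]
}

#' Simulate gene-family top-HSP hits matching a truth table
#'
#' For every transcript flagged a family member in the truth table, emits a
#' top-HSP row passing all five membership thresholds; for every
#' non-member, a row failing exactly one randomly chosen criterion. Query
#' lengths are in amino acids (longest-ORF scale).
#'
#' @param truth Truth data.frame from \code{\link{simulateTranscripts}}.
#' @param cfg The matching \code{\link{simConfig}}.
#' @param label Family label recorded in the calls (default \code{"GST"}).
#' @return data.frame of top-HSP rows (\code{qseqid}, \code{qlen},
#'   \code{sseqid}, \code{slen}, \code{length}, \code{positive},
#'   \code{bitscore}).
#' @export
simulateFamilyHits <- function(truth, cfg, label = "GST") {
  set.seed(cfg@seed + 2L)
  t <- familyThresholds()
  n <- nrow(truth)
  slen <- sample(100:300, n, replace = TRUE)
  hit <- ceiling(slen * 0.95)
  qlen <- floor(hit / 0.80)          # hit/query ~ 0.84 > 0.75
  positive <- ceiling(hit * 0.85)
  bitscore <- round(stats::runif(n, 80, 200), 1)
  fail <- sample(c("bit", "subject", "hitSubject", "hitQuery", "positive"),
                 n, replace = TRUE)
  for (i in which(!truth$familyMember)) {
    switch(fail[i],
      bit = { bitscore[i] <- t@minBitscore - 0.1 },
      subject = { slen[i] <- t@minSubjectAa - 1L
                  hit[i] <- ceiling(slen[i] * 0.95)
                  qlen[i] <- floor(hit[i] / 0.80)
                  positive[i] <- ceiling(hit[i] * 0.85) },
      hitSubject = { hit[i] <- floor(slen[i] * 0.80)
                     qlen[i] <- floor(hit[i] / 0.80)
                     positive[i] <- ceiling(hit[i] * 0.85) },
      hitQuery = { qlen[i] <- ceiling(hit[i] / 0.70) },
      positive = { positive[i] <- floor(hit[i] * 0.70) })
  }
  data.frame(qseqid = truth$id, qlen = qlen,
             sseqid = sprintf("%s_REF%03d", label,
                              sample(20L, n, replace = TRUE)),
             slen = slen, length = hit, positive = positive,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Simulate a four-sample count matrix with planted fold-changes
#'
#' Draws nonnegative integer counts for the four samples (2nd, 4th, female,
#' male) from Poisson distributions whose means realise planted TPM-scale
#' fold-changes in expectation. Baseline abundances are log-normal across
#' transcripts and equal across samples; a \code{deSpec} entry
#' \code{(index, fold, contrast)} multiplies the numerator group's TPM
#' target by \code{fold}. A \code{zeroExprFrac} subset receives exact zeros
#' in designated samples to exercise the undefined/plus-minus-infinity
#' contrast sentinels.
#'
#' @param truth Truth data.frame from \code{\link{simulateTranscripts}}.
#' @param cfg The matching \code{\link{simConfig}}.
#' @return List with \code{se} (a \code{SummarizedExperiment} from
#'   \code{\link{countMatrix}}, effective length = core transcript length)
#'   and \code{zeroPattern} (data.frame: \code{index}, \code{pattern}).
#' @export
simulateCounts <- function(truth, cfg) {
  set.seed(cfg@seed + 3L)
  n <- nrow(truth)
  if (n == 0L) stop("truth table is empty")
  base <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.5)
  tpm <- matrix(base, n, 4L,
                dimnames = list(truth$id, .sampleLabels))
  if (nrow(cfg@deSpec)) {
    for (k in seq_len(nrow(cfg@deSpec))) {
      i <- cfg@deSpec$index[k]
      f <- cfg@deSpec$fold[k]
      num <- contrastColumns(cfg@deSpec$contrast[k])[1]
      cols <- switch(num,
                     adults = c("female", "male"),
                     nymphs = c("2nd", "4th"),
                     num)
      tpm[i, cols] <- tpm[i, cols] * f
    }
  }
  deIdx <- if (nrow(cfg@deSpec)) unique(cfg@deSpec$index) else integer()
  nz <- round(cfg@zeroExprFrac * n)
  zeroPattern <- data.frame(index = integer(), pattern = character())
  if (nz > 0L) {
    pool <- setdiff(seq_len(n), deIdx)
    pick <- sample(pool, min(nz, length(pool)))
    pat <- sample(c("both_fm_zero", "female_zero", "male_zero"),
                  length(pick), replace = TRUE)
    for (j in seq_along(pick)) {
      cols <- switch(pat[j], both_fm_zero = c("female", "male"),
                     female_zero = "female", male_zero = "male")
      tpm[pick[j], cols] <- 0
    }
    zeroPattern <- data.frame(index = pick, pattern = pat)
  }
  lens <- truth$coreLength
  counts <- vapply(.sampleLabels, function(s) {
    w <- tpm[, s] * lens
    lambda <- if (sum(w) > 0) w / sum(w) * cfg@meanDepth * n else w
    stats::rpois(n, lambda)
  }, numeric(n))
  if (n == 1L)
    counts <- matrix(counts, 1L, dimnames = list(truth$id, .sampleLabels))
  rownames(counts) <- truth$id
  list(se = countMatrix(counts, lens), zeroPattern = zeroPattern)
}

#' Simulate a rooted three-aspect toy ontology and Pfam map
#'
#' Builds one rooted is_a DAG per GO aspect: terms are arranged in levels
#' below the root, every level-1 term is a direct child of the root, and
#' each deeper term draws one or two parents from the level above (so the
#' graph is acyclic and every term reaches its root). Also builds a
#' pfam2go-style map associating each supplied Pfam accession with zero or
#' more terms.
#'
#' @param nPerAspect Non-root terms per aspect.
#' @param depth Number of levels below each root (\code{depth = 1} makes
#'   every term a direct child of its root).
#' @param seed RNG seed.
#' @param pfams Character vector of Pfam accessions to map (default the ten
#'   synthetic accessions used by \code{\link{simulateTranscripts}}).
#' @return List with \code{graph} (an \code{\link{OntologyGraph}}) and
#'   \code{map} (data.frame: \code{pfam}, \code{go}).
#' @examples
#' simulateOntology(nPerAspect = 6, depth = 2, seed = 1)$graph
#' @export
simulateOntology <- function(nPerAspect = 10L, depth = 3L, seed = 1L,
                             pfams = sprintf("PF9%04d", 1:10)) {
  stopifnot(nPerAspect >= 1L, depth >= 1L)
  set.seed(seed)
  ids <- names <- aspects <- character()
  parents <- list()
  roots <- character()
  counter <- 0L
  for (a in .aspects) {
    counter <- counter + 1L
    root <- sprintf("GO:%07d", counter * 1000000L)
    roots[[a]] <- root
    ids <- c(ids, root); names <- c(names, paste0(a, " root"))
    aspects <- c(aspects, a)
    parents[[root]] <- character()
    perLevel <- diff(round(seq(0, nPerAspect, length.out = depth + 1L)))
    perLevel[perLevel == 0L] <- 1L
    perLevel <- perLevel[seq_len(depth)]
    prev <- root
    made <- 0L
    for (lev in seq_len(depth)) {
      if (made >= nPerAspect) break
      k <- min(perLevel[lev], nPerAspect - made)
      lvl <- character(k)
      for (j in seq_len(k)) {
        made <- made + 1L
        id <- sprintf("GO:%07d", counter * 1000000L + made)
        lvl[j] <- id
        npar <- if (lev == 1L) 1L else sample(1:min(2L, length(prev)), 1L)
        parents[[id]] <- if (lev == 1L) root else
          sample(prev, npar)
        ids <- c(ids, id)
        names <- c(names, sprintf("%s term %d", a, made))
        aspects <- c(aspects, a)
      }
      prev <- lvl
    }
  }
  g <- ontologyGraph(data.frame(id = ids, name = names, aspect = aspects,
                                stringsAsFactors = FALSE),
                     parents, roots = roots)
  nonroot <- setdiff(ids, roots)
  map <- do.call(rbind, lapply(pfams, function(p) {
    k <- sample(0:3, 1L)
    if (k == 0L) NULL else
      data.frame(pfam = p, go = sample(nonroot, k),
                 stringsAsFactors = FALSE)
  }))
  if (is.null(map))
    map <- data.frame(pfam = character(), go = character())
  list(graph = g, map = map)
}

#' Write a complete fixture set to disk
#'
#' Runs the whole generator for one \code{\link{simConfig}} and writes every
#' downstream input as plain text: transcripts (FASTA), vector matches,
#' alignment and family-hit tables, counts, truth table (TSV), the toy
#' ontology (OBO subset) and the pfam2go map. Identical configs give
#' byte-identical files.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writeFixtures <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateTranscripts(cfg)
  hits <- simulateAlignments(sim$truth, cfg)
  fam <- simulateFamilyHits(sim$truth, cfg)
  cnt <- simulateCounts(sim$truth, cfg)
  ont <- simulateOntology(seed = cfg@seed + 4L)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(sim$transcripts, p("transcripts.fa"))
  wt <- function(d, f) utils::write.table(
    d, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$vectorMatches, "vector_matches.tsv")
  wt(hits, "alignments.tsv")
  wt(fam, "family_hits.tsv")
  counts <- SummarizedExperiment::assay(cnt$se, "counts")
  cd <- data.frame(transcript = rownames(counts),
                   length = SummarizedExperiment::rowData(cnt$se)$effLength,
                   counts, check.names = FALSE)
  names(cd) <- c("transcript", "length", colnames(counts))
  wt(cd, "counts.tsv")
  wt(sim$truth, "truth.tsv")
  writeObo(ont$graph, p("ontology.obo"))
  wt(ont$map, "pfam2go.tsv")
  pa <- sim$truth[nzchar(sim$truth$pfams), c("id", "pfams")]
  pfamRows <- if (nrow(pa)) do.call(rbind, lapply(seq_len(nrow(pa)),
    function(i) data.frame(id = pa$id[i],
                           pfam = strsplit(pa$pfams[i], ",")[[1]]))) else
    data.frame(id = character(), pfam = character())
  wt(pfamRows, "pfam_assignments.tsv")
  invisible(stats::setNames(
    p(c("transcripts.fa", "vector_matches.tsv", "alignments.tsv",
        "family_hits.tsv", "counts.tsv", "truth.tsv", "ontology.obo",
        "pfam2go.tsv", "pfam_assignments.tsv")),
    c("transcripts", "vectorMatches", "alignments", "familyHits", "counts",
      "truth", "ontology", "pfam2go", "pfamAssignments")))
}
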