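#' @import methods
NULL

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' Transcript QC configuration
#'
#' Parameters controlling post-assembly cleanup: poly-A/T tail clipping,
#' the minimum-length filter and the vector-screen category ladder.
#'
#' A vector-screen match is *terminal* when it begins within
#' \code{terminalWindow} nucleotides of either sequence end; otherwise it is
#' *internal*. The six score thresholds form two descending ladders
#' (Strong > Moderate > Weak), one per position class, mirroring the NCBI
#' VecScreen classification scheme.
#'
#' @slot minTailRun integer, minimum homopolymer run length clipped from a
#'   transcript end (default 5).
#' @slot minLength integer, minimum post-clip transcript length in nt kept by
#'   the length filter (default 200).
#' @slot terminalWindow integer, nt from either end within which a match is
#'   considered terminal (default 25).
#' @slot strongTerminal,moderateTerminal,weakTerminal integer score floors for
#'   terminal matches (defaults 24, 19, 16).
#' @slot strongInternal,moderateInternal,weakInternal integer score floors for
#'   internal matches (defaults 30, 25, 23).
#' @name QcConfig-class
#' @rdname QcConfig
#' @exportClass QcConfig
setClass("QcConfig",
  representation(
    minTailRun = "integer",
    minLength = "integer",
    terminalWindow = "integer",
    strongTerminal = "integer",
    moderateTerminal = "integer",
    weakTerminal = "integer",
    strongInternal = "integer",
    moderateInternal = "integer",
    weakInternal = "integer"
  )
)

setValidity("QcConfig", function(object) {
  msg <- character()
  if (length(object@minLength) != 1L || is.na(object@minLength) ||
      object@minLength < 1L)
    msg <- c(msg, "minLength must be a single integer >= 1")
  if (length(object@minTailRun) != 1L || is.na(object@minTailRun) ||
      object@minTailRun < 1L)
    msg <- c(msg, "minTailRun must be a single integer >= 1")
  if (length(object@terminalWindow) != 1L || is.na(object@terminalWindow) ||
      object@terminalWindow < 0L)
    msg <- c(msg, "terminalWindow must be a single integer >= 0")
  if (!(object@strongTerminal > object@moderateTerminal &&
        object@moderateTerminal > object@weakTerminal))
    msg <- c(msg, "terminal thresholds must satisfy strong > moderate > weak")
  if (!(object@strongInternal > object@moderateInternal &&
        object@moderateInternal > object@weakInternal))
    msg <- c(msg, "internal thresholds must satisfy strong > moderate > weak")
  if (length(msg)) msg else TRUE
})

#' @param minTailRun,minLength,terminalWindow,strongTerminal,moderateTerminal,weakTerminal,strongInternal,moderateInternal,weakInternal
#'   see slot documentation.
#' @return A \code{QcConfig} object.
#' @examples
#' qcConfig(minLength = 200)
#' @rdname QcConfig
#' @export
qcConfig <- function(minTailRun = 5L, minLength = 200L, terminalWindow = 25L,
                     strongTerminal = 24L, moderateTerminal = 19L,
                     weakTerminal = 16L, strongInternal = 30L,
                     moderateInternal = 25L, weakInternal = 23L) {
  new("QcConfig",
      minTailRun = as.integer(minTailRun),
      minLength = as.integer(minLength),
      terminalWindow = as.integer(terminalWindow),
      strongTerminal = as.integer(strongTerminal),
      moderateTerminal = as.integer(moderateTerminal),
      weakTerminal = as.integer(weakTerminal),
      strongInternal = as.integer(strongInternal),
      moderateInternal = as.integer(moderateInternal),
      weakInternal = as.integer(weakInternal))
}

setMethod("show", "QcConfig", function(object) {
  cat("QcConfig\n",
      "  minTailRun: ", object@minTailRun,
      "  minLength: ", object@minLength, " nt\n",
      "  terminal (<=", object@terminalWindow, " nt from an end): ",
      "Strong>=", object@strongTerminal,
      " Moderate>=", object@moderateTerminal,
      " Weak>=", object@weakTerminal, "\n",
      "  internal: Strong>=", object@strongInternal,
      " Moderate>=", object@moderateInternal,
      " Weak>=", object@weakInternal, "\n", sep = "")
})

#' Homology-tier thresholds
#'
#' Cut-offs for the gold/silver/bronze annotation-confidence partition of
#' transcripts based on their best protein alignment. A gold call requires a
#' query of at least \code{goldMinQueryNt} nt whose hit consists of a single
#' HSP against a subject of at least \code{goldMinSubjectAa} aa, with at least
#' \code{goldMinPositiveFrac} of aligned residues positively similar and a
#' hit-length/subject-length ratio of at least \code{goldMinHitSubjectRatio}.
#' Silver and bronze relax this to a minimum query length plus a
#' subject-coverage floor.
#'
#' @slot goldMinQueryNt,goldMinSubjectAa integer floors (defaults 300 nt,
#'   100 aa).
#' @slot goldMinPositiveFrac,goldMinHitSubjectRatio numeric fractions
#'   (defaults 0.75, 0.90).
#' @slot silverMinQueryNt,bronzeMinQueryNt integer floors (default 100 nt).
#' @slot silverMinSubjectCov,bronzeMinSubjectCov numeric subject-coverage
#'   floors (defaults 0.75, 0.30).
#' @name TierThresholds-class
#' @rdname TierThresholds
#' @exportClass TierThresholds
setClass("TierThresholds",
  representation(
    goldMinQueryNt = "numeric",
    goldMinSubjectAa = "numeric",
    goldMinPositiveFrac = "numeric",
    goldMinHitSubjectRatio = "numeric",
    silverMinQueryNt = "numeric",
    silverMinSubjectCov = "numeric",
    bronzeMinQueryNt = "numeric",
    bronzeMinSubjectCov = "numeric"
  )
)

setValidity("TierThresholds", function(object) {
  msg <- character()
  fr <- c(object@goldMinPositiveFrac, object@goldMinHitSubjectRatio,
          object@silverMinSubjectCov, object@bronzeMinSubjectCov)
  if (any(fr <= 0) || any(fr > 1))
    msg <- c(msg, "all fractional thresholds must lie in (0, 1]")
  if (object@silverMinSubjectCov <= object@bronzeMinSubjectCov)
    msg <- c(msg, "silverMinSubjectCov must exceed bronzeMinSubjectCov")
  if (length(msg)) msg else TRUE
})

#' @param goldMinQueryNt,goldMinSubjectAa,goldMinPositiveFrac,goldMinHitSubjectRatio,silverMinQueryNt,silverMinSubjectCov,bronzeMinQueryNt,bronzeMinSubjectCov
#'   see slot documentation.
#' @return A \code{TierThresholds} object.
#' @examples
#' tierThresholds()
#' @rdname TierThresholds
#' @export
tierThresholds <- function(goldMinQueryNt = 300, goldMinSubjectAa = 100,
                           goldMinPositiveFrac = 0.75,
                           goldMinHitSubjectRatio = 0.90,
                           silverMinQueryNt = 100, silverMinSubjectCov = 0.75,
                           bronzeMinQueryNt = 100,
                           bronzeMinSubjectCov = 0.30) {
  new("TierThresholds",
      goldMinQueryNt = goldMinQueryNt, goldMinSubjectAa = goldMinSubjectAa,
      goldMinPositiveFrac = goldMinPositiveFrac,
      goldMinHitSubjectRatio = goldMinHitSubjectRatio,
      silverMinQueryNt = silverMinQueryNt,
      silverMinSubjectCov = silverMinSubjectCov,
      bronzeMinQueryNt = bronzeMinQueryNt,
      bronzeMinSubjectCov = bronzeMinSubjectCov)
}

setMethod("show", "TierThresholds", function(object) {
  cat("TierThresholds\n",
      "  gold:   query>=", object@goldMinQueryNt, " nt, 1 HSP, subject>=",
      object@goldMinSubjectAa, " aa, positives/hit>=",
      object@goldMinPositiveFrac, ", hit/subject>=",
      object@goldMinHitSubjectRatio, "\n",
      "  silver: query>=", object@silverMinQueryNt, " nt, hit/subject>=",
      object@silverMinSubjectCov, "\n",
      "  bronze: query>=", object@bronzeMinQueryNt, " nt, hit/subject>=",
      object@bronzeMinSubjectCov, "\n", sep = "")
})

#' Gene-family membership thresholds
#'
#' Five-way AND rule deciding whether a transcript's longest-ORF product
#' belongs to a curated gene family (GST/COE style), judged from its top HSP
#' against the family protein set: bit score, subject length, hit/subject
#' ratio, hit/query ratio and positive-similarity fraction must all clear
#' their floors.
#'
#' @slot minBitscore numeric (default 75).
#' @slot minSubjectAa numeric, subject length floor in aa (default 100).
#' @slot minHitSubjectRatio numeric (default 0.90).
#' @slot minHitQueryRatio numeric (default 0.75).
#' @slot minPositiveFrac numeric (default 0.80).
#' @name FamilyThresholds-class
#' @rdname FamilyThresholds
#' @exportClass FamilyThresholds
setClass("FamilyThresholds",
  representation(
    minBitscore = "numeric",
    minSubjectAa = "numeric",
    minHitSubjectRatio = "numeric",
    minHitQueryRatio = "numeric",
    minPositiveFrac = "numeric"
  )
)

setValidity("FamilyThresholds", function(object) {
  msg <- character()
  fr <- c(object@minHitSubjectRatio, object@minHitQueryRatio,
          object@minPositiveFrac)
  if (any(fr <= 0) || any(fr > 1))
    msg <- c(msg, "ratio thresholds must lie in (0, 1]")
  if (object@minBitscore <= 0)
    msg <- c(msg, "minBitscore must be positive")
  if (length(msg)) msg else TRUE
})

#' @param minBitscore,minSubjectAa,minHitSubjectRatio,minHitQueryRatio,minPositiveFrac
#'   see slot documentation.
#' @return A \code{FamilyThresholds} object.
#' @examples
#' familyThresholds()
#' @rdname FamilyThresholds
#' @export
familyThresholds <- function(minBitscore = 75, minSubjectAa = 100,
                             minHitSubjectRatio = 0.90,
                             minHitQueryRatio = 0.75,
                             minPositiveFrac = 0.80) {
  new("FamilyThresholds",
      minBitscore = minBitscore, minSubjectAa = minSubjectAa,
      minHitSubjectRatio = minHitSubjectRatio,
      minHitQueryRatio = minHitQueryRatio,
      minPositiveFrac = minPositiveFrac)
}

setMethod("show", "FamilyThresholds", function(object) {
  cat("FamilyThresholds: bit>=", object@minBitscore,
      ", subject>=", object@minSubjectAa, " aa, hit/subject>=",
      object@minHitSubjectRatio, ", hit/query>=", object@minHitQueryRatio,
      ", positives/hit>=", object@minPositiveFrac, "\n", sep = "")
})

#' Expression contrast configuration
#'
#' Settings for replicate-free log2 fold-change contrasts between two
#' samples or pooled read groups. \code{tpmFloor} implements the floor on TPM
#' values; under \code{floorMode = "filter_min_both"} a transcript enters the
#' ranking only when both contrasted TPM values reach the floor, while
#' \code{"clamp"} instead replaces each TPM by \code{max(tpm, tpmFloor)}.
#'
#' @slot contrast character, one of \code{"4th:2nd"}, \code{"female:male"},
#'   \code{"adults:nymphs"}.
#' @slot tpmFloor numeric TPM floor (default 5).
#' @slot minFold numeric minimum fold differential of interest (default 2).
#' @slot floorMode character, \code{"filter_min_both"} (default) or
#'   \code{"clamp"}.
#' @slot topK integer, rows reported per direction (default 5).
#' @name ContrastConfig-class
#' @rdname ContrastConfig
#' @exportClass ContrastConfig
setClass("ContrastConfig",
  representation(
    contrast = "character",
    tpmFloor = "numeric",
    minFold = "numeric",
    floorMode = "character",
    topK = "integer"
  )
)

.validContrasts <- c("4th:2nd", "female:male", "adults:nymphs")

setValidity("ContrastConfig", function(object) {
  msg <- character()
  if (!object@contrast %in% .validContrasts)
    msg <- c(msg, paste0("contrast must be one of ",
                         paste(.validContrasts, collapse = ", ")))
  if (object@tpmFloor < 0) msg <- c(msg, "tpmFloor must be >= 0")
  if (object@minFold < 1) msg <- c(msg, "minFold must be >= 1")
  if (!object@floorMode %in% c("filter_min_both", "clamp"))
    msg <- c(msg, "floorMode must be 'filter_min_both' or 'clamp'")
  if (object@topK < 1L) msg <- c(msg, "topK must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param contrast,tpmFloor,minFold,floorMode,topK see slot documentation.
#' @return A \code{ContrastConfig} object.
#' @examples
#' contrastConfig("female:male")
#' @rdname ContrastConfig
#' @export
contrastConfig <- function(contrast = "female:male", tpmFloor = 5,
                           minFold = 2, floorMode = "filter_min_both",
                           topK = 5L) {
  new("ContrastConfig", contrast = contrast, tpmFloor = tpmFloor,
      minFold = minFold, floorMode = floorMode, topK = as.integer(topK))
}

setMethod("show", "ContrastConfig", function(object) {
  cat("ContrastConfig: ", object@contrast, ", floor ", object@tpmFloor,
      " TPM (", object@floorMode, "), min fold ", object@minFold,
      ", top ", object@topK, " per direction\n", sep = "")
})

## ---------------------------------------------------------------------------
## Ontology graph
## ---------------------------------------------------------------------------

#' Rooted is_a ontology
#'
#' A Gene-Ontology-like directed acyclic graph over three aspects
#' (\code{biological_process}, \code{cellular_component},
#' \code{molecular_function}). Edges are is_a links from child to parent and
#' never cross aspects; every aspect has exactly one root and every non-root
#' term reaches its aspect root by at least one is_a path.
#'
#' @slot terms data.frame with columns \code{id}, \code{name}, \code{aspect}.
#' @slot parents named list mapping each term id to the character vector of
#'   its direct is_a parents (empty for roots).
#' @slot roots named character vector mapping each aspect to its root term id.
#' @name OntologyGraph-class
#' @rdname OntologyGraph
#' @exportClass OntologyGraph
setClass("OntologyGraph",
  representation(
    terms = "data.frame",
    parents = "list",
    roots = "character"
  )
)

.aspects <- c("biological_process", "cellular_component", "molecular_function")

setValidity("OntologyGraph", function(object) {
  msg <- character()
  tm <- object@terms
  if (!all(c("id", "name", "aspect") %in% names(tm)))
    return("terms must have columns id, name, aspect")
  if (anyDuplicated(tm$id))
    msg <- c(msg, "term ids must be unique")
  if (!all(tm$aspect %in% .aspects))
    msg <- c(msg, "unknown aspect in terms")
  if (!all(names(object@roots) %in% .aspects))
    msg <- c(msg, "roots must be named by aspect")
  if (!all(object@roots %in% tm$id))
    msg <- c(msg, "every root must be a term")
  if (!setequal(names(object@parents), tm$id))
    msg <- c(msg, "parents list must cover exactly the term ids")
  if (length(msg)) return(msg)
  asp <- stats::setNames(tm$aspect, tm$id)
  edges <- .ontologyEdges(object)
  if (nrow(edges)) {
    if (!all(edges$parent %in% tm$id))
      return("is_a edge points at unknown term")
    if (any(asp[edges$child] != asp[edges$parent]))
      msg <- c(msg, "is_a edges must not cross aspects")
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = tm$id)
    if (!igraph::is_dag(g))
      msg <- c(msg, "is_a graph must be acyclic")
  }
  nonroot <- setdiff(tm$id, object@roots)
  if (any(lengths(object@parents[nonroot]) == 0L))
    msg <- c(msg, "every non-root term needs at least one is_a parent")
  for (a in unique(tm$aspect)) {
    root <- object@roots[[a]]
    ids <- tm$id[tm$aspect == a]
    reach <- vapply(ids, function(t) .reachesRoot(t, object@parents, root),
                    logical(1))
    if (!all(reach))
      msg <- c(msg, paste0("terms unreachable from the ", a, " root: ",
                           paste(ids[!reach], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

.ontologyEdges <- function(g) {
  child <- rep(names(g@parents), lengths(g@parents))
  data.frame(child = child, parent = unlist(g@parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}

.reachesRoot <- function(term, parents, root) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    if (root %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        seen)
  }
  FALSE
}

#' @param terms data.frame with columns \code{id}, \code{name}, \code{aspect}.
#' @param parents named list of character vectors of direct is_a parents.
#' @param roots named character vector, aspect -> root id. When omitted, the
#'   parentless term of each aspect is taken as its root.
#' @return An \code{OntologyGraph}.
#' @examples
#' g <- ontologyGraph(
#'   terms = data.frame(id = c("R", "a", "t"), name = c("root", "a", "t"),
#'                      aspect = "molecular_function"),
#'   parents = list(R = character(), a = "R", t = "a"))
#' resolveGoSlim("t", g)
#' @rdname OntologyGraph
#' @export
ontologyGraph <- function(terms, parents, roots = NULL) {
  terms$id <- as.character(terms$id)
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) as.character(p %||% character()))
  if (is.null(roots)) {
    idx <- lengths(parents) == 0L
    roots <- stats::setNames(terms$id[idx], terms$aspect[idx])
    if (anyDuplicated(names(roots)))
      stop("aspect with more than one parentless term; pass roots explicitly")
  }
  new("OntologyGraph", terms = terms, parents = parents, roots = roots)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "OntologyGraph", function(object) {
  tab <- table(object@terms$aspect)
  cat("OntologyGraph with ", nrow(object@terms), " terms (",
      paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "),
      "); ", nrow(.ontologyEdges(object)), " is_a edges\n", sep = "")
})

#' @return \code{aspectRoots} returns the named character vector of aspect
#'   roots; \code{ontologyTerms} the terms data.frame.
#' @param g An \code{OntologyGraph}.
#' @rdname OntologyGraph
#' @export
aspectRoots <- function(g) g@roots

#' @rdname OntologyGraph
#' @export
ontologyTerms <- function(g) g@terms

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Synthetic-data generator configuration
#'
#' Controls the ground-truth simulator that emulates the survey's downstream
#' inputs: assembled transcripts with residual poly-A/T tails and planted
#' vector segments, a protein-alignment table with a controllable
#' gold/silver/bronze/untiered composition, and a four-sample count matrix
#' (2nd instar, 4th instar, female, male) with planted fold-changes and
#' zero-expression edge cases.
#'
#' @slot seed integer RNG seed; identical configs give byte-identical output.
#' @slot nTranscripts integer number of transcripts.
#' @slot lengthRange integer pair, core (tail-free) transcript length range in
#'   nt.
#' @slot polyAProb probability a transcript carries a residual 3' poly-A or 5'
#'   poly-T tail.
#' @slot vectorProb probability a transcript carries a planted vector segment.
#' @slot tierMix named numeric proportions over gold/silver/bronze/untiered,
#'   summing to 1.
#' @slot deSpec data.frame with columns \code{index}, \code{fold},
#'   \code{contrast}: planted fold-changes.
#' @slot zeroExprFrac probability a transcript is given exact zeros in
#'   designated samples.
#' @slot meanDepth numeric mean read count per transcript per sample.
#' @name SimConfig-class
#' @rdname SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer",
    nTranscripts = "integer",
    lengthRange = "integer",
    polyAProb = "numeric",
    vectorProb = "numeric",
    tierMix = "numeric",
    deSpec = "data.frame",
    zeroExprFrac = "numeric",
    meanDepth = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nTranscripts < 0L)
    msg <- c(msg, "nTranscripts must be >= 0")
  if (length(object@lengthRange) != 2L || object@lengthRange[1] < 1L ||
      object@lengthRange[2] < object@lengthRange[1])
    msg <- c(msg, "lengthRange must be an increasing pair with min >= 1")
  for (p in c("polyAProb", "vectorProb", "zeroExprFrac")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste0(p, " must be a probability in [0, 1]"))
  }
  if (!setequal(names(object@tierMix),
                c("gold", "silver", "bronze", "untiered")))
    msg <- c(msg, "tierMix must be named gold/silver/bronze/untiered")
  else if (abs(sum(object@tierMix) - 1) > 1e-9 || any(object@tierMix < 0))
    msg <- c(msg, "tierMix proportions must be nonnegative and sum to 1")
  if (nrow(object@deSpec) &&
      !all(c("index", "fold", "contrast") %in% names(object@deSpec)))
    msg <- c(msg, "deSpec needs columns index, fold, contrast")
  if (object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be positive")
  if (length(msg)) msg else TRUE
})

#' @param seed,nTranscripts,lengthRange,polyAProb,vectorProb,tierMix,deSpec,zeroExprFrac,meanDepth
#'   see slot documentation.
#' @return A \code{SimConfig} object.
#' @examples
#' simConfig(seed = 1, nTranscripts = 50)
#' @rdname SimConfig
#' @export
simConfig <- function(seed = 1L, nTranscripts = 200L,
                      lengthRange = c(300L, 2000L),
                      polyAProb = 0.3, vectorProb = 0.1,
                      tierMix = c(gold = 0.3, silver = 0.3, bronze = 0.3,
                                  untiered = 0.1),
                      deSpec = data.frame(index = integer(), fold = numeric(),
                                          contrast = character()),
                      zeroExprFrac = 0.05, meanDepth = 500) {
  new("SimConfig", seed = as.integer(seed),
      nTranscripts = as.integer(nTranscripts),
      lengthRange = as.integer(lengthRange),
      polyAProb = polyAProb, vectorProb = vectorProb, tierMix = tierMix,
      deSpec = deSpec, zeroExprFrac = zeroExprFrac, meanDepth = meanDepth)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nTranscripts, " transcripts (",
      object@lengthRange[1], "-", object@lengthRange[2], " nt core), seed ",
      object@seed, "\n  polyA ", object@polyAProb, ", vector ",
      object@vectorProb, ", tier mix ",
      paste(names(object@tierMix), object@tierMix, sep = "=",
            collapse = " "),
      "\n  ", nrow(object@deSpec), " planted fold-changes, zeroExprFrac ",
      object@zeroExprFrac, ", mean depth ", object@meanDepth, "\n",
      sep = "")
})
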