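#' Read an OBO-format ontology
#'
#' Minimal reader for the OBO stanza subset needed for is_a GO-Slim work:
#' \code{[Term]} stanzas with \code{id}, \code{name}, \code{namespace} and
#' \code{is_a} lines. Obsolete terms (\code{is_obsolete: true}) are dropped
#' with a warning, and \code{alt_id} lines are ignored. Only is_a edges are
#' kept; other relationship types are not represented.
#'
#' @param path Path to the OBO file.
#' @return An \code{\link{OntologyGraph}}.
#' @export
readObo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- names <- aspects <- character()
  parents <- list()
  dropped <- 0L
  for (i in seq_along(starts)) {
    block <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ": *"), "", v))
    }
    if (any(field("is_obsolete") == "true")) { dropped <- dropped + 1L; next }
    id <- field("id")[1]
    isa <- field("is_a")
    isa <- sub(" *!.*$", "", isa)  # strip trailing "! name" comments
    ids <- c(ids, id)
    names <- c(names, field("name")[1] %||% id)
    aspects <- c(aspects, field("namespace")[1])
    parents[[id]] <- isa
  }
  if (dropped)
    warning(dropped, " obsolete term(s) dropped while reading ", path)
  ontologyGraph(data.frame(id = ids, name = names, aspect = aspects,
                           stringsAsFactors = FALSE), parents)
}

#' Write an ontology as an OBO subset
#'
#' Serialises an \code{\link{OntologyGraph}} using the same stanza subset
#' \code{\link{readObo}} consumes, so graphs round-trip exactly.
#'
#' @param g An \code{OntologyGraph}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeObo <- function(g, path) {
  tm <- g@terms
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(tm))) {
    out <- c(out, "[Term]",
             paste0("id: ", tm$id[i]),
             paste0("name: ", tm$name[i]),
             paste0("namespace: ", tm$aspect[i]),
             if (length(g@parents[[tm$id[i]]]))
               paste0("is_a: ", g@parents[[tm$id[i]]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a pfam2go-style mapping table
#'
#' Two-column TSV mapping Pfam accessions to GO term ids; version suffixes on
#' accessions are stripped at read time.
#'
#' @param path Path to the TSV (columns \code{pfam}, \code{go}).
#' @return data.frame with columns \code{pfam}, \code{go}.
#' @export
readPfamToGo <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pfam", "go") %in% names(m)))
    stop("pfam2go table needs columns 'pfam' and 'go'")
  bad <- which(!nzchar(m$pfam) | !nzchar(m$go))
  if (length(bad))
    stop("malformed pfam2go row at line ", bad[1] + 1L, " of ", path)
  m$pfam <- stripPfamVersion(m$pfam)
  m
}

#' Strip the version suffix from Pfam accessions
#'
#' @param acc Character vector of accessions like \code{"PF00067.20"}.
#' @return Accessions without the \code{.v} suffix.
#' @export
stripPfamVersion <- function(acc) sub("\\.\\d+$", "", acc)

#' Map Pfam domain assignments to GO terms
#'
#' Joins transcript-level Pfam assignments against a pfam2go map, ignoring
#' accession version suffixes, and returns the union of mapped terms per
#' transcript. Transcripts whose Pfams have no mapping contribute nothing.
#'
#' @param assignments data.frame with columns \code{id} (transcript) and
#'   \code{pfam} (accession).
#' @param map data.frame with columns \code{pfam}, \code{go} (as from
#'   \code{\link{readPfamToGo}}).
#' @return data.frame of distinct (\code{id}, \code{go}) pairs.
#' @examples
#' a <- data.frame(id = "t1", pfam = "PF00067.20")
#' m <- data.frame(pfam = "PF00067", go = "GO:0000001")
#' mapPfamToGo(a, m)
#' @export
mapPfamToGo <- function(assignments, map) {
  if (nrow(assignments) == 0L)
    return(data.frame(id = character(), go = character()))
  a <- data.frame(id = as.character(assignments$id),
                  pfam = stripPfamVersion(as.character(assignments$pfam)),
                  stringsAsFactors = FALSE)
  j <- merge(a, map, by = "pfam")
  unique(j[order(j$id, j$go), c("id", "go")])
}

#' Resolve a term to its GO-Slim (penultimate) ancestors
#'
#' Projects a fine-grained term onto the direct children of its aspect root:
#' the result is every term that is a direct is_a child of the root and lies
#' on at least one is_a path from the query term to the root. A term that is
#' itself a direct child of the root resolves to itself. Only is_a edges are
#' traversed.
#'
#' @param term Term id (must exist in \code{g} and not be an aspect root).
#' @param g An \code{\link{OntologyGraph}}.
#' @return Character vector of slim term ids (never empty).
#' @examples
#' g <- ontologyGraph(
#'   terms = data.frame(id = c("R", "a", "b", "t"),
#'                      name = c("root", "a", "b", "t"),
#'                      aspect = "molecular_function"),
#'   parents = list(R = character(), a = "R", b = "R", t = c("a", "b")))
#' resolveGoSlim("t", g)  # diamond: both ancestors
#' @export
resolveGoSlim <- function(term, g) {
  if (!term %in% g@terms$id) stop("unknown term: ", term)
  if (term %in% g@roots)
    stop("aspect root has no penultimate ancestor: ", term)
  aspect <- g@terms$aspect[match(term, g@terms$id)]
  root <- g@roots[[aspect]]
  ## every is_a ancestor of `term` (term included) that has the root as a
  ## direct parent lies on a path term -> ... -> ancestor -> root
  anc <- term
  frontier <- term
  while (length(frontier)) {
    up <- setdiff(unique(unlist(g@parents[frontier], use.names = FALSE)),
                  anc)
    anc <- c(anc, up)
    frontier <- up
  }
  sort(anc[vapply(anc, function(u) root %in% g@parents[[u]], logical(1))])
}

#' Count distinct GO terms per aspect
#'
#' Tallies distinct term ids per ontology aspect, both on the full ontology
#' and after GO-Slim resolution.
#'
#' @param pairs data.frame of (\code{id}, \code{go}) pairs, as from
#'   \code{\link{mapPfamToGo}}.
#' @param g An \code{\link{OntologyGraph}}.
#' @return List with \code{full} and \code{slim}, each a named integer vector
#'   over the three aspects.
#' @export
countDistinctTerms <- function(pairs, g) {
  aspOf <- stats::setNames(g@terms$aspect, g@terms$id)
  empty <- stats::setNames(integer(length(.aspects)), .aspects)
  if (nrow(pairs) == 0L) return(list(full = empty, slim = empty))
  unknown <- setdiff(unique(pairs$go), g@terms$id)
  if (length(unknown))
    stop("pairs reference unknown term(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  full <- empty
  tab <- tapply(pairs$go, aspOf[pairs$go],
                function(v) length(unique(v)))
  full[names(tab)] <- as.integer(tab)
  terms <- setdiff(unique(pairs$go), g@roots)
  slimOf <- lapply(stats::setNames(terms, terms), resolveGoSlim, g = g)
  slimTerms <- unique(unlist(slimOf, use.names = FALSE))
  slim <- empty
  if (length(slimTerms)) {
    tab <- tapply(slimTerms, aspOf[slimTerms],
                  function(v) length(unique(v)))
    slim[names(tab)] <- as.integer(tab)
  }
  list(full = full, slim = slim)
}

#' Resolve transcript GO assignments to GO-Slim
#'
#' Applies \code{\link{resolveGoSlim}} to every (transcript, term) pair and
#' returns distinct (transcript, aspect, slim term) rows. Aspect-root terms
#' in the input are skipped.
#'
#' @param pairs data.frame of (\code{id}, \code{go}) pairs.
#' @param g An \code{\link{OntologyGraph}}.
#' @return data.frame with columns \code{id}, \code{aspect}, \code{slim}.
#' @export
slimAssignments <- function(pairs, g) {
  pairs <- pairs[!pairs$go %in% g@roots, , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(data.frame(id = character(), aspect = character(),
                      slim = character()))
  aspOf <- stats::setNames(g@terms$aspect, g@terms$id)
  slimOf <- lapply(stats::setNames(unique(pairs$go), unique(pairs$go)),
                   resolveGoSlim, g = g)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    s <- slimOf[[pairs$go[i]]]
    data.frame(id = pairs$id[i], aspect = unname(aspOf[s]), slim = s,
               stringsAsFactors = FALSE)
  }))
  out <- unique(out)
  out[order(out$id, out$aspect, out$slim), , drop = FALSE]
}

#' Tabulate Pfam family abundance
#'
#' Counts transcripts per Pfam accession and returns the \code{topK} most
#' abundant families, ranked by descending count with ties broken by
#' accession.
#'
#' @param assignments data.frame with columns \code{id}, \code{pfam}.
#' @param topK Number of rows to return (whole table when larger).
#' @return data.frame with columns \code{pfam}, \code{count}.
#' @examples
#' tabulatePfam(data.frame(id = c("a", "b", "c"),
#'                         pfam = c("PF1", "PF1", "PF2")), topK = 1)
#' @export
tabulatePfam <- function(assignments, topK = 25L) {
  if (topK < 0) stop("topK must be nonnegative")
  a <- unique(data.frame(id = as.character(assignments$id),
                         pfam = stripPfamVersion(
                           as.character(assignments$pfam)),
                         stringsAsFactors = FALSE))
  if (nrow(a) == 0L)
    return(data.frame(pfam = character(), count = integer()))
  tab <- table(a$pfam)
  d <- data.frame(pfam = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$pfam), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, topK)
}
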