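## Independent brute-force oracles used across the suite. These deliberately
## re-derive each rule with plain if/else logic or exhaustive enumeration, so
## they share no code path with the package implementation.

## per-row tier rule, written straight from the tier definition
oracleTier <- function(qlen, nhsps, slen, hlen, pos, t = tierThresholds()) {
  if (qlen >= t@goldMinQueryNt && nhsps == 1 && slen >= t@goldMinSubjectAa &&
      pos / hlen >= t@goldMinPositiveFrac &&
      hlen / slen >= t@goldMinHitSubjectRatio) return("gold")
  if (qlen >= t@silverMinQueryNt && hlen / slen >= t@silverMinSubjectCov)
    return("silver")
  if (qlen >= t@bronzeMinQueryNt && hlen / slen >= t@bronzeMinSubjectCov)
    return("bronze")
  "untiered"
}

## five-way AND family rule
oracleFamily <- function(bit, slen, qlen, hlen, pos,
                         t = familyThresholds()) {
  bit >= t@minBitscore && slen >= t@minSubjectAa &&
    hlen / slen >= t@minHitSubjectRatio &&
    hlen / qlen >= t@minHitQueryRatio &&
    pos / hlen >= t@minPositiveFrac
}

## exhaustive enumeration of all is_a paths term -> root; returns the set of
## penultimate nodes (the node just before the root on each path)
oraclePenultimate <- function(term, parents, root) {
  pens <- character()
  rec <- function(node, prev) {
    if (node == root) {
      pens <<- c(pens, prev)
      return()
    }
    for (p in parents[[node]]) rec(p, node)
  }
  rec(term, NA_character_)
  sort(unique(pens))
}

## random rooted single-aspect is_a DAG: term i > 1 picks parents among
## earlier terms only, so acyclicity and root reachability hold by
## construction
randomOntology <- function(n, aspect = "molecular_function") {
  ids <- sprintf("T%02d", seq_len(n))
  parents <- list()
  parents[[ids[1]]] <- character()
  for (i in seq_len(n)[-1]) {
    k <- sample(1:min(3L, i - 1L), 1L)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
  }
  ontologyGraph(data.frame(id = ids, name = ids, aspect = aspect,
                           stringsAsFactors = FALSE), parents)
}

## O(n^2) longest stop-free codon stretch over all six frames
oracleLongestOrf <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  best <- ""
  for (s in c(seq, rc)) {
    L <- nchar(s)
    for (off in 0:2) {
      ncod <- (L - off) %/% 3
      if (ncod < 1) next
      aas <- vapply(seq_len(ncod), function(j) {
        codon <- substr(s, off + 3 * j - 2, off + 3 * j)
        if (grepl("[^ACGT]", codon)) "X" else
          as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                             no.init.codon = TRUE))
      }, character(1))
      for (i in seq_len(ncod)) for (j in i:ncod) {
        stretch <- aas[i:j]
        if (!"*" %in% stretch && j - i + 1 > nchar(best))
          best <- paste(stretch, collapse = "")
      }
    }
  }
  best
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
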