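#' Longest ORF across six frames
#'
#' Finds, for each transcript, the longest open reading frame considered
#' across all six frames under the standard genetic code, where an ORF is
#' the longest stop-free stretch of codons beginning at any codon position
#' (no start codon required). Ambiguous codons translate to \code{X} and do
#' not terminate an ORF.
#'
#' @param x A \code{\link[Biostrings]{DNAStringSet}} (or character vector).
#' @return An \code{\link[Biostrings]{AAStringSet}} of the longest ORF
#'   translation per transcript (empty string when a sequence is shorter than
#'   one codon in every frame).
#' @examples
#' longestOrf(Biostrings::DNAStringSet(c(t = "ATGAAATTTTAGATG")))
#' @export
longestOrf <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  rc <- Biostrings::reverseComplement(x)
  best <- character(length(x))
  for (i in seq_along(x)) {
    cands <- character()
    for (strand in list(x[[i]], rc[[i]])) {
      L <- length(strand)
      for (off in 0:2) {
        ncod <- (L - off) %/% 3L
        if (ncod < 1L) next
        frame <- Biostrings::subseq(strand, off + 1L, off + 3L * ncod)
        aa <- as.character(Biostrings::translate(
          frame, if.fuzzy.codon = "X", no.init.codon = TRUE))
        cands <- c(cands, strsplit(aa, "*", fixed = TRUE)[[1]])
      }
    }
    best[i] <- if (length(cands)) cands[which.max(nchar(cands))] else ""
  }
  out <- Biostrings::AAStringSet(best)
  names(out) <- names(x)
  out
}

#' Call gene-family membership
#'
#' Decides inclusion of transcripts in a curated gene family (e.g., GST or
#' COE) from the top high-scoring segment pair of each longest-ORF query
#' against the family protein set. Membership requires all five thresholds to
#' pass: bit score, subject length, hit/subject length ratio, hit/query
#' length ratio, and positive-similarity fraction. For non-members the failed
#' criteria are recorded.
#'
#' Here \code{qlen} is the longest-ORF length in amino acids.
#'
#' @param hits data.frame with columns \code{qseqid}, \code{qlen} (aa),
#'   \code{sseqid}, \code{slen}, \code{length}, \code{positive},
#'   \code{bitscore} — the top HSP per query.
#' @param t A \code{\link{familyThresholds}}.
#' @param label Family label to record (e.g. \code{"GST"}).
#' @return data.frame with columns \code{id}, \code{family}, \code{member},
#'   \code{failed} (comma-joined names of failed criteria, \code{""} for
#'   members).
#' @examples
#' h <- data.frame(qseqid = "t1", qlen = 120, sseqid = "G1", slen = 100,
#'                 length = 95, positive = 80, bitscore = 75)
#' callFamily(h, label = "GST")
#' @export
callFamily <- function(hits, t = familyThresholds(), label = "family") {
  if (any(hits$qlen <= 0) || any(hits$slen <= 0))
    stop("query and subject lengths must be positive")
  checks <- cbind(
    minBitscore = hits$bitscore >= t@minBitscore,
    minSubjectAa = hits$slen >= t@minSubjectAa,
    minHitSubjectRatio = hits$length / hits$slen >= t@minHitSubjectRatio,
    minHitQueryRatio = hits$length / hits$qlen >= t@minHitQueryRatio,
    minPositiveFrac = hits$positive / hits$length >= t@minPositiveFrac)
  member <- rowSums(checks) == ncol(checks)
  failed <- apply(checks, 1L, function(ok)
    paste(colnames(checks)[!ok], collapse = ","))
  data.frame(id = as.character(hits$qseqid), family = label,
             member = unname(member), failed = unname(failed),
             stringsAsFactors = FALSE)
}

#' Collapse protein sequences to unique entries
#'
#' Collapses a protein set by exact string identity, returning the unique
#' sequences (first occurrence kept, input order preserved) and the map from
#' every input entry to its representative.
#'
#' @param seqs A named \code{\link[Biostrings]{AAStringSet}} or named
#'   character vector of protein sequences.
#' @return List with \code{unique} (same class as input) and \code{map}
#'   (data.frame: \code{id}, \code{representative}).
#' @examples
#' dedupProteins(c(a = "MA", b = "MA", c = "MV"))$unique
#' @export
dedupProteins <- function(seqs) {
  if (length(seqs) == 0L) stop("protein set must be nonempty")
  chr <- as.character(seqs)
  if (any(nchar(chr) == 0L)) stop("empty protein sequence in input")
  ids <- names(seqs)
  if (is.null(ids)) stop("protein sequences must be named")
  keep <- !duplicated(chr)
  rep_ <- ids[keep][match(chr, chr[keep])]
  list(unique = seqs[keep],
       map = data.frame(id = ids, representative = rep_,
                        stringsAsFactors = FALSE))
}

#' Group queries by shared best hit
#'
#' Partitions queries by their best-hit subject, the sorting step that
#' clusters closely related sequences (as used for cytochrome P450 triage).
#' Within a group, queries are ordered by descending query length.
#'
#' @param rows data.frame with columns \code{qseqid}, \code{sseqid} and
#'   \code{qlen}; one best hit per query.
#' @return Named list of character vectors of query ids, keyed by subject.
#' @examples
#' clusterByBestHit(data.frame(qseqid = c("a", "b"), sseqid = "P1",
#'                             qlen = c(100, 300)))
#' @export
clusterByBestHit <- function(rows) {
  if (nrow(rows) == 0L) return(stats::setNames(list(), character()))
  if (anyDuplicated(rows$qseqid))
    stop("duplicate query id; deduplicate to one best hit per query first")
  o <- order(as.character(rows$sseqid), -rows$qlen,
             as.character(rows$qseqid))
  rows <- rows[o, , drop = FALSE]
  split(as.character(rows$qseqid), factor(rows$sseqid,
                                          levels = unique(rows$sseqid)))
}

#' Summarize genome locus mappings
#'
#' Counts how many family proteins splice-aligned to the reference genome and
#' how many distinct loci those alignments cover.
#'
#' @param m data.frame with columns \code{protein}, \code{scaffold},
#'   \code{locus}, \code{aligned} (logical); one row per (protein, best
#'   locus).
#' @return Named integer vector \code{c(nAligned, nLoci)}.
#' @examples
#' summarizeLoci(data.frame(protein = c("p1", "p2"), scaffold = "s1",
#'                          locus = "L1", aligned = TRUE))
#' @export
summarizeLoci <- function(m) {
  al <- m[isTRUE_vec(m$aligned), , drop = FALSE]
  c(nAligned = nrow(al), nLoci = length(unique(al$locus)))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
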