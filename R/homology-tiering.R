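#' Classify transcripts into homology-confidence tiers
#'
#' Assigns the gold/silver/bronze annotation-confidence label to alignment
#' summaries (one row per transcript/best-hit pair). A transcript is
#' \emph{gold} when the query is at least 300 nt, the hit comprises a single
#' HSP against a subject of at least 100 aa, at least 75\% of aligned
#' residues are positively similar and the hit covers at least 90\% of the
#' subject; \emph{silver} when the query is at least 100 nt with the hit
#' spanning at least 75\% of the subject; \emph{bronze} when the query is at
#' least 100 nt with at least 30\% subject coverage; otherwise
#' \emph{untiered}. Precedence is gold > silver > bronze.
#'
#' Vectorised over rows.
#'
#' @param queryLen Query (transcript) length in nt.
#' @param nHsps Number of HSPs in the hit.
#' @param subjectLen Subject (protein) length in aa.
#' @param hitLen Aligned columns in aa.
#' @param positives Count of positively similar aligned residues.
#' @param t A \code{\link{tierThresholds}}.
#' @return Character vector over \code{c("gold","silver","bronze","untiered")}.
#' @examples
#' classifyTier(300, 1, 100, 90, 68)  # gold at the rule boundary
#' classifyTier(300, 2, 100, 90, 68)  # silver: single-HSP clause fails
#' @export
classifyTier <- function(queryLen, nHsps, subjectLen, hitLen, positives,
                         t = tierThresholds()) {
  n <- length(queryLen)
  stopifnot(length(nHsps) == n, length(subjectLen) == n,
            length(hitLen) == n, length(positives) == n)
  if (any(hitLen < 1) || any(subjectLen < 1))
    stop("hitLen and subjectLen must be >= 1")
  if (any(positives > hitLen))
    stop("positives cannot exceed hitLen")
  cov <- hitLen / subjectLen
  posFrac <- positives / hitLen
  gold <- queryLen >= t@goldMinQueryNt & nHsps == 1L &
    subjectLen >= t@goldMinSubjectAa & posFrac >= t@goldMinPositiveFrac &
    cov >= t@goldMinHitSubjectRatio
  silver <- queryLen >= t@silverMinQueryNt & cov >= t@silverMinSubjectCov
  bronze <- queryLen >= t@bronzeMinQueryNt & cov >= t@bronzeMinSubjectCov
  out <- rep("untiered", n)
  out[bronze] <- "bronze"
  out[silver & !gold] <- "silver"
  out[gold] <- "gold"
  out
}

#' Read a protein-alignment summary table
#'
#' Reads the extended BLAST-outfmt-6-like TSV dialect with named columns
#' \code{qseqid}, \code{qlen}, \code{sseqid}, \code{slen}, \code{length}
#' (aligned columns), \code{positive}, \code{bitscore} and \code{n_hsps}.
#' Malformed rows are reported with their line number.
#'
#' @param path Path to the TSV file.
#' @return data.frame of alignment summaries.
#' @export
readAlignmentTable <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qseqid", "qlen", "sseqid", "slen", "length", "positive",
            "bitscore", "n_hsps")
  if (!all(need %in% names(h)))
    stop("alignment table needs columns: ", paste(need, collapse = ", "))
  num <- c("qlen", "slen", "length", "positive", "bitscore", "n_hsps")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(h[[cn]]))
    bad <- which(is.na(v) & !is.na(h[[cn]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   cn, bad[1] + 1L, path))
    h[[cn]] <- v
  }
  h
}

#' Tier a whole alignment table
#'
#' Classifies each transcript by its best hit (highest bitscore; ties broken
#' by the lexicographically lowest subject id) and tallies the tier counts.
#' Transcripts listed in \code{allIds} but absent from the table are
#' untiered.
#'
#' @param hits data.frame as from \code{\link{readAlignmentTable}}; may hold
#'   multiple hits per query.
#' @param t A \code{\link{tierThresholds}}.
#' @param allIds Optional character vector of all transcript ids under
#'   consideration (defaults to the queries present in \code{hits}).
#' @return List with \code{labels} (data.frame: \code{id}, \code{tier}) and
#'   \code{counts} (named integer vector gold/silver/bronze/untiered).
#' @examples
#' h <- data.frame(qseqid = "t1", qlen = 400, sseqid = "P1", slen = 100,
#'                 length = 95, positive = 90, bitscore = 200, n_hsps = 1)
#' tierTable(h)$counts
#' @export
tierTable <- function(hits, t = tierThresholds(), allIds = NULL) {
  if (is.null(allIds)) allIds <- unique(as.character(hits$qseqid))
  lab <- stats::setNames(rep("untiered", length(allIds)), allIds)
  if (nrow(hits)) {
    unknown <- setdiff(unique(as.character(hits$qseqid)), allIds)
    if (length(unknown))
      stop("hits reference unknown transcript id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    ## best hit: highest bitscore, tie -> lowest subject id
    o <- order(hits$qseqid, -hits$bitscore, as.character(hits$sseqid))
    best <- hits[o, , drop = FALSE]
    best <- best[!duplicated(best$qseqid), , drop = FALSE]
    lab[as.character(best$qseqid)] <- classifyTier(
      best$qlen, best$n_hsps, best$slen, best$length, best$positive, t)
  }
  lv <- c("gold", "silver", "bronze", "untiered")
  counts <- table(factor(lab, levels = lv))
  list(labels = data.frame(id = allIds, tier = unname(lab),
                           stringsAsFactors = FALSE),
       counts = stats::setNames(as.integer(counts), lv))
}
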