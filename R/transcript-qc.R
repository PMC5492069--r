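#' Clip residual poly-A/T tails
#'
#' Removes a maximal run of at least \code{minTailRun} consecutive \code{A}
#' from the 3' end and of consecutive \code{T} from the 5' end of each
#' assembled transcript. Runs are exact homopolymers (an \code{N} never counts
#' toward a run), the interior of the sequence is untouched, and the
#' operation is idempotent.
#'
#' @param x A \code{\link[Biostrings]{DNAStringSet}} (or character vector) of
#'   transcripts.
#' @param cfg A \code{\link{qcConfig}}.
#' @return Object of the same class as \code{x} with tails clipped.
#' @examples
#' clipPolyAT(Biostrings::DNAStringSet(c(t1 = "TTTTTTACGTAAAAA")))
#' @export
clipPolyAT <- function(x, cfg = qcConfig()) {
  chr <- as.character(x)
  k <- cfg@minTailRun
  chr <- sub(sprintf("A{%d,}$", k), "", chr)
  chr <- sub(sprintf("^T{%d,}", k), "", chr)
  if (is.character(x)) return(stats::setNames(chr, names(x)))
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Filter transcripts on minimum length
#'
#' Keeps exactly the transcripts whose (post-clipping) length is at least
#' \code{minLength} nucleotides, preserving input order.
#'
#' @param x A \code{DNAStringSet} or character vector of transcripts.
#' @param minLength Minimum retained length in nt (default 200).
#' @return The retained subset of \code{x}.
#' @examples
#' x <- Biostrings::DNAStringSet(c(a = strrep("A", 150), b = strrep("C", 250)))
#' filterByLength(x, 200)
#' @export
filterByLength <- function(x, minLength = 200L) {
  if (length(minLength) != 1L || is.na(minLength) || minLength < 1)
    stop("minLength must be a single value >= 1")
  len <- if (is.character(x)) nchar(x) else Biostrings::width(x)
  x[len >= minLength]
}

#' Categorize a vector-screen match
#'
#' Classifies vector-contamination matches into Strong/Moderate/Weak/None
#' following the VecScreen-style two-ladder scheme: a match is terminal when
#' it begins within \code{terminalWindow} nt of either sequence end, and its
#' alignment score is compared against the terminal or internal threshold
#' ladder of \code{cfg}. Scores below the Weak floor give \code{None}.
#'
#' Vectorised over matches; intervals are 0-based half-open on the
#' transcript.
#'
#' @param score Integer alignment score(s).
#' @param start,end 0-based half-open match interval(s).
#' @param seqLen Transcript length(s) in nt.
#' @param cfg A \code{\link{qcConfig}}.
#' @return Character vector over \code{c("Strong","Moderate","Weak","None")}.
#' @examples
#' categorizeVectorMatch(25, 0, 30, 500)   # terminal Strong
#' categorizeVectorMatch(25, 100, 130, 500) # internal Moderate
#' @export
categorizeVectorMatch <- function(score, start, end, seqLen,
                                  cfg = qcConfig()) {
  n <- max(length(score), length(start), length(end), length(seqLen))
  score <- rep_len(score, n); start <- rep_len(start, n)
  end <- rep_len(end, n); seqLen <- rep_len(seqLen, n)
  if (any(start < 0 | end <= start | end > seqLen))
    stop("match interval outside sequence (need 0 <= start < end <= seqLen)")
  terminal <- start < cfg@terminalWindow |
    (seqLen - end) < cfg@terminalWindow
  strong <- ifelse(terminal, cfg@strongTerminal, cfg@strongInternal)
  moderate <- ifelse(terminal, cfg@moderateTerminal, cfg@moderateInternal)
  weak <- ifelse(terminal, cfg@weakTerminal, cfg@weakInternal)
  out <- rep("None", n)
  out[score >= weak] <- "Weak"
  out[score >= moderate] <- "Moderate"
  out[score >= strong] <- "Strong"
  out
}

#' Purge vector-contaminated transcripts
#'
#' Drops every transcript having at least one match categorized Strong or
#' Moderate; Weak and None matches never cause removal. Matches referencing
#' an unknown transcript id raise an error.
#'
#' @param x Named \code{DNAStringSet} (or character vector) of transcripts.
#' @param matches data.frame with columns \code{id}, \code{score},
#'   \code{start}, \code{end} (0-based half-open), as read by
#'   \code{\link{readVectorMatches}}.
#' @param cfg A \code{\link{qcConfig}}.
#' @return The retained subset of \code{x}.
#' @examples
#' x <- Biostrings::DNAStringSet(c(a = strrep("ACGT", 100)))
#' m <- data.frame(id = "a", score = 30, start = 0, end = 30)
#' purgeContaminated(x, m)  # empty: terminal Strong match
#' @export
purgeContaminated <- function(x, matches, cfg = qcConfig()) {
  ids <- names(x)
  if (is.null(ids)) stop("transcripts must be named")
  if (nrow(matches) == 0L) return(x)
  bad <- setdiff(matches$id, ids)
  if (length(bad))
    stop("vector matches reference unknown transcript id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  len <- stats::setNames(
    if (is.character(x)) nchar(x) else Biostrings::width(x), ids)
  cat_ <- categorizeVectorMatch(matches$score, matches$start, matches$end,
                                len[matches$id], cfg)
  purge <- unique(matches$id[cat_ %in% c("Strong", "Moderate")])
  x[!ids %in% purge]
}

#' Read a vector-screen match table
#'
#' Reads a TSV with columns \code{id}, \code{score}, \code{start}, \code{end}
#' (0-based half-open interval on the transcript).
#'
#' @param path Path to the TSV file.
#' @return data.frame of matches.
#' @export
readVectorMatches <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "score", "start", "end")
  if (!all(need %in% names(m)))
    stop("vector match table needs columns: ", paste(need, collapse = ", "))
  m
}

#' Run the post-assembly QC stage
#'
#' Applies the cleanup pipeline in order: poly-A/T tail clipping, the
#' minimum-length filter, then the vector-screen purge of transcripts with
#' Strong or Moderate matches.
#'
#' @param x Named \code{DNAStringSet} of assembled transcripts.
#' @param matches Vector-screen match data.frame (may be empty).
#' @param cfg A \code{\link{qcConfig}}.
#' @return List with elements \code{transcripts} (the cleaned set) and
#'   \code{report} (data.frame of record counts entering/leaving each step).
#' @examples
#' x <- Biostrings::DNAStringSet(c(a = paste0(strrep("ACGT", 100),
#'                                            strrep("A", 10))))
#' runQc(x, data.frame(id = character(), score = numeric(),
#'                     start = numeric(), end = numeric()))
#' @export
runQc <- function(x, matches = NULL, cfg = qcConfig()) {
  if (is.null(matches))
    matches <- data.frame(id = character(), score = numeric(),
                          start = numeric(), end = numeric())
  n0 <- length(x)
  clipped <- clipPolyAT(x, cfg)
  kept <- filterByLength(clipped, cfg@minLength)
  n1 <- length(kept)
  ## matches on dropped transcripts no longer apply
  matches <- matches[matches$id %in% names(kept), , drop = FALSE]
  final <- purgeContaminated(kept, matches, cfg)
  report <- data.frame(
    step = c("input", "length_filter", "vector_purge"),
    records = c(n0, n1, length(final)))
  list(transcripts = final, report = report)
}
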