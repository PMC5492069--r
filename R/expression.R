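.sampleLabels <- c("2nd", "4th", "female", "male")

#' Build a count container for the four-sample design
#'
#' Wraps per-transcript read counts for the survey's four samples (2nd
#' instar, 4th instar, female, male) and their effective lengths in a
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}} (assay
#' \code{"counts"}, rowData column \code{effLength}).
#'
#' @param counts Numeric matrix of nonnegative counts, one column per sample
#'   label in \code{c("2nd", "4th", "female", "male")}, rownames = transcript
#'   ids.
#' @param lengths Positive effective lengths in nt, one per transcript.
#' @return A \code{SummarizedExperiment}.
#' @examples
#' m <- matrix(1:8, 2, 4, dimnames = list(c("t1", "t2"),
#'             c("2nd", "4th", "female", "male")))
#' countMatrix(m, c(500, 800))
#' @export
countMatrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!setequal(colnames(counts), .sampleLabels))
    stop("count columns must be exactly: ",
         paste(.sampleLabels, collapse = ", "))
  counts <- counts[, .sampleLabels, drop = FALSE]
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(lengths) != nrow(counts) || any(lengths <= 0))
    stop("need one positive effective length per transcript")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(effLength = lengths))
}

#' Read a count table
#'
#' Reads a TSV with columns \code{transcript}, \code{length}, \code{2nd},
#' \code{4th}, \code{female}, \code{male} into a count container.
#'
#' @param path Path to the TSV file.
#' @return A \code{SummarizedExperiment} as from \code{\link{countMatrix}}.
#' @export
readCountMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("transcript", "length", .sampleLabels)
  if (!all(need %in% names(d)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  m <- as.matrix(d[, .sampleLabels])
  rownames(m) <- d$transcript
  countMatrix(m, d$length)
}

#' Compute TPM from counts and effective lengths
#'
#' Transcripts-per-million: for each sample,
#' \code{TPM_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6}. Columns of the
#' result sum to one million whenever the sample has any nonzero count; an
#' all-zero sample stays all-zero.
#'
#' @param counts Count matrix (transcripts x samples) or a
#'   \code{SummarizedExperiment} from \code{\link{countMatrix}}.
#' @param lengths Effective lengths (ignored when \code{counts} is a
#'   \code{SummarizedExperiment}).
#' @return Numeric TPM matrix with the dimnames of \code{counts}.
#' @examples
#' computeTpm(cbind(s = c(10, 10)), c(100, 200))
#' @export
computeTpm <- function(counts, lengths = NULL) {
  if (methods::is(counts, "SummarizedExperiment")) {
    lengths <- SummarizedExperiment::rowData(counts)$effLength
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(lengths) != nrow(counts) || any(lengths <= 0))
    stop("need one positive effective length per transcript")
  rate <- counts / lengths
  tot <- colSums(rate)
  tpm <- sweep(rate, 2L, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm
}

#' Pool read groups and recompute TPM
#'
#' Pools the nymphal samples (2nd + 4th instar) and the adult samples
#' (female + male) by summing counts within each group and recomputing TPM
#' from the pooled counts — not by averaging member TPM values, which differs
#' whenever member depths differ.
#'
#' @param cm A \code{SummarizedExperiment} from \code{\link{countMatrix}}.
#' @param groups Named list mapping group names to sample labels (default
#'   \code{list(nymphs = c("2nd", "4th"), adults = c("female", "male"))}).
#' @return List with \code{counts} (pooled count matrix) and \code{tpm}
#'   (pooled TPM matrix).
#' @export
poolGroups <- function(cm, groups = list(nymphs = c("2nd", "4th"),
                                         adults = c("female", "male"))) {
  counts <- SummarizedExperiment::assay(cm, "counts")
  unknown <- setdiff(unlist(groups), colnames(counts))
  if (length(unknown))
    stop("unknown sample label(s): ", paste(unknown, collapse = ", "))
  pooled <- vapply(groups, function(g)
    rowSums(counts[, g, drop = FALSE]), numeric(nrow(counts)))
  if (nrow(counts) == 1L)
    pooled <- matrix(pooled, nrow = 1L,
                     dimnames = list(rownames(counts), names(groups)))
  lengths <- SummarizedExperiment::rowData(cm)$effLength
  list(counts = pooled, tpm = computeTpm(pooled, lengths))
}

#' Replicate-free log2 fold-change with sentinel semantics
#'
#' Computes \code{log2(num/den)} with the sentinel rules used for
#' replicate-free contrasts: both values zero gives \code{NaN} (printed as
#' \code{"undefined"}), a zero denominator gives \code{+Inf}
#' (\code{"+inf"}), a zero numerator gives \code{-Inf} (\code{"-inf"}).
#'
#' @param num,den Nonnegative TPM values (recycled to a common length).
#' @return Numeric vector; use \code{\link{formatLog2fc}} for the fixed
#'   sentinel spellings.
#' @examples
#' log2FoldChange(253.24, 7.24)   # 5.1284 at 4 dp
#' formatLog2fc(log2FoldChange(c(0, 1, 0), c(0, 0, 1)))
#' @export
log2FoldChange <- function(num, den) {
  if (any(num < 0, na.rm = TRUE) || any(den < 0, na.rm = TRUE))
    stop("TPM values must be nonnegative")
  n <- max(length(num), length(den))
  num <- rep_len(num, n); den <- rep_len(den, n)
  out <- suppressWarnings(log2(num / den))
  out[num == 0 & den == 0] <- NaN
  out[num > 0 & den == 0] <- Inf
  out[num == 0 & den > 0] <- -Inf
  out
}

#' Fixed string spellings for log2 fold-change sentinels
#'
#' @param x Numeric vector from \code{\link{log2FoldChange}}.
#' @param digits Decimal places for finite values (default 4).
#' @return Character vector using \code{"undefined"}, \code{"+inf"},
#'   \code{"-inf"} for the sentinel states.
#' @export
formatLog2fc <- function(x, digits = 4L) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.nan(x)] <- "undefined"
  out[is.infinite(x) & x > 0] <- "+inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out
}

#' Rank a contrast by absolute log2 fold-change
#'
#' Applies the TPM floor, computes log2 ratios and returns the strongest
#' \code{topK} transcripts per direction. Under
#' \code{floorMode = "filter_min_both"} only transcripts with
#' \code{min(num, den) >= tpmFloor} are ranked (so sentinels never enter);
#' under \code{"clamp"} each TPM is first replaced by
#' \code{max(tpm, tpmFloor)}. Ranking is by decreasing finite
#' \code{|log2fc|} and is invariant to input row order (ties broken by id).
#'
#' @param ids Transcript identifiers.
#' @param tpmNum,tpmDen TPM values of the contrast's numerator and
#'   denominator samples.
#' @param cfg A \code{\link{contrastConfig}}.
#' @return data.frame with columns \code{id}, \code{tpmNum}, \code{tpmDen},
#'   \code{log2fc}, \code{direction} (\code{"up"}/\code{"down"}), the top
#'   \code{topK} rows per direction.
#' @examples
#' rankContrast(c("a", "b"), c(253.24, 8.17), c(7.24, 334.68),
#'              contrastConfig("4th:2nd", topK = 1))
#' @export
rankContrast <- function(ids, tpmNum, tpmDen, cfg = contrastConfig()) {
  if (cfg@topK < 1L) stop("topK must be >= 1")
  stopifnot(length(ids) == length(tpmNum), length(ids) == length(tpmDen))
  if (cfg@floorMode == "clamp") {
    tpmNum <- pmax(tpmNum, cfg@tpmFloor)
    tpmDen <- pmax(tpmDen, cfg@tpmFloor)
    keep <- rep(TRUE, length(ids))
  } else {
    keep <- pmin(tpmNum, tpmDen) >= cfg@tpmFloor
  }
  d <- data.frame(id = as.character(ids), tpmNum = tpmNum, tpmDen = tpmDen,
                  stringsAsFactors = FALSE)[keep, , drop = FALSE]
  d$log2fc <- log2FoldChange(d$tpmNum, d$tpmDen)
  d <- d[is.finite(d$log2fc) & abs(d$log2fc) >= log2(cfg@minFold), ,
         drop = FALSE]
  d$direction <- ifelse(d$log2fc > 0, "up", "down")
  d <- d[order(-abs(d$log2fc), d$id), , drop = FALSE]
  out <- do.call(rbind, lapply(c("up", "down"), function(dir)
    utils::head(d[d$direction == dir, , drop = FALSE], cfg@topK)))
  rownames(out) <- NULL
  out
}

#' Classify sex-preferential expression patterns
#'
#' Bins (male TPM, female TPM) pairs into the survey's sex-expression
#' categories. A \emph{dominant-expressed} call requires both sexes at or
#' above \code{minExpressed} TPM and an absolute log2 ratio of at least
#' \code{log2(minFold)}; a \emph{specific/dominant} call requires the low
#' sex below \code{tauLo} and the high sex at or above \code{tauHi}. The
#' female-skewed form of the latter is reported as
#' \code{"female_specific"}, the male-skewed form as \code{"male_dominant"}.
#'
#' @param tpmM,tpmF Male and female TPM values.
#' @param minExpressed TPM floor for the dominant-expressed rule (default 5).
#' @param minFold Fold differential for the dominant-expressed rule
#'   (default 2).
#' @param tauLo,tauHi Low/high TPM cut-offs for the specific rule (defaults
#'   0.5 and 3.0).
#' @return Character vector over \code{c("female_specific", "male_dominant",
#'   "female_dominant_expressed", "male_dominant_expressed", "none")}.
#' @examples
#' classifySexPattern(c(0.03, 38.09, 4.9), c(18.87, 6.24, 4.9))
#' @export
classifySexPattern <- function(tpmM, tpmF, minExpressed = 5, minFold = 2,
                               tauLo = 0.5, tauHi = 3.0) {
  n <- max(length(tpmM), length(tpmF))
  tpmM <- rep_len(tpmM, n); tpmF <- rep_len(tpmF, n)
  if (any(tpmM < 0) || any(tpmF < 0)) stop("TPM values must be nonnegative")
  lfc <- log2FoldChange(tpmM, tpmF)
  out <- rep("none", n)
  expressed <- pmin(tpmM, tpmF) >= minExpressed &
    abs(lfc) >= log2(minFold)
  out[expressed & tpmM > tpmF] <- "male_dominant_expressed"
  out[expressed & tpmF > tpmM] <- "female_dominant_expressed"
  specF <- tpmM < tauLo & tpmF >= tauHi
  specM <- tpmF < tauLo & tpmM >= tauHi
  out[specF] <- "female_specific"
  out[specM] <- "male_dominant"
  out
}

#' Split a contrast label into numerator/denominator sample columns
#'
#' @param contrast A label like \code{"female:male"} (numerator first).
#' @return Character vector \code{c(num, den)}.
#' @export
contrastColumns <- function(contrast) {
  parts <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("contrast must look like 'num:den'")
  parts
}
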