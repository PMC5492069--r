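#' Read and validate a pipeline run configuration
#'
#' Loads a YAML run configuration with an \code{inputs} block (paths to the
#' transcript FASTA, vector-match, alignment, family-hit, count, Pfam
#' assignment, pfam2go and OBO files), an output directory, a seed, and
#' optional per-stage parameter blocks (\code{qc}, \code{tier},
#' \code{family}, \code{contrast}). Referenced input files must exist;
#' validation happens before any stage runs.
#'
#' @param path Path to the YAML file.
#' @return A validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg A run-configuration list (as from \code{yaml::read_yaml}).
#' @export
validateRunConfig <- function(cfg) {
  need <- c("transcripts", "vector_matches", "alignments", "family_hits",
            "counts", "pfam_assignments", "pfam2go", "obo")
  if (is.null(cfg$inputs))
    stop("run config needs an 'inputs' block")
  missing <- setdiff(need, names(cfg$inputs))
  if (length(missing))
    stop("run config inputs missing: ", paste(missing, collapse = ", "))
  absent <- need[!vapply(cfg$inputs[need], file.exists, logical(1))]
  if (length(absent))
    stop("input file(s) not found: ",
         paste(unlist(cfg$inputs[absent]), collapse = ", "))
  if (is.null(cfg$outdir)) stop("run config needs 'outdir'")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

.qcFromList <- function(x) do.call(qcConfig, x %||% list())
.tierFromList <- function(x) do.call(tierThresholds, x %||% list())
.familyFromList <- function(x) {
  x <- x %||% list()
  label <- x$label %||% "family"
  x$label <- NULL
  list(thresholds = do.call(familyThresholds, x), label = label)
}
.contrastFromList <- function(x) do.call(contrastConfig, x %||% list())

.log <- function(stage, ...) {
  message(sprintf("[INFO] %s: %s", stage, paste0(...)))
}

#' Run the downstream pipeline end to end
#'
#' Executes the stages in order — transcript QC (clip, length filter,
#' vector purge), homology tiering, gene-family calling, Pfam/GO-Slim
#' annotation and expression contrasts — writing every stage output plus a
#' JSON run manifest recording all parameters actually used (defaults
#' included), the seed and the output files. A rerun with the same
#' configuration reproduces byte-identical outputs. Any stage failure halts
#' with the stage name and cause.
#'
#' @param cfg Run-configuration list (from \code{\link{readRunConfig}}) or a
#'   path to the YAML file.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  cfg <- validateRunConfig(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  wt <- function(d, f) {
    utils::write.table(d, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  files <- character()
  params <- list(seed = cfg$seed)

  qcCfg <- .qcFromList(cfg$qc)
  qcRes <- stage("qc", {
    x <- Biostrings::readDNAStringSet(cfg$inputs$transcripts)
    names(x) <- sub(" .*$", "", names(x))
    vm <- readVectorMatches(cfg$inputs$vector_matches)
    runQc(x, vm, qcCfg)
  })
  .log("qc", length(qcRes$transcripts), " transcripts retained")
  Biostrings::writeXStringSet(qcRes$transcripts, out("qc_transcripts.fa"))
  files <- c(files, "qc_transcripts.fa", wt(qcRes$report, "qc_report.tsv"))
  params$qc <- .slotsAsList(qcCfg)

  tierT <- .tierFromList(cfg$tier)
  tiers <- stage("tier", {
    hits <- readAlignmentTable(cfg$inputs$alignments)
    hits <- hits[hits$qseqid %in% names(qcRes$transcripts), , drop = FALSE]
    tierTable(hits, tierT, allIds = names(qcRes$transcripts))
  })
  .log("tier", paste(names(tiers$counts), tiers$counts, sep = "=",
                     collapse = " "))
  files <- c(files, wt(tiers$labels, "tiers.tsv"))
  jsonlite::write_json(as.list(tiers$counts), out("tier_counts.json"),
                       auto_unbox = TRUE)
  files <- c(files, "tier_counts.json")
  params$tier <- .slotsAsList(tierT)

  famCfg <- .familyFromList(cfg$family)
  calls <- stage("family", {
    fh <- readAlignmentTable2(cfg$inputs$family_hits)
    callFamily(fh, famCfg$thresholds, famCfg$label)
  })
  .log("family", sum(calls$member), " of ", nrow(calls), " members")
  files <- c(files, wt(calls, "family_calls.tsv"))
  params$family <- c(.slotsAsList(famCfg$thresholds),
                     list(label = famCfg$label))

  slim <- stage("goslim", {
    g <- readObo(cfg$inputs$obo)
    map <- readPfamToGo(cfg$inputs$pfam2go)
    pa <- utils::read.delim(cfg$inputs$pfam_assignments,
                            stringsAsFactors = FALSE)
    pairs <- mapPfamToGo(pa, map)
    list(assignments = slimAssignments(pairs, g),
         counts = countDistinctTerms(pairs, g))
  })
  .log("goslim", nrow(slim$assignments), " slim assignments")
  files <- c(files, wt(slim$assignments, "goslim.tsv"))
  jsonlite::write_json(lapply(slim$counts, as.list),
                       out("aspect_counts.json"), auto_unbox = TRUE)
  files <- c(files, "aspect_counts.json")

  conCfg <- .contrastFromList(cfg$contrast)
  expr <- stage("expression", {
    cm <- readCountMatrix(cfg$inputs$counts)
    tpm <- computeTpm(cm)
    pooled <- poolGroups(cm)
    tpmAll <- cbind(tpm, pooled$tpm)
    cc <- contrastColumns(conCfg@contrast)
    ranked <- rankContrast(rownames(tpmAll), tpmAll[, cc[1]],
                           tpmAll[, cc[2]], conCfg)
    list(tpm = tpmAll, ranked = ranked)
  })
  .log("expression", nrow(expr$ranked), " ranked contrast rows")
  tpmOut <- data.frame(transcript = rownames(expr$tpm), expr$tpm,
                       check.names = FALSE)
  files <- c(files, wt(tpmOut, "tpm.tsv"),
             wt(expr$ranked, "contrast.tsv"))
  params$contrast <- .slotsAsList(conCfg)

  manifest <- list(inputs = cfg$inputs, outdir = cfg$outdir,
                   parameters = params, outputs = sort(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

.slotsAsList <- function(obj) {
  nm <- methods::slotNames(class(obj))
  stats::setNames(lapply(nm, function(s) methods::slot(obj, s)), nm)
}

## family hit tables share the alignment dialect minus n_hsps
readAlignmentTable2 <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qseqid", "qlen", "sseqid", "slen", "length", "positive",
            "bitscore")
  if (!all(need %in% names(h)))
    stop("family hit table needs columns: ", paste(need, collapse = ", "))
  h
}

#' Summarize sequencing data volumes
#'
#' Column totals for a per-sample volume table (read pairs and bases, raw
#' and post-normalization), with a consistency flag for the paired-end
#' relationship \code{bases = pairs * 2 * readLength}.
#'
#' @param v data.frame with column \code{sample} and numeric volume columns
#'   (e.g. \code{raw_pairs}, \code{raw_bases}, \code{norm_pairs},
#'   \code{norm_bases}).
#' @param readLength Uniform read length in bp for the consistency check
#'   (default 100; set \code{NA} to skip).
#' @return List with \code{totals} (named numeric of column sums) and
#'   \code{consistent} (logical, \code{NA} when not checked).
#' @examples
#' summarizeVolumes(data.frame(sample = c("a", "b"),
#'                             raw_pairs = c(10, 20),
#'                             raw_bases = c(4000, 8000)))
#' @export
summarizeVolumes <- function(v, readLength = 100) {
  num <- vapply(v, is.numeric, logical(1))
  if (any(as.matrix(v[, num, drop = FALSE]) < 0, na.rm = TRUE))
    stop("volume entries must be nonnegative")
  totals <- colSums(v[, num, drop = FALSE])
  consistent <- NA
  if (!is.na(readLength) &&
      all(c("raw_pairs", "raw_bases") %in% names(v))) {
    consistent <- all(v$raw_bases == v$raw_pairs * 2 * readLength)
    if (!consistent)
      .log("volumes", "bases != pairs * 2 * ", readLength,
           " for at least one sample")
  }
  list(totals = totals, consistent = consistent)
}

#' Path to a bundled reference table
#'
#' Access the plain-text reference tables shipped with the package:
#' \code{sequencing_volumes.tsv} (per-sample read-pair and base volumes),
#' \code{stage_contrast_tpm.tsv} (top fold-change transcripts per contrast
#' with their TPM pairs), \code{p450_sex_tpm.tsv} (cytochrome P450
#' male/female TPM pairs) and \code{terpene_pathway_tpm.tsv} (terpene
#' biosynthesis gene TPM values and printed log2 ratios for the harlequin
#' bug and brown marmorated stink bug).
#'
#' @param file File name under \code{extdata}; empty to list all.
#' @return Path to the file.
#' @examples
#' head(read.delim(hbugExtdata("stage_contrast_tpm.tsv")))
#' @export
hbugExtdata <- function(file = "") {
  system.file("extdata", file, package = "hbugkit", mustWork = nzchar(file))
}
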