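#' Developmental stages of the single-embryo RNA-Seq design
#'
#' Yolk (Y), embryonic stages S2-S8, clonal asexual adults (C4) and virgin
#' sexually mature adults (SX).
#' @export
STAGES <- c("Y", "S2", "S3", "S4", "S5", "S6", "S7", "S8", "C4", "SX")

RRNA_ROLES <- c("16S", "18S", "28S", "none")

#' Construct a count study
#'
#' A transcripts-by-samples integer count matrix with transcript metadata
#' (length, ORF flag, transposon/retrovirus flag, ribosomal role) and sample
#' metadata (stage, replicate), mirroring a single-embryo RNA-Seq design.
#'
#' @param counts non-negative integer matrix, rownames = transcript ids,
#'   colnames = sample ids.
#' @param transcripts data frame with columns `transcript_id`, `length_bp`
#'   (\eqn{\ge 1}), `has_orf`, `is_transposon`, `is_ribosomal`, `rrna_role`
#'   (one of "16S", "18S", "28S", "none"); one row per matrix row, in
#'   order.
#' @param samples data frame with columns `sample`, `stage` (one of
#'   [STAGES]) and `replicate`; one row per matrix column, in order.
#' @return An object of class `"count_study"`.
#' @export
count_study <- function(counts, transcripts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("'counts' must be non-negative without NAs", call. = FALSE)
  }
  need_t <- c("transcript_id", "length_bp", "has_orf", "is_transposon",
              "is_ribosomal", "rrna_role")
  if (!all(need_t %in% names(transcripts))) {
    stop("'transcripts' must have columns ", paste(need_t, collapse = ", "),
         call. = FALSE)
  }
  need_s <- c("sample", "stage", "replicate")
  if (!all(need_s %in% names(samples))) {
    stop("'samples' must have columns ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(transcripts) != nrow(counts) ||
      !identical(as.character(transcripts$transcript_id), rownames(counts))) {
    stop("'transcripts' rows must match the count matrix rownames in order",
         call. = FALSE)
  }
  if (nrow(samples) != ncol(counts) ||
      !identical(as.character(samples$sample), colnames(counts))) {
    stop("'samples' rows must match the count matrix colnames in order",
         call. = FALSE)
  }
  if (any(transcripts$length_bp < 1)) {
    stop("transcript lengths must be >= 1 bp", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(samples$stage)), STAGES)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(as.character(transcripts$rrna_role)), RRNA_ROLES)
  if (length(bad)) {
    stop("unknown rrna_role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts,
                 transcripts = transcripts[, need_t],
                 samples = samples[, need_s]),
            class = "count_study")
}

#' @export
print.count_study <- function(x, ...) {
  st <- table(factor(x$samples$stage, levels = STAGES))
  st <- st[st > 0]
  cat(sprintf("Count study: %d transcripts x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(st), st), collapse = " ")))
  cat(sprintf("  rRNA rows: %d; transposon-flagged: %d; with ORF: %d\n",
              sum(x$transcripts$is_ribosomal),
              sum(x$transcripts$is_transposon),
              sum(x$transcripts$has_orf)))
  invisible(x)
}

# columns of a study belonging to the given stages
stage_columns <- function(study, stages) {
  which(as.character(study$samples$stage) %in% stages)
}

subset_transcripts <- function(study, keep) {
  count_study(study$counts[keep, , drop = FALSE],
              study$transcripts[keep, , drop = FALSE],
              study$samples)
}
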