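#' Write embryo spot clouds to CSV
#'
#' One row per spot with columns `embryo_id, spot_id, class, x_um, y_um,
#' z_um`; the embryo center and pharynx landmarks are stored as rows with
#' class `center` / `pharynx` (one each per embryo). With `dialect =
#' "position"`, the coordinate columns are headed `Position X`, `Position
#' Y`, `Position Z`, the dialect of imaging-software spot exports.
#'
#' @param frames an [embryo_frame()] or list of them.
#' @param path output file path.
#' @param dialect `"canonical"` or `"position"` header dialect.
#' @return `path`, invisibly.
#' @export
write_spots_csv <- function(frames, path, dialect = c("canonical", "position")) {
  dialect <- match.arg(dialect)
  if (inherits(frames, "embryo_frame")) frames <- list(frames)
  stopifnot(all(vapply(frames, inherits, logical(1), "embryo_frame")))
  rows <- do.call(rbind, lapply(frames, function(fr) {
    lm <- data.frame(
      spot_id = c("center", "pharynx"),
      class = c("center", "pharynx"),
      x_um = c(fr$center[1], fr$pharynx[1]),
      y_um = c(fr$center[2], fr$pharynx[2]),
      z_um = c(fr$center[3], fr$pharynx[3]))
    out <- rbind(fr$cells, lm)
    cbind(embryo_id = fr$embryo_id, out)
  }))
  if (dialect == "position") {
    names(rows)[names(rows) == "x_um"] <- "Position X"
    names(rows)[names(rows) == "y_um"] <- "Position Y"
    names(rows)[names(rows) == "z_um"] <- "Position Z"
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read embryo spot clouds from CSV
#'
#' Accepts both the canonical `x_um/y_um/z_um` header and the imaging
#' export dialect `Position X/Position Y/Position Z`. Each embryo must
#' carry a `pharynx` landmark row; a missing `center` row is an error
#' unless `center_fallback = TRUE`, in which case the centroid of the
#' embryo's non-bead spots is used (flagged in the frame's
#' `center_source`).
#'
#' @param path CSV file path.
#' @param center_fallback back-fill a missing center landmark from the
#'   non-bead spot centroid instead of erroring.
#' @return A named list of [embryo_frame()] objects, one per `embryo_id`.
#' @export
read_spots_csv <- function(path, center_fallback = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  pos_names <- c("Position X", "Position Y", "Position Z")
  if (all(pos_names %in% names(raw))) {
    names(raw)[match(pos_names, names(raw))] <- c("x_um", "y_um", "z_um")
  }
  need <- c("embryo_id", "spot_id", "class", "x_um", "y_um", "z_um")
  if (!all(need %in% names(raw))) {
    stop("spot CSV '", path, "' lacks column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  frames <- lapply(split(raw, raw$embryo_id), function(d) {
    id <- as.character(d$embryo_id[1])
    landmark <- function(what) {
      r <- d[d$class == what, , drop = FALSE]
      if (nrow(r) == 0L) return(NULL)
      if (nrow(r) > 1L) {
        stop("embryo '", id, "' has ", nrow(r), " '", what,
             "' landmark rows; expected exactly one", call. = FALSE)
      }
      c(r$x_um, r$y_um, r$z_um)
    }
    pharynx <- landmark("pharynx")
    if (is.null(pharynx)) {
      stop("embryo '", id, "' is missing its 'pharynx' landmark row",
           call. = FALSE)
    }
    center <- landmark("center")
    center_source <- "landmark"
    cells <- d[!d$class %in% c("center", "pharynx"), need[-1], drop = FALSE]
    if (is.null(center)) {
      if (!center_fallback) {
        stop("embryo '", id, "' is missing its 'center' landmark row",
             call. = FALSE)
      }
      nb <- cells[cells$class != "bead", , drop = FALSE]
      if (nrow(nb) == 0L) {
        stop("embryo '", id,
             "' has no center landmark and no non-bead spots to take a centroid from",
             call. = FALSE)
      }
      center <- c(mean(nb$x_um), mean(nb$y_um), mean(nb$z_um))
      center_source <- "centroid"
      message("embryo '", id,
              "': center landmark absent; using centroid of ", nrow(nb),
              " non-bead spots")
    }
    rownames(cells) <- NULL
    embryo_frame(id, cells, center, pharynx, center_source = center_source)
  })
  frames[order(names(frames))]
}

#' Write a count study as TSV tables
#'
#' Writes `counts.tsv` (first column `transcript_id`, one column per sample
#' named `<stage>_<rep>`), `transcripts.tsv` and `samples.tsv` into `dir`.
#'
#' @param study a [count_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_study <- function(study, dir) {
  stopifnot(inherits(study, "count_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- data.frame(transcript_id = rownames(study$counts),
                    study$counts, check.names = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$transcripts, file.path(dir, "transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count study from TSV tables
#'
#' Counterpart of [write_count_study()]. Malformed metadata produces an
#' error naming the offending file and row.
#'
#' @param dir directory holding `counts.tsv`, `transcripts.tsv`,
#'   `samples.tsv`.
#' @return A [count_study()].
#' @export
read_count_study <- function(dir) {
  paths <- file.path(dir, c("counts.tsv", "transcripts.tsv", "samples.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cnt <- utils::read.delim(paths[1], check.names = FALSE,
                           stringsAsFactors = FALSE)
  tx <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
  smp <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  if (names(cnt)[1] != "transcript_id") {
    stop("'", paths[1], "': first column must be 'transcript_id'",
         call. = FALSE)
  }
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$transcript_id
  bad <- which(!is.finite(tx$length_bp) | tx$length_bp < 1)
  if (length(bad)) {
    stop("'", paths[2], "', row ", bad[1],
         ": invalid length_bp for transcript '", tx$transcript_id[bad[1]],
         "'", call. = FALSE)
  }
  bad <- which(!smp$stage %in% STAGES)
  if (length(bad)) {
    stop("'", paths[3], "', row ", bad[1], ": unknown stage '",
         smp$stage[bad[1]], "'", call. = FALSE)
  }
  count_study(counts, tx, smp)
}
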