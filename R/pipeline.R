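#' Run the spatial (oral-aboral) analysis end to end
#'
#' From spot clouds to fitted damped-sine models: pools oral-aboral angles
#' across embryos separately for each requested spot class (piwi-1+ cells;
#' mitotic cells), fits the dampening parameter by maximum likelihood,
#' attaches a parametric-bootstrap SE, compares against the
#' uniform-on-sphere null, and tabulates a histogram. Classes with no spots
#' are reported as absent rather than failing the run.
#'
#' @param input a spot CSV path (or vector of paths), an [embryo_frame()],
#'   or a list of frames.
#' @param classes spot classes analyzed separately.
#' @param B bootstrap datasets per class (0 skips the bootstrap).
#' @param bins histogram bins on \eqn{[0, \pi]}.
#' @param seed integer seed for the bootstrap.
#' @param theta_max upper bound for the \eqn{\theta'} search.
#' @param out_dir optional output directory; writes `spatial_report.json`
#'   and `histogram_<class>.tsv` files.
#' @return A list of class `"spatial_report"`: per-class sections (each
#'   with the fit, bootstrap SE, null comparison and histogram), per-embryo
#'   cell counts, and the configuration.
#' @export
run_spatial <- function(input, classes = c("piwi1", "mitotic"), B = 1000,
                        bins = 20, seed = 1, theta_max = 20,
                        out_dir = NULL) {
  frames <- if (inherits(input, "embryo_frame")) {
    list(input)
  } else if (is.character(input)) {
    unlist(lapply(input, read_spots_csv), recursive = FALSE)
  } else {
    input
  }
  stopifnot(all(vapply(frames, inherits, logical(1), "embryo_frame")))
  if (length(frames) == 0L) stop("no embryo frames to analyze", call. = FALSE)

  embryo_counts <- do.call(rbind, lapply(frames, function(fr) {
    data.frame(embryo_id = fr$embryo_id,
               n_piwi1 = sum(fr$cells$class == "piwi1"),
               n_mitotic = sum(fr$cells$class == "mitotic"),
               n_bead = sum(fr$cells$class == "bead"))
  }))

  sections <- list()
  for (cl in classes) {
    pooled <- pool_theta(lapply(frames, oral_aboral_angles,
                                include_classes = cl))
    if (pooled$n == 0L) {
      sections[[cl]] <- list(present = FALSE, n = 0L)
      next
    }
    fit <- fit_damped_sine(pooled, theta_max = theta_max)
    if (B > 0) fit <- add_bootstrap_se(fit, B = B, seed = seed)
    sections[[cl]] <- list(
      present = TRUE,
      n = pooled$n,
      fit = fit,
      null_comparison = compare_to_null(fit),
      histogram = theta_histogram(pooled, bins = bins))
  }
  if (!any(vapply(sections, `[[`, logical(1), "present"))) {
    stop("no usable spots in any requested class", call. = FALSE)
  }

  report <- structure(list(sections = sections,
                           embryo_counts = embryo_counts,
                           config = list(classes = classes, B = B,
                                         bins = bins, seed = seed,
                                         theta_max = theta_max)),
                      class = "spatial_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    js <- list(config = report$config,
               embryo_counts = embryo_counts,
               sections = lapply(sections, function(s) {
                 if (!s$present) return(list(present = FALSE))
                 list(present = TRUE, n = s$n,
                      fit = jsonlite::fromJSON(fit_to_json(s$fit)),
                      verdict = s$null_comparison$verdict)
               }))
    jsonlite::write_json(js, file.path(out_dir, "spatial_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (cl in names(sections)) {
      if (sections[[cl]]$present) {
        utils::write.table(sections[[cl]]$histogram,
                           file.path(out_dir, paste0("histogram_", cl, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  report
}

#' @export
print.spatial_report <- function(x, ...) {
  cat(sprintf("Spatial analysis: %d embryos\n", nrow(x$embryo_counts)))
  for (cl in names(x$sections)) {
    s <- x$sections[[cl]]
    if (!s$present) {
      cat(sprintf("  %s: absent (no spots)\n", cl))
    } else {
      se <- if (is.na(s$fit$se_boot)) "" else
        sprintf(" +/- %.3g", s$fit$se_boot)
      cat(sprintf("  %s: n = %d, theta' = %.3g%s rad, log10 LR = %.3g\n",
                  cl, s$n, s$fit$theta_prime, se, s$fit$log10_lr))
    }
  }
  invisible(x)
}

#' Run the molecular staging analysis end to end
#'
#' From a count study to stage signatures: low-expression/rRNA filtering,
#' TMM-scaled RPKM, pairwise and mixed-stage-reference enrichment for every
#' embryonic stage present, per-stage signature union, and EEE
#' classification (when S5-S8 samples exist). When a planted ground-truth
#' table is supplied, per-stage recall of the planted transcripts is
#' reported.
#'
#' @param input a [count_study()] or a directory readable by
#'   [read_count_study()].
#' @param thresholds a [staging_thresholds()]; echoed verbatim into the
#'   provenance block.
#' @param ground_truth optional planted-truth table as produced by
#'   [simulate_count_study()].
#' @param out_dir optional output directory; writes `enrichment.tsv`,
#'   `signatures.tsv`, `eee.tsv` and `provenance.json`.
#' @return A list of class `"staging_report"` with `signatures` (named
#'   list per stage), `gates` (the full gate-flag table), `eee`,
#'   `recovery` (if ground truth given), `removed` and `provenance`.
#' @export
run_staging <- function(input, thresholds = staging_thresholds(),
                        ground_truth = NULL, out_dir = NULL) {
  study <- if (inherits(input, "count_study")) input else read_count_study(input)
  prep <- staging_prepare(study, thresholds)
  stages_present <- intersect(paste0("S", 2:8),
                              unique(as.character(study$samples$stage)))
  signatures <- list()
  gate_tables <- list()
  for (s in stages_present) {
    sig <- stage_signature(study, s, thresholds, prep = prep)
    signatures[[s]] <- as.character(sig)
    pw <- attr(sig, "pairwise")
    mx <- attr(sig, "mixed")
    pw$pass_fold <- pw$pass_fold_up
    pw$pass_rpkm <- pw$pass_rpkm_up
    pw$pass_not_yolk_up <- NA
    pw$enriched <- pw$enriched_up
    mx$pass_fold_down <- NA
    mx$pass_rpkm_down <- NA
    mx$enriched_down <- NA
    shared <- c("transcript_id", "stage", "comparison", "log2fc", "padj",
                "avg_rpkm_focal", "pass_padj", "pass_fold",
                "pass_fold_down", "pass_rpkm", "pass_rpkm_down", "pass_orf",
                "pass_not_transposon", "pass_not_yolk_up", "enriched",
                "enriched_down")
    gate_tables[[paste0(s, "_pairwise")]] <- pw[, shared]
    gate_tables[[paste0(s, "_mixed")]] <- mx[, shared]
  }
  eee <- if (all(paste0("S", 2:8) %in% study$samples$stage)) {
    classify_eee(study, thresholds, prep = prep)
  } else {
    NULL
  }
  recovery <- NULL
  if (!is.null(ground_truth) && nrow(ground_truth)) {
    recovery <- do.call(rbind, lapply(split(ground_truth,
                                            ground_truth$stages),
                                      function(g) {
      planted_stages <- strsplit(g$stages[1], ",")[[1]]
      single <- intersect(planted_stages, names(signatures))
      rec <- if (length(single) == 1 && length(planted_stages) == 1) {
        mean(g$transcript_id %in% signatures[[single]])
      } else {
        NA_real_
      }
      data.frame(stages = g$stages[1], n_planted = nrow(g),
                 fold = g$fold[1], recall = rec)
    }))
    rownames(recovery) <- NULL
  }
  provenance <- list(
    thresholds = unclass(thresholds),
    log2fc_printed = sprintf("%.3f", thresholds$log2fc),
    n_transcripts_in = nrow(study$counts),
    n_transcripts_kept = nrow(prep$study$counts),
    n_removed = nrow(prep$removed),
    stages = stages_present,
    tmm_factors = as.list(prep$tmm))
  report <- structure(list(signatures = signatures,
                           gates = do.call(rbind, c(gate_tables,
                                                    make.row.names = FALSE)),
                           eee = eee,
                           recovery = recovery,
                           removed = prep$removed,
                           stage_rpkm = prep$stage_rpkm,
                           provenance = provenance),
                      class = "staging_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$gates, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig_df <- do.call(rbind, lapply(names(signatures), function(s) {
      if (length(signatures[[s]]) == 0) return(NULL)
      data.frame(stage = s, transcript_id = signatures[[s]])
    }))
    if (is.null(sig_df)) {
      sig_df <- data.frame(stage = character(), transcript_id = character())
    }
    utils::write.table(sig_df, file.path(out_dir, "signatures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(eee)) {
      utils::write.table(eee, file.path(out_dir, "eee.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.staging_report <- function(x, ...) {
  cat("Molecular staging analysis\n")
  cat(sprintf("  transcripts: %d kept of %d (%d removed)\n",
              x$provenance$n_transcripts_kept, x$provenance$n_transcripts_in,
              x$provenance$n_removed))
  for (s in names(x$signatures)) {
    cat(sprintf("  %s signature: %d transcripts\n", s,
                length(x$signatures[[s]])))
  }
  if (!is.null(x$eee)) {
    cat(sprintf("  EEE transcripts: %d of %d early-signature transcripts\n",
                sum(x$eee$is_eee), nrow(x$eee)))
  }
  invisible(x)
}

#' Mitotic index of labeled cells
#'
#' Fraction of labeled cells (piwi1 + mitotic spots) that are mitotic, per
#' embryo, with the pooled mean and SD across embryos. Embryos with no
#' labeled cells are excluded with a warning.
#'
#' @param frames an [embryo_frame()] or list of them.
#' @return A list with `per_embryo` (data frame of counts and fractions),
#'   `mean` and `sd` across embryos.
#' @export
mitotic_index <- function(frames) {
  if (inherits(frames, "embryo_frame")) frames <- list(frames)
  per <- do.call(rbind, lapply(frames, function(fr) {
    n_lab <- sum(fr$cells$class %in% c("piwi1", "mitotic"))
    n_mit <- sum(fr$cells$class == "mitotic")
    data.frame(embryo_id = fr$embryo_id, n_labeled = n_lab,
               n_mitotic = n_mit,
               fraction = if (n_lab > 0) n_mit / n_lab else NA_real_)
  }))
  empty <- is.na(per$fraction)
  if (any(empty)) {
    warning(sum(empty), " embryo(s) with zero labeled cells excluded",
            call. = FALSE)
  }
  used <- per$fraction[!empty]
  list(per_embryo = per,
       mean = if (length(used)) mean(used) else NA_real_,
       sd = if (length(used) > 1) stats::sd(used) else NA_real_)
}
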