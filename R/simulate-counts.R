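#' Specification for a simulated single-embryo RNA-Seq count study
#'
#' Describes a negative-binomial count study emulating the single-embryo
#' RNA-Seq design: stages Y, S2-S8, C4 and SX with four biological
#' replicates each. Per-transcript means are proportional to transcript
#' length (so RPKM behaves sensibly) with per-sample lognormal depth
#' variation; designated ribosomal transcripts receive an inflated,
#' sample-variable mean so that they soak up a variable fraction of reads,
#' with the 16S rRNA the most variable. "Planted" transcripts carry a
#' known fold change in the replicates of their planted stage(s) and are
#' reported in a ground-truth table.
#'
#' @param n_transcripts number of non-ribosomal transcripts; three rRNA
#'   rows (16S/18S/28S) are appended when `rRNA_fraction > 0`.
#' @param stages ordered stage labels, a subset of [STAGES].
#' @param reps_per_stage biological replicates per stage (default 4).
#' @param planted list of plantings, each a list with fields `stage` (one
#'   or more stage labels; a multi-stage planting makes a persistent
#'   profile), `n` (number of transcripts) and `fold` (> 1).
#' @param nb_dispersion common negative-binomial dispersion \eqn{\phi}
#'   (variance \eqn{\mu + \phi\mu^2}); 0 gives Poisson counts.
#' @param baseline_mean expected baseline count for a transcript of average
#'   length at unit depth.
#' @param rRNA_fraction expected fraction of each library taken by the
#'   three rRNA transcripts, in [0, 1).
#' @param transcript_length_range min/max transcript length in bases.
#' @param orf_rate,transposon_rate probabilities that a background
#'   transcript has an ORF / is transposon-derived. Planted transcripts are
#'   always given an ORF and never flagged as transposons, so recovery
#'   experiments measure the statistical cascade rather than random
#'   metadata.
#' @param depth_sdlog lognormal SD of per-sample sequencing depth.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return An object of class `"count_sim_spec"`.
#' @export
count_sim_spec <- function(n_transcripts = 2000, stages = STAGES,
                           reps_per_stage = 4, planted = list(),
                           nb_dispersion = 0.05, baseline_mean = 100,
                           rRNA_fraction = 0.15,
                           transcript_length_range = c(500, 5000),
                           orf_rate = 0.9, transposon_rate = 0.05,
                           depth_sdlog = 0.2, seed = 1) {
  if (n_transcripts < 1) stop("'n_transcripts' must be positive", call. = FALSE)
  bad <- setdiff(stages, STAGES)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (reps_per_stage < 1) stop("'reps_per_stage' must be positive", call. = FALSE)
  if (nb_dispersion < 0) stop("'nb_dispersion' must be >= 0", call. = FALSE)
  if (baseline_mean <= 0) stop("'baseline_mean' must be positive", call. = FALSE)
  if (rRNA_fraction < 0 || rRNA_fraction >= 1) {
    stop("'rRNA_fraction' must lie in [0, 1)", call. = FALSE)
  }
  if (length(transcript_length_range) != 2L ||
      transcript_length_range[1] < 1 ||
      transcript_length_range[1] > transcript_length_range[2]) {
    stop("invalid 'transcript_length_range'", call. = FALSE)
  }
  total_planted <- 0L
  for (p in planted) {
    if (!all(c("stage", "n", "fold") %in% names(p))) {
      stop("each planting needs fields 'stage', 'n', 'fold'", call. = FALSE)
    }
    if (!all(p$stage %in% stages)) {
      stop("planted stage(s) not in 'stages': ",
           paste(setdiff(p$stage, stages), collapse = ", "), call. = FALSE)
    }
    if (p$fold <= 1) stop("planted folds must exceed 1", call. = FALSE)
    total_planted <- total_planted + as.integer(p$n)
  }
  if (total_planted > n_transcripts) {
    stop("planted transcripts (", total_planted,
         ") exceed 'n_transcripts' (", n_transcripts, ")", call. = FALSE)
  }
  structure(list(n_transcripts = as.integer(n_transcripts), stages = stages,
                 reps_per_stage = as.integer(reps_per_stage),
                 planted = planted, nb_dispersion = nb_dispersion,
                 baseline_mean = baseline_mean,
                 rRNA_fraction = rRNA_fraction,
                 transcript_length_range = transcript_length_range,
                 orf_rate = orf_rate, transposon_rate = transposon_rate,
                 depth_sdlog = depth_sdlog, seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Simulate a count study with planted enriched transcripts
#'
#' @param spec a [count_sim_spec()].
#' @return A list with `study` (a [count_study()]) and `ground_truth`, a
#'   data frame listing every planted transcript with its stage(s) and
#'   fold — exactly the transcripts whose generating fold differs from 1.
#'   Deterministic given `spec$seed`.
#' @examples
#' sim <- simulate_count_study(count_sim_spec(
#'   n_transcripts = 300, planted = list(list(stage = "S5", n = 10, fold = 10)),
#'   seed = 42))
#' sim$study
#' head(sim$ground_truth)
#' @export
simulate_count_study <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)

  nt <- spec$n_transcripts
  ids <- sprintf("t%05d", seq_len(nt))
  len <- round(stats::runif(nt, spec$transcript_length_range[1],
                            spec$transcript_length_range[2]))
  samples <- data.frame(
    sample = as.vector(vapply(spec$stages, function(s) {
      paste0(s, "_", seq_len(spec$reps_per_stage))
    }, character(spec$reps_per_stage))),
    stage = rep(spec$stages, each = spec$reps_per_stage),
    replicate = rep(seq_len(spec$reps_per_stage), length(spec$stages)))
  ns <- nrow(samples)

  # fold matrix from the plantings; transcripts assigned sequentially
  fold <- matrix(1, nt, ns)
  next_t <- 1L
  gt <- list()
  for (p in spec$planted) {
    idx <- seq.int(next_t, next_t + p$n - 1L)
    next_t <- next_t + as.integer(p$n)
    cols <- which(samples$stage %in% p$stage)
    fold[idx, cols] <- p$fold
    gt[[length(gt) + 1L]] <- data.frame(
      transcript_id = ids[idx],
      stages = paste(p$stage, collapse = ","),
      fold = p$fold)
  }
  ground_truth <- if (length(gt)) do.call(rbind, gt) else {
    data.frame(transcript_id = character(), stages = character(),
               fold = numeric())
  }
  planted_idx <- seq_len(next_t - 1L)

  len_factor <- len / mean(spec$transcript_length_range)
  depth <- stats::rlnorm(ns, 0, spec$depth_sdlog)
  mu <- outer(spec$baseline_mean * len_factor, depth) * fold

  has_orf <- stats::runif(nt) < spec$orf_rate
  is_transposon <- stats::runif(nt) < spec$transposon_rate
  has_orf[planted_idx] <- TRUE
  is_transposon[planted_idx] <- FALSE

  transcripts <- data.frame(
    transcript_id = ids, length_bp = len, has_orf = has_orf,
    is_transposon = is_transposon, is_ribosomal = FALSE,
    rrna_role = "none")

  if (spec$rRNA_fraction > 0) {
    # rRNA mass relative to the expected non-rRNA library, most of it on
    # the 16S transcript with strong per-sample variability
    share <- c(`16S` = 0.6, `18S` = 0.15, `28S` = 0.25)
    sdlog <- c(`16S` = 0.6, `18S` = 0.2, `28S` = 0.2)
    base_total <- colSums(mu)
    rmu <- t(vapply(names(share), function(role) {
      spec$rRNA_fraction / (1 - spec$rRNA_fraction) * base_total *
        share[[role]] * stats::rlnorm(ns, 0, sdlog[[role]])
    }, numeric(ns)))
    mu <- rbind(mu, rmu)
    rlen <- c(`16S` = 1200, `18S` = 1800, `28S` = 3500)
    transcripts <- rbind(transcripts, data.frame(
      transcript_id = paste0("rRNA_", names(share)),
      length_bp = unname(rlen[names(share)]), has_orf = FALSE,
      is_transposon = FALSE, is_ribosomal = TRUE,
      rrna_role = names(share)))
  }

  nall <- nrow(transcripts)
  counts <- matrix(0L, nall, ns,
                   dimnames = list(transcripts$transcript_id,
                                   samples$sample))
  for (j in seq_len(ns)) {
    counts[, j] <- if (spec$nb_dispersion == 0) {
      stats::rpois(nall, mu[, j])
    } else {
      stats::rnbinom(nall, size = 1 / spec$nb_dispersion, mu = mu[, j])
    }
  }
  storage.mode(counts) <- "integer"

  list(study = count_study(counts, transcripts, samples),
       ground_truth = ground_truth)
}
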