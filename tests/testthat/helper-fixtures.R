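# Shared fixtures and independent oracles used across the suite.

# quadrature value of the damped-sine normalizer (oracle for closed forms)
quad_normalizer <- function(tp) {
  stats::integrate(function(th) (1 - exp(-th / tp)) * sin(th), 0, pi,
                   rel.tol = 1e-12)$value
}

# brute-force grid-search MLE over theta' (oracle for the optimizer)
grid_mle <- function(theta, grid = c(0, seq(1e-3, 3, by = 1e-3))) {
  ll <- vapply(grid, function(tp) sum(ddsine(theta, tp, log = TRUE)),
               numeric(1))
  grid[which.max(ll)]
}

# naive O(m^2) Benjamini-Hochberg step-up reference
naive_bh <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- sum(p <= p[i])
    # step-up: minimum of p[j]*m/rank(j) over all j with p[j] >= p[i]
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) p[j] * m / sum(p <= p[j]) else Inf
    }, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# a small deterministic count study with hand-checkable numbers:
# 6 transcripts (one rRNA, one low-CPM) x 4 samples over two stages
toy_study <- function() {
  counts <- rbind(                       # libraries ~5e6-8e6 reads, so the
    t1 = c(100, 110, 90, 100) * 1000,    # single count on 'low' sits below
    t2 = c(10, 12, 9, 11) * 1000,        # 1 CPM summed over samples
    t3 = c(1000, 900, 1100, 1000) * 1000,
    t4 = c(500, 480, 520, 510) * 1000,
    low = c(0, 1, 0, 0),
    rrna = c(5000, 4000, 6000, 5000) * 1000)
  colnames(counts) <- c("S3_1", "S3_2", "S4_1", "S4_2")
  transcripts <- data.frame(
    transcript_id = rownames(counts),
    length_bp = c(1000, 2000, 1000, 500, 1000, 1200),
    has_orf = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    is_transposon = FALSE,
    is_ribosomal = c(rep(FALSE, 5), TRUE),
    rrna_role = c(rep("none", 5), "16S"))
  samples <- data.frame(sample = colnames(counts),
                        stage = c("S3", "S3", "S4", "S4"),
                        replicate = c(1, 2, 1, 2))
  count_study(counts, transcripts, samples)
}

# study with planted enriched transcripts used by the cascade tests
planted_study <- function(seed = 101, n_transcripts = 500,
                          planted = list(list(stage = "S5", n = 50,
                                              fold = 10))) {
  simulate_count_study(count_sim_spec(
    n_transcripts = n_transcripts, planted = planted, seed = seed))
}

# independent gate-by-gate reapplication of the pairwise cascade, working
# from its own CPM/RPKM arithmetic (package TMM factors are an input; they
# are cross-checked against edgeR elsewhere)
naive_pairwise_survivors <- function(study, stage_a, stage_b,
                                     thr = staging_thresholds()) {
  cols_cmp <- which(study$samples$stage %in%
                      setdiff(STAGES, c("C4", "SX")))
  sub <- study$counts[, cols_cmp, drop = FALSE]
  cpm_sum <- rowSums(sweep(sub, 2, colSums(sub) / 1e6, "/"))
  keep <- cpm_sum >= thr$cpm_sum_min & study$transcripts$rrna_role == "none"
  cnt <- study$counts[keep, , drop = FALSE]
  tx <- study$transcripts[keep, , drop = FALSE]
  smp <- study$samples
  f <- tmm_factors(cnt, thr$trim_m, thr$trim_a)
  eff <- colSums(cnt) * f
  rpkm <- sweep(sweep(cnt, 2, eff / 1e6, "/"), 1, tx$length_bp / 1000, "/")
  ca <- which(smp$stage == stage_a)
  cb <- which(smp$stage == stage_b)
  p <- de_test(cnt, ca, cb, eff_lib = eff)
  padj <- stats::p.adjust(p, "BH")
  cpm_eff <- sweep(cnt, 2, eff / 1e6, "/")
  fc <- log2((rowMeans(cpm_eff[, cb, drop = FALSE]) + thr$fc_prior_cpm) /
               (rowMeans(cpm_eff[, ca, drop = FALSE]) + thr$fc_prior_cpm))
  up <- padj < thr$padj_early & fc >= thr$log2fc &
    rowMeans(rpkm[, cb, drop = FALSE]) >= thr$min_rpkm &
    tx$has_orf & !tx$is_transposon
  sort(rownames(cnt)[up])
}

# a frame with known geometry: cells placed explicitly around given
# landmarks
manual_frame <- function(cells, center = c(0, 0, 0),
                         pharynx = c(0, 0, 100), id = "manual") {
  embryo_frame(id, cells, center, pharynx)
}

cells_df <- function(...) {
  pos <- rbind(...)
  data.frame(spot_id = sprintf("s%d", seq_len(nrow(pos))),
             class = "piwi1",
             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_frame <- function(frame, R = diag(3), shift = c(0, 0, 0),
                            scale = 1) {
  cells <- frame$cells
  pos <- t(R %*% t(scale * cbind(cells$x_um, cells$y_um, cells$z_um))) +
    matrix(shift, nrow(cells), 3, byrow = TRUE)
  cells$x_um <- pos[, 1]; cells$y_um <- pos[, 2]; cells$z_um <- pos[, 3]
  embryo_frame(frame$embryo_id, cells,
               center = as.numeric(R %*% (scale * frame$center)) + shift,
               pharynx = as.numeric(R %*% (scale * frame$pharynx)) + shift)
}
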