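test_that("simulated angles follow the damped-sine law", {
  fr0 <- simulate_embryo(embryo_sim_spec(1e5, 0, n_beads = 0, seed = 51))
  th0 <- oral_aboral_angles(fr0, include_classes = c("piwi1", "mitotic"))
  expect_lt(abs(mean(th0$angles) - pi / 2),
            3 * sd(th0$angles) / sqrt(th0$n))
  fr <- simulate_embryo(embryo_sim_spec(1e5, 0.45, n_beads = 0, seed = 52))
  th <- sort(oral_aboral_angles(fr)$angles)
  n <- length(th)
  ks <- max(abs(seq_len(n) / n - pdsine(th, 0.45)),
            abs((seq_len(n) - 1) / n - pdsine(th, 0.45)))
  expect_lt(ks, 0.01)
})

test_that("downstream MLE recovers the generator's ground truth", {
  fr <- simulate_embryo(embryo_sim_spec(4411, 0.45, seed = 53))
  fit <- fit_damped_sine(oral_aboral_angles(fr))
  expect_lt(abs(fit$theta_prime - 0.45), 3 * 0.045)
})

test_that("embryo simulation respects its specification", {
  fr <- simulate_embryo(embryo_sim_spec(0, 0.45, n_beads = 3, seed = 1))
  expect_equal(sum(fr$cells$class != "bead"), 0L)
  expect_equal(sum(fr$cells$class == "bead"), 3L)
  expect_length(fr$center, 3)
  expect_length(fr$pharynx, 3)

  spec <- embryo_sim_spec(500, 0.45, shell_inner_um = 100,
                          shell_outer_um = 140, seed = 2)
  fr2 <- simulate_embryo(spec)
  cells <- fr2$cells[fr2$cells$class != "bead", ]
  r <- sqrt(cells$x_um^2 + cells$y_um^2 + cells$z_um^2)
  expect_true(all(r >= 100 & r <= 140))
  # mitotic labels approx Bernoulli(rate)
  frm <- simulate_embryo(embryo_sim_spec(5000, 0.45, mitotic_rate = 0.2,
                                         n_beads = 0, seed = 3))
  frac <- mean(frm$cells$class == "mitotic")
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
})

test_that("invalid embryo specifications name the offending field", {
  expect_error(embryo_sim_spec(-1, 0.45), "n_cells")
  expect_error(embryo_sim_spec(10, -0.1), "theta_prime")
  expect_error(embryo_sim_spec(10, 0.45, shell_inner_um = 150,
                               shell_outer_um = 140), "shell")
  expect_error(embryo_sim_spec(10, 0.45, mitotic_rate = 1.5), "mitotic_rate")
  expect_error(embryo_sim_spec(10, 0.45, n_beads = -2), "n_beads")
})

test_that("embryo and count simulations are deterministic given seeds", {
  f1 <- simulate_embryo(embryo_sim_spec(100, 0.45, seed = 7))
  f2 <- simulate_embryo(embryo_sim_spec(100, 0.45, seed = 7))
  expect_identical(f1, f2)
  s1 <- simulate_count_study(count_sim_spec(n_transcripts = 100, seed = 8))
  s2 <- simulate_count_study(count_sim_spec(n_transcripts = 100, seed = 8))
  expect_identical(s1$study$counts, s2$study$counts)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("near-Poisson counts match their expected means", {
  spec <- count_sim_spec(n_transcripts = 400, nb_dispersion = 0,
                         rRNA_fraction = 0, depth_sdlog = 0,
                         baseline_mean = 100, seed = 9)
  sim <- simulate_count_study(spec)
  cnt <- sim$study$counts
  mu <- 100 * sim$study$transcripts$length_bp /
    mean(spec$transcript_length_range)
  z <- (rowMeans(cnt) - mu) / sqrt(mu / ncol(cnt))
  expect_gt(mean(abs(z) < 3), 0.98)
})

test_that("ground truth lists exactly the planted transcripts", {
  sim <- simulate_count_study(count_sim_spec(
    n_transcripts = 200,
    planted = list(list(stage = "S5", n = 10, fold = 10),
                   list(stage = c("S2", "S3"), n = 5, fold = 4)),
    seed = 10))
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 15)
  expect_equal(sum(gt$stages == "S5"), 10)
  expect_equal(sum(gt$stages == "S2,S3"), 5)
  # rRNA designation is exactly the three ribosomal rows
  tx <- sim$study$transcripts
  expect_equal(tx$transcript_id[tx$is_ribosomal],
               c("rRNA_16S", "rRNA_18S", "rRNA_28S"))
  expect_true(all(tx$rrna_role[!tx$is_ribosomal] == "none"))
  # planted transcripts always pass the metadata gates
  planted_meta <- tx[tx$transcript_id %in% gt$transcript_id, ]
  expect_true(all(planted_meta$has_orf))
  expect_false(any(planted_meta$is_transposon))
})

test_that("invalid count specifications are rejected", {
  expect_error(count_sim_spec(planted = list(list(stage = "S5", n = 10,
                                                  fold = 0.5))),
               "exceed 1")
  expect_error(count_sim_spec(n_transcripts = 5,
                              planted = list(list(stage = "S5", n = 10,
                                                  fold = 2))),
               "exceed")
  expect_error(count_sim_spec(stages = c("Y", "S9")), "unknown stage")
  expect_error(count_sim_spec(planted = list(list(stage = "C9", n = 1,
                                                  fold = 2)),
                              stages = c("Y", "S2")), "not in")
  expect_error(count_sim_spec(rRNA_fraction = 1), "rRNA_fraction")
})

test_that("cohort simulation produces distinct, reproducible embryos", {
  spec <- embryo_sim_spec(50, 0.45, seed = 12)
  cohort <- simulate_embryo_cohort(4, spec)
  expect_length(cohort, 4)
  expect_false(identical(cohort[[1]]$cells$x_um, cohort[[2]]$cells$x_um))
  again <- simulate_embryo_cohort(4, spec)
  expect_identical(cohort, again)
  sizes <- simulate_embryo_cohort(3, spec, cells_per_embryo = c(10, 20, 30))
  expect_equal(vapply(sizes, function(f) sum(f$cells$class != "bead"),
                      integer(1)),
               c(emb001 = 10L, emb002 = 20L, emb003 = 30L))
})
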