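test_that("low-expression filter removes sub-CPM and ribosomal transcripts", {
  st <- toy_study()
  filtered <- filter_low_expression(st)
  expect_setequal(rownames(filtered$counts), c("t1", "t2", "t3", "t4"))
  removed <- attr(filtered, "removed")
  expect_setequal(removed$transcript_id, c("low", "rrna"))
  expect_equal(removed$reason[removed$transcript_id == "rrna"], "rRNA")
  expect_equal(removed$reason[removed$transcript_id == "low"], "low_cpm")
  # zero-count transcripts always go; clean matrices pass through unchanged
  clean <- subset_counts <- filtered
  expect_equal(nrow(filter_low_expression(clean)$counts), 4)
})

test_that("TMM factors behave on degenerate and composition cases", {
  m <- matrix(rep(c(100, 200, 50, 400), 3), 4, 3,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  expect_equal(unname(tmm_factors(m)), rep(1, 3), tolerance = 1e-12)
  # pure depth difference: factors stay equal after depth adjustment
  m2 <- cbind(a = c(100, 200, 50, 400), b = 2 * c(100, 200, 50, 400))
  f <- tmm_factors(m2)
  expect_lt(abs(f[["a"]] / f[["b"]] - 1), 1e-6)
  # geometric mean is 1 on any input
  set.seed(71)
  m3 <- matrix(rnbinom(600, size = 5, mu = 80), 100, 6)
  expect_equal(exp(mean(log(tmm_factors(m3)))), 1, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 2))), "zero library")
})

test_that("TMM factors agree with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(72)
  for (i in 1:3) {
    m <- matrix(rnbinom(500 * 6, size = 10,
                        mu = rep(50 * exp(rnorm(500, 0, 1.5)), 6)), 500, 6)
    m[1:50, 1] <- m[1:50, 1] * 8  # composition bias in one sample
    ours <- unname(tmm_factors(m))
    ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("scaled RPKM is definitional and shielded from 16S inflation", {
  mk <- function(c16) {
    counts <- rbind(a = c(10, 10), b = c(989990, 989990),
                    c = c(5000, 5000), r16 = c16)
    colnames(counts) <- c("S3_1", "S3_2")
    count_study(counts,
                data.frame(transcript_id = rownames(counts),
                           length_bp = c(1000, 2000, 500, 1500),
                           has_orf = TRUE, is_transposon = FALSE,
                           is_ribosomal = c(FALSE, FALSE, FALSE, TRUE),
                           rrna_role = c("none", "none", "none", "16S")),
                data.frame(sample = colnames(counts), stage = "S3",
                           replicate = 1:2))
  }
  st <- mk(c(5000, 5000))
  rp <- rpkm_scaled(st)
  # identical samples: factors 1, library (sans 16S) exactly 1e6 + 5000 - wait
  expect_false("r16" %in% rownames(rp))
  lib <- 10 + 989990 + 5000
  expect_equal(rp["a", 1], 10 / (1 * lib / 1e6), tolerance = 1e-12)
  expect_equal(unname(attr(rp, "tmm_factors")), c(1, 1), tolerance = 1e-12)
  # inflating only the 16S row leaves everything else untouched
  rp2 <- rpkm_scaled(mk(c(5000, 500000)))
  expect_equal(rp2, rp, tolerance = 1e-12)
  # zero count -> zero RPKM
  st0 <- mk(c(5000, 5000))
  st0$counts["c", ] <- 0L
  expect_equal(unname(rpkm_scaled(st0)["c", ]), c(0, 0))
})

test_that("NB test is calibrated under the null and powered for planted folds", {
  set.seed(4)
  nt <- 2000
  mu <- 100 * exp(rnorm(nt, 0, 1))
  cnt <- matrix(rnbinom(nt * 8, size = 20, mu = rep(mu, 8)), nt, 8,
                dimnames = list(sprintf("t%04d", 1:nt), paste0("s", 1:8)))
  p <- de_test(cnt, 1:4, 5:8)
  se3 <- 3 * sqrt(0.05 * 0.95 / nt)
  expect_lt(abs(mean(p < 0.05) - 0.05), se3)
  # a planted ten-fold transcript at 4 vs 4 replicates
  cnt2 <- cnt
  cnt2[1, 5:8] <- rnbinom(4, size = 20, mu = 10 * mu[1])
  expect_lt(de_test(cnt2, 1:4, 5:8)[1], 1e-5)
})

test_that("supplied p-values pass through the test engine unchanged", {
  cnt <- matrix(5L, 4, 4, dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
  supplied <- c(t3 = 0.3, t1 = 0.1, t2 = 0.2, t4 = 0.4)
  out <- de_test(cnt, 1:2, 3:4, pvalues = supplied)
  expect_identical(out, supplied[rownames(cnt)])
  expect_error(de_test(cnt, 1:2, 3:4, pvalues = c(t1 = 0.1)), "missing")
  expect_error(de_test(cnt, integer(0), 3:4), "at least one")
  expect_warning(de_test(cnt, 1, 2:4, dispersion = 0.1), "single replicate")
})

test_that("BH adjustment matches a naive quadratic reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(73)
  for (i in 1:5) {
    p <- runif(40)
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
  }
  p2 <- rbeta(40, 0.2, 3)  # heavy near zero
  expect_equal(bh_adjust(p2), naive_bh(p2), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "NA")
})

test_that("pairwise cascade survivors equal an independent gate-by-gate oracle", {
  for (seed in 1:10) {
    sim <- planted_study(seed = 200 + seed, n_transcripts = 150,
                         planted = list(list(stage = "S5", n = 15,
                                             fold = 10)))
    res <- pairwise_enriched(sim$study, "S4", "S5")
    ours <- sort(res$transcript_id[res$enriched_up])
    expect_identical(ours,
                     naive_pairwise_survivors(sim$study, "S4", "S5"))
  }
})

test_that("planted five-fold-up transcripts show up as pairwise calls in both directions", {
  sim <- planted_study(seed = 301, n_transcripts = 400,
                       planted = list(list(stage = "S5", n = 50, fold = 10)))
  planted <- sim$ground_truth$transcript_id
  up <- pairwise_enriched(sim$study, "S4", "S5")
  recall <- mean(planted %in% up$transcript_id[up$enriched_up])
  expect_gte(recall, 0.9)
  # the same transcripts fall back down between S5 and S6
  down <- pairwise_enriched(sim$study, "S5", "S6")
  recall_down <- mean(planted %in% down$transcript_id[down$enriched_down])
  expect_gte(recall_down, 0.9)
})

test_that("every failed call is attributable to a named gate", {
  sim <- planted_study(seed = 302, n_transcripts = 200,
                       planted = list(list(stage = "S5", n = 20, fold = 10)))
  study <- sim$study
  # break the ORF flag of one planted transcript
  tid <- sim$ground_truth$transcript_id[1]
  study$transcripts$has_orf[study$transcripts$transcript_id == tid] <- FALSE
  res <- pairwise_enriched(study, "S4", "S5")
  row <- res[res$transcript_id == tid, ]
  expect_false(row$pass_orf)
  expect_false(row$enriched_up)
  expect_true(row$pass_padj && row$pass_fold_up && row$pass_rpkm_up)
  gates <- c("pass_padj", "pass_fold_up", "pass_rpkm_up", "pass_orf",
             "pass_not_transposon")
  not_enriched <- res[!res$enriched_up, gates]
  expect_true(all(rowSums(!not_enriched) >= 1))
  enriched <- res[res$enriched_up, gates]
  if (nrow(enriched)) expect_true(all(as.matrix(enriched)))
})

test_that("relaxing any single threshold never shrinks the enriched set", {
  sim <- planted_study(seed = 303, n_transcripts = 200,
                       planted = list(list(stage = "S5", n = 20, fold = 6)))
  base <- staging_thresholds()
  base_set <- with(pairwise_enriched(sim$study, "S4", "S5", base),
                   transcript_id[enriched_up])
  relaxed <- list(staging_thresholds(padj_early = 1e-3),
                  staging_thresholds(log2fc = 1),
                  staging_thresholds(min_rpkm = 0.1))
  for (thr in relaxed) {
    bigger <- with(pairwise_enriched(sim$study, "S4", "S5", thr),
                   transcript_id[enriched_up])
    expect_true(all(base_set %in% bigger))
  }
})

test_that("mixed-reference call flips exactly at the late-stage padj gate", {
  sim <- planted_study(seed = 304, n_transcripts = 100,
                       planted = list(list(stage = "S6", n = 5, fold = 10)))
  prep <- smedembryo:::staging_prepare(sim$study, staging_thresholds())
  kept <- rownames(prep$study$counts)
  m <- length(kept)
  target <- sim$ground_truth$transcript_id[1]
  mk_p <- function(padj_target) {
    p <- setNames(rep(1, m), kept)
    p[target] <- padj_target / m   # BH: smallest p adjusts to p * m
    p
  }
  res_pass <- mixed_reference_enriched(sim$study, "S6", prep = prep,
                                       pvalues = mk_p(1e-21))
  res_fail <- mixed_reference_enriched(sim$study, "S6", prep = prep,
                                       pvalues = mk_p(1e-19))
  row_pass <- res_pass[res_pass$transcript_id == target, ]
  row_fail <- res_fail[res_fail$transcript_id == target, ]
  expect_true(row_pass$pass_fold && row_pass$pass_rpkm)
  expect_true(row_pass$enriched)
  expect_false(row_fail$pass_padj)
  expect_false(row_fail$enriched)
  expect_equal(unique(res_pass$padj_gate), 1e-20)
})

test_that("early-stage mixed calls exclude yolk-upregulated transcripts", {
  sim <- planted_study(seed = 305, n_transcripts = 200,
                       planted = list(
                         list(stage = c("Y", "S3"), n = 5, fold = 100),
                         list(stage = "S3", n = 5, fold = 10)))
  gt <- sim$ground_truth
  yolk_ids <- gt$transcript_id[gt$stages == "Y,S3"]
  clean_ids <- gt$transcript_id[gt$stages == "S3"]
  res <- mixed_reference_enriched(sim$study, "S3")
  yolk_rows <- res[res$transcript_id %in% yolk_ids, ]
  expect_true(all(!yolk_rows$pass_not_yolk_up))
  expect_true(all(!yolk_rows$enriched))
  clean_rows <- res[res$transcript_id %in% clean_ids, ]
  expect_true(all(clean_rows$pass_not_yolk_up))
  expect_gte(mean(clean_rows$enriched), 0.8)
})

test_that("stage signatures are the union of pairwise and mixed calls", {
  sim <- planted_study(seed = 306, n_transcripts = 200,
                       planted = list(list(stage = "S5", n = 20, fold = 10)))
  sig <- stage_signature(sim$study, "S5")
  pw <- attr(sig, "pairwise")
  mx <- attr(sig, "mixed")
  expect_identical(as.character(sig),
                   sort(union(pw$transcript_id[pw$enriched_up],
                              mx$transcript_id[mx$enriched])))
  expect_true(all(sim$ground_truth$transcript_id %in% sig))
  expect_error(stage_signature(sim$study, "Y"), "S2..S8")
})

test_that("EEE classification recovers planted early-decline profiles", {
  sim <- simulate_count_study(count_sim_spec(
    n_transcripts = 400,
    planted = list(
      list(stage = "S3", n = 20, fold = 10),
      list(stage = c("S2", "S3", "S4", "S5", "S6", "S7", "S8"), n = 20,
           fold = 10)),
    seed = 307))
  gt <- sim$ground_truth
  truth <- gt$transcript_id[gt$stages == "S3"]
  decoys <- gt$transcript_id[gt$stages != "S3"]
  eee <- classify_eee(sim$study)
  called <- eee$transcript_id[eee$is_eee]
  expect_gte(mean(truth %in% called), 0.9)            # sensitivity
  expect_gte(mean(!decoys %in% called), 0.9)          # specificity
  # evidence columns mirror the reported fractions' ingredients
  tr <- eee[eee$transcript_id %in% truth, ]
  expect_true(all(tr$peak_stage == "S3"))
  expect_true(all(tr$s2_vs_y_fold > 0))
  expect_true(all(tr$max_late_rpkm <= tr$peak_rpkm / 5))
})

test_that("EEE rule: early signature membership plus sustained decline", {
  sim <- planted_study(seed = 308, n_transcripts = 150,
                       planted = list(list(stage = "S3", n = 10, fold = 10)))
  eee <- classify_eee(sim$study)
  # every EEE transcript sits in an early signature and declined five-fold
  sigs <- attr(eee, "signatures")
  pool <- union(union(sigs$S2, sigs$S3), sigs$S4)
  expect_true(all(eee$transcript_id %in% pool))
  expect_identical(eee$is_eee, eee$declined)
  # a study without late stages cannot classify
  sub_cols <- sim$study$samples$stage %in% c("Y", "S2", "S3", "S4")
  small <- count_study(sim$study$counts[, sub_cols],
                       sim$study$transcripts,
                       sim$study$samples[sub_cols, ])
  expect_error(classify_eee(small), "S5")
})

test_that("the fold gate is log2(5), printed as 2.322", {
  thr <- staging_thresholds()
  expect_identical(thr$log2fc, log2(5))
  expect_identical(sprintf("%.3f", thr$log2fc), "2.322")
})
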