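test_that("CPM columns scale by library size and sum to one million", {
  counts <- make_counts(matrix(c(100, 999900, 5, 995), ncol = 2,
                               dimnames = list(c("a", "b"), c("S1", "S2"))))
  cpm <- compute_cpm(counts)
  expect_equal(cpm$S1[1], 100)     # 100 reads in a 1e6 library
  expect_equal(cpm$S2[1], 5000)    # 5 reads in a 1e3 library
  for (i in 1:10) {
    rc <- make_panel_counts(n_genes = 7, n_samples = 5, seed = i)
    sums <- colSums(compute_cpm(rc)[-1])
    expect_equal(unname(sums), rep(1e6, 5), tolerance = 1e-6)
  }
  zero <- make_counts(matrix(c(1, 0, 2, 0), ncol = 2,
                             dimnames = list(c("a", "b"), c("S1", "S2"))))
  zero$S2 <- c(0, 0)
  expect_error(compute_cpm(zero), "S2")
})

test_that("control fractions are percentages of the total library", {
  m <- matrix(c(450, 50, 500, 0, 0, 1000), ncol = 2,
              dimnames = list(c("POS1", "ANT1", "GENE1"), c("S1", "S2")))
  counts <- make_counts(m)
  expect_equal(control_fraction(counts, "POS1", "S1")$pct, 45)
  expect_equal(control_fraction(counts, "POS1", "S2")$pct, 0)
  expect_equal(control_fraction(counts, c("POS1", "ANT1", "GENE1"), "S1")$pct, 100)
  expect_error(control_fraction(counts, "POS9"), "POS9")
  expect_error(control_fraction(counts, "POS1", "S9"), "S9")
})

test_that("negative-control mean CPM is the arithmetic mean over the set", {
  cpm <- make_counts(matrix(c(10, 20, 30, 40, 0, 0, 0, 0), ncol = 2,
                            dimnames = list(paste0("ANT", 1:4), c("S1", "S2"))))
  out <- negative_mean_cpm(cpm, paste0("ANT", 1:4))
  expect_equal(out$neg_mean_cpm, c(25, 0))
  one <- negative_mean_cpm(cpm, "ANT3")
  expect_equal(one$neg_mean_cpm[1], 30)
  expect_error(negative_mean_cpm(cpm, character(0)), "Empty")
})

test_that("deviances are centered on the run mean and sum to zero", {
  expect_equal(negative_deviance(c(25, 75)), c(-25, 25))
  expect_equal(negative_deviance(c(7, 7, 7)), c(0, 0, 0))
  expect_equal(negative_deviance(c(0, 10, 20)), c(-10, 0, 10))
  expect_error(negative_deviance(numeric(0)), "Empty")
  set.seed(3)
  for (i in 1:50) {
    x <- runif(sample(2:30, 1), 0, 1e4)
    d <- negative_deviance(x)
    expect_lt(abs(sum(d)) / max(abs(d), 1), 1e-9)
  }
})

test_that("positive flags use strict 'exceeds' thresholds", {
  thr <- qc_thresholds()
  expect_equal(as.character(flag_positive(45, thr)), "FAIL")
  expect_equal(as.character(flag_positive(15, thr)), "ALERT")
  expect_equal(as.character(flag_positive(4, thr)), "PASS")
  # boundary values are not exceeded
  expect_equal(as.character(flag_positive(c(10, 40), thr)), c("PASS", "ALERT"))
  expect_equal(as.character(flag_positive(c(10 + 1e-9, 40 + 1e-9), thr)),
               c("ALERT", "FAIL"))
})

test_that("positive flag severity is monotone in the percentage", {
  thr <- qc_thresholds()
  sev <- as.integer(flag_positive(seq(0, 100, by = 0.5), thr))
  expect_true(all(diff(sev) >= 0))
})

test_that("negative flags combine the fraction rule and the deviance band", {
  thr <- qc_thresholds()
  expect_equal(as.character(flag_negative(12, 0, 1, thr)), "FAIL")
  expect_equal(as.character(flag_negative(3, 3, 1, thr)), "ALERT")   # |d| > 2 SD
  expect_equal(as.character(flag_negative(3, -3, 1, thr)), "ALERT")  # two-sided
  expect_equal(as.character(flag_negative(3, 0, 1, thr)), "PASS")
  # one-sided band only reacts to elevated background
  expect_equal(as.character(flag_negative(3, -3, 1, thr, band = "upper")), "PASS")
  expect_equal(as.character(flag_negative(3, 3, 1, thr, band = "upper")), "ALERT")
  # sub-filter off: only the fraction rule acts
  expect_equal(as.character(flag_negative(3, 99, 1, thr, deviance_filter_applied = FALSE)),
               "PASS")
  # degenerate SD: strict inequality means zero deviance never alerts
  expect_equal(as.character(flag_negative(3, 0, 0, thr)), "PASS")
})

test_that("flag combination: FAIL dominates ALERT dominates PASS", {
  combos <- expand.grid(pos = c("PASS", "ALERT", "FAIL"),
                        neg = c("PASS", "ALERT", "FAIL"),
                        stringsAsFactors = FALSE)
  got <- as.character(combine_flags(combos$pos, combos$neg))
  want <- ifelse(combos$pos == "FAIL" | combos$neg == "FAIL", "FAIL",
                 ifelse(combos$pos == "ALERT" | combos$neg == "ALERT",
                        "ALERT", "PASS"))
  expect_equal(got, want)
  expect_error(combine_flags("PASS", "MAYBE"), "PASS, ALERT or FAIL")
})

test_that("run_qc matches an independent first-principles recomputation", {
  set.seed(99)
  for (i in 1:25) {
    n_genes <- sample(1:2, 1)  # 4+4 controls + genes, <= 10 probes
    n_samples <- sample(3:6, 1)
    counts <- make_panel_counts(n_genes = n_genes, n_samples = n_samples,
                                gene_mean = sample(c(10, 200, 5000), 1),
                                seed = 1000 + i)
    # spike contamination into some runs so all flag paths are exercised
    if (i %% 3 == 0) counts[1, 2] <- counts[[1 + 1]][1] + 8000
    if (i %% 4 == 0) counts[5, 2] <- counts[[1 + 1]][5] + 3000
    qc <- run_qc(counts)
    o <- oracle_qc(counts, paste0("POS", 1:4), paste0("ANT", 1:4))
    expect_equal(qc$samples$sample_id, o$sample_id)
    expect_equal(qc$samples$library_size, o$library_size)
    expect_equal(qc$samples$pos_pct, o$pos_pct, tolerance = 1e-12)
    expect_equal(qc$samples$neg_pct, o$neg_pct, tolerance = 1e-12)
    expect_equal(qc$samples$neg_mean_cpm, o$neg_mean_cpm, tolerance = 1e-12)
    expect_equal(qc$samples$delta, o$delta, tolerance = 1e-12)
    expect_equal(qc$delta_sd, o$delta_sd, tolerance = 1e-12)
    expect_equal(as.character(qc$samples$pos_flag), o$pos_flag)
    expect_equal(as.character(qc$samples$neg_flag), o$neg_flag)
    expect_equal(as.character(qc$samples$overall_flag), o$overall_flag)
  }
})

test_that("run_qc flags engineered failures and nothing else", {
  run <- simulate_run(scenario_config("single_pos_failure", n_samples = 8, seed = 21))
  qc <- run_qc(run$counts)
  flagged <- qc_flagged_table(qc)
  expect_equal(flagged$sample_id, "S1")
  expect_equal(as.character(flagged$overall_flag), "FAIL")
  expect_gt(flagged$pos_pct, 40)

  run2 <- simulate_run(scenario_config("single_neg_contamination", n_samples = 8, seed = 22))
  qc2 <- run_qc(run2$counts)
  fail2 <- dplyr::filter(qc2$samples, overall_flag == "FAIL")
  expect_equal(fail2$sample_id, "S1")
  expect_gt(fail2$neg_pct, 10)
  expect_equal(as.character(fail2$neg_flag), "FAIL")
})

test_that("identical sample columns give zero deviance everywhere", {
  col <- exact_pct_column(2, 1)
  m <- matrix(rep(col, 4), ncol = 4,
              dimnames = list(c(paste0("POS", 1:4), paste0("ANT", 1:4),
                                paste0("GENE", 1:8)), paste0("S", 1:4)))
  qc <- run_qc(make_counts(m))
  expect_equal(qc$samples$delta, rep(0, 4))
  expect_equal(qc$delta_sd, 0)
  expect_equal(as.character(qc$samples$overall_flag), rep("PASS", 4))
})

test_that("sample permutation permutes records without changing flags", {
  counts <- make_panel_counts(n_genes = 6, n_samples = 6, seed = 13)
  counts[1, 3] <- 9000  # one contaminated sample
  qc <- run_qc(counts)
  set.seed(77)
  perm <- c(1, sample(2:7))
  qc_p <- run_qc(counts[, perm])
  reord <- qc_p$samples[match(qc$samples$sample_id, qc_p$samples$sample_id), ]
  expect_equal(reord$delta, qc$samples$delta)
  expect_equal(as.character(reord$overall_flag),
               as.character(qc$samples$overall_flag))
  expect_equal(qc_p$delta_sd, qc$delta_sd)
})

test_that("runs of fewer than 3 samples skip the deviance sub-filter with a warning", {
  counts <- make_panel_counts(n_genes = 5, n_samples = 2, seed = 8)
  counts[5, 2] <- 500  # large deviance between the two samples
  expect_warning(qc <- run_qc(counts), "deviance")
  expect_false(qc$deviance_filter_applied)
  expect_false(any(qc$samples$neg_flag == "ALERT"))
})

test_that("glance counts always match the pass/flagged table rows", {
  for (scen in c("clean_run", "single_pos_failure", "alert_only",
                 "complete_run_failure")) {
    qc <- run_qc(simulate_run(scenario_config(scen, seed = 4))$counts)
    g <- glance(qc)
    expect_equal(g$n_pass, nrow(qc_pass_table(qc)))
    expect_equal(g$n_alert + g$n_fail, nrow(qc_flagged_table(qc)))
    expect_equal(g$n_samples, nrow(tidy(qc)))
    expect_equal(g$band_high, -g$band_low)
    expect_equal(g$band_high, 2 * g$delta_sd)
  }
})

test_that("threshold objects validate their ordering constraints", {
  expect_error(qc_thresholds(pos_fail = 10, pos_alert = 40), "pos_alert < pos_fail")
  expect_error(qc_thresholds(neg_fail = 0), "neg_fail")
  expect_error(qc_thresholds(sd_mult = -1), "sd_mult")
  custom <- qc_thresholds(pos_fail = 50, pos_alert = 20, neg_fail = 15, sd_mult = 3)
  expect_equal(as.character(flag_positive(45, custom)), "ALERT")
})
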