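# Synthetic claims generator: determinism, calibration, label structure,
# transfer pairs.

test_that("same seed yields byte-identical corpora", {
  cfg <- sim_config(n_patients = 40L, seed = 7L)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_claims(a$records, fa); write_claims(b$records, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$ground_truth$states, b$ground_truth$states)
})

test_that("corpus summary reports exact marginals", {
  r <- patient_record("p", "M", 2008L, list(
    visit("2014-01-01", "OP", dx = c("a", "b")),
    visit("2014-02-01", "IP", dx = "a", px = "q"),
    visit("2014-03-01", "RX", rx = c("m", "n"))))
  s <- corpus_summary(list(r))
  expect_equal(s$mean_visits_per_patient, 3)
  expect_equal(s$mean_codes_per_visit, 2)
  expect_equal(s$unique_codes_diag, 2L)
  expect_equal(s$unique_codes_proc, 1L)
  expect_equal(s$unique_codes_drug, 2L)
  expect_equal(s$male_pct, 100)
  # DIAG-only corpus has zero unique PROC codes
  r2 <- patient_record("q", "F", 2010L, list(visit("2014-01-01", "OP", dx = "z")))
  expect_equal(corpus_summary(list(r2))$unique_codes_proc, 0L)
  expect_error(corpus_summary(list()), "empty")
})

test_that("default marginals are calibrated within 5% at n = 2000", {
  sim <- simulate_population(sim_config(n_patients = 2000L, seed = 3L))
  s <- corpus_summary(sim$records)
  expect_lt(abs(s$mean_visits_per_patient - 10.4) / 10.4, 0.05)
  expect_lt(abs(s$mean_codes_per_visit - 2.8) / 2.8, 0.05)
  expect_lt(abs(s$male_pct / 100 - 0.498) / 0.498, 0.05)
  expect_gt(s$mean_age, 8); expect_lt(s$mean_age, 11)
})

test_that("label_effect = 0 gives chance-level labels independent of history", {
  sim <- simulate_population(sim_config(n_patients = 1000L, label_effect = 0,
                                        seed = 13L))
  gt <- sim$ground_truth
  expect_true(all(gt$p_label == 0.5))
  rate <- mean(gt$labels)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 1000))  # binomial 3-sigma
  expect_equal(bayes_optimal_auc(gt), 0.5)
})

test_that("latent states carry information and drive the label", {
  sim <- simulate_population(sim_config(n_patients = 500L, seed = 19L))
  expect_gt(generator_state_code_mi(sim$ground_truth$params), 0)
  expect_gt(bayes_optimal_auc(sim$ground_truth), 0.5)
})

test_that("transfer pairs interpolate the state-conditional code distributions", {
  ca <- sim_config(n_patients = 30L, seed = 21L)
  cb <- sim_config(n_patients = 30L, seed = 22L)
  p1 <- make_transfer_pair(ca, cb, overlap = 1)
  p0 <- make_transfer_pair(ca, cb, overlap = 0)
  ph <- make_transfer_pair(ca, cb, overlap = 0.5)
  tv <- function(p) generator_tv_distance(p$a$ground_truth$params,
                                          p$b$ground_truth$params)
  expect_equal(tv(p1), 0)
  expect_gt(tv(p0), 0)
  expect_gt(tv(ph), tv(p1))
  expect_lt(tv(ph), tv(p0))
  expect_error(make_transfer_pair(ca, cb, 1.5), "overlap")
})

test_that("implanted index events enable event-based cohort selection", {
  sim <- simulate_population(sim_config(n_patients = 300L, implant_event = TRUE,
                                        seed = 31L))
  pred <- function(v) "EVT" %in% v$dx
  # roughly half the population is labelled positive, so cap the cases to
  # keep the 1:2 case/control design feasible
  has_event <- vapply(sim$records, function(r)
    any(vapply(r$visits, pred, logical(1))), logical(1))
  keep <- c(which(has_event)[1:40], which(!has_event))
  coh <- select_cohort(sim$records[keep], pred, control_ratio = 2, seed = 1L)
  labs <- vapply(coh, `[[`, integer(1), "label")
  expect_gt(sum(labs == 1L), 10L)
  expect_identical(sum(labs == 0L), 2L * sum(labs == 1L))
  # the implanted event sits at the end of the history: truncation removes
  # exactly one visit, so case and control history lengths stay comparable
  n_vis <- vapply(coh, function(ex) length(ex$record$visits), integer(1))
  expect_lt(abs(mean(n_vis[labs == 1L]) - (mean(n_vis[labs == 0L]) - 1)), 1.5)
})
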