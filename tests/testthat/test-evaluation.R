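# AUC, logistic baselines, experiment runners, embedding export.

test_that("auc equals normalized pairwise concordance", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")

  # exact agreement with a brute-force pair-counting oracle
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_identical(auc(s, y), brute(s, y))
  }
})

test_that("logistic baselines behave at the nulls and extremes", {
  # labels independent of codes -> chance
  sim0 <- simulate_population(sim_config(
    n_patients = 600L, n_codes = c(DIAG = 30L, PROC = 18L, DRUG = 12L),
    n_categories = c(DIAG = 5L, PROC = 3L, DRUG = 2L),
    label_effect = 0, seed = 41L))
  coh0 <- cohort_from_labels(sim0$records)
  r0 <- logistic_baseline(coh0, build_vocabulary(sim0$records, 1L),
                          sim0$grouper, "SPARSE_COUNTS", repeats = 5L, seed = 2L)
  expect_lt(abs(r0$mean_auc - 0.5), 0.05)

  # deterministic single-code label rule -> near-perfect
  set.seed(7)
  mk <- function(id, y) {
    codes <- c(sample(paste0("D", 1:20), 3), if (y == 1) "MARKER")
    r <- patient_record(id, "M", 2008L,
                        list(visit("2014-01-01", "OP", dx = codes)))
    r$label <- y
    r
  }
  recs <- c(lapply(1:60, function(i) mk(paste0("p", i), 1L)),
            lapply(61:120, function(i) mk(paste0("p", i), 0L)))
  coh <- cohort_from_labels(recs)
  vocab <- build_vocabulary(lapply(recs, identity), 1L)
  grouper <- category_grouper(data.frame(
    channel = "DIAG", code = names(vocab$channels$DIAG), category = "c",
    stringsAsFactors = FALSE))
  r1 <- logistic_baseline(coh, vocab, grouper, "SPARSE_COUNTS",
                          repeats = 3L, seed = 3L)
  expect_gt(r1$mean_auc, 0.95)

  # dense features have one column per category
  sim <- small_sim()
  toks <- claimformer:::tokenize_corpus(cohort_records(cohort_from_labels(sim$records)),
                                        small_vocab(), sim$grouper)
  expect_identical(length(unlist(toks[[1]]$cp_targets[1])) <=
                     claimformer:::n_categories(sim$grouper), TRUE)
})

test_that("input-channel ablation orders demographics-only below +codes", {
  # a cohort whose label is a deterministic function of one diagnosis code
  # and, by construction, independent of gender and age
  set.seed(52)
  mk <- function(id, y) {
    vs <- lapply(1:4, function(i) {
      codes <- sample(paste0("D", sprintf("%03d", 1:25)), 3)
      if (y == 1 && i == 2) codes <- c(codes, "MARKER")
      visit(16000L + 20L * i, c("IP", "OP", "RX")[1 + (i %% 3)], dx = codes)
    })
    # gender varies (and is independent of the label); age is held fixed so
    # the demographic token stays low-variance relative to the code signal
    r <- patient_record(id, sample(c("M", "F"), 1), 2008L, vs)
    r$label <- y
    r
  }
  cohort_recs <- lapply(1:240, function(i) mk(paste0("c", i), as.integer(i <= 120)))
  corpus <- lapply(1:160, function(i) mk(paste0("u", i), rbinom(1, 1, 0.5)))
  cohort <- cohort_from_labels(cohort_recs)
  grouper <- category_grouper(data.frame(
    channel = "DIAG", code = c(paste0("D", sprintf("%03d", 1:25)), "MARKER"),
    category = "c"))
  pcfg <- pretrain_config(d = 12L, n_heads = 3L, d_ff = 10L, batch_size = 80L,
                          max_epochs = 3L, min_count = 1L, seed = 6L)
  fcfg <- finetune_config(epochs = 20L, repeats = 3L, batch_size = 20L, seed = 6L)
  res <- run_ablation_inputs(corpus, grouper, cohort, pcfg, fcfg)
  expect_named(res, c("demo", "demo_codes", "demo_codes_util",
                      "demo_codes_util_date"))
  # demographics-only sits near chance, codes carry the full signal
  expect_lt(abs(res$demo$mean_auc - 0.5), 0.12)
  expect_gt(res$demo_codes$mean_auc, res$demo$mean_auc)
  # all arms evaluated the same patients under the same number of repeats
  expect_identical(lengths(lapply(res, `[[`, "auc")),
                   c(demo = 3L, demo_codes = 3L, demo_codes_util = 3L,
                     demo_codes_util_date = 3L))
})

test_that("embedding export is complete, stable, and round-trips", {
  m <- small_model()
  df <- export_embeddings(m, "codes", channel = "DIAG")
  expect_identical(nrow(df), length(m$vocab$channels$DIAG))
  expect_identical(ncol(df), m$meta$d + 1L)

  recs <- small_sim()$records[1:8]
  dfp <- export_embeddings(m, "patients", records = recs)
  expect_identical(nrow(dfp), 8L)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_embeddings(m, "codes", path = f1)
  export_embeddings(m, "codes", path = f2)
  expect_identical(readLines(f1), readLines(f2))
})
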