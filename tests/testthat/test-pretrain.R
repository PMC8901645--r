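# The unsupervised training loop: learning signal, objective toggles,
# early stopping, reproducibility.

pt_fixture <- function() memo("pt_fixture", {
  sim <- small_sim()
  cfg <- pretrain_config(d = 12L, n_heads = 3L, d_ff = 10L, batch_size = 20L,
                         max_epochs = 8L, min_count = 1L, dropout = 0,
                         l2 = 0, seed = 5L)
  list(sim = sim, cfg = cfg,
       res = pretrain(sim$records, cfg, grouper = sim$grouper))
})

test_that("training reduces both objectives below their initial values", {
  fx <- pt_fixture()
  tr <- fx$res$trace
  first <- tr[tr$epoch == 1 & tr$split == "train", ]
  last <- tr[tr$epoch == max(tr$epoch) & tr$split == "train", ]
  expect_lt(last$loss[last$objective == "nvp"], first$loss[first$objective == "nvp"])
  expect_lt(last$loss[last$objective == "cp"], first$loss[first$objective == "cp"])

  # and below the frozen initial parameters on the same batches
  seeds <- seed_everything(fx$cfg$seed, c("split", "init"))
  vocab <- build_vocabulary(fx$sim$records, 1L)
  init <- init_model(vocab, fx$sim$grouper, d = 12L, n_heads = 3L, d_ff = 10L,
                     seed = seeds[["init"]])
  toks <- claimformer:::tokenize_corpus(fx$sim$records, vocab, fx$sim$grouper, 128L)
  ev0 <- claimformer:::pretrain_eval(toks, init, fx$cfg)
  evT <- claimformer:::pretrain_eval(toks, fx$res$model, fx$cfg)
  expect_lt(evT[["nvp"]], ev0[["nvp"]])
  expect_lt(evT[["cp"]], ev0[["cp"]])
})

test_that("a disabled objective receives no gradient and leaves its head at init", {
  sim <- small_sim()
  cfg <- pretrain_config(d = 12L, n_heads = 3L, d_ff = 10L, batch_size = 20L,
                         max_epochs = 2L, min_count = 1L, cp = FALSE, seed = 5L)
  res <- pretrain(sim$records, cfg, grouper = sim$grouper)
  expect_false("cp" %in% res$trace$objective)
  seeds <- seed_everything(5L, c("split", "init"))
  init <- init_model(build_vocabulary(sim$records, 1L), sim$grouper, d = 12L,
                     n_heads = 3L, d_ff = 10L, seed = seeds[["init"]])
  expect_identical(res$model$W$cp_w, init$W$cp_w)
  expect_identical(res$model$W$cp_b, init$W$cp_b)
  expect_false(identical(res$model$W$nvp_w, init$W$nvp_w))
  # both objectives off is rejected
  expect_error(pretrain_config(nvp = FALSE, cp = FALSE), "at least one")
})

test_that("early stopping halts after `patience` stale epochs and keeps the best", {
  sim <- small_sim()
  # a diverging learning rate makes validation worsen immediately
  cfg <- pretrain_config(d = 12L, n_heads = 3L, d_ff = 10L, batch_size = 20L,
                         max_epochs = 50L, patience = 3L, lr = 0.5,
                         min_count = 1L, dropout = 0, seed = 5L)
  res <- pretrain(sim$records, cfg, grouper = sim$grouper)
  expect_lt(res$stopped_epoch, 50L)
  tr <- res$trace[res$trace$objective == "total", ]
  expect_identical(res$best_epoch, tr$epoch[which.min(tr$loss)])
})

test_that("identical seeds reproduce the trace and final parameters", {
  fx <- pt_fixture()
  res2 <- pretrain(fx$sim$records, fx$cfg, grouper = fx$sim$grouper)
  expect_equal(fx$res$trace, res2$trace)
  expect_identical(fx$res$model$W, res2$model$W)
})

test_that("the unigram baseline is the memoryless cross-entropy", {
  # two codes, 3:1 frequency, add-one smoothed over the vocab incl. OOVs
  mk <- function(codes) patient_record(paste(codes, collapse = ""), "M", 2008L,
    lapply(seq_along(codes), function(i) visit(16000L + i, "OP", dx = codes[[i]])))
  train <- list(mk(c("a", "a", "a", "b")))
  val <- list(mk(c("a", "b")))
  vocab <- build_vocabulary(train, 1L)
  grouper <- category_grouper(data.frame(channel = "DIAG", code = c("a", "b"),
                                         category = "c"))
  V <- claimformer:::vocab_size(vocab)   # 2 codes + 3 OOVs
  p_b <- (1 + 1) / (4 + V)
  expect_equal(nvp_unigram_baseline(train, val, vocab, grouper),
               -log(p_b))               # the only next-visit target is "b"
})
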