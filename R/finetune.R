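# Task adaptation: a linear softmax head on the aggregate patient vector,
# trained in one of four modes:
#   FULL_FINETUNE - update the pre-trained body and the new head;
#   PROBE_START   - freeze the body, train the head on pe ("zero-shot start");
#   PROBE_POOL    - freeze the body, train the head on the element-wise max
#                   (or mean) over visit hidden states ("zero-shot pool");
#   FROM_SCRATCH  - randomly re-initialise the body and train end-to-end
#                   (the no-pretraining control).

FT_MODES <- c("FULL_FINETUNE", "PROBE_START", "PROBE_POOL", "FROM_SCRATCH")

#' Fine-tuning configuration
#'
#' Defaults follow the downstream-task protocol: 20 training epochs, 70/30
#' train/test split, 5 repeats with repeat-specific splits. FULL_FINETUNE
#' and FROM_SCRATCH share the same optimisation protocol (`lr_body` for the
#' encoder, `lr_head` for the new head), so the comparison between them
#' isolates the initialisation — pre-trained versus random. Minibatches
#' default to 20 patients: cohorts hold a few hundred patients, and the
#' 20-epoch budget only converges with step counts in the hundreds.
#'
#' @param mode One of `"FULL_FINETUNE"`, `"PROBE_START"`, `"PROBE_POOL"`,
#'   `"FROM_SCRATCH"`.
#' @param epochs Training epochs per repeat.
#' @param lr_body,lr_head Learning rates for the encoder body and the head.
#' @param batch_size Patients per minibatch.
#' @param train_frac Training fraction of each repeat's split.
#' @param repeats Number of repeat runs (re-split each time).
#' @param pool `"max"` or `"mean"`: pooling operator of PROBE_POOL.
#' @param channels Input-channel flags ([default_channels()]).
#' @param seed Master seed (repeat-specific seeds are derived from it).
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(mode = "FULL_FINETUNE", epochs = 20L,
                            lr_body = 1e-4, lr_head = 1e-3,
                            batch_size = 20L, train_frac = 0.7, repeats = 5L,
                            pool = c("max", "mean"),
                            channels = default_channels(), seed = 1L) {
  pool <- match.arg(pool)
  cfg <- as.list(environment())
  if (!mode %in% FT_MODES)
    stop("mode must be one of ", paste(FT_MODES, collapse = ", "))
  stopifnot(epochs >= 1, train_frac > 0, train_frac < 1, repeats >= 1)
  structure(cfg, class = "finetune_config")
}

init_head <- function(d, seed) {
  set.seed(seed)
  list(W = matrix(stats::rnorm(d * 2, sd = 0.02), d, 2L), b = numeric(2L))
}

head_n_parameters <- function(head) length(head$W) + length(head$b)

# pooled representation over visit hidden states (rows)
pool_states <- function(states, pool) {
  if (nrow(states) == 1L) return(states[1L, ])
  if (pool == "max") apply(states, 2L, max) else colMeans(states)
}

# features for a forward_batch result under a given mode
ft_features <- function(fw, mode, pool) {
  if (mode == "PROBE_POOL") {
    t(vapply(seq_along(fw$Ls), function(i) {
      rows <- fw$starts[i] + seq_len(fw$Ts[i])
      pool_states(fw$out[rows, , drop = FALSE], pool)
    }, numeric(ncol(fw$out))))
  } else {
    fw$out[fw$starts, , drop = FALSE]
  }
}

#' Class probabilities for one record
#'
#' Encodes the record bidirectionally and applies the task head to the
#' aggregate patient vector `pe` (FULL_FINETUNE / PROBE_START /
#' FROM_SCRATCH) or to the pooled visit hidden states (PROBE_POOL). The
#' two probabilities sum to 1.
#'
#' @param record A `patient_record`.
#' @param model A `claims_model` (pass `expected_vocab_fp` to refuse a
#'   checkpoint whose vocabulary differs from the one the head was trained
#'   against).
#' @param head Task head from [finetune()].
#' @param mode Fine-tuning mode string.
#' @param pool,channels As in [finetune_config()].
#' @param expected_vocab_fp Optional vocabulary fingerprint to enforce.
#' @return Named numeric vector `c(p0, p1)`.
#' @export
predict_proba <- function(record, model, head, mode = "FULL_FINETUNE",
                          pool = "max", channels = default_channels(),
                          expected_vocab_fp = NULL) {
  if (!is.null(expected_vocab_fp) && !identical(expected_vocab_fp, model$meta$vocab_fp))
    stop("vocabulary fingerprint mismatch: head was trained against a ",
         "different vocabulary than this checkpoint")
  enc <- encode_patient(record, model, mode = "BIDIRECTIONAL", channels = channels)
  f <- if (mode == "PROBE_POOL") pool_states(enc$visit_states, pool) else enc$pe
  z <- drop(f %*% head$W) + head$b
  p <- exp(z - max(z)); p <- p / sum(p)
  stats::setNames(p, c("p0", "p1"))
}

# stratified train/test split: per class, train_frac goes to train
stratified_split <- function(labels, train_frac, seed) {
  set.seed(seed)
  train <- unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
    idx[sample.int(length(idx), n_tr)]
  }))
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

#' Fine-tune (or probe, or train from scratch) on a labelled cohort
#'
#' Runs `repeats` independent repetitions: each re-splits the cohort
#' (stratified `train_frac`), trains for `epochs` epochs with RMSprop and
#' cross-entropy on the binary label, and scores the held-out patients.
#' Probe modes leave the body parameters bit-for-bit untouched;
#' FROM_SCRATCH re-initialises the body from a repeat-specific seed.
#'
#' @param cohort A `labeled_cohort` with both classes present.
#' @param model A pre-trained `claims_model` (its vocabulary and grouper
#'   are reused in every mode so arms are comparable).
#' @param config A [finetune_config()].
#' @return A `finetune_result`: `auc` (per repeat), `mean_auc`, `sd_auc`,
#'   `predictions` (repeat, patient_id, score, label), `model` and `head`
#'   of the last repeat, `mode`, `body_changed` flag.
#' @export
finetune <- function(cohort, model, config = finetune_config()) {
  stopifnot(inherits(config, "finetune_config"))
  labels <- cohort_labels(cohort)
  if (length(unique(labels)) < 2L) stop("cohort must contain both classes")
  records <- cohort_records(cohort)
  toks <- tokenize_corpus(records, model$vocab, model$grouper,
                          model$meta$max_seq_len)
  mode <- config$mode
  d <- model$meta$d
  body_frozen <- mode %in% c("PROBE_START", "PROBE_POOL")
  aucs <- numeric(config$repeats)
  preds <- list()
  W0 <- model$W

  for (r in seq_len(config$repeats)) {
    seeds <- seed_everything(config$seed, paste0(c("split", "init", "shuffle"), "_rep", r))
    sp <- stratified_split(labels, config$train_frac, seeds[[1]])
    run_model <- model
    if (mode == "FROM_SCRATCH") {
      run_model <- init_model(model$vocab, model$grouper, d = d,
                              n_heads = model$meta$n_heads,
                              n_layers = model$meta$n_layers,
                              d_ff = model$meta$d_ff,
                              max_seq_len = model$meta$max_seq_len,
                              seed = seeds[[2]])
    }
    head <- init_head(d, seeds[[2]] + 1L)
    hstate <- rmsprop_state(head)
    bstate <- if (!body_frozen) rmsprop_state(run_model$W)
    lr_body <- config$lr_body

    # frozen body: features are constant across epochs, encode once
    Fcache <- if (body_frozen) {
      fw <- forward_batch(toks[sp$train], run_model, mode = "bidir",
                          channels = config$channels, train = FALSE)
      Fm <- ft_features(fw, mode, config$pool)
      rownames(Fm) <- as.character(sp$train)
      Fm
    }

    for (epoch in seq_len(config$epochs)) {
      set.seed(seeds[[3]] + epoch)
      order_e <- sample(sp$train)
      batches <- split(order_e, ceiling(seq_along(order_e) / config$batch_size))
      for (b in batches) {
        if (body_frozen) {
          Fm <- Fcache[as.character(b), , drop = FALSE]
        } else {
          fw <- forward_batch(toks[b], run_model, mode = "bidir",
                              channels = config$channels, train = FALSE)
          Fm <- ft_features(fw, mode, config$pool)
        }
        y <- labels[b]
        n <- length(b)
        logits <- addrow(Fm %*% head$W, head$b)
        P <- row_softmax(logits)
        dlogits <- P
        dlogits[cbind(seq_len(n), y + 1L)] <- dlogits[cbind(seq_len(n), y + 1L)] - 1
        dlogits <- dlogits / n
        hg <- list(W = crossprod(Fm, dlogits), b = colSums(dlogits))
        upd <- rmsprop_step(head, hg, hstate, lr = config$lr_head)
        head <- upd$W; hstate <- upd$state
        if (!body_frozen) {
          dF <- dlogits %*% t(head$W)
          dOut <- matrix(0, nrow(fw$out), d)
          dOut[fw$starts, ] <- dF   # pe rows (POOL is always frozen)
          grads <- backward_batch(dOut, fw, run_model)
          bupd <- rmsprop_step(run_model$W, grads, bstate, lr = lr_body)
          run_model$W <- bupd$W; bstate <- bupd$state
        }
      }
    }
    fw <- forward_batch(toks[sp$test], run_model, mode = "bidir",
                        channels = config$channels, train = FALSE)
    Fm <- ft_features(fw, mode, config$pool)
    logits <- addrow(Fm %*% head$W, head$b)
    score <- row_softmax(logits)[, 2L]
    aucs[r] <- auc(score, labels[sp$test])
    preds[[r]] <- data.frame(
      repeat_ = r,
      patient_id = vapply(records[sp$test], `[[`, character(1), "patient_id"),
      score = score, label = labels[sp$test])
  }
  structure(list(auc = aucs, mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 predictions = do.call(rbind, preds),
                 model = run_model, head = head, mode = mode, config = config,
                 body_changed = !identical(run_model$W, W0)),
            class = "finetune_result")
}
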