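# Unsupervised pre-training: the next-visit prediction (NVP) and categorial
# prediction (CP) objectives and the minibatch RMSprop training loop.
#
# NVP is autoregressive: from the hidden state of visit i (causal encoding),
# a softmax over the full code vocabulary scores the codes of visit i+1; the
# per-position loss is the mean cross-entropy over the codes actually
# present in the next visit (a uniform target over next-visit codes).
# CP is per-visit multi-label: from the hidden state of visit i
# (bidirectional encoding), a sigmoid per category scores the categories of
# the codes in visit i itself; the loss is mean binary cross-entropy over
# visits and categories.

# head forward+gradient on gathered hidden rows --------------------------

# H: M x d hidden states; targets: list of 1-based class-id vectors per row.
# Softmax cross-entropy against a uniform target over each row's ids
# (ids collapsing to the same index, e.g. several rare codes mapping to OOV,
# accumulate weight). Returns loss, dH, dW, db.
softmax_multi_head <- function(H, targets, W, b, want_grad = TRUE) {
  M <- nrow(H)
  if (M == 0L) stop("no contributing positions for the next-visit objective")
  logits <- cbind(H, 1) %*% rbind(W, b)
  z <- logits - row_max(logits)
  ez <- exp(z)
  se <- rowSums(ez)
  ri <- rep(seq_len(M), lengths(targets))
  ci <- unlist(targets, use.names = FALSE)
  wi <- 1 / rep(lengths(targets), lengths(targets))
  li <- (ci - 1L) * M + ri
  agg <- rowsum(wi, group = li)
  uli <- as.numeric(rownames(agg))
  # log softmax at a target cell = z - log(se of its row)
  loss <- -sum(agg[, 1] * (z[uli] - log(se)[((uli - 1) %% M) + 1])) / M
  if (!want_grad) return(list(loss = loss))
  dlogits <- (ez / se) / M
  dlogits[uli] <- dlogits[uli] - agg[, 1] / M
  list(loss = loss, dH = tcrossprod(dlogits, W),
       dW = crossprod(H, dlogits), db = colSums(dlogits))
}

stable_softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Multi-label sigmoid binary cross-entropy, mean over rows and classes.
sigmoid_multi_head <- function(H, targets, W, b, want_grad = TRUE) {
  M <- nrow(H)
  if (M == 0L) stop("no visits in batch")
  C <- length(b)
  logits <- cbind(H, 1) %*% rbind(W, b)
  ri <- rep(seq_len(M), lengths(targets))
  ci <- unlist(targets)
  yz <- sum(logits[cbind(ri, ci)])
  loss <- (sum(stable_softplus(logits)) - yz) / (M * C)
  if (!want_grad) return(list(loss = loss))
  dlogits <- stats::plogis(logits)
  dlogits[cbind(ri, ci)] <- dlogits[cbind(ri, ci)] - 1
  dlogits <- dlogits / (M * C)
  list(loss = loss, dH = dlogits %*% t(W),
       dW = crossprod(H, dlogits), db = colSums(dlogits))
}

#' Next-visit prediction loss
#'
#' For each visit position `i = 1..T-1` of each record, scores the codes of
#' visit `i+1` with a softmax over the full code vocabulary from the
#' causally-encoded hidden state of visit `i`; the per-position loss is the
#' mean negative log-probability of the next visit's codes, averaged over
#' all contributing positions in the batch. Records with a single visit
#' contribute nothing; a batch with no contributing position is an error.
#'
#' @param visit_states A `T x d` matrix (one record) or list of such
#'   matrices, from `encode_patient(..., mode = "CAUSAL")`.
#' @param records The matching `patient_record`(s).
#' @param model A `claims_model`.
#' @return Non-negative scalar loss (nats).
#' @export
nvp_loss <- function(visit_states, records, model) {
  if (is.matrix(visit_states)) visit_states <- list(visit_states)
  if (inherits(records, "patient_record")) records <- list(records)
  toks <- tokenize_corpus(records, model$vocab, model$grouper,
                          model$meta$max_seq_len)
  H <- NULL; targets <- list()
  for (i in seq_along(toks)) {
    Tn <- toks[[i]]$T
    stopifnot(nrow(visit_states[[i]]) == Tn)
    if (Tn < 2L) next
    H <- rbind(H, visit_states[[i]][seq_len(Tn - 1L), , drop = FALSE])
    targets <- c(targets, toks[[i]]$nvp_targets)
  }
  if (is.null(H)) stop("no contributing positions: every record has a single visit")
  softmax_multi_head(H, targets, model$W$nvp_w, model$W$nvp_b,
                     want_grad = FALSE)$loss
}

#' Categorial prediction loss
#'
#' Per visit, the multi-label target is the set of categories of the codes
#' in that visit (via the model's grouper); each category is scored by a
#' sigmoid from the visit's bidirectionally-encoded hidden state. The loss
#' is the mean binary cross-entropy over visits and categories.
#'
#' @inheritParams nvp_loss
#' @param visit_states From `encode_patient(..., mode = "BIDIRECTIONAL")`.
#' @return Non-negative scalar loss (nats).
#' @export
cp_loss <- function(visit_states, records, model) {
  if (is.matrix(visit_states)) visit_states <- list(visit_states)
  if (inherits(records, "patient_record")) records <- list(records)
  toks <- tokenize_corpus(records, model$vocab, model$grouper,
                          model$meta$max_seq_len)
  H <- do.call(rbind, visit_states)
  targets <- do.call(c, lapply(toks, `[[`, "cp_targets"))
  sigmoid_multi_head(H, targets, model$W$cp_w, model$W$cp_b,
                     want_grad = FALSE)$loss
}

#' Pre-training configuration
#'
#' Defaults follow the framework's training recipe: RMSprop at learning
#' rate 0.001, minibatches of 100 patients, up to 1000 epochs with early
#' stopping, dropout and L2 regularisation, 80/20 train/validation patient
#' split, and both objectives enabled with equal weight.
#'
#' @param lr Learning rate.
#' @param batch_size Patients per minibatch.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param dropout Dropout rate on the residual branches.
#' @param l2 L2 penalty coefficient on weight matrices.
#' @param nvp,cp Objective on/off flags (at least one must be on).
#' @param lambda_cp Weight of the CP term in the total loss.
#' @param train_frac Training fraction of the patient split.
#' @param d,n_heads,n_layers,d_ff,max_seq_len Architecture dimensions.
#' @param min_count Vocabulary frequency cutoff (codes below it map to OOV).
#' @param rmsprop_decay,rmsprop_eps RMSprop accumulator constants.
#' @param channels Input-channel flags ([default_channels()]).
#' @param seed Master seed for split/init/shuffle/dropout.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(lr = 0.001, batch_size = 100L, max_epochs = 1000L,
                            patience = 10L, dropout = 0.1, l2 = 1e-3,
                            nvp = TRUE, cp = TRUE, lambda_cp = 1.0,
                            train_frac = 0.8, d = 100L, n_heads = 4L,
                            n_layers = 1L, d_ff = 100L, max_seq_len = 128L,
                            min_count = 5L, rmsprop_decay = 0.9,
                            rmsprop_eps = 1e-8,
                            channels = default_channels(), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
            dropout >= 0, dropout < 1, l2 >= 0,
            train_frac > 0, train_frac < 1)
  if (!nvp && !cp) stop("at least one pre-training objective must be enabled")
  structure(cfg, class = "pretrain_config")
}

# One training step's losses and gradients for a batch, with the embedding
# stage (and its backward) shared between the causal NVP pass and the
# bidirectional CP pass.
pretrain_batch_joint <- function(toks_b, model, config) {
  inp <- embed_inputs(toks_b, model, config$channels)
  dX0 <- NULL
  grads <- NULL
  losses <- c(nvp = NA_real_, cp = NA_real_)
  if (config$nvp) {
    enc <- encode_layers(inp, model, "causal", config$dropout, train = TRUE)
    rows <- unlist(lapply(seq_along(toks_b), function(i) {
      Tn <- toks_b[[i]]$T
      if (Tn < 2L) integer(0) else inp$starts[i] + seq_len(Tn - 1L)
    }), use.names = FALSE)
    if (length(rows)) {
      targets <- do.call(c, lapply(toks_b, `[[`, "nvp_targets"))
      head <- softmax_multi_head(enc$out[rows, , drop = FALSE], targets,
                                 model$W$nvp_w, model$W$nvp_b)
      dOut <- matrix(0, nrow(enc$out), model$meta$d)
      dOut[rows, ] <- head$dH
      bl <- backward_layers(dOut, enc$caches, model)
      grads <- add_grads(grads, bl$grads)
      grads$nvp_w <- head$dW; grads$nvp_b <- head$db
      dX0 <- bl$dX0
      losses[["nvp"]] <- head$loss
    }
  }
  if (config$cp) {
    enc <- encode_layers(inp, model, "bidir", config$dropout, train = TRUE)
    targets <- do.call(c, lapply(toks_b, `[[`, "cp_targets"))
    head <- sigmoid_multi_head(enc$out[inp$visit_rows, , drop = FALSE], targets,
                               model$W$cp_w, model$W$cp_b)
    dOut <- matrix(0, nrow(enc$out), model$meta$d)
    dOut[inp$visit_rows, ] <- head$dH
    bl <- backward_layers(dOut, enc$caches, model)
    lam <- config$lambda_cp
    grads <- add_grads(grads, bl$grads, lam)
    grads$cp_w <- head$dW * lam; grads$cp_b <- head$db * lam
    dX0 <- if (is.null(dX0)) bl$dX0 * lam else dX0 + bl$dX0 * lam
    losses[["cp"]] <- head$loss
  }
  if (!is.null(dX0)) grads <- add_grads(grads, embed_backward(dX0, inp, model))
  list(losses = losses, grads = grads)
}

# loss (and optionally gradients) of one batch under one objective
pretrain_batch_pass <- function(toks_b, model, objective, config, train) {
  if (objective == "nvp") {
    fw <- forward_batch(toks_b, model, mode = "causal",
                        channels = config$channels,
                        dropout_p = config$dropout, train = train)
    rows <- unlist(lapply(seq_along(toks_b), function(i) {
      Tn <- toks_b[[i]]$T
      if (Tn < 2L) integer(0) else fw$starts[i] + seq_len(Tn - 1L)
    }), use.names = FALSE)
    targets <- do.call(c, lapply(toks_b, `[[`, "nvp_targets"))
    if (!length(rows)) return(NULL)
    head <- softmax_multi_head(fw$out[rows, , drop = FALSE], targets,
                               model$W$nvp_w, model$W$nvp_b, want_grad = train)
    if (!train) return(list(loss = head$loss))
    dOut <- matrix(0, nrow(fw$out), model$meta$d)
    dOut[rows, ] <- head$dH
    grads <- backward_batch(dOut, fw, model)
    grads$nvp_w <- head$dW; grads$nvp_b <- head$db
    list(loss = head$loss, grads = grads)
  } else {
    fw <- forward_batch(toks_b, model, mode = "bidir",
                        channels = config$channels,
                        dropout_p = config$dropout, train = train)
    targets <- do.call(c, lapply(toks_b, `[[`, "cp_targets"))
    head <- sigmoid_multi_head(fw$out[fw$visit_rows, , drop = FALSE], targets,
                               model$W$cp_w, model$W$cp_b, want_grad = train)
    if (!train) return(list(loss = head$loss))
    dOut <- matrix(0, nrow(fw$out), model$meta$d)
    dOut[fw$visit_rows, ] <- head$dH
    grads <- backward_batch(dOut, fw, model)
    grads$cp_w <- head$dW; grads$cp_b <- head$db
    list(loss = head$loss, grads = grads)
  }
}

# mean validation losses over batches (no dropout)
pretrain_eval <- function(toks, model, config) {
  idx <- split(seq_along(toks), ceiling(seq_along(toks) / config$batch_size))
  out <- c(nvp = NA_real_, cp = NA_real_)
  for (obj in c("nvp", "cp")) {
    if (!config[[obj]]) next
    losses <- ns <- numeric(0)
    for (b in idx) {
      r <- pretrain_batch_pass(toks[b], model, obj, config, train = FALSE)
      if (is.null(r)) next
      losses <- c(losses, r$loss); ns <- c(ns, length(b))
    }
    out[obj] <- sum(losses * ns) / sum(ns)
  }
  out
}

#' Pre-train a model on an unlabelled claims corpus
#'
#' Splits patients into training and validation sets, then iterates
#' minibatches of patients: each enabled objective runs its own forward
#' pass (causal for next-visit prediction, bidirectional for category
#' prediction), the total loss is `NVP + lambda_cp * CP`, and all
#' parameters are updated by RMSprop with L2 decay. Training stops when the
#' validation total loss fails to improve for `patience` consecutive
#' epochs; the best-validation parameters are returned.
#'
#' @param records Unlabelled `patient_record`s.
#' @param config A [pretrain_config()].
#' @param vocab Optional pre-built vocabulary (built from `records` with
#'   `config$min_count` when `NULL`).
#' @param grouper A `category_grouper` covering the corpus.
#' @return A `pretrain_result`: `model` (best validation parameters),
#'   `trace` (long data frame: epoch, split, objective, loss),
#'   `best_epoch`, `stopped_epoch`, `config`.
#' @export
pretrain <- function(records, config = pretrain_config(), vocab = NULL,
                     grouper = NULL) {
  stopifnot(inherits(config, "pretrain_config"))
  if (length(records) == 0L) stop("empty corpus")
  if (is.null(grouper)) stop("a category grouper is required")
  if (is.null(vocab)) vocab <- build_vocabulary(records, config$min_count)
  seeds <- seed_everything(config$seed, c("split", "init", "shuffle"))
  model <- init_model(vocab, grouper, d = config$d, n_heads = config$n_heads,
                      n_layers = config$n_layers, d_ff = config$d_ff,
                      max_seq_len = config$max_seq_len, seed = seeds[["init"]])
  toks <- tokenize_corpus(records, vocab, grouper, config$max_seq_len)
  n <- length(toks)
  set.seed(seeds[["split"]])
  perm <- sample.int(n)
  n_train <- max(1L, floor(config$train_frac * n))
  if (n_train >= n && n > 1L) n_train <- n - 1L
  train_idx <- perm[seq_len(n_train)]
  val_idx <- if (n_train < n) perm[(n_train + 1L):n] else integer(0)
  if (!length(train_idx)) stop("empty training split")

  state <- rmsprop_state(model$W)
  trace <- list()
  best <- list(loss = Inf, W = model$W, epoch = 0L)
  bad <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(seeds[["shuffle"]] + epoch)
    order_e <- sample(train_idx)
    batches <- split(order_e, ceiling(seq_along(order_e) / config$batch_size))
    ep_loss <- c(nvp = 0, cp = 0); ep_n <- c(nvp = 0, cp = 0)
    for (b in batches) {
      r <- pretrain_batch_joint(toks[b], model, config)
      if (is.null(r$grads)) next
      for (obj in c("nvp", "cp")) {
        if (!is.na(r$losses[[obj]])) {
          ep_loss[obj] <- ep_loss[obj] + r$losses[[obj]] * length(b)
          ep_n[obj] <- ep_n[obj] + length(b)
        }
      }
      upd <- rmsprop_step(model$W, grads = r$grads, state, lr = config$lr,
                          decay = config$rmsprop_decay,
                          eps = config$rmsprop_eps, l2 = config$l2)
      model$W <- upd$W; state <- upd$state
    }
    tr_loss <- ep_loss / pmax(ep_n, 1)
    val <- if (length(val_idx)) pretrain_eval(toks[val_idx], model, config)
           else c(nvp = NA_real_, cp = NA_real_)
    val_total <- sum(c(val[["nvp"]] * config$nvp,
                       config$lambda_cp * val[["cp"]] * config$cp), na.rm = TRUE)
    for (obj in c("nvp", "cp")) if (config[[obj]]) {
      trace[[length(trace) + 1L]] <- data.frame(
        epoch = epoch, split = "train", objective = obj, loss = tr_loss[[obj]])
      if (length(val_idx))
        trace[[length(trace) + 1L]] <- data.frame(
          epoch = epoch, split = "validation", objective = obj, loss = val[[obj]])
    }
    trace[[length(trace) + 1L]] <- data.frame(
      epoch = epoch, split = "validation", objective = "total", loss = val_total)
    if (length(val_idx) && val_total < best$loss) {
      best <- list(loss = val_total, W = model$W, epoch = epoch)
      bad <- 0L
    } else bad <- bad + 1L
    if (length(val_idx) && bad >= config$patience) break
  }
  if (length(val_idx)) model$W <- best$W
  structure(list(model = model, trace = do.call(rbind, trace),
                 best_epoch = if (length(val_idx)) best$epoch else epoch,
                 stopped_epoch = epoch, config = config),
            class = "pretrain_result")
}

#' Unigram cross-entropy baseline for next-visit prediction
#'
#' The loss a memoryless predictor achieves on the NVP task: code
#' probabilities are the add-one-smoothed empirical frequencies of the
#' training records' codes, and the loss is the mean (over validation
#' next-visit positions and their codes) negative log-probability. A model
#' whose validation NVP loss falls below this baseline has learned
#' history-dependent structure.
#'
#' @param records_train,records_val Record lists.
#' @param vocab,grouper Vocabulary and grouper (as used by the model).
#' @param max_seq_len Truncation used during tokenization.
#' @return Scalar baseline loss (nats).
#' @export
nvp_unigram_baseline <- function(records_train, records_val, vocab, grouper,
                                 max_seq_len = 128L) {
  V <- vocab_size(vocab)
  toks_tr <- tokenize_corpus(records_train, vocab, grouper, max_seq_len)
  counts <- tabulate(unlist(lapply(toks_tr, `[[`, "code_gid")), nbins = V)
  p <- (counts + 1) / sum(counts + 1)
  toks_va <- tokenize_corpus(records_val, vocab, grouper, max_seq_len)
  per_pos <- unlist(lapply(toks_va, function(tk)
    vapply(tk$nvp_targets, function(ids) mean(-log(p[ids])), numeric(1))))
  mean(per_pos)
}

#' Per-category validation AUC of the category-prediction head
#'
#' Scores every validation visit's categories with the CP head under
#' bidirectional encoding and computes, for each category present in both
#' classes, the AUC of predicted score against actual presence; returns the
#' macro average.
#'
#' @param model A `claims_model`.
#' @param records Validation records.
#' @param batch_size Patients per scoring batch.
#' @return Macro-averaged AUC.
#' @export
cp_validation_auc <- function(model, records, batch_size = 100L) {
  toks <- tokenize_corpus(records, model$vocab, model$grouper,
                          model$meta$max_seq_len)
  idx <- split(seq_along(toks), ceiling(seq_along(toks) / batch_size))
  scores <- NULL; targets <- list()
  for (b in idx) {
    fw <- forward_batch(toks[b], model, mode = "bidir", train = FALSE)
    logits <- addrow(fw$out[fw$visit_rows, , drop = FALSE] %*% model$W$cp_w,
                     model$W$cp_b)
    scores <- rbind(scores, logits)
    targets <- c(targets, do.call(c, lapply(toks[b], `[[`, "cp_targets")))
  }
  n <- nrow(scores)
  pres <- matrix(0L, n, model$meta$n_cat)
  pres[cbind(rep(seq_len(n), lengths(targets)), unlist(targets))] <- 1L
  aucs <- vapply(seq_len(ncol(pres)), function(j) {
    y <- pres[, j]
    if (all(y == 1L) || all(y == 0L)) return(NA_real_)
    auc(scores[, j], y)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}
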