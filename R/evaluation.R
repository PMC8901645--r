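# Metrics, repeat-averaged experiment runners (input-channel ablation,
# objective ablation, cross-corpus transfer), the bag-of-codes logistic
# baselines, and embedding export.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`, with ties counted 0.5 — the probability that a random
#' positive outscores a random negative.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

experiment_result <- function(aucs, arm, extra = list()) {
  c(list(arm = arm, auc = aucs, mean_auc = mean(aucs),
         sd_auc = stats::sd(aucs)), extra)
}

#' Logistic regression baselines on bag-of-codes features
#'
#' `SPARSE_COUNTS` fits an L2-regularised logistic regression on per-patient
#' code count vectors (one column per vocabulary entry);
#' `DENSE_CATEGORY_COUNTS` on grouper-aggregated category count vectors.
#' Uses the same stratified split and repeat protocol as [finetune()], so
#' with the same seed the splits are identical across arms.
#'
#' @param cohort A `labeled_cohort`.
#' @param vocab,grouper Vocabulary and grouper defining the feature spaces.
#' @param mode `"SPARSE_COUNTS"` or `"DENSE_CATEGORY_COUNTS"`.
#' @param train_frac,repeats,seed Split protocol.
#' @param lambda Ridge penalty passed to glmnet.
#' @return An experiment result list: per-repeat `auc`, `mean_auc`, `sd_auc`.
#' @export
logistic_baseline <- function(cohort, vocab, grouper,
                              mode = c("SPARSE_COUNTS", "DENSE_CATEGORY_COUNTS"),
                              train_frac = 0.7, repeats = 5L, seed = 1L,
                              lambda = 0.01) {
  mode <- match.arg(mode)
  labels <- cohort_labels(cohort)
  if (length(unique(labels)) < 2L) stop("cohort must contain both classes")
  toks <- tokenize_corpus(cohort_records(cohort), vocab, grouper)
  p <- if (mode == "SPARSE_COUNTS") vocab_size(vocab) else n_categories(grouper)
  X <- t(vapply(toks, function(tk) {
    ids <- if (mode == "SPARSE_COUNTS") tk$code_gid else unlist(tk$cp_targets)
    tabulate(ids, nbins = p)
  }, numeric(p)))
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    seeds <- seed_everything(seed, paste0(c("split", "init", "shuffle"), "_rep", r))
    sp <- stratified_split(labels, train_frac, seeds[[1]])
    fit <- glmnet::glmnet(X[sp$train, , drop = FALSE], labels[sp$train],
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = TRUE)
    score <- stats::predict(fit, X[sp$test, , drop = FALSE], type = "response")[, 1]
    aucs[r] <- auc(score, labels[sp$test])
  }
  experiment_result(aucs, paste0("LR_", mode))
}

#' Input-channel ablation
#'
#' Reproduces the cumulative input design: demographics only, then adding
#' medical codes, then visit-type (utilization), then service-date
#' information. The demographics-only arm has no visit tokens and hence
#' nothing to pre-train, so it trains its head from scratch; every other
#' arm pre-trains with its channel set and fully fine-tunes. All arms share
#' seeds, so cohort splits are identical and differences are attributable
#' to the channels.
#'
#' @param records Unlabelled pre-training corpus.
#' @param grouper A `category_grouper`.
#' @param cohort A `labeled_cohort`.
#' @param pretrain_cfg A [pretrain_config()].
#' @param finetune_cfg A [finetune_config()].
#' @return Named list of experiment results, one per arm, in cumulative
#'   order `demo`, `demo_codes`, `demo_codes_util`, `demo_codes_util_date`.
#' @export
run_ablation_inputs <- function(records, grouper, cohort, pretrain_cfg,
                                finetune_cfg) {
  arms <- list(
    demo                 = list(codes = FALSE, util = FALSE, date = FALSE),
    demo_codes           = list(codes = TRUE,  util = FALSE, date = FALSE),
    demo_codes_util      = list(codes = TRUE,  util = TRUE,  date = FALSE),
    demo_codes_util_date = list(codes = TRUE,  util = TRUE,  date = TRUE))
  out <- list()
  for (arm in names(arms)) {
    a <- arms[[arm]]
    ch <- list(diag = a$codes, proc = a$codes, drug = a$codes,
               util = a$util, date = a$date)
    fcfg <- finetune_cfg
    fcfg$channels <- ch
    if (!a$codes && !a$util && !a$date) {
      fcfg$mode <- "FROM_SCRATCH"
      dummy <- init_model(build_vocabulary(records, pretrain_cfg$min_count),
                          grouper, d = pretrain_cfg$d,
                          n_heads = pretrain_cfg$n_heads,
                          n_layers = pretrain_cfg$n_layers,
                          d_ff = pretrain_cfg$d_ff, seed = pretrain_cfg$seed)
      ft <- finetune(cohort, dummy, fcfg)
    } else {
      pcfg <- pretrain_cfg
      pcfg$channels <- ch
      pt <- pretrain(records, pcfg, grouper = grouper)
      fcfg$mode <- "FULL_FINETUNE"
      ft <- finetune(cohort, pt$model, fcfg)
    }
    out[[arm]] <- experiment_result(ft$auc, arm, list(channels = ch))
  }
  out
}

#' Objective ablation
#'
#' Pre-trains three models with identical seeds — next-visit prediction
#' only, category prediction only, and both objectives — and fully
#' fine-tunes each on the same cohort with identical splits.
#'
#' @inheritParams run_ablation_inputs
#' @return Named list of experiment results: `nvp`, `cp`, `nvp_cp`.
#' @export
run_ablation_objectives <- function(records, grouper, cohort, pretrain_cfg,
                                    finetune_cfg) {
  arms <- list(nvp = c(TRUE, FALSE), cp = c(FALSE, TRUE), nvp_cp = c(TRUE, TRUE))
  out <- list()
  for (arm in names(arms)) {
    pcfg <- pretrain_cfg
    pcfg$nvp <- arms[[arm]][1]; pcfg$cp <- arms[[arm]][2]
    pt <- pretrain(records, pcfg, grouper = grouper)
    fcfg <- finetune_cfg
    fcfg$mode <- "FULL_FINETUNE"
    ft <- finetune(cohort, pt$model, fcfg)
    out[[arm]] <- experiment_result(ft$auc, arm,
                                    list(objectives = c(nvp = pcfg$nvp, cp = pcfg$cp)))
  }
  out
}

#' Cross-corpus transfer experiment
#'
#' Pre-trains once on corpus A, then for each target cohort (drawn from
#' corpora generated at different overlaps with A's generative parameters)
#' compares full fine-tuning from the pre-trained checkpoint against the
#' from-scratch control with shared seeds. Reports absolute and relative
#' AUC gains (relative gain = (pretrained - scratch) / scratch).
#'
#' @param records_a Corpus A records (pre-training institution).
#' @param grouper_a Corpus A grouper.
#' @param cohorts_b Named list of `labeled_cohort`s, one per target corpus.
#' @param pretrain_cfg,finetune_cfg Configurations.
#' @return List with the pre-trained model's result per cohort: each
#'   element has `pretrained`, `scratch` (experiment results),
#'   `abs_gain`, `rel_gain`.
#' @export
run_transfer <- function(records_a, grouper_a, cohorts_b, pretrain_cfg,
                         finetune_cfg) {
  pt <- pretrain(records_a, pretrain_cfg, grouper = grouper_a)
  out <- list()
  for (nm in names(cohorts_b)) {
    fcfg <- finetune_cfg
    fcfg$mode <- "FULL_FINETUNE"
    full <- finetune(cohorts_b[[nm]], pt$model, fcfg)
    fcfg$mode <- "FROM_SCRATCH"
    scratch <- finetune(cohorts_b[[nm]], pt$model, fcfg)
    out[[nm]] <- list(
      pretrained = experiment_result(full$auc, paste0(nm, "_pretrained")),
      scratch = experiment_result(scratch$auc, paste0(nm, "_scratch")),
      abs_gain = mean(full$auc) - mean(scratch$auc),
      rel_gain = (mean(full$auc) - mean(scratch$auc)) / mean(scratch$auc))
  }
  out
}

#' Export code or patient embeddings
#'
#' Code embeddings are the rows of the requested channel's embedding table;
#' patient embeddings are the aggregate vectors `pe` under bidirectional
#' encoding. Written as TSV (identifier + d columns) for external
#' projection (t-SNE, UMAP, ...).
#'
#' @param model A `claims_model`.
#' @param what `"codes"` or `"patients"`.
#' @param channel Channel for code export (default `"DIAG"`).
#' @param records Records for patient export.
#' @param path Optional TSV output path.
#' @return Data frame: `id` column plus `d` embedding columns.
#' @export
export_embeddings <- function(model, what = c("codes", "patients"),
                              channel = "DIAG", records = NULL, path = NULL) {
  what <- match.arg(what)
  if (what == "codes") {
    tab <- model$vocab$channels[[channel]]
    rows <- vocab_global_index(model$vocab, channel, names(tab)) + 1L
    emb <- model$W$emb_code[rows, , drop = FALSE]
    df <- data.frame(id = names(tab), emb, check.names = FALSE)
  } else {
    if (is.null(records)) stop("patient export requires records")
    emb <- t(vapply(records, function(r)
      encode_patient(r, model, mode = "BIDIRECTIONAL")$pe,
      numeric(model$meta$d)))
    df <- data.frame(id = vapply(records, `[[`, character(1), "patient_id"),
                     emb, check.names = FALSE)
  }
  names(df) <- c("id", paste0("d", seq_len(model$meta$d)))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
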