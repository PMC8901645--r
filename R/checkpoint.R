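# Checkpoints: a directory holding the model weights plus the vocabulary
# and grouper they were trained against (as TSV) and a JSON meta file with
# content fingerprints, so downstream fine-tuning can refuse a mismatched
# vocabulary.

#' Save / load a model checkpoint
#'
#' A checkpoint directory contains `weights.rds` (the parameter list),
#' `vocab.tsv`, `grouper.tsv` and `meta.json` (dimensions + fingerprints).
#' `load_checkpoint` recomputes the fingerprints of the stored vocabulary
#' and grouper and refuses a checkpoint whose contents disagree with its
#' meta file.
#'
#' @param model A `claims_model`.
#' @param dir Checkpoint directory (created if missing).
#' @return `load_checkpoint` returns a `claims_model`; `save_checkpoint`
#'   returns `dir` invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$W, file.path(dir, "weights.rds"))
  write_vocabulary(model$vocab, file.path(dir, "vocab.tsv"))
  write_grouper(model$grouper, file.path(dir, "grouper.tsv"))
  jsonlite::write_json(model$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  vocab <- read_vocabulary(file.path(dir, "vocab.tsv"))
  grouper <- read_grouper(file.path(dir, "grouper.tsv"))
  if (!identical(vocab_fingerprint(vocab), meta$vocab_fp))
    stop("checkpoint refused: vocabulary fingerprint mismatch")
  if (!identical(grouper_fingerprint(grouper), meta$grouper_fp))
    stop("checkpoint refused: grouper fingerprint mismatch")
  W <- readRDS(file.path(dir, "weights.rds"))
  meta <- lapply(meta, function(x) if (is.numeric(x)) as.integer(x) else x)
  meta$vocab_fp <- as.character(meta$vocab_fp)
  meta$grouper_fp <- as.character(meta$grouper_fp)
  structure(list(meta = meta, W = W, vocab = vocab, grouper = grouper),
            class = "claims_model")
}
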