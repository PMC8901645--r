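# Patient encoding: channel embeddings, max-pooled visit vectors, the
# demographic first token, and the transformer body producing the aggregate
# patient vector `pe` and per-visit hidden states.
#
# Internally, records are "tokenized" once into integer index structures and
# then batches are packed into one tall matrix (one row per sequence
# position) so that all dense algebra runs as a few large BLAS calls;
# attention is computed per patient block so it never crosses patients.

# Inter-visit gap (days) -> date bucket 1..6: 0 | 1-7 | 8-30 | 31-90 |
# 91-365 | >365. The first visit of a sequence uses bucket 1.
date_bucket <- function(gap_days) {
  findInterval(gap_days, c(0, 1, 8, 31, 91, 366))
}

# Demographic one-hot rows of w_demo: gender (M/F/U -> 1..3) and age bucket
# (annual 0..18 -> rows 4..22, >=19 -> row 23).
demo_rows <- function(gender, age_years) {
  gi <- match(gender, c("M", "F", "U"))
  ai <- min(as.integer(floor(max(age_years, 0))), 19L)
  c(gi, 3L + ai + 1L)
}

#' Demographic token vector
#'
#' Concatenated one-hot encoding of gender (3 levels) and age-at-first-visit
#' bucket (annual buckets 0-18 plus 19+), projected to the hidden width by
#' the demographic projection matrix. Prepended as the first token of every
#' patient sequence; the transformer output at this position is the
#' aggregate patient representation `pe`.
#'
#' @param gender `"M"`, `"F"` or `"U"`.
#' @param age_at_first_visit Age in years (>= 0).
#' @param model A `claims_model`.
#' @return Numeric vector of width `d`.
#' @export
demographic_token <- function(gender, age_at_first_visit, model) {
  stopifnot(age_at_first_visit >= 0)
  r <- demo_rows(gender, age_at_first_visit)
  model$W$w_demo[r[1], ] + model$W$w_demo[r[2], ]
}

# channel flags: which inputs contribute rows to the visit max-pool
default_channels <- function() {
  list(diag = TRUE, proc = TRUE, drug = TRUE, util = TRUE, date = TRUE)
}

#' Embed one visit by max-pooling its component embeddings
#'
#' Stacks, as rows, the code embeddings of every enabled channel, the
#' visit-type embedding, and the date-bucket embedding of the gap since the
#' previous visit, and returns the element-wise maximum over rows. The
#' result is invariant to code order; disabled channels contribute nothing.
#'
#' @param v A `claims_visit`.
#' @param model A `claims_model` (embedding tables + vocabulary).
#' @param channels Flag list from [default_channels()]; elements `diag`,
#'   `proc`, `drug`, `util`, `date`.
#' @param prev_date Previous visit's service date in days, or `NULL` for the
#'   first visit (date bucket 0 days).
#' @return Numeric vector of width `d`.
#' @export
embed_visit <- function(v, model, channels = default_channels(), prev_date = NULL) {
  rows <- NULL
  add <- function(rows, m) if (is.null(rows)) m else rbind(rows, m)
  if (isTRUE(channels$diag) && length(v$dx))
    rows <- add(rows, model$W$emb_code[vocab_global_index(model$vocab, "DIAG", v$dx) + 1L, , drop = FALSE])
  if (isTRUE(channels$proc) && length(v$px))
    rows <- add(rows, model$W$emb_code[vocab_global_index(model$vocab, "PROC", v$px) + 1L, , drop = FALSE])
  if (isTRUE(channels$drug) && length(v$rx))
    rows <- add(rows, model$W$emb_code[vocab_global_index(model$vocab, "DRUG", v$rx) + 1L, , drop = FALSE])
  if (isTRUE(channels$util))
    rows <- add(rows, model$W$emb_type[match(v$type, VISIT_TYPES), , drop = FALSE])
  if (isTRUE(channels$date)) {
    gap <- if (is.null(prev_date)) 0L else max(0L, v$date - prev_date)
    rows <- add(rows, model$W$emb_date[date_bucket(gap), , drop = FALSE])
  }
  if (is.null(rows)) stop("no enabled channel contributes any row to this visit")
  apply(rows, 2L, max)
}

# ---------------------------------------------------------------------------
# Tokenization

# Convert a record into dense index structures (1-based):
#   demo: 2 rows of w_demo; type/date: per-visit indices;
#   code_gid / code_visit / code_chan: flattened code contributions;
#   nvp_targets: per position 1..T-1, global code ids of the NEXT visit;
#   cp_targets: per visit, unique global category ids.
tokenize_record <- function(record, vocab, grouper, max_seq_len = 128L) {
  vs <- record$visits
  if (length(vs) > max_seq_len) vs <- vs[(length(vs) - max_seq_len + 1L):length(vs)]
  Tn <- length(vs)
  dates <- vapply(vs, `[[`, integer(1), "date")
  gaps <- c(0L, pmax(0L, diff(dates)))
  gid <- lapply(vs, function(v) {
    c(if (length(v$dx)) vocab_global_index(vocab, "DIAG", v$dx) + 1L,
      if (length(v$px)) vocab_global_index(vocab, "PROC", v$px) + 1L,
      if (length(v$rx)) vocab_global_index(vocab, "DRUG", v$rx) + 1L)
  })
  chan <- lapply(vs, function(v)
    rep(CHANNELS, c(length(v$dx), length(v$px), length(v$rx))))
  cp <- lapply(vs, function(v) {
    unique(c(if (length(v$dx)) category_global_index(grouper, "DIAG", v$dx) + 1L,
             if (length(v$px)) category_global_index(grouper, "PROC", v$px) + 1L,
             if (length(v$rx)) category_global_index(grouper, "DRUG", v$rx) + 1L))
  })
  type_idx <- match(vapply(vs, `[[`, character(1), "type"), VISIT_TYPES)
  date_idx <- date_bucket(gaps)
  code_gid <- unlist(gid, use.names = FALSE)
  code_visit <- rep(seq_len(Tn), lengths(gid))
  # flattened max-pool contributions in the combined embedding row space
  # [codes (V rows); visit types (3); date buckets (6)]
  V <- vocab_size(vocab)
  contrib_row <- c(code_gid, V + type_idx, V + 3L + date_idx)
  contrib_vis <- c(code_visit, seq_len(Tn), seq_len(Tn))
  contrib_kind <- rep.int(1:3, c(length(code_gid), Tn, Tn))
  contrib_chan <- c(match(unlist(chan, use.names = FALSE), CHANNELS),
                    integer(2L * Tn))
  list(demo = demo_rows(record$gender, age_at_first_visit(record)),
       T = Tn,
       type_idx = type_idx,
       date_idx = date_idx,
       code_gid = code_gid,
       code_visit = code_visit,
       contrib_row = contrib_row,
       contrib_vis = contrib_vis,
       contrib_kind = contrib_kind,
       contrib_chan = contrib_chan,
       nvp_targets = if (Tn >= 2L) gid[2:Tn] else list(),
       cp_targets = cp)
}

tokenize_corpus <- function(records, vocab, grouper, max_seq_len = 128L) {
  lapply(records, tokenize_record, vocab = vocab, grouper = grouper,
         max_seq_len = max_seq_len)
}

# ---------------------------------------------------------------------------
# Batched visit embedding (max-pool) forward/backward

# Build the pooled visit embedding matrix E (one row per visit across the
# batch) plus the argmax bookkeeping needed for the backward pass. Gathers
# from a single combined row space [codes; types; date buckets] so the
# whole batch needs one subset operation.
visit_embed_forward <- function(toks, W, channels) {
  all_on <- isTRUE(channels$diag) && isTRUE(channels$proc) &&
    isTRUE(channels$drug) && isTRUE(channels$util) && isTRUE(channels$date)
  Ts <- vapply(toks, `[[`, integer(1), "T")
  n_vis <- sum(Ts)
  voff <- cumsum(c(0L, Ts[-length(Ts)]))
  row <- unlist(lapply(toks, `[[`, "contrib_row"), use.names = FALSE)
  vis <- unlist(Map(function(tk, off) tk$contrib_vis + off, toks, voff),
                use.names = FALSE)
  if (!all_on) {
    kind <- unlist(lapply(toks, `[[`, "contrib_kind"), use.names = FALSE)
    chan <- unlist(lapply(toks, `[[`, "contrib_chan"), use.names = FALSE)
    use_code <- c(isTRUE(channels$diag), isTRUE(channels$proc), isTRUE(channels$drug))
    keep <- (kind == 1L & use_code[pmax(chan, 1L)]) |
            (kind == 2L & isTRUE(channels$util)) |
            (kind == 3L & isTRUE(channels$date))
    row <- row[keep]; vis <- vis[keep]
  }
  d <- ncol(W$emb_code)
  V <- nrow(W$emb_code)
  emb_all <- rbind(W$emb_code, W$emb_type, W$emb_date)
  ord <- order(vis, method = "radix")
  row <- row[ord]; vis <- vis[ord]
  counts <- tabulate(vis, nbins = n_vis)
  if (any(counts == 0L))
    stop("some visit has no enabled channel contribution")
  M <- emb_all[row, , drop = FALSE]
  mp <- maxpool_forward_cpp(M, vis, n_vis)
  list(E = mp$E, Amat = mp$Amat, row = row, n_contrib = length(vis), V = V)
}

# Scatter dE back onto the embedding tables. Returns grads for emb_code,
# emb_type, emb_date (dense, zero rows untouched).
visit_embed_backward <- function(dE, cache, W) {
  d <- ncol(dE)
  dM <- maxpool_backward_cpp(dE, cache$Amat, cache$n_contrib)
  rs <- rowsum(dM, group = cache$row)
  rid <- as.integer(rownames(rs))
  V <- cache$V
  out <- list(emb_code = matrix(0, nrow(W$emb_code), d),
              emb_type = matrix(0, nrow(W$emb_type), d),
              emb_date = matrix(0, nrow(W$emb_date), d))
  sel <- rid <= V
  if (any(sel)) out$emb_code[rid[sel], ] <- rs[sel, , drop = FALSE]
  sel <- rid > V & rid <= V + 3L
  if (any(sel)) out$emb_type[rid[sel] - V, ] <- rs[sel, , drop = FALSE]
  sel <- rid > V + 3L
  if (any(sel)) out$emb_date[rid[sel] - V - 3L, ] <- rs[sel, , drop = FALSE]
  out
}

# ---------------------------------------------------------------------------
# Full forward/backward over a batch of tokenized records

# Stage 1: pack [demo; e_1..e_T] per record into one tall input matrix.
# When no visit channel is enabled the sequences are demographic-token-only
# (L = 1, no visit states). Shared by the causal and bidirectional passes.
embed_inputs <- function(toks, model, channels = default_channels()) {
  W <- model$W
  d <- model$meta$d
  any_visit_channel <- isTRUE(channels$diag) || isTRUE(channels$proc) ||
    isTRUE(channels$drug) || isTRUE(channels$util) || isTRUE(channels$date)
  Ts <- vapply(toks, `[[`, integer(1), "T")
  Ls <- if (any_visit_channel) Ts + 1L else rep(1L, length(toks))
  starts <- cumsum(c(1L, Ls[-length(Ls)]))
  N <- sum(Ls)
  X0 <- matrix(0, N, d)
  demo_mat <- do.call(rbind, lapply(toks, `[[`, "demo"))
  X0[starts, ] <- W$w_demo[demo_mat[, 1], , drop = FALSE] +
    W$w_demo[demo_mat[, 2], , drop = FALSE]
  ve <- NULL
  visit_rows <- integer(0)
  if (any_visit_channel) {
    ve <- visit_embed_forward(toks, W, channels)
    visit_rows <- setdiff(seq_len(N), starts)
    X0[visit_rows, ] <- ve$E
  }
  blocks <- lapply(seq_along(toks), function(i) starts[i]:(starts[i] + Ls[i] - 1L))
  list(X0 = X0, starts = starts, Ls = Ls, Ts = Ts, blocks = blocks,
       visit_rows = visit_rows, demo_mat = demo_mat, ve = ve,
       any_visit_channel = any_visit_channel)
}

# Stage 2: transformer stack under a causal or all-to-all mask.
encode_layers <- function(inp, model, mode, dropout_p = 0, train = FALSE) {
  W <- model$W; meta <- model$meta
  X <- inp$X0
  caches <- vector("list", meta$n_layers)
  for (l in seq_len(meta$n_layers)) {
    fw <- layer_forward(X, inp$blocks, W, meta, layer = l, mode = mode,
                        dropout_p = dropout_p, train = train)
    caches[[l]] <- fw$cache
    X <- fw$out
  }
  list(out = X, caches = caches)
}

# Backward through the transformer stack only; returns dX0 + layer grads.
backward_layers <- function(dOut, caches, model) {
  W <- model$W; meta <- model$meta
  grads <- NULL
  dX <- dOut
  for (l in rev(seq_len(meta$n_layers))) {
    bw <- layer_backward(dX, caches[[l]], W, meta)
    grads <- add_grads(grads, bw$grads)
    dX <- bw$dX
  }
  list(dX0 = dX, grads = grads)
}

# Backward through the embedding stage given the gradient on X0.
embed_backward <- function(dX0, inp, model) {
  W <- model$W
  grads <- list()
  # demographic projection: both one-hot rows of each record receive the
  # gradient of that record's first position
  ddemo <- dX0[inp$starts, , drop = FALSE]
  dw_demo <- matrix(0, nrow(W$w_demo), model$meta$d)
  for (j in 1:2) {
    rs <- rowsum(ddemo, group = inp$demo_mat[, j])
    rid <- as.integer(rownames(rs))
    dw_demo[rid, ] <- dw_demo[rid, ] + rs
  }
  grads$w_demo <- dw_demo
  if (inp$any_visit_channel && length(inp$visit_rows)) {
    emb <- visit_embed_backward(dX0[inp$visit_rows, , drop = FALSE], inp$ve, W)
    grads <- add_grads(grads, emb)
  }
  grads
}

# Convenience composition used by inference, fine-tuning and the public ops.
forward_batch <- function(toks, model, mode = c("bidir", "causal"),
                          channels = default_channels(),
                          dropout_p = 0, train = FALSE) {
  mode <- match.arg(mode)
  inp <- embed_inputs(toks, model, channels)
  enc <- encode_layers(inp, model, mode, dropout_p, train)
  c(list(out = enc$out, caches = enc$caches), inp)
}

backward_batch <- function(dOut, fw, model) {
  bl <- backward_layers(dOut, fw$caches, model)
  add_grads(bl$grads, embed_backward(bl$dX0, fw, model))
}

#' Encode a patient record
#'
#' Builds the input sequence `[demographic token, e_1, ..., e_T]`, applies
#' the transformer body, and returns the aggregate patient vector `pe`
#' (output at the first position) and the per-visit hidden states.
#' `CAUSAL` mode restricts each position to attend to itself and earlier
#' positions (used by the next-visit objective); `BIDIRECTIONAL` is
#' all-to-all (used by category prediction, fine-tuning and probes).
#'
#' @param record A `patient_record` with at least one visit.
#' @param model A `claims_model`.
#' @param mode `"BIDIRECTIONAL"` or `"CAUSAL"`.
#' @param channels Input-channel flags, see [default_channels()].
#' @return List with `pe` (length-`d` vector) and `visit_states`
#'   (`T x d` matrix).
#' @export
encode_patient <- function(record, model, mode = c("BIDIRECTIONAL", "CAUSAL"),
                           channels = default_channels()) {
  mode <- match.arg(mode)
  if (length(record$visits) == 0L) stop("record has no visits")
  tk <- tokenize_record(record, model$vocab, model$grouper, model$meta$max_seq_len)
  fw <- forward_batch(list(tk), model,
                      mode = if (mode == "CAUSAL") "causal" else "bidir",
                      channels = channels, dropout_p = 0, train = FALSE)
  out <- fw$out
  list(pe = out[1, ],
       visit_states = if (fw$any_visit_channel)
         out[1L + seq_len(tk$T), , drop = FALSE]
       else matrix(0, 0L, model$meta$d))
}
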