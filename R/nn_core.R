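# Low-level neural network machinery: parameter initialisation, layer-norm,
# multi-head attention, feed-forward, dropout, and the RMSprop update.
# Everything is dense base-R matrix algebra (BLAS-backed); gradients are
# derived by hand and verified against finite differences and per-term
# oracles in the test suite.

LN_EPS <- 1e-5
N_DATE_BUCKETS <- 6L
DEMO_DIM <- 23L   # 3 gender one-hots + 20 age buckets (annual 0-18, 19+)

layer_param_names <- function(l) {
  paste0("l", l, "_", c("wq", "wk", "wv", "wo", "bq", "bk", "bv", "bo",
                        "ln1_g", "ln1_b", "ffn_w1", "ffn_b1", "ffn_w2",
                        "ffn_b2", "ln2_g", "ln2_b"))
}

# add a row vector to every row (no byrow matrix construction / transpose)
addrow <- function(M, b) M + rep(b, each = nrow(M))

#' Initialise model parameters
#'
#' Builds the embedding tables (codes, visit type, date bucket, demographic
#' projection), the transformer layer weights, and the two pre-training
#' heads (next-visit softmax over the full code vocabulary; per-category
#' sigmoid). Weights are Gaussian (sd 0.02), norms start at identity,
#' biases at zero.
#'
#' @param vocab A `code_vocabulary`.
#' @param grouper A `category_grouper` covering the vocabulary.
#' @param d Hidden width (default 100, shared by every layer).
#' @param n_heads Attention heads (default 4); must divide `d`.
#' @param n_layers Transformer layers (default 1).
#' @param d_ff Feed-forward inner width (default `d`).
#' @param max_seq_len Maximum visits kept per patient (oldest truncated).
#' @param seed Integer seed for the initial draw.
#' @return A `claims_model`: list with `meta`, weight list `W`, and the
#'   bundled `vocab`/`grouper` (so encoding is self-contained).
#' @export
init_model <- function(vocab, grouper, d = 100L, n_heads = 4L, n_layers = 1L,
                       d_ff = d, max_seq_len = 128L, seed = 1L) {
  if (d %% n_heads != 0L) stop("hidden width d must be divisible by n_heads")
  V <- vocab_size(vocab)
  n_cat <- n_categories(grouper)
  set.seed(seed)
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  W <- list(
    emb_code = g(V, d),
    emb_type = g(3L, d),
    emb_date = g(N_DATE_BUCKETS, d),
    w_demo   = g(DEMO_DIM, d))
  for (l in seq_len(n_layers)) {
    lw <- stats::setNames(vector("list", 16L), layer_param_names(l))
    lw[[paste0("l", l, "_wq")]] <- g(d, d)
    lw[[paste0("l", l, "_wk")]] <- g(d, d)
    lw[[paste0("l", l, "_wv")]] <- g(d, d)
    lw[[paste0("l", l, "_wo")]] <- g(d, d)
    for (nm in paste0("l", l, "_", c("bq", "bk", "bv", "bo"))) lw[[nm]] <- numeric(d)
    lw[[paste0("l", l, "_ln1_g")]] <- rep(1, d)
    lw[[paste0("l", l, "_ln1_b")]] <- numeric(d)
    lw[[paste0("l", l, "_ffn_w1")]] <- g(d, d_ff)
    lw[[paste0("l", l, "_ffn_b1")]] <- numeric(d_ff)
    lw[[paste0("l", l, "_ffn_w2")]] <- g(d_ff, d)
    lw[[paste0("l", l, "_ffn_b2")]] <- numeric(d)
    lw[[paste0("l", l, "_ln2_g")]] <- rep(1, d)
    lw[[paste0("l", l, "_ln2_b")]] <- numeric(d)
    W <- c(W, lw)
  }
  W$nvp_w <- g(d, V);     W$nvp_b <- numeric(V)
  W$cp_w  <- g(d, n_cat); W$cp_b  <- numeric(n_cat)
  structure(list(
    meta = list(d = as.integer(d), n_heads = as.integer(n_heads),
                n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                dh = as.integer(d %/% n_heads), V = V, n_cat = n_cat,
                max_seq_len = as.integer(max_seq_len),
                vocab_fp = vocab_fingerprint(vocab),
                grouper_fp = grouper_fingerprint(grouper)),
    W = W, vocab = vocab, grouper = grouper), class = "claims_model")
}

#' Total trainable parameter count of a model body
#' @param model A `claims_model`.
#' @return Integer parameter count (embeddings + transformer + both heads).
#' @export
n_parameters <- function(model) sum(vapply(model$W, length, integer(1)))

# weights that receive L2 decay (matrices; not biases or layer-norm params)
decay_param <- function(nm) {
  grepl("^(emb_|w_demo|nvp_w|cp_w)", nm) | grepl("_(wq|wk|wv|wo|ffn_w1|ffn_w2)$", nm)
}

# ---- layer norm -----------------------------------------------------------

ln_forward <- function(R, g, b) ln_forward_cpp(R, g, b, LN_EPS)

ln_backward <- function(dY, cache, g) ln_backward_cpp(dY, cache$xhat, cache$inv, g)

# ---- attention masks ------------------------------------------------------

# allowed[i, j] == TRUE means position i may attend to position j
make_mask <- function(L, mode) {
  if (mode == "causal") outer(seq_len(L), seq_len(L), ">=") else matrix(TRUE, L, L)
}

masked_softmax_rows <- function(S, mask) {
  S[!mask] <- -Inf
  row_softmax(S)
}

#' Apply one transformer layer to a sequence
#'
#' Standard post-norm block: multi-head scaled dot-product self-attention
#' (forbidden positions get exactly zero attention weight), residual
#' connection, layer normalisation, position-wise feed-forward (ReLU),
#' residual, layer normalisation.
#'
#' @param inputs `L x d` matrix of input vectors.
#' @param model A `claims_model` (supplies the layer weights).
#' @param mask `L x L` logical matrix; `mask[i, j]` allows position `i` to
#'   attend to `j`. Every row must allow at least one position.
#' @param layer Which layer's weights to use (default 1).
#' @return `L x d` output matrix. Use [attention_weights()] for the
#'   per-head attention distributions.
#' @export
transformer_layer <- function(inputs, model, mask = NULL, layer = 1L) {
  L <- nrow(inputs)
  if (is.null(mask)) mask <- matrix(TRUE, L, L)
  stopifnot(is.matrix(mask), nrow(mask) == L, ncol(mask) == L)
  if (any(rowSums(mask) == 0L)) stop("attention mask forbids all positions for some row")
  fw <- layer_forward(inputs, list(seq_len(L)), model$W, model$meta,
                      layer = layer, mode = "explicit", masks = list(mask),
                      dropout_p = 0, train = FALSE)
  fw$out
}

#' Attention weights of one transformer layer
#'
#' @inheritParams transformer_layer
#' @return List of `L x L` row-stochastic matrices, one per head.
#' @export
attention_weights <- function(inputs, model, mask = NULL, layer = 1L) {
  L <- nrow(inputs)
  if (is.null(mask)) mask <- matrix(TRUE, L, L)
  if (any(rowSums(mask) == 0L)) stop("attention mask forbids all positions for some row")
  fw <- layer_forward(inputs, list(seq_len(L)), model$W, model$meta,
                      layer = layer, mode = "explicit", masks = list(mask),
                      dropout_p = 0, train = FALSE)
  fw$cache$attn$P[[1]]
}

# Per-layer weight list in the fixed order the compiled kernels expect.
layer_weights <- function(W, layer) {
  nms <- c("wq", "bq", "wk", "bk", "wv", "bv", "wo", "bo", "ln1_g", "ln1_b",
           "ffn_w1", "ffn_b1", "ffn_w2", "ffn_b2", "ln2_g", "ln2_b")
  stats::setNames(W[paste0("l", layer, "_", nms)], nms)
}

# Forward pass of one transformer layer over a batch of sequences packed as
# rows of X. `blocks` lists the row indices of each sequence (contiguous);
# attention never crosses a block boundary. mode "causal"/"bidir" runs the
# fused compiled kernel; mode "explicit" (arbitrary masks, the public
# transformer_layer surface) runs a plain-R reference path that the test
# suite checks against the compiled one.
layer_forward <- function(X, blocks, W, meta, layer, mode, masks = NULL,
                          dropout_p = 0, train = TRUE) {
  starts <- vapply(blocks, `[`, integer(1), 1L)
  lens <- lengths(blocks)
  if (mode != "explicit") {
    r <- layer_forward_cpp(X, starts, lens, meta$n_heads, mode == "causal",
                           layer_weights(W, layer), dropout_p, train, LN_EPS)
    return(list(out = r$out,
                cache = list(type = "cpp", X = X, starts = starts, lens = lens,
                             cpp = r, layer = layer)))
  }
  p <- function(nm) W[[paste0("l", layer, "_", nm)]]
  d <- meta$d; H <- meta$n_heads; dh <- meta$dh
  # biases folded into the matmul via a ones column
  X1 <- cbind(X, 1)
  Q <- X1 %*% rbind(p("wq"), p("bq"))
  K <- X1 %*% rbind(p("wk"), p("bk"))
  Vv <- X1 %*% rbind(p("wv"), p("bv"))
  Ctx <- matrix(0, nrow(X), d)
  Plist <- vector("list", length(blocks))
  sdh <- sqrt(dh)
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    msk <- masks[[bi]]
    Qb <- Q[rows, , drop = FALSE]
    Kb <- K[rows, , drop = FALSE]
    Vb <- Vv[rows, , drop = FALSE]
    Cb <- matrix(0, length(rows), d)
    Ph <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) / sdh
      S[!msk] <- -Inf
      P <- row_softmax(S)
      Cb[, cols] <- P %*% Vb[, cols, drop = FALSE]
      Ph[[h]] <- P
    }
    Ctx[rows, ] <- Cb
    Plist[[bi]] <- Ph
  }
  A <- cbind(Ctx, 1) %*% rbind(p("wo"), p("bo"))
  m1 <- dropout_mask(dim(A), dropout_p, train)
  R1 <- X + if (is.null(m1)) A else A * m1
  ln1 <- ln_forward(R1, p("ln1_g"), p("ln1_b"))
  H1 <- ln1$out
  Z1 <- cbind(H1, 1) %*% rbind(p("ffn_w1"), p("ffn_b1"))
  Arelu <- pmax(Z1, 0)
  Fo <- cbind(Arelu, 1) %*% rbind(p("ffn_w2"), p("ffn_b2"))
  m2 <- dropout_mask(dim(Fo), dropout_p, train)
  R2 <- H1 + if (is.null(m2)) Fo else Fo * m2
  ln2 <- ln_forward(R2, p("ln2_g"), p("ln2_b"))
  list(out = ln2$out,
       cache = list(type = "r", attn = list(P = Plist), layer = layer))
}

# inverted dropout mask (already scaled); NULL when inactive
dropout_mask <- function(dm, p, train) {
  if (!train || p <= 0) return(NULL)
  matrix((stats::runif(prod(dm)) >= p) / (1 - p), dm[1], dm[2])
}

# Backward through one layer (compiled-path caches only; the explicit-mask
# reference path is inference-only). Returns dX plus this layer's gradients.
layer_backward <- function(dOut, cache, W, meta) {
  if (!identical(cache$type, "cpp"))
    stop("backward pass is only available for the compiled attention path")
  layer <- cache$layer
  r <- layer_backward_cpp(dOut, cache$cpp, cache$X, cache$starts, cache$lens,
                          meta$n_heads, layer_weights(W, layer))
  grads <- r[names(r) != "dX"]
  names(grads) <- paste0("l", layer, "_", names(grads))
  list(dX = r$dX, grads = grads)
}

# ---- optimizer ------------------------------------------------------------

rmsprop_state <- function(W) lapply(W, function(w) array(0, dim = dim(w) %||% length(w)))

# One RMSprop step; lr may be a single rate or a function of the parameter
# name (used by fine-tuning's body/head split). The elementwise update runs
# in the fused compiled kernel.
rmsprop_step <- function(W, grads, state, lr, decay = 0.9, eps = 1e-8, l2 = 0) {
  nms <- names(grads)[!vapply(grads, is.null, logical(1))]
  if (!length(nms)) return(list(W = W, state = state))
  rates <- if (is.function(lr)) vapply(nms, lr, numeric(1)) else rep(lr, length(nms))
  upd <- rmsprop_update_cpp(W[nms], grads[nms], state[nms],
                            rates, decay_param(nms), decay, eps, l2)
  W[nms] <- upd$W
  state[nms] <- upd$state
  list(W = W, state = state)
}

# elementwise sum of two gradient lists (second scaled)
add_grads <- function(a, b, scale = 1) {
  if (is.null(a)) { if (scale == 1) return(b); return(lapply(b, function(x) x * scale)) }
  for (nm2 in names(b)) {
    a[[nm2]] <- if (is.null(a[[nm2]])) b[[nm2]] * scale else a[[nm2]] + b[[nm2]] * scale
  }
  a
}

l2_penalty <- function(W, l2) {
  if (l2 <= 0) return(0)
  l2 * sum(vapply(names(W)[decay_param(names(W))],
                  function(nm2) sum(W[[nm2]]^2), numeric(1)))
}
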