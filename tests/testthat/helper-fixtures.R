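# Shared fixtures: small simulated corpora and models, memoised so several
# test files can reuse the same objects without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# a small but structured corpus: 4 latent states, 60 codes, quick to encode
small_sim <- function() memo("small_sim", {
  simulate_population(sim_config(
    n_patients = 60L,
    n_codes = c(DIAG = 30L, PROC = 18L, DRUG = 12L),
    n_categories = c(DIAG = 5L, PROC = 3L, DRUG = 2L),
    mean_visits_per_patient = 5, seed = 101L))
})

small_vocab <- function() memo("small_vocab", build_vocabulary(small_sim()$records, 1L))

# compact model over the small corpus (d = 12, 3 heads)
small_model <- function() memo("small_model", {
  init_model(small_vocab(), small_sim()$grouper, d = 12L, n_heads = 3L,
             d_ff = 10L, seed = 7L)
})

# a small labelled cohort with latent-state-driven labels
ft_cohort <- function() memo("ft_cohort", {
  sim <- simulate_population(sim_config(
    n_patients = 80L, n_codes = c(DIAG = 30L, PROC = 18L, DRUG = 12L),
    n_categories = c(DIAG = 5L, PROC = 3L, DRUG = 2L),
    mean_visits_per_patient = 5, label_effect = 6, seed = 303L))
  cohort_from_labels(sim$records)
})

# hand-built two-visit record for exact-value tests
toy_record <- function(px = character(), rx = character()) {
  patient_record("p1", "F", 2005L, list(
    visit("2014-01-10", "OP", dx = "D001", px = px, rx = rx),
    visit("2014-02-01", "RX", dx = c("D001", "D002"))))
}

# naive per-term reference implementations of the two pre-training losses
# (independent scalar loops; the vectorized versions are tested against them)
naive_nvp_loss <- function(visit_states, records, model) {
  vocab <- model$vocab; grouper <- model$grouper
  W <- model$W$nvp_w; b <- model$W$nvp_b
  per_pos <- c()
  for (i in seq_along(records)) {
    tk <- claimformer:::tokenize_record(records[[i]], vocab, grouper,
                                        model$meta$max_seq_len)
    if (tk$T < 2) next
    for (pos in 1:(tk$T - 1)) {
      h <- visit_states[[i]][pos, ]
      logits <- as.vector(h %*% W) + b
      logp <- logits - max(logits) - log(sum(exp(logits - max(logits))))
      terms <- vapply(tk$nvp_targets[[pos]], function(g) -logp[g], numeric(1))
      per_pos <- c(per_pos, mean(terms))
    }
  }
  mean(per_pos)
}

naive_cp_loss <- function(visit_states, records, model) {
  W <- model$W$cp_w; b <- model$W$cp_b
  n_cat <- model$meta$n_cat
  per_visit <- c()
  for (i in seq_along(records)) {
    tk <- claimformer:::tokenize_record(records[[i]], model$vocab, model$grouper,
                                        model$meta$max_seq_len)
    for (pos in seq_len(tk$T)) {
      h <- visit_states[[i]][pos, ]
      z <- as.vector(h %*% W) + b
      y <- as.integer(seq_len(n_cat) %in% tk$cp_targets[[pos]])
      bce <- ifelse(y == 1, -log(stats::plogis(z)), -log(1 - stats::plogis(z)))
      per_visit <- c(per_visit, mean(bce))
    }
  }
  mean(per_visit)
}
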