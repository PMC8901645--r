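# Synthetic claims simulator.
#
# Generative process (per patient): a first-order Markov chain over K latent
# health states drives everything that varies clinically. Each visit draws
# its gap from a log-normal (visits are unevenly spaced), its type (IP/OP/RX)
# from a state-conditional categorical, its code count from a shifted
# Poisson, and its codes from a state-conditional categorical whose base
# popularity is Zipf (long-tailed code frequencies). Categories are
# contiguous blocks of the popularity-sorted code list per channel, so every
# code maps deterministically to one category. The downstream binary label
# depends on the fraction of time spent in the designated high-risk state.

#' Simulation configuration
#'
#' Defaults emulate a large pediatric Medicaid-style claims corpus: on
#' average 10.4 visits per patient and 2.8 codes per visit, 49.8% male,
#' ages 0-18 at first visit, log-normal inter-visit gaps with median ~30
#' days, and a long-tailed code distribution.
#'
#' @param n_patients Number of patients.
#' @param n_codes Named integer vector: codes per channel.
#' @param n_categories Named integer vector: categories per channel.
#' @param n_latent_states Number of latent health states K.
#' @param mean_visits_per_patient Mean visits per patient (shifted Poisson).
#' @param mean_codes_per_visit Mean codes per visit (shifted Poisson).
#' @param gap_meanlog,gap_sdlog Log-normal parameters of the inter-visit gap
#'   in days.
#' @param transition_stickiness Self-transition probability of the latent
#'   chain; remaining mass spread uniformly.
#' @param state_code_concentration Std-dev of the log-normal state-specific
#'   boost applied to code popularity; larger values make codes more
#'   informative about the latent state.
#' @param zipf_alpha Power-law exponent of within-channel code popularity.
#' @param label_effect Strength of the latent-state to label association;
#'   0 gives labels independent of the history at rate 0.5.
#' @param male_fraction Fraction of male patients.
#' @param implant_event If `TRUE`, each positive-label patient with at least
#'   two visits gets a designated index-event diagnosis code
#'   (`event_code`) implanted in one visit after the first, enabling
#'   event-based cohort selection with truncation.
#' @param event_code The index-event code string.
#' @param first_visit_years Calendar-year range of first visits.
#' @param seed Integer seed; the same seed yields a byte-identical corpus.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 5000L,
                       n_codes = c(DIAG = 300L, PROC = 120L, DRUG = 80L),
                       n_categories = c(DIAG = 15L, PROC = 6L, DRUG = 4L),
                       n_latent_states = 4L,
                       mean_visits_per_patient = 10.4,
                       mean_codes_per_visit = 2.8,
                       gap_meanlog = log(30), gap_sdlog = 0.8,
                       transition_stickiness = 0.7,
                       state_code_concentration = 1.0,
                       zipf_alpha = 1.0,
                       label_effect = 4,
                       male_fraction = 0.498,
                       implant_event = FALSE,
                       event_code = "EVT",
                       first_visit_years = c(2010L, 2015L),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 1, all(n_codes >= 1), all(n_categories >= 1),
            n_latent_states >= 2, mean_visits_per_patient >= 1,
            mean_codes_per_visit >= 1,
            transition_stickiness > 0, transition_stickiness <= 1,
            male_fraction >= 0, male_fraction <= 1)
  if (any(n_categories > n_codes))
    stop("infeasible config: n_categories exceeds n_codes for some channel")
  stopifnot(identical(names(n_codes), CHANNELS), identical(names(n_categories), CHANNELS))
  structure(cfg, class = "sim_config")
}

# Draw the generative parameter tables (not patients) from their own seed.
# Returned object:
#   code_names / code_channel: global code list in CHANNELS order
#   state_code_probs: K x V row-stochastic (state-conditional code dists)
#   type_probs: K x 3 row-stochastic over IP/OP/RX
#   trans: K x K latent transition matrix; high_risk_state: index
sim_params <- function(config, param_seed) {
  K <- config$n_latent_states
  set.seed(param_seed)
  code_names <- unlist(lapply(CHANNELS, function(ch) {
    sprintf("%s%03d", substr(ch, 1, 1), seq_len(config$n_codes[[ch]]))
  }))
  code_channel <- rep(CHANNELS, times = config$n_codes)
  V <- length(code_names)
  # within-channel Zipf popularity, channels weighted by typical claims mix
  chan_w <- c(DIAG = 0.55, PROC = 0.25, DRUG = 0.20)
  base <- unlist(lapply(CHANNELS, function(ch) {
    z <- (1 / seq_len(config$n_codes[[ch]])^config$zipf_alpha)
    chan_w[[ch]] * z / sum(z)
  }))
  boost <- matrix(exp(config$state_code_concentration * stats::rnorm(K * V)), K, V)
  w <- boost * rep(base, each = K)
  state_code_probs <- w / rowSums(w)
  type_probs <- matrix(stats::rgamma(K * 3, shape = rep(c(1, 5, 2.5), each = K)), K, 3)
  type_probs <- type_probs / rowSums(type_probs)
  colnames(type_probs) <- VISIT_TYPES
  trans <- matrix((1 - config$transition_stickiness) / (K - 1), K, K)
  diag(trans) <- config$transition_stickiness
  list(code_names = code_names, code_channel = code_channel,
       state_code_probs = state_code_probs, type_probs = type_probs,
       trans = trans, high_risk_state = K)
}

# Deterministic grouper: contiguous category blocks over the
# popularity-sorted (= generation-order) code list of each channel.
sim_grouper <- function(config, params) {
  rows <- do.call(rbind, lapply(CHANNELS, function(ch) {
    n <- config$n_codes[[ch]]
    k <- config$n_categories[[ch]]
    block <- ceiling(seq_len(n) / (n / k))
    block <- pmin(block, k)
    data.frame(channel = ch,
               code = params$code_names[params$code_channel == ch],
               category = sprintf("%s:C%02d", ch, block))
  }))
  category_grouper(rows)
}

#' Simulate a claims population
#'
#' Runs the latent-state generative process of [sim_config()] and returns the
#' patient records, the deterministic code-to-category grouper used, and a
#' ground-truth sidecar (latent state sequences, label probabilities, and the
#' parameter tables) that enables parameter-recovery and oracle tests.
#'
#' @param config A `sim_config`.
#' @param params Optional pre-built parameter tables (used by
#'   [make_transfer_pair()] to share or interpolate generative parameters);
#'   normally left `NULL`.
#' @return List with elements `records`, `grouper`, `ground_truth`.
#' @export
simulate_population <- function(config, params = NULL) {
  seeds <- seed_everything(config$seed, c("params", "population"))
  if (is.null(params)) params <- sim_params(config, seeds[["params"]])
  K <- config$n_latent_states
  V <- length(params$code_names)
  set.seed(seeds[["population"]])
  day0 <- as.integer(as.Date(sprintf("%d-01-01", config$first_visit_years[1])))
  day1 <- as.integer(as.Date(sprintf("%d-12-31", config$first_visit_years[2])))

  records <- vector("list", config$n_patients)
  states_list <- vector("list", config$n_patients)
  p_label <- numeric(config$n_patients)
  labels <- integer(config$n_patients)
  by_channel <- split(seq_len(V), params$code_channel)[CHANNELS]

  for (i in seq_len(config$n_patients)) {
    gender <- if (stats::runif(1) < config$male_fraction) "M" else "F"
    age0 <- sample.int(19L, 1L) - 1L
    first_day <- day0 + sample.int(day1 - day0 + 1L, 1L) - 1L
    birth_year <- as.integer(format(days_to_date(first_day), "%Y")) - age0
    Tn <- 1L + stats::rpois(1, config$mean_visits_per_patient - 1)
    s <- integer(Tn)
    s[1] <- sample.int(K, 1L)
    if (Tn > 1) for (t in 2:Tn) s[t] <- sample.int(K, 1L, prob = params$trans[s[t - 1L], ])
    gaps <- if (Tn > 1) pmax(1L, round(stats::rlnorm(Tn - 1L, config$gap_meanlog,
                                                     config$gap_sdlog))) else integer()
    dates <- as.integer(first_day + cumsum(c(0L, gaps)))
    visits <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      m <- 1L + stats::rpois(1, config$mean_codes_per_visit - 1)
      m <- min(m, V)
      gids <- sample.int(V, m, prob = params$state_code_probs[s[t], ])
      type <- sample(VISIT_TYPES, 1L, prob = params$type_probs[s[t], ])
      visits[[t]] <- visit(dates[t], type,
                           dx = params$code_names[gids[params$code_channel[gids] == "DIAG"]],
                           px = params$code_names[gids[params$code_channel[gids] == "PROC"]],
                           rx = params$code_names[gids[params$code_channel[gids] == "DRUG"]])
    }
    frac_high <- mean(s == params$high_risk_state)
    p <- stats::plogis(config$label_effect * (frac_high - 1 / K))
    y <- as.integer(stats::runif(1) < p)
    if (config$implant_event && y == 1L && Tn >= 2L) {
      # the index event is the final recorded visit (the downstream task
      # predicts an event at the next encounter), so truncation removes only
      # the event visit itself and history length stays uninformative
      visits[[Tn]]$dx <- unique(c(visits[[Tn]]$dx, config$event_code))
    }
    records[[i]] <- patient_record(sprintf("P%06d", i), gender, birth_year,
                                   visits, label = y)
    states_list[[i]] <- s
    p_label[i] <- p
    labels[i] <- y
  }
  list(records = records,
       grouper = sim_grouper(config, params),
       ground_truth = structure(list(states = states_list, p_label = p_label,
                                     labels = labels, params = params,
                                     config = config),
                                class = "sim_ground_truth"))
}

#' Generate two corpora with controlled generative overlap
#'
#' Corpus A plays the role of the large pre-training institution. Corpus B's
#' state-conditional code and visit-type distributions are a mixture
#' `overlap * A + (1 - overlap) * independent redraw`: `overlap = 1` gives a
#' same-institution hold-out (B drawn from A's generative parameters),
#' `overlap = 0` an unrelated institution, intermediate values interpolate.
#'
#' @param config_a,config_b `sim_config`s for the two corpora (seeds should
#'   differ so B's patients are fresh draws).
#' @param overlap Real in `[0, 1]`.
#' @return List with `a` and `b` (each a [simulate_population()] result) and
#'   `overlap`.
#' @export
make_transfer_pair <- function(config_a, config_b, overlap) {
  if (!is.numeric(overlap) || length(overlap) != 1 || overlap < 0 || overlap > 1)
    stop("overlap must be a single number in [0, 1]")
  if (!identical(config_a$n_codes, config_b$n_codes) ||
      config_a$n_latent_states != config_b$n_latent_states)
    stop("transfer pair requires matching code and state dimensions")
  pa <- sim_params(config_a, seed_everything(config_a$seed, "params")[[1]])
  pb <- sim_params(config_b, seed_everything(config_b$seed, "params")[[1]])
  pb$state_code_probs <- overlap * pa$state_code_probs +
    (1 - overlap) * pb$state_code_probs
  pb$type_probs <- overlap * pa$type_probs + (1 - overlap) * pb$type_probs
  list(a = simulate_population(config_a, params = pa),
       b = simulate_population(config_b, params = pb),
       overlap = overlap)
}

#' Marginal statistics of a corpus
#'
#' @param records Non-empty list of `patient_record`s.
#' @return One-row data frame: patient and visit counts, mean visits per
#'   patient, mean codes per visit, unique codes per channel and overall,
#'   male percentage, mean age at first visit.
#' @export
corpus_summary <- function(records) {
  if (length(records) == 0L) stop("empty corpus")
  n_visits <- vapply(records, function(r) length(r$visits), integer(1))
  codes_per_visit <- unlist(lapply(records, function(r)
    vapply(r$visits, function(v) length(v$dx) + length(v$px) + length(v$rx),
           integer(1))))
  uniq <- vapply(CHANNEL_FIELDS, function(field)
    length(unique(unlist(lapply(records, function(r)
      unlist(lapply(r$visits, `[[`, field)))))), integer(1))
  data.frame(
    n_patients = length(records),
    n_visits = sum(n_visits),
    mean_visits_per_patient = mean(n_visits),
    mean_codes_per_visit = mean(codes_per_visit),
    unique_codes_diag = unname(uniq[["DIAG"]]),
    unique_codes_proc = unname(uniq[["PROC"]]),
    unique_codes_drug = unname(uniq[["DRUG"]]),
    unique_codes = sum(uniq),
    male_pct = 100 * mean(vapply(records, `[[`, character(1), "gender") == "M"),
    mean_age = mean(vapply(records, age_at_first_visit, numeric(1))))
}

#' Write simulator ground truth as a JSONL sidecar
#'
#' One line per patient: `patient_id`, latent `states`, `p_label`, `label`.
#'
#' @param ground_truth A `sim_ground_truth`.
#' @param records The matching records (for patient ids).
#' @param path Output path.
#' @export
write_ground_truth <- function(ground_truth, records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(jsonlite::toJSON(list(
      patient_id = records[[i]]$patient_id,
      states = ground_truth$states[[i]],
      p_label = ground_truth$p_label[i],
      label = ground_truth$labels[i]), auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

# --- analytic helpers over generator parameters (used by oracle tests) -----

#' Total-variation distance between two generators' code distributions
#'
#' Mean over latent states of the TV distance between the state-conditional
#' code distributions of two parameter tables.
#'
#' @param params_a,params_b Parameter tables from [simulate_population()]
#'   ground truth.
#' @return Numeric in `[0, 1]`.
#' @export
generator_tv_distance <- function(params_a, params_b) {
  mean(0.5 * rowSums(abs(params_a$state_code_probs - params_b$state_code_probs)))
}

#' Mutual information between latent state and emitted code
#'
#' Computed exactly from the generator's parameter tables under a uniform
#' state distribution (the chain's stationary law for the symmetric default
#' transition matrix). Positive iff codes carry information about the state.
#'
#' @param params Parameter tables.
#' @return Mutual information in nats.
#' @export
generator_state_code_mi <- function(params) {
  P <- params$state_code_probs
  K <- nrow(P)
  marg <- colMeans(P)
  sum((P / K) * log(sweep(P, 2, marg, "/")), na.rm = TRUE)
}

#' Bayes-optimal AUC of the simulated labels
#'
#' The AUC achieved by scoring each patient with its true label-generating
#' probability; exceeds 0.5 whenever `label_effect > 0`.
#'
#' @param ground_truth A `sim_ground_truth`.
#' @return AUC in `[0, 1]`.
#' @export
bayes_optimal_auc <- function(ground_truth) {
  auc(ground_truth$p_label, ground_truth$labels)
}
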