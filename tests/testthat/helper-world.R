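# Shared synthetic worlds and brute-force oracles, built once per run.

.world_cache <- new.env(parent = emptyenv())

split_target <- function(s) strsplit(s, " ")[[1]]

# Small trained world for decoder/decision tests.
tiny_world <- function() {
  if (!is.null(.world_cache$tiny)) return(.world_cache$tiny)
  gt <- make_phone_inventory(6, separation = 4, seed = 101)
  lex <- make_zipf_lexicon(8, gt, min_len = 3, max_len = 4, seed = 102)
  train <- generate_training_trials(lex, n_per_word = 5, seed = 103)
  ms <- suppressWarnings(
    train_for_lexicon(labeled_from_trials(train, gt), lex, n_iter = 3))
  .world_cache$tiny <- list(
    gt = gt, lex = lex, ms = ms,
    tree = compile_cohort_tree(lex, ms),
    pw = build_pseudoword_network(lex))
  .world_cache$tiny
}

# World built around explicit minimal pairs (for noise / speed-accuracy).
pair_world <- function(separation = 4, seed = 131) {
  key <- paste0("pair", separation, "_", seed)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  gt <- make_phone_inventory(6, separation = separation, seed = seed)
  # targ/comp differ in their middle phone (the noise-degradation pair);
  # sha1/sha2 share their first sharing key (first two phones) and split
  # only at the final phone (the cohort-overlap pair)
  lex <- lexicon(c("targ", "comp", "fill1", "fill2", "sha1", "sha2"),
                 c("p01 p03 p02", "p01 p04 p02",
                   "p05 p06 p05", "p02 p06 p01",
                   "p02 p05 p03", "p02 p05 p06"),
                 c(100, 100, 50, 50, 50, 50))
  train <- manual_trials(lex, n_per_word = 10, seed = seed + 1)
  ms <- suppressWarnings(
    train_for_lexicon(labeled_from_trials(train, gt), lex, n_iter = 3))
  .world_cache[[key]] <- list(gt = gt, lex = lex, ms = ms,
                              tree = compile_cohort_tree(lex, ms),
                              pw = build_pseudoword_network(lex))
  .world_cache[[key]]
}

# Balanced word-only trial list over a given lexicon.
manual_trials <- function(lex, n_per_word = 5, seed = 1,
                          dur_range = c(80, 140)) {
  generate_training_trials(lex, n_per_word = n_per_word, seed = seed,
                           dur_range_ms = dur_range)
}

# Full-size study world: 10 phones, 20 words, balanced training.
study_world <- function(seed = 501) {
  key <- paste0("study", seed)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  gt <- make_phone_inventory(10, separation = 4, seed = seed)
  lex <- make_zipf_lexicon(20, gt, min_len = 3, max_len = 5,
                           seed = seed + 1)
  train <- generate_training_trials(lex, n_per_word = 5, seed = seed + 2)
  ms <- suppressWarnings(
    train_for_lexicon(labeled_from_trials(train, gt), lex, n_iter = 5))
  .world_cache[[key]] <- list(gt = gt, lex = lex, ms = ms,
                              tree = compile_cohort_tree(lex, ms),
                              pw = build_pseudoword_network(lex))
  .world_cache[[key]]
}

# Tiny two-word world with hand-built models for oracle comparisons.
oracle_world <- function(seed = 201, d = 4) {
  withr::with_seed(seed, {
    lex <- lexicon(c("wa", "wb"), c("a b", "a c"), c(2, 1))
    keys <- lexicon_keys(lex, context_independent = FALSE)
    models <- lapply(keys, function(k) {
      p <- strsplit(k, "/", fixed = TRUE)[[1]]
      sts <- lapply(1:3, function(s)
        state_model(s, 1, stats::rnorm(d), stats::rexp(d) + 0.3))
      sl <- stats::runif(3, 0.3, 0.7)
      phone_model(p[2], p[1], p[3], sts, sl, 1 - sl)
    })
    names(models) <- keys
    list(lex = lex, ms = model_set(models),
         tree = compile_cohort_tree(lex, model_set(models)))
  })
}

# --- independent oracles -------------------------------------------------

# Direct least-squares regression slope over +-hw frames (replication pad).
oracle_delta <- function(statics, hw = 2) {
  T_ <- nrow(statics)
  out <- matrix(0, T_, ncol(statics))
  for (t in seq_len(T_)) {
    for (j in seq_len(ncol(statics))) {
      ks <- -hw:hw
      y <- statics[pmin(pmax(t + ks, 1), T_), j]
      out[t, j] <- sum(ks * y) / sum(ks^2)
    }
  }
  out
}

# Brute-force Gaussian mixture log density.
oracle_mixture_loglik <- function(weights, means, variances, x) {
  dens <- sum(vapply(seq_along(weights), function(k) {
    weights[k] * prod(stats::dnorm(x, means[k, ], sqrt(variances[k, ])))
  }, numeric(1)))
  log(dens)
}

# All monotone left-to-right state paths over S states for t frames,
# starting in state 1, no skips (increments of 0 or 1).
enumerate_state_paths <- function(S, t) {
  paths <- list(1L)
  for (i in seq_len(t - 1)) {
    paths <- unlist(lapply(paths, function(p) {
      last <- p[length(p)]
      nxt <- if (last < S) list(c(p, last), c(p, last + 1L))
             else list(c(p, last))
      nxt
    }), recursive = FALSE)
  }
  paths
}

# Exhaustive best-path log-likelihood of frames 1..t through a chain of
# phone models, ending in any state of the final phone (used against the
# tree decoder on tiny instances).
oracle_chain_loglik <- function(models, frames, t) {
  S <- 3L * length(models)
  sts <- unlist(lapply(models, function(pm) pm$states), recursive = FALSE)
  lsl <- unlist(lapply(models, function(pm) log(pm$self_loop)))
  ladv <- unlist(lapply(models, function(pm) log(pm$advance)))
  paths <- enumerate_state_paths(S, t)
  best <- -Inf
  lo <- S - 2L
  for (p in paths) {
    if (p[length(p)] < lo) next
    ll <- 0
    for (i in seq_len(t)) ll <- ll + state_loglik(sts[[p[i]]], frames[i, ])
    if (t > 1) {
      for (i in seq_len(t - 1)) {
        ll <- ll + if (p[i + 1] == p[i]) lsl[p[i]] else ladv[p[i]]
      }
    }
    best <- max(best, ll)
  }
  best
}

# O(n^2) substring filter for nested-candidate removal.
oracle_remove_nested <- function(df) {
  toks <- lapply(df$phones, function(s) strsplit(s, " ")[[1]])
  contig <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na >= nb) return(FALSE)
    any(vapply(0:(nb - na), function(s) all(a == b[(s + 1):(s + na)]),
               logical(1)))
  }
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i != j && contig(toks[[i]], toks[[j]]) &&
          df$activation[i] <= df$activation[j]) keep[i] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

# Hand-built activation trace with prescribed values (lm_weight 0 so class
# re-weighting leaves them untouched).
make_trace <- function(values, kinds, phones,
                       orthography = rep(NA_character_, nrow(values))) {
  T_ <- ncol(values)
  ids <- paste0(kinds, ":", ifelse(is.na(orthography), phones, orthography))
  A0 <- sweep(values, 2, seq_len(T_), "*")
  A0[is.na(A0)] <- -Inf
  rownames(A0) <- ids
  tr <- structure(list(
    hypotheses = data.frame(id = ids, kind = kinds, phones = phones,
                            orthography = orthography,
                            stringsAsFactors = FALSE),
    A0 = A0, lm_weight = 0, word_class_prior = 0.5,
    offset_frame = T_, beam = Inf, frame_step_ms = 10),
    class = "activation_trace")
  tr$values <- activation_values(tr)
  tr$alive <- matrix(TRUE, nrow(values), T_)
  tr
}
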