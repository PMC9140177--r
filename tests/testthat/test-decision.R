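test_that("identification fires at the first frame the gap reaches theta", {
  # constructed 2-word trace: the gap grows linearly and first reaches
  # theta = 2 at frame 37
  T_ <- 60
  a <- rep(0, T_)
  b <- -seq_len(T_) * (2 / 37)
  tr <- make_trace(rbind(a, b), c("word", "word"), c("x y", "x z"),
                   c("wa", "wb"))
  r <- decide_identification(tr, decision_config(theta = 2, exec_ms = 200))
  expect_equal(r$label, "wa")
  expect_true(r$decided_before_offset)
  expect_equal(r$decision_ms, 370)
  expect_equal(r$choice_ms, 0)
  expect_equal(r$rt_ms, 570)
  # theta = 0: decides at the first frame with a unique maximum
  r0 <- decide_identification(tr, decision_config(theta = 0))
  expect_equal(r0$decision_ms, 10)
  expect_equal(r0$label, "wa")
})

test_that("undecided-at-offset identification adds the Hick-Hyman choice time", {
  # two words stay equal throughout a 600 ms stimulus
  T_ <- 60
  tr <- make_trace(rbind(rep(-1, T_), rep(-1, T_)),
                   c("word", "word"), c("x y", "x z"), c("wa", "wb"))
  cfg <- decision_config(theta = 0.5, hick_a = 30, hick_b = 100,
                         exec_ms = 200)
  r <- decide_identification(tr, cfg)
  expect_false(r$decided_before_offset)
  expect_equal(r$decision_ms, 600)
  # two equiprobable survivors: H = 1 bit
  expect_equal(r$entropy_bits, 1)
  expect_equal(r$choice_ms, 30 + 100 * 1)
  expect_equal(r$rt_ms, 600 + 130 + 200)
  # ties at crossing break lexicographically by phone string
  expect_equal(r$label, "wa")
})

test_that("rt decomposition is exact for both decision paths", {
  w <- tiny_world()
  sp <- stimulus_spec(split_target(w$lex$phones[1]), TRUE,
                      rep(90, length(split_target(w$lex$phones[1]))),
                      seed = 601)
  X <- extract_features(synthesize_word_waveform(sp, w$gt))
  tr <- compute_activation_traces(X, w$tree, pw = w$pw)
  for (th in c(5, 1e9)) {
    r <- decide_identification(tr, decision_config(theta = th,
                                                   hick_a = 25))
    expect_identical(r$rt_ms, r$decision_ms + r$choice_ms + r$exec_ms)
    expect_equal(r$choice_ms == 0, r$decided_before_offset)
  }
})

test_that("lexical decision crosses theta_ld with the sign fixing the label", {
  T_ <- 60
  word <- c(rep(0, 49), seq(0.5, 5.5, by = 0.5))   # pulls ahead late
  pseudo <- rep(0, T_)
  tr <- make_trace(rbind(word, pseudo), c("word", "pseudo"),
                   c("x y", "x q"), c("wa", NA))
  r <- decide_lexical(tr, decision_config(theta_ld = 2))
  expect_equal(r$label, "word")
  expect_true(r$decided_before_offset)
  expect_equal(r$decision_ms, 530)  # first frame with gap >= 2
  # mirrored trace: pseudo ahead
  tr2 <- make_trace(rbind(pseudo, word), c("word", "pseudo"),
                    c("x y", "x q"), c("wa", NA))
  r2 <- decide_lexical(tr2, decision_config(theta_ld = 2))
  expect_equal(r2$label, "pseudo-word")
  # symmetric traces never reach the threshold: offset path with choice RT
  tr3 <- make_trace(rbind(rep(0.5, T_), rep(0.5, T_)), c("word", "pseudo"),
                    c("x y", "x q"), c("wa", NA))
  r3 <- decide_lexical(tr3, decision_config(theta_ld = 2, hick_a = 10))
  expect_false(r3$decided_before_offset)
  expect_gt(r3$choice_ms, 0)
  expect_equal(r3$label, "word")  # tie resolves to the word side
  expect_error(decide_lexical(make_trace(matrix(0, 1, 5), "word", "x", "wa"),
                              decision_config()), "both word and pseudo")
})

test_that("postponing to offset ignores earlier crossings", {
  T_ <- 40
  word <- c(rep(5, 20), rep(0, 20))  # big early gap, gone by offset
  pseudo <- rep(0, T_)
  tr <- make_trace(rbind(word, pseudo), c("word", "pseudo"),
                   c("x y", "x q"), c("wa", NA))
  early <- decide_lexical(tr, decision_config(theta_ld = 2))
  late <- decide_lexical(tr, decision_config(theta_ld = 2,
                                             postpone_to_offset = TRUE))
  expect_equal(early$decision_ms, 10)
  expect_false(late$decided_before_offset)
  expect_equal(late$decision_ms, 400)
})

test_that("a pseudo-word stimulus is judged pseudo-word", {
  w <- tiny_world()
  trials <- generate_experiment(w$lex, w$gt, n_trials = 6, p_pseudo = 1,
                                seed = 611)
  correct <- 0
  for (i in seq_len(nrow(trials))) {
    sp <- trial_stimulus(trials[i, ])
    X <- extract_features(synthesize_word_waveform(sp, w$gt))
    tr <- compute_activation_traces(X, w$tree, pw = w$pw)
    r <- decide_lexical(tr, decision_config(theta_ld = 60))
    correct <- correct + (r$label == "pseudo-word")
  }
  expect_gte(correct, 5)
})

test_that("choice RT entropy matches direct computation and its bounds", {
  cfg <- decision_config(tau = 1, hick_a = 40, hick_b = 120)
  # single candidate: no uncertainty
  one <- data.frame(activation = -3)
  expect_equal(choice_rt(one, cfg),
               list(entropy_bits = 0, choice_ms = 40))
  # two / four equal activations: 1 and 2 bits
  expect_equal(choice_rt(data.frame(activation = c(-1, -1)),
                         cfg)$entropy_bits, 1)
  expect_equal(choice_rt(data.frame(activation = rep(2, 4)),
                         cfg)$entropy_bits, 2)
  # random sets against explicit normalized exponentials
  withr::with_seed(621, {
    for (rep in 1:20) {
      n <- sample(2:10, 1)
      a <- stats::rnorm(n, sd = 3)
      tau <- stats::runif(1, 0.5, 2)
      cfg2 <- decision_config(tau = tau, hick_a = 0, hick_b = 100)
      p <- exp(a / tau) / sum(exp(a / tau))
      H <- -sum(p * log2(p))
      got <- choice_rt(data.frame(activation = a), cfg2)
      expect_equal(got$entropy_bits, H, tolerance = 1e-12)
      expect_equal(got$choice_ms, 100 * H, tolerance = 1e-10)
      # bounds and shift invariance
      expect_gte(got$entropy_bits, 0)
      expect_lte(got$entropy_bits, log2(n) + 1e-12)
      shifted <- choice_rt(data.frame(activation = a + 17.3), cfg2)
      expect_equal(shifted$entropy_bits, got$entropy_bits,
                   tolerance = 1e-10)
    }
  })
  expect_error(choice_rt(data.frame(activation = numeric()), cfg),
               "empty candidate set")
})

test_that("raising theta trades speed for accuracy on confusable pairs", {
  w <- pair_world(separation = 2.5, seed = 641)
  trials <- manual_trials(w$lex[1:2, ], n_per_word = 8, seed = 642)
  thetas <- c(1, 15, 60, 1e9)
  acc <- numeric(0); rt <- numeric(0)
  per_trial_rt <- matrix(0, nrow(trials), length(thetas))
  for (k in seq_along(thetas)) {
    res <- run_experiment(trials, w$ms, w$lex, task = "identification",
                          decision_cfg = decision_config(theta = thetas[k]),
                          gt = w$gt)
    acc <- c(acc, res$summary$accuracy)
    rt <- c(rt, res$summary$mean_rt_ms)
    per_trial_rt[, k] <- res$records$rt_ms
  }
  expect_true(all(diff(acc) >= 0))
  expect_true(all(diff(rt) >= 0))
  # monotone per trial, not just on average
  expect_true(all(apply(per_trial_rt, 1, function(x) all(diff(x) >= 0))))
  # the extremes actually differ: low theta is fast and error-prone
  expect_gt(rt[length(rt)], rt[1])
})

test_that("segment noise never makes the decision strictly earlier", {
  w <- pair_world()
  durs <- c(100, 120, 100)
  for (rep in 1:5) {
    clean <- stimulus_spec(c("p01", "p03", "p02"), TRUE, durs,
                           seed = 700 + rep)
    noisy <- stimulus_spec(c("p01", "p03", "p02"), TRUE, durs,
                           noise = noise_spec(100, 220, -5),
                           seed = 700 + rep)
    trc <- compute_activation_traces(
      extract_features(synthesize_word_waveform(clean, w$gt)), w$tree)
    trn <- compute_activation_traces(
      extract_features(synthesize_word_waveform(noisy, w$gt)), w$tree)
    rc <- decide_identification(trc, decision_config(theta = 40))
    rn <- decide_identification(trn, decision_config(theta = 40))
    expect_gte(rn$decision_ms, rc$decision_ms)
  }
})

test_that("noise on the discriminating vowel drops and delays activations", {
  w <- pair_world()
  durs <- c(100, 120, 100)
  for (rep in 1:4) {
    clean <- stimulus_spec(c("p01", "p03", "p02"), TRUE, durs,
                           seed = 720 + rep)
    noisy <- stimulus_spec(c("p01", "p03", "p02"), TRUE, durs,
                           noise = noise_spec(100, 220, -5),
                           seed = 720 + rep)
    trc <- compute_activation_traces(
      extract_features(synthesize_word_waveform(clean, w$gt)), w$tree)
    trn <- compute_activation_traces(
      extract_features(synthesize_word_waveform(noisy, w$gt)), w$tree)
    vc <- activation_values(trc); vn <- activation_values(trn)
    it <- which(trc$hypotheses$orthography %in% "targ")
    ic <- which(trc$hypotheses$orthography %in% "comp")
    # identical before the noise can reach any analysis window
    expect_identical(vc[, 1:5], vn[, 1:5])
    # (i) the correct word's activation drops after noise onset
    expect_gt(mean(vc[it, 15:32] - vn[it, 15:32]), 0)
    # (ii) the pair gap shrinks under noise over the discriminating span
    gap_c <- vc[it, 15:32] - vc[ic, 15:32]
    gap_n <- vn[it, 15:32] - vn[ic, 15:32]
    expect_gt(mean(gap_c), mean(gap_n))
    # and a clear separation margin is reached later (or never)
    first_cross <- function(g, margin = 20) {
      i <- which(g >= margin)
      if (length(i)) i[1] else Inf
    }
    expect_gte(first_cross(gap_n), first_cross(gap_c))
  }
})
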