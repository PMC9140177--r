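#' Generate a ground-truth phone inventory
#'
#' Creates a synthetic phone world with known statistics: per-phone
#' three-state emission models over the 39-dimensional feature space whose
#' state means lie at pairwise distances controlled by `separation`, plus
#' matching stationary log-Mel spectral profiles used to synthesize audio.
#' With `separation = 0` all phones are statistically identical. The same
#' seed always yields identical parameters.
#'
#' The spectral profile of each phone is a smooth random curve over the Mel
#' bands scaled by `separation`; the emission means of its states are the
#' DCT cepstra of that profile (so features extracted from synthesized audio
#' land near the generating means), with derivative components at zero.
#'
#' @param n_phones Number of phones (>= 2); labels are `p01`, `p02`, ...
#' @param separation Distance scale (>= 0) between phone spectra.
#' @param seed Integer seed.
#' @param rate Sampling rate of synthesized audio in Hz.
#' @param static_var,delta_var Emission variances for static and derivative
#'   components.
#' @param n_mel Number of Mel bands of the profiles (matches the front end).
#' @return An object of class `ground_truth`: list with `model_set`
#'   (context-independent `*/p/*` models), `profiles` (`n_mel x n_phones`
#'   log-power matrix), `phones`, `rate`, `seed`.
#' @export
make_phone_inventory <- function(n_phones, separation = 4, seed = 1,
                                 rate = 16000, static_var = 1,
                                 delta_var = 0.1, n_mel = 26) {
  if (n_phones < 2) stop("need at least 2 phones")
  if (separation < 0) stop("separation must be >= 0")
  phones <- sprintf("p%02d", seq_len(n_phones))
  prof <- with_local_seed(seed, {
    raw <- matrix(stats::rnorm(n_mel * n_phones), n_mel, n_phones)
    # smooth over neighbouring bands so profiles look like spectra
    sm <- apply(raw, 2, function(v) stats::filter(c(v[1], v, v[n_mel]),
                                                  rep(1 / 3, 3))[2:(n_mel + 1)])
    sm <- apply(sm, 2, function(v) v / stats::sd(v))
    sm * separation
  })
  B <- dct_basis(13, n_mel)
  models <- list()
  for (j in seq_len(n_phones)) {
    mu <- c(drop(B %*% prof[, j]), rep(0, 26))
    v <- c(rep(static_var, 13), rep(delta_var, 26))
    states <- lapply(1:3, function(s)
      state_model((j - 1L) * 3L + s, 1, mu, v))
    models[[model_key("*", phones[j], "*")]] <-
      phone_model(phones[j], "*", "*", states)
  }
  structure(list(model_set = model_set(models), profiles = prof,
                 phones = phones, rate = rate, seed = seed,
                 separation = separation, n_mel = n_mel),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d phones, separation %g, %d Hz>\n",
              length(x$phones), x$separation, x$rate))
  invisible(x)
}

#' Specify a synthetic stimulus
#'
#' @param target Character vector of phones (the stimulus phone string).
#' @param is_word Whether the string is a lexical entry.
#' @param durations_ms Positive per-phone durations in ms.
#' @param noise Optional [noise_spec()].
#' @param seed Integer seed controlling the stimulus noise excitation.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(target, is_word, durations_ms, noise = NULL,
                          seed = 1) {
  if (length(durations_ms) != length(target)) {
    stop("need one duration per phone")
  }
  if (any(durations_ms <= 0)) stop("durations must be positive")
  structure(list(target = target, is_word = is_word,
                 durations_ms = durations_ms, noise = noise, seed = seed),
            class = "stimulus_spec")
}

# Noise-excited stationary segment shaped by a log-Mel profile.
shaped_noise <- function(n, profile, rate, n_mel, seed_offset = 0) {
  n_bins <- n %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * rate / n
  centers <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2),
                           length.out = n_mel + 2))[2:(n_mel + 1)]
  lp <- stats::approx(centers, profile, xout = freqs, rule = 2)$y
  H <- exp(lp / 2)  # log power -> amplitude
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  Hfull <- c(H, rev(H[2:(n - n_bins + 1)]))
  x <- Re(stats::fft(Z * Hfull, inverse = TRUE)) / n
  x / stats::sd(x) * 0.1
}

#' Synthesize the waveform of a stimulus
#'
#' Concatenates per-phone noise-excited segments shaped by the inventory's
#' stationary spectral profiles; total duration is the sum of the requested
#' per-phone durations. Segment-localized noise, if specified, is then
#' superimposed.
#'
#' @param spec A [stimulus_spec()].
#' @param gt A [make_phone_inventory()] ground truth.
#' @return A [waveform()].
#' @export
synthesize_word_waveform <- function(spec, gt) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(gt, "ground_truth"))
  unknown <- setdiff(spec$target, gt$phones)
  if (length(unknown)) {
    stop("unknown phone(s): ", paste(unknown, collapse = ", "))
  }
  segs <- with_local_seed(spec$seed, {
    lapply(seq_along(spec$target), function(i) {
      n <- round(spec$durations_ms[i] * gt$rate / 1000)
      shaped_noise(n, gt$profiles[, match(spec$target[i], gt$phones)],
                   gt$rate, gt$n_mel)
    })
  })
  w <- waveform(unlist(segs), gt$rate)
  if (!is.null(spec$noise)) {
    w <- add_segment_noise(w, spec$noise, spec$seed + 7919L)
  }
  w
}

#' Frame-level segmentation of a synthetic stimulus
#'
#' Converts the known per-phone durations into inclusive frame-index
#' segments (10 ms frames) with context-dependent labels, as needed for
#' [init_models()] / [train_models()].
#'
#' @param spec A [stimulus_spec()].
#' @param step_ms Frame step of the front end.
#' @param context_independent If `TRUE`, label segments with wildcard
#'   contexts (for context-independent training).
#' @return A data.frame with columns `left`, `phone`, `right`, `start`,
#'   `end`.
#' @export
stimulus_segments <- function(spec, step_ms = 10,
                              context_independent = FALSE) {
  bounds <- round(cumsum(c(0, spec$durations_ms)) / step_ms)
  n <- length(spec$target)
  data.frame(
    left = if (context_independent) rep("*", n)
           else c(BOUNDARY, spec$target[-n]),
    phone = spec$target,
    right = if (context_independent) rep("*", n)
            else c(spec$target[-1], BOUNDARY),
    start = bounds[-(n + 1)] + 1L,
    end = pmax(bounds[-1], bounds[-(n + 1)] + 1L),
    stringsAsFactors = FALSE)
}

#' Sample a labeled feature token from ground-truth models
#'
#' Draws frames from a phone model's state emission densities, with state
#' durations governed by the self-loop probabilities (each state emits at
#' least one frame).
#'
#' @param pm A [phone_model()].
#' @param seed Integer seed.
#' @param min_frames Minimum total frames (states re-sampled until reached).
#' @return A list with `frames` (matrix) and `path` (state index per frame).
#' @export
sample_phone_token <- function(pm, seed, min_frames = 3) {
  with_local_seed(seed, {
    repeat {
      lens <- 1 + stats::rgeom(3, prob = pm$advance)
      if (sum(lens) >= min_frames) break
    }
    path <- rep(1:3, lens)
    d <- ncol(pm$states[[1]]$means)
    frames <- t(vapply(path, function(s) {
      st <- pm$states[[s]]
      k <- sample.int(length(st$weights), 1, prob = st$weights)
      stats::rnorm(d, st$means[k, ], sqrt(st$variances[k, ]))
    }, numeric(d)))
    list(frames = frames, path = path)
  })
}

#' Generate a Zipf-frequency lexicon of random phone strings
#'
#' Draws `n_words` unique phone strings with lengths uniform in
#' `[min_len, max_len]` and assigns token frequencies proportional to
#' `rank^(-zipf_s)` (all equal when `zipf_s = 0`). By default immediately
#' repeated phones are avoided, mirroring the cross-linguistic dispreference
#' for identical adjacent segments within a word (a repeated stationary
#' segment would also be acoustically indistinguishable from a single long
#' one).
#'
#' @param n_words Number of entries.
#' @param inventory A `ground_truth` or a character vector of phones.
#' @param min_len,max_len Word length bounds in phones.
#' @param zipf_s Zipf exponent (>= 0).
#' @param seed Integer seed.
#' @param allow_repeats Permit identical adjacent phones.
#' @param allow_nested Permit one word's phone string to be a contiguous
#'   substring of another's. Off by default: the synthetic world's
#'   stationary phones carry no word-boundary cues, so embedded words would
#'   be indistinguishable from their hosts by construction.
#' @return A [lexicon()] with orthographies `w001`, `w002`, ...
#' @export
make_zipf_lexicon <- function(n_words, inventory, min_len = 3, max_len = 5,
                              zipf_s = 1, seed = 1, allow_repeats = FALSE,
                              allow_nested = FALSE) {
  phones <- if (inherits(inventory, "ground_truth")) inventory$phones
            else as.character(inventory)
  k <- length(phones)
  n_avail <- if (allow_repeats) sum(k^(min_len:max_len))
             else sum(k * (k - 1)^(min_len:max_len - 1))
  if (n_words > n_avail) {
    stop("n_words = ", n_words, " exceeds the ", n_avail,
         " distinct strings available")
  }
  strings <- with_local_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n_words) {
      tries <- tries + 1L
      if (tries > 1000L * n_words) {
        stop("could not draw ", n_words, " distinct word strings ",
             "under the nesting/repetition constraints")
      }
      len <- sample(min_len:max_len, 1)
      ph <- character(len)
      ph[1] <- sample(phones, 1)
      for (j in seq_len(len - 1) + 1) {
        pool <- if (allow_repeats) phones else setdiff(phones, ph[j - 1])
        ph[j] <- sample(pool, 1)
      }
      s <- paste(ph, collapse = " ")
      clash <- s %in% out
      if (!clash && !allow_nested && length(out)) {
        toks <- lapply(out, split_phones)
        clash <- any(vapply(toks, function(o)
          is_contig_subseq(ph, o) || is_contig_subseq(o, ph), logical(1)))
      }
      if (!clash) out <- c(out, s)
    }
    out
  })
  freq <- round(1000 * seq_len(n_words)^(-zipf_s))
  freq <- pmax(freq, 1)
  lexicon(sprintf("w%03d", seq_len(n_words)), strings, freq)
}

#' Generate a recognition / lexical-decision trial list
#'
#' Emulates a psycholinguistic experiment design: each trial is a word
#' (drawn uniformly from the lexicon) or a pseudo-word (a phonotactically
#' licensed random walk through the lexicon's phone-pair network, never
#' equal to an entry) with probability `p_pseudo` — 0.5 for the balanced
#' design. Per-phone durations are drawn uniformly from `dur_range_ms`.
#'
#' @param lex A [lexicon()].
#' @param gt A `ground_truth` inventory.
#' @param n_trials Number of trials.
#' @param p_pseudo Probability that a trial is a pseudo-word, in `[0, 1]`.
#' @param noise Optional [noise_spec()] template; `start_ms`/`end_ms` are
#'   interpreted relative to each stimulus and clipped to its duration.
#' @param seed Integer seed; the whole trial list is reproducible.
#' @param dur_range_ms Per-phone duration range in ms.
#' @return A data.frame of class `trial_list` with columns `stimulus_id`,
#'   `phones`, `is_word`, `orthography`, `durations_ms` (comma-joined),
#'   `snr_db`, `noise_start_ms`, `noise_end_ms`, `seed`.
#' @export
generate_experiment <- function(lex, gt, n_trials, p_pseudo = 0.5,
                                noise = NULL, seed = 1,
                                dur_range_ms = c(60, 160)) {
  if (p_pseudo < 0 || p_pseudo > 1) stop("p_pseudo must be in [0, 1]")
  pw <- build_pseudoword_network(lex)
  if (p_pseudo > 0 && nrow(pw$edges) == 0 && max(lengths(
        lapply(lex$phones, split_phones))) > 1) {
    stop("cannot draw pseudo-words from an empty licensing network")
  }
  lens <- lengths(lapply(lex$phones, split_phones))
  with_local_seed(seed, {
    rows <- lapply(seq_len(n_trials), function(i) {
      is_pseudo <- stats::runif(1) < p_pseudo
      if (is_pseudo) {
        ph <- draw_pseudo_string(pw, min(lens), max(lens))
      } else {
        e <- sample.int(nrow(lex), 1)
        ph <- split_phones(lex$phones[e])
      }
      durs <- round(stats::runif(length(ph), dur_range_ms[1],
                                 dur_range_ms[2]))
      total <- sum(durs)
      ns <- nn <- ne <- NA_real_
      if (!is.null(noise)) {
        ns <- min(noise$start_ms, total - 1)
        ne <- min(noise$end_ms, total)
        nn <- noise$snr_db
      }
      orth <- if (is_pseudo) NA_character_
              else lex$orthography[match(paste(ph, collapse = " "),
                                         lex$phones)]
      data.frame(stimulus_id = sprintf("s%04d", i),
                 phones = paste(ph, collapse = " "),
                 is_word = !is_pseudo, orthography = orth,
                 durations_ms = paste(durs, collapse = ","),
                 snr_db = nn, noise_start_ms = ns, noise_end_ms = ne,
                 seed = sample.int(.Machine$integer.max %/% 2, 1),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("trial_list", "data.frame")
    out
  })
}

#' Generate a balanced training trial list
#'
#' Cycles through the lexicon so that every word receives exactly
#' `n_per_word` tokens — unlike [generate_experiment()], which samples
#' words at random and may miss rare ones. Intended for acoustic-model
#' training, which needs every sharing key attested.
#'
#' @param lex A [lexicon()].
#' @param n_per_word Tokens per word.
#' @param seed Integer seed.
#' @param dur_range_ms Per-phone duration range in ms.
#' @return A trial-list data.frame (same schema as [generate_experiment()]).
#' @export
generate_training_trials <- function(lex, n_per_word = 5, seed = 1,
                                     dur_range_ms = c(60, 160)) {
  with_local_seed(seed, {
    rows <- lapply(seq_len(n_per_word * nrow(lex)), function(i) {
      e <- ((i - 1L) %% nrow(lex)) + 1L
      ph <- split_phones(lex$phones[e])
      durs <- round(stats::runif(length(ph), dur_range_ms[1],
                                 dur_range_ms[2]))
      data.frame(stimulus_id = sprintf("tr%04d", i),
                 phones = lex$phones[e], is_word = TRUE,
                 orthography = lex$orthography[e],
                 durations_ms = paste(durs, collapse = ","),
                 snr_db = NA_real_, noise_start_ms = NA_real_,
                 noise_end_ms = NA_real_,
                 seed = sample.int(.Machine$integer.max %/% 2, 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# Rejection-sample a licensed phone string absent from the lexicon.
draw_pseudo_string <- function(pw, min_len, max_len, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    len <- sample(min_len:max_len, 1)
    ph <- character(len)
    ph[1] <- sample(pw$starts, 1)
    ok <- TRUE
    if (len > 1) {
      for (j in 2:len) {
        nxt <- pw$edges[pw$edges[, 1] == ph[j - 1], 2]
        if (!length(nxt)) { ok <- FALSE; break }
        ph[j] <- sample(c(nxt), 1)
      }
    }
    if (ok && pw_licensed(pw, ph) && !pw_is_lexical(pw, ph)) return(ph)
  }
  stop("could not draw a licensed pseudo-word (network too sparse)")
}

#' Reconstruct the stimulus spec of a trial row
#'
#' @param trial One row of a [generate_experiment()] trial list.
#' @return A [stimulus_spec()].
#' @export
trial_stimulus <- function(trial) {
  durs <- as.numeric(strsplit(trial$durations_ms, ",")[[1]])
  ns <- if (!is.na(trial$snr_db)) {
    noise_spec(trial$noise_start_ms, trial$noise_end_ms, trial$snr_db)
  } else NULL
  stimulus_spec(split_phones(trial$phones), trial$is_word, durs,
                noise = ns, seed = trial$seed)
}

#' Write stimulus WAVs and a trial manifest
#'
#' @param trials A [generate_experiment()] trial list.
#' @param gt The `ground_truth` inventory.
#' @param dir Output directory (created if needed).
#' @return The manifest CSV path, invisibly.
#' @export
write_stimuli <- function(trials, gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials$wav <- file.path(dir, paste0(trials$stimulus_id, ".wav"))
  for (i in seq_len(nrow(trials))) {
    w <- synthesize_word_waveform(trial_stimulus(trials[i, ]), gt)
    write_wav(w, trials$wav[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(as.data.frame(trials), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Build a labeled training set from synthetic trials
#'
#' Synthesizes each trial's waveform, extracts features, and attaches the
#' known frame segmentation with both context-dependent and
#' context-independent labels (each phone segment appears once per labeling
#' so that both model families can be trained from the same data).
#'
#' @param trials A trial list (rows of [generate_experiment()]).
#' @param gt The `ground_truth` inventory.
#' @param context_independent Include wildcard-context segment labels too.
#' @return A labeled token list as expected by [init_models()].
#' @export
labeled_from_trials <- function(trials, gt, context_independent = TRUE) {
  lapply(seq_len(nrow(trials)), function(i) {
    spec <- trial_stimulus(trials[i, ])
    ft <- extract_features(synthesize_word_waveform(spec, gt))
    seg <- stimulus_segments(spec)
    seg$end <- pmin(seg$end, n_frames(ft))
    if (context_independent) {
      ci <- stimulus_segments(spec, context_independent = TRUE)
      ci$end <- pmin(ci$end, n_frames(ft))
      seg <- rbind(seg, ci)
    }
    list(features = ft, segments = seg)
  })
}
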