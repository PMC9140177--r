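#' Train phone models for a lexicon from labeled synthetic trials
#'
#' Convenience wrapper: collects the lexicon's context-dependent sharing
#' keys plus one context-independent key per phone, flat-start initializes
#' and EM-trains them on the labeled set.
#'
#' @param labeled Labeled token list (see [init_models()]).
#' @param lex A [lexicon()].
#' @param n_iter EM iterations.
#' @return A trained [model_set()].
#' @export
train_for_lexicon <- function(labeled, lex, n_iter = 5) {
  keys <- lexicon_keys(lex, context_independent = TRUE)
  ms <- init_models(keys, labeled)
  train_models(ms, labeled, n_iter = n_iter)
}

#' Run a recognition or lexical-decision experiment
#'
#' Decodes every trial of a manifest and applies the task's decision rule.
#' Inputs may be in-memory objects or file paths (manifest CSV from
#' [write_stimuli()], model-set JSON, lexicon TSV). When trial waveforms
#' are not on disk (no `wav` column), stimuli are re-synthesized from the
#' trial specs, which requires `gt`.
#'
#' @param manifest A trial list data.frame or path to a manifest CSV.
#' @param models A [model_set()] or path to its JSON.
#' @param lex A [lexicon()] or path to its TSV.
#' @param task `"identification"` or `"lexical_decision"`.
#' @param decoder_cfg A [decoder_config()].
#' @param decision_cfg A [decision_config()].
#' @param lm Optional `language_model` (default: unigram from `lex`).
#' @param gt Optional `ground_truth` for re-synthesis.
#' @return An object of class `experiment_result`: `records` (one row per
#'   trial: response joined with trial truth and a `correct` flag) and
#'   `summary` (accuracy and RT summaries overall).
#' @export
run_experiment <- function(manifest, models, lex,
                           task = c("identification", "lexical_decision"),
                           decoder_cfg = decoder_config(),
                           decision_cfg = decision_config(),
                           lm = NULL, gt = NULL) {
  task <- match.arg(task)
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  req <- c("stimulus_id", "phones", "is_word", "durations_ms", "seed")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (is.character(models)) models <- read_model_set(models)
  if (is.character(lex)) lex <- read_lexicon(lex)
  if (is.null(lm)) lm <- lm_unigram(lex)
  tree <- compile_cohort_tree(lex, models)
  pw <- if (task == "lexical_decision") build_pseudoword_network(lex)
        else NULL
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    trial <- manifest[i, ]
    w <- if (!is.null(trial$wav) && !is.na(trial$wav) &&
             file.exists(trial$wav)) {
      read_wav(trial$wav)
    } else {
      if (is.null(gt)) stop("trial ", trial$stimulus_id,
                            " has no wav file and no ground truth given")
      synthesize_word_waveform(trial_stimulus(trial), gt)
    }
    ft <- extract_features(w)
    tr <- compute_activation_traces(ft, tree, pw = pw, lm = lm,
                                    cfg = decoder_cfg)
    resp <- if (task == "identification") {
      decide_identification(tr, decision_cfg)
    } else {
      decide_lexical(tr, decision_cfg)
    }
    truth <- if (task == "identification") trial$orthography
             else if (trial$is_word) "word" else "pseudo-word"
    cbind(data.frame(stimulus_id = trial$stimulus_id,
                     phones = trial$phones, is_word = trial$is_word,
                     truth = truth, stringsAsFactors = FALSE),
          as.data.frame(resp),
          data.frame(correct = identical(resp$label, truth)))
  })
  records <- do.call(rbind, rows)
  summary <- data.frame(
    task = task,
    n_trials = nrow(records),
    accuracy = mean(records$correct),
    mean_rt_ms = mean(records$rt_ms),
    median_rt_ms = stats::median(records$rt_ms),
    prop_decided_before_offset = mean(records$decided_before_offset))
  structure(list(records = records, summary = summary),
            class = "experiment_result")
}

#' @export
format.experiment_result <- function(x, ...) {
  s <- x$summary
  sprintf("<experiment_result: %s, %d trials, accuracy %.3f, mean RT %.1f ms>",
          s$task, s$n_trials, s$accuracy, s$mean_rt_ms)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' @export
summary.experiment_result <- function(object, ...) {
  print(object$summary, row.names = FALSE)
  invisible(object$summary)
}

#' Write experiment results to CSV
#'
#' Writes `records.csv` (per-trial responses joined with truth) and
#' `summary.csv` under `dir`, with floating values at fixed 6-digit
#' precision and a declared column order.
#'
#' @param res An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fixed <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    df
  }
  cols <- c("stimulus_id", "task", "label", "truth", "correct",
            "decided_before_offset", "decision_ms", "choice_ms", "exec_ms",
            "rt_ms", "entropy_bits", "phones", "is_word")
  rec_path <- file.path(dir, "records.csv")
  sum_path <- file.path(dir, "summary.csv")
  utils::write.csv(fixed(res$records[, cols]), rec_path, row.names = FALSE)
  utils::write.csv(fixed(res$summary), sum_path, row.names = FALSE)
  invisible(c(records = rec_path, summary = sum_path))
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the package functions, used by the
#' `inst/scripts/cohortsim` Rscript. Subcommands: `simulate` (generate a
#' synthetic world, train, run a task end to end), `train`, `recognize`,
#' `lexdec`, `trace-export`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cohortsim <simulate|train|recognize|lexdec|trace-export> [options]",
    "  common options: --seed INT --out-dir DIR --theta X --theta-ld X",
    "                  --lm-weight X --beam X --exec-ms X --config FILE",
    "  simulate:  --n-phones INT --n-words INT --n-trials INT --task NAME",
    "  train:     --manifest CSV --lexicon TSV --n-iter INT",
    "  recognize/lexdec: --manifest CSV --models JSON --lexicon TSV",
    "  trace-export: --wav FILE --models JSON --lexicon TSV",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(seed = 1, `out-dir` = ".", theta = 1, `theta-ld` = 1,
              `lm-weight` = 1, beam = Inf, `exec-ms` = 200,
              `n-phones` = 10, `n-words` = 20, `n-trials` = 100,
              `n-iter` = 5, task = "identification",
              manifest = NULL, models = NULL, lexicon = NULL, wav = NULL,
              config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option --", key, "\n", usage)
    val <- args[i + 1]
    opt[[key]] <- if (key %in% c("manifest", "models", "lexicon", "wav",
                                 "task", "config", "out-dir")) val
                  else as.numeric(val)
    i <- i + 2
  }
  if (!is.null(opt$config)) {
    cfg <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
    for (k in names(cfg)) if (k %in% names(opt)) opt[[k]] <- cfg[[k]]
  }
  dcfg <- decoder_config(lm_weight = opt$`lm-weight`, beam = opt$beam)
  ecfg <- decision_config(theta = opt$theta, theta_ld = opt$`theta-ld`,
                          exec_ms = opt$`exec-ms`)
  dir.create(opt$`out-dir`, showWarnings = FALSE, recursive = TRUE)
  message("resolved options: ",
          paste(names(opt), vapply(opt, function(x)
            paste(format(x), collapse = ","), character(1)),
            sep = "=", collapse = " "))
  if (cmd == "simulate") {
    gt <- make_phone_inventory(opt$`n-phones`, seed = opt$seed)
    lex <- make_zipf_lexicon(opt$`n-words`, gt, seed = opt$seed + 1)
    train <- generate_training_trials(lex, n_per_word = 5,
                                      seed = opt$seed + 2)
    ms <- train_for_lexicon(labeled_from_trials(train, gt), lex,
                            n_iter = opt$`n-iter`)
    trials <- generate_experiment(
      lex, gt, n_trials = opt$`n-trials`,
      p_pseudo = if (opt$task == "lexical_decision") 0.5 else 0,
      seed = opt$seed + 3)
    res <- run_experiment(trials, ms, lex, task = opt$task,
                          decoder_cfg = dcfg, decision_cfg = ecfg, gt = gt)
    write_results(res, opt$`out-dir`)
    message(format(res))
  } else if (cmd == "train") {
    stop("train requires synthetic manifests with ground truth; ",
         "use simulate, or train_for_lexicon() from R")
  } else if (cmd %in% c("recognize", "lexdec")) {
    res <- run_experiment(opt$manifest, opt$models, opt$lexicon,
                          task = if (cmd == "lexdec") "lexical_decision"
                                 else "identification",
                          decoder_cfg = dcfg, decision_cfg = ecfg)
    write_results(res, opt$`out-dir`)
    message(format(res))
  } else if (cmd == "trace-export") {
    ms <- read_model_set(opt$models)
    lex <- read_lexicon(opt$lexicon)
    tree <- compile_cohort_tree(lex, ms)
    ft <- extract_features(read_wav(opt$wav))
    tr <- compute_activation_traces(ft, tree,
                                    pw = build_pseudoword_network(lex),
                                    cfg = dcfg)
    write_trace_csv(tr, file.path(opt$`out-dir`, "trace.csv"))
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
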