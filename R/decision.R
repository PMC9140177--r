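#' Decision-rule configuration
#'
#' Parameters of the decision component. `theta` and `theta_ld` are the
#' activation-gap thresholds of identification and lexical decision; larger
#' values demand more evidence before responding (the speed-accuracy
#' trade-off). The Hick-Hyman constants `hick_a`/`hick_b` and the softmax
#' temperature `tau` govern the entropy-based choice component added when no
#' threshold decision is reached by stimulus offset; they are fit-to-data
#' parameters and the defaults are placeholders.
#'
#' @param theta Identification gap threshold (activation units, >= 0).
#' @param theta_ld Lexical-decision gap threshold (activation units, >= 0).
#' @param tau Softmax temperature (activation units, > 0).
#' @param hick_a Choice-RT intercept in ms.
#' @param hick_b Choice-RT slope in ms per bit (>= 0).
#' @param exec_ms Constant execution latency in ms.
#' @param word_class_prior Probability mass of the word class (0.5 in a
#'   balanced lexical decision design).
#' @param postpone_to_offset If `TRUE`, lexical decisions are evaluated only
#'   at stimulus offset (the strategy listeners adopt when stimuli turn
#'   non-word only at their final segments).
#' @return A list of class `decision_config`.
#' @export
decision_config <- function(theta = 1, theta_ld = 1, tau = 1,
                            hick_a = 0, hick_b = 100, exec_ms = 200,
                            word_class_prior = 0.5,
                            postpone_to_offset = FALSE) {
  if (theta < 0 || theta_ld < 0) stop("thresholds must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (hick_b < 0) stop("hick_b must be >= 0")
  if (exec_ms < 0) stop("exec_ms must be >= 0")
  if (word_class_prior < 0 || word_class_prior > 1) {
    stop("word_class_prior must be in [0, 1]")
  }
  structure(list(theta = theta, theta_ld = theta_ld, tau = tau,
                 hick_a = hick_a, hick_b = hick_b, exec_ms = exec_ms,
                 word_class_prior = word_class_prior,
                 postpone_to_offset = postpone_to_offset),
            class = "decision_config")
}

response <- function(task, label, decided_before_offset, decision_ms,
                     choice_ms, exec_ms, entropy_bits = NA_real_) {
  structure(list(task = task, label = label,
                 decided_before_offset = decided_before_offset,
                 decision_ms = decision_ms, choice_ms = choice_ms,
                 exec_ms = exec_ms,
                 rt_ms = decision_ms + choice_ms + exec_ms,
                 entropy_bits = entropy_bits),
            class = "response")
}

#' @export
print.response <- function(x, ...) {
  cat(sprintf(
    "<response: %s -> %s at %g ms (%s)%s; rt %g ms>\n",
    x$task, x$label, x$decision_ms,
    if (x$decided_before_offset) "before offset" else "at offset",
    if (x$choice_ms > 0) sprintf(" + choice %g ms (H = %.3f bits)",
                                 x$choice_ms, x$entropy_bits) else "",
    x$rt_ms))
  invisible(x)
}

#' @export
as.data.frame.response <- function(x, ...) {
  data.frame(task = x$task, label = x$label,
             decided_before_offset = x$decided_before_offset,
             decision_ms = x$decision_ms, choice_ms = x$choice_ms,
             exec_ms = x$exec_ms, rt_ms = x$rt_ms,
             entropy_bits = x$entropy_bits, stringsAsFactors = FALSE)
}

# Candidate table at frame t: alive hypotheses with defined activations.
candidates_at <- function(tr, t, values) {
  ok <- tr$alive[, t] & !is.na(values[, t])
  data.frame(id = tr$hypotheses$id[ok],
             kind = tr$hypotheses$kind[ok],
             phones = tr$hypotheses$phones[ok],
             orthography = tr$hypotheses$orthography[ok],
             activation = values[ok, t],
             stringsAsFactors = FALSE)
}

# Order by activation (desc), ties broken lexicographically by phone string.
order_candidates <- function(df) {
  df[order(-df$activation, df$phones), , drop = FALSE]
}

#' Hick-Hyman choice reaction time of a candidate set
#'
#' Activations are converted to choice probabilities by a softmax at
#' temperature `tau`; the entropy `H = -sum p log2 p` of that distribution
#' gives the choice time `hick_a + hick_b * H`. Nested variants must already
#' have been removed.
#'
#' @param candidates A data.frame with an `activation` column (one row per
#'   competing candidate).
#' @param cfg A [decision_config()].
#' @return A list with `entropy_bits` and `choice_ms`.
#' @export
choice_rt <- function(candidates, cfg = decision_config()) {
  a <- candidates$activation
  if (!length(a)) stop("empty candidate set")
  z <- a / cfg$tau
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  list(entropy_bits = h, choice_ms = cfg$hick_a + cfg$hick_b * h)
}

offset_response <- function(task, label, tr, cands, cfg) {
  ch <- choice_rt(cands, cfg)
  response(task, label, FALSE,
           decision_ms = tr$offset_frame * tr$frame_step_ms,
           choice_ms = ch$choice_ms, exec_ms = cfg$exec_ms,
           entropy_bits = ch$entropy_bits)
}

#' Word identification decision over an activation trace
#'
#' At each frame (candidates filtered by [remove_nested()]), the best word
#' hypothesis is selected as soon as its activation exceeds the second-best
#' word's by at least `theta`. If no frame reaches the threshold by stimulus
#' offset, the highest-activation candidate at offset is selected and a
#' Hick-Hyman choice component is added to the reaction time. The constant
#' execution latency is always added.
#'
#' @param tr An `activation_trace` containing word hypotheses.
#' @param cfg A [decision_config()].
#' @return A `response` object.
#' @export
decide_identification <- function(tr, cfg = decision_config()) {
  stopifnot(inherits(tr, "activation_trace"))
  values <- activation_values(tr, cfg$word_class_prior)
  T_ <- tr$offset_frame
  for (t in seq_len(T_)) {
    cands <- candidates_at(tr, t, values)
    if (!nrow(cands)) next
    cands <- remove_nested(cands)
    words <- order_candidates(cands[cands$kind == "word", , drop = FALSE])
    if (!nrow(words)) next
    gap <- if (nrow(words) >= 2) {
      words$activation[1] - words$activation[2]
    } else Inf
    if (gap >= cfg$theta) {
      return(response("identification", words$orthography[1], TRUE,
                      decision_ms = t * tr$frame_step_ms,
                      choice_ms = 0, exec_ms = cfg$exec_ms))
    }
  }
  cands <- remove_nested(candidates_at(tr, T_, values))
  if (!nrow(cands)) stop("empty candidate set at offset")
  cands <- order_candidates(cands)
  label <- if (!is.na(cands$orthography[1])) cands$orthography[1]
           else cands$phones[1]
  offset_response("identification", label, tr, cands, cfg)
}

#' Lexical decision over an activation trace
#'
#' Tracks the signed activation gap between the best word and the best
#' pseudo-word hypothesis; once its magnitude reaches `theta_ld` the
#' lexicality label follows the sign (word ahead: "word"; pseudo ahead:
#' "pseudo-word"). If the threshold is not reached by offset, the label is
#' decided by the offset comparison and a Hick-Hyman choice component is
#' added over the nested-removed surviving candidates. Class priors enter
#' the activations through `word_class_prior`.
#'
#' @param tr An `activation_trace` with at least one word-kind and one
#'   pseudo-kind hypothesis.
#' @param cfg A [decision_config()].
#' @return A `response` with label `"word"` or `"pseudo-word"`.
#' @export
decide_lexical <- function(tr, cfg = decision_config()) {
  stopifnot(inherits(tr, "activation_trace"))
  kinds <- tr$hypotheses$kind
  if (!any(kinds == "word") || !any(kinds == "pseudo")) {
    stop("lexical decision needs both word and pseudo hypotheses")
  }
  values <- activation_values(tr, cfg$word_class_prior)
  T_ <- tr$offset_frame
  gap_at <- function(t) {
    cands <- candidates_at(tr, t, values)
    bw <- suppressWarnings(max(cands$activation[cands$kind == "word"]))
    bp <- suppressWarnings(max(cands$activation[cands$kind == "pseudo"]))
    if (!is.finite(bw) || !is.finite(bp)) return(NA_real_)
    bw - bp
  }
  frames <- if (cfg$postpone_to_offset) T_ else seq_len(T_)
  for (t in frames) {
    g <- gap_at(t)
    if (!is.na(g) && abs(g) >= cfg$theta_ld) {
      return(response("lexical_decision",
                      if (g > 0) "word" else "pseudo-word", TRUE,
                      decision_ms = t * tr$frame_step_ms,
                      choice_ms = 0, exec_ms = cfg$exec_ms))
    }
  }
  g <- gap_at(T_)
  label <- if (is.na(g) || g >= 0) "word" else "pseudo-word"
  cands <- remove_nested(candidates_at(tr, T_, values))
  if (!nrow(cands)) stop("empty candidate set at offset")
  offset_response("lexical_decision", label, tr, cands, cfg)
}
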