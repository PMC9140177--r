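#' Decoder configuration
#'
#' @param lm_weight Top-down scale \eqn{\lambda} (dimensionless, >= 0)
#'   applied to log priors before combining with bottom-up log-likelihood.
#' @param beam Pruning threshold in activation units (> 0; `Inf` disables
#'   pruning): hypotheses whose activation falls more than `beam` below the
#'   current best are discarded and never revived.
#' @param max_pseudo_len Maximum pseudo-word length in phones.
#' @param word_class_prior Probability mass of the word class (pseudo-words
#'   get the remainder); used for the exported activation values and as the
#'   default for decisions.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(lm_weight = 1, beam = Inf, max_pseudo_len = 8,
                           word_class_prior = 0.5) {
  if (beam <= 0) stop("beam must be > 0")
  if (lm_weight < 0) stop("lm_weight must be >= 0")
  if (word_class_prior < 0 || word_class_prior > 1) {
    stop("word_class_prior must be in [0, 1]")
  }
  structure(list(lm_weight = lm_weight, beam = beam,
                 max_pseudo_len = max_pseudo_len,
                 word_class_prior = word_class_prior),
            class = "decoder_config")
}

# Node-id chain of each lexicon entry through the tree (ordered by depth).
entry_chains <- function(tree) {
  chains <- rep(list(integer()), nrow(tree$lexicon))
  for (nd in tree$nodes) {
    if (nd$id == 1L) next
    for (e in nd$completions) chains[[e]] <- c(chains[[e]], nd$id)
  }
  lapply(chains, function(ch) ch[order(vapply(ch, function(i)
    tree$nodes[[i]]$depth, integer(1)))])
}

# Best-path scores through the cohort tree. Returns bu[node, t]: the
# maximal log-likelihood (emissions + transitions) of frames 1..t through
# the node's key sequence, ending in any state of its final phone.
tree_bottom_up <- function(tree, frames) {
  nodes <- tree$nodes
  ms <- tree$model_set
  T_ <- nrow(frames)
  n_nodes <- length(nodes)
  # DP states: 3 per non-root node
  st_node <- integer(0); st_s <- integer(0)
  for (nd in nodes) {
    if (nd$id == 1L) next
    st_node <- c(st_node, rep(nd$id, 3)); st_s <- c(st_s, 1:3)
  }
  n_st <- length(st_node)
  # emission rows cache per (key, s)
  ekey <- paste(vapply(st_node, function(i) nodes[[i]]$key, character(1)),
                st_s)
  uniq <- !duplicated(ekey)
  E <- matrix(NA_real_, n_st, T_)
  for (i in which(uniq)) {
    pm <- ms$models[[nodes[[st_node[i]]]$key]]
    E[i, ] <- state_loglik_frames(pm$states[[st_s[i]]], frames)
  }
  E <- E[which(uniq)[match(ekey, ekey[uniq])], , drop = FALSE]
  lsl <- numeric(n_st); ladv <- numeric(n_st)
  for (i in seq_len(n_st)) {
    pm <- ms$models[[nodes[[st_node[i]]]$key]]
    lsl[i] <- log(pm$self_loop[st_s[i]]); ladv[i] <- log(pm$advance[st_s[i]])
  }
  # predecessor (for entry transitions): DP index or 0 (start)
  idx_of <- function(node, s) which(st_node == node & st_s == s)
  pred <- integer(n_st)
  for (i in seq_len(n_st)) {
    if (st_s[i] > 1L) {
      pred[i] <- idx_of(st_node[i], st_s[i] - 1L)
    } else {
      par <- nodes[[st_node[i]]]$parent
      pred[i] <- if (par == 1L) 0L else idx_of(par, 3L)
    }
  }
  D <- matrix(-Inf, n_st, T_)
  starts <- which(pred == 0L)
  D[starts, 1] <- E[starts, 1]
  if (T_ > 1) {
    for (t in 2:T_) {
      stay <- D[, t - 1] + lsl
      come <- ifelse(pred > 0L, D[pmax(pred, 1L), t - 1] + ladv[pmax(pred, 1L)],
                     -Inf)
      D[, t] <- pmax(stay, come) + E[, t]
    }
  }
  bu <- matrix(-Inf, n_nodes, T_)
  for (i in seq_len(n_st)) {
    bu[st_node[i], ] <- pmax(bu[st_node[i], ], D[i, ])
  }
  bu
}

# Best-path pseudo-word lattice over the licensing network using
# context-independent models. Returns a list of hypotheses:
# list(phones = "a b", scores = numeric(T) with -Inf where unrealized).
pseudo_bottom_up <- function(pw, ms, frames, max_len) {
  T_ <- nrow(frames)
  if (!length(pw$phones) || !length(pw$starts)) return(list())
  ci_key <- function(p) model_key("*", p, "*")
  missing <- pw$phones[!vapply(pw$phones, function(p)
    ci_key(p) %in% names(ms$models), logical(1))]
  if (length(missing)) {
    stop("no context-independent model for phone(s): ",
         paste(missing, collapse = ", "))
  }
  # reachable (depth, phone) pairs
  levels <- list(sort(unique(pw$starts)))
  d <- 1L
  while (d < max_len) {
    nxt <- sort(unique(pw$edges[pw$edges[, 1] %in% levels[[d]], 2]))
    if (!length(nxt)) break
    levels[[d + 1L]] <- nxt
    d <- d + 1L
  }
  st_d <- integer(0); st_p <- character(0); st_s <- integer(0)
  for (d in seq_along(levels)) {
    for (p in levels[[d]]) {
      st_d <- c(st_d, rep(d, 3)); st_p <- c(st_p, rep(p, 3))
      st_s <- c(st_s, 1:3)
    }
  }
  n_st <- length(st_d)
  E <- matrix(NA_real_, n_st, T_)
  lsl <- numeric(n_st); ladv <- numeric(n_st)
  for (p in unique(st_p)) {
    pm <- ms$models[[ci_key(p)]]
    rows <- which(st_p == p)
    for (s in 1:3) {
      r <- rows[st_s[rows] == s]
      e <- state_loglik_frames(pm$states[[s]], frames)
      for (i in r) { E[i, ] <- e; lsl[i] <- log(pm$self_loop[s]);
                     ladv[i] <- log(pm$advance[s]) }
    }
  }
  preds <- vector("list", n_st)  # entry predecessors (state 3 of prev phone)
  for (i in seq_len(n_st)) {
    if (st_s[i] != 1L || st_d[i] == 1L) next
    qs <- pw$edges[pw$edges[, 2] == st_p[i], 1]
    preds[[i]] <- which(st_d == st_d[i] - 1L & st_p %in% qs & st_s == 3L)
  }
  D <- matrix(-Inf, n_st, T_)
  sid <- matrix(NA_integer_, n_st, T_)   # phone-string id of the best path
  strings <- character(0)
  str_id <- function(s) {
    i <- match(s, strings)
    if (is.na(i)) { strings[length(strings) + 1L] <<- s; length(strings) }
    else i
  }
  init <- which(st_d == 1L & st_s == 1L)
  D[init, 1] <- E[init, 1]
  for (i in init) sid[i, 1] <- str_id(st_p[i])
  if (T_ > 1) {
    for (t in 2:T_) {
      for (i in seq_len(n_st)) {
        stay <- D[i, t - 1] + lsl[i]
        best <- stay; src <- i; entered <- FALSE
        if (st_s[i] > 1L) {
          j <- i - 1L  # state s-1 of same (d, p) is the previous row
          come <- D[j, t - 1] + ladv[j]
          if (come > best) { best <- come; src <- j }
        } else if (length(preds[[i]])) {
          for (j in preds[[i]]) {
            come <- D[j, t - 1] + ladv[j]
            if (come > best) { best <- come; src <- j; entered <- TRUE }
          }
        }
        if (is.finite(best) || is.finite(E[i, t])) {
          D[i, t] <- best + E[i, t]
          if (is.finite(D[i, t])) {
            sid[i, t] <- if (entered) {
              str_id(paste(strings[sid[src, t - 1]], st_p[i]))
            } else sid[src, t - 1]
          }
        }
      }
    }
  }
  if (!length(strings)) return(list())
  out <- lapply(strings, function(s) list(phones = s,
                                          scores = rep(-Inf, T_)))
  names(out) <- strings
  for (t in seq_len(T_)) {
    for (i in seq_len(n_st)) {
      k <- sid[i, t]
      if (!is.na(k) && is.finite(D[i, t])) {
        out[[k]]$scores[t] <- max(out[[k]]$scores[t], D[i, t])
      }
    }
  }
  out
}

#' Compute time-synchronous activation traces for all hypotheses
#'
#' Decodes a feature trajectory against the cohort tree (words and their
#' cohorts) and, optionally, the phonotactic pseudo-word lattice. The
#' activation of hypothesis `h` at frame `t` is the frame-normalized
#' combination of bottom-up and top-down evidence:
#' \deqn{a(h, t) = (1/t) [\max_{\mathrm{paths}} \log P(x_{1..t} | h) +
#'   \lambda \log P(h)]}
#' where the path maximum runs over all left-to-right state alignments of
#' frames `1..t` ending in any state of `h`'s final phone. A full word
#' adopts, at every frame, the best activation over its cohort prefixes, so
#' words sharing a sharing-key prefix have identical traces until their
#' paths diverge.
#'
#' @param ft A [extract_features()] trajectory (or a `T x 39` matrix).
#' @param tree A [compile_cohort_tree()] tree.
#' @param pw Optional [build_pseudoword_network()]; when supplied,
#'   pseudo-word hypotheses are decoded with the context-independent models.
#' @param lm A `language_model` (defaults to unigram over the tree lexicon).
#' @param cfg A [decoder_config()].
#' @return An object of class `activation_trace`: `hypotheses` (data.frame
#'   with `id`, `kind` in word/cohort/pseudo, `phones`, `orthography`),
#'   `values` (hypotheses x frames activation matrix, `NA` where a
#'   hypothesis is not yet realizable or pruned-by-birth), `alive` (logical
#'   matrix after beam pruning), `offset_frame`, and the score components
#'   needed to re-weight class priors.
#' @export
compute_activation_traces <- function(ft, tree, pw = NULL, lm = NULL,
                                      cfg = decoder_config()) {
  frames <- if (inherits(ft, "feature_trajectory")) ft$frames else as.matrix(ft)
  T_ <- nrow(frames)
  if (T_ < 1) stop("empty feature trajectory")
  if (is.null(lm)) lm <- lm_unigram(tree$lexicon)
  lam <- cfg$lm_weight
  bu <- tree_bottom_up(tree, frames)
  nodes <- tree$nodes
  # class-free per-node log priors (cohort prior = sum of completions)
  node_prior <- vapply(nodes, function(nd) {
    if (nd$id == 1L) return(NA_real_)
    log_prior(nd, lm = lm, tree = tree)
  }, numeric(1))
  # class-free unnormalized score A0 = bu + lambda * prior
  pr_term <- function(pr) if (lam > 0) lam * pr else 0
  node_A0 <- bu
  for (i in seq_along(nodes)[-1]) node_A0[i, ] <- bu[i, ] + pr_term(node_prior[i])

  hyp_id <- character(0); hyp_kind <- character(0)
  hyp_phones <- character(0); hyp_orth <- character(0)
  A0 <- NULL
  # cohort hypotheses: non-word-final nodes
  for (nd in nodes) {
    if (nd$id == 1L || length(nd$words)) next
    hyp_id <- c(hyp_id, paste0("cohort:", paste(nd$prefix, collapse = " ")))
    hyp_kind <- c(hyp_kind, "cohort")
    hyp_phones <- c(hyp_phones, paste(nd$prefix, collapse = " "))
    hyp_orth <- c(hyp_orth, NA_character_)
    A0 <- rbind(A0, node_A0[nd$id, ])
  }
  # word hypotheses: adopt the best over the entry's prefix chain
  chains <- entry_chains(tree)
  for (e in seq_len(nrow(tree$lexicon))) {
    ch <- chains[[e]]
    adopted <- do.call(pmax, lapply(ch, function(i) node_A0[i, ]))
    hyp_id <- c(hyp_id, paste0("word:", tree$lexicon$orthography[e]))
    hyp_kind <- c(hyp_kind, "word")
    hyp_phones <- c(hyp_phones, tree$lexicon$phones[e])
    hyp_orth <- c(hyp_orth, tree$lexicon$orthography[e])
    A0 <- rbind(A0, adopted)
  }
  # pseudo-word hypotheses
  if (!is.null(pw)) {
    ph <- pseudo_bottom_up(pw, tree$model_set, frames, cfg$max_pseudo_len)
    lp <- log(pw$pseudo_prior)
    for (h in ph) {
      if (h$phones %in% pw$lexical) next  # lexical strings are words
      hyp_id <- c(hyp_id, paste0("pseudo:", h$phones))
      hyp_kind <- c(hyp_kind, "pseudo")
      hyp_phones <- c(hyp_phones, h$phones)
      hyp_orth <- c(hyp_orth, NA_character_)
      A0 <- rbind(A0, h$scores + pr_term(lp))
    }
  }
  rownames(A0) <- hyp_id
  hyps <- data.frame(id = hyp_id, kind = hyp_kind, phones = hyp_phones,
                     orthography = hyp_orth, stringsAsFactors = FALSE)
  tr <- structure(list(hypotheses = hyps, A0 = A0,
                       lm_weight = lam,
                       word_class_prior = cfg$word_class_prior,
                       offset_frame = T_, beam = cfg$beam,
                       frame_step_ms = if (inherits(ft, "feature_trajectory"))
                         ft$frame_step_ms else 10),
                  class = "activation_trace")
  tr$values <- activation_values(tr)
  tr$alive <- compute_alive(tr$values, cfg$beam)
  if (!any(tr$alive[, T_])) stop("all hypotheses pruned: beam too tight")
  tr
}

#' Activation values of a trace, optionally re-weighting class priors
#'
#' @param tr An `activation_trace`.
#' @param word_class_prior Word-class probability mass (pseudo-words get
#'   `1 - word_class_prior`); defaults to the decoding value.
#' @return A hypotheses x frames matrix; `NA` where unrealizable.
#' @export
activation_values <- function(tr, word_class_prior = tr$word_class_prior) {
  lam <- tr$lm_weight
  T_ <- tr$offset_frame
  mass <- ifelse(tr$hypotheses$kind == "pseudo",
                 1 - word_class_prior, word_class_prior)
  off <- if (lam > 0) lam * log(mass) else rep(0, length(mass))
  v <- sweep(tr$A0, 1, off, "+") / matrix(rep(seq_len(T_), each = nrow(tr$A0)),
                                          nrow(tr$A0))
  v[!is.finite(v)] <- NA_real_
  v
}

# Forward beam filter: once a hypothesis falls more than `beam` below the
# best surviving activation at a frame it is dead for all later frames.
# Hypotheses not yet realizable (NA) are not subject to the beam.
compute_alive <- function(values, beam) {
  n <- nrow(values); T_ <- ncol(values)
  alive <- matrix(TRUE, n, T_, dimnames = dimnames(values))
  prev <- rep(TRUE, n)
  for (t in seq_len(T_)) {
    v <- values[, t]
    cand <- prev & !is.na(v)
    if (any(cand)) {
      best <- max(v[cand])
      now <- prev & (is.na(v) | (best - v) <= beam)
    } else now <- prev
    alive[, t] <- now
    prev <- now
  }
  alive
}

#' Surviving hypotheses after beam pruning at a frame
#'
#' Implements threshold pruning with no revival: a hypothesis survives at
#' frame `t` iff it survived at `t - 1` and its activation is within `beam`
#' of the best surviving activation at `t`.
#'
#' @param tr An `activation_trace`.
#' @param t Frame index within the trace.
#' @param beam Pruning threshold (activation units).
#' @return Character vector of surviving hypothesis ids.
#' @export
prune_hypotheses <- function(tr, t, beam = tr$beam) {
  stopifnot(inherits(tr, "activation_trace"))
  if (t < 1 || t > tr$offset_frame) stop("frame out of range")
  alive <- compute_alive(tr$values, beam)
  tr$hypotheses$id[alive[, t]]
}

is_contig_subseq <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na >= nb) return(FALSE)
  any(vapply(0:(nb - na), function(s) all(a == b[(s + 1):(s + na)]),
             logical(1)))
}

#' Remove nested candidates from a scored hypothesis set
#'
#' A candidate is removed iff its phone string is a contiguous (proper)
#' substring of another candidate's phone string and its activation is not
#' higher; at equal activation the longer candidate is kept. Nested
#' candidates lead to the recognition of the same longer form and are not
#' treated as competitors.
#'
#' @param candidates A data.frame with at least columns `phones`
#'   (space-separated strings) and `activation`.
#' @return The filtered data.frame.
#' @export
remove_nested <- function(candidates) {
  n <- nrow(candidates)
  if (is.null(n) || n <= 1) return(candidates)
  toks <- lapply(candidates$phones, split_phones)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (is_contig_subseq(toks[[i]], toks[[j]]) &&
          candidates$activation[i] <= candidates$activation[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  candidates[keep, , drop = FALSE]
}

#' @export
print.activation_trace <- function(x, ...) {
  k <- table(x$hypotheses$kind)
  cat(sprintf("<activation_trace: %d frames, %s>\n", x$offset_frame,
              paste(sprintf("%d %s", k, names(k)), collapse = ", ")))
  invisible(x)
}

#' Plot activation traces
#'
#' Activation (frame-normalized log score) against time for every
#' hypothesis; the winning hypothesis at offset is drawn in red.
#'
#' @param x An `activation_trace`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.activation_trace <- function(x, ...) {
  tms <- seq_len(x$offset_frame) * x$frame_step_ms
  v <- t(x$values)
  win <- which.max(x$values[, x$offset_frame])
  cols <- rep("grey30", ncol(v)); cols[win] <- "red"
  lwd <- rep(1, ncol(v)); lwd[win] <- 2
  graphics::matplot(tms, v, type = "l", lty = 1, col = cols, lwd = lwd,
                    xlab = "time (ms)", ylab = "activation", ...)
  invisible(x)
}

#' Export an activation trace to CSV
#'
#' Long format: one row per hypothesis per frame with columns `hypothesis`,
#' `kind`, `frame`, `time_ms`, `activation` (NA rows are dropped).
#'
#' @param tr An `activation_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(tr, path) {
  T_ <- tr$offset_frame
  df <- data.frame(
    hypothesis = rep(tr$hypotheses$id, T_),
    kind = rep(tr$hypotheses$kind, T_),
    frame = rep(seq_len(T_), each = nrow(tr$hypotheses)),
    time_ms = rep(seq_len(T_) * tr$frame_step_ms, each = nrow(tr$hypotheses)),
    activation = as.vector(tr$values))
  df <- df[!is.na(df$activation), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
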