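#' State emission model (diagonal-covariance Gaussian mixture)
#'
#' Each hidden state of a phone model carries an emission density over the
#' 39-dimensional feature space — the package's realization of a
#' spectro-temporal receptive field. Densities are diagonal-covariance
#' Gaussian mixtures (one component by default).
#'
#' @param id Integer index of the state within the model set (the receptive
#'   field index used by [phone_state_correspondence()]).
#' @param weights Mixture weights; must sum to 1.
#' @param means `n_comp x d` matrix of component means.
#' @param variances `n_comp x d` matrix of positive diagonal variances.
#' @return An object of class `state_model`.
#' @export
state_model <- function(id, weights, means, variances) {
  means <- rbind(means); variances <- rbind(variances)
  dimnames(means) <- NULL; dimnames(variances) <- NULL
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(variances <= 0)) stop("variances must be positive")
  if (nrow(means) != length(weights) || !all(dim(means) == dim(variances))) {
    stop("inconsistent mixture dimensions")
  }
  structure(list(id = as.integer(id), weights = as.numeric(weights),
                 means = means, variances = variances),
            class = "state_model")
}

#' Log emission density of a state at a feature vector
#'
#' @param s A [state_model()].
#' @param x Feature vector of the model's dimension.
#' @return Log of the mixture density at `x`.
#' @export
state_loglik <- function(s, x) {
  stopifnot(inherits(s, "state_model"))
  if (length(x) != ncol(s$means)) {
    stop("dimension mismatch: state has dim ", ncol(s$means),
         ", vector has ", length(x))
  }
  lp <- vapply(seq_along(s$weights), function(k) {
    log(s$weights[k]) - 0.5 * sum(log(2 * pi * s$variances[k, ])) -
      0.5 * sum((x - s$means[k, ])^2 / s$variances[k, ])
  }, numeric(1))
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Per-frame log densities of one state for a whole T x d frame matrix.
state_loglik_frames <- function(s, frames) {
  out <- matrix(-Inf, length(s$weights), nrow(frames))
  for (k in seq_along(s$weights)) {
    ctr <- sweep(frames, 2, s$means[k, ])
    q <- colSums(t(ctr^2) / s$variances[k, ])
    out[k, ] <- log(s$weights[k]) -
      0.5 * sum(log(2 * pi * s$variances[k, ])) - 0.5 * q
  }
  if (nrow(out) == 1L) return(drop(out))
  m <- apply(out, 2, max)
  m + log(colSums(exp(sweep(out, 2, m))))
}

#' Context-dependent three-state phone model
#'
#' A left-to-right Markov model with exactly three emitting states (head,
#' body, tail), no skips and no backward transitions. Self-loop
#' probabilities absorb duration variation.
#'
#' @param phone SAMPA phone label.
#' @param left_ctx,right_ctx Neighbouring phone labels, the boundary symbol
#'   `"#"`, or the wildcard `"*"` for context-independent models.
#' @param states List of exactly 3 [state_model()] objects.
#' @param self_loop,advance Length-3 per-state transition probabilities;
#'   `self_loop + advance == 1` per state.
#' @return An object of class `phone_model`.
#' @export
phone_model <- function(phone, left_ctx, right_ctx, states,
                        self_loop = rep(0.5, 3), advance = 1 - self_loop) {
  if (length(states) != 3L) stop("a phone model has exactly 3 states")
  if (any(abs(self_loop + advance - 1) > 1e-9)) {
    stop("self_loop + advance must equal 1 for every state")
  }
  if (any(self_loop < 0) || any(advance < 0)) stop("negative transition prob")
  structure(list(phone = phone, left_ctx = left_ctx, right_ctx = right_ctx,
                 states = states, self_loop = as.numeric(self_loop),
                 advance = as.numeric(advance)),
            class = "phone_model")
}

#' Sharing key of a context-dependent phone model
#'
#' @param left,phone,right Labels (boundary `"#"`, wildcard `"*"`).
#' @return The key string `"left/phone/right"`.
#' @export
model_key <- function(left, phone, right) paste(left, phone, right, sep = "/")

#' A keyed set of phone models
#'
#' Holds one [phone_model()] per sharing key; keying enforces the rule that
#' a phone with identical pre- and post-context is modeled once.
#'
#' @param models Named list of [phone_model()] objects, names being
#'   [model_key()] strings.
#' @return An object of class `model_set`.
#' @export
model_set <- function(models = list()) {
  if (length(models) && is.null(names(models))) stop("models must be named")
  structure(list(models = models), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set: %d context-dependent phone models, %d states>\n",
              length(x$models), 3L * length(x$models)))
  invisible(x)
}

#' @export
summary.model_set <- function(object, ...) {
  keys <- names(object$models)
  ll <- attr(object, "loglik")
  cat(sprintf("Model set with %d models:\n", length(keys)))
  if (length(keys)) cat(" ", paste(utils::head(keys, 12), collapse = ", "),
                        if (length(keys) > 12) "...", "\n")
  if (!is.null(ll)) {
    cat(sprintf("Trained %d iterations; log-likelihood %s -> %s\n",
                length(ll), format(ll[1]), format(ll[length(ll)])))
  }
  invisible(object)
}

# Segments of `labeled` that carry a given key. `labeled` is a list of
# tokens: list(features = T x d matrix (or feature_trajectory),
#              segments = data.frame(left, phone, right, start, end)).
token_frames <- function(tok) {
  f <- tok$features
  if (inherits(f, "feature_trajectory")) f$frames else as.matrix(f)
}

collect_key_frames <- function(labeled, key) {
  out <- list()
  for (tok in labeled) {
    fr <- token_frames(tok)
    seg <- tok$segments
    kk <- model_key(seg$left, seg$phone, seg$right)
    for (j in which(kk == key)) {
      out[[length(out) + 1L]] <- fr[seg$start[j]:seg$end[j], , drop = FALSE]
    }
  }
  out
}

#' Flat-start initialization of a model set
#'
#' Initializes each requested model from a uniform three-way temporal split
#' of all its labeled frames: each state's mean/variance is the sample
#' mean/variance of its third of every token. Transitions start at
#' `self_loop = 0.5`.
#'
#' @param keys Character vector of [model_key()] strings to initialize.
#' @param labeled Labeled training set: a list of tokens, each a list with
#'   `features` (a `T x d` matrix or [extract_features()] output) and
#'   `segments` (a data.frame with columns `left`, `phone`, `right`,
#'   `start`, `end` — inclusive frame indices).
#' @param var_floor Lower bound applied to variances.
#' @return A [model_set()].
#' @export
init_models <- function(keys, labeled, var_floor = 1e-3) {
  keys <- unique(keys)
  models <- list()
  missing <- character()
  next_id <- 1L
  for (key in keys) {
    segs <- collect_key_frames(labeled, key)
    if (!length(segs)) { missing <- c(missing, key); next }
    parts <- c(key_parts(key))
    state_frames <- list(NULL, NULL, NULL)
    for (m in segs) {
      T_ <- nrow(m)
      cut <- round(T_ * c(1, 2) / 3)
      idx <- list(seq_len(max(cut[1], 1L)),
                  if (cut[2] > cut[1]) (cut[1] + 1L):cut[2] else integer(),
                  if (T_ > cut[2]) (cut[2] + 1L):T_ else integer())
      for (s in 1:3) {
        if (length(idx[[s]])) {
          state_frames[[s]] <- rbind(state_frames[[s]],
                                     m[idx[[s]], , drop = FALSE])
        }
      }
    }
    pooled <- do.call(rbind, segs)
    states <- lapply(1:3, function(s) {
      fr <- state_frames[[s]]
      if (is.null(fr) || !nrow(fr)) fr <- pooled
      v <- apply(fr, 2, stats::var)
      v[!is.finite(v) | v < var_floor] <- var_floor
      state_model(next_id + s - 1L, 1, colMeans(fr), v)
    })
    models[[key]] <- phone_model(parts[2], parts[1], parts[3], states)
    next_id <- next_id + 3L
  }
  if (length(missing)) {
    stop("no labeled frames for keys: ", paste(missing, collapse = ", "))
  }
  model_set(models)
}

key_parts <- function(key) strsplit(key, "/", fixed = TRUE)[[1]]

# Best-path (Viterbi) alignment of a segment's frames to the 3 states of a
# phone model; returns state indices and the best-path log-likelihood
# (emissions + transitions, entry into state 1 with probability 1).
align_segment <- function(pm, frames) {
  T_ <- nrow(frames)
  E <- rbind(state_loglik_frames(pm$states[[1]], frames),
             state_loglik_frames(pm$states[[2]], frames),
             state_loglik_frames(pm$states[[3]], frames))
  E <- matrix(E, nrow = 3)
  lsl <- log(pm$self_loop); ladv <- log(pm$advance)
  if (T_ < 3) {
    # too short to traverse all states: emit everything from state 1
    return(list(path = rep(1L, T_),
                loglik = sum(E[1, ]) + (T_ - 1) * lsl[1]))
  }
  D <- matrix(-Inf, 3, T_); P <- matrix(0L, 3, T_)
  D[1, 1] <- E[1, 1]
  for (t in 2:T_) {
    for (s in 1:3) {
      stay <- D[s, t - 1] + lsl[s]
      come <- if (s > 1) D[s - 1, t - 1] + ladv[s - 1] else -Inf
      if (stay >= come) { D[s, t] <- stay + E[s, t]; P[s, t] <- s }
      else { D[s, t] <- come + E[s, t]; P[s, t] <- s - 1L }
    }
  }
  path <- integer(T_); path[T_] <- 3L
  for (t in T_:2) path[t - 1] <- P[path[t], t]
  list(path = path, loglik = D[3, T_])
}

#' Train a model set by segmental Viterbi EM
#'
#' Iterates hard (best-path) alignment of each labeled phone segment to its
#' model's three states, followed by re-estimation of state means, variances
#' and transition probabilities from the aligned frames. The total best-path
#' log-likelihood is recorded per iteration (attribute `"loglik"`) and is
#' non-decreasing.
#'
#' @param ms An initialized [model_set()].
#' @param labeled Labeled training set (see [init_models()]).
#' @param n_iter Number of EM iterations (>= 1).
#' @param var_floor Variance floor; a warning is issued if it binds.
#' @return The trained [model_set()], with per-iteration log-likelihoods in
#'   `attr(, "loglik")`.
#' @export
train_models <- function(ms, labeled, n_iter = 10, var_floor = 1e-3) {
  stopifnot(inherits(ms, "model_set"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  keys <- names(ms$models)
  # pre-extract segments per key once
  seg_frames <- lapply(keys, collect_key_frames, labeled = labeled)
  names(seg_frames) <- keys
  loglik <- numeric(n_iter)
  floored <- FALSE
  for (it in seq_len(n_iter)) {
    total <- 0
    for (key in keys) {
      pm <- ms$models[[key]]
      segs <- seg_frames[[key]]
      if (!length(segs)) next
      acc <- lapply(1:3, function(s) list(frames = NULL))
      stay_n <- numeric(3); adv_n <- numeric(3)
      sf <- vector("list", 3)
      for (m in segs) {
        al <- align_segment(pm, m)
        total <- total + al$loglik
        for (s in 1:3) {
          sel <- al$path == s
          if (any(sel)) sf[[s]] <- rbind(sf[[s]], m[sel, , drop = FALSE])
        }
        p <- al$path
        if (length(p) > 1) {
          trans <- cbind(p[-length(p)], p[-1])
          for (s in 1:3) {
            stay_n[s] <- stay_n[s] + sum(trans[, 1] == s & trans[, 2] == s)
            adv_n[s] <- adv_n[s] + sum(trans[, 1] == s & trans[, 2] == s + 1)
          }
        }
        adv_n[3] <- adv_n[3] + 1  # implicit exit at segment end
      }
      states <- pm$states
      for (s in 1:3) {
        fr <- sf[[s]]
        if (is.null(fr) || nrow(fr) < 1) next
        mu <- colMeans(fr)
        v <- if (nrow(fr) > 1) apply(fr, 2, stats::var) * (nrow(fr) - 1) / nrow(fr)
             else rep(var_floor, ncol(fr))
        if (any(v < var_floor)) floored <- TRUE
        v <- pmax(v, var_floor)
        states[[s]] <- state_model(states[[s]]$id, states[[s]]$weights, mu, v)
      }
      denom <- stay_n + adv_n
      sl <- ifelse(denom > 0, stay_n / denom, pm$self_loop)
      sl <- pmin(pmax(sl, 1e-4), 1 - 1e-4)
      ms$models[[key]] <- phone_model(pm$phone, pm$left_ctx, pm$right_ctx,
                                      states, sl, 1 - sl)
    }
    loglik[it] <- total
  }
  if (floored) warning("variance floor applied during training")
  attr(ms, "loglik") <- loglik
  ms
}

#' Phone-to-state correspondence matrix
#'
#' Forced-aligns every labeled segment of the evaluation set with its model
#' and tabulates, per phone, which state indices its frames are assigned to.
#' Rows (phones) are normalized to sum to 1; phones without evaluation data
#' get a zero row with a warning. Off-diagonal mass indicates emission
#' structure shared between related phones.
#'
#' @param ms A trained [model_set()].
#' @param labeled Evaluation set (see [init_models()] for the format).
#' @return A `phones x state-ids` matrix with phone row names and integer
#'   state-id column names.
#' @export
phone_state_correspondence <- function(ms, labeled) {
  stopifnot(inherits(ms, "model_set"))
  phones <- sort(unique(vapply(ms$models, function(m) m$phone, character(1))))
  ids <- sort(unique(unlist(lapply(ms$models, function(m)
    vapply(m$states, function(s) s$id, integer(1))))))
  M <- matrix(0, length(phones), length(ids),
              dimnames = list(phones, as.character(ids)))
  for (tok in labeled) {
    fr <- token_frames(tok)
    seg <- tok$segments
    for (j in seq_len(nrow(seg))) {
      key <- model_key(seg$left[j], seg$phone[j], seg$right[j])
      pm <- ms$models[[key]]
      if (is.null(pm)) next
      al <- align_segment(pm, fr[seg$start[j]:seg$end[j], , drop = FALSE])
      sid <- vapply(pm$states, function(s) s$id, integer(1))
      for (s in 1:3) {
        M[pm$phone, as.character(sid[s])] <-
          M[pm$phone, as.character(sid[s])] + sum(al$path == s)
      }
    }
  }
  rs <- rowSums(M)
  empty <- rs == 0
  if (any(empty)) {
    warning("phones absent from evaluation set: ",
            paste(phones[empty], collapse = ", "))
  }
  M[!empty, ] <- M[!empty, , drop = FALSE] / rs[!empty]
  M
}

#' Write a phone-state correspondence matrix to CSV
#'
#' Rows are phone labels, columns the integer state (receptive-field)
#' indices, as produced by [phone_state_correspondence()].
#'
#' @param M The correspondence matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correspondence_csv <- function(M, path) {
  df <- data.frame(phone = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a model set to JSON
#'
#' @param ms A [model_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(ms, path) {
  stopifnot(inherits(ms, "model_set"))
  obj <- lapply(ms$models, function(pm) {
    list(phone = pm$phone, left_ctx = pm$left_ctx, right_ctx = pm$right_ctx,
         self_loop = pm$self_loop, advance = pm$advance,
         states = lapply(pm$states, function(s)
           list(id = s$id, weights = s$weights,
                means = unclass(s$means), variances = unclass(s$variances))))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model set from JSON written by [write_model_set()]
#'
#' @param path JSON path.
#' @return A [model_set()].
#' @export
read_model_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  as_mat <- function(x, k) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = k, byrow = TRUE)
  }
  models <- lapply(obj, function(pm) {
    states <- lapply(pm$states, function(s) {
      k <- length(unlist(s$weights))
      state_model(s$id, unlist(s$weights),
                  as_mat(s$means, k), as_mat(s$variances, k))
    })
    phone_model(pm$phone, pm$left_ctx, pm$right_ctx, states,
                unlist(pm$self_loop), unlist(pm$advance))
  })
  model_set(models)
}
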