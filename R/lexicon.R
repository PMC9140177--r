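#' Construct a lexicon
#'
#' A lexicon is a table of entries: orthographic word, SAMPA phone string
#' and token frequency. Homophones are allowed (identical phone strings,
#' distinct orthographies and frequencies).
#'
#' @param orthography Character vector of word forms.
#' @param phones Character vector of space-separated SAMPA phone strings.
#' @param frequency Non-negative occurrence counts.
#' @return A data.frame of class `lexicon`.
#' @export
lexicon <- function(orthography, phones, frequency) {
  if (any(!nzchar(trimws(phones)))) stop("phone strings must be non-empty")
  if (any(frequency < 0)) stop("frequencies must be >= 0")
  df <- data.frame(orthography = as.character(orthography),
                   phones = trimws(as.character(phones)),
                   frequency = as.numeric(frequency),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[c("orthography", "phones")])
  if (any(dup)) {
    stop("duplicate lexicon entries: ",
         paste(df$orthography[dup], collapse = ", "))
  }
  class(df) <- c("lexicon", "data.frame")
  df
}

#' Read a lexicon from a tab-separated file
#'
#' Columns: orthography, space-separated SAMPA phones, integer frequency.
#' No header.
#'
#' @param path Path to the lexicon file.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("orthography", "phones", "frequency"),
                          quote = "")
  lexicon(df$orthography, df$phones, df$frequency)
}

#' Write a lexicon to a tab-separated file
#' @param lex A [lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  utils::write.table(as.data.frame(lex), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

split_phones <- function(s) strsplit(trimws(s), "\\s+")[[1]]

BOUNDARY <- "#"

#' Context-dependent sharing key of a phone in a phone string
#'
#' Two words share the model for a phone exactly when its pre- and
#' post-context agree; word edges contribute the boundary symbol `"#"`.
#'
#' @param phones Character vector of phones (one word).
#' @param i Position, `1 <= i <= length(phones)`.
#' @return Character vector `c(left, phone, right)`.
#' @export
sharing_key <- function(phones, i) {
  n <- length(phones)
  if (i < 1 || i > n) stop("position ", i, " out of range 1..", n)
  c(if (i > 1) phones[i - 1] else BOUNDARY,
    phones[i],
    if (i < n) phones[i + 1] else BOUNDARY)
}

# All sharing keys of a phone vector, as "l/p/r" strings.
sharing_keys <- function(phones) {
  vapply(seq_along(phones), function(i) {
    k <- sharing_key(phones, i); model_key(k[1], k[2], k[3])
  }, character(1))
}

#' All sharing keys occurring in a lexicon
#'
#' The set of context-dependent model keys needed to decode every entry,
#' optionally together with one context-independent (`"*"`) key per phone
#' (used for pseudo-word hypotheses).
#'
#' @param lex A [lexicon()].
#' @param context_independent Also include `*/p/*` keys per phone.
#' @return Character vector of [model_key()] strings.
#' @export
lexicon_keys <- function(lex, context_independent = TRUE) {
  keys <- unique(unlist(lapply(lex$phones,
                               function(p) sharing_keys(split_phones(p)))))
  if (context_independent) {
    phs <- unique(unlist(lapply(lex$phones, split_phones)))
    keys <- c(keys, model_key("*", phs, "*"))
  }
  unique(keys)
}

#' Compile a lexicon into a cohort prefix tree
#'
#' Entries share a path exactly as far as their sharing keys agree (so
#' "ham" and "hamster" share the /h/ and vowel nodes but split at /m/,
#' whose post-contexts differ). Every node is a cohort hypothesis carrying
#' the set of entries it can still become; nodes whose key sequence
#' completes an entry are word-final.
#'
#' @param lex A [lexicon()].
#' @param ms A [model_set()] resolving every sharing key in the lexicon.
#' @return An object of class `cohort_tree`: list with `nodes` (a list of
#'   node records: `id`, `parent`, `key`, `phone`, `depth`, `prefix`,
#'   `children`, `completions` (entry row indices), `words` (entry rows
#'   ending here)), plus `lexicon` and `model_set`.
#' @export
compile_cohort_tree <- function(lex, ms) {
  stopifnot(inherits(lex, "lexicon"), inherits(ms, "model_set"))
  nodes <- list(list(id = 1L, parent = 0L, key = NA_character_,
                     phone = NA_character_, depth = 0L, prefix = character(),
                     children = integer(), completions = integer(),
                     words = integer()))
  for (e in seq_len(nrow(lex))) {
    ph <- split_phones(lex$phones[e])
    keys <- sharing_keys(ph)
    unknown <- keys[!keys %in% names(ms$models)]
    if (length(unknown)) {
      stop("unknown phone model(s) for entry '", lex$orthography[e], "': ",
           paste(unknown, collapse = ", "))
    }
    cur <- 1L
    nodes[[cur]]$completions <- c(nodes[[cur]]$completions, e)
    for (i in seq_along(ph)) {
      kids <- nodes[[cur]]$children
      hit <- kids[vapply(kids, function(k) nodes[[k]]$key == keys[i],
                         logical(1))]
      if (length(hit)) {
        nxt <- hit[1]
      } else {
        nxt <- length(nodes) + 1L
        nodes[[nxt]] <- list(id = nxt, parent = cur, key = keys[i],
                             phone = ph[i], depth = i,
                             prefix = ph[seq_len(i)],
                             children = integer(), completions = integer(),
                             words = integer())
        nodes[[cur]]$children <- c(nodes[[cur]]$children, nxt)
      }
      nodes[[nxt]]$completions <- c(nodes[[nxt]]$completions, e)
      if (i == length(ph)) nodes[[nxt]]$words <- c(nodes[[nxt]]$words, e)
      cur <- nxt
    }
  }
  structure(list(nodes = nodes, lexicon = lex, model_set = ms),
            class = "cohort_tree")
}

#' @export
print.cohort_tree <- function(x, ...) {
  cat(sprintf("<cohort_tree: %d nodes over %d entries>\n",
              length(x$nodes) - 1L, nrow(x$lexicon)))
  invisible(x)
}

#' Build the phonotactic pseudo-word network of a lexicon
#'
#' Pseudo-word hypotheses are phone strings all of whose adjacent phone
#' pairs — including the word-boundary pairs at both edges — are attested in
#' the lexicon. Strings identical to a lexical entry are flagged as words
#' and never offered as pseudo-words.
#'
#' @param lex A [lexicon()] (may be empty, yielding an empty network).
#' @param pseudo_prior Stimulus-independent prior probability assigned to
#'   every pseudo-word hypothesis; defaults to `1 / (nrow(lex) + 1)` (as
#'   probable as one extra lexical entry).
#' @return An object of class `pseudoword_network`: list with `phones`,
#'   `edges` (two-column matrix of attested pairs), `starts`, `ends`,
#'   `lexical` (attested full strings) and `pseudo_prior`.
#' @export
build_pseudoword_network <- function(lex, pseudo_prior = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  pairs <- matrix(character(), 0, 2)
  starts <- character(); ends <- character()
  for (p in lex$phones) {
    ph <- split_phones(p)
    starts <- c(starts, ph[1])
    ends <- c(ends, ph[length(ph)])
    if (length(ph) > 1) {
      pairs <- rbind(pairs, cbind(ph[-length(ph)], ph[-1]))
    }
  }
  pairs <- unique(pairs)
  if (is.null(pseudo_prior)) pseudo_prior <- 1 / (nrow(lex) + 1)
  structure(list(phones = unique(unlist(lapply(lex$phones, split_phones))),
                 edges = pairs,
                 starts = unique(starts), ends = unique(ends),
                 lexical = unique(lex$phones),
                 pseudo_prior = pseudo_prior),
            class = "pseudoword_network")
}

#' @export
print.pseudoword_network <- function(x, ...) {
  cat(sprintf(
    "<pseudoword_network: %d phones, %d licensed pairs, prior %.4g>\n",
    length(x$phones), nrow(x$edges), x$pseudo_prior))
  invisible(x)
}

pw_has_edge <- function(pw, a, b) {
  any(pw$edges[, 1] == a & pw$edges[, 2] == b)
}

#' Does the phonotactic network license a phone string?
#'
#' A string is licensed iff every adjacent pair, including the boundary
#' pairs (word start to first phone, last phone to word end), is attested
#' in the lexicon.
#'
#' @param pw A [build_pseudoword_network()] result.
#' @param phones Character vector of phones.
#' @return `TRUE`/`FALSE`.
#' @export
pw_licensed <- function(pw, phones) {
  n <- length(phones)
  if (n == 0) return(FALSE)
  if (!phones[1] %in% pw$starts) return(FALSE)
  if (!phones[n] %in% pw$ends) return(FALSE)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (!pw_has_edge(pw, phones[i], phones[i + 1])) return(FALSE)
    }
  }
  TRUE
}

#' Is a phone string a lexical entry (rather than a pseudo-word)?
#' @param pw A [build_pseudoword_network()] result.
#' @param phones Character vector of phones.
#' @return `TRUE` if the string equals some entry's phone string.
#' @export
pw_is_lexical <- function(pw, phones) {
  paste(phones, collapse = " ") %in% pw$lexical
}

#' Unigram language model from lexicon frequencies
#'
#' @param lex A [lexicon()].
#' @return An object of class `language_model` with `order = 1`; word
#'   probabilities are relative frequencies (uniform if all counts are 0).
#' @export
lm_unigram <- function(lex) {
  p <- lex$frequency
  p <- if (sum(p) > 0) p / sum(p) else rep(1 / nrow(lex), nrow(lex))
  probs <- tapply(p, lex$orthography, sum)
  structure(list(order = 1L,
                 probs = list(`_` = as.list(probs))),
            class = "language_model")
}

#' Read an N-gram language model from JSON
#'
#' The JSON maps a context (preceding words joined by spaces; `""` or `"_"`
#' for the empty context) to an object of word probabilities. For each
#' context the probabilities must sum to at most 1 (the remainder is
#' implicitly reserved for pseudo-words).
#'
#' @param path JSON path.
#' @return A `language_model`.
#' @export
read_lm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  names(obj)[names(obj) == ""] <- "_"
  for (ctx in names(obj)) {
    s <- sum(unlist(obj[[ctx]]))
    if (s > 1 + 1e-9) stop("probabilities for context '", ctx,
                           "' sum to ", s, " > 1")
  }
  ord <- max(vapply(names(obj), function(ctx) {
    if (ctx == "_") 1L else length(strsplit(ctx, " ")[[1]]) + 1L
  }, integer(1)))
  structure(list(order = ord, probs = obj), class = "language_model")
}

lm_word_prob <- function(lm, word, context = character()) {
  ctx_key <- "_"
  if (lm$order > 1 && length(context)) {
    use <- utils::tail(context, lm$order - 1L)
    key <- paste(use, collapse = " ")
    if (!is.null(lm$probs[[key]])) {
      ctx_key <- key
    } else {
      warning("unknown context '", key, "': backing off to unigram")
    }
  }
  p <- lm$probs[[ctx_key]][[word]]
  if (is.null(p)) 0 else as.numeric(p)
}

#' Top-down log prior of a hypothesis
#'
#' A full word's prior is its (context-conditional) language-model
#' probability — in isolation, its relative frequency. A cohort's prior is
#' the summed probability of its completions: the total probability of the
#' prefix becoming any word. A pseudo-word's prior is the network's
#' configured stimulus-independent constant. `class_mass` multiplies the
#' prior by the hypothesis class's share (e.g. 0.5/0.5 word/pseudo-word in
#' a balanced lexical decision experiment).
#'
#' @param x A word (single orthography string), a cohort node record from a
#'   [compile_cohort_tree()] tree, or a pseudo phone string (character
#'   vector of length > 1, or wrapped by [pseudo_path()]).
#' @param lm A `language_model` (needed for words/cohorts).
#' @param context Preceding words (character vector), for N-gram priors.
#' @param tree The cohort tree (needed to resolve a cohort's completions).
#' @param pw The pseudo-word network (needed for pseudo paths).
#' @param class_mass Class probability mass multiplier in `[0, 1]`.
#' @return Log probability (`-Inf` for zero-probability hypotheses).
#' @export
log_prior <- function(x, lm = NULL, context = character(), tree = NULL,
                      pw = NULL, class_mass = 1) {
  base <- if (inherits(x, "pseudo_path")) {
    if (is.null(pw)) stop("pseudo prior needs the pseudo-word network")
    pw$pseudo_prior
  } else if (is.list(x) && !is.null(x$completions)) {
    if (is.null(tree) || is.null(lm)) stop("cohort prior needs tree and lm")
    comp <- unique(tree$lexicon$orthography[x$completions])
    sum(vapply(comp, lm_word_prob, numeric(1), lm = lm, context = context))
  } else if (is.character(x) && length(x) == 1L) {
    if (is.null(lm)) stop("word prior needs a language model")
    lm_word_prob(lm, x, context)
  } else {
    stop("cannot interpret hypothesis for log_prior()")
  }
  log(base) + log(class_mass)
}

#' Mark a phone string as a pseudo-word hypothesis
#' @param phones Character vector of phones.
#' @return The vector with class `pseudo_path`.
#' @export
pseudo_path <- function(phones) structure(phones, class = "pseudo_path")
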