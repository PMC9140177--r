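# Brute-force sharing-key prefix count: number of distinct key-sequence
# prefixes across the lexicon equals the cohort tree's node count.
oracle_node_count <- function(lex) {
  prefixes <- character(0)
  for (p in lex$phones) {
    ph <- strsplit(p, " ")[[1]]
    keys <- vapply(seq_along(ph), function(i) {
      k <- sharing_key(ph, i); paste(k, collapse = "|")
    }, character(1))
    for (i in seq_along(keys)) {
      prefixes <- c(prefixes, paste(keys[1:i], collapse = " > "))
    }
  }
  length(unique(prefixes))
}

dummy_models_for <- function(lex, extra_phones = character()) {
  keys <- lexicon_keys(lex, context_independent = TRUE)
  models <- lapply(keys, function(k) {
    p <- strsplit(k, "/", fixed = TRUE)[[1]]
    phone_model(p[2], p[1], p[3],
                lapply(1:3, function(s) state_model(s, 1, rep(0, 4),
                                                    rep(1, 4))))
  })
  names(models) <- keys
  model_set(models)
}

test_that("sharing keys follow the pre/post-context rule", {
  speech <- c("s", "p", "i", "tS")
  speed <- c("s", "p", "i", "d")
  spell <- c("s", "p", "e", "l")
  # 'speech' and 'speed' share /s/ and /p/ models (same contexts)
  expect_equal(sharing_key(speech, 1), sharing_key(speed, 1))
  expect_equal(sharing_key(speech, 2), sharing_key(speed, 2))
  # 'spell' shares only /s/: the /p/ post-context differs
  expect_equal(sharing_key(spell, 1), sharing_key(speech, 1))
  expect_false(identical(sharing_key(spell, 2), sharing_key(speech, 2)))
  # single-phone word: both contexts are word edges
  expect_equal(sharing_key("a", 1), c("#", "a", "#"))
  expect_error(sharing_key(speech, 5), "out of range")
  expect_error(sharing_key(speech, 0), "out of range")
})

test_that("cohort tree shares paths exactly while sharing keys agree", {
  lex <- lexicon(c("ham", "hamster"), c("h { m", "h { m s t @ r"),
                 c(10, 5))
  tree <- compile_cohort_tree(lex, dummy_models_for(lex))
  # shared /h/ and /{/ nodes, separate /m/ nodes (post-contexts differ)
  depth1 <- tree$nodes[[1]]$children
  expect_length(depth1, 1)
  depth2 <- tree$nodes[[depth1]]$children
  expect_length(depth2, 1)
  depth3 <- tree$nodes[[depth2]]$children
  expect_length(depth3, 2)
  expect_setequal(vapply(depth3, function(i) tree$nodes[[i]]$phone,
                         character(1)), c("m", "m"))
  # completions propagate: the shared vowel node can become either word
  expect_setequal(tree$nodes[[depth2]]$completions, c(1L, 2L))
  # words with different initial phones split at the root
  lex2 <- lexicon(c("a", "b"), c("x y", "z y"), c(1, 1))
  tree2 <- compile_cohort_tree(lex2, dummy_models_for(lex2))
  expect_length(tree2$nodes[[1]]$children, 2)
})

test_that("tree node count equals the brute-force prefix enumeration", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      phones <- letters[1:5]
      n <- 20
      strs <- unique(replicate(n, paste(sample(phones,
                                               sample(2:5, 1),
                                               replace = TRUE),
                                        collapse = " ")))
      lex <- lexicon(sprintf("w%02d", seq_along(strs)), strs,
                     rep(1, length(strs)))
      tree <- compile_cohort_tree(lex, dummy_models_for(lex))
      expect_equal(length(tree$nodes) - 1L, oracle_node_count(lex))
    }
  })
})

test_that("tree compilation validates entries", {
  lex <- lexicon(c("a", "b"), c("x y", "x z"), c(1, 1))
  ms <- dummy_models_for(lexicon("a", "x y", 1))
  expect_error(compile_cohort_tree(lex, ms), "unknown phone model")
  expect_error(lexicon(c("a", "a"), c("x y", "x y"), c(1, 1)), "duplicate")
  expect_error(lexicon("a", "  ", 1), "non-empty")
  expect_error(lexicon("a", "x", -1), "frequencies")
})

test_that("pseudo-word licensing accepts exactly the attested-pair strings", {
  lex <- lexicon(c("w1", "w2"), c("a b", "b c"), c(1, 1))
  pw <- build_pseudoword_network(lex)
  # /a b c/ is licensed: pairs (#,a), (a,b), (b,c), (c,#) all attested
  expect_true(pw_licensed(pw, c("a", "b", "c")))
  # /c a/ is not: no (c, a) pair
  expect_false(pw_licensed(pw, c("c", "a")))
  # strings equal to entries are lexical, not pseudo
  expect_true(pw_is_lexical(pw, c("a", "b")))
  expect_false(pw_is_lexical(pw, c("a", "b", "c")))
  # enumeration oracle over all strings up to length 3
  alph <- c("a", "b", "c")
  all_strs <- c(as.list(alph),
                unlist(lapply(alph, function(x) lapply(alph, function(y)
                  c(x, y))), recursive = FALSE),
                unlist(lapply(alph, function(x) unlist(lapply(alph,
                  function(y) lapply(alph, function(z) c(x, y, z))),
                  recursive = FALSE)), recursive = FALSE))
  attested <- function(s) {
    full <- c("#", s, "#")
    pairs_all <- rbind(c("#", "a"), c("a", "b"), c("b", "#"),
                       c("#", "b"), c("b", "c"), c("c", "#"))
    all(vapply(seq_len(length(full) - 1), function(i)
      any(pairs_all[, 1] == full[i] & pairs_all[, 2] == full[i + 1]),
      logical(1)))
  }
  for (s in all_strs) expect_equal(pw_licensed(pw, s), attested(s))
  # empty lexicon: empty network licenses nothing
  pw0 <- build_pseudoword_network(lexicon(character(), character(),
                                          numeric()))
  expect_equal(nrow(pw0$edges), 0)
  expect_false(pw_licensed(pw0, "a"))
})

test_that("priors: unigram, cohort sum, class mass, bigram backoff", {
  lex <- lexicon(c("a", "b"), c("x y q", "x y r"), c(3, 1))
  lm <- lm_unigram(lex)
  expect_equal(log_prior("a", lm), log(0.75))
  expect_equal(log_prior("b", lm), log(0.25))
  # the shared /x y/ cohort can become either word: total mass 1
  tree <- compile_cohort_tree(lex, dummy_models_for(lex))
  root_child <- tree$nodes[[tree$nodes[[1]]$children[1]]]
  expect_setequal(root_child$completions, c(1L, 2L))
  expect_equal(log_prior(root_child, lm, tree = tree), log(1))
  # class mass multiplies the prior
  expect_equal(log_prior("a", lm, class_mass = 0.5), log(0.75 * 0.5))
  # pseudo prior is the configured network constant
  pw <- build_pseudoword_network(lex, pseudo_prior = 0.05)
  expect_equal(log_prior(pseudo_path(c("x", "y", "z")), pw = pw),
               log(0.05))
  # bigram table: conditional probabilities match direct lookup
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"_": {"a": 0.6, "b": 0.4},
               "a": {"a": 0.1, "b": 0.8},
               "b a": {"b": 0.9}}', path)
  lm2 <- read_lm_json(path)
  expect_equal(log_prior("b", lm2, context = "a"), log(0.8))
  expect_equal(log_prior("b", lm2, context = c("b", "a")), log(0.9))
  # unknown context backs off to the unigram row with a warning
  expect_warning(p <- log_prior("a", lm2, context = "zzz"), "backing off")
  expect_equal(p, log(0.6))
  expect_error(read_lm_json({
    p2 <- withr::local_tempfile(fileext = ".json")
    writeLines('{"_": {"a": 0.9, "b": 0.4}}', p2); p2
  }), "sum to")
})

test_that("completion closure and sharing soundness hold on random lexicons", {
  withr::with_seed(88, {
    for (rep in 1:4) {
      strs <- unique(replicate(12, paste(sample(letters[1:4],
                                                sample(2:4, 1),
                                                replace = TRUE),
                                         collapse = " ")))
      lex <- lexicon(sprintf("w%02d", seq_along(strs)), strs,
                     seq_along(strs))
      tree <- compile_cohort_tree(lex, dummy_models_for(lex))
      # completion closure: a node's completions are exactly the entries
      # whose key sequence extends the node's key-sequence prefix
      keyseq <- lapply(lex$phones, function(p) {
        ph <- strsplit(p, " ")[[1]]
        vapply(seq_along(ph), function(i) {
          k <- sharing_key(ph, i); model_key(k[1], k[2], k[3])
        }, character(1))
      })
      node_keyseq <- function(nd) {
        out <- character(0); cur <- nd
        while (cur$id != 1L) {
          out <- c(cur$key, out)
          cur <- tree$nodes[[cur$parent]]
        }
        out
      }
      for (nd in tree$nodes[-1]) {
        nk <- node_keyseq(nd)
        expected <- which(vapply(keyseq, function(ks)
          length(ks) >= length(nk) &&
            identical(ks[seq_along(nk)], nk), logical(1)))
        expect_setequal(nd$completions, expected)
      }
      # sharing soundness: shared node depth of two entries equals the
      # longest pairwise-equal sharing-key prefix
      chains <- cohortsim:::entry_chains(tree)
      for (i in seq_len(nrow(lex) - 1)) {
        for (j in (i + 1):nrow(lex)) {
          shared_nodes <- length(intersect(chains[[i]], chains[[j]]))
          k <- 0
          while (k < min(lengths(keyseq)[c(i, j)]) &&
                 keyseq[[i]][k + 1] == keyseq[[j]][k + 1]) k <- k + 1
          expect_equal(shared_nodes, k)
        }
      }
    }
  })
})

test_that("lexicon files round-trip", {
  lex <- lexicon(c("ham", "hamster"), c("h { m", "h { m s t @ r"),
                 c(10, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  lex2 <- read_lexicon(path)
  expect_equal(as.data.frame(lex2), as.data.frame(lex))
})
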