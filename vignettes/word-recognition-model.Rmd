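---
title: "A process-oriented simulation of spoken-word recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A process-oriented simulation of spoken-word recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortsim)
```

## The model

`cohortsim` simulates a listener in a psycholinguistic experiment: audio in,
a task decision plus a predicted reaction time out. The simulation has three
serial-parallel components:

1. **Activation.** The waveform is converted to a trajectory of
   39-dimensional feature vectors (13 Mel-frequency cepstral coefficients
   over 25 ms windows every 10 ms, plus first and second regression
   derivatives). Each phone in the lexicon is a context-dependent,
   three-state, left-to-right hidden Markov model; each state carries an
   emission density over feature space — the package's statistical stand-in
   for a spectro-temporal receptive field. Word hypotheses live in a prefix
   tree built from *sharing keys* `(left context, phone, right context)`:
   two words share a tree path exactly as far as their sharing keys agree,
   so *speech* and *speed* share their initial /s p/ models while *spell*
   shares only /s/. At every frame $t$ the decoder computes, for every
   hypothesis $h$ (word, cohort prefix, or phonotactically licensed
   pseudo-word), the frame-normalized activation
   $$ a(h, t) = \frac{1}{t}\Bigl[\max_{\text{alignments}}
      \log P(x_{1..t} \mid h) \;+\; \lambda \log P(h)\Bigr], $$
   where the maximum runs over all monotone state alignments of frames
   $1..t$ ending in any state of $h$'s final phone, and $P(h)$ is the
   top-down prior: a word's ($N$-gram or unigram-frequency) probability, a
   cohort's summed completion probability, or a constant pseudo-word prior.
   A full word *adopts*, at every frame, the best activation over its
   cohort prefixes, reflecting that a cohort under way is part of the full
   form being recognized.

2. **Decision.** Identification selects the best word once its activation
   exceeds the second-best word's by a threshold $\theta$; lexical decision
   compares the best word against the best pseudo-word with a threshold
   $\theta_{ld}$, labeling by the sign of the gap. Candidates are screened
   by beam pruning (hypotheses falling further than `beam` below the best
   are discarded for good) and by *nested-candidate removal*: a hypothesis
   whose phone string is a contiguous substring of a better-scoring
   candidate is dropped, because both lead to the recognition of the same
   longer form. If no threshold is crossed by stimulus offset, the
   highest-activation candidate is chosen and the ambiguity is paid for in
   time: activations are softmaxed at temperature $\tau$, their entropy $H$
   (bits) is computed over the nested-removed candidate set, and a
   Hick–Hyman choice time $a + bH$ is added.

3. **Execution.** A constant latency (default 200 ms) models response
   externalization. Reaction time always decomposes exactly as
   `rt_ms = decision_ms + choice_ms + exec_ms`.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `lm_weight` ($\lambda$) | – | 1 | top-down vs bottom-up balance; task-dependent |
| `beam` | activation (nats/frame) | `Inf` | pruning threshold; `Inf` disables |
| `theta`, `theta_ld` | activation (nats/frame) | 1 | evidence gap required to respond |
| `tau` | activation | 1 | softmax temperature for the choice entropy |
| `hick_a`, `hick_b` | ms, ms/bit | 0, 100 | choice-RT intercept and slope |
| `exec_ms` | ms | 200 | execution latency |
| `word_class_prior` | probability | 0.5 | word-class mass in lexical decision |

Activations are per-frame log scores, so thresholds are in nats per frame.
A single frame's log-density is of order tens of nats for well-separated
emission models, and early frames (whose analysis windows overlap the
stimulus edge) are the most variable; thresholds well below that scale make
the model respond on single-frame noise. In the synthetic experiments
shipped with the package we use $\theta = \theta_{ld} = 60$, which under
the default world (below) yields mostly-early decisions at near-ceiling
accuracy; the speed–accuracy analyses sweep $\theta$ instead of fixing it.
`hick_a`/`hick_b`/`tau` are fit-to-data constants in behavioral modeling;
the defaults are placeholders, not estimates.

The pseudo-word prior defaults to $1/(V+1)$ for a $V$-word lexicon — as
probable as one more word — and is configurable on the licensing network.
In lexical decision the class masses (default 0.5/0.5, the balanced
design) multiply the word and pseudo-word priors respectively.

## The synthetic world

Everything is testable without corpora because the package generates its
own ground truth:

* **Phone inventories** (`make_phone_inventory`): each phone gets a smooth
  random log-Mel spectral profile whose scale is set by `separation`, and a
  matching three-state emission model whose static means are the DCT
  cepstra of that profile (derivative means zero). `separation = 0` makes
  all phones statistically identical; the study worlds use `separation = 4`,
  at which realized inter-phone feature distances are an order of magnitude
  above within-phone spread.
* **Waveforms** (`synthesize_word_waveform`): concatenated noise-excited
  stationary segments shaped by the per-phone spectra, with per-phone
  durations drawn from 60–160 ms (exercising the self-loop duration
  model). Segment-localized white noise at a stated SNR emulates the
  degradation experiments.
* **Lexicons** (`make_zipf_lexicon`): unique random phone strings with
  Zipf-ranked frequencies. By default words avoid immediate phone
  repetition and word-in-word embedding, because stationary phones carry no
  boundary or durational cues: a repeated phone is acoustically identical
  to a single long one, and an embedded word is indistinguishable from its
  host by construction. Natural speech marks these distinctions with
  coarticulation and prosodic lengthening; the synthetic world does not, so
  passing tests here say nothing about embedded-word competition in real
  audio (the tree machinery itself handles embedding and is unit-tested on
  *ham*/*hamster*-style lexicons directly).
* **Trial lists** (`generate_experiment`, `generate_training_trials`): the
  former samples words uniformly and pseudo-words by rejection from the
  phone-bigram licensing network (never equal to an entry); the latter
  cycles the lexicon so every sharing key is attested, which training
  requires.

The default study configuration — 10 phones, 20 words, 5 training tokens
per word, 5 EM iterations, 100 clean test trials — is what
`scripts/acceptance.R` and the heavier tests run; it recognizes words at
or near ceiling and completes in well under a minute.

## Numerical and design choices

* **Best-path scoring.** Activations use Viterbi (maximum) alignment
  rather than forward summation: it decomposes over the prefix tree, and
  it is checkable against exhaustive alignment enumeration on small
  instances (the test suite does exactly that, to 1e-9).
* **Training.** Segmental hard-EM (Viterbi alignment within labeled phone
  segments, then re-estimation). The per-iteration total best-path
  log-likelihood is recorded and is non-decreasing; variances are floored
  at `1e-3` with a warning when the floor binds. Hard assignment was
  chosen over posterior weighting for oracle-testability; the alignment
  step is the same machinery the decoder uses.
* **Context-dependent vs context-independent models.** Lexical hypotheses
  use sharing-key models; pseudo-word hypotheses always use per-phone
  context-independent models, since a hypothesis's future context is
  unknowable while the input unfolds. Both families are trained from the
  same labeled data.
* **Edge conventions.** Frames are centered (reflect padding), frame $t$
  covering $[(t-1)\cdot 10, t\cdot 10)$ ms, so 1 s of audio gives exactly
  100 frames. Delta regressions replicate edge frames. Degenerate inputs
  error early: audio shorter than one window, empty trajectories, empty
  candidate sets, missing hypothesis classes.
* **Ties.** At threshold crossings ties break lexicographically by phone
  string; in nested removal equal-activation ties keep the longer
  candidate (both are deterministic).
* **Reproducibility.** Every stochastic operation takes an explicit seed
  and restores the caller's RNG state (`with_local_seed`), so whole
  experiments are bit-reproducible from a manifest.

## Known limitations

* The synthetic phones are stationary: no coarticulation, pitch, formant
  dynamics, or speaker variation. Context-dependent models therefore all
  estimate the same per-phone density, and the benefit of context
  dependency is not measurable in this world.
* Decoding is isolated-word: no across-word continuous-speech search and
  no lexical feedback from words to the feature level.
* The confidence bands sometimes drawn around activation traces in
  behavioral modeling have no agreed construction here and are not
  produced; `plot.activation_trace` draws point traces only.
* Hick–Hyman constants and thresholds are not fitted to any human data
  set; predictions are qualitative (orderings, monotonicities), which is
  what the test suite asserts.
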