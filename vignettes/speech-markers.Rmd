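---
title: "Automated speech markers for psychosis-spectrum research: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated speech markers for psychosis-spectrum research: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechmarkers)
```

Disorganized speech is among the most robust behavioural markers of the
psychosis spectrum: formal thought disorder manifests as derailment, loose
associations, tangentiality and perseveration, and milder forms of the same
phenomena accompany subclinical schizotypy and delusional ideation.
`speechmarkers` implements a complete marker-extraction and analysis chain
for short, prompt-elicited speech excerpts (the typical design: eight
one-minute picture descriptions per participant), transcribed both
automatically and manually, and related to questionnaire outcomes
(an SPQ-like schizotypy total, a PDI-like delusional-ideation total).
Because recordings from such studies are rarely shareable, the package also
ships a synthetic cohort generator with planted marker–symptom structure,
so the entire chain can be exercised and validated end to end.

## The marker set

### Speech-graph connectivity

A non-semantic word graph represents an excerpt as a directed multigraph:
one node per unique word, one edge per consecutive word transition.
Recurrence structure in the trajectory — returning to recently used words —
shows up as loops and dense strongly connected structure; impoverished
long-range planning shows up as small connected components and short
diameters. `graph_measures()` reports 14 statistics:

* `nodes` (N), `edges` (E, multigraph count = window length − 1);
* `repeated_edges` (surplus duplicate edges in the same direction) and
  `parallel_edges` (unordered word pairs connected in both directions);
* `loop1`, `loop2`, `loop3` — loops of one, two, three nodes: immediate
  word repetitions (self-loops), back-and-forth pairs, 3-cycles. Cycles
  are counted on the binary adjacency with zeroed diagonal
  (`loop2 = tr(A²)/2`, `loop3 = tr(A³)/3`), so self-loops never inflate
  longer loops;
* `lcc`, `lsc` — node counts of the largest (weakly) connected and largest
  strongly connected components;
* `average_total_degree` = 2E/N, `density` = simple directed density
  (self-loops excluded; 0 for a one-node graph);
* `diameter` and `average_shortest_path` over *reachable ordered pairs* of
  the directed simple graph (unreachable pairs are ignored; a graph with
  no reachable pair scores 0 — transition graphs of real windows are
  always chains, so this arises only in degenerate constructions);
* `clustering`: mean undirected local clustering coefficient, nodes of
  degree < 2 contributing 0.

Verbosity strongly confounds raw graph statistics, so
`windowed_measures()` computes every measure on sliding windows of 30
words with a 15-word step and averages across windows; excerpts shorter
than one window form a single whole-sequence window, and a trailing
fragment beyond the last full window is dropped (a partial window would
reintroduce the verbosity effect windowing exists to remove).
`shuffle_null()` compares an excerpt against random speech: the whole
excerpt token sequence is uniformly permuted (100 times by default), the
windowed measures recomputed, and a per-measure z-score reported.
Downstream analyses use the raw windowed measures by default; z-scored
measures are available but optional, since the shuffle null is a
per-excerpt diagnostic rather than part of the marker definitions.

```{r graphs}
toks <- c("the", "cat", "sat", "on", "the", "mat")
graph_measures(toks)[c("nodes", "edges", "lcc", "lsc")]
```

### Semantic coherence

Each sentence is embedded by the smooth-inverse-frequency (SIF) scheme:
stop words and fillers are removed, each remaining in-vocabulary word
contributes its vector weighted by `a / (a + p(w))` with `a = 1e-3`, and
the weighted vectors are averaged. Word probabilities come from a supplied
frequency table — not from the analysed corpus — so the weighting is
reproducible across corpora. Four statistics summarise the sentence
trajectory:

* **coherence** — mean cosine similarity of adjacent sentences;
* **on-topic** — mean cosine of each sentence with the a-priori stimulus
  description of the prompt;
* **tangentiality** — the ordinary-least-squares slope of the
  sentence-to-stimulus cosine over sentence index (drifting away from the
  prompt gives a negative slope);
* **repetition** — the maximum cosine over all sentence pairs.

Verbosity counts (`n_words`, `n_sentences`, `words_per_sentence`) use the
unfiltered token stream, since they measure output quantity rather than
content. Two design points deserve note. First, tangentiality is defined
against the stimulus-similarity series rather than the adjacent-sentence
series: the coherence-model literature this statistic comes from defines
tangentiality as drift away from the prompt, and the on-topic series makes
that directly available. Second, the full SIF recipe removes a corpus-wide
common component from the sentence embeddings; this is **off** by default
(`sif_pc_remove = FALSE` in `extract_corpus()`) because one-minute
excerpts contain roughly 5–15 sentences and the common direction cannot be
estimated stably excerpt by excerpt; when enabled it is estimated once per
corpus and removed from sentence and stimulus embeddings alike.

Missing values are never fabricated: a sentence with no in-vocabulary
word, or whose weighted vectors cancel to a zero vector, is dropped (and
counted in `n_dropped_sentences`); cosines with an undefined direction are
missing, not zero; the pairwise statistics are missing when fewer than two
valid sentences remain.

### Syntactic features

Part-of-speech tag frequencies are computed per excerpt: all tags plus the
six focal categories (comparative adjectives JJR, personal pronouns PRP,
possessive pronouns PRP$, wh-determiners WDT, wh-pronouns WP, wh-adverbs
WRB), each as raw count and per-word rate. Analyses default to raw counts,
which track verbosity the same way the all-tags count does. Both pronoun
categories are computed because the literature is inconsistent about which
one carries the negative association with outcomes; the default marker set
reports both. The tagger backend is pluggable (any function mapping a
token vector to an equal-length Penn tag vector). The built-in default is
a deterministic lexicon-plus-suffix-rule tagger covering English closed
classes exactly and falling back to suffix heuristics for open classes;
it is transparent and fully reproducible, and on the generator's
template-based language it is exact. For naturalistic corpora a
corpus-trained tagger should be plugged in; the frequency logic is
independent of the backend.

### Transcription quality

`align()` computes a minimum-edit-distance word alignment (unit costs)
between a reference (manual) and hypothesis (automated) transcript, with
the counts made deterministic by preferring hits, then substitutions, then
deletions among equal-cost traces (the metrics themselves are
tie-invariant). From the counts:

* WER = (S + D + I) / N_ref,
* MER = (S + D + I) / (H + S + D + I),
* WIL = 1 − H² / (N_ref · N_hyp).

Tokens are compared after the same lowercasing and punctuation stripping
as `tokenize()`, so transcription-style differences do not count as word
errors. `corpus_quality()` reports metrics per excerpt, per participant
(macro-average over the participant's excerpts, mirroring the marker
aggregation rule), and corpus-wide (micro-average, counts pooled before
dividing); studies differ on which average they report, so both are
provided.

## The inferential chain

Markers are averaged per participant over available excerpts (missing
excerpt-level values excluded pairwise, with a logged count). The analysis
then mirrors the standard two-step design:

1. **Agreement**: Spearman correlation per marker between manual and
   automated participant-level means.
2. **Correlations**: Spearman rho of every marker with each outcome,
   separately per transcript version, Benjamini–Hochberg corrected within
   each (outcome × version) family, flagged at the 0.05 and 0.01 levels.
   Pairwise deletion is used here; a constant marker is excluded from the
   family rather than given a fabricated correlation.
3. **Group tests** (extreme-groups designs): two-sided Mann–Whitney tests
   per marker, BH-corrected within each version.
4. **Regression ladders**: five regressor sets — demographics only;
   markers only (automated, manual); demographics + markers (automated,
   manual) — fitted by OLS for continuous outcomes and by maximum-
   likelihood logistic regression for the binary group, all in-sample and
   on a common set of complete-case rows, so R² (and log-likelihood) are
   non-decreasing along each nested pair. Education enters as an ordered
   integer; gender and device are one-hot with first-level reference.
   Linear fits report R², adjusted R², RMSE and the overall F test;
   logistic fits report threshold-0.5 accuracy, sensitivity, specificity,
   precision, F-measure, rank-statistic AUC, and the Cox & Snell,
   Nagelkerke and Tjur pseudo-R². No cross-validation is applied by
   design: the reported quantities are in-sample fit metrics.

Two numerical points: several markers coincide exactly by construction on
fully windowed excerpts (the largest connected component equals the node
count because a word-trajectory window is one chain; the all-tags count
equals the word count; 2-cycles equal parallel edges), so the ladders drop
marker columns that are linearly dependent given the rest of the design,
with a message — a dependency among *demographic* columns, by contrast, is
treated as a genuine design defect and raises an error naming the columns.
Perfect separation in a logistic fit is flagged with a warning and the
metrics are reported from the converged-bounded estimates.

## The synthetic cohort generator

`gen_cohort()` emulates the study design the analysis assumes, with a
per-participant latent disorganization trait θ ~ N(0, 1) driving both the
text and the outcomes:

* **Lexicon**: `n_topics` clusters of unit word vectors around mutually
  orthonormal centres (within-topic cosine ≈ 0.8, between ≈ 0), Zipf-like
  word probabilities, one stimulus description per prompt drawn from its
  assigned topic.
* **Text**: sentences sample content words from the prompt's topic,
  interleaved with closed-class function words; each sentence switches to
  a random other topic with probability `drift_base + drift_slope · θ`
  (defaults 0.15 + 0.15 θ), and each word is immediately repeated with
  probability `repeat_base + repeat_slope · θ` (defaults 0.02 + 0.02 θ).
  Chance adjacent duplicates are collapsed so that immediate repetition is
  exclusively a planted signal. Excerpt length is Normal(100, 20) words —
  a realistic one-minute description.
* **Outcomes**: `round(clip(base + loading · (θ + ε)))` with
  ε ~ N(0, 1), clipped to the questionnaire ranges (0–74 and 0–21);
  defaults SPQ = 26 + 6·(θ + ε), PDI = 7 + 2.5·(θ + ε). Demographics are
  drawn independently of θ. A two-group design (`two_group = TRUE`) draws
  θ from N(∓1.2, 0.6) halves and labels the groups, emulating
  extreme-groups screening.
* **Transcription channel**: each word is independently corrupted with
  probability `asr_error_rate`, the action drawn from a
  substitution/deletion/insertion mix (default 0.5/0.25/0.25); each
  corrupted word contributes exactly one unit edit, so the expected WER of
  long excerpts equals the nominal rate. Punctuation is perturbed
  separately (`punct_error_rate`, default 0.05: boundary merges and
  sentence splits), because the sentence-level semantic measures are
  sensitive to automated punctuation. Two presets fix the channel
  regimes: `"noisy_asr"` (rate 0.21) and `"clean_asr"` (rate 0.08, with
  the two-group design).

What the generator does *not* emulate: natural-language syntax and
semantics beyond topic membership (so the built-in tagger is exact on it,
and coherence reflects topic geometry only), acoustic or speaker effects,
demographic associations with outcomes, and participant dropout. Passing
tests therefore demonstrate that the pipeline recovers structure of the
kind it assumes, at realistic sizes and noise levels — not that the
markers are valid in real speech.

```{r cohort}
co <- gen_cohort(generator_config(n_participants = 6, seed = 42))
co
features <- suppressMessages(aggregate_participants(extract_corpus(co)))
features[1:3, c("participant_id", "version", "loop1", "on_topic")]
```

## Validation scale and reproducibility

All randomness flows from explicit seeds (`generator_config(seed = )`,
`graph_config(seed = )`), and a cohort is byte-reproducible from its
configuration and seed. The test suite validates the implementation
against independent oracles: brute-force and igraph recomputation of the
graph measures (100 random sequences), exhaustive permutation enumeration
for the shuffle null, closed-form SIF and OLS identities, a naive
recursive edit-distance oracle plus `utils::adist` for the aligner, the
literal BH step-up rule, exhaustive Mann–Whitney enumeration, and
hand-computed Bernoulli likelihoods for the pseudo-R². End-to-end
parameter recovery is checked on 50 replicate cohorts of 400 participants
(8 excerpts × 2 versions each): the planted negative on-topic association
must be detected after BH correction, and the demographics+markers model
must beat demographics alone, in at least 90% of replicates; the type-I
arm (all outcome loadings zero) runs at 100 participants, where the
per-family false-rejection rate must stay at the nominal 0.05 within
binomial error. These problem sizes were chosen to match the design the
package targets while keeping the full validation run on a single CPU
practical.

## Known limitations

* The default stop-word list is a compact English list; the exact list
  used by any given study is rarely published, and coherence values shift
  slightly with the list. It is overridable in `filter_config()`.
* The built-in tagger is exact only on closed-class words and regular
  morphology; plug in a trained tagger for naturalistic text.
* The aligner is word-level; no time-aligned or character-level scoring.
* Logistic metrics are in-sample by design; expect optimism relative to
  held-out evaluation, especially with 28 markers and small cohorts.
* The semantic measures inherit the sentence segmentation: with automated
  punctuation, coherence-family markers degrade with the punctuation
  error rate — this is a property of the measurement chain the package
  deliberately preserves (and the generator's punctuation channel lets
  you quantify it).
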