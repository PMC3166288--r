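---
title: "Detecting nucleolar localization sequences with nolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nucleolar localization sequences with nolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nolscan)
```

## The problem

Nucleolar localization sequences (NoLSs) are short protein segments,
typically rich in lysine and arginine, that are sufficient to target a
protein — or a fused reporter — to the nucleolus, the non-membrane-bound
subnuclear compartment where ribosomes are assembled. Unlike nuclear
localization signals, NoLSs have no crisp consensus; the practical way to
find candidates in a sequence is a trained scoring model scanned along the
protein. `nolscan` implements the NoD/clinod detection pipeline: a
sliding-window neural scorer with a segment-averaging caller, the
interval-overlap framework used to benchmark it across organisms, a
synthetic-data generator for self-contained training, and clinod-compatible
batch output.

## The prediction model

Three stages turn a protein sequence of length $L$ into predicted NoLS
intervals.

**Window encoding.** Every 13-residue window (step 1; $L - 12$ windows) is
sparsely encoded: each of the 13 positions contributes a one-hot vector over
a *reduced alphabet* of 12 residue groups, giving a binary feature vector of
length $13 \times 12 = 156$ with exactly 13 ones. The published description
of the original encoder fixes the window size and the alphabet size but not
the group composition, so the grouping is a package design choice,
configurable and embedded in every saved model:

| group | residues | rationale |
|---|---|---|
| basic | K R | the dominant NoLS signal, kept unmerged |
| acidic | D E | standard physicochemical class |
| hydroxyl | S T | |
| amide | N Q | |
| aliphatic | I L V | |
| aromatic | F Y | |
| singletons | A, G, P, C, M | structurally/chemically distinctive |
| bulky | H W | merged to reach exactly 12 groups |

An optional secondary-structure channel appends a one-hot 3-state
(helix/strand/coil) block of $13 \times 3$ bits (feature length 195). It is
a precomputed per-residue string supplied by the user — the role JPred
predictions play for the original server — and is disabled by default; no
remote service is ever invoked. The structure bits are appended as a
trailing block (whether the original interleaved them per residue is not
documented; the trailing-block layout was fixed here once).

**Window scoring.** A feed-forward network maps each window vector to a
score in $[0,1]$. The original tool defers its architecture to an external
neural-network simulator and does not print it, so the smallest architecture
consistent with "artificial neural network" was chosen: one hidden layer
(default 10 units) with logistic activations throughout,

$$p(\mathbf{x}) = \sigma\!\big(\mathbf{w}_2^\top \sigma(W_1^\top \mathbf{x}
+ \mathbf{b}_1) + b_2\big),$$

which trains in seconds at desk scale and keeps every score in the closed
unit interval for arbitrary finite weights. All of hidden size, epochs,
learning rate and momentum are arguments of `train_model()`.

**Segment calling.** The caller averages the scores of 8 consecutive
windows, i.e. of every 20-residue *candidate segment*
($13 + 8 - 1 = 20$), and calls a segment positive when its mean score is at
least 0.8 (inclusive — "at least" is taken literally). Overlapping positive
segments are merged into one interval, which is the only way intervals
longer than 20 residues arise; positive segments whose spans do not overlap
stay separate even when they touch end-to-start, since a 19-residue run of
sub-threshold segments separates their starts. Every called interval
therefore spans at least 20 residues. Coordinates are 1-based inclusive
throughout.

### Key parameters (`nols_params()`)

| parameter | default | unit | meaning |
|---|---|---|---|
| `window_length` | 13 | residues | scoring window |
| `alphabet_size` | 12 | groups | reduced-alphabet size |
| `consecutive_windows` | 8 | windows | averaged per candidate segment |
| `score_threshold` | 0.8 | — | inclusive calling threshold |
| `min_overlap_fraction` | 0.6 | — | interval-match criterion |
| `max_test_nols_length` | 50 | residues | evaluation length cap |

The first four define the published operating point; changing them changes
the method, not just its sensitivity. Raising `score_threshold` never
increases the number of residues covered by calls (a tested invariant).

### Numerical and degenerate-input conventions

* Sequences shorter than 13 residues produce no windows, and shorter than
  20 no candidate segments; batch prediction reports "no NoLS" with a
  warning instead of failing, so one fragment never aborts a proteome scan.
* The per-residue score profile (for plots and the FULL/COMPLETE formats)
  assigns residue $i \le L-19$ the score of the segment starting at $i$;
  the trailing 19 residues repeat the last defined segment score so that
  every residue has a value. The original graph's convention for the tail
  is not documented; repetition was chosen over zero-filling because it
  does not fabricate an artificial cliff at $L-19$.
* Ambiguous characters (anything outside the 20 standard codes, including
  B/Z/J/X/U/O, `*`, gaps, digits and whitespace) are *removed*, not
  substituted, when cleaning is requested; every removal is logged with its
  original coordinate, and all downstream positions refer to the cleaned
  sequence. A record that cleans to nothing is an error.
* Model files store weights as `%.17g` decimal strings inside JSON: 17
  significant digits reproduce every IEEE double exactly, so a
  save/load round-trip changes no score by even one ulp. The file embeds
  the alphabet and a fingerprint; loading against a tampered alphabet is
  refused rather than silently mis-encoding.

## Training

`train_model()` uses full-batch gradient descent with momentum on weighted
binary cross-entropy. Full-batch (rather than stochastic) descent makes
training exactly reproducible from a single seed without any dependence on
batch partitioning; at the corpus sizes involved (thousands of 156-bit
windows) each epoch is a pair of matrix products and the whole fit takes
well under a second. Classes receive equal effective weight by default
because realistic corpora are heavily imbalanced — the original predictor
was trained on 46 positive NoLSs against several hundred negative proteins
— and the same knob is needed to replicate that regime on synthetic data.
Early stopping monitors a held-out fraction (default 10%) and keeps the
best weights after 25 epochs without improvement. All randomness — weight
initialisation and shuffling — flows from one explicit seed, and two runs
with the same data and seed produce bit-identical weights.

The original human-trained network weights are not distributed and cannot
be reproduced here; the architecture is replicated and retrainable instead.
Published per-protein predictions of the benchmark are therefore shipped as
fixture data, not recomputed.

## The synthetic corpus

`motif_model()` defines what a planted NoLS looks like: motif length
uniform on 15–40 residues, motif residues i.i.d. from a K/R-enriched
composition (K = 0.30, R = 0.25, the remaining 0.45 uniform over the other
18 residues), background residues uniform. These defaults were chosen once
as a caricature of the real signal — experimentally mapped NoLSs are mostly
15–40 residues long and roughly half basic residues — and are deliberately
simple: i.i.d. draws, no positional profile, no secondary structure, no
compositional autocorrelation, no divergent signals of the kind
trypanosomes appear to use. End-to-end tests train on 2,000 positive and
2,000 negative windows and scan 200 held-out 300-residue proteins, each
with one planted motif; these problem sizes are the package's fixed study
conditions. Passing them shows the pipeline is wired correctly — encoding,
training, calling and evaluation compose into a detector that recovers a
strong planted signal with few spurious calls — but says nothing about
accuracy on real proteomes, which depends entirely on the training corpus
used.

## Evaluation framework

The benchmark (`nod_benchmark()`) pairs 31 experimentally determined NoLSs
on 27 proteins across eukaryotes and viruses with the 28 intervals the
original NoD predictor called on those proteins. The accuracy framework
reproduces the published analysis:

* **Overlap criterion.** A predicted and an experimental interval match
  when their intersection covers at least 60% of the *shorter* of the two
  (`overlap_fraction()`); containment in either direction scores 1.
* **Many-to-many matching.** An experimental NoLS is detected if any
  prediction matches it; a prediction is a true positive if it matches any
  experimental NoLS. No one-to-one assignment is made — this is the only
  reading that reproduces the published counts (TP = 22, FP = 6) row by
  row. A single prediction matching two experimental NoLSs would count
  twice; the case does not arise in the benchmark.
* **Per-protein specificity.** The fraction of proteins with zero
  false-positive segments (21/27 = 78%), the only definition consistent
  with the published phrasing; sensitivity is detected/total NoLSs (22/31 =
  71%) and PPV is TP predictions over all predictions (22/28 = 79%).
* **Length filter.** Only experimental NoLSs up to 50 residues *inclusive*
  enter the evaluation. The published wording says "less than 50", but the
  benchmark retains an interval of inclusive length exactly 50, so `<=` is
  the default and the strict variant is available via
  `nols_params(strict_length_filter = TRUE)`. Predictions whose only
  potential match is filtered out count as false positives.
* **Rounding.** Group metrics are reported to 2 decimals and overall
  metrics as integer percentages, matching the published presentation
  (`print()` on the metrics table applies this; the underlying columns stay
  raw fractions).

One internal inconsistency in the published worked example is resolved in
favour of positions: the example output lists a second NoLS at 165–213 (49
residues) but prints a 25-residue segment sequence for it. Interval
positions are treated as authoritative; the rendering layer prints whatever
segment strings it is handed.

## Output formats

`render_block()`/`nod_run()` reproduce the five clinod output levels —
MINIMAL, SHORT, MEDIUM (default), FULL, COMPLETE — each a strict superset
of the previous: name; + `NOLS_segment_number`; + `NOLS_segments_positions`
(comma+space separated `start-end` pairs); + `NOLS_segments`; + one
per-residue score per line (2 decimals; the published example lost its
delimiters in typesetting, and newline separation was chosen for
unambiguous parsing); COMPLETE additionally echoes the input sequence.
`exec/nolscan` wraps this as a command-line batch tool with `--clean`,
`--skip-negative`, `--threshold`, `--structure` and `--format` switches
(the original tool's switch names are not documented in the main text, so
descriptive long names are used).

## Known limitations

* Scores from the bundled `demo_model()` are calibrated on synthetic data
  only; it is a demonstration and test model, not a substitute for a model
  trained on curated NoLSs.
* The reduced-alphabet composition is a reconstruction; the original
  12-group scheme is not published. Any grouping can be supplied, and
  models carry theirs with them.
* The evaluation benchmark is small (31 NoLSs); per-group metrics rest on
  one or two proteins in several groups and should be read accordingly.
* Divergent nucleolar-targeting signals (e.g. trypanosomes, where the
  human-trained predictor finds nothing) are outside what the synthetic
  generator emulates.
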