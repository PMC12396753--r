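---
title: "Modelling R-loop formation with a probabilistic grammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling R-loop formation with a probabilistic grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.2)
library(rloopgrammar)
library(dplyr)
```

## The model

An R-loop is a three-stranded structure that forms during transcription: the
nascent RNA hybridises with the template DNA strand and displaces the
non-template strand. Single-molecule R-loop footprinting (SMRF-seq) reports,
for each molecule, one interval $[i, j]$ on the plasmid where an R-loop
formed. `rloopgrammar` models a population of such footprints with a
probabilistic right-linear grammar over ten terminal symbols.

The gene region $[b, e]$ of the plasmid (non-template strand, 5'→3') is
tiled, relative to one R-loop $[i, j]$, into *parsing blocks* of $k$
nucleotides, plus two variable-length blocks `alpha` (just before $i$) and
`omega` (just after $j$) of length $0..k-1$ that absorb the coordinate
remainders and model the experimentally imprecise branch-migration
boundaries. Each $k$-block is mapped through a dictionary to a terminal
symbol that depends on whether the block lies outside or inside the R-loop:

| outside (DNA:DNA duplex) | inside (RNA:DNA hybrid) | meaning |
|---|---|---|
| `sigma` | `tau_hat` | start-associated: duplex prone to open, hybrid stable |
| `sigma_hat` | `tau` | end-associated: duplex stable, hybrid prone to revert |
| `delta` | `beta` | ambiguous (both start- and end-associated) |
| `gamma` | `rho` | no information in the training data |

Three rule families generate every word: `S -> x S | x alpha R` (before the
R-loop), `R -> y R | y omega Q` (inside), `Q -> x Q | x` (after); 24 rules
in total. The grammar is unambiguous, so every word has exactly one
derivation and maximum-likelihood estimation reduces to relative-frequency
counting of rule applications (`fit_grammar()`; a pseudocount argument
provides Laplace smoothing for degenerate corpora, default 0). The
probability of a word is the product of its rule probabilities
(`word_probability()`).

## From footprints to a dictionary

For each footprint, sliding windows of width $k$ shifted $p$ times collect
the k-mers just upstream of initiation (region r1), at the start of the
R-loop (r2), at its end (r3) and just downstream of termination (r4)
(`extract_region_kmers()`). Each k-mer $s$ in region $r_i$ receives the
weight
$$w_i(s) = \frac{n_i(s)}{N \, m_s},$$
where $n_i(s)$ counts occurrences of $s$ across all footprints' $r_i$
windows, $N$ is the number of footprints and $m_s$ the number of
(overlapping) occurrences of $s$ in the gene region. Weights are rescaled by
the top weight, each rank gets the entropy $H = -w' \log_{10} w'$, and the
running average $h_n$ of $H$ over ranks is maximised to find the cutoff: the
ranks up to the (first) global maximum of $h$ form the *highly weighted*
list (`entropy_threshold()`). K-mers with exactly equal weight share one
rank — equality is decided on the reduced fraction $n/m$, so floating-point
noise cannot split a tied group — and tied groups enter or leave the list
whole.

A k-mer's symbol follows from where its highly-weighted maximum lies: start
regions (r1/r2) give `sigma`/`tau_hat`, end regions (r3/r4) give
`sigma_hat`/`tau`, an exact start–end tie gives `delta`/`beta`, and absence
gives `gamma`/`rho` (`assign_symbols()`). Within one training set all four
region weights of a k-mer share the denominator $N m_s$, so maxima and ties
are decided on the integer counts. Dictionaries from two plasmids merge into
a union dictionary entry by entry; conflicts are resolved either
deterministically (indeterminate loses to determinate, any other
disagreement becomes the ambiguity symbol) or stochastically (a seeded coin
picks one side), `merge_dictionaries()`.

## Prediction

All candidate R-loops on a plasmid are the intervals $[i, j]$ with length a
multiple of $k$ and at least one full block on each side of the gene region
(the start and end rule families each emit at least one block, so shorter
margins admit no derivation). Each candidate's word probability is computed
in log space and normalised over the candidate set; the per-nucleotide
probability of R-loop formation is then the total probability of the
candidates covering each position (`predict_track()`). The implementation
evaluates candidates in O(1) from prefix sums of per-position rule
log-probabilities; an explicit enumeration oracle (`method = "enumerate"`)
is retained and the two are tested to agree to $10^{-10}$. Log-zero is
represented by a finite sentinel ($-10^9$) so prefix differences never
produce NaN; a candidate whose accumulated log-probability falls below
$-10^8$ is treated as having probability zero, and if every candidate is
zero the distribution falls back to uniform with a warning rather than
propagating NaN.

The full protocol (`ensemble_predict()`) reserves one third of the data as
a holdout, then trains each of 30 models on an independent 10% subsample
(without replacement) of the remaining two thirds, builds per-plasmid
dictionaries, merges them, encodes the subsample as words, fits the rules,
and predicts a track; the reported track is the per-position ensemble mean
with its standard error. All randomness derives from one master seed
(per-model and per-plasmid sub-seeds), so runs are bit-reproducible.

## Choosing k and p

`threefold_cv()` evaluates a $(k, p)$ grid — the protocol grid is
$k \in \{3,4,5\}$, $p \in \{7,13\}$ — by three-fold cross-validation:
predictions for each validation fold are compared with that fold's
empirical coverage track by RMSD and Pearson correlation, and the pair with
the lowest mean RMSD (ties: highest Pearson) wins. The padding values
correspond to roughly one ($p=7$) and one and a half ($p=13$) turns of
A-form helix, the geometry of an RNA:DNA hybrid, and absorb the ~15 nt
experimental imprecision of footprint boundaries. By default each fold is
scored with the same subsample-ensemble protocol used for prediction
(`n_models`, `subsample_frac` arguments); a single model trained on the
whole training portion of a fold is markedly noisier between folds, which
on desk-scale data can dominate the differences between grid cells.

## The synthetic-data generator

`synthetic_spec()` + `generate_smrf_dataset()` produce a plasmid and a
footprint population with known ground truth, sized to the study
conditions: a 1.4 kb gene region inside 120 nt flanks and 600 footprints
per condition (the supercoiled pFC53 dataset has 612). Initiation positions
are a two-component Gaussian mixture whose means shift towards the promoter
by 0/5/15% of the gene as topology moves from linear to hyper-negatively
supercoiled — topology is emulated *only* through this positional shift,
matching how the grammar itself learns topology from the data rather than
from an explicit parameter.

The sequence model embodies three deliberate choices:

* **Low-complexity background** (`complexity = 0.25`): the backbone is
  assembled from a small tile vocabulary reused along the whole plasmid,
  with 5% point substitutions. CpG-island-class sequence is repeat-rich,
  and this property matters for the grammar: if background k-mers were
  unique to the R-loop zone (as in an i.i.d. background), the fitted
  inside-context chain rules would be systematically cheaper than the
  outside ones along that zone and the predicted R-loop lengths would
  inflate; a shared vocabulary keeps the per-block economics position-free,
  and the predicted track amplitude matches the empirical one.
* **Composite boundary elements**: initiation sites carry `GGTTGTGG`
  (planted start 4-mers `GGTT`, `GTGG`), termination sites `TTGGTGTT`
  (end 4-mers `TTGG`, `TGTT`). The two elements are different orderings of
  the *same* 3-mer multiset with disjoint 4-mer sets, so the start/end
  distinction is carried exactly at scale $k = 4$ and is invisible to
  3-mer statistics; every site carries the whole motif set, so each planted
  k-mer receives an equal share of footprints. Termination elements sit
  $\lfloor k/2 \rfloor$ nt downstream of the footprint end so that rounding
  footprint lengths to multiples of $k$ (ties up) never moves the element
  out of the downstream harvest windows.
* **Diffuse boundaries**: a footprint snaps to the nearest element with
  probability 0.6 and both boundaries then receive Gaussian read-out error
  (sd 12 nt, within the ~15 nt imprecision reported for the assay). The
  diffuse component spreads harvested windows over the whole cluster zone,
  which is what gives the weight lists their flat tail and the dictionaries
  realistic coverage.

What the generator does *not* emulate: thermodynamics or supercoiling
energetics (topology is positional only), bisulfite conversion artefacts,
multi-R-loop molecules (each record is one footprint), and any base
composition gradient along the gene. Passing tests on this generator
demonstrate that the pipeline recovers planted sequence structure from
interval data under realistic noise — not that the grammar's biological
interpretation is correct for real plasmids.

## Worked example

```{r pipeline}
spec <- synthetic_spec(seed = 421)
d <- generate_smrf_dataset(spec)
d$plasmid

ds <- preprocess_rloops(d$rloops, d$plasmid, k = 4)
split <- split_train_holdout(ds, holdout_frac = 1 / 3, seed = 1)

ens <- ensemble_predict(split$train, d$plasmid, k = 4, p = 13,
                        n_models = 30, subsample_frac = 0.10,
                        seed = 7, max_len = 600)
emp <- empirical_track(split$holdout, d$plasmid)
compare_tracks(ens$tracks$synthetic, emp)
```

```{r plot}
plot_track_comparison(ens$tracks$synthetic, emp)
```

The planted dictionary classes are recovered from the data alone:

```{r dict}
dict <- build_symbol_dictionary(split$train, d$plasmid, k = 4, p = 13)
dict |> filter(kmer %in% c(spec$start_kmers, spec$end_kmers))
dictionary_coverage(dict)
```

## Numerical and design notes

* Internal coordinates are 1-based inclusive $[i, j]$; BED's 0-based
  half-open convention is converted at the file boundary and round-trips
  bit-exactly.
* Footprint lengths are rounded to the nearest multiple of $k$ with ties
  up, clipping at the gene-region end; a footprint that cannot keep one
  full block of gene sequence on each side has no derivation and is
  dropped with a message.
* The entropy logarithm is base 10; the first rank attaining the global
  maximum of $h$ wins ties.
* `m_s` counts overlapping occurrences in the gene region of the
  non-template strand only.
* Rule probabilities of unobserved rules are exactly zero by default; the
  `pseudocount` argument is the single knob for degenerate small corpora.
* Candidate enumeration cost is bounded by `max_len`; analyses in this
  package use 600 nt, comfortably above the generator's mean footprint
  length of 240 nt.
* Problem sizes used in the test-suite experiments: one 1.4 kb plasmid,
  400–600 footprints, ensembles of up to 30 models, 3-fold CV over the
  six-cell grid with 6-model ensembles per fold.

## Limitations

* The grammar models exactly one R-loop per molecule; reads carrying
  several footprints are split and treated as independent molecules.
* Probabilities are composition-driven: the grammar has no explicit
  position or length potential beyond what the rule frequencies imply, so
  data whose dictionaries are mostly indeterminate (sparse coverage) yield
  weakly anchored predictions.
* On a single desk-scale plasmid the $(k, p)$ selection of
  `threefold_cv()` carries substantial fold-to-fold variance; ensemble
  scoring reduces but does not eliminate it.
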