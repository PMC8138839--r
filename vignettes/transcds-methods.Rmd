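---
title: "Models and methods behind transcds"
author: "transcds authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind transcds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A mature eukaryotic mRNA is, structurally, a 5' untranslated region (UTR),
a coding sequence (CDS) running from an ATG start codon through an in-frame
stop codon, and a 3'UTR.  De novo transcriptome assemblies deliver
transcripts whose CDS boundaries are unknown, whose strand may be unknown
(many RNA-seq libraries are unstranded), and which are frequently
fragments missing the start codon, the stop codon, or both.  `transcds`
locates the single CDS (and thereby both UTRs) in each transcript under
all of these conditions.

# The model

Transcripts are modeled with generalized hidden Markov models (GHMMs):
hidden semi-Markov models whose states emit variable-length segments with
explicitly modeled length distributions.  Two architectures are used.

**Full-transcript architecture.**  A linear skeleton
`UTR5 -> Start -> fullCDS -> Stop -> UTR3`.  `Start` and `Stop` are
fixed-duration 3-base signal states; `fullCDS` is an explicit-duration
content state; the UTR states are geometric (self-loop) states.  A path
may also end inside `UTR5`, giving a no-CDS labeling so that non-coding
sequences can yield "no prediction".

**Partial-transcript architecture.**  Adds three entry states `pCDS0`,
`pCDS1`, `pCDS2` for fragments that begin inside the CDS.  State `pCDSf`
emits fragments whose first *complete* codon begins at offset `f` (the
frame reported in calls and GTF output); the codon phase of its first base
is therefore `(3 - f) mod 3`.  Paths may begin in `UTR`, `Start` or any
`pCDSf`, and may end in `UTR`, `fullCDS`, any `pCDSf`, `Stop` or `UTR3`,
covering every combination of missing start and/or stop.  Both
architectures allow at most one contiguous coding segment per path.

## Emission models

* **Coding states** use a three-periodic Markov chain: one order-4
  conditional table per codon position (order configurable via
  `trainingConfig()`).  Contexts observed fewer than 10 times during
  training automatically back off to the next-lower order, down to the
  order-0 marginal, so sparse training data degrade gracefully rather
  than overfitting the Laplace prior.
* **UTR states** use homogeneous order-3 chains.
* **Start/Stop signal states** use positional weight models: 12 columns at
  offsets -6..+5 around the start codon (a Kozak-like context plus the
  codon itself) and 6 columns over the stop codon plus 3 downstream bases.
  The codon positions are additionally hard-constrained: a `Start` segment
  must read `ATG` and a `Stop` segment must read TAA, TAG or TGA, so every
  complete call is biologically valid by construction.

Window columns that fall outside the signal state's emitted 3 bases
overlap the flanking UTR or CDS segments.  Their window score *replaces*
the flanking chain's score (the flank model's per-position log-probability
over those columns is subtracted from the anchor score).  Without this
log-odds treatment the flanking bases would be emitted twice, and every
path containing a Start/Stop state would carry a constant spurious
penalty relative to paths that skip them; with it, the window contributes
a proper positive or negative signal-vs-content evidence term.

In-frame stop codons inside any coding segment score `-Inf` rather than
being merely disfavored: predicted complete CDSs are always translatable.
`N` bases are marginalization symbols: they contribute zero log-probability,
and contexts containing `N` fall back to the model's uniform-context
marginal, so ambiguity codes never produce `-Inf`.

## Duration models

Explicit-duration states use a Gaussian-kernel-smoothed empirical pmf over
the observed length range plus a geometric tail holding mass `1/(n+1)`,
whose decay matches the mean excess of the upper decile of the training
lengths.  `fullCDS` durations (CDS length minus the 6 codon-anchor bases)
live on a mod-3 lattice, which enforces frame consistency between the
start and stop codons by construction; partial-CDS durations are
unquantized, and the mod-3 relation between a `pCDSf` fragment and its
following stop codon is enforced as a length-congruence constraint
(`len mod 3 = f`) on internal segments instead.

Because no natural "partial transcript" training data exist, the
partial-CDS duration model is fitted to simulated uniform truncations of
the training CDSs, mirroring the evaluation construction: the truncation
point is uniform over admissible offsets subject to a 150 nt floor on the
*resulting sequence* (CDS fragment plus remaining 3'UTR), falling back to
pruning exactly at the codon when the transcript is too short.

**Censored final segments.**  A fragment's last segment is cut off by the
end of the sequence, so its observed length is right-censored.  Final
segments of explicit-duration states are therefore scored with the
duration survival function `P(D >= d)` rather than the pmf.  This also
resolves what would otherwise be a contradiction: a truncated `fullCDS`
(missing stop) can have any length, while the quantized pmf only supports
multiples of 3.

## Decoding

An exact explicit-duration Viterbi algorithm (implemented in C++) computes
the maximum joint log-probability labeling: initial + segment emissions
(codon phases threaded through coding segments) + duration terms +
transitions + final-state weight.  Emissions enter as phase-threaded
cumulative sums, so each candidate segment scores in O(1); positions with
`-Inf` emission are tracked in a parallel cumulative mask-count array,
which keeps the finite sums exact (no large-negative sentinel can absorb
them) while making any segment containing such a position inadmissible.
The duration search for explicit states is bounded by
`max_len + ceil(10 * step / (1 - r))` with `r` the tail continuation
ratio; the truncation error is negligible because the tail mass beyond
that horizon is below `r^10/(n+1)`.  Complexity is O(L·D) per explicit
state.  Among exactly equal-scoring paths the decoder keeps the first
found under a fixed enumeration order (shorter durations, lower state
index), which makes results deterministic; exact ties between distinct
real-valued scorings essentially never occur with trained models.

A call is emitted only when the best coding path outscores the best
non-coding path (a single UTR-state segment, the only coding-free labeling
the skeletons admit) by at least a margin (default 0, so coding wins exact
ties).  The same margin, made configurable, turns the predictor into a
coding-potential classifier.

**Strand-blind decoding** decodes the input and its reverse complement
with the same strand-specific model and keeps the higher-scoring call,
mapped back to input coordinates; the plus strand wins exact ties.

# Training

Training is fully supervised from annotated transcripts (no
expectation-maximization): periodic chains from in-frame interior codon
positions (start and stop codons excluded), UTR chains from their regions,
positional models from aligned windows, durations as above, and
initial/self-loop probabilities from region presence frequencies and mean
region lengths, all Laplace-smoothed (pseudocount 1 per cell).

Because GC content shifts codon usage and background composition, the
training set is partitioned into GC bins (default `[0, 0.45)`,
`[0.45, 0.55)`, `[0.55, 1]`; configurable) with one full/partial
architecture pair per bin.  At prediction time the bin is chosen from the
whole transcript's GC fraction, since the CDS is unknown.  Bins with fewer
than 30 training transcripts borrow the nearest populated bin's
parameters, which is recorded in the bundle metadata.  The spec's initial
state for the full architecture is the 5'UTR; transcripts with empty
5'UTRs are accommodated by estimating the initial distribution over
{UTR5, Start} from the smoothed fraction of training transcripts with a
non-empty 5'UTR.  The partial architecture's entry distribution is uniform
over its five entry states, as nothing in (full-length) training data
identifies truncation frequencies.

Bundles serialize to a versioned, human-diffable text format: a one-line
JSON header carrying the format name, version and an MD5 checksum of the
payload, followed by a pretty-printed JSON payload with all
log-probabilities at 17 significant digits, so decoding scores are
bit-identical before saving and after loading.

# The synthetic corpus generator

`generateCorpus()` emulates the structure the model assumes: 5'UTR +
ATG + a run of sense codons drawn i.i.d. from a codon-usage table (no
in-frame stop by construction) + stop codon + 3'UTR, with non-coding
negatives drawn from a UTR-like composition (no constraint against chance
ORFs, as in real ncRNA).  Defaults were chosen once as a realistic
strong-signal corpus: median 150 sense codons (rounded clamped log-normal,
50-600), median 5'UTR 80 nt and 3'UTR 150 nt, AT-leaning UTR
compositions, a gccacc-style start context at 70% consensus, stop usage
TAA 0.45 / TGA 0.35 / TAG 0.20, and exponential-weight codon usage
(`codonUsageTable("strong")`); a near-uniform `"weak"` preset exists for
hard-case testing.  What the generator does **not** emulate: sequencing
error, assembly chimeras, secondary structure, length-dependent codon
bias, and real organisms' usage tables.  Passing the synthetic benchmarks
therefore demonstrates correctness of the machinery and learnability of
the modeled signal, not field accuracy on any particular organism.

Test sets derive from a complete corpus exactly as the evaluation protocol
prescribes: strand scrambling of a random half, NoStart / NoStop /
NoStart&NoStop truncations (uniform truncation points, 150 nt floor with
prune-at-codon fallback), complete 3'UTRs as poly-A-selection negatives,
and seeded mixed runs of 500 full + 500 partial positives with >=200 nt
non-coding negatives.

# Evaluation conventions

True positives are predictions that exactly match the reference under the
chosen criterion: the stop codon (position and strand) for
`stop_match`, or start, end and strand for `full_cds_match`; any other
prediction is a false positive, and a missing prediction a false negative.
On negative sets any prediction counts as a false positive.  The
specificity operation reports both `FP/(FP+TN)` (the printed form, a
false-positive rate) and its complement `TN/(TN+FP)` (the standard form),
clearly labeled; they always sum to 1 and neither is silently corrected
into the other.

# Problem sizes and numerical choices

The packaged benchmarks train on 1000 synthetic transcripts and evaluate
500 held-out transcripts per condition, with parameter recovery measured
on 2000; these sizes give stable metrics (binomial standard error on an
F1 near 0.97 at n = 500 is about 0.008) at interactive runtimes.  All
distribution constructors assert normalization to 1e-9; scores are
natural-log throughout with no scaling tricks, since segment scores of
desk-scale transcripts stay far from double underflow.  Sequences shorter
than 60 nt yield a logged no-call.

# Known limitations

* One CDS per transcript by design; polycistronic or overlapping ORFs are
  out of scope.
* The partial architecture's entry prior is uniform rather than learned.
* GC sub-models share nothing across bins; very sparse bins fall back to
  borrowing wholesale.
* The generator's negatives are compositional only; classifiers that
  exploit RNA secondary structure would not be stressed by them.
* The full architecture cannot represent transcripts with an empty 3'UTR
  ending exactly at the stop codon; the partial architecture handles them.
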