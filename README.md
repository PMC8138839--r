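# transcds

CDS and UTR annotation in eukaryotic transcript sequences with
explicit-duration generalized hidden Markov models.

De novo transcriptome assemblies produce transcripts whose protein-coding
region (CDS) is unannotated, whose strand is often unknown, and which are
frequently fragments missing the start codon, the stop codon, or both.
`transcds` locates the single CDS — and thereby the 5′ and 3′ UTRs — in
each transcript under all of these conditions, trains its own models from
annotated transcripts, and ships the evaluation machinery and a synthetic
corpus generator needed to benchmark itself without any external data.

## The model

A transcript is decoded against one of two generalized hidden Markov
models (hidden semi-Markov models): a **full-transcript** architecture

    UTR5 → Start → fullCDS → Stop → UTR3

and a **partial-transcript** architecture that adds entry states
`pCDS0/pCDS1/pCDS2` for fragments beginning inside the CDS at frame 0, 1
or 2, and allows paths to end inside the coding region (missing stop).
Coding segments are scored by three-periodic Markov chains (order 4 by
default, with automatic back-off for sparse contexts), UTRs by order-3
chains, and the start/stop codons by fixed-length anchored positional
weight models with hard codon constraints — a complete call always begins
`ATG`, ends in a stop codon, has length ≡ 0 (mod 3) and contains no
in-frame internal stop.  Segment lengths of the coding states follow
smoothed empirical duration distributions with geometric tails (mod-3
quantized for complete CDSs); final segments are scored with the duration
survival function, since a fragment's last segment is right-censored.
An exact explicit-duration Viterbi algorithm (O(L·D) per explicit state,
implemented in C++) returns the maximum-probability labeling; a call is
emitted only when the best coding path outscores the best non-coding path.
Models are trained per GC-content bin and selected at prediction time from
the transcript's GC fraction.  Strand-blind decoding runs the
strand-specific model on the input and its reverse complement and keeps
the higher-scoring call.

## Worked example

```r
library(transcds)

## a synthetic ground-truth corpus: 5'UTR + ATG + codon run + stop + 3'UTR
train <- generateCorpus(generatorConfig(seed = 42L, n = 200L))
bundle <- trainBundle(train)

test <- generateCorpus(generatorConfig(seed = 99L, n = 40L))
calls <- predictTranscripts(bundle, test, mode = "full", strand = "plus")
as.data.frame(calls)[1, c("transcriptId", "start", "end", "strand",
                          "frame", "hasStart", "hasStop", "logScore")]
#>   transcriptId start end strand frame hasStart hasStop  logScore
#> 1      tx00001    91 562      +     0     TRUE    TRUE -989.0229

truthTable(test)[1, c("id", "cdsStart", "cdsEnd")]
#> DataFrame with 1 row and 3 columns
#>            id  cdsStart    cdsEnd
#>   <character> <integer> <integer>
#> 1     tx00001        91       562

out <- evaluatePredictions(truthTable(test), calls, "full_cds_match")
out
#> EvalOutcome (full_cds_match): TP=40 FP=0 FN=0 TN=0
precisionRecallF1(out)
#> precision    recall        f1
#>         1         1         1
```

`start`/`end` are 0-based half-open offsets in input orientation; the call
above reproduces the generator's ground-truth CDS exactly, so precision,
recall and F1 on this 40-transcript held-out set are all 1.
`writePredictions()` serializes calls as `CDS.fasta`, `UTR5.fasta`,
`UTR3.fasta` and a 9-column `predictions.gtf` (1-based inclusive
coordinates).  `degradeCorpus()` / `buildTestSets()` derive the standard
strand-blind, NoStart, NoStop, NoStart&NoStop and negative evaluation
sets; `classifyCoding()` turns the score margin into a coding-potential
classifier.

A command-line interface is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "transcds", package = "transcds"))')
Rscript "$CLI" train    --transcripts train.fa --annotations train.gtf --output model.bundle
Rscript "$CLI" predict  --input assembly.fa --model model.bundle \
                        --strand both --output predictions/
Rscript "$CLI" classify --input assembly.fa --model model.bundle
```

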