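---
title: "Transcript geography encodings for RNA modification site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript geography encodings for RNA modification site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geotx)
```

## The problem

N6-methyladenosine (m6A) and related RNA modifications are laid down at
specific positions of specific transcripts, and where a ribonucleotide sits
*within* its transcript — in a long exon, in the last exon, just upstream of
the stop codon, deep inside a 3'UTR — is strongly associated with whether it
can be modified. Most sequence-based site predictors see only a local window
of primary sequence and discard this sub-molecular *geography*. `geotx`
encodes the geography of a target ribonucleotide relative to the whole
transcript in several compact forms, feeds those encodings to small
convolutional and attention-based models, and provides the supporting
machinery: annotation ingestion and coordinate mapping, a permutation-FDR
procedure for multi-technique site agreement, and a fully synthetic data
generator so that every operation is testable without downloads.

## Region model and coordinate conventions

All internal coordinates are 1-based inclusive, the GTF dialect; BED input
(0-based half-open) is converted at the read boundary. A transcript is an
ordered set of exons with an optional CDS span. `decompose_regions()` tiles
the transcript span with maximal runs of identical region type over five
indicators — exon, intron, CDS, 5'UTR, 3'UTR — with two structural
invariants: every run is exonic or intronic but never both, and CDS/UTR
flags only occur on exonic runs. UTRs are inferred as exonic space outside
the CDS; the stop codon is taken exactly as annotated, with no ±3
adjustment, because annotation sources differ in whether the stop codon is
part of the CDS and second-guessing the annotation invites silent
off-by-three errors. Every encoder works in transcript orientation (position
1 is the 5' end), which makes all encodings strand-invariant by
construction — a property the test suite checks on mirrored transcripts.

## The four encodings

**Landmark distances** (`encode_landmark_tx()`): six numbers, the distances
from the site to the 5' and 3' boundaries of its exon, of the CDS, and of
the transcript. Distances are positional differences, so a boundary site has
distance 0 and region width equals `d5 + d3 + 1`; a model can recover the
width of the containing exon by adding two features. The CDS distances are
signed: `d_cds5 = pos(site) - pos(CDS start)` is negative in the 5'UTR and
`d_cds3 = pos(CDS end) - pos(site)` is negative in the 3'UTR, so the sign
itself tells the model which side of the coding region the site falls on.
For non-coding transcripts both CDS fields are 0 and a `has_cds` attribute
is set, keeping the vector at exactly six entries.

**Grid composition** (`encode_grid_tx()`): the unspliced span is cut into
`G` near-equal fragments (widths differ by at most one nucleotide) and each
fragment reports its five region-type fractions, its log-width, and whether
it overlaps the target. With one-nucleotide fragments the composition
columns reduce exactly to the per-nucleotide one-hot region indicators — the
stated limiting case, and one of the acceptance properties.

**Region chunks** (`encode_chunk_tx()`): the maximal region runs themselves
are the rows, after the target splits its containing run into left / target
/ right sub-regions. The (first) target row is centered in a fixed-height
matrix of `C` rows — default 35, sized to the typical region-count
distribution of genes — with zero padding on the short side and trimming on
the long side. Because rows are maximal runs with exact widths, the encoding
is lossless whenever nothing is trimmed: `decode_chunk_tx()` recovers the
full region layout, inverting the `log(width + 1)` transform. At the default
`C = 35` the matrix has 7 columns and exactly 245 entries, about a fifth of
a 251-nt one-hot region window (1255 entries).

**One-hot matrices** (`encode_onehot_region()`, `encode_onehot_seq()`): the
conventional per-nucleotide region-type and A/C/G/U indicators over an odd
window centered on the site, kept both as a baseline and as the sequence
input of the fused models.

The width columns of grid and chunk matrices are natural-log transformed as
`log(width + 1)`; the `+1` keeps all-zero padding rows exactly zero, and the
log keeps kilobase intron widths on the same scale as short exonic runs.
Landmark distances are left raw: they are consumed by tree or shallow
models for which monotone transforms are immaterial. The grid's width column
stores the *fragment* width (the quantity the grid actually varies), not the
containing region's width.

## Isoform ambiguity and attention pooling

Short-read profiling reports genome coordinates, so a site overlapping
several isoforms has an unknown carrier transcript. `build_bag()` encodes
the site against every overlapping mature isoform; the `i_gepse` model
extracts features per isoform with shared weights, concatenates a shared
sequence feature, and pools members with gated attention
(`tanh(hV) ⊙ sigmoid(hU)` scored against a context vector, softmax over the
bag). The attention weights sum to one and indicate which isoform the model
considers the carrier. Softmax was chosen as the normalizer because the
weighted average requires weights on the simplex; the attention hidden size
and member-feature width default to 64 each (two 64-unit projections give a
128-dimensional member feature) and are config-overridable.

For peak-level (low-resolution) data, `ti_gepse` nests a second
instance-attention stage: the peak sequence is cut into 50-nt windows at
10-nt stride (`make_instances()`), pooled by a first attention layer into a
region-level sequence feature, which then joins the isoform-level bag as
above. For direct-RNA sequencing, `read_gepse` scores each read on its
read-specific geography — `truncate_to_read()` crops the chunk rows to the
read's actual span — and aggregates the read probabilities with Noisy-OR,
`1 - prod(1 - p_i)`; bags are fixed at 20 reads via seeded down-sampling or
all-zero padding members, and padding members are masked out of both
attention and the Noisy-OR product. The Noisy-OR gradient
`(P - y) p_i / P` trains the read scorer from site-level labels only.

## Training harness

The networks are small: the geographic branch is two convolutions (64 then
32 filters, kernels 5 and 3) with one max-pool and one dropout layer in
between; the sequence branch is a stack of convolution blocks. All layers,
the gated attention, and Adam are implemented in the package with plain
matrix algebra (im2col convolutions), and every analytic gradient is checked
against central finite differences in the test suite. Training minimizes
binary cross-entropy with Adam, mini-batches of 128, and 20 epochs for
fixed-shape inputs or 1 epoch for variable-shape bag data by default; one
config seed drives initialization, shuffling and dropout, so a run is
bit-reproducible. Cross-validation is stratified by label (10-fold for
site-level data, 5-fold where positives are scarce) and independent-set
predictions average the fold models.

## Technique agreement and the permutation FDR

Two techniques' site sets are compared with the min-normalized overlap,
`s = |A∩B| / min(|A|, |B|)`, reported as a percentage;
`pairwise_consistency()` assembles the full matrix (sizes on the diagonal,
intersection counts above, percentages below) either from `technique_set`
objects or directly from a published count table, and the package bundles
the nine-technique housekeeping-gene counts used in its tests. To decide how
many techniques must support a site before it is trusted,
`permutation_fdr()` re-places each technique's sites independently and
uniformly over the DRACH candidate universe, preserving per-technique
counts, and reports `FDR(k) = E[N_null(≥k)] / N_obs(≥k)`. The uniform
placement is the simplest exchangeable null consistent with a motif-level
permutation; whether the original analysis preserved per-gene counts is not
determinable, and a gene-stratified null is an easy extension. Site identity
is exact `(chrom, pos, strand)` — no fuzzy matching window, since none is
defined for the source data.

## The synthetic generator

`simulate_annotation()` emits genes on one synthetic chromosome: 2-8 exons
with lognormal widths (median 150 nt; introns median 300 nt), 1-5 isoforms
per gene derived from the full-length form by 3'-truncation or a single
internal exon skip (so isoforms always share exons), and a CDS spanning
roughly the 10-20% to 60-85% quantiles of the spliced length on ~90% of
isoforms. DRACH candidate motifs are planted about every 75 exonic
nucleotides so that desk-scale gene counts yield enough candidates.

`plant_sites()` draws labels from a logistic model of the geography the
field associates with m6A:

```
P(positive) = logistic(b0 + b_last * lastExon
              + b_logw * log(exonWidth / 150)
              + b_stop * exp(-distToStop / 200))
```

with defaults `b = (-3.5, 2.0, 0.9, 3.0)`. These effect sizes were
calibrated once, at design time, so that geography alone carries a Bayes
AUC of about 0.82 — the level of geographic signal reported for real m6A —
and were not revisited. The generating ("signal-carrying") isoform is the
longest with probability 0.75, reflecting a dominant major isoform, and
uniform among the rest otherwise. Half of the positives have their motif
rewritten to the canonical GGACU, giving the sequence channel an
independent, weaker signal (sequence-only Bayes AUC ≈ 0.74); a
geography-free condition (`beta = c(-1.5, 0, 0, 0)`) keeps the sequence
signal but removes all geographic dependence. Negatives are drawn from the
remaining DRACH candidates of the same transcripts at a configurable ratio
(1:1 for training, 1:10 for independent testing, with an optional 10x
positive up-sampling for imbalanced training).

What the generator does *not* emulate: real exon/intron length tails,
expression-dependent detection, overlapping genes, alternative TSSs,
sequencing noise in the motif neighborhood, and any coupling between
sequence context and geography. Passing benchmarks on this generator
therefore demonstrates that the encoders preserve geographic information
and that the models can exploit it — not that real-data accuracies are
reproduced.

## The desk-scale benchmark

`synthetic_benchmark()` ties everything together on problem sizes chosen
for a single CPU: 4,000 balanced sites from 800 genes, a stratified 75/25
split, 12 training epochs for the fixed-shape models and 4 for the
attention model, and 1,000 bags for the attention condition. At these sizes
(seed 1) the geography-only CNN reaches a held-out AUC of 0.78, fusing
geography with sequence beats the sequence-only branch by 0.12 AUC when
geography is planted and by under 0.01 when it is not, and the attention
model places its top weight on the signal-carrying isoform in all held-out
positive bags. The test suite asserts these at conservative margins (0.75,
0.03, 0.01, 80%).

The attention condition deserves its own note. Under the stochastic
logistic planting, positive-preferring geography occurs on members of
negative bags and on several members of the same bag, so "which isoform
carries the signal" is not identifiable bag by bag and attention recovery is
weakly defined. The benchmark therefore uses a purified condition
(`simulate_isoform_signal_bags()`): positive bags are candidates whose
planted propensity is at least 0.7 on exactly one member and at most 0.3 on
all others; negative bags are low-propensity everywhere. The cutoffs define
what "carries the signal" means; the planting model itself is unchanged.

## Numerical choices and degenerate inputs

- Chunk row counts must be odd so a single center row exists; even `C` is
  rejected rather than tie-broken.
- A target area spanning several runs flags every overlapped fragment and
  centers on the first target row.
- A whole-transcript chunk variant without the target split/column
  (`target_column = FALSE`) is available for target-free encodings.
- `decode_chunk_tx()` on a trimmed matrix returns the partial layout with a
  `truncated` attribute rather than failing.
- Grid encodings with more fragments than nucleotides are refused with a
  pointer to the one-hot encoder.
- Intronic targets error by default in the landmark encoder;
  `allow_intronic = TRUE` measures against the containing intron instead.
- A read that misses the target yields a flagged (all-zero target column)
  encoding, not an error; reads are never required to cover the whole
  transcript.
- `noisy_or()` refuses empty input; the read model clamps the site
  probability to `[1e-7, 1 - 1e-7]` for a finite gradient.
- Single-class training data and single-class CV folds are refused with a
  diagnostic rather than silently producing degenerate metrics.

## Limitations

The models here are deliberately small reference implementations of the
architecture contracts — they demonstrate the encodings' information
content at desk scale and are not tuned for competitive accuracy on real
epitranscriptome data. The encoders cover the five basic region types only;
polyadenylation sites, 5' caps and DNA-specific regions are out of scope.
Trans-spliced and circular transcripts are not supported, and chromosome
naming is matched exactly (no "chr1"/"1" normalization unless enabled).
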