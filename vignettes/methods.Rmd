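---
title: "How smorfselect estimates the number of protein-coding small ORFs in bacterial sRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How smorfselect estimates the number of protein-coding small ORFs in bacterial sRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smorfselect)
```

## The problem

Annotated bacterial small RNAs (sRNAs) are usually treated as noncoding, but
many contain canonical open reading frames of 10–50 amino acids. Any single
short ORF carries too little sequence information for a confident coding
call, so `smorfselect` asks an aggregate question instead: *how many* sRNA
ORFs in a genome score higher than a matched noncoding background can
explain? The package scores every candidate ORF with three weak but
independent signals, combines them with a bagged decision-tree classifier,
and converts the score distribution into an excess-over-null count with a
confidence interval, via an empirical false discovery rate against "mock
ORF" controls.

## Candidate enumeration

ORFs are opened at every ATG (only ATG; GTG/TTG starts are a known,
deliberate omission) on the sRNA strand inside the annotated sRNA interval
and extended to the nearest in-frame stop codon, past the annotated 3' end
if necessary (3' boundaries of sRNA annotations are often imprecise; such
candidates are flagged `extended_3prime`). Peptide length is counted in
codons excluding the stop: a 10-aa ORF spans 33 nt. Candidates with in-frame
same-strand overlap with an annotated CDS are discarded — they are fragments
of known genes. Remaining candidates are classified as `none`,
`sense_outframe`, or `antisense` by their overlap with annotated CDS, with
precedence `sense_inframe > sense_outframe > antisense` when several CDS
overlap. Several ATGs often feed one stop codon; such in-frame families are
merged to the longest member, which inherits the family's best coding score,
so each potential protein is counted once.

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
BED conventions are converted only at I/O boundaries. Candidate windows
containing `N` are dropped. ORF search does not wrap the origin of circular
genomes in this version.

## The three features

**Shine–Dalgarno strength.** The 20 nt upstream of the start codon are
hybridized in silico against the species' anti-SD sequence (the 3' tail of
the 16S rRNA, a configuration input). The duplex model is a
nearest-neighbor minimum-free-energy calculation: Watson–Crick and GU
wobble pairs, Turner stacking free energies at 37 °C (converted to kJ/mol
at 4.184 kJ/kcal), a duplex-initiation penalty of +4.10 kcal/mol, and a
linear cost of 2.1 kJ/mol per unpaired nucleotide in interior loops and
bulges. We compute the single best structure rather than a
partition-function ensemble: the MFE has an exact brute-force oracle for
testing, and the downstream classifier consumes the score only through rank
order. Terminal-AU and tetraloop corrections are deliberately omitted for
the same reason. Internally ΔG ≤ 0 (0 = no stable duplex), so the
literature convention "stronger than −11 kJ/mol" reads directly as
`delta_g < -11`. ORFs within 20 nt of a genome edge get a missing value,
not an error.

**dN/dS likelihood-ratio statistic.** For ORFs with caller-supplied ortholog
codon alignments, a GY94-style codon substitution model over the 61 sense
codons is fitted twice: with the nonsynonymous/synonymous rate ratio ω fixed
at 1 and with ω free. The reported statistic is
`max(lnl_free − lnl_fixed, 0)`, large when substitution patterns are
selectively constrained (ω̂ < 1) or accelerated (ω̂ > 1). Model choices:
one ω across sites and branches; transition/transversion ratio κ fixed at 2
(short ORFs cannot inform κ; configurable); F1×4 codon frequencies from the
alignment; stop codons excluded from the state space; gapped or ambiguous
codons treated as missing data in the pruning recursion. Branch lengths come
from the input genome-wide tree and are multiplied by one free global scale
optimized alternately with ω (golden-section searches on the log scale, C++
kernels with an eigendecomposition of the reversible rate matrix); the free
scale absorbs the unit mismatch between a nucleotide-level tree and
codon-level divergence. The free ω is *unrestricted* (both ω < 1 and ω > 1),
because the intergenic pseudogene filter needs to detect positive selection;
consequently the null distribution of the statistic is approximately ½χ²₁
rather than the boundary mixture that a one-sided ω ≤ 1 test would give, and
exact zeros arise only when the optimizer cannot improve on the fixed model.
Alignments are preprocessed reference-frame-first: columns where the
reference has a gap are spliced out, in-frame stop codons in orthologs
become gaps, and trailing partial reference codons are trimmed silently
(windowed alignments may carry ragged tails; an error is raised only when no
complete codon remains). Trees larger than 50 leaves are pruned by
repeatedly deleting one random member of the closest leaf pair, preserving
all surviving pairwise path lengths; the reference species is never removed.
ORFs overlapping annotated CDS never get a dN/dS value — conservation of
the annotated gene would dominate — and carry a missing value instead.

**Composition bias.** Each sequence is mapped to a 69-component
phase-specific Z-curve vector: 9 mononucleotide contrasts (x, y, z per codon
position), 12 dinucleotide contrasts over codon positions (1,2), and 48
trinucleotide contrasts anchored at the 16 first-dinucleotides — every
component a frequency contrast in [−1, 1]. We use (1,2)-anchored
dinucleotides (an open convention choice); a poly-A input pins the
parameterization in the tests (exactly 15 components equal to 1). All ATG
codons are removed before counting, in every sequence class, because mock
ORFs are constrained never to start with ATG and the start codon would
otherwise leak the label. A logistic regression with a near-zero ridge
(10⁻⁸ on the sum of squared slopes, intercept unpenalized, classes
reweighted to equal mass) maps the vector to a coding probability in [0, 1];
the fit is a damped penalized IRLS written in-package because the penalty
parameterization is part of the method's convention.

One further convention matters: composition is computed on the *coding part
only* (the first `aa_length` codons). Real ORFs carry a terminal stop codon;
mock ORFs are stop-free by construction and annotated in-frame subsets carry
no stop either. Including the stop would hand the classifier a perfect
label give-away and inflate the excess-over-null count by an order of
magnitude (we observed exactly this on synthetic data), so every sequence
class is scored on the same stop-free footing.

## Controls

Twenty positive and twenty negative control sets are built per genome, each
matching the sRNA-ORF peptide-length multiset exactly (not approximately).
Positives are random in-frame windows of random annotated CDS (terminal stop
excluded, frame preserved). Negatives ("mock ORFs") are intergenic segments
spanning the same nt footprint as a real ORF of the matched length
(3m + 3 nt, a documented convention — the paper-silent alternative of 3m nt
changes nothing downstream because composition uses the first m codons),
whose first codon is not ATG, which contain no in-frame stop, and which
avoid all annotated CDS and all real sRNA ORFs of 10–50 aa. Sampling is
rejection sampling with a 10,000-retry cap and a clear failure message.
Mocks get a nominal strand uniformly at random. Mock sets are sampled
independently per set.

ORFs that overlap annotated CDS get their own mocks: each reproduces the
template's overlap length, relative orientation and the overlapped CDS end
(in the CDS's own 5'→3' sense), with the remainder in intergenic space.
Because annotated CDS lengths are codon multiples, anchoring at the matched
boundary also reproduces the template's reading-frame offset.

For training, positive rows carry the *real* SD score of the annotated ORF
containing the window; negative rows draw from the pooled shuffled-upstream
SD scores of the sRNA ORFs (per-upstream letter shuffles preserve
composition). Shuffles throughout are plain uniform letter permutations, not
dinucleotide-preserving.

### Composition-model holdout

The near-unpenalized 69-parameter logistic fit memorizes its training
sequences whenever training sets are small. The classifier/FDR machinery
requires mock ORFs to be *exchangeable* with unseen noncoding ORFs, so when
more composition-training sets are available than classifier sets
(`n_comp_sets > n_sets`), the classifier/FDR sets are held out of the
composition fit and scored out-of-sample, exactly like the sRNA ORFs they
stand in for. At full scale (20 sets, thousands of rows) the overfit is
negligible and the holdout is a no-op.

## The classifier

The three features are combined by a bagged ensemble of 100 CART trees
(rpart), each grown on a bootstrap resample with class weights balancing
coding and noncoding mass, minimum leaf size 2, no depth cap. Each tree is
pruned by choosing the cost-complexity level with minimum out-of-bag
misclassification — a reduced-error-pruning analogue that avoids a second
data split. Missing features (dN/dS for overlap categories, SD at genome
edges) are routed by CART surrogate splits at training and prediction time;
we use surrogate routing rather than C4.5-style fractional instances because
it is the native missing-data semantics of the CART implementation and
preserves "treated as missing data" behavior without a hand-written tree
learner. The coding score of an ORF is the mean coding-leaf frequency over
trees, always in [0, 1]. One classifier serves all overlap categories; the
categories differ only through their mock sets and the missingness pattern.

Mock ORFs are scored under 10-fold cross-validation: each fold is scored by
a model trained on the other folds' mocks plus all positives, so no mock is
scored by a model that saw it.

## From scores to a coding count

Within each overlap category, with S merged sRNA ORFs and M mocks, and
S_T/M_T the counts scoring at least T:

* empirical FDR: `FDR_T = (M_T / M) / (S_T / S)` at every observed score;
* q-value: the Storey running minimum of FDR over thresholds at or below T
  (the rejection regions containing the ORF); q is capped at 1 for
  reporting, and thresholds attained only by mocks above every ORF score
  have undefined FDR and are skipped;
* truncation: thresholds at or below the largest t with
  `S_t − (M_t / M) S ≤ −1` (a deficit of real ORFs) are not trusted;
* raw count: `C = max over admissible T of S_T (1 − q_T)`;
* fluctuation correction: twenty random mock subsets of size S are run
  through the identical machinery against the remaining mocks;
  `C' = C − mean(C_i)`, with the 95% CI `±1.96 sd(C_i)`.

One numerical guard matters at small scale. sRNA ORFs are scored by the
full classifier while mocks are scored by cross-validation fold models, so
the two score sets come from slightly different model families. An ensemble
of B trees cannot meaningfully resolve score differences smaller than one
tree's vote, yet the threshold sweep would happily split hairs at 10⁻³ and
count a family-specific baseline offset as coding signal. Both score sets
are therefore snapped to the ensemble's natural grid (multiples of 1/B)
before the sweep — a symmetric rounding, not a tuning knob.

Per-category corrected counts add up to the genome total; the total's CI
uses the standard deviation of the *summed* per-subset estimates. The
fraction of sRNAs with at least one coding ORF is estimated by drawing,
100 times, `round(C')` ORFs per category from the ORFs scoring at or above
that category's optimal threshold (extending down the ranking when fewer
qualify — the eligible pool is an open design point, documented here), and
counting sRNAs containing at least one drawn ORF.

Intergenic scans add a pseudogene filter: ORFs with ω̂ > 1 and a
log-likelihood difference ≥ 3 show positive selection typical of
out-of-frame windows in decaying genes and are removed. The companion
homology rule (discarding ORFs inside long protein BLAST hits) requires an
external search and is only flagged, never applied.

## Auxiliary evidence

**Ribosome profiling.** An ORF is called ribosome-bound iff any position
within ±3 codons (9 nt, boundary-inclusive and symmetric — the simplest
faithful reading of "within 3 codons") of the start codon's first base or
the stop codon's last base, on the ORF's strand, has coverage > 0. Calls are
presence/absence by design and invariant to magnitude. Sense out-of-frame
overlappers are excluded upstream (no sub-codon resolution). The excess of
bound ORFs over 20 matched mock sets is reported with a ±1.96 sd interval.

**Type I toxin screen.** Candidate peptides are described by seven
physicochemical features: mean 7-residue-window Chou–Fasman helix, strand
and turn propensities; the maximum 7-window Kyte–Doolittle hydropathy (an
aggregating-stretch proxy) and the maximum hydropathy×helix window (a
helical-aggregation proxy); GRAVY; and the isoelectric point solved from
the Henderson–Hasselbalch net-charge equation with a fixed pKa table
(N-terminus 9.0, C-terminus 2.0, standard side chains). These are
scale-based window statistics that play the roles of dedicated
structure-prediction tools without claiming concordance with any of them.
Training positives are deduplicated by greedy longest-first clustering at
90% global identity; negatives are drawn at exactly 20 per positive with
the positive length distribution matched exactly; the model is a random
forest of 10 trees, evaluated by 10-fold CV ROC. The transmembrane screen
flags any peptide with a 19-residue window of mean hydropathy ≥ 1.6.

## The synthetic test bed

`simulate_genome()` plants non-overlapping CDS (ATG + codon-usage-biased
body + stop, SD core upstream) in iid background at a chosen GC;
`simulate_srnas()` places sRNAs in intergenic space and equips a chosen
subset with a planted ORF carrying an upstream SD core (AGGAGG, 7-nt
spacer) and a biased codon body; `simulate_ortholog_alignment()` evolves
codons along a tree from the reference sequence using the same rate matrix
the LRT uses — stated openly: the recovery tests check *internal
consistency* of the estimator chain, not external validity against real
evolutionary processes; `simulate_ribo_coverage()` adds Poisson background
plus anchored reads for translated ORFs. Default effect sizes (6-nt perfect
SD core, synonymous codon bias 0.8, ω = 0.2 for coding ORFs against ω = 1
background on a four-leaf tree of total length 1.0) are what we consider a
strongly-coding small protein in a well-annotated bacterial genome.

What the generator does *not* emulate: operon structure, repeats,
horizontally transferred composition islands, annotation errors, alignment
errors, and non-equilibrium base composition. A passing recovery test
therefore shows the statistical machinery is unbiased and calibrated under
its own assumptions, nothing more.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run at desk scale, chosen once:
recovery worlds use 300 sRNAs with 30 planted coding ORFs in a 200-kb
genome with 60 CDS, two classifier/FDR control sets with ten
composition-training sets, 25 bagging iterations, 5 background CV folds,
10 SD shuffles per upstream, and likelihood tolerances of 0.12 on the log
scale with search bounds ω ∈ [0.002, 20], scale ∈ [0.02, 20]. Function
defaults remain at the full-scale study conditions (20 control sets, 100
bags, 10 folds, 1000 shuffles for the expected-ORF-count background). The
null-calibration checks use 200 replicates at S = 300 against 1500 mocks;
LRT calibration uses 200 null alignments of 30 codons on 4 leaves and 100
replicates of 60 codons on 8 leaves at ω = 0.2.

## Known limitations

* Only ATG starts are considered; a real genome's GTG/TTG initiators are
  invisible, so counts are conservative.
* The SD energy model is a reduced nearest-neighbor scheme; absolute
  energies are not comparable with full secondary-structure packages,
  ranks are.
* The dN/dS statistic assumes the supplied tree and alignment are correct;
  misalignment pushes the statistic toward zero, again conservative.
* The unrestricted-ω LRT statistic is not ½χ²₀ + ½χ²₁ distributed; users
  comparing it with boundary-mixture critical values will over-reject.
* Mock ORFs may contain genuine non-ATG-initiated genes; the null is
  therefore slightly contaminated and C' is a lower bound in expectation.
* Estimates are not comparable across species with different sRNA
  annotation depth.
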