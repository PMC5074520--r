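---
title: "Predicting non-canonical translation initiation sites from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting non-canonical translation initiation sites from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiscall)
```

## The problem

Initiation-arrested ribosome profiling shows that mammalian translation
frequently initiates inside annotated 5′ UTRs, at AUG and at the nine
near-cognate codons one substitution away from AUG. Such upstream starts
create uORFs and N-terminal protein extensions, and which candidate codons
are actually used is encoded largely in the local mRNA sequence. `tiscall`
turns that observation into a predictor: given transcripts with annotated
CDS starts and a table of profiling-reported start sites, it learns a
regression from sequence-derived features to a 0–1 *initiation confidence*,
and can then score unseen candidates and simulate point mutations in their
flanking contexts.

## Candidate definition and labels

Positions are Kozak-style: the first annotated CDS nucleotide is +1, the
nucleotide upstream of it is −1, and there is no position 0. A 5′ UTR
triplet becomes a candidate when (i) it belongs to the ten-codon alphabet,
(ii) a stop codon exists downstream in its frame, and (iii) the transcript
provides 99 nt on both sides of the codon (needed by the position-specific
features). The downstream in-frame stop is searched over the whole
transcript, not only the UTR, because out-of-frame uORFs commonly terminate
inside the CDS; a configuration switch restricts the search to stops that
begin before the transcript end for users who want the stricter reading.
The flank length is configurable (tests use short toys) but every
documented count assumes 99.

Labels follow the linear-scanning logic of the profiling studies: reported
(transcript, position) pairs are true starts; an unreported candidate is a
false start only when it lies strictly upstream of the transcript's most
downstream reported start (downstream candidates may simply never have been
reachable by a scanning ribosome, so they are excluded rather than called
negative); transcripts with no reported start contribute no negatives at
all, since no anchor exists.

A candidate is in frame when its position is a multiple of 3. Note that
with no position 0, the codon at −3 is the one immediately preceding the
annotated start, which is why multiples of 3 — not positions ≡ +1 (mod 3) —
are the in-frame ones.

## The 1,252 features

**PWM scores (3).** Contexts spanning 15 nt upstream of the codon, the
codon, and 10 nt downstream (28 nt) are summarized in position frequency
matrices for the true and the false class; entries are
`PWM(nt, i) = ln(PFM(nt, i) / bg_nt)` with the background `bg_nt` pooled
from the training transcripts' 5′ UTRs, plus a log-ratio matrix
(elementwise `pwm_pos − pwm_neg`). A context's score is the sum of its
per-position entries. A pseudocount of 0.5 per cell prevents log-of-zero
for rare nucleotides; it is small enough to leave well-populated cells
essentially untouched. PWMs are rebuilt inside every training repetition so
test contexts never leak into the matrices.

On the context-window extent: the −15..+10 description and the count of 75
SNP contexts are mutually inconsistent under no-zero numbering (−15..+10
holds only 22 non-codon positions). We resolved this in favour of the
printed 75: the window is 15 nt upstream + codon + 10 nt downstream
(mutable positions −15..−1 and +4..+13). The literal −15..+10 window (22
mutable positions, 66 contexts) remains available via
`window_mode = "literal"`.

**Biologically motivated features (20).** 5′ UTR length and its four
nucleotide fractions; 5′ UTR conservation, plus binary codon and amino-acid
conservation of the start against a user-supplied ortholog (below); the
four-level Kozak class from the −3R/+4G rule (strong = 4 … none = 1); the
experimentally derived translational efficiency of the −6..+5 context, with
the candidate codon replaced by AUG for the lookup (near-cognates are
assumed to behave like AUG codons in the same flanks; contexts missing from
the table fall back to the table mean with a warning); folding energy and
GC content in four windows (+14..+73, +20..+79, −10..+50, −50..+50); ORF
length; and the candidate's reading frame relative to the main ORF. The
frame indicator completes the published count of 20; it is the one
candidate-level quantity the other slots do not encode, and in-frame versus
out-of-frame initiation is biologically meaningful (N-terminal extensions
versus independent uORFs).

**k-mers (1,229).** 792 position-specific indicators ("position −12 is C")
over the 198 non-codon flank positions; 320 codon counts — all 64 triplets
counted with overlap in five regions (the complete upstream+codon+downstream
concatenation, each flank alone, and frame-locked stride-3 counts in each
flank); 100 amino-acid counts and 5 stop counts derived from the triplet
counts through the standard genetic code; and 12 mononucleotide counts over
complete/upstream/downstream. Region counts overlap deliberately: the
existence of separate in-frame slots implies the plain region slots are
frame-agnostic, and overlapping counting is the natural frame-agnostic
reading. Codon-spanning triplets are counted in the complete region but in
neither flank.

## Conservation

The ortholog is explicit input (a FASTA plus a pairing table); no homology
search is performed. The concatenated 5′ UTR+CDS of both transcripts is
translated in all three frames with stops kept in-line, and each primary
frame is globally aligned (BLOSUM62, gap open 11 / extend 1) against the
best-scoring ortholog frame; the 5′ UTRs are also aligned at the nucleotide
level (match +2 / mismatch −3, gap open 5 / extend 2). Alignment scores
only choose the frame pairing — they are never features. The protein
alignment is back-translated to find the ortholog codon opposite a
candidate: identical codons set `codon_conserved`, identical literal
translations set `aa_conserved`, and gaps set both to 0. UTR conservation
is matching columns divided by the primary UTR length, gaps counting only
against the denominator. Transcripts without an ortholog get all-zero
conservation features — a neutral default that simply removes these
features' contribution. Whether the original pipeline paired frames by
index or by score is not recoverable; best-scoring is the default and
`frame_pairing = "matched"` the alternative.

## The folding proxy

The built-in energy engine is a Nussinov-style dynamic program over
non-crossing pairings with weights GC = −3, AU = −2, GU = −1 kcal/mol and a
minimum hairpin loop of 3 nt — a *stability proxy*, deliberately not a
nearest-neighbour (Turner) model. Two considerations justify this: the
folding windows serve only as candidate features (feature selection decides
whether they carry signal), and the engine is pluggable — `mfe_rnafold()`
adapts an external Turner-model folder for users who have one. The proxy is
validated in the tests against exhaustive enumeration of all secondary
structures on short RNAs.

## Training

Per repetition: the classes are balanced by under-sampling the majority
class; the balanced set is split 70/30, stratified by class (with balanced
classes stratification is nearly moot, but it keeps the test split exactly
balanced); PWMs are rebuilt from the training split; every feature gets a
two-sided Wilcoxon rank-sum p-value (exact permutation null below 12 per
class and tie-free, otherwise the tie- and continuity-corrected normal
approximation), with significance at 0.01/1252 ≈ 8 × 10⁻⁶; the candidate
pool is all significant biological and PWM features plus the 50 most
significant k-mers, greedily pruned in ascending-p order to pairwise
|r| < 0.7 (the smaller p-value wins among correlated features, and
cross-correlations between k-mer and biological features are considered
jointly — pruning within groups only would readmit redundancy);
zero-variance features are removed before normalization since they carry no
information and break z-scaling. Features are z-normalized with training
moments. The linear model is ordinary least squares (singular designs fall
back to a 10⁻⁸ ridge jitter with a warning — near-separable synthetic data
can co-linearize indicators that survive pairwise pruning); SVR models
(linear, RBF, polynomial kernels) choose cost ∈ {0.1, 1, 10, 100} and
ε ∈ {0.01, 0.1, 1, 10} by 10-fold cross-validation on held-out mean squared
error (the criterion is unspecified in the source description; MSE is the
natural regression choice), other hyperparameters at library defaults.
Grid points whose ε-tube swallows the whole response leave no support
vectors and score infinitely badly rather than aborting the search.

Predictions are clamped to [0, 1]. The threshold scan evaluates
t = 0.00 … 1.00 in steps of 0.01 — 101 points; "100 thresholds" cannot
cover that range at that step, so both endpoints are included — and picks
the accuracy-maximizing t, ties broken by the most balanced
sensitivity/specificity and then the smaller t ("best overall performance"
is otherwise unspecified). AUC is computed rank-based, independent of the
grid. The whole procedure is repeated (default 10×) over fresh balancing
draws; the best run's model, with its PWMs and threshold, is retained and
serialized as a single JSON document (feature list, normalization moments,
coefficients or SVR dual representation, frequency matrices, background,
threshold, seed) — diff-able, so provenance survives.

Confidence classes follow fixed bounds: very high ≥ 0.9, high ≥ 0.8,
moderate ≥ 0.7, low ≥ t (t must stay below 0.7 for the classes to nest).

## The in-silico SNP scan

Each mutable context position is substituted by the three alternative
bases; features are recomputed on the mutated transcript and the model
re-applied, giving 75 variant contexts per fully flanked candidate under
the default window. Folding energies are memoised by window sequence, so
windows untouched by a substitution are reused and the incremental and
full-recompute modes agree bit for bit (the tests assert this). The ORF
length is re-derived on the mutated sequence because a substitution can
create or destroy the in-frame stop. Conservation is recomputed against the
mutated primary sequence by default; a frozen mode keeps the wildtype
values for users who regard conservation as a property of the reference.

## The synthetic-data generator

The generator emulates the *structure* of a curated corpus: log-normal
5′ UTR lengths (mean ± SD 414 ± 270 nt for transcripts carrying true starts
versus 675 ± 545 nt otherwise, matching the contrast reported for real true
and false start populations), a GC-rich UTR background (A/C/G/U =
0.21/0.27/0.30/0.22), CDSs that begin with AUG, lack premature in-frame
stops and end in a stop, and planted true starts using the reported codon
preferences (AUG 0.26, CUG 0.30, GUG 0.13, remainder uniform). Planted
starts receive a strong Kozak context with probability 0.45 and the GCCACC
consensus at −6..−1 with probability 0.5 — chosen once to mirror the
moderate Kozak enrichment seen in profiling data, where many true starts
have weak contexts. Orthologs are per-base substituted copies (rate 0.25,
planted codons restored with probability 0.6); there are no indels, so
alignment difficulty is *not* emulated. False starts are not planted: they
arise from background composition, as real negatives do. The
`strong_signal = TRUE` preset (every true start strong-context and
consensus-motif) produces nearly separable classes for power checks.

The stand-in efficiency table assigns every 11-nt context
base 60 + 15·[purine at −3] + 10·[G at +4] + N(0, 8), clipped to [0, 150] —
the right shape (context-dependent, −3/+4-dominated, bounded) without
claiming the measured values.

What passing tests on this generator shows — and what it does not: the
pipeline recovers planted signal of known strength, behaves at chance on
permuted labels, and reproduces its own structural constants. It does not
show field performance on real transcripts, where negatives are noisier
(condition-specific starts mislabelled as negative), orthologs are
diverged with indels, and the efficiency values are measured rather than
parametric.

## Problem sizes and numerical choices

The shipped tests run the repeated experiment on corpora of 40–330
transcripts (up to ~3,000 labeled candidates), sizes chosen so that the
permuted-label check has a test split of about 600 candidates — large
enough that the optimism of picking the best of 101 thresholds on the test
split (~2–3 accuracy points at that size) stays well inside the 0.5 ± 0.05
acceptance band. Coefficient recovery uses n = 2000 and noise σ = 0.1,
where the 3-standard-error band is tight but comfortably achievable by
least squares. Ties in the threshold scan are broken deterministically
(balance, then smaller t); the CV grid search breaks ties by grid order
(smaller cost, then smaller ε). All randomness flows from explicit seeds
and fixed seeds reproduce results — including serialized models — byte for
byte.

## Known limitations

- The folding proxy is not a thermodynamic model; absolute kcal/mol values
  are not comparable to Turner-model energies (the plug-in hook exists for
  that).
- Conservation assumes a co-linear ortholog transcript; rearranged or
  partial orthologs will degrade the back-translated codon mapping.
- The efficiency lookup treats near-cognates exactly like AUG in the same
  flanks, an assumption inherited from the method it implements.
- Real profiling labels contain false negatives (condition-specific
  starts); the regression's confidence is calibrated against those labels,
  not against ground truth.
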