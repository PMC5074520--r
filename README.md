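# tiscall

Prediction of non-canonical translation initiation sites (TIS) in mRNA
5′ UTRs.

Ribosome profiling with initiation inhibitors has shown that translation in
mammalian cells frequently starts upstream of the annotated CDS, at AUG or
at *near-cognate* codons that differ from AUG by one nucleotide (CUG, UUG,
GUG, AAG, ACG, AGG, AUA, AUC, AUU). `tiscall` is for researchers who want to
rank such upstream start sites on new transcripts, or to ask how a single
nucleotide change in a start-site context would shift its predicted
usability — without running a profiling experiment.

## What it does

1. **Candidate enumeration.** Every 5′ UTR offset is scanned; a triplet
   becomes a candidate when it belongs to the ten-codon alphabet, has a
   downstream in-frame stop codon, and carries full ±99-nt flanks
   (positions are Kozak-style: the annotated CDS start is +1, there is no
   position 0).
2. **Labels from reported start sites.** Candidates matching a
   profiling-derived table (transcript, position, codon) are true starts;
   unmatched candidates strictly upstream of the most downstream reported
   start are false starts; everything else is excluded.
3. **1,252 features per candidate:** three position-weight-matrix scores
   over the −15..+13 context window, `PWM(nt, i) = ln(PFM(nt, i) / bg_nt)`
   with the background taken from the training-set 5′ UTRs; 20 biologically
   motivated features (5′ UTR length, composition and conservation,
   codon/amino-acid conservation against a user-supplied ortholog, Kozak
   class from the −3R/+4G rule, flanking-context translational efficiency,
   folding-energy and GC windows, ORF length, reading frame); and 1,229
   k-mer features (792 position-specific nucleotide indicators, 320 codon,
   100 amino-acid and 5 stop-codon region counts, 12 mononucleotide
   counts).
4. **Regression to an initiation confidence.** Classes are balanced by
   under-sampling, features screened by Wilcoxon rank-sum tests with
   Bonferroni correction (0.01/1252 ≈ 8×10⁻⁶) and pruned to pairwise
   |r| < 0.7, then a linear or support-vector regression maps the
   z-normalized features to [0, 1] (clamped). A 101-point threshold scan
   picks the operating point t; confidences are binned into very high
   (≥0.9), high, moderate and low classes.
5. **In-silico SNP scan.** Each of the 25 mutable context positions
   (−15..−1, +4..+13) is substituted by the three alternative bases — 75
   variant contexts per site — features are recomputed and
   `IC_difference = IC_mutation − IC_wildtype` reported.

A synthetic-data module generates transcript corpora with planted true
starts, ortholog copies, reported-TIS tables and a parametric stand-in
efficiency table, so the whole pipeline runs and is tested fully offline.

## Worked example

```r
library(tiscall)

eff <- read_efficiency_table(generate_efficiency_table(seed = 1))
fx  <- end_to_end_fixture(sim_params(n_transcripts = 120, seed = 1),
                          training_config(n_repeats = 5, seed = 1),
                          efficiency = eff, use_orthologs = FALSE,
                          max_false = 1200)
fx$experiment
#> <tis_experiment> 5 runs (best: run 2)
#>   threshold    0.570 +/- 0.094
#>   accuracy     0.771 +/- 0.067
#>   sensitivity  0.668 +/- 0.130
#>   specificity  0.874 +/- 0.073
#>   precision    0.844 +/- 0.071
#>   auc          0.816 +/- 0.067

model <- fx$experiment$best_model
model$feature_names
#> [1] "pwm_ratio_score" "kozak_class" "kmer:pos:4:G" "utr_length" "kmer:pos:-5:C"
```

The retained features are the biologically expected ones: the PWM context
score, the Kozak class, the "+4 is G" indicator and the 5′ UTR length.
Scoring all candidates of one transcript and ranking by confidence:

```r
tx    <- fx$generated$transcripts[["tx0003"]]
cands <- enumerate_candidates(tx)
pred  <- predict_candidates(model, fx$generated$transcripts, cands, eff)
head(pred[order(-pred$confidence),
          c("position", "codon", "frame", "confidence", "class")])
#>    position codon        frame confidence     class
#> 58     -605   AAG out_of_frame  0.9226231 very_high
#> 53     -658   GUG out_of_frame  0.8231217      high
#> 89     -414   GUG     in_frame  0.8071607      high
#> 19     -888   GUG     in_frame  0.7468933  moderate
```

The top candidate (confidence 0.92, class `very_high`) is an AAG whose
randomly generated flanking context happens to be strong — exactly the kind
of site the method is meant to surface as a *hot* candidate. Mutating its
flanking context one base at a time:

```r
scan <- snp_scan(tx, pred[which.max(pred$confidence), ], model, eff)
round(scan$ic_difference[, c("-6", "-3", "4")], 3)
#>       -6     -3      4
#> A -0.094  0.000 -0.299
#> C -0.040 -0.175 -0.280
#> G  0.000 -0.049  0.000
#> U -0.128 -0.156 -0.304
```

Replacing the −3 purine by a pyrimidine, or the +4 G by any other base,
lowers the predicted confidence — the classic Kozak positions dominate, as
they should.

A command-line front end wrapping the same functions is installed at
`inst/cli/tiscall.R`:

```sh
Rscript inst/cli/tiscall.R simulate --out sim --n 50 --seed 1
Rscript inst/cli/tiscall.R train --transcripts sim/transcripts.fasta \
    --annotation sim/annotation.tsv --reported sim/reported_tis.tsv \
    --efficiency sim/efficiency.tsv --out run1 --seed 1
Rscript inst/cli/tiscall.R predict --transcripts sim/transcripts.fasta \
    --model run1/model.json --efficiency sim/efficiency.tsv --out run1
Rscript inst/cli/tiscall.R snp --transcripts sim/transcripts.fasta \
    --model run1/model.json --efficiency sim/efficiency.tsv \
    --position all --out run1/snp
```

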