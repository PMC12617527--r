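# sercodon

Codon-centric analysis of translational regulation under serine
limitation, for researchers working on ribosome profiling, tRNA biology
and nutrient-dependent translation.

Serine's six codons fall into classes — UC[C/U], AG[U/C] and UC[G/A] —
that respond differently when cells run out of serine: ribosomes stall on
UC[C/U] codons in serine/glycine-deprived parental cells, and the stall
switches to AG[U/C] when 3' pre-tRNA processing (ELAC2) is lost, because
the charged tRNA-Ser isoacceptor pools shift. A gene's serine codon class
composition then predicts how strongly its protein output falls under
starvation. `sercodon` implements the quantitative layer of this
analysis:

* **Codon composition** — per-gene class counts and percentages over the
  longest CDS, the codon-balance z-score
  `z = (n_AG[U/C] − n_UC[C/U]) / sqrt(n_AG[U/C] + n_UC[C/U])`, and
  percentage binning (`0-10` ... `91-100`, plus a coarse
  `0-60 / 61-90 / 91-100` grouping).
* **Ribosome stalling** — per-transcript coverage tracks normalized to
  mean 1, codon-anchored metagenes (±150 nt around every occurrence,
  pooled with equal weight), deprived-minus-rich deltas, and a pause
  score (mean delta over positions −15...+17) ranked across all 61 sense
  codons. A labelled naive differential-TE double ratio is included for
  simulation-backed checks.
* **Charged tRNA-seq arithmetic** — 3'-end read classification
  (...CCA = charged, ...CC = uncharged, leader/trailer = pre-tRNA),
  charging percentages, isodecoder→isoacceptor aggregation, charged
  pools (`pct/100 × mature`), and isoacceptor pool/pairwise ratios.
* **Reporter & screen arithmetic** — geometric-mean GFP/mCherry reporter
  values with translation-blocked background subtraction
  (`(v_dep − v_chx)/(v_rich − v_chx)`), and CRISPR screen beta-score
  differencing with strict `> 0.25` selection.
* **Proteome coupling** — SILAC log2 fold changes of newly synthesized
  protein joined to codon profiles; binned means, Spearman correlation
  (binned and individual), quadratic trend fits with explicit bin
  exclusion, and two-stage Benjamini-Hochberg adjustment.
* **Synthetic data** — seeded generators for transcriptomes, footprints
  with codon-class dwell multipliers, tRNA-seq counts with known
  charging, and composition-coupled SILAC tables, each with recorded
  ground truth.

The package consumes plain-text inputs (CDS FASTA, alignment/count/
intensity TSVs) and starts downstream of read processing: alignment,
tRNA read assignment, beta-score estimation (MAGeCK) and peptide search
are consumed as tables, never re-implemented.

## Worked example

Simulate the deprived-vs-rich experiment (200 genes, 4x dwell on UC[C/U]
codons under deprivation) and recover the stalled class:

```r
library(sercodon)

cfg <- sim_config(seed = 1, n_genes = 200)
tx  <- gen_transcriptome(cfg)
fp  <- simulate_footprints(tx$cds, cfg)
ranks <- codon_pause_scores(fp$deprived, fp$rich, tx$cds)
head(ranks, 4)
#>   codon pause_score rank
#> 1   TCC 0.208222973    1
#> 2   TCT 0.204639405    2
#> 3   ATT 0.007770806    3
#> 4   CGC 0.005509259    4
```

The two UC[C/U] codons carry pause scores ~0.21 — their windows hold about
21% more normalized ribosome density under deprivation — while every
other sense codon sits near zero. Quantify the simulated tRNA pools
(charging drops to ~40% under deprivation):

```r
ct <- charging_table(simulate_trna_seq(cfg)$counts)
ct[ct$condition == "deprived",
   c("isoacceptor_id", "pct_charged", "charged_level", "ratio_in_pool")]
#>   isoacceptor_id pct_charged charged_level ratio_in_pool
#> 1        Ser-AGA        37.2        135067         0.362
#> 3        Ser-CGA        40.2         49874         0.134
#> 5        Ser-GCU        40.8        117795         0.315
#> 7        Ser-UGA        41.3         70638         0.189
```

And link composition to simulated newly synthesized protein (effect
−1 log2 unit per 100% UC[C/U], noise sd 0.3):

```r
si   <- simulate_silac(tx$truth, cfg)
prof <- tx$truth[tx$truth$defined, ]
res  <- binned_spearman(setNames(si$log2_fc, si$gene_id),
                        setNames(prof$pct_ucc_ucu, prof$gene_id))
res$r
#> [1] -0.9636364
```

Genes binned by UC[C/U] percentage show a strongly negative rank
correlation between bin midpoint and mean fold change — the signature of
class-specific stalling propagating into the proteome. `run_pipeline()`
wires the same stages over files in a directory, with a logged,
hash-stamped, deterministic output set.

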