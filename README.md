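# selnc

Tools for discovering candidate **super-enhancer associated lncRNAs
(SE-lncRNAs)** in a tumour cohort and deciding which of them carry a
**repeat insertion domain (RIDL)** — a transposable-element derived
fragment that can make a lncRNA functional — and a prognostic signal.

The package is aimed at computational biologists who have, or can
simulate: super-enhancer regions (BED), lncRNA gene models (GTF),
transcript sequences (FASTA), a TE consensus library (FASTA), an
expression matrix (TSV) and clinical survival data (TSV). It chains
four analysis stages into one reproducible pipeline:

1. **Catalogue** — a gene is an SE-lncRNA if its locus overlaps a
   super-enhancer (≥1 bp, strand-ignored; a TSS-window mode is
   available), plus per-chromosome density summaries.
2. **RIDL screen** — exact Smith–Waterman local alignment (affine
   gaps, iterative masking) against the consensus library, a
   low-complexity veto for poly(A)-like fragments, and SEEKR-style
   k-mer evidence: standardised profiles
   `z = (log2(counts/kb + pc) − μ)/σ` against a functional lncRNA
   reference, compared by Pearson correlation, with a
   dinucleotide-shuffle null (`kmer_delta`). Verdict per transcript:
   `valid_RIDL` / `polyA_only` / `no_RIDL`.
3. **Expression analytics** — nearest-centroid subtype assignment
   (with `Unknown`), ridge-regularised LDA, and an empirical-Bayes
   moderated t (posterior variance `(d0·s0² + d·s²)/(d0+d)`) with
   Benjamini–Hochberg FDR.
4. **Prognosis** — univariate Cox screen (Breslow ties, Newton to
   1e-8), L1-penalised Cox selection with cross-validation, a random
   survival forest risk score (log-rank splits, Nelson–Aalen leaves,
   ensemble mortality), Kaplan–Meier/log-rank risk groups, IPCW
   time-dependent AUC, permutation importance.

A candidate passes the final funnel iff it is an SE-lncRNA **and**
differentially expressed in the target subtype **and** prognostic
**and** `valid_RIDL`. A synthetic-data module plants ground truth for
every stage, so the whole cascade is testable offline.

## Worked example

Simulate a cohort in which exactly one gene (`LNC001`) carries all
four properties, then run the full pipeline:

```r
library(selnc)
d <- tempfile()
b <- simulate_hit_bundle(seed = 1, out_dir = file.path(d, "sim"))
cfg <- run_config(b$se_bed, b$genes_gtf, b$transcripts_fa, b$te_fa,
                  b$functional_fa, b$expr_tsv, b$clinical_tsv,
                  out_dir = file.path(d, "out"), seed = 1)
res <- run_pipeline(cfg)
res$manifest$record_counts
#> $se          [1] 50
#> $genes       [1] 60
#> $se_lncrnas  [1] 15
#> $de_target   [1] 1
#> $prognostic  [1] 1
#> $selected    [1] 1
#> $final       [1] 1
subset(res$report, final_flag)
#>   gene_id de_target prognostic in_risk_model ridl_status final_flag
#> 1  LNC001      TRUE       TRUE          TRUE  valid_RIDL       TRUE
```

Reading: of 60 genes, 15 overlap a super-enhancer; one of them is
differentially expressed in the Basal subtype, one passes the
univariate Cox screen at FDR 0.05, and the same gene carries a valid
TE-derived fragment — so `LNC001`, the planted hit, is the unique
flagged candidate. The output directory also holds `auc.tsv` (risk
model discrimination at 1/3/5 years — here 0.86/0.84/0.83),
`km_logrank.json` (high- vs low-risk split: chi2 = 47.8,
p = 4.8e-12, score–time correlation −0.60 among events), per-stage
TSVs and a `manifest.json` with seeds and md5 checksums; rerunning the
same config reproduces the checksums bit for bit.

Small building blocks work standalone:

```r
km_estimate(c(2, 4, 5, 7), c(1, 1, 0, 1))$surv
#> [1] 0.75 0.50 0.00
ddct(19, 20, 20, 20)                     # one cycle earlier -> 2.0
estimate_half_life(c(0, 2, 4, 6, 8),
                   2^-(c(0, 2, 4, 6, 8) / 2))  # halves every 2 h -> 2
```

A command-line front end is installed at `inst/cli/selnc`
(subcommands `simulate`, `catalog`, `ridl`, `de`, `prognosis`,
`run --config config.json`).

## Documentation

`vignettes/selnc-methods.Rmd` describes the models, parameter
defaults and units, what the synthetic generator does and does not
emulate, numerical choices, and known limitations.
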