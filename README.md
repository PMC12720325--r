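# hrepipe

Integrative ChIP-Seq + expression analysis that classifies
transcription-factor-bound genes into **responsive** and **unresponsive**
programs, built around the hypoxia-inducible factor HIF-1α and its
hypoxia-response element (HRE), the promoter motif with core consensus
**5′-RCGTG-3′** (R = A or G).

The question the pipeline answers: HIF-1α binds thousands of promoters
under inflammatory (LPS) or hypoxic stimulation, but which bound genes
actually respond? A gene is called *responsive* when its wild-type (WT)
expression exceeds the HIF-1α-knockout (KO) expression by **more than
twofold** at a post-stimulus timepoint; bound genes failing that are
*unresponsive* despite carrying a bound promoter HRE.

## What it computes

For peaks *P*, genes *G* with promoter windows *W(g)* = TSS −1500/+500 bp
(strand-aware), and an expression matrix *X* (log2 TPM):

1. **Definitive peaks**: keep peaks with caller score > 20 (strict);
   merge intervals overlapping by ≥ 1 bp (book-ended intervals stay
   apart); annotate each peak by its midpoint as
   promoter / exon / intron-or-intergenic and assign it to the nearest
   TSS (signed, transcription-oriented distance).
2. **Bound-HRE genes**: select g iff ∃ peak p and RCGTG hit h with
   p ∩ h ≠ ∅ and h ⊂ W(g) (both strands scanned).
3. **Expression cascade** (fixed order): drop NA rows → drop rows with SD
   exactly 0 → keep genes with mean expression at 24 h > 1.2 × mean at
   4 h (strict, on log2 means).
4. **Two-level Ward clustering**: Euclidean distance, R's `ward.D`
   linkage, cut at height 50, then the largest cluster re-cut into k = 2.
5. **Permutation test** for the subdivision: statistic = mean
   between-cluster − mean within-cluster distance; 999 size-preserving
   label permutations; p = #(perm ≥ observed)/999 (exact exhaustive
   enumeration available as an oracle).
6. **Motif enrichment**: presence/absence counts of a motif panel in
   target vs GC/length-matched background sequences, cumulative binomial
   upper tail, Benjamini–Hochberg adjustment.

A synthetic-data generator plants all of this structure (bound / HRE /
responsive labels, peak scores, expression effects) on a toy genome so the
whole pipeline is testable without sequencing downloads, and
`classification_accuracy()` grades any run against the planted truth.

## Worked example

```r
library(hrepipe)
cfg <- pipeline_config(out_dir = "demo_run",
                       sim = simulation_config(n_genes = 120, seed = 42),
                       seed = 42)
res <- run_pipeline(cfg)
```

The per-stage log prints the funnel:

```
[simulate] n_genes=120 n_peaks=110 n_samples=36
[filter_peaks] n_in=110 n_definitive=60
[merge_peaks] n_merged=60
[annotate] promoter=1 exon=0 intron_or_intergenic=0
[select_genes] n_selected=48
[expression_filters] n_after_na=120 n_after_sd=120 n_induced=39 n_cluster_set=28
[cluster] n_primary=2 p_value=0
[classify] responsive=24 unresponsive=24 unbound=72
[enrich] top_motif=HRE top_p=0.605
```

Reading it: 110 simulated peaks (60 true promoter peaks, 50 sub-threshold
decoys) reduce to 60 definitive peaks — every decoy dies at the strict
score > 20 filter, and every survivor sits in a promoter window. 48 of the
60 bound genes carry a planted HRE under the peak and are selected; 39
genes pass the 1.2-fold induction filter (the 24 responsive genes plus
noise-induced bystanders), 28 of which are in the selected set and get
clustered. The second-level cut separates cleanly (separation statistic
3.55, permutation p = 0/999, i.e. below 1/999). Classification against
the planted truth is perfect:

```r
classification_accuracy(res$classification, res$truth)
#> $accuracy
#> [1] 1
#> $confusion
#>               predicted
#> truth          responsive unbound unresponsive
#>   responsive           24       0            0
#>   unbound               0      72            0
#>   unresponsive          0       0           24
```

(The enrichment p of 0.605 on full 2000-bp windows illustrates a real
phenomenon: presence/absence of a 5-mer saturates on long sequences —
see the vignette; short-fragment benchmarks show the expected strong
ranking.)

The same stages are scriptable:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/hrepipe", package = "hrepipe"))')
Rscript $CLI simulate --out sim --n-genes 120 --seed 42
Rscript $CLI scan --fasta sim/promoters.fasta --out hits.tsv
Rscript $CLI peaks --bed sim/peaks.bed --min-score 20 --out merged.bed
Rscript $CLI run-all --config config.yaml --out run1 --seed 42
```

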