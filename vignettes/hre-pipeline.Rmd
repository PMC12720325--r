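---
title: "Classifying HRE-bound genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying HRE-bound genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrepipe)
```

## The problem

Hypoxia-inducible factor 1α (HIF-1α) binds hypoxia-response elements
(HREs), short promoter motifs with the core consensus 5′-RCGTG-3′
(R = A or G). In stimulated macrophages, HIF-1α binds thousands of sites
genome-wide, yet only a fraction of the bound genes respond
transcriptionally. `hrepipe` implements the integrative analysis that
separates these two groups: it intersects ChIP-Seq binding peaks with HRE
occurrences in promoter windows, filters an expression time course for
stimulus-induced genes, clusters the bound genes by their trajectories,
tests whether a cluster subdivision is statistically real, and classifies
bound genes as *responsive* (wild-type expression more than twofold above
the knockout) or *unresponsive*.

Because the original conclusions rest on deep-sequencing data that cannot
be regenerated at desk scale, the package ships a synthetic-data generator
with planted ground truth. Every downstream stage is exercised and graded
against that ground truth rather than against irreproducible headline
counts.

## The model and its parameters

**Promoter windows.** The promoter is the interval from 1500 bp upstream
to 500 bp downstream of the transcription start site (TSS), in
transcription orientation. Internally all coordinates are 0-based
half-open; for a `-` strand gene the window is the mirror image about the
TSS base, `[tss - 499, tss + 1501)`, so that it covers exactly 1500 bp 5′
of the TSS and 500 bp from the TSS onward on the transcribed strand.

**Definitive peaks.** Peak-caller scores are filtered with a *strict*
`score > 20` rule. Merging unions intervals that share at least 1 bp;
book-ended intervals (end == start) are not merged, matching the
"merge on literal overlap" reading of the upstream tool's `-d given`
option.

**HRE selection.** A gene enters the bound-HRE set iff some definitive
peak, some RCGTG occurrence, and the promoter window have a common
intersection (the intersection test is applied at the motif-hit level).
The alternative reading — peak-in-window and motif-in-window checked
independently — differs only on contrived layouts and is available via
`strict = FALSE`. Scanning covers both strands by default: RCGTG is not
palindromic, but enhancer-element function is orientation-independent, and
the original method description does not state strandedness. A
single-strand mode exists for sensitivity analysis.

**Expression filters.** Counts are converted per sample as
`TPM_g = (count_g / length_kb_g) / sum_g(count_g / length_kb_g) * 1e6`,
then `log2(TPM + 1)`. The filter cascade is fixed: drop rows with any
missing value, drop rows with *exactly* zero standard deviation, then keep
genes whose mean expression at 24 h exceeds 1.2 times the mean at 4 h.
All fold thresholds ("more than 1.2-fold", "more than twofold") are strict
and evaluated as differences of mean log2 values against `log2(ratio)`.
Whether the original filter used log2 or linear means, and which timepoint
anchored the WT-vs-KO comparison, is not recorded anywhere; this package
uses log2 means and takes the *maximum* WT/KO ratio over the post-stimulus
timepoints (4 h, 24 h) in either condition, recording the winning
condition/timepoint in its output so the choice is auditable.

**Clustering.** Euclidean distances with the `ward.D` linkage — the
Lance–Williams Ward update applied to *unsquared* distances, exactly R's
`ward.D` convention that the original analysis names. The classical Ward
criterion (`ward.D2`) is selectable. The primary cut is at dendrogram
height 50 on the data's own scale (rows are deliberately *not*
standardised — no row scaling is mentioned in the source method, and the
height threshold is only meaningful relative to that choice); the largest
primary cluster is then re-clustered and cut into k = 2 subclusters.
The number of primary clusters is data-dependent and is not asserted
anywhere.

**Permutation test.** Cluster separation is measured as
(mean between-cluster distance) − (mean within-cluster distance) over all
unordered item pairs. Significance comes from 999 random label
reassignments that preserve group sizes; the p-value is the literal
proportion of permutations with a statistic ≥ the observed value. This
literal rule can return p = 0, so an `add_one` option implements the
standard (count+1)/(n+1) variant — that variant is what the null
calibration test uses, since the literal rule is anti-conservative by
1/(n+1). An exhaustive enumerator over all size-preserving arrangements
serves as the exact oracle where feasible.

**Enrichment.** Motif enrichment uses presence/absence counting (does a
sequence contain ≥ 1 hit), a cumulative binomial upper tail with the
background hit fraction as the null probability, and Benjamini–Hochberg
adjustment across the motif panel. The background is sampled to match the
targets' GC-fraction bins (10 equal-width bins by default) and length bins
(1 by default — promoter windows are fixed-length). When the background
count is 0 or n, the null probability is clamped to
`[1/(2n), 1 - 1/(2n)]` to avoid p-values of exactly 0 or 1 from a finite
background. Occurrence-level counting (more than one hit per sequence
contributing) is available behind the scanner API but presence/absence is
the default, matching standard known-motif practice; the upstream tool's
internal weighting is undocumented, so this is the package's own choice.

## What the generator emulates — and what it does not

`simulation_config()` states the emulated world once:

* design: WT and KO genotypes × LPS and hypoxia × 0/4/24 h, 3 replicates
  per cell (the source study reports triplicate expression measurements);
* half the genes bound; 80% of bound promoters carry a planted HRE; half
  of those are responsive with a planted +2 log2 fold-change at the
  induced timepoint (24 h for LPS, 4 h for hypoxia), KO flat at baseline;
* baseline log2-TPM ~ N(6, 1.5) and additive N(0, 0.25) noise — typical
  magnitudes for moderately expressed genes in bulk RNA-seq;
* definitive peak scores ~ N(60, 15) for bound promoters, decoy peaks
  ~ N(10, 3) placed intergenically (sub-threshold by construction);
* background sequence i.i.d. at 45% GC, 200-bp peaks centered on the TSS.

Two deliberate departures from naive i.i.d. sequence keep the ground truth
clean: chance RCGTG occurrences are scrubbed from each bound gene's peak
footprint before planting (selection demands peak ∩ HRE ∩ window, so only
the footprint matters), and planting rejection-resamples up to 100 times
if the inserted core's flanks create a second overlapping occurrence.
Chance HREs elsewhere in the 2000-bp window are left alone — they are
real features of promoters and exercise the intersection logic.

The generator does **not** model read-level noise, ChIP fragment-size
effects, GC bias, multi-peak genes (a config extension, default off), or
correlated expression noise. A green end-to-end test therefore
establishes that the *integration logic* is correct under the stated
world, not that the pipeline is robust to every artefact of real
sequencing data.

One scale caveat, documented because it shapes the enrichment benchmark:
on 2000-bp promoter windows at realistic GC, presence/absence of a 5-mer
saturates (almost every window contains some RCGTG by chance), so the
sequence-level enrichment statistic is only informative for short
cis-regulatory fragments. The ranking benchmark consequently uses 100-bp
sequences at 40% GC, where the planted 0.8-vs-0.05 contrast is visible
above the ~0.2 chance-hit floor.

## Numerical choices and tie-breaks

* All interval coordinates 0-based half-open internally; BED is native,
  GFF3 shifted at the I/O boundary only.
* Nearest-gene ties broken by lexicographically smallest gene id;
  agglomeration ties by smallest cluster-index pair — both for
  determinism.
* Peak midpoint (`floor((start+end)/2)`), not the full span, drives
  genomic-category and nearest-TSS decisions, mirroring standard peak
  annotators; category priority is promoter > exon > intron/intergenic.
* The exhaustive permutation test compares statistics with a 1e-12
  absolute slack so mirror-symmetric arrangements that are equal in exact
  arithmetic are not split by floating-point noise.
* Zero-variance rows are removed on an exact-zero criterion (a 1e-9
  wiggle keeps a row), matching the stated rule rather than a tolerance.
* Stage seeds derive from the global seed by stage-name hashing (kept
  below 2^31), so any stage rerun in isolation reproduces its slice of a
  full run.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "demo_run",
                       sim = simulation_config(n_genes = 120, seed = 42),
                       seed = 42)
res <- run_pipeline(cfg)
res$manifest$counts
classification_accuracy(res$classification, res$truth)$accuracy
```

The manifest records the funnel (peaks in, definitive peaks, selected
genes, genes surviving each expression filter, cluster sizes) and the
permutation p-value; counts never increase along a filter chain.

## Known limitations

* The clustering cut height (50) is inherited verbatim and is only
  meaningful on unstandardised log2-TPM-scale data of comparable column
  count; on other scales it degenerates to one cluster or all singletons.
* The literal permutation p-value divides by 999 and can be 0; use
  `add_one = TRUE` when calibration matters.
* GC/length background matching bins on realised GC, so very small pools
  can leave a target bin empty; the sampler then errors (or, with
  within-bin exhaustion, falls back to sampling with replacement and
  warns) rather than silently mismatching.
* The pipeline consumes peak *tables*; peak calling from reads, de novo
  motif discovery, and pathway-database lookups are out of scope.
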