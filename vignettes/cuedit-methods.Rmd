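---
title: "Methods: calling and trans-regulator screening of plant organellar C-to-U editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and trans-regulator screening of plant organellar C-to-U editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuedit)
```

# The problem

Plant mitochondrial and chloroplast transcripts undergo cytidine-to-uridine
(C-to-U) RNA editing, visible in cDNA sequencing as C-to-T substitutions.
Editing is catalysed at specific cytidines by sequence-specific trans
factors (the PPR protein family), but sites differ widely in their editing
*levels*, and the cis and trans features that modulate those levels are the
analytical target here. `cuedit` implements the complete analysis chain:

1. calling editing sites from per-position base counts (pileups),
2. characterising the sequence neighbourhood of edited cytidines and the
   codon consequences of editing,
3. testing whether edited cytidines avoid base-paired (double-stranded) RNA,
4. resolving allele-specific editing in an interspecies hybrid, where two
   diverged parental alleles share a single trans environment, and
5. screening genome-wide expression for candidate trans-regulators by
   correlation with per-site editing levels across samples.

Because the package is developed and tested without access to sequencing
archives, a first-class synthetic-data module generates data with exactly
the statistical structure the analysis assumes; every downstream stage is
validated against that generator's ground truth.

# Site calling

The pileup model is deliberately minimal: one row per (gene, CDS position,
sample) with quality-filtered A/C/G/T read counts. Mapping, duplicate
handling and base-quality filtering are upstream of the package's entry
point. Coordinates are 1-based positions on the sense strand of each
gene's longest CDS.

A variant's level is `alt_count / depth`; for a C-to-U site this is
`T / (C + T)`. Discovery applies three filters, with the comparison
directions chosen deliberately:

* depth of at least 10 reads (`>=`),
* level strictly greater than 0.05 (`>`), and
* exactly one variation type present. A second alternative base counts as
  "present" when it has at least 2 reads *and* at least 1% of the depth;
  pure singletons at high depth are treated as sequencing noise. Both
  thresholds are exposed (`second_alt_min_reads`, `second_alt_min_frac`).

Site selection keeps C>T records only, collapses them to one site per
(gene, position), and then reports the *full* per-sample level vector,
including samples where the level is below 0.05 — the discovery filter
applies to discovery, not to the level vectors the correlation screen
needs. A site is `detectable_all` when its depth reaches the minimum in
every sample; only those sites enter the trans screen.

# Sequence context and codon consequences

Contexts are `2k+1`-mers (default k = 4) centred on the edited C, padded
with `N` at CDS boundaries; composition profiles exclude the padding from
their denominators. Editing levels are grouped by the base at a chosen
offset (the -1, i.e. 5', base is the interesting one) and compared with
two-sided Wilcoxon rank-sum tests; a site's level is summarised as its
mean across samples (the alternative — per-sample values — is a
documented choice; the mean keeps one observation per site and avoids
pseudo-replication).

Codon consequences are annotated with the standard genetic code for all
compartments (plant organelles use the standard code). The implementation
computes `codon_index = ceiling(pos / 3)` and mutates the codon at
`pos_in_codon`; a brute-force oracle in the test suite instead mutates the
whole CDS and translates both versions with Biostrings.

# RNA secondary structure

The analysis needs only a structured/unstructured partition of each CDS,
not folding energies. `fold_local()` therefore uses a Nussinov-style
base-pair maximisation dynamic program (Watson-Crick plus G·U pairs,
minimum hairpin loop 3 nt), implemented in C++, applied to consecutive
non-overlapping 150-nt windows. The windowing mirrors local-folding tools;
tiling without overlap keeps the reported dot-bracket and the regions
mutually consistent, at the cost of missing hairpins spanning a window
boundary — acceptable for a partition used only in aggregate.

Reported regions are maximal runs of stacked pairs (helices) with at least
`min_helix = 3` pairs. When a helix closes a terminal hairpin loop, the
loop positions count as structured (`loops_structured = TRUE`; whether
loops are "structured" is genuinely debatable, so the flag exposes the
alternative). Multiloop interiors are *not* blanket-counted: under maximum
pairing almost every position of a long random sequence is enclosed by
some pair, and counting enclosures would declare ~100% of the genome
structured. With these conventions random-sequence CDSs come out ~40–50%
structured, a sensible operating point for the overlap test.

Each region carries a pairing-density score (`-helix_length / window`,
negative = structured). This is **not** an energy Z-score; it only
preserves the "keep score < 0" convention used when importing real
local-fold output via `parse_fold_regions()`, which accepts the
`"((((...)))) ( -5.40) 17 z= -1.20"` dialect and keeps regions with
negative z (falling back to the energy when no z is present).

Regions are merged per CDS (interval union; `structure_percent` = merged
length / CDS length), and the association between editing and structure is
tested with a two-sided Fisher exact test on the 2×2 table of
edited/unedited × structured/unstructured cytidines. The unedited
population is all cytidines of CDSs that carry at least one called site,
minus the called sites — keeping compartment composition comparable.

# Hybrid allele-specific editing

In an interspecies hybrid, both parental alleles are transcribed in the
same cellular (trans) environment, so a site edited on one allele and not
the other isolates cis effects. Reads are assigned to an allele when they
match it exactly and mismatch the other at one or more diagnostic
positions; at catalogued C sites both C and T are accepted on both
alleles, so editing itself can neither break nor create an assignment.
"Fully edited" and "completely unedited" are quantified as level ≥ 0.95
and ≤ 0.05 (the verbal absolutes need numeric form; both thresholds are
arguments), with at least 10 covering reads per allele — the same depth
standard as site discovery, since no separate "adequate depth" is defined
for the hybrid setting.

`hybrid_example()` reconstructs the package's worked example as a
*synthetic* stand-in CDS: codon 121 is ACA and codon 126 is CGT, so the
cytidines at positions 362 and 376 produce ACA(Thr)→AUA(Ile) and
CGU(Arg)→UGU(Cys) missense changes; allele depths are 103 and 31 reads.

# The trans-regulator screen

Expression is RPKM (`reads / kb / million mapped reads`), with a Ribo-seq
count matrix as the intended input. Genes first pass a standard-error
filter: with three root and three shoot replicates, a gene is considered
only when `SE_root < SE_all` and `SE_shoot < SE_all` — expression must
vary between tissues more than within them. The pipeline applies this
filter on log2 RPKM: RPKM is approximately log-normal, and the
within-vs-between-group comparison assumes additive, roughly normal
variation, which holds on the log scale. The filter defines the *tested
family*: genes failing it are excluded before correlation testing. This
ordering matters — with six samples the exact permutation p-value cannot
go below 2/720 ≈ 0.0028, so FDR control over a family inflated with
uninformative genes would leave nothing significant at any realistic
effect size; restricting the family to expression profiles that are even
candidates for tissue-coupled regulation is both the biological intent of
the filter and the arithmetic precondition of the screen.

Each detectable site's 6-sample level vector is correlated with each
tested gene's RPKM vector: Spearman rho as Pearson correlation on average
(tie-aware) ranks, and a two-sided p-value computed *exactly* by
enumerating all 720 permutations of the site's ranks (asymptotic
approximations are unreliable at n = 6; above n = 8 the implementation
switches to the t approximation). Pairs with a constant vector are
skipped. Benjamini–Hochberg FDR is then controlled at 0.05 over the full
site × gene family by default (`family = "global"`); a per-site family is
available by configuration.

Classification follows set rules:

* **Sites.** With `n_pos` / `n_neg` significantly positively / negatively
  correlated genes, a site is class I when `n_pos >= 5` and
  `n_pos >= 2 * n_neg`, class III symmetrically, class II otherwise. The
  class boundaries are not recoverable from a verbal "generally divided
  into three classes", so the rule is declared, configurable
  (`n_min`, `dominance`), and recorded in the run manifest.
* **Genes.** n1 = genes positively correlated with ≥ 10 sites, n2 = the
  negative analogue; positive = n1 \\ n2, negative = n2 \\ n1, both =
  n1 ∩ n2.

Downstream summaries: per-class mean level, per-site level standard
deviation and nonsynonymous fraction (pairwise Wilcoxon tests); genes
whose sites belong to exactly one class (mixed-class genes excluded);
per-gene relative level profiles (samples ordered by the gene's RPKM, each
site's series shifted so its minimum is zero); the 5'-base composition of
the sites pooled per gene class against the all-sites background; and a
hypergeometric term enrichment with BH correction standing in for an
external annotation web service.

# The synthetic study

`sim_config()` defaults define the simulated study: 2000 CDSs of 300–1500
nt (30 mitochondrial + 12 chloroplast carrying the editing; nuclear genes
enter through expression only), 100 true sites, six samples (3 root +
3 shoot), and 20 positive + 20 negative regulator genes. Design choices
that matter, and why:

* **5'-base level map** `T:0.80, C:0.60, A:0.40, G:0.15` — reproduces the
  observed *ordering* of levels by upstream base (T highest, G lowest);
  the numeric values are generator choices, not estimates. Site placement
  is weighted by the same map, so one mechanism yields both the context
  enrichment of edited cytidines and the level ordering.
* **Structure avoidance 0.9** — a site lands inside a base-paired region
  with probability 0.1; the structured intervals come from `fold_local()`
  on the generated reference itself, so placement truth and analysis see
  the same partition.
* **Regulator coupling.** One latent activity factor per regulator module
  (positive and negative), with a root/shoot shift of 2.5 (log2) and
  within-group spread 1.0. Regulator log2 expression tracks its module's
  factor; a targeted site's level is
  `inv_logit(logit(base) + sum_r effect * sign_r * z_r + noise)` with
  `effect = 0.11` per regulator and noise SD 0.02 — a logit-linear link,
  the minimal monotone assumption that Spearman correlation can recover.
  80% of sites are targeted (half per module); the positive module's
  targets are sampled with weight proportional to squared base level, so
  positively regulated sites are enriched for 5'-T — letting the screen's
  gene-class composition analysis find the association between trans
  regulation and cis context. Untargeted sites receive much larger level
  noise (SD 1.0 on the logit scale), so regulated sites are the higher
  *and more stable* ones, as the per-class statistics expect.
* **Factor construction constraints.** All regulators of a module share
  one factor draw, so the draw itself must carry the properties the
  analysis assumes of regulators, deterministically rather than in
  expectation: it is redrawn until (a) its realised within-group variance
  is below 0.35 × total variance (a tissue-differential gene *by
  construction*, not by luck), (b) within-group adjacent gaps are at
  least 0.45 × the within-group SD (two near-tied samples would flip
  ranks at every correlated site), and (c) the two modules' rank orders
  are neither identical nor exactly reversed (rank-colliding modules
  would make every regulator correlate with every targeted site and
  collapse the positive/negative labels into "both").
* **Coverage 800–3000 reads per position** — organellar transcripts are
  highly abundant, and with six samples the screen's currency is *exact
  rank agreement*; binomial level noise at shallower depth flips adjacent
  sample ranks and dissolves the floor-level p-values the FDR step needs.
* **Expression background.** 5% of non-regulator genes are built to pass
  the SE filter (group shift ≫ within-group noise); the rest are built to
  fail it (equal group means, within-group spread dominating, patterns
  permuted per gene so library totals stay balanced). Keeping the
  SE-passing background small is a deliberate scaled-down condition: the
  tested family must stay small enough for the discrete permutation
  p-floor to clear FDR at 0.05. Real tissue pairs have a larger
  differential fraction — and correspondingly more samples or deeper
  designs would be needed to screen against them.
* **Sequencing error 0.2%** per base, symmetric over the three
  alternatives, applied at non-edited positions only — enough to exercise
  the level filter without contaminating the substitution spectrum.
* **Hybrid divergence 3%** per nt between parental alleles, editing
  positions protected (C on both alleles); designated sites fully edited
  on exactly one allele; 100-nt reads at ~4× per allele.

Determinism: every stage derives its own sub-seed from `config$seed`, so
stages are reproducible independently of call order, and identical configs
give byte-identical outputs.

## What passing on synthetic data does and does not show

The generator emulates the *statistical couplings* the analysis targets —
it does not emulate mapping bias, quality-score structure, isoform
ambiguity, genomic SNP contamination, PCR duplicates, or continuous
(rather than two-block) expression covariation. Recovery results on
synthetic data therefore validate the pipeline's logic and calibration
(the null screen yields essentially no significant pairs), not its
robustness to those real-data artefacts, which are deliberately upstream
of the package's pileup-level entry point.

# Numerical choices and degenerate inputs

* Exact rational level `alt / depth`; depth 0 is an error, never NaN.
* Permutation p-values compare `|rho|` with a 1e-12 slack so floating
  ties at ±1 are counted; constant vectors are skipped and reported.
* Spearman ties use average ranks; the permutation null is over the
  observed (tied) values.
* `merge_regions` treats adjacent intervals (`end + 1 == start`) as one
  region; region ordering and duplication do not affect the result.
* Classification is vectorised set algebra — no iteration-order effects.
* One-site classes report their level SD as unavailable rather than 0.
* The BH step is `stats::p.adjust(method = "BH")`; the test suite holds
  it against a brute-force step-up implementation, as it does Fisher's
  test against hypergeometric enumeration and the fold against an
  exhaustive structure search.

# Problem sizes used in validation

Module tests run on 60-gene configurations; the end-to-end recovery
properties use the full default study (2000 genes, 100 sites — 200 for
the structure test) over five generator replicates, the scale at which
the screen's family arithmetic is meaningful. At these sizes the complete
validation, including the exhaustive oracles, runs in a few minutes on
one CPU.

# Known limitations

* The fold is a pairing-maximisation partition, not a thermodynamic
  model; its regions are comparable between populations within a run but
  not against energy-based structure predictions.
* With six samples the exact-permutation floor (p = 2/720) makes the
  screen inherently all-or-nothing at FDR 0.05: essentially only perfect
  rank agreement can become significant, so power depends sharply on
  coverage and on the size of the tested family. This is a property of
  the design being emulated, surfaced — not created — by the exact test.
* The "longest CDS per gene" de-redundancy rule is honoured implicitly:
  the generator emits one CDS per gene, and real input is expected to be
  pre-collapsed to longest-CDS coordinates.
* Gene labels rest on a ≥ 10-site threshold; with ~100 sites total, the
  label set is sensitive to that constant, which is why it is an exposed
  argument recorded in the manifest.

# A minimal run

```{r example, eval = FALSE}
library(cuedit)
res <- run_pipeline(sim_config(seed = 1), out_dir = "results/run1")
print(res)
evaluate_recovery(res)
```
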