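---
title: "Methods: rubric scoring, burden statistics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rubric scoring, burden statistics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crl4score)
```

# Scope and model

`crl4score` interprets regulatory variants found by panel sequencing of
the CRL4–Cereblon complex genes in small case cohorts. The analysis has
three layers: a per-variant severity score aggregating functional
predictions, per-individual burden statistics compared between phenotype
subgroups and a reference panel, and sequence-level computations (CpG
islands, codon usage, motif disruption, bisulfite methylation, pairwise
dN/dS). Because the motivating patient data are confidential, a seeded
synthetic-cohort generator is a first-class module: every statistical
claim the test suite makes is made about data whose generating parameters
are known exactly.

# The severity rubric

Each variant is annotated in ten evidence categories (see
`rubric_categories()`). External predictors are *not* run by this package;
their verdicts are ingested as a normalized table with three ordered
levels, `none < possible < strong`. When several predictors feed one
category, consolidation keeps the most severe verdict (ties keep the first
record and are noted). The default rubric awards 0/1/2 points per verdict
in every category, giving a per-variant total between 0 and 20 — the
ceiling of the published score scale this design reconstructs. The
original study's exact point table is not public, so the rubric is fully
configurable: any table with columns `category`, `verdict`, `points` that
passes `validate_rubric()` (zero for `none`, monotone in severity) can be
supplied, and `rubric_max_total()` reports the resulting ceiling.

Two deliberate choices:

* **Missing annotations score 0** rather than being treated as missing
  data; the score aggregates *predicted effects*, and silence from a
  predictor is absence of evidence, scored as such.
* **The critical-exon modifier promotes within the verdict scale**
  (`possible` → `strong`) instead of adding bonus points, so the ceiling
  stays at `max_total`. The rule: a splicing verdict is promoted when the
  variant lies in, or within the intronic flank of, an exon strictly
  upstream (5', strand-aware) of the gene's first critical exon — the
  biological rationale being that mis-splicing there can truncate the
  protein before an essential domain such as Cereblon's C-terminal
  drug-binding region.

The reporting heatmap keeps variants with total ≥ 10 (half the ceiling),
ordered by total descending and then variant id — a deterministic
tie-break so reruns are byte-identical.

# Burden statistics

For individual $i$ with score table $S(v)$, the burden is
$B(i) = \sum_{v \in \text{carried}(i)} w_i(v)\, S(v)$ with carrier
weighting ($w = 1$ for any dosage ≥ 1) by default; dosage weighting
($w =$ alt-allele count) is a flag. Carrier weighting is the default
because the genotype presentation this mirrors distinguishes only
present/absent/homozygous, and the source analysis does not state that
homozygotes counted twice; the flag preserves the alternative reading.
Count burden replaces $S(v)$ by 1.

Statistical machinery is deliberately classical, matching what a clinical
genetics group would run in SPSS/R:

* two-sided pooled-variance Student's t (Welch optional) for two-group
  burden comparisons; degenerate zero-variance cases return $t = 0, p = 1$
  when means agree;
* one-way equal-variance ANOVA across the two case endophenotypes and the
  reference panel;
* Pearson chi-square *without* continuity correction for contingency
  tables, with Fisher's exact test alongside for 2×2 tables (carrier ×
  endophenotype); monomorphic variants are skipped with a notice;
* chi-square homogeneity test for location distributions, with a
  Monte-Carlo fallback reported when an expected cell drops below 1;
* nominal p-values by default; Benjamini–Hochberg via `adjust = "BH"`.

These are computed with `stats::t.test`, `stats::oneway.test`,
`stats::chisq.test(correct = FALSE)` and `stats::fisher.test`; the test
suite cross-checks them against independently coded closed forms and an
exhaustive hypergeometric enumeration, so the package's contribution (the
rubric and burden layer) is never validated by the same code that
implements it.

Location percentages are **truncated**, not rounded, to one decimal: 11
coding variants among 145 report as 7.5%, reproducing the printed
convention of the source analysis.

# Sequence-level computations

**CpG islands.** Gardiner-Garden–Frommer criteria with the standard
defaults (window = minimum length 200 bp, GC ≥ 0.5, CpG obs/exp ≥ 0.6,
obs/exp computed as $\#CpG \cdot L / (\#C \cdot \#G)$), sliding step 1,
qualifying windows merged into maximal islands. The exact tool parameters
behind the motivating study are unstated, so all three thresholds are
exposed as arguments. Variant impact re-runs the detector on the
alt-substituted sequence and compares islands within ± one window length
of the variant: `created`, `disrupted`, `enlarged`, `shrunk`, or `none`.

**Codon usage.** Tables count codons and report within-synonymous-family
relative frequencies; stop codons are excluded from families. A
synonymous variant's verdict compares the alt codon's family rank against
the ref codon's: moving up in rank is `to_most_frequent`, down is
`to_less_frequent`, a tie `unchanged_rank`; both a gene-scope table and a
genome-scope table are consulted because the two can disagree. Which
human genome-wide table the motivating study used is unstated, so any
table can be supplied; the packaged
`human_codon_usage_synthetic.tsv` is an approximate, rounded human-like
fixture (labelled synthetic) sufficient for rank comparisons.

**Motif disruption.** PWMs (JASPAR tab format) are converted to log2-odds
against a uniform background after pseudocount smoothing (0.8, split by
background frequency). Every motif-length window covering the variant is
scored on both strands for the reference and alt sequence and the best
scores compared. Defaults are conservative: a site "breaks" only if the
reference reaches 80% of the motif's maximum score and the alt falls
below it; weakening/strengthening requires at least 1 bit of change. Both
thresholds are arguments.

**Bisulfite.** Conversion assumes complete chemistry by default
(unmethylated C → T everywhere, methylated CpG C retained); a
conversion-failure rate exists for simulating incomplete treatment. The
caller inverts the mapping per CpG site and reports `uninformative` for
bases that read neither C nor T. Calling after converting recovers the
planted states exactly — an identity the suite asserts on random
fixtures.

**Pairwise dN/dS.** The Nei–Gojobori (1986) counting method with
equal-weight averaging over substitution pathways and Jukes–Cantor
correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$; $\omega = dN/dS$ is
flagged undefined when $dS = 0$ or $p \ge 3/4$. Mutations to stop codons
count as nonsynonymous rather than being excluded, which keeps the site
identity $N + S = 3 \times$ codons exact; this and the absence of a
transition/transversion bias are documented simplifications relative to
maximum-likelihood codon models, which are out of scope. The screen's
purpose is qualitative — $\omega \ll 1$ indicates purifying selection —
and the suite verifies $\omega < 0.1$ under synonymous-only simulated
divergence and $\omega \approx 1$ under neutral simulation.

# The synthetic cohort: what it emulates, and what it does not

`synthetic_config()` defaults *are* the stated world:

| parameter | default | source of the choice |
|---|---|---|
| case subgroups | 10 pre-axial, 14 intercalary, 11 other | cohort structure being emulated |
| reference panel | 99 | European reference sample size |
| variants | 145 over 5 genes (CRBN 45, IKZF1 40, CUL4A/DDB1/IKZF3 20) | total and "CRBN and IKZF1 richest" pattern |
| coding variants | CUL4A 3, others 2 (11 = 7.5%) | printed per-gene exonic counts |
| rare variants | 43 (MAF < 0.01) | printed rare fraction |
| MAF mixture | rare U(5e-4, 0.01); common U(0.01, 0.3) | plausible panel allele-frequency spread |
| verdict probabilities | none .60 / possible .25 / strong .15 | see calibration below |
| noncoding placement | UTR3 .45 / UTR5 .15 / intron .40 | UTR3-heavy location profile |
| burden shift δ | 34 points into the pre-axial subgroup | mirrors the 228.9 − 195 group contrast |

Genotypes are Hardy–Weinberg draws, independent across variants (no LD —
no statistic in scope uses it). The enrichment mechanism biases the
*carried-variant set* of the named subgroup: non-carried variants are
flipped to heterozygous, sampled proportionally to score, until at least
δ points have been added, so the variant catalogue stays shared across
groups rather than gaining phantom sites. Realised added scores are
recorded per individual in the truth table, and the suite checks the
estimated group contrast against the realised plant.

**Power calibration (a priori, not iterated).** With the defaults, the
per-individual score-sum SD is ≈ 25 points: the variance is
$\sum_v S(v)^2 p_v (1 - p_v)$ with carrier probability
$p_v = 1-(1-q_v)^2$, and with ~102 common variants at mean $E[S^2] \approx
36$ and $E[p(1-p)] \approx 0.17$ this gives $\sigma \approx 25$. A
34-point shift in a 10-individual group against 14 + 99 unshifted
individuals yields an ANOVA noncentrality of ≈ 17 (power ≈ 0.95 at
α = 0.05) and a two-group t effect size d ≈ 1.35. The verdict
probabilities and MAF ranges were fixed once from this computation and
not revisited after observing test results.

**Sequence realism.** Backgrounds are drawn at 40% GC and then
CpG-depleted (≈ 90% of background CpGs rewritten), and CDS codons are
sampled from the human-like table with strong suppression of CpG-bearing
and CpG-forming codons — emulating the CpG depletion of real vertebrate
DNA so that *only* the deterministically planted island block (80% GC,
obs/exp 2.5 in every window) satisfies the island criteria. Consequences:
the planted island is found exactly, and island-free configurations are
clean; but the CDS codon usage is more CpG-poor than real human coding
sequence, and annotation verdicts are drawn from the configured category
distributions *independently* of the sequences (a `cpg_island` verdict is
not recomputed from the FASTA). A green test therefore establishes the
statistical behaviour of the scoring and burden machinery under a known
world — not that real predictor output or real human sequence was
reproduced.

# Numerical and engineering choices

* Coordinates: VCF positions are 1-based; all internal intervals are
  0-based half-open. Gene models live on per-gene contigs named by the
  gene symbol, matching the panel design.
* Multi-allelic VCF records are decomposed into biallelic variants;
  scoring and burden are per-allele.
* Missing genotypes are excluded from an individual's burden sums (and
  counted in a message); unscored variants contribute to counts with
  score 0.
* All generator randomness flows from one master seed through named
  substreams (placement, MAFs, annotations, genotypes, sequences,
  enrichment), so any layer can be regenerated independently and a fixed
  seed yields byte-identical output files.
* Deterministic pipeline stages are byte-stable; the run manifest records
  md5 checksums of all inputs and outputs plus per-stage row counts. The
  manifest's timestamp is the only non-reproducible field.

# Known limitations

* The reconstruction of the scoring rubric (10 × {0,1,2}) matches the
  published ceiling and threshold semantics but is not the original
  (unpublished) point table; any alternative can be dropped in as a TSV.
* The dN/dS screen is a counting stand-in for likelihood codon models; it
  supports qualitative purifying-selection statements only.
* No LD, no population structure, no pedigrees in the generator; burden
  tests here are classical location tests, not SKAT-style kernel tests.
* The location-distribution comparison treats the supplied reference
  counts as fixed (a large-panel approximation), as the homogeneity
  chi-square assumes.
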