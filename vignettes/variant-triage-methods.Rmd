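---
title: "Methods: rare-variant triage for targeted gene panels"
author: "variantTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant triage for targeted gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variantTriage)
```

# Scope

`variantTriage` implements the desk-scale computations used to interpret
rare variants found by targeted panel sequencing in pulmonary arterial
hypertension (PAH) gene-panel screening — the setting in which rare
*ABCC8* (SUR1) variants are curated. Five analysis stages are covered:
in-silico predictor aggregation mapped to ACMG evidence, transcript-level
splice/indel consequence simulation, cohort depth-ratio CNV calling,
conservation logos, and descriptive cohort statistics, plus seeded
generators that produce ground-truthed synthetic inputs for each stage.
Wet-lab steps (minigene assays), the internal algorithms of the upstream
predictors, and structural modeling are out of scope: their *outputs* are
inputs here.

# The 7-point predictor aggregation score

Each variant carries outputs from seven tools: Annovar impact, CADD,
SIFT, PolyPhen-2, MutationAssessor, FATHMM and VEST. Each output is
discretized to one of three levels and scored

$$ S \;=\; \sum_{i=1}^{7} s_i,\qquad
   s_i = \begin{cases} 1 & \text{damaging / high}\\
                       0.5 & \text{possibly damaging / moderate}\\
                       0 & \text{benign or missing,} \end{cases} $$

so $S$ lies on a 0.5 grid in $[0,7]$. Two conventions matter and both are
forced by the printed per-variant totals this scheme reproduces:

* **"Probably damaging" earns 0.5, not 1.** PolyPhen-2's verbal top
  category is not the literal "Damaging/High" label; rows containing it
  only sum to their printed totals if it contributes half a point.
* **Missing predictors contribute 0 but the denominator stays 7.** A
  splice-region variant scored by CADD alone is a "1/7", not a "1/1".

Numeric scores are discretized by the published per-tool intervals
(`?discretizeCall` lists them). The published ranges leave a few interval
endpoints unassigned (CADD 14, SIFT 0.23, PolyPhen-2 0.03 and 0.3,
MutationAssessor 1.8). A total, deterministic partition is required, so
these boundaries are assigned to the adjacent more-damaging-leaning side
by default; `boundaryPolicy = "strict"` assigns them to the
less-damaging side instead. Endpoints the ranges do assign (SIFT 0.06,
MutationAssessor 1.12, VEST 0.17 and 0.65, CADD 11) are fixed under both
policies. The choice never affects data simulated by
`simPredictorTable()`, which draws scores strictly inside band
interiors.

## From score to ACMG evidence and class

The score bands map to computational evidence codes with half-open
boundaries: $[0,2) \rightarrow$ BP4 (benign supporting),
$[2,4) \rightarrow$ no code (VUS level), $[4,7] \rightarrow$ PP3
(pathogenic supporting). Placing 4 inside the PP3 band follows the
observed classification of a score-4 variant as likely pathogenic, while
2.5-point variants are VUS. Frameshift variants and variants with
experimentally confirmed exon skipping receive the very-strong
null-variant code PVS1 irrespective of score.

`combineEvidence()` applies the published ACMG combining criteria,
encoded as a declarative rule table (`acmgRules()`): each rule is a
minimum count per strength category (PVS/PS/PM/PP/BA/BS/BP) sufficient
for a class. Conflicting pathogenic-side and benign-side evidence, or no
firing rule, yields VUS. The test suite cross-checks the rule engine
against an independently written counting implementation over every
evidence set of size up to three. Non-computational codes (PM2, PS3, ...)
are caller-supplied via the `other_codes` column — the package never
infers them — so final five-tier classes are reproducible only given the
curator's code assignments.

# Splice and indel consequence simulation

`TranscriptModel` holds a spliced cDNA, its exon segmentation (1-based,
contiguous, covering the sequence) and the CDS span; validity enforces a
CDS that starts with ATG, ends with a stop and contains no internal
stop. HGVS c./r. coordinates are CDS-relative. `skipExon()` removes an
internal coding exon, re-translates from the unchanged CDS start and
reports:

* frame status — frameshift iff the exon length is not a multiple of 3;
* the first stop codon reached, mapped back to the *former* exon that
  harbours it;
* the protein length excluding the terminating codon, and `aaLost`
  relative to the reference;
* HGVS strings: `r.<start>_<end>del` (the legacy `r.del<start>_<end>`
  dialect is emitted on request and accepted on input), and a protein
  description derived by diffing the mutant against the reference
  translation. Deletion names are right-aligned within residue runs, per
  HGVS 3'-rule; frameshifts use `p.(Xaa#YaafsTer#)` whose implied length
  `pos + offset - 2` is checked against re-translation on hundreds of
  randomized transcripts.

Skips that would remove the CDS start or stop codon, terminal exons and
fully non-coding exons are rejected rather than guessed. Lengths, not
"residues lost" phrasings, are the asserted quantities throughout,
because loss figures quoted in narrative text are frequently off by the
one or two residues exchanged at the novel junction.

## The synthetic ABCC8-like transcript

The real SUR1 transcript (Ensembl accession ENST00000389817) cannot be
redistributed with the package, so `syntheticAbcc8Transcript()`
deterministically reconstructs its *coding geometry*: a 1581-residue
product over 39 exons with the analysis-relevant exon spans pinned
(exon 22 = c.2557_2694, 138 nt, in frame; exon 27 = c.3330_3399, 70 nt,
frameshifting; exon 20/26/28/32 bounds likewise), and stop codons planted
in the shifted reading frames exactly where the documented truncations
place them: skipping exon 27 terminates in former exon 28 after 1118
residues; exons 20, 26 and 32 give 836, 1056 and 1292; the c.3288_3289del
frameshift gives p.(His1097ProfsTer16) and 1111. The filler sequence is
random under a fixed internal seed and is *not* the real ABCC8 sequence —
only the geometry is faithful. Construction is self-verifying: a naive
codon-by-codon oracle, independent of `skipExon()`/`applyIndel()`,
re-derives every planted consequence at build time and construction
aborts on any mismatch. Tests against this object therefore certify the
consequence engine's arithmetic on a transcript of realistic size, not
the identity of the real sequence.

# Depth-ratio CNV calling

The caller re-implements the LACONv-style procedure used on capture
panels. After minimum-depth filtering (samples below a 20× mean, then
intervals below a 15× cohort mean — the published thresholds name only
"minimal depth"; means are used here), per-cell dose ratios are computed
by two-stage median-of-ratios normalization:

$$ \mathrm{dose}_{ij} \;=\;
   \frac{d_{ij} / \mathrm{med}_i\, d_{ij}}
        {\mathrm{med}_j \left( d_{ij} / \mathrm{med}_i\, d_{ij} \right)} $$

(first over intervals within a sample, then over samples within an
interval), so every interval's cohort-median dose is 1 and a diploid cell
sits near 1, a heterozygous deletion near 0.5. The normalization scheme
itself is a design choice — only the thresholds are published — but it is
the standard construction for panel ratio methods and delivers exact
invariance to per-sample scaling, which the tests assert bitwise.

Z-scores are taken per interval across samples,
$z_{ij} = (\mathrm{dose}_{ij} - \bar{\mathrm{dose}}_i)/\mathrm{sd}_i$.
Deletions require dose ≤ 0.60 **and** z ≤ −2.0; duplications require
dose ≥ 1.20, on dose alone by default because no duplication Z threshold
is published (`dupZ = TRUE` adds a symmetric z ≥ +2 requirement).
Zero-variance intervals with an out-of-range dose are called on the dose
criterion alone, with a warning. Adjacent called intervals of one sample
and kind merge into a single call.

## What the thresholds imply at 150×

At a Poisson depth of 150× the relative depth noise is
$1/\sqrt{150} \approx 8.2\%$, so the deletion criterion sits ~4.9σ from
the diploid baseline and null cohorts essentially never produce deletion
calls (the suite verifies a mean well below one per 20-sample ×
50-interval cohort). The duplication dose threshold, however, is only
~2.4σ: the expected number of single-interval duplication flags on a
null 20 × 50 cohort is $1000 \times P(\mathrm{Pois}(150) \ge 180)
\approx 9.4$, and adding the symmetric z ≥ 2 requirement removes little
because dose ≥ 1.2 nearly implies z ≥ 2. This is a property of the
published threshold at that depth, not of the implementation; the
dose-only duplication pathway should be treated as a screening flag that
needs manual review, while the deletion pathway is specific as
published. The property suite runs 100 null cohorts and 100 spiked
cohorts (three-interval dose-0.5 deletions, ~8% cohort CV) of 20 samples
× 50 intervals each — sizes chosen so the Monte-Carlo error on a
99/100 recovery assertion is negligible while the suite stays fast.

# Conservation logos

`logoMatrix()` converts pre-aligned fixed-width windows (default width
5, variant at column 3) from multiple species into per-position letter
frequencies and information content
$IC = \log_2 |\mathcal{A}| - H$ (Shannon entropy, bits; alphabet size 20
or 4), with no small-sample correction. Gaps are excluded from frequency
denominators; all-gap columns get IC 0. The conservation *class* of the
variant column is module policy, not a logo property: highly conserved
iff the modal residue reaches frequency ≥ 0.9 over all species,
conserved-in-vertebrates iff it reaches 0.9 within a caller-designated
subset only. No numeric cutoff is published for the verbal conservation
statements this mirrors; 0.9 is the package default and both cutoff and
subset are arguments.

# Cohort summaries

`summarizeCohort()` reports n, mean and sample (n−1) standard deviation
per numeric column with column-wise missing-data exclusion, and
counts/percentages over non-missing values per categorical column. The
"±" in the source tables is undefined; the sample SD is assumed.
Blood-pressure cells holding `sys/dia/mean` triplets are split; single
values are treated as mean-only. The packaged clinical fixture
transcribes a published table whose print concatenation is ambiguous for
a few rows (PVR, survival time, cardiac index, functional class); the
parses adopted are the ones consistent with that table's own printed
summary statistics, and PVR — whose printed mean no unambiguous parse
reproduces — is summarized but never asserted.

# Synthetic-data generators

Each generator returns data plus machine-readable truth and is exactly
reproducible under a seed:

* `simPredictorTable()` draws numeric scores uniformly strictly inside
  the requested category's band, so discretization must recover the
  planted category in 100% of cells under either boundary policy.
* `simTranscript()` plants a codon-aligned internal exon of requested
  length; truth (frame, protein length, residues lost) comes from a
  naive re-translation oracle at generation time, independent of the
  consequence engine under test.
* `simDepthCohort()` models depth as noise(mean × log-normal interval
  capture profile (5% CV default) × uniform per-sample library scale
  (±10%) × spiked dose), with Poisson noise by default and a
  negative-binomial option because real capture panels are
  over-dispersed.
* `simAlignmentWindow()` emits each position's modal letter with the
  requested probability per species.

What these emulate — counting noise, capture efficiency, library size,
clean single-event CNVs, independent per-species residues — is the
minimum needed to give every stage a ground truth. What they do not
emulate: GC-dependent coverage bias, inter-target correlation, mapping
artifacts, phylogenetic correlation between species, real exon length
distributions. Passing tests therefore certify the *computations*
(normalization algebra, thresholds, translation arithmetic, information
content), not performance on real capture data, where over-dispersion
and batch structure would raise the effective false-call floor.

# Numerical and degenerate-input choices

* All scores and thresholds compare with closed/half-open conventions
  stated at each function; no epsilon fudging is applied to user data.
* Score grid membership is validated (`score * 2` integral) before band
  mapping; off-grid scores are rejected.
* A variant row with all seven predictors missing is admissible only
  when its variant class (frameshift, confirmed skip) carries evidence
  by itself; it is reported with score `NA`.
* Division by zero in dose normalization (non-positive sample or
  interval medians) is an error, not an NA cascade; zero-variance
  Z-scores fall back to the dose criterion with a warning.
* Merged CNV calls report mean dose and z over their span;
  `mergeCnvCalls()` is idempotent on caller output.
* Sequence work uses codon table 1 only; selenocysteine recoding and
  non-standard initiation are unsupported.

# Limitations

The evidence combiner covers the published rule table but not
laboratory-specific rule modifications (e.g. PVS1 strength
down-grading). Genomic-coordinate liftover, splice-site strength
prediction and read-level simulation are out of scope. The ABCC8-like
transcript certifies arithmetic, not the real sequence; users with
access to the real accession can load it via `readTranscriptModel()`
(cDNA FASTA plus exon/CDS JSON sidecar) and run the same analyses
unchanged.
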