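# variantTriage

Rare-variant triage for targeted gene panels: in-silico predictor
aggregation mapped to ACMG evidence, splice-consequence simulation,
depth-ratio CNV calling, conservation logos and cohort summaries — the
desk-scale half of the interpretation workflow used when curating rare
variants (e.g. in *ABCC8*/SUR1) found by panel sequencing of pulmonary
arterial hypertension (PAH) cohorts. Every stage runs offline on plain
text inputs, and seeded generators provide ground-truthed synthetic data
for all of it.

## The core computations

**7-point predictor score.** Seven tool outputs (Annovar impact, CADD,
SIFT, PolyPhen-2, MutationAssessor, FATHMM, VEST) are discretized to
damaging (1), possibly damaging (0.5) or benign/missing (0) by the
published per-tool score intervals, and summed:

    S = Σᵢ sᵢ,  sᵢ ∈ {0, 0.5, 1},  S ∈ [0, 7]  on a 0.5 grid.

The score maps to ACMG computational evidence with half-open bands —
[0, 2) → BP4, [2, 4) → none (VUS level), [4, 7] → PP3 — while frameshift
and confirmed exon-skipping variants receive PVS1 regardless of score.
`combineEvidence()` then applies the published ACMG combining rules
(encoded declaratively in `acmgRules()`) to the computational code plus
caller-supplied codes, yielding the five-tier class.

**Splice/indel consequences.** A `TranscriptModel` (cDNA + exon map +
CDS) supports `skipExon()` and `applyIndel()`: re-translation from the
CDS start, frame status (frameshift ⇔ net change mod 3 ≠ 0), novel-stop
location by former exon, truncated protein length, and HGVS r./p.
output including `p.(Xaa#YaafsTer#)` nomenclature, whose implied length
`pos + offset − 2` is exposed as `fsLength()`.

**Depth-ratio CNV calls.** Per-target depths are normalized by two-stage
median-of-ratios (within sample, then across the cohort) to dose ratios
with cohort median 1; deletions need dose ≤ 0.60 and interval Z ≤ −2.0,
duplications dose ≥ 1.20; adjacent hits merge into single calls.

**Conservation logos.** Fixed-width multi-species windows centred on a
variant become per-position frequencies and information content
IC = log₂|alphabet| − H (bits), with a modal-frequency conservation
class for the variant column.

## Worked example

Classify the packaged 12-variant predictor table (11 *ABCC8* variants
plus one *SMAD1* frameshift):

```r
library(variantTriage)
tab <- readVariantTable(system.file("extdata", "abcc8_predictor_calls.tsv",
                                    package = "variantTriage"))
res <- classifyVariants(tab)
res[, c("variant_id", "score", "computational_code", "final_class")]
```

```
               variant_id score computational_code       final_class
1                c.211C>T   5.5                PP3               VUS
2                c.298G>A   2.5               none               VUS
3               c.1429G>A   6.0                PP3               VUS
...
9          c.3288_3289del   1.0               PVS1 likely_pathogenic
10              c.3394G>A   6.0               PVS1        pathogenic
11              c.3976G>A   4.0                PP3               VUS
12 SMAD1:c.27delinsGTAAAG    NA               PVS1 likely_pathogenic
```

The score column is the 7-point aggregate (5.5 means e.g. five damaging
calls plus one "probably damaging"); `PVS1` rows are null variants
(frameshift or confirmed exon skip); final classes combine the
computational code with the `other_codes` column, so missense rows
without curator-supplied codes stay VUS even at PP3 — supporting
evidence alone never classifies.

Simulate an exon-27-like skip on the synthetic ABCC8-like transcript
(same coding geometry as the real SUR1 transcript; synthetic filler
sequence):

```r
tx <- syntheticAbcc8Transcript()
skipExon(tx, 27)
```

```
ProteinConsequence
 frame:   frameshift
 hgvs:    r.3330_3399del / p.(Ser1112ArgfsTer8)
 protein: 1118 aa (463 aa lost)
  novel stop in former exon 28
```

The 70-nt exon frameshifts, a stop appears in former exon 28 and the
protein truncates to 1118 residues; the in-frame 138-nt exon 22 skip
(`skipExon(tx, 22)`) instead loses exactly 46 residues. Cohort-level:

```r
s <- summarizeCohort(readClinicalTable(system.file("extdata",
       "abcc8_clinical_table.tsv", package = "variantTriage")))
subset(s$numeric, column %in% c("age_at_diagnosis", "t6mw_m", "pap_mean"))
#             column  n       mean        sd
#   age_at_diagnosis 10  34.000000  10.06645
#             t6mw_m 11 400.272727 124.86080
#           pap_mean 11  58.818182  21.83492
carrierFraction(11, 624)
# [1] 1.76
```

## Command line

A thin CLI wraps the exported functions:

```sh
triage=$(Rscript -e 'cat(system.file("exec/triage", package="variantTriage"))')
Rscript $triage classify --variants table.tsv --out report/
Rscript $triage cnv-call --bed targets.bed --depths depths.tsv
Rscript $triage logo --fasta windows.fa --alphabet aa --out logo.tsv
Rscript $triage simulate --stage depths --seed 7 --out sim/
```

See `vignettes/variant-triage-methods.Rmd` for the full model
description, parameter defaults and design rationale.
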