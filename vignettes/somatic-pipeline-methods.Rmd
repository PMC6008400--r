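---
title: "Methods: somatic filtering and matched-pair burden analysis for BBD panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtering and matched-pair burden analysis for BBD panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and design

`bbdsomatic` re-implements, as tested reusable code, the post-calling half
of a tumor/normal targeted-sequencing study of benign breast disease (BBD):
given per-caller somatic variant calls and read counts from an 83-gene
breast-cancer panel applied to matched case/control BBD biopsies, it decides
which calls are genuine somatic mutations and asks whether mutation burden
differs between women who later progressed to invasive breast cancer (IBC)
and matched controls who did not.

The upstream callers themselves (samtools/Somatic Sniper, VarScan, Strelka,
MuTect, GATK somatic-indel) are out of scope: the pipeline consumes their
VCF outputs, real or simulated, with caller-internal filters assumed already
applied. Because the patient sequencing data underlying the original study
were never deposited, a synthetic-cohort simulator with complete ground
truth is a first-class component: every downstream stage is validated
against the simulator's truth tables.

# The pipeline

## Ensemble merge

Per-sample call sets are combined by fixed set algebra over normalized
variant keys:

* SNVs: (samtools ∩ SomaticSniper) ∪ VarScan ∪ Strelka ∪ MuTect
* indels: GATK ∪ VarScan ∪ Strelka

Keys are left-aligned and made parsimonious before the set operations, since
callers encode the same indel in different representations; without this,
unions silently double-count. Read counts for merged calls come from a
single read-count sidecar (bam-readcount style), not from the caller VCFs,
eliminating caller-specific count dialects. The `callers` field of each
output records exactly the callers that reported it.

## Filter cascade

Applied in order, each a pure predicate over one call:

1. **Coverage**: ≥ 20 reads in *both* tumor and normal (inclusive). The
   normal-side requirement is a design choice: somatic status is
   undecidable without adequate normal depth.
2. **Panel of normals**: drop calls whose key appears in a blacklist of
   variants recurrently seen across a large normal cohort.
3. **Population frequency**: drop calls whose population allele frequency
   *exceeds* 0.1% (strict; a frequency of exactly 0.001 is kept).
4. **Somatic classifier**: a three-model binomial log-likelihood
   comparison, natural-log units, retained when labelled somatic with a
   margin ≥ 5.

The classifier evaluates, summing tumor and normal log-likelihoods:

* *reference noise*: alt ∼ Binomial(depth, e) in both samples;
* *germline het*: alt ∼ Binomial(depth, 0.5) in both samples;
* *somatic*: tumor alt at its maximum-likelihood VAF, normal alt at e.

The somatic margin is LL(somatic) − max(LL(noise), LL(germline)). Two
numerical choices matter. First, the somatic VAF estimate is floored at the
error rate `e`: the raw MLE would let a site with *zero* alt reads score as
"somatic" with a positive margin, because a Binomial(depth, 0) model assigns
probability 1 to observing nothing. Second, ties are broken toward the least
remarkable explanation (noise, then germline, then somatic), so a
zero-evidence site is labelled reference noise with margin 0. The margin is
monotone in tumor alt reads as long as reference noise is the best competing
model; as tumor VAF approaches 0.5 the germline model takes over and the
margin correctly declines. The published pipeline names its classifier only
by a repository link; this three-model formulation, with threshold τ = 5 as
printed and e = 0.001 by default, is this package's declared instantiation.

## FFPE deamination screen

Formalin fixation deaminates cytosine, creating spurious low-frequency C→T
calls concentrated at CpG dinucleotides. A *putative artifact* is an SNV in
CG>TG context with VAF strictly below 10%. A sample with at least 3 putative
artifacts is *flagged*, and exactly its putative artifacts are removed;
below the threshold, nothing is removed. The screen also recognizes the
reverse-strand image of the motif (G→A preceded by C), since deamination is
strand-symmetric in sequencing output; the original study states only the
forward motif, so this is exposed as `both_strands` (default `TRUE`).

## Effect annotation

One CDS model per gene. Coding SNVs are translated through the standard
nuclear codon table on the coding strand (synonymous → silent, stop-gain →
nonsense, otherwise missense). In-CDS indels are frameshift unless their
length is a multiple of 3. Variants within 2 bp outside a CDS exon boundary
are splice (2 bp is the standard convention; the study does not state its
window). Everything else inside the panel is noncoding. Noncoding and
silent calls count toward *overall* burden but not *non-silent* burden —
consistent with the study's overall totals exceeding its non-silent totals.
Indels are annotated over their full repeat-equivalence span: a left-aligned
deletion whose repeat run extends into an exon is classified by that exonic
contact, not by its leftmost placement.

## Statistics

* **Burden tests**: per-pair mutation counts (overall, non-silent, and a
  founding-clone stratum at VAF strictly \> 25%), compared by paired t-test
  on within-pair differences. Degenerate inputs follow explicit
  conventions: all-zero differences give t = 0, p = 1; a constant non-zero
  difference gives p = 0 with a warning.
* **Per-gene tests**: one paired t-test per gene on per-subject counts
  (counts, not presence/absence, to match the overall analysis), with
  Benjamini–Hochberg adjustment across all genes with at least one mutated
  subject; untouched genes are reported untested and excluded from the
  family. With 83 tests, a raw p of 0.0302 adjusts to 1.
* **Exclusivity**: genes mutated in ≥ 1 case and 0 controls (and the
  mirror).
* **Hotspot contrast**: 2×2 (case/control × at-residue/elsewhere) Fisher
  exact test, e.g. codon 1047 of PIK3CA versus other PIK3CA mutations.
* **Gene-set enrichment**: the statistic is the mean within-pair
  difference of counts summed over a set's genes; the null swaps
  case/control labels independently within each pair. When 2^n_pairs fits
  inside the permutation budget the null is enumerated exhaustively and
  p = #{|null| ≥ |obs|}/2^n (the identity assignment keeps p positive);
  otherwise Monte Carlo sign draws are applied to the sorted absolute
  differences (distributionally identical, and it makes the estimate
  invariant to pair ordering) with the add-one estimator. The original
  study used external pathway resources for this step; the permutation
  scheme here is a transparent stand-in, not a reconstruction.

## Progression overlap

For subjects with both a BBD biopsy and a later ipsilateral IBC sample,
every variant in the union of the two call sets is categorized from
force-called read counts: `candidate_shared` needs alt reads \> 0 in both
samples; `definitively_shared` additionally needs ≥ 3 alt reads in both —
the direct negation of "two or fewer supporting reads in one of the
samples". Categories partition the union, and definitive ⊂ candidate.

# The simulator

`generate_cohort()` emulates the study's inputs end to end. Defaults are
the study's own conditions where the study states them: 218 matched pairs
(436 samples), 83 panel genes, mean variant coverage 90.4× (negative
binomial, size 8 — FFPE depth is overdispersed), error rate 0.001, an
FFPE-affected sample fraction of 18/436 with 84/18 artifacts per affected
sample, and a null case effect (the study found no burden difference). The
somatic rate of 2.3 mutations per sample reproduces the study's ≈ 500
mutations per arm. Where the study is silent, values were chosen once on
realism grounds and not revisited: somatic VAFs Beta(2, 6); artifact VAFs
Beta(2, 40) rejected to \< 0.10; 3 heterozygous germline variants per
sample drawn from a 200-site population pool (80% of sites above the 0.1%
frequency cut); a 30-site panel-of-normals pool at 0.3 hits per sample; 10%
indels; flat per-caller sensitivities of 0.90–0.95 (a VAF-logistic option
exists but is off by default); and 0.5 spurious calls per caller per
sample whose sidecar alt fraction is error-level (0.002) — a spurious call
has no real variant under it, which is also why its truth record carries
origin `sequencing_error` and VAF 0. Per-caller sensitivities and
false-call rates are unconstrained by the study and are synthetic
assumptions.

Determinism: a single seed drives named substreams (one per sample, one per
shared resource), so outputs are byte-identical across runs and adding
samples never perturbs earlier ones.

What the simulator does **not** model: read-level data (no FASTQ/BAM),
realistic human genome background (each gene gets an independent random
contig), caller-internal behaviour beyond sensitivity/false calls, copy
number, and tumor heterogeneity beyond a single VAF per variant. Passing
tests therefore demonstrate that the *decision logic* — set algebra,
filters, screen, annotation, statistics — is correct on data whose
generating process is known, not that the pipeline's operating
characteristics transfer to real FFPE libraries.

# Validation strategy and problem sizes

Every operation with a closed-form or enumerable answer is checked against
an independent oracle: ensemble merge against brute-force set evaluation,
the BH adjustment against the sorted step-up recursion, classifier margins
against direct `lgamma`-based log-pmf summation, Fisher p-values against
hypergeometric enumeration over all small tables, and the 5-pair
permutation test against exhaustive 2^5 enumeration. Calibration and
recovery are checked at sizes chosen to make the answers statistically
stable while keeping the default test run fast: 2,000 replicate null
cohorts of 50 pairs for the type-I error of the paired burden test
(expected rejection 5% ± 1.5% at α = 0.05), and a 100-pair, 20-gene
"easy" cohort at depth 200× with somatic VAFs centred on 0.3 for truth
recovery, where the cascade achieves precision ≥ 0.95 and recall ≥ 0.90
and the FFPE screen removes every screen-eligible injected artifact in
flagged samples. `scripts/acceptance.R` recomputes all of these from
scratch, plus a full default-condition cohort (218 pairs, 83 genes).

# Known limitations

* The classifier formulation and the permutation enrichment statistic are
  declared interpretations of under-specified methods; both are documented
  above and parameterized so alternatives can be swapped in.
* FFPE artifacts at observed VAF ≥ 10% (possible when the true artifact
  fraction is near the cutoff) are invisible to the screen by definition.
* True somatic mutations that are low-VAF C→T at CpG are indistinguishable
  from artifacts by design; in flagged samples they are removed.
* One transcript per gene; no HGVS output; splice classification is
  interval arithmetic, not a splicing model.
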