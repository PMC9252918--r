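---
title: "Models and methods behind mmclonetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmclonetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmclonetrack)
```

# Scope

`mmclonetrack` analyzes paired early/late tumor samples from multiple
myeloma patients along two axes — what changed in the genome (mutation
catalogs, mutational signatures, subclonal structure) and what changed in
the transcriptome (pathway scores, proliferation, antigen expression) —
and classifies each patient's trajectory. Upstream variant calling, copy
number calling, differential expression and cohort-level GSEA are
deliberately out of scope: the package starts from called SNVs, segments,
purity estimates and TPM matrices, the same contracts those external
tools emit.

# Mutation catalogs and strand assignment

Single-base substitutions are classified into the standard 96 channels:
six pyrimidine-normalized substitution classes (C>A, C>G, C>T, T>A, T>C,
T>G) crossed with the 16 flanking-base combinations. When the mutated
base is a purine, the substitution and its trinucleotide context are
reverse-complemented, which makes channel assignment an involution — a
property the tests verify exhaustively over all 192 raw cases against a
hand-written reverse-complement oracle.

Coordinate dialects are fixed at the boundaries: mutation tables and VCF
positions are 1-based, transcript intervals are BED-style 0-based
half-open, and the conversion is property-tested at interval edges.
Records whose context contains N, or that sit at a contig edge, are
counted as unclassifiable rather than erroring; catalog totals plus
unclassifiable counts always equal the input size.

For transcriptional strand analysis, a mutation inside an annotated
transcript is labeled by where its pyrimidine sits: on the coding (sense)
strand it is *untranscribed*, on the template strand *transcribed*.
Mutations outside transcripts are excluded, as are mutations covered by
transcripts on both strands — the annotation is ambiguous there and
exclusion biases neither stratum.

# Signature refitting

Exposures of known signatures are estimated by maximum likelihood: the
catalog is modeled as multinomial counts over channels with mixture
probabilities $p_c = \sum_s w_s P_{sc}$, and EM is run to convergence
(absolute log-likelihood change below $10^{-8}$, at most $10^4$
iterations, uniform start). EM guarantees a monotone log-likelihood, and
the tests assert exactly that guarantee (plus an improvement in
reconstruction cosine over the uniform start) rather than per-iteration
cosine monotonicity, which EM does not in fact guarantee.

A parsimony pass then removes, by backward elimination, signatures whose
removal costs less than 0.01 in reconstruction cosine similarity, and
refits. The melphalan signature is never pruned: its presence is judged
by its bootstrap confidence interval, not by parsimony. Converged weights
below $10^{-4}$ are truncated to exact zeros so that absent signatures
report 0 rather than EM dust.

Confidence intervals are percentile bootstrap: mutations are resampled
with replacement (a multinomial draw of the same total from the observed
channel frequencies), each replicate is refit, and the interval is read
off the replicate quantiles. A signature is *present* when the lower
bound of its 95% interval is strictly positive. Because interior EM
weights never reach exactly zero, each replicate additionally gets a
signature-wise support check: the replicate is refit without the
signature, and if keeping it improves the log-likelihood by less than
1.92 (the 95% point of the half-$\chi^2_1$ boundary distribution) its
replicate weight is recorded as zero. This is what makes the lower CI
bound a meaningful presence test; without it every bound would be
positive by construction. On simulated catalogs of 500 mutations the
resulting 95% intervals cover a true melphalan weight of 0.15 in
roughly 90–99% of replicates, and the false-presence rate with the
signature truly absent stays below 10%.

Group-level analysis pools catalogs by summation before fitting. A
signature carried by a minority of members is diluted in the pool and
may not be called at group level even when individually detectable —
and conversely, weak per-sample contributions can become detectable in
a pooled exposure group. The packaged 5-signature toy reference exists
for tests and simulation; real analyses should supply a published
reference matrix as a TSV.

## Strand-bias test

The melphalan signature shows transcriptional strand asymmetry of C>T
mutations in the contexts CCA, GCA, GCC, GCG, GCT. Conditional on the
total count in those contexts, the transcribed count under no bias is
Binomial(n, 1/2), so the package uses the two-sided exact binomial test
(minimum-likelihood summation). This conditional binomial is the exact
equivalent of comparing two Poisson mutation rates, which is how
signature tools usually phrase the test. The type-I error of the exact
test at $\alpha = 0.05$, measured over 2000 symmetric simulations, sits
in the conservative 3–7% band expected of a discrete exact test.

# Cancer cell fractions and clonal evolution

CCFs use the standard transform. With purity $\rho$, local tumor copy
number $CN_t$, normal copy number 2 and mutation multiplicity $m$:

$$VAF = \frac{CCF \cdot \rho \cdot m}{\rho \, CN_t + (1 - \rho) \cdot 2}$$

Multiplicity is the rounded value of $VAF/\rho \cdot (\rho CN_t +
(1-\rho)2)$ clamped to $[1, \max(CN_t, 1)]$. CCF estimates above 1.5 are
capped and flagged — uncapped outliers (usually multiplicity or copy
number errors) destabilize clustering. Positions without a covering
segment fall back to $CN_t = 2$ with a warning flag.

Subclonal structure of a sample pair is approximated with finite 2-D
Gaussian mixtures on (early, late) CCF pairs rather than a
Dirichlet-process MCMC: shared spherical variance, kmeans
initialization, 10 restarts per component count, $k \le 6$, selection by
BIC. The downstream classifier consumes only cluster means and weights,
for which the finite-mixture approximation is sufficient and nearly
deterministic under a fixed seed. Variants private to one timepoint
enter with CCF 0 at the other — appearing and vanishing clusters are
precisely the signal for the linear and differential calls. Points at
exactly CCF 0 have no noise in that coordinate, which can lead BIC to
over-split such clusters; this is harmless for classification, which
thresholds cluster mean movements, not cluster counts. A `shared_only`
style analysis can be had by intersecting the variant sets before
calling `cluster_pair()`.

Evolution patterns are assigned by thresholded rules with precedence
differential > linear > stable:

* **differential** — one cluster falls by at least $\tau_{shift}$ while
  another rises by at least $\tau_{shift}$, or a cluster vanishes
  (early $\ge \tau_{new}$, late $< \tau_{minor}$) while a distinct one
  emerges (early $< \tau_{minor}$, late $\ge \tau_{new}$);
* **linear** — a new cluster emerges while an ancestral cluster is
  retained at both timepoints;
* **stable** — all clusters move by less than $\tau_{minor}$; it is
  also the fallback for minor drift matching no rule, recorded as such
  in the evidence.

The literature defines these patterns qualitatively, not with numeric
cutoffs, so the defaults $\tau_{shift} = 0.3$, $\tau_{new} = 0.25$,
$\tau_{minor} = 0.1$ are explicit stand-ins, configuration-exposed and
recorded in the output metadata. The choice is robust in simulation:
end-to-end recovery of planted scenarios (from simulated reads through
CCF, clustering and classification) exceeds 90% per class, and the
planted layouts remain correctly classified under moderate threshold
perturbations. A RAS shift is called when one KRAS/NRAS hotspot
mutation falls by $\tau_{shift}$ (or disappears from an appreciable
CCF) while a *different* RAS mutation rises by $\tau_{new}$ — the
replacement of one RAS-mutant clone by another.

# Transcriptomic scoring

All scores operate on TPM with the transform log2(TPM + 1) followed by
per-gene z-scoring across samples; zero-variance genes are set to 0 and
flagged. Scoring is therefore relative to the analyzed cohort — adding
or removing samples changes every score, which is intended: the
questions are about within-patient change against the cohort
distribution.

**ssGSEA.** Genes are ranked per sample in descending z-score (stable
tie-break on gene id); set members accumulate weight
$|z|^{\mathrm{exponent}}$, non-members accumulate the uniform ECDF, and
the score is the summed difference of the two running distributions.
The exponent defaults to 0.25 (the published algorithm's convention);
exponent 0 gives a purely rank-based score, invariant to monotone
transforms — both properties are tested against an independent
brute-force implementation. The raw running sum is reported by default
because z-scoring already makes scores comparable across samples;
dividing by gene count is available for cross-set comparisons.

**Proliferation index.** The sum of z-scored values over an 11-gene
proliferation panel. Sum (not mean) is the default aggregation: the
published change thresholds (increase > 0.4, decrease < −0.4, high
increase > 1) and reported index magnitudes are only sensible on the
sum scale; the aggregation mode is nonetheless configurable and flagged
in output. At least 8 of the 11 genes must be present.

**CGA counting.** A cancer germline antigen counts as expressed when
TPM is *strictly* greater than 2, and a patient's CGA expression is
*increased* when the late count exceeds the early count by at least 3.
The published rule defines only the increase; a symmetric decrease
class at −3 was added so the classifier partitions the integers, which
the tests require.

**Panels.** The NFkB index, HLA-I/II scores, ABC transporters and
exportins are gene-panel means of z-scored expression. The shipped
panels are *reconstructed* from the sources the field cites — the exact
published lists are external — and live as an editable GMT data file,
not as code. Fold changes use a pseudocount of 1 and the reporting
thresholds FC > 1.5 and FC > 3; Spearman correlation summaries report
raw p-values alongside Benjamini–Hochberg adjusted ones, with the
conventional highlight at $\rho \ge 0.45$.

# The synthetic cohort

The simulator defines the study conditions for every test:

* **Catalogs** are multinomial draws from known signature mixtures over
  the toy reference. Melphalan-attributed C>T mutations in the five
  characteristic contexts get transcribed-strand labels at ratio 2:1
  by default (1:1 switches the bias off); all other mutations are
  labeled 50/50. Half of all records are emitted in purine-strand
  representation so that pyrimidine normalization is always exercised.
* **Paired variant sets** plant cluster layouts per scenario (stable:
  clonal + subclone unchanged; linear: emerging subclone at CCF
  0→0.45 on a retained backbone; differential: subclones swapping
  dominance 0.75→0.05 and 0→0.8 under a clonal backbone), back-compute
  VAFs through the CCF transform on diploid segments at purity 0.95
  (the cohort median purity scale), and add binomial read noise at
  Poisson depth 100 — exome-like. A variant is detected at ≥ 2
  alternate reads. Infinite depth gives the noiseless limit used by the
  round-trip tests. Newly acquired (late-only) variants draw their
  channels from a separate signature mixture, which is how the
  melphalan signature enters only post-treatment mutations of exposed
  patients.
* **Expression** uses a paired model on the log2(TPM+1) scale:
  per-gene baselines N(2, 1), a pair-shared per-patient gene effect of
  sd 0.5 (between-patient biological variation), and within-pair noise
  of sd 0.02 (sampling/technical variation). The pairing matters: with
  independent early/late draws, z-scored proliferation-index deltas
  under a zero effect would have sd near $\sqrt{22}$ and the ±0.4
  no-change band would be meaningless; sharing the patient effect makes
  an unperturbed patient transcriptionally stable, which is what the
  paired study design assumes. Panel shifts in late samples are given
  in log2 units (default 0.5, one between-patient sd), and CGA genes
  are modeled as off early and switched on (TPM 8) in four genes for
  half the patients' late samples.
* **Cohorts** default to 12 patients split 7/3/2
  differential/linear/stable — the differential-heavy shape reported
  for relapsed myeloma — with treatment groups HDM/LDM/noM assigned
  round-robin and a melphalan-signature weight of 0.35 among the new
  mutations of HDM patients. Early mutation counts are log-normal
  around a median of 67.

What the simulator does *not* emulate — realistic genome coordinates,
copy-number heterogeneity, germline contamination, signature profiles
with realistic inter-signature correlation, RNA-level noise models —
bounds what passing tests show: they demonstrate that each method
recovers the structure it models under its own assumptions at realistic
sample sizes, not that those assumptions hold in any particular real
cohort.

# Pipeline and reproducibility

`run_pipeline()` wires the stages over a cohort directory: the purity
filter (inclusive ≥ 0.80) runs first; signatures are fit per sample
with the melphalan presence call taken from the late (post-treatment)
sample, since therapy-induced mutations are confined to newly acquired
clones; pairing uses the first retained timepoint as "early" and the
latest available as "late". All randomness (bootstraps, restarts) flows
from the single configured seed, and the manifest intentionally
excludes timestamps so that a rerun with the same configuration is
byte-identical — which the tests check literally.

Problem sizes used by the test-suite and acceptance runs — 100 catalogs
of n = 1000 for recovery, 200 replicates with 500 bootstraps for
coverage, 30 simulations per scenario for classification, a 12-patient
cohort with 200 bootstraps for the end-to-end run — were chosen as the
smallest sizes at which the binomial/bootstrap tolerances above are
meaningful, and are stated here as the package's own simulation design.

# Known limitations

* Percentile bootstrap intervals on simplex-constrained weights can be
  slightly conservative near the boundary; the presence rule inherits
  this (it errs toward "absent" for very small contributions, matching
  the dilution behavior seen in pooled groups).
* BIC with a shared spherical variance over-splits clusters containing
  exact zeros (absent variants); classification is insensitive to
  this, but reported cluster counts should not be read as clone counts.
* The evolution thresholds are stand-ins for qualitative definitions;
  borderline patients near the thresholds are sensitive to them, and
  the rule firings are therefore reported as evidence rather than only
  the label.
* Gene panels are reconstructed, case-sensitive symbol lists; users
  with authoritative lists should replace the GMT file.
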