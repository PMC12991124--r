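---
title: "Quantifying state-dependent cysteine reactivity: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying state-dependent cysteine reactivity: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysreact)
library(dplyr)
```

## The measurement and its model

Activity-based protein profiling (ABPP) with a broad-spectrum
iodoacetamide probe converts the chemical environment of each proteomic
cysteine into a quantifiable signal: the probe labels reactive, accessible
thiols, labeled peptides are enriched and quantified by isobaric (TMT)
reporter ions, and a change in a site's signal between cell states — beyond
what protein abundance explains — indicates a change in that cysteine's
reactivity or accessibility. Such changes report on post-translational
regulation invisible to expression measurements: oxidation, ligand or
nucleotide occupancy, conformational change, or altered interactions.

`cysreact` analyzes this design for multi-state comparisons (the defaults
name the states of a chronic T cell receptor stimulation time course:
activated `D2`, acute `D4A`/`D8A`, chronic `D4C`/`D8C`), with one
multiplexed plex per donor and the reference state present in every plex.
All quantities are formed within a plex, so between-plex (between-donor)
scale differences never enter a ratio.

The reporter-intensity model used throughout — by the simulator by
construction and by the estimators by assumption — is multiplicative:

$$
\log_2 I_{p,c,d} \;=\; \beta_P + \iota_p + a_{P,c} +
  \underbrace{r_{s,c}}_{\text{enriched only}} + u_{P,c,d} + \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, \sigma^2),
$$

with protein base abundance $\beta_P$, peptide ionization offset
$\iota_p$, condition-level abundance offset $a_{P,c}$, site-level
reactivity offset $r_{s,c}$ (present only in the probe-enriched
experiment), donor-by-condition biological offset $u_{P,c,d}$, and
log-normal measurement error. The raw site ratio estimates $a + r$; the
matched unenriched experiment estimates $a$; their difference isolates
$r$. That subtraction is the abundance deconvolution at the heart of the
calling rule.

## From channels to calls

1. **Channel normalization** rescales each channel of a plex by one
   factor so channel totals agree, emulating equal protein content per
   sample. Totals are computed over complete-case records only, so
   intensity-dependent missingness cannot bias the column sums; the
   factors are then applied to every record. The operation is exactly
   idempotent.
2. **Ratios.** Per record, the reference value is the geometric mean of
   its observed reference-state channels (the arithmetic mean in log2
   space — the natural choice under the multiplicative error model; the
   upstream report does not specify a convention). Each channel yields a
   log2 ratio against it; the per-condition value is the median over that
   condition's channels. Records with no observed reference channel are
   dropped and counted, never imputed.
3. **Rollup.** Peptides map to protein residues by first exact occurrence
   of the peptide in the database sequence; sites are named
   `ACCESSION_C<residue>` (1-based). Site and protein values per
   (condition, donor) are medians over contributing peptides. Peptides
   carrying more than one modified cysteine are kept under a composite
   identifier but excluded from single-site calling. Donor-level values
   are kept separate through rollup; the cross-donor median is taken only
   at calling time, so a single discordant donor among five cannot move
   an aggregate.
4. **Calling.** A site in a comparison condition is a `reactivity_change`
   when both the raw cross-donor median log2 fold change and the
   abundance-corrected fold change (raw minus baseline) reach the
   2-fold gate ($|\log_2 \mathrm{FC}| \ge 1$ by default). The baseline is
   the protein's unenriched log2 fold change when the protein was
   quantified there, else the leave-one-out median of the protein's other
   quantified cysteine sites (at least two others required, so a
   single-cysteine protein can never self-normalize). A site whose raw
   change is explained by the baseline is `expression_coupled`. Evidence
   tiers mirror the profiling rule: `multi_peptide` for proteins with at
   least two distinct quantified cysteine peptides, else
   `single_peptide_with_proteome` when the unenriched baseline exists,
   else `insufficient_evidence`.

Two readings of the rule were genuinely open. "Matching unenriched
proteomics data" is operationalized as *the protein is quantified in the
unenriched dataset for the same comparison* — the only reading that makes
the single-peptide tier computable. And the abundance-corrected gate
reuses the same 2-fold threshold as the raw gate (configurable), treating
the comparison to the proteome or to the median cysteine as a second
2-fold test. The calling rule is threshold-based, not p-value-based, so no
multiple-testing correction applies to it; per-donor observation counts
are reported for transparency rather than gated on.

## Ligand sensitivity and engagement

The ATP add-back design treats lysates with 5 mM ATP before probe
labeling, in paired control/treated channels inside one plex. Per state,
the within-plex paired delta $\Delta = \log_2(I_{\mathrm{ATP}} /
I_{\mathrm{ctrl}})$ (median over replicate pairs, then peptides, then
donors) measures nucleotide-proximal occlusion; $|\Delta| \ge 1$ flags a
sensitive site, with decreased labeling the expected direction for
occlusion (both directions are reported). The cross-state rule flags
differential sensitivity between states X and Y when
$|\Delta_X - \Delta_Y| \ge \log_2 2$ — algebraically identical to a
greater-than-2-fold ratio of the two fold changes. Pairing inside the
plex removes channel loading effects because the add-back is a
lysate-level perturbation of the same sample.

Covalent-inhibitor engagement uses the same competition logic: the
engagement fraction is $1 - I_{\mathrm{treated}}/I_{\mathrm{ctrl}}$,
clamped to $[0, 1]$, with a 2-fold loss calling a site engaged.

The 16-channel add-back replicate structure is not fixed by the design
being emulated; the default layout pairs control/+ATP arms with two
replicates in `D2` and three each in `D8A` and `D8C` (16 channels), with
two add-back donors. All of it is configurable through the layout.

## Enrichment, differential tables, PCA

Annotation-class enrichment among called proteins uses the one-sided
hypergeometric upper tail with Benjamini–Hochberg adjustment across
classes. The enrichment unit is the parent protein (deduplicated) and the
background is every protein bearing at least one quantified site —
multi-site proteins would otherwise pseudo-replicate.

Differential feature tables (proteins, metabolites, lipids) use the
unequal-variance Welch t test across donors, two-sided, with the volcano
flag requiring both p < 0.05 and a 1.5-fold change; the unadjusted p
drives the flag (matching the plotted gates) and a BH column is always
emitted alongside. The degenerate zero-variance case is defined (p = 1
when the means agree) rather than refused.

PCA is computed on complete-case features only (features quantified in
all samples), column-centered but not variance-scaled — inputs share a
common log2-ratio scale; scaling is available as an option. Components
come from the singular value decomposition, with each component's sign
fixed by making its largest-magnitude loading positive so that reports
are reproducible, and the five highest and lowest loadings per component
are tabulated.

## Metabolomics and isotope tracing

Cells in different states differ substantially in size, so steady-state
feature tables are normalized by sampled biovolume: intensity divided by
cell count × mean cell volume (fL). Whether the intended divisor was
total biovolume or volume alone is ambiguous; total biovolume is the
default and volume-only is an option. Complete-case filtering before
multivariate analysis mirrors the "quantified in all replicates" rule.

Isotopologue correction is carbon-only: column $j$ of the correction
matrix is the mass-shift distribution of a molecule with $j$
tracer-labeled carbons, the convolution of Binomial($j$, purity) tracer
atoms with Binomial($n-j$, $p_{\mathrm{nat}}$) natural heavy carbons
($p_{\mathrm{nat}} = 0.0107$ by default, tracer purity 1.0; both
configurable). Because only the molecule's own carbons shift its mass,
every column sums to exactly one and the matrix needs no truncation.
Observed patterns are inverted by nonnegative least squares — plain
inversion can hand noise a negative fraction — and renormalized to sum
one. H/N/O isotopes and resolution-dependent effects are out of scope.

## What the simulator emulates, and what it does not

The generator plants known effects in a synthetic proteome whose
geometry matches the assay: every target cysteine sits inside a
6–25-residue tryptic-style peptide bounded by K/R, with missed-cleavage
peptide forms providing multi-peptide evidence. Planted effects are
protein abundance shifts, site reactivity shifts, and ATP occlusions
(each: fraction, magnitude, random sign, one random non-reference
condition), with membership in a `nucleotide_binding` class linked to
occlusion by a configurable odds multiplier. Noise is log-normal;
missingness is intensity-dependent (logistic in log2 intensity, scaled to
the requested overall rate) with an MCAR fallback. Isobaric ratio
compression is *not* modeled by default — no compression correction is
part of the analyzed workflow — and no spectrum-level phenomena
(co-isolation, retention time) are simulated. Donor-to-donor biological
variability defaults to a Normal(0, 0.1) log2 offset per protein ×
condition × donor.

Two generator-level design choices matter for interpretation:

* **Expression and reactivity plants are disjoint at the protein
  level.** A 4-fold abundance increase and a 4-fold reactivity loss
  planted on the same site in the same condition cancel to a raw fold
  change of zero, which no threshold rule can recover; overlapping
  plants would make "recover every planted effect at zero noise"
  unsatisfiable by construction rather than by any property of the
  pipeline.
* **Totals-based normalization is deliberately biased by planted
  effects.** When a planted fraction of sites shifts 4-fold in one
  condition, the channel totals of that condition shift too, and
  equalizing totals displaces every ratio by that amount (about
  0.1–0.2 log2 under the default planting density). This is a real
  property of "equal protein content" normalization whenever the
  unchanged-majority assumption is strained, not an implementation
  artifact. The pipeline therefore exposes a `normalize` stage toggle;
  exactness checks run with the stage off (the generator plants no
  channel-loading imbalance, so the stage is scientifically a no-op
  there), while the recovery, confound, and ATP properties hold with it
  on, since the displacement is small against the 2-fold gate.

Passing recovery tests on these synthetic data show that the estimators
and rules are correct *under the stated model*; they do not certify
behavior under phenomena the generator omits (ratio compression,
co-isolation interference, peptide-level missingness structure tied to
sequence, shared peptides across proteins).

## Numerical conventions and degenerate inputs

Missing cells are never coerced to zero (a written `0` is an observed
value); no imputation exists anywhere, all filters are explicit and
counted. Ties in medians follow `stats::median`. Repeated peptide matches
within a protein resolve to the first exact occurrence. Cross-donor and
cross-peptide reducers are medians throughout. Channel normalization
refuses plexes with a zero-total channel or no complete-case record;
ratio formation refuses nothing but drops and counts reference-less
records; correction-matrix inversion refuses all-zero observations.
Seeded runs are byte-identical, verified by md5 digests in the run
manifest.

## Problem sizes

The validation suite exercises: a noise-free 500-protein, five-condition,
five-donor run (exact recovery to 1e-9); ten seeded 500-protein runs at
the default noise and missingness for recovery and confound rates; ten
seeded add-back runs (two donors) for the cross-state rule; exhaustive
hypergeometric enumeration for all universes up to N = 20; and a
10,000-protein class-independence check of the generator. These sizes
were chosen as the smallest at which the binomial uncertainty of the
estimated rates is well inside the asserted margins.

## A short worked run

```{r example, eval = FALSE}
cfg <- simulation_config(n_proteins = 200, seed = 7)
out <- run_pipeline(cfg, tempdir())
out$recovery
summarize_calls(out$calls)
```

## Known limitations

No protein inference beyond accession identity (shared peptides are out
of scope), no reporter isotopic-impurity correction, no stoichiometry
estimation, no attribution of a reactivity change to a specific
modification, no dose-response modeling for the single-concentration
add-back, and no flux modeling downstream of labeling fractions.
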