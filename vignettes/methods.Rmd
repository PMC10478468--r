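---
title: "Models and methods behind evohotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evohotspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the conventions it commits to, the synthetic study conditions it
tests itself under, and the places where a genuinely open design choice had
to be made. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and formats

All coordinates inside the package are **1-based, closed intervals** — the
native convention of GFF3, GenBank and VCF alike, and of the R/Bioconductor
containers (`IRanges`) the implementation builds on. A VCF position 100 is
position 100 internally; a GFF CDS `1..30` has `start = 1`, `end = 30`,
`length = 30`. Committing to one convention at the boundary removes the
off-by-one ambiguity that otherwise creeps in between formats; a variant
whose REF allele disagrees with the reference base at its stated position is
treated as an error (it almost always signals a coordinate-convention fault
upstream), never silently re-anchored.

Bacterial chromosomes are circular by default. A gene annotated across the
origin is unwrapped internally (its `end` exceeds the chromosome length),
and sequence access, promoter windows and codon arithmetic all honour the
wrap. Only single-chromosome references are accepted; plasmids are out of
scope.

The alternate-allele frequency field of a VCF is caller-dependent; the key
is configurable (`freq_key`, default `FREQ` with an `AF` fallback) and both
percent strings (`"53.2%"`) and proportions (`0.532`) are normalised to
[0, 1].

## Variant annotation

**Region assignment.** A position inside a CDS belongs to that CDS. A
position not in any CDS but within 200 bp upstream of a CDS start *on that
CDS's strand* is a promoter variant of that gene; the window size is a
parameter (`promoter_window`). No downstream (terminator) window is
considered. Ties are resolved deterministically: CDS membership always beats
a promoter window; a position inside two promoter windows goes to the gene
whose start is nearer, and at equal distance to the lexicographically lower
locus tag. Promoter variants are reported as their own effect class, never
folded into the nonsynonymous counts.

**Coding effects.** SNP effects are decided at the codon level with the
bacterial genetic code (translation table 11). Table 11 differs from the
standard code only in its set of initiation codons, so the codon→residue map
used here is the standard one and start-codon variants are translated
positionally like any other codon — there is no special start-loss logic.
Minus-strand genes are handled by complementing the alleles onto the coding
strand. A change is `synonymous` if the residue is unchanged, `nonsense` if
a stop is introduced, otherwise `nonsynonymous` with `protein_change` in
`RefAA-index-AltAA` notation (`D735G`). Small InDels are recorded as
`small_indel` without frameshift sub-typing — the motivating use case is an
alkylating mutagen whose spectrum is essentially InDel-free, so finer typing
has nothing to calibrate against. The test suite holds the codon arithmetic
to a fully independent oracle: mutate the genome, re-extract and retranslate
the whole CDS with Biostrings, and diff the two proteins; the two routes
must agree on every random SNP, and all calls must survive
reverse-complementing the entire genome.

**Filters.** The comparative analysis discards variants with read frequency
below 0.50 — the boundary itself is kept — and synonymous substitutions.
Both thresholds are arguments; the removed counts are attached to the result
so filtering is auditable. Filtering is idempotent.

**Spectrum.** The 12 directed substitutions collapse onto 6 strand-symmetric
classes; transitions are purine↔purine / pyrimidine↔pyrimidine. The
G:C>A:T share is the single most informative number for checking that a
mutagenized cohort looks like alkylation chemistry.

**Coverage anomalies.** Large deletions and duplications leave fold-change
footprints in read depth. The detector reports maximal runs of at least
`min_window` (default 500 bp) consecutive bases at ≤ `low_fold` (0.25) or
≥ `high_fold` (1.75) times the genome-median depth. These defaults are
deliberately blunt: the goal is flagging for inspection, not breakpoint
calling.

## Hotspot genes and enrichment

The count matrix records, per strain and gene, the retained mutations in the
default effect classes `nonsynonymous` + `nonsense`; a flag widens this to
all gene-assigned classes (promoter, InDel) since the hotspot idea itself
only requires "carries a mutation". Genes with zero counts stay in the
matrix — they carry information through the enrichment denominators.

A gene is a hotspot when mutated in at least `min_fraction` (default 10 %)
of the strains, threshold inclusive. Ranking is by number of mutated strains
(dense ranks), ties broken by total mutations and then locus tag, so output
order is reproducible to the byte.

Length enrichment compares each gene's observed count with
`N_total · L_g / Σ L`. The default background `Σ L` is the summed length of
the annotated genes, under which expected counts conserve the observed total
exactly; a `background = "genome"` switch divides by the chromosome length
instead (part of the total is then expected to fall outside genes). Both
definitions are plausible readings of "more often than expected for its
length", which is why the choice is explicit and switchable rather than
hidden.

The co-mutation fraction of genes *a, b* — of the strains mutated in *a*,
the share also mutated in *b* — is undefined (an error, not a zero) when no
strain is mutated in *a*.

Candidate-SNP ranking implements the two computable selection criteria:
lower *hotspot abundance* first (the number of other hotspot genes mutated
in the same strain — a sparse background makes causality more plausible),
then higher titer improvement, then the milder biomass reduction. A third
criterion, expert judgement about metabolic plausibility, cannot be computed
and is exposed only as a pass-through `user_flag`. Pathway attribution is
strictly file-driven (a locus-tag → pathway TSV); the core never performs
network lookups, so analyses are reproducible offline.

No significance testing (dN/dS, Poisson models) is attached to hotspot
calls: the definition is a threshold count by construction, and dressing it
in p-values would suggest an error model the procedure does not have.

## Screen decision rules

Stage 1 (single measurement per variant): pass when the titer exceeds the
upper bound of the **two-sided 90 % t-interval of the same-plate control
mean** and is at least 1 mM above that mean. Stage 2 (technical
triplicates): *improved* when the variant mean exceeds the control CI upper
bound, the relative titer gain is ≥ 10 % (exactly 10.0 % passes) and biomass
formation is reduced by at most 35 %.

Two readings were open here. "Exceeding the 90 % confidence interval" is
implemented as exceeding the upper bound of a two-sided t-based CI of the
control mean — neither the distribution nor the sidedness is forced by the
decision's verbal form, and the t-interval on the mean is the conservative,
standard choice; for stage 1, where variants are unreplicated, the interval
is likewise the control-mean CI rather than a prediction interval for single
measurements. Plate-to-plate variation (humidity and similar) is real and
simulated; decisions therefore only ever compare against same-plate
controls, and cross-plate comparisons are refused by construction.

Percent improvements are rounded half-away-from-zero for display only;
decisions always use unrounded values. Group comparisons use Student's
pooled-variance t-test by default with a Welch option; degenerate
zero-variance inputs are handled explicitly (equal means → p = 1; unequal →
p → 0 with a warning) instead of erroring mid-pipeline.

## The Monod batch model

States are biomass X (g CDW/L), glucose S (g/L) and product P (mM):

$$\frac{dX}{dt} = \mu(S)\,X,\qquad \mu(S)=\mu_{max}\frac{S}{K_S+S}$$
$$\frac{dP}{dt} = q_P(S)\,X,\qquad q_P(S)=q_{P,max}\frac{S}{K_S+S}$$
$$\frac{dS}{dt} = -\frac{\mu}{Y_{XS}}X \;-\; q_P\,X\,\frac{M_{glc}}{1000}$$

with µ_max [1/h], K_S [g/L], Y_XS [g/g] and q_P,max [mmol/(g h)]. The
product term in the substrate balance fixes the product-on-substrate yield
at the 1 mol glucose : 1 mol histidine stoichiometry (both C6), i.e.
Y_PS = M(His)/M(glc) g/g — a constant, not a fitted parameter, which keeps
the four-parameter fit identifiable. Glucose is floored at zero, after which
growth and production stop. "Growth-coupled" production (q_P ∝ µ) is not a
separate structure here: with production saturating through the same Monod
term, q_P = α µ is an exact reparameterisation (α = q_P,max/µ_max) of the
implemented model, so a switch would toggle nothing. A maintenance term is
deliberately omitted; batch data of this shape cannot separate it from
Y_XS. The right-hand side is compiled C (`src/monod.c`, deSolve's
compiled-model interface) because the bootstrap integrates it hundreds of
thousands of times.

**Fitting.** Multi-batch weighted least squares with a global/local scope
split: the user names which parameters are shared across batches (the
motivating campaign shares the Monod constant and yields while growth rates
differ between strains); all others are estimated per batch. Residuals are
*per-point relative*: each residual is divided by the predicted level,
floored at `floor_frac` (0.5 %) of the observable's maximum. This matches a
constant-CV noise model, weighs mM and g/L observables comparably — and,
decisively, preserves the information in the short glucose-depletion phase,
which is where K_S lives; scaling by batch-mean levels instead was measured
(during design, on synthetic data) to inflate K_S errors several-fold.
Optimisation is Levenberg–Marquardt (minpack.lm) on log-parameters, which
enforces positivity, with data-driven starting values (growth rate from the
early log-linear biomass phase, yield from the X/S balance, production rate
from the product increment over the biomass integral) and seeded
multi-start. Initial conditions are taken from each batch's first row, and
non-convergence across all starts is an error, never a silently returned
estimate.

**Bootstrap.** Uncertainty is parametric-bootstrap percentile: simulate
`n_boot` datasets from the fitted trajectories plus the fitted
per-observable relative residual SD, refit each (single start from the point
estimate), and take 2.5/97.5 percentiles. Percentile rather than BCa because
the bounds are reported per parameter at modest `n_boot` where BCa's
acceleration estimate is itself noisy. Bounds are asymmetric in general and
collapse onto the estimate for noise-free data.

**KPIs.** Titer g/L = mM·M(His)/1000; yields on glucose in C-mol/C-mol,
mol/mol and g/g; volumetric productivity = titer/duration. For the C6 → C6
conversion the C-molar and molar yields are identical by construction and
asserted as such. Displayed values are rounded to two decimals; stored
values never are.

## The synthetic study conditions

The generator's defaults are the conditions the package tests itself under;
they are fixed once, here, and not revisited per test.

* **Cohort**: 100 independently mutagenized strains; mutation loads drawn
  from a negative binomial with mean 180, clamped to [47, 470]. The negative
  binomial (dispersion `size = 5`) rather than a Poisson reflects the wide
  spread chemical dosing produces across cultures; the clamp reproduces the
  observed extremes.
* **Spectrum**: a SNP is a G:C>A:T transition with probability 0.9,
  otherwise uniform over the substitution classes available at the drawn
  base. The alkylating-mutagen literature shows a dominant G:C>A:T share
  without printing one number; 0.9 is this package's explicit choice.
* **Read frequencies**: true mutations draw from U(0.5, 1); a 10 % decoy
  fraction draws below 0.5 to exercise the frequency filter. No InDels by
  default; an option enables them for robustness tests.
* **Planted hotspots**: named genes receive an extra, verified
  nonsynonymous SNP per strain with the configured probability (0.20 in the
  recovery tests) on top of the background.
* **Cohort genome**: 3.2 Mb, 3000 genes of 600–1200 bp, GC 0.54 —
  chromosome-scale on purpose, because hotspot detection only makes sense
  when the per-gene background probability is realistically small (here
  ≈ 0.03 per strain and gene after filtering, against 0.20 + background for
  planted genes). Toy examples elsewhere use 25–300 kb genomes.
* **Screen**: plates carry a control triplicate plus variants; titers are
  control level × (1 + effect) × lognormal noise (CV 5 %), with a per-plate
  lognormal factor (SD 3 %) emulating plate-to-plate variation. Control
  titer 11.5 mM and biomass OD 18.4 match the motivating strain's scale.
* **Fermentation**: µ_max 0.15 /h, K_S 1.0 g/L, Y_XS 0.21 g/g, q_P,max
  0.13 mmol/(g h), X₀ 0.25 g/L, S₀ 40 g/L, hourly sampling to 48 h,
  1 % multiplicative noise. K_S = 1.0 g/L and the hourly grid were chosen
  together, before the tests were frozen, from an identifiability argument:
  the Monod constant is informed only by the deceleration phase around
  depletion, whose duration scales with K_S, and it must span several
  sampling points for a three-batch fit to pin K_S within a few percent.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing and alignment artefacts (it writes
variant calls, not reads), strain relatedness (no sister clones; every
strain is independent), clustered or context-dependent mutagenesis (sites
are uniform given the base class), real operon structure and overlapping
genes, selection (background mutations are neutral by construction), and
dose–mortality chemistry (mutagen dose never enters; the load distribution
is specified directly).

## Problem sizes and determinism

Every generator is a pure function of (configuration, seed); identical seeds
give byte-identical files. The test suite runs the full pipeline at the
cohort scale above: 500 random SNPs against the retranslation oracle, 21
cohorts of ~18,000 mutations for hotspot null calibration and planted
recovery (20 seeds), 1,000 simulated null plates plus 20 seeded recovery
campaigns for the screen rules, and 20 replicate three-batch fitting
experiments with 50-replicate bootstraps. The hotspot null check compares
the observed hotspot count against a 2,000-replicate count-level binomial
simulation of the same cohort — an independent oracle that never touches the
sequence machinery.

## Known limitations

* Frameshift versus in-frame InDel typing is not implemented; InDels are a
  single class.
* Hotspot calls are threshold counts without attached significance; the
  enrichment folds are descriptive.
* The bioprocess model is batch-only (no fed-batch, pH or DO dynamics) and
  assumes constant yields; maintenance metabolism is absorbed into Y_XS.
* The stage-1 rule applies a mean-CI bound to single measurements, which is
  anti-conservative relative to a prediction interval; it reproduces the
  campaign's decision logic rather than improving on it.
* Campaign-specific outputs of the motivating study (its hotspot table,
  fitted rates and enrichment folds) depend on its raw sequencing and
  fermentation data and are not reproducible from a desk; the package's
  claims are therefore calibration and recovery properties on synthetic
  data, plus the exactly reproducible KPI arithmetic.
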