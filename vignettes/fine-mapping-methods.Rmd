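---
title: "Mendelizing a QTL: methods and design choices in hifmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelizing a QTL: methods and design choices in hifmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifmapr)
```

## The problem

A quantitative trait locus (QTL) detected in a biparental population is a
statistical object: a LOD peak spanning megabases. Turning it into a
candidate gene requires *Mendelizing* it — isolating the locus in a genetic
background where it is the only thing segregating, so its two alleles can be
compared like a Mendelian gene. The heterogeneous inbred family (HIF)
strategy does this with late-generation inbred lines that are still
heterozygous across the target region: their selfed progeny ("sister lines")
differ only there, which removes the genome-wide genetic variance from the
comparison and collapses the required experiment from hundreds of field
plots to a few dozen greenhouse plants.

`hifmapr` implements the full inference chain on which such a campaign
rests, together with a population simulator that makes each stage testable
against known truth. The package's worked reference inputs are the
coordinates, counts and diagnostic rules of the wheat 7AL
spikelet-number-per-spike (SNS) locus whose candidate gene is the wheat
ortholog of rice *APO1* (*WAPO-A1*, *TraesCS7A02G481600*).

## Coordinate and interval conventions

All coordinates are 1-based and inclusive (the RefSeq-style convention of
wheat physical maps). Two width conventions coexist in this literature and
both are deliberate:

* **marker-bounded** intervals carry flanking-marker positions as endpoints
  and the locus in their open interior; width is `end - start`. Every
  printed candidate-interval size (87 kb, 498 kb, 423 kb, 8.7 Mb)
  reproduces under this rule.
* **feature** intervals (e.g. the 115-bp promoter deletion spanning
  −599..−485) are inclusive; width is `end - start + 1`.

Printed sizes round half-up (kb to integers, Mb to one decimal), as do
percentages (one decimal); `round_half_up()` exists because R's banker's
rounding does not reproduce figures such as 83.2%.

The constraint algebra of locus deduction uses *fencepost* semantics: a
marker-bounded interval `[L, R]` asserts the locus lies strictly between
the two marker coordinates. Subtracting an exclusion zone therefore leaves
pieces whose endpoints are again marker coordinates, which is exactly how
published candidate intervals are reported.

## The meiosis and population model

Gametes follow the Haldane model: crossovers are a Poisson process on the
cM scale with no interference. Restricted to marker positions this is a
two-state Markov chain whose switch probability between adjacent markers at
distance `d` cM is `r = (1 - exp(-d/50))/2`; the simulator draws that chain
directly, which is distributionally identical to drawing crossover counts
and positions and far faster. Consequences used by the tests: the gamete
recombination fraction across 50 cM is `(1 - e^{-1})/2 ≈ 0.316`; F2
genotypes at an unlinked marker segregate 1:2:1; selfed RILs at generation
*g* retain heterozygosity `(1/2)^{g-1}`.

HIF populations are built the way breeding programs build them: RILs are
simulated to the requested generation, founders are kept when heterozygous
at a target marker — optionally requiring a breakpoint inside the mapping
region (a screened recombinant) and a single contiguous heterozygous run
(the single-breakpoint recombinants a program retains; double-recombinant
founders would make a homozygous family's exclusion zone overstate what its
progeny test shows) — and each founder is selfed once. Sister lines are
then genotypically identical outside the founder's residual heterozygous
segments, which the tests assert exactly.

Linkage maps may be supplied in cM or derived from physical positions via a
cM/Mb scalar. The default scalar is *calibrated*, not assumed: it is chosen
so that the initial 9.13-Mb screening window reproduces the observed
plant-level recombinant fraction of 12.0% (74 of 617 plants), using the
F2 plant-level relation `p = 1 - (1 - r)^2`. The observed count is thus a
calibration anchor, not a validation claim.

## Trait model and defaults

Phenotypes follow
`value = μ + Σ_q a_q x_q + d_q z_q + polygenic + environment + ε` with
additive dosage `x ∈ {-1, 0, +1}`, dominance indicator `z`, and no
epistasis (QTL effects are additive across loci). Defaults
(`sns_defaults()`):

* `μ = 18` spikelets and `a = 1.05` at the main locus, so the homozygote
  gap is 2.1 spikelets — the gap the downstream power analyses assume;
* plant-level residual SD 0.9 spikelets, the scale of a homogeneous
  greenhouse progeny test;
* an optional polygenic background (SD 3.3, off by default) assigning each
  marker an effect drawn once from `N(0, σ²/M)`. It segregates between
  RILs but is essentially fixed within a HIF, reproducing the roughly
  fourfold pooled-SD contrast between RIL-level field trials and HIF
  progeny tests that motivates the HIF design (the exact ratio is a
  tunable default, not an asserted value). Because the term rides on the
  simulated markers, analyses that classify lines by a marker on the same
  chromosome should exclude that chromosome from the background
  (`polygenic_exclude_chrom`) to keep the background unlinked;
* two background QTLs (additive 0.7 and 0.5) on chromosomes 2BS and 7AS —
  plausible smaller companions to the main locus, chosen once for the
  demonstrations.

The simulator emulates the statistical structure these analyses assume:
Mendelian segregation, additive multi-locus effects, block-structured
environments, Gaussian residuals, and assay noise (missingness and a
uniform-wrong-code error kernel). It does not emulate segregation
distortion, genotyping batch effects, G×E interaction, or crossover
interference; passing tests therefore validate the inference logic, not
those aspects of real data.

## Interval mapping

`conditional_genotype_probs()` computes, per line and evaluation position,
the genotype distribution given the nearest informative flanking markers:
a three-state Markov chain conditioned on both flanks for F2 (exactly equal
to exhaustive two-gamete enumeration, which the tests assert at 1e-10), and
a two-state chain with the selfing-expanded fraction `R = 2r/(1+2r)` for
RILs, where residual heterozygous calls are treated as missing and flagged.
Typed markers receive point masses; lines with no informative call on a
chromosome fall back to the population prior and are flagged.

`hk_scan()` is Haley–Knott regression: phenotype on expected dosage (plus
expected dominance for F2), `LOD = (n/2) log10(RSS0/RSS1)`, with the
identity `pve = 1 - 10^{-2·LOD/n}` holding at every position. The scan
grid is every marker plus pseudo-positions (default 1 cM); ties in peak
LOD break toward the smaller bp coordinate. Significance uses the fixed
LOD 2.0 threshold of the original campaign; the suite also *estimates* the
genome-wide null exceedance rate of that threshold by simulation (about
5% at 150 lines over three 100-cM chromosomes) rather than asserting a
value. Support intervals use a 1.5-LOD drop — a common default, stated
here because the original report does not specify one. `multi_qtl_fit()`
is a joint additive fit at the peak positions with drop-one PVE; no
interaction terms, consistent with the additivity the data showed.

## Progeny tests and locus deduction

A progeny test compares the two homozygous sister-line classes of a family
across experiments with a fixed-effects blocked ANOVA
(`value ~ experiment + class`); `blocked_ls_means()` computes the
extra-sum-of-squares F for the class effect and least-squares means that
average fitted cell means over blocks with equal weight. This deliberately
replaces mixed-model BLUP adjustment: it is deterministic, matches the
combined-ANOVA analysis the published effect tables actually report, and
its LS means are verified in the tests both against a normal-equations
solve and against the independent `emmeans` implementation. The
classification rule is `P < α` with `α = 0.05`, two-sided (the original
report says only "significant"; 0.05 is the stated package default).

Deduction is constraint intersection. A heterozygous-classified family
confines the locus to the open interior of its *maximal* heterozygous
segment (bounded by the nearest non-heterozygous, non-missing markers); a
homozygous-classified family excludes its *minimal* segment (the span of
its observed `H` calls). This asymmetry is intentional: maximal for
containment is conservative, minimal for exclusion excises only where
heterozygosity was actually observed. The candidate is the intersection of
the containment constraints minus the union of the exclusions; when
exclusions split the result, all surviving pieces are returned and the
largest is reported as the candidate interval (a deliberately simple,
reproducible reporting rule — with the dense marker coverage of a real
campaign a single piece survives). Families that would empty the result
are removed greedily (largest restored width first) and reported as
conflicts, never dropped silently. On simulated campaigns with correctly
classified single-breakpoint families, the deduced feasible set contains
the true locus in 100% of runs and the reported interval equals a
brute-force gap-by-gap constraint check.

`plan_rescreen()` converts a candidate interval into screening effort via
the calibrated cM/Mb scalar: `N = ceiling(target/p)` plants for a desired
number of new recombinants, plus the probability `(1-p)^N` of seeing none
— the quantity that says when an interval is exhausted.

## Haplotypes, alleles, and the candidate filter

Historical haplotype blocks are detected with the four-gamete test:
a boundary falls between adjacent sites exhibiting all four gametes among
accessions non-missing at both. (The original analysis presents its blocks
without naming a method; the four-gamete test is this package's documented
interpretation.) Haplotype groups are missing-tolerant exact-match classes
labelled H1, H2, … in descending size with lexicographic tie-breaks; the
numbering is arbitrary — it carries no ancestral meaning — so anchor
accessions can rename groups.

The diagnostic allele classifier encodes the published natural-variation
rules for *WAPO-A1*: the 115-bp promoter deletion (P−) is unique to allele
*a*; the codon-47 C→F change in the conserved F-box is unique to allele
*b*; the ancestral P+/C47/D384 background splits into alleles *c* and *d*
by linked SNPs, and remains `ancestral_unresolved` without them. The D384N
change is treated as confirmatory rather than required for allele *a*
because the deployed PCR assay uses only the P−/C47 combination.
Contradictory evidence (e.g. P− with F47, or c- and d-diagnostics
together) yields the value `inconsistent`, never an error; whether such
combinations occur in nature is unresolved, so they are surfaced rather
than resolved. The classifier is total and deterministic over every
diagnostic tuple, which the tests enumerate.

The dual-population candidate filter captures the decisive genetic
argument: a gene can explain a trait difference seen in both an H2×H1 and
an H2×H3 cross only if a functional polymorphism (non-synonymous or
promoter indel) differentiates H2 from *both* alternatives at the same
position, within the candidate region. Applied to the published
polymorphism table restricted to the 87-kb interval, exactly one gene
survives. The region restriction matters: the flanking-marker gene itself
carries a dual-contrast change but sits on the recombination breakpoint,
outside the candidate interval.

## Frequencies, effects, expression

Frequency tables report counts and half-up one-decimal percentages, with
unclassifiable calls excluded from denominators (configurable). The
homogeneity test is Pearson's chi-square with `(r−1)(c−1)` degrees of
freedom, flagging cells with expected counts below 5; its null calibration
is verified by simulation. Effect tables chain the blocked ANOVA per trait
and add absolute and percent differences at printed precision.
qRT-PCR quantification is plain `2^{ΔCT}` fold-reference (the
efficiency-corrected mode exists but is off by default, matching the
published quantification); group comparisons run on the ΔCT (log2) scale
with Tukey HSD and a compact-letter display.

## Numerical and degenerate-input choices

* Map functions: Kosambi by default (the convention of the source maps);
  Haldane for everything the simulator touches, since that is its model.
  Round trips invert to 1e-10; `r ≥ 0.5` is rejected.
* Zero phenotypic variance yields a flat LOD curve with a warning, not an
  error; constant genotype columns contribute LOD 0 exactly.
* Unconnected block designs make LS means inestimable and error explicitly.
* Genotype CSV readers reject unknown symbols, ragged rows and duplicate
  ids, naming the offending line and marker.
* VCF input keeps biallelic SNPs, converts heterozygous calls of inbred
  accessions to missing, and converts BED-style half-open query bounds to
  the internal 1-based inclusive convention, with boundary cases tested.

## Problem sizes

The validation suite simulates at sizes chosen to give tight Monte-Carlo
error while remaining quick on a laptop: 1e5 gametes for closed-form
recombination checks, 500 replicate HIF campaigns for deduction exactness,
500 progeny tests at 25 plants per class × 2 experiments for power
(the observed rate is ~100% at the 2.1-spikelet gap), 500 null genome
scans of 150 RILs for the LOD-2.0 false-positive rate, and 200-line RIL
trials for parameter recovery. The analysis scripts use comparable sizes.

## Known limitations

The deduction reports marker-bounded intervals, so its resolution is the
marker density — it cannot narrow below the innermost flanking markers.
The simulator's no-interference meiosis slightly overstates double
crossovers relative to real wheat. The blocked fixed-effects analysis
assumes homogeneous residual variance across environments; strongly
heteroscedastic multi-environment data would call for a mixed model, which
is outside this package's scope. Haplotype grouping is exact-match based
and intended for inbred panels; heterozygous outbred material would need
phasing first.
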