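---
title: "Reconciling chemostat growth data with a constraint-based model"
author: "fluxrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling chemostat growth data with a constraint-based model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxrecon)
```

# Scope and model

`fluxrecon` connects three layers of evidence about a glucose-limited
bacterial culture — steady-state chemostat measurements, a stoichiometric
model solved by linear optimization, and microarray expression calls — into
one reconciliation chain. This vignette explains the underlying models and
assumptions, the tunable parameters with their defaults and units, the
numerical choices, what the synthetic-data generators do and do not emulate,
and the known limitations.

## Chemostat growth analytics

At steady state in a chemostat the specific growth rate equals the dilution
rate, $\mu = D$ (h$^{-1}$). Per steady state the package computes the
biomass production rate $R_x = D\,C_x$, the glucose uptake rate
$R_{glc} = D\,(C_{glc,feed}-C_{glc,res})\,M_{glc}/1000$ (g L$^{-1}$
h$^{-1}$), the CO$_2$ production rate from the off-gas mole-fraction
difference via the ideal gas law $pV = nRT$ at the record's temperature and
pressure, the specific uptake rate $q_s = R_{glc}/C_x$ and the yield
$Y_{x/s} = R_x/R_{glc}$.

The cell density $C_x$ is taken from two measurement routes: an OD$_{600}$
calibration $C_x = 0.35\,\mathrm{OD}_{600}$ (regression forced through the
origin, because the calibration law has no blank term) and a direct
dry-weight route corrected by a filter blank (`residue`, default 0.356 g/L)
and a slope ratio (`direct_dcw_factor`, default $0.35/0.399$, the OD
calibration slope over the slope implied by the uncorrected direct
measurements). When both are present the unweighted mean is taken. Each
measurement is corrected individually before averaging; a corrected value
below zero is treated as an input error (mis-specified blank) rather than
clipped.

Maintenance partitioning follows the linear Pirt model
$$q_s = \frac{D}{Y_{x/s}^{max}} + m_s,$$
fitted by ordinary least squares of $q_s$ on $D$; the maximal yield is the
inverse slope, the maintenance coefficient the intercept. A Monod-type
model of residual substrate is deliberately not fitted: under carbon
limitation in this regime residual glucose stays near zero and carries no
usable signal. The maximal growth rate comes from a washout experiment at
$D > \mu_{max}$, where $C_x(t) = C_x(0)\,e^{(\mu_{max}-D)t}$; the package
fits $\ln C_x$ on $t$ by least squares (deterministic, exactly the
linearization of the stated law) rather than a nonlinear exponential fit.

Carbon and nitrogen balances divide the glucose-minus-CO$_2$ carbon flow by
$R_x$, and the consumed ammonium nitrogen by $C_x$, per record, then
average. Records are balanced individually because the balance inputs are
record-specific; averaging afterwards keeps each steady state's error
independent.

The glucose molar mass is a package constant (180.16 g/mol) but an argument
everywhere it enters, since printed literature values are sometimes
consistent with 180.0.

## The biomass equation

The biomass pseudo-reaction consumes monomer residues (water of
polymerization already subtracted) in proportions that assemble exactly 1 g
of dry biomass per unit of flux, with fluxes in mmol gDCW$^{-1}$ h$^{-1}$ —
so the biomass flux numerically equals $\mu$. For each macromolecule with
mass fraction $f$ and monomer mol fractions $x_i$, the coefficient of
monomer $i$ is
$$c_i = \frac{1000\, f\, x_i}{\sum_j x_j m_j} \quad (\mathrm{mmol\,gDCW^{-1}}),$$
with $m_j$ the residue molar masses. Mass closure ($\sum_i c_i m_i / 1000 =
f$) holds per macromolecule by construction and for the whole equation
within $10^{-6}$ g.

Composition assembly applies two additions to the measured fractions: a
water-insoluble protein increment (12.2 percentage points; standard protein
assays only capture the soluble fraction) and a peptidoglycan constant
(8.6% w/w, not captured by any of the assays). The default composition
reads the published total protein fraction of 52.8% as *already containing*
the insoluble increment (stored as 40.6% soluble + 12.2 pp): the
alternative reading (52.8 soluble + 12.2 pp) drives the macromolecule sum
to 108.9% and cannot close mass. Both readings remain expressible through
`assembleComposition()`'s arguments. Closure to 1 g/g follows one of two
policies: the default assigns the remainder (3.3% at the default
composition) to a small cofactor pool — cofactors are present in the cell
but quantitatively negligible, and their presence matters for essentiality
predictions rather than yield — while `"proportional"` rescales all
fractions.

Monomer reference data (amino-acid, NMP and dNMP residues, phospholipid
backbones and acyl chains, an LPS aggregate, glycogen and murein units, the
cofactor species, the ATP hydrolysis couple) ship as an editable TSV whose
masses are derived from the stored elemental formulas, so the
mass-formula consistency invariant holds exactly. The LPS entry is a coarse
synthetic aggregate (~2.4 kDa, lipid A plus core oligosaccharide, no
CDP-ethanolamine moiety) and is labelled as such; the murein unit is an
approximate GlcNAc-MurNAc-tetrapeptide formula.

Specific composition choices, each overridable:

* Amino acids: measured mol% at $D = 0.2$ h$^{-1}$; the assay's combined
  Asx/Glx categories are split 50/50 into acid/amide forms; Cys, Met and
  Trp (destroyed by hydrolysis) are filled in at reference mol% from the
  *E. coli* biomass (1.7 / 2.9 / 1.1) and the profile renormalized.
  Filling is idempotent.
* DNA: paired-base model from GC content (default 0.615, the organism's
  genomic value) or counted directly from a genome FASTA; no base
  composition is hard-coded as truth.
* RNA: reference *E. coli* composition at $D = 0.6$ h$^{-1}$.
* Lipids: head groups at the measured 73.7 / 21.3 / 4.9 mol% for
  PE/cardiolipin/PG, two acyl chains per phospholipid (four for
  cardiolipin) drawn from a reference fatty-acid mix; LPS at 3.4% of dry
  weight within the lipid fraction.
* Carbohydrates: entirely glycogen, as a proxy for all sugar polymers.

The growth-associated maintenance enters the finished equation as a
mass-neutral hydrolysis couple, GAM $\times$ (ATP + H$_2$O $\to$ ADP +
P$_i$). Polymerization energy is *not* itemized per bond; it is carried by
this lumped fitted term, which keeps the equation's mass closure and the
energy accounting cleanly separated. The elemental composition of the
assembled biomass is computed from the same monomer formulas with the GAM
couple excluded (it is mass- and element-neutral).

## Maintenance energy

NGAM converts the measured maintenance coefficient through the network's
maximal ATP yield:
$$\mathrm{NGAM} = m_s \cdot \frac{1000}{M_{glc}} \cdot Y_{ATP}
\quad (\mathrm{mmol\,ATP\,gDCW^{-1}h^{-1}}),$$
exactly linear in both inputs. $Y_{ATP}$ is computed from the model by
maximizing the ATP-drain flux per unit glucose with growth fixed to zero;
it is affine in the P:O ratio with slope equal to the number of reduced
electron carriers per glucose. For a genome-scale model whose printed
$Y_{ATP}$ (e.g. 19.25 mol/mol at P:O 1.33) is known, that value is treated
as an input constant rather than a reproduction target, since it depends on
the full network's stoichiometry.

GAM is fitted so that the FBA-predicted maximal yield matches the measured
$Y_{x/s}^{max}$. The predicted yield is defined by the *two-point slope* of
the minimized glucose demand between $\mu = 0.1$ and $0.5$ h$^{-1}$:
because NGAM is a constant flux offset, the slope construction cancels it
exactly and makes GAM and NGAM separable — the defining property that
motivated this choice, which the source procedure leaves open. The fit is
bisection on GAM over [0, 1000] mmol gDCW$^{-1}$ (at most 60 iterations,
relative tolerance $10^{-4}$): the yield is monotonically non-increasing in
GAM, so convergence is guaranteed. GAM values that render a probe growth
rate infeasible count as zero yield. One identifiability caveat is inherent
to the definition: at low GAM a network can be carbon- rather than
ATP-limited, where the yield is flat in GAM; the fitted value is then only
determined down to the limitation switch point.

## FBA, FVA and the LP engine

FBA maximizes or minimizes one reaction's flux subject to $S v = 0$ and
bounds; reversibility is encoded solely through bounds, and gene deletions
zero the bounds of reactions whose GPR rule (AND = complex, OR = isozymes,
case-insensitive, no negation; empty = spontaneous) evaluates inactive. FVA
fixes the objective flux at a prescribed value and minimizes/maximizes each
reaction in turn. Degeneracy is expected: alternate optima make individual
FBA flux vectors non-unique, so only objective values and FVA intervals are
treated as contract-stable, and the test suite never asserts non-unique
flux vectors.

No linear-programming package is available in the target R stack
(lpSolve/Rglpk-class solvers are absent), so the package includes a dense
bounded-variable two-phase primal simplex with Bland's anti-cycling rule,
written for the small, often degenerate LPs of flux analysis. The
recommended-package simplex routine that does exist was found to abort with
undefined pivots on exactly these degenerate instances, which is why the
engine is in-package; its correctness is cross-checked in the tests against
closed-form solutions and brute-force enumeration of basic solutions on
small networks. Solver tolerance is $10^{-9}$; assertions use $10^{-6}$
(double-precision LP). Infinite bounds are capped at $10^5$ mmol
gDCW$^{-1}$ h$^{-1}$ internally, and an optimum riding such a cap is
reported as unbounded rather than returned silently.

## FVA-distance

For measured flux $f$ and interval $[lo, hi]$: minimal contribution 0 if
$f \in [lo,hi]$, else $\min((f-lo)^2,(f-hi)^2)$; maximal contribution
$\max((f-lo)^2,(f-hi)^2)$; the FVA-distance is the pair of sums. This is
the simplest reading of a "squared distance" between a point set and
intervals and is stated prominently because the source of the statistic
does not spell out the formula. Unnormalized sums are the default;
SD-weighting is available by flag because whether the original statistic
normalized by measurement error is unknown. Measurements are aligned to
model reactions through an explicit mapping table with a sign column
(measured pathway fluxes may be reported against the opposite direction
convention); unmapped measurements are reported, never dropped. Intervals
with an unbounded endpoint contribute $\infty$ to the maximal distance and
the offending reactions are listed. Constraining a reaction to its measured
value only tightens the feasible set, so all other intervals nest and the
maximal distance cannot increase — both asserted as properties in the
tests.

## Transcriptomics consistency

The three assessments use the published thresholds: a gene is "potentially
not expressed" when >2 of 4 arrays call it absent, <3 of 4 call it present,
or its mean log2 value is below 7.5; marginal calls count as neither.
Reaction-level expression aggregates gene means through the GPR algebra
with OR $\to$ max and AND $\to$ min — chosen so that an isozyme-pair
reaction is flagged only when *both* isozymes are low, matching the
motivating observation. "Non-zero minimal flux" uses a numerical epsilon of
$10^{-9}$. The high-expression cutoff for assessment iii has no published
number; the package requires it explicitly (the dataset mean is the
pipeline's default choice, recorded in the report). Flux magnitudes are
absolute values so reversible reactions are treated symmetrically; the
low-flux threshold defaults to 0.1 mmol gDCW$^{-1}$ h$^{-1}$ at the
$\mu = 0.2$ h$^{-1}$ condition.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their arguments and a seed, and their
defaults *are* the study conditions: $Y_{x/s}^{max} = 0.397$ gDCW/g,
$m_s = 0.037$ g gDCW$^{-1}$ h$^{-1}$, $\mu_{max} = 0.59$ h$^{-1}$, $D$ from
0.05 to 0.5 h$^{-1}$ on a 10 mM glucose feed, washout at $D = 1.2$
h$^{-1}$, GAM 85 mmol gDCW$^{-1}$, NGAM 3.96 mmol gDCW$^{-1}$ h$^{-1}$,
P:O 1.33, four arrays. Chemostat records are generated by inverting the
Pirt relation, with full glucose consumption (carbon limitation), OD and
direct dry-weight channels back-computed through the calibration constants,
CO$_2$ from the carbon balance at a set biomass carbon fraction (0.488),
and ammonium from a nitrogen fraction of 0.143. Concentration noise is
multiplicative log-normal-style (positivity); expression noise is additive
on the log2 scale (background N(9, 0.5) with present calls; planted
non-expressed genes N(6.5, 0.3) with absent calls; planted high-expression
genes N(11, 0.3)). The anabolic reducing-power demand of the toy biomass
(5 mmol NADPH-equivalent gDCW$^{-1}$) is a modest fixed choice on the low
side of typical bacterial anabolic NADPH budgets; it only shifts the toy
network's absolute yields, not any fitted relationship.

The toy network is a fixed ~20-reaction single-compartment model: glucose
transport (isozyme pair), an optional periplasmic gluconate loop (direct
glucose oxidation to the quinone pool with gluconate re-entry via an
Entner-Doudoroff route), lumped EMP- and ED-style glycolysis variants,
pyruvate dehydrogenase, a lumped TCA cycle, electron transport at ATP:NADH
= P:O, an ATP maintenance drain, and a biomass reaction whose carbon and
nitrogen demands are derived from the assembled biomass equation's
elemental composition (pyruvate at 1/3 mmol per mmol C, ammonia per mmol
N), which makes the tracked carbon balance close exactly. Its maximal
growth, ATP yield ($4 + 12\,\mathrm{P{:}O}$ from 4 substrate-level ATP, 10
NAD(P)H and 2 FADH$_2$ per glucose) and essential-gene set are all
hand-derivable, and the tests pin them to those closed forms.

What passing tests on this material demonstrate: the estimators invert
their generating models exactly at zero noise and are unbiased at realistic
noise; the solver, the distance statistic and the consistency assessments
behave per their definitions; the maintenance machinery is self-consistent
(round-trip GAM recovery within 0.1%). What they do not demonstrate:
anything about a genome-scale network's biology — compartments, transport
diversity, cofactor specificity (NADH vs NADPH are pooled in the toy),
isotopomer-level flux identifiability, probe-level microarray artifacts, or
the numerical conditioning of LPs with thousands of reactions. Quantities
that depend on a specific external genome-scale model and dataset (its
fitted GAM value, its FVA-distances, its essential-gene counts) are
exercised as procedures here, not reproduced as numbers.

## Pipeline and problem sizes

`runPipeline()` executes growth fits, biomass assembly, NGAM/GAM fitting,
FVA and distances, the constraint-perturbation experiment and the three
omics assessments, and writes a versioned JSON report carrying every
threshold and constant actually used, input file hashes, the seed and the
package version — reruns are identical up to the timestamp. The
perturbation experiment runs in the biomass-fixed mode (glucose free within
its bound) because the glucose-minimized solution space of the toy network
is a single point, which leaves no room to impose a noisy measured value;
an infeasible fix is reported as a measurement-model conflict rather than
aborting the run. Default problem sizes (10 steady states, a ~20-reaction
network, 4 arrays, 100-200 replicate simulations in the statistical tests)
keep the whole suite in the tens of seconds on one CPU while leaving every
estimator's sampling error measurable.

## Known limitations

* Single compartment, one exchange convention; no thermodynamic or
  loopless constraints, no parsimonious FBA.
* The dense simplex targets networks up to a few hundred reactions;
  genome-scale models would need a sparse revised implementation or an
  external solver.
* The SBML support is a minimal Level 3 subset (with FBC-style attributes)
  sufficient to round-trip this package's own documents; JSON is the
  primary interchange format.
* Reference monomer data are literature-derived defaults, clearly marked
  and editable, not measurements of this package's target organism.
* The GAM/NGAM separation relies on the linearity of the glucose demand in
  $\mu$; regulatory effects that bend $q_{glc}(\mu)$ would bias the
  two-point slope.
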