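---
title: "Modelling enterocyte diet response with enteroflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enterocyte diet response with enteroflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enteroflux)
```

## The modelling problem

Enterocytes absorb the hydrolysis products of dietary carbohydrate,
lipid and protein at their apical (luminal) membrane and secrete
glucose basolaterally and triacylglycerol (TAG) as chylomicrons into
the lymph. A constraint-based model treats this cell as a reaction
network: a stoichiometric matrix $S$ of size $m \times n$, with
$S_{ij}$ the coefficient of metabolite $i$ in reaction $j$ (positive
for production, negative for consumption), flux bounds
$l_i \le v_i \le u_i$, and the steady-state mass balance $S v = 0$.
Flux balance analysis (FBA) maximizes or minimizes one flux subject to
these constraints; every question this package answers is phrased as
such an optimization.

Exchange reactions are single-metabolite boundary pseudo-reactions with
uptake negative and secretion positive. Diet enters the model entirely
through their lower bounds: an intake of $q$ mol·mouse⁻¹·day⁻¹ becomes
a lower bound $-qA$, with

$$A = \frac{10^3\ \text{mmol}}{m_\text{dw}\ \text{g} \times 24\ \text{h}},
\qquad m_\text{dw} = 1.094 \times (1 - 0.76) \times 0.552 \approx 0.1449\ \text{g},$$

the dry mass of the enterocyte population of one mouse (small-intestine
wet weight × dry fraction × enterocyte cell fraction). With the default
body parameters $A \approx 287.49$. Only lower bounds are touched:
secretion back into the lumen remains possible, which matters for the
lipid pathways below.

## Species-resolved lipid pathways

Dietary TAG is resolved into six fatty acid (FA) species — C14:0,
C16:0, C18:0, C18:1, C18:2, C18:3 — with *uniform-acyl* TAG/DAG/MAG
(all acyl chains of a molecule identical). This keeps the molecule
count linear in the number of species instead of cubic, and is
justified by luminal hydrolysis: TAG is broken to 2-MAG + 2 FFA before
absorption, so mixed-acyl identity is not observable downstream.

`generate_lipid_reactions()` emits, per species:

* 1 hydrolysis (luminal lipase): TAG → MAG + 2 FFA;
* 3 absorption reactions: carrier-mediated FFA transport (CD36/FATP
  class), FFA diffusion, and MAG transport — the carrier/diffusion pair
  is deliberately redundant;
* 6 re-esterification steps: acyl-CoA activation (2 ATP), acyl-CoA and
  MAG transport into the ER, MGAT (MAG + acyl-CoA → DAG), DGAT
  (DAG + acyl-CoA → TAG), and an MTTP-like transfer of ER TAG into a
  common chylomicron TAG pool;
* 1 cholesteryl ester formation (acyl-CoA + cholesterol → CE).

Six species therefore give 18 absorption, 36 re-synthesis and 6
cholesteryl ester reactions. The per-species breakdown of those totals
into templates (which internal steps make up the "6 re-synthesis
reactions") is this package's own reconstruction; the templates are
plain constants in the source so the counts are auditable, and a
carbon-balance check covers every generated reaction whose metabolites
all carry formulas (the mixed-species pool steps deliberately do not).

### Chylomicron assembly

Chylomicrons are modelled as a pseudo-reaction (`CHYLOMGE`) consuming
TAG, phospholipid, cholesteryl ester and an apolipoprotein precursor
and producing one secreted particle. The printed particle composition
(~95 % TAG, ~4 % phospholipid, ~1 % CE, ~2 % protein) slightly
overfills 100 %, so the package normalizes to 95/4/1 with the protein
contribution folded into a small fixed apolipoprotein demand. Mass
fractions are converted to molar coefficients through declared molar
masses (ester-bond bookkeeping from the free-acid masses; generic
760 g/mol phospholipid) against a reference particle mass of
10⁴ g/mol — only ratios matter for the LP, the reference mass sets the
flux scale of the particle counter.

Two TAG wirings are provided. The literal one consumes species-specific
TAG in fixed profile proportions. The toy model instead uses a pooled
wiring: per-species MTTP-like steps feed a common TAG pool that the
assembly consumes, so the *realized* FA composition of secreted
chylomicrons is free, and under a cholesterol-free diet with no FA
interconversion it provably tracks the dietary FA profile — which is
exactly the composition experiment the scenario layer runs. The
cholesteryl ester demand (1 % of particle mass) may draw its acyl
chains from any species at the optimum, so the recovered fractions can
deviate from the dietary ones by up to about 1.5 %; tests assert
agreement within 0.02 absolute.

## The linear-programming backend

All optimizations go through one narrow interface
(`solve_lp(obj, A, b, lb, ub, direction)`), implemented as a dense
bounded-variable two-phase simplex: phase 1 drives artificial variables
to zero (detecting infeasibility), phase 2 optimizes the objective.
Dantzig pricing with a Bland's-rule fallback after a run of degenerate
pivots guarantees termination; the basis is refactorized every
iteration, which is numerically conservative and entirely adequate at
the model sizes involved (~10² reactions). Tolerances: feasibility
1e-9, steady-state residual 1e-6, optimality 1e-8. In the test suite
every optimum on the small fixture networks is checked against an
independent brute-force vertex-enumeration oracle at 1e-8.

Alternate optima are a fact of FBA: only the objective value is
contract-guaranteed, individual fluxes are solver-dependent. Flux
ranges should be interrogated with `flux_variability()`; tests never
assert individual fluxes directly.

`lexicographic_optimize()` fixes the stage-1 optimum within a band of
$\pm 10^{-8}\max(1, |z^*|)$ before optimizing the secondary objective —
an exact equality constraint would occasionally be infeasible through
round-off. Because uptake is negative flux, "minimal oxygen uptake" is
obtained by *maximizing* the oxygen exchange flux at fixed maximal
chylomicron secretion.

## The synthetic study system

The package's generator is the test bed for every pipeline stage; its
defaults are the study conditions, not tuning knobs.

**Toy model** (`build_toy_model()`): five compartments (lumen, cytosol,
mitochondrion, ER, basolateral space) and ~134 reactions: SGLT1 with a
configurable Na⁺:glucose stoichiometry (default 2:1, the physiological
value; some reconstructions use 1:1, hence the parameter), apical and
basolateral GLUT2, GLUT5 fructose transport, Na⁺/K⁺-ATPase (3 Na⁺ per
ATP; the potassium counter-flux is not tracked), a lumped glycolysis
(glucose → 2 pyruvate + 2 ATP), a lumped TCA/oxidative phosphorylation
reaction with a declared P:O yield (default 2.5 ATP per oxygen atom),
glutamine uptake feeding a lumped gluconeogenesis (2 gln + 3 ATP →
glucose, carbon- and nitrogen-balanced), five transit amino acids
(casein-reduced profile including glutamine), the full species-resolved
lipid module, lumped cholesterol biosynthesis with a declared ATP cost
(default 100 ATP per cholesterol, the order of magnitude of the
acetyl-CoA + NADPH investment), lumped phospholipid and apolipoprotein
supplies, and chylomicron assembly/secretion. Every optimum is
computable by hand from these declared constants; the minimal-oxygen
test in the suite does exactly that accounting. The default model
passes `validate_model()` with no dead ends and no blocked reactions.
Pathway switches (`include_apical_glut2`, `include_gluconeogenesis`)
remove reactions at build time; scenario settings instead zero bounds,
keeping indices stable for comparisons.

**Diets** (`build_synthetic_diet()`): 10/20/30/45 en% fat at fixed
20 en% protein, carbohydrate the remainder, cholesterol-free. Energy
densities 4/4/9 kcal·g⁻¹; default intake 12 kcal·day⁻¹ (a typical adult
mouse). Fat is a palm/soy TAG blend in which the soy contribution is a
constant 3 en% floor and palm is exchanged against starch as fat rises,
so the FA profile shifts C16:0-rich at high fat. Carbohydrate is
glucose plus fructose with a fixed 10 en% sucrose contribution
providing the fructose. Protein is an 18-amino-acid casein-like
profile; sodium enters at 2.5×10⁻⁵ mol·kcal⁻¹ (≈0.25 % NaCl in feed
mass). Altogether 39 dietary nutrients — 6 FA × 3 luminal lipid forms
(TAG, and zero-intake MAG/FFA entries that matter for rescue scans),
2 hexoses, 18 amino acids, Na⁺. The toy model carries exchanges for a
5-amino-acid subset; diet nutrients without a model exchange are
reported, never silently dropped. Generation is fully deterministic.

What the synthetic system does *not* emulate: enzyme capacities or
saturation kinetics (all internal bounds are ±1000), biliary and
pancreatic secretions (notably their Na⁺ and cholesterol), basolateral
nutrient uptake from circulation, and the exact supplementary diet
table values. Passing tests therefore demonstrate the wiring and the
qualitative diet-response logic, not quantitative agreement with the
full published reconstruction; the quantitative anchors that are
desk-checkable (dry-mass arithmetic, conversion factor, lipid expansion
counts) are asserted exactly.

## Scenarios

* **Glucose transport**: maximal apical absorption is the negated
  minimal luminal exchange flux; maximal basolateral secretion the
  maximal basolateral exchange flux; both for glucose and fructose,
  with apical GLUT2 active or zeroed. With 2:1 SGLT1 alone, absorption
  is pinned at half the luminal Na⁺ supply.
* **Sodium titration**: the absorption optimum as a function of the
  luminal Na⁺ bound — piecewise linear with slope 1/(Na:glc
  stoichiometry) up to a plateau at total luminal glucose, flat when
  apical GLUT2 is present. The minimal Na⁺ reaching 99.9 % of the
  plateau is refined by bisection and compared with the dietary Na⁺
  supply (the >10× ratio; biliary/pancreatic Na⁺ is deliberately out of
  scope of the denominator).
* **Gluconeogenesis**: surplus = max secretion − max absorption; a
  positive surplus indicates de novo glucose synthesis. Exhaustive
  single-nutrient ablation over the amino-acid exchanges traces it (to
  glutamine in the toy). The surplus is larger with apical GLUT2
  because absorption via SGLT1 burns glucose to pump Na⁺.
* **Chylomicron/oxygen**: the study diets are cholesterol-free, so with
  no cholesterol source secretion is zero. A luminal source (absorbed
  biliary cholesterol) is modelled as an openable intracellular supply;
  endogenous biosynthesis as an openable lumped pathway plus
  basolateral O₂ uptake. The two-stage LP reports the minimal O₂
  compatible with maximal secretion, converted back to
  moles·mouse⁻¹·day⁻¹ by dividing by $A$; it increases monotonically
  with dietary fat.

## Knockout classification and rescue

`screen_knockouts()` zeroes each non-exchange reaction's bounds in turn
(reaction-level deletion; gene-rule-aware deletion is available through
`evaluate_gene_rule()` but the canonical screen is reaction-level) and
re-optimizes the task. Classes: Type II if the task drops below
10⁻⁶ × baseline (complete blockage), Type I if the reduction is ≤5 %,
Type III otherwise — the 5 % boundary is applied strictly ("greater
than"), and exchange reactions are excluded by default since deleting a
diet input is a diet change, not an enzymopathy.

`dietary_rescue()` scans, for a Type III record, each macronutrient
class scaled by {1.5, 2, 5, 10}. Nutrients of the scanned class that
the diet supplies at zero (pre-hydrolyzed FFA/MAG) are granted the
class's mean non-zero intake before scaling — otherwise a multiplicative
grid could never switch them on, and "feed the pre-hydrolyzed form"
(the natural rescue for a luminal lipase defect) would be unreachable.
The reported `recovered_fraction` is task-after/baseline and may exceed
1 when the modification also raises the un-knocked-out capacity; the
record's class is never rewritten.

## Numerical and design choices

* Default bounds ±1000 mmol·gdw⁻¹·h⁻¹ (the COBRA convention) stand in
  for "unconstrained".
* Blocked-reaction validation opens all exchange bounds to ±1000 and
  maximizes |flux| per reaction; dead ends are detected from the
  directionality pattern. "No holes" = both lists empty.
* Degenerate inputs: empty models produce 0×0 matrices; empty titration
  grids produce empty curves; a zero-baseline task refuses to screen
  rather than classifying against 0.
* Ties in the simplex are broken by Dantzig pricing until degeneracy
  persists, then by smallest index (Bland), which cannot cycle.
* SBML I/O targets Level 3 + FBC v2 (compartments, species with
  formulas, flux-bound parameters, gene-product associations, the
  active objective); the TSV dialect is a flat reaction table with an
  equation grammar. Both round-trip exactly in the test suite. COBRA
  `.mat` structures are not read in this build — convert to SBML or TSV
  first.

## Problem sizes

The bundled analyses run at deliberately modest scale: the toy model
has ~134 reactions (two-species variants ~79 for the screens in the
test suite), the oracle-checked fixtures at most 10 reactions, and the
full 4-diet scenario sweep plus both knockout screens completes in
about a minute. These sizes were chosen so that every optimum remains
hand-checkable; the pipeline itself is size-agnostic and reads
full-scale reconstructions through the same interfaces.

## Known limitations

No thermodynamic (ΔG) constraints, no gap filling, no flux sampling or
parsimonious FBA, no VLDL assembly, no enantiomer-resolved MAG/DAG, no
phospholipid species resolution, and no time-course (postprandial vs
fasting) dynamics. The knockout screen is single-deletion only. The
full-model integration tests run only when a locally converted copy of
the published murine enterocyte reconstruction is supplied; class
counts there may shift by ±1 under alternate optima across solvers.
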