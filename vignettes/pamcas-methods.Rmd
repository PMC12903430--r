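---
title: "Dendrimer construction calculus, nanofiltration modelling and solution properties with pamcas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendrimer construction calculus, nanofiltration modelling and solution properties with pamcas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamcas)
```

`pamcas` models the design space of modular poly(amide-carbosilane)
(PAMCAS) dendrimers: macromolecules grown from a tetravalent
tetraallylsilane core by alternating two reactions, an amide coupling
that attaches a branched carboxylic-acid building block to every
ammonium end group, and a radical thiol--ene addition that caps every
terminal allyl with cysteamine hydrochloride.  Because two
interchangeable branch modules exist -- AB3 with three allyl end groups
and AB6 with six -- each generation multiplies the number of distinct
structures by two: the grammar, not the chemistry, becomes the object
of study.  The package implements that grammar, the
constant-transmission model of the organic solvent nanofiltration (OSN)
used to purify each intermediate, and the solution-property descriptors
used to characterise the products.

## The construction grammar

A `building_block` carries an elemental composition, a branch
multiplicity (end groups produced per attachment) and a *coupling
delta*, the small molecule lost when the block is attached.  A
`dendrimer_spec` is a core, an ordered layer sequence (innermost first)
and a terminal form: `A` for an allyl periphery, `N` for the ammonium
hydrochloride one.

```{r grammar}
sp <- parse_dendrimer_name("G2-3-6-N")
sp
dendrimer_table(sp)
```

The peripheral-group (PG) count is the branching calculus
$N_\mathrm{PG} = m_\mathrm{core} \prod_i m_i$: four 6-fold layers never
occur, but three do, and the all-AB6 third generation reaches
$4 \times 6^3 = 864$ end groups while the all-AB3 one has 108.  With
$k$ interchangeable blocks there are $k^n$ sequences per generation
$n$; for $k = 2$ the number of sequences sharing a PG count follows the
binomial coefficients of Pascal's triangle:

```{r pascal}
pg_class_histogram(3)
sum(sapply(1:3, function(g) length(enumerate_sequences(g))))  # 14 analogs
```

### Mass bookkeeping conventions

Compositions use IUPAC standard atomic weights (abridged to the
precision chemists print: C 12.011, H 1.008, O 15.999, Si 28.085,
S 32.06, Cl 35.45, N 14.007) and exact principal-isotope masses for
monoisotopic values.  Three conventions matter, and all are fixed by
the printed masses they must reproduce:

* **Block formulas.**  The registry ships AB3 = C19H26O3Si (330 g/mol)
  and AB6 = C31H46O4Si2 (539 g/mol), reconstructed from the described
  structures (a para- respectively 3,5-bis-alkoxybenzoic acid carrying
  one or two triallylsilylpropyl wedges).
* **Hydrochloride salts.**  Every terminal amine is modelled as
  NH~3~^+^Cl^--^, and the amide coupling onto such an end group removes
  H~2~O + HCl per bond.  This convention -- and only this one --
  reproduces the 17,107 g/mol theoretical mass of G2-3-6-N (the package
  computes 17,106.4, inside the $\pm 1$ g/mol band we allow against
  integer-printed masses).
* **Atom-economic capping.**  The thiol--ene addition loses nothing,
  so `mass(N form) - mass(A form) = N_PG * 113.603` g/mol identically;
  113.60 is also the spacing of the missing-cap defect mass ladder.

One known tension is documented rather than forced: the printed MW
ratio of the G1-6-A dendrimer to its AB6 module is 4.9:1, while the
reconstructed compositions give 4.80; the companion 3.9:1 ratio
(G1-3-A against the benzotriazolyl-activated AB3 ester) is reproduced
exactly.

### Defects and mass ladders

Sub-percent defectiveness is read off mass spectra as a ladder of
species below the perfect mass.  `defect_ladder()` generates that
forward model (one missing cap per rung); `defect_variant()`
additionally removes whole branch subtrees, with the parent site kept
as an intact ammonium chloride -- which is why the removed composition
credits the coupling delta back.  Mixed defects compose additively.
Adducts (Na^+^, matrix) are out of scope.

```{r ladder}
defect_ladder(parse_dendrimer_name("G1-6-N"), 3)[, c(1, 3)]
```

### Structure export

`smiles()` assembles a single-line encoding from per-block templates
whose `{*}` markers are filled with allyl termini, ammonium caps, or
the next layer's acyl fragment; chloride counter-ions are appended as
dot components because dots are illegal inside branches.  Ring-closure
digits are reused by nesting depth (only ancestor rings are
simultaneously open), keeping even the 172-ring G3-6-6-6 structure
within single-digit labels.  `smiles_atom_counts()` is a deliberately
independent audit: a minimal reader for the emitted dialect that fills
implicit hydrogens to standard valences, so every exported structure
can be checked atom-for-atom against `elemental_composition()`.

## The nanofiltration model

OSN purification is modelled with a single parameter per solute, the
transmission $r = c_f / c_r$ (filtrate over retentate concentration).
Treating $r$ as constant during dead-end concentration gives the
instantaneous mass balance $\mathrm{d}m/\mathrm{d}V = r\,m/V$, hence
$m \propto V^r$: one cycle concentrating to a fraction $f$ of the
volume retains $f^r$.  The package states this closed form and the
tests verify it against a 10^4^-step numerical integration of the mass
balance (relative agreement better than 10^--6^).

* `simulate_batch()` iterates cycles with optional redilution;
  species are independent and mass is conserved to 10^--9^ relative.
* `cycles_to_purity()` inverts the closed form,
  $n = \lceil \ln t / (r \ln f) \rceil$.  With the mean transmission
  0.17 measured for the AB3 module and $f = 0.1$, reaching 1% residual
  impurity takes 12 cycles -- the model's account of why real
  purifications need 4--20 cycles.
* `simulate_continuous()` implements constant-volume diafiltration,
  $m = m_0 e^{-r V_f / V_r}$.  Batch and continuous agree in the
  fine-cycle limit ($f = 0.99$, matched permeate volume, deviation
  below 1%).  Continuous operation saves solvent *because* it runs at
  the minimal retentate volume ($V_r \approx f V_0$); at equal working
  volume, batch cycling at $f = 0.1$ would be the more
  solvent-efficient mode per unit permeate.
* `estimate_transmission()` inverts the model on measured per-cycle
  series, $r_i = \ln(m_i/m_{i-1}) / \ln f$, reporting the unweighted
  per-cycle mean by default (it is unclear in general whether reported
  mean transmissions are cycle- or mass-weighted, so both are
  returned).
* `simulate_transmission_test()` reproduces the stirred-cell protocol
  (5 mg/mL, 9 mL, 2.7 mL lead filtrate discarded, sample, redilute).
  The 0.25 mL filtrate sample is treated as instantaneous and taken at
  the same moment as the retentate sample, making the sampled ratio
  return $r$ exactly; a window-averaged sample would bias it low by
  about 2% at $r = 0.1$.

Transmission values themselves are solvent- and membrane-dependent
inputs (0.02--0.30 across the DCM/methanol range on 1--3 kDa
membranes); the package deliberately contains no physical model
predicting $r$ from membrane cutoff or solvent composition, and no
flux, fouling or osmotic-pressure physics.  `r > 1` warns (conceivable
under concentration polarisation) but does not error.

## Solution properties

`radius_of_gyration()` is the mass-weighted root-mean-square distance
from the centre of mass; `r_max()` is the maximal distance from the
*unweighted* centre of geometry.  The differing centres are
intentional: they mirror how the two descriptors are conventionally
defined for simulation snapshots, and the package preserves that
asymmetry rather than silently harmonising it.

The shape factor $\rho = R_g / R_h$ compares a theoretical $R_g$
against an experimental hydrodynamic radius; the hard-sphere reference
is $\sqrt{3/5} \approx 0.775$, which the uniform-ball generator
reproduces by Monte Carlo.  Because the two inputs typically come from
different sources (simulation vs light scattering with its solvation
envelope), $\rho$ carries a classification label, not a correction.

`stokes_einstein()` converts between $D$ and $R_h$ via
$D = k_B T / (6 \pi \eta R_h)$ with the exact SI Boltzmann constant;
temperature and viscosity are required arguments because they are
properties of the experiment, not defaults of the model.
`scaling_exponent()` fits $\log D$ against $\log N$ (natural logs,
unweighted OLS -- no weighting scheme is assumed) and returns the
slope with its standard error; homolayered AB3- and AB6-type series
generated with exponents around $-0.29$ and $-0.22$ are recovered
exactly at zero noise and within 0.03 at 2% noise on three points.

`mn_mw_dispersity()` computes $M_n = \sum n_i M_i / \sum n_i$,
$M_w = \sum n_i M_i^2 / \sum n_i M_i$ and $Đ = M_w / M_n \ge 1$.  For
a binomial missing-cap ensemble the dispersity has the closed form
$Đ = 1 + m_c^2 N p (1-p) / M_n^2$; at $p = 0.01$ on 144 end groups
this is below 1.0001 -- defect levels that dominate a mass spectrum
are invisible to dispersity.

## Synthetic data

Every analysis stage has a seeded generator with known ground truth:
geometric filtration decay (`gen_filtration_series`), power-law
diffusion series (`gen_diffusion_series`), uniform-ball point clouds
(`gen_sphere_cloud`, radial-CDF method: direction from a normalised
Gaussian triple, radius $R U^{1/3}$), and binomial defect ensembles
(`gen_defect_ensemble`).  Noise is multiplicative log-normal
throughout (all modelled quantities are positive), with
$\sigma = 0.05$ as the default for concentration-grade data and 0.02
for diffusion data; $\sigma = 0$ reduces every generator to its closed
form.  One seed argument fans out into independent substreams per
generator, reruns are bit-identical, and the caller's RNG state is
restored.

What the generators emulate -- and what they do not: they produce the
*statistical* structure of filtration, diffusion and defect data under
the package's own models.  Passing the recovery tests therefore shows
the estimators invert those models correctly at realistic noise; it
does not validate the constant-transmission assumption itself against
instrument data, nor solvent-dependent transmission drift,
concentration-dependent viscosity effects, or aggregation, none of
which the generators simulate.

## Numerical choices and problem sizes

Masses are computed in double precision and compared to printed
integer masses within $\pm 1$ g/mol (the weight table behind printed
values is never stated, and abridged-weight conventions differ in the
third decimal).  Cycle planning guards its ceiling against
floating-point overshoot by $10^{-9}$ and never returns fewer than one
cycle.  Enumeration order is lexicographic by layer-name tuple.  The
test suite uses 10^5^ points for the Monte-Carlo ball (relative
standard error of $R_g$ about $7 \times 10^{-4}$), 200 cycles for the
fine-cycle limit, 2$\times$10^4^ molecules for defect ensembles and
10-cycle filtration series -- sizes chosen so each law is tested well
inside its sampling error while the whole suite runs in seconds.

## Limitations

The grammar assumes complete, defect-free coupling except where
defects are modelled explicitly; it does not model reaction
feasibility, sterics, isotope patterns, 3-D structure, or adduct
formation.  The OSN model is a single-parameter idealisation: no
membrane physics, no prediction of transmission.  Solution-property
routines consume point clouds and tabulated series; generating
conformers is out of scope.
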