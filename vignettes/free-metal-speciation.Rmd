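---
title: "Methods: free metal speciation in chelator buffers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free metal speciation in chelator buffers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chelation)
```

## The problem and the model

A chelator buffer contains metals (Ca²⁺, Mg²⁺, ...) and polyprotic ligands
(EGTA, EDTA, ATP, ...) that compete for the metals with the protons in
solution.  At equilibrium every 1:1 complex obeys a mass-action law, and the
package reduces the full proton-metal-ligand network to one *apparent*
association constant per metal-ligand pair at the stated conditions, then
solves the remaining metal-ligand mass balances.

For a ligand with stepwise protonation association constants
$K_{H1} > K_{H2} > \dots$ (step 1 puts the first proton on the fully
deprotonated form), the fraction of *unbound* ligand that is fully
deprotonated is

$$\alpha = \frac{1}{1 + \sum_{i} \left(\prod_{j\le i} K_{Hj}\right) [H^+]^i},$$

and, writing $\beta_p$ for the corrected cumulative formation constant of
the complex carrying $p$ protons (from free metal plus fully deprotonated
ligand), the apparent constant between free metal and *all* unbound ligand
forms is

$$K_{app} = \alpha \sum_p \beta_p\,[H^+]^p .$$

The solved system, for ligand totals $L_{T,j}$ (after purity correction)
and metal totals $M_{T,m}$, is

$$L_{T,j} = L_j\Big(1 + \sum_m K_{app}(m,j)\,M_m\Big), \qquad
  M_{T,m} = M_m\Big(1 + \sum_j K_{app}(m,j)\,L_j\Big),$$

whose positive solution is unique (each residual is strictly increasing in
its own unknown).  "Free ligand" $L_j$ in the output therefore means *all
non-metal-bound forms*, protonated ones included.

Assumptions inherited from this calculator lineage: only 1:1:p
metal-ligand-proton species (no ternary or polynuclear complexes), activity
corrections applied to the constants rather than to the reported free
concentrations, temperature-independent reaction enthalpies (no ΔCp), and
pH read as −log₁₀ of the proton *concentration* — no electrode/activity
conversion is applied, so users with activity-calibrated meters should
pre-correct.

## Corrections and their conventions

**Temperature.**  Integrated van't Hoff with constant ΔH (kJ/mol,
association reaction, exothermic negative):
$\log K(T_2) = \log K(T_1) - \frac{\Delta H}{\ln 10 \cdot R}
(\tfrac1{T_2} - \tfrac1{T_1})$, $R = 8.31446$ J mol⁻¹ K⁻¹, 0 °C = 273.15 K.
A missing ΔH means *no* correction — also for protonation constants; the
built-in sets carry enthalpies for the constants where the literature
reports them (notably ATP, whose constants are conventionally corrected to
20 °C this way).

**Ionic strength.**  The activity term is the extended Debye-Hückel form
used throughout this family of calculators,
$f(I,T) = A(T)\big(\sqrt I/(1+\sqrt I) - 0.25\,I\big)$, applied *per unit
z²* ($-\log_{10}\gamma = z^2 f$), with the ionic equivalence
$I_e = 0.5\sum C_i |z_i|$ used directly as $I$ (in molar) — a deliberate
lineage convention, not the textbook ionic strength.  The slope $A(T)$
comes from $1.8246\times10^6/(\varepsilon T)^{3/2}$ with the
Malmberg-Maryott polynomial for water's dielectric constant
($A \approx 0.51$ at 25 °C).  Transfer between ionic equivalences is
$\log K(I_2) = \log K(I_1) - \Delta z^2\,(f(I_2,T)-f(I_1,T))$ with
$\Delta z^2 = \sum z^2(\text{reactants}) - z^2(\text{product})$; the minus
sign makes association between oppositely charged species weaken as ionic
strength rises, as Debye-Hückel theory requires.  Note that $f$ is *not*
monotone over the whole validated range: the linear $-0.25 I$ term gives it
a maximum near $I \approx 485$ mM, so constants transferred to the extreme
top of the range move slightly the "wrong" way; this is a property of the
lineage formula itself, and tests assert monotonicity only up to 480 mM.

**Order.**  Temperature first, then ionic strength evaluated at the target
temperature.  Both corrections are additive on the log₁₀ scale, so this
order is exactly interchangeable with the reverse; the test suite asserts
the difference is below 10⁻⁶ on a grid (it is zero to rounding).

**Validation ranges.**  0–40 °C, pH 0–14, ionic equivalence (0, 500] mM,
boundaries inclusive.  These reflect where the dielectric polynomial and
the lineage conventions are trusted; out-of-range conditions are reported
as data (one violation per field), not exceptions, and every solver entry
point refuses them.

## The solver

The scheme is an alternating elimination: given metal frees, ligand frees
are closed-form; given ligand frees, each metal is updated.  The naive
update $M \leftarrow M_T/(1+\sum_j K L_j)$ is provably sublinear on stiff
near-equimolar buffers — for $KM \gg 1$ it degenerates to the harmonic map
$1/M' = 1/M + 1/M_T$ and needs thousands of iterations — so the package
updates each metal by a *partial solve*: its ligand environment is
collapsed into one effective ligand whose binding curve matches the true
bound-sum and its derivative at the current iterate, and the 1:1 quadratic
is solved in closed form (the numerically stable root, no cancellation).
For a single ligand this is exact; for several it is exact at the fixed
point, so the iteration converges to the true solution, typically in 3–30
iterations.  Three safeguards wrap it:

* geometric damping ($M \leftarrow \sqrt{M_{old} M_{new}}$, a factor-0.5
  step in log space), engaged per metal once its update direction
  oscillates, and sticky thereafter;
* Aitken Δ² extrapolation when two successive steps shrink geometrically in
  the same direction, carried out in the solver's arithmetic kernel so it
  still acts below double resolution;
* a per-metal log-space bisection fallback on the single-metal residual
  (bracket $[10^{-30} M_T,\ M_T]$) if the fixed point has not converged
  after 3000 iterations, with an overall cap of 10 000 iterations and a
  hard error carrying the last residual beyond that.

Convergence is declared when the largest relative change falls below
10⁻¹² (native doubles) or $10^{-(d+2)}$ at $d$ significant digits in
decimal mode — a fixed 10⁻¹² would make high-precision arithmetic
pointless.  The final metal mass-balance residual is recomputed and stored
in the result (`$convergence`).  Degenerate inputs short-circuit: zero
totals stay zero (and remain in the result, so report shapes are stable),
no ligands means free = total, and a mixture may legally contain only
chelators.  In free-known mode the fixed metals simply enter every ligand
denominator as constants; several metals may be fixed at once — an
extension beyond the single-metal use the lineage GUIs expose, flagged here
because the uniqueness argument covers it unchanged.

Two independent oracles check the solver: the stable closed-form quadratic
for 1:1 systems and a nested log-space bisection (ligands eliminated in
closed form, metals bracketed recursively) that shares no code with the
production path.  Cross-method agreement is asserted to 10⁻¹⁰ (1:1) and
10⁻⁸ (seeded 2×2/3×3 systems).

## Arbitrary-precision decimal arithmetic

The decimal mode exists to rule out floating-point rounding as a source of
disagreement between calculators.  Numbers are sign/exponent/limb triples
in base 10⁷, all limb arithmetic in doubles with every intermediate below
2⁵³ (which caps the supported precision at 500 significant digits; the
default decimal context carries 50).  Division and square root are Newton
iterations seeded from a double approximation with one correction step;
doubles enter *exactly* (binary mantissa times scaled powers of 2 or 5),
so a 50-digit run reproduces an mpmath-style reference to the full
requested width.  The solver runs the same code path in both modes through
a small arithmetic-kernel interface, warm-starting the decimal solve from
the double solution.  On the reference-buffer titration the two modes agree
to ~10⁻¹² relative — consistent with the lineage observation that these
calculations are not precision-limited — and the suite asserts < 10⁻⁶.

## Constant sets

Constants are data, not code: four built-in JSON files (NIST, Chelator,
SPECS, Calcium lineages) under `inst/extdata/constants/`, one schema file
documenting the conventions (stepwise association constants; step 1 = first
proton; a complex with `protons = 1` forms from M + HL; ΔH in kJ/mol,
exothermic negative).  The shipped numeric values are representative
transcriptions compiled from the critical stability-constant literature for
each lineage — adequate for method validation and for reproducing the
qualitative source-to-source differences, but users comparing against a
specific published table should load their own values via the JSON
interchange (unknown keys round-trip untouched, so community extensions are
safe).  Charges are stored exactly so that protonation constants receive
the same two corrections as metal constants.

## The synthetic generator and what passing tests mean

`make_synthetic_constant_set()` draws ML log K uniformly on [2, 11]
(ATP-weak to EGTA-strong), pK values on [1, 10] sorted into decreasing
steps, optional MHL complexes (probability 0.5, at least 2 log units weaker
than ML) and enthalpies on [−40, 25] kJ/mol — the regimes spanned by the
reference buffer's chemistry.  Mixture totals are log-uniform on
[10 µM, 10 mM].  All draws sit in a private RNG stream keyed by an integer
seed, so fixtures are reproducible and do not disturb the caller's RNG.
What the generator does *not* emulate: correlated errors between a source's
constants, ternary species, ionic-strength-dependent enthalpies, or
impurity speciation (purity is a single scale factor).  Passing the
property suite therefore demonstrates that the *solver and correction
machinery* are right, not that any shipped constant matches a particular
laboratory's measurements — for that, the constant set itself is the
degree of freedom.

## Reporting and interchange choices

Workbook export writes one long-format sheet per calculation
(entity, quantity, value, unit) plus a summary sheet (one row per
calculation and metal) — machine-readable and diff-friendly, since the
lineage only fixes "a single spreadsheet file", not a layout.  Numbers are
written with 10 significant digits by default (configurable): below solver
tolerance, above lab needs.  Exports carry no timestamps, so identical
sessions export identical bytes; the CSV export mirrors the sheets exactly.
The workbook container itself is written by the package (stored ZIP,
inline-string SpreadsheetML) and is readable by standard spreadsheet
tools.  Unit input spans M to nM; conversion divides by the exact power of
ten, so decimal literals land on their nearest double and chained
conversions drift by at most one ulp.

## Known limitations

* Results are concentrations; no activity is reported for the free ion
  itself.
* No ternary complexes, no metal-metal or ligand-ligand species, no
  kinetics.
* The dielectric polynomial and validation ranges stop at 40 °C and
  500 mM; the Debye-Hückel term's turnover near 485 mM is inherited from
  the lineage formula.
* Shipped constants are representative, not authoritative (see above).
* Purity enters as a scale factor on the chelator total; contaminating
  metals in an impure chelator lot are not modelled.
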