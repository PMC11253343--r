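# chelation

Free metal ion speciation in chelator buffers.

Experiments on calcium-regulated systems (muscle fibres, motility assays,
permeabilised cells) need buffers with a *defined free* metal-ion
concentration, but what goes into the flask is a *total* amount of metal plus
chelators — EGTA, EDTA, ATP — that bind both the metal and protons.
`chelation` computes the equilibrium partitioning: given total (or desired
free) concentrations, the working temperature, pH and ionic composition, it
returns free, bound and total concentrations for every metal and chelator,
including pX values such as pCa, in the tradition of the
SPECS/Chelator/Calcium/MaxChelator family of calculators.

## The model

Stability constants are stored as absolute stepwise association constants
(log10, molar) at reference conditions and corrected to the working
conditions in three steps:

1. **Temperature** — integrated van't Hoff relation with the stored reaction
   enthalpy ΔH (kJ/mol):
   log K(T₂) = log K(T₁) − ΔH/(ln 10 · R) · (1/T₂ − 1/T₁).
2. **Ionic strength** — extended Debye–Hückel transfer between ionic
   equivalences (Ie = 0.5·ΣCᵢ|zᵢ|, the charge-weighted sum this calculator
   lineage uses in place of the standard ionic strength):
   log K(I₂) = log K(I₁) − Δz² · (f(I₂,T) − f(I₁,T)), with
   f(I,T) = A(T)·(√I/(1+√I) − 0.25·I) and Δz² = Σz²(reactants) − z²(product).
3. **Proton competition** — the fraction of unbound ligand in the
   metal-avid, fully deprotonated form,
   α = 1/(1 + Σᵢ (Π_{j≤i} K_Hj)[H⁺]ⁱ), combines with the corrected
   formation constants into one apparent constant per pair:
   K_app = α · Σ_p β_p [H⁺]^p.

The coupled mass balances

    L_T,j = L_j (1 + Σ_m K_app(m,j) M_m)      M_T,m = M_m (1 + Σ_j K_app(m,j) L_j)

are then solved for the free concentrations by a damped, Aitken-accelerated
alternating iteration (closed-form ligand elimination, per-metal quadratic
partial solves, bisection fallback), either in native doubles or in
arbitrary-precision decimal arithmetic.

## Worked example

The classic assay buffer: 1 mM total CaCl₂ and 6 mM MgCl₂ buffered by 1 mM
EGTA (97 % assayed purity) and 2 mM ATP at 20 °C, pH 7.0, Ie 100 mM, with
the NIST-lineage constants:

```r
library(chelation)

mix <- mixture_spec(
  chelators = list(chelator_entry("EGTA", 1, "mM", purity = 97),
                   chelator_entry("ATP",  2, "mM")),
  metals    = list(metal_entry("Ca", 1, "mM"), metal_entry("Mg", 6, "mM")),
  conditions = buffer_conditions(20, 7.0, 100))

res <- speciate(mix)            # constants default to load_builtin("NIST")
res
#> Speciation at 20 degC, pH 7, Ie 100 mM (constants: NIST, arithmetic: double)
#>  metal  mode total        free     px
#>     Ca total 0.001 3.15543e-05 4.5009
#>     Mg total 0.006 4.03740e-03 2.3939
#>  ligand effective_total free_unbound
#>    EGTA         0.00097  6.61994e-06
#>     ATP         0.00200  3.23329e-05
#> converged by fixed-point in 10 iterations (residual 4.34e-16)
```

Reading: of the 1 mM total calcium, only 31.6 µM is free (pCa 4.50) — the
rest sits in Ca·EGTA (0.96 mM) and Ca·ATP (6.4 µM); ATP mostly buffers the
magnesium instead (Mg·ATP 1.96 mM, see `summary(res)`).  The `effective_total`
column shows the purity-corrected EGTA (0.97 mM).

The inverse question — how much total calcium yields pCa 6? — is one mode
flag away:

```r
mixf <- mixture_spec(mix$chelators,
  metals = list(metal_entry("Ca", 1, "uM", mode = "free"),
                metal_entry("Mg", 6, "mM")),
  conditions = buffer_conditions(20, 7.0, 100))
speciate(mixf)$metals
#>   metal  mode        total        free       px
#> 1    Ca  free 0.0007709687 0.000001000 6.000000
#> 2    Mg total 0.0060000000 0.003999837 2.397958
```

i.e. add 0.771 mM total CaCl₂.  Apparent constants themselves are one call:

```r
build_table(load_builtin("NIST"), c("Ca", "Mg"), c("EGTA", "ATP"),
            buffer_conditions(20, 7.0, 100))
#> <apparent constants from 'NIST' at 20 degC, pH 7, Ie 100 mM>
#> log10 K_app (1/M):
#>      EGTA    ATP
#> Ca 6.6633 3.7967
#> Mg 1.6947 4.1768
```

Four built-in constant sources (`NIST`, `Chelator`, `SPECS`, `Calcium`) can
be swapped freely; user constants travel as JSON
(`parse_constant_set()` / `serialize_constant_set()`, schema under
`inst/extdata/constants/`).  Because the sources genuinely differ, reported
pCa values should always name the constant set used.  Repeated calculations
accumulate in a session and export to a single workbook:

```r
sess <- append_result(new_session(), res)
export_session(sess, "buffers.xlsx")      # or format = "csv"
```

High-precision decimal arithmetic (50 significant digits by default) is a
context away — `speciate(mix, context = arithmetic_context("decimal"))` —
and agrees with the native-float path to well below reporting precision.

## Command line

A thin wrapper script is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "chelation", package = "chelation"))') \
  calc --source NIST --temp 20 --ph 7.0 --ie 100 \
  --chelator EGTA=1mM@97% --chelator ATP=2mM \
  --metal Ca=1mM:total --metal Mg=6mM:total -o out.xlsx
```

Other subcommands: `ie Na:150 Cl:-1:150` (ionic-equivalence helper),
`constants list|dump|validate`, `adjust` (apparent-constant CSV dump).
Exit codes: 0 success, 1 validation error, 2 solver non-convergence.

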