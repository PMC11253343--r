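# Conversion of absolute stability constants to apparent association
# constants at the working temperature, pH and ionic equivalence.
#
# Each stored constant is corrected for temperature first (van't Hoff, using
# the stored reaction enthalpy when present), then for ionic equivalence
# (extended Debye-Hueckel activity term evaluated at the target temperature).
# Both corrections are additive on the log10 scale, so their order does not
# affect the result.  Proton competition at the working pH then collapses all
# non-metal-bound ligand forms into a single effective association constant.

.R_GAS <- 8.31446    # molar gas constant, J/(mol K)
.KELVIN0 <- 273.15   # 0 degrees Celsius in kelvin

#' Buffer conditions
#'
#' The experimental context for all constant corrections: temperature in
#' degrees Celsius, pH (interpreted as -log10 of the free proton
#' concentration; no electrode/activity conversion is applied) and ionic
#' equivalence in mM.  Ionic equivalence is the charge-weighted sum
#' Ie = 0.5 * sum(Ci * |zi|) used by this calculator lineage in place of the
#' standard ionic strength; see [ionic_equivalence()].
#'
#' @param temperature temperature in degrees Celsius.
#' @param ph pH of the buffer.
#' @param ionic_equivalence ionic equivalence in mM.
#' @return an object of class `buffer_conditions`.
#' @examples
#' buffer_conditions(20, 7.0, 100)
#' @export
buffer_conditions <- function(temperature, ph, ionic_equivalence) {
  stopifnot(is.numeric(temperature), is.numeric(ph), is.numeric(ionic_equivalence),
            length(temperature) == 1L, length(ph) == 1L, length(ionic_equivalence) == 1L)
  structure(list(temperature = as.numeric(temperature), ph = as.numeric(ph),
                 ionic_equivalence = as.numeric(ionic_equivalence)),
            class = "buffer_conditions")
}

#' @export
print.buffer_conditions <- function(x, ...) {
  cat(sprintf("<buffer conditions: %g degC, pH %g, Ie %g mM>\n",
              x$temperature, x$ph, x$ionic_equivalence))
  invisible(x)
}

#' Validate buffer conditions
#'
#' Accepts temperatures of 0-40 degrees Celsius, pH 0-14 and ionic
#' equivalence 0-500 mM (boundaries inclusive, except that the ionic
#' equivalence must be strictly positive).  Violations are returned as data,
#' one message per field naming the offending value and the accepted range;
#' an empty character vector means the conditions are valid.
#'
#' @param conditions a [buffer_conditions()] object.
#' @return a character vector of violations (length zero when valid).
#' @examples
#' validate_conditions(buffer_conditions(20, 7, 100))   # character(0)
#' validate_conditions(buffer_conditions(41, 7, 100))   # one violation
#' @export
validate_conditions <- function(conditions) {
  stopifnot(inherits(conditions, "buffer_conditions"))
  v <- character(0)
  t <- conditions$temperature
  if (!is.finite(t) || t < 0 || t > 40)
    v <- c(v, sprintf("temperature %g degC outside the accepted range 0-40 degC", t))
  p <- conditions$ph
  if (!is.finite(p) || p < 0 || p > 14)
    v <- c(v, sprintf("ph %g outside the accepted range 0-14", p))
  ie <- conditions$ionic_equivalence
  if (!is.finite(ie) || ie <= 0 || ie > 500)
    v <- c(v, sprintf("ionic_equivalence %g mM outside the accepted range (0, 500] mM", ie))
  v
}

.assert_conditions <- function(conditions) {
  v <- validate_conditions(conditions)
  if (length(v)) stop("invalid buffer conditions: ", paste(v, collapse = "; "))
  invisible(conditions)
}

#' Temperature correction of a log10 equilibrium constant
#'
#' Applies the integrated van't Hoff relation assuming a
#' temperature-independent reaction enthalpy:
#' `log_k - delta_h / (ln(10) * R) * (1/T_target - 1/T_ref)` with
#' temperatures in kelvin.  When no enthalpy is available the constant is
#' returned unchanged.
#'
#' @param log_k association constant, log10 scale.
#' @param delta_h reaction enthalpy in kJ/mol (exothermic negative), or
#'   `NULL`/`NA` when unknown.
#' @param t_ref,t_target reference and target temperatures, degrees Celsius.
#' @return the adjusted log10 constant.
#' @export
vant_hoff_adjust <- function(log_k, delta_h, t_ref, t_target) {
  if (is.null(delta_h) || length(delta_h) == 0L || is.na(delta_h)) return(log_k)
  if (!all(is.finite(c(log_k, delta_h, t_ref, t_target))))
    stop("vant_hoff_adjust: all inputs must be finite")
  tr <- t_ref + .KELVIN0
  tt <- t_target + .KELVIN0
  log_k - (delta_h * 1000 / (log(10) * .R_GAS)) * (1 / tt - 1 / tr)
}

# Malmberg-Maryott polynomial for the static dielectric constant of water
.water_dielectric <- function(t_celsius) {
  87.740 - 0.40008 * t_celsius + 9.398e-4 * t_celsius^2 - 1.410e-6 * t_celsius^3
}

# Debye-Hueckel limiting slope A(T) in (L/mol)^1/2; about 0.51 near room temp
.dh_slope <- function(t_celsius) {
  1.8246e6 / (.water_dielectric(t_celsius) * (t_celsius + .KELVIN0))^1.5
}

#' Extended Debye-Hueckel activity term
#'
#' Evaluates `f(I, T) = A(T) * (sqrt(I)/(1 + sqrt(I)) - 0.25 * I)` with `I`
#' the ionic equivalence converted to molar, the activity-coefficient form
#' used throughout this calculator lineage (`-log10(gamma) = z^2 * f`).  The
#' slope `A(T)` is computed from the Malmberg-Maryott polynomial for the
#' static dielectric constant of water.  Note the linear `-0.25 I` term makes
#' `f` peak near 485 mM; it is increasing everywhere below that.
#'
#' @param ionic_equivalence ionic equivalence in mM (>= 0).
#' @param temperature temperature in degrees Celsius.
#' @return the dimensionless activity term (per unit z^2).
#' @export
debye_huckel_term <- function(ionic_equivalence, temperature) {
  if (!is.numeric(ionic_equivalence) || !is.finite(ionic_equivalence) ||
      ionic_equivalence < 0)
    stop("ionic_equivalence must be a finite non-negative number of mM")
  I <- ionic_equivalence / 1000
  s <- sqrt(I)
  .dh_slope(temperature) * (s / (1 + s) - 0.25 * I)
}

#' Ionic-strength correction of a log10 association constant
#'
#' Transfers a constant between ionic equivalences at a fixed temperature.
#' For an association reaction, `delta_z_sq` is the charge-square excess of
#' the reactants over the product, `sum(z_reactants^2) - z_product^2`
#' (e.g. 16 for Ca2+ + EGTA4-), and the correction is
#' `log_k - delta_z_sq * (f(Ie_target, T) - f(Ie_ref, T))` with `f` from
#' [debye_huckel_term()]: raising the ionic strength weakens the association
#' of oppositely charged species.
#'
#' @param log_k association constant, log10 scale, valid at `ie_ref`.
#' @param delta_z_sq `sum(z^2)` of the reactants minus `z^2` of the product.
#' @param ie_ref,ie_target reference and target ionic equivalence, mM.
#' @param temperature temperature in degrees Celsius.
#' @return the adjusted log10 constant.
#' @export
ionic_strength_adjust <- function(log_k, delta_z_sq, ie_ref, ie_target, temperature) {
  log_k - delta_z_sq * (debye_huckel_term(ie_target, temperature) -
                        debye_huckel_term(ie_ref, temperature))
}

# charge-square excess for the p-th protonation step of a ligand of charge zl
.dz2_protonation <- function(zl, step) {
  1 + (zl + step - 1)^2 - (zl + step)^2
}

# charge-square excess for M + HpL -> MHpL
.dz2_complex <- function(zm, zl, protons) {
  zm^2 + (zl + protons)^2 - (zm + zl + protons)^2
}

# stepwise protonation log K of a ligand corrected to the working conditions
.corrected_protonation <- function(ligand, conditions) {
  vapply(ligand$protonation, function(p) {
    lk <- vant_hoff_adjust(p$log_k, p$delta_h, ligand$ref_temperature,
                           conditions$temperature)
    ionic_strength_adjust(lk, .dz2_protonation(ligand$charge, p$step),
                          ligand$ref_ionic_equivalence,
                          conditions$ionic_equivalence,
                          conditions$temperature)
  }, numeric(1))
}

#' Fraction of unbound ligand in the fully deprotonated form
#'
#' Computes `alpha = 1 / (1 + sum_i (prod_{j<=i} K_Hj) * [H+]^i)` from the
#' stepwise protonation association constants, with `[H+] = 10^-ph`.  A
#' ligand with no protonation steps has `alpha = 1` at any pH; `alpha` is
#' nondecreasing in pH.
#'
#' @param ligand a ligand record from a `constant_set`.
#' @param ph working pH.
#' @param log_kh optional vector of condition-corrected stepwise protonation
#'   log10 constants (step 1 first); defaults to the constants stored on the
#'   ligand record, uncorrected.
#' @return the dimensionless fraction in (0, 1].
#' @export
proton_competition <- function(ligand, ph, log_kh = NULL) {
  if (is.null(log_kh))
    log_kh <- vapply(ligand$protonation, `[[`, numeric(1), "log_k")
  if (!length(log_kh)) return(1)
  cum <- cumsum(log_kh)
  i <- seq_along(cum)
  1 / (1 + sum(10^(cum - i * ph)))
}

#' Apparent association constant of a metal-ligand pair
#'
#' The single effective association constant (per molar, linear scale)
#' between the free metal ion and all non-metal-bound ligand forms at the
#' given conditions.  Every stored constant is first van't Hoff-adjusted to
#' the working temperature, then Debye-Hueckel-adjusted to the working ionic
#' equivalence; proton competition at the working pH contributes the alpha
#' fraction and any protonated complexes (e.g. CaHEGTA):
#' `K_app = alpha * sum_p beta_p * [H+]^p`, where `beta_p` is the corrected
#' cumulative formation constant of the p-fold protonated complex from free
#' metal plus fully deprotonated ligand.
#'
#' @param ligand a ligand record from a `constant_set`.
#' @param metal a metal record from the same set.
#' @param conditions a valid [buffer_conditions()] object.
#' @return `K_app` in 1/M (linear scale).
#' @export
apparent_constant <- function(ligand, metal, conditions) {
  .assert_conditions(conditions)
  cx <- Filter(function(cc) cc$metal == metal$id, ligand$complexes)
  if (!length(cx))
    stop("constant set has no complex of metal ", metal$id, " with ligand ", ligand$id)
  lkh <- .corrected_protonation(ligand, conditions)
  cum_lkh <- cumsum(lkh)
  alpha <- proton_competition(ligand, conditions$ph, lkh)
  terms <- vapply(cx, function(cc) {
    lk <- vant_hoff_adjust(cc$log_k, cc$delta_h, ligand$ref_temperature,
                           conditions$temperature)
    lk <- ionic_strength_adjust(lk, .dz2_complex(metal$charge, ligand$charge, cc$protons),
                                ligand$ref_ionic_equivalence,
                                conditions$ionic_equivalence,
                                conditions$temperature)
    # cumulative formation from M + L + p H, then weighted by [H+]^p
    p <- cc$protons
    lbeta <- lk + if (p > 0L) cum_lkh[p] else 0
    10^(lbeta - p * conditions$ph)
  }, numeric(1))
  alpha * sum(terms)
}

#' Build a table of apparent constants
#'
#' Evaluates [apparent_constant()] for every selected metal-ligand pair that
#' has constants in the set, and records the per-ligand alpha fraction.  The
#' table is tagged with its conditions; solvers refuse tables whose
#' conditions differ from the mixture's.
#'
#' @param set a `constant_set`.
#' @param metals character vector of metal ids (default: all in the set).
#' @param ligands character vector of ligand ids (default: all in the set).
#' @param conditions a valid [buffer_conditions()] object.
#' @return an object of class `apparent_table` with components `kapp` (a
#'   metals x ligands matrix in 1/M, `NA` where the set has no constants),
#'   `alpha` (named per-ligand vector) and `conditions`.
#' @examples
#' tab <- build_table(load_builtin(), c("Ca", "Mg"), c("EGTA", "ATP"),
#'                    buffer_conditions(20, 7.0, 100))
#' log10(tab$kapp)
#' @export
build_table <- function(set, metals = names(set$metals),
                        ligands = names(set$ligands), conditions) {
  stopifnot(inherits(set, "constant_set"))
  .assert_conditions(conditions)
  for (m in metals) .find_metal(set, m)
  for (l in ligands) .find_ligand(set, l)
  kapp <- matrix(NA_real_, length(metals), length(ligands),
                 dimnames = list(metals, ligands))
  alpha <- numeric(length(ligands))
  names(alpha) <- ligands
  for (lid in ligands) {
    lig <- set$ligands[[lid]]
    lkh <- .corrected_protonation(lig, conditions)
    alpha[lid] <- proton_competition(lig, conditions$ph, lkh)
    for (mid in metals) {
      has <- any(vapply(lig$complexes, function(cc) cc$metal == mid, logical(1)))
      if (has)
        kapp[mid, lid] <- apparent_constant(lig, set$metals[[mid]], conditions)
    }
  }
  structure(list(kapp = kapp, alpha = alpha, conditions = conditions,
                 source = set$source),
            class = "apparent_table")
}

#' @export
print.apparent_table <- function(x, ...) {
  cat(sprintf("<apparent constants from '%s' at %g degC, pH %g, Ie %g mM>\n",
              x$source, x$conditions$temperature, x$conditions$ph,
              x$conditions$ionic_equivalence))
  cat("log10 K_app (1/M):\n")
  print(round(log10(x$kapp), 4))
  cat("alpha (fraction fully deprotonated):\n")
  print(signif(x$alpha, 6))
  invisible(x)
}

#' @export
as.data.frame.apparent_table <- function(x, ...) {
  idx <- which(!is.na(x$kapp), arr.ind = TRUE)
  data.frame(
    metal = rownames(x$kapp)[idx[, 1]],
    ligand = colnames(x$kapp)[idx[, 2]],
    log_K_app = log10(x$kapp[idx]),
    alpha = unname(x$alpha[colnames(x$kapp)[idx[, 2]]]),
    temperature_c = x$conditions$temperature,
    ph = x$conditions$ph,
    ionic_equivalence_mm = x$conditions$ionic_equivalence,
    stringsAsFactors = FALSE
  )
}
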