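# Mixture specification: chelator and metal entries with units, purity and
# per-metal calculation mode.  All concentrations are converted to molar on
# ingestion; results are always reported in molar.

.UNIT_NAMES <- c("M", "mM", "uM", "nM")
.UNIT_DIVISORS <- c(M = 1, mM = 1e3, uM = 1e6, nM = 1e9)

#' Convert a concentration to molar
#'
#' Exact power-of-ten scaling from one of the four supported input units.
#' `"μM"` is accepted as an alias for `"uM"`.
#'
#' @param value numeric concentration value(s).
#' @param unit one of `"M"`, `"mM"`, `"uM"` (`"μM"`), `"nM"`.
#' @return the concentration in molar.
#' @examples
#' convert_unit(1, "mM")    # 1e-3
#' convert_unit(250, "nM")  # 2.5e-7
#' @export
convert_unit <- function(value, unit) {
  stopifnot(is.numeric(value))
  unit <- sub("μ", "u", unit)
  if (!is.character(unit) || length(unit) != 1L || !(unit %in% .UNIT_NAMES))
    stop("unknown unit ", deparse(unit), "; valid units are: ",
         paste(.UNIT_NAMES, collapse = ", "))
  value / .UNIT_DIVISORS[[unit]]
}

#' Chelator entry of a mixture
#'
#' @param ligand_id ligand name, matching a ligand in the constant set.
#' @param concentration nominal concentration (>= 0) in `unit`.
#' @param unit input unit, see [convert_unit()].
#' @param purity assay purity in percent, in (0, 100]; the nominal
#'   concentration is scaled by `purity/100` before solving, since impure
#'   chelator overstates the buffering capacity.
#' @return an object of class `chelator_entry`.
#' @export
chelator_entry <- function(ligand_id, concentration, unit = "M", purity = 100) {
  stopifnot(is.character(ligand_id), length(ligand_id) == 1L,
            is.numeric(concentration), length(concentration) == 1L)
  if (!is.finite(concentration) || concentration < 0)
    stop("chelator ", ligand_id, ": concentration must be >= 0")
  if (!is.numeric(purity) || length(purity) != 1L || !is.finite(purity) ||
      purity <= 0 || purity > 100)
    stop("chelator ", ligand_id, ": purity must be in (0, 100] percent")
  structure(list(ligand_id = ligand_id,
                 concentration = convert_unit(concentration, unit),
                 purity = as.numeric(purity)),
            class = "chelator_entry")
}

#' Effective chelator concentration after purity correction
#'
#' @param entry a [chelator_entry()].
#' @return the effective total concentration in molar,
#'   `nominal * purity / 100`.
#' @export
apply_purity <- function(entry) {
  stopifnot(inherits(entry, "chelator_entry"))
  if (entry$purity <= 0 || entry$purity > 100)
    stop("chelator ", entry$ligand_id, ": purity must be in (0, 100] percent")
  entry$concentration * entry$purity / 100
}

#' Metal entry of a mixture
#'
#' @param metal_id metal name, matching a metal in the constant set.
#' @param concentration concentration (>= 0) in `unit`.  In `"total"` mode
#'   this is the known total from which the free concentration is solved; in
#'   `"free"` mode it is the desired free concentration from which the
#'   required total is computed.
#' @param unit input unit, see [convert_unit()].
#' @param mode `"total"` (total known) or `"free"` (free known).
#' @return an object of class `metal_entry`.
#' @export
metal_entry <- function(metal_id, concentration, unit = "M",
                        mode = c("total", "free")) {
  stopifnot(is.character(metal_id), length(metal_id) == 1L,
            is.numeric(concentration), length(concentration) == 1L)
  mode <- match.arg(mode)
  if (!is.finite(concentration) || concentration < 0)
    stop("metal ", metal_id, ": concentration must be >= 0")
  structure(list(metal_id = metal_id,
                 concentration = convert_unit(concentration, unit),
                 mode = mode),
            class = "metal_entry")
}

#' Mixture specification
#'
#' The user's buffer recipe: chelators with purities, metals with per-metal
#' calculation mode, and the buffer conditions everything is evaluated at.
#'
#' @param chelators list of [chelator_entry()] objects.
#' @param metals list of [metal_entry()] objects.
#' @param conditions a [buffer_conditions()] object.
#' @return an object of class `mixture_spec`.
#' @examples
#' mixture_spec(
#'   chelators = list(chelator_entry("EGTA", 1, "mM", purity = 97),
#'                    chelator_entry("ATP", 2, "mM")),
#'   metals = list(metal_entry("Ca", 1, "mM"), metal_entry("Mg", 6, "mM")),
#'   conditions = buffer_conditions(20, 7.0, 100)
#' )
#' @export
mixture_spec <- function(chelators = list(), metals = list(), conditions) {
  stopifnot(inherits(conditions, "buffer_conditions"))
  if (inherits(chelators, "chelator_entry")) chelators <- list(chelators)
  if (inherits(metals, "metal_entry")) metals <- list(metals)
  stopifnot(all(vapply(chelators, inherits, logical(1), "chelator_entry")),
            all(vapply(metals, inherits, logical(1), "metal_entry")))
  if (!length(chelators) && !length(metals))
    stop("a mixture needs at least one metal or chelator")
  lids <- vapply(chelators, `[[`, character(1), "ligand_id")
  mids <- vapply(metals, `[[`, character(1), "metal_id")
  if (anyDuplicated(lids)) stop("duplicate chelator id: ",
                                paste(unique(lids[duplicated(lids)]), collapse = ", "))
  if (anyDuplicated(mids)) stop("duplicate metal id: ",
                                paste(unique(mids[duplicated(mids)]), collapse = ", "))
  names(chelators) <- lids
  names(metals) <- mids
  structure(list(chelators = chelators, metals = metals, conditions = conditions),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("<mixture:",
      paste(vapply(x$metals, function(m)
        sprintf("%s %.4g M (%s)", m$metal_id, m$concentration, m$mode),
        character(1)), collapse = ", "),
      "|",
      paste(vapply(x$chelators, function(l)
        sprintf("%s %.4g M @%g%%", l$ligand_id, l$concentration, l$purity),
        character(1)), collapse = ", "),
      ">\n")
  print(x$conditions)
  invisible(x)
}
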