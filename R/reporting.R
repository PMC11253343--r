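# Session accumulation, report configuration and export: repeated
# calculations are appended to a session and written out as one spreadsheet
# workbook (or CSV files), with per-calculation control over which
# quantities appear.

#' Ionic equivalence of a solution
#'
#' `Ie = 0.5 * sum(C_i * |z_i|)` — the charge-weighted concentration sum
#' used by this calculator lineage in place of the standard ionic strength
#' (which would square the charges).
#'
#' @param concentration ion concentrations in mM (nonnegative).
#' @param charge integer ion charges (nonzero), recycled against
#'   `concentration`.
#' @return the ionic equivalence in mM.
#' @examples
#' ionic_equivalence(c(150, 150), c(1, -1))   # 150 mM NaCl -> 150
#' ionic_equivalence(c(100, 50), c(1, -2))    # K2SO4-style -> 100
#' @export
ionic_equivalence <- function(concentration, charge) {
  if (!length(concentration)) stop("ionic_equivalence needs at least one ion")
  stopifnot(is.numeric(concentration), is.numeric(charge))
  if (any(!is.finite(concentration) | concentration < 0))
    stop("ion concentrations must be finite and >= 0")
  if (any(charge == 0 | charge != round(charge)))
    stop("ion charges must be nonzero integers")
  0.5 * sum(concentration * abs(charge))
}

#' Report configuration
#'
#' Controls which quantities of a calculation appear in exported reports,
#' mirroring per-parameter checkboxes: the buffer conditions, the apparent
#' constants, the alpha fractions, the bound-species concentrations and the
#' pX values, plus an optional restriction to selected metals/ligands.  Free
#' and total metal concentrations are always reported.
#'
#' @param conditions,kapp,alpha,bound,px logical include flags.
#' @param metals,ligands optional character vectors restricting the report
#'   to these ids (`NULL` = all).
#' @return an object of class `report_config`.
#' @export
report_config <- function(conditions = TRUE, kapp = TRUE, alpha = TRUE,
                          bound = TRUE, px = TRUE,
                          metals = NULL, ligands = NULL) {
  flags <- c(conditions = conditions, kapp = kapp, alpha = alpha,
             bound = bound, px = px)
  stopifnot(is.logical(flags), !anyNA(flags))
  structure(list(conditions = conditions, kapp = kapp, alpha = alpha,
                 bound = bound, px = px, metals = metals, ligands = ligands),
            class = "report_config")
}

#' Start an empty calculation session
#'
#' A session is an append-only, ordered collection of speciation results
#' with their report configurations, mirroring how repeated calculations
#' accumulate before a single download.
#'
#' @return an object of class `chelation_session` of length 0.
#' @seealso [append_result()], [export_session()]
#' @export
new_session <- function() {
  structure(list(records = list()), class = "chelation_session")
}

#' Append a calculation to a session
#'
#' Returns a longer session; earlier records are never modified.
#'
#' @param session a [new_session()] object.
#' @param result a `speciation` result from [speciate()].
#' @param config a [report_config()] for this calculation.
#' @param timestamp record timestamp (kept in the session, excluded from
#'   exports so identical sessions export identical bytes).
#' @return the extended session.
#' @export
append_result <- function(session, result, config = report_config(),
                          timestamp = Sys.time()) {
  stopifnot(inherits(session, "chelation_session"),
            inherits(result, "speciation"),
            inherits(config, "report_config"))
  session$records <- c(session$records,
                       list(list(result = result, config = config,
                                 source = result$source,
                                 timestamp = timestamp)))
  session
}

#' @export
length.chelation_session <- function(x) length(x$records)

#' @export
print.chelation_session <- function(x, ...) {
  cat(sprintf("<session of %d calculation(s)>\n", length(x$records)))
  invisible(x)
}

.fmt_val <- function(x, digits) {
  ifelse(is.na(x), NA_character_, sprintf("%.*g", digits, x))
}

# long-format sheet for one calculation, honouring its report config
.calc_sheet <- function(record, digits) {
  res <- record$result
  cfg <- record$config
  keep_m <- if (is.null(cfg$metals)) res$metals$metal else
    intersect(res$metals$metal, cfg$metals)
  keep_l <- if (is.null(cfg$ligands)) res$ligands$ligand else
    intersect(res$ligands$ligand, cfg$ligands)
  rows <- list()
  add <- function(entity, quantity, value, unit)
    rows[[length(rows) + 1L]] <<- data.frame(
      entity = entity, quantity = quantity, value = value, unit = unit,
      stringsAsFactors = FALSE)
  add("calculation", "constant_source", record$source, "")
  if (cfg$conditions) {
    cond <- res$conditions
    add("conditions", "temperature", .fmt_val(cond$temperature, digits), "degC")
    add("conditions", "ph", .fmt_val(cond$ph, digits), "")
    add("conditions", "ionic_equivalence", .fmt_val(cond$ionic_equivalence, digits), "mM")
  }
  m <- res$metals[res$metals$metal %in% keep_m, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    add(m$metal[i], "total", .fmt_val(m$total[i], digits), "M")
    add(m$metal[i], "free", .fmt_val(m$free[i], digits), "M")
    if (cfg$px) add(m$metal[i], "pX", .fmt_val(m$px[i], digits), "")
  }
  l <- res$ligands[res$ligands$ligand %in% keep_l, , drop = FALSE]
  for (i in seq_len(nrow(l))) {
    add(l$ligand[i], "effective_total", .fmt_val(l$effective_total[i], digits), "M")
    add(l$ligand[i], "free_unbound", .fmt_val(l$free_unbound[i], digits), "M")
    if (cfg$alpha)
      add(l$ligand[i], "alpha", .fmt_val(res$table$alpha[[l$ligand[i]]], digits), "")
  }
  if (cfg$bound && length(keep_m) && length(keep_l)) {
    for (mi in keep_m) for (lj in keep_l) {
      if (!is.na(res$table$kapp[mi, lj]))
        add(paste0(mi, "-", lj), "bound", .fmt_val(res$bound[mi, lj], digits), "M")
    }
  }
  if (cfg$kapp && length(keep_m) && length(keep_l)) {
    for (mi in keep_m) for (lj in keep_l) {
      k <- res$table$kapp[mi, lj]
      if (!is.na(k)) add(paste0(mi, "-", lj), "log10_K_app",
                         .fmt_val(log10(k), digits), "")
    }
  }
  do.call(rbind, rows)
}

.summary_sheet <- function(session, digits) {
  rows <- list()
  for (i in seq_along(session$records)) {
    rec <- session$records[[i]]
    res <- rec$result
    for (j in seq_len(nrow(res$metals))) {
      rows[[length(rows) + 1L]] <- data.frame(
        calc = as.character(i), source = rec$source,
        temperature_c = .fmt_val(res$conditions$temperature, digits),
        ph = .fmt_val(res$conditions$ph, digits),
        ionic_equivalence_mm = .fmt_val(res$conditions$ionic_equivalence, digits),
        metal = res$metals$metal[j],
        free_M = .fmt_val(res$metals$free[j], digits),
        pX = .fmt_val(res$metals$px[j], digits),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export a session as a workbook or CSV files
#'
#' Writes one worksheet per calculation (`calc_1`, `calc_2`, ...) in
#' long format (entity, quantity, value, unit), honouring each record's
#' [report_config()], plus a `summary` sheet with one row per calculation
#' and metal.  With `format = "csv"` the same tables are written as
#' `<path>_summary.csv`, `<path>_calc_N.csv` (UTF-8, comma-delimited).
#' Exports contain no timestamps, so equal sessions export equal bytes.
#'
#' @param session a nonempty session.
#' @param path output path (the `.xlsx` file, or the prefix for CSV files).
#' @param format `"xlsx"` or `"csv"`.
#' @param digits significant digits for exported numbers (default 10, below
#'   solver tolerance and above typical lab needs).
#' @return the written file path(s), invisibly.
#' @export
export_session <- function(session, path, format = c("xlsx", "csv"),
                           digits = 10L) {
  stopifnot(inherits(session, "chelation_session"))
  format <- match.arg(format)
  if (!length(session$records)) stop("cannot export an empty session")
  sheets <- list(summary = .summary_sheet(session, digits))
  for (i in seq_along(session$records))
    sheets[[sprintf("calc_%d", i)]] <- .calc_sheet(session$records[[i]], digits)
  if (format == "xlsx") {
    write_workbook(sheets, path)
    return(invisible(path))
  }
  prefix <- sub("\\.csv$", "", path)
  paths <- character(0)
  for (nm in names(sheets)) {
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(sheets[[nm]], p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' JSON echo of a speciation result
#'
#' A machine-readable rendering of one result (metals, ligands, bound
#' species, convergence, conditions) for programmatic consumption.
#'
#' @param result a `speciation` object.
#' @return a length-one character string of JSON.
#' @export
speciation_json <- function(result) {
  stopifnot(inherits(result, "speciation"))
  bound <- result$bound
  bound_df <- if (length(bound)) {
    idx <- which(!is.na(bound) & bound != 0, arr.ind = TRUE)
    data.frame(metal = rownames(bound)[idx[, 1]],
               ligand = colnames(bound)[idx[, 2]],
               concentration_m = bound[idx], stringsAsFactors = FALSE)
  } else data.frame()
  doc <- list(
    source = jsonlite::unbox(result$source),
    conditions = lapply(result$conditions[c("temperature", "ph",
                                            "ionic_equivalence")],
                        jsonlite::unbox),
    arithmetic = jsonlite::unbox(result$precision),
    metals = result$metals,
    ligands = result$ligands,
    bound = bound_df,
    convergence = lapply(result$convergence, jsonlite::unbox)
  )
  as.character(jsonlite::toJSON(doc, dataframe = "rows", digits = NA,
                                na = "null", pretty = 2L))
}
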