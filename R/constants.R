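# Constant-set store: built-in stability-constant libraries, a JSON
# interchange reader/writer, and structural validation.
#
# Conventions (also recorded in inst/extdata/constants/constant-set.schema.json):
#   * all stored log K are stepwise ASSOCIATION constants, log10, molar basis,
#     at the record's reference temperature and ionic equivalence;
#   * protonation step 1 is the first proton onto the fully deprotonated
#     ligand (so step 1 carries the highest pK);
#   * a complex with protons = 1 is formed from free metal + the
#     monoprotonated ligand (M + HL <=> MHL);
#   * delta_h is the standard enthalpy of the association reaction in kJ/mol,
#     exothermic negative; absent delta_h means no temperature correction.

.BUILTIN_SOURCES <- c("NIST", "Chelator", "SPECS", "Calcium")

#' Load a built-in stability-constant set
#'
#' Four constant libraries ship with the package, following the lineage of
#' the classic free-metal calculators: `"NIST"` (critically selected
#' constants; the default), `"Chelator"` (the Schoenmakers-style set),
#' `"SPECS"` (the Fabiato-style set) and `"Calcium"` (the Foehr-style set).
#' Each contains at least Ca and Mg as metals and EGTA, EDTA and ATP as
#' ligands, with protonation constants, metal complexes and reaction
#' enthalpies at 20 degrees C and 100 mM ionic equivalence.
#'
#' The shipped numeric values are representative transcriptions compiled from
#' the critical stability-constant literature for each lineage; they are
#' replaceable data, not an authoritative copy of any single table (see each
#' set's `citation` field).
#'
#' @param source_name one of `"NIST"`, `"Chelator"`, `"SPECS"`, `"Calcium"`.
#' @return a validated object of class `constant_set`.
#' @examples
#' nist <- load_builtin()
#' names(nist$ligands)
#' @export
load_builtin <- function(source_name = "NIST") {
  if (!is.character(source_name) || length(source_name) != 1L ||
      !(source_name %in% .BUILTIN_SOURCES)) {
    stop("unknown constant source ", deparse(source_name),
         "; valid sources are: ", paste(.BUILTIN_SOURCES, collapse = ", "))
  }
  path <- system.file("extdata", "constants",
                      paste0(tolower(source_name), ".json"),
                      package = "chelation", mustWork = TRUE)
  set <- parse_constant_set(paste(readLines(path, warn = FALSE), collapse = "\n"))
  issues <- validate_constant_set(set)
  if (length(issues))
    stop("built-in constant set ", source_name, " failed validation: ",
         paste(issues, collapse = "; "))
  set
}

.known_keys <- list(
  top = c("source", "citation", "metals", "ligands"),
  metal = c("id", "charge"),
  ligand = c("id", "charge", "ref_temperature_c", "ref_ionic_equivalence_mm",
             "protonation", "complexes"),
  prot = c("step", "log_k", "delta_h_kj_mol"),
  cmplx = c("metal", "protons", "log_k", "delta_h_kj_mol")
)

.extra_of <- function(node, known) {
  ex <- node[setdiff(names(node), known)]
  if (length(ex)) ex[order(names(ex))] else NULL
}

.req <- function(node, key, where) {
  if (is.null(node[[key]]))
    stop("constant-set document: required field '", key, "' missing in ", where)
  node[[key]]
}

.num1 <- function(x, key, where) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("constant-set document: field '", key, "' in ", where,
         " must be a single finite number")
  as.numeric(x)
}

#' Parse a constant-set JSON document
#'
#' Reads the JSON interchange format described in
#' `system.file("extdata", "constants", "constant-set.schema.json",
#' package = "chelation")`.  Unknown keys are preserved and round-trip
#' through [serialize_constant_set()], but are ignored by all computation.
#' Structural problems (missing required fields, wrong types) raise errors;
#' semantic invariants are checked separately by [validate_constant_set()].
#'
#' @param document a length-one character string of JSON text, or the path of
#'   a file containing it.
#' @return an object of class `constant_set`.
#' @export
parse_constant_set <- function(document) {
  stopifnot(is.character(document), length(document) == 1L)
  if (!grepl("[{\\[]", document) && file.exists(document))
    document <- paste(readLines(document, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  if (!is.list(doc)) stop("constant-set document: top level must be an object")

  src <- doc[["source"]]
  if (is.null(src)) src <- "custom"
  metals_doc <- .req(doc, "metals", "top level")
  ligands_doc <- .req(doc, "ligands", "top level")

  metals <- lapply(metals_doc, function(m) {
    id <- as.character(.req(m, "id", "a metal record"))
    structure(list(id = id,
                   charge = .num1(.req(m, "charge", paste0("metal ", id)),
                                  "charge", paste0("metal ", id)),
                   extra = .extra_of(m, .known_keys$metal)),
              class = "metal_record")
  })
  names(metals) <- vapply(metals, `[[`, character(1), "id")

  ligands <- lapply(ligands_doc, function(l) {
    id <- as.character(.req(l, "id", "a ligand record"))
    where <- paste0("ligand ", id)
    prot <- lapply(l[["protonation"]] %||% list(), function(p) {
      list(step = as.integer(.num1(.req(p, "step", where), "step", where)),
           log_k = .num1(.req(p, "log_k", where), "log_k", where),
           delta_h = if (is.null(p[["delta_h_kj_mol"]])) NULL
                     else .num1(p[["delta_h_kj_mol"]], "delta_h_kj_mol", where),
           extra = .extra_of(p, .known_keys$prot))
    })
    cmplx <- lapply(l[["complexes"]] %||% list(), function(cc) {
      list(metal = as.character(.req(cc, "metal", where)),
           protons = as.integer(.num1(.req(cc, "protons", where), "protons", where)),
           log_k = .num1(.req(cc, "log_k", where), "log_k", where),
           delta_h = if (is.null(cc[["delta_h_kj_mol"]])) NULL
                     else .num1(cc[["delta_h_kj_mol"]], "delta_h_kj_mol", where),
           extra = .extra_of(cc, .known_keys$cmplx))
    })
    structure(list(
      id = id,
      charge = .num1(.req(l, "charge", where), "charge", where),
      ref_temperature = .num1(.req(l, "ref_temperature_c", where),
                              "ref_temperature_c", where),
      ref_ionic_equivalence = .num1(.req(l, "ref_ionic_equivalence_mm", where),
                                    "ref_ionic_equivalence_mm", where),
      protonation = prot,
      complexes = cmplx,
      extra = .extra_of(l, .known_keys$ligand)
    ), class = "ligand_record")
  })
  names(ligands) <- vapply(ligands, `[[`, character(1), "id")

  structure(list(
    source = as.character(src),
    citation = as.character(doc[["citation"]] %||% ""),
    metals = metals,
    ligands = ligands,
    extra = .extra_of(doc, .known_keys$top)
  ), class = "constant_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a constant set to canonical JSON
#'
#' Emits the JSON interchange format with keys in a fixed, deterministic
#' order, so serializing the same set twice yields byte-identical text and
#' `parse_constant_set(serialize_constant_set(x))` reproduces `x`.
#'
#' @param set a `constant_set`.
#' @return a length-one character string of pretty-printed JSON.
#' @export
serialize_constant_set <- function(set) {
  stopifnot(inherits(set, "constant_set"))
  unbox_deep <- function(x) {
    if (is.list(x)) lapply(x, unbox_deep)
    else if (is.atomic(x) && length(x) == 1L) jsonlite::unbox(x)
    else x
  }
  with_extra <- function(known, extra) {
    if (is.null(extra) || !length(extra)) known
    else c(known, unbox_deep(extra[order(names(extra))]))
  }
  doc <- with_extra(list(
    source = jsonlite::unbox(set$source),
    citation = jsonlite::unbox(set$citation),
    metals = lapply(unname(set$metals), function(m) {
      with_extra(list(id = jsonlite::unbox(m$id),
                      charge = jsonlite::unbox(m$charge)), m$extra)
    }),
    ligands = lapply(unname(set$ligands), function(l) {
      with_extra(list(
        id = jsonlite::unbox(l$id),
        charge = jsonlite::unbox(l$charge),
        ref_temperature_c = jsonlite::unbox(l$ref_temperature),
        ref_ionic_equivalence_mm = jsonlite::unbox(l$ref_ionic_equivalence),
        protonation = lapply(l$protonation, function(p) {
          with_extra(list(
            step = jsonlite::unbox(p$step),
            log_k = jsonlite::unbox(p$log_k),
            delta_h_kj_mol = if (is.null(p$delta_h)) NULL else jsonlite::unbox(p$delta_h)
          ), p$extra)
        }),
        complexes = lapply(l$complexes, function(cc) {
          with_extra(list(
            metal = jsonlite::unbox(cc$metal),
            protons = jsonlite::unbox(cc$protons),
            log_k = jsonlite::unbox(cc$log_k),
            delta_h_kj_mol = if (is.null(cc$delta_h)) NULL else jsonlite::unbox(cc$delta_h)
          ), cc$extra)
        })
      ), l$extra)
    })
  ), set$extra)
  as.character(jsonlite::toJSON(doc, pretty = 2L, digits = NA, null = "null",
                                auto_unbox = FALSE))
}

#' Validate the semantic invariants of a constant set
#'
#' Checks uniqueness of identifiers, metal charge in 1..3, consecutive
#' protonation steps starting at 1, finite constants, resolvable metal
#' references, and complex proton counts not exceeding the ligand's
#' protonation capacity.  Issues are returned as data, one human-readable
#' message per problem, naming the offending record and field; an empty
#' character vector means the set is valid.
#'
#' @param set a `constant_set`.
#' @return a character vector of issues (length zero when valid).
#' @export
validate_constant_set <- function(set) {
  issues <- character(0)
  add <- function(...) issues <<- c(issues, paste0(...))
  if (!inherits(set, "constant_set")) return("not a constant_set object")

  mids <- vapply(set$metals, `[[`, character(1), "id")
  lids <- vapply(set$ligands, `[[`, character(1), "id")
  if (!length(set$metals)) add("set ", set$source, ": field metals is empty")
  if (!length(set$ligands)) add("set ", set$source, ": field ligands is empty")
  if (anyDuplicated(mids))
    add("metal id not unique: ", paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(lids))
    add("ligand id not unique: ", paste(unique(lids[duplicated(lids)]), collapse = ", "))

  for (m in set$metals) {
    if (!(m$charge %in% 1:3))
      add("metal ", m$id, ": field charge must be 1, 2 or 3 (got ", m$charge, ")")
  }

  for (l in set$ligands) {
    w <- paste0("ligand ", l$id)
    if (l$charge != round(l$charge)) add(w, ": field charge must be an integer")
    if (!is.finite(l$ref_temperature) || !is.finite(l$ref_ionic_equivalence))
      add(w, ": reference conditions must be finite")
    if (!length(l$complexes) && !length(l$protonation))
      add(w, ": needs at least one complex or protonation step")
    steps <- vapply(l$protonation, `[[`, integer(1), "step")
    nstep <- length(steps)
    if (nstep) {
      if (!identical(sort(steps), seq_len(nstep)))
        add(w, ": protonation steps must be consecutive integers starting at 1")
      if (nstep > 4L) add(w, ": at most 4 protonation steps are supported")
      for (p in l$protonation)
        if (!is.finite(p$log_k)) add(w, " protonation step ", p$step, ": log_k not finite")
    }
    seen <- character(0)
    for (cc in l$complexes) {
      if (!(cc$metal %in% mids))
        add(w, " complex: field metal '", cc$metal, "' does not resolve to a metal record")
      if (is.na(cc$protons) || cc$protons < 0L)
        add(w, " complex with ", cc$metal, ": field protons must be >= 0")
      else if (cc$protons > nstep)
        add(w, " complex with ", cc$metal, ": protons (", cc$protons,
            ") exceeds the ligand's ", nstep, " protonation steps")
      if (!is.finite(cc$log_k))
        add(w, " complex with ", cc$metal, ": log_k not finite")
      key <- paste(cc$metal, cc$protons)
      if (key %in% seen)
        add(w, ": duplicate complex for metal ", cc$metal, " with ", cc$protons, " protons")
      seen <- c(seen, key)
    }
  }
  issues
}

#' @export
print.constant_set <- function(x, ...) {
  cat(sprintf("<constant set '%s': %d metals (%s), %d ligands (%s)>\n",
              x$source, length(x$metals), paste(names(x$metals), collapse = ", "),
              length(x$ligands), paste(names(x$ligands), collapse = ", ")))
  invisible(x)
}

.find_ligand <- function(set, ligand_id) {
  l <- set$ligands[[ligand_id]]
  if (is.null(l)) stop("unknown ligand '", ligand_id, "' in constant set ", set$source)
  l
}

.find_metal <- function(set, metal_id) {
  m <- set$metals[[metal_id]]
  if (is.null(m)) stop("unknown metal '", metal_id, "' in constant set ", set$source)
  m
}
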