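# Synthetic constant sets, random mixtures and an independent brute-force
# speciation oracle, so the whole package is testable without any external
# data.  The oracle solves the same mass-balance system as the production
# solver but by a deliberately different method (nested log-space bisection
# with inner closed-form ligand elimination) and shares no solver code.

# run `expr` under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic constant set
#'
#' Draws a validation-clean `constant_set` with uniformly distributed log K
#' values: metal-ligand association in `logk_range` (default 2-11, spanning
#' ATP-weak through EGTA-strong binding), protonation pK in `pk_range`
#' (default 1-10, sorted so step 1 carries the highest pK).  About half of
#' the complexes get a protonated MHL species and half of all constants get
#' a reaction enthalpy in -40..25 kJ/mol.  The same seed always yields an
#' identical set.
#'
#' @param n_metals,n_ligands number of metal and ligand records.
#' @param logk_range range of complex log K values (log10, association).
#' @param pk_range range of protonation pK values.
#' @param steps_range range of protonation step counts per ligand (0-4).
#' @param seed integer seed; the generator uses a private RNG stream and does
#'   not disturb the caller's.
#' @return a `constant_set` with metals `M1..Mn` and ligands `L1..Ln`.
#' @export
make_synthetic_constant_set <- function(n_metals = 2L, n_ligands = 2L,
                                        logk_range = c(2, 11),
                                        pk_range = c(1, 10),
                                        steps_range = c(2L, 4L),
                                        seed = 1L) {
  stopifnot(n_metals >= 1L, n_ligands >= 1L,
            steps_range[1] >= 0L, steps_range[2] <= 4L)
  .with_seed(seed, {
    mids <- paste0("M", seq_len(n_metals))
    lids <- paste0("L", seq_len(n_ligands))
    metals <- lapply(mids, function(id)
      structure(list(id = id, charge = as.numeric(sample(1:3, 1L)),
                     extra = NULL),
                class = "metal_record"))
    names(metals) <- mids
    ligands <- lapply(lids, function(id) {
      nstep <- sample(seq(steps_range[1], steps_range[2]), 1L)
      pks <- sort(stats::runif(nstep, pk_range[1], pk_range[2]), decreasing = TRUE)
      prot <- lapply(seq_len(nstep), function(s) {
        list(step = s, log_k = pks[s],
             delta_h = if (stats::runif(1) < 0.5) stats::runif(1, -40, 25) else NULL,
             extra = NULL)
      })
      cmplx <- list()
      for (mid in mids) {
        lk <- stats::runif(1, logk_range[1], logk_range[2])
        cmplx <- c(cmplx, list(list(
          metal = mid, protons = 0L, log_k = lk,
          delta_h = if (stats::runif(1) < 0.5) stats::runif(1, -40, 25) else NULL,
          extra = NULL)))
        if (nstep > 0L && stats::runif(1) < 0.5) {
          cmplx <- c(cmplx, list(list(
            metal = mid, protons = 1L,
            log_k = stats::runif(1, logk_range[1], max(logk_range[1], lk - 2)),
            delta_h = NULL, extra = NULL)))
        }
      }
      structure(list(id = id, charge = -4, ref_temperature = 20,
                     ref_ionic_equivalence = 100,
                     protonation = prot, complexes = cmplx, extra = NULL),
                class = "ligand_record")
    })
    names(ligands) <- lids
    structure(list(source = "custom",
                   citation = sprintf("synthetic fixture (seed %d)", seed),
                   metals = metals, ligands = ligands, extra = NULL),
              class = "constant_set")
  })
}

#' Generate a random mixture for a constant set
#'
#' Totals are drawn log-uniformly in `conc_range` (default 10 uM to 10 mM)
#' for every metal and ligand of the set; all metals are in `"total"` mode
#' and purities are 100 percent.  Deterministic under `seed`.
#'
#' @param set a `constant_set` (typically from
#'   [make_synthetic_constant_set()]).
#' @param conditions a [buffer_conditions()] object.
#' @param conc_range range of total concentrations, molar.
#' @param seed integer seed.
#' @return a [mixture_spec()].
#' @export
make_random_mixture <- function(set, conditions = buffer_conditions(20, 7, 100),
                                conc_range = c(1e-5, 1e-2), seed = 1L) {
  .with_seed(seed, {
    lr <- log10(conc_range)
    chel <- lapply(names(set$ligands), function(id)
      chelator_entry(id, 10^stats::runif(1, lr[1], lr[2])))
    met <- lapply(names(set$metals), function(id)
      metal_entry(id, 10^stats::runif(1, lr[1], lr[2])))
    mixture_spec(chel, met, conditions)
  })
}

#' Brute-force speciation oracle
#'
#' Solves the metal-chelator mass-balance system by nested log-space
#' bisection over each free-metal unknown, with the ligand frees eliminated
#' in closed form at every trial point — a method independent of the
#' production solver, intended as a test oracle for systems of up to 3
#' metals and 3 ligands.  Each metal's residual is bracketed in
#' `[total * 1e-30, total]` and bisected to below 1e-14 relative.
#'
#' @param mixture a [mixture_spec()] with all metals in `"total"` mode.
#' @param table an [build_table()] table at the mixture's conditions.
#' @return named numeric vector of free metal concentrations (molar), with
#'   the free ligand concentrations attached as attribute `"ligand_free"`.
#' @export
brute_force_speciation_oracle <- function(mixture, table) {
  stopifnot(inherits(mixture, "mixture_spec"), inherits(table, "apparent_table"))
  mids <- names(mixture$metals)
  lids <- names(mixture$chelators)
  if (length(mids) > 3L || length(lids) > 3L)
    stop("the brute-force oracle handles at most 3 metals and 3 ligands")
  if (any(vapply(mixture$metals, `[[`, character(1), "mode") != "total"))
    stop("the brute-force oracle requires all metals in 'total' mode")
  mt <- vapply(mixture$metals, `[[`, numeric(1), "concentration")
  lt <- vapply(mixture$chelators, apply_purity, numeric(1))
  K <- table$kapp[mids, lids, drop = FALSE]
  K[is.na(K)] <- 0
  nm <- length(mt)

  lfree <- function(mf) {
    if (!length(lt)) return(numeric(0))
    lt / (1 + as.vector(crossprod(K, mf)))
  }
  residual <- function(i, mf) mf[i] * (1 + sum(K[i, ] * lfree(mf))) - mt[i]

  solve_from <- function(i, mf) {
    if (i > nm) return(mf)
    if (mt[i] == 0 || !length(lt) || all(K[i, ] == 0)) {
      mf[i] <- mt[i]
      return(solve_from(i + 1L, mf))
    }
    g <- function(x) { mf[i] <- x; residual(i, solve_from(i + 1L, mf)) }
    lo <- mt[i] * 1e-30
    hi <- mt[i]
    if (g(lo) > 0 || g(hi) < 0) stop("oracle bracket failure for metal ", mids[i])
    for (b in 1:70) {
      mid <- sqrt(lo * hi)
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    mf[i] <- sqrt(lo * hi)
    solve_from(i + 1L, mf)
  }

  mf <- solve_from(1L, numeric(nm))
  names(mf) <- mids
  lf <- lfree(mf)
  if (length(lf)) names(lf) <- lids
  attr(mf, "ligand_free") <- lf
  mf
}
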