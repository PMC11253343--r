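# Coupled mass-balance solver for metal-chelator mixtures.
#
# The system solved is, per ligand j and metal m,
#   L_T,j = L_free,j * (1 + sum_m K_app(m,j) * M_free,m)
#   M_T,m = M_free,m * (1 + sum_j K_app(m,j) * L_free,j)
# where L_free collects ALL non-metal-bound ligand forms (the proton states
# are folded into K_app).  The scheme is damped alternating fixed-point
# iteration: ligand frees are eliminated in closed form given the metal
# frees, metal frees are updated from the ligand frees, and a geometric
# (log-space factor 0.5) damping step engages only when a metal's update
# direction starts to oscillate.  A per-metal bisection fallback handles the
# rare stalls.  All arithmetic goes through an arithmetic kernel, so the same
# code path runs in native doubles or arbitrary-precision decimals.

.kernel_ext <- function(kern, ctx) {
  if (kern$mode == "double") {
    kern$zero <- 0
    kern$sgn <- function(a) sign(a)
    kern$rel <- function(new, old) {
      d <- abs(new - old)
      if (d == 0) 0 else d / max(abs(old), abs(new), 1e-300)
    }
    kern$digits <- 16L
  } else {
    kern$zero <- .dec_zero
    kern$sgn <- function(a) a$s
    kern$rel <- function(new, old) {
      d <- .dec_sub(new, old, 4L)  # few limbs suffice for a magnitude estimate
      if (.dec_is_zero(d)) return(0)
      if (.dec_is_zero(old)) return(Inf)
      ad <- .dec_approx(d); ao <- .dec_approx(old)
      abs(ad$m / ao$m) * 10^(ad$e10 - ao$e10)
    }
    kern$digits <- ctx$precision
  }
  kern
}

.no_convergence <- function(residual, iterations) {
  stop(structure(class = c("chelation_no_convergence", "error", "condition"),
                 list(message = sprintf(
                   "solver did not converge after %d iterations (last residual %.3g)",
                   iterations, residual), call = NULL, residual = residual)))
}

# denominators 1 + sum_m K*M and the implied ligand frees (closed form)
.ligand_dens <- function(M, ltk, Kk, kern) {
  nl <- length(ltk)
  dens <- vector("list", nl)
  L <- vector("list", nl)
  for (j in seq_len(nl)) {
    den <- kern$one
    for (i in seq_along(M)) {
      if (!is.null(Kk[[i]][[j]]))
        den <- kern$add(den, kern$mul(Kk[[i]][[j]], M[[i]]))
    }
    dens[[j]] <- den
    L[[j]] <- kern$div(ltk[[j]], den)
  }
  list(dens = dens, L = L)
}

.ligand_update <- function(M, ltk, Kk, kern) .ligand_dens(M, ltk, Kk, kern)$L

# positive root of K x^2 + (1 + K (LT - MT)) x - MT = 0, stable quadratic form
.cf11_kernel <- function(MT, LT, K, kern) {
  b <- kern$add(kern$one, kern$mul(K, kern$sub(LT, MT)))
  disc <- kern$sqrt(kern$add(kern$mul(b, b),
                             kern$mul(kern$from(4), kern$mul(K, MT))))
  if (kern$sgn(b) >= 0L) kern$div(kern$mul(kern$from(2), MT), kern$add(b, disc))
  else kern$div(kern$sub(disc, b), kern$mul(kern$from(2), K))
}

# partial solve for metal i given the other metals: collapse its ligand
# environment into one effective ligand whose binding curve matches the true
# bound-sum and its derivative at the current iterate (exact for a single
# ligand, tangent-matched for several, hence exact again at the fixed point),
# then take the stable quadratic root
.metal_partial_solve <- function(i, M, mtk, ltk, dens, Kk, kern) {
  x0 <- M[[i]]
  bnd <- NULL; P <- NULL   # bound-sum at x0 and minus its derivative
  for (j in seq_along(ltk)) {
    if (is.null(Kk[[i]][[j]])) next
    s1 <- kern$sub(dens[[j]], kern$mul(Kk[[i]][[j]], x0))  # 1 + other metals
    a <- kern$div(Kk[[i]][[j]], s1)
    d <- kern$add(kern$one, kern$mul(a, x0))
    t <- kern$div(kern$mul(a, ltk[[j]]), d)
    p <- kern$div(kern$mul(a, t), d)
    bnd <- if (is.null(bnd)) t else kern$add(bnd, t)
    P <- if (is.null(P)) p else kern$add(P, p)
  }
  if (is.null(bnd) || kern$sgn(bnd) == 0L) return(mtk[[i]])
  den <- kern$sub(bnd, kern$mul(x0, P))   # always > 0 analytically
  if (kern$sgn(den) <= 0L || kern$sgn(P) == 0L)
    return(kern$div(mtk[[i]], kern$add(kern$one, bnd)))
  Keff <- kern$div(P, den)
  Leff <- kern$div(kern$mul(bnd, kern$add(kern$one, kern$mul(Keff, x0))), Keff)
  .cf11_kernel(mtk[[i]], Leff, Keff, kern)
}

# metal-side residual denominator 1 + sum_j K * L_j
.metal_denominator <- function(i, L, Kk, kern) {
  den <- kern$one
  for (j in seq_along(L)) {
    if (!is.null(Kk[[i]][[j]]))
      den <- kern$add(den, kern$mul(Kk[[i]][[j]], L[[j]]))
  }
  den
}

.solve_core <- function(mt, fixed, mf_fixed, lt, K, kern,
                        tol, max_iter = 10000L, warm = NULL) {
  nm <- length(mt); nl <- length(lt)
  Kk <- lapply(seq_len(nm), function(i) lapply(seq_len(nl), function(j) {
    if (is.na(K[i, j]) || K[i, j] == 0) NULL else kern$from(K[i, j])
  }))
  ltk <- lapply(lt, kern$from)
  mtk <- lapply(mt, function(x) if (is.na(x)) NULL else kern$from(x))
  unknown <- which(!fixed)
  M <- vector("list", nm)
  for (i in seq_len(nm)) {
    M[[i]] <- if (fixed[i]) kern$from(mf_fixed[i])
              else kern$from(if (!is.null(warm)) warm[i] else mt[i])
  }
  L <- .ligand_update(M, ltk, Kk, kern)

  active <- unknown[mt[unknown] > 0]
  iterations <- 0L
  method <- "fixed-point"
  if (length(active) && nl) {
    prev_dir <- integer(nm)
    damped <- logical(nm)              # sticky once oscillation is seen
    prev_delta <- vector("list", nm)   # last update step, for Aitken extrapolation
    converged <- FALSE
    stall_at <- 3000L
    for (it in seq_len(max_iter)) {
      iterations <- it
      ld <- .ligand_dens(M, ltk, Kk, kern)
      Lnew <- ld$L
      rel <- 0
      for (j in seq_len(nl)) rel <- max(rel, kern$rel(Lnew[[j]], L[[j]]))
      L <- Lnew
      for (i in active) {
        target <- .metal_partial_solve(i, M, mtk, ltk, ld$dens, Kk, kern)
        dir <- kern$sgn(kern$sub(target, M[[i]]))
        if (dir != 0L && prev_dir[i] != 0L && dir == -prev_dir[i]) damped[i] <- TRUE
        newv <- if (damped[i]) kern$sqrt(kern$mul(M[[i]], target)) else target
        delta <- kern$sub(newv, M[[i]])
        # Aitken delta-squared: when two successive steps shrink geometrically
        # in the same direction, jump to the extrapolated fixed point
        if (!is.null(prev_delta[[i]]) && kern$sgn(delta) != 0L &&
            kern$sgn(delta) == kern$sgn(prev_delta[[i]])) {
          r <- kern$to(kern$div(delta, prev_delta[[i]]))
          if (is.finite(r) && r > 0 && r < 0.99) {
            cand <- kern$add(newv, kern$mul(kern$from(r / (1 - r)), delta))
            if (kern$sgn(cand) > 0L) { newv <- cand; delta <- NULL }
          }
        }
        rel <- max(rel, kern$rel(newv, M[[i]]))
        prev_dir[i] <- dir
        prev_delta[i] <- list(delta)
        M[[i]] <- newv
      }
      if (rel < tol) { converged <- TRUE; break }
      if (it >= stall_at) break
    }
    if (!converged) {
      method <- "bisection"
      M <- .solve_bisect(mtk, active, M, ltk, Kk, kern, tol)
      L <- .ligand_update(M, ltk, Kk, kern)
    }
  } else if (length(active)) {
    # no ligands: free equals total
    for (i in active) M[[i]] <- mtk[[i]]
  }

  # final residual on the metal mass balances, relative to each total
  residual <- 0
  L <- .ligand_update(M, ltk, Kk, kern)
  for (i in unknown) {
    if (mt[i] == 0) next
    lhs <- kern$mul(M[[i]], .metal_denominator(i, L, Kk, kern))
    residual <- max(residual, kern$rel(lhs, mtk[[i]]))
  }
  if (residual > 1e-6) .no_convergence(residual, iterations)

  list(M = M, L = L, iterations = iterations, residual = residual,
       method = method)
}

# Gauss-Seidel sweeps of log-space bisection on each metal's own residual
.solve_bisect <- function(mtk, active, M, ltk, Kk, kern, tol) {
  nbis <- as.integer(ceiling((kern$digits + 25) * log2(10)))
  tiny <- kern$from(1e-30)
  resid_sign <- function(i, x) {
    M[[i]] <- x
    L <- .ligand_update(M, ltk, Kk, kern)
    lhs <- kern$mul(x, .metal_denominator(i, L, Kk, kern))
    kern$sgn(kern$sub(lhs, mtk[[i]]))
  }
  for (sweep in 1:60) {
    delta <- 0
    for (i in active) {
      lo <- kern$mul(mtk[[i]], tiny)
      hi <- mtk[[i]]
      for (b in seq_len(nbis)) {
        mid <- kern$sqrt(kern$mul(lo, hi))
        if (resid_sign(i, mid) > 0L) hi <- mid else lo <- mid
      }
      mid <- kern$sqrt(kern$mul(lo, hi))
      delta <- max(delta, kern$rel(mid, M[[i]]))
      M[[i]] <- mid
    }
    if (delta < tol * 10) return(M)
  }
  .no_convergence(delta, 60L * nbis)
}

.check_table_match <- function(mixture, table) {
  stopifnot(inherits(mixture, "mixture_spec"), inherits(table, "apparent_table"))
  a <- mixture$conditions; b <- table$conditions
  if (a$temperature != b$temperature || a$ph != b$ph ||
      a$ionic_equivalence != b$ionic_equivalence)
    stop("apparent-constant table conditions (", b$temperature, " degC, pH ",
         b$ph, ", Ie ", b$ionic_equivalence, " mM) do not match the mixture's")
}

.solver_tol <- function(ctx) {
  if (is.null(ctx) || ctx$mode == "double") 1e-12 else 10^-(ctx$precision + 2)
}

.assemble_system <- function(mixture, table) {
  mids <- names(mixture$metals)
  lids <- names(mixture$chelators)
  bad_m <- setdiff(mids, rownames(table$kapp))
  bad_l <- setdiff(lids, colnames(table$kapp))
  if (length(bad_m)) stop("no apparent constants for metal(s): ",
                          paste(bad_m, collapse = ", "))
  if (length(bad_l)) stop("no apparent constants for ligand(s): ",
                          paste(bad_l, collapse = ", "))
  K <- table$kapp[mids, lids, drop = FALSE]
  K[is.na(K)] <- 0
  list(
    mids = mids, lids = lids, K = K,
    mt = vapply(mixture$metals, `[[`, numeric(1), "concentration"),
    mode = vapply(mixture$metals, `[[`, character(1), "mode"),
    lt = vapply(mixture$chelators, apply_purity, numeric(1))
  )
}

.build_result <- function(sys, core, mixture, table, ctx, kern) {
  mf <- vapply(core$M, kern$to, numeric(1))
  lf <- if (length(core$L)) vapply(core$L, kern$to, numeric(1)) else numeric(0)
  names(mf) <- sys$mids
  names(lf) <- sys$lids
  bound <- sys$K * outer(mf, rep(1, length(sys$lids))) *
    outer(rep(1, length(sys$mids)), lf)
  dimnames(bound) <- list(sys$mids, sys$lids)
  total <- ifelse(sys$mode == "total", sys$mt, mf * (1 + as.vector(sys$K %*% lf)))
  if (!length(sys$lids)) total <- ifelse(sys$mode == "total", sys$mt, mf)
  metals <- data.frame(
    metal = sys$mids, mode = unname(sys$mode), total = unname(total),
    free = unname(mf), px = p_transform(unname(mf)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ligands <- data.frame(
    ligand = sys$lids, effective_total = unname(sys$lt),
    free_unbound = unname(lf), row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    metals = metals, ligands = ligands, bound = bound,
    convergence = list(iterations = core$iterations, residual = core$residual,
                       method = core$method),
    conditions = mixture$conditions, source = table$source,
    mixture = mixture, table = table,
    precision = if (is.null(ctx) || ctx$mode == "double") "double"
                else sprintf("decimal (%d digits)", ctx$precision)
  ), class = "speciation")
}

#' Solve free metal concentrations from known totals
#'
#' All metals of the mixture must be in `"total"` mode.  Returns the unique
#' nonnegative solution of the coupled mass-balance system at the table's
#' conditions.
#'
#' @param mixture a [mixture_spec()]; its conditions must equal the table's.
#' @param table an [build_table()] result at the same conditions.
#' @param context an [arithmetic_context()]; `NULL` means native doubles.
#'   In decimal mode the solver warm-starts from the double solution and
#'   iterates to a relative tolerance of `10^-(digits + 2)`.
#' @return an object of class `speciation`.
#' @export
solve_free_from_total <- function(mixture, table, context = NULL) {
  .check_table_match(mixture, table)
  sys <- .assemble_system(mixture, table)
  if (any(sys$mode != "total"))
    stop("solve_free_from_total requires every metal in 'total' mode")
  fixed <- rep(FALSE, length(sys$mids))
  warm <- NULL
  if (!is.null(context) && context$mode == "decimal") {
    pre <- .solve_core(sys$mt, fixed, numeric(length(sys$mids)), sys$lt, sys$K,
                       .kernel_ext(.kernel_double(), NULL), 1e-12)
    warm <- vapply(pre$M, identity, numeric(1))
    warm[warm <= 0] <- sys$mt[warm <= 0]
  }
  kern <- .kernel_ext(.kernel_for(context), context)
  core <- .solve_core(sys$mt, fixed, numeric(length(sys$mids)), sys$lt, sys$K,
                      kern, .solver_tol(context), warm = warm)
  .build_result(sys, core, mixture, table, context, kern)
}

#' Solve required totals from known free concentrations
#'
#' Metals in `"free"` mode are held fixed at their requested free
#' concentrations while the remaining system is solved; their required totals
#' are then `free * (1 + sum_j K_app * L_free_j)`.  At least one metal must
#' be in `"free"` mode; any others are in `"total"` mode and are solved as in
#' [solve_free_from_total()].  Multiple free-known metals are supported by
#' fixing all of them simultaneously.
#'
#' @inheritParams solve_free_from_total
#' @return an object of class `speciation`.
#' @export
solve_total_from_free <- function(mixture, table, context = NULL) {
  .check_table_match(mixture, table)
  sys <- .assemble_system(mixture, table)
  if (!any(sys$mode == "free"))
    stop("solve_total_from_free requires at least one metal in 'free' mode")
  fixed <- sys$mode == "free"
  mf_fixed <- ifelse(fixed, sys$mt, 0)
  mt <- ifelse(fixed, NA_real_, sys$mt)
  warm <- NULL
  if (!is.null(context) && context$mode == "decimal") {
    pre <- .solve_core(mt, fixed, mf_fixed, sys$lt, sys$K,
                       .kernel_ext(.kernel_double(), NULL), 1e-12)
    warm <- vapply(pre$M, identity, numeric(1))
    bad <- !fixed & (warm <= 0) & !is.na(mt)
    warm[bad] <- mt[bad]
  }
  kern <- .kernel_ext(.kernel_for(context), context)
  core <- .solve_core(mt, fixed, mf_fixed, sys$lt, sys$K, kern,
                      .solver_tol(context), warm = warm)
  .build_result(sys, core, mixture, table, context, kern)
}

#' Closed-form solution of the 1-metal/1-ligand system
#'
#' The positive root of `K*Mf^2 + (1 + K*(L_T - M_T))*Mf - M_T = 0`,
#' evaluated by the numerically stable form of the quadratic formula (no
#' subtraction of nearly equal quantities).  Used as an independent oracle
#' for the iterative solver.
#'
#' @param m_total,l_total total metal and ligand concentrations, molar.
#' @param k_app apparent association constant, 1/M.
#' @param context optional [arithmetic_context()]; in decimal mode the root
#'   is carried at the context's precision and attached as attribute
#'   `"decimal"` (formattable with more digits than a double holds).
#' @return the free metal concentration in molar.
#' @export
closed_form_1_1 <- function(m_total, l_total, k_app, context = NULL) {
  stopifnot(m_total >= 0, l_total >= 0, k_app >= 0)
  if (k_app == 0 || l_total == 0 || m_total == 0) return(m_total)
  kern <- .kernel_ext(.kernel_for(context), context)
  root <- .cf11_kernel(kern$from(m_total), kern$from(l_total),
                       kern$from(k_app), kern)
  out <- kern$to(root)
  if (!is.null(context) && context$mode == "decimal") attr(out, "decimal") <- root
  out
}

#' pX transform of a free concentration
#'
#' `pX = -log10(free)`, e.g. pCa for free calcium.  Non-positive inputs have
#' no pX and yield `NA` rather than an error.
#'
#' @param free free concentration(s), molar.
#' @return the pX value(s); `NA` where `free <= 0`.
#' @examples
#' p_transform(1e-6)  # 6
#' @export
p_transform <- function(free) {
  ifelse(is.finite(free) & free > 0, -log10(free), NA_real_)
}

#' Speciate a metal-chelator mixture
#'
#' The main entry point: builds the apparent-constant table for the mixture's
#' conditions from a constant set and solves the mass-balance system, in the
#' mode implied by the metal entries (all-`"total"`: free concentrations are
#' computed; any `"free"`: required totals are computed).
#'
#' @param mixture a [mixture_spec()].
#' @param constants a `constant_set` (see [load_builtin()],
#'   [parse_constant_set()]) or a prebuilt [build_table()] table at the
#'   mixture's conditions.
#' @param context an [arithmetic_context()], or `NULL` for native doubles.
#' @return an object of class `speciation` with components `metals` (data
#'   frame: total, free, pX per metal), `ligands` (effective total and free
#'   unbound per chelator), `bound` (metal x ligand matrix of complex
#'   concentrations), and `convergence`.
#' @examples
#' mix <- mixture_spec(
#'   chelators = list(chelator_entry("EGTA", 1, "mM"),
#'                    chelator_entry("ATP", 2, "mM")),
#'   metals = list(metal_entry("Ca", 1, "mM"), metal_entry("Mg", 6, "mM")),
#'   conditions = buffer_conditions(20, 7.0, 100)
#' )
#' speciate(mix)
#' @export
speciate <- function(mixture, constants = load_builtin(), context = NULL) {
  stopifnot(inherits(mixture, "mixture_spec"))
  table <- if (inherits(constants, "apparent_table")) constants
           else build_table(constants, names(mixture$metals),
                            names(mixture$chelators), mixture$conditions)
  if (any(vapply(mixture$metals, `[[`, character(1), "mode") == "free"))
    solve_total_from_free(mixture, table, context)
  else
    solve_free_from_total(mixture, table, context)
}

#' @export
print.speciation <- function(x, ...) {
  cat(sprintf("Speciation at %g degC, pH %g, Ie %g mM (constants: %s, arithmetic: %s)\n",
              x$conditions$temperature, x$conditions$ph,
              x$conditions$ionic_equivalence, x$source, x$precision))
  m <- x$metals
  m$total <- signif(m$total, 6); m$free <- signif(m$free, 6)
  m$px <- round(m$px, 4)
  print(m, row.names = FALSE)
  if (nrow(x$ligands)) {
    l <- x$ligands
    l$effective_total <- signif(l$effective_total, 6)
    l$free_unbound <- signif(l$free_unbound, 6)
    print(l, row.names = FALSE)
  }
  cat(sprintf("converged by %s in %d iterations (residual %.2e)\n",
              x$convergence$method, x$convergence$iterations,
              x$convergence$residual))
  invisible(x)
}

#' @export
summary.speciation <- function(object, ...) {
  cat("Free metal concentrations (M) and pX:\n")
  m <- object$metals
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-4s free = %.6e M  (p%s = %s, %s known)\n",
                m$metal[i], m$free[i], m$metal[i],
                ifelse(is.na(m$px[i]), "NA", sprintf("%.4f", m$px[i])),
                m$mode[i]))
  if (nrow(object$ligands)) {
    cat("Bound species (M):\n")
    b <- object$bound
    for (i in rownames(b)) for (j in colnames(b))
      if (b[i, j] > 0) cat(sprintf("  %s-%s = %.6e\n", i, j, b[i, j]))
  }
  invisible(object)
}

#' @export
as.data.frame.speciation <- function(x, ...) {
  m <- x$metals
  data.frame(entity = m$metal, kind = "metal", mode = m$mode,
             total = m$total, free = m$free, px = m$px,
             stringsAsFactors = FALSE) -> dm
  if (nrow(x$ligands)) {
    dl <- data.frame(entity = x$ligands$ligand, kind = "ligand", mode = NA_character_,
                     total = x$ligands$effective_total,
                     free = x$ligands$free_unbound, px = NA_real_,
                     stringsAsFactors = FALSE)
    rbind(dm, dl)
  } else dm
}
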