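# Arbitrary-precision decimal floating point.
#
# A decimal number is a list(s, e, m): sign s in {-1, 0, 1}, decimal exponent
# e (power of ten of the least-significant limb) and a little-endian limb
# vector m in base 1e7, so  value = s * sum(m[i] * 1e7^(i-1)) * 10^e.
# All arithmetic is carried out in R doubles on limbs; every intermediate
# stays below 2^53, which caps supported precision at 500 significant digits.
# Operations round to a working precision of `digits` significant digits plus
# two guard limbs; this module is the arithmetic behind the solver's
# arbitrary-precision mode.

.DEC_BASE <- 1e7
.DEC_LDIG <- 7L
.DEC_MAX_DIGITS <- 500L

.dec_limbs <- function(digits) as.integer(ceiling((digits + 14L) / 7L))

.dec_zero <- list(s = 0L, e = 0L, m = numeric(0))

.dec_is_zero <- function(x) x$s == 0L || length(x$m) == 0L

# propagate carries so every limb is in [0, 1e7)
.dec_carry <- function(m) {
  repeat {
    c <- m %/% .DEC_BASE
    if (!any(c > 0)) break
    m <- m - c * .DEC_BASE
    m <- c(m, 0)
    m[-1L] <- m[-1L] + c
  }
  while (length(m) && m[length(m)] == 0) m <- m[-length(m)]
  m
}

# multiply a limb vector by 10^d (d >= 0 decimal digits)
.dec_shift_up <- function(m, d) {
  if (d == 0L || length(m) == 0L) return(m)
  q <- d %/% .DEC_LDIG
  r <- d %% .DEC_LDIG
  if (r > 0L) m <- .dec_carry(m * 10^r)
  if (q > 0L) m <- c(numeric(q), m)
  m
}

# round to nl limbs by dropping low limbs (round half up on the top dropped limb)
.dec_round <- function(x, nl) {
  m <- x$m
  while (length(m) && m[length(m)] == 0) m <- m[-length(m)]
  if (length(m) == 0L) return(.dec_zero)
  drop <- length(m) - nl
  if (drop > 0L) {
    up <- m[drop] >= .DEC_BASE / 2
    m <- m[-seq_len(drop)]
    e <- x$e + drop * .DEC_LDIG
    if (up) m <- .dec_carry(c(m[1L] + 1, m[-1L]))
    if (length(m) == 0L) return(.dec_zero)
    return(list(s = x$s, e = e, m = m))
  }
  list(s = x$s, e = x$e, m = m)
}

.dec_from_parts <- function(sign, digit_string, exp10) {
  digit_string <- sub("^0+", "", digit_string)
  if (digit_string == "") return(.dec_zero)
  nd <- nchar(digit_string)
  pad <- (.DEC_LDIG - nd %% .DEC_LDIG) %% .DEC_LDIG
  ds <- paste0(strrep("0", pad), digit_string)
  n <- nchar(ds) %/% .DEC_LDIG
  limbs <- vapply(seq_len(n), function(i) {
    as.numeric(substr(ds, (i - 1L) * .DEC_LDIG + 1L, i * .DEC_LDIG))
  }, numeric(1))
  list(s = as.integer(sign), e = as.integer(exp10), m = rev(limbs))
}

# exact binary-to-decimal conversion: x = m53 * 2^k with integer m53, then
# m53 is scaled by powers of 2 (k >= 0) or 5 (k < 0) in limb arithmetic
.dec_from_double <- function(x) {
  if (!is.finite(x)) stop("non-finite value cannot enter decimal arithmetic")
  if (x == 0) return(.dec_zero)
  s <- if (x < 0) -1L else 1L
  ax <- abs(x)
  k_extra <- 0L
  if (ax < 2^-1000) { ax <- ax * 2^200; k_extra <- -200L }  # avoid subnormals
  e2 <- floor(log2(ax))
  m53 <- ax / 2^(e2 - 52)
  if (m53 >= 2^53) { m53 <- m53 / 2; e2 <- e2 + 1 }
  if (m53 < 2^52) { m53 <- m53 * 2; e2 <- e2 - 1 }
  m53 <- round(m53)
  k <- e2 - 52 + k_extra
  m <- .dec_from_parts(1L, sprintf("%.0f", m53), 0L)$m
  if (k >= 0) {
    while (k >= 20L) { m <- .dec_carry(m * 2^20); k <- k - 20L }
    if (k > 0L) m <- .dec_carry(m * 2^k)
    e10 <- 0L
  } else {
    e10 <- k
    k <- -k
    while (k >= 7L) { m <- .dec_carry(m * 5^7); k <- k - 7L }
    if (k > 0L) m <- .dec_carry(m * 5^k)
  }
  list(s = s, e = as.integer(e10), m = m)
}

.dec_from_string <- function(s) {
  s <- trimws(s)
  stopifnot(grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s))
  sign <- 1L
  if (startsWith(s, "-")) { sign <- -1L; s <- substring(s, 2L) }
  if (startsWith(s, "+")) s <- substring(s, 2L)
  ex <- 0L
  if (grepl("[eE]", s)) {
    ex <- as.integer(sub("^.*[eE]", "", s))
    s <- sub("[eE].*$", "", s)
  }
  frac <- 0L
  if (grepl("\\.", s)) {
    frac <- nchar(sub("^.*\\.", "", s))
    s <- gsub("\\.", "", s)
  }
  .dec_from_parts(sign, s, ex - frac)
}

# leading ~21 digits as (mantissa in [1,10), base-10 exponent)
.dec_approx <- function(x) {
  if (.dec_is_zero(x)) return(list(m = 0, e10 = 0L))
  n <- length(x$m)
  k <- min(3L, n)
  v <- 0
  for (i in seq(n, n - k + 1L)) v <- v * .DEC_BASE + x$m[i]
  ex <- floor(log10(v))
  list(m = x$s * v / 10^ex, e10 = as.integer(ex + x$e + (n - k) * .DEC_LDIG))
}

.dec_to_double <- function(x) {
  a <- .dec_approx(x)
  if (a$m == 0) return(0)
  if (a$e10 > 308L) return(sign(a$m) * Inf)
  if (a$e10 < -320L) return(0)
  a$m * 10^a$e10
}

.dec_cmp_abs <- function(a, b) {
  # compare |a| vs |b|; -1, 0, 1
  if (.dec_is_zero(a)) return(if (.dec_is_zero(b)) 0L else -1L)
  if (.dec_is_zero(b)) return(1L)
  ha <- a$e + length(a$m) * .DEC_LDIG   # upper bound on digit position
  hb <- b$e + length(b$m) * .DEC_LDIG
  if (ha - hb > .DEC_LDIG) return(1L)
  if (hb - ha > .DEC_LDIG) return(-1L)
  # align and compare limbwise
  e <- min(a$e, b$e)
  ma <- .dec_shift_up(a$m, a$e - e)
  mb <- .dec_shift_up(b$m, b$e - e)
  n <- max(length(ma), length(mb))
  ma <- c(ma, numeric(n - length(ma)))
  mb <- c(mb, numeric(n - length(mb)))
  for (i in seq(n, 1L)) {
    if (ma[i] > mb[i]) return(1L)
    if (ma[i] < mb[i]) return(-1L)
  }
  0L
}

.dec_add <- function(a, b, nl) {
  if (.dec_is_zero(a)) return(.dec_round(b, nl))
  if (.dec_is_zero(b)) return(.dec_round(a, nl))
  # if magnitudes are too far apart the smaller operand is below one ulp
  span <- (nl + 2L) * .DEC_LDIG
  ha <- a$e + length(a$m) * .DEC_LDIG
  hb <- b$e + length(b$m) * .DEC_LDIG
  if (ha - hb > span) return(.dec_round(a, nl))
  if (hb - ha > span) return(.dec_round(b, nl))
  e <- min(a$e, b$e)
  ma <- .dec_shift_up(a$m, a$e - e)
  mb <- .dec_shift_up(b$m, b$e - e)
  n <- max(length(ma), length(mb))
  ma <- c(ma, numeric(n - length(ma)))
  mb <- c(mb, numeric(n - length(mb)))
  if (a$s == b$s) {
    m <- .dec_carry(ma + mb)
    return(.dec_round(list(s = a$s, e = e, m = m), nl))
  }
  cmp <- .dec_cmp_abs(a, b)
  if (cmp == 0L) return(.dec_zero)
  if (cmp < 0L) { tmp <- ma; ma <- mb; mb <- tmp; s <- b$s } else s <- a$s
  d <- ma - mb
  while (any(d < 0)) {
    idx <- which(d < 0)
    d[idx] <- d[idx] + .DEC_BASE
    d[idx + 1L] <- d[idx + 1L] - 1
  }
  while (length(d) && d[length(d)] == 0) d <- d[-length(d)]
  if (length(d) == 0L) return(.dec_zero)
  .dec_round(list(s = s, e = e, m = d), nl)
}

.dec_neg <- function(x) { x$s <- -x$s; x }

.dec_sub <- function(a, b, nl) .dec_add(a, .dec_neg(b), nl)

.dec_cmp <- function(a, b) {
  if (a$s != b$s) return(if (a$s > b$s) 1L else -1L)
  if (a$s == 0L) return(0L)
  a$s * .dec_cmp_abs(a, b)
}

.dec_mul <- function(a, b, nl) {
  if (.dec_is_zero(a) || .dec_is_zero(b)) return(.dec_zero)
  ma <- a$m; mb <- b$m
  if (length(ma) < length(mb)) { tmp <- ma; ma <- mb; mb <- tmp }
  la <- length(ma); lb <- length(mb)
  res <- numeric(la + lb)
  for (i in seq_len(lb)) {
    seg <- i:(i + la - 1L)
    res[seg] <- res[seg] + mb[i] * ma
  }
  m <- .dec_carry(res)
  .dec_round(list(s = a$s * b$s, e = a$e + b$e, m = m), nl)
}

.dec_div <- function(a, b, nl) {
  if (.dec_is_zero(b)) stop("decimal division by zero")
  if (.dec_is_zero(a)) return(.dec_zero)
  # Newton-Raphson reciprocal seeded from a double approximation
  ap <- .dec_approx(b)
  x <- .dec_from_double(1 / ap$m)
  x$e <- x$e - ap$e10
  niter <- max(3L, as.integer(ceiling(log2((nl * .DEC_LDIG) / 15))) + 1L)
  two <- .dec_from_parts(1L, "2", 0L)
  for (i in seq_len(niter)) {
    bx <- .dec_mul(b, x, nl + 2L)
    x <- .dec_mul(x, .dec_sub(two, bx, nl + 2L), nl + 2L)
  }
  q <- .dec_mul(a, x, nl + 2L)
  # one correction step: q <- q + x*(a - b*q)
  r <- .dec_sub(a, .dec_mul(b, q, nl + 2L), nl + 2L)
  q <- .dec_add(q, .dec_mul(x, r, nl + 2L), nl)
  q
}

.dec_sqrt <- function(a, nl) {
  if (.dec_is_zero(a)) return(.dec_zero)
  if (a$s < 0L) stop("decimal square root of a negative number")
  # Newton iteration on y = 1/sqrt(a), seeded from doubles
  ap <- .dec_approx(a)
  m <- ap$m; e10 <- ap$e10
  if (e10 %% 2L != 0L) { m <- m * 10; e10 <- e10 - 1L }
  y <- .dec_from_double(1 / sqrt(m))
  y$e <- y$e - e10 %/% 2L
  half <- .dec_from_parts(1L, "5", -1L)
  three <- .dec_from_parts(1L, "3", 0L)
  niter <- max(4L, as.integer(ceiling(log2((nl * .DEC_LDIG) / 15))) + 2L)
  for (i in seq_len(niter)) {
    ay2 <- .dec_mul(a, .dec_mul(y, y, nl + 2L), nl + 2L)
    y <- .dec_mul(y, .dec_mul(half, .dec_sub(three, ay2, nl + 2L), nl + 2L), nl + 2L)
  }
  r <- .dec_mul(a, y, nl + 2L)
  # correction: r <- r + (a - r^2) * y / 2
  d <- .dec_sub(a, .dec_mul(r, r, nl + 2L), nl + 2L)
  .dec_add(r, .dec_mul(half, .dec_mul(d, y, nl + 2L), nl + 2L), nl)
}

# scientific-notation string with `digits` significant digits (round half up)
.dec_format <- function(x, digits = 17L) {
  if (.dec_is_zero(x)) return("0")
  ds <- paste(sprintf("%07.0f", rev(x$m)), collapse = "")
  lead <- regmatches(ds, regexpr("^0*", ds))
  ds <- sub("^0+", "", ds)
  e10 <- x$e + nchar(ds) - 1L
  if (nchar(ds) > digits) {
    keep <- substr(ds, 1L, digits)
    nxt <- as.integer(substr(ds, digits + 1L, digits + 1L))
    if (!is.na(nxt) && nxt >= 5L) {
      v <- as.numeric(keep) + 1
      keep <- sprintf("%.0f", v)
      if (nchar(keep) > digits) { keep <- substr(keep, 1L, digits); e10 <- e10 + 1L }
    }
    ds <- keep
  }
  ds <- sub("0+$", "", ds)
  if (ds == "") ds <- "1" # rounding overflowed to a bare power of ten
  body <- if (nchar(ds) > 1L) paste0(substr(ds, 1L, 1L), ".", substring(ds, 2L)) else ds
  sprintf("%s%se%+d", if (x$s < 0L) "-" else "", body, e10)
}

# ---------------------------------------------------------------------------
# Arithmetic kernels: a common closure interface over native doubles and
# arbitrary-precision decimals, so the solver runs identically in both modes.

.kernel_double <- function() {
  list(
    mode = "double",
    from = function(x) x,
    to = function(x) x,
    add = function(a, b) a + b,
    sub = function(a, b) a - b,
    mul = function(a, b) a * b,
    div = function(a, b) a / b,
    sqrt = function(a) sqrt(a),
    one = 1
  )
}

.kernel_decimal <- function(digits) {
  nl <- .dec_limbs(digits)
  list(
    mode = "decimal",
    from = function(x) .dec_round(.dec_from_double(x), nl),
    to = .dec_to_double,
    add = function(a, b) .dec_add(a, b, nl),
    sub = function(a, b) .dec_sub(a, b, nl),
    mul = function(a, b) .dec_mul(a, b, nl),
    div = function(a, b) .dec_div(a, b, nl),
    sqrt = function(a) .dec_sqrt(a, nl),
    one = .dec_from_parts(1L, "1", 0L)
  )
}

#' Arithmetic context for the equilibrium solver
#'
#' The speciation solver can run either in native double-precision floating
#' point (the default, about 16 significant digits) or in arbitrary-precision
#' decimal arithmetic where every solver operation carries at least the
#' requested number of significant decimal digits.  The decimal mode exists to
#' rule out accumulated rounding error as a source of discrepancy between
#' calculators; in practice the two modes agree to well below reporting
#' precision on well-conditioned buffers.
#'
#' @param mode `"double"` for native floating point or `"decimal"` for
#'   arbitrary-precision decimal arithmetic.
#' @param digits number of significant decimal digits carried in `"decimal"`
#'   mode; at least 15 (the capability of a native double), at most 500.
#'   Defaults to 50 digits.
#' @return an object of class `arithmetic_context`.
#' @examples
#' arithmetic_context()            # native doubles
#' arithmetic_context("decimal")   # 50 significant digits
#' @seealso [with_precision()]
#' @export
arithmetic_context <- function(mode = c("double", "decimal"), digits = 50L) {
  mode <- match.arg(mode)
  digits <- as.integer(digits)
  if (is.na(digits) || digits < 15L)
    stop("precision must be at least 15 significant digits")
  if (digits > .DEC_MAX_DIGITS)
    stop("precision must be at most ", .DEC_MAX_DIGITS, " significant digits")
  structure(list(mode = mode, precision = digits), class = "arithmetic_context")
}

#' Change the precision of an arithmetic context
#'
#' Returns a copy of `ctx` carrying at least `digits` significant decimal
#' digits.  Raising the precision of a `"double"`-mode context switches it to
#' `"decimal"` mode.
#'
#' @param ctx an [arithmetic_context()].
#' @param digits requested significant decimal digits (>= 15).
#' @return a new `arithmetic_context`.
#' @export
with_precision <- function(ctx, digits) {
  stopifnot(inherits(ctx, "arithmetic_context"))
  digits <- as.integer(digits)
  if (is.na(digits) || digits < 15L)
    stop("precision must be at least 15 significant digits")
  arithmetic_context(if (digits > 17L) "decimal" else ctx$mode, digits)
}

#' @export
print.arithmetic_context <- function(x, ...) {
  if (x$mode == "double")
    cat("<arithmetic context: native double precision>\n")
  else
    cat(sprintf("<arithmetic context: decimal, %d significant digits>\n", x$precision))
  invisible(x)
}

.kernel_for <- function(ctx) {
  if (is.null(ctx) || ctx$mode == "double") .kernel_double() else .kernel_decimal(ctx$precision)
}
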