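#' Laurent polynomials with exact integer coefficients
#'
#' A minimal exact Laurent-polynomial arithmetic used by the bracket and
#' homology code.  Exponents are stored as integers in units of
#' `1/denom`, so that quarter powers of `t` (as they arise in the Jones
#' polynomial substitution a = t^(-1/4)) are represented exactly with
#' `denom = 4`.  Coefficients are integer-valued numerics; every
#' operation in this file is exact (no floating-point rounding can occur
#' because only integer addition and multiplication are used).
#'
#' @param exps integer vector of exponents (units of `1/denom`).
#' @param coefs numeric vector of integer coefficients, same length.
#' @param var single variable name, e.g. `"q"`, `"a"` or `"t"`.
#' @param denom exponent denominator; 1 for ordinary Laurent polynomials,
#'   4 for quarter powers.
#' @return an object of class `laurent`.
#' @export
laurent <- function(exps = integer(), coefs = numeric(), var = "q", denom = 1L) {
  stopifnot(length(exps) == length(coefs), denom >= 1L)
  x <- list(exps = as.numeric(exps), coefs = as.numeric(coefs),
            var = var, denom = as.integer(denom))
  class(x) <- "laurent"
  lp_normalize(x)
}

lp_normalize <- function(x) {
  if (length(x$exps)) {
    tab <- tapply(x$coefs, x$exps, sum)
    e <- as.numeric(names(tab)); c0 <- as.numeric(tab)
    keep <- c0 != 0
    o <- order(e[keep])
    x$exps <- e[keep][o]; x$coefs <- c0[keep][o]
  }
  x
}

#' @export
lp_zero <- function(var = "q", denom = 1L) laurent(var = var, denom = denom)

#' @export
lp_one <- function(var = "q", denom = 1L) laurent(0, 1, var = var, denom = denom)

#' Monomial c * var^e
#' @export
lp_mono <- function(coef = 1, exp = 0, var = "q", denom = 1L)
  laurent(exp, coef, var = var, denom = denom)

lp_check_compat <- function(a, b) {
  if (!identical(a$var, b$var) || a$denom != b$denom)
    stop("incompatible Laurent polynomials: ", a$var, "/", a$denom,
         " vs ", b$var, "/", b$denom)
}

#' @export
lp_add <- function(a, b) {
  lp_check_compat(a, b)
  laurent(c(a$exps, b$exps), c(a$coefs, b$coefs), var = a$var, denom = a$denom)
}

#' @export
lp_neg <- function(a) laurent(a$exps, -a$coefs, var = a$var, denom = a$denom)

#' @export
lp_sub <- function(a, b) lp_add(a, lp_neg(b))

#' @export
lp_mul <- function(a, b) {
  lp_check_compat(a, b)
  if (!length(a$exps) || !length(b$exps))
    return(lp_zero(a$var, a$denom))
  e <- outer(a$exps, b$exps, `+`)
  c0 <- outer(a$coefs, b$coefs, `*`)
  laurent(as.vector(e), as.vector(c0), var = a$var, denom = a$denom)
}

#' @export
lp_scale <- function(a, k) laurent(a$exps, a$coefs * k, var = a$var, denom = a$denom)

#' Non-negative integer power
#' @export
lp_pow <- function(a, n) {
  stopifnot(n >= 0, n == round(n))
  out <- lp_one(a$var, a$denom)
  for (i in seq_len(n)) out <- lp_mul(out, a)
  out
}

#' @export
lp_is_zero <- function(a) length(a$exps) == 0L

#' Coefficient-map equality (same variable and exponent scale)
#' @export
lp_equal <- function(a, b) {
  identical(a$var, b$var) && a$denom == b$denom &&
    length(a$exps) == length(b$exps) &&
    all(a$exps == b$exps) && all(a$coefs == b$coefs)
}

#' Exact Laurent division; errors unless the division is exact
#'
#' Both operands are shifted so the divisor becomes an ordinary
#' polynomial with nonzero constant term, then classical long division
#' runs from the top degree down.
#' @export
lp_divide <- function(num, den) {
  lp_check_compat(num, den)
  if (lp_is_zero(den)) stop("division by the zero polynomial")
  if (lp_is_zero(num)) return(lp_zero(num$var, num$denom))
  shift <- min(den$exps)
  den0 <- laurent(den$exps - shift, den$coefs, var = den$var, denom = den$denom)
  rem <- laurent(num$exps - shift, num$coefs, var = num$var, denom = num$denom)
  qexps <- numeric(); qcoefs <- numeric()
  lead_e <- max(den0$exps); lead_c <- den0$coefs[which.max(den0$exps)]
  guard <- 0L
  while (!lp_is_zero(rem)) {
    re <- max(rem$exps); rc <- rem$coefs[which.max(rem$exps)]
    if (rc %% lead_c != 0) stop("non-exact Laurent division")
    qe <- re - lead_e; qc <- rc / lead_c
    qexps <- c(qexps, qe); qcoefs <- c(qcoefs, qc)
    rem <- lp_sub(rem, lp_mul(lp_mono(qc, qe, var = num$var, denom = num$denom), den0))
    guard <- guard + 1L
    if (guard > 20000L) stop("non-exact Laurent division (no terminating quotient)")
  }
  laurent(qexps, qcoefs, var = num$var, denom = num$denom)
}

#' Map exponents e -> k * e, optionally renaming the variable.
#'
#' Used for the substitution a = t^(-1/4): exponents are multiplied by
#' -1/4 in the quarter-power representation (`denom = 4`).
#' @export
lp_subst_power <- function(a, num, den = 1L, var = a$var) {
  e <- a$exps * num / den
  d <- a$denom * abs(den)
  ints <- e * d
  if (any(abs(ints - round(ints)) > 1e-9)) stop("substitution leaves the exponent lattice")
  g <- d
  for (v in unique(abs(round(ints)))) if (v != 0) g <- gcd2(g, v)
  laurent(e, a$coefs, var = var, denom = as.integer(d / g))
}

gcd2 <- function(a, b) { a <- abs(a); b <- abs(b); while (b) { t <- b; b <- a %% b; a <- t }; a }

#' Evaluate at a numeric point (exponents in units of 1/denom)
#' @export
lp_eval <- function(a, x) sum(a$coefs * x^(a$exps))

#' @export
format.laurent <- function(x, ...) {
  if (!length(x$exps)) return("0")
  term <- function(c0, e) {
    ce <- if (e == 0) as.character(abs(c0))
    else {
      es <- if (e == round(e)) as.character(e) else as.character(e)
      base <- if (e == 1) x$var else paste0(x$var, "^", es)
      if (abs(c0) == 1) base else paste0(abs(c0), base)
    }
    ce
  }
  out <- character(0)
  for (i in seq_along(x$exps)) {
    s <- if (x$coefs[i] < 0) " - " else if (i == 1) "" else " + "
    if (i == 1 && x$coefs[i] < 0) s <- "-"
    out <- c(out, s, term(x$coefs[i], x$exps[i]))
  }
  paste0(out, collapse = "")
}

#' @export
print.laurent <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Serialize to a list {variable, terms: exponent -> coefficient}
#' @export
lp_to_list <- function(a) {
  list(variable = a$var, denom = a$denom,
       terms = stats::setNames(as.list(a$coefs), as.character(a$exps)))
}

#' Construct from a named coefficient list, e.g. list(`-1` = 1, `3` = -2)
#' @export
lp_from_list <- function(terms, var = "q", denom = 1L) {
  laurent(as.numeric(names(terms)), as.numeric(unlist(terms)),
          var = var, denom = denom)
}

# ---- two-variable (t, q) polynomials -------------------------------------

#' Two-variable Laurent polynomial in (t, q)
#'
#' Stored as parallel vectors of t-exponents, q-exponents and integer
#' coefficients.  Used for the graded Poincare polynomial
#' Kh(L) = sum_k qdim H^k(L) t^k.
#' @export
laurent2 <- function(texps = integer(), qexps = integer(), coefs = numeric()) {
  stopifnot(length(texps) == length(qexps), length(qexps) == length(coefs))
  key <- paste(texps, qexps)
  tab <- tapply(coefs, key, sum)
  ks <- strsplit(names(tab), " ", fixed = TRUE)
  te <- as.numeric(vapply(ks, `[`, "", 1L)); qe <- as.numeric(vapply(ks, `[`, "", 2L))
  c0 <- as.numeric(tab); keep <- c0 != 0
  o <- order(te[keep], qe[keep])
  x <- list(texps = te[keep][o], qexps = qe[keep][o], coefs = c0[keep][o])
  class(x) <- "laurent2"
  x
}

#' @export
l2_add <- function(a, b)
  laurent2(c(a$texps, b$texps), c(a$qexps, b$qexps), c(a$coefs, b$coefs))

#' Substitute t = tval (typically -1), collapsing to a polynomial in q
#' @export
l2_at_t <- function(a, tval = -1)
  laurent(a$qexps, a$coefs * tval^a$texps, var = "q")

#' @export
format.laurent2 <- function(x, ...) {
  if (!length(x$coefs)) return("0")
  tm <- function(i) {
    parts <- character(0)
    if (abs(x$coefs[i]) != 1 || (x$texps[i] == 0 && x$qexps[i] == 0))
      parts <- as.character(abs(x$coefs[i]))
    if (x$texps[i] != 0) parts <- c(parts, paste0("t^", x$texps[i]))
    if (x$qexps[i] != 0) parts <- c(parts, paste0("q^", x$qexps[i]))
    paste(parts, collapse = " ")
  }
  out <- character(0)
  for (i in seq_along(x$coefs)) {
    s <- if (x$coefs[i] < 0) " - " else if (i == 1) "" else " + "
    if (i == 1 && x$coefs[i] < 0) s <- "-"
    out <- c(out, s, tm(i))
  }
  paste0(out, collapse = "")
}

#' @export
print.laurent2 <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
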