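#' Kauffman bracket and Jones polynomials
#'
#' Two conventions of the bracket are provided.  In the classical
#' variable `a` the bracket satisfies <O> = 1, <O u L> = (-a^2 - a^-2)<L>
#' and <L> = a <L_0> + a^-1 <L_1>, giving the state sum
#' sum_s a^(alpha(s) - beta(s)) (-a^2 - a^-2)^(gamma(s) - 1).
#' In the `q` convention (q = -a^-2) the bracket satisfies
#' <O> = q + q^-1 and <L> = <L_0> - q <L_1>, giving
#' sum_s (-q)^beta(s) (q + q^-1)^gamma(s).
#' Here alpha and beta count the 0- and 1-smoothed crossings of the
#' state s and gamma(s) its circles (free loops included).
#'
#' @name bracket
NULL

state_gammas <- function(d) {
  n <- n_crossings(d)
  if (!n) return(data.frame(beta = 0L, gamma = resolve_state(d, integer(0))$count))
  # column j = crossing j in sorted-id order, first crossing fastest
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(states) <- NULL
  data.frame(
    beta = rowSums(states),
    gamma = vapply(seq_len(nrow(states)),
                   function(r) resolve_state(d, states[r, ])$count, integer(1)))
}

#' Kauffman bracket in the variable a
#'
#' Normalized so a single unknot gives 1.  The empty diagram (no
#' crossings, no loops) is assigned 1 as the empty product.
#' @param d a [link_diagram()].
#' @return a [laurent()] in `a`.
#' @export
bracket_a <- function(d) {
  if (!n_crossings(d) && d$free_loops == 0L) return(lp_one("a"))
  sg <- state_gammas(d)
  n <- n_crossings(d)
  loop <- laurent(c(-2, 2), c(-1, -1), var = "a")
  out <- lp_zero("a")
  for (r in seq_len(nrow(sg))) {
    alpha <- n - sg$beta[r]
    term <- lp_mul(lp_mono(1, alpha - sg$beta[r], var = "a"),
                   lp_pow(loop, sg$gamma[r] - 1L))
    out <- lp_add(out, term)
  }
  out
}

#' Kauffman bracket in the variable q
#' @param d a [link_diagram()].
#' @return a [laurent()] in `q`.
#' @export
bracket_q <- function(d) {
  if (!n_crossings(d) && d$free_loops == 0L) return(lp_one("q"))
  sg <- state_gammas(d)
  loop <- laurent(c(-1, 1), c(1, 1), var = "q")
  out <- lp_zero("q")
  for (r in seq_len(nrow(sg))) {
    term <- lp_mul(lp_mono((-1)^sg$beta[r], sg$beta[r], var = "q"),
                   lp_pow(loop, sg$gamma[r]))
    out <- lp_add(out, term)
  }
  out
}

#' Recursive skein evaluation of the q-bracket (independent code path)
#'
#' Expands <L> = <L_0> - q <L_1> at the first crossing and multiplies
#' (q + q^-1) per circle at the crossingless leaves.  Used as a
#' cross-check of the closed state sum.
#' @export
bracket_q_skein <- function(d) {
  if (!n_crossings(d)) {
    if (d$free_loops == 0L) return(lp_one("q"))
    return(lp_pow(laurent(c(-1, 1), c(1, 1), var = "q"), d$free_loops))
  }
  x <- d$ids[1]
  lp_sub(bracket_q_skein(smooth_crossing(d, x, 0L)),
         lp_mul(lp_mono(1, 1, var = "q"), bracket_q_skein(smooth_crossing(d, x, 1L))))
}

#' Kauffman polynomial X_L(a) = (-a)^(-3 w(L)) <L>
#' @export
kauffman_polynomial <- function(d) {
  w <- writhe(d)
  lp_scale(lp_mul(lp_mono(1, -3 * w, var = "a"), bracket_a(d)), (-1)^w)
}

#' Jones polynomial V_L(t) = X_L(t^(-1/4)), in quarter powers of t
#' @export
jones_t <- function(d) {
  x <- kauffman_polynomial(d)
  lp_subst_power(x, -1, 4L, var = "t")
}

#' Unnormalized Jones polynomial J^(L) = (-1)^(n-) q^(n+ - 2 n-) <L>_q
#'
#' Equals the graded Euler characteristic of the Khovanov homology.
#' @export
unnormalized_jones_q <- function(d) {
  sc <- sign_counts(d)
  lp_scale(lp_mul(lp_mono(1, sc["pos"] - 2 * sc["neg"], var = "q"), bracket_q(d)),
           (-1)^sc["neg"])
}

#' Jones polynomial in q: J(L) = J^(L) / (q + q^-1)
#' @export
jones_q <- function(d) {
  jh <- unnormalized_jones_q(d)
  lp_divide(jh, laurent(c(-1, 1), c(1, 1), var = "q"))
}

#' Is the diagram's unnormalized Jones that of an unlink?
#'
#' TRUE when J^ equals (q + q^-1)^c for the diagram's number of
#' components c, i.e. the diagram carries no Jones-detectable knotting.
#' @export
is_jones_trivial <- function(d) {
  cc <- n_components(d)
  lp_equal(unnormalized_jones_q(d),
           lp_pow(laurent(c(-1, 1), c(1, 1), var = "q"), cc))
}

#' Knot determinant |V_L(-1)| evaluated from the Jones polynomial
#' @export
knot_determinant <- function(d) {
  v <- jones_q(d)
  # q = -t^(1/2): t = -1 corresponds to q = i; V(q) has integer powers of
  # q^2 up to a sign pattern, so evaluate |V(i)| via complex arithmetic.
  abs(sum(v$coefs * (1i)^(v$exps)))
}
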