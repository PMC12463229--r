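#' Built-in fixture knot table
#'
#' Small diagrams used across examples, tests and the documentation,
#' each stored with externally checkable expected invariants (component
#' count, writhe, unnormalized Jones polynomial).  The table is
#' self-checking: [fixture_table()] recomputes every stored invariant
#' with the bracket machinery at load time and refuses to return a
#' fixture that fails.
#'
#' Entries:
#' \describe{
#'   \item{unknot0}{crossingless unknot (one free loop).}
#'   \item{kink_pos, kink_neg}{one-crossing unknot diagrams (R1 kinks)
#'     of either handedness.}
#'   \item{unknot_r2}{two-crossing unknot diagram (R2 pair).}
#'   \item{hopf_neg, hopf_pos}{the two-crossing Hopf link diagrams of
#'     negative and positive sign.}
#'   \item{trefoil_left, trefoil_right}{the three-crossing trefoil
#'     diagrams.}
#'   \item{fig8}{a four-crossing figure-eight diagram, found by search
#'     over alternating four-crossing codes (determinant 5, writhe 0
#'     identify the knot type).}
#'   \item{example31}{a four-crossing diagram of the two-component
#'     unlink whose crossings x1..x4 support two contrasting
#'     filtrations: smoothing x1 then x3 yields the negative Hopf link
#'     diagram, while the order x1, x2, x3, x4 passes through unlinked
#'     stages only.  Found by bounded brute-force search over
#'     two-circle chord diagrams and committed here; its properties are
#'     re-verified in the test suite.}
#'   \item{k7_6}{a seven-crossing reduced alternating knot diagram with
#'     determinant 19, which identifies the knot type 7_6 (up to mirror
#'     image) among the seven-crossing knots; found by search over
#'     alternating chord diagrams.  Its Jones span of 16 certifies the
#'     diagram reduced and the crossing number 7.}
#' }
#'
#' @return named list of fixture entries: each has `name`, `pd`,
#'   `free_loops`, the [link_diagram()] in `diagram`, and the expected
#'   `components`, `writhe`, `jhat` (a [laurent()] in q).
#' @export
fixture_table <- function() {
  jq <- function(exps, coefs) laurent(exps, coefs, var = "q")
  loop <- jq(c(-1, 1), c(1, 1))
  raw <- list(
    unknot0 = list(pd = "", free_loops = 1L, components = 1L, writhe = 0L,
                   jhat = loop),
    kink_pos = list(pd = "X(1,1,2,2)", free_loops = 0L, components = 1L,
                    writhe = 1L, jhat = loop),
    kink_neg = list(pd = "X(1,2,2,1)", free_loops = 0L, components = 1L,
                    writhe = -1L, jhat = loop),
    unknot_r2 = list(pd = "X(1,1,2,4) X(2,3,3,4)", free_loops = 0L,
                     components = 1L, writhe = 0L, jhat = loop),
    hopf_neg = list(pd = "X(4,1,3,2) X(2,3,1,4)", free_loops = 0L,
                    components = 2L, writhe = -2L,
                    jhat = jq(c(-6, -4, -2, 0), c(1, 1, 1, 1))),
    hopf_pos = list(pd = "X(4,2,3,1) X(2,4,1,3)", free_loops = 0L,
                    components = 2L, writhe = 2L,
                    jhat = jq(c(0, 2, 4, 6), c(1, 1, 1, 1))),
    trefoil_left = list(pd = "X(1,4,2,5) X(3,6,4,1) X(5,2,6,3)",
                        free_loops = 0L, components = 1L, writhe = -3L,
                        jhat = jq(c(-9, -5, -3, -1), c(-1, 1, 1, 1))),
    trefoil_right = list(pd = "X(1,5,2,4) X(3,1,4,6) X(5,3,6,2)",
                         free_loops = 0L, components = 1L, writhe = 3L,
                         jhat = jq(c(1, 3, 5, 9), c(1, 1, 1, -1))),
    fig8 = list(pd = "X(8,4,1,3) X(2,5,3,6) X(4,8,5,7) X(6,1,7,2)",
                free_loops = 0L, components = 1L, writhe = 0L,
                jhat = jq(c(-5, 5), c(1, 1))),
    example31 = list(pd = "X(4,5,1,8) X(1,7,2,8) X(2,7,3,6) X(3,5,4,6)",
                     free_loops = 0L, components = 2L, writhe = 0L,
                     jhat = jq(c(-2, 0, 2), c(1, 2, 1))),
    k7_6 = list(pd = paste("X(14,11,1,12) X(2,8,3,7) X(4,14,5,13)",
                           "X(6,10,7,9) X(8,4,9,3) X(10,1,11,2) X(12,6,13,5)"),
                free_loops = 0L, components = 1L, writhe = 3L,
                jhat = jq(c(-3, -1, 1, 5, 7, 9, 11, 13),
                          c(1, -1, 1, 1, 1, -1, 1, -1)))
  )
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    d <- parse_pd(e$pd, free_loops = e$free_loops)
    if (n_components(d) != e$components)
      stop("fixture ", nm, ": component count ", n_components(d),
           " != expected ", e$components)
    if (writhe(d) != e$writhe)
      stop("fixture ", nm, ": writhe ", writhe(d), " != expected ", e$writhe)
    jh <- unnormalized_jones_q(d)
    if (!lp_equal(jh, e$jhat))
      stop("fixture ", nm, ": unnormalized Jones ", format(jh),
           " != expected ", format(e$jhat))
    c(list(name = nm, diagram = d), e)
  })
  stats::setNames(out, names(raw))
}

#' Fetch one fixture diagram by name
#' @export
fixture_diagram <- function(name) {
  tb <- fixture_table()
  if (!name %in% names(tb))
    stop("unknown fixture: ", name, " (available: ",
         paste(names(tb), collapse = ", "), ")")
  tb[[name]]$diagram
}

#' The printed planar crossing coordinates of the seven-crossing example
#'
#' Returns the bundled 3D crossing coordinates (one row per crossing of
#' a 7_6-type knot diagram) used for the distance-based filtration
#' example; the xy-columns are the projection-plane coordinates.
#' @export
example_crossing_coords <- function() {
  path <- system.file("extdata", "crossings_7_6.csv", package = "ekhom")
  utils::read.csv(path)
}
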