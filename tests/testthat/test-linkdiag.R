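test_that("PD parsing infers signs, components and round-trips", {
  tre <- left_trefoil()
  expect_equal(n_crossings(tre), 3L)
  expect_equal(tre$signs, c(-1L, -1L, -1L))      # all left-handed
  expect_equal(unname(sign_counts(tre)), c(0L, 3L))
  expect_equal(n_components(tre), 1L)

  hopf <- neg_hopf()
  expect_equal(n_crossings(hopf), 2L)
  expect_equal(n_components(hopf), 2L)
  expect_equal(hopf$signs, c(-1L, -1L))

  # mirror kinks get opposite handedness
  expect_equal(kink_pos()$signs, 1L)
  expect_equal(kink_neg()$signs, -1L)

  # round-trip: emit -> parse reproduces the diagram exactly
  re <- parse_pd(emit_pd(tre))
  expect_identical(re$ends, tre$ends)
  expect_identical(re$signs, tre$signs)

  # crossingless unknot
  u <- unknot_loop()
  expect_equal(n_crossings(u), 0L)
  expect_equal(u$free_loops, 1L)

  expect_error(parse_pd("X(1,2,3,4)"), "dangling arc")
  expect_error(parse_pd("X(1,2"), "malformed")
})

test_that("writhe sums signs and flips under mirroring", {
  expect_equal(writhe(left_trefoil()), -3L)
  expect_equal(writhe(right_trefoil()), 3L)
  expect_equal(writhe(unknot_loop()), 0L)
  set.seed(7)
  for (rep in 1:10) {
    d <- random_knot_diagram(sample(2:5, 1))
    mir <- link_diagram(d$ends[, c(1, 4, 3, 2), drop = FALSE], -d$signs)
    expect_equal(writhe(mir), -writhe(d))
  }
})

test_that("state resolution matches the worked trefoil circle counts and a brute-force tracer", {
  tre <- left_trefoil()
  expect_equal(resolve_state(tre, c(0, 0, 0))$count, 3L)
  expect_equal(resolve_state(tre, c(1, 0, 1))$count, 1L)
  expect_equal(resolve_state(tre, c(1, 1, 1))$count, 2L)
  expect_error(resolve_state(tre, c(0, 1)), "unassigned")
  set.seed(11)
  for (rep in 1:8) {
    d <- random_knot_diagram(sample(2:5, 1))
    n <- n_crossings(d)
    for (t in 1:4) {
      s <- sample(0:1, n, replace = TRUE)
      expect_equal(resolve_state(d, s)$count, brute_circle_count(d, s))
    }
  }
})

test_that("smoothing removes one crossing and books free loops", {
  tre <- left_trefoil()
  s1 <- smooth_crossing(tre, 1, 1L)   # orientation-compatible resolution
  expect_equal(n_crossings(s1), 2L)
  expect_true(lp_equal(unnormalized_jones_q(s1), jhat_neg_hopf()))
  # the other resolution is disoriented: the inherited signs no longer
  # normalize the bracket, but the unoriented bracket keeps the
  # kinked-unknot shape (q + q^-1 times a kink monomial)
  s0 <- smooth_crossing(tre, 1, 0L)
  expect_true(lp_equal(bracket_q(s0), lp_mul(q_loop(), lp_mono(1, -2))))
  k <- smooth_crossing(kink_neg(), 1, 0L)
  expect_equal(n_crossings(k), 0L)
  expect_equal(k$free_loops, 1L)
  expect_error(smooth_crossing(tre, 9, 0L), "unknown crossing")
})

test_that("rho is the subcomplex-inducing resolution and commutes", {
  tre <- left_trefoil()
  r1 <- rho(tre, 1)
  expect_true(lp_equal(unnormalized_jones_q(r1), jhat_neg_hopf()))
  # order independence over all pairs on random fixtures
  set.seed(3)
  for (rep in 1:6) {
    d <- random_knot_diagram(4)
    prs <- utils::combn(d$ids, 2)
    for (cidx in seq_len(ncol(prs))) {
      x <- prs[1, cidx]; y <- prs[2, cidx]
      a <- rho(rho(d, x), y); b <- rho(rho(d, y), x)
      expect_identical(a$ends, b$ends)
      expect_identical(a$signs, b$signs)
      expect_identical(a$free_loops, b$free_loops)
    }
  }
  # full smoothing leaves a crossingless diagram
  full <- rho_set(tre, tre$ids)
  expect_equal(n_crossings(full), 0L)
  expect_gte(full$free_loops, 1L)
  expect_identical(rho_set(tre, integer(0))$ends, tre$ends)
  expect_error(rho(unknot_loop(), 1), "unknown crossing")
})

test_that("Gauss codes label first visits and balance over/under", {
  tre <- left_trefoil()
  g <- emit_gauss_code(tre, 1, 1L)
  expect_equal(nrow(g), 6L)
  expect_true(all(g$hand == "L"))
  expect_true(all(table(g$label) == 2L))
  # each label appears once over, once under
  for (lb in unique(g$label))
    expect_equal(sort(g$ou[g$label == lb]), c(-1L, 1L))
  # alternating diagram: over/under alternate along the traversal
  expect_true(all(abs(diff(g$ou)) == 2L))
  set.seed(23)
  for (rep in 1:6) {
    d <- random_knot_diagram(sample(3:6, 1))
    g2 <- emit_gauss_code(d, d$ids[1], 1L)
    expect_equal(nrow(g2), 2L * n_crossings(d))
    for (lb in unique(g2$label)) {
      expect_equal(sort(g2$ou[g2$label == lb]), c(-1L, 1L))
      expect_equal(length(unique(g2$hand[g2$label == lb])), 1L)
    }
  }
  expect_error(emit_gauss_code(tre, 99), "not a crossing")
})

test_that("genus detects non-realizable rotation systems", {
  expect_equal(diagram_genus(left_trefoil()), 0L)
  expect_equal(diagram_genus(neg_hopf()), 0L)
  # swapping two slots of one tuple breaks planarity of the trefoil code
  bad <- link_diagram(matrix(c(1,4,2,5, 3,6,4,1, 5,2,3,6), 3, 4, byrow = TRUE),
                      c(-1L,-1L,-1L))
  expect_gt(diagram_genus(bad), 0L)
})

test_that("JSON mirror round-trips diagrams with coordinates", {
  tre <- left_trefoil()
  tre$coords <- matrix(seq_len(6) / 2, 3, 2)
  tmp <- tempfile(fileext = ".json")
  diagram_to_json(tre, tmp)
  back <- diagram_from_json(tmp)
  expect_identical(back$ends, tre$ends)
  expect_identical(back$signs, tre$signs)
  expect_equal(back$coords, tre$coords)
  unlink(tmp)
})
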