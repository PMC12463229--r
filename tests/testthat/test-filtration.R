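test_that("indexed links respect the threshold mode", {
  tre <- left_trefoil()
  w <- weighted_link(tre, c(1, 2, 3), "ascending")
  expect_identical(indexed_link(w, 0.5)$ends, tre$ends)        # below all weights
  expect_equal(n_crossings(indexed_link(w, 1)), 2L)
  expect_equal(n_crossings(indexed_link(w, 10)), 0L)           # above all weights
  wd <- weighted_link(tre, c(1, 2, 3), "descending")
  expect_equal(n_crossings(indexed_link(wd, 3)), 2L)
  expect_identical(indexed_link(wd, 4)$ends, tre$ends)
  # monotonicity: larger ascending threshold smooths a superset
  set.seed(71)
  for (rep in 1:5) {
    d <- random_knot_diagram(4)
    wts <- stats::runif(4)
    wr <- weighted_link(d, wts, "ascending")
    as <- sort(c(wts, stats::runif(2)))
    for (i in seq_len(length(as) - 1L)) {
      sa <- crossing_set_at(wr, as[i]); sb <- crossing_set_at(wr, as[i + 1])
      expect_true(all(sa %in% sb))
    }
  }
})

test_that("filtration sequences end crossingless and group equal weights", {
  tre <- left_trefoil()
  fs <- filtration_sequence(weighted_link(tre, c(1, 2, 3), "ascending"))
  expect_equal(length(fs$diagrams), 4L)
  expect_equal(vapply(fs$diagrams, n_crossings, integer(1)), c(3L, 2L, 1L, 0L))
  expect_true(lp_equal(unnormalized_jones_q(fs$diagrams[[2]]), jhat_neg_hopf()))
  # constant weights: single event
  fs2 <- filtration_sequence(weighted_link(tre, c(5, 5, 5), "ascending"))
  expect_equal(length(fs2$diagrams), 2L)
  expect_equal(n_crossings(fs2$diagrams[[2]]), 0L)
  # final stage crossingless on random weighted fixtures
  set.seed(5)
  for (rep in 1:5) {
    d <- random_knot_diagram(sample(3:5, 1))
    w <- weighted_link(d, sample(10, n_crossings(d), replace = TRUE),
                       sample(c("ascending", "descending"), 1))
    fs3 <- filtration_sequence(w)
    last <- fs3$diagrams[[length(fs3$diagrams)]]
    expect_equal(n_crossings(last), 0L)
    expect_gte(last$free_loops, 1L)
  }
})

test_that("distance weights implement disk-touching radii", {
  d <- left_trefoil()
  d$coords <- matrix(c(0, 0, 2, 0, 1, 2), 3, 2, byrow = TRUE)
  wh <- distance_weights(d, "half")
  wf <- distance_weights(d, "full")
  expect_equal(unname(wf), 2 * unname(wh))
  expect_equal(unname(wf[1]), 2)        # nearest neighbour of crossing 1
  # two crossings at distance 2 -> both weights 1 (half)
  d2 <- neg_hopf()
  d2$coords <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(unname(distance_weights(d2, "half")), c(1, 1))
  # equilateral triangle, side s -> all s/2
  d3 <- left_trefoil()
  s <- 3
  d3$coords <- s * matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  expect_equal(unname(distance_weights(d3, "half")), rep(s / 2, 3))
  d4 <- left_trefoil()
  expect_error(distance_weights(d4), "coordinates")
})

test_that("critical radii reproduce the printed seven-crossing table", {
  path <- system.file("extdata", "crossings_7_6.csv", package = "ekhom")
  xyz <- utils::read.csv(path)
  r8 <- critical_radii(xyz[, c("x", "y")], 8L)
  expect_equal(round(r8, 3),
               c(1.053, 1.109, 1.279, 1.366, 1.724, 1.904, 1.953, 2.019))
  expect_equal(critical_radii(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE), 1L), 1)
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_equal(critical_radii(sq, 4L), rep(0.5, 4))
  expect_error(critical_radii(sq, 10L), "exceeds")
})

test_that("the printed coordinates give the documented per-crossing weights", {
  path <- system.file("extdata", "crossings_7_6.csv", package = "ekhom")
  xyz <- utils::read.csv(path)
  d <- fixture_diagram("k7_6")          # carries the 7-crossing topology
  d$coords <- as.matrix(xyz[, c("x", "y")])
  wh <- distance_weights(d, "half")
  expect_equal(round(min(wh), 3), 1.053)
  expect_equal(round(sort(unique(round(wh, 3)))[1:2], 3), c(1.053, 1.109))
})

test_that("unzip weights are a traversal-order bijection", {
  tre <- left_trefoil()
  uw <- unzip_weights(tre, start = 1, direction = 1L)
  expect_equal(sort(unname(uw)), c(1, 2, 3))
  expect_equal(unname(uw["1"]), 1)
  bw <- unzip_weights(tre, start = 1, direction = -1L)
  expect_equal(sort(unname(bw)), c(1, 2, 3))
  set.seed(9)
  for (rep in 1:5) {
    d <- random_knot_diagram(sample(3:6, 1))
    u <- unzip_weights(d, start = sample(d$ids, 1),
                       direction = sample(c(-1L, 1L), 1))
    expect_equal(sort(unname(u)), as.numeric(seq_len(n_crossings(d))))
  }
})
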