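# All-left-handed diagrams keep every stage inclusion height-preserving,
# mirroring the worked trefoil example; mixed-sign diagrams exercise the
# shifted gradings.
all_negative <- function(n) random_knot_diagram(n, fixed_sign = -1L)

test_that("the filtered trefoil complex nests as advertised", {
  w <- weighted_link(left_trefoil(), c(1, 2, 3), "ascending")
  fc <- build_filtered_complex(w)
  expect_equal(vapply(0:3, function(j) stage_subbasis_size(fc, j), integer(1)),
               c(30L, 12L, 6L, 4L))
  # subcomplex closure: the differential never points to a later-entering
  # basis vector
  tr <- fc$complex$d_triplets
  expect_true(all(fc$entry[tr$i] <= fc$entry[tr$j]))
  expect_error(build_filtered_complex(w, "Z"), "field")
})

test_that("subcomplex closure holds for every sign pattern", {
  set.seed(83)
  for (rep in 1:6) {
    d <- random_knot_diagram(sample(3:5, 1))
    w <- weighted_link(d, sample(10, n_crossings(d), replace = TRUE),
                       sample(c("ascending", "descending"), 1))
    fc <- build_filtered_complex(w)
    tr <- fc$complex$d_triplets
    expect_true(all(fc$entry[tr$i] <= fc$entry[tr$j]))
  }
})

test_that("weighted trefoil barcode reproduces the worked example", {
  w <- weighted_link(left_trefoil(), c(1, 2, 3), "ascending")
  bc <- ekh_barcode(w)
  alive <- bar_alive_at_stage(bc, 0) & bar_alive_at_stage(bc, 1)
  expect_equal(sum(alive), 3L)
  expect_equal(sort(bar_degree_at_stage(bc, 0)[alive]), c(-5L, -3L, -1L))
  expect_equal(sort(bar_degree_at_stage(bc, 1)[alive]), c(-4L, -2L, 0L))
  expect_equal(sort(bc$bars$k[alive]), c(-2L, 0L, 0L))
  expect_true(lp_equal(evolutionary_jones(bc, 0, 1),
                       laurent(c(-5, -3, -1), c(1, 1, 1))))
  # the one torsion-born class is confined to the Hopf stage
  short <- bc$bars$birth_stage == 1L & bc$bars$death_stage == 1L
  expect_equal(sum(short), 1L)
  expect_equal(bc$bars$k[short], -2L)
  expect_equal(bar_degree_at_stage(bc, 1)[short], -6L)
})

test_that("a = b evolutionary ranks equal the stage homology", {
  set.seed(37)
  cases <- list(weighted_link(left_trefoil(), c(1, 2, 3), "ascending"))
  for (rep in 1:5) {
    d <- random_knot_diagram(sample(3:5, 1))
    cases <- c(cases, list(weighted_link(
      d, sample(8, n_crossings(d), replace = TRUE), "ascending")))
  }
  for (w in cases) {
    bc <- ekh_barcode(w)
    for (a in unique(c(0, critical_parameters(w)))) {
      rk <- ekh_rank(bc, a, a)
      h <- khovanov_homology(khovanov_complex(indexed_link(w, a)), "Q")
      hk <- tapply(h$table$rank, h$table$k, sum)
      expect_equal(sum(rk), total_rank(h))
      expect_equal(as.integer(rk[names(hk)]), as.integer(hk))
    }
  }
})

test_that("barcode counts match stage Betti numbers at every stage", {
  set.seed(97)
  for (rep in 1:5) {
    d <- all_negative(sample(3:5, 1))
    w <- weighted_link(d, sample(9, n_crossings(d), replace = TRUE),
                       "ascending")
    bc <- ekh_barcode(w)
    for (j in 0:bc$m) {
      a <- if (j == 0) min(w$weights) - 1 else critical_parameters(w)[j]
      h <- khovanov_homology(khovanov_complex(indexed_link(w, a)), "Q")
      kj <- bar_height_at_stage(bc, j)
      expect_equal(sum(!is.na(kj)), total_rank(h))
      for (k in unique(h$table$k))
        expect_equal(sum(kj == k, na.rm = TRUE),
                     sum(h$table$rank[h$table$k == k]))
    }
  }
})

test_that("rank functoriality: spanning a wider window never increases rank", {
  set.seed(29)
  for (rep in 1:4) {
    d <- all_negative(4)
    w <- weighted_link(d, sample(8, 4, replace = TRUE), "ascending")
    bc <- ekh_barcode(w)
    cp <- c(0, critical_parameters(w))
    for (i in seq_along(cp)) for (j in seq_along(cp)) for (l in seq_along(cp)) {
      if (!(i <= j && j <= l)) next
      a <- cp[i]; b <- cp[j]; c0 <- cp[l]
      expect_lte(sum(ekh_rank(bc, a, c0)),
                 min(sum(ekh_rank(bc, a, b)), sum(ekh_rank(bc, b, c0))))
    }
  }
})

test_that("degree profiles change by the accumulated smoothing shifts", {
  w <- weighted_link(left_trefoil(), c(1, 2, 3), "ascending")
  bc <- ekh_barcode(w)
  prof <- bar_degree_profiles(bc)
  for (r in seq_len(nrow(bc$bars))) {
    p <- prof[[r]]
    if (length(p) > 1) {
      # all smoothed crossings are left-handed: -1 per stage toward L
      expect_true(all(diff(p) == 1L))
    }
  }
})

test_that("crossingless diagrams give immortal height-0 bar pairs", {
  u <- parse_pd("", free_loops = 1L)
  bc <- ekh_barcode(weighted_link(u, numeric(0), "ascending"))
  expect_equal(nrow(bc$bars), 2L)
  expect_true(all(bc$bars$k == 0L))
  expect_true(all(bc$bars$reaches_original))
  expect_equal(sort(bc$bars$q_ambient), c(-1L, 1L))
})

test_that("an unlinked diagram can carry non-trivial evolutionary homology", {
  d <- fixture_diagram("example31")
  expect_true(is_jones_trivial(d))
  g <- c(1, 3, 2, 4)
  wg <- weighted_link(d, g, "ascending")
  rk <- ekh_rank(wg, 2, 2)
  expect_equal(sum(rk), 4L)
  expect_equal(sort(as.integer(names(rk))), c(-2L, 0L))
  # the a = 2 stage is exactly the negative Hopf diagram
  hopf_stage <- indexed_link(wg, 2)
  expect_true(lp_equal(unnormalized_jones_q(hopf_stage),
                       jhat_neg_hopf()))
  # weight f passes through unlink-type stages only: each stage homology
  # sits at a single homological height with rank 2^(#components)
  wf <- weighted_link(d, c(1, 2, 3, 5), "ascending")
  for (a in critical_parameters(wf)) {
    ds <- indexed_link(wf, a)
    h <- khovanov_homology(khovanov_complex(ds), "Q")
    expect_equal(length(unique(h$table$k)), 1L)
    expect_equal(total_rank(h), 2L^n_components(ds))
  }
  # ... so the f barcode never shows two heights at one stage, while the
  # g barcode exhibits the Hopf signature at its a = 2 stage
  bf <- ekh_barcode(wf)
  for (j in 0:bf$m)
    expect_lte(length(unique(stats::na.omit(bar_height_at_stage(bf, j)))), 1L)
  bg <- ekh_barcode(wg)
  expect_equal(sort(unique(stats::na.omit(bar_height_at_stage(bg, 2)))),
               c(-2L, 0L))
})

test_that("evolutionary Jones at a window matches the bracket oracle at a = b", {
  set.seed(61)
  for (rep in 1:4) {
    d <- all_negative(sample(3:4, 1))
    w <- weighted_link(d, sample(6, n_crossings(d), replace = TRUE), "ascending")
    bc <- ekh_barcode(w)
    for (a in unique(c(0, critical_parameters(w)))) {
      expect_true(lp_equal(evolutionary_jones(bc, a, a),
                           unnormalized_jones_q(indexed_link(w, a))))
    }
  }
})

test_that("poincare_over_filtration matches the graded Euler characteristic stagewise", {
  w <- weighted_link(left_trefoil(), c(1, 2, 3), "ascending")
  po <- poincare_over_filtration(w)
  expect_equal(length(po), 4L)
  for (s in po) {
    d <- filtration_sequence(w)$diagrams[[s$stage + 1L]]
    expect_true(lp_equal(s$euler, unnormalized_jones_q(d)))
  }
  # the rho_x1 stage value from the worked example
  expect_true(lp_equal(po[[2]]$euler, laurent(c(-6, -4, -2, 0), rep(1, 4))))
})

test_that("barcodes serialize with parameters and degree profiles", {
  w <- weighted_link(left_trefoil(), c(1, 2, 3), "ascending")
  bc <- ekh_barcode(w)
  tmp <- tempfile(fileext = ".json")
  barcode_to_json(bc, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(length(back$bars), nrow(bc$bars))
  expect_equal(back$parameters, list(1L, 2L, 3L))
  unlink(tmp)
  pdg <- persistence_diagram(bc)
  expect_equal(nrow(pdg), nrow(bc$bars))
  expect_error(ekh_rank(bc, 2, 1), "a <= b")
})
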