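test_that("trefoil complex has the documented chain ranks and differential", {
  kc <- khovanov_complex(left_trefoil())
  expect_equal(unname(chain_ranks(kc)), c(8L, 12L, 6L, 4L))
  expect_true(d_squared_is_zero(kc))
  # the height -1 differential, written with basis expansions as rows
  B <- t(differential_matrix(kc, -1L))
  expect_equal(B, matrix(c(0, 1, 1, 0,
                           0, 0, 0, 1,
                           0, -1, -1, 0,
                           0, 0, 0, -1,
                           0, 1, 1, 0,
                           0, 0, 0, 1), 6, 4, byrow = TRUE))
})

test_that("trefoil homology reproduces the integral table with its 2-torsion", {
  tre <- left_trefoil()
  hz <- khovanov_homology(tre, "Z")
  free <- hz$table[hz$table$rank > 0, c("k", "l", "rank")]
  expect_equal(free[order(free$k, free$l), , drop = FALSE],
               data.frame(k = c(-3L, -2L, 0L, 0L), l = c(-9L, -5L, -3L, -1L),
                          rank = 1L),
               ignore_attr = TRUE)
  tor <- hz$table[nzchar(hz$table$torsion), ]
  expect_equal(nrow(tor), 1L)
  expect_equal(c(tor$k, tor$l), c(-2L, -7L))
  expect_identical(tor$torsion, "2")
  # characteristic 2 doubles H^-2; other fields do not
  h2 <- khovanov_homology(tre, 2)
  hq <- khovanov_homology(tre, "Q")
  expect_equal(sum(h2$table$rank[h2$table$k == -2]), 2L)
  expect_equal(sum(hq$table$rank[hq$table$k == -2]), 1L)
  expect_equal(sum(hq$table$rank[hq$table$k == -1]), 0L)
})

test_that("hopf link homology sits at heights -2 and 0 with dimension 2 each", {
  h <- khovanov_homology(neg_hopf(), "Q")
  expect_equal(total_rank(h), 4L)
  expect_equal(sort(unique(h$table$k)), c(-2L, 0L))
  expect_equal(sum(h$table$rank[h$table$k == -2]), 2L)
  expect_equal(sum(h$table$rank[h$table$k == 0]), 2L)
  expect_equal(sort(h$table$l), c(-6L, -4L, -2L, 0L))
})

test_that("rho stage of the trefoil reproduces its homology table", {
  h <- khovanov_homology(rho(left_trefoil(), 1), "Q")
  expect_equal(h$table[order(h$table$k, h$table$l), c("k", "l", "rank")],
               data.frame(k = c(-2L, -2L, 0L, 0L), l = c(-6L, -4L, -2L, 0L),
                          rank = 1L),
               ignore_attr = TRUE)
  expect_true(lp_equal(graded_euler(h),
                       laurent(c(-6, -4, -2, 0), rep(1, 4))))
})

test_that("crossingless diagrams concentrate at height 0 with (q+q^-1)^gamma", {
  for (g in 1:3) {
    h <- khovanov_homology(parse_pd("", free_loops = g), "Q")
    expect_equal(unique(h$table$k), 0L)
    expect_true(lp_equal(graded_betti(h, 0L), lp_pow(q_loop(), g)))
  }
  u <- khovanov_homology(unknot_loop(), "Q")
  expect_true(lp_equal(poincare_polynomial(u) |> l2_at_t(1),
                       q_loop()))
})

test_that("graded Euler characteristic equals the unnormalized Jones everywhere", {
  set.seed(101)
  fixtures <- list(left_trefoil(), right_trefoil(), neg_hopf(), kink_pos())
  for (rep in 1:8) fixtures <- c(fixtures, list(random_knot_diagram(sample(2:6, 1))))
  for (d in fixtures) {
    kc <- khovanov_complex(d)
    expect_true(d_squared_is_zero(kc))
    hq <- khovanov_homology(kc, "Q")
    expect_true(lp_equal(graded_euler(hq), unnormalized_jones_q(d)))
    # chain-level Euler characteristic agrees too
    chain_chi <- lp_zero("q")
    for (k in sort(unique(kc$basis$k))) {
      qs <- kc$basis$q[kc$basis$k == k]
      chain_chi <- lp_add(chain_chi,
                          lp_scale(laurent(qs, rep(1, length(qs))), (-1)^k))
    }
    expect_true(lp_equal(chain_chi, unnormalized_jones_q(d)))
  }
})

test_that("universal coefficients reconcile Q, F2 and Z", {
  set.seed(59)
  fixtures <- list(left_trefoil(), neg_hopf())
  for (rep in 1:5) fixtures <- c(fixtures, list(random_knot_diagram(sample(2:5, 1))))
  for (d in fixtures) {
    kc <- khovanov_complex(d)
    hq <- khovanov_homology(kc, "Q")$table
    h2 <- khovanov_homology(kc, 2)$table
    hz <- khovanov_homology(kc, "Z")$table
    dim_at <- function(tb, k, l) {
      r <- tb$rank[tb$k == k & tb$l == l]
      if (length(r)) sum(r) else 0L
    }
    tor2_at <- function(k, l) {
      tt <- hz$torsion[hz$k == k & hz$l == l]
      if (!length(tt) || !nzchar(tt)) return(0L)
      sum(as.numeric(strsplit(tt, ",")[[1]]) %% 2 == 0)
    }
    kls <- unique(rbind(hq[c("k", "l")], h2[c("k", "l")], hz[c("k", "l")]))
    for (r in seq_len(nrow(kls))) {
      k <- kls$k[r]; l <- kls$l[r]
      # free rank over Z equals the Q-dimension
      expect_equal(dim_at(hz, k, l), dim_at(hq, k, l))
      # F2 dimension = free rank + 2-torsion at k and at k+1 (UCT)
      expect_equal(dim_at(h2, k, l),
                   dim_at(hq, k, l) + tor2_at(k, l) + tor2_at(k + 1L, l))
    }
  }
})

test_that("coefficient guards reject invalid requests", {
  tre <- left_trefoil()
  hz <- khovanov_homology(tre, "Z")
  expect_error(graded_betti(hz, 0L), "field")
  expect_error(graded_euler(hz), "field")
  expect_error(khovanov_homology(tre, "F?"), "unknown coefficient")
  expect_error(khovanov_complex(left_trefoil(), max_crossings = 2L),
               "max_crossings")
})
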