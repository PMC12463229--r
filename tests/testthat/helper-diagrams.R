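# Shared diagram constructors and small oracles for the test suite.

left_trefoil <- function() parse_pd("X(1,4,2,5) X(3,6,4,1) X(5,2,6,3)")
right_trefoil <- function() parse_pd("X(1,5,2,4) X(3,1,4,6) X(5,3,6,2)")
neg_hopf <- function() parse_pd("X(4,1,3,2) X(2,3,1,4)")

unknot_loop <- function() parse_pd("", free_loops = 1L)
kink_pos <- function() parse_pd("X(1,1,2,2)")
kink_neg <- function() parse_pd("X(1,2,2,1)")

q_loop <- function() laurent(c(-1, 1), c(1, 1), var = "q")   # q + q^-1

jhat_neg_hopf <- function() laurent(c(-6, -4, -2, 0), rep(1, 4), var = "q")
jhat_left_trefoil <- function() laurent(c(-9, -5, -3, -1), c(-1, 1, 1, 1), var = "q")

# random realizable knot diagram via chord diagrams on 2n points:
# random pairing + over/under + signs, retried until the rotation system
# has genus zero
random_knot_diagram <- function(n, max_tries = 200L, fixed_sign = NULL) {
  stopifnot(n >= 1L)
  N <- 2L * n
  inc <- function(p) if (p == 1L) N else p - 1L
  for (t in seq_len(max_tries)) {
    pts <- sample(N)
    pairing <- lapply(seq_len(n), function(i) sort(pts[c(2 * i - 1, 2 * i)]))
    under <- sample(1:2, n, replace = TRUE)
    signs <- if (is.null(fixed_sign)) sample(c(-1L, 1L), n, replace = TRUE)
             else rep(as.integer(fixed_sign), n)
    ends <- matrix(0L, n, 4L)
    for (i in seq_len(n)) {
      pq <- pairing[[i]]
      u <- pq[under[i]]; o <- pq[3L - under[i]]
      a <- inc(u); cc <- u
      o_in <- inc(o); o_out <- o
      ends[i, ] <- if (signs[i] == 1L) c(a, o_out, cc, o_in) else c(a, o_in, cc, o_out)
    }
    d <- tryCatch(link_diagram(ends, signs), error = function(e) NULL)
    if (!is.null(d) && diagram_genus(d) == 0L) return(d)
  }
  stop("no planar random diagram found")
}

# independent brute-force circle count: resolve a state by tracing arcs
# through explicit end-gluings (no union-find)
brute_circle_count <- function(d, s) {
  pairs <- list()
  for (i in seq_len(n_crossings(d))) {
    r <- d$ends[i, ]
    if (s[i] == 0L) pairs <- c(pairs, list(r[c(1, 2)], r[c(3, 4)]))
    else pairs <- c(pairs, list(r[c(1, 4)], r[c(2, 3)]))
  }
  arcs <- sort(unique(as.vector(d$ends)))
  if (!length(arcs)) return(d$free_loops)
  grp <- as.list(arcs)
  find_grp <- function(a) which(vapply(grp, function(g) a %in% g, TRUE))[1]
  for (p in pairs) {
    ga <- find_grp(p[1]); gb <- find_grp(p[2])
    if (ga != gb) { grp[[ga]] <- c(grp[[ga]], grp[[gb]]); grp[[gb]] <- integer(0) }
  }
  sum(vapply(grp, length, 1L) > 0) + d$free_loops
}
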