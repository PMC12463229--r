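#' The Khovanov cochain complex of a link diagram
#'
#' States of the n-crossing diagram are the vertices of the cube
#' \{0,1\}^n (coordinates in sorted crossing-id order, first crossing
#' fastest).  A state s with circle count c(s) contributes the chain
#' group V^(x) c(s) at homological height k = l(s) - n-, where l(s) is the
#' number of 1-smoothings; a basis vector labels every circle of the
#' resolved state with v+ or v-, and has quantum degree
#' (#v+ - #v-) + l(s) + n+ - 2 n-.  Along a cube edge flipping one
#' coordinate 0 -> 1 the differential applies the Frobenius merge map m
#' (v+ v+ -> v+, mixed -> v-, v- v- -> 0) when two circles fuse, the
#' comultiplication Delta (v+ -> v+ v- + v- v+, v- -> v- v-) when one
#' circle splits, and the identity elsewhere, with the edge sign
#' (-1)^(s_1 + ... + s_(i-1)).
#'
#' @param d a [link_diagram()].
#' @param max_crossings guard on the exponential state cube.
#' @return an object of class `khovanov_complex` with the basis table,
#'   per-height sparse differentials, and state/circle bookkeeping.
#' @export
khovanov_complex <- function(d, max_crossings = 14L) {
  n <- n_crossings(d)
  if (n > max_crossings)
    stop("diagram has ", n, " crossings; raise max_crossings (state cube is 2^n)")
  sc <- sign_counts(d)
  npos <- unname(sc["pos"]); nneg <- unname(sc["neg"])
  nstates <- 2L^n
  states <- if (n) {
    m <- as.matrix(expand.grid(rep(list(0:1), n))); dimnames(m) <- NULL; m
  } else matrix(integer(), 1, 0)
  circ <- vector("list", nstates)   # circle arc-sets per state
  keys <- vector("list", nstates)   # string keys per circle
  gam <- integer(nstates)
  for (r in seq_len(nstates)) {
    rs <- resolve_state(d, states[r, ])
    circ[[r]] <- rs$circles
    keys[[r]] <- vapply(rs$circles, function(cc) paste(cc, collapse = ","), "")
    gam[r] <- rs$count
  }
  ell <- if (n) rowSums(states) else 0L
  # basis enumeration: per state, labeling masks 0..2^gamma-1
  # (bit j set = v- on circle j; circles ordered by smallest arc id)
  off <- c(0L, cumsum(2L^gam))
  nbasis <- off[nstates + 1L]
  b_state <- integer(nbasis); b_lab <- integer(nbasis)
  for (r in seq_len(nstates)) {
    idx <- (off[r] + 1L):off[r + 1L]
    b_state[idx] <- r
    b_lab[idx] <- 0:(2L^gam[r] - 1L)
  }
  b_nm <- vapply(b_lab, function(m) { c0 <- 0L; while (m > 0) { c0 <- c0 + m %% 2L; m <- m %/% 2L }; c0 }, integer(1))
  b_k <- ell[b_state] - nneg
  b_q <- (gam[b_state] - 2L * b_nm) + ell[b_state] + npos - 2L * nneg
  # differential triplets: global source/target basis indices, sign
  tri_i <- integer(0); tri_j <- integer(0); tri_x <- integer(0)
  if (n) {
    pow2 <- 2L^(0:(n - 1L))
    for (r in seq_len(nstates)) {
      s <- states[r, ]
      for (i in which(s == 0L)) {
        r2 <- r + pow2[i]
        sgn <- if (i > 1L && sum(s[seq_len(i - 1L)]) %% 2L == 1L) -1L else 1L
        k_src <- keys[[r]]; k_tgt <- keys[[r2]]
        src_only <- which(!(k_src %in% k_tgt))
        tgt_only <- which(!(k_tgt %in% k_src))
        common_map <- match(k_src, k_tgt)  # NA on src_only
        glab <- gam[r]
        for (lab in 0:(2L^glab - 1L)) {
          bits <- as.integer(intToBits(lab))[seq_len(glab)]
          tbits_base <- integer(gam[r2])
          ok <- TRUE
          for (cidx in seq_len(glab)) {
            if (!is.na(common_map[cidx])) tbits_base[common_map[cidx]] <- bits[cidx]
          }
          if (length(src_only) == 2L) {
            l1 <- bits[src_only[1]]; l2 <- bits[src_only[2]]
            if (l1 == 1L && l2 == 1L) next            # m(v- v-) = 0
            tb <- tbits_base
            tb[tgt_only[1]] <- if (l1 == 0L && l2 == 0L) 0L else 1L
            tlab <- sum(tb * 2L^(seq_along(tb) - 1L))
            tri_i <- c(tri_i, off[r2] + tlab + 1L)
            tri_j <- c(tri_j, off[r] + lab + 1L)
            tri_x <- c(tri_x, sgn)
          } else {
            l0 <- bits[src_only[1]]
            if (l0 == 0L) {
              for (pm in 1:2) {
                tb <- tbits_base
                tb[tgt_only[1]] <- if (pm == 1L) 0L else 1L
                tb[tgt_only[2]] <- if (pm == 1L) 1L else 0L
                tlab <- sum(tb * 2L^(seq_along(tb) - 1L))
                tri_i <- c(tri_i, off[r2] + tlab + 1L)
                tri_j <- c(tri_j, off[r] + lab + 1L)
                tri_x <- c(tri_x, sgn)
              }
            } else {
              tb <- tbits_base
              tb[tgt_only[1]] <- 1L; tb[tgt_only[2]] <- 1L
              tlab <- sum(tb * 2L^(seq_along(tb) - 1L))
              tri_i <- c(tri_i, off[r2] + tlab + 1L)
              tri_j <- c(tri_j, off[r] + lab + 1L)
              tri_x <- c(tri_x, sgn)
            }
          }
        }
      }
    }
  }
  kc <- list(diagram = d, n = n, npos = npos, nneg = nneg,
             states = states, circles = circ, keys = keys, gamma = gam,
             ell = ell, offsets = off,
             basis = data.frame(state = b_state, lab = b_lab,
                                k = b_k, q = b_q),
             d_triplets = data.frame(i = tri_i, j = tri_j, x = tri_x))
  class(kc) <- "khovanov_complex"
  kc
}

#' @export
print.khovanov_complex <- function(x, ...) {
  rk <- table(factor(x$basis$k, levels = sort(unique(x$basis$k))))
  cat("Khovanov complex: heights", -x$nneg, "..", x$npos,
      "; chain ranks:", paste(names(rk), unname(rk), sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

#' Chain ranks by homological height
#' @export
chain_ranks <- function(kc) {
  ks <- sort(unique(kc$basis$k))
  stats::setNames(vapply(ks, function(k) sum(kc$basis$k == k), integer(1)),
                  as.character(ks))
}

#' Dense differential matrix from height k to k+1 (rows = height k+1)
#' @export
differential_matrix <- function(kc, k, rows = NULL, cols = NULL) {
  src <- which(kc$basis$k == k)
  tgt <- which(kc$basis$k == k + 1L)
  if (!is.null(cols)) src <- intersect(src, cols)
  if (!is.null(rows)) tgt <- intersect(tgt, rows)
  M <- matrix(0L, length(tgt), length(src))
  tr <- kc$d_triplets
  sel <- tr$j %in% src & tr$i %in% tgt
  if (any(sel)) {
    ii <- match(tr$i[sel], tgt); jj <- match(tr$j[sel], src)
    for (t in seq_along(ii)) M[ii[t], jj[t]] <- M[ii[t], jj[t]] + tr$x[sel][t]
  }
  M
}

#' Verify d o d = 0 for the whole complex
#' @export
d_squared_is_zero <- function(kc) {
  for (k in sort(unique(kc$basis$k))) {
    A <- differential_matrix(kc, k)
    B <- differential_matrix(kc, k + 1L)
    if (length(A) && length(B) && any(B %*% A != 0)) return(FALSE)
  }
  TRUE
}

#' Khovanov homology of a complex
#'
#' Field coefficients give dimensions per (height k, degree l); integer
#' coefficients give free ranks plus torsion invariant factors from the
#' Smith normal form of the degree-l block of the incoming differential.
#'
#' @param kc a [khovanov_complex()] (or a [link_diagram()], which is
#'   promoted).
#' @param coeff `"Q"` (default), a prime such as `2`, or `"Z"`.
#' @return `khovanov_homology` object: data frame (k, l, rank, torsion)
#'   keeping only rows with a nonzero group.
#' @export
khovanov_homology <- function(kc, coeff = "Q") {
  if (inherits(kc, "link_diagram")) kc <- khovanov_complex(kc)
  co <- coeff_descriptor(coeff)
  bs <- kc$basis
  out <- data.frame(k = integer(), l = integer(), rank = integer(),
                    torsion = character(), stringsAsFactors = FALSE)
  for (k in sort(unique(bs$k))) {
    for (l in sort(unique(bs$q[bs$k == k]))) {
      cols_k <- which(bs$k == k & bs$q == l)
      dim_c <- length(cols_k)
      Mout <- differential_matrix(kc, k, cols = cols_k)
      Min <- differential_matrix(kc, k - 1L, rows = cols_k)
      if (co$type == "field") {
        rk_out <- field_rank(Mout, co)
        rk_in <- field_rank(Min, co)
        r <- dim_c - rk_out - rk_in
        if (r > 0)
          out <- rbind(out, data.frame(k = k, l = l, rank = r, torsion = ""))
      } else {
        f_in <- smith_invariant_factors(Min)
        rk_in <- length(f_in)
        rk_out <- int_rank(Mout)
        r <- dim_c - rk_out - rk_in
        tor <- f_in[f_in > 1]
        if (r > 0 || length(tor))
          out <- rbind(out, data.frame(k = k, l = l, rank = r,
                                       torsion = paste(tor, collapse = ",")))
      }
    }
  }
  structure(list(table = out, coeff = co$label,
                 heights = range(bs$k), complex_ranks = chain_ranks(kc)),
            class = "khovanov_homology")
}

coeff_descriptor <- function(coeff) {
  if (identical(coeff, "Z") || identical(coeff, "integer"))
    return(list(type = "Z", label = "Z"))
  if (identical(coeff, "Q") || identical(coeff, "rational"))
    return(list(type = "field", p = 0, label = "Q"))
  if (is.numeric(coeff) && length(coeff) == 1 && coeff >= 2)
    return(list(type = "field", p = as.integer(coeff),
                label = paste0("F", as.integer(coeff))))
  stop("unknown coefficient choice: ", coeff)
}

field_rank <- function(M, co) {
  if (!length(M)) return(0L)
  if (co$p == 0) int_rank(M) else modp_rank(M, co$p)
}

#' @export
print.khovanov_homology <- function(x, ...) {
  cat("Khovanov homology over", x$coeff, "\n")
  tb <- x$table
  if (!nrow(tb)) { cat("  trivial\n"); return(invisible(x)) }
  for (r in seq_len(nrow(tb))) {
    cat(sprintf("  H^{%d, %d}: rank %d%s\n", tb$k[r], tb$l[r], tb$rank[r],
                if (nzchar(tb$torsion[r])) paste0(" + torsion Z/", tb$torsion[r]) else ""))
  }
  invisible(x)
}

#' Total rank (sum of ranks/dimensions over all bidegrees)
#' @export
total_rank <- function(h) sum(h$table$rank)

#' Graded Betti polynomial at height k: beta_k(q) = sum_l dim H^{k,l} q^l
#' @export
graded_betti <- function(h, k) {
  if (!identical(substr(h$coeff, 1, 1), "Q") && !grepl("^F", h$coeff))
    stop("graded dimensions need field coefficients, not ", h$coeff)
  tb <- h$table[h$table$k == k, , drop = FALSE]
  if (!nrow(tb)) return(lp_zero("q"))
  laurent(tb$l, tb$rank, var = "q")
}

#' Graded Poincare polynomial Kh(L) = sum_k beta_k(q) t^k
#' @export
poincare_polynomial <- function(h) {
  if (identical(h$coeff, "Z")) stop("graded dimensions need field coefficients")
  tb <- h$table
  laurent2(tb$k, tb$l, tb$rank)
}

#' Graded Euler characteristic chi_q(L) = sum_k (-1)^k beta_k(q)
#'
#' Equals the unnormalized Jones polynomial (categorification).
#' @export
graded_euler <- function(h) {
  if (identical(h$coeff, "Z")) stop("graded dimensions need field coefficients")
  tb <- h$table
  if (!nrow(tb)) return(lp_zero("q"))
  laurent(tb$l, tb$rank * (-1)^tb$k, var = "q")
}

#' Write a homology table as CSV (columns k, l, rank, torsion)
#' @export
write_homology_csv <- function(h, path) {
  utils::write.csv(h$table, path, row.names = FALSE)
  invisible(path)
}
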