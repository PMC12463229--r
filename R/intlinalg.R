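# Exact linear algebra over Z, Q and F_p on small dense integer matrices.
# All entries stay integral: rank over Q uses integer row elimination with
# gcd reduction, so no floating-point rounding can affect the result.

#' Exact rank of an integer matrix (over the rationals)
#' @param M numeric matrix with integer entries.
#' @export
int_rank <- function(M) {
  M <- as.matrix(M)
  if (!length(M)) return(0L)
  stopifnot(all(M == round(M)))
  nr <- nrow(M); nc <- ncol(M)
  r <- 0L
  for (col in seq_len(nc)) {
    piv <- which(M[, col] != 0 & seq_len(nr) > r)
    if (!length(piv)) next
    # smallest pivot keeps entries tame
    piv <- piv[which.min(abs(M[piv, col]))]
    r <- r + 1L
    if (piv != r) { tmp <- M[r, ]; M[r, ] <- M[piv, ]; M[piv, ] <- tmp }
    below <- which(M[, col] != 0 & seq_len(nr) > r)
    for (i in below) {
      a <- M[r, col]; b <- M[i, col]
      g <- int_gcd(a, b)
      M[i, ] <- (a / g) * M[i, ] - (b / g) * M[r, ]
      gi <- int_gcd_vec(M[i, ])
      if (gi > 1) M[i, ] <- M[i, ] / gi
    }
    if (r == nr) break
  }
  r
}

int_gcd <- function(a, b) { a <- abs(a); b <- abs(b); while (b) { t <- b; b <- a %% b; a <- t }; a }
int_gcd_vec <- function(v) { g <- 0; for (x in v) { g <- int_gcd(g, x); if (g == 1) break }; max(g, 1) }

#' Rank of an integer matrix over the prime field F_p
#' @export
modp_rank <- function(M, p) {
  M <- as.matrix(M) %% p
  if (!length(M)) return(0L)
  nr <- nrow(M); nc <- ncol(M)
  r <- 0L
  for (col in seq_len(nc)) {
    piv <- which(M[, col] != 0 & seq_len(nr) > r)
    if (!length(piv)) next
    piv <- piv[1]
    r <- r + 1L
    if (piv != r) { tmp <- M[r, ]; M[r, ] <- M[piv, ]; M[piv, ] <- tmp }
    inv <- modp_inv(M[r, col], p)
    M[r, ] <- (M[r, ] * inv) %% p
    for (i in seq_len(nr)) {
      if (i != r && M[i, col] != 0)
        M[i, ] <- (M[i, ] - M[i, col] * M[r, ]) %% p
    }
    if (r == nr) break
  }
  r
}

modp_inv <- function(a, p) {
  a <- a %% p
  # p is prime and small; Fermat
  r <- 1; b <- a; e <- p - 2
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * b) %% p
    b <- (b * b) %% p
    e <- e %/% 2
  }
  r
}

#' Smith normal form invariant factors of an integer matrix
#'
#' Returns the nonzero invariant factors d1 | d2 | ... (positive), whose
#' count is the rank.  Row/column operations pivot on a smallest nonzero
#' entry to limit coefficient growth; matrices arising from Khovanov
#' differentials are small and have entries bounded well below 2^53, so
#' double-precision integer arithmetic is exact here.
#' @export
smith_invariant_factors <- function(M) {
  M <- as.matrix(M)
  if (!length(M) || all(M == 0)) return(numeric(0))
  stopifnot(all(M == round(M)))
  factors <- numeric(0)
  t0 <- 1L
  repeat {
    sub <- M[t0:nrow(M), t0:ncol(M), drop = FALSE]
    if (!length(sub) || all(sub == 0)) break
    repeat {
      nz <- which(sub != 0, arr.ind = TRUE)
      pick <- nz[which.min(abs(sub[nz])), , drop = TRUE]
      pi <- pick[1]; pj <- pick[2]
      if (pi != 1) { tmp <- sub[1, ]; sub[1, ] <- sub[pi, ]; sub[pi, ] <- tmp }
      if (pj != 1) { tmp <- sub[, 1]; sub[, 1] <- sub[, pj]; sub[, pj] <- tmp }
      p <- sub[1, 1]
      # clear column
      changed <- FALSE
      for (i in seq_len(nrow(sub))[-1]) {
        if (sub[i, 1] != 0) {
          q <- round(sub[i, 1] / p)
          sub[i, ] <- sub[i, ] - q * sub[1, ]
          if (sub[i, 1] != 0) changed <- TRUE
        }
      }
      for (j in seq_len(ncol(sub))[-1]) {
        if (sub[1, j] != 0) {
          q <- round(sub[1, j] / p)
          sub[, j] <- sub[, j] - q * sub[, 1]
          if (sub[1, j] != 0) changed <- TRUE
        }
      }
      if (!changed &&
          all(sub[-1, 1] == 0) && all(sub[1, -1] == 0)) {
        # pivot must divide every remaining entry for the divisibility chain
        rest <- sub[-1, -1, drop = FALSE]
        bad <- which(rest %% sub[1, 1] != 0, arr.ind = TRUE)
        if (length(bad)) {
          i <- bad[1, 1] + 1L
          sub[1, ] <- sub[1, ] + sub[i, ]
        } else break
      }
    }
    factors <- c(factors, abs(sub[1, 1]))
    M[t0:nrow(M), t0:ncol(M)] <- sub
    t0 <- t0 + 1L
    if (t0 > nrow(M) || t0 > ncol(M)) break
  }
  factors
}
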