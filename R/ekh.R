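#' Evolutionary Khovanov homology
#'
#' The weighted link's filtration of diagrams gives a nested tower of
#' Khovanov complexes: smoothing a crossing with the orientation-
#' compatible resolution realizes the smaller complex as the subcomplex
#' of the ambient complex spanned by the basis vectors whose state takes
#' the fixed coordinate at every smoothed crossing (1 at left-handed, 0
#' at right-handed crossings).  The induced maps on homology form a
#' persistence module; its interval decomposition is computed by the
#' standard column reduction of the differential, run over the tower
#' ordered from the most-smoothed complex to the original one.  Because
#' all stage complexes share the ambient grading, the reduction splits
#' into independent (height, degree) blocks.
#'
#' @name ekh
NULL

#' Build the filtered Khovanov complex of a weighted link
#'
#' @param w a [weighted_link()].
#' @param coeff field coefficients: `"Q"` (default) or a prime.
#' @return object of class `filtered_khovanov` holding the ambient
#'   complex, per-basis-vector entry times into the increasing tower
#'   (0 = already present in the fully smoothed complex), the stage
#'   parameters, and per-stage q-degree shifts.
#' @export
build_filtered_complex <- function(w, coeff = "Q") {
  co <- coeff_descriptor(coeff)
  if (co$type != "field")
    stop("persistence needs field coefficients (got ", co$label, ")")
  d <- w$diagram
  kc <- khovanov_complex(d)
  n <- n_crossings(d)
  cp <- critical_parameters(w)
  m <- length(cp)
  # stage at which each crossing is smoothed (1..m)
  cross_stage <- vapply(seq_len(n), function(i) {
    if (w$mode == "ascending") match(w$weights[i], cp) else match(w$weights[i], cp)
  }, integer(1))
  rv <- vapply(seq_len(n), function(i) rho_value(d$signs[i]), integer(1))
  # depth of a basis vector: number of leading stages whose smoothed set
  # it is compatible with (state pinned to 1 at every smoothed crossing);
  # entry time into the increasing tower F_i = C_(m - i) is m - depth.
  depth <- integer(nrow(kc$basis))
  if (n) {
    st <- kc$states[kc$basis$state, , drop = FALSE]
    ok <- st == matrix(rv, nrow(st), n, byrow = TRUE)
    for (v in seq_len(nrow(st))) {
      bad <- which(!ok[v, ])
      depth[v] <- if (!length(bad)) m else min(cross_stage[bad]) - 1L
    }
  } else depth <- rep(0L, nrow(kc$basis))
  # grading seen inside the stage-j subcomplex, relative to the ambient
  # grading of C(L): each smoothed left-handed crossing shifts the
  # quantum degree by +1; each right-handed one shifts degree by -2 and
  # homological height by -1.
  shift_q <- vapply(0:m, function(j) {
    S <- if (j == 0L) integer(0) else which(cross_stage <= j)
    sum(d$signs[S] == -1L) - 2L * sum(d$signs[S] == 1L)
  }, integer(1))
  shift_k <- vapply(0:m, function(j) {
    S <- if (j == 0L) integer(0) else which(cross_stage <= j)
    -sum(d$signs[S] == 1L)
  }, integer(1))
  out <- list(weighted = w, complex = kc, m = m, parameters = cp,
              entry = m - depth, cross_stage = cross_stage,
              stage_shift = shift_q, stage_shift_k = shift_k, coeff = co)
  class(out) <- "filtered_khovanov"
  out
}

#' Total rank of a stage subcomplex (basis vectors present at stage j)
#' @export
stage_subbasis_size <- function(fc, j) sum(fc$entry <= fc$m - j)

# column reduction of one (height, degree) block over Q (exact integer
# columns, normalized by gcd) or F_p
reduce_block <- function(cols, p = 0) {
  # cols: integer matrix (rows already sorted by entry order)
  nc <- ncol(cols)
  pivot_owner <- integer(0)  # row -> column index
  low <- integer(nc)
  for (v in seq_len(nc)) {
    col <- cols[, v]
    if (p > 0) col <- col %% p
    repeat {
      nz <- which(col != 0)
      if (!length(nz)) break
      piv <- max(nz)
      u <- if (as.character(piv) %in% names(pivot_owner)) pivot_owner[[as.character(piv)]] else 0L
      if (u == 0L) break
      colu <- cols[, u]
      if (p > 0) {
        col <- (col - (col[piv] * modp_inv(colu[piv], p)) * colu) %% p
      } else {
        a <- colu[piv]; b <- col[piv]
        g <- int_gcd(a, b)
        col <- (a / g) * col - (b / g) * colu
        gg <- int_gcd_vec(col)
        if (gg > 1) col <- col / gg
      }
    }
    cols[, v] <- col
    nz <- which(col != 0)
    if (length(nz)) {
      low[v] <- max(nz)
      pivot_owner[[as.character(low[v])]] <- v
    }
  }
  list(cols = cols, low = low)
}

#' Barcode of the evolutionary Khovanov homology
#'
#' Runs the persistence reduction over the filtered complex and returns
#' one bar per interval summand.  Bars are reported on the stage axis of
#' the filtration: `birth_stage` is the most-smoothed stage at which the
#' class exists, `death_stage` the least-smoothed stage (0 = the
#' original diagram; such bars are flagged `reaches_original`, they are
#' the free part of the decomposition).  Every bar carries its
#' homological height `k`, its ambient quantum degree `q_ambient`, and a
#' per-stage degree profile obtained from the accumulated +/-1 shifts of
#' the subcomplex inclusions.
#'
#' @param w a [weighted_link()] or prebuilt [build_filtered_complex()].
#' @param coeff `"Q"` or a prime.
#' @param keep_empty keep zero-length intervals? (default drops them)
#' @return object of class `ekh_barcode`: data frame of bars plus
#'   filtration metadata.
#' @export
ekh_barcode <- function(w, coeff = "Q", keep_empty = FALSE) {
  fc <- if (inherits(w, "filtered_khovanov")) w else build_filtered_complex(w, coeff)
  kc <- fc$complex
  bs <- kc$basis
  p <- fc$coeff$p
  nb <- nrow(bs)
  ord <- order(fc$entry, seq_len(nb))  # global filtration order
  pos <- integer(nb); pos[ord] <- seq_len(nb)
  birth <- rep(NA_integer_, nb)   # entry time of created class, by creator
  death <- rep(NA_integer_, nb)   # death entry time, by creator
  creator <- logical(nb)
  tr <- kc$d_triplets
  for (k in sort(unique(bs$k))) {
    for (qd in sort(unique(bs$q[bs$k == k]))) {
      src <- which(bs$k == k & bs$q == qd)
      tgt <- which(bs$k == k + 1L & bs$q == qd)
      src <- src[order(fc$entry[src], src)]
      if (!length(src)) next
      if (!length(tgt)) {
        creator[src] <- TRUE; birth[src] <- fc$entry[src]
        next
      }
      tgt <- tgt[order(fc$entry[tgt], tgt)]
      M <- matrix(0L, length(tgt), length(src))
      sel <- tr$j %in% src & tr$i %in% tgt
      if (any(sel)) {
        ii <- match(tr$i[sel], tgt); jj <- match(tr$j[sel], src)
        xx <- tr$x[sel]
        for (t in seq_along(ii)) M[ii[t], jj[t]] <- M[ii[t], jj[t]] + xx[t]
      }
      red <- reduce_block(M, p)
      for (v in seq_along(src)) {
        if (red$low[v] == 0L) {
          creator[src[v]] <- TRUE
          birth[src[v]] <- fc$entry[src[v]]
        } else {
          u <- tgt[red$low[v]]
          death[u] <- fc$entry[src[v]]
        }
      }
    }
  }
  # creators at the top height never get columns; killed-ness recorded via death
  bars <- data.frame(
    k = bs$k[creator],
    q_ambient = bs$q[creator],
    birth_entry = birth[creator],
    death_entry = ifelse(is.na(death[creator]), Inf, death[creator]))
  # translate to stage axis: alive at stage j iff birth <= m - j < death
  m <- fc$m
  bars$birth_stage <- m - bars$birth_entry
  bars$death_stage <- ifelse(is.infinite(bars$death_entry), 0L,
                             m - bars$death_entry + 1L)
  bars$reaches_original <- bars$death_stage == 0L
  if (!keep_empty) bars <- bars[bars$death_stage <= bars$birth_stage, , drop = FALSE]
  rownames(bars) <- NULL
  out <- list(bars = bars, m = m, parameters = fc$parameters,
              stage_shift = fc$stage_shift, stage_shift_k = fc$stage_shift_k,
              mode = fc$weighted$mode,
              coeff = fc$coeff$label, filtered = fc)
  class(out) <- "ekh_barcode"
  out
}

#' @export
print.ekh_barcode <- function(x, ...) {
  cat("EKH barcode over ", x$coeff, " (", x$mode, " filtration, ",
      x$m, " critical parameter(s))\n", sep = "")
  b <- x$bars
  if (!nrow(b)) { cat("  empty\n"); return(invisible(x)) }
  for (r in seq_len(nrow(b))) {
    j0 <- b$death_stage[r]
    cat(sprintf("  k = %2d: stages [%d, %d]%s, (height, degree) there = (%d, %d)\n",
                b$k[r], j0, b$birth_stage[r],
                if (b$reaches_original[r]) " (reaches the original link)" else "",
                b$k[r] + x$stage_shift_k[j0 + 1L],
                b$q_ambient[r] + x$stage_shift[j0 + 1L]))
  }
  invisible(x)
}

#' Is a bar alive at a given stage?
#' @export
bar_alive_at_stage <- function(bc, j) {
  b <- bc$bars
  b$death_stage <= j & j <= b$birth_stage
}

#' q-degree of each bar at a given stage (NA when not alive there)
#' @export
bar_degree_at_stage <- function(bc, j) {
  deg <- bc$bars$q_ambient + bc$stage_shift[j + 1L]
  deg[!bar_alive_at_stage(bc, j)] <- NA_integer_
  deg
}

#' Homological height of each bar as graded inside a given stage
#' (NA when not alive there)
#' @export
bar_height_at_stage <- function(bc, j) {
  k <- bc$bars$k + bc$stage_shift_k[j + 1L]
  k[!bar_alive_at_stage(bc, j)] <- NA_integer_
  k
}

#' Per-stage degree profile of every bar
#' @export
bar_degree_profiles <- function(bc) {
  lapply(seq_len(nrow(bc$bars)), function(r) {
    js <- bc$bars$death_stage[r]:bc$bars$birth_stage[r]
    stats::setNames(bc$bars$q_ambient[r] + bc$stage_shift[js + 1L],
                    as.character(js))
  })
}

#' Rank of the (a, b)-evolutionary Khovanov homology at height k
#'
#' The image rank of the map on height-k homology induced by the
#' inclusion of the more-smoothed stage complex into the less-smoothed
#' one; equals the number of bars at height k alive at both stages.  At
#' a = b this is the homology dimension of the a-indexed link.
#'
#' @param w a [weighted_link()] or an [ekh_barcode()].
#' @param a,b window thresholds, a <= b.
#' @param k single height, or NULL for all heights (named vector);
#'   heights are graded inside the less-smoothed stage of the window.
#' @export
ekh_rank <- function(w, a, b = a, k = NULL, coeff = "Q") {
  if (a > b) stop("window must have a <= b")
  bc <- if (inherits(w, "ekh_barcode")) w else ekh_barcode(w, coeff)
  fw <- bc$filtered$weighted
  ja <- stage_of_param(fw, a); jb <- stage_of_param(fw, b)
  jdeg <- min(ja, jb)
  alive <- bar_alive_at_stage(bc, ja) & bar_alive_at_stage(bc, jb)
  kk_all <- bc$bars$k + bc$stage_shift_k[jdeg + 1L]
  if (is.null(k)) {
    ks <- sort(unique(kk_all[alive]))
    stats::setNames(vapply(ks, function(kk) sum(alive & kk_all == kk),
                           integer(1)), as.character(ks))
  } else sum(alive & kk_all == k)
}

#' (a, b)-evolutionary Betti table: bar counts per (height, degree at the
#' less-smoothed stage of the window)
#' @export
evolutionary_betti <- function(w, a, b = a, coeff = "Q") {
  bc <- if (inherits(w, "ekh_barcode")) w else ekh_barcode(w, coeff)
  fw <- bc$filtered$weighted
  ja <- stage_of_param(fw, a); jb <- stage_of_param(fw, b)
  jdeg <- min(ja, jb)
  alive <- bar_alive_at_stage(bc, ja) & bar_alive_at_stage(bc, jb)
  b2 <- bc$bars[alive, , drop = FALSE]
  if (!nrow(b2)) return(data.frame(k = integer(), l = integer(), rank = integer()))
  deg <- b2$q_ambient + bc$stage_shift[jdeg + 1L]
  kk <- b2$k + bc$stage_shift_k[jdeg + 1L]
  agg <- stats::aggregate(list(rank = rep(1L, nrow(b2))),
                          by = list(k = kk, l = deg), FUN = sum)
  agg[order(agg$k, agg$l), ]
}

#' (a, b)-evolutionary unnormalized Jones polynomial
#'
#' The alternating sum over heights of the graded dimensions of the
#' evolutionary homology, graded at the less-smoothed stage of the
#' window.
#' @export
evolutionary_jones <- function(w, a, b = a, coeff = "Q") {
  tb <- evolutionary_betti(w, a, b, coeff)
  if (!nrow(tb)) return(lp_zero("q"))
  laurent(tb$l, tb$rank * (-1)^tb$k, var = "q")
}

#' Graded Poincare polynomial of every stage of the filtration
#'
#' Computes the Khovanov homology of each indexed link independently
#' (not through the barcode), one (stage, polynomial) entry per critical
#' parameter plus the original diagram at stage 0.
#' @export
poincare_over_filtration <- function(w, coeff = "Q") {
  fs <- filtration_sequence(w)
  lapply(seq_along(fs$diagrams), function(j) {
    h <- khovanov_homology(khovanov_complex(fs$diagrams[[j]]), coeff)
    list(stage = j - 1L,
         parameter = if (j > 1) fs$parameters[j - 1L] else NA_real_,
         poincare = poincare_polynomial(h),
         euler = graded_euler(h))
  })
}

#' Serialize a barcode to JSON
#' @export
barcode_to_json <- function(bc, path = NULL) {
  prof <- bar_degree_profiles(bc)
  obj <- list(
    coeff = bc$coeff, mode = bc$mode, parameters = bc$parameters,
    bars = lapply(seq_len(nrow(bc$bars)), function(r) {
      b <- bc$bars[r, ]
      list(k = b$k,
           birth_stage = b$birth_stage,
           death_stage = b$death_stage,
           birth_param = if (b$birth_stage >= 1) bc$parameters[b$birth_stage] else NULL,
           death_param = if (b$death_stage >= 1) bc$parameters[b$death_stage] else NULL,
           reaches_original = b$reaches_original,
           degree_profile = as.list(prof[[r]]))
    }))
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Persistence-diagram table (birth, death, k) on the stage axis
#' @export
persistence_diagram <- function(bc) {
  data.frame(birth = bc$bars$birth_stage, death = bc$bars$death_stage,
             k = bc$bars$k)
}
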