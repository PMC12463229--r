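#' Space curves and planar projection
#'
#' A space curve is an ordered 3D polyline, optionally closed and
#' optionally split into several components (chains).  Projecting a
#' closed curve onto a coordinate plane and recording, at every
#' transverse segment intersection, which strand lies closer to the
#' viewer produces a link diagram; this is how knotted biomolecular
#' backbones (e.g. RNA phosphorus traces) enter the pipeline.
#'
#' @param points numeric matrix with 3 columns (x, y, z).
#' @param closed is the curve closed (last point joins the first)?
#' @param breaks optional integer vector: row indices that start a new
#'   component (for multi-chain links); the first component always
#'   starts at row 1.
#' @export
space_curve <- function(points, closed = FALSE, breaks = integer()) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns")
  starts <- sort(unique(c(1L, as.integer(breaks))))
  idx <- split(seq_len(nrow(points)),
               findInterval(seq_len(nrow(points)), starts))
  for (cmp in idx) {
    if (length(cmp) < 3L) stop("each component needs at least 3 points")
    p <- points[cmp, , drop = FALSE]
    if (any(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2) == 0))
      stop("consecutive points must be distinct")
  }
  sc <- list(points = points, closed = closed, starts = starts)
  class(sc) <- "space_curve"
  sc
}

#' @export
print.space_curve <- function(x, ...) {
  cat(sprintf("space curve: %d point(s), %d component(s), %s\n",
              nrow(x$points), length(x$starts),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Close an open curve by joining the terminal points of each component
#' @export
close_curve <- function(sc) {
  if (sc$closed) return(sc)
  sc$closed <- TRUE
  sc
}

curve_components <- function(sc) {
  ends <- c(sc$starts[-1] - 1L, nrow(sc$points))
  lapply(seq_along(sc$starts), function(i)
    sc$points[sc$starts[i]:ends[i], , drop = FALSE])
}

# segment list of a closed component: rows i -> i+1 and last -> first
component_segments <- function(p) {
  a <- p
  b <- p[c(2:nrow(p), 1L), , drop = FALSE]
  list(a = a, b = b)
}

seg_intersect_2d <- function(p1, p2, p3, p4, eps) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < eps) {
    # parallel: degenerate only if collinear with overlapping extents
    cr <- (p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]
    if (abs(cr) < eps * (sum(abs(d1)) + 1)) {
      t0 <- sum((p3 - p1) * d1) / sum(d1^2)
      t1 <- sum((p4 - p1) * d1) / sum(d1^2)
      if (max(min(t0, t1), 0) <= min(max(t0, t1), 1)) return("degenerate")
    }
    return(NULL)
  }
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) {
    if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) return(NULL)
    return("degenerate")                     # endpoint hit / near-tangency
  }
  list(t = t, u = u, pt = p1 + t * d1)
}

rotation_xyz <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Project a closed space curve to a link diagram
#'
#' All pairwise intersections between non-adjacent projected segments
#' are found by a quadratic scan.  At each intersection the strand with
#' the larger value along the discarded axis is the over-strand, and
#' handedness follows from the planar cross product of the oriented
#' over- and under-strand directions.  A projection failing regularity
#' (near-parallel segments, endpoint hits, crossings too close together,
#' or equal depths) triggers a small seeded random rotation of the whole
#' curve and a retry.
#'
#' @param sc a closed [space_curve()].
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param seed seed for the perturbation rotations (default 0).
#' @param max_retries maximum number of rotation retries.
#' @param angle0 initial rotation magnitude in radians (doubles per retry).
#' @param eps relative regularity tolerance.
#' @return list of class `projection_result`: `diagram` (a
#'   [link_diagram()] with planar coordinates), `plane`, `rotated`,
#'   `retries`.
#' @export
project_curve <- function(sc, plane = c("xy", "xz", "yz"), seed = 0L,
                          max_retries = 20L, angle0 = 1e-3, eps = 1e-9) {
  plane <- match.arg(plane)
  if (!sc$closed) stop("curve must be closed before projection (see close_curve)")
  # the in-plane frame (first two axes) viewed from the positive side of
  # the discarded axis: (x,y) from +z and (y,z) from +x are right-handed,
  # (x,z) from +y is left-handed, so handedness signs flip there
  axes <- switch(plane, xy = c(1L, 2L, 3L), xz = c(1L, 3L, 2L), yz = c(2L, 3L, 1L))
  flip <- if (plane == "xz") -1 else 1
  pts0 <- sc$points
  rng <- local({ set.seed(seed); function(n) stats::runif(n, -1, 1) })
  angle <- angle0
  for (try in 0:max_retries) {
    pts <- if (try == 0L) pts0 else {
      R <- rotation_xyz(angle * rng(1), angle * rng(1), angle * rng(1))
      angle <- angle * 2
      pts0 %*% t(R)
    }
    res <- try_projection(pts, sc$starts, axes, eps, flip)
    if (!is.null(res)) {
      res$plane <- plane
      res$rotated <- try > 0L
      res$retries <- try
      class(res) <- "projection_result"
      return(res)
    }
  }
  stop("no regular projection found after ", max_retries,
       " perturbation retries; the configuration stays degenerate")
}

try_projection <- function(pts, starts, axes, eps, flip = 1) {
  comps <- curve_components(space_curve(pts, closed = TRUE, breaks = starts[-1]))
  segs_a <- NULL; segs_b <- NULL; seg_comp <- integer(0); seg_idx <- integer(0)
  nseg_comp <- integer(0)
  for (ci in seq_along(comps)) {
    s <- component_segments(comps[[ci]])
    segs_a <- rbind(segs_a, s$a); segs_b <- rbind(segs_b, s$b)
    seg_comp <- c(seg_comp, rep(ci, nrow(s$a)))
    seg_idx <- c(seg_idx, seq_len(nrow(s$a)))
    nseg_comp <- c(nseg_comp, nrow(s$a))
  }
  nseg <- nrow(segs_a)
  scale <- max(apply(rbind(segs_a, segs_b)[, axes[1:2], drop = FALSE], 2,
                     function(v) diff(range(v))), 1)
  tol <- eps * scale
  xing <- list()
  for (i in seq_len(nseg - 1L)) {
    for (j in (i + 1L):nseg) {
      adjacent <- seg_comp[i] == seg_comp[j] &&
        (abs(seg_idx[i] - seg_idx[j]) == 1L ||
           abs(seg_idx[i] - seg_idx[j]) == nseg_comp[seg_comp[i]] - 1L)
      if (adjacent) next
      r <- seg_intersect_2d(segs_a[i, axes[1:2]], segs_b[i, axes[1:2]],
                            segs_a[j, axes[1:2]], segs_b[j, axes[1:2]], 1e-9)
      if (is.null(r)) next
      if (identical(r, "degenerate")) return(NULL)
      zi <- segs_a[i, axes[3]] + r$t * (segs_b[i, axes[3]] - segs_a[i, axes[3]])
      zj <- segs_a[j, axes[3]] + r$u * (segs_b[j, axes[3]] - segs_a[j, axes[3]])
      if (abs(zi - zj) < tol) return(NULL)   # equal depths
      xing[[length(xing) + 1L]] <- list(i = i, j = j, t = r$t, u = r$u,
                                        pt = r$pt, zi = zi, zj = zj)
    }
  }
  # triple points / crossings too close
  if (length(xing) > 1L) {
    P <- t(vapply(xing, function(x) x$pt, numeric(2)))
    if (min(stats::dist(P)) < 1e-6 * scale) return(NULL)
  }
  diagram <- crossings_to_diagram(xing, seg_comp, seg_idx, nseg_comp,
                                  segs_a, segs_b, axes, flip)
  list(diagram = diagram)
}

# Convert intersection records into a PD-style diagram by walking each
# component and cutting it at its crossing passages.
crossings_to_diagram <- function(xing, seg_comp, seg_idx, nseg_comp,
                                 segs_a, segs_b, axes, flip = 1) {
  ncross <- length(xing)
  ncomp <- length(nseg_comp)
  if (ncross == 0L)
    return(link_diagram(free_loops = ncomp))
  # passages: two per crossing (segment, position along segment)
  pas <- do.call(rbind, lapply(seq_len(ncross), function(c0) {
    x <- xing[[c0]]
    rbind(data.frame(crossing = c0, seg = x$i, tpos = x$t,
                     over = x$zi > x$zj),
          data.frame(crossing = c0, seg = x$j, tpos = x$u,
                     over = x$zj > x$zi))
  }))
  pas$comp <- seg_comp[pas$seg]
  # involved components only: others become free loops
  involved <- sort(unique(pas$comp))
  free_loops <- ncomp - length(involved)
  # order passages along each component's traversal -> arcs
  arc_of_passage <- integer(nrow(pas))
  next_arc <- 1L
  pass_in_arc <- list()  # per component: ordered passage row indices
  for (ci in involved) {
    rows <- which(pas$comp == ci)
    rows <- rows[order(seg_idx[pas$seg[rows]], pas$tpos[rows])]
    np <- length(rows)
    # arc r: from passage r to passage r+1 (cyclic); the arc BEFORE
    # passage r is arc (r-1); assign labels consecutively along the
    # orientation so PD parsing conventions hold
    arcs <- next_arc:(next_arc + np - 1L)
    next_arc <- next_arc + np
    for (r in seq_len(np)) {
      # incoming arc at passage r is arcs[r - 1] (cyclic), outgoing arcs[r]
      arc_of_passage[rows[r]] <- arcs[r]
    }
    pass_in_arc[[as.character(ci)]] <- rows
  }
  incoming_arc <- function(row) {
    ci <- pas$comp[row]
    rows <- pass_in_arc[[as.character(ci)]]
    r <- match(row, rows)
    prev <- if (r == 1L) length(rows) else r - 1L
    arc_of_passage[rows[prev]]
  }
  ends <- matrix(0L, ncross, 4L)
  signs <- integer(ncross)
  coords <- matrix(0, ncross, 2L)
  for (c0 in seq_len(ncross)) {
    rows <- which(pas$crossing == c0)
    under <- rows[!pas$over[rows]]; over <- rows[pas$over[rows]]
    u_in <- incoming_arc(under); u_out <- arc_of_passage[under]
    o_in <- incoming_arc(over); o_out <- arc_of_passage[over]
    # direction vectors in the projection plane
    dvec <- function(row) {
      s <- pas$seg[row]
      v <- segs_b[s, axes[1:2]] - segs_a[s, axes[1:2]]
      v / sqrt(sum(v^2))
    }
    du <- dvec(under); dov <- dvec(over)
    s0 <- flip * sign(dov[1] * du[2] - dov[2] * du[1])  # det[over, under]
    signs[c0] <- if (s0 >= 0) 1L else -1L
    # tuple (a, b, c, d) counterclockwise from incoming under-strand:
    # positive crossing has over-strand incoming at d, negative at b
    if (signs[c0] == 1L) ends[c0, ] <- c(u_in, o_out, u_out, o_in)
    else ends[c0, ] <- c(u_in, o_in, u_out, o_out)
    coords[c0, ] <- xing[[c0]]$pt
  }
  link_diagram(ends, signs, free_loops = free_loops, coords = coords)
}

#' @export
print.projection_result <- function(x, ...) {
  cat("projection onto the", x$plane, "plane",
      if (x$rotated) sprintf("(after %d perturbation retries)", x$retries) else "",
      "\n")
  print(x$diagram)
  invisible(x)
}

# ---- readers -------------------------------------------------------------

#' Read a curve from an xyz table (CSV with columns x, y, z and an
#' optional component column)
#' @export
read_xyz <- function(path, closed = FALSE) {
  tb <- utils::read.csv(path)
  names(tb) <- tolower(names(tb))
  need <- c("x", "y", "z")
  if (!all(need %in% names(tb))) {
    if (ncol(tb) >= 3 && all(vapply(tb[1:3], is.numeric, TRUE)))
      names(tb)[1:3] <- need
    else stop("xyz table needs numeric columns x, y, z: ", path)
  }
  breaks <- integer()
  if ("component" %in% names(tb)) {
    comp <- tb$component
    breaks <- which(c(FALSE, comp[-1] != comp[-length(comp)]))
  }
  space_curve(as.matrix(tb[, need]), closed = closed, breaks = breaks)
}

#' Read a backbone curve from a minimal PDB file
#'
#' Only `ATOM`/`HETATM` records are considered; the curve consists of
#' the selected atom (phosphorus `P` for nucleic-acid backbones or `CA`
#' for protein traces) in record order, which follows the chain from 5'
#' to 3' (or N- to C-terminus).  Multiple chains become separate
#' components.
#'
#' @param path PDB file.
#' @param atom `"P"` or `"CA"`.
#' @param chain optional chain identifier filter.
#' @export
read_backbone <- function(path, atom = c("P", "CA"), chain = NULL) {
  atom <- match.arg(atom)
  lines <- readLines(path)
  recs <- grep("^(ATOM|HETATM)", lines)
  if (!length(recs)) stop("no ATOM records in ", path)
  pts <- NULL; chains <- character(0)
  for (ln in recs) {
    l <- lines[ln]
    if (nchar(l) < 54) stop("malformed ATOM record at line ", ln, " of ", path)
    nm <- trimws(substr(l, 13, 16))
    ch <- trimws(substr(l, 22, 22))
    if (nm != atom) next
    if (!is.null(chain) && ch != chain) next
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz)) stop("malformed coordinates at line ", ln, " of ", path)
    pts <- rbind(pts, xyz)
    chains <- c(chains, ch)
  }
  if (is.null(pts))
    stop("no atoms named ", atom,
         if (!is.null(chain)) paste0(" in chain ", chain), " found in ", path)
  breaks <- which(c(FALSE, chains[-1] != chains[-length(chains)]))
  rownames(pts) <- NULL
  space_curve(pts, closed = FALSE, breaks = breaks)
}

# ---- synthetic curves ----------------------------------------------------

#' Synthetic space curves for tests and examples
#'
#' `torus(p, q)` samples the (p,q)-torus knot on the standard torus
#' (`torus(2, 3)` projects to a 3-crossing trefoil diagram for 40+
#' samples); `circle` is a planar circle (unknot); `random_walk` is a
#' closed seeded random loop (a smoothed random polygon).
#'
#' @param kind `"torus"`, `"circle"` or `"random_walk"`.
#' @param samples number of polyline points (>= 12).
#' @param seed RNG seed (random_walk only).
#' @param p,q torus-knot parameters.
#' @export
synthetic_curve <- function(kind = c("torus", "circle", "random_walk"),
                            samples = 60L, seed = 0L, p = 2L, q = 3L) {
  kind <- match.arg(kind)
  if (samples < 12L) stop("need at least 12 samples")
  t0 <- 2 * pi * (seq_len(samples) - 1L) / samples
  pts <- switch(kind,
    torus = cbind((2 + cos(q * t0)) * cos(p * t0),
                  (2 + cos(q * t0)) * sin(p * t0),
                  sin(q * t0)),
    circle = cbind(cos(t0), sin(t0), 0 * t0),
    random_walk = {
      set.seed(seed)
      # random Fourier loop: smooth, closed, seeded
      nmodes <- 4L
      a <- matrix(stats::rnorm(3 * nmodes, sd = 1 / seq_len(nmodes)), 3, nmodes, byrow = TRUE)
      b <- matrix(stats::rnorm(3 * nmodes, sd = 1 / seq_len(nmodes)), 3, nmodes, byrow = TRUE)
      pts <- vapply(1:3, function(dim0)
        colSums(a[dim0, ] * cos(outer(seq_len(nmodes), t0)) +
                b[dim0, ] * sin(outer(seq_len(nmodes), t0))), numeric(samples))
      pts
    })
  space_curve(pts, closed = TRUE)
}
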