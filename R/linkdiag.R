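#' Planar link diagrams
#'
#' A link diagram is stored combinatorially: one row per crossing holding
#' the four incident arc identifiers in the fixed rotational convention
#' (counterclockwise starting from the incoming under-strand: `a` =
#' under-in, `b`, `c` = under-out, `d`), a handedness sign per crossing
#' (+1 right-handed, -1 left-handed), an optional planar coordinate per
#' crossing, and a count of crossing-free circle components ("free
#' loops") so that smoothing can disconnect circles without losing them.
#'
#' @param ends integer matrix with 4 columns (a, b, c, d), one row per
#'   crossing.
#' @param signs vector of crossing signs in \{-1, +1\}.
#' @param ids integer crossing identifiers (default 1..n); rows are kept
#'   sorted by id, and all state-cube coordinates use this order.
#' @param free_loops number of crossingless circle components.
#' @param coords optional n x 2 matrix of planar crossing coordinates.
#' @return an object of class `link_diagram`.
#' @export
link_diagram <- function(ends = matrix(integer(), 0, 4), signs = integer(),
                         ids = NULL, free_loops = 0L, coords = NULL) {
  ends <- matrix(as.integer(ends), ncol = 4)
  n <- nrow(ends)
  if (length(signs) != n) stop("need one sign per crossing")
  if (n && !all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  if (is.null(ids)) ids <- seq_len(n)
  if (anyDuplicated(ids)) stop("crossing ids must be unique")
  o <- order(ids)
  ends <- ends[o, , drop = FALSE]
  signs <- as.integer(signs)[o]
  ids <- as.integer(ids)[o]
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 2)[o, , drop = FALSE]
  }
  if (n) {
    tab <- table(as.vector(ends))
    bad <- names(tab)[tab != 2]
    if (length(bad))
      stop("arc id(s) not occurring exactly twice: ", paste(bad, collapse = ", "))
  }
  d <- list(ends = ends, signs = signs, ids = ids,
            free_loops = as.integer(free_loops), coords = coords)
  class(d) <- "link_diagram"
  d
}

#' @export
n_crossings <- function(d) nrow(d$ends)

#' Crossing sign counts n+ and n-
#' @export
sign_counts <- function(d)
  c(pos = sum(d$signs == 1L), neg = sum(d$signs == -1L))

#' Writhe number: n+ - n-
#' @export
writhe <- function(d) {
  stopifnot(inherits(d, "link_diagram"))
  sum(d$signs == 1L) - sum(d$signs == -1L)
}

#' @export
arcs_of <- function(d) sort(unique(as.vector(d$ends)))

# ---- union-find ----------------------------------------------------------

uf_new <- function(labels) {
  stats::setNames(labels, as.character(labels))
}
uf_find <- function(uf, x) {
  k <- as.character(x)
  while (uf[[k]] != x) { x <- uf[[k]]; k <- as.character(x) }
  x
}
uf_union <- function(uf, x, y) {
  rx <- uf_find(uf, x); ry <- uf_find(uf, y)
  if (rx != ry) uf[[as.character(max(rx, ry))]] <- min(rx, ry)
  uf
}

# ---- orientation / flow --------------------------------------------------

# For each crossing, the over-strand's incoming and outgoing arc follow
# from the sign: left-handed (-1) crossings have the over-strand
# entering at b and leaving at d; right-handed (+1) the reverse.
over_in <- function(d, i) if (d$signs[i] == -1L) d$ends[i, 2L] else d$ends[i, 4L]
over_out <- function(d, i) if (d$signs[i] == -1L) d$ends[i, 4L] else d$ends[i, 2L]

#' Connected components of the underlying strands
#'
#' Arcs joined through a crossing (under-in with under-out, and the two
#' over arcs) belong to the same link component.
#' @return list of sorted arc-id vectors, ordered by smallest arc id.
#' @export
strand_components <- function(d) {
  arcs <- arcs_of(d)
  if (!length(arcs)) return(list())
  uf <- uf_new(arcs)
  for (i in seq_len(n_crossings(d))) {
    uf <- uf_union(uf, d$ends[i, 1L], d$ends[i, 3L])
    uf <- uf_union(uf, d$ends[i, 2L], d$ends[i, 4L])
  }
  reps <- vapply(arcs, function(a) uf_find(uf, a), numeric(1))
  comps <- split(arcs, reps)
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  unname(lapply(comps, sort))
}

#' Number of link components (including free loops)
#' @export
n_components <- function(d) length(strand_components(d)) + d$free_loops

# ---- PD code parsing -----------------------------------------------------

#' Parse a planar-diagram (PD) code
#'
#' Accepts text such as `"X(1,4,2,5) X(3,6,4,1) X(5,2,6,3)"` with tuples
#' in the convention: arcs listed counterclockwise starting from the
#' incoming under-strand, and arcs numbered consecutively along each
#' oriented component.  Crossing signs are inferred from the orientation
#' of the over-strand relative to the under-strand.
#'
#' @param text PD code string (one diagram).
#' @param free_loops extra crossingless circles to attach.
#' @return a [link_diagram()].
#' @export
parse_pd <- function(text, free_loops = 0L) {
  text <- paste(text, collapse = " ")
  m <- gregexpr("X\\s*[\\(\\[]\\s*(-?\\d+)\\s*,\\s*(-?\\d+)\\s*,\\s*(-?\\d+)\\s*,\\s*(-?\\d+)\\s*[\\)\\]]", text, perl = TRUE)
  tuples <- regmatches(text, m)[[1]]
  if (!length(tuples)) {
    if (grepl("X", text)) stop("malformed PD tuple in: ", text)
    return(link_diagram(free_loops = free_loops))
  }
  leftover <- gsub("X\\s*[\\(\\[][^\\)\\]]*[\\)\\]]", "", text, perl = TRUE)
  if (grepl("X", leftover))
    stop("malformed PD tuple near position ",
         regexpr("X", leftover)[1], " of: ", trimws(leftover))
  ends <- t(vapply(tuples, function(tp) {
    as.integer(strsplit(gsub("[^0-9,-]", "", tp), ",")[[1]])
  }, integer(4)))
  rownames(ends) <- NULL
  tab <- table(as.vector(ends))
  bad <- names(tab)[tab != 2]
  if (length(bad))
    stop("dangling arc id(s): ", paste(bad, collapse = ", "),
         " (every arc must occur exactly twice)")
  signs <- infer_pd_signs(ends)
  link_diagram(ends, signs, free_loops = free_loops)
}

# Successor of each arc under the consecutive-numbering convention:
# within each component the arcs are sorted and the successor of the
# largest wraps to the smallest.
arc_successors <- function(ends) {
  arcs <- sort(unique(as.vector(ends)))
  uf <- uf_new(arcs)
  for (i in seq_len(nrow(ends))) {
    uf <- uf_union(uf, ends[i, 1L], ends[i, 3L])
    uf <- uf_union(uf, ends[i, 2L], ends[i, 4L])
  }
  reps <- vapply(arcs, function(a) uf_find(uf, a), numeric(1))
  succ <- integer(0)
  for (comp in split(arcs, reps)) {
    comp <- sort(comp)
    succ[as.character(comp)] <- c(comp[-1], comp[1])
  }
  succ
}

infer_pd_signs <- function(ends) {
  n <- nrow(ends)
  succ <- arc_successors(ends)
  for (i in seq_len(n))
    if (succ[as.character(ends[i, 1L])] != ends[i, 3L])
      stop("tuple ", i, ": under-strand ", ends[i, 1L], " -> ", ends[i, 3L],
           " breaks the consecutive arc-numbering convention")
  # flow assignment: each arc occurrence is "in" or "out"; under slots are
  # fixed, over slots are propagated so every arc has one of each.
  occ <- data.frame(crossing = rep(seq_len(n), 4L),
                    slot = rep(1:4, each = n),
                    arc = as.vector(ends))
  occ$dir <- NA_character_
  occ$dir[occ$slot == 1L] <- "in"
  occ$dir[occ$slot == 3L] <- "out"
  repeat {
    changed <- FALSE
    for (a in unique(occ$arc)) {
      w <- which(occ$arc == a)
      dirs <- occ$dir[w]
      if (sum(is.na(dirs)) == 1L) {
        occ$dir[w[is.na(dirs)]] <- setdiff(c("in", "out"), dirs)
        changed <- TRUE
      } else if (!any(is.na(dirs)) && dirs[1] == dirs[2]) {
        stop("inconsistent strand orientation at arc ", a)
      }
    }
    for (i in seq_len(n)) {
      w <- which(occ$crossing == i & occ$slot %in% c(2L, 4L))
      dirs <- occ$dir[w]
      if (sum(is.na(dirs)) == 1L) {
        occ$dir[w[is.na(dirs)]] <- setdiff(c("in", "out"), dirs)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # any still-undetermined over pair (a component that is over-strand at
  # every crossing): orient it by the consecutive-numbering rule, with the
  # smaller arc taken as flowing toward the larger.
  for (i in seq_len(n)) {
    wb <- which(occ$crossing == i & occ$slot == 2L)
    if (is.na(occ$dir[wb])) {
      b <- ends[i, 2L]; dd <- ends[i, 4L]
      occ$dir[wb] <- if (succ[as.character(b)] == dd) "in" else "out"
      wd <- which(occ$crossing == i & occ$slot == 4L)
      occ$dir[wd] <- setdiff(c("in", "out"), occ$dir[wb])
      # re-propagate
      repeat {
        changed <- FALSE
        for (a in unique(occ$arc)) {
          w <- which(occ$arc == a)
          dirs <- occ$dir[w]
          if (sum(is.na(dirs)) == 1L) {
            occ$dir[w[is.na(dirs)]] <- setdiff(c("in", "out"), dirs)
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
  }
  vapply(seq_len(n), function(i) {
    bdir <- occ$dir[occ$crossing == i & occ$slot == 2L]
    if (identical(bdir, "in")) -1L else 1L
  }, integer(1))
}

#' Emit the PD code text of a diagram
#' @export
emit_pd <- function(d) {
  if (!n_crossings(d))
    return(if (d$free_loops > 0) paste0("O", strrep(" O", d$free_loops - 1L)) else "")
  paste(apply(d$ends, 1L, function(r) sprintf("X(%d,%d,%d,%d)", r[1], r[2], r[3], r[4])),
        collapse = " ")
}

# ---- smoothing and resolution --------------------------------------------

# arc pairings created by each smoothing of tuple (a, b, c, d):
#   0-smoothing joins (a,b) and (c,d); 1-smoothing joins (a,d) and (b,c).
# This labelling is fixed by the state cube of the complex: for an
# all-left-handed trefoil the (0,0,0) resolution has three circles.
smoothing_pairs <- function(row, choice) {
  if (choice == 0L) list(c(row[1L], row[2L]), c(row[3L], row[4L]))
  else list(c(row[1L], row[4L]), c(row[2L], row[3L]))
}

#' Replace one crossing by a smoothing
#'
#' @param d a [link_diagram()].
#' @param x crossing id.
#' @param choice 0 or 1.
#' @return a diagram with one crossing fewer; a circle that loses all its
#'   crossings becomes a free loop.
#' @export
smooth_crossing <- function(d, x, choice) {
  i <- match(x, d$ids)
  if (is.na(i)) stop("unknown crossing id: ", x)
  stopifnot(choice %in% c(0L, 1L))
  prs <- smoothing_pairs(d$ends[i, ], choice)
  rest <- d$ends[-i, , drop = FALSE]
  arcs4 <- unique(as.vector(d$ends[i, ]))
  uf <- uf_new(arcs4)
  for (p in prs) uf <- uf_union(uf, p[1L], p[2L])
  reps <- vapply(arcs4, function(a) uf_find(uf, a), numeric(1))
  relab <- stats::setNames(reps, as.character(arcs4))
  if (nrow(rest)) {
    v <- as.vector(rest)
    hit <- v %in% arcs4
    v[hit] <- relab[as.character(v[hit])]
    rest <- matrix(as.integer(v), ncol = 4L)
  }
  new_loops <- sum(!unique(reps) %in% as.vector(rest))
  link_diagram(rest, d$signs[-i], ids = d$ids[-i],
               free_loops = d$free_loops + new_loops,
               coords = if (!is.null(d$coords)) d$coords[-i, , drop = FALSE])
}

#' Circles of a full resolution
#'
#' @param d a [link_diagram()].
#' @param s state: 0/1 vector over crossings in sorted-id order, or a
#'   named vector keyed by crossing id.
#' @return list with `circles` (list of sorted arc-id vectors; free loops
#'   appear as negative singleton pseudo-ids) and `count`.
#' @export
resolve_state <- function(d, s) {
  n <- n_crossings(d)
  s <- state_vector(d, s)
  arcs <- arcs_of(d)
  circles <- list()
  if (length(arcs)) {
    uf <- uf_new(arcs)
    for (i in seq_len(n)) {
      prs <- smoothing_pairs(d$ends[i, ], s[i])
      for (p in prs) uf <- uf_union(uf, p[1L], p[2L])
    }
    reps <- vapply(arcs, function(a) uf_find(uf, a), numeric(1))
    circles <- unname(lapply(split(arcs, reps), sort))
  }
  if (d$free_loops > 0)
    circles <- c(circles, lapply(seq_len(d$free_loops), function(j) -j))
  circles <- circles[order(vapply(circles, min, numeric(1)))]
  list(circles = circles, count = length(circles))
}

state_vector <- function(d, s) {
  n <- n_crossings(d)
  if (!is.null(names(s)) && all(names(s) %in% as.character(d$ids))) {
    miss <- setdiff(as.character(d$ids), names(s))
    if (length(miss)) stop("state leaves crossing(s) unassigned: ",
                           paste(miss, collapse = ", "))
    s <- s[as.character(d$ids)]
  }
  if (length(s) != n) stop("state leaves crossing(s) unassigned: expected ",
                           n, " coordinates, got ", length(s))
  s <- as.integer(s)
  if (n && !all(s %in% c(0L, 1L))) stop("state coordinates must be 0 or 1")
  s
}

#' The smoothing operator used by filtrations
#'
#' Replaces crossing `x` by its 1-smoothing.  The state-cube face with
#' coordinate 1 at `x` is the unique face closed under the Khovanov
#' differential (the differential only turns 0-coordinates into 1s), so
#' the complex of `rho(d, x)` embeds into the complex of `d` as a
#' genuine subcomplex for every handedness of `x`.  At a left-handed
#' crossing this resolution is also the orientation-compatible one and
#' the inclusion preserves homological height while shifting the
#' quantum degree by -1; at a right-handed crossing the inclusion
#' shifts height by +1 and degree by +2.
#' @export
rho <- function(d, x) {
  i <- match(x, d$ids)
  if (is.na(i)) stop("unknown crossing id: ", x)
  smooth_crossing(d, x, 1L)
}

#' Apply the smoothing operator over a set of crossings
#'
#' The result is independent of the order in which the crossings of `S`
#' are smoothed.
#' @export
rho_set <- function(d, S) {
  S <- unique(S)
  if (!all(S %in% d$ids))
    stop("unknown crossing id(s): ", paste(setdiff(S, d$ids), collapse = ", "))
  for (x in S) d <- rho(d, x)
  d
}

# the state-cube coordinate a smoothed crossing is pinned to inside the
# subcomplex of its rho-smoothing (always the closed 1-face)
rho_value <- function(sign) 1L

# ---- Gauss code ----------------------------------------------------------

#' Emit the (extended) Gauss code of a diagram
#'
#' Walks the diagram from the chosen starting crossing in the chosen
#' direction, labelling crossings 1, 2, ... in first-visit order.  An
#' overcrossing visit is recorded with a positive sign and an
#' undercrossing visit with a negative one; the extended form appends
#' the handedness mark `R` (right-handed) or `L` (left-handed).
#' Components beyond the first are visited in order of their smallest
#' incident arc id and separated by `|` in the text form.
#'
#' @param d a [link_diagram()] with at least one crossing.
#' @param start crossing id at which labelling starts.
#' @param direction +1 to follow the orientation, -1 to walk against it.
#' @param extended append handedness marks?
#' @return object of class `gauss_code`: a data frame (label, ou, hand,
#'   crossing, component) with the text form in attribute `"text"`.
#' @export
emit_gauss_code <- function(d, start = d$ids[1], direction = 1L, extended = TRUE) {
  n <- n_crossings(d)
  if (!n) stop("diagram has no crossings")
  if (!start %in% d$ids) stop("start is not a crossing id: ", start)
  stopifnot(direction %in% c(-1L, 1L))
  # incoming-arc lookup: arc -> (crossing index, passage type)
  inc <- list()
  for (i in seq_len(n)) {
    u_in <- d$ends[i, 1L]; u_out <- d$ends[i, 3L]
    o_in <- over_in(d, i); o_out <- over_out(d, i)
    if (direction == -1L) { tmp <- u_in; u_in <- u_out; u_out <- tmp
                            tmp <- o_in; o_in <- o_out; o_out <- tmp }
    inc[[as.character(u_in)]] <- rbind(inc[[as.character(u_in)]],
                                       c(i, 0L, u_out))  # under passage
    inc[[as.character(o_in)]] <- rbind(inc[[as.character(o_in)]],
                                       c(i, 1L, o_out))  # over passage
  }
  si <- match(start, d$ids)
  # begin at the start crossing's own under passage so it gets label 1:
  # the walk starts on its incoming under-strand arc
  first_arc <- if (direction == 1L) d$ends[si, 1L] else d$ends[si, 3L]
  visits <- data.frame(crossing = integer(), over = integer(), component = integer())
  seen_arcs <- integer(0)
  comp <- 1L
  arc <- first_arc
  repeat {
    repeat {
      if (arc %in% seen_arcs) break
      seen_arcs <- c(seen_arcs, arc)
      entry <- inc[[as.character(arc)]]
      if (is.null(entry) || nrow(entry) != 1L)
        stop("diagram is not traversable: arc ", arc,
             " is the head of ", if (is.null(entry)) 0L else nrow(entry),
             " passages (crossing signs inconsistent with an orientation)")
      pick <- entry[1, ]
      visits <- rbind(visits, data.frame(crossing = pick[1], over = pick[2], component = comp))
      arc <- pick[3]
    }
    remaining <- setdiff(arcs_of(d), seen_arcs)
    if (!length(remaining)) break
    comp <- comp + 1L
    arc <- min(remaining)
  }
  if (nrow(visits) != 2L * n)
    stop("traversal visited ", nrow(visits), " passages, expected ", 2L * n)
  # first-visit labels
  lab <- integer(n)
  nxt <- 1L
  labels <- integer(nrow(visits))
  for (v in seq_len(nrow(visits))) {
    ci <- visits$crossing[v]
    if (lab[ci] == 0L) { lab[ci] <- nxt; nxt <- nxt + 1L }
    labels[v] <- lab[ci]
  }
  hand <- ifelse(d$signs[visits$crossing] == 1L, "R", "L")
  out <- data.frame(label = labels,
                    ou = ifelse(visits$over == 1L, 1L, -1L),
                    hand = hand,
                    crossing = d$ids[visits$crossing],
                    component = visits$component)
  txt <- paste(vapply(seq_len(nrow(out)), function(v) {
    paste0(ifelse(out$ou[v] > 0, "+", "-"), out$label[v],
           if (extended) out$hand[v] else "")
  }, ""), collapse = ",")
  if (max(out$component) > 1L) {
    parts <- split(seq_len(nrow(out)), out$component)
    txt <- paste(vapply(parts, function(w) paste(vapply(w, function(v)
      paste0(ifelse(out$ou[v] > 0, "+", "-"), out$label[v],
             if (extended) out$hand[v] else ""), ""), collapse = ","), ""),
      collapse = " | ")
  }
  attr(out, "text") <- txt
  attr(out, "extended") <- extended
  class(out) <- c("gauss_code", class(out))
  out
}

#' @export
print.gauss_code <- function(x, ...) {
  cat(attr(x, "text"), "\n"); invisible(x)
}

# ---- planarity -----------------------------------------------------------

#' Genus of the rotation system; 0 means the diagram is realizable in the
#' plane (sphere).
#'
#' Faces are traced from the counterclockwise rotation at each crossing;
#' Euler's formula on each connected piece gives the genus.
#' @export
diagram_genus <- function(d) {
  n <- n_crossings(d)
  if (!n) return(0L)
  # darts: (crossing, slot) stored column-major like as.vector(ends):
  # dart k has crossing i = ((k-1) %% n) + 1 and slot p = ((k-1) %/% n) + 1
  arcs <- as.vector(d$ends)
  other <- integer(4L * n)
  for (a in unique(arcs)) {
    w <- which(arcs == a)
    other[w[1]] <- w[2]; other[w[2]] <- w[1]
  }
  # face permutation: cross the arc, then take the next slot counterclockwise
  nxt <- function(k) {
    k2 <- other[k]
    i <- (k2 - 1L) %% n + 1L; p <- (k2 - 1L) %/% n + 1L
    (p %% 4L) * n + i
  }
  seen <- logical(4L * n)
  faces <- 0L
  for (k0 in seq_len(4L * n)) {
    if (seen[k0]) next
    faces <- faces + 1L
    k <- k0
    repeat {
      seen[k] <- TRUE
      k <- nxt(k)
      if (k == k0) break
    }
  }
  # connected components of the crossing graph
  uf <- uf_new(seq_len(n))
  for (a in unique(arcs)) {
    w <- which(arcs == a)
    uf <- uf_union(uf, (w[1] - 1L) %% n + 1L, (w[2] - 1L) %% n + 1L)
  }
  ncomp <- length(unique(vapply(seq_len(n), function(i) uf_find(uf, i), numeric(1))))
  v <- n; e <- 2L * n
  # for each sphere component: V - E + F = 2; summed: v - e + faces = 2*ncomp - 2*genus_total
  as.integer((2L * ncomp - (v - e + faces)) / 2L)
}

#' @export
is_planar_diagram <- function(d) diagram_genus(d) == 0L

#' @export
print.link_diagram <- function(x, ...) {
  cat(sprintf("link diagram: %d crossing(s) (n+ = %d, n- = %d), %d component(s), %d free loop(s)\n",
              n_crossings(x), sum(x$signs == 1L), sum(x$signs == -1L),
              n_components(x), x$free_loops))
  if (n_crossings(x)) cat(" ", emit_pd(x), "\n")
  invisible(x)
}

# ---- JSON mirror ---------------------------------------------------------

#' Serialize a diagram to the JSON mirror (explicit signs, optional coords)
#' @export
diagram_to_json <- function(d, path = NULL) {
  obj <- list(
    crossings = lapply(seq_len(n_crossings(d)), function(i) {
      x <- list(id = d$ids[i], sign = d$signs[i], ends = as.integer(d$ends[i, ]))
      if (!is.null(d$coords)) x$coord <- as.numeric(d$coords[i, ])
      x
    }),
    free_loops = d$free_loops)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
diagram_from_json <- function(json) {
  obj <- if (file.exists(json[1])) jsonlite::read_json(json) else jsonlite::fromJSON(json, simplifyVector = FALSE)
  cr <- obj$crossings
  ends <- t(vapply(cr, function(x) as.integer(unlist(x$ends)), integer(4)))
  coords <- NULL
  if (length(cr) && !is.null(cr[[1]]$coord))
    coords <- t(vapply(cr, function(x) as.numeric(unlist(x$coord)), numeric(2)))
  link_diagram(if (length(cr)) ends else matrix(integer(), 0, 4),
               vapply(cr, function(x) as.integer(x$sign), integer(1)),
               ids = vapply(cr, function(x) as.integer(x$id), integer(1)),
               free_loops = as.integer(obj$free_loops %||% 0L),
               coords = coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
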