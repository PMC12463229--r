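#' Weighted links and smoothing filtrations
#'
#' A weighted link is a diagram together with a real weight per crossing
#' and a threshold mode.  In `ascending` mode the a-indexed link smooths
#' every crossing of weight <= a (unzipping filtrations); in
#' `descending` mode it smooths every crossing of weight >= a
#' (distance-based filtrations, where isolated crossings - the ones with
#' the largest disk radius - are smoothed first).
#'
#' @param d a [link_diagram()].
#' @param weights numeric weights, either unnamed in sorted crossing-id
#'   order or named by crossing id.
#' @param mode `"ascending"` or `"descending"`.
#' @export
weighted_link <- function(d, weights, mode = c("ascending", "descending")) {
  mode <- match.arg(mode)
  n <- n_crossings(d)
  if (!is.null(names(weights))) {
    miss <- setdiff(as.character(d$ids), names(weights))
    if (length(miss)) stop("missing weight for crossing(s): ",
                           paste(miss, collapse = ", "))
    weights <- weights[as.character(d$ids)]
  }
  if (length(weights) != n) stop("need one weight per crossing")
  w <- list(diagram = d, weights = stats::setNames(as.numeric(weights),
                                                   as.character(d$ids)),
            mode = mode)
  class(w) <- "weighted_link"
  w
}

#' @export
print.weighted_link <- function(x, ...) {
  cat("weighted link (", x$mode, " mode), ", n_crossings(x$diagram),
      " crossing(s)\n", sep = "")
  print(data.frame(crossing = x$diagram$ids, weight = unname(x$weights)))
  invisible(x)
}

#' Ordered critical parameters (distinct weights in smoothing order)
#' @export
critical_parameters <- function(w) {
  u <- unique(sort(w$weights, decreasing = (w$mode == "descending")))
  u
}

#' Crossings smoothed at threshold a
#' @export
crossing_set_at <- function(w, a) {
  if (w$mode == "ascending") w$diagram$ids[w$weights <= a]
  else w$diagram$ids[w$weights >= a]
}

#' The a-indexed link: rho-smooth every crossing past the threshold
#' @export
indexed_link <- function(w, a) rho_set(w$diagram, crossing_set_at(w, a))

#' Stage index of a parameter value (0 = nothing smoothed yet)
#' @export
stage_of_param <- function(w, a) {
  cp <- critical_parameters(w)
  if (w$mode == "ascending") sum(cp <= a) else sum(cp >= a)
}

#' The full filtration of links
#'
#' One entry per distinct critical weight; equal weights are smoothed
#' simultaneously (the smoothing operator commutes, so the result is
#' order-independent).  Stage 0 is the original diagram; the final stage
#' is always crossingless.
#'
#' @return object of class `filtration_sequence`: list with `parameters`,
#'   `smoothed` (cumulative crossing-id sets) and `diagrams`.
#' @export
filtration_sequence <- function(w) {
  cp <- critical_parameters(w)
  sets <- lapply(cp, function(a) crossing_set_at(w, a))
  diagrams <- c(list(w$diagram), lapply(sets, function(S) rho_set(w$diagram, S)))
  out <- list(parameters = cp, smoothed = c(list(integer(0)), sets),
              diagrams = diagrams, mode = w$mode)
  class(out) <- "filtration_sequence"
  out
}

#' @export
print.filtration_sequence <- function(x, ...) {
  for (j in seq_along(x$diagrams)) {
    d <- x$diagrams[[j]]
    cat(sprintf("stage %d%s: %d crossing(s), %d free loop(s)%s\n",
                j - 1L,
                if (j > 1) sprintf(" (a = %g)", x$parameters[j - 1L]) else "",
                n_crossings(d), d$free_loops,
                if (j > 1) paste0("  smoothed {",
                                  paste(x$smoothed[[j]], collapse = ","), "}") else ""))
  }
  invisible(x)
}

#' Distance-derived crossing weights (disk-growth radii)
#'
#' The weight of a crossing is the radius at which a disk grown around
#' it first touches a disk grown around another crossing: half the
#' nearest-neighbour planar distance (`convention = "half"`, the
#' default) or the nearest-neighbour distance itself
#' (`convention = "full"`).  Distance weights are used with descending
#' mode: the most isolated crossings are smoothed out first.
#'
#' @param d a [link_diagram()] with planar coordinates.
#' @param convention `"half"` or `"full"`.
#' @return named weight vector suitable for [weighted_link()].
#' @export
distance_weights <- function(d, convention = c("half", "full")) {
  convention <- match.arg(convention)
  if (is.null(d$coords)) stop("diagram has no planar coordinates")
  n <- n_crossings(d)
  if (n < 2L) stop("need at least two crossings for distance weights")
  D <- as.matrix(stats::dist(d$coords))
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  wts <- if (convention == "half") nn / 2 else nn
  stats::setNames(wts, as.character(d$ids))
}

#' Critical disk radii of a planar point configuration
#'
#' The `count` smallest half pairwise distances, in increasing order:
#' the radii at which growing disks around the points successively
#' touch.
#' @param coords matrix of 2D points.
#' @param count number of radii requested.
#' @export
critical_radii <- function(coords, count) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least two points")
  dd <- sort(as.vector(stats::dist(coords))) / 2
  if (count > length(dd))
    stop("count ", count, " exceeds the ", length(dd), " point pairs")
  dd[seq_len(count)]
}

#' Traversal (unzipping) weights from the Gauss code
#'
#' Each crossing is weighted by its first-visit label in the Gauss code
#' starting at `start` in the given direction; used with ascending mode,
#' so the link is unzipped from the starting crossing onward.
#' @export
unzip_weights <- function(d, start = d$ids[1], direction = 1L) {
  gc <- emit_gauss_code(d, start = start, direction = direction)
  first <- !duplicated(gc$crossing)
  stats::setNames(as.numeric(gc$label[first]),
                  as.character(gc$crossing[first]))[as.character(d$ids)]
}

#' Write a weight map as CSV (crossing id, weight)
#' @export
write_weights_csv <- function(w, path) {
  utils::write.csv(data.frame(crossing = w$diagram$ids, weight = unname(w$weights)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize a filtration sequence to JSON
#' @export
filtration_to_json <- function(fs, path = NULL) {
  obj <- lapply(seq_along(fs$diagrams), function(j) {
    list(stage = j - 1L,
         parameter = if (j > 1) fs$parameters[j - 1L] else NULL,
         smoothed = as.integer(fs$smoothed[[j]]),
         pd = emit_pd(fs$diagrams[[j]]),
         free_loops = fs$diagrams[[j]]$free_loops)
  })
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
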