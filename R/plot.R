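#' Plot an EKH barcode
#'
#' Bars are drawn on the stage axis (0 = the original diagram, larger =
#' more smoothed), one horizontal segment per interval summand, grouped
#' and coloured by homological height.  Bars reaching the original link
#' (the free part of the decomposition) get an arrowhead on the left,
#' echoing the fact that those classes persist toward earlier moments of
#' the filtration.
#'
#' @param x an [ekh_barcode()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.ekh_barcode <- function(x, ...) {
  b <- x$bars
  if (!nrow(b)) {
    graphics::plot(0, 0, type = "n", xlab = "stage", ylab = "",
                   main = "EKH barcode (empty)", xlim = c(0, max(1, x$m)),
                   ylim = c(0, 1))
    return(invisible(x))
  }
  ks <- sort(unique(b$k))
  cols <- grDevices::hcl.colors(max(2L, length(ks)), "Dark 2")[seq_along(ks)]
  ord <- order(b$k, b$death_stage, b$birth_stage)
  b <- b[ord, ]
  graphics::plot(NA, xlim = c(-0.3, x$m + 0.3), ylim = c(0.5, nrow(b) + 0.5),
                 xlab = "filtration stage (0 = original diagram)",
                 ylab = "", yaxt = "n", main = "evolutionary Khovanov barcode", ...)
  for (r in seq_len(nrow(b))) {
    colr <- cols[match(b$k[r], ks)]
    graphics::segments(b$death_stage[r], r, b$birth_stage[r], r,
                       lwd = 3, col = colr)
    if (b$reaches_original[r])
      graphics::arrows(b$death_stage[r] + 0.25, r, b$death_stage[r] - 0.2, r,
                       length = 0.08, lwd = 2, col = colr)
  }
  graphics::legend("topright", legend = paste0("k = ", ks), col = cols,
                   lwd = 3, bty = "n")
  invisible(x)
}

#' Betti curves of a filtration: per-height homology dimension at every
#' stage (computed from the bars alive there)
#' @export
betti_curves <- function(bc) {
  rows <- list()
  for (j in 0:bc$m) {
    kj <- bar_height_at_stage(bc, j)
    for (k in sort(unique(kj[!is.na(kj)])))
      rows[[length(rows) + 1L]] <- data.frame(stage = j, k = k,
                                              rank = sum(kj == k, na.rm = TRUE))
  }
  if (!length(rows)) return(data.frame(stage = integer(), k = integer(),
                                       rank = integer()))
  do.call(rbind, rows)
}

#' Stage-by-stage (t, q) summary of the graded Poincare polynomials
#'
#' One row per (stage, height, degree) with the homology dimension,
#' suitable for surface-style displays of the evolution.
#' @export
poincare_surface_table <- function(w, coeff = "Q") {
  po <- poincare_over_filtration(w, coeff)
  do.call(rbind, lapply(po, function(s) {
    pp <- s$poincare
    if (!length(pp$coefs)) return(NULL)
    data.frame(stage = s$stage, parameter = s$parameter,
               k = pp$texps, l = pp$qexps, dim = pp$coefs)
  }))
}
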