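#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run (input -> closure ->
#' projection -> weighting -> filtration -> EKH -> serialization) in one
#' validated list, so that runs are reproducible from a config alone.
#'
#' @param input path to an input file, or a PD code string when
#'   `input_type = "pd"`.
#' @param input_type `"xyz"` (CSV of coordinates), `"pdb"` (minimal PDB
#'   backbone), or `"pd"` (PD code text).
#' @param atom backbone atom for PDB input (`"P"` or `"CA"`).
#' @param chain optional PDB chain filter.
#' @param plane projection plane (`"xy"`, `"xz"`, `"yz"`).
#' @param close close open curves before projection?
#' @param filtration `"distance"`, `"unzip"` or `"explicit"`.
#' @param convention distance convention, `"half"` or `"full"`.
#' @param start,direction unzipping traversal start crossing and
#'   direction.
#' @param weights named weight vector for `filtration = "explicit"`.
#' @param mode threshold mode for explicit weights.
#' @param coeff `"Q"` or a prime (e.g. 2).
#' @param window optional c(a, b) reporting window.
#' @param seed projection perturbation seed.
#' @param out_dir output directory (created if missing).
#' @param prefix output file prefix.
#' @param timestamps include timestamps in the manifest? (disable for
#'   byte-identical reruns)
#' @param log_level `"info"`, `"debug"` or `"quiet"`.
#' @export
pipeline_config <- function(input, input_type = c("pd", "xyz", "pdb"),
                            atom = "P", chain = NULL,
                            plane = "xy", close = TRUE,
                            filtration = c("unzip", "distance", "explicit"),
                            convention = "half", start = NULL, direction = 1L,
                            weights = NULL, mode = "ascending",
                            coeff = "Q", window = NULL, seed = 0L,
                            out_dir = tempfile("ekh_run_"), prefix = "run",
                            timestamps = TRUE,
                            log_level = c("info", "debug", "quiet")) {
  cfg <- list(input = input, input_type = match.arg(input_type),
              atom = atom, chain = chain, plane = plane, close = close,
              filtration = match.arg(filtration), convention = convention,
              start = start, direction = direction, weights = weights,
              mode = mode, coeff = coeff, window = window, seed = seed,
              out_dir = out_dir, prefix = prefix, timestamps = timestamps,
              log_level = match.arg(log_level))
  if (cfg$filtration == "explicit" && is.null(cfg$weights))
    stop("explicit filtration needs a weights vector")
  class(cfg) <- "ekh_config"
  cfg
}

#' Round-trip a config through a JSON file
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- if (length(x$weights)) unlist(x$weights) else NULL
  do.call(pipeline_config, x[!vapply(x, is.null, TRUE)])
}

plog <- function(cfg, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[cfg$log_level]] >= lv[[level]])
    message("[", toupper(level), "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Reads the input, closes and projects curves where needed, derives
#' crossing weights, computes the evolutionary Khovanov barcode, and
#' writes the artifact bundle: `<prefix>_diagram.json`,
#' `<prefix>_weights.csv`, `<prefix>_barcode.json`,
#' `<prefix>_stages.csv` (per-stage homology table) and
#' `<prefix>_manifest.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with the diagram, weighted link, barcode and
#'   output paths.
#' @export
run_pipeline <- function(cfg) {
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (check the corresponding config fields)", call. = FALSE))
    plog(cfg, "debug", name, " done in ", round(proc.time()[3] - t0, 3), "s")
    out
  }
  timings <- list()
  d <- stage("read/project", {
    if (cfg$input_type == "pd") {
      parse_pd(if (file.exists(cfg$input)) paste(readLines(cfg$input), collapse = " ")
               else cfg$input)
    } else {
      sc <- if (cfg$input_type == "xyz") read_xyz(cfg$input)
            else read_backbone(cfg$input, atom = cfg$atom, chain = cfg$chain)
      if (cfg$close) sc <- close_curve(sc)
      project_curve(sc, plane = cfg$plane, seed = cfg$seed)$diagram
    }
  })
  plog(cfg, "info", "diagram: ", n_crossings(d), " crossing(s), ",
       n_components(d), " component(s), writhe ", writhe(d))
  w <- stage("weights", {
    switch(cfg$filtration,
      distance = weighted_link(d, distance_weights(d, cfg$convention), "descending"),
      unzip = weighted_link(d, unzip_weights(
        d, start = cfg$start %||% d$ids[1], direction = cfg$direction), "ascending"),
      explicit = weighted_link(d, cfg$weights, cfg$mode))
  })
  bc <- stage("ekh", ekh_barcode(w, cfg$coeff))
  plog(cfg, "info", "barcode: ", nrow(bc$bars), " bar(s) over ",
       bc$m, " critical parameter(s)")
  stages <- stage("stage homology", {
    po <- poincare_over_filtration(w, cfg$coeff)
    do.call(rbind, lapply(po, function(s) {
      pp <- s$poincare
      if (!length(pp$coefs))
        return(data.frame(stage = s$stage, parameter = s$parameter,
                          k = NA, l = NA, rank = NA))
      data.frame(stage = s$stage, parameter = s$parameter,
                 k = pp$texps, l = pp$qexps, rank = pp$coefs)
    }))
  })
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    diagram = file.path(cfg$out_dir, paste0(cfg$prefix, "_diagram.json")),
    weights = file.path(cfg$out_dir, paste0(cfg$prefix, "_weights.csv")),
    barcode = file.path(cfg$out_dir, paste0(cfg$prefix, "_barcode.json")),
    stages = file.path(cfg$out_dir, paste0(cfg$prefix, "_stages.csv")),
    manifest = file.path(cfg$out_dir, paste0(cfg$prefix, "_manifest.json")))
  diagram_to_json(d, paths$diagram)
  write_weights_csv(w, paths$weights)
  barcode_to_json(bc, paths$barcode)
  utils::write.csv(stages, paths$stages, row.names = FALSE)
  manifest <- list(config = unclass(cfg),
                   diagram = list(crossings = n_crossings(d),
                                  components = n_components(d),
                                  writhe = writhe(d),
                                  free_loops = d$free_loops),
                   bars = nrow(bc$bars),
                   elapsed_s = round(proc.time()[3] - t_all, 3))
  if (cfg$timestamps) manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  plog(cfg, "info", "artifacts written to ", cfg$out_dir)
  invisible(list(diagram = d, weighted = w, barcode = bc, paths = paths))
}
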