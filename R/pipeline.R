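#' Default end-to-end demonstration configuration
#'
#' The canonical run covering all stages: ten 7-filament bundle
#' elements with central rotations spanning 0-10 degrees, eight
#' 22-filament three-layer bundles, the m = 4 tau sweep, and planted
#' bundle-graph recovery over twenty seeded regions.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("fascinet_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    score = list(mode = "idealized", m = 4, tau = 0.4),
    stages = c("elements", "bundles", "sweep", "graphs"),
    elements = list(n_bundles = 10, rotation_range = c(0, 10),
                    n_protomers = 16),
    bundles = list(rows = c(7, 8, 7), n_bundles = 8, n_protomers = 17),
    sweep = list(m_values = 4, tau_values = seq(0.1, 0.8, by = 0.1),
                 runs = 50),
    graphs = list(n_regions = 20, n_filaments = 24, k_clusters = 2,
                  weak_factor = 0.3, region_length = 400))
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks: stage names, threshold ranges
#' (`0 < tau < 1`, `m >= 1`, `0 < weak_factor < 1`), sweep grid sizes,
#' and lattice capacity for the requested filament counts.
#'
#' @param config a config list, or a path to a YAML file holding one.
#' @return a list of class `config_report` with `valid` (logical) and
#'   `errors` (character vector).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("cannot read config file: ", config)
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  known <- c("elements", "bundles", "sweep", "graphs")
  chk(all(config$stages %in% known),
      paste("unknown stage(s):",
            paste(setdiff(config$stages, known), collapse = ", ")))
  sc <- config$score
  if (!is.null(sc)) {
    chk(is.null(sc$tau) || (sc$tau > 0 && sc$tau < 1),
        "score$tau must satisfy 0 < tau < 1")
    chk(is.null(sc$m) || sc$m >= 1, "score$m must be >= 1")
  }
  if ("elements" %in% config$stages) {
    el <- config$elements
    chk(el$n_bundles >= 1, "elements$n_bundles must be >= 1")
    chk(el$n_protomers == 16,
        "elements$n_protomers must be 16 (contact maps index A-P)")
  }
  if ("bundles" %in% config$stages) {
    bu <- config$bundles
    cap <- sum(bu$rows)
    nf <- if (is.null(bu$n_filaments)) cap else bu$n_filaments
    chk(nf <= cap, sprintf(
      "bundles: %d filaments exceed lattice capacity %d", nf, cap))
  }
  if ("graphs" %in% config$stages) {
    gr <- config$graphs
    chk(gr$weak_factor > 0 && gr$weak_factor < 1,
        "graphs$weak_factor must lie in (0, 1)")
    chk(gr$n_filaments >= 2 * gr$k_clusters,
        "graphs: n_filaments too small for k_clusters")
  }
  structure(list(valid = !length(errs), errors = errs),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  if (x$valid) cat("Configuration valid\n")
  else cat("Configuration invalid:\n",
           paste(" -", x$errors, collapse = "\n"), "\n")
  invisible(x)
}

.stage_seed <- function(seed, stage, k) {
  (as.integer(seed) * 131L + match(stage, c("elements", "bundles",
                                            "sweep", "graphs")) * 7919L +
     as.integer(k)) %% 2147483647L
}

#' Run the simulate-analyze-report pipeline
#'
#' Executes the requested stages in order against one seeded
#' configuration and writes all outputs plus a manifest (inputs,
#' outputs with content hashes, seeds, parameter provenance, package
#' version) into the output directory. Identical configurations and
#' seeds reproduce identical data outputs.
#'
#' @param config a config list (see [demo_config()]) or a YAML path.
#' @return the manifest, invisibly (class `pipeline_manifest`).
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  rep <- validate_config(config)
  if (!rep$valid)
    stop("invalid configuration:\n", paste(" -", rep$errors,
                                           collapse = "\n"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$score
  params <- synth_score_params(mode = sc$mode, m = sc$m, tau = sc$tau)
  files <- character(0)
  info <- list()
  for (stage in config$stages) {
    res <- switch(stage,
      elements = .stage_elements(config, params, out_dir),
      bundles = .stage_bundles(config, params, out_dir),
      sweep = .stage_sweep(config, params, out_dir),
      graphs = .stage_graphs(config, out_dir))
    files <- c(files, res$files)
    info[[stage]] <- res$info
  }
  manifest <- list(
    package = "fascinet",
    version = as.character(utils::packageVersion("fascinet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    score_set = params$set,
    stages = info,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(manifest, class = "pipeline_manifest"))
}

.stage_elements <- function(config, params, out_dir) {
  el <- config$elements
  rots <- seq(el$rotation_range[1], el$rotation_range[2],
              length.out = el$n_bundles)
  bundles <- lapply(seq_len(el$n_bundles), function(b) {
    cfg <- assembly_config(hex_lattice(1), n_filaments = 7,
                           n_protomers = el$n_protomers, params = params,
                           seed = .stage_seed(config$seed, "elements", b),
                           first_site = 1, first_rotation = rots[b])
    assemble(cfg)
  })
  cm <- contact_map(bundles)
  f1 <- file.path(out_dir, "element_contact_map.csv")
  write_contact_map_csv(cm, f1)
  f2 <- file.path(out_dir, "element_bundles.json")
  jsonlite::write_json(lapply(bundles, function(b) list(
    rotations = vapply(b$filaments, `[[`, 0, "rotation"),
    n_crossbridges = nrow(b$crossbridges))), f2,
    auto_unbox = TRUE, digits = NA)
  list(files = c(f1, f2),
       info = list(n_bundles = el$n_bundles,
                   central_rotations = rots,
                   seeds = vapply(seq_len(el$n_bundles), function(b)
                     .stage_seed(config$seed, "elements", b), 0L),
                   total_crossbridges = sum(cm) / 2))
}

.stage_bundles <- function(config, params, out_dir) {
  bu <- config$bundles
  lat <- row_lattice(bu$rows)
  bundles <- lapply(seq_len(bu$n_bundles), function(b) {
    cfg <- assembly_config(lat, n_protomers = bu$n_protomers,
                           params = params,
                           seed = .stage_seed(config$seed, "bundles", b))
    assemble(cfg)
  })
  tt <- triplet_scatter(bundles)
  f1 <- file.path(out_dir, "bundle_triplets.csv")
  utils::write.csv(tt, f1, row.names = FALSE)
  # classify the crossband of every full lattice row of each bundle
  cls <- lapply(seq_along(bundles), function(b) {
    bd <- bundles[[b]]
    ys <- vapply(bd$filaments, function(f) f$position[2], 0)
    lapply(split(seq_along(ys), round(ys, 3)), function(ids) {
      if (length(ids) < 3) return(NULL)
      xs <- vapply(bd$filaments[ids], function(f) f$position[1], 0)
      cc <- classify_crossband(bd, ids[order(xs)])
      list(bundle = b, filaments = ids[order(xs)], label = cc$label,
           flagged = cc$flagged, shifts = round(cc$shifts, 2))
    })
  })
  f2 <- file.path(out_dir, "bundle_crossbands.json")
  jsonlite::write_json(cls, f2, auto_unbox = TRUE, digits = NA)
  list(files = c(f1, f2),
       info = list(n_bundles = bu$n_bundles, n_triplets = nrow(tt),
                   seeds = vapply(seq_len(bu$n_bundles), function(b)
                     .stage_seed(config$seed, "bundles", b), 0L)))
}

.stage_sweep <- function(config, params, out_dir) {
  sw <- config$sweep
  seed <- .stage_seed(config$seed, "sweep", 1)
  res <- parameter_sweep(m_values = sw$m_values,
                         tau_values = sw$tau_values, runs = sw$runs,
                         seed = seed, base_params = params)
  f1 <- file.path(out_dir, "sweep_runs.csv")
  utils::write.csv(res, f1, row.names = FALSE)
  f2 <- file.path(out_dir, "sweep_fractions.csv")
  utils::write.csv(crossbridge_fraction(res), f2, row.names = FALSE)
  list(files = c(f1, f2),
       info = list(rows = nrow(res), seed = seed))
}

.stage_graphs <- function(config, out_dir) {
  gr <- config$graphs
  seeds <- vapply(seq_len(gr$n_regions), function(k)
    .stage_seed(config$seed, "graphs", k), 0L)
  regions <- lapply(seeds, function(s)
    synth_bundle_graph(n_filaments = gr$n_filaments,
                       k_clusters = gr$k_clusters,
                       weak_factor = gr$weak_factor,
                       region_length = gr$region_length, seed = s))
  cl <- hierarchical_cluster(lapply(regions, `[[`, "graph"))
  mets <- lapply(seq_along(regions), function(k)
    cluster_metrics(cl[[k]], regions[[k]]$graph))
  curves <- do.call(rbind, lapply(seq_along(mets), function(k)
    cbind(region = k, mets[[k]]$curves)))
  f1 <- file.path(out_dir, "graph_metric_curves.csv")
  utils::write.csv(curves, f1, row.names = FALSE)
  recov <- lapply(seq_along(mets), function(k) list(
    region = k, seed = seeds[k],
    planted = unname(regions[[k]]$labels),
    modularity_peak = unname(mets[[k]]$peaks$modularity$partition),
    transitivity_peak_distance = mets[[k]]$peaks$transitivity$distance,
    modularity_peak_distance = mets[[k]]$peaks$modularity$distance))
  f2 <- file.path(out_dir, "graph_recovery.json")
  jsonlite::write_json(recov, f2, auto_unbox = TRUE, digits = NA)
  list(files = c(f1, f2),
       info = list(n_regions = gr$n_regions, seeds = seeds))
}
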