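#' Configuration object for a full discretization run
#'
#' Collects everything a pipeline run needs; all downstream stages receive
#' their parameters only through this object, and it serializes to JSON for
#' reproducible re-runs.
#'
#' @param model Fixture name (`"aearm"`, `"toy_bifurcation"`) or path to a
#'   model DSL file.
#' @param target Target species for dominance tracing.
#' @param ensemble Path to an ensemble file, or `NULL` to synthesize one.
#' @param synth For `ensemble = NULL`: list with `n` (size) and optional
#'   `log10_sd` controlling prior sampling; for the toy fixture a list with
#'   `regimes = TRUE` plants the three-regime ensemble with `n_per_regime`.
#' @param rho,depth,direction Dominance settings ([dominance_config()]).
#' @param time_grid Simulation grid (numeric vector), or `NULL` for the
#'   fixture default.
#' @param method Clustering method.
#' @param n_clusters Cluster count, or `NULL` for silhouette selection over
#'   `k_range`.
#' @param k_range Candidate cluster counts for automatic selection.
#' @param seed Root seed; all stage seeds derive from it.
#' @param rtol,atol Solver tolerances.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config`.
#' @export
run_config <- function(model, target, ensemble = NULL, synth = list(n = 50),
                       rho = 1, depth = 5L, direction = "production",
                       time_grid = NULL, method = "agglomerative",
                       n_clusters = NULL, k_range = 2:6, seed = 1L,
                       rtol = 1e-6, atol = 1e-6, out_dir = NULL) {
  structure(list(model = model, target = target, ensemble = ensemble,
                 synth = synth, rho = rho, depth = as.integer(depth),
                 direction = direction, time_grid = time_grid,
                 method = method, n_clusters = n_clusters,
                 k_range = k_range, seed = as.integer(seed),
                 rtol = rtol, atol = atol, out_dir = out_dir),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param cfg A [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

resolve_model <- function(model) {
  if (is.reaction_network(model)) return(model)
  switch(model,
         aearm = make_aearm(),
         toy_bifurcation = make_toy_bifurcation(),
         read_model_dsl(model))
}

#' Run the full discretization pipeline
#'
#' simulate -> fingerprint -> LCS distance -> cluster -> mode report, with
#' every intermediate artifact written to `cfg$out_dir` (when set) and a
#' manifest recording the configuration hash, seeds and per-file content
#' hashes.
#'
#' @param cfg A [run_config()].
#' @return A results bundle: `network`, `ensemble`, `fingerprints`,
#'   `distance`, `assignments`, `modes`, `n_clusters`, `true_labels` (for
#'   planted synthesis), and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  net <- resolve_model(cfg$model)
  if (!cfg$target %in% species_names(net)) {
    stop("stage model: target species '", cfg$target, "' not in model")
  }
  time_grid <- cfg$time_grid
  if (is.null(time_grid)) {
    time_grid <- if (identical(cfg$model, "toy_bifurcation")) {
      toy_time_grid()
    } else if (identical(cfg$model, "aearm")) {
      aearm_time_grid()
    } else {
      stop("stage config: time_grid is required for a DSL model")
    }
  }
  true_labels <- NULL
  if (!is.null(cfg$ensemble)) {
    ensemble <- read_ensemble(cfg$ensemble, parameters = net$parameters)
  } else if (isTRUE(cfg$synth$regimes)) {
    pr <- planted_regime_ensemble(
      net, toy_regimes(),
      n_per_regime = cfg$synth$n_per_regime %||% 50L,
      jitter_sd = cfg$synth$jitter_sd %||% 0.05,
      seed = cfg$seed, time_grid = time_grid, target = cfg$target,
      cfg = dominance_config(cfg$rho, cfg$depth, cfg$direction))
    ensemble <- pr$ensemble
    true_labels <- pr$true_labels
  } else {
    ensemble <- sample_ensemble(
      default_prior(net, log10_sd = cfg$synth$log10_sd %||% 1),
      n = cfg$synth$n %||% 50L, seed = cfg$seed)
  }
  if (length(ensemble) == 0L) stop("stage ensemble: empty ensemble")

  dom_cfg <- dominance_config(cfg$rho, cfg$depth, cfg$direction)
  fps <- fingerprint_ensemble(net, ensemble, cfg$target, time_grid,
                              dom_cfg, rtol = cfg$rtol, atol = cfg$atol)
  dm <- distance_matrix(fps)
  k <- cfg$n_clusters
  if (is.null(k) && cfg$method != "hdbscan") {
    k <- select_n_clusters(dm, method = cfg$method, k_range = cfg$k_range,
                           seed = cfg$seed)
  }
  assignments <- cluster_modes(dm, method = cfg$method, n_clusters = k,
                               seed = cfg$seed)
  modes <- execution_modes(assignments, ensemble, fps)

  manifest <- NULL
  if (!is.null(cfg$out_dir)) {
    manifest <- write_run_artifacts(cfg, net, ensemble, fps, dm,
                                    assignments, modes)
  }
  list(network = net, ensemble = ensemble, fingerprints = fps,
       distance = dm, assignments = assignments, modes = modes,
       n_clusters = length(unique(assignments[assignments != 0L])),
       true_labels = true_labels, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fingerprint matrix and label registry to disk
#'
#' Fingerprints as a delimited integer matrix (rows = ensemble members,
#' columns = time points); the registry as a JSON map from label to
#' canonical edge list.
#'
#' @param fps [fingerprint_ensemble()] result (or plain label matrix).
#' @param registry The registry (taken from `fps` when omitted).
#' @param path Output path for the matrix; the registry goes to
#'   `registry_path`.
#' @param registry_path Output path for the registry JSON.
#' @return Invisibly, the paths written.
#' @export
write_fingerprints <- function(fps, path, registry = NULL,
                               registry_path = NULL) {
  labels <- if (is.list(fps) && !is.null(fps$labels)) fps$labels else fps
  registry <- registry %||% fps$registry
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(registry_path) && !is.null(registry)) {
    write_registry(registry, registry_path)
  }
  invisible(c(path, registry_path))
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "integer"))
}

#' Persist / restore a subnetwork label registry as JSON
#'
#' @param registry A [new_registry()] object.
#' @param path JSON file path.
#' @return `read_registry` returns a restored registry.
#' @export
write_registry <- function(registry, path) {
  labs <- unlist(registry$map, use.names = FALSE)
  entries <- lapply(seq_along(labs), function(i) {
    e <- registry_edges(registry, labs[i])
    list(label = labs[i], edges = paste0(e$from, ">", e$to))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- new_registry()
  ord <- order(vapply(entries, function(e) e$label, numeric(1)))
  for (e in entries[ord]) {
    key <- paste(sort(unlist(e$edges)), collapse = ";")
    reg$map[[key]] <- as.integer(e$label)
    reg$next_label <- max(reg$next_label, as.integer(e$label) + 1L)
  }
  reg
}

#' Persist / restore a distance matrix (dense binary + index)
#'
#' The matrix is stored as little-endian doubles in row-major order next to
#' a one-line text index file recording its dimension.
#'
#' @param dm Square numeric matrix.
#' @param path Binary output path; the index goes to `<path>.idx`.
#' @return `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(dm)), con, size = 8L, endian = "little")
  writeLines(as.character(nrow(dm)), paste0(path, ".idx"))
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  n <- as.integer(readLines(paste0(path, ".idx"))[1])
  con <- file(path, "rb")
  on.exit(close(con))
  matrix(readBin(con, "numeric", n = n * n, size = 8L,
                 endian = "little"),
         n, n, byrow = TRUE)
}

write_run_artifacts <- function(cfg, net, ensemble, fps, dm, assignments,
                                modes) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_run_config(cfg, p("config.json"))
  write_ensemble(ensemble, p("ensemble.tsv"))
  write_fingerprints(fps, p("fingerprints.tsv"),
                     registry_path = p("registry.json"))
  write_distance_matrix(dm, p("distances.bin"))
  utils::write.table(
    data.frame(ensemble_index = seq_along(assignments),
               mode_id = assignments),
    p("assignments.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  report <- lapply(seq_len(nrow(modes$summary)), function(i) {
    m <- modes$summary[i, ]
    rep_edges <- registry_edges(fps$registry, m$representative_label)
    list(mode_id = m$mode_id, n_members = m$n_members,
         probability = m$probability,
         representative_label = m$representative_label,
         representative_edges = paste0(rep_edges$from, ">", rep_edges$to))
  })
  jsonlite::write_json(report, p("modes.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c("config.json", "ensemble.tsv", "fingerprints.tsv",
             "registry.json", "distances.bin", "distances.bin.idx",
             "assignments.tsv", "modes.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("fluxmodes")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(p("config.json"))),
    n_modes = nrow(modes$summary),
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(p(f))))
    }))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}
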