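#' Dominance analysis configuration
#'
#' @param rho Positive log10 separation below which two rate monomials are
#'   "on par" (default 1 = one order of magnitude).
#' @param depth Number of back-trace iterations from the target species when
#'   assembling a dominant subnetwork (default 5).
#' @param direction `"production"` traces the fluxes producing the target;
#'   `"consumption"` traces the fluxes consuming it (implemented as
#'   production tracing on the mirrored network).
#' @return A `dominance_config`.
#' @export
dominance_config <- function(rho = 1, depth = 5L,
                             direction = c("production", "consumption")) {
  direction <- match.arg(direction)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("rho must be a positive number")
  }
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 ||
      depth != round(depth)) {
    stop("depth must be a positive integer")
  }
  structure(list(rho = as.numeric(rho), depth = as.integer(depth),
                 direction = direction, log_base = 10),
            class = "dominance_config")
}

#' Log-scale separation between two rate magnitudes
#'
#' `sep(m1, m2) = |log10(m1) - log10(m2)|`: the distance in orders of
#' magnitude between two strictly positive monomial values.
#'
#' @param m1,m2 Strictly positive magnitudes.
#' @return Nonnegative separation (symmetric in its arguments).
#' @export
sep <- function(m1, m2) {
  if (any(c(m1, m2) <= 0) || any(!is.finite(c(m1, m2)))) {
    stop("sep() requires strictly positive finite magnitudes")
  }
  abs(log10(m1) - log10(m2))
}

#' Are two rate magnitudes on par?
#'
#' Two monomials are on par at level `rho` when their log10 separation is
#' strictly below `rho`; one dominates the other when the separation is at
#' least `rho`.
#'
#' @inheritParams sep
#' @param rho Positive separation threshold.
#' @return Logical.
#' @export
on_par <- function(m1, m2, rho) {
  sep(m1, m2) < rho
}

#' Net rate terms of a focal species
#'
#' One term per reaction touching the focal species: irreversible reactions
#' contribute their single monomial, reversible reactions are collapsed to
#' the net term (forward and reverse monomials signed by the focal species'
#' stoichiometry and summed). Signs are with respect to production of the
#' focal species: positive terms produce it, negative terms consume it.
#'
#' @param net A [reaction_network()].
#' @param state Named nonnegative state vector.
#' @param params Parameter values.
#' @param focal Focal species name.
#' @return A data frame with columns `reaction` (id), `value` (signed net
#'   rate), and `sources` (list column: reactant species of the producing
#'   direction, the trace-back sources when `value > 0`).
#' @export
net_rate_terms <- function(net, state, params, focal) {
  if (!focal %in% species_names(net)) stop("unknown species: ", focal)
  u <- net$unidir
  rates <- unidir_rates(net, state, params)
  s_focal <- u$S[focal, ]
  touched <- unique(u$reaction[s_focal != 0])
  if (!length(touched)) {
    return(data.frame(reaction = character(0), value = numeric(0),
                      sources = I(list())))
  }
  rows <- lapply(touched, function(rid) {
    idx <- which(u$reaction == rid)
    contrib <- s_focal[idx] * rates[idx]
    value <- sum(contrib)
    ## reactants of the direction that produces the focal species
    prod_dir <- idx[s_focal[idx] > 0]
    sources <- if (length(prod_dir)) {
      a <- u$alpha[prod_dir[1L], ]
      names(a)[a > 0]
    } else character(0)
    list(reaction = rid, value = value, sources = sources)
  })
  data.frame(
    reaction = vapply(rows, `[[`, character(1), "reaction"),
    value = vapply(rows, `[[`, numeric(1), "value"),
    sources = I(lapply(rows, `[[`, "sources")),
    stringsAsFactors = FALSE)
}

#' Restrict net rate terms to the production set
#'
#' Keeps the strictly positive terms (the fluxes producing the focal
#' species); the result may be empty.
#'
#' @param terms Data frame from [net_rate_terms()].
#' @return The filtered data frame.
#' @export
production_set <- function(terms) {
  terms[terms$value > 0, , drop = FALSE]
}

#' Select the dominant production reactions
#'
#' From a production set, the term with the largest magnitude is dominant;
#' every other term within `rho` orders of magnitude of it (on par) is kept
#' as well. Ties at exactly `rho` separation are non-dominant (strict
#' inequality).
#'
#' @param pset Production set data frame ([production_set()]).
#' @param rho Positive log10 separation threshold.
#' @return Character vector of dominant reaction ids (empty when the
#'   production set is empty).
#' @export
dominant_reactions <- function(pset, rho) {
  if (nrow(pset) == 0L) return(character(0))
  md <- max(pset$value)
  keep <- vapply(pset$value, function(m) on_par(md, m, rho), logical(1))
  pset$reaction[keep]
}

#' Trace the dominant subnetwork feeding a target species
#'
#' Hierarchical back-trace on the bipartite species-reaction graph at one
#' state snapshot: starting from the target, find the dominant reactions
#' producing each frontier species, add edges from those reactions' source
#' reactants to the frontier species, and advance the frontier to the newly
#' reached sources. The trace stops after `cfg$depth` iterations or when the
#' frontier empties; species already expanded are recorded as edge sources
#' but not re-expanded (cycles such as self-amplification terminate).
#'
#' @param net A [reaction_network()].
#' @param state Named state vector (one time-point snapshot).
#' @param params Parameter values.
#' @param target Target species name.
#' @param cfg A [dominance_config()].
#' @return A `dominant_subnetwork`: `target`, `edges` (data frame with
#'   `from`, `to`, `reaction`), and the species expanded.
#' @export
trace_dominant_subnetwork <- function(net, state, params, target,
                                      cfg = dominance_config()) {
  if (!target %in% species_names(net)) stop("unknown species: ", target)
  if (cfg$direction == "consumption") {
    net <- reverse_network(net)
  }
  edges_from <- character(0); edges_to <- character(0)
  edges_rx <- character(0)
  expanded <- character(0)
  frontier <- target
  for (step in seq_len(cfg$depth)) {
    if (!length(frontier)) break
    nxt <- character(0)
    for (sp in frontier) {
      expanded <- c(expanded, sp)
      terms <- net_rate_terms(net, state, params, sp)
      pset <- production_set(terms)
      dom <- dominant_reactions(pset, cfg$rho)
      for (rid in dom) {
        sources <- pset$sources[[match(rid, pset$reaction)]]
        for (src in sources) {
          dup <- edges_from == src & edges_to == sp & edges_rx == rid
          if (!any(dup)) {
            edges_from <- c(edges_from, src)
            edges_to <- c(edges_to, sp)
            edges_rx <- c(edges_rx, rid)
          }
          if (!src %in% expanded) nxt <- c(nxt, src)
        }
      }
    }
    frontier <- setdiff(unique(nxt), expanded)
  }
  structure(list(target = target,
                 edges = data.frame(from = edges_from, to = edges_to,
                                    reaction = edges_rx,
                                    stringsAsFactors = FALSE),
                 expanded = unique(expanded)),
            class = "dominant_subnetwork")
}

#' @export
print.dominant_subnetwork <- function(x, ...) {
  cat("dominant_subnetwork: target", x$target, "-", nrow(x$edges),
      "edge(s)\n")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to,
               " [", x$edges$reaction, "]", collapse = "\n"), "\n")
  }
  invisible(x)
}

## Canonical key of a subnetwork: sorted species->species edge list.
## Reaction identities are metadata and do not enter the key.
subnetwork_key <- function(sub) {
  if (nrow(sub$edges) == 0L) return("")
  paste(sort(unique(paste0(sub$edges$from, ">", sub$edges$to))),
        collapse = ";")
}

#' Create a subnetwork label registry
#'
#' A mutable mapping from canonical edge-set keys to integer labels. The
#' empty subnetwork (no producing reactions) always maps to the sentinel
#' label 0; new edge sets receive consecutive labels 1, 2, ... in insertion
#' order. Sharing one registry across simulations (e.g. wild-type and
#' knockdown conditions) keeps labels comparable.
#'
#' @return A `subnetwork_registry` (environment).
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$map <- list()
  reg$next_label <- 1L
  class(reg) <- "subnetwork_registry"
  reg
}

#' @export
print.subnetwork_registry <- function(x, ...) {
  cat("subnetwork_registry:", length(x$map),
      "edge set(s) registered (+ sentinel 0)\n")
  invisible(x)
}

#' Canonical integer label of a dominant subnetwork
#'
#' Identical species-to-species edge sets always receive the same label,
#' regardless of edge insertion order or the reactions that generated them.
#'
#' @param sub A `dominant_subnetwork`.
#' @param registry A [new_registry()] object (mutated in place).
#' @return Integer label (0 for the empty subnetwork).
#' @export
canonical_label <- function(sub, registry) {
  key <- subnetwork_key(sub)
  if (key == "") return(0L)
  hit <- registry$map[[key]]
  if (!is.null(hit)) return(hit)
  lab <- registry$next_label
  registry$map[[key]] <- lab
  registry$next_label <- lab + 1L
  lab
}

#' Decode a registry label back to its canonical edge list
#'
#' @param registry A `subnetwork_registry`.
#' @param label Integer label.
#' @return Data frame with columns `from`, `to` (empty for label 0).
#' @export
registry_edges <- function(registry, label) {
  if (label == 0L) {
    return(data.frame(from = character(0), to = character(0)))
  }
  keys <- names(registry$map)
  labs <- unlist(registry$map, use.names = FALSE)
  key <- keys[match(label, labs)]
  if (is.na(key)) stop("label ", label, " not present in registry")
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], ">", fixed = TRUE)
  data.frame(from = vapply(parts, `[[`, character(1), 1L),
             to = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Dynamic fingerprint of one simulation
#'
#' Traces the dominant subnetwork feeding `target` at every time point of a
#' trajectory and encodes the sequence of canonical labels: the digital
#' signature of that simulation under the given dominance configuration.
#'
#' @param net A [reaction_network()].
#' @param traj A `trajectory` from [simulate_network()].
#' @param params The parameter values used for the simulation.
#' @param target Target species.
#' @param cfg A [dominance_config()].
#' @param registry A shared [new_registry()].
#' @return A `dynamic_fingerprint`: integer vector `labels` (one per grid
#'   point) plus the target and configuration used.
#' @export
fingerprint <- function(net, traj, params, target,
                        cfg = dominance_config(), registry) {
  labels <- vapply(seq_along(traj$time), function(i) {
    sub <- trace_dominant_subnetwork(net, traj$species[i, ], params,
                                     target, cfg)
    canonical_label(sub, registry)
  }, integer(1))
  structure(list(labels = labels, target = target, cfg = cfg),
            class = "dynamic_fingerprint")
}

#' Fingerprint every member of a parameter ensemble
#'
#' Simulates each parameter vector on a shared time grid and assembles the
#' fingerprint matrix (rows = ensemble members, columns = time points) with
#' one shared label registry, so labels are positionally comparable across
#' the whole ensemble.
#'
#' @param net A [reaction_network()].
#' @param ensemble A [parameter_ensemble()].
#' @param target Target species.
#' @param time_grid Shared simulation time grid.
#' @param cfg A [dominance_config()].
#' @param registry Optional shared registry (a fresh one by default).
#' @param rtol,atol Solver tolerances passed to [simulate_network()].
#' @return A list with `labels` (integer matrix), `registry`, `target`,
#'   `time_grid` and `cfg`.
#' @export
fingerprint_ensemble <- function(net, ensemble, target, time_grid,
                                 cfg = dominance_config(),
                                 registry = new_registry(),
                                 rtol = 1e-6, atol = 1e-6) {
  n <- length(ensemble)
  if (n == 0L) stop("empty ensemble")
  labs <- matrix(0L, n, length(time_grid))
  for (i in seq_len(n)) {
    pv <- ensemble_member(ensemble, i)
    traj <- simulate_network(net, pv, time_grid, rtol = rtol, atol = atol)
    labs[i, ] <- fingerprint(net, traj, pv, target, cfg, registry)$labels
  }
  list(labels = labs, registry = registry, target = target,
       time_grid = time_grid, cfg = cfg)
}
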