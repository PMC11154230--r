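#' Define a molecular species
#'
#' @param name Species identifier (unique within a network).
#' @param initial Initial abundance in copies per cell (nonnegative).
#' @param tag Optional free-text role label (e.g. `"ligand"`, `"enzyme"`).
#' @return A `species_def` list.
#' @export
species_def <- function(name, initial, tag = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(initial) || length(initial) != 1L || is.na(initial) ||
      initial < 0) {
    stop("initial abundance of '", name, "' must be a nonnegative number")
  }
  structure(list(name = name, initial = as.numeric(initial),
                 tag = as.character(tag)),
            class = "species_def")
}

#' Define a mass-action reaction
#'
#' The forward rate monomial has exponents equal to the reactant
#' stoichiometries; for a reversible reaction the reverse monomial exponents
#' equal the product stoichiometries (mass-action kinetics only).
#'
#' @param id Reaction identifier.
#' @param reactants Named integer vector of reactant stoichiometries.
#' @param products Named integer vector of product stoichiometries.
#' @param kf Name of the forward rate parameter.
#' @param kr Name of the reverse rate parameter (required iff `reversible`).
#' @param reversible Logical flag.
#' @return A `reaction` list.
#' @export
reaction <- function(id, reactants, products, kf, kr = NULL,
                     reversible = !is.null(kr)) {
  stopifnot(is.character(id), length(id) == 1L)
  chk_stoich <- function(x, side) {
    if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("reaction '", id, "': ", side, " stoichiometries must be named")
    }
    if (any(x <= 0) || any(x != round(x))) {
      stop("reaction '", id, "': ", side,
           " stoichiometries must be positive integers")
    }
    stats::setNames(as.integer(x), names(x))
  }
  reactants <- chk_stoich(reactants, "reactant")
  products <- chk_stoich(products, "product")
  if (reversible && is.null(kr)) {
    stop("reaction '", id, "' is reversible but has no reverse rate parameter")
  }
  if (!reversible) kr <- NULL
  structure(list(id = id, reactants = reactants, products = products,
                 kf = kf, kr = kr, reversible = isTRUE(reversible)),
            class = "reaction")
}

#' Assemble a reaction network
#'
#' Builds the network container used by all simulation and dominance
#' routines: an ordered species list, an ordered reaction list, the net
#' stoichiometric matrix (species x reactions) and the unidirectional
#' expansion in which every reversible reaction contributes separate forward
#' and reverse rate monomial columns.
#'
#' @param species List of [species_def()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A `reaction_network` object with elements `species` (data frame),
#'   `reactions`, `parameters` (ordered parameter names), `S` (net
#'   stoichiometric matrix), and `unidir` (per-column metadata of the
#'   unidirectional rate expansion).
#' @export
reaction_network <- function(species, reactions) {
  if (inherits(species, "species_def")) species <- list(species)
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  sp_names <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(sp_names)) {
    stop("duplicate species name: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  }
  rx_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rx_ids)) {
    stop("duplicate reaction id: ",
         paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", "))
  }
  for (rx in reactions) {
    undeclared <- setdiff(c(names(rx$reactants), names(rx$products)), sp_names)
    if (length(undeclared)) {
      stop("reaction '", rx$id, "' references undeclared species: ",
           paste(undeclared, collapse = ", "))
    }
  }
  ## parameter order: declaration order of first appearance
  pars <- character(0)
  for (rx in reactions) pars <- c(pars, rx$kf, rx$kr)
  if (anyDuplicated(pars)) {
    stop("rate parameter used by more than one reaction direction: ",
         paste(unique(pars[duplicated(pars)]), collapse = ", "))
  }

  n_sp <- length(sp_names)
  S <- matrix(0, n_sp, length(reactions),
              dimnames = list(sp_names, rx_ids))
  ## unidirectional expansion: one column per direction
  u_rx <- character(0); u_dir <- character(0); u_par <- character(0)
  alpha <- NULL; Su <- NULL
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    net <- numeric(n_sp); names(net) <- sp_names
    net[names(rx$products)] <- net[names(rx$products)] + rx$products
    net[names(rx$reactants)] <- net[names(rx$reactants)] - rx$reactants
    S[, j] <- net
    dirs <- list(list(dir = "forward", par = rx$kf,
                      from = rx$reactants, to = rx$products))
    if (rx$reversible) {
      dirs <- c(dirs, list(list(dir = "reverse", par = rx$kr,
                                from = rx$products, to = rx$reactants)))
    }
    for (d in dirs) {
      a <- numeric(n_sp); names(a) <- sp_names
      a[names(d$from)] <- d$from
      s <- numeric(n_sp); names(s) <- sp_names
      s[names(d$to)] <- s[names(d$to)] + d$to
      s[names(d$from)] <- s[names(d$from)] - d$from
      alpha <- rbind(alpha, a)
      Su <- cbind(Su, s)
      u_rx <- c(u_rx, rx$id); u_dir <- c(u_dir, d$dir); u_par <- c(u_par, d$par)
    }
  }
  rownames(alpha) <- u_par
  colnames(Su) <- u_par
  structure(list(
    species = data.frame(
      name = sp_names,
      initial = vapply(species, `[[`, numeric(1), "initial"),
      tag = vapply(species, `[[`, character(1), "tag"),
      stringsAsFactors = FALSE),
    reactions = stats::setNames(reactions, rx_ids),
    parameters = pars,
    S = S,
    unidir = list(reaction = u_rx, direction = u_dir, parameter = u_par,
                  alpha = alpha, S = Su)),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", nrow(x$species), "species,",
      length(x$reactions), "reactions (",
      nrow(x$unidir$alpha), "unidirectional ),",
      length(x$parameters), "parameters\n")
  invisible(x)
}

#' @rdname reaction_network
#' @param x Object to test.
#' @export
is.reaction_network <- function(x) inherits(x, "reaction_network")

n_species <- function(net) nrow(net$species)

species_names <- function(net) net$species$name

#' Initial state vector of a network
#'
#' @param net A `reaction_network`.
#' @return Named numeric vector of initial abundances (copies per cell).
#' @export
initial_state <- function(net) {
  stats::setNames(net$species$initial, net$species$name)
}

#' Evaluate all unidirectional rate monomials at a state
#'
#' Each column of the unidirectional expansion is a mass-action monomial
#' `k * prod(state^alpha)`. Negative state entries are clipped to zero before
#' evaluation so the log-scale dominance comparisons stay defined.
#'
#' @param net A `reaction_network`.
#' @param state Named nonnegative numeric vector over all species.
#' @param params Parameter values (named vector or `parameter_vector`).
#' @return Named numeric vector, one nonnegative rate per unidirectional
#'   monomial (names are the rate parameter names).
#' @export
unidir_rates <- function(net, state, params) {
  k <- param_values(params, net$parameters)
  s <- pmax(as.numeric(state[species_names(net)]), 0)
  A <- net$unidir$alpha
  k[rownames(A)] * apply(A, 1L, function(a) prod(s^a))
}

## Coerce params (named vector or parameter_vector) to a full named vector,
## validating coverage of `needed`.
param_values <- function(params, needed) {
  if (inherits(params, "parameter_vector")) params <- params$values
  if (is.null(names(params))) stop("parameters must be named")
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    stop("missing parameter value(s): ", paste(missing, collapse = ", "))
  }
  params[needed]
}

#' Scale a species' initial abundance (in-silico knockdown)
#'
#' Returns a copy of the network in which the initial abundance of `species`
#' is multiplied by `1 - fraction`; everything else is untouched. A fraction
#' of 0.5 models a 50% knockdown of the protein's expression level.
#'
#' @param net A `reaction_network`.
#' @param species Species name to knock down.
#' @param fraction Knockdown fraction in \[0, 1\].
#' @return The modified `reaction_network`.
#' @export
apply_knockdown <- function(net, species, fraction) {
  stopifnot(is.reaction_network(net))
  if (!species %in% species_names(net)) {
    stop("unknown species: ", species)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("knockdown fraction must lie in [0, 1]")
  }
  i <- match(species, net$species$name)
  net$species$initial[i] <- net$species$initial[i] * (1 - fraction)
  net
}

#' Reverse every reaction of a network
#'
#' Swaps reactant and product sides (and forward/reverse rate parameters of
#' reversible reactions). Used to express consumption-directed dominance
#' tracing as production tracing on the mirrored network.
#'
#' @param net A `reaction_network`.
#' @return The mirrored `reaction_network`.
#' @export
reverse_network <- function(net) {
  sp <- lapply(seq_len(nrow(net$species)), function(i) {
    species_def(net$species$name[i], net$species$initial[i],
                net$species$tag[i])
  })
  rx <- lapply(net$reactions, function(r) {
    if (r$reversible) {
      reaction(r$id, r$products, r$reactants, kf = r$kr, kr = r$kf)
    } else {
      reaction(r$id, r$products, r$reactants, kf = r$kf)
    }
  })
  reaction_network(sp, unname(rx))
}
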