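# Independent oracles and generators shared across tests.

# Random small mass-action network: 3-5 species, up to `max_rx` reactions
# with random stoichiometries and a random mix of reversible steps.
random_network <- function(max_rx = 8L) {
  n_sp <- sample(3:5, 1)
  sp_names <- paste0("X", seq_len(n_sp))
  sp <- lapply(sp_names, function(s) species_def(s, stats::runif(1, 1, 100)))
  n_rx <- sample(2:max_rx, 1)
  rx <- lapply(seq_len(n_rx), function(j) {
    repeat {
      lhs <- sample(sp_names, sample(1:2, 1))
      rhs <- sample(sp_names, sample(1:2, 1))
      st_l <- stats::setNames(sample(1:2, length(lhs), replace = TRUE), lhs)
      st_r <- stats::setNames(sample(1:2, length(rhs), replace = TRUE), rhs)
      # avoid reactions with identical sides (zero net change everywhere)
      if (!identical(st_l[order(names(st_l))], st_r[order(names(st_r))])) break
    }
    rev <- stats::runif(1) < 0.5
    reaction(paste0("r", j), st_l, st_r,
             kf = paste0("kf", j),
             kr = if (rev) paste0("kr", j) else NULL)
  })
  reaction_network(sp, rx)
}

random_params <- function(net) {
  stats::setNames(10^stats::runif(length(net$parameters), -3, 3),
                  net$parameters)
}

random_state <- function(net) {
  stats::setNames(10^stats::runif(nrow(net$species), -2, 2),
                  net$species$name)
}

# Brute-force dominant production reactions, computed from the raw reaction
# definitions (not the package's unidirectional tables): evaluate each
# direction's monomial k * prod(state^reactant_stoich), sign it by the focal
# species' net stoichiometry in that direction, sum per reaction, keep the
# positive net terms, and apply the pairwise log10 par test against the
# largest one.
brute_force_dominant <- function(net, state, params, focal, rho) {
  vals <- c()
  for (rx in net$reactions) {
    dirs <- list(list(from = rx$reactants, to = rx$products, k = rx$kf))
    if (rx$reversible) {
      dirs <- c(dirs, list(list(from = rx$products, to = rx$reactants,
                                k = rx$kr)))
    }
    total <- 0
    for (d in dirs) {
      mono <- params[[d$k]]
      for (s in names(d$from)) mono <- mono * state[[s]]^d$from[[s]]
      s_focal <- (if (focal %in% names(d$to)) d$to[[focal]] else 0) -
        (if (focal %in% names(d$from)) d$from[[focal]] else 0)
      total <- total + s_focal * mono
    }
    if (total > 0) vals[rx$id] <- total
  }
  if (!length(vals)) return(character(0))
  md <- max(vals)
  names(vals)[abs(log10(md) - log10(vals)) < rho]
}

# Exhaustive LCS length: enumerate all subsequences of the shorter sequence
# and keep the longest that is also a subsequence of the other.
is_subsequence <- function(sub, seqn) {
  if (!length(sub)) return(TRUE)
  j <- 1L
  for (v in seqn) {
    if (v == sub[j]) {
      j <- j + 1L
      if (j > length(sub)) return(TRUE)
    }
  }
  FALSE
}

brute_force_lcs <- function(x, y) {
  if (length(y) < length(x)) { tmp <- x; x <- y; y <- tmp }
  best <- 0L
  for (mask in 0:(2^length(x) - 1)) {
    sub <- x[bitwAnd(mask, 2^(seq_along(x) - 1)) != 0]
    if (length(sub) > best && is_subsequence(sub, y)) {
      best <- length(sub)
    }
  }
  best
}

# Small closed binding network used across simulation tests.
binding_network <- function() {
  reaction_network(
    list(species_def("A", 60), species_def("B", 40), species_def("C", 5)),
    list(reaction("bind", c(A = 1L, B = 1L), c(C = 1L),
                  kf = "kf", kr = "kr")))
}
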