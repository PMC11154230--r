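#' Abridged extrinsic apoptosis reaction model (aEARM)
#'
#' A coarse-grained mass-action model of TRAIL-induced (type-II) apoptosis
#' with 22 molecular species and 28 kinetic parameters. The pathway is
#' encoded as simple dynamic motifs:
#'
#' * TRAIL ligand binding its death receptor (`L + R <-> L:R`), followed by
#'   reversible maturation of the ligand-receptor complex into the
#'   death-inducing signaling complex (`L:R <-> DISC`);
#' * catalytic activation of initiator caspase-8 by the DISC, with feedback
#'   re-activation of initiator caspases by active effector caspases;
#' * initiator-caspase truncation of Bid (tBid);
#' * tBid-dependent activation of the lumped MOMP species, and MOMP
#'   self-amplification (`MOMP* + MOMP -> 2 MOMP*`) reproducing the
#'   snap-action, switch-like onset of mitochondrial outer membrane
#'   permeabilization;
#' * type-1 (initiator-caspase) and type-2 (MOMP-dependent) activation of
#'   effector caspase-3;
#' * cleavage of the apoptosis completion marker PARP by active effector
#'   caspase.
#'
#' Every catalysis step is a 3-parameter enzyme-substrate-complex block
#' `E + S <-> E:S -> E + P` (kf, kr, kcat). Abundances are in copies per
#' cell and drawn from published extrinsic-apoptosis models; rate parameters
#' default to biologically plausible centers (1e-6 /s/molecule for
#' bimolecular binding, 1e-3 /s for unbinding, 1 /s for catalysis).
#'
#' @return A [reaction_network()] with 22 species and 28 rate parameters.
#' @seealso [aearm_nominal_params()] for the plausible-center parameter
#'   vector, [make_toy_bifurcation()] for a minimal two-branch fixture.
#' @export
make_aearm <- function() {
  sp <- list(
    species_def("L", 3000, "ligand"),          # TRAIL
    species_def("R", 200, "receptor"),         # death receptor DR4/5
    species_def("L_R", 0, "complex"),
    species_def("DISC", 0, "enzyme"),
    species_def("iC", 20000, "zymogen"),       # procaspase-8
    species_def("DISC_iC", 0, "complex"),
    species_def("iC_star", 0, "enzyme"),       # active caspase-8
    species_def("eC_star_iC", 0, "complex"),
    species_def("Bid", 40000, "substrate"),
    species_def("iC_star_Bid", 0, "complex"),
    species_def("tBid", 0, "enzyme"),
    species_def("MOMP", 100000, "substrate"),  # Bax/Bak-like pool
    species_def("tBid_MOMP", 0, "complex"),
    species_def("MOMP_star", 0, "enzyme"),
    species_def("MOMP_star_MOMP", 0, "complex"),
    species_def("eC", 10000, "zymogen"),       # procaspase-3
    species_def("iC_star_eC", 0, "complex"),
    species_def("MOMP_star_eC", 0, "complex"),
    species_def("eC_star", 0, "enzyme"),       # active caspase-3
    species_def("PARP", 1000000, "substrate"),
    species_def("eC_star_PARP", 0, "complex"),
    species_def("cPARP", 0, "product"))

  ## catalysis motif: E + S <-> E:S -> E + P (3 parameters)
  catalysis <- function(stem, E, S, ES, P, extra_product = NULL) {
    prod2 <- stats::setNames(c(1L, 1L), c(E, P))
    if (identical(E, P)) prod2 <- stats::setNames(2L, P)
    list(
      reaction(paste0(stem, "_bind"),
               stats::setNames(c(1L, 1L), c(E, S)),
               stats::setNames(1L, ES),
               kf = paste0("kf_", stem), kr = paste0("kr_", stem)),
      reaction(paste0(stem, "_cat"),
               stats::setNames(1L, ES), prod2,
               kf = paste0("kc_", stem)))
  }
  rx <- c(
    list(
      reaction("trail_bind", c(L = 1L, R = 1L), c(L_R = 1L),
               kf = "kf_LR", kr = "kr_LR"),
      reaction("disc_form", c(L_R = 1L), c(DISC = 1L),
               kf = "kf_DISC", kr = "kr_DISC")),
    catalysis("iC_act", "DISC", "iC", "DISC_iC", "iC_star"),
    catalysis("iC_fb", "eC_star", "iC", "eC_star_iC", "iC_star"),
    catalysis("bid_trunc", "iC_star", "Bid", "iC_star_Bid", "tBid"),
    catalysis("momp_act", "tBid", "MOMP", "tBid_MOMP", "MOMP_star"),
    catalysis("momp_amp", "MOMP_star", "MOMP", "MOMP_star_MOMP",
              "MOMP_star"),
    catalysis("eC_act1", "iC_star", "eC", "iC_star_eC", "eC_star"),
    catalysis("eC_act2", "MOMP_star", "eC", "MOMP_star_eC", "eC_star"),
    catalysis("parp_cleave", "eC_star", "PARP", "eC_star_PARP", "cPARP"))
  reaction_network(sp, rx)
}

#' Nominal (prior-center) parameter values for aEARM
#'
#' Bimolecular binding rates default to 1e-6 /s/molecule, unbinding to
#' 1e-3 /s and catalysis to 1 /s; the unimolecular DISC maturation step uses
#' the unbinding-scale center in both directions.
#'
#' @return A [parameter_vector()] covering all 28 aEARM parameters.
#' @export
aearm_nominal_params <- function() {
  pars <- make_aearm()$parameters
  v <- vapply(pars, function(p) {
    switch(substr(p, 1, 2), kf = 1e-6, kr = 1e-3, kc = 1, stop(p))
  }, numeric(1))
  v["kf_DISC"] <- 1e-3
  parameter_vector(v)
}

#' Default simulation time grid for aEARM
#'
#' @param n Number of grid points (default 100).
#' @param horizon End time in seconds (default 20000, covering the
#'   characteristic ~10000 s time of death).
#' @return Numeric vector of `n` uniformly spaced times starting at 0.
#' @export
aearm_time_grid <- function(n = 100L, horizon = 20000) {
  seq(0, horizon, length.out = n)
}

#' Minimal two-branch bifurcation fixture
#'
#' Three species, three parameters. The target `T` is produced along two
#' branches, `A -> T` (rate `k1`) and `B -> T` (rate `k2`), while `A`
#' converts into `B` (`A -> B`, rate `kconv`). With the default rates the
#' production flux into `T` is dominated by branch 1 early (while `B` is
#' still scarce), passes through a period where both branches are on par,
#' and ends dominated by branch 2 — so dominance of either branch, or a
#' mid-course switch, is controlled by a single rate ratio.
#'
#' @return A [reaction_network()] with species `A`, `B`, `T`.
#' @export
make_toy_bifurcation <- function() {
  reaction_network(
    list(species_def("A", 100), species_def("B", 0), species_def("T", 0)),
    list(reaction("conv", c(A = 1L), c(B = 1L), kf = "kconv"),
         reaction("branch1", c(A = 1L), c(T = 1L), kf = "k1"),
         reaction("branch2", c(B = 1L), c(T = 1L), kf = "k2")))
}

#' Nominal parameters and time grid for the toy bifurcation fixture
#'
#' @return A [parameter_vector()] with `kconv = 0.02`, `k1 = 0.01`,
#'   `k2 = 0.01`.
#' @export
toy_nominal_params <- function() {
  parameter_vector(c(kconv = 0.02, k1 = 0.01, k2 = 0.01))
}

#' @rdname toy_nominal_params
#' @param n Number of grid points.
#' @param horizon End time in seconds.
#' @export
toy_time_grid <- function(n = 50L, horizon = 300) {
  seq(0, horizon, length.out = n)
}
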