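test_that("log-space separation and the par relation behave as defined", {
  expect_equal(sep(10, 10), 0)
  expect_equal(sep(1000, 10), 2)
  expect_equal(sep(10, 5), log10(2), tolerance = 1e-12)
  expect_equal(sep(5, 10), sep(10, 5))
  expect_true(on_par(7, 7, 0.001))
  expect_true(on_par(10, 5, 1))
  expect_false(on_par(1000, 1, 1))
  # ties at exactly rho are non-dominant partners no more: strict inequality
  expect_false(on_par(100, 10, 1))
  expect_error(sep(0, 1), "positive")
  expect_error(sep(-2, 1), "positive")
})

test_that("net rate terms collapse reversible pairs and sign by production", {
  net <- read_model_dsl(text = c(
    "species A 10", "species B 2",
    "reaction r1: A <-> B kf kr"))
  # w.r.t. B: net = kf A - kr B = 0.5*10 - 1*2 = +3
  terms <- net_rate_terms(net, c(A = 10, B = 2), c(kf = 0.5, kr = 1), "B")
  expect_equal(terms$value, 3)
  expect_equal(terms$sources[[1]], "A")
  # w.r.t. A the same flux is consumption
  terms_a <- net_rate_terms(net, c(A = 10, B = 2), c(kf = 0.5, kr = 1), "A")
  expect_equal(terms_a$value, -3)
  # detailed balance: kf = kr and A = B gives a zero net term
  bal <- net_rate_terms(net, c(A = 4, B = 4), c(kf = 1, kr = 1), "B")
  expect_equal(bal$value, 0)
  # irreversible: single negative monomial w.r.t. the reactant
  irr <- read_model_dsl(text = c(
    "species A 10", "species B 0", "reaction r1: A -> B k"))
  expect_equal(net_rate_terms(irr, c(A = 10, B = 0), c(k = 2), "A")$value,
               -20)
  expect_error(net_rate_terms(irr, c(A = 1, B = 0), c(k = 1), "Z"),
               "unknown species")
})

test_that("production set keeps strictly positive terms only", {
  terms <- data.frame(reaction = c("a", "b", "c", "d"),
                      value = c(10, 0.5, -3, 0),
                      sources = I(list("x", "x", "x", "x")))
  expect_equal(production_set(terms)$reaction, c("a", "b"))
  allneg <- data.frame(reaction = "a", value = -1, sources = I(list("x")))
  expect_equal(nrow(production_set(allneg)), 0L)
})

test_that("dominant reactions are the argmax plus everything on par", {
  pset <- data.frame(reaction = c("rA", "rB"), value = c(10, 0.9),
                     sources = I(list("x", "y")))
  expect_equal(dominant_reactions(pset, 1), "rA")   # sep = 1.046
  pset$value <- c(10, 2)
  expect_setequal(dominant_reactions(pset, 1), c("rA", "rB"))  # sep = 0.699
  expect_equal(dominant_reactions(pset[0, ], 1), character(0))
})

test_that("dominant reactions match brute force on random networks", {
  set.seed(101)
  for (rep in 1:40) {
    net <- random_network(max_rx = 8L)
    params <- random_params(net)
    state <- random_state(net)
    focal <- sample(net$species$name, 1)
    for (rho in c(0.5, 1, 2)) {
      got <- dominant_reactions(
        production_set(net_rate_terms(net, state, params, focal)), rho)
      want <- brute_force_dominant(net, state, params, focal, rho)
      expect_setequal(got, want)
    }
  }
})

test_that("dominant set grows monotonically with rho", {
  set.seed(7)
  for (rep in 1:20) {
    net <- random_network()
    params <- random_params(net)
    state <- random_state(net)
    focal <- sample(net$species$name, 1)
    pset <- production_set(net_rate_terms(net, state, params, focal))
    prev <- character(0)
    for (rho in c(0.25, 0.5, 1, 2, 4)) {
      cur <- dominant_reactions(pset, rho)
      expect_true(all(prev %in% cur))
      if (nrow(pset)) {
        # the argmax is always a member of a nonempty dominant set
        expect_true(pset$reaction[which.max(pset$value)] %in% cur)
      }
      prev <- cur
    }
  }
})

linear_cascade <- function() {
  read_model_dsl(text = c(
    "species A 100", "species B 10", "species C 1",
    "reaction r1: A -> B k1", "reaction r2: B -> C k2"))
}

test_that("subnetwork tracing follows producers to the requested depth", {
  net <- linear_cascade()
  st <- c(A = 100, B = 10, C = 1)
  p <- c(k1 = 1, k2 = 1)
  sub2 <- trace_dominant_subnetwork(net, st, p, "C",
                                    dominance_config(depth = 2))
  expect_setequal(paste(sub2$edges$from, sub2$edges$to),
                  c("B C", "A B"))
  sub1 <- trace_dominant_subnetwork(net, st, p, "C",
                                    dominance_config(depth = 1))
  expect_equal(paste(sub1$edges$from, sub1$edges$to), "B C")
  expect_error(trace_dominant_subnetwork(net, st, p, "Q",
                                         dominance_config()),
               "unknown species")
})

test_that("tracing picks the dominant branch of the toy bifurcation", {
  toy <- make_toy_bifurcation()
  p <- c(kconv = 0.002, k1 = 0.01, k2 = 1e-4)  # branch 1 rate 100x branch 2
  tr <- simulate_network(toy, p, toy_time_grid())
  st <- tr$species[25, ]
  expect_gt(p[["k1"]] * st[["A"]], 10 * p[["k2"]] * st[["B"]])
  sub <- trace_dominant_subnetwork(toy, st, p, "T",
                                   dominance_config(rho = 1, depth = 1))
  expect_equal(sub$edges$from, "A")
  expect_equal(sub$edges$to, "T")
})

test_that("cycles terminate: expanded species are not re-expanded", {
  # self-amplifying motif akin to MOMP feedback
  net <- read_model_dsl(text = c(
    "species S 100", "species P 10",
    "reaction seed: S -> P k1",
    "reaction amp: S + P -> 2 P k2"))
  sub <- trace_dominant_subnetwork(net, c(S = 100, P = 10),
                                   c(k1 = 1e-6, k2 = 1), "P",
                                   dominance_config(depth = 10))
  expect_true(nrow(sub$edges) <= 4)
  expect_true(all(c("S", "P") %in% sub$expanded))
})

test_that("consumption tracing mirrors production on the reversed network", {
  net <- linear_cascade()
  st <- c(A = 100, B = 10, C = 1)
  p <- c(k1 = 1, k2 = 1)
  cons <- trace_dominant_subnetwork(net, st, p, "A",
                                    dominance_config(depth = 2,
                                                     direction = "consumption"))
  prod_mirror <- trace_dominant_subnetwork(reverse_network(net), st, p, "A",
                                           dominance_config(depth = 2))
  expect_equal(cons$edges, prod_mirror$edges)
  # the consumed flux of A flows A -> B on the mirror: edge reversed
  expect_equal(paste(cons$edges$from, cons$edges$to)[1], "B A")
})

test_that("canonical labels are stable under edge permutation and injective", {
  reg <- new_registry()
  sub_a <- list(target = "C",
                edges = data.frame(from = c("B", "A"), to = c("C", "B"),
                                   reaction = c("r1", "r2")))
  sub_b <- list(target = "C",
                edges = sub_a$edges[2:1, ])
  sub_c <- list(target = "C",
                edges = data.frame(from = "B", to = "C", reaction = "r1"))
  empty <- list(target = "C",
                edges = data.frame(from = character(0), to = character(0),
                                   reaction = character(0)))
  l1 <- canonical_label(sub_a, reg)
  expect_identical(canonical_label(sub_b, reg), l1)
  expect_false(canonical_label(sub_c, reg) == l1)
  expect_identical(canonical_label(empty, reg), 0L)
  # labels decode back to their canonical edge sets
  ed <- registry_edges(reg, l1)
  expect_setequal(paste(ed$from, ed$to), c("B C", "A B"))
})

test_that("fingerprints are constant in a constant-dominance regime", {
  toy <- make_toy_bifurcation()
  p <- c(kconv = 1e-8, k1 = 0.01, k2 = 1e-8)
  reg <- new_registry()
  tr <- simulate_network(toy, p, toy_time_grid())
  fp <- fingerprint(toy, tr, p, "T", dominance_config(depth = 1), reg)
  expect_equal(length(fp$labels), length(toy_time_grid()))
  expect_equal(length(unique(fp$labels)), 1L)
})

test_that("a mid-course dominance switch lands at the monomial crossing", {
  toy <- make_toy_bifurcation()
  p <- c(kconv = 0.02, k1 = 0.01, k2 = 0.01)
  tg <- toy_time_grid()
  tr <- simulate_network(toy, p, tg)
  # locate the crossing of the two production monomials numerically
  m1 <- p[["k1"]] * tr$species[, "A"]
  m2 <- p[["k2"]] * tr$species[, "B"]
  cross_idx <- which(diff(sign(m1 - m2)) != 0)[1]
  reg <- new_registry()
  # rho small enough that the on-par band is narrower than one grid step
  fp <- fingerprint(toy, tr, p, "T", dominance_config(rho = 0.01, depth = 1),
                    reg)
  changes <- which(diff(fp$labels) != 0)
  expect_equal(length(changes), 1L)
  expect_lte(abs(changes[1] - cross_idx), 1L)
})

test_that("an empty system yields the sentinel label everywhere", {
  toy <- make_toy_bifurcation()
  p <- toy_nominal_params()
  reg <- new_registry()
  # no molecules anywhere: every rate monomial is exactly zero
  tr <- simulate_network(toy, p, toy_time_grid(),
                         initial = c(A = 0, B = 0, T = 0))
  fp <- fingerprint(toy, tr, p, "T", dominance_config(), reg)
  expect_true(all(fp$labels == 0L))
})

test_that("re-running an ensemble with the same registry is bit-exact", {
  toy <- make_toy_bifurcation()
  pr <- planted_regime_ensemble(toy, toy_regimes(), n_per_regime = 4,
                                seed = 11)
  f1 <- fingerprint_ensemble(toy, pr$ensemble, "T", toy_time_grid())
  f2 <- fingerprint_ensemble(toy, pr$ensemble, "T", toy_time_grid())
  expect_identical(f1$labels, f2$labels)
})
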