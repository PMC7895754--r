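test_that("build_rhs sums stoichiometric fluxes", {
  net <- network(
    species = list(species("A", initial_amount = 10),
                   species("B", initial_amount = 0)),
    reactions = list(reaction("r", reactants = c(A = 1), products = c(B = 1),
                              law = rate_law("mass_action", "k"))),
    parameters = list(parameter("k", 1)))
  rhs <- build_rhs(net)
  expect_equal(rhs(c(A = 10, B = 0)), c(A = -10, B = 10))
})

test_that("constant species have exactly zero derivative", {
  net <- network(
    species = list(species("O2", is_constant = TRUE, initial_amount = 50),
                   species("H", initial_amount = 0)),
    reactions = list(
      reaction("r", reactants = c(H = 1, O2 = 1), products = c(O2 = 1),
               law = rate_law("mass_action", "k"))),
    parameters = list(parameter("k", 2)))
  rhs <- build_rhs(net)
  d <- rhs(c(O2 = 50, H = 7))
  expect_identical(d[["O2"]], 0)
  expect_equal(d[["H"]], -2 * 7 * 50)
})

test_that("build_rhs refuses invalid networks with the validation report", {
  bad <- binding_network()
  bad$reactions[["bind"]]$products <- c(X9 = 1)
  expect_error(build_rhs(bad), "X9")
})

test_that("engine RHS matches the brute-force flux-summation oracle", {
  for (seed in c(2, 7, 19)) {
    net <- random_network(seed)
    rhs <- build_rhs(net)
    set.seed(seed + 100)
    for (i in 1:5) {
      st <- stats::setNames(stats::runif(length(net$species), 0, 800),
                            species_ids(net))
      expect_equal(rhs(st), rhs_oracle(net, st), tolerance = 1e-12)
    }
  }
})

test_that("equilibrate finds closed-form steady states", {
  # symmetric A <-> B: equal split of the conserved total
  st <- equilibrate(isomer_network(), criterion = 1e-10)
  expect_equal(unname(st[c("A", "B")]), c(50, 50), tolerance = 1e-6)
  # linear synthesis/decay: X* = ks/kd
  st2 <- equilibrate(synth_decay_network(ks = 120, kd = 0.4),
                     criterion = 1e-10)
  expect_equal(unname(st2[["X"]]), 300, tolerance = 1e-6)
})

test_that("equilibrate reports the worst offender on non-convergence", {
  # pure synthesis never converges
  net <- network(species = list(species("X", initial_amount = 0)),
                 reactions = list(reaction("syn", products = c(X = 1),
                                           law = rate_law("synthesis", "k"))),
                 parameters = list(parameter("k", 5)))
  expect_error(equilibrate(net, horizon = 20), "'X'")
})

test_that("a zero-event protocol from an equilibrated state stays flat", {
  net <- binding_network()
  st <- equilibrate(net, criterion = 1e-10)
  sim <- simulate_protocol(net, stimulation_protocol(duration = 24),
                           state = st)
  drift <- apply(abs(sim$states - rep(sim$states[1, ],
                                      each = nrow(sim$states))), 2, max)
  expect_lt(max(drift / (abs(sim$states[1, ]) + 1)), 1e-6)
})

test_that("bolus bimolecular binding matches the closed-form solution", {
  k <- 2e-3; A0 <- 800; B0 <- 300
  net <- irreversible_binding_network(k, A0 = 0, B0 = B0)
  p <- stimulation_protocol(events = dose_event(0, "A", A0, "copies"),
                            duration = 6, name = "bolus")
  sim <- simulate_protocol(net, p, solver_settings(rel_tol = 1e-9,
                                                   abs_tol = 1e-12),
                           state = initial_state(net))
  expected <- bimolecular_solution(sim$time, k, A0, B0)
  got <- sim$states[, "C"]
  expect_lt(max(abs(got - expected) / pmax(expected, 1)), 1e-6)
})

test_that("declared moiety totals are conserved along trajectories", {
  net <- binding_network()
  p <- stimulation_protocol(events = dose_event(0, "L", 5000, "copies"),
                            duration = 48, name = "dose")
  sim <- simulate_protocol(net, p, state = initial_state(net))
  tot <- apply(sim$states, 1, function(s)
    conserved_totals(net, s)[["R_total"]])
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
})

test_that("dosed species jump by the dose amount, others are continuous", {
  net <- binding_network()
  st <- equilibrate(net, criterion = 1e-10)
  p <- stimulation_protocol(events = dose_event(10, "L", 500, "copies"),
                            duration = 20, name = "late dose")
  sim <- simulate_protocol(net, p, state = st)
  i <- match(10, sim$time)
  # the state recorded at the event time is post-jump: L gains the dose
  # relative to the previous grid point while LR is continuous
  expect_gt(sim$states[i, "L"] - sim$states[i - 1, "L"], 450)
  expect_lt(abs(sim$states[i, "LR"] - sim$states[i - 1, "LR"]),
            0.05 * sim$states[i - 1, "LR"] + 1)
})

test_that("halving rel_tol leaves 24-h endpoints essentially unchanged", {
  net <- ref_network()
  p <- stimulation_protocol(events = dose_event(0, "L_IFNG", 10),
                            duration = 24, name = "grid")
  tg <- c(0, 12, 24)
  s1 <- simulate_protocol(net, p, solver_settings(rel_tol = 1e-6),
                          time_grid = tg, state = ref_state())
  s2 <- simulate_protocol(net, p, solver_settings(rel_tol = 5e-7),
                          time_grid = tg, state = ref_state())
  end1 <- s1$states[nrow(s1$states), ]
  end2 <- s2$states[nrow(s2$states), ]
  expect_lt(max(abs(end1 - end2) / (abs(end1) + 1)), 1e-3)
})

test_that("no species dips materially negative", {
  net <- ref_network()
  p <- stimulation_protocol(events = dose_event(0, "L_IL4", 10),
                            oxygen_percent = 2, duration = 24, name = "mix")
  sim <- simulate_protocol(net, p, state = ref_state())
  expect_gt(min(sim$states), -10 * sim$abs_tol)
})

test_that("production rates report secretion-tagged fluxes", {
  net <- ref_network()
  sim <- simulate_protocol(net, stimulation_protocol(duration = 2),
                           state = ref_state())
  # at rest, TNF-alpha secretion flux = k_sec * intracellular TNF-alpha
  k_sec <- parameter_values(net)[["k_TNFA_sec"]]
  expect_equal(unname(sim$production[1, "L_TNFA"]),
               unname(k_sec * ref_state()[["TNFA"]]),
               tolerance = 1e-6)
})
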