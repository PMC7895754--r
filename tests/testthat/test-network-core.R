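test_that("evaluate_rate matches its defining formulas", {
  pars <- c(k = 2)
  rx <- reaction("r", reactants = c(A = 1, B = 1), products = c(C = 1),
                 law = rate_law("mass_action", "k"))
  expect_equal(evaluate_rate(rx$law, c(A = 3, B = 4), rx, pars), 24.0)

  hill <- reaction("h", products = c(C = 1),
                   law = rate_law("hill_activation", "k", K = 100, n = 2.5,
                                  regulator = "A"))
  expect_equal(evaluate_rate(hill$law, c(A = 100), hill, pars), 0.5 * 2)

  # hill n = 1 is analytically identical to Michaelis-Menten
  h1 <- reaction("h1", products = c(C = 1),
                 law = rate_law("hill_activation", "k", K = 37, n = 1,
                                regulator = "A"))
  mm <- reaction("mm", products = c(C = 1),
                 law = rate_law("michaelis_menten", "k", K = 37,
                                regulator = "A"))
  set.seed(11)
  for (a in stats::runif(20, 0, 500))
    expect_equal(evaluate_rate(h1$law, c(A = a), h1, pars),
                 evaluate_rate(mm$law, c(A = a), mm, pars))
})

test_that("rate laws are non-negative and have the right limits", {
  pars <- c(k = 3)
  set.seed(5)
  for (i in 1:50) {
    a <- stats::runif(1, 0, 1e4)
    ha <- reaction("x", products = c(C = 1),
                   law = rate_law("hill_activation", "k", K = 50, n = 2,
                                  regulator = "A"))
    hi <- reaction("x", products = c(C = 1),
                   law = rate_law("hill_inhibition", "k", K = 50, n = 2,
                                  regulator = "A"))
    expect_gte(evaluate_rate(ha$law, c(A = a), ha, pars), 0)
    expect_gte(evaluate_rate(hi$law, c(A = a), hi, pars), 0)
  }
  ha <- reaction("x", products = c(C = 1),
                 law = rate_law("hill_activation", "k", K = 50, n = 2,
                                regulator = "A"))
  hi <- reaction("x", products = c(C = 1),
                 law = rate_law("hill_inhibition", "k", K = 50, n = 2,
                                regulator = "A"))
  expect_equal(evaluate_rate(ha$law, c(A = 0), ha, pars), 0)
  expect_equal(evaluate_rate(hi$law, c(A = 0), hi, pars), 3)
  expect_equal(evaluate_rate(ha$law, c(A = 1e9), ha, pars), 3,
               tolerance = 1e-6)
  expect_lt(evaluate_rate(hi$law, c(A = 1e9), hi, pars), 1e-6)
})

test_that("evaluate_rate errors name the reaction", {
  rx <- reaction("needs_reg", products = c(C = 1),
                 law = rate_law("hill_activation", "k", K = 10,
                                regulator = "Z"))
  expect_error(evaluate_rate(rx$law, c(A = 1), rx, c(k = 1)), "needs_reg")
  mass <- reaction("neg", reactants = c(A = 1), products = c(B = 1),
                   law = rate_law("mass_action", "k"))
  expect_error(evaluate_rate(mass$law, c(A = -1), mass, c(k = 1)),
               "negative")
})

test_that("validate_network reports violations by id", {
  expect_length(validate_network(binding_network()), 0)

  bad <- binding_network()
  bad$reactions[["bind"]]$products <- c(X9 = 1)
  report <- validate_network(bad)
  expect_length(report, 1)
  expect_match(report, "X9")

  # moiety violated: consume R without producing a member
  leaky <- binding_network()
  leaky$reactions[["leak"]] <- reaction("leak", reactants = c(R = 1),
                                        law = rate_law("first_order_decay",
                                                       "kr"))
  report <- validate_network(leaky)
  expect_true(any(grepl("R_total", report) & grepl("leak", report)))
})

test_that("constant species may not be net-consumed", {
  net <- binding_network()
  net$species[["L"]]$is_constant <- TRUE
  report <- validate_network(net)
  expect_true(any(grepl("constant species 'L'", report)))
})

test_that("conserved_totals computes weighted totals", {
  net <- binding_network()
  expect_equal(conserved_totals(net, c(R = 100, LR = 0, L = 7)),
               c(R_total = 100, L_total = 7))
  dimer <- network(
    species = list(species("M", initial_amount = 10),
                   species("M2", initial_amount = 5)),
    reactions = list(reaction("dim", reactants = c(M = 2),
                              products = c(M2 = 1),
                              law = rate_law("mass_action", "k"))),
    parameters = list(parameter("k", 1)),
    moieties = list(moiety("M_total", c(M = 1, M2 = 2))))
  expect_length(validate_network(dimer), 0)
  expect_equal(conserved_totals(dimer, c(M = 4, M2 = 3)),
               c(M_total = 10))
  expect_error(conserved_totals(net, c(R = 1, L = 1)), "LR")
})

test_that("constructors enforce their invariants", {
  expect_error(species("s", initial_amount = -1), "initial_amount")
  expect_error(parameter("p", 0), "positive")
  expect_error(rate_law("hill_activation", "k", K = 10, n = 0.5,
                        regulator = "A"), "n must be")
  expect_error(rate_law("hill_activation", "k"), "regulator")
  expect_error(reaction("r", law = rate_law("synthesis", "k")),
               "neither reactants nor products")
  expect_error(set_parameters(binding_network(), c(nope = 1)), "nope")
})
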