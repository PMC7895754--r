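# Shared fixtures and independent oracles. Everything is built in code; the
# expensive reference-network equilibration is memoized for the whole run.

.cache <- new.env(parent = emptyenv())

ref_network <- function() {
  if (is.null(.cache$net)) .cache$net <- build_reference_network()
  .cache$net
}

ref_state <- function() {
  if (is.null(.cache$state)) .cache$state <- equilibrate(ref_network())
  .cache$state
}

# closed reversible binding: L + R <-> LR
binding_network <- function(kf = 1e-3, kr = 0.1, L0 = 1000, R0 = 100) {
  network(
    species = list(
      species("L", role = "ligand", compartment = "extracellular",
              initial_amount = L0),
      species("R", role = "receptor", initial_amount = R0),
      species("LR", role = "complex", initial_amount = 0)),
    reactions = list(
      reaction("bind", reactants = c(L = 1, R = 1), products = c(LR = 1),
               law = rate_law("mass_action", "kf")),
      reaction("unbind", reactants = c(LR = 1), products = c(L = 1, R = 1),
               law = rate_law("mass_action", "kr"))),
    parameters = list(parameter("kf", kf), parameter("kr", kr)),
    moieties = list(moiety("R_total", c(R = 1, LR = 1)),
                    moiety("L_total", c(L = 1, LR = 1))),
    name = "binding")
}

# irreversible bimolecular binding A + B -> C with closed-form solution
irreversible_binding_network <- function(k = 1e-3, A0 = 800, B0 = 300) {
  network(
    species = list(species("A", initial_amount = A0),
                   species("B", initial_amount = B0),
                   species("C", initial_amount = 0)),
    reactions = list(
      reaction("bind", reactants = c(A = 1, B = 1), products = c(C = 1),
               law = rate_law("mass_action", "k"))),
    parameters = list(parameter("k", k)),
    name = "irreversible_binding")
}

# closed form for A + B -> C, distinct initial amounts
bimolecular_solution <- function(t, k, A0, B0) {
  d <- A0 - B0
  e <- exp(-d * k * t)
  # C(t) = A0*B0*(1 - e^{-(A0-B0) k t}) / (A0 - B0 e^{-(A0-B0) k t})
  A0 * B0 * (1 - e) / (A0 - B0 * e)
}

# linear synthesis/decay motif
synth_decay_network <- function(ks = 100, kd = 0.5, X0 = 10) {
  network(
    species = list(species("X", initial_amount = X0)),
    reactions = list(
      reaction("syn", products = c(X = 1),
               law = rate_law("synthesis", "ks"), tags = "transcription"),
      reaction("deg", reactants = c(X = 1),
               law = rate_law("first_order_decay", "kd"))),
    parameters = list(parameter("ks", ks), parameter("kd", kd)),
    name = "synth_decay")
}

# symmetric isomerization A <-> B
isomer_network <- function(kf = 1, kr = 1, A0 = 100) {
  network(
    species = list(species("A", initial_amount = A0),
                   species("B", initial_amount = 0)),
    reactions = list(
      reaction("fwd", reactants = c(A = 1), products = c(B = 1),
               law = rate_law("mass_action", "kf")),
      reaction("rev", reactants = c(B = 1), products = c(A = 1),
               law = rate_law("mass_action", "kr"))),
    parameters = list(parameter("kf", kf), parameter("kr", kr)),
    moieties = list(moiety("AB_total", c(A = 1, B = 1))),
    name = "isomer")
}

# 3-parameter screening motif: only k_synth couples the dosed ligand to the
# M1 readout; k2/k3 drive a disconnected decoy species.
screen_motif <- function() {
  net <- network(
    species = list(
      species("L", role = "ligand", compartment = "extracellular",
              initial_amount = 0),
      species("X", initial_amount = 0),
      species("Y", initial_amount = 0),
      species("D", initial_amount = 0)),
    reactions = list(
      reaction("L_deg", reactants = c(L = 1),
               law = rate_law("first_order_decay", "kL")),
      reaction("X_basal", products = c(X = 1),
               law = rate_law("synthesis", "kxb")),
      reaction("X_induced", products = c(X = 1),
               law = rate_law("hill_activation", "k_synth", K = 500, n = 2,
                              regulator = "L")),
      reaction("X_deg", reactants = c(X = 1),
               law = rate_law("first_order_decay", "kxd")),
      reaction("Y_basal", products = c(Y = 1),
               law = rate_law("synthesis", "kyb")),
      reaction("Y_deg", reactants = c(Y = 1),
               law = rate_law("first_order_decay", "kyd")),
      reaction("D_syn", products = c(D = 1),
               law = rate_law("synthesis", "k2")),
      reaction("D_deg", reactants = c(D = 1),
               law = rate_law("first_order_decay", "k3"))),
    parameters = list(parameter("kL", 0.05), parameter("kxb", 10),
                      parameter("k_synth", 200), parameter("kxd", 0.5),
                      parameter("kyb", 10), parameter("kyd", 0.5),
                      parameter("k2", 5), parameter("k3", 0.2)),
    name = "screen_motif",
    annotations = list(marker_panel = marker_panel(
      m1 = data.frame(species = "X", readout = "level",
                      stringsAsFactors = FALSE),
      m2 = data.frame(species = "Y", readout = "level",
                      stringsAsFactors = FALSE))))
  net
}

screen_motif_protocol <- function(duration = 24)
  stimulation_protocol(events = dose_event(0, "L", 2000, "copies"),
                       duration = duration, name = "screen")

# deliberately non-identifiable pair: only the product k1*k2 is constrained
# by steady-state observations of Y
degenerate_motif <- function(k1 = 50, k2 = 0.4) {
  network(
    species = list(species("X", initial_amount = 1),
                   species("Y", initial_amount = 1)),
    reactions = list(
      reaction("X_syn", products = c(X = 1),
               law = rate_law("synthesis", "k1")),
      reaction("X_deg", reactants = c(X = 1),
               law = rate_law("first_order_decay", "kx")),
      reaction("Y_syn", reactants = c(X = 1), products = c(X = 1, Y = 1),
               law = rate_law("mass_action", "k2")),
      reaction("Y_deg", reactants = c(Y = 1),
               law = rate_law("first_order_decay", "ky"))),
    parameters = list(parameter("k1", k1), parameter("kx", 1),
                      parameter("k2", k2), parameter("ky", 0.5)),
    name = "degenerate")
}

# brute-force PRCC oracle: explicit rank regressions via lm()
prcc_oracle <- function(X, y) {
  R <- apply(as.matrix(X), 2, rank)
  ry <- rank(y)
  vapply(seq_len(ncol(R)), function(j) {
    others <- R[, -j, drop = FALSE]
    rx_res <- stats::residuals(stats::lm(R[, j] ~ others))
    ry_res <- stats::residuals(stats::lm(ry ~ others))
    stats::cor(rx_res, ry_res)
  }, 0)
}

# brute-force RHS oracle: per-reaction flux bookkeeping in plain R
rhs_oracle <- function(net, state) {
  pv <- parameter_values(net)
  d <- stats::setNames(numeric(length(state)), names(state))
  for (rx in net$reactions) {
    v <- evaluate_rate(rx$law, state, rx, pv)
    for (id in names(rx$reactants)) d[id] <- d[id] - rx$reactants[[id]] * v
    for (id in names(rx$products)) d[id] <- d[id] + rx$products[[id]] * v
  }
  for (s in net$species) if (s$is_constant) d[s$id] <- 0
  d
}

# random mass-action/hill network generator for property tests
random_network <- function(seed, n_species = 6, n_reactions = 10) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n_species))
  sp <- lapply(ids, function(i)
    species(i, initial_amount = stats::runif(1, 10, 1000)))
  pm <- list()
  rx <- list()
  for (r in seq_len(n_reactions)) {
    pid <- paste0("p", r)
    pm[[pid]] <- parameter(pid, 10 ^ stats::runif(1, -3, 0))
    kind <- sample(c("mass_action", "hill_activation", "hill_inhibition",
                     "synthesis", "first_order_decay",
                     "michaelis_menten"), 1)
    reactants <- if (kind %in% c("mass_action", "first_order_decay"))
      stats::setNames(sample(1:2, 1), sample(ids, 1)) else NULL
    if (identical(kind, "first_order_decay") && !is.null(reactants))
      reactants[] <- 1
    products <- stats::setNames(1, sample(ids, 1))
    law <- if (kind %in% c("hill_activation", "hill_inhibition",
                           "michaelis_menten"))
      rate_law(kind, pid, K = stats::runif(1, 50, 500),
               n = sample(c(1, 2, 3), 1), regulator = sample(ids, 1))
    else rate_law(kind, pid)
    rx[[paste0("r", r)]] <- reaction(paste0("r", r), reactants, products, law)
  }
  network(sp, rx, pm, name = paste0("random", seed))
}

# minimal mp_sim stand-in with prescribed readouts, for scoring unit tests
fake_sim <- function(time, values) {
  ids <- names(values)
  states <- do.call(cbind, values)
  colnames(states) <- ids
  structure(list(time = time, states = states,
                 production = states, baseline = states[1, ],
                 protocol = stimulation_protocol(duration = max(time)),
                 abs_tol = 1e-9),
            class = "mp_sim")
}
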