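LAW_CODES <- c(mass_action = 0L, hill_activation = 1L, hill_inhibition = 2L,
               synthesis = 3L, first_order_decay = 4L, michaelis_menten = 5L)

# Flatten an mp_network into the array form consumed by the C++ engine.
flatten_network <- function(net) {
  sp <- species_ids(net)
  idx <- stats::setNames(seq_along(sp) - 1L, sp)   # 0-based
  pv <- parameter_values(net)
  nr <- length(net$reactions)
  law <- integer(nr); rate <- K <- nh <- numeric(nr)
  reg <- integer(nr)
  re_ptr <- pr_ptr <- integer(nr + 1)
  re_idx <- pr_idx <- integer(0)
  re_st <- pr_st <- numeric(0)
  for (i in seq_len(nr)) {
    rx <- net$reactions[[i]]
    law[i] <- LAW_CODES[[rx$law$kind]]
    rate[i] <- pv[[rx$law$rate_param]]
    K[i] <- if (is.na(rx$law$K)) 0 else rx$law$K
    nh[i] <- if (is.na(rx$law$n)) 1 else rx$law$n
    reg[i] <- if (is.na(rx$law$regulator)) -1L else idx[[rx$law$regulator]]
    re_idx <- c(re_idx, unname(idx[names(rx$reactants)]))
    re_st <- c(re_st, unname(rx$reactants))
    pr_idx <- c(pr_idx, unname(idx[names(rx$products)]))
    pr_st <- c(pr_st, unname(rx$products))
    re_ptr[i + 1] <- length(re_idx)
    pr_ptr[i + 1] <- length(pr_idx)
  }
  list(n_species = length(sp), law = law, rate = rate, K = K, n_hill = nh,
       regulator = reg, re_ptr = re_ptr, re_idx = re_idx, re_st = re_st,
       pr_ptr = pr_ptr, pr_idx = pr_idx, pr_st = pr_st,
       is_const = as.integer(vapply(net$species, `[[`, TRUE, "is_constant")))
}

#' Solver settings
#'
#' @param rel_tol Relative tolerance (default `1e-6`).
#' @param abs_tol Absolute tolerance; default `1e-9` times the largest
#'   initial amount of the network being integrated (resolved lazily).
#' @param max_step Maximum step size in hours.
#' @param stiff Use the stiff Rosenbrock integrator (the only integrator
#'   shipped; the flag is kept for interface stability).
#' @return An object of class `mp_solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-6, abs_tol = NULL, max_step = Inf,
                            stiff = TRUE) {
  stopifnot(rel_tol > 0, is.null(abs_tol) || abs_tol > 0, max_step > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 stiff = isTRUE(stiff)),
            class = "mp_solver_settings")
}

resolve_abs_tol <- function(settings, net) {
  if (!is.null(settings$abs_tol)) return(settings$abs_tol)
  m <- max(initial_state(net), 1)
  1e-9 * m
}

#' Build the ODE right-hand side of a network
#'
#' @param net A validated `mp_network`.
#' @return A function `(state, t = 0)` returning the named derivative vector
#'   d(species)/dt in copies/hour. Constant species have zero derivative.
#' @export
build_rhs <- function(net) {
  issues <- validate_network(net)
  if (length(issues))
    stop("invalid network:\n  ", paste(issues, collapse = "\n  "))
  spec <- flatten_network(net)
  ids <- species_ids(net)
  function(state, t = 0) {
    stats::setNames(.cpp_rhs(spec, as.numeric(state[ids])), ids)
  }
}

# Integrate one event-free segment; returns matrix (times x species).
integrate_segment <- function(spec, state, times, settings, abs_tol) {
  if (length(times) == 1) return(matrix(state, 1, length(state)))
  ms <- settings$max_step
  if (!is.finite(ms)) ms <- max(diff(range(times)), 1e-6)
  res <- .cpp_integrate(spec, as.numeric(state), as.numeric(times),
                        settings$rel_tol, abs_tol, ms, 1000000L)
  res$states
}

#' Pre-equilibrate a network to its resting state
#'
#' Integrates the unstimulated system until the relative derivative
#' criterion `max |dX/dt| / (|X| + 1) < criterion` is met, in chunks of one
#' tenth of the horizon.
#'
#' @param net A validated `mp_network` (ligand inputs at baseline, no
#'   stimulation events).
#' @param settings [solver_settings()].
#' @param criterion Relative-derivative tolerance per hour (default `1e-6`).
#' @param horizon Maximum integration time in hours (default 500).
#' @param state Optional starting state (default: the network's initial
#'   amounts).
#' @return Named numeric resting state, with attribute `"t_equilibrated"`.
#' @export
equilibrate <- function(net, settings = solver_settings(),
                        criterion = 1e-6, horizon = 500, state = NULL) {
  issues <- validate_network(net)
  if (length(issues))
    stop("invalid network:\n  ", paste(issues, collapse = "\n  "))
  spec <- flatten_network(net)
  abs_tol <- resolve_abs_tol(settings, net)
  ids <- species_ids(net)
  state <- if (is.null(state)) initial_state(net) else as.numeric(state[ids])
  chunk <- horizon / 10
  t <- 0
  repeat {
    d <- .cpp_rhs(spec, as.numeric(state))
    relrate <- abs(d) / (abs(state) + 1)
    if (max(relrate) < criterion) {
      state <- stats::setNames(pmax(as.numeric(state), 0), ids)
      attr(state, "t_equilibrated") <- t
      return(state)
    }
    if (t >= horizon) {
      worst <- ids[which.max(relrate)]
      stop("equilibration did not converge within ", horizon,
           " h; worst offender: '", worst, "' (|dX/dt|/(|X|+1) = ",
           signif(max(relrate), 3), ")")
    }
    tr <- integrate_segment(spec, state, c(t, t + chunk), settings, abs_tol)
    state <- stats::setNames(tr[nrow(tr), ], ids)
    t <- t + chunk
  }
}

# Resolve one dose event to a copy-number jump.
event_copies <- function(net, ev) {
  if (ev$units == "copies") return(ev$dose)
  mw <- net$annotations$molecular_weights[[ev$species]]
  if (is.null(mw))
    stop("no molecular weight annotated for dosed species '", ev$species, "'")
  vol <- net$annotations$medium_volume_ml
  if (is.null(vol)) vol <- 1e-6
  ngml <- switch(ev$units, `ng/mL` = ev$dose, `pg/mL` = ev$dose / 1000,
                 stop("unknown dose units '", ev$units, "'"))
  dose_to_copies(ngml, mw, vol)
}

#' Simulate a stimulation protocol
#'
#' The network is pre-equilibrated (unless `state` is given), oxygen is
#' applied, and the system is integrated with a restart at every event time.
#' Simultaneous events are applied in a stable order: doses, then oxygen,
#' then interventions. Dosed species jump by the dose amount; all other
#' trajectories are continuous across events.
#'
#' @param net A validated `mp_network`.
#' @param protocol A [stimulation_protocol()].
#' @param settings [solver_settings()].
#' @param time_grid Output times in hours; defaults to steps of 0.25 h over
#'   the protocol duration. Event times are merged in.
#' @param state Optional pre-equilibrated starting state.
#' @return An object of class `mp_sim` with fields `time` (hours),
#'   `states` (time-by-species matrix, copies), `production`
#'   (time-by-species matrix of secretion-tagged synthesis fluxes,
#'   copies/hour), `baseline` (the t = 0 state) and `protocol`.
#' @export
simulate_protocol <- function(net, protocol, settings = solver_settings(),
                              time_grid = NULL, state = NULL) {
  stopifnot(inherits(protocol, "mp_protocol"))
  net0 <- net
  # oxygen and onset-0 interventions act from t = 0
  net <- apply_oxygen(net, protocol$oxygen_percent)
  iv <- protocol$interventions
  iv0 <- Filter(function(x) x$onset <= 0, iv)
  ivl <- Filter(function(x) x$onset > 0, iv)
  if (length(iv0)) net <- apply_interventions(net, iv0)

  if (is.null(state)) {
    # resting state of the untouched network: the untreated t=0 baseline
    state <- equilibrate(net0, settings)
  }
  ids <- species_ids(net)
  state <- state[ids]

  duration <- protocol$duration
  if (is.null(time_grid))
    time_grid <- seq(0, duration, by = min(0.25, duration / 20))
  ev_times <- c(if (nrow(protocol$events)) protocol$events$time,
                vapply(ivl, `[[`, 0, "onset"))
  time_grid <- sort(unique(c(time_grid, ev_times, 0, duration)))
  if (any(time_grid < 0) || any(ev_times > duration))
    stop("protocol events must lie within [0, duration]")

  abs_tol <- resolve_abs_tol(settings, net)
  boundaries <- sort(unique(c(0, ev_times, duration)))
  traj <- matrix(NA_real_, length(time_grid), length(ids),
                 dimnames = list(NULL, ids))
  prod_rates <- matrix(NA_real_, length(time_grid), length(ids),
                       dimnames = list(NULL, ids))
  sec_map <- secretion_flux_map(net)

  cur <- as.numeric(state)
  for (b in seq_len(length(boundaries) - 1)) {
    t0 <- boundaries[b]; t1 <- boundaries[b + 1]
    # apply events scheduled at t0 (doses first, then interventions)
    evs <- protocol$events[protocol$events$time == t0, , drop = FALSE]
    if (nrow(evs)) {
      for (k in seq_len(nrow(evs))) {
        ev <- evs[k, ]
        if (!ev$species %in% ids)
          stop("dosed species '", ev$species, "' not in network")
        cur[match(ev$species, ids)] <- cur[match(ev$species, ids)] +
          event_copies(net, ev) * protocol$dose_scale
      }
    }
    on <- Filter(function(x) x$onset == t0, ivl)
    if (length(on)) net <- apply_interventions(net, on)
    spec <- flatten_network(net)

    seg_times <- time_grid[time_grid >= t0 & time_grid <= t1]
    if (!t0 %in% seg_times) seg_times <- c(t0, seg_times)
    tr <- integrate_segment(spec, cur, seg_times, settings, abs_tol)
    keep <- seg_times %in% time_grid
    rows <- match(seg_times[keep], time_grid)
    traj[rows, ] <- tr[keep, , drop = FALSE]
    for (r in rows)
      prod_rates[r, ] <- production_at(spec, traj[r, ], sec_map, length(ids))
    cur <- tr[nrow(tr), ]
  }

  structure(list(time = time_grid,
                 states = traj,
                 production = prod_rates,
                 baseline = stats::setNames(as.numeric(state), ids),
                 protocol = protocol,
                 network_name = net$name,
                 panel = net$annotations$marker_panel,
                 abs_tol = abs_tol),
            class = "mp_sim")
}

# reaction index -> product species index map for secretion-tagged reactions
secretion_flux_map <- function(net) {
  out <- list()
  ids <- species_ids(net)
  for (i in seq_along(net$reactions)) {
    rx <- net$reactions[[i]]
    if ("secretion" %in% rx$tags)
      for (p in names(rx$products))
        out[[length(out) + 1]] <- c(i, match(p, ids), rx$products[[p]])
  }
  out
}

production_at <- function(spec, state, sec_map, n_sp) {
  pr <- numeric(n_sp)
  if (!length(sec_map)) return(pr)
  rates <- .cpp_reaction_rates(spec, as.numeric(state))
  for (e in sec_map) pr[e[2]] <- pr[e[2]] + e[3] * rates[e[1]]
  pr
}

#' @export
print.mp_sim <- function(x, ...) {
  cat("<mp_sim> ", length(x$time), " time points (0-",
      max(x$time), " h), ", ncol(x$states), " species\n", sep = "")
  invisible(x)
}

#' Extract a readout trajectory from a simulation
#'
#' @param result An `mp_sim`.
#' @param id Species id.
#' @param mode `"level"` or `"mRNA"` (species amount; for `"mRNA"` the id is
#'   expected to name the transcript species) or `"production_rate"`
#'   (secretion-tagged synthesis flux, copies/hour).
#' @return Numeric vector along `result$time`, clipped at zero.
#' @export
get_readout <- function(result, id,
                        mode = c("level", "mRNA", "production_rate")) {
  mode <- match.arg(mode)
  m <- if (mode == "production_rate") result$production else result$states
  if (!id %in% colnames(m)) stop("unknown readout species '", id, "'")
  pmax(m[, id], 0)
}

#' Tidy data frame of a simulation result
#'
#' @param x An `mp_sim`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return Long data frame with columns time, species, amount,
#'   production_rate (amounts clipped at zero).
#' @export
as.data.frame.mp_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  ids <- colnames(x$states)
  data.frame(time = rep(x$time, times = length(ids)),
             species = rep(ids, each = length(x$time)),
             amount = pmax(as.vector(x$states), 0),
             production_rate = as.vector(x$production))
}
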