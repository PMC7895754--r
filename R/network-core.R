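#' @useDynLib macpol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SPECIES_ROLES <- c("ligand", "receptor", "complex", "protein",
                   "phospho-protein", "mRNA", "miRNA", "compound")
COMPARTMENTS <- c("extracellular", "cytoplasm", "nucleus")
LAW_KINDS <- c("mass_action", "hill_activation", "hill_inhibition",
               "synthesis", "first_order_decay", "michaelis_menten")

#' Define a biochemical species
#'
#' Amounts are absolute copy numbers per cell (dimensionless counts);
#' extracellular ligands use the same convention via the medium-volume
#' conversion in [dose_to_copies()].
#'
#' @param id Short unique identifier.
#' @param name Free-text name; defaults to `id`.
#' @param role One of ligand, receptor, complex, protein, phospho-protein,
#'   mRNA, miRNA, compound.
#' @param compartment One of extracellular, cytoplasm, nucleus.
#' @param initial_amount Copies per cell, `>= 0`.
#' @param is_constant Clamped input (e.g. an experimentally fixed pool);
#'   derivative forced to zero.
#' @param secreted Logical; marks species whose synthesis flux is reported
#'   as a production rate by [simulate_protocol()].
#' @return An object of class `mp_species`.
#' @export
species <- function(id, name = id, role = "protein",
                    compartment = "cytoplasm", initial_amount = 0,
                    is_constant = FALSE, secreted = FALSE) {
  stopifnot(is.character(id), nchar(id) > 0)
  role <- match.arg(role, SPECIES_ROLES)
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (!is.numeric(initial_amount) || length(initial_amount) != 1 ||
      is.na(initial_amount) || initial_amount < 0)
    stop("species '", id, "': initial_amount must be a single number >= 0")
  structure(list(id = id, name = name, role = role,
                 compartment = compartment,
                 initial_amount = as.numeric(initial_amount),
                 is_constant = isTRUE(is_constant),
                 secreted = isTRUE(secreted)),
            class = "mp_species")
}

#' Define a kinetic parameter
#'
#' @param id Short identifier (the `kf*`/`kr*`/`k*` convention is used by the
#'   shipped reference network).
#' @param value Positive real; units implied by the arity of the rate law
#'   that uses it.
#' @param description Free text.
#' @return An object of class `mp_parameter`.
#' @export
parameter <- function(id, value, description = "") {
  stopifnot(is.character(id), nchar(id) > 0)
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value <= 0)
    stop("parameter '", id, "': value must be a single positive number")
  structure(list(id = id, value = as.numeric(value),
                 description = description),
            class = "mp_parameter")
}

#' Define a rate law
#'
#' Supported kinds: `mass_action` (k times the product of reactant amounts
#' raised to their stoichiometries), `hill_activation`
#' (k A^n / (K^n + A^n) in the regulator A), `hill_inhibition`
#' (k K^n / (K^n + A^n)), `synthesis` (constant k), `first_order_decay`
#' (k times the single substrate), and `michaelis_menten`
#' (k A / (K + A) in the regulator).
#'
#' @param kind Law kind, see above.
#' @param rate_param Parameter id providing the rate constant.
#' @param K Half-saturation constant in copies (Hill/MM kinds only), `> 0`.
#' @param n Hill coefficient, real-valued `>= 1` (Hill kinds only).
#' @param regulator Species id read by Hill/MM kinds.
#' @return An object of class `mp_rate_law`.
#' @export
rate_law <- function(kind, rate_param, K = NULL, n = 1, regulator = NULL) {
  kind <- match.arg(kind, LAW_KINDS)
  stopifnot(is.character(rate_param), length(rate_param) == 1)
  needs_reg <- kind %in% c("hill_activation", "hill_inhibition",
                           "michaelis_menten")
  if (needs_reg) {
    if (is.null(regulator))
      stop("rate law '", kind, "' requires a regulator species")
    if (is.null(K) || !is.numeric(K) || K <= 0)
      stop("rate law '", kind, "' requires K > 0")
  }
  if (kind %in% c("hill_activation", "hill_inhibition")) {
    if (!is.numeric(n) || length(n) != 1 || n < 1)
      stop("Hill coefficient n must be >= 1")
  }
  structure(list(kind = kind, rate_param = rate_param,
                 K = if (needs_reg) as.numeric(K) else NA_real_,
                 n = if (needs_reg) as.numeric(n) else NA_real_,
                 regulator = if (needs_reg) regulator else NA_character_),
            class = "mp_rate_law")
}

#' Define a reaction
#'
#' @param id Reaction identifier.
#' @param reactants Named numeric vector: species id -> stoichiometry (>= 1).
#'   `NULL` for pure synthesis.
#' @param products Named numeric vector, as `reactants`.
#' @param law An [rate_law()] object.
#' @param modifiers Character vector of species ids that influence the rate
#'   (via the law's regulator slot) without being consumed.
#' @param tags Character vector of free-form labels. The engine understands
#'   `"secretion"` (flux counted as the product species' production rate),
#'   `"transcription"` and `"translation"` (scaled by [hss_variant()]).
#' @return An object of class `mp_reaction`.
#' @export
reaction <- function(id, reactants = NULL, products = NULL, law,
                     modifiers = character(), tags = character()) {
  stopifnot(is.character(id), inherits(law, "mp_rate_law"))
  norm <- function(x, what) {
    if (is.null(x) || length(x) == 0) return(stats::setNames(numeric(0), character(0)))
    if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
    if (is.null(names(x)) || any(names(x) == ""))
      stop("reaction '", id, "': ", what, " must be named by species id")
    if (any(x < 1)) stop("reaction '", id, "': stoichiometries must be >= 1")
    x
  }
  reactants <- norm(reactants, "reactants")
  products <- norm(products, "products")
  if (length(reactants) == 0 && length(products) == 0)
    stop("reaction '", id, "' has neither reactants nor products")
  if (law$kind == "first_order_decay" && length(reactants) == 0)
    stop("reaction '", id, "': first_order_decay needs a substrate")
  if (!is.na(law$regulator) && !(law$regulator %in% c(names(reactants), modifiers)))
    modifiers <- c(modifiers, law$regulator)
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = modifiers, law = law, tags = tags),
            class = "mp_reaction")
}

#' Declare a conserved moiety
#'
#' @param name Moiety name (e.g. `"IFNGR_total"`).
#' @param members Named numeric vector: species id -> stoichiometric weight.
#' @param total Declared total (checked against initial amounts by
#'   [validate_network()] only when supplied).
#' @return An object of class `mp_moiety`.
#' @export
moiety <- function(name, members, total = NULL) {
  if (is.character(members)) members <- stats::setNames(rep(1, length(members)), members)
  stopifnot(is.numeric(members), !is.null(names(members)))
  structure(list(name = name, members = members,
                 total = if (is.null(total)) NA_real_ else as.numeric(total)),
            class = "mp_moiety")
}

#' Assemble a network
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param parameters List of [parameter()] objects.
#' @param moieties List of [moiety()] declarations.
#' @param name Network name.
#' @param annotations Free-form list. The engine and scoring layers read
#'   `oxygen_parameters` (parameter ids scaled by O2 level),
#'   `molecular_weights` (Da, named by ligand species id),
#'   `medium_volume_ml` (medium volume per cell for dose conversion) and
#'   `marker_panel` (see [marker_panel()]).
#' @return An object of class `mp_network`.
#' @export
network <- function(species = list(), reactions = list(),
                    parameters = list(), moieties = list(),
                    name = "network", annotations = list()) {
  sp_ids <- vapply(species, `[[`, "", "id")
  rx_ids <- vapply(reactions, `[[`, "", "id")
  pm_ids <- vapply(parameters, `[[`, "", "id")
  structure(list(name = name,
                 species = stats::setNames(species, sp_ids),
                 reactions = stats::setNames(reactions, rx_ids),
                 parameters = stats::setNames(parameters, pm_ids),
                 moieties = moieties,
                 annotations = annotations),
            class = "mp_network")
}

#' @export
print.mp_network <- function(x, ...) {
  cat("<mp_network> ", x$name, ": ", length(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$parameters),
      " parameters, ", length(x$moieties), " conserved moieties\n", sep = "")
  invisible(x)
}

#' Species ids of a network
#' @param net An `mp_network`.
#' @return Character vector of species ids in declaration order.
#' @export
species_ids <- function(net) names(net$species)

#' Parameter values of a network
#' @param net An `mp_network`.
#' @return Named numeric vector of parameter values.
#' @export
parameter_values <- function(net)
  vapply(net$parameters, `[[`, 0, "value")

#' Initial state of a network
#' @param net An `mp_network`.
#' @return Named numeric vector of initial copy numbers.
#' @export
initial_state <- function(net)
  vapply(net$species, `[[`, 0, "initial_amount")

#' Replace parameter values
#' @param net An `mp_network`.
#' @param values Named numeric vector of new values (subset of parameters).
#' @return The modified network (pure; input untouched).
#' @export
set_parameters <- function(net, values) {
  unknown <- setdiff(names(values), names(net$parameters))
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "))
  for (id in names(values)) {
    if (values[[id]] <= 0)
      stop("parameter '", id, "' must stay positive")
    net$parameters[[id]]$value <- as.numeric(values[[id]])
  }
  net
}

#' Evaluate a single rate law
#'
#' @param law An [rate_law()] object.
#' @param amounts Named numeric vector of species amounts (copies).
#' @param reaction The [reaction()] the law belongs to (supplies reactant
#'   stoichiometries for mass action / decay).
#' @param parameters Named numeric vector of parameter values, or a list of
#'   [parameter()] objects.
#' @return Reaction rate in copies per hour (always `>= 0` for non-negative
#'   amounts).
#' @export
evaluate_rate <- function(law, amounts, reaction, parameters) {
  if (is.list(parameters) && !is.numeric(parameters))
    parameters <- vapply(parameters, `[[`, 0, "value")
  k <- parameters[[law$rate_param]]
  if (is.null(k) || is.na(k))
    stop("rate parameter '", law$rate_param, "' not found (reaction '",
         reaction$id, "')")
  need <- unique(c(names(reaction$reactants),
                   if (!is.na(law$regulator)) law$regulator))
  missing <- setdiff(need, names(amounts))
  if (length(missing))
    stop("reaction '", reaction$id, "': amount(s) missing for ",
         paste(missing, collapse = ", "))
  if (any(amounts[need] < 0))
    stop("reaction '", reaction$id, "': negative amount supplied")
  switch(law$kind,
    mass_action = k * prod(amounts[names(reaction$reactants)] ^
                             reaction$reactants),
    hill_activation = {
      a <- amounts[[law$regulator]]
      k * a ^ law$n / (law$K ^ law$n + a ^ law$n)
    },
    hill_inhibition = {
      a <- amounts[[law$regulator]]
      k * law$K ^ law$n / (law$K ^ law$n + a ^ law$n)
    },
    synthesis = k,
    first_order_decay = k * amounts[[names(reaction$reactants)[1]]],
    michaelis_menten = {
      a <- amounts[[law$regulator]]
      k * a / (law$K + a)
    })
}

#' Stoichiometry matrix
#'
#' @param net An `mp_network`.
#' @return Species-by-reaction matrix of net stoichiometric coefficients.
#' @export
stoichiometry_matrix <- function(net) {
  sp <- species_ids(net)
  S <- matrix(0, length(sp), length(net$reactions),
              dimnames = list(sp, names(net$reactions)))
  for (rx in net$reactions) {
    for (id in names(rx$reactants)) S[id, rx$id] <- S[id, rx$id] - rx$reactants[[id]]
    for (id in names(rx$products)) S[id, rx$id] <- S[id, rx$id] + rx$products[[id]]
  }
  S
}

#' Validate a network
#'
#' Checks referential integrity, type invariants, symbolic invariance of the
#' declared conserved moieties under every reaction, and that constant
#' species are never net-consumed.
#'
#' @param net An `mp_network`.
#' @return Character vector of violations (empty iff the network is valid),
#'   each naming the offending reaction/species/parameter id.
#' @export
validate_network <- function(net) {
  out <- character()
  sp <- names(net$species)
  pm <- names(net$parameters)
  if (anyDuplicated(sp))
    out <- c(out, paste0("duplicate species id: ",
                         paste(sp[duplicated(sp)], collapse = ", ")))
  if (anyDuplicated(pm))
    out <- c(out, paste0("duplicate parameter id: ",
                         paste(pm[duplicated(pm)], collapse = ", ")))
  for (s in net$species)
    if (s$initial_amount < 0)
      out <- c(out, paste0("species '", s$id, "': negative initial amount"))
  for (p in net$parameters)
    if (p$value <= 0)
      out <- c(out, paste0("parameter '", p$id, "': non-positive value"))
  for (rx in net$reactions) {
    refs <- c(names(rx$reactants), names(rx$products), rx$modifiers)
    bad <- setdiff(refs[!is.na(refs)], sp)
    if (length(bad))
      out <- c(out, paste0("reaction '", rx$id, "': unknown species ",
                           paste(unique(bad), collapse = ", ")))
    if (!rx$law$rate_param %in% pm)
      out <- c(out, paste0("reaction '", rx$id, "': unknown parameter '",
                           rx$law$rate_param, "'"))
    if (rx$law$kind %in% c("hill_activation", "hill_inhibition",
                           "michaelis_menten") && is.na(rx$law$regulator))
      out <- c(out, paste0("reaction '", rx$id, "': missing regulator"))
  }
  ok_refs <- !length(out)
  if (ok_refs && length(net$reactions)) {
    S <- stoichiometry_matrix(net)
    # constant species must not be net-consumed (or produced) by any reaction
    for (s in net$species) {
      if (s$is_constant && any(S[s$id, ] != 0))
        out <- c(out, paste0("constant species '", s$id,
                             "' has non-zero net stoichiometry in: ",
                             paste(colnames(S)[S[s$id, ] != 0], collapse = ", ")))
    }
    for (m in net$moieties) {
      bad <- setdiff(names(m$members), sp)
      if (length(bad)) {
        out <- c(out, paste0("moiety '", m$name, "': unknown species ",
                             paste(bad, collapse = ", ")))
        next
      }
      w <- stats::setNames(numeric(nrow(S)), rownames(S))
      w[names(m$members)] <- m$members
      net_change <- drop(w %*% S)
      viol <- colnames(S)[abs(net_change) > 1e-12]
      if (length(viol))
        out <- c(out, paste0("moiety '", m$name,
                             "' not invariant under reaction(s): ",
                             paste(viol, collapse = ", ")))
      if (!is.na(m$total)) {
        tot0 <- sum(m$members * initial_state(net)[names(m$members)])
        if (abs(tot0 - m$total) > 1e-8 * max(1, abs(m$total)))
          out <- c(out, paste0("moiety '", m$name, "': declared total ",
                               m$total, " != initial total ", tot0))
      }
    }
  }
  out
}

#' Conserved-moiety totals for a state
#'
#' @param net An `mp_network` with declared moieties.
#' @param state Named numeric vector covering all moiety members.
#' @return Named numeric vector: moiety name -> weighted total.
#' @export
conserved_totals <- function(net, state) {
  vapply(net$moieties, function(m) {
    missing <- setdiff(names(m$members), names(state))
    if (length(missing))
      stop("state does not cover moiety member(s): ",
           paste(missing, collapse = ", "))
    sum(m$members * state[names(m$members)])
  }, 0, USE.NAMES = FALSE) -> tot
  stats::setNames(tot, vapply(net$moieties, `[[`, "", "name"))
}
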