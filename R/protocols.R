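#' Avogadro constant (1/mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Convert a cytokine dose to copies per cell
#'
#' `copies = dose[g/mL] / MW[g/mol] * N_A * volume[mL]`, i.e. the number of
#' ligand molecules in the medium volume attributed to one cell.
#'
#' @param dose_ng_ml Dose in ng/mL, `>= 0`.
#' @param molecular_weight Molar mass in Da, `> 0`.
#' @param medium_volume_ml Medium volume per cell in mL (default `1e-6`,
#'   i.e. ~1e6 cells/mL culture).
#' @return Copies per cell (dimensionless count).
#' @export
dose_to_copies <- function(dose_ng_ml, molecular_weight,
                           medium_volume_ml = 1e-6) {
  if (!is.numeric(dose_ng_ml) || any(dose_ng_ml < 0))
    stop("dose must be >= 0")
  if (!is.numeric(molecular_weight) || any(molecular_weight <= 0))
    stop("molecular weight must be > 0")
  if (!is.numeric(medium_volume_ml) || any(medium_volume_ml <= 0))
    stop("medium volume must be > 0")
  dose_ng_ml * 1e-9 / molecular_weight * AVOGADRO * medium_volume_ml
}

#' Define a timed dose event
#'
#' @param time Hours after protocol start, `>= 0`.
#' @param species Dosed (extracellular) species id.
#' @param dose Dose value, `>= 0`.
#' @param units One of `"ng/mL"`, `"pg/mL"`, `"copies"`.
#' @return One-row data frame used by [stimulation_protocol()].
#' @export
dose_event <- function(time, species, dose, units = "ng/mL") {
  units <- match.arg(units, c("ng/mL", "pg/mL", "copies"))
  stopifnot(time >= 0, dose >= 0)
  data.frame(time = time, species = species, dose = dose, units = units,
             stringsAsFactors = FALSE)
}

#' Define a parameter-multiplier intervention
#'
#' @param parameter Target parameter id.
#' @param multiplier Positive multiplier applied to the nominal value.
#' @param onset Hours after protocol start (default 0).
#' @return An object of class `mp_intervention`.
#' @export
intervention <- function(parameter, multiplier, onset = 0) {
  stopifnot(is.character(parameter), multiplier > 0, onset >= 0)
  structure(list(parameter = parameter, multiplier = multiplier,
                 onset = onset),
            class = "mp_intervention")
}

#' Define a stimulation protocol
#'
#' One in-silico experiment: timed cytokine doses, an oxygen level, optional
#' parameter interventions, a duration, and a global dose-scale multiplier
#' (used by [in_vivo_scaling()]).
#'
#' @param events A data frame of [dose_event()] rows (rbind-ed), or `NULL`.
#' @param oxygen_percent O2 percentage in `(0, 21]` (default 21 = normoxia).
#' @param duration Simulated duration in hours.
#' @param dose_scale Multiplier applied to every dose (default 1).
#' @param interventions List of [intervention()] objects.
#' @param name Protocol label.
#' @return An object of class `mp_protocol`.
#' @export
stimulation_protocol <- function(events = NULL, oxygen_percent = 21,
                                 duration = 48, dose_scale = 1,
                                 interventions = list(), name = "protocol") {
  if (is.null(events))
    events <- data.frame(time = numeric(), species = character(),
                         dose = numeric(), units = character(),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(events))
  if (nrow(events) && (any(events$time < 0) || any(events$time > duration)))
    stop("event times must lie in [0, duration]")
  if (nrow(events) && any(events$dose < 0)) stop("doses must be >= 0")
  if (oxygen_percent <= 0 || oxygen_percent > 21)
    stop("oxygen_percent must lie in (0, 21]")
  stopifnot(dose_scale > 0, duration > 0)
  structure(list(events = events, oxygen_percent = oxygen_percent,
                 duration = duration, dose_scale = dose_scale,
                 interventions = interventions, name = name),
            class = "mp_protocol")
}

#' @export
print.mp_protocol <- function(x, ...) {
  cat("<mp_protocol> ", x$name, ": ", nrow(x$events), " dose event(s), O2 ",
      x$oxygen_percent, "%, ", x$duration, " h, dose scale ", x$dose_scale,
      ", ", length(x$interventions), " intervention(s)\n", sep = "")
  invisible(x)
}

#' Apply an oxygen level to a network
#'
#' Oxygen enters the model exclusively through prolyl-hydroxylase (PHD)
#' activity: the parameters listed in the network annotation
#' `oxygen_parameters` are scaled linearly by `percent / 21`, so 21%
#' (normoxia) leaves the network unchanged and 2% scales PHD-mediated HIF
#' hydroxylation to 2/21 of nominal.
#'
#' @param net An `mp_network` annotated with `oxygen_parameters`.
#' @param oxygen_percent O2 percentage in `(0, 21]`.
#' @return The scaled network (pure; input untouched).
#' @export
apply_oxygen <- function(net, oxygen_percent) {
  if (oxygen_percent <= 0 || oxygen_percent > 21)
    stop("oxygen_percent must lie in (0, 21]")
  if (oxygen_percent == 21) return(net)
  pars <- net$annotations$oxygen_parameters
  if (is.null(pars) || !length(pars))
    stop("network '", net$name, "' has no oxygen_parameters annotation")
  f <- oxygen_percent / 21
  set_parameters(net, stats::setNames(parameter_values(net)[pars] * f, pars))
}

#' Apply parameter interventions to a network
#'
#' @param net An `mp_network`.
#' @param interventions List of [intervention()] objects (onsets ignored
#'   here; timing is handled by [simulate_protocol()]).
#' @return The modified network (pure transformation).
#' @export
apply_interventions <- function(net, interventions) {
  if (inherits(interventions, "mp_intervention"))
    interventions <- list(interventions)
  pv <- parameter_values(net)
  for (iv in interventions) {
    if (!iv$parameter %in% names(pv))
      stop("intervention targets unknown parameter '", iv$parameter, "'")
    pv[[iv$parameter]] <- pv[[iv$parameter]] * iv$multiplier
  }
  set_parameters(net, pv[vapply(interventions, `[[`, "", "parameter")])
}

#' Scale a protocol to in-vivo cytokine levels
#'
#' Multiplies the protocol's dose scale by 0.01, turning ng/mL-range in-vitro
#' stimuli into the 100-fold lower (high pg/mL) concentrations used to mimic
#' in-vivo cytokine upregulation. Applying it twice compounds to 1e-4 (the
#' operation is multiplicative, not idempotent).
#'
#' @param protocol An `mp_protocol`.
#' @return The scaled protocol.
#' @export
in_vivo_scaling <- function(protocol) {
  protocol$dose_scale <- protocol$dose_scale * 0.01
  protocol$name <- paste0(protocol$name, " (in vivo)")
  protocol
}

#' Globally reduced-synthesis (HSS) network variant
#'
#' Scales the rate parameters of every transcription- and translation-tagged
#' reaction by `synthesis_scale`. Combined with 2% O2 this is the alternative
#' representation of hypoxia serum starvation in which starvation suppresses
#' protein and RNA synthesis.
#'
#' @param net An `mp_network` with tagged synthesis reactions.
#' @param synthesis_scale Factor in `(0, 1]`.
#' @return The scaled network.
#' @export
hss_variant <- function(net, synthesis_scale) {
  if (synthesis_scale <= 0 || synthesis_scale > 1)
    stop("synthesis_scale must lie in (0, 1]")
  if (synthesis_scale == 1) return(net)
  tagged <- unique(unlist(lapply(net$reactions, function(rx)
    if (any(c("transcription", "translation") %in% rx$tags))
      rx$law$rate_param)))
  if (!length(tagged))
    stop("network '", net$name,
         "' has no transcription/translation-tagged reactions")
  pv <- parameter_values(net)[tagged]
  set_parameters(net, pv * synthesis_scale)
}

#' Serialize / deserialize protocols
#'
#' Protocols round-trip through plain lists suitable for YAML or JSON.
#'
#' @param protocol An `mp_protocol`.
#' @param path File path; extension `.yaml`/`.yml` or `.json`.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns an `mp_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(name = protocol$name,
              oxygen_percent = protocol$oxygen_percent,
              duration = protocol$duration,
              dose_scale = protocol$dose_scale,
              events = if (nrow(protocol$events))
                lapply(seq_len(nrow(protocol$events)), function(i)
                  as.list(protocol$events[i, ])) else list(),
              interventions = lapply(protocol$interventions, unclass))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  ev <- if (length(obj$events))
    do.call(rbind, lapply(obj$events, function(e)
      dose_event(e$time, e$species, e$dose, e$units))) else NULL
  iv <- lapply(obj$interventions, function(i)
    intervention(i$parameter, i$multiplier, i$onset))
  stimulation_protocol(events = ev, oxygen_percent = obj$oxygen_percent,
                       duration = obj$duration, dose_scale = obj$dose_scale,
                       interventions = iv, name = obj$name)
}
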