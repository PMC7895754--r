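#' Write a network in the native JSON dialect
#'
#' The native format is a JSON document with top-level keys `name`,
#' `species`, `parameters`, `reactions`, `moieties`, `annotations`,
#' mirroring the in-memory types one-to-one; it is lossless and, with
#' canonical key ordering, byte-stable under round trips.
#'
#' @param net An `mp_network`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_native <- function(net, path) {
  doc <- list(
    format = "macpol-network",
    version = 1L,
    name = net$name,
    species = lapply(unname(net$species), function(s)
      list(id = s$id, name = s$name, role = s$role,
           compartment = s$compartment,
           initial_amount = s$initial_amount,
           is_constant = s$is_constant, secreted = s$secreted)),
    parameters = lapply(unname(net$parameters), function(p)
      list(id = p$id, value = p$value, description = p$description)),
    reactions = lapply(unname(net$reactions), function(rx)
      list(id = rx$id,
           reactants = as.list(rx$reactants),
           products = as.list(rx$products),
           modifiers = as.list(rx$modifiers),
           tags = as.list(rx$tags),
           law = list(kind = rx$law$kind, rate_param = rx$law$rate_param,
                      K = rx$law$K, n = rx$law$n,
                      regulator = rx$law$regulator))),
    moieties = lapply(net$moieties, function(m)
      list(name = m$name, members = as.list(m$members), total = m$total)),
    annotations = serialize_annotations(net$annotations))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

serialize_annotations <- function(ann) {
  if (is.null(ann)) return(structure(list(), names = character()))
  out <- ann
  if (!is.null(out$marker_panel) && inherits(out$marker_panel, "mp_marker_panel"))
    out$marker_panel <- list(m1 = out$marker_panel$m1, m2 = out$marker_panel$m2)
  # named atomic vectors must become lists or toJSON drops the names
  if (!is.null(out$molecular_weights))
    out$molecular_weights <- as.list(out$molecular_weights)
  out
}

deserialize_annotations <- function(ann) {
  if (is.null(ann) || !length(ann)) return(list())
  rows_to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    data.frame(species = vapply(x, `[[`, "", "species"),
               readout = vapply(x, `[[`, "", "readout"),
               stringsAsFactors = FALSE)
  }
  if (!is.null(ann$marker_panel))
    ann$marker_panel <- marker_panel(m1 = rows_to_df(ann$marker_panel$m1),
                                     m2 = rows_to_df(ann$marker_panel$m2))
  for (k in c("molecular_weights")) {
    if (!is.null(ann[[k]])) ann[[k]] <- unlist(ann[[k]])
  }
  if (!is.null(ann$oxygen_parameters))
    ann$oxygen_parameters <- as.character(unlist(ann$oxygen_parameters))
  ann
}

#' Read a network from the native JSON dialect
#'
#' @param path Path to a native-format JSON file.
#' @return An `mp_network` with attribute `"provenance"`.
#' @export
read_native <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "macpol-network")
    stop("'", path, "' is not a native network document")
  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  sp <- lapply(doc$species, function(s)
    species(s$id, s$name, s$role, s$compartment, s$initial_amount,
            isTRUE(s$is_constant), isTRUE(s$secreted)))
  pm <- lapply(doc$parameters, function(p)
    parameter(p$id, p$value, p$description %||% ""))
  rx <- lapply(doc$reactions, function(r) {
    law <- rate_law(r$law$kind, r$law$rate_param,
                    K = if (is.null(r$law$K) || is.na(num(r$law$K))) NULL
                        else num(r$law$K),
                    n = if (is.null(r$law$n) || is.na(num(r$law$n))) 1
                        else num(r$law$n),
                    regulator = if (is.null(r$law$regulator) ||
                                    is.na(r$law$regulator)) NULL
                                else r$law$regulator)
    reaction(r$id,
             reactants = unlist_stoich(r$reactants),
             products = unlist_stoich(r$products),
             law = law,
             modifiers = as.character(unlist(r$modifiers)),
             tags = as.character(unlist(r$tags)))
  })
  mo <- lapply(doc$moieties, function(m)
    moiety(m$name, unlist_stoich(m$members),
           total = if (is.null(m$total) || is.na(num(m$total))) NULL
                   else num(m$total)))
  net <- network(sp, rx, pm, mo, name = doc$name %||% "network",
                 annotations = deserialize_annotations(doc$annotations))
  attr(net, "provenance") <- list(path = path, format = "native-json")
  net
}

unlist_stoich <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  stats::setNames(vapply(x, as.numeric, 0), names(x))
}
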