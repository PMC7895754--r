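SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version2/core"
SBML_L2_NS <- "http://www.sbml.org/sbml/level2/version4"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
MACPOL_NS <- "https://macpol.invalid/sbml-annotations"

#' Write a network as SBML
#'
#' Exports SBML Level 3 Version 2: compartments, species (copy-number
#' amounts, dimensionless substance units), global parameters, and
#' reactions whose kinetic laws are rendered as MathML. A package
#' annotation (custom namespace) carries the rate-law kind, Hill constants,
#' reaction tags, moiety declarations and marker-panel metadata so that
#' re-import is lossless; readers that ignore annotations still get a valid
#' SBML model with equivalent MathML kinetics.
#'
#' @param net An `mp_network`.
#' @param path Output path (`.xml`).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                            "xmlns:macpol" = MACPOL_NS,
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = sanitize_sbml_id(net$name),
                               name = net$name,
                               substanceUnits = "dimensionless",
                               timeUnits = "dimensionless",
                               extentUnits = "dimensionless")
  meta <- xml2::xml_add_child(model, "annotation")
  payload <- xml2::xml_add_child(meta, "macpol:metadata")
  xml2::xml_set_text(payload, as.character(jsonlite::toJSON(list(
    moieties = lapply(net$moieties, function(m)
      list(name = m$name, members = as.list(m$members), total = m$total)),
    annotations = serialize_annotations(net$annotations),
    species_extra = lapply(unname(net$species), function(s)
      list(id = s$id, role = s$role, secreted = s$secreted)),
    reaction_extra = lapply(unname(net$reactions), function(rx)
      list(id = rx$id, tags = as.list(rx$tags),
           law = list(kind = rx$law$kind, rate_param = rx$law$rate_param,
                      K = rx$law$K, n = rx$law$n,
                      regulator = rx$law$regulator)))),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")))

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in COMPARTMENTS)
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true",
                        size = "1", spatialDimensions = "3")
  spl <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in net$species)
    xml2::xml_add_child(spl, "species", id = s$id, name = s$name,
                        compartment = s$compartment,
                        initialAmount = format(s$initial_amount, digits = 17),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = if (s$is_constant) "true" else "false",
                        constant = if (s$is_constant) "true" else "false")
  pml <- xml2::xml_add_child(model, "listOfParameters")
  for (p in net$parameters)
    xml2::xml_add_child(pml, "parameter", id = p$id,
                        value = format(p$value, digits = 17),
                        constant = "true", name = p$description)
  rxl <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in net$reactions) {
    rn <- xml2::xml_add_child(rxl, "reaction", id = rx$id,
                              reversible = "false")
    add_refs <- function(tag, refs) {
      if (!length(refs)) return()
      lst <- xml2::xml_add_child(rn, tag)
      for (id in names(refs))
        xml2::xml_add_child(lst,
                            if (tag == "listOfReactants") "speciesReference"
                            else "speciesReference",
                            species = id,
                            stoichiometry = format(refs[[id]]),
                            constant = "true")
    }
    add_refs("listOfReactants", rx$reactants)
    add_refs("listOfProducts", rx$products)
    mods <- setdiff(rx$modifiers, c(names(rx$reactants), names(rx$products)))
    if (length(mods)) {
      lst <- xml2::xml_add_child(rn, "listOfModifiers")
      for (id in mods)
        xml2::xml_add_child(lst, "modifierSpeciesReference", species = id)
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    law_mathml(math, rx)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sanitize_sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

# append the MathML expression for a rate law under `math`
law_mathml <- function(math, rx) {
  law <- rx$law
  ci <- function(parent, id) {
    n <- xml2::xml_add_child(parent, "ci")
    xml2::xml_set_text(n, id)
    n
  }
  cn <- function(parent, v) {
    n <- xml2::xml_add_child(parent, "cn")
    xml2::xml_set_text(n, format(v, digits = 17))
    n
  }
  pow <- function(parent, base_fun, expo) {
    a <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(a, "power")
    base_fun(a)
    cn(a, expo)
    a
  }
  switch(law$kind,
    synthesis = ci(math, law$rate_param),
    mass_action = ,
    first_order_decay = {
      a <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(a, "times")
      ci(a, law$rate_param)
      reac <- if (law$kind == "first_order_decay")
        rx$reactants[1] else rx$reactants
      for (id in names(reac)) {
        if (reac[[id]] == 1) ci(a, id)
        else pow(a, function(p) ci(p, id), reac[[id]])
      }
    },
    hill_activation = {
      a <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(a, "divide")
      num <- xml2::xml_add_child(a, "apply")
      xml2::xml_add_child(num, "times")
      ci(num, law$rate_param)
      pow(num, function(p) ci(p, law$regulator), law$n)
      den <- xml2::xml_add_child(a, "apply")
      xml2::xml_add_child(den, "plus")
      pow(den, function(p) cn(p, law$K), law$n)
      pow(den, function(p) ci(p, law$regulator), law$n)
    },
    hill_inhibition = {
      a <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(a, "divide")
      num <- xml2::xml_add_child(a, "apply")
      xml2::xml_add_child(num, "times")
      ci(num, law$rate_param)
      pow(num, function(p) cn(p, law$K), law$n)
      den <- xml2::xml_add_child(a, "apply")
      xml2::xml_add_child(den, "plus")
      pow(den, function(p) cn(p, law$K), law$n)
      pow(den, function(p) ci(p, law$regulator), law$n)
    },
    michaelis_menten = {
      a <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(a, "divide")
      num <- xml2::xml_add_child(a, "apply")
      xml2::xml_add_child(num, "times")
      ci(num, law$rate_param)
      ci(num, law$regulator)
      den <- xml2::xml_add_child(a, "apply")
      xml2::xml_add_child(den, "plus")
      cn(den, law$K)
      ci(den, law$regulator)
    })
}

#' Read an SBML model
#'
#' Accepts SBML Level 2 Version 4 and Level 3 Version 2 (the subset without
#' events, rules, constraints, function definitions and initial
#' assignments). Kinetic laws are mapped to the native rate-law kinds: via
#' the package annotation when present, otherwise by structural recognition
#' of MathML products of identifiers (mass action / synthesis); anything
#' else raises an unsupported-feature error naming the reaction. Substance
#' amounts are taken as dimensionless copy numbers; species with
#' concentration-only initial values or unit mismatches are reported in the
#' `"import_report"` attribute (not fatal). Local (per-reaction) parameters
#' are hoisted to namespaced global parameters `reactionId.paramId`.
#'
#' @param path Path to an SBML `.xml` file.
#' @return An `mp_network` with attributes `"provenance"` and
#'   `"import_report"`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path,
                                           "': ", conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  root_ns <- xml2::xml_attr(doc, "xmlns")
  unsupported <- character()
  for (tag in c("listOfEvents", "listOfRules", "listOfConstraints",
                "listOfFunctionDefinitions", "listOfInitialAssignments")) {
    hits <- xml2::xml_find_all(doc, paste0(".//s:", tag, "/*"), ns)
    if (length(hits))
      unsupported <- c(unsupported,
                       paste0(tag, ": ", paste(unique(xml2::xml_name(hits)),
                                               collapse = ", ")))
  }
  if (length(unsupported))
    stop("unsupported SBML construct(s): ",
         paste(unsupported, collapse = "; "))

  report <- character()
  meta <- parse_macpol_metadata(doc, ns)

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp <- lapply(sp_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    amt <- xml2::xml_attr(n, "initialAmount")
    if (is.na(amt)) {
      conc <- xml2::xml_attr(n, "initialConcentration")
      if (!is.na(conc)) {
        amt <- conc
        report <<- c(report, paste0("species '", id,
          "': initialConcentration interpreted as copy number"))
      } else amt <- "0"
    }
    extra <- meta$species_extra[[id]]
    comp <- xml2::xml_attr(n, "compartment")
    if (!comp %in% COMPARTMENTS) {
      report <<- c(report, paste0("species '", id, "': compartment '", comp,
                                  "' mapped to cytoplasm"))
      comp <- "cytoplasm"
    }
    species(id,
            name = if (is.na(xml2::xml_attr(n, "name"))) id
                   else xml2::xml_attr(n, "name"),
            role = extra$role %||% "protein",
            compartment = comp,
            initial_amount = as.numeric(amt),
            is_constant = identical(xml2::xml_attr(n, "boundaryCondition"),
                                    "true") ||
                          identical(xml2::xml_attr(n, "constant"), "true"),
            secreted = isTRUE(extra$secreted))
  })
  sp_ids <- vapply(sp, `[[`, "", "id")

  pm_nodes <- xml2::xml_find_all(doc,
    ".//s:model/s:listOfParameters/s:parameter", ns)
  pm <- lapply(pm_nodes, function(n)
    parameter(xml2::xml_attr(n, "id"),
              as.numeric(xml2::xml_attr(n, "value")),
              description = xml2::xml_attr(n, "name") %|na|% ""))
  pm_ids <- vapply(pm, `[[`, "", "id")

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rx <- list()
  for (n in rx_nodes) {
    rid <- xml2::xml_attr(n, "id")
    refs <- function(tag) {
      rr <- xml2::xml_find_all(n, paste0("./s:", tag, "/s:speciesReference"),
                               ns)
      if (!length(rr)) return(NULL)
      st <- as.numeric(xml2::xml_attr(rr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(rr, "species"))
    }
    reactants <- refs("listOfReactants")
    products <- refs("listOfProducts")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(n, "./s:listOfModifiers/s:modifierSpeciesReference",
                         ns), "species")
    # hoist local parameters
    lp <- xml2::xml_find_all(n,
      "./s:kineticLaw/s:listOfLocalParameters/s:localParameter | ./s:kineticLaw/s:listOfParameters/s:parameter",
      ns)
    local_map <- character()
    for (l in lp) {
      lid <- xml2::xml_attr(l, "id")
      gid <- paste0(rid, ".", lid)
      pm[[length(pm) + 1]] <- parameter(gid,
        as.numeric(xml2::xml_attr(l, "value")))
      pm_ids <- c(pm_ids, gid)
      local_map[[lid]] <- gid
    }
    extra <- meta$reaction_extra[[rid]]
    law <- if (!is.null(extra)) {
      rate_param <- if (extra$law$rate_param %in% names(local_map))
        local_map[[extra$law$rate_param]] else extra$law$rate_param
      rate_law(extra$law$kind, rate_param,
               K = if (is.null(extra$law$K) || is.na(extra$law$K)) NULL
                   else extra$law$K,
               n = if (is.null(extra$law$n) || is.na(extra$law$n)) 1
                   else extra$law$n,
               regulator = if (is.null(extra$law$regulator) ||
                               is.na(extra$law$regulator)) NULL
                           else extra$law$regulator)
    } else {
      infer_law_from_mathml(n, ns, rid, reactants, pm_ids, sp_ids, local_map)
    }
    rx[[length(rx) + 1]] <- reaction(rid, reactants, products, law,
      modifiers = as.character(mods),
      tags = as.character(unlist(extra$tags)))
  }

  mo <- lapply(meta$moieties, function(m)
    moiety(m$name, unlist_stoich(m$members),
           total = if (is.null(m$total) || is.na(m$total)) NULL else m$total))
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  net <- network(sp, rx, pm, mo,
                 name = xml2::xml_attr(model_node, "name") %|na|%
                        xml2::xml_attr(model_node, "id") %|na|% "sbml_model",
                 annotations = deserialize_annotations(meta$annotations))
  attr(net, "provenance") <- list(path = path, format = "sbml",
                                  namespace = root_ns)
  attr(net, "import_report") <- report
  net
}

`%|na|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

parse_macpol_metadata <- function(doc, ns) {
  node <- xml2::xml_find_first(
    doc, ".//s:model/s:annotation/*[local-name() = 'metadata']", ns)
  if (inherits(node, "xml_missing")) return(list())
  out <- jsonlite::fromJSON(xml2::xml_text(node), simplifyVector = FALSE)
  names(out$species_extra) <- vapply(out$species_extra, `[[`, "", "id")
  names(out$reaction_extra) <- vapply(out$reaction_extra, `[[`, "", "id")
  out
}

# Structural recognition of simple MathML kinetics: a product of identifiers
# (one parameter, reactant species with optional integer powers) is mass
# action; a lone parameter identifier is constitutive synthesis.
infer_law_from_mathml <- function(rx_node, ns, rid, reactants, pm_ids,
                                  sp_ids, local_map) {
  math <- xml2::xml_find_first(rx_node, "./s:kineticLaw/*[local-name() = 'math']", ns)
  if (inherits(math, "xml_missing"))
    stop("reaction '", rid, "': no kinetic law")
  expr <- xml2::xml_find_first(math, "./*")
  factors <- tryCatch(flatten_times(expr), error = function(e) NULL)
  if (is.null(factors))
    stop("unsupported SBML construct(s): reaction '", rid,
         "' has a kinetic law that is neither a recognizable mass-action/",
         "synthesis product nor annotated with a rate-law kind")
  ids <- vapply(factors, `[[`, "", "id")
  ids <- vapply(ids, function(i)
    if (i %in% names(local_map)) local_map[[i]] else i, "")
  is_par <- ids %in% pm_ids
  if (sum(is_par) != 1)
    stop("unsupported SBML construct(s): reaction '", rid,
         "' kinetic law must reference exactly one rate parameter")
  sp_refs <- ids[!is_par]
  if (!all(sp_refs %in% sp_ids))
    stop("reaction '", rid, "': kinetic law references unknown id(s) ",
         paste(setdiff(sp_refs, sp_ids), collapse = ", "))
  if (!length(sp_refs))
    return(rate_law("synthesis", ids[is_par]))
  # must match the reactant multiset (catalysts included as reactants)
  rate_law("mass_action", ids[is_par])
}

# flatten <apply><times/>...</apply> into ci/power factors
flatten_times <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(list(list(id = trimws(xml2::xml_text(node)), pow = 1)))
  if (nm != "apply") stop("not a product")
  children <- xml2::xml_children(node)
  op <- xml2::xml_name(children[[1]])
  if (op == "power") {
    base <- children[[2]]; expo <- children[[3]]
    if (xml2::xml_name(base) != "ci" || xml2::xml_name(expo) != "cn")
      stop("unsupported power")
    return(list(list(id = trimws(xml2::xml_text(base)),
                     pow = as.numeric(xml2::xml_text(expo)))))
  }
  if (op != "times") stop("not a product")
  out <- list()
  for (ch in children[-1]) out <- c(out, flatten_times(ch))
  out
}

#' Structural SBML document check
#'
#' A lightweight offline validator: verifies well-formed XML, an SBML
#' Level 2/3 namespace, presence of a model element, id uniqueness,
#' resolvable species/parameter references in reactions, and absence of
#' constructs outside the supported subset.
#'
#' @param path Path to an SBML file.
#' @return Character vector of problems (empty iff the document passes).
#' @export
validate_sbml_document <- function(path) {
  out <- character()
  doc <- tryCatch(xml2::read_xml(path), error = function(e) NULL)
  if (is.null(doc)) return(paste("not well-formed XML:", path))
  root_ns <- xml2::xml_attr(doc, "xmlns")
  if (!root_ns %in% c(SBML_L3_NS, SBML_L2_NS,
                      "http://www.sbml.org/sbml/level3/version1/core"))
    out <- c(out, paste("unrecognized SBML namespace:", root_ns))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) return(c(out, "no <model> element"))
  ids <- xml2::xml_attr(xml2::xml_find_all(
    doc, ".//s:species | .//s:model/s:listOfParameters/s:parameter | .//s:reaction | .//s:compartment",
    ns), "id")
  if (anyDuplicated(ids))
    out <- c(out, paste("duplicate id(s):",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  sp_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:species", ns), "id")
  refs <- xml2::xml_attr(xml2::xml_find_all(
    doc, ".//s:speciesReference | .//s:modifierSpeciesReference", ns),
    "species")
  bad <- setdiff(refs, sp_ids)
  if (length(bad))
    out <- c(out, paste("unresolved species reference(s):",
                        paste(bad, collapse = ", ")))
  out
}
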