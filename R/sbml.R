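## Minimal SBML Level 3 export/import for interoperability with the COPASI
## ecosystem. Covers exactly the constructs this cascade model uses: one
## compartment, species with boundaryCondition flags, reactions with integer
## stoichiometry and local kinetic parameters, and the substrate-depletion
## stop event. Anything else on import is rejected explicitly.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"
.anno_ns <- "https://phbcascade.r-pkg/annotation"

#' Export a network (and optionally its kinetics) to SBML Level 3
#'
#' Species roles travel as the SBML `boundaryCondition` flag; element
#' compositions, rate-law bindings and the stop event threshold travel in a
#' package annotation namespace so that a round trip through
#' [import_sbml()] reconstructs the model exactly.
#'
#' @param network A `phb_network`.
#' @param path Output file path.
#' @param params Optional `kinetic_parameters` to embed as local kinetic-law
#'   parameters.
#' @param scenario Optional `phb_scenario`: initial concentrations and the
#'   stop event threshold are embedded.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path, params = NULL, scenario = NULL) {
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns,
                            "xmlns:phb" = .anno_ns,
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("phbcascade_", network$variant),
                               "phb:variant" = network$variant)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")

  init <- if (!is.null(scenario)) scenario$initial else c()
  losp <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$species))) {
    s <- network$species[i, ]
    conc <- if (s$id %in% names(init)) init[[s$id]] else 0
    xml2::xml_add_child(
      losp, "species", id = s$id, name = s$name, compartment = "cell",
      initialConcentration = format(conc, digits = 15),
      boundaryCondition = tolower(as.character(s$role == "boundary")),
      hasOnlySubstanceUnits = "false", constant = "false",
      "phb:composition" = paste(c("C", "H", "O", "P", "CoA", "NADP"),
                                s[c("C", "H", "O", "P", "CoA", "NADP")],
                                sep = "=", collapse = " ")
    )
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rx <- xml2::xml_add_child(
      lor, "reaction", id = make.names(r$id), name = r$name,
      reversible = tolower(as.character(r$reversible)),
      "phb:rid" = r$id, "phb:law" = r$law,
      "phb:substrates" = paste(r$substrates, collapse = " "),
      "phb:products" = paste(r$products, collapse = " ")
    )
    reac <- xml2::xml_add_child(rx, "listOfReactants")
    prod <- xml2::xml_add_child(rx, "listOfProducts")
    for (sp in names(r$stoich)) {
      coef <- r$stoich[[sp]]
      parent <- if (coef < 0) reac else prod
      xml2::xml_add_child(parent, "speciesReference", species = sp,
                          stoichiometry = format(abs(coef)),
                          constant = "true")
    }
    if (!is.null(params)) {
      pr <- params$reactions[[r$id]]
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
      add_par <- function(id, value) {
        xml2::xml_add_child(lp, "localParameter", id = id,
                            value = format(value, digits = 15))
      }
      add_par("vmax", pr$vmax)
      if (!is.null(pr$keq)) add_par("keq", pr$keq)
      for (sp in names(pr$km)) add_par(paste0("km_", sp), pr$km[[sp]])
      if (!is.null(pr$c_bind)) add_par("c_bind", pr$c_bind)
      if (!is.null(pr$n)) add_par("n_exp", pr$n)
    }
  }

  if (!is.null(scenario) && !is.na(scenario$stop_threshold)) {
    loe <- xml2::xml_add_child(model, "listOfEvents")
    ev <- xml2::xml_add_child(loe, "event", id = "substrate_stop",
                              useValuesFromTriggerTime = "true",
                              "phb:threshold" =
                                format(scenario$stop_threshold, digits = 15))
    tr <- xml2::xml_add_child(ev, "trigger", initialValue = "true",
                              persistent = "true")
    math <- xml2::xml_add_child(
      tr, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    apply_ <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(apply_, "leq")
    xml2::xml_add_child(apply_, "ci", "MD")
    xml2::xml_add_child(apply_, "cn",
                        format(scenario$stop_threshold *
                                 (if ("MD" %in% names(init)) init[["MD"]]
                                  else 0)))
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname export_sbml
#' @param strict On import, reject documents containing SBML constructs this
#'   reader does not implement (rules, function definitions, constraints,
#'   initial assignments); default `TRUE`.
#' @return `import_sbml`: list with `network` (a `phb_network`), `params`
#'   (`kinetic_parameters` or `NULL`), `initial` (named numeric) and
#'   `stop_threshold` (or `NA`).
#' @export
import_sbml <- function(path, strict = TRUE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")

  unsupported <- c("listOfRules", "listOfFunctionDefinitions",
                   "listOfConstraints", "listOfInitialAssignments")
  present <- unsupported[vapply(unsupported, function(tag) {
    !is.na(xml2::xml_find_first(model, paste0("./", tag)))
  }, logical(1))]
  if (strict && length(present)) {
    stop("unsupported SBML constructs: ", paste(present, collapse = ", "))
  }

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  parse_pairs <- function(txt) {
    kv <- strsplit(strsplit(txt, " ")[[1]], "=")
    stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  }
  species <- do.call(rbind, lapply(sp_nodes, function(n) {
    comp <- parse_pairs(xml2::xml_attr(n, "composition"))
    data.frame(id = xml2::xml_attr(n, "id"),
               name = xml2::xml_attr(n, "name"),
               role = if (xml2::xml_attr(n, "boundaryCondition") == "true")
                 "boundary" else "internal",
               C = comp[["C"]], H = comp[["H"]], O = comp[["O"]],
               P = comp[["P"]], CoA = comp[["CoA"]], NADP = comp[["NADP"]],
               initial_conc = 0, stringsAsFactors = FALSE)
  }))
  initial <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")),
    species$id)

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- list()
  params_list <- list()
  have_params <- TRUE
  for (n in rx_nodes) {
    raw <- xml2::xml_attrs(n)
    ## the annotation attribute carries the exact reaction label (the SBML
    ## core id must be an NCName, so e.g. "6PGDH" is mangled there)
    rid <- if ("rid" %in% names(raw)) raw[["rid"]] else raw[["id"]]
    subs <- strsplit(raw[["substrates"]], " ")[[1]]
    prods <- if (nzchar(raw[["products"]]))
      strsplit(raw[["products"]], " ")[[1]] else character()
    reacs <- xml2::xml_find_all(n, "./listOfReactants/speciesReference")
    pros <- xml2::xml_find_all(n, "./listOfProducts/speciesReference")
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reacs, "stoichiometry")),
                      xml2::xml_attr(reacs, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(pros, "stoichiometry")),
                      xml2::xml_attr(pros, "species"))
    )
    entry <- list(id = rid, name = xml2::xml_attr(n, "name"),
                  stoich = st,
                  reversible = xml2::xml_attr(n, "reversible") == "true",
                  law = raw[["law"]], substrates = subs, products = prods)
    reactions[[rid]] <- entry

    lp <- xml2::xml_find_all(n, ".//localParameter")
    if (length(lp) == 0) { have_params <- FALSE; next }
    vals <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                            xml2::xml_attr(lp, "id"))
    pr <- list(vmax = unname(vals[["vmax"]]))
    if ("keq" %in% names(vals)) pr$keq <- unname(vals[["keq"]])
    km <- vals[grepl("^km_", names(vals))]
    names(km) <- sub("^km_", "", names(km))
    pr$km <- km
    if ("c_bind" %in% names(vals)) pr$c_bind <- unname(vals[["c_bind"]])
    if ("n_exp" %in% names(vals)) pr$n <- unname(vals[["n_exp"]])
    params_list[[rid]] <- pr
  }

  variant <- {
    raw <- xml2::xml_attrs(model)
    if ("variant" %in% names(raw)) raw[["variant"]] else "full"
  }
  rownames(species) <- NULL
  net <- structure(list(species = species, reactions = reactions,
                        variant = variant), class = "phb_network")
  validate_network(net)

  ev <- xml2::xml_find_first(model, ".//listOfEvents/event")
  threshold <- NA_real_
  if (!is.na(ev)) {
    raw <- xml2::xml_attrs(ev)
    if ("threshold" %in% names(raw)) threshold <- as.numeric(raw[["threshold"]])
  }

  params <- if (have_params && length(params_list)) {
    kinetic_parameters(params_list)
  }
  list(network = net, params = params,
       initial = initial[initial > 0], stop_threshold = threshold)
}
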