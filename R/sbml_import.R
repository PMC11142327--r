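# SBML Level 3 import: the inverse of export on the emitted subset.
# Unsupported constructs (function definitions, units, event delays and
# priorities) are dropped with warning diagnostics; an unsupported package
# marked required aborts the import.

xp1 <- function(node, local) {
  xml2::xml_find_first(node, sprintf("./*[local-name() = '%s']", local))
}

xpall <- function(node, local) {
  xml2::xml_find_all(node, sprintf("./*[local-name() = '%s']", local))
}

missing_node <- function(x) inherits(x, "xml_missing")

attr_or <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

# prefixed attribute lookup; libxml2 reports attribute names without their
# namespace prefix, so fall back to the local part
pkg_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (!is.na(v)) return(v)
  v <- xml2::xml_attr(node, sub("^.*:", "", name))
  if (!is.na(v)) v else NA_character_
}

import_metadata <- function(model_el, model) {
  notes <- xp1(model_el, "notes")
  if (!missing_node(notes)) {
    p <- xml2::xml_find_first(notes, ".//*[local-name() = 'p']")
    txt <- if (missing_node(p)) trimws(xml2::xml_text(notes)) else xml2::xml_text(p)
    if (nzchar(txt)) model$metadata$notes <- txt
  }
  ann <- xp1(model_el, "annotation")
  if (missing_node(ann)) return(model)
  desc <- xml2::xml_find_first(ann,
    ".//*[local-name() = 'RDF']/*[local-name() = 'Description']")
  if (missing_node(desc)) return(model)
  get_resource <- function(qual) {
    li <- xml2::xml_find_first(desc, sprintf(
      "./*[local-name() = '%s']/*[local-name() = 'Bag']/*[local-name() = 'li']", qual))
    if (missing_node(li)) return(NULL)
    v <- pkg_attr(li, "rdf:resource")
    if (is.na(v)) NULL else v
  }
  model$metadata$model_source <- get_resource("isDerivedFrom")
  model$metadata$publication <- get_resource("isDescribedBy")
  model$metadata$biological_system <- get_resource("is")
  model$metadata$taxon <- get_resource("hasTaxon")
  for (key in c("created", "modified")) {
    w <- xml2::xml_find_first(desc, sprintf(
      "./*[local-name() = '%s']/*[local-name() = 'W3CDTF']", key))
    if (!missing_node(w)) model$metadata[[key]] <- xml2::xml_text(w)
  }
  lis <- xml2::xml_find_all(desc,
    "./*[local-name() = 'creator']/*[local-name() = 'Bag']/*[local-name() = 'li']")
  for (i in seq_along(lis)) {
    li <- lis[[i]]
    txt_of <- function(xpath) {
      nd <- xml2::xml_find_first(li, xpath)
      if (missing_node(nd)) NULL else xml2::xml_text(nd)
    }
    model$metadata$creators[[i]] <- list(
      index = i,
      givenName = txt_of(".//*[local-name() = 'Given']"),
      familyName = txt_of(".//*[local-name() = 'Family']"),
      organization = txt_of(".//*[local-name() = 'Orgname']"),
      email = txt_of("./*[local-name() = 'EMAIL']"))
  }
  model
}

import_uncertainty <- function(node, model, symbol) {
  lou <- xp1(node, "listOfUncertainties")
  if (missing_node(lou)) return(model)
  unc <- xp1(lou, "uncertainty")
  if (missing_node(unc)) return(model)
  rec <- empty_uncertainty()
  read_scalar <- function(el) {
    v <- pkg_attr(el, "distrib:value")
    if (!is.na(v)) return(ex_number(as.numeric(v)))
    v <- pkg_attr(el, "distrib:var")
    if (!is.na(v)) return(ex_symbol(v))
    read_math_child(el)
  }
  read_bound <- function(el, which) {
    v <- pkg_attr(el, paste0("distrib:value", which))
    if (!is.na(v)) return(ex_number(as.numeric(v)))
    v <- pkg_attr(el, paste0("distrib:var", which))
    if (!is.na(v)) return(ex_symbol(v))
    NULL
  }
  for (el in xml2::xml_children(unc)) {
    type <- pkg_attr(el, "distrib:type")
    if (is.na(type)) next
    local <- xml2::xml_name(el)
    if (local == "uncertParameter") {
      if (type %in% c("distribution", "externalParameter")) {
        uri <- pkg_attr(el, "distrib:definitionURL")
        rec[[type]] <- if (!is.na(uri)) {
          list(form = "uri", uri = uri)
        } else {
          list(form = "formula", value = read_scalar(el))
        }
      } else {
        slot <- canonical_uncert_attr(type)
        rec$scalars[[slot]] <- read_scalar(el)
      }
    } else if (local == "uncertSpan") {
      pair <- list(lower = read_bound(el, "Lower"),
                   upper = read_bound(el, "Upper"))
      if (type %in% c("distribution", "externalParameter")) {
        rec[[type]] <- c(list(form = "pair"), pair)
      } else {
        rec$intervals[[type]] <- pair
      }
    }
  }
  model$uncertainty[[symbol]] <- rec
  model
}

import_participants <- function(rxn_el, which, sr_map) {
  lo <- xp1(rxn_el, which)
  parts <- list()
  if (missing_node(lo)) return(parts)
  for (ref in xpall(lo, "speciesReference")) {
    species <- xml2::xml_attr(ref, "species")
    srid <- xml2::xml_attr(ref, "id")
    st <- xml2::xml_attr(ref, "stoichiometry")
    if (!is.na(srid) && !is.null(sr_map[[srid]])) {
      parts[[length(parts) + 1L]] <- list(species = species,
                                          stoich = sr_map[[srid]],
                                          symbolic = TRUE)
    } else {
      parts[[length(parts) + 1L]] <- list(
        species = species,
        stoich = if (is.na(st)) 1 else as.numeric(st),
        symbolic = FALSE)
    }
  }
  parts
}

#' Import an SBML Level 3 document as a model
#'
#' Inverse of [ant_export_sbml()] on the subset that export emits (core plus
#' distrib uncertainty/draws plus FBC v1).  Constructs outside that subset
#' are dropped with warning diagnostics; a required package this importer
#' does not understand is a fatal `ant_unsupported_error`, and an FBC
#' version 2 namespace is reported as unsupported (only version 1 is read).
#'
#' @param x SBML XML: a file path, XML string, or `xml2::xml_document`.
#' @return An `ant_model`; import warnings are in `model$diagnostics`.
#' @export
ant_import_sbml <- function(x) {
  doc <- if (inherits(x, "xml_document")) {
    x
  } else if (is.character(x) && length(x) == 1 && !grepl("<", x, fixed = TRUE)) {
    xml2::read_xml(x)
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    ant_stop("not an SBML document (root element is not <sbml>)",
             class = "ant_sbml_error")
  }
  level <- attr_or(root, "level")
  if (!identical(level, "3")) {
    ant_stop(sprintf("only SBML Level 3 is supported (document is Level %s)",
                     level), class = "ant_unsupported_error")
  }
  ns_map <- tryCatch(as.list(xml2::xml_ns(doc)), error = function(e) list())
  known_ns <- c(SBML_CORE_NS, SBML_FBC1_NS, SBML_DISTRIB_NS, MATHML_NS,
                XHTML_NS, RDF_NS, DCTERMS_NS, VCARD_NS, BQBIOL_NS, BQMODEL_NS)
  root_attrs <- xml2::xml_attrs(root)
  diags <- list()
  fbc_ok <- TRUE
  for (prefix in names(ns_map)) {
    uri <- ns_map[[prefix]]
    if (uri %in% known_ns) next
    if (identical(uri, SBML_FBC2_NS)) {
      diags[[length(diags) + 1L]] <- ant_diagnostic("error",
        "FBC version 2 is not supported; only FBC version 1 can be read")
      fbc_ok <- FALSE
      next
    }
    req_attr <- pkg_attr(root, paste0(sub("^d[0-9]+$", "", prefix), ":required"))
    if (identical(req_attr, "true")) {
      ant_stop(sprintf("document requires unsupported SBML package '%s'", uri),
               class = "ant_unsupported_error")
    }
    diags[[length(diags) + 1L]] <- ant_diagnostic("warning",
      sprintf("ignoring unsupported SBML package namespace '%s'", uri))
  }

  model_el <- xp1(root, "model")
  if (missing_node(model_el)) {
    ant_stop("document has no <model> element", class = "ant_sbml_error")
  }
  model_id <- attr_or(model_el, "id")
  model <- new_model(if (is.na(model_id) || model_id == "__main") NULL else model_id)
  model$diagnostics <- diags
  warn <- function(msg) {
    model$diagnostics <<- c(model$diagnostics,
                            list(ant_diagnostic("warning", msg)))
  }

  for (dropped in c("listOfFunctionDefinitions", "listOfUnitDefinitions",
                    "listOfConstraints")) {
    if (!missing_node(xp1(model_el, dropped))) {
      warn(sprintf("%s is not supported and was dropped", dropped))
    }
  }

  model <- import_metadata(model_el, model)

  los <- xp1(model_el, "listOfSpecies")
  if (!missing_node(los)) {
    for (el in xpall(los, "species")) {
      id <- xml2::xml_attr(el, "id")
      init <- attr_or(el, "initialConcentration")
      if (is.na(init)) init <- attr_or(el, "initialAmount")
      model$species[[id]] <- list(
        id = id,
        init = ex_number(if (is.na(init)) 0 else as.numeric(init)),
        boundary = identical(attr_or(el, "boundaryCondition"), "true"),
        explicit_init = !is.na(init))
      model <- import_uncertainty(el, model, id)
    }
  }

  lop <- xp1(model_el, "listOfParameters")
  if (!missing_node(lop)) {
    for (el in xpall(lop, "parameter")) {
      id <- xml2::xml_attr(el, "id")
      val <- attr_or(el, "value")
      model$parameters[[id]] <- list(
        id = id,
        init = ex_number(if (is.na(val)) 0 else as.numeric(val)),
        constant = !identical(attr_or(el, "constant"), "false"),
        explicit_init = !is.na(val))
      model <- import_uncertainty(el, model, id)
    }
  }

  # initial assignments and rules, with species-reference targets split out
  init_list <- list()
  loi <- xp1(model_el, "listOfInitialAssignments")
  if (!missing_node(loi)) {
    for (el in xpall(loi, "initialAssignment")) {
      init_list[[length(init_list) + 1L]] <-
        list(symbol = xml2::xml_attr(el, "symbol"), expr = read_math_child(el))
    }
  }
  rule_list <- list()
  lor <- xp1(model_el, "listOfRules")
  if (!missing_node(lor)) {
    for (el in xml2::xml_children(lor)) {
      nm <- xml2::xml_name(el)
      if (!nm %in% c("assignmentRule", "rateRule", "algebraicRule")) next
      rule_list[[length(rule_list) + 1L]] <- list(
        element = nm,
        variable = attr_or(el, "variable"),
        id = attr_or(el, "id"),
        expr = read_math_child(el))
    }
  }

  # collect symbolic stoichiometry references: a rule or initial assignment
  # targeting a speciesReference id whose math is a single symbol
  lorx <- xp1(model_el, "listOfReactions")
  sr_ids <- character(0)
  if (!missing_node(lorx)) {
    for (rxn in xpall(lorx, "reaction")) {
      for (which in c("listOfReactants", "listOfProducts")) {
        lo <- xp1(rxn, which)
        if (missing_node(lo)) next
        for (ref in xpall(lo, "speciesReference")) {
          srid <- xml2::xml_attr(ref, "id")
          if (!is.na(srid)) sr_ids <- c(sr_ids, srid)
        }
      }
    }
  }
  sr_map <- list()
  keep_inits <- rep(TRUE, length(init_list))
  for (i in seq_along(init_list)) {
    e <- init_list[[i]]
    if (e$symbol %in% sr_ids && !is.null(e$expr) && e$expr$kind == "symbol") {
      sr_map[[e$symbol]] <- e$expr$name
      keep_inits[i] <- FALSE
    }
  }
  init_list <- init_list[keep_inits]
  keep_rules <- rep(TRUE, length(rule_list))
  for (i in seq_along(rule_list)) {
    ru <- rule_list[[i]]
    if (identical(ru$element, "assignmentRule") && !is.na(ru$variable) &&
        ru$variable %in% sr_ids && !is.null(ru$expr) &&
        ru$expr$kind == "symbol") {
      sr_map[[ru$variable]] <- ru$expr$name
      keep_rules[i] <- FALSE
    }
  }
  rule_list <- rule_list[keep_rules]

  for (e in init_list) {
    if (!is.null(model$species[[e$symbol]])) {
      model$species[[e$symbol]]$init <- e$expr
      model$species[[e$symbol]]$explicit_init <- TRUE
    } else if (!is.null(model$parameters[[e$symbol]])) {
      model$parameters[[e$symbol]]$init <- e$expr
      model$parameters[[e$symbol]]$explicit_init <- TRUE
    } else {
      warn(sprintf("initial assignment targets unknown symbol '%s'", e$symbol))
    }
  }
  for (ru in rule_list) {
    kind <- switch(ru$element, assignmentRule = "continuous",
                   rateRule = "rate", "algebraic")
    model$rules[[length(model$rules) + 1L]] <- list(
      kind = kind,
      target = if (kind == "algebraic") NULL else ru$variable,
      formula = ru$expr,
      name = if (kind == "algebraic" && !is.na(ru$id)) ru$id else NULL)
    if (kind != "algebraic" && !is.null(model$parameters[[ru$variable]])) {
      model$parameters[[ru$variable]]$constant <- FALSE
    }
  }

  if (!missing_node(lorx)) {
    for (rxn in xpall(lorx, "reaction")) {
      id <- xml2::xml_attr(rxn, "id")
      kl <- xp1(rxn, "kineticLaw")
      if (!missing_node(kl) && !missing_node(xp1(kl, "listOfLocalParameters"))) {
        warn(sprintf("local parameters in reaction '%s' are not supported", id))
      }
      model$reactions[[id]] <- list(
        id = id, auto = grepl("^_J[0-9]+$", id),
        reactants = import_participants(rxn, "listOfReactants", sr_map),
        products = import_participants(rxn, "listOfProducts", sr_map),
        law = if (missing_node(kl)) NULL else read_math_child(kl),
        reversible = !identical(attr_or(rxn, "reversible"), "false"))
      model <- import_uncertainty(rxn, model, id)
    }
  }

  loe <- xp1(model_el, "listOfEvents")
  if (!missing_node(loe)) {
    for (el in xpall(loe, "event")) {
      tr <- xp1(el, "trigger")
      if (missing_node(tr)) {
        warn("event without trigger was dropped")
        next
      }
      if (!missing_node(xp1(el, "delay"))) {
        warn("event delay is not supported and was dropped")
      }
      if (!missing_node(xp1(el, "priority"))) {
        warn("event priority is not supported and was dropped")
      }
      assigns <- list()
      loa <- xp1(el, "listOfEventAssignments")
      if (!missing_node(loa)) {
        for (ea in xpall(loa, "eventAssignment")) {
          assigns[[length(assigns) + 1L]] <- list(
            target = xml2::xml_attr(ea, "variable"),
            value = read_math_child(ea))
        }
      }
      model$events[[length(model$events) + 1L]] <-
        list(trigger = read_math_child(tr), assignments = assigns)
    }
  }

  if (fbc_ok) {
    lofb <- xp1(model_el, "listOfFluxBounds")
    if (!missing_node(lofb)) {
      k <- 0L
      for (fb in xpall(lofb, "fluxBound")) {
        cid <- pkg_attr(fb, "fbc:id")
        if (is.na(cid)) {
          cid <- sprintf("_c%d", k)
        }
        k <- k + 1L
        model$fbc$constraints[[length(model$fbc$constraints) + 1L]] <- list(
          id = cid,
          reaction = pkg_attr(fb, "fbc:reaction"),
          comparator = switch(pkg_attr(fb, "fbc:operation"),
            greaterEqual = ">=", lessEqual = "<=", equal = "=",
            ant_stop("unknown fluxBound operation", class = "ant_sbml_error")),
          bound = as.numeric(pkg_attr(fb, "fbc:value")))
      }
    }
    loo <- xp1(model_el, "listOfObjectives")
    if (!missing_node(loo)) {
      for (oel in xpall(loo, "objective")) {
        terms <- list()
        lofo <- xp1(oel, "listOfFluxObjectives")
        if (!missing_node(lofo)) {
          for (fo in xpall(lofo, "fluxObjective")) {
            coef <- pkg_attr(fo, "fbc:coefficient")
            terms[[length(terms) + 1L]] <- list(
              reaction = pkg_attr(fo, "fbc:reaction"),
              coef = if (is.na(coef)) 1 else as.numeric(coef))
          }
        }
        model$fbc$objectives[[length(model$fbc$objectives) + 1L]] <- list(
          id = pkg_attr(oel, "fbc:id"),
          sense = pkg_attr(oel, "fbc:type"),
          terms = terms)
      }
    }
  }
  model
}
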