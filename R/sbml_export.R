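# SBML Level 3 Version 2 export: core + distrib + FBC v1 subset.
#
# The emitted document is fully deterministic — element and attribute order
# is a pure function of the model — so export . import . export reaches a
# byte-identical fixed point.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version2/core"
SBML_FBC1_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version1"
SBML_FBC2_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_DISTRIB_NS <- "http://www.sbml.org/sbml/level3/version1/distrib/version1"
XHTML_NS <- "http://www.w3.org/1999/xhtml"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
DCTERMS_NS <- "http://purl.org/dc/terms/"
VCARD_NS <- "http://www.w3.org/2001/vcard-rdf/3.0#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"
BQMODEL_NS <- "http://biomodels.net/model-qualifiers/"

DEFAULT_COMPARTMENT <- "default_compartment"

valid_sid <- function(id) grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)

sanitize_sid <- function(id) {
  out <- gsub("[^A-Za-z0-9_]", "_", id)
  if (!grepl("^[A-Za-z_]", out)) out <- paste0("_", out)
  out
}

uses_distrib <- function(model) {
  if (length(model$uncertainty) > 0L) return(TRUE)
  for (entry in model_expressions(model)) {
    for (cl in expr_calls(entry$expr)) {
      if (is_distribution_call(cl)) return(TRUE)
    }
  }
  FALSE
}

uses_fbc <- function(model) {
  length(model$fbc$objectives) > 0L || length(model$fbc$constraints) > 0L
}

expr_is_number <- function(e) !is.null(e) && e$kind == "number"

# species-reference ids for symbolic stoichiometries; deterministic
sr_id <- function(rxn_id, side, index) sprintf("_sr_%s_%s%d", rxn_id, side, index)

add_uncertainty_element <- function(parent, rec) {
  lou <- xml2::xml_add_child(parent, "distrib:listOfUncertainties")
  unc <- xml2::xml_add_child(lou, "distrib:uncertainty")
  put_scalar <- function(el, expr) {
    if (expr$kind == "number") {
      xml2::xml_set_attr(el, "distrib:value", format_number(expr$value))
    } else if (expr$kind == "symbol") {
      xml2::xml_set_attr(el, "distrib:var", expr$name)
    } else {
      add_math_element(el, expr)
    }
  }
  put_bound <- function(el, which, expr) {
    if (expr$kind == "number") {
      xml2::xml_set_attr(el, paste0("distrib:value", which),
                         format_number(expr$value))
    } else if (expr$kind == "symbol") {
      xml2::xml_set_attr(el, paste0("distrib:var", which), expr$name)
    } else {
      ant_stop("interval endpoints must be numbers or symbols for SBML export",
               class = "ant_sbml_error")
    }
  }
  scalar_order <- setdiff(UNCERTAINTY_SCALAR_ATTRS, "standardDeviation")
  for (a in scalar_order) {
    e <- rec$scalars[[a]]
    if (is.null(e)) next
    el <- xml2::xml_add_child(unc, "distrib:uncertParameter")
    xml2::xml_set_attr(el, "distrib:type",
                       if (a == "stdev") "standardDeviation" else a)
    put_scalar(el, e)
  }
  for (a in UNCERTAINTY_PAIR_ATTRS) {
    iv <- rec$intervals[[a]]
    if (is.null(iv)) next
    el <- xml2::xml_add_child(unc, "distrib:uncertSpan")
    xml2::xml_set_attr(el, "distrib:type", a)
    put_bound(el, "Lower", iv$lower)
    put_bound(el, "Upper", iv$upper)
  }
  for (slot in c("distribution", "externalParameter")) {
    v <- rec[[slot]]
    if (is.null(v)) next
    if (identical(v$form, "pair")) {
      el <- xml2::xml_add_child(unc, "distrib:uncertSpan")
      xml2::xml_set_attr(el, "distrib:type", slot)
      put_bound(el, "Lower", v$lower)
      put_bound(el, "Upper", v$upper)
    } else {
      el <- xml2::xml_add_child(unc, "distrib:uncertParameter")
      xml2::xml_set_attr(el, "distrib:type", slot)
      if (identical(v$form, "uri")) {
        xml2::xml_set_attr(el, "distrib:definitionURL", v$uri)
      } else {
        put_scalar(el, v$value)
      }
    }
  }
  invisible(lou)
}

add_rdf_bag <- function(parent, qualifier, uri) {
  q <- xml2::xml_add_child(parent, qualifier)
  bag <- xml2::xml_add_child(q, "rdf:Bag")
  li <- xml2::xml_add_child(bag, "rdf:li")
  xml2::xml_set_attr(li, "rdf:resource", uri)
  invisible(q)
}

add_metadata_annotation <- function(model_el, rec, metaid) {
  ann <- xml2::xml_add_child(model_el, "annotation")
  # the rdf prefix must be in scope before prefixed children can be created,
  # so the RDF root is parsed from a fragment that declares every namespace
  rdf_frag <- xml2::read_xml(sprintf(
    paste0('<rdf:RDF xmlns:rdf="%s" xmlns:dcterms="%s" xmlns:vCard="%s" ',
           'xmlns:bqbiol="%s" xmlns:bqmodel="%s"/>'),
    RDF_NS, DCTERMS_NS, VCARD_NS, BQBIOL_NS, BQMODEL_NS))
  rdf <- xml2::xml_add_child(ann, rdf_frag)
  desc <- xml2::xml_add_child(rdf, "rdf:Description")
  xml2::xml_set_attr(desc, "rdf:about", paste0("#", metaid))
  if (length(rec$creators) > 0L) {
    cr_el <- xml2::xml_add_child(desc, "dcterms:creator")
    bag <- xml2::xml_add_child(cr_el, "rdf:Bag")
    for (cr in rec$creators) {
      li <- xml2::xml_add_child(bag, "rdf:li")
      xml2::xml_set_attr(li, "rdf:parseType", "Resource")
      if (!is.null(cr$familyName) || !is.null(cr$givenName)) {
        n_el <- xml2::xml_add_child(li, "vCard:N")
        xml2::xml_set_attr(n_el, "rdf:parseType", "Resource")
        if (!is.null(cr$familyName)) {
          xml2::xml_add_child(n_el, "vCard:Family", cr$familyName)
        }
        if (!is.null(cr$givenName)) {
          xml2::xml_add_child(n_el, "vCard:Given", cr$givenName)
        }
      }
      if (!is.null(cr$email)) xml2::xml_add_child(li, "vCard:EMAIL", cr$email)
      if (!is.null(cr$organization)) {
        org <- xml2::xml_add_child(li, "vCard:ORG")
        xml2::xml_set_attr(org, "rdf:parseType", "Resource")
        xml2::xml_add_child(org, "vCard:Orgname", cr$organization)
      }
    }
  }
  for (key in c("created", "modified")) {
    if (is.null(rec[[key]])) next
    el <- xml2::xml_add_child(desc, paste0("dcterms:", key))
    xml2::xml_set_attr(el, "rdf:parseType", "Resource")
    xml2::xml_add_child(el, "dcterms:W3CDTF", rec[[key]])
  }
  # qualifier mapping mirrors BioModels curation conventions
  if (!is.null(rec$model_source)) add_rdf_bag(desc, "bqmodel:isDerivedFrom", rec$model_source)
  if (!is.null(rec$publication)) add_rdf_bag(desc, "bqmodel:isDescribedBy", rec$publication)
  if (!is.null(rec$biological_system)) add_rdf_bag(desc, "bqbiol:is", rec$biological_system)
  if (!is.null(rec$taxon)) add_rdf_bag(desc, "bqbiol:hasTaxon", rec$taxon)
  invisible(ann)
}

#' Export a model to an SBML Level 3 Version 2 document
#'
#' Core constructs plus the Distributions package (distribution draws,
#' per-symbol uncertainty) and Flux Balance Constraints version 1
#' (flux bounds, linear objectives).  Packages are declared only when used;
#' distrib is marked `required="true"` and FBC `required="false"`, as their
#' specifications dictate.
#'
#' @param model A validated `ant_model`.
#' @return An `xml2::xml_document`.
#' @export
ant_export_sbml <- function(model) {
  pre_errors <- c(diag_errors(ant_check_rateof(model)),
                  diag_errors(ant_check_distrib_contexts(model)))
  if (length(pre_errors) > 0L) {
    ant_stop(paste("model fails validation:", pre_errors[[1]]$message),
             class = "ant_sbml_error")
  }
  for (id in c(names(model$species), names(model$parameters),
               names(model$reactions))) {
    if (!valid_sid(id)) {
      ant_stop(sprintf("'%s' is not a valid SBML SId", id),
               class = "ant_sbml_error")
    }
  }
  with_distrib <- uses_distrib(model)
  with_fbc <- uses_fbc(model)

  attrs <- list(xmlns = SBML_CORE_NS, level = "3", version = "2")
  if (with_fbc) {
    attrs[["xmlns:fbc"]] <- SBML_FBC1_NS
    attrs[["fbc:required"]] <- "false"
  }
  if (with_distrib) {
    attrs[["xmlns:distrib"]] <- SBML_DISTRIB_NS
    attrs[["distrib:required"]] <- "true"
  }
  doc <- do.call(xml2::xml_new_root, c(list(.value = "sbml"), attrs))
  model_el <- xml2::xml_add_child(doc, "model")
  model_id <- if (!is.null(model$name)) model$name else "__main"
  xml2::xml_set_attr(model_el, "id", model_id)
  has_annotation <- !metadata_is_empty(model$metadata) &&
    !(is.null(model$metadata$model_source) && is.null(model$metadata$publication) &&
      is.null(model$metadata$biological_system) && is.null(model$metadata$taxon) &&
      is.null(model$metadata$created) && is.null(model$metadata$modified) &&
      length(model$metadata$creators) == 0L)
  metaid <- paste0("_meta_", model_id)
  if (has_annotation) xml2::xml_set_attr(model_el, "metaid", metaid)

  if (!is.null(model$metadata$notes)) {
    notes <- xml2::xml_add_child(model_el, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    xml2::xml_add_child(body, "p", model$metadata$notes)
  }
  if (has_annotation) add_metadata_annotation(model_el, model$metadata, metaid)

  cont <- continuous_targets(model)
  uncert_for <- function(el, id) {
    rec <- model$uncertainty[[id]]
    if (!is.null(rec)) add_uncertainty_element(el, rec)
  }

  if (length(model$species) > 0L) {
    loc <- xml2::xml_add_child(model_el, "listOfCompartments")
    cmp <- xml2::xml_add_child(loc, "compartment")
    xml2::xml_set_attrs(cmp, c(id = DEFAULT_COMPARTMENT, spatialDimensions = "3",
                               size = "1", constant = "true"))
    los <- xml2::xml_add_child(model_el, "listOfSpecies")
    for (sp in model$species) {
      el <- xml2::xml_add_child(los, "species")
      xml2::xml_set_attrs(el, c(
        id = sp$id, compartment = DEFAULT_COMPARTMENT,
        boundaryCondition = if (sp$boundary) "true" else "false",
        hasOnlySubstanceUnits = "false",
        constant = "false"))
      if (expr_is_number(sp$init) && !(sp$id %in% cont)) {
        xml2::xml_set_attr(el, "initialConcentration",
                           format_number(sp$init$value))
      }
      uncert_for(el, sp$id)
    }
  }

  if (length(model$parameters) > 0L) {
    lop <- xml2::xml_add_child(model_el, "listOfParameters")
    for (p in model$parameters) {
      el <- xml2::xml_add_child(lop, "parameter")
      xml2::xml_set_attrs(el, c(id = p$id,
                                constant = if (p$constant) "true" else "false"))
      if (expr_is_number(p$init) && !(p$id %in% cont)) {
        xml2::xml_set_attr(el, "value", format_number(p$init$value))
      }
      uncert_for(el, p$id)
    }
  }

  # initial assignments: non-constant initial formulas, then symbolic
  # stoichiometry references whose symbols are initial-assigned
  init_entries <- list()
  for (sp in model$species) {
    if (!expr_is_number(sp$init) && !(sp$id %in% cont)) {
      init_entries[[length(init_entries) + 1L]] <- list(symbol = sp$id,
                                                        expr = sp$init)
    }
  }
  for (p in model$parameters) {
    if (!expr_is_number(p$init) && !(p$id %in% cont)) {
      init_entries[[length(init_entries) + 1L]] <- list(symbol = p$id,
                                                        expr = p$init)
    }
  }
  sr_rules <- list()
  for (r in model$reactions) {
    for (side in c("r", "p")) {
      parts <- if (side == "r") r$reactants else r$products
      for (i in seq_along(parts)) {
        pt <- parts[[i]]
        if (!pt$symbolic) next
        ref <- sr_id(r$id, side, i)
        target_expr <- ex_symbol(pt$stoich)
        if (pt$stoich %in% cont) {
          sr_rules[[length(sr_rules) + 1L]] <- list(symbol = ref,
                                                    expr = target_expr)
        } else {
          init_entries[[length(init_entries) + 1L]] <- list(symbol = ref,
                                                            expr = target_expr)
        }
      }
    }
  }
  if (length(init_entries) > 0L) {
    loi <- xml2::xml_add_child(model_el, "listOfInitialAssignments")
    for (e in init_entries) {
      el <- xml2::xml_add_child(loi, "initialAssignment")
      xml2::xml_set_attr(el, "symbol", e$symbol)
      add_math_element(el, e$expr)
    }
  }

  if (length(model$rules) > 0L || length(sr_rules) > 0L) {
    lor <- xml2::xml_add_child(model_el, "listOfRules")
    for (ru in model$rules) {
      if (ru$kind == "continuous") {
        el <- xml2::xml_add_child(lor, "assignmentRule")
        xml2::xml_set_attr(el, "variable", ru$target)
      } else if (ru$kind == "rate") {
        el <- xml2::xml_add_child(lor, "rateRule")
        xml2::xml_set_attr(el, "variable", ru$target)
      } else {
        el <- xml2::xml_add_child(lor, "algebraicRule")
        if (!is.null(ru$name)) xml2::xml_set_attr(el, "id", ru$name)
      }
      add_math_element(el, ru$formula)
    }
    for (e in sr_rules) {
      el <- xml2::xml_add_child(lor, "assignmentRule")
      xml2::xml_set_attr(el, "variable", e$symbol)
      add_math_element(el, e$expr)
    }
  }

  if (length(model$reactions) > 0L) {
    lorx <- xml2::xml_add_child(model_el, "listOfReactions")
    for (r in model$reactions) {
      el <- xml2::xml_add_child(lorx, "reaction")
      xml2::xml_set_attrs(el, c(id = r$id,
                                reversible = if (r$reversible) "true" else "false"))
      uncert_for(el, r$id)
      for (side in c("r", "p")) {
        parts <- if (side == "r") r$reactants else r$products
        if (length(parts) == 0L) next
        lo <- xml2::xml_add_child(el, if (side == "r") "listOfReactants" else "listOfProducts")
        for (i in seq_along(parts)) {
          pt <- parts[[i]]
          ref <- xml2::xml_add_child(lo, "speciesReference")
          xml2::xml_set_attr(ref, "species", pt$species)
          if (pt$symbolic) {
            xml2::xml_set_attr(ref, "id", sr_id(r$id, side, i))
            xml2::xml_set_attr(ref, "constant", "false")
          } else {
            xml2::xml_set_attr(ref, "stoichiometry", format_number(pt$stoich))
            xml2::xml_set_attr(ref, "constant", "true")
          }
        }
      }
      if (!is.null(r$law)) {
        kl <- xml2::xml_add_child(el, "kineticLaw")
        add_math_element(kl, r$law)
      }
    }
  }

  if (length(model$events) > 0L) {
    loe <- xml2::xml_add_child(model_el, "listOfEvents")
    for (k in seq_along(model$events)) {
      ev <- model$events[[k]]
      el <- xml2::xml_add_child(loe, "event")
      xml2::xml_set_attrs(el, c(id = sprintf("_E%d", k - 1L),
                                useValuesFromTriggerTime = "true"))
      tr <- xml2::xml_add_child(el, "trigger")
      xml2::xml_set_attrs(tr, c(initialValue = "true", persistent = "true"))
      add_math_element(tr, ev$trigger)
      loa <- xml2::xml_add_child(el, "listOfEventAssignments")
      for (a in ev$assignments) {
        ea <- xml2::xml_add_child(loa, "eventAssignment")
        xml2::xml_set_attr(ea, "variable", a$target)
        add_math_element(ea, a$value)
      }
    }
  }

  if (with_fbc) {
    if (length(model$fbc$constraints) > 0L) {
      lofb <- xml2::xml_add_child(model_el, "fbc:listOfFluxBounds")
      for (cn in model$fbc$constraints) {
        fb <- xml2::xml_add_child(lofb, "fbc:fluxBound")
        xml2::xml_set_attr(fb, "fbc:id", cn$id)
        xml2::xml_set_attr(fb, "fbc:reaction", cn$reaction)
        xml2::xml_set_attr(fb, "fbc:operation", switch(cn$comparator,
          ">=" = "greaterEqual", "<=" = "lessEqual", "=" = "equal"))
        xml2::xml_set_attr(fb, "fbc:value", format_number(cn$bound))
      }
    }
    if (length(model$fbc$objectives) > 0L) {
      loo <- xml2::xml_add_child(model_el, "fbc:listOfObjectives")
      xml2::xml_set_attr(loo, "fbc:activeObjective",
                         model$fbc$objectives[[1]]$id)
      for (obj in model$fbc$objectives) {
        oel <- xml2::xml_add_child(loo, "fbc:objective")
        xml2::xml_set_attr(oel, "fbc:id", obj$id)
        xml2::xml_set_attr(oel, "fbc:type", obj$sense)
        lofo <- xml2::xml_add_child(oel, "fbc:listOfFluxObjectives")
        for (t in obj$terms) {
          fo <- xml2::xml_add_child(lofo, "fbc:fluxObjective")
          xml2::xml_set_attr(fo, "fbc:reaction", t$reaction)
          xml2::xml_set_attr(fo, "fbc:coefficient", format_number(t$coef))
        }
      }
    }
  }
  doc
}

#' Serialize a model to SBML text
#'
#' @param model An `ant_model`.
#' @return A character scalar holding the XML document.
#' @export
ant_to_sbml <- function(model) {
  doc <- ant_export_sbml(model)
  as.character(doc)
}

#' Write a model to an SBML file
#'
#' @param model An `ant_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
ant_write_sbml <- function(model, path) {
  writeLines(sub("\n$", "", ant_to_sbml(model)), path, useBytes = TRUE)
  invisible(path)
}
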