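# Semantic model: resolve AST statements into a validated network.
#
# Classification rules: an identifier first seen in a reaction participant
# list is a species; an identifier seen only in expressions or assignments is
# a parameter.  `$` marks boundary species, whose amounts the reactions they
# take part in do not change.  A species governed by a rate rule or a
# continuous assignment while also participating in reactions must be marked
# boundary, otherwise two sources would fight over its derivative.

MATH_FUNCTIONS <- c("sin", "cos", "tan", "asin", "acos", "atan", "sinh",
                    "cosh", "tanh", "exp", "ln", "log", "log10", "sqrt",
                    "abs", "ceil", "ceiling", "floor", "piecewise", "rateOf")

new_model <- function(name = NULL) {
  structure(list(
    name = name,
    species = list(),
    parameters = list(),
    reactions = list(),
    rules = list(),
    events = list(),
    metadata = empty_metadata(),
    uncertainty = list(),
    fbc = list(objectives = list(), constraints = list()),
    diagnostics = list()
  ), class = "ant_model")
}

symbol_exists <- function(model, id) {
  !is.null(model$species[[id]]) || !is.null(model$parameters[[id]]) ||
    !is.null(model$reactions[[id]])
}

declare_species <- function(model, id, boundary = FALSE) {
  sp <- model$species[[id]]
  if (is.null(sp)) {
    if (!is.null(model$parameters[[id]])) {
      # promoted: first classified as parameter, later seen in a reaction
      p <- model$parameters[[id]]
      model$parameters[[id]] <- NULL
      sp <- list(id = id, init = p$init, boundary = boundary,
                 explicit_init = p$explicit_init)
    } else {
      sp <- list(id = id, init = ex_number(0), boundary = boundary,
                 explicit_init = FALSE)
    }
  } else {
    sp$boundary <- sp$boundary || boundary
  }
  model$species[[id]] <- sp
  model
}

declare_parameter <- function(model, id, init = ex_number(0),
                              explicit = FALSE) {
  if (is.null(model$parameters[[id]]) && is.null(model$species[[id]])) {
    model$parameters[[id]] <- list(id = id, init = init, constant = TRUE,
                                   explicit_init = explicit)
  }
  model
}

add_warning <- function(model, msg, loc = NULL) {
  model$diagnostics <- c(model$diagnostics, list(ant_diagnostic(
    "warning", msg,
    if (is.null(loc)) NA else loc$line, if (is.null(loc)) NA else loc$col)))
  model
}

# every expression in the model, tagged with the context it appears in
model_expressions <- function(model) {
  out <- list()
  add <- function(context, expr, where) {
    if (!is.null(expr)) {
      out[[length(out) + 1L]] <<- list(context = context, expr = expr,
                                       where = where)
    }
  }
  for (r in model$reactions) add("kinetic-law", r$law, r$id)
  for (ru in model$rules) {
    ctx <- switch(ru$kind, continuous = "continuous-assignment",
                  rate = "rate-rule", algebraic = "algebraic-rule")
    add(ctx, ru$formula, if (is.null(ru$target)) ru$name else ru$target)
  }
  for (sp in model$species) add("initial-assignment", sp$init, sp$id)
  for (p in model$parameters) add("initial-assignment", p$init, p$id)
  for (ev in model$events) {
    add("event-trigger", ev$trigger, NA_character_)
    for (a in ev$assignments) add("event-assignment", a$value, a$target)
  }
  for (tgt in names(model$uncertainty)) {
    rec <- model$uncertainty[[tgt]]
    for (e in rec$scalars) add("uncertainty", e, tgt)
    for (iv in rec$intervals) {
      add("uncertainty", iv$lower, tgt)
      add("uncertainty", iv$upper, tgt)
    }
    for (slot in c("distribution", "externalParameter")) {
      v <- rec[[slot]]
      if (!is.null(v) && identical(v$form, "formula")) add("uncertainty", v$value, tgt)
      if (!is.null(v) && identical(v$form, "pair")) {
        add("uncertainty", v$lower, tgt)
        add("uncertainty", v$upper, tgt)
      }
    }
  }
  out
}

continuous_targets <- function(model) {
  vapply(Filter(function(r) r$kind == "continuous", model$rules),
         `[[`, "", "target")
}

rate_targets <- function(model) {
  vapply(Filter(function(r) r$kind == "rate", model$rules),
         `[[`, "", "target")
}

species_in_reactions <- function(model) {
  unique(unlist(lapply(model$reactions, function(r) {
    vapply(c(r$reactants, r$products), `[[`, "", "species")
  })))
}

#' Build a semantic model from parsed statements
#'
#' Resolves identifiers into species, parameters and reactions, applies
#' initial assignments (last statement wins, with a warning on duplicates),
#' collects rules, events, metadata, uncertainty and flux-balance records,
#' and enforces the language's structural restrictions.
#'
#' @param statements AST statements from [ant_parse()].
#' @return An object of class `ant_model`. Warnings accumulate in
#'   `model$diagnostics`; violations raise `ant_semantic_error`.
#' @examples
#' m <- ant_build_model(ant_parse("A -> B; k1*A\nA = 5\nB = 0\nk1 = 0.1"))
#' names(m$species)
#' @export
ant_build_model <- function(statements) {
  begins <- which(vapply(statements, function(s) identical(s$variant, "model-begin"), TRUE))
  ends <- which(vapply(statements, function(s) identical(s$variant, "model-end"), TRUE))
  if (length(begins) > 1L) {
    s <- statements[[begins[2]]]
    ant_stop("model blocks may not nest or repeat", s$loc$line, s$loc$col,
             "ant_semantic_error")
  }
  if (length(ends) > length(begins)) {
    s <- statements[[ends[length(ends)]]]
    ant_stop("'end' without a matching 'model name()'", s$loc$line,
             s$loc$col, "ant_semantic_error")
  }
  if (length(begins) == 1L && length(ends) == 0L) {
    s <- statements[[begins[1]]]
    ant_stop("'model name()' without a matching 'end'", s$loc$line,
             s$loc$col, "ant_semantic_error")
  }
  name <- if (length(begins) == 1L) statements[[begins[1]]]$name else NULL
  model <- new_model(name)

  body <- Filter(function(s) !s$variant %in% c("model-begin", "model-end"),
                 statements)

  # pass 1: reactions declare species and reaction ids
  auto_k <- 0L
  stoich_symbols <- list()
  for (s in body) {
    if (!identical(s$variant, "reaction")) next
    id <- s$name
    if (is.null(id)) {
      id <- sprintf("_J%d", auto_k)
      auto_k <- auto_k + 1L
    }
    if (!is.null(model$reactions[[id]])) {
      ant_stop(sprintf("duplicate reaction id '%s'", id), s$loc$line,
               s$loc$col, "ant_semantic_error")
    }
    for (p in c(s$reactants, s$products)) {
      model <- declare_species(model, p$species, p$boundary)
      if (p$symbolic) {
        stoich_symbols[[length(stoich_symbols) + 1L]] <-
          list(sym = p$stoich, loc = s$loc)
      }
      if (is.numeric(p$stoich) && p$stoich <= 0) {
        ant_stop(sprintf("stoichiometry of '%s' must be positive", p$species),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
    }
    model$reactions[[id]] <- list(
      id = id, auto = is.null(s$name),
      reactants = lapply(s$reactants, function(p) p[c("species", "stoich", "symbolic")]),
      products = lapply(s$products, function(p) p[c("species", "stoich", "symbolic")]),
      law = s$law, reversible = TRUE)
  }
  for (st in stoich_symbols) {
    if (!symbol_exists(model, st$sym)) model <- declare_parameter(model, st$sym)
  }

  meta_stmts <- list()
  uncert_stmts <- list()
  fbc_stmts <- list()

  # pass 2: assignments, rules, events, deferred statement kinds
  for (s in body) {
    v <- s$variant
    if (v == "reaction") next
    if (v == "initial-assignment") {
      tgt <- s$target
      if (!is.null(model$reactions[[tgt]])) {
        ant_stop(sprintf("cannot assign a value to reaction '%s'", tgt),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
      if (!is.null(model$species[[tgt]])) {
        sp <- model$species[[tgt]]
        if (sp$explicit_init) {
          model <- add_warning(model, sprintf(
            "duplicate initialization of '%s'; the last statement wins", tgt), s$loc)
        }
        sp$init <- s$value
        sp$explicit_init <- TRUE
        sp$boundary <- sp$boundary || isTRUE(s$boundary)
        model$species[[tgt]] <- sp
      } else {
        p <- model$parameters[[tgt]]
        if (is.null(p)) {
          p <- list(id = tgt, init = s$value, constant = TRUE,
                    explicit_init = TRUE)
        } else {
          if (p$explicit_init) {
            model <- add_warning(model, sprintf(
              "duplicate initialization of '%s'; the last statement wins", tgt), s$loc)
          }
          p$init <- s$value
          p$explicit_init <- TRUE
        }
        model$parameters[[tgt]] <- p
      }
    } else if (v == "continuous-assignment" || v == "rate-rule") {
      kind <- if (v == "continuous-assignment") "continuous" else "rate"
      tgt <- s$target
      if (!is.null(model$reactions[[tgt]])) {
        ant_stop(sprintf("'%s' is a reaction and cannot be a rule target", tgt),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
      if (!symbol_exists(model, tgt)) {
        model <- declare_parameter(model, tgt)
      }
      if (!is.null(model$species[[tgt]]) && isTRUE(s$boundary)) {
        model$species[[tgt]]$boundary <- TRUE
      }
      if (!is.null(model$parameters[[tgt]])) {
        model$parameters[[tgt]]$constant <- FALSE
      }
      prior <- Filter(function(r) r$kind %in% c("continuous", "rate") &&
                        identical(r$target, tgt), model$rules)
      if (length(prior) > 0L) {
        other <- prior[[1]]$kind
        msg <- if (other == kind) {
          sprintf("only one %s rule may target '%s'",
                  if (kind == "continuous") "assignment" else "rate", tgt)
        } else {
          sprintf("'%s' cannot have both an assignment rule and a rate rule", tgt)
        }
        ant_stop(msg, s$loc$line, s$loc$col, "ant_semantic_error")
      }
      model$rules[[length(model$rules) + 1L]] <-
        list(kind = kind, target = tgt, formula = s$value, name = NULL)
    } else if (v == "algebraic-rule") {
      model$rules[[length(model$rules) + 1L]] <-
        list(kind = "algebraic", target = NULL, formula = s$formula,
             name = s$name)
    } else if (v == "event") {
      model$events[[length(model$events) + 1L]] <-
        list(trigger = s$trigger, assignments = s$assignments)
      for (a in s$assignments) {
        if (!is.null(model$reactions[[a$target]])) {
          ant_stop(sprintf("event cannot assign to reaction '%s'", a$target),
                   s$loc$line, s$loc$col, "ant_semantic_error")
        }
        if (!symbol_exists(model, a$target)) {
          model <- declare_parameter(model, a$target)
          model <- add_warning(model, sprintf(
            "event target '%s' was not declared; created as a parameter with value 0",
            a$target), s$loc)
        }
        if (!is.null(model$parameters[[a$target]])) {
          model$parameters[[a$target]]$constant <- FALSE
        }
      }
    } else if (v == "metadata") {
      meta_stmts[[length(meta_stmts) + 1L]] <- s
    } else if (v == "uncertainty") {
      uncert_stmts[[length(uncert_stmts) + 1L]] <- s
    } else if (v %in% c("objective", "constraint")) {
      fbc_stmts[[length(fbc_stmts) + 1L]] <- s
    } else {
      ant_stop(sprintf("unhandled statement variant '%s'", v),
               s$loc$line, s$loc$col, "ant_semantic_error")
    }
  }

  model <- ant_apply_metadata(model, meta_stmts)
  model <- ant_attach_uncertainty(model, uncert_stmts)
  model <- ant_build_fbc(model, fbc_stmts)

  # pass 3: close the symbol table — symbols only ever referenced inside
  # expressions become parameters defaulting to 0, with a warning
  repeat {
    created <- FALSE
    for (entry in model_expressions(model)) {
      for (sym in expr_symbols(entry$expr)) {
        if (!symbol_exists(model, sym)) {
          model <- declare_parameter(model, sym)
          model <- add_warning(model, sprintf(
            "symbol '%s' is never initialized; it defaults to 0", sym))
          created <- TRUE
        }
      }
    }
    if (!created) break
  }
  for (sp in model$species) {
    if (!sp$explicit_init && !(sp$id %in% continuous_targets(model))) {
      model <- add_warning(model, sprintf(
        "species '%s' is never initialized; it defaults to 0", sp$id))
    }
  }

  # pass 4: structural restrictions
  in_rxn <- species_in_reactions(model)
  for (ru in model$rules) {
    if (ru$kind %in% c("continuous", "rate") && ru$target %in% in_rxn &&
        !isTRUE(model$species[[ru$target]]$boundary)) {
      what <- if (ru$kind == "rate") "a rate rule" else "an assignment rule"
      ant_stop(sprintf(
        "species '%s' participates in reactions and is governed by %s; it must be declared as a boundary species ($%s)",
        ru$target, what, ru$target), NA, NA, "ant_semantic_error")
    }
  }
  check_assignment_cycles(model)
  model
}

# topological sort of continuous-assignment dependencies; cycles are fatal
assignment_order <- function(model) {
  cont <- Filter(function(r) r$kind == "continuous", model$rules)
  if (length(cont) == 0L) return(list())
  targets <- vapply(cont, `[[`, "", "target")
  deps <- lapply(cont, function(r) intersect(expr_symbols(r$formula), targets))
  names(deps) <- targets
  ordered <- character(0)
  remaining <- targets
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(t) {
      length(setdiff(deps[[t]], ordered)) == 0L
    }, TRUE)]
    if (length(ready) == 0L) {
      ant_stop(sprintf("cyclic assignment rules involving: %s",
                       paste(sort(remaining), collapse = ", ")),
               NA, NA, "ant_semantic_error")
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  cont[match(ordered, targets)]
}

check_assignment_cycles <- function(model) {
  invisible(assignment_order(model))
}

#' Check rateOf usage restrictions
#'
#' `rateOf(x)` retrieves the rate of change of a species or rate-rule target.
#' It cannot be applied to a reaction (a reaction rate is not a state
#' variable) or to the target of an assignment rule (whose derivative is not
#' part of the ODE system).
#'
#' @param model An `ant_model`.
#' @return A list of error diagnostics; empty when every use is legal.
#' @export
ant_check_rateof <- function(model) {
  diags <- list()
  cont <- continuous_targets(model)
  for (entry in model_expressions(model)) {
    for (cl in expr_calls(entry$expr)) {
      if (cl$callee != "rateOf") next
      if (length(cl$args) != 1L || cl$args[[1]]$kind != "symbol") {
        diags[[length(diags) + 1L]] <- ant_diagnostic("error",
          "rateOf takes exactly one symbol argument")
        next
      }
      arg <- cl$args[[1]]$name
      if (!is.null(model$reactions[[arg]])) {
        diags[[length(diags) + 1L]] <- ant_diagnostic("error", sprintf(
          "rateOf cannot be applied to reaction '%s' (reaction rates have no rate of change)", arg))
      } else if (arg %in% cont) {
        diags[[length(diags) + 1L]] <- ant_diagnostic("error", sprintf(
          "rateOf cannot be applied to '%s', the target of an assignment rule", arg))
      }
    }
  }
  diags
}

#' Check that distribution draws appear only in discrete contexts
#'
#' Distribution calls may initialize a value or reset one from an event; they
#' cannot appear in kinetic laws, assignment rules, rate rules, algebraic
#' rules or event triggers, where they would be re-drawn continuously.
#'
#' @param model An `ant_model`.
#' @return A list of error diagnostics; empty when every use is legal.
#' @export
ant_check_distrib_contexts <- function(model) {
  diags <- list()
  continuous_ctx <- c("kinetic-law", "continuous-assignment", "rate-rule",
                      "algebraic-rule", "event-trigger")
  for (entry in model_expressions(model)) {
    for (cl in expr_calls(entry$expr)) {
      if (!is_distribution_call(cl)) next
      if (entry$context %in% continuous_ctx) {
        where <- if (is.na(entry$where)) entry$context else
          sprintf("%s of '%s'", entry$context, entry$where)
        diags[[length(diags) + 1L]] <- ant_diagnostic("error", sprintf(
          "distribution '%s' used in a continuous context (%s); distributions may only initialize or reset values",
          cl$callee, where))
      } else {
        diags <- c(diags, ant_validate_distribution(cl$callee, length(cl$args)))
      }
    }
  }
  diags
}

#' Run all semantic checks on a model
#'
#' @param model An `ant_model`.
#' @return All diagnostics: build warnings plus rateOf and
#'   distribution-context errors.
#' @export
ant_validate_model <- function(model) {
  c(model$diagnostics, ant_check_rateof(model), ant_check_distrib_contexts(model))
}

#' Parse and build a model from text in one step
#'
#' @param text Model text.
#' @return An `ant_model`.
#' @examples
#' m <- ant_model("J1: A + B -> C; k1*A*B\nA = 5\nB = 2\nC = 0\nk1 = 0.1")
#' names(m$reactions)
#' @export
ant_model <- function(text) {
  ant_build_model(ant_parse(text))
}

#' @export
print.ant_model <- function(x, ...) {
  cat(sprintf("<ant_model%s: %d species, %d parameters, %d reactions, %d rules, %d events>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$species), length(x$parameters), length(x$reactions),
              length(x$rules), length(x$events)))
  invisible(x)
}

participant_text <- function(p) {
  coef <- if (is.character(p$stoich)) {
    paste0(p$stoich, " ")
  } else if (p$stoich != 1) {
    paste0(format_number(p$stoich), " ")
  } else {
    ""
  }
  paste0(coef, p$species)
}

#' Render a model back to canonical language text
#'
#' The output reparses to a semantically identical model: ASCII arrows, one
#' statement per line, reactions first (always labelled), then rules in
#' source order, events, initial values, uncertainty, flux-balance
#' statements, with metadata inside the `model name() ... end` bracket.
#'
#' @param model An `ant_model`.
#' @return A single string of model text.
#' @export
ant_unparse <- function(model) {
  boundary <- function(id) isTRUE(model$species[[id]]$boundary)
  lines <- character(0)
  named <- !is.null(model$name)
  if (named) lines <- c(lines, sprintf("model %s()", model$name))
  lines <- c(lines, metadata_unparse_lines(model$metadata))
  for (r in model$reactions) {
    side <- function(ps) paste(vapply(ps, function(p) {
      paste0(if (boundary(p$species)) "$" else "", participant_text(p))
    }, character(1)), collapse = " + ")
    line <- sprintf("%s: %s -> %s", r$id, side(r$reactants), side(r$products))
    if (!is.null(r$law)) line <- paste0(line, "; ", ant_deparse_expression(r$law))
    lines <- c(lines, line)
  }
  for (ru in model$rules) {
    lines <- c(lines, switch(ru$kind,
      continuous = sprintf("%s := %s", ru$target,
                           ant_deparse_expression(ru$formula)),
      rate = sprintf("%s%s' = %s",
                     if (boundary(ru$target)) "$" else "", ru$target,
                     ant_deparse_expression(ru$formula)),
      algebraic = sprintf("%s0 = %s",
                          if (is.null(ru$name)) "" else paste0(ru$name, ": "),
                          ant_deparse_expression(ru$formula))))
  }
  for (ev in model$events) {
    lines <- c(lines, sprintf("if %s:", ant_deparse_expression(ev$trigger)))
    for (a in ev$assignments) {
      lines <- c(lines, sprintf("  %s = %s", a$target,
                                ant_deparse_expression(a$value)))
    }
  }
  cont <- continuous_targets(model)
  for (sp in model$species) {
    if (sp$id %in% cont) next
    lines <- c(lines, sprintf("%s = %s", sp$id,
                              ant_deparse_expression(sp$init)))
  }
  for (p in model$parameters) {
    if (p$id %in% cont) next
    lines <- c(lines, sprintf("%s = %s", p$id,
                              ant_deparse_expression(p$init)))
  }
  lines <- c(lines, uncertainty_unparse_lines(model))
  lines <- c(lines, fbc_unparse_lines(model))
  if (named) lines <- c(lines, "end")
  paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
}

# content view used for equality: drops diagnostics and bookkeeping flags;
# species/parameter declaration order is presentation, not meaning, so both
# are sorted by id
normalize_model <- function(model) {
  sort_by_id <- function(x) if (length(x) > 0L) x[order(names(x))] else x
  sp <- sort_by_id(model$species)
  par <- sort_by_id(model$parameters)
  strip_attrs(list(
    name = model$name,
    species = lapply(sp, function(s) s[c("id", "init", "boundary")]),
    parameters = lapply(par, function(p) p[c("id", "init", "constant")]),
    reactions = lapply(model$reactions, function(r)
      r[c("id", "reactants", "products", "law", "reversible")]),
    rules = model$rules,
    events = model$events,
    metadata = model$metadata,
    uncertainty = model$uncertainty,
    fbc = model$fbc
  ))
}

#' Compare two models for semantic equality
#'
#' Equality of content: species (with boundary flags and initial values),
#' parameters, reactions, rules, events, metadata, uncertainty and
#' flux-balance records.  Diagnostics and bookkeeping are ignored.
#'
#' @param a,b `ant_model` objects.
#' @return `TRUE` or `FALSE`.
#' @export
ant_model_equal <- function(a, b) {
  identical(normalize_model(a), normalize_model(b))
}
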