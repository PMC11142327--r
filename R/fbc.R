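# Flux balance constraints: linear objectives over reaction fluxes plus
# per-reaction bounds, as encoded by the SBML FBC package (version 1).
# No LP solver is attached: the deliverables are the records themselves,
# the folded bounds table and FBC-v1 serialization.

# decompose an objective expression into linear (coefficient, reaction) terms
objective_terms <- function(expr, loc) {
  fail <- function() {
    ant_stop("objective must be a linear combination of reaction fluxes",
             loc$line, loc$col, "ant_semantic_error")
  }
  terms <- list()
  walk <- function(node, sign) {
    if (node$kind == "binary" && node$op %in% c("+", "-")) {
      walk(node$lhs, sign)
      walk(node$rhs, if (node$op == "-") -sign else sign)
    } else if (node$kind == "unary" && node$op == "-") {
      walk(node$arg, -sign)
    } else if (node$kind == "symbol") {
      terms[[length(terms) + 1L]] <<- list(reaction = node$name,
                                           coef = sign * 1)
    } else if (node$kind == "binary" && node$op == "*") {
      lhs <- node$lhs
      rhs <- node$rhs
      if (lhs$kind == "number" && rhs$kind == "symbol") {
        terms[[length(terms) + 1L]] <<- list(reaction = rhs$name,
                                             coef = sign * lhs$value)
      } else if (lhs$kind == "symbol" && rhs$kind == "number") {
        terms[[length(terms) + 1L]] <<- list(reaction = lhs$name,
                                             coef = sign * rhs$value)
      } else {
        fail()
      }
    } else {
      fail()
    }
  }
  walk(expr, 1)
  terms
}

#' Collect flux-balance statements into a model's FBC record
#'
#' Objectives (`ID: maximize R1 + 2*R2`) and constraints
#' (`constraint c0: R16 >= 0`) are collected in source order.  Objective
#' terms and constraints must reference declared reactions.  A warning lists
#' reactions that end up without both a lower and an upper bound.
#'
#' @param model An `ant_model`.
#' @param statements Objective- and constraint-variant AST statements.
#' @return The model with `model$fbc` populated.
#' @export
ant_build_fbc <- function(model, statements) {
  for (s in statements) {
    if (identical(s$variant, "objective")) {
      terms <- objective_terms(s$expr, s$loc)
      for (t in terms) {
        if (is.null(model$reactions[[t$reaction]])) {
          ant_stop(sprintf("objective term '%s' is not a reaction", t$reaction),
                   s$loc$line, s$loc$col, "ant_semantic_error")
        }
      }
      model$fbc$objectives[[length(model$fbc$objectives) + 1L]] <-
        list(id = s$id, sense = s$sense, terms = terms)
    } else if (identical(s$variant, "constraint")) {
      if (is.null(model$reactions[[s$reaction]])) {
        ant_stop(sprintf("constraint '%s' references '%s', which is not a reaction",
                         s$id, s$reaction), s$loc$line, s$loc$col,
                 "ant_semantic_error")
      }
      ids <- vapply(model$fbc$constraints, `[[`, "", "id")
      if (s$id %in% ids) {
        ant_stop(sprintf("duplicate constraint id '%s'", s$id),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
      model$fbc$constraints[[length(model$fbc$constraints) + 1L]] <-
        list(id = s$id, reaction = s$reaction, comparator = s$comparator,
             bound = s$bound)
    }
  }
  if (length(model$fbc$objectives) > 0L || length(model$fbc$constraints) > 0L) {
    bounded <- ant_bounds_table(model$fbc)
    unbounded <- names(model$reactions)[vapply(names(model$reactions), function(id) {
      b <- bounded[[id]]
      is.null(b) || is.infinite(b[1]) || is.infinite(b[2])
    }, TRUE)]
    if (length(unbounded) > 0L) {
      model <- add_warning(model, sprintf(
        "reactions without both a finite lower and upper flux bound: %s",
        paste(unbounded, collapse = ", ")))
    }
  }
  model
}

#' Fold flux constraints into per-reaction bounds
#'
#' For each reaction, the lower bound is the tightest (largest) `>=`
#' constraint and the upper bound the tightest (smallest) `<=` constraint;
#' `=` sets both.  Unconstrained sides default to minus/plus infinity.
#'
#' @param fbc An FBC record (`model$fbc`).
#' @return A named list mapping reaction id to `c(lower, upper)`.
#' @examples
#' m <- ant_model("R1: A -> B\nconstraint c0: R1 >= 0\nconstraint c1: R1 <= 10")
#' ant_bounds_table(m$fbc)
#' @export
ant_bounds_table <- function(fbc) {
  out <- list()
  for (cn in fbc$constraints) {
    b <- out[[cn$reaction]]
    if (is.null(b)) b <- c(-Inf, Inf)
    if (cn$comparator == ">=") {
      b[1] <- max(b[1], cn$bound)
    } else if (cn$comparator == "<=") {
      b[2] <- min(b[2], cn$bound)
    } else {
      b[1] <- max(b[1], cn$bound)
      b[2] <- min(b[2], cn$bound)
    }
    out[[cn$reaction]] <- b
  }
  for (id in names(out)) {
    if (out[[id]][1] > out[[id]][2]) {
      ant_stop(sprintf("infeasible flux bounds for reaction '%s': lower %g > upper %g",
                       id, out[[id]][1], out[[id]][2]),
               NA, NA, "ant_semantic_error")
    }
  }
  out
}

objective_expr_text <- function(obj) {
  parts <- character(0)
  for (i in seq_along(obj$terms)) {
    t <- obj$terms[[i]]
    mag <- abs(t$coef)
    core <- if (mag == 1) t$reaction else
      paste0(format_number(mag), "*", t$reaction)
    if (i == 1L) {
      parts <- if (t$coef < 0) paste0("-", core) else core
    } else {
      parts <- paste0(parts, if (t$coef < 0) " - " else " + ", core)
    }
  }
  parts
}

fbc_unparse_lines <- function(model) {
  lines <- character(0)
  for (obj in model$fbc$objectives) {
    lines <- c(lines, sprintf("%s: %s %s", obj$id, obj$sense,
                              objective_expr_text(obj)))
  }
  for (cn in model$fbc$constraints) {
    lines <- c(lines, sprintf("constraint %s: %s %s %s", cn$id, cn$reaction,
                              cn$comparator, format_number(cn$bound)))
  }
  lines
}
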