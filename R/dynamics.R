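# Numerical semantics: compile a model into an ODE + event system.
#
# State variables are the non-boundary species that take part in reactions
# plus every rate-rule target.  Continuous assignments are applied, in
# dependency order, before any rate is evaluated, so forcing functions hold
# exactly at every output point.  `rateOf(x)` evaluates the RHS component
# for x on demand.  Events are edge-triggered (false -> true), localised by
# bisection, and re-arm only after their trigger returns to false.
#
# Integrator: deSolve::lsoda, relative tolerance 1e-8, absolute 1e-12 —
# tight enough that closed-form checks at 1e-6 relative error are meaningful.

# map language-level function names onto their R evaluators
EVAL_FUNS <- list(
  sin = sin, cos = cos, tan = tan, asin = asin, acos = acos, atan = atan,
  sinh = sinh, cosh = cosh, tanh = tanh, exp = exp,
  ln = log, log = log10, log10 = log10,
  sqrt = sqrt, abs = abs, ceil = ceiling, ceiling = ceiling, floor = floor
)

# AST -> R call object, evaluated later in the system environment
to_r_call <- function(node) {
  switch(node$kind,
    number = node$value,
    symbol = as.name(node$name),
    time = as.name("time"),
    unary = call("-", to_r_call(node$arg)),
    binary = do.call(call, c(list(node$op), lapply(list(node$lhs, node$rhs),
                                                   to_r_call)), quote = TRUE),
    call = as.call(c(list(as.name(node$callee)), lapply(node$args, to_r_call))),
    stop("cannot compile expression node of kind ", node$kind))
}

#' Compile a model into an executable ODE + event system
#'
#' @param model A validated `ant_model`.  Models containing algebraic rules
#'   cannot be simulated (they are serialization-only) and raise
#'   `ant_not_simulatable`; rateOf- and distribution-placement violations
#'   are also fatal here.
#' @return An object of class `ant_system`.
#' @examples
#' sys <- ant_compile(ant_model(ant_listing(1)))
#' sys$state_ids
#' @export
ant_compile <- function(model) {
  if (any(vapply(model$rules, function(r) r$kind == "algebraic", TRUE))) {
    ant_stop("model contains algebraic rules, which this engine does not simulate",
             class = "ant_not_simulatable")
  }
  errs <- c(diag_errors(ant_check_rateof(model)),
            diag_errors(ant_check_distrib_contexts(model)))
  if (length(errs) > 0L) {
    ant_stop(paste("model fails validation:", errs[[1]]$message),
             class = "ant_not_simulatable")
  }
  cont_rules <- assignment_order(model)
  cont <- vapply(cont_rules, `[[`, "", "target")
  rr <- Filter(function(r) r$kind == "rate", model$rules)
  rate_tgts <- vapply(rr, `[[`, "", "target")

  in_rxn <- species_in_reactions(model)
  state_ids <- character(0)
  for (sp in model$species) {
    if (sp$id %in% in_rxn && !sp$boundary && !(sp$id %in% cont)) {
      state_ids <- c(state_ids, sp$id)
    }
  }
  state_ids <- unique(c(state_ids, rate_tgts))

  # reaction-derived stoichiometry contributions per species
  contribs <- list()
  for (ri in seq_along(model$reactions)) {
    r <- model$reactions[[ri]]
    for (p in r$reactants) {
      contribs[[length(contribs) + 1L]] <-
        list(species = p$species, rxn = ri, sign = -1, stoich = p$stoich)
    }
    for (p in r$products) {
      contribs[[length(contribs) + 1L]] <-
        list(species = p$species, rxn = ri, sign = 1, stoich = p$stoich)
    }
  }

  output_ids <- unique(c(names(model$species), rate_tgts, cont,
                         names(model$parameters)))

  structure(list(
    model = model,
    state_ids = state_ids,
    rate_rules = lapply(rr, function(r) list(target = r$target,
                                             code = to_r_call(r$formula))),
    assignments = lapply(cont_rules, function(r) list(target = r$target,
                                                      code = to_r_call(r$formula))),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, code = if (is.null(r$law)) 0 else to_r_call(r$law))
    }),
    contribs = contribs,
    events = lapply(model$events, function(ev) {
      list(trigger = to_r_call(ev$trigger),
           assignments = lapply(ev$assignments, function(a) {
             list(target = a$target, code = to_r_call(a$value))
           }))
    }),
    output_ids = output_ids
  ), class = "ant_system")
}

# evaluation environment holding symbol values, time and functions
new_eval_env <- function(sys, rng = NULL) {
  e <- new.env(parent = baseenv())
  for (fn in names(EVAL_FUNS)) assign(fn, EVAL_FUNS[[fn]], e)
  if (!is.null(rng)) {
    for (dn in names(DIST_TABLE)) {
      local({
        nm <- dn
        assign(nm, function(...) ant_sample_distribution(nm, c(...), rng), e)
      })
    }
  }
  e$time <- 0
  e$.rateof_stack <- character(0)
  e$rateOf <- function(x) {
    sym <- as.character(substitute(x))
    rate_of_symbol(sys, e, sym)
  }
  environment(e$rateOf) <- list2env(list(sys = sys, e = e,
                                         rate_of_symbol = rate_of_symbol),
                                    parent = baseenv())
  e
}

# RHS component for one symbol, honouring the rateOf restrictions
rate_of_symbol <- function(sys, e, sym) {
  model <- sys$model
  if (!is.null(model$reactions[[sym]])) {
    ant_stop(sprintf("rateOf cannot be applied to reaction '%s'", sym),
             class = "ant_restriction_error")
  }
  cont <- vapply(sys$assignments, `[[`, "", "target")
  if (sym %in% cont) {
    ant_stop(sprintf("rateOf cannot be applied to assignment-rule target '%s'", sym),
             class = "ant_restriction_error")
  }
  if (sym %in% e$.rateof_stack) {
    ant_stop(sprintf("circular rateOf evaluation at '%s'", sym),
             class = "ant_restriction_error")
  }
  e$.rateof_stack <- c(e$.rateof_stack, sym)
  on.exit(e$.rateof_stack <- setdiff(e$.rateof_stack, sym))
  for (rrule in sys$rate_rules) {
    if (rrule$target == sym) return(eval(rrule$code, e))
  }
  sp <- model$species[[sym]]
  if (!is.null(sp) && sp$boundary) return(0)
  if (is.null(sp)) return(0)  # constant parameter
  total <- 0
  for (cn in sys$contribs) {
    if (cn$species != sym) next
    rate <- eval(sys$reactions[[cn$rxn]]$code, e)
    st <- if (is.character(cn$stoich)) get(cn$stoich, e) else cn$stoich
    total <- total + cn$sign * st * rate
  }
  total
}

apply_assignments <- function(sys, e) {
  for (a in sys$assignments) assign(a$target, eval(a$code, e), e)
}

# derivatives of the state vector given values already loaded into e
state_derivatives <- function(sys, e) {
  vapply(sys$state_ids, function(sym) rate_of_symbol(sys, e, sym), numeric(1))
}

load_state <- function(e, state) {
  for (nm in names(state)) assign(nm, unname(state[[nm]]), e)
}

#' Evaluate the rate of change of a symbol
#'
#' Returns the right-hand-side component for a species (the
#' stoichiometry-weighted sum of its reaction rates) or a rate-rule target
#' (its rate formula) at the given time and state.  Applying it to a
#' reaction or to an assignment-rule target is an error, mirroring the
#' rateOf restrictions in the language.
#'
#' @param sys An `ant_system` from [ant_compile()].
#' @param symbol The symbol name.
#' @param t Time point.
#' @param state Named numeric vector of symbol values (state variables and
#'   any boundary/parameter overrides); missing symbols take their initial
#'   values.
#' @return The instantaneous rate of change, a numeric scalar.
#' @export
ant_rate_of <- function(sys, symbol, t = 0, state = numeric(0)) {
  e <- new_eval_env(sys)
  init <- initial_values(sys, rng = NULL)
  load_state(e, init)
  e$time <- t
  load_state(e, state)
  apply_assignments(sys, e)
  rate_of_symbol(sys, e, symbol)
}

# dependency-ordered initial values for all non-continuous symbols;
# distribution draws are taken from `rng` (once, at time zero)
initial_values <- function(sys, rng) {
  model <- sys$model
  cont <- vapply(sys$assignments, `[[`, "", "target")
  entries <- list()
  for (sp in model$species) {
    if (!(sp$id %in% cont)) entries[[sp$id]] <- sp$init
  }
  for (p in model$parameters) {
    if (!(p$id %in% cont)) entries[[p$id]] <- p$init
  }
  ordered <- character(0)
  remaining <- names(entries)
  deps <- lapply(entries, function(x) intersect(expr_symbols(x), names(entries)))
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(s) {
      length(setdiff(setdiff(deps[[s]], s), ordered)) == 0L
    }, TRUE)]
    if (length(ready) == 0L) {
      ant_stop(sprintf("circular initial assignments involving: %s",
                       paste(sort(remaining), collapse = ", ")),
               class = "ant_semantic_error")
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  e <- new_eval_env(sys, rng)
  vals <- numeric(0)
  for (sym in ordered) {
    v <- eval(to_r_call(entries[[sym]]), e)
    assign(sym, v, e)
    vals[[sym]] <- v
  }
  vals
}

#' Simulate a compiled system
#'
#' Distribution draws in initial assignments are sampled once at time zero
#' from a stream seeded with `seed`; event assignments may draw again when
#' they fire.  Event triggers are edge-detected between output points and
#' localised by bisection to a tolerance of `1e-9 * t_end`; assignments are
#' applied atomically in listed order.  The same seed always yields the
#' identical trajectory and event log.
#'
#' @param sys An `ant_system` (or an `ant_model`, compiled on the fly).
#' @param t_end End time (> 0); output starts at 0.
#' @param n_points Number of equally spaced output points (>= 2).
#' @param seed Integer seed for all stochastic draws.
#' @return An `ant_trajectory`: list with `times`, a `values` matrix (one
#'   column per reported symbol) and an `events` data frame of firing times.
#' @examples
#' tr <- ant_simulate(ant_model(ant_listing(1)), t_end = 10, n_points = 11)
#' tr$values[11, "A"]  # ~ 5*exp(-0.1*10)
#' @export
ant_simulate <- function(sys, t_end, n_points = 101L, seed = 0L) {
  if (inherits(sys, "ant_model")) sys <- ant_compile(sys)
  stopifnot(inherits(sys, "ant_system"), t_end > 0, n_points >= 2)
  rng <- ant_rng(seed)
  e <- new_eval_env(sys, rng = NULL)

  init <- initial_values(sys, rng)
  load_state(e, init)
  e$time <- 0
  apply_assignments(sys, e)

  times <- seq(0, t_end, length.out = n_points)
  tol <- 1e-9 * t_end
  n_ev <- length(sys$events)
  trigger_val <- function() {
    vapply(sys$events, function(ev) isTRUE(eval(ev$trigger, e)), TRUE)
  }
  armed <- !trigger_val()
  event_log <- list()

  state <- vapply(sys$state_ids, function(s) get(s, e), numeric(1))
  has_state <- length(state) > 0L

  deriv_fn <- function(t, y, parms) {
    e$time <- t
    if (has_state) load_state(e, stats::setNames(y, sys$state_ids))
    apply_assignments(sys, e)
    list(state_derivatives(sys, e))
  }
  integrate_to <- function(y, t0, t1) {
    if (!has_state || t1 <= t0) return(y)
    out <- deSolve::lsoda(y = y, times = c(t0, t1), func = deriv_fn,
                          parms = NULL, rtol = 1e-8, atol = 1e-12)
    if (nrow(out) < 2L) {
      ant_stop(sprintf("integration failed at time %g", out[nrow(out), 1]),
               class = "ant_solver_error")
    }
    stats::setNames(as.numeric(out[2L, -1L]), sys$state_ids)
  }
  # load `y` at time `t` and refresh assignment targets
  sync <- function(t, y) {
    e$time <- t
    if (has_state) load_state(e, y)
    apply_assignments(sys, e)
  }

  values <- matrix(NA_real_, nrow = n_points, ncol = length(sys$output_ids),
                   dimnames = list(NULL, sys$output_ids))
  record <- function(i) {
    for (nm in sys$output_ids) values[i, nm] <<- get(nm, e)
  }
  record(1L)

  t_cur <- times[1]
  for (i in seq_len(n_points - 1L)) {
    t_target <- times[i + 1L]
    repeat {
      y0 <- if (has_state) vapply(sys$state_ids, function(s) get(s, e), numeric(1)) else numeric(0)
      t0 <- t_cur
      y1 <- integrate_to(y0, t0, t_target)
      sync(t_target, y1)
      trig <- trigger_val()
      fired_idx <- which(armed & trig)
      if (n_ev == 0L || length(fired_idx) == 0L) {
        armed <- armed | !trig
        t_cur <- t_target
        break
      }
      # locate the earliest false->true crossing by bisection
      locate <- function(k) {
        lo <- t0
        hi <- t_target
        while (hi - lo > tol) {
          mid <- (lo + hi) / 2
          ym <- integrate_to(y0, t0, mid)
          sync(mid, ym)
          if (isTRUE(eval(sys$events[[k]]$trigger, e))) hi <- mid else lo <- mid
        }
        hi
      }
      t_fires <- vapply(fired_idx, locate, numeric(1))
      k_first <- fired_idx[which.min(t_fires)]
      t_fire <- min(t_fires)
      yf <- integrate_to(y0, t0, t_fire)
      sync(t_fire, yf)
      # atomic application: all RHS evaluated against the pre-event state
      ev <- sys$events[[k_first]]
      rhs_env <- new_eval_env(sys, rng)
      for (nm in c(sys$output_ids, names(init))) {
        if (exists(nm, e, inherits = FALSE)) assign(nm, get(nm, e), rhs_env)
      }
      rhs_env$time <- t_fire
      new_vals <- vapply(ev$assignments, function(a) eval(a$code, rhs_env),
                         numeric(1))
      for (j in seq_along(ev$assignments)) {
        assign(ev$assignments[[j]]$target, new_vals[[j]], e)
      }
      apply_assignments(sys, e)
      armed[k_first] <- FALSE
      trig_now <- trigger_val()
      armed <- armed | !trig_now
      event_log[[length(event_log) + 1L]] <-
        list(time = t_fire, event = k_first)
      t_cur <- t_fire
      if (t_cur >= t_target - tol) {
        sync(t_target, if (has_state) vapply(sys$state_ids, function(s) get(s, e), numeric(1)) else numeric(0))
        t_cur <- t_target
        break
      }
    }
    record(i + 1L)
  }

  events_df <- if (length(event_log) > 0L) {
    data.frame(time = vapply(event_log, `[[`, 0, "time"),
               event = vapply(event_log, `[[`, 0L, "event"))
  } else {
    data.frame(time = numeric(0), event = integer(0))
  }
  structure(list(times = times, values = values, events = events_df),
            class = "ant_trajectory")
}

#' @export
print.ant_trajectory <- function(x, ...) {
  cat(sprintf("<ant_trajectory: %d points over [%g, %g], %d symbols, %d event firings>\n",
              length(x$times), min(x$times), max(x$times), ncol(x$values),
              nrow(x$events)))
  invisible(x)
}

#' @export
as.data.frame.ant_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$values, check.names = FALSE)
}
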