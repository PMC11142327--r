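# Probability-distribution calls and uncertainty attributes.
#
# Distribution draws may appear only in discrete contexts (initial
# assignments and event assignments), never in kinetic laws or continuous
# rules.  Each family has a fixed base arity; all families except `uniform`
# and `bernoulli` additionally accept a truncated form with two extra
# arguments `min, max`, realised by rejection sampling.

# base arities; truncatable families accept base + 2 arguments
DIST_TABLE <- list(
  normal = list(arity = 2L, truncatable = TRUE),
  uniform = list(arity = 2L, truncatable = FALSE),
  bernoulli = list(arity = 1L, truncatable = FALSE),
  binomial = list(arity = 2L, truncatable = TRUE),
  cauchy = list(arity = 2L, truncatable = TRUE),
  chisquare = list(arity = 1L, truncatable = TRUE),
  exponential = list(arity = 1L, truncatable = TRUE),
  gamma = list(arity = 2L, truncatable = TRUE),
  laplace = list(arity = 2L, truncatable = TRUE),
  lognormal = list(arity = 2L, truncatable = TRUE),
  poisson = list(arity = 1L, truncatable = TRUE),
  rayleigh = list(arity = 1L, truncatable = TRUE)
)

#' Names of the supported distribution families
#' @return Character vector of the 12 family names.
#' @export
ant_distribution_names <- function() names(DIST_TABLE)

is_distribution_call <- function(node) {
  node$kind == "call" && node$callee %in% names(DIST_TABLE)
}

#' Validate a distribution call's name and arity
#'
#' @param name Family name, e.g. `"normal"`.
#' @param n_args Number of arguments in the call.
#' @param line,col Optional source position for the diagnostics.
#' @return A list of diagnostics; empty when the signature is valid.
#' @examples
#' ant_validate_distribution("uniform", 2)  # valid: empty
#' ant_validate_distribution("normal", 1)   # arity error
#' @export
ant_validate_distribution <- function(name, n_args, line = NA, col = NA) {
  entry <- DIST_TABLE[[name]]
  if (is.null(entry)) {
    return(list(ant_diagnostic("error",
      sprintf("unknown distribution '%s'", name), line, col)))
  }
  ok <- n_args == entry$arity ||
    (entry$truncatable && n_args == entry$arity + 2L)
  if (!ok) {
    allowed <- if (entry$truncatable) {
      sprintf("%d or %d", entry$arity, entry$arity + 2L)
    } else {
      as.character(entry$arity)
    }
    return(list(ant_diagnostic("error",
      sprintf("distribution '%s' takes %s arguments, got %d",
              name, allowed, n_args), line, col)))
  }
  list()
}

#' Create a reproducible random-number stream
#'
#' An isolated Mersenne-Twister stream: draws taken through it never touch
#' (and are never affected by) the global `.Random.seed`, so two streams with
#' the same seed always produce the same draw sequence.
#'
#' @param seed Integer seed.
#' @return An object of class `ant_rng`.
#' @export
ant_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$algorithm <- "Mersenne-Twister"
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(env$seed, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else {
    rm(".Random.seed", envir = globalenv())
  }
  class(env) <- "ant_rng"
  env
}

# run a draw inside the stream's state, leaving the global RNG untouched
with_rng <- function(rng, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else {
      rm(".Random.seed", envir = globalenv())
    }
  })
  fn()
}

draw_base <- function(name, args) {
  bad <- function(msg) ant_stop(msg, class = "ant_sample_error")
  switch(name,
    normal = {
      if (args[2] < 0) bad("normal: standard deviation must be >= 0")
      if (args[2] == 0) args[1] else stats::rnorm(1, args[1], args[2])
    },
    uniform = {
      if (args[1] > args[2]) bad("uniform: min must be <= max")
      stats::runif(1, args[1], args[2])
    },
    bernoulli = {
      if (args[1] < 0 || args[1] > 1) bad("bernoulli: probability must be in [0, 1]")
      as.numeric(stats::rbinom(1, 1L, args[1]))
    },
    binomial = {
      if (args[1] < 0 || args[1] != round(args[1])) bad("binomial: nTrials must be a non-negative integer")
      if (args[2] < 0 || args[2] > 1) bad("binomial: probability must be in [0, 1]")
      as.numeric(stats::rbinom(1, as.integer(args[1]), args[2]))
    },
    cauchy = {
      if (args[2] < 0) bad("cauchy: scale must be >= 0")
      if (args[2] == 0) args[1] else stats::rcauchy(1, args[1], args[2])
    },
    chisquare = {
      if (args[1] <= 0) bad("chisquare: degrees of freedom must be > 0")
      stats::rchisq(1, args[1])
    },
    exponential = {
      if (args[1] <= 0) bad("exponential: rate must be > 0")
      stats::rexp(1, args[1])
    },
    gamma = {
      if (args[1] <= 0 || args[2] <= 0) bad("gamma: shape and scale must be > 0")
      stats::rgamma(1, shape = args[1], scale = args[2])
    },
    laplace = {
      if (args[2] < 0) bad("laplace: scale must be >= 0")
      u <- stats::runif(1, -0.5, 0.5)
      args[1] - args[2] * sign(u) * log(1 - 2 * abs(u))
    },
    lognormal = {
      # parameters are on the log scale (mean and sd of the underlying normal)
      if (args[2] < 0) bad("lognormal: log-scale sd must be >= 0")
      stats::rlnorm(1, meanlog = args[1], sdlog = args[2])
    },
    poisson = {
      if (args[1] < 0) bad("poisson: rate must be >= 0")
      as.numeric(stats::rpois(1, args[1]))
    },
    rayleigh = {
      if (args[1] < 0) bad("rayleigh: scale must be >= 0")
      args[1] * sqrt(-2 * log(stats::runif(1)))
    },
    bad(sprintf("unknown distribution '%s'", name)))
}

#' Draw one value from a distribution call
#'
#' Truncated forms (two extra `min, max` arguments) are realised by rejection
#' sampling with an iteration cap, so every draw lies inside `[min, max]`.
#'
#' @param name Distribution family name.
#' @param args Numeric argument vector (base arity or base arity + 2).
#' @param rng An [ant_rng()] stream.
#' @return One numeric draw.
#' @examples
#' rng <- ant_rng(1)
#' ant_sample_distribution("uniform", c(2.5, 5.5), rng)
#' @export
ant_sample_distribution <- function(name, args, rng) {
  diags <- ant_validate_distribution(name, length(args))
  if (length(diags) > 0L) {
    ant_stop(diags[[1]]$message, class = "ant_sample_error")
  }
  entry <- DIST_TABLE[[name]]
  base <- args[seq_len(entry$arity)]
  with_rng(rng, function() {
    if (length(args) == entry$arity) {
      return(draw_base(name, base))
    }
    lo <- args[entry$arity + 1L]
    hi <- args[entry$arity + 2L]
    if (!(lo < hi)) {
      ant_stop(sprintf("%s: truncation requires min < max", name),
               class = "ant_sample_error")
    }
    for (i in seq_len(1e6)) {
      x <- draw_base(name, base)
      if (x >= lo && x <= hi) return(x)
    }
    ant_stop(sprintf("%s: rejection sampling exceeded 1e6 iterations for bounds [%g, %g]",
                     name, lo, hi), class = "ant_sample_error")
  })
}

# ---- uncertainty records ----------------------------------------------------

empty_uncertainty <- function() {
  list(scalars = list(), intervals = list(), distribution = NULL,
       externalParameter = NULL)
}

# canonical slot for the stdev/standardDeviation alias pair
canonical_uncert_attr <- function(attribute) {
  if (attribute == "standardDeviation") "stdev" else attribute
}

#' Attach uncertainty statements to a model
#'
#' Statements of the forms `A.mean = x`, `A.confidenceInterval = {x, y}`,
#' `A.distribution = normal(0, 1)` and `A.distribution is "http://uri"`
#' populate per-symbol uncertainty records.  `A` may be any symbol with
#' mathematical meaning (species, parameter or reaction).
#'
#' @param model An `ant_model`.
#' @param statements Uncertainty-variant AST statements.
#' @return The model with its `uncertainty` map populated.
#' @export
ant_attach_uncertainty <- function(model, statements) {
  for (s in statements) {
    stopifnot(identical(s$variant, "uncertainty"))
    tgt <- s$target
    if (!symbol_exists(model, tgt)) {
      model <- declare_parameter(model, tgt)
      model$diagnostics <- c(model$diagnostics, list(ant_diagnostic("warning",
        sprintf("uncertainty target '%s' was not declared; created as a parameter with value 0", tgt),
        s$loc$line, s$loc$col)))
    }
    rec <- model$uncertainty[[tgt]]
    if (is.null(rec)) rec <- empty_uncertainty()
    attr_name <- canonical_uncert_attr(s$attribute)
    if (attr_name %in% c(UNCERTAINTY_SCALAR_ATTRS[UNCERTAINTY_SCALAR_ATTRS != "standardDeviation"])) {
      if (!identical(s$form, "scalar")) {
        ant_stop(sprintf("uncertainty attribute '%s' takes a scalar value", s$attribute),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
      rec$scalars[[attr_name]] <- s$value
    } else if (attr_name %in% UNCERTAINTY_PAIR_ATTRS) {
      if (!identical(s$form, "pair")) {
        ant_stop(sprintf("uncertainty attribute '%s' takes an interval {x, y}", s$attribute),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
      rec$intervals[[attr_name]] <- list(lower = s$lower, upper = s$upper)
    } else if (attr_name %in% UNCERTAINTY_FREE_ATTRS) {
      rec[[attr_name]] <- switch(s$form,
        uri = list(form = "uri", uri = s$uri),
        pair = list(form = "pair", lower = s$lower, upper = s$upper),
        list(form = "formula", value = s$value))
      if (attr_name == "distribution" && !identical(s$form, "uri") &&
          !identical(s$form, "pair")) {
        calls <- expr_calls(s$value)
        for (cl in calls) {
          for (d in ant_validate_distribution(cl$callee, length(cl$args),
                                              s$loc$line, s$loc$col)) {
            model$diagnostics <- c(model$diagnostics, list(d))
          }
        }
      }
    } else {
      ant_stop(sprintf("unknown uncertainty attribute '%s'", s$attribute),
               s$loc$line, s$loc$col, "ant_semantic_error")
    }
    model$uncertainty[[tgt]] <- rec
  }
  model
}

uncertainty_unparse_lines <- function(model) {
  lines <- character(0)
  scalar_order <- setdiff(UNCERTAINTY_SCALAR_ATTRS, "standardDeviation")
  for (tgt in names(model$uncertainty)) {
    rec <- model$uncertainty[[tgt]]
    for (a in scalar_order) {
      if (!is.null(rec$scalars[[a]])) {
        lines <- c(lines, sprintf("%s.%s = %s", tgt, a,
                                  ant_deparse_expression(rec$scalars[[a]])))
      }
    }
    for (a in UNCERTAINTY_PAIR_ATTRS) {
      iv <- rec$intervals[[a]]
      if (!is.null(iv)) {
        lines <- c(lines, sprintf("%s.%s = {%s, %s}", tgt, a,
                                  ant_deparse_expression(iv$lower),
                                  ant_deparse_expression(iv$upper)))
      }
    }
    for (a in UNCERTAINTY_FREE_ATTRS) {
      v <- rec[[a]]
      if (is.null(v)) next
      lines <- c(lines, switch(v$form,
        uri = sprintf("%s.%s is \"%s\"", tgt, a, v$uri),
        pair = sprintf("%s.%s = {%s, %s}", tgt, a,
                       ant_deparse_expression(v$lower),
                       ant_deparse_expression(v$upper)),
        sprintf("%s.%s = %s", tgt, a, ant_deparse_expression(v$value))))
    }
  }
  lines
}
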