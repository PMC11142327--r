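# Statement parser: token stream -> AST statements with source locations.
#
# Statements are separated by newline or `;`.  The one subtlety is the
# reaction form `A -> B; k1*A`, where the first `;` after an arrow introduces
# the kinetic law rather than ending the statement; any later `;` (or the
# newline) ends it.  Event bodies are delimited by indentation: `if expr:` is
# followed by the maximal run of more-indented assignment statements.

split_statement_groups <- function(tokens) {
  groups <- list()
  cur <- list()
  has_arrow <- FALSE
  law_semi <- FALSE
  flush <- function() {
    if (length(cur) > 0L) groups[[length(groups) + 1L]] <<- cur
    cur <<- list()
    has_arrow <<- FALSE
    law_semi <<- FALSE
  }
  for (tok in tokens) {
    if (tok$kind == "NEWLINE") {
      flush()
    } else if (tok$kind == "SEMI") {
      if (has_arrow && !law_semi) {
        law_semi <- TRUE
        cur[[length(cur) + 1L]] <- tok
      } else {
        flush()
      }
    } else {
      if (tok$kind == "ARROW") has_arrow <- TRUE
      cur[[length(cur) + 1L]] <- tok
    }
  }
  flush()
  groups
}

stmt <- function(variant, loc, ...) {
  c(list(variant = variant, loc = loc), list(...))
}

group_loc <- function(group) list(line = group[[1]]$line, col = group[[1]]$col)

METADATA_SCALAR_KEYS <- c("model_source", "publication", "biological_system",
                          "taxon", "created", "modified", "notes")
CREATOR_FIELDS <- c("givenName", "familyName", "organization", "email")

UNCERTAINTY_SCALAR_ATTRS <- c("mean", "stdev", "standardDeviation",
                              "coefficientOfVariation", "kurtosis", "median",
                              "mode", "sampleSize", "skewness",
                              "standardError", "variance")
UNCERTAINTY_PAIR_ATTRS <- c("confidenceInterval", "credibleInterval",
                            "interquartileRange", "range")
UNCERTAINTY_FREE_ATTRS <- c("distribution", "externalParameter")

# fold an expression that must be a numeric constant (`inf` allowed)
eval_const_expr <- function(node, loc) {
  v <- switch(node$kind,
    number = node$value,
    symbol = if (tolower(node$name) %in% c("inf", "infinity")) Inf else NA_real_,
    unary = -eval_const_expr(node$arg, loc),
    binary = {
      l <- eval_const_expr(node$lhs, loc)
      r <- eval_const_expr(node$rhs, loc)
      switch(node$op, "+" = l + r, "-" = l - r, "*" = l * r,
             "/" = l / r, "^" = l^r, NA_real_)
    },
    NA_real_)
  if (is.na(v) && !is.nan(v)) {
    ant_stop("expected a numeric constant", loc$line, loc$col, "ant_parse_error")
  }
  v
}

parse_participants <- function(ts, stop_kinds) {
  parts <- list()
  if (ts_kind(ts) %in% stop_kinds || ts_at_end(ts)) return(parts)
  repeat {
    stoich <- 1
    symbolic <- FALSE
    boundary <- FALSE
    if (ts_kind(ts) == "NUMBER") {
      stoich <- ts_next(ts)$value
    } else if (ts_kind(ts) == "ID" && ts_kind(ts, 1L) %in% c("ID", "DOLLAR")) {
      stoich <- ts_next(ts)$text
      symbolic <- TRUE
    }
    if (ts_kind(ts) == "DOLLAR") {
      ts_next(ts)
      boundary <- TRUE
    }
    sp <- ts_expect(ts, "ID", "a species identifier")
    parts[[length(parts) + 1L]] <- list(
      species = sp$text, stoich = stoich, symbolic = symbolic,
      boundary = boundary)
    if (ts_kind(ts) == "PLUS") ts_next(ts) else break
  }
  parts
}

parse_reaction_group <- function(group, loc) {
  ts <- new_tok_stream(group)
  name <- NULL
  if (ts_kind(ts) == "ID" && ts_kind(ts, 1L) == "COLON") {
    name <- ts_next(ts)$text
    ts_next(ts)
  }
  reactants <- parse_participants(ts, "ARROW")
  ts_expect(ts, "ARROW", "'->'")
  products <- parse_participants(ts, "SEMI")
  law <- NULL
  if (ts_kind(ts) == "SEMI") {
    ts_next(ts)
    if (!ts_at_end(ts)) {
      law <- parse_expr_tokens(ts)
    }
  }
  if (!ts_at_end(ts)) {
    tok <- ts_peek(ts)
    ant_stop(sprintf("unexpected '%s' after reaction", tok$text),
             tok$line, tok$col, "ant_parse_error")
  }
  stmt("reaction", loc, name = name, reactants = reactants,
       products = products, law = law)
}

parse_statement_group <- function(group) {
  loc <- group_loc(group)
  kinds <- vapply(group, `[[`, "", "kind")
  texts <- vapply(group, `[[`, "", "text")
  first <- group[[1]]

  if (first$kind == "ID" && first$text == "model") {
    if (length(group) == 4L && kinds[2] == "ID" && kinds[3] == "LPAREN" &&
        kinds[4] == "RPAREN") {
      return(stmt("model-begin", loc, name = texts[2]))
    }
    # metadata: model <keyword> "value"  or  model creatorN.<field> "value"
    ts <- new_tok_stream(group)
    ts_next(ts)
    key_tok <- ts_expect(ts, "ID", "a metadata keyword")
    key <- key_tok$text
    if (ts_kind(ts) == "DOT") {
      ts_next(ts)
      field <- ts_expect(ts, "ID", "a creator field")
      key <- paste0(key, ".", field$text)
    }
    val <- ts_expect(ts, "STRING", "a quoted string")
    if (!ts_at_end(ts)) {
      tok <- ts_peek(ts)
      ant_stop(sprintf("unexpected '%s' after metadata value", tok$text),
               tok$line, tok$col, "ant_parse_error")
    }
    return(stmt("metadata", loc, key = key, value = val$value))
  }

  if (first$kind == "ID" && first$text == "end" && length(group) == 1L) {
    return(stmt("model-end", loc))
  }

  if (first$kind == "ID" && first$text == "constraint") {
    ts <- new_tok_stream(group)
    ts_next(ts)
    id <- ts_expect(ts, "ID", "a constraint id")$text
    ts_expect(ts, "COLON", "':'")
    rxn <- ts_expect(ts, "ID", "a reaction id")$text
    cmp_tok <- ts_next(ts)
    if (is.null(cmp_tok) || !cmp_tok$kind %in% c("GE", "LE", "ASSIGN")) {
      ant_stop("expected '<=', '>=' or '=' in constraint",
               loc$line, loc$col, "ant_parse_error")
    }
    comparator <- switch(cmp_tok$kind, GE = ">=", LE = "<=", ASSIGN = "=")
    bound <- eval_const_expr(parse_expr_tokens(ts), loc)
    if (!ts_at_end(ts)) {
      tok <- ts_peek(ts)
      ant_stop(sprintf("unexpected '%s' after constraint", tok$text),
               tok$line, tok$col, "ant_parse_error")
    }
    return(stmt("constraint", loc, id = id, reaction = rxn,
                comparator = comparator, bound = bound))
  }

  if (first$kind == "ID" && first$text == "if") {
    ts <- new_tok_stream(group)
    ts_next(ts)
    trigger <- parse_expr_tokens(ts)
    ts_expect(ts, "COLON", "':' after event trigger")
    if (!ts_at_end(ts)) {
      tok <- ts_peek(ts)
      ant_stop(sprintf("unexpected '%s' after event trigger", tok$text),
               tok$line, tok$col, "ant_parse_error")
    }
    return(stmt("event-header", loc, trigger = trigger))
  }

  if (length(group) >= 3L && kinds[1] == "ID" && kinds[2] == "COLON" &&
      kinds[3] == "ID" && texts[3] %in% c("maximize", "minimize")) {
    ts <- new_tok_stream(group[-(1:3)])
    expr <- parse_expr_tokens(ts)
    if (!ts_at_end(ts)) {
      tok <- ts_peek(ts)
      ant_stop(sprintf("unexpected '%s' after objective", tok$text),
               tok$line, tok$col, "ant_parse_error")
    }
    return(stmt("objective", loc, id = texts[1], sense = texts[3], expr = expr))
  }

  if ("ARROW" %in% kinds) {
    return(parse_reaction_group(group, loc))
  }

  # algebraic rule: [name:] 0 = formula
  alg_off <- if (length(group) >= 2L && kinds[1] == "ID" && kinds[2] == "COLON") 2L else 0L
  if (length(group) >= alg_off + 2L && kinds[alg_off + 1L] == "NUMBER" &&
      group[[alg_off + 1L]]$value == 0 && kinds[alg_off + 2L] == "ASSIGN") {
    ts <- new_tok_stream(group[-seq_len(alg_off + 2L)])
    formula <- parse_expr_tokens(ts)
    if (!ts_at_end(ts)) {
      tok <- ts_peek(ts)
      ant_stop(sprintf("unexpected '%s' after algebraic rule", tok$text),
               tok$line, tok$col, "ant_parse_error")
    }
    return(stmt("algebraic-rule", loc,
                name = if (alg_off > 0L) texts[1] else NULL, formula = formula))
  }

  # rate rule: [$]sym' = expr
  ts <- new_tok_stream(group)
  boundary <- FALSE
  if (ts_kind(ts) == "DOLLAR") {
    ts_next(ts)
    boundary <- TRUE
  }
  if (ts_kind(ts) == "ID") {
    target <- ts_peek(ts)$text
    if (ts_kind(ts, 1L) == "PRIME") {
      ts_next(ts)
      ts_next(ts)
      ts_expect(ts, "ASSIGN", "'=' after rate-of-change target")
      value <- parse_expr_tokens(ts)
      if (!ts_at_end(ts)) {
        tok <- ts_peek(ts)
        ant_stop(sprintf("unexpected '%s' after rate rule", tok$text),
                 tok$line, tok$col, "ant_parse_error")
      }
      return(stmt("rate-rule", loc, target = target, boundary = boundary,
                  value = value))
    }
    if (!boundary && ts_kind(ts, 1L) == "WALRUS") {
      ts_next(ts)
      ts_next(ts)
      value <- parse_expr_tokens(ts)
      if (!ts_at_end(ts)) {
        tok <- ts_peek(ts)
        ant_stop(sprintf("unexpected '%s' after assignment", tok$text),
                 tok$line, tok$col, "ant_parse_error")
      }
      return(stmt("continuous-assignment", loc, target = target, value = value))
    }
    # uncertainty: sym.attr = value | {x, y} | sym.attr is "uri"
    if (!boundary && ts_kind(ts, 1L) == "DOT") {
      ts_next(ts)
      ts_next(ts)
      attr_tok <- ts_expect(ts, "ID", "an uncertainty attribute name")
      attribute <- attr_tok$text
      if (ts_kind(ts) == "ID" && ts_peek(ts)$text == "is") {
        ts_next(ts)
        uri <- ts_expect(ts, "STRING", "a quoted URI")
        if (!ts_at_end(ts)) {
          tok <- ts_peek(ts)
          ant_stop(sprintf("unexpected '%s'", tok$text), tok$line, tok$col,
                   "ant_parse_error")
        }
        return(stmt("uncertainty", loc, target = target, attribute = attribute,
                    form = "uri", uri = uri$value))
      }
      ts_expect(ts, "ASSIGN", "'=' or 'is' after uncertainty attribute")
      if (ts_kind(ts) == "LBRACE") {
        ts_next(ts)
        lo <- parse_expr_tokens(ts)
        ts_expect(ts, "COMMA", "',' inside interval")
        hi <- parse_expr_tokens(ts)
        ts_expect(ts, "RBRACE", "'}'")
        if (!ts_at_end(ts)) {
          tok <- ts_peek(ts)
          ant_stop(sprintf("unexpected '%s'", tok$text), tok$line, tok$col,
                   "ant_parse_error")
        }
        return(stmt("uncertainty", loc, target = target, attribute = attribute,
                    form = "pair", lower = lo, upper = hi))
      }
      value <- parse_expr_tokens(ts)
      if (!ts_at_end(ts)) {
        tok <- ts_peek(ts)
        ant_stop(sprintf("unexpected '%s'", tok$text), tok$line, tok$col,
                 "ant_parse_error")
      }
      return(stmt("uncertainty", loc, target = target, attribute = attribute,
                  form = "scalar", value = value))
    }
    if (ts_kind(ts, 1L) == "ASSIGN") {
      target <- ts_next(ts)$text
      ts_next(ts)
      value <- parse_expr_tokens(ts)
      if (!ts_at_end(ts)) {
        tok <- ts_peek(ts)
        ant_stop(sprintf("unexpected '%s' after assignment", tok$text),
                 tok$line, tok$col, "ant_parse_error")
      }
      return(stmt("initial-assignment", loc, target = target,
                  boundary = boundary, value = value))
    }
  }
  ant_stop(sprintf("cannot parse statement starting at '%s'", first$text),
           first$line, first$col, "ant_parse_error")
}

# attach indented assignment runs to their `if` headers
assemble_events <- function(stmts) {
  out <- list()
  i <- 1L
  n <- length(stmts)
  while (i <= n) {
    s <- stmts[[i]]
    if (identical(s$variant, "event-header")) {
      body <- list()
      j <- i + 1L
      while (j <= n) {
        nxt <- stmts[[j]]
        if (identical(nxt$variant, "initial-assignment") &&
            !isTRUE(nxt$boundary) &&
            nxt$loc$line > s$loc$line && nxt$loc$col > s$loc$col) {
          body[[length(body) + 1L]] <- list(target = nxt$target,
                                            value = nxt$value)
          j <- j + 1L
        } else {
          break
        }
      }
      if (length(body) == 0L) {
        ant_stop("event has an empty body (no indented assignments follow)",
                 s$loc$line, s$loc$col, "ant_parse_error")
      }
      out[[length(out) + 1L]] <- stmt("event", s$loc, trigger = s$trigger,
                                      assignments = body)
      i <- j
    } else {
      out[[length(out) + 1L]] <- s
      i <- i + 1L
    }
  }
  out
}

#' Parse model-language text into AST statements
#'
#' @param text Model text (UTF-8). Typeset punctuation (Unicode minus, curly
#'   quotes, en dash) is accepted and normalised.
#' @return A list of statement records; each has a `variant` field (one of
#'   `reaction`, `initial-assignment`, `continuous-assignment`, `rate-rule`,
#'   `algebraic-rule`, `event`, `metadata`, `objective`, `constraint`,
#'   `uncertainty`, `model-begin`, `model-end`) and a `loc` source location.
#' @examples
#' stmts <- ant_parse("A -> B; k1*A\nA = 5\nB = 0\nk1 = 0.1")
#' vapply(stmts, `[[`, "", "variant")
#' @export
ant_parse <- function(text) {
  tokens <- ant_tokenize(text)
  groups <- split_statement_groups(tokens)
  stmts <- lapply(groups, parse_statement_group)
  assemble_events(stmts)
}
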