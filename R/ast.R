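# Expression AST: operator trees over numbers, symbols, `time` and calls.
# Nodes are plain lists tagged by `kind`:
#   number(value) | symbol(name) | time | unary(op, arg) |
#   binary(op, lhs, rhs) | call(callee, args)
# Comparison operators appear only in event triggers but are ordinary nodes.

ex_number <- function(value) list(kind = "number", value = as.numeric(value))
ex_symbol <- function(name) list(kind = "symbol", name = name)
ex_time <- function() list(kind = "time")
ex_unary <- function(op, arg) list(kind = "unary", op = op, arg = arg)
ex_binary <- function(op, lhs, rhs) list(kind = "binary", op = op, lhs = lhs, rhs = rhs)
ex_call <- function(callee, args) list(kind = "call", callee = callee, args = args)

# parser state: an environment over a token list with a cursor
new_tok_stream <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$toks <- tokens
  env$pos <- 1L
  env
}

ts_peek <- function(ts, offset = 0L) {
  i <- ts$pos + offset
  if (i > length(ts$toks)) NULL else ts$toks[[i]]
}

ts_next <- function(ts) {
  tok <- ts_peek(ts)
  ts$pos <- ts$pos + 1L
  tok
}

ts_at_end <- function(ts) ts$pos > length(ts$toks)

ts_kind <- function(ts, offset = 0L) {
  tok <- ts_peek(ts, offset)
  if (is.null(tok)) "EOF" else tok$kind
}

ts_expect <- function(ts, kind, what = kind) {
  tok <- ts_peek(ts)
  if (is.null(tok)) {
    last <- if (length(ts$toks)) ts$toks[[length(ts$toks)]] else NULL
    ant_stop(sprintf("expected %s but input ended", what),
             if (is.null(last)) NA else last$line,
             if (is.null(last)) NA else last$col, "ant_parse_error")
  }
  if (tok$kind != kind) {
    ant_stop(sprintf("expected %s but found '%s'", what, tok$text),
             tok$line, tok$col, "ant_parse_error")
  }
  ts_next(ts)
}

# precedence climbing; `^` binds tighter than unary minus, which binds
# tighter than `*`/`/`, then `+`/`-`, with comparisons loosest
parse_expr_tokens <- function(ts) parse_comparison(ts)

parse_comparison <- function(ts) {
  lhs <- parse_additive(ts)
  k <- ts_kind(ts)
  if (k %in% c("GT", "LT", "GE", "LE", "EQEQ", "NEQ")) {
    op <- switch(k, GT = ">", LT = "<", GE = ">=", LE = "<=",
                 EQEQ = "==", NEQ = "!=")
    ts_next(ts)
    rhs <- parse_additive(ts)
    return(ex_binary(op, lhs, rhs))
  }
  lhs
}

parse_additive <- function(ts) {
  lhs <- parse_multiplicative(ts)
  repeat {
    k <- ts_kind(ts)
    if (k == "PLUS" || k == "MINUS") {
      ts_next(ts)
      rhs <- parse_multiplicative(ts)
      lhs <- ex_binary(if (k == "PLUS") "+" else "-", lhs, rhs)
    } else {
      return(lhs)
    }
  }
}

parse_multiplicative <- function(ts) {
  lhs <- parse_unary(ts)
  repeat {
    k <- ts_kind(ts)
    if (k == "STAR" || k == "SLASH") {
      ts_next(ts)
      rhs <- parse_unary(ts)
      lhs <- ex_binary(if (k == "STAR") "*" else "/", lhs, rhs)
    } else {
      return(lhs)
    }
  }
}

parse_unary <- function(ts) {
  if (ts_kind(ts) == "MINUS") {
    ts_next(ts)
    ex_unary("-", parse_unary(ts))
  } else if (ts_kind(ts) == "PLUS") {
    ts_next(ts)
    parse_unary(ts)
  } else {
    parse_power(ts)
  }
}

parse_power <- function(ts) {
  base <- parse_atom(ts)
  if (ts_kind(ts) == "CARET") {
    ts_next(ts)
    # right-associative; unary minus allowed in the exponent
    ex_binary("^", base, parse_unary(ts))
  } else {
    base
  }
}

parse_atom <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) {
    ant_stop("expected an expression but input ended", NA, NA, "ant_parse_error")
  }
  if (tok$kind == "NUMBER") {
    ts_next(ts)
    return(ex_number(tok$value))
  }
  if (tok$kind == "LPAREN") {
    ts_next(ts)
    inner <- parse_expr_tokens(ts)
    ts_expect(ts, "RPAREN", "')'")
    return(inner)
  }
  if (tok$kind == "ID") {
    ts_next(ts)
    if (ts_kind(ts) == "LPAREN") {
      ts_next(ts)
      args <- list()
      if (ts_kind(ts) != "RPAREN") {
        repeat {
          args[[length(args) + 1L]] <- parse_expr_tokens(ts)
          if (ts_kind(ts) == "COMMA") ts_next(ts) else break
        }
      }
      ts_expect(ts, "RPAREN", "')'")
      return(ex_call(tok$text, args))
    }
    if (tok$text == "time") return(ex_time())
    return(ex_symbol(tok$text))
  }
  ant_stop(sprintf("unexpected '%s' in expression", tok$text),
           tok$line, tok$col, "ant_parse_error")
}

#' Parse a single mathematical expression
#'
#' Standard precedence: `^` (right-associative) binds tighter than unary
#' minus, then `*`/`/`, then `+`/`-`, with comparison operators loosest.
#' The bare identifier `time` denotes simulation time.
#'
#' @param text Expression text, e.g. `"k1*S1^n"`.
#' @return An expression AST (nested list tagged by `kind`).
#' @examples
#' ast <- ant_parse_expression("1 + amp*sin(time*freq)")
#' ast$kind  # "binary"
#' @export
ant_parse_expression <- function(text) {
  toks <- Filter(function(t) t$kind != "NEWLINE", ant_tokenize(text))
  ts <- new_tok_stream(toks)
  node <- parse_expr_tokens(ts)
  if (!ts_at_end(ts)) {
    tok <- ts_peek(ts)
    ant_stop(sprintf("trailing input after expression: '%s'", tok$text),
             tok$line, tok$col, "ant_parse_error")
  }
  node
}

expr_precedence <- function(node) {
  switch(node$kind,
    binary = switch(node$op,
      ">" = , "<" = , ">=" = , "<=" = , "==" = , "!=" = 1L,
      "+" = , "-" = 2L,
      "*" = , "/" = 3L,
      "^" = 5L),
    unary = 4L,
    6L)
}

# canonical decimal rendering; 15 significant digits round-trip the literals
# that occur in model text
format_number <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "inf" else "-inf")
  s <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  s
}

#' Render an expression AST back to text
#'
#' Emits the canonical form: minimal parentheses, ASCII operators, one space
#' around binary operators only where precedence requires none.
#'
#' @param node An expression AST as returned by [ant_parse_expression()].
#' @return A character scalar that reparses to a structurally identical AST.
#' @export
ant_deparse_expression <- function(node) {
  prec <- expr_precedence(node)
  wrap <- function(child, need_gt = FALSE) {
    cp <- expr_precedence(child)
    txt <- ant_deparse_expression(child)
    if (cp < prec || (need_gt && cp == prec)) paste0("(", txt, ")") else txt
  }
  switch(node$kind,
    number = format_number(node$value),
    symbol = node$name,
    time = "time",
    unary = {
      arg <- node$arg
      txt <- ant_deparse_expression(arg)
      if (expr_precedence(arg) < prec) txt <- paste0("(", txt, ")")
      paste0("-", txt)
    },
    binary = {
      right_assoc <- node$op == "^"
      lhs <- wrap(node$lhs, need_gt = right_assoc)
      rhs <- wrap(node$rhs, need_gt = !right_assoc)
      sep <- if (node$op == "^") "" else " "
      paste0(lhs, sep, node$op, sep, rhs)
    },
    call = paste0(node$callee, "(",
                  paste(vapply(node$args, ant_deparse_expression, character(1)),
                        collapse = ", "), ")"),
    stop("unknown expression node kind: ", node$kind)
  )
}

# walk an expression tree, calling fn on every node
expr_walk <- function(node, fn) {
  fn(node)
  switch(node$kind,
    unary = expr_walk(node$arg, fn),
    binary = {
      expr_walk(node$lhs, fn)
      expr_walk(node$rhs, fn)
    },
    call = for (a in node$args) expr_walk(a, fn),
    invisible(NULL))
  invisible(NULL)
}

# all symbol names referenced in an expression (excluding call names)
expr_symbols <- function(node) {
  out <- character(0)
  expr_walk(node, function(n) {
    if (n$kind == "symbol") out <<- c(out, n$name)
  })
  unique(out)
}

# all call nodes in an expression
expr_calls <- function(node) {
  out <- list()
  expr_walk(node, function(n) {
    if (n$kind == "call") out[[length(out) + 1L]] <<- n
  })
  out
}

expr_identical <- function(a, b) identical(strip_attrs(a), strip_attrs(b))

strip_attrs <- function(x) {
  if (is.list(x)) lapply(x, strip_attrs) else x
}
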