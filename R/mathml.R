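# MathML (SBML Level 3 content subset) <-> expression AST.
#
# Dialect: <ci>, <cn>, <csymbol definitionURL=...> for `time` and `rateOf`,
# distribution draws as csymbol-headed applies using the distrib package's
# symbol URLs, `^` as <power/>, comparisons as gt/lt/geq/leq/eq/neq.

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
CSYMBOL_TIME <- "http://www.sbml.org/sbml/symbols/time"
CSYMBOL_RATEOF <- "http://www.sbml.org/sbml/symbols/rateOf"
CSYMBOL_DISTRIB_BASE <- "http://www.sbml.org/sbml/symbols/distrib/"

MATHML_BINARY_OPS <- c("+" = "plus", "-" = "minus", "*" = "times",
                       "/" = "divide", "^" = "power",
                       ">" = "gt", "<" = "lt", ">=" = "geq", "<=" = "leq",
                       "==" = "eq", "!=" = "neq")

# function names with a dedicated MathML element
MATHML_FUNCTIONS <- c(sin = "sin", cos = "cos", tan = "tan", asin = "arcsin",
                      acos = "arccos", atan = "arctan", sinh = "sinh",
                      cosh = "cosh", tanh = "tanh", exp = "exp", ln = "ln",
                      log = "log", log10 = "log", abs = "abs",
                      ceil = "ceiling", ceiling = "ceiling", floor = "floor",
                      sqrt = "root")

expr_to_mathml_node <- function(parent, node) {
  add <- function(tag, ...) xml2::xml_add_child(parent, tag, ...)
  if (node$kind == "number") {
    add("cn", format_number(node$value))
  } else if (node$kind == "symbol") {
    add("ci", node$name)
  } else if (node$kind == "time") {
    add("csymbol", "time", encoding = "text", definitionURL = CSYMBOL_TIME)
  } else if (node$kind == "unary") {
    ap <- add("apply")
    xml2::xml_add_child(ap, "minus")
    expr_to_mathml_node(ap, node$arg)
  } else if (node$kind == "binary") {
    ap <- add("apply")
    xml2::xml_add_child(ap, MATHML_BINARY_OPS[[node$op]])
    expr_to_mathml_node(ap, node$lhs)
    expr_to_mathml_node(ap, node$rhs)
  } else if (node$kind == "call") {
    ap <- add("apply")
    if (node$callee == "rateOf") {
      xml2::xml_add_child(ap, "csymbol", "rateOf", encoding = "text",
                          definitionURL = CSYMBOL_RATEOF)
    } else if (node$callee %in% names(DIST_TABLE)) {
      xml2::xml_add_child(ap, "csymbol", node$callee, encoding = "text",
                          definitionURL = paste0(CSYMBOL_DISTRIB_BASE, node$callee))
    } else if (node$callee %in% names(MATHML_FUNCTIONS)) {
      xml2::xml_add_child(ap, MATHML_FUNCTIONS[[node$callee]])
    } else {
      # user-level function with no MathML head: emit as csymbol by name
      xml2::xml_add_child(ap, "csymbol", node$callee, encoding = "text",
                          definitionURL = paste0("urn:antsembly:function:", node$callee))
    }
    for (a in node$args) expr_to_mathml_node(ap, a)
  } else {
    stop("cannot serialize expression node of kind ", node$kind)
  }
  invisible(parent)
}

# add a <math> element holding the expression under `parent`
add_math_element <- function(parent, expr) {
  math <- xml2::xml_add_child(parent, "math", xmlns = MATHML_NS)
  expr_to_mathml_node(math, expr)
  invisible(math)
}

mathml_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_name(kids) != ""]
}

mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- mathml_children(node)
    if (length(kids) != 1L) {
      ant_stop("expected exactly one expression inside <math>",
               class = "ant_sbml_error")
    }
    return(mathml_to_expr(kids[[1]]))
  }
  if (name == "cn") {
    return(ex_number(as.numeric(xml2::xml_text(node))))
  }
  if (name == "ci") {
    return(ex_symbol(trimws(xml2::xml_text(node))))
  }
  if (name == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (identical(url, CSYMBOL_TIME)) return(ex_time())
    ant_stop(sprintf("bare csymbol '%s' is not a value", trimws(xml2::xml_text(node))),
             class = "ant_sbml_error")
  }
  if (name != "apply") {
    ant_stop(sprintf("unsupported MathML element <%s>", name),
             class = "ant_sbml_error")
  }
  kids <- mathml_children(node)
  head <- kids[[1]]
  args <- lapply(kids[-1], mathml_to_expr)
  hname <- xml2::xml_name(head)
  if (hname == "csymbol") {
    url <- xml2::xml_attr(head, "definitionURL")
    callee <- trimws(xml2::xml_text(head))
    if (identical(url, CSYMBOL_RATEOF)) {
      return(ex_call("rateOf", args))
    }
    if (!is.na(url) && startsWith(url, CSYMBOL_DISTRIB_BASE)) {
      return(ex_call(sub(CSYMBOL_DISTRIB_BASE, "", url, fixed = TRUE), args))
    }
    return(ex_call(callee, args))
  }
  op <- names(MATHML_BINARY_OPS)[match(hname, MATHML_BINARY_OPS)]
  if (!is.na(op)) {
    if (hname == "minus" && length(args) == 1L) {
      return(ex_unary("-", args[[1]]))
    }
    if (length(args) == 2L) {
      return(ex_binary(op, args[[1]], args[[2]]))
    }
    # n-ary plus/times fold left
    if (hname %in% c("plus", "times") && length(args) > 2L) {
      acc <- args[[1]]
      for (a in args[-1]) acc <- ex_binary(op, acc, a)
      return(acc)
    }
    ant_stop(sprintf("operator <%s> with %d operands", hname, length(args)),
             class = "ant_sbml_error")
  }
  fn <- names(MATHML_FUNCTIONS)[match(hname, MATHML_FUNCTIONS)]
  if (!is.na(fn)) {
    if (hname == "root") {
      # degree-2 root (with or without an explicit <degree>) is sqrt
      return(ex_call("sqrt", args[length(args)]))
    }
    if (hname == "log") {
      return(ex_call("log", args))
    }
    return(ex_call(fn, args))
  }
  ant_stop(sprintf("unsupported MathML operator <%s>", hname),
           class = "ant_sbml_error")
}

# read the <math> child of an SBML element, NULL when absent
read_math_child <- function(node) {
  math <- xml2::xml_find_first(node, "./*[local-name() = 'math']")
  if (inherits(math, "xml_missing")) return(NULL)
  mathml_to_expr(math)
}
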