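# Lexing and parsing of the model language.

test_that("tokenizer produces the expected token stream for a reaction line", {
  expect_equal(token_kinds("A -> B; k1*A"),
               c("ID", "ARROW", "ID", "SEMI", "ID", "STAR", "ID"))
  # Unicode minus arrow and ASCII arrow lex identically
  expect_equal(token_kinds("A −> B; k1*A"), token_kinds("A -> B; k1*A"))
  expect_equal(token_kinds(""), character(0))
})

test_that("boundary marker, walrus and prime are distinct tokens", {
  kinds <- token_kinds("$X -> Y; k1*X")
  expect_equal(kinds[1:2], c("DOLLAR", "ID"))
  expect_true("WALRUS" %in% token_kinds("X := 1"))
  expect_false("WALRUS" %in% token_kinds("X = 1"))
  expect_equal(token_kinds("C' = 1")[1:2], c("ID", "PRIME"))
})

test_that("typeset punctuation is normalised before lexing", {
  for (i in 1:13) {
    plain <- ant_listing(i)
    fancy <- gsub("->", "−>", plain, fixed = TRUE)
    fancy <- gsub("\"", "“", fancy, fixed = TRUE)
    expect_equal(token_kinds(fancy), token_kinds(plain), info = paste("listing", i))
  }
  # en dash as minus, curly single quote as prime
  expect_equal(token_kinds("0 = S2*k2 – 20"), token_kinds("0 = S2*k2 - 20"))
  expect_equal(token_kinds("C’ = 10*k3"), token_kinds("C' = 10*k3"))
})

test_that("lex errors carry in-bounds source locations", {
  err <- tryCatch(ant_tokenize("A = \"unterminated"), ant_lex_error = identity)
  expect_s3_class(err, "ant_lex_error")
  expect_equal(err$line, 1L)
  expect_gte(err$col, 1L)
  err2 <- tryCatch(ant_tokenize("A = 1\nB = @"), ant_lex_error = identity)
  expect_equal(err2$line, 2L)
})

test_that("statement variants match the language constructs", {
  expect_equal(statement_variants(ant_listing(2)),
               c(rep("reaction", 3), rep("initial-assignment", 8)))
  expect_equal(statement_variants("alg2: 0 = S2*k2 - 20"), "algebraic-rule")
  expect_equal(statement_variants("X := 1 + amp*sin(time*freq)"),
               "continuous-assignment")
  expect_equal(statement_variants("$A' = k2 * A"), "rate-rule")
  expect_equal(statement_variants("model mymodel()\nend"),
               c("model-begin", "model-end"))
})

test_that("event bodies are the maximal indented assignment run", {
  stmts <- ant_parse(ant_listing(9))
  ev <- Filter(function(s) s$variant == "event", stmts)
  expect_length(ev, 1L)
  expect_length(ev[[1]]$assignments, 1L)
  expect_equal(ev[[1]]$assignments[[1]]$target, "k0")
  # following column-1 statements are plain initializations
  expect_equal(sum(statement_variants(ant_listing(9)) == "initial-assignment"), 3L)
  # two indented lines both belong to the body
  two <- "A -> B; k*A\nif A > 1:\n  k = 2\n  A = 0\nB = 1"
  ev2 <- Filter(function(s) s$variant == "event", ant_parse(two))[[1]]
  expect_length(ev2$assignments, 2L)
  expect_error(ant_parse("A -> B; k*A\nif A > 1:\nB = 1"), class = "ant_parse_error")
})

test_that("expression parsing matches R's own precedence on operator triples", {
  ops <- c("+", "-", "*", "/", "^")
  env <- new.env()
  for (o1 in ops) {
    for (o2 in ops) {
      text <- sprintf("2 %s 3 %s 4", o1, o2)
      ours <- eval(antsembly:::to_r_call(ant_parse_expression(text)), env)
      rs <- eval(parse(text = text)[[1]])
      expect_equal(ours, rs, info = text)
    }
  }
  # left associativity explicitly: (k1*A)*B not k1*(A*B) structurally
  ast <- ant_parse_expression("k1*A*B")
  expect_equal(ast$lhs$kind, "binary")
  expect_equal(ast$rhs$name, "B")
})

test_that("power binds tighter than unary minus and is right-associative", {
  expect_equal(eval(antsembly:::to_r_call(ant_parse_expression("-2^2")),
                    new.env()), -4)
  expect_equal(eval(antsembly:::to_r_call(ant_parse_expression("2^3^2")),
                    new.env()), 512)
  ast <- ant_parse_expression("k1*S1^n")
  expect_equal(ast$op, "*")
  expect_equal(ast$rhs$op, "^")
})

test_that("double negation evaluates to the identity", {
  e <- new.env()
  e$x <- 1
  expect_equal(eval(antsembly:::to_r_call(ant_parse_expression("-(-x)")), e), 1)
})

test_that("time parses as the time symbol and calls tolerate spaces", {
  ast <- ant_parse_expression("1 + amp*sin (time*freq)")
  expect_equal(ast$kind, "binary")
  expect_equal(ast$op, "+")
  expect_equal(ast$rhs$op, "*")
  expect_equal(ast$rhs$rhs$kind, "call")
  expect_equal(ast$rhs$rhs$args[[1]]$lhs$kind, "time")
})

test_that("expression deparse-reparse is structurally stable", {
  cases <- c("k1*A", "k1*S1^n", "1 + amp*sin(time*freq)", "-(-x)",
             "a/b/c", "a-(b-c)", "(a+b)*c", "2^-3", "rateOf(S1) + 1")
  for (txt in cases) {
    ast <- ant_parse_expression(txt)
    expect_true(antsembly:::expr_identical(
      ast, ant_parse_expression(ant_deparse_expression(ast))), info = txt)
  }
})

test_that("parse errors carry locations and name the offending token", {
  err <- tryCatch(ant_parse("A -> B k1*A"), ant_parse_error = identity)
  expect_s3_class(err, "ant_parse_error")
  expect_gte(err$line, 1L)
  err2 <- tryCatch(ant_parse("A = 1\nB = * 2"), ant_parse_error = identity)
  expect_equal(err2$line, 2L)
})
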