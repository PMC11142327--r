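# Semantic resolution: species/parameter classification, boundary rules,
# conflicts, canonical unparsing.

test_that("a branched pathway resolves to the expected network", {
  m <- ant_model(ant_listing(2))
  expect_equal(names(m$species), c("A", "B", "C", "D"))
  expect_equal(names(m$parameters), c("k1", "k2", "k3", "k4"))
  expect_length(m$reactions, 3L)
  inits <- vapply(m$parameters, function(p) p$init$value, numeric(1))
  expect_equal(unname(inits), c(0.1, 0.2, 0.15, 3.4))
})

test_that("an empty statement list builds an empty anonymous model", {
  m <- ant_build_model(list())
  expect_null(m$name)
  expect_length(m$species, 0L)
  expect_length(m$parameters, 0L)
})

test_that("symbolic stoichiometries resolve to parameters with their rules", {
  m <- ant_model(ant_listing(12))
  j1 <- m$reactions[["J1"]]
  expect_true(j1$reactants[[1]]$symbolic)
  expect_equal(j1$reactants[[1]]$stoich, "n")
  expect_equal(j1$products[[1]]$stoich, "m")
  cont <- Filter(function(r) r$kind == "continuous", m$rules)
  expect_equal(cont[[1]]$target, "n")
  expect_equal(ant_deparse_expression(cont[[1]]$formula), "k2 / 2")
  expect_equal(eval(antsembly:::to_r_call(m$parameters[["m"]]$init)), 2 / 3)
})

test_that("unnamed reactions are auto-labelled in source order", {
  m <- ant_model("A -> B; k*A\nB -> C; k*B\nJx: C -> A; k*C")
  expect_equal(names(m$reactions), c("_J0", "_J1", "Jx"))
})

test_that("rate-ruled or assigned species in reactions must be boundary", {
  expect_error(ant_model("A -> B; k*A\nA' = 2"),
               class = "ant_semantic_error")
  expect_error(ant_model("X -> Y; k*X\nX := 1 + sin(time)"),
               class = "ant_semantic_error")
  # boundary-marked versions are accepted
  expect_s3_class(ant_model("$A -> B; k*A\n$A' = 2"), "ant_model")
  expect_s3_class(ant_model("$X -> Y; k*X\nX := 1 + sin(time)"), "ant_model")
})

test_that("conflicting or duplicated rules on one target are rejected", {
  expect_error(ant_model("x := 1\nx' = 2"), class = "ant_semantic_error")
  expect_error(ant_model("x' = 1\nx := 2"), class = "ant_semantic_error")
  expect_error(ant_model("x := 1\nx := 2"), class = "ant_semantic_error")
  expect_error(ant_model("x' = 1\nx' = 2"), class = "ant_semantic_error")
  expect_error(ant_model("a := b\nb := a"), class = "ant_semantic_error")
})

test_that("duplicate initializations warn and the last statement wins", {
  m <- ant_model("A -> B; k*A\nA = 1\nA = 7\nk = 0.1\nB = 0")
  expect_equal(m$species[["A"]]$init$value, 7)
  warns <- Filter(function(d) d$severity == "warning", m$diagnostics)
  expect_true(any(grepl("last statement wins", vapply(warns, `[[`, "", "message"))))
})

test_that("uninitialized symbols default to zero with a warning", {
  m <- ant_model("A -> B; k1*A")
  expect_equal(m$parameters[["k1"]]$init$value, 0)
  warns <- vapply(Filter(function(d) d$severity == "warning", m$diagnostics),
                  `[[`, "", "message")
  expect_true(any(grepl("k1", warns)))
})

test_that("permuting initial-assignment statements leaves the model unchanged", {
  base <- c("A -> B; k1*A", "B -> C; k2*B")
  inits <- c("A = 5", "B = 0", "C = 1", "k1 = 0.1", "k2 = 0.2")
  ref <- ant_model(paste(c(base, inits), collapse = "\n"))
  for (seed in 1:5) {
    set.seed(seed)
    m <- ant_model(paste(c(base, sample(inits)), collapse = "\n"))
    expect_true(ant_model_equal(ref, m), info = paste("seed", seed))
  }
})

test_that("species and parameters partition the non-reaction identifiers", {
  for (i in 1:13) {
    m <- ant_model(ant_listing(i))
    ids <- c(names(m$species), names(m$parameters))
    expect_equal(length(ids), length(unique(ids)), info = paste("listing", i))
    expect_length(intersect(ids, names(m$reactions)), 0L)
  }
})

test_that("rateOf restriction check flags reactions and assignment targets", {
  expect_length(ant_check_rateof(ant_model(ant_listing(8))), 0L)
  m <- ant_model("J0: A -> B; k*A\nX := rateOf(J0)")
  expect_length(ant_check_rateof(m), 1L)
  m2 <- ant_model("Y := 2*time\nX := rateOf(Y)")
  expect_length(ant_check_rateof(m2), 1L)
  expect_length(ant_check_rateof(ant_model("A -> B; k*A")), 0L)
})

test_that("distribution calls are rejected in continuous contexts only", {
  expect_length(ant_check_distrib_contexts(ant_model(ant_listing(9))), 0L)
  expect_length(ant_check_distrib_contexts(
    ant_model("J: A -> B; uniform(0,1)*A")), 1L)
  expect_length(ant_check_distrib_contexts(ant_model("X := normal(0,1)")), 1L)
  expect_length(ant_check_distrib_contexts(ant_model("X' = normal(0,1)")), 1L)
  expect_length(ant_check_distrib_contexts(
    ant_model("S0 = normal(0.5, 0.2)")), 0L)
})

test_that("unparse reaches a canonical fixed point after one application", {
  for (i in 1:13) {
    m <- ant_model(ant_listing(i))
    t1 <- ant_unparse(m)
    m2 <- ant_model(t1)
    expect_true(ant_model_equal(m, m2), info = paste("listing", i))
    expect_identical(ant_unparse(m2), t1, info = paste("listing", i))
  }
})

test_that("model blocks must be properly bracketed and unnested", {
  expect_error(ant_model("model a()\nmodel b()\nend\nend"),
               class = "ant_semantic_error")
  expect_error(ant_model("end"), class = "ant_semantic_error")
  expect_error(ant_model("model a()\nA -> B; k*A"),
               class = "ant_semantic_error")
})
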