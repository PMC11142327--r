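# Flux-balance objectives and constraints.

test_that("the flux-balance example yields one objective and six constraints", {
  m <- ant_model(ant_listing(11))
  expect_length(m$fbc$objectives, 1L)
  obj <- m$fbc$objectives[[1]]
  expect_equal(obj$id, "OBJF")
  expect_equal(obj$sense, "maximize")
  expect_equal(vapply(obj$terms, `[[`, "", "reaction"), c("R16", "R03"))
  expect_equal(vapply(obj$terms, `[[`, 0, "coef"), c(1, 1))
  expect_length(m$fbc$constraints, 6L)
  bt <- ant_bounds_table(m$fbc)
  expect_equal(bt[["R16"]], c(0, 1000))
  expect_equal(bt[["R03"]], c(-1000, 1000))
  expect_equal(bt[["R02"]], c(-1000, 1000))
})

test_that("a model without flux statements has an empty record", {
  m <- ant_model(ant_listing(1))
  expect_length(m$fbc$objectives, 0L)
  expect_length(m$fbc$constraints, 0L)
  expect_length(ant_bounds_table(m$fbc), 0L)
})

test_that("bounds folding is order-independent and handles equality", {
  m <- ant_model(ant_listing(11))
  ref <- ant_bounds_table(m$fbc)
  for (seed in 1:5) {
    set.seed(seed)
    fbc <- m$fbc
    fbc$constraints <- sample(fbc$constraints)
    perm <- ant_bounds_table(fbc)
    expect_identical(perm[sort(names(perm))], ref[sort(names(ref))])
  }
  meq <- ant_model("R1: A -> B\nconstraint c0: R1 = 5")
  expect_equal(ant_bounds_table(meq$fbc)[["R1"]], c(5, 5))
})

test_that("contradictory bounds are an infeasibility error", {
  m <- ant_model("R1: A -> B\nconstraint c0: R1 >= 5")
  m$fbc$constraints[[2]] <- list(id = "c1", reaction = "R1",
                                 comparator = "<=", bound = 3)
  expect_error(ant_bounds_table(m$fbc), class = "ant_semantic_error")
})

test_that("objectives must be linear combinations of declared reactions", {
  expect_error(ant_model("R1: A -> B\nOBJ: maximize R1*R1"),
               class = "ant_semantic_error")
  expect_error(ant_model("R1: A -> B\nk = 1\nOBJ: maximize k"),
               class = "ant_semantic_error")
  expect_error(ant_model("R1: A -> B\nconstraint c0: R1 >= 0\nconstraint c0: R1 <= 1"),
               class = "ant_semantic_error")
  m <- ant_model("R1: A -> B\nR2: B -> C\nOBJ: minimize 2*R1 - R2")
  obj <- m$fbc$objectives[[1]]
  expect_equal(obj$sense, "minimize")
  expect_equal(vapply(obj$terms, `[[`, 0, "coef"), c(2, -1))
})

test_that("reactions lacking a finite bound pair draw a warning", {
  m <- ant_model("R1: A -> B\nR2: B -> C\nconstraint c0: R1 >= 0\nconstraint c1: R1 <= 10")
  warns <- vapply(Filter(function(d) d$severity == "warning", m$diagnostics),
                  `[[`, "", "message")
  expect_true(any(grepl("R2", warns)))
  expect_false(any(grepl("\\bR1\\b", warns)))
})

test_that("FBC v1 round trip preserves objectives and the bounds table", {
  m <- ant_model(ant_listing(11))
  m2 <- ant_import_sbml(ant_to_sbml(m))
  expect_identical(antsembly:::strip_attrs(m$fbc),
                   antsembly:::strip_attrs(m2$fbc))
  expect_identical(ant_bounds_table(m2$fbc), ant_bounds_table(m$fbc))
})
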