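# Distribution registry, sampling semantics, uncertainty attributes.

dist_arities <- c(normal = 2, uniform = 2, bernoulli = 1, binomial = 2,
                  cauchy = 2, chisquare = 1, exponential = 1, gamma = 2,
                  laplace = 2, lognormal = 2, poisson = 1, rayleigh = 1)
truncatable <- setdiff(names(dist_arities), c("uniform", "bernoulli"))

test_that("all 22 table signatures validate and perturbed arities fail", {
  n_valid <- 0L
  for (nm in names(dist_arities)) {
    base <- dist_arities[[nm]]
    valid <- if (nm %in% truncatable) c(base, base + 2L) else base
    for (k in valid) {
      expect_equal(length(ant_validate_distribution(nm, k)), 0L,
                   info = sprintf("%s/%s", nm, k))
      n_valid <- n_valid + 1L
    }
    for (k in setdiff(unique(c(valid - 1L, valid + 1L)), valid)) {
      expect_gt(length(ant_validate_distribution(nm, k)), 0L,
                label = sprintf("diagnostics for %s/%s", nm, k))
    }
  }
  expect_equal(n_valid, 22L)
  expect_gt(length(ant_validate_distribution("dirichlet", 2)), 0L)
})

test_that("uniform draws stay inside their interval", {
  for (seed in c(1, 7, 99)) {
    rng <- ant_rng(seed)
    draws <- replicate(200, ant_sample_distribution("uniform", c(2.5, 5.5), rng))
    expect_true(all(draws >= 2.5 & draws <= 5.5))
  }
})

test_that("degenerate widths collapse to their location", {
  rng <- ant_rng(3)
  expect_equal(ant_sample_distribution("normal", c(0.7, 0), rng), 0.7)
  expect_equal(ant_sample_distribution("cauchy", c(-1.2, 0), rng), -1.2)
})

test_that("count-valued families return integer-valued reals", {
  rng <- ant_rng(11)
  for (i in 1:50) {
    expect_true(ant_sample_distribution("bernoulli", 0.4, rng) %in% c(0, 1))
    expect_equal(ant_sample_distribution("poisson", 3, rng) %% 1, 0)
    expect_equal(ant_sample_distribution("binomial", c(10, 0.3), rng) %% 1, 0)
  }
})

test_that("truncated sampling honours the bounds, including the mean", {
  rng <- ant_rng(5)
  draws <- replicate(500,
    ant_sample_distribution("normal", c(0.5, 0.2, 0.4, 0.6), rng))
  expect_true(all(draws >= 0.4 & draws <= 0.6))
  expect_gte(mean(draws), 0.4)
  expect_lte(mean(draws), 0.6)
  # every truncatable family respects its bounds
  args_for <- list(normal = c(1, 2), binomial = c(20, 0.5), cauchy = c(0, 1),
                   chisquare = 3, exponential = 1, gamma = c(2, 1),
                   laplace = c(0, 1), lognormal = c(0, 0.5), poisson = 4,
                   rayleigh = 1)
  for (nm in names(args_for)) {
    d <- replicate(50, ant_sample_distribution(nm, c(args_for[[nm]], 1, 3), rng))
    expect_true(all(d >= 1 & d <= 3), info = nm)
  }
})

test_that("equal seeds reproduce equal 1000-draw sequences", {
  r1 <- ant_rng(1234)
  r2 <- ant_rng(1234)
  s1 <- replicate(1000, ant_sample_distribution("normal", c(0, 1), r1))
  s2 <- replicate(1000, ant_sample_distribution("normal", c(0, 1), r2))
  expect_identical(s1, s2)
  r3 <- ant_rng(1235)
  s3 <- replicate(1000, ant_sample_distribution("normal", c(0, 1), r3))
  expect_false(identical(s1, s3))
})

test_that("draws never disturb the session RNG state", {
  set.seed(42)
  before <- .Random.seed
  rng <- ant_rng(9)
  invisible(replicate(10, ant_sample_distribution("uniform", c(0, 1), rng)))
  expect_identical(.Random.seed, before)
})

test_that("invalid parameter domains raise sampling errors", {
  rng <- ant_rng(2)
  expect_error(ant_sample_distribution("normal", c(0, -1), rng),
               class = "ant_sample_error")
  expect_error(ant_sample_distribution("cauchy", c(0, -2), rng),
               class = "ant_sample_error")
  expect_error(ant_sample_distribution("normal", c(0, 1, 5, 2), rng),
               class = "ant_sample_error")
  expect_error(ant_sample_distribution("normal", 0.5, rng),
               class = "ant_sample_error")
})

test_that("lognormal parameters act on the log scale", {
  rng <- ant_rng(77)
  draws <- replicate(4000, ant_sample_distribution("lognormal", c(1, 0.25), rng))
  expect_equal(mean(log(draws)), 1, tolerance = 0.02)
  expect_equal(stats::sd(log(draws)), 0.25, tolerance = 0.05)
})

test_that("uncertainty attributes populate per-symbol records", {
  m <- ant_model("A = 1\nS1 = 2\nA.mean = 2.4\nA.confidenceInterval = {S1, 8.2}")
  rec <- m$uncertainty[["A"]]
  expect_equal(rec$scalars$mean$value, 2.4)
  expect_equal(rec$intervals$confidenceInterval$lower$name, "S1")
  expect_equal(rec$intervals$confidenceInterval$upper$value, 8.2)
  # stdev and standardDeviation alias one slot
  m2 <- ant_model("A = 1\nA.standardDeviation = 3")
  expect_equal(m2$uncertainty[["A"]]$scalars$stdev$value, 3)
  # URI and formula forms for distribution
  m3 <- ant_model("A = 1\nA.distribution is \"http://example.org/d\"")
  expect_equal(m3$uncertainty[["A"]]$distribution$form, "uri")
  m4 <- ant_model("A = 1\nA.distribution = normal(0.5, 0.2)")
  expect_equal(m4$uncertainty[["A"]]$distribution$form, "formula")
})

test_that("unknown uncertainty attributes are rejected and no-ops preserved", {
  expect_error(ant_model("A = 1\nA.wibble = 2"), class = "ant_semantic_error")
  m <- ant_model("A = 1")
  expect_length(m$uncertainty, 0L)
})
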