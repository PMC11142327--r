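# The thirteen reference models that exercise every language feature:
# mass-action reactions, branched pathways, non-unity and symbolic
# stoichiometries, named reactions, boundary species, forcing functions,
# explicit rate rules, metadata blocks, rateOf, events with distribution
# draws, uncertainty attributes, flux-balance objectives/constraints and
# algebraic rules.
#
# The texts are ASCII-normalised (plain '-', straight quotes).  Three are
# lightly concretised so that every fixture is a complete, buildable model:
#   * fixture 9 indents the event body (indentation is what delimits it);
#   * fixture 10's placeholder formula/URI values are filled with a concrete
#     distribution call and URI;
#   * fixture 11 declares the three reactions its flux constraints refer to
#     (flux-balance models list reactions without kinetic laws).

LISTING_TEXTS <- list(
  `1` = paste(
    "// Define a single reaction with reactant A and product B and rate law k1*A",
    "A -> B; k1*A",
    "// Initialize values",
    "A = 5",
    "B = 0",
    "k1 = 0.1",
    sep = "\n"),
  `2` = paste(
    "// Define three reactions forming a simple branch",
    "A -> B; k1*A",
    "B -> C; k2*B",
    "B -> D; k3*B - k4*C",
    "// Initialize values",
    "A = 5; B = 0; C = 0; D = 0;",
    "k1 = 0.1; k2 = 0.2; k3 = 0.15; k4 = 3.4",
    sep = "\n"),
  `3` = paste(
    "// A reaction with multiple reactants",
    "A + B -> C; k1*A*B",
    "// A reaction with non-unity stoichiometry",
    "2 C -> D + E; k2*C",
    "// Initialize values",
    "A = 5; B = 0; C = 0; D = 0; E = 0; k1 = 0.1; k2 = 0.2;",
    sep = "\n"),
  `4` = paste(
    "// Name a reaction 'J1'.",
    "J1: A + B -> C; k1*A*B",
    "// Initialize values",
    "A = 5; B = 2; C = 0; k1 = 0.1;",
    sep = "\n"),
  `5` = paste(
    "// A reaction with an external reactant, A, indicated with a dollar symbol.",
    "// Species A will be fixed in any model generated from this script",
    "$A -> B; k1*A",
    "// A reaction with a forcing function: a sine wave of a given frequency",
    "// and amplitude. The ':=' assignment is part of the model and is",
    "// executed continuously when the model is simulated.",
    "X := 1 + amp*sin (time*freq)",
    "$X -> Y; k1*X",
    "// Initialize values",
    "A = 1",
    "amp = 2.5; freq = 0.5; k1 = 0.1;",
    sep = "\n"),
  `6` = paste(
    "// Define a reaction.",
    "J1: $A + B -> C; k1*A*B",
    "// The 'A' species here is not consumed by reaction J1, and instead",
    "// increases at an autocatalytic rate",
    "$A' = k2 * A",
    "// Initialize values",
    "A = 5; B = 2; C = 0; k1 = 0.1; k2 = 0.01",
    sep = "\n"),
  `7` = paste(
    "model mymodel()",
    "S1 -> S2; k1*S1",
    "model notes \"This is a small model\"",
    "end",
    sep = "\n"),
  `8` = paste(
    "J0: S0 -> S1; k0*S0",
    "J1: S1 -> S2; k1*S1",
    "X1 := rateOf(S1)",
    "C' = 10*k3",
    "X2 := rateOf(C)",
    sep = "\n"),
  `9` = paste(
    "J0: S0 -> S1; k0*S0",
    "J1: S1 -> S2; k1*S1",
    "if S1 > 10:",
    "  k0 = uniform(2.5, 5.5)",
    "S0 = normal(0.5, 0.2)",
    "S1 = normal(0.5, 0.2)",
    "S2 = 0",
    sep = "\n"),
  `10` = paste(
    "A.mean = x",
    "A.stdev = x",
    "A.coefficientOfVariation = x",
    "A.kurtosis = x",
    "A.median = x",
    "A.mode = x",
    "A.sampleSize = x",
    "A.skewness = x",
    "A.standardError = x",
    "A.variance = x",
    "A.confidenceInterval = {x, y}",
    "A.credibleInterval = {x, y}",
    "A.interquartileRange = {x, y}",
    "A.range = {x, y}",
    "A.distribution = normal(x, y)",
    "A.externalParameter is \"http://identifiers.org/distribution/external\"",
    sep = "\n"),
  `11` = paste(
    "// Reaction network (no kinetic laws; only the fluxes are constrained)",
    "R02: A -> B",
    "R03: B -> C",
    "R16: C -> A",
    "// The objective function (for FBC analysis):",
    "OBJF: maximize R16 + R03;",
    "// Constraints:",
    "constraint c0: R16 >= 0",
    "constraint c1: R16 <= 1000",
    "constraint c2: R03 >= -1000",
    "constraint c3: R03 <= 1000",
    "constraint c4: R02 >= -1000",
    "constraint c5: R02 <= 1000",
    sep = "\n"),
  `12` = paste(
    "J0: S0 -> S1; k0*S0",
    "J1: n S1 -> m S2; k1*S1^n",
    "n := k2/2",
    "m = 2/3",
    sep = "\n"),
  `13` = paste(
    "0 = S1*k1 - 10",
    "alg2: 0 = S2*k2 - 20",
    sep = "\n")
)

#' Retrieve a bundled reference model
#'
#' @param n Listing number, 1 to 13.
#' @return The model text as a character scalar.
#' @examples
#' cat(ant_listing(1))
#' @export
ant_listing <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > length(LISTING_TEXTS)) {
    stop("listing number must be between 1 and ", length(LISTING_TEXTS))
  }
  paste0(LISTING_TEXTS[[as.character(n)]], "\n")
}

#' All bundled reference models
#' @return A named character vector of the 13 model texts.
#' @export
ant_listings <- function() {
  vapply(seq_along(LISTING_TEXTS), ant_listing, character(1))
}

#' Write the reference models out as `.ant` fixture files
#'
#' Deterministic: re-running produces byte-identical files.
#'
#' @param out_dir Directory to write into (created if missing).
#' @return Invisibly, the paths written, named `listing01.ant` ...
#'   `listing13.ant`.
#' @export
ant_write_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(LISTING_TEXTS)) {
    path <- file.path(out_dir, sprintf("listing%02d.ant", i))
    writeLines(sub("\n$", "", ant_listing(i)), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
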