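# Shared fixtures, built in code.

# two-step chain with an event that fires: the threshold crossing needs
# nonzero rate constants, so the uninitialized constants of the bundled
# event example are given driving values here
driven_event_model <- function() {
  paste(
    "J0: S0 -> S1; k0*S0",
    "J1: S1 -> S2; k1*S1",
    "if S1 > 10:",
    "  k0 = uniform(2.5, 5.5)",
    "S0 = 20",
    "S1 = 0",
    "S2 = 0",
    "k0 = 2",
    "k1 = 0.1",
    sep = "\n")
}

# the rateOf example with all constants given values, so rates are nonzero
rateof_model_with_values <- function() {
  paste(
    "J0: S0 -> S1; k0*S0",
    "J1: S1 -> S2; k1*S1",
    "X1 := rateOf(S1)",
    "C' = 10*k3",
    "X2 := rateOf(C)",
    "S0 = 4; S1 = 1; S2 = 0",
    "k0 = 0.8; k1 = 0.3; k3 = 0.25; C = 0",
    sep = "\n")
}

# provenance metadata block (identifiers.org links, creator, notes)
metadata_block <- function() {
  paste(
    "model mymeta()",
    "model model_source \"http://identifiers.org/biomodels.db/BIOMD0000000141\"",
    "model publication \"http://identifiers.org/pubmed/15484883\"",
    "model biological_system \"http://identifiers.org/go/GO:0019228\"",
    "model taxon \"http://identifiers.org/taxonomy/40674\"",
    "model created \"2007-07-16T09:41:14Z\"",
    "model modified \"2015-02-25T11:18:57Z\"",
    "model creator1.givenName \"John\"",
    "model creator1.familyName \"Smith\"",
    "model creator1.organization \"Oxford\"",
    "model creator1.email \"John@university.edu\"",
    "model notes \"This model describes how...\"",
    "end",
    sep = "\n")
}

# random linear chain with unit stoichiometries and mass-action laws;
# deterministic in `seed`
random_chain_model <- function(n_species, seed) {
  set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  k <- round(stats::runif(n_species - 1, 0.05, 0.5), 3)
  x0 <- round(stats::runif(n_species, 0, 5), 3)
  lines <- character(0)
  for (i in seq_len(n_species - 1)) {
    lines <- c(lines, sprintf("%s -> %s; k%d*%s", sp[i], sp[i + 1], i, sp[i]))
  }
  lines <- c(lines, sprintf("%s = %s", sp, x0),
             sprintf("k%d = %s", seq_len(n_species - 1), k))
  paste(lines, collapse = "\n")
}

read_file_text <- function(path) {
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

token_kinds <- function(text) {
  vapply(ant_tokenize(text), `[[`, "", "kind")
}

statement_variants <- function(text) {
  vapply(ant_parse(text), `[[`, "", "variant")
}

build_errors <- function(text) {
  diag_err <- Filter(function(d) d$severity == "error",
                     ant_validate_model(ant_model(text)))
  diag_err
}
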