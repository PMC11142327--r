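# SBML Level 3 translation: structure of the emitted documents, the import
# inverse, and MathML faithfulness.

test_that("a single mass-action reaction exports the expected elements", {
  doc <- ant_export_sbml(ant_model(ant_listing(1)))
  expect_length(xml2::xml_find_all(doc, "//*[local-name() = 'species']"), 2L)
  expect_length(xml2::xml_find_all(doc, "//*[local-name() = 'parameter']"), 1L)
  rxn <- xml2::xml_find_all(doc, "//*[local-name() = 'reaction']")
  expect_length(rxn, 1L)
  law_cis <- xml2::xml_text(xml2::xml_find_all(doc,
    "//*[local-name() = 'kineticLaw']//*[local-name() = 'ci']"))
  expect_setequal(trimws(law_cis), c("k1", "A"))
  root <- xml2::xml_root(doc)
  expect_equal(xml2::xml_attr(root, "level"), "3")
  expect_equal(xml2::xml_attr(root, "version"), "2")
})

test_that("every exported id is a valid SId and species have compartments", {
  for (i in 1:13) {
    doc <- ant_export_sbml(ant_model(ant_listing(i)))
    ids <- xml2::xml_attr(xml2::xml_find_all(doc, "//*[@id]"), "id")
    expect_true(all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)),
                info = paste("listing", i))
    sp <- xml2::xml_find_all(doc, "//*[local-name() = 'species']")
    expect_true(all(!is.na(xml2::xml_attr(sp, "compartment"))),
                info = paste("listing", i))
  }
})

test_that("an empty model exports a minimal valid document and reimports", {
  doc <- ant_export_sbml(ant_build_model(list()))
  expect_equal(xml2::xml_name(xml2::xml_root(doc)), "sbml")
  m <- ant_import_sbml(as.character(doc))
  expect_length(m$species, 0L)
  expect_length(m$reactions, 0L)
})

test_that("boundary species carry boundaryCondition but stay non-constant", {
  doc <- ant_export_sbml(ant_model(ant_listing(6)))
  a <- xml2::xml_find_first(doc, "//*[local-name() = 'species'][@id = 'A']")
  expect_equal(xml2::xml_attr(a, "boundaryCondition"), "true")
  expect_equal(xml2::xml_attr(a, "constant"), "false")
})

test_that("symbolic stoichiometries export as identified species references", {
  doc <- ant_export_sbml(ant_model(ant_listing(12)))
  refs <- xml2::xml_find_all(doc,
    "//*[local-name() = 'speciesReference'][@id]")
  expect_length(refs, 2L)
  ref_ids <- xml2::xml_attr(refs, "id")
  # the continuous-assigned stoichiometry n arrives via an assignment rule,
  # the initial-assigned m via an initial assignment
  ar <- xml2::xml_find_all(doc, "//*[local-name() = 'assignmentRule']")
  ia <- xml2::xml_find_all(doc, "//*[local-name() = 'initialAssignment']")
  expect_true(any(xml2::xml_attr(ar, "variable") %in% ref_ids))
  expect_true(any(xml2::xml_attr(ia, "symbol") %in% ref_ids))
})

test_that("rateOf and time serialize as csymbols", {
  doc <- ant_export_sbml(ant_model(ant_listing(8)))
  cs <- xml2::xml_find_all(doc, "//*[local-name() = 'csymbol']")
  urls <- xml2::xml_attr(cs, "definitionURL")
  expect_true("http://www.sbml.org/sbml/symbols/rateOf" %in% urls)
  doc5 <- ant_export_sbml(ant_model(ant_listing(5)))
  cs5 <- xml2::xml_find_all(doc5, "//*[local-name() = 'csymbol']")
  expect_true("http://www.sbml.org/sbml/symbols/time" %in%
                xml2::xml_attr(cs5, "definitionURL"))
})

test_that("import is the inverse of export on every bundled model", {
  for (i in 1:13) {
    m <- ant_model(ant_listing(i))
    m2 <- ant_import_sbml(ant_to_sbml(m))
    expect_true(ant_model_equal(m, m2), info = paste("listing", i))
  }
})

test_that("export-import-export is a byte-identical fixed point", {
  for (i in 1:13) {
    m <- ant_model(ant_listing(i))
    x1 <- ant_to_sbml(m)
    x2 <- ant_to_sbml(ant_import_sbml(x1))
    expect_identical(x2, x1, info = paste("listing", i))
  }
})

test_that("emitted MathML evaluates identically to the source expression", {
  texts <- c("k1*A", "k1*S1^n", "1 + amp*sin(time*freq)", "a/b - c*d",
             "-(x + y)/2", "2^-3 + sqrt(a)", "exp(-k*time) + ln(b)",
             "rateOf(S1)*2")
  syms <- c("k1", "A", "S1", "n", "amp", "freq", "a", "b", "c", "d",
            "x", "y", "k")
  set.seed(99)
  for (txt in texts) {
    ast <- ant_parse_expression(txt)
    math <- xml2::xml_new_root("math", xmlns = antsembly:::MATHML_NS)
    antsembly:::expr_to_mathml_node(math, ast)
    back <- antsembly:::mathml_to_expr(math)
    for (rep in 1:100) {
      e <- new.env()
      for (s in syms) assign(s, stats::runif(1, 0.1, 2), e)
      e$time <- stats::runif(1, 0, 10)
      e$rateOf <- function(x) 1.5
      e$ln <- log
      e$log <- log10
      v1 <- eval(antsembly:::to_r_call(ast), e)
      v2 <- eval(antsembly:::to_r_call(back), e)
      expect_equal(v2, v1, info = txt)
    }
  }
})

test_that("FBC version 2 namespaces are reported as unsupported", {
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="2" fbc:required="false"><model id="m"/></sbml>')
  m <- ant_import_sbml(xml)
  errs <- Filter(function(d) d$severity == "error", m$diagnostics)
  expect_length(errs, 1L)
  expect_match(errs[[1]]$message, "version 2")
})

test_that("unknown required packages abort, unknown optional ones warn", {
  req <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1" ',
    'level="3" version="2" comp:required="true"><model id="m"/></sbml>')
  expect_error(ant_import_sbml(req), class = "ant_unsupported_error")
  opt <- sub('comp:required="true"', 'comp:required="false"', req)
  m <- ant_import_sbml(opt)
  warns <- Filter(function(d) d$severity == "warning", m$diagnostics)
  expect_gt(length(warns), 0L)
})

test_that("unsupported core constructs are dropped with warnings", {
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2"><model id="m">',
    "<listOfFunctionDefinitions><functionDefinition id=\"f\"/></listOfFunctionDefinitions>",
    "</model></sbml>")
  m <- ant_import_sbml(xml)
  warns <- vapply(Filter(function(d) d$severity == "warning", m$diagnostics),
                  `[[`, "", "message")
  expect_true(any(grepl("FunctionDefinitions", warns)))
  expect_error(ant_import_sbml("<notsbml/>"), class = "ant_sbml_error")
  expect_error(ant_import_sbml(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4"><model/></sbml>'),
    class = "ant_unsupported_error")
})
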