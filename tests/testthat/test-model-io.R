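annotated_fixture_model <- function() {
  m <- make_toy_models("same_namespace_overlap")[[1]]
  m$metabolites[["glc__D_c"]]$annotations <-
    list("kegg.compound" = "C00031", chebi = "CHEBI:17634")
  m$metabolites[["atp_c"]]$charge <- -4L
  m$metabolites[["atp_c"]]$formula <- "C10H12N5O13P3"
  m$reactions[["HEX1"]]$annotations <- list("kegg.reaction" = "R00299")
  m$reactions[["HEX1"]]$gpr <- "(gA1 and gA3) or gA2"
  m
}

test_that("fixture SBML reads back with expected counts and objective", {
  m <- annotated_fixture_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  back <- read_model(path)
  expect_length(back$metabolites, 7)
  expect_length(back$reactions, 3)
  expect_equal(back$objective$coefficients, c(biomass_A = 1))
  expect_equal(back$objective$direction, "max")
  expect_equal(back$metabolites[["glc__D_c"]]$annotations$kegg.compound,
               "C00031")
})

test_that("models round trip identically through all three formats", {
  m <- annotated_fixture_model()
  for (fmt in c("sbml", "json", "mat")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_model(m, path, format = fmt)
    back <- read_model(path, format = fmt)
    expect_equal(back, m, info = fmt)
  }
})

test_that("reaction ids with the merge-conflict marker survive SBML", {
  m <- annotated_fixture_model()
  old <- names(m$reactions)[1]
  marked <- paste0(old, "∼")
  names(m$reactions)[1] <- marked
  m$reactions[[1]]$id <- marked
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  back <- read_model(path)
  expect_true(marked %in% names(back$reactions))
  # and the escaped SId in the file is still schema-legal
  ids <- xml2::xml_attr(xml2::xml_find_all(
    xml2::read_xml(path), ".//*[local-name()='reaction']"), "id")
  expect_true(all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)))
})

test_that("an empty model writes a valid minimal file in every format", {
  e <- gem_model("empty")
  for (fmt in c("sbml", "json", "mat")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_model(e, path, format = fmt)
    back <- read_model(path, format = fmt)
    expect_length(back$metabolites, 0)
    expect_length(back$reactions, 0)
  }
})

test_that("format inference and error reporting work", {
  expect_error(read_model(file.path(tempdir(), "absent.xml")),
               "does not exist")
  path <- withr::local_tempfile(fileext = ".gem")
  writeLines("x", path)
  expect_error(read_model(path), "cannot infer")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not xml <", bad)
  expect_error(read_model(bad), "SBML")
})

test_that("reading does not mutate the file", {
  m <- annotated_fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  before <- tools::md5sum(path)
  read_model(path)
  expect_identical(tools::md5sum(path), before)
})

test_that("reactants and products partition participants by sign", {
  r <- gem_reaction("r", c(A = -1, B = -2, C = 1))
  expect_setequal(reactants_of(r), c("A", "B"))
  expect_setequal(products_of(r), "C")
  r2 <- gem_reaction("r2", c(A = 2, B = 1))
  expect_length(reactants_of(r2), 0)
  expect_setequal(products_of(r2), c("A", "B"))
})

test_that("model invariants are enforced", {
  expect_error(gem_model("m", reactions = list(
    gem_reaction("r", c(ghost = -1)))), "unknown metabolites")
  expect_error(gem_reaction("r", c(a = -1), lower_bound = 5,
                            upper_bound = 1), "lower_bound")
  expect_error(gem_model("m",
    metabolites = list(gem_metabolite("a"), gem_metabolite("a"))),
    "duplicate")
})

test_that("our MAT files are readable by an independent implementation", {
  py <- Sys.which("python")
  m <- annotated_fixture_model()
  path <- withr::local_tempfile(fileext = ".mat")
  back_path <- withr::local_tempfile(fileext = ".mat")
  write_model(m, path, format = "mat")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, cobra.io",
    "m = cobra.io.load_matlab_model(sys.argv[1])",
    "assert len(m.metabolites) == 7 and len(m.reactions) == 3",
    "r = m.reactions.get_by_id('HEX1')",
    "assert r.gene_reaction_rule == '(gA1 and gA3) or gA2'",
    "assert r.bounds == (0.0, 1000.0)",
    "cobra.io.save_matlab_model(m, sys.argv[2])"), script)
  status <- system2(py, c(script, path, back_path),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  back <- read_model(back_path)
  expect_length(back$metabolites, 7)
  expect_length(back$reactions, 3)
  expect_equal(back$reactions[["HEX1"]]$lower_bound, 0)
  expect_equal(gemmerge:::gpr_normalize(back$reactions[["HEX1"]]$gpr),
               gemmerge:::gpr_normalize(m$reactions[["HEX1"]]$gpr))
})

test_that("GPR strings normalize and OR-merge with deduplication", {
  expect_equal(gemmerge:::gpr_normalize("g1 AND ( g2 or g3 )"),
               "g1 and (g2 or g3)")
  expect_equal(gemmerge:::gpr_or_merge("g1", "g2"), "(g1) or (g2)")
  expect_equal(gemmerge:::gpr_or_merge("g1", "g1"), "g1")
  expect_equal(gemmerge:::gpr_or_merge("(g1) or (g2)", "g2"),
               "(g1) or (g2)")
  expect_equal(gemmerge:::gpr_or_merge("", "g2"), "g2")
  expect_error(gemmerge:::gpr_parse("g1 and (g2"), "parse")
})
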