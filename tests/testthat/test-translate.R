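test_that("translation renames exactly the entities with target members", {
  mapper <- test_mapper()
  m <- make_toy_models("same_namespace_overlap")[[2]]  # has f6p (BiGG-only)
  out <- translate_model(m, "modelseed", mapper)
  ids <- names(out$model$metabolites)
  expect_true(all(c("cpd00027_c", "cpd00002_c", "cpd00079_c") %in% ids))
  # f6p has no ModelSEED member in the fixture mapper
  expect_true("f6p_c" %in% ids)
  expect_true("f6p_c" %in% out$report$metabolites$untranslatable)
  expect_equal(out$report$metabolites$translated, 5L)
  # report partition covers every metabolite
  r <- out$report$metabolites
  expect_equal(r$translated + length(r$untranslatable) +
                 length(r$ambiguous), length(m$metabolites))
})

test_that("translation to KEGG renames only KEGG-covered metabolites", {
  mapper <- test_mapper()
  m <- make_toy_models("stoichiometry_mismatch")[[1]]
  out <- translate_model(m, "kegg", mapper)
  ids <- names(out$model$metabolites)
  expect_true(all(c("C00031_c", "C00002_c", "C00008_c") %in% ids))
  expect_true("g6p_c" %in% ids)   # no KEGG member in the fixture mapper
})

test_that("translating into the model's own namespace is the identity", {
  mapper <- test_mapper()
  m <- make_toy_models("cross_namespace")[[2]]  # ModelSEED ids, _c0 tags
  out <- translate_model(m, "modelseed", mapper)
  # same native ids, canonical compartment suffix
  expect_setequal(names(out$model$metabolites),
                  sub("_c0$", "_c", names(m$metabolites)))
  again <- translate_model(out$model, "modelseed", mapper)
  expect_equal(again$model, out$model)
})

test_that("structure is untouched by translation", {
  mapper <- test_mapper()
  m <- make_toy_models("same_namespace_overlap")[[1]]
  out <- translate_model(m, "metanetx", mapper)
  for (i in seq_along(m$reactions)) {
    r0 <- m$reactions[[i]]
    r1 <- out$model$reactions[[i]]   # possibly renamed, same position
    expect_equal(unname(r1$participants), unname(r0$participants))
    expect_equal(r1$lower_bound, r0$lower_bound)
    expect_equal(r1$upper_bound, r0$upper_bound)
    expect_equal(r1$gpr, r0$gpr)
  }
})

test_that("unknown targets are rejected with the supported list", {
  expect_error(
    translate_model(make_toy_models("objective_merge")[[1]], "biocyc",
                    test_mapper()),
    "metanetx.*modelseed.*bigg.*kegg.*chebi")
})

test_that("rename collisions leave the later entity as ambiguous", {
  mapper <- test_mapper()
  # nh3 and nh4 share a universal entity; translating to ModelSEED both
  # want cpd00013_c, so the second keeps its id and is reported
  m <- make_toy_models("nh2_nh3_conflict")[[1]]
  out <- translate_model(m, "modelseed", mapper)
  ids <- names(out$model$metabolites)
  expect_true("cpd00013_c" %in% ids)
  expect_true("nh4_c" %in% ids)
  expect_true("nh4_c" %in% names(out$report$metabolites$ambiguous))
})

test_that("annotation extension adds one entry per member database", {
  mapper <- test_mapper()
  m <- make_toy_models("same_namespace_overlap")[[1]]
  ann <- extend_annotations(m, mapper)
  glc <- ann$metabolites[["glc__D_c"]]$annotations
  expect_gte(length(glc), 3)
  expect_equal(glc$metanetx.chemical, "MNXM41")
  expect_equal(glc$chebi, "CHEBI:17634")
  # reactions annotate through the reaction mapper
  hex <- ann$reactions[["HEX1"]]$annotations
  expect_equal(hex$kegg.reaction, "R00299")
  # unmapped entities are untouched
  expect_length(ann$metabolites[["f6p_c"]]$annotations, 0)
  f6p_in <- m$metabolites[["f6p_c"]]
  expect_equal(ann$metabolites[["f6p_c"]], f6p_in)
})

test_that("annotation extension is idempotent and preserves structure", {
  mapper <- test_mapper()
  m <- make_toy_models("same_namespace_overlap")[[1]]
  m$metabolites[["glc__D_c"]]$annotations <-
    list("kegg.compound" = "C00031", custom = "keepme")
  once <- extend_annotations(m, mapper)
  twice <- extend_annotations(once, mapper)
  expect_equal(twice, once)
  expect_true("keepme" %in%
                once$metabolites[["glc__D_c"]]$annotations$custom)
  expect_equal(once$metabolites[["glc__D_c"]]$annotations$kegg.compound,
               "C00031")
  for (rid in names(m$reactions))
    expect_equal(once$reactions[[rid]]$participants,
                 m$reactions[[rid]]$participants)
})
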