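test_that("compartment labels normalize to canonical short codes", {
  expect_equal(normalize_compartment("c0"), "c")
  expect_equal(normalize_compartment("[c]"), "c")
  expect_equal(normalize_compartment("Cytosol"), "c")
  expect_equal(normalize_compartment("extracellular space"), "e")
  expect_equal(normalize_compartment("boundary"), "b")
  expect_equal(normalize_compartment("mitochondria"), "m")
  expect_equal(normalize_compartment("xyz"), "xyz")
})

test_that("mergem ids concatenate universal id and compartment code", {
  mapper <- test_mapper()
  h <- gem_metabolite("h_c", compartment = "c")
  u <- map_to_universal("h", "metabolite", mapper)
  expect_equal(as.character(mergem_id(h, mapper)),
               paste0("mergem_", u, "_c"))
  # annotations are consulted when the id itself is unknown
  mystery <- gem_metabolite("mystery_c", compartment = "c0",
                            annotations = list("kegg.compound" = "C00031"))
  expect_equal(as.character(mergem_id(mystery, mapper)),
               paste0("mergem_",
                      map_to_universal("C00031", "metabolite", mapper),
                      "_c"))
  # unmapped metabolites keep their own id
  alien <- gem_metabolite("alien_c", compartment = "c")
  expect_equal(as.character(mergem_id(alien, mapper)), "alien_c")
})

test_that("reaction keys pair participants with signed integers", {
  r <- gem_reaction("r", c(mergem_23_c = -1, mergem_45_c = -1,
                           mergem_67_c = 1))
  k <- reaction_key(r)
  expect_setequal(paste(k$id, k$value),
                  c("mergem_23_c -1", "mergem_45_c -1", "mergem_67_c 1"))
  # default keys ignore coefficient magnitude
  r2 <- gem_reaction("r2", c(mergem_23_c = -7, mergem_45_c = -0.5,
                             mergem_67_c = 2))
  expect_equal(format(reaction_key(r2)), format(k))
  # exact mode keeps signed coefficients
  r3 <- gem_reaction("r3", c(mergem_15_c = -3, mergem_32_c = -1,
                             mergem_56_c = 2))
  k3 <- reaction_key(r3, exact_stoichiometry = TRUE)
  expect_setequal(paste(k3$id, k3$value),
                  c("mergem_15_c -3", "mergem_32_c -1", "mergem_56_c 2"))
  expect_error(reaction_key(gem_reaction("z", numeric())),
               "no participants")
})

test_that("reverse_key negates pairings and is an involution", {
  r <- gem_reaction("r", c(a = -1, b = 1))
  k <- reaction_key(r)
  rk <- reverse_key(k)
  expect_setequal(paste(rk$id, rk$value), c("a 1", "b -1"))
  expect_equal(format(reverse_key(rk)), format(k))
  ke <- reaction_key(gem_reaction("r2", c(a = -3, b = 2)),
                     exact_stoichiometry = TRUE)
  rke <- reverse_key(ke)
  expect_setequal(paste(rke$id, rke$value), c("a 3", "b -2"))
})

test_that("proton and boundary filtering falls back on empty keys", {
  mapper <- test_mapper()
  r <- gem_reaction("EX_h", c(h_e = -1, h_c = 1))
  omit <- c("h_e", "h_c")
  k <- reaction_key(r, omit = omit)
  expect_length(k$id, 2)       # unfiltered fallback kept the protons
  # include_protons retains them explicitly
  k2 <- reaction_key(r, include_protons = TRUE, omit = omit)
  expect_equal(format(k2), format(k))
  # a mixed reaction drops only the omitted participant
  r3 <- gem_reaction("r3", c(glc__D_c = -1, h_c = 1))
  k3 <- reaction_key(r3, omit = "h_c")
  expect_equal(k3$id, "glc__D_c")
})

test_that("template models are absorbed in full", {
  mapper <- test_mapper()
  models <- make_toy_models("same_namespace_overlap")
  res <- merge_gems(models, mapper = mapper)
  template <- models[[1]]
  for (mid in names(template$metabolites)) {
    hit <- vapply(res$mu, function(df)
      any(df$model == 1 & df$id == mid), TRUE)
    expect_true(any(hit), info = mid)
  }
  for (rid in names(template$reactions)) {
    hit <- vapply(res$rho, function(df)
      any(df$model == 1 & df$id == rid), TRUE)
    expect_true(any(hit), info = rid)
  }
  expect_gte(length(res$merged$metabolites),
             length(template$metabolites))
  expect_gte(length(res$merged$reactions), length(template$reactions))
})

test_that("a reaction matches the exact reverse of a template reaction", {
  mapper <- test_mapper()
  models <- make_toy_models("reversed_reaction")
  res <- merge_gems(models, mapper = mapper)
  expect_length(res$merged$reactions, length(models[[1]]$reactions))
  expect_setequal(res$rho[["HEX1"]]$model, c(1, 2))
  expect_true("HEX1_rev" %in% res$rho[["HEX1"]]$id)
})

test_that("GPRs of matched reactions are OR-combined", {
  mapper <- test_mapper()
  res <- merge_gems(make_toy_models("same_namespace_overlap"),
                    mapper = mapper)
  expect_equal(res$merged$reactions[["HEX1"]]$gpr, "(gA1) or (gB1)")
})

test_that("metabolites sharing a mergem id keep the original ids", {
  mapper <- test_mapper()
  models <- make_toy_models("nh2_nh3_conflict")
  res <- merge_gems(models, mapper = mapper)
  expect_setequal(names(res$merged$metabolites),
                  c("nh3_c", "nh4_c", "glc__D_c"))
  # the second model's nh4_c joined the untranslated template metabolite
  expect_setequal(res$mu[["nh4_c"]]$model, c(1, 2))
})

test_that("proton differences do not block reaction matching", {
  mapper <- test_mapper()
  models <- make_toy_models("proton_exchange")
  res <- merge_gems(models, mapper = mapper)
  # hexokinase written with and without the explicit proton merges
  expect_setequal(res$rho[["HEX1"]]$id, c("HEX1", "HEX1_noh"))
  # proton-only exchange reactions merge through the unfiltered fallback
  expect_setequal(res$rho[["EX_h"]]$id, c("EX_h", "EX_h_b"))
  # but with include_protons the proton-free variant stays separate
  res2 <- merge_gems(models, include_protons = TRUE, mapper = mapper)
  expect_true("HEX1_noh" %in% names(res2$merged$reactions))
})

test_that("exact stoichiometry mode separates coefficient mismatches", {
  mapper <- test_mapper()
  models <- make_toy_models("stoichiometry_mismatch")
  res_default <- merge_gems(models, mapper = mapper)
  res_exact <- merge_gems(models, exact_stoichiometry = TRUE,
                          mapper = mapper)
  expect_true("R1b" %in% names(res_exact$merged$reactions))
  expect_false("R1b" %in% names(res_default$merged$reactions))
})

test_that("conflicting reaction ids get the marker suffix", {
  mapper <- test_mapper()
  a <- gem_model("idA",
    metabolites = list(gem_metabolite("x_c"), gem_metabolite("y_c")),
    reactions = list(
      gem_reaction("R1", c(x_c = -1, y_c = 1)),
      gem_reaction("bioA", c(x_c = -1), lower_bound = 0)),
    objective = c(bioA = 1))
  b <- gem_model("idB",
    metabolites = list(gem_metabolite("x_c"), gem_metabolite("z_c")),
    reactions = list(
      gem_reaction("R1", c(x_c = -1, z_c = 1)),  # same id, other chemistry
      gem_reaction("bioB", c(x_c = -1), lower_bound = 0)),
    objective = c(bioB = 1))
  res <- merge_gems(list(a, b), mapper = test_mapper())
  expect_true("R1∼" %in% names(res$merged$reactions))
})

test_that("merged ids revert to the first model's original ids", {
  mapper <- test_mapper()
  for (sc in all_scenarios) {
    res <- merge_gems(make_toy_models(sc), mapper = mapper)
    expect_false(any(grepl("^mergem_", names(res$merged$metabolites))),
                 info = sc)
    participants <- unlist(lapply(res$merged$reactions, function(r)
      names(r$participants)))
    expect_false(any(grepl("^mergem_", participants)), info = sc)
  }
  # a metabolite first seen in model 2 keeps model 2's original id
  models <- make_toy_models("same_namespace_overlap")
  res <- merge_gems(models, mapper = mapper)
  expect_true("f6p_c" %in% names(res$merged$metabolites))
})

test_that("every input entity is accounted for in the source maps", {
  mapper <- test_mapper()
  for (sc in all_scenarios) {
    models <- make_toy_models(sc)
    res <- merge_gems(models, mapper = mapper)
    for (i in seq_along(models)) {
      for (mid in names(models[[i]]$metabolites)) {
        n <- sum(vapply(res$mu, function(df)
          any(df$model == i & df$id == mid), TRUE))
        expect_equal(n, 1L, info = paste(sc, "model", i, "met", mid))
      }
      obj <- names(models[[i]]$objective$coefficients)
      for (rid in names(models[[i]]$reactions)) {
        n <- sum(vapply(res$rho, function(df)
          any(df$model == i & df$id == rid), TRUE))
        if (rid %in% obj) {
          # objective reactions can appear both as a structural copy and
          # behind the merged objective
          expect_gte(n, 1L)
        } else {
          expect_equal(n, 1L, info = paste(sc, "model", i, "rxn", rid))
        }
      }
    }
  }
})

test_that("merged counts are insensitive to input order", {
  mapper <- test_mapper()
  for (sc in c("same_namespace_overlap", "cross_namespace")) {
    models <- make_toy_models(sc)
    fwd <- merge_gems(models, mapper = mapper)
    rev <- merge_gems(rev(models), mapper = mapper)
    expect_equal(length(fwd$merged$metabolites),
                 length(rev$merged$metabolites), info = sc)
    expect_equal(length(fwd$merged$reactions),
                 length(rev$merged$reactions), info = sc)
  }
})

test_that("objective copying reproduces the chosen model's objective", {
  mapper <- test_mapper()
  models <- make_toy_models("same_namespace_overlap")
  res1 <- merge_gems(models, objective = 1, mapper = mapper)
  expect_equal(res1$merged$objective$coefficients, c(biomass_A = 1))
  res2 <- merge_gems(models, objective = 2, mapper = mapper)
  expect_equal(names(res2$merged$objective$coefficients), "biomass_B")
  p <- res2$merged$reactions[["biomass_B"]]$participants
  expect_equal(p[order(names(p))], c(atp_c = -3, f6p_c = -1))
  expect_error(merge_gems(models, objective = 7, mapper = mapper),
               "model index")
})

test_that("merged objective averages per containing reaction", {
  mapper <- test_mapper()
  res <- merge_gems(make_toy_models("objective_merge"), mapper = mapper)
  p <- res$merged$reactions[["merged_objective"]]$participants
  expect_equal(p[["atp_c"]], -2)      # (1 + 3) / 2
  expect_equal(p[["pyr_c"]], -5)      # present in one reaction only
  expect_equal(p[["g6p_c"]], -1)
  expect_equal(res$merged$objective$coefficients,
               c(merged_objective = 1))
  expect_equal(res$merged$objective$direction, "max")
})

test_that("fewer than two models is rejected", {
  expect_error(merge_gems(list(make_toy_models("objective_merge")[[1]]),
                          mapper = test_mapper()), "at least two")
})

test_that("merged reaction counts match the canonical-key oracle", {
  mapper <- test_mapper()
  for (sc in all_scenarios) {
    models <- make_toy_models(sc)
    for (exact in c(FALSE, TRUE)) {
      res <- merge_gems(models, objective = 1, exact_stoichiometry = exact,
                        mapper = mapper)
      expect_equal(length(res$merged$reactions),
                   oracle_reaction_count(models, mapper, exact),
                   info = paste(sc, "exact:", exact))
    }
  }
})

test_that("fixture files serialize and re-read in every format", {
  dir <- withr::local_tempdir()
  models <- make_toy_models("cross_namespace")
  paths <- write_fixture_files(models, dir)
  expect_length(paths, 6)
  for (p in paths) {
    back <- read_model(p)
    expect_gt(length(back$metabolites), 0)
  }
  # deterministic bytes for the text formats
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture_files(models, dir2, formats = c("sbml", "json"))
  for (p in paths2) {
    ref <- file.path(dir, basename(p))
    expect_identical(readLines(p), readLines(ref))
  }
})
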