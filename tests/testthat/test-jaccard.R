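test_that("Jaccard distance hits its limits and the formula", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a", "b"), c("c", "d")), 1)
  expect_equal(jaccard_distance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_distance(character(), character()), 0)
  expect_equal(jaccard_distance(c("a", "a", "b"), c("a", "b")), 0)
})

test_that("distance matrices stay in range on random set families", {
  set.seed(421)
  universe <- paste0("m", 1:30)
  for (rep in 1:50) {
    a <- sample(universe, sample(0:20, 1))
    b <- sample(universe, sample(1:20, 1))
    d <- jaccard_distance(a, b)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, jaccard_distance(b, a))
  }
})

test_that("merge distance matrices have zero diagonals and [0,1] entries", {
  mapper <- test_mapper()
  for (sc in all_scenarios) {
    res <- merge_gems(make_toy_models(sc), mapper = mapper)
    jm <- res$jaccard
    expect_true(all(diag(jm) == 0), info = sc)
    expect_true(all(jm >= 0 & jm <= 1), info = sc)
  }
})

test_that("matrix carries metabolite distances above, reactions below", {
  mapper <- test_mapper()
  res <- merge_gems(make_toy_models("same_namespace_overlap"),
                    mapper = mapper)
  # hand count: 5 of 8 merged metabolites shared
  expect_equal(res$jaccard[1, 2], 1 - 5 / 8)
  # reactions: HEX1 and the merged objective shared, 5 total entries
  expect_equal(res$jaccard[2, 1], 1 - 2 / 5)
})

test_that("the matrix is invariant under metabolite relabeling", {
  mapper <- test_mapper()
  models <- make_toy_models("cross_namespace")
  res <- merge_gems(models, mapper = mapper)
  # relabel the template into ModelSEED ids (mapping-preserving renames)
  relabeled <- translate_model(models[[1]], "modelseed", mapper)$model
  res2 <- merge_gems(list(relabeled, models[[2]]), mapper = mapper)
  expect_equal(unname(res2$jaccard), unname(res$jaccard))
})

test_that("disjoint unmappable models are at distance one", {
  a <- gem_model("dja",
    metabolites = list(gem_metabolite("only_a_c")),
    reactions = list(gem_reaction("ra", c(only_a_c = 1)),
                     gem_reaction("bioa", c(only_a_c = -1),
                                  lower_bound = 0)),
    objective = c(bioa = 1))
  b <- gem_model("djb",
    metabolites = list(gem_metabolite("only_b_c")),
    reactions = list(gem_reaction("rb", c(only_b_c = 1)),
                     gem_reaction("biob", c(only_b_c = -1),
                                  lower_bound = 0)),
    objective = c(biob = 1))
  res <- merge_gems(list(a, b), objective = 1, mapper = test_mapper())
  expect_equal(res$jaccard[1, 2], 1)
  expect_equal(res$jaccard[2, 1], 1)
})

test_that("three-model merges fill every off-diagonal cell", {
  mapper <- test_mapper()
  models <- c(make_toy_models("same_namespace_overlap"),
              make_toy_models("cross_namespace")[2])
  res <- merge_gems(models, mapper = mapper)
  expect_equal(dim(res$jaccard), c(3, 3))
  expect_true(all(diag(res$jaccard) == 0))
  # model 3 is the ModelSEED twin of model 1: identical chemistry
  expect_equal(res$jaccard[1, 3], 0)
})
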