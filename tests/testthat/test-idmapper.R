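test_that("MetaNetX xref parsing yields entity records and pairs", {
  dir <- withr::local_tempdir()
  xref <- file.path(dir, "chem_xref.tsv")
  writeLines(c("#source\tID\tdescription",
               "mnx:MNXM41\tMNXM41\tglucose",
               "biggM:glc__D\tMNXM41\tglucose",
               "keggC:C00031\tMNXM41\tglucose"), xref)
  out <- parse_database_dump("metanetx", c(chem_xref = xref))
  expect_length(out$records, 1)
  expect_equal(out$records[[1]]$native_id, "MNXM41")
  expect_length(out$xrefs, 2)
  expect_setequal(vapply(out$xrefs, `[[`, "", "target_db"),
                  c("bigg", "kegg"))
})

test_that("empty dump files parse to empty record and xref lists", {
  dir <- withr::local_tempdir()
  for (db in c("metanetx", "kegg")) {
    f <- file.path(dir, "empty.tsv")
    writeLines(character(), f)
    role <- if (db == "metanetx") c(chem_prop = f) else c(compound = f)
    out <- parse_database_dump(db, role)
    expect_length(out$records, 0)
    expect_length(out$xrefs, 0)
  }
})

test_that("ModelSEED obsolete rows and alias mappings are excluded", {
  dumps <- make_mini_dumps(withr::local_tempdir())
  out <- parse_database_dump("modelseed", dumps$modelseed)
  ids <- vapply(out$records, `[[`, "", "native_id")
  expect_false("cpd99999" %in% ids)       # is_obsolete row dropped
  expect_true("cpd00027" %in% ids)
  expect_length(out$xrefs, 0)             # alias mappings never emitted
})

test_that("conflicting cross-reference leaves the second source id apart", {
  mapper <- test_mapper()
  u_first <- map_to_universal("MNXM100", "metabolite", mapper)
  u_second <- map_to_universal("MNXM200", "metabolite", mapper)
  expect_false(u_first == u_second)
  # q8 was claimed by MNXM100 first, so it stays there
  expect_equal(map_to_universal("q8", "metabolite", mapper), u_first)
  # q8h2 reached MNXM200 through an unconflicted BiGG link
  expect_equal(map_to_universal("q8h2", "metabolite", mapper), u_second)
})

test_that("mapper partition matches the sequential-replay oracle", {
  dir <- withr::local_tempdir()
  xref <- file.path(dir, "chem_xref.tsv")
  # A(db1)-X(db2), then B(db1)-X(db2) must skip; plus a transitive chain
  writeLines(c("biggM:X\tA\t",
               "biggM:X\tB\t",
               "keggC:K\tA\t"), xref)
  mapper <- build_universal_mapper(list(metanetx = c(chem_xref = xref)))
  oracle <- replay_partition(
    entities = list(),
    pairs = list(c("metanetx", "A", "bigg", "X"),
                 c("metanetx", "B", "bigg", "X"),
                 c("metanetx", "A", "kegg", "K")))
  expect_equal(mapper_partition(mapper), oracle)
  # A, X and K share one universal id; B stands alone
  uA <- map_to_universal("A", "metabolite", mapper)
  expect_equal(map_to_universal("X", "metabolite", mapper), uA)
  expect_equal(map_to_universal("K", "metabolite", mapper), uA)
  expect_false(map_to_universal("B", "metabolite", mapper) == uA)
})

test_that("full mini-dump partition equals the replay oracle", {
  dumps <- make_mini_dumps(withr::local_tempdir())
  mapper <- build_universal_mapper(dumps)
  entities <- list()
  pairs <- list()
  for (db in names(dumps)) {
    parsed <- parse_database_dump(db, dumps[[db]])
    for (r in parsed$records)
      if (r$entity_class == "metabolite")
        entities[[length(entities) + 1L]] <- c(r$database, r$native_id)
    for (x in parsed$xrefs)
      if (x$entity_class == "metabolite")
        pairs[[length(pairs) + 1L]] <- c(x$source_db, x$source_id,
                                         x$target_db, x$target_id)
  }
  expect_equal(mapper_partition(mapper, "metabolite"),
               replay_partition(entities, pairs))
})

test_that("a single database without xrefs yields one entity per record", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "compound.tsv")
  writeLines(c("C00001\tWater", "C00002\tATP", "C00003\tNAD+"), f)
  mapper <- build_universal_mapper(list(kegg = c(compound = f)))
  expect_equal(mapper$n_met, 3L)
})

test_that("adding a cross-reference never increases the entity count", {
  dir <- withr::local_tempdir()
  prop <- file.path(dir, "chem_prop.tsv")
  writeLines(c("MNXM1\twater\t\tH2O\t0\t18.02\t\t\t",
               "MNXM2\tatp\t\tC10H12N5O13P3\t-4\t507.18\t\t\t",
               "MNXM3\tglc\t\tC6H12O6\t0\t180.16\t\t\t"), prop)
  bigg <- file.path(dir, "metabolites.tsv")
  writeLines(c(paste("bigg_id", "universal_bigg_id", "name",
                     "model_list", "database_links", sep = "\t"),
               "glc_c\tglc\tGlucose\tm\t", "atp_c\tatp\tATP\tm\t"), bigg)
  pairs <- c("biggM:glc\tMNXM3\t", "biggM:atp\tMNXM2\t",
             "biggM:glc\tMNXM1\t", "biggM:atp\tMNXM2\t")
  counts <- integer()
  for (k in seq(0, length(pairs))) {
    f <- file.path(dir, "chem_xref.tsv")
    writeLines(pairs[seq_len(k)], f)
    m <- build_universal_mapper(
      list(metanetx = c(chem_prop = prop, chem_xref = f),
           bigg = c(metabolites = bigg)))
    counts <- c(counts, m$n_met)
  }
  expect_equal(counts[1], 5L)           # 3 MNX + 2 BiGG singletons
  expect_true(all(diff(counts) <= 0))   # links only ever merge
})

test_that("building twice from identical dumps is deterministic", {
  dumps <- make_mini_dumps(withr::local_tempdir())
  m1 <- build_universal_mapper(dumps)
  m2 <- build_universal_mapper(dumps)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_mapper_csv(m1, d1)
  export_mapper_csv(m2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("every native id belongs to exactly one universal entity", {
  mapper <- test_mapper()
  members <- unlist(mapper_partition(mapper, "metabolite"))
  expect_false(anyDuplicated(members) > 0)
  members_r <- unlist(mapper_partition(mapper, "reaction"))
  expect_false(anyDuplicated(members_r) > 0)
  # and every mapped id points at an entity with a property bundle
  for (raw in ls(mapper$met_id2u)) {
    u <- mapper$met_id2u[[raw]]
    expect_false(is.null(mapper$met_props[[as.character(u)]]))
  }
})

test_that("raw-id lookup strips prefixes and compartment tags in order", {
  mapper <- test_mapper()
  u_glc <- map_to_universal("glc__D", "metabolite", mapper)
  expect_equal(map_to_universal("glc__D_c", "metabolite", mapper), u_glc)
  expect_equal(map_to_universal("M_glc__D_c", "metabolite", mapper), u_glc)
  expect_equal(map_to_universal("glc__D[c]", "metabolite", mapper), u_glc)
  u_seed <- map_to_universal("cpd00027", "metabolite", mapper)
  expect_equal(map_to_universal("M_cpd00027_c0", "metabolite", mapper),
               u_seed)
  expect_equal(
    map_to_universal("bigg.metabolite:glc__D", "metabolite", mapper),
    u_glc)
  expect_equal(map_to_universal("CHEBI:17634", "metabolite", mapper),
               u_glc)
  expect_null(map_to_universal("", "metabolite", mapper))
  expect_null(map_to_universal("no_such_met", "metabolite", mapper))
})

test_that("consolidated properties union names and keep first scalars", {
  mapper <- test_mapper()
  p <- get_properties("glc__D", "metabolite", mapper)
  expect_equal(p$formula, "C6H12O6")
  expect_equal(p$molecular_weight, 180.16)
  expect_equal(p$inchi_key, "WQZGKKKJIJFFOK-GASJEMHNSA-N")
  # names merged across MetaNetX, ModelSEED, KEGG and ChEBI entries
  expect_true(all(c("D-glucose", "D-Glucose", "Dextrose") %in% p$names))
  expect_setequal(names(p$member_ids),
                  c("metanetx", "modelseed", "bigg", "kegg", "chebi"))
  expect_null(get_properties("unknown_xyz", "metabolite", mapper))
  # reaction properties: EC numbers unioned
  pr <- get_properties("HEX1", "reaction", mapper)
  expect_true("2.7.1.1" %in% pr$ec_numbers)
  expect_true("rxn00216" %in% pr$member_ids$modelseed)
})

test_that("metabolite and reaction id spaces never mix", {
  mapper <- test_mapper()
  expect_null(map_to_universal("HEX1", "metabolite", mapper))
  expect_null(map_to_universal("glc__D", "reaction", mapper))
})

test_that("mapper save/load round trips, including proton flags", {
  mapper <- test_mapper()
  path <- withr::local_tempfile(fileext = ".rds")
  save_mapper(mapper, path)
  back <- load_mapper(path)
  expect_equal(gemmerge:::mapper_to_list(back),
               gemmerge:::mapper_to_list(mapper))
  expect_identical(back$proton_ids, mapper$proton_ids)
  expect_error(load_mapper(file.path(tempdir(), "nope.rds")),
               "does not exist")
  # version mismatch is an explicit error
  bad <- gemmerge:::mapper_to_list(mapper)
  bad$version <- 999L
  saveRDS(bad, path)
  expect_error(load_mapper(path), "version")
})

test_that("CSV export has one row per raw id and reimports losslessly", {
  mapper <- test_mapper()
  dir <- withr::local_tempdir()
  paths <- export_mapper_csv(mapper, dir)
  idmap <- utils::read.csv(file.path(dir, "met_id_map.csv"))
  expect_equal(nrow(idmap), length(ls(mapper$met_id2u)))
  back <- import_mapper_csv(dir)
  expect_equal(as.list(back$met_id2u, sorted = TRUE),
               as.list(mapper$met_id2u, sorted = TRUE))
  expect_equal(as.list(back$reac_id2u, sorted = TRUE),
               as.list(mapper$reac_id2u, sorted = TRUE))
  expect_identical(back$proton_ids, mapper$proton_ids)
  # empty mapper exports header-only tables
  dir2 <- withr::local_tempdir()
  f <- file.path(dir2, "compound.tsv")
  writeLines(character(), f)
  empty <- build_universal_mapper(list(kegg = c(compound = f)))
  dir3 <- withr::local_tempdir()
  export_mapper_csv(empty, dir3)
  expect_length(readLines(file.path(dir3, "met_id_map.csv")), 1L)
})

test_that("update_mapper with a fully pre-placed cache stays offline", {
  cache <- withr::local_tempdir()
  dumps <- make_mini_dumps(withr::local_tempdir())
  for (db in names(dumps)) {
    for (role in names(dumps[[db]])) {
      file.copy(dumps[[db]][[role]],
                file.path(cache, paste0(db, "_", role, ".tsv")))
    }
  }
  m <- update_mapper(cache)
  ref <- build_universal_mapper(dumps)
  expect_equal(gemmerge:::mapper_to_list(m),
               gemmerge:::mapper_to_list(ref))
})

test_that("protons are recognized by formula and by name", {
  mapper <- test_mapper()
  u <- map_to_universal("h", "metabolite", mapper)
  expect_true(u %in% mapper$proton_ids)
  expect_false(map_to_universal("h2o", "metabolite", mapper) %in%
                 mapper$proton_ids)
})
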