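# Deterministic fixtures: mini database dumps and toy GEMs.
#
# The mini dumps cover, in ~50 records per database: a glucose entity
# cross-referenced across all five databases; an ammonia entity holding two
# distinct BiGG ids (nh3/nh4, the "two metabolites, one universal id"
# situation); a proton (formula "H"); a ubiquinone/ubiquinol conflict pair
# exercising the cross-reference skip rule; and matching reaction records.
# Everything is written from string literals, so regeneration is
# byte-identical and the resulting universal-id numbering never drifts.

MINI_METANETX_CHEM_PROP <- c(
  "#ID\tname\treference\tformula\tcharge\tmass\tInChI\tInChIKey\tSMILES",
  "MNXM1\tH(+)\tchebi:15378\tH\t1\t1.008\t\tGPRLSGONYQIRFK-UHFFFAOYSA-N\t",
  "MNXM3\tATP\tchebi:30616\tC10H12N5O13P3\t-4\t507.18\t\t\t",
  "MNXM7\tADP\tchebi:456216\tC10H12N5O10P2\t-3\t427.2\t\t\t",
  "MNXM9\tphosphate\tchebi:43474\tHPO4\t-2\t95.98\t\t\t",
  "MNXM41\tD-glucose\tchebi:17634\tC6H12O6\t0\t180.16\t\tWQZGKKKJIJFFOK-GASJEMHNSA-N\t",
  "MNXM2\twater\tchebi:15377\tH2O\t0\t18.02\t\t\t",
  "MNXM15\tammonia\tchebi:16134\tH3N\t0\t17.03\t\t\t",
  "MNXM23\tpyruvate\tchebi:15361\tC3H3O3\t-1\t87.05\t\t\t",
  "MNXM105\tD-glucose 6-phosphate\tchebi:4170\tC6H11O9P\t-2\t258.12\t\t\t",
  "MNXM100\tubiquinone-8\tchebi:61683\tC49H74O4\t0\t727.1\t\t\t",
  "MNXM200\tubiquinol-8\tchebi:61682\tC49H76O4\t0\t729.1\t\t\t")

MINI_METANETX_CHEM_XREF <- c(
  "#source\tID\tdescription",
  "mnx:MNXM41\tMNXM41\tD-glucose",
  "biggM:glc__D\tMNXM41\tD-Glucose",
  "keggC:C00031\tMNXM41\tD-Glucose",
  "seedM:cpd00027\tMNXM41\tD-Glucose",
  "CHEBI:17634\tMNXM41\tD-glucopyranose",
  "biggM:atp\tMNXM3\tATP",
  "seedM:cpd00002\tMNXM3\tATP",
  "keggC:C00002\tMNXM3\tATP",
  "biggM:adp\tMNXM7\tADP",
  "seedM:cpd00008\tMNXM7\tADP",
  "keggC:C00008\tMNXM7\tADP",
  "biggM:pi\tMNXM9\tphosphate",
  "seedM:cpd00009\tMNXM9\tphosphate",
  "biggM:h\tMNXM1\tproton",
  "seedM:cpd00067\tMNXM1\tproton",
  "keggC:C00080\tMNXM1\tproton",
  "CHEBI:15378\tMNXM1\thydron",
  "biggM:h2o\tMNXM2\twater",
  "seedM:cpd00001\tMNXM2\twater",
  "biggM:nh3\tMNXM15\tammonia",
  "biggM:nh4\tMNXM15\tammonium",
  "seedM:cpd00013\tMNXM15\tammonia",
  "biggM:pyr\tMNXM23\tpyruvate",
  "seedM:cpd00020\tMNXM23\tpyruvate",
  "keggC:C00022\tMNXM23\tpyruvate",
  "biggM:g6p\tMNXM105\tD-glucose 6-phosphate",
  "seedM:cpd00079\tMNXM105\tD-glucose 6-phosphate",
  "biggM:q8\tMNXM100\tubiquinone-8",
  "biggM:q8\tMNXM200\tubiquinol-8 (conflicting mapping)")

MINI_METANETX_REAC_PROP <- c(
  "#ID\tmnx_equation\treference\tclassifs\tis_balanced\tis_transport",
  "MNXR100\t1 MNXM41 + 1 MNXM3 = 1 MNXM105 + 1 MNXM7 + 1 MNXM1\tbigg:HEX1\t2.7.1.1\tB\t0",
  "MNXR101\t1 MNXM105 = 1 MNXM106\tbigg:PGI\t5.3.1.9\tB\t0")

MINI_METANETX_REAC_XREF <- c(
  "#source\tID\tdescription",
  "biggR:HEX1\tMNXR100\thexokinase",
  "seedR:rxn00216\tMNXR100\thexokinase",
  "keggR:R00299\tMNXR100\thexokinase",
  "biggR:PGI\tMNXR101\tglucose-6-phosphate isomerase")

MINI_MODELSEED_COMPOUNDS <- c(
  paste("id", "abbreviation", "name", "formula", "mass", "source",
        "inchikey", "charge", "is_obsolete", "aliases", sep = "\t"),
  "cpd00027\tglc\tD-Glucose\tC6H12O6\t180.16\tPrimary\tWQZGKKKJIJFFOK-GASJEMHNSA-N\t0\t0\tBiGG: glc__D; KEGG: C00031",
  "cpd00002\tatp\tATP\tC10H12N5O13P3\t507.18\tPrimary\t\t-4\t0\tBiGG: atp",
  "cpd00008\tadp\tADP\tC10H12N5O10P2\t427.2\tPrimary\t\t-3\t0\tBiGG: adp",
  "cpd00009\tpi\tPhosphate\tHPO4\t95.98\tPrimary\t\t-2\t0\tBiGG: pi",
  "cpd00067\th\tH+\tH\t1.008\tPrimary\t\t1\t0\tBiGG: h",
  "cpd00001\th2o\tH2O\tH2O\t18.02\tPrimary\t\t0\t0\tBiGG: h2o",
  "cpd00013\tnh3\tNH3\tH3N\t17.03\tPrimary\t\t0\t0\tBiGG: nh4",
  "cpd00020\tpyr\tPyruvate\tC3H3O3\t87.05\tPrimary\t\t-1\t0\tBiGG: pyr",
  "cpd00079\tg6p\tD-glucose-6-phosphate\tC6H11O9P\t258.12\tPrimary\t\t-2\t0\tBiGG: g6p",
  "cpd99999\toldglc\tD-Glucose (obsolete)\tC6H12O6\t180.16\tSecondary\t\t0\t1\tBiGG: glc__D")

MINI_MODELSEED_REACTIONS <- c(
  paste("id", "name", "ec_numbers", "is_obsolete", "aliases", sep = "\t"),
  "rxn00216\tATP:D-glucose 6-phosphotransferase\t2.7.1.1\t0\tBiGG: HEX1",
  "rxn01111\talcohol dehydrogenase\t1.1.1.1\t0\t")

MINI_BIGG_METABOLITES <- c(
  paste("bigg_id", "universal_bigg_id", "name", "model_list",
        "database_links", sep = "\t"),
  "glc__D_c\tglc__D\tD-Glucose\tiML1515\tCHEBI: http://identifiers.org/chebi/CHEBI:17634; KEGG Compound: http://identifiers.org/kegg.compound/C00031; InChI Key: https://identifiers.org/inchikey/WQZGKKKJIJFFOK-GASJEMHNSA-N",
  "atp_c\tatp\tATP\tiML1515\tKEGG Compound: http://identifiers.org/kegg.compound/C00002",
  "adp_c\tadp\tADP\tiML1515\tKEGG Compound: http://identifiers.org/kegg.compound/C00008",
  "pi_c\tpi\tPhosphate\tiML1515\t",
  "h_c\th\tH+\tiML1515\tCHEBI: http://identifiers.org/chebi/CHEBI:15378",
  "h2o_c\th2o\tH2O\tiML1515\t",
  "nh3_c\tnh3\tAmmonia\tiML1515\t",
  "nh4_c\tnh4\tAmmonium\tiML1515\t",
  "pyr_c\tpyr\tPyruvate\tiML1515\tKEGG Compound: http://identifiers.org/kegg.compound/C00022",
  "g6p_c\tg6p\tD-Glucose 6-phosphate\tiML1515\t",
  "f6p_c\tf6p\tD-Fructose 6-phosphate\tiML1515\t",
  "q8_c\tq8\tUbiquinone-8\tiML1515\t",
  "q8h2_c\tq8h2\tUbiquinol-8\tiML1515\tMetaNetX (MNX) Chemical: http://identifiers.org/metanetx.chemical/MNXM200")

MINI_BIGG_REACTIONS <- c(
  paste("bigg_id", "name", "reaction_string", "model_list",
        "database_links", sep = "\t"),
  "HEX1\tHexokinase\tatp_c + glc__D_c <-> adp_c + g6p_c + h_c\tiML1515\tKEGG Reaction: http://identifiers.org/kegg.reaction/R00299; EC Number: http://identifiers.org/ec-code/2.7.1.1",
  "PGI\tGlucose-6-phosphate isomerase\tg6p_c <-> f6p_c\tiML1515\t",
  "PYK\tPyruvate kinase\tadp_c + h_c + pep_c <-> atp_c + pyr_c\tiML1515\t")

MINI_KEGG_COMPOUND <- c(
  "C00031\tD-Glucose; Grape sugar; Dextrose",
  "C00002\tATP; Adenosine 5'-triphosphate",
  "C00008\tADP; Adenosine 5'-diphosphate",
  "C00080\tH+; Hydron",
  "C00022\tPyruvate; Pyruvic acid",
  "C00014\tAmmonia; NH3")

MINI_KEGG_REACTION <- c(
  "R00299\tHexokinase; ATP:D-glucose 6-phosphotransferase",
  "R00200\tPyruvate kinase reaction")

MINI_CHEBI_NAMES <- c(
  paste("ID", "COMPOUND_ID", "TYPE", "SOURCE", "NAME", "ADAPTED",
        "LANGUAGE", sep = "\t"),
  "1001\t17634\tNAME\tChEBI\tD-glucopyranose\tNO\ten",
  "1002\t17634\tSYNONYM\tKEGG COMPOUND\tDextrose\tNO\ten",
  "1003\t15378\tNAME\tChEBI\thydron\tNO\ten",
  "1004\t17234\tNAME\tChEBI\tglucose\tNO\ten",
  "1005\t16761\tNAME\tChEBI\tADP\tNO\ten")

MINI_CHEBI_ACCESSIONS <- c(
  paste("ID", "COMPOUND_ID", "SOURCE", "TYPE", "ACCESSION_NUMBER",
        sep = "\t"),
  "2001\t17634\tKEGG COMPOUND\tKEGG COMPOUND accession\tC00031",
  "2002\t16761\tKEGG COMPOUND\tKEGG COMPOUND accession\tC00008")

MINI_CHEBI_CHEMICAL_DATA <- c(
  paste("ID", "COMPOUND_ID", "SOURCE", "TYPE", "CHEMICAL_DATA", sep = "\t"),
  "3001\t17634\tChEBI\tFORMULA\tC6H12O6",
  "3002\t17634\tChEBI\tMASS\t180.16",
  "3003\t15378\tChEBI\tFORMULA\tH")

#' Write the bundled mini database dumps
#'
#' Writes, with no network access, a miniature but dialect-faithful set of
#' database dump files for all five supported databases into `out_dir`.
#' Feeding the returned list to [build_universal_mapper()] yields a fully
#' deterministic fixture mapper: 14 metabolite and 5 reaction universal
#' entities, with glucose cross-referenced across all databases, an ammonia
#' entity containing both BiGG `nh3` and `nh4`, a proton entity (formula
#' `"H"`), and a ubiquinone/ubiquinol pair whose conflicting `q8`
#' cross-reference must be skipped.
#'
#' @param out_dir output directory, created if needed.
#' @return named list of per-database dump file paths, in default precedence
#'   order, ready for [build_universal_mapper()].
#' @export
make_mini_dumps <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name, lines) {
    path <- file.path(out_dir, name)
    writeLines(lines, path, useBytes = TRUE)
    path
  }
  list(
    metanetx = c(
      chem_prop = w("metanetx_chem_prop.tsv", MINI_METANETX_CHEM_PROP),
      chem_xref = w("metanetx_chem_xref.tsv", MINI_METANETX_CHEM_XREF),
      reac_prop = w("metanetx_reac_prop.tsv", MINI_METANETX_REAC_PROP),
      reac_xref = w("metanetx_reac_xref.tsv", MINI_METANETX_REAC_XREF)),
    modelseed = c(
      compounds = w("modelseed_compounds.tsv", MINI_MODELSEED_COMPOUNDS),
      reactions = w("modelseed_reactions.tsv", MINI_MODELSEED_REACTIONS)),
    bigg = c(
      metabolites = w("bigg_models_metabolites.txt", MINI_BIGG_METABOLITES),
      reactions = w("bigg_models_reactions.txt", MINI_BIGG_REACTIONS)),
    kegg = c(
      compound = w("kegg_compound.tsv", MINI_KEGG_COMPOUND),
      reaction = w("kegg_reaction.tsv", MINI_KEGG_REACTION)),
    chebi = c(
      names = w("chebi_names.tsv", MINI_CHEBI_NAMES),
      accessions = w("chebi_database_accession.tsv", MINI_CHEBI_ACCESSIONS),
      chemical_data = w("chebi_chemical_data.tsv",
                        MINI_CHEBI_CHEMICAL_DATA)))
}

.fixture_cache <- new.env(parent = emptyenv())

#' Fixture mapper built from the mini dumps
#'
#' Builds (and memoizes per session) the universal mapper from
#' [make_mini_dumps()] written to a temporary directory.
#'
#' @return a `gem_mapper`.
#' @export
fixture_mapper <- function() {
  if (is.null(.fixture_cache$mapper)) {
    dumps <- make_mini_dumps(file.path(tempdir(), "gemmerge_mini_dumps"))
    .fixture_cache$mapper <- build_universal_mapper(dumps)
  }
  .fixture_cache$mapper
}

## --- Toy models -------------------------------------------------------------

toy_bigg_met <- function(id, compartment = "c", name = NA_character_,
                         annotations = list()) {
  gem_metabolite(id, name = name, compartment = compartment,
                 annotations = annotations)
}

toy_model_A <- function() {
  gem_model("toyA",
    metabolites = list(
      toy_bigg_met("glc__D_c", name = "D-Glucose"),
      toy_bigg_met("atp_c", name = "ATP"),
      toy_bigg_met("adp_c", name = "ADP"),
      toy_bigg_met("g6p_c", name = "D-Glucose 6-phosphate"),
      toy_bigg_met("h_c", name = "H+"),
      toy_bigg_met("pi_c", name = "Phosphate"),
      toy_bigg_met("h2o_c", name = "H2O")),
    reactions = list(
      gem_reaction("HEX1",
        participants = c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1,
                         h_c = 1),
        lower_bound = 0, gpr = "gA1"),
      gem_reaction("ATPS",
        participants = c(adp_c = -1, pi_c = -1, atp_c = 1, h2o_c = 1),
        lower_bound = 0, gpr = "gA2"),
      gem_reaction("biomass_A",
        participants = c(atp_c = -1, g6p_c = -2),
        lower_bound = 0)),
    objective = c(biomass_A = 1),
    compartments = c(c = "cytosol"))
}

toy_model_B <- function() {
  gem_model("toyB",
    metabolites = list(
      toy_bigg_met("glc__D_c"), toy_bigg_met("atp_c"),
      toy_bigg_met("adp_c"), toy_bigg_met("g6p_c"), toy_bigg_met("h_c"),
      toy_bigg_met("f6p_c", name = "D-Fructose 6-phosphate")),
    reactions = list(
      gem_reaction("HEX1",
        participants = c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1,
                         h_c = 1),
        lower_bound = 0, gpr = "gB1"),
      gem_reaction("PGI", participants = c(g6p_c = -1, f6p_c = 1)),
      gem_reaction("biomass_B",
        participants = c(atp_c = -3, f6p_c = -1),
        lower_bound = 0)),
    objective = c(biomass_B = 1),
    compartments = c(c = "cytosol"))
}

toy_model_seed <- function() {
  met <- function(id, name) gem_metabolite(id, name = name,
                                           compartment = "c0")
  gem_model("toySeed",
    metabolites = list(
      met("cpd00027_c0", "D-Glucose"), met("cpd00002_c0", "ATP"),
      met("cpd00008_c0", "ADP"), met("cpd00079_c0", "G6P"),
      met("cpd00067_c0", "H+"), met("cpd00009_c0", "Phosphate"),
      met("cpd00001_c0", "H2O")),
    reactions = list(
      gem_reaction("rxn00216",
        participants = c(cpd00027_c0 = -1, cpd00002_c0 = -1,
                         cpd00079_c0 = 1, cpd00008_c0 = 1,
                         cpd00067_c0 = 1),
        lower_bound = 0, gpr = "gS1"),
      gem_reaction("rxn_atps",
        participants = c(cpd00008_c0 = -1, cpd00009_c0 = -1,
                         cpd00002_c0 = 1, cpd00001_c0 = 1),
        lower_bound = 0),
      gem_reaction("bio1",
        participants = c(cpd00002_c0 = -1, cpd00079_c0 = -2),
        lower_bound = 0)),
    objective = c(bio1 = 1),
    compartments = c(c0 = "Cytosol"))
}

#' Toy models exercising each merging branch
#'
#' Returns a list of two small GEMs engineered for one scenario:
#' \describe{
#'   \item{same_namespace_overlap}{two BiGG-style models sharing part of
#'     their chemistry (shared hexokinase, distinct biomass).}
#'   \item{cross_namespace}{the BiGG-style model against a ModelSEED-style
#'     model of the same chemistry — zero string-equal ids.}
#'   \item{reversed_reaction}{second model carries the exact reverse of a
#'     template reaction.}
#'   \item{nh2_nh3_conflict}{template holds two metabolites mapping to the
#'     same universal id (ammonia nh3/nh4).}
#'   \item{proton_exchange}{proton-only exchange reaction plus a hexokinase
#'     written with and without the explicit proton.}
#'   \item{objective_merge}{two biomass reactions sharing ATP at
#'     coefficients 1 and 3, plus precursors unique to each model.}
#'   \item{stoichiometry_mismatch}{same participants with different
#'     coefficients — merges in default mode, not in exact mode.}
#' }
#'
#' @param scenario scenario name, see above.
#' @return list of two `gem_model` objects (template first).
#' @export
make_toy_models <- function(scenario = c("same_namespace_overlap",
                                         "cross_namespace",
                                         "reversed_reaction",
                                         "nh2_nh3_conflict",
                                         "proton_exchange",
                                         "objective_merge",
                                         "stoichiometry_mismatch")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    same_namespace_overlap = list(toy_model_A(), toy_model_B()),
    cross_namespace = list(toy_model_A(), toy_model_seed()),
    reversed_reaction = {
      b <- gem_model("toyRev",
        metabolites = list(
          toy_bigg_met("glc__D_c"), toy_bigg_met("atp_c"),
          toy_bigg_met("adp_c"), toy_bigg_met("g6p_c"),
          toy_bigg_met("h_c")),
        reactions = list(
          gem_reaction("HEX1_rev",
            participants = c(g6p_c = -1, adp_c = -1, h_c = -1,
                             glc__D_c = 1, atp_c = 1),
            gpr = "gR1"),
          gem_reaction("bio_rev", participants = c(atp_c = -1),
                       lower_bound = 0)),
        objective = c(bio_rev = 1),
        compartments = c(c = "cytosol"))
      list(toy_model_A(), b)
    },
    nh2_nh3_conflict = {
      a <- gem_model("toyN1",
        metabolites = list(
          toy_bigg_met("nh3_c", name = "Ammonia"),
          toy_bigg_met("nh4_c", name = "Ammonium"),
          toy_bigg_met("glc__D_c")),
        reactions = list(
          gem_reaction("AMM", participants = c(nh3_c = -1, glc__D_c = -1,
                                               nh4_c = 1)),
          gem_reaction("bio_n", participants = c(glc__D_c = -1),
                       lower_bound = 0)),
        objective = c(bio_n = 1),
        compartments = c(c = "cytosol"))
      b <- gem_model("toyN2",
        metabolites = list(
          toy_bigg_met("nh4_c", name = "Ammonium"),
          toy_bigg_met("glc__D_c")),
        reactions = list(
          gem_reaction("R2", participants = c(glc__D_c = -1, nh4_c = 1)),
          gem_reaction("bio_n2", participants = c(glc__D_c = -1),
                       lower_bound = 0)),
        objective = c(bio_n2 = 1),
        compartments = c(c = "cytosol"))
      list(a, b)
    },
    proton_exchange = {
      a <- gem_model("toyP1",
        metabolites = list(
          toy_bigg_met("h_c", name = "H+"),
          toy_bigg_met("h_e", compartment = "e", name = "H+"),
          toy_bigg_met("glc__D_c"), toy_bigg_met("atp_c"),
          toy_bigg_met("adp_c"), toy_bigg_met("g6p_c")),
        reactions = list(
          gem_reaction("EX_h", participants = c(h_e = -1, h_c = 1)),
          gem_reaction("HEX1",
            participants = c(glc__D_c = -1, atp_c = -1, g6p_c = 1,
                             adp_c = 1, h_c = 1),
            lower_bound = 0, gpr = "gP1"),
          gem_reaction("bio_p", participants = c(g6p_c = -1),
                       lower_bound = 0)),
        objective = c(bio_p = 1),
        compartments = c(c = "cytosol", e = "extracellular space"))
      b <- gem_model("toyP2",
        metabolites = list(
          toy_bigg_met("h_c", name = "H+"),
          toy_bigg_met("h_e", compartment = "e", name = "H+"),
          toy_bigg_met("glc__D_c"), toy_bigg_met("atp_c"),
          toy_bigg_met("adp_c"), toy_bigg_met("g6p_c")),
        reactions = list(
          gem_reaction("EX_h_b", participants = c(h_e = -1, h_c = 1)),
          gem_reaction("HEX1_noh",
            participants = c(glc__D_c = -1, atp_c = -1, g6p_c = 1,
                             adp_c = 1),
            lower_bound = 0, gpr = "gP2"),
          gem_reaction("bio_p2", participants = c(g6p_c = -1),
                       lower_bound = 0)),
        objective = c(bio_p2 = 1),
        compartments = c(c = "cytosol", e = "extracellular space"))
      list(a, b)
    },
    objective_merge = {
      a <- gem_model("toyO1",
        metabolites = list(toy_bigg_met("atp_c"), toy_bigg_met("pyr_c")),
        reactions = list(
          gem_reaction("biomass_A",
            participants = c(atp_c = -1, pyr_c = -5), lower_bound = 0)),
        objective = c(biomass_A = 1),
        compartments = c(c = "cytosol"))
      b <- gem_model("toyO2",
        metabolites = list(toy_bigg_met("atp_c"), toy_bigg_met("g6p_c")),
        reactions = list(
          gem_reaction("biomass_B",
            participants = c(atp_c = -3, g6p_c = -1), lower_bound = 0)),
        objective = c(biomass_B = 1),
        compartments = c(c = "cytosol"))
      list(a, b)
    },
    stoichiometry_mismatch = {
      a <- gem_model("toyS1",
        metabolites = list(
          toy_bigg_met("glc__D_c"), toy_bigg_met("atp_c"),
          toy_bigg_met("adp_c"), toy_bigg_met("g6p_c")),
        reactions = list(
          gem_reaction("R1",
            participants = c(glc__D_c = -1, atp_c = -1, g6p_c = 1,
                             adp_c = 1),
            lower_bound = 0),
          gem_reaction("bio_s", participants = c(g6p_c = -1),
                       lower_bound = 0)),
        objective = c(bio_s = 1),
        compartments = c(c = "cytosol"))
      b <- gem_model("toyS2",
        metabolites = list(
          toy_bigg_met("glc__D_c"), toy_bigg_met("atp_c"),
          toy_bigg_met("adp_c"), toy_bigg_met("g6p_c")),
        reactions = list(
          gem_reaction("R1b",
            participants = c(glc__D_c = -2, atp_c = -1, g6p_c = 1,
                             adp_c = 1),
            lower_bound = 0),
          gem_reaction("bio_s2", participants = c(g6p_c = -1),
                       lower_bound = 0)),
        objective = c(bio_s2 = 1),
        compartments = c(c = "cytosol"))
      list(a, b)
    })
}

#' Serialize toy models in every supported format
#'
#' @param models list of `gem_model` objects.
#' @param out_dir output directory, created if needed.
#' @param formats formats to write (default all three).
#' @return character vector of the written paths.
#' @export
write_fixture_files <- function(models, out_dir,
                                formats = c("sbml", "json", "mat")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- c(sbml = "xml", json = "json", mat = "mat")
  paths <- character()
  for (m in models) {
    for (f in formats) {
      p <- file.path(out_dir, paste0(m$id, ".", ext[[f]]))
      write_model(m, p, format = f)
      paths <- c(paths, p)
    }
  }
  paths
}
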