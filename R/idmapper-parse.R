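# Database dump parsers for the universal identifier mapper.
#
# Each supported database publishes flat-file dumps in its own dialect:
#   metanetx : chem_prop / chem_xref / reac_prop / reac_xref TSV,
#              comment lines start with '#'
#   modelseed: compounds / reactions TSV with a header row
#   bigg     : metabolites / reactions TSV with a 'database_links' column
#   kegg     : flat "ID<TAB>name1; name2; ..." lists
#   chebi    : names / database_accession / chemical_data TSV with headers
#
# Parsers return plain records (one per primary entity) and cross-reference
# pairs; the precedence-aware merging happens in build_universal_mapper().

GEM_DATABASES <- c("metanetx", "modelseed", "bigg", "kegg", "chebi")

new_entity_record <- function(database, native_id, entity_class,
                              name = character(), formula = NA_character_,
                              molecular_weight = NA_real_,
                              inchi_key = NA_character_,
                              ec_numbers = character()) {
  list(database = database, native_id = native_id,
       entity_class = entity_class,
       name = name[nzchar(name) & !is.na(name)],
       formula = formula, molecular_weight = molecular_weight,
       inchi_key = inchi_key, ec_numbers = ec_numbers)
}

new_xref <- function(source_db, source_id, target_db, target_id,
                     entity_class) {
  list(source_db = source_db, source_id = source_id,
       target_db = target_db, target_id = target_id,
       entity_class = entity_class)
}

# Map a cross-reference namespace prefix (as found in MetaNetX xref files or
# identifiers.org URLs) to one of the supported databases; NA when foreign.
xref_prefix_db <- function(prefix) {
  p <- tolower(prefix)
  if (p %in% c("bigg.metabolite", "bigg.reaction", "biggm", "biggr", "bigg"))
    return("bigg")
  if (p %in% c("kegg.compound", "kegg.reaction", "keggc", "keggr", "kegg"))
    return("kegg")
  if (p %in% c("seed.compound", "seed.reaction", "seedm", "seedr", "seed"))
    return("modelseed")
  if (p == "chebi") return("chebi")
  if (p %in% c("metanetx.chemical", "metanetx.reaction", "mnx"))
    return("metanetx")
  NA_character_
}

# ChEBI ids are stored bare ("17634"); accept and strip a CHEBI: prefix.
strip_chebi_prefix <- function(id) sub("^(?i)chebi:", "", id, perl = TRUE)

read_dump_lines <- function(path) {
  if (!file.exists(path))
    stop("cannot read database dump file: ", path, call. = FALSE)
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

# TSV with a header row, no quoting (ModelSEED / BiGG / ChEBI dumps).
read_dump_table <- function(path) {
  if (!file.exists(path))
    stop("cannot read database dump file: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", "null", ""))
}

col_or_na <- function(df, name) {
  if (name %in% names(df)) df[[name]] else rep(NA, nrow(df))
}

warn_malformed <- function(path, i, line) {
  warning("skipping malformed line ", i, " in ", basename(path), ": ",
          substr(line, 1, 60), call. = FALSE)
}

## --- MetaNetX ---------------------------------------------------------------

parse_mnx_prop <- function(path, entity_class) {
  lines <- read_dump_lines(path)
  records <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(f[1])) { warn_malformed(path, i, line); next }
    if (entity_class == "metabolite") {
      # ID name reference formula charge mass InChI InChIKey SMILES
      mw <- suppressWarnings(as.numeric(if (length(f) >= 6) f[6] else NA))
      records[[length(records) + 1L]] <- new_entity_record(
        "metanetx", f[1], "metabolite", name = f[2],
        formula = if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_,
        molecular_weight = mw,
        inchi_key = if (length(f) >= 8 && nzchar(f[8])) f[8]
                    else NA_character_)
    } else {
      # ID mnx_equation reference classifs is_balanced is_transport
      ecs <- if (length(f) >= 4 && nzchar(f[4]) && !is.na(f[4]))
        strsplit(f[4], ";", fixed = TRUE)[[1]] else character()
      records[[length(records) + 1L]] <- new_entity_record(
        "metanetx", f[1], "reaction", ec_numbers = trimws(ecs))
    }
  }
  records
}

parse_mnx_xref <- function(path, entity_class) {
  lines <- read_dump_lines(path)
  xrefs <- list()
  extra_ids <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) { warn_malformed(path, i, line); next }
    mnx_id <- f[2]
    extra_ids <- c(extra_ids, mnx_id)
    src <- strsplit(f[1], ":", fixed = TRUE)[[1]]
    if (length(src) < 2) next           # unprefixed or identity row
    db <- xref_prefix_db(src[1])
    if (is.na(db) || db == "metanetx") next  # foreign or self reference
    target_id <- paste(src[-1], collapse = ":")
    if (db == "chebi") target_id <- strip_chebi_prefix(target_id)
    if (!nzchar(target_id)) { warn_malformed(path, i, line); next }
    xrefs[[length(xrefs) + 1L]] <- new_xref("metanetx", mnx_id, db,
                                            target_id, entity_class)
  }
  list(xrefs = xrefs, ids = unique(extra_ids))
}

parse_metanetx <- function(files) {
  records <- list()
  xrefs <- list()
  seen <- character()
  add_records <- function(rs) {
    for (r in rs) {
      records[[length(records) + 1L]] <<- r
      seen <<- c(seen, paste0(r$entity_class, "|", r$native_id))
    }
  }
  if (!is.na(files["chem_prop"]))
    add_records(parse_mnx_prop(files[["chem_prop"]], "metabolite"))
  if (!is.na(files["reac_prop"]))
    add_records(parse_mnx_prop(files[["reac_prop"]], "reaction"))
  for (spec in list(c("chem_xref", "metabolite"), c("reac_xref", "reaction"))) {
    if (is.na(files[spec[1]])) next
    out <- parse_mnx_xref(files[[spec[1]]], spec[2])
    xrefs <- c(xrefs, out$xrefs)
    # MNX ids appearing only in the xref table still name entities
    new_ids <- setdiff(paste0(spec[2], "|", out$ids, recycle0 = TRUE),
                       seen)
    for (key in new_ids) {
      id <- sub("^[a-z]+\\|", "", key)
      add_records(list(new_entity_record("metanetx", id, spec[2])))
    }
  }
  list(records = records, xrefs = xrefs)
}

## --- ModelSEED --------------------------------------------------------------

# ModelSEED alias columns (secondary ids / mappings) are excluded entirely:
# one ModelSEED id can alias multiple dissimilar metabolites elsewhere.
parse_modelseed <- function(files) {
  records <- list()
  if (!is.na(files["compounds"])) {
    df <- read_dump_table(files[["compounds"]])
    obsolete <- col_or_na(df, "is_obsolete")
    for (i in seq_len(nrow(df))) {
      if (isTRUE(obsolete[i] == 1)) next
      id <- df$id[i]
      if (is.na(id) || !nzchar(id)) next
      records[[length(records) + 1L]] <- new_entity_record(
        "modelseed", id, "metabolite",
        name = as.character(col_or_na(df, "name")[i]),
        formula = as.character(col_or_na(df, "formula")[i]),
        molecular_weight = suppressWarnings(
          as.numeric(col_or_na(df, "mass")[i])),
        inchi_key = as.character(col_or_na(df, "inchikey")[i]))
    }
  }
  if (!is.na(files["reactions"])) {
    df <- read_dump_table(files[["reactions"]])
    obsolete <- col_or_na(df, "is_obsolete")
    ec_col <- col_or_na(df, "ec_numbers")
    for (i in seq_len(nrow(df))) {
      if (isTRUE(obsolete[i] == 1)) next
      id <- df$id[i]
      if (is.na(id) || !nzchar(id)) next
      ecs <- if (!is.na(ec_col[i]))
        strsplit(as.character(ec_col[i]), "[|;]")[[1]] else character()
      records[[length(records) + 1L]] <- new_entity_record(
        "modelseed", id, "reaction",
        name = as.character(col_or_na(df, "name")[i]),
        ec_numbers = trimws(ecs))
    }
  }
  list(records = records, xrefs = list())  # ModelSEED mappings excluded
}

## --- BiGG -------------------------------------------------------------------

bigg_link_db <- function(label) {
  l <- tolower(label)
  if (grepl("chebi", l)) return("chebi")
  if (grepl("kegg (compound|reaction)", l)) return("kegg")
  if (grepl("seed", l)) return("modelseed")
  if (grepl("metanetx", l)) return("metanetx")
  NA_character_
}

parse_bigg_links <- function(s) {
  # "CHEBI: http://identifiers.org/chebi/CHEBI:17634; KEGG Compound: http..."
  out <- list()
  if (is.na(s) || !nzchar(s)) return(out)
  for (part in strsplit(s, ";", fixed = TRUE)[[1]]) {
    m <- regmatches(part, regexec("^\\s*([^:]+):\\s*(\\S+)\\s*$", part))[[1]]
    if (length(m) < 3) next
    id <- basename(m[3])
    out[[length(out) + 1L]] <- list(label = trimws(m[2]), id = id)
  }
  out
}

parse_bigg <- function(files) {
  records <- list()
  xrefs <- list()
  parse_one <- function(path, entity_class) {
    df <- read_dump_table(path)
    id_col <- if (entity_class == "metabolite" &&
                  "universal_bigg_id" %in% names(df))
      df$universal_bigg_id else df$bigg_id
    seen <- character()
    for (i in seq_len(nrow(df))) {
      id <- id_col[i]
      if (is.na(id) || !nzchar(id) || id %in% seen) next
      seen <- c(seen, id)
      inchi <- NA_character_
      ecs <- character()
      for (lk in parse_bigg_links(as.character(
             col_or_na(df, "database_links")[i]))) {
        if (grepl("inchi", tolower(lk$label))) { inchi <- lk$id; next }
        if (grepl("ec number", tolower(lk$label))) {
          ecs <- c(ecs, lk$id); next
        }
        db <- bigg_link_db(lk$label)
        if (is.na(db)) next
        tid <- if (db == "chebi") strip_chebi_prefix(lk$id) else lk$id
        xrefs[[length(xrefs) + 1L]] <<- new_xref("bigg", id, db, tid,
                                                 entity_class)
      }
      records[[length(records) + 1L]] <<- new_entity_record(
        "bigg", id, entity_class,
        name = as.character(col_or_na(df, "name")[i]),
        inchi_key = inchi, ec_numbers = ecs)
    }
  }
  if (!is.na(files["metabolites"]))
    parse_one(files[["metabolites"]], "metabolite")
  if (!is.na(files["reactions"])) parse_one(files[["reactions"]], "reaction")
  list(records = records, xrefs = xrefs)
}

## --- KEGG -------------------------------------------------------------------

parse_kegg_list <- function(path, entity_class) {
  lines <- read_dump_lines(path)
  records <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (!nzchar(f[1])) { warn_malformed(path, i, line); next }
    id <- sub("^(cpd|rn):", "", f[1])
    nm <- if (length(f) >= 2)
      trimws(strsplit(f[2], ";", fixed = TRUE)[[1]]) else character()
    records[[length(records) + 1L]] <- new_entity_record(
      "kegg", id, entity_class, name = nm)
  }
  records
}

parse_kegg <- function(files) {
  records <- list()
  if (!is.na(files["compound"]))
    records <- c(records, parse_kegg_list(files[["compound"]], "metabolite"))
  if (!is.na(files["reaction"]))
    records <- c(records, parse_kegg_list(files[["reaction"]], "reaction"))
  list(records = records, xrefs = list())
}

## --- ChEBI ------------------------------------------------------------------

chebi_accession_db <- function(type) {
  t <- tolower(type)
  if (grepl("kegg compound", t)) return("kegg")
  if (grepl("metanetx", t)) return("metanetx")
  if (grepl("seed", t)) return("modelseed")
  if (grepl("bigg", t)) return("bigg")
  NA_character_
}

parse_chebi <- function(files) {
  names_by_id <- list()
  formula_by_id <- list()
  mass_by_id <- list()
  xrefs <- list()
  if (!is.na(files["names"])) {
    df <- read_dump_table(files[["names"]])
    for (i in seq_len(nrow(df))) {
      cid <- as.character(col_or_na(df, "COMPOUND_ID")[i])
      nm <- as.character(col_or_na(df, "NAME")[i])
      if (is.na(cid) || !nzchar(cid)) next
      names_by_id[[cid]] <- c(names_by_id[[cid]], nm)
    }
  }
  if (!is.na(files["chemical_data"])) {
    df <- read_dump_table(files[["chemical_data"]])
    for (i in seq_len(nrow(df))) {
      cid <- as.character(col_or_na(df, "COMPOUND_ID")[i])
      type <- toupper(as.character(col_or_na(df, "TYPE")[i]))
      val <- as.character(col_or_na(df, "CHEMICAL_DATA")[i])
      if (is.na(cid) || is.na(type)) next
      if (type == "FORMULA") formula_by_id[[cid]] <- val
      if (type == "MASS")
        mass_by_id[[cid]] <- suppressWarnings(as.numeric(val))
    }
  }
  if (!is.na(files["accessions"])) {
    df <- read_dump_table(files[["accessions"]])
    for (i in seq_len(nrow(df))) {
      cid <- as.character(col_or_na(df, "COMPOUND_ID")[i])
      type <- as.character(col_or_na(df, "TYPE")[i])
      acc <- as.character(col_or_na(df, "ACCESSION_NUMBER")[i])
      if (is.na(cid) || is.na(type) || is.na(acc)) next
      db <- chebi_accession_db(type)
      if (is.na(db)) next
      xrefs[[length(xrefs) + 1L]] <- new_xref("chebi", cid, db, acc,
                                              "metabolite")
      if (!cid %in% names(names_by_id)) names_by_id[[cid]] <- character()
    }
  }
  records <- lapply(names(names_by_id), function(cid) {
    new_entity_record("chebi", cid, "metabolite",
                      name = unique(names_by_id[[cid]]),
                      formula = if (is.null(formula_by_id[[cid]]))
                        NA_character_ else formula_by_id[[cid]],
                      molecular_weight = if (is.null(mass_by_id[[cid]]))
                        NA_real_ else mass_by_id[[cid]])
  })
  list(records = records, xrefs = xrefs)
}

## --- Dispatcher -------------------------------------------------------------

DUMP_ROLES <- list(
  metanetx = c("chem_prop", "chem_xref", "reac_prop", "reac_xref"),
  modelseed = c("compounds", "reactions"),
  bigg = c("metabolites", "reactions"),
  kegg = c("compound", "reaction"),
  chebi = c("names", "accessions", "chemical_data")
)

# Assign a role to each dump file; unnamed files are matched on filename.
resolve_dump_roles <- function(database, dump_files) {
  roles <- DUMP_ROLES[[database]]
  out <- stats::setNames(rep(NA_character_, length(roles)), roles)
  nm <- names(dump_files)
  if (is.null(nm)) nm <- rep("", length(dump_files))
  for (i in seq_along(dump_files)) {
    role <- if (nzchar(nm[i]) && nm[i] %in% roles) nm[i] else {
      base <- tolower(basename(dump_files[[i]]))
      hit <- roles[vapply(roles, function(r) grepl(r, base, fixed = TRUE),
                          TRUE)]
      # "reactions" matches before "compound"/"metabolites" style overlaps
      if (length(hit)) hit[which.max(nchar(hit))] else NA_character_
    }
    if (is.na(role))
      stop("cannot infer the role of dump file '", dump_files[[i]],
           "' for database '", database, "'", call. = FALSE)
    out[role] <- dump_files[[i]]
  }
  out
}

#' Parse a metabolic database dump
#'
#' Reads the flat-file dump(s) of one supported database and extracts its
#' primary metabolite/reaction records together with the cross-reference
#' pairs it publishes. ModelSEED alias/secondary identifiers are excluded
#' entirely (one alias can point at several dissimilar entities elsewhere),
#' so ModelSEED contributes properties but no cross-references.
#'
#' @param database one of `"metanetx"`, `"modelseed"`, `"bigg"`, `"kegg"`,
#'   `"chebi"`.
#' @param dump_files character vector of file paths; optionally named by role
#'   (e.g. `c(chem_prop = ..., chem_xref = ...)` for MetaNetX), otherwise the
#'   role is inferred from the file name.
#' @return a list with elements `records` (list of entity records) and
#'   `xrefs` (list of cross-reference pairs with `source_db`, `source_id`,
#'   `target_db`, `target_id`, `entity_class`).
#' @seealso [build_universal_mapper()]
#' @export
parse_database_dump <- function(database, dump_files) {
  database <- match.arg(tolower(database), GEM_DATABASES)
  files <- resolve_dump_roles(database, dump_files)
  for (p in files[!is.na(files)]) {
    if (!file.exists(p))
      stop("cannot read database dump file: ", p, call. = FALSE)
  }
  switch(database,
         metanetx = parse_metanetx(files),
         modelseed = parse_modelseed(files),
         bigg = parse_bigg(files),
         kegg = parse_kegg(files),
         chebi = parse_chebi(files))
}
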