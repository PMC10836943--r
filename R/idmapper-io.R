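# Mapper persistence: versioned binary dump, CSV export/import, and the
# online rebuild path.

mapper_to_list <- function(mapper) {
  list(version = mapper$version,
       precedence = mapper$precedence,
       met_id2u = as.list(mapper$met_id2u, sorted = TRUE),
       reac_id2u = as.list(mapper$reac_id2u, sorted = TRUE),
       met_props = as.list(mapper$met_props, sorted = TRUE),
       reac_props = as.list(mapper$reac_props, sorted = TRUE),
       n_met = mapper$n_met, n_reac = mapper$n_reac,
       proton_ids = mapper$proton_ids)
}

mapper_from_list <- function(x) {
  mapper <- list(precedence = x$precedence, version = x$version)
  for (f in c("met_id2u", "reac_id2u", "met_props", "reac_props"))
    mapper[[f]] <- list2env(x[[f]], parent = emptyenv())
  mapper$n_met <- x$n_met
  mapper$n_reac <- x$n_reac
  mapper$proton_ids <- x$proton_ids
  class(mapper) <- "gem_mapper"
  mapper
}

#' Save and load a universal mapper
#'
#' The mapper is serialized as a versioned binary table dump; loading a file
#' written by an incompatible package version raises an explicit error.
#' `load_mapper(save_mapper(m, path))` reproduces `m` exactly.
#'
#' @param mapper a `gem_mapper`.
#' @param path file path for the serialized mapper.
#' @return `save_mapper` returns `path` invisibly; `load_mapper` returns the
#'   `gem_mapper`.
#' @export
save_mapper <- function(mapper, path) {
  stopifnot(inherits(mapper, "gem_mapper"))
  saveRDS(mapper_to_list(mapper), path)
  invisible(path)
}

#' @rdname save_mapper
#' @export
load_mapper <- function(path) {
  if (!file.exists(path))
    stop("mapper file does not exist: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!identical(x$version, MAPPER_FORMAT_VERSION))
    stop("mapper file ", path, " has format version ", x$version,
         " but this package reads version ", MAPPER_FORMAT_VERSION,
         call. = FALSE)
  mapper_from_list(x)
}

join_multi <- function(x) paste(x, collapse = "|")
split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else
    strsplit(x, "|", fixed = TRUE)[[1]]
}

props_to_df <- function(props_env, proton_ids = integer()) {
  us <- sort(as.integer(ls(props_env)))
  rows <- lapply(us, function(u) {
    b <- props_env[[as.character(u)]]
    members <- unlist(lapply(names(b$member_ids), function(db)
      paste0(db, ":", b$member_ids[[db]])), use.names = FALSE)
    data.frame(universal_id = u, names = join_multi(b$names),
               formula = b$formula, molecular_weight = b$molecular_weight,
               inchi_key = b$inchi_key,
               ec_numbers = join_multi(b$ec_numbers),
               member_ids = join_multi(members),
               is_proton = u %in% proton_ids,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(universal_id = integer(), names = character(),
               formula = character(), molecular_weight = numeric(),
               inchi_key = character(), ec_numbers = character(),
               member_ids = character(), is_proton = logical(),
               stringsAsFactors = FALSE)
}

id_map_to_df <- function(env) {
  ids <- ls(env)
  df <- data.frame(raw_id = ids,
                   universal_id = vapply(ids, function(k) env[[k]], 1L),
                   stringsAsFactors = FALSE)
  df[order(df$universal_id, df$raw_id), , drop = FALSE]
}

#' Export a mapper as CSV tables
#'
#' Writes four CSV files into `directory`: `met_id_map.csv` and
#' `reac_id_map.csv` (columns `raw_id`, `universal_id`) plus
#' `met_properties.csv` and `reac_properties.csv` (consolidated property
#' bundles; multi-valued fields joined with `"|"`, member ids as
#' `"database:id"` tokens). [import_mapper_csv()] reads them back.
#'
#' @param mapper a `gem_mapper`.
#' @param directory output directory, created if needed.
#' @return character vector of the four file paths, invisibly.
#' @export
export_mapper_csv <- function(mapper, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create export directory: ", directory, call. = FALSE)
  paths <- file.path(directory,
                     c("met_id_map.csv", "reac_id_map.csv",
                       "met_properties.csv", "reac_properties.csv"))
  utils::write.csv(id_map_to_df(mapper$met_id2u), paths[1],
                   row.names = FALSE)
  utils::write.csv(id_map_to_df(mapper$reac_id2u), paths[2],
                   row.names = FALSE)
  utils::write.csv(props_to_df(mapper$met_props, mapper$proton_ids),
                   paths[3], row.names = FALSE)
  utils::write.csv(props_to_df(mapper$reac_props), paths[4],
                   row.names = FALSE)
  invisible(paths)
}

df_to_props_env <- function(df) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df))) {
    members <- split_multi(df$member_ids[i])
    member_ids <- list()
    for (m in members) {
      db <- sub(":.*$", "", m)
      id <- sub("^[^:]*:", "", m)
      member_ids[[db]] <- c(member_ids[[db]], id)
    }
    env[[as.character(df$universal_id[i])]] <- list(
      universal_id = as.integer(df$universal_id[i]),
      names = split_multi(df$names[i]),
      formula = if (is.na(df$formula[i])) NA_character_ else df$formula[i],
      molecular_weight = df$molecular_weight[i],
      inchi_key = if (is.na(df$inchi_key[i])) NA_character_ else
        df$inchi_key[i],
      ec_numbers = split_multi(df$ec_numbers[i]),
      member_ids = member_ids)
  }
  env
}

#' @rdname export_mapper_csv
#' @export
import_mapper_csv <- function(directory) {
  read1 <- function(name) {
    p <- file.path(directory, name)
    if (!file.exists(p)) stop("missing mapper CSV: ", p, call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  met_map <- read1("met_id_map.csv")
  reac_map <- read1("reac_id_map.csv")
  met_props <- read1("met_properties.csv")
  reac_props <- read1("reac_properties.csv")
  mapper <- list(precedence = GEM_DATABASES,
                 version = MAPPER_FORMAT_VERSION)
  mapper$met_id2u <- list2env(
    stats::setNames(as.list(as.integer(met_map$universal_id)),
                    met_map$raw_id), parent = emptyenv())
  mapper$reac_id2u <- list2env(
    stats::setNames(as.list(as.integer(reac_map$universal_id)),
                    reac_map$raw_id), parent = emptyenv())
  mapper$met_props <- df_to_props_env(met_props)
  mapper$reac_props <- df_to_props_env(reac_props)
  mapper$n_met <- nrow(met_props)
  mapper$n_reac <- nrow(reac_props)
  mapper$proton_ids <-
    sort(as.integer(met_props$universal_id[met_props$is_proton]))
  class(mapper) <- "gem_mapper"
  mapper
}

# Current download locations of the database dumps.
DUMP_URLS <- list(
  metanetx = c(
    chem_prop = "https://www.metanetx.org/cgi-bin/mnxget/mnxref/chem_prop.tsv",
    chem_xref = "https://www.metanetx.org/cgi-bin/mnxget/mnxref/chem_xref.tsv",
    reac_prop = "https://www.metanetx.org/cgi-bin/mnxget/mnxref/reac_prop.tsv",
    reac_xref = "https://www.metanetx.org/cgi-bin/mnxget/mnxref/reac_xref.tsv"),
  modelseed = c(
    compounds = "https://raw.githubusercontent.com/ModelSEED/ModelSEEDDatabase/master/Biochemistry/compounds.tsv",
    reactions = "https://raw.githubusercontent.com/ModelSEED/ModelSEEDDatabase/master/Biochemistry/reactions.tsv"),
  bigg = c(
    metabolites = "http://bigg.ucsd.edu/static/namespace/bigg_models_metabolites.txt",
    reactions = "http://bigg.ucsd.edu/static/namespace/bigg_models_reactions.txt"),
  kegg = c(
    compound = "https://rest.kegg.jp/list/compound",
    reaction = "https://rest.kegg.jp/list/reaction"),
  chebi = c(
    names = "https://ftp.ebi.ac.uk/pub/databases/chebi/Flat_file_tab_delimited/names.tsv.gz",
    accessions = "https://ftp.ebi.ac.uk/pub/databases/chebi/Flat_file_tab_delimited/database_accession.tsv",
    chemical_data = "https://ftp.ebi.ac.uk/pub/databases/chebi/Flat_file_tab_delimited/chemical_data.tsv")
)

#' Download current database dumps and rebuild the mapper
#'
#' Fetches the flat-file dumps of every database in `order` into
#' `cache_dir` (files already present are kept, so a partial cache only
#' fetches what is missing) and rebuilds the universal mapper from them.
#' Requires network access; with all files pre-placed in `cache_dir` it
#' behaves exactly like [build_universal_mapper()].
#'
#' @param cache_dir directory holding (or receiving) the dump files.
#' @param order database precedence order.
#' @return a `gem_mapper`.
#' @export
update_mapper <- function(cache_dir, order = GEM_DATABASES) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dumps <- list()
  for (db in order) {
    urls <- DUMP_URLS[[db]]
    files <- character()
    for (role in names(urls)) {
      dest <- file.path(cache_dir, paste0(db, "_", role, ".tsv"))
      if (!file.exists(dest)) {
        ok <- tryCatch(
          utils::download.file(urls[[role]], dest, quiet = TRUE) == 0,
          error = function(e) FALSE, warning = function(w) FALSE)
        if (!ok || !file.exists(dest)) {
          unlink(dest)
          stop("failed to download ", db, " dump from ", urls[[role]],
               call. = FALSE)
        }
      }
      files[role] <- dest
    }
    dumps[[db]] <- files
  }
  build_universal_mapper(dumps)
}
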