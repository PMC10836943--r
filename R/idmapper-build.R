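# Building the universal identifier mapper.
#
# Every native (database, id) pair ends up in exactly one universal entity.
# Cross-reference pairs are processed sequentially in database-precedence
# order; a pair whose target id is already linked (via an earlier pair) to a
# *different* id of the source database is skipped, so the first database
# where a cross-reference was found wins conflicts. Union-find with that
# guard reproduces sequential pair replay exactly.

PROTON_NAMES <- c("h", "h+", "h(+)", "proton", "hydrogen")
MAPPER_FORMAT_VERSION <- 1L

entity_key <- function(db, id) paste0(db, "|", id)

uf_new <- function() {
  list(parent = new.env(parent = emptyenv()),
       members = new.env(parent = emptyenv()),  # root key -> n x 2 matrix
       order = new.env(parent = emptyenv()),    # creation order counter
       n = 0L)
}

uf_add <- function(uf, db, id) {
  key <- entity_key(db, id)
  if (is.null(uf$parent[[key]])) {
    uf$parent[[key]] <- key
    uf$members[[key]] <- matrix(c(db, id), ncol = 2)
    uf$n <- uf$n + 1L
    uf$order[[key]] <- uf$n
  }
  uf
}

uf_find <- function(uf, key) {
  root <- key
  while (!identical(uf$parent[[root]], root)) root <- uf$parent[[root]]
  # path compression
  while (!identical(uf$parent[[key]], root)) {
    nxt <- uf$parent[[key]]
    uf$parent[[key]] <- root
    key <- nxt
  }
  root
}

# Merge the target's group into the source's group unless the guard bites:
# the target id must not already be linked to a different id of the source
# database. Returns TRUE when a union happened (or groups already equal).
uf_union_guarded <- function(uf, source_db, source_id, target_db, target_id) {
  ks <- entity_key(source_db, source_id)
  kt <- entity_key(target_db, target_id)
  rs <- uf_find(uf, ks)
  rt <- uf_find(uf, kt)
  if (identical(rs, rt)) return(list(uf = uf, merged = TRUE))
  mt <- uf$members[[rt]]
  clash <- mt[, 1] == source_db & mt[, 2] != source_id
  if (any(clash)) return(list(uf = uf, merged = FALSE))
  # keep the earlier-created root so universal numbering follows ingestion
  if (uf$order[[rs]] > uf$order[[rt]]) { tmp <- rs; rs <- rt; rt <- tmp }
  uf$parent[[rt]] <- rs
  uf$members[[rs]] <- rbind(uf$members[[rs]], uf$members[[rt]])
  rm(list = rt, envir = uf$members)
  list(uf = uf, merged = TRUE)
}

# Merge a newly parsed record into any previous record for the same
# (database, native id): names accumulate, scalars keep the first
# non-missing value.
merge_record <- function(old, new) {
  if (is.null(old)) return(new)
  old$name <- unique(c(old$name, new$name))
  for (f in c("formula", "inchi_key", "molecular_weight")) {
    if (is.na(old[[f]]) && !is.na(new[[f]])) old[[f]] <- new[[f]]
  }
  old$ec_numbers <- unique(c(old$ec_numbers, new$ec_numbers))
  old
}

normalize_met_name <- function(x) tolower(trimws(x))

#' Build the universal identifier mapper
#'
#' Processes database dumps in precedence order into a `gem_mapper`: every
#' native metabolite/reaction id is assigned one integer universal id, and
#' each universal id carries a consolidated property bundle (names unioned;
#' formula, molecular weight and InChI key take the first non-missing value
#' in precedence order; EC numbers unioned). Metabolite and reaction
#' identifier spaces are kept fully separate.
#'
#' Cross-reference pairs are applied in the order the databases are given:
#' when a pair links two existing universal entities they are merged, except
#' when the target id is already mapped, through an earlier pair, to a
#' different id of the source database — such conflicting pairs are skipped,
#' which gives the first database where a cross-reference was found priority.
#'
#' Universal entities whose consolidated formula is exactly `"H"`, or one of
#' whose names normalizes to `"h"`, `"h+"`, `"h(+)"`, `"proton"` or
#' `"hydrogen"`, are flagged as protons (ignored by default during reaction
#' key construction).
#'
#' @param dumps named list in precedence order: database name (see
#'   [parse_database_dump()]) to character vector of dump file paths. The
#'   default precedence is MetaNetX, ModelSEED, BiGG, KEGG, ChEBI.
#' @return an object of class `gem_mapper`.
#' @examples
#' dir <- tempfile(); dumps <- make_mini_dumps(dir)
#' mapper <- build_universal_mapper(dumps)
#' mapper
#' @export
build_universal_mapper <- function(dumps) {
  if (length(dumps) == 0)
    stop("at least one database dump is required", call. = FALSE)
  dbs <- tolower(names(dumps))
  bad <- setdiff(dbs, GEM_DATABASES)
  if (length(bad) || is.null(names(dumps)))
    stop("unknown database(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(GEM_DATABASES, collapse = ", "), ")",
         call. = FALSE)
  names(dumps) <- dbs

  uf <- list(metabolite = uf_new(), reaction = uf_new())
  recs <- list(metabolite = new.env(parent = emptyenv()),
               reaction = new.env(parent = emptyenv()))
  creation <- list(metabolite = character(), reaction = character())

  for (db in dbs) {
    parsed <- parse_database_dump(db, dumps[[db]])
    for (r in parsed$records) {
      cls <- r$entity_class
      key <- entity_key(r$database, r$native_id)
      if (is.null(uf[[cls]]$parent[[key]])) {
        uf[[cls]] <- uf_add(uf[[cls]], r$database, r$native_id)
        creation[[cls]] <- c(creation[[cls]], key)
      }
      recs[[cls]][[key]] <- merge_record(recs[[cls]][[key]], r)
    }
    for (x in parsed$xrefs) {
      cls <- x$entity_class
      if (!cls %in% c("metabolite", "reaction")) {
        warning("skipping cross-reference with unknown entity class: ",
                cls, call. = FALSE)
        next
      }
      for (side in list(c(x$source_db, x$source_id),
                        c(x$target_db, x$target_id))) {
        key <- entity_key(side[1], side[2])
        if (is.null(uf[[cls]]$parent[[key]])) {
          uf[[cls]] <- uf_add(uf[[cls]], side[1], side[2])
          creation[[cls]] <- c(creation[[cls]], key)
        }
      }
      out <- uf_union_guarded(uf[[cls]], x$source_db, x$source_id,
                              x$target_db, x$target_id)
      uf[[cls]] <- out$uf
    }
  }

  mapper <- list(precedence = dbs, version = MAPPER_FORMAT_VERSION)
  for (cls in c("metabolite", "reaction")) {
    id_map <- new.env(parent = emptyenv())
    props <- new.env(parent = emptyenv())
    u_of_root <- new.env(parent = emptyenv())
    next_u <- 0L
    for (key in creation[[cls]]) {
      root <- uf_find(uf[[cls]], key)
      if (is.null(u_of_root[[root]])) {
        next_u <- next_u + 1L
        u_of_root[[root]] <- next_u
        members <- uf[[cls]]$members[[root]]
        # order members by database precedence, then by creation
        ord <- order(match(members[, 1], dbs),
                     match(apply(members, 1, function(m)
                       entity_key(m[1], m[2])), creation[[cls]]))
        members <- members[ord, , drop = FALSE]
        bundle <- list(universal_id = next_u, names = character(),
                       formula = NA_character_,
                       molecular_weight = NA_real_,
                       inchi_key = NA_character_,
                       ec_numbers = character(), member_ids = list())
        for (i in seq_len(nrow(members))) {
          mkey <- entity_key(members[i, 1], members[i, 2])
          bundle$member_ids[[members[i, 1]]] <-
            c(bundle$member_ids[[members[i, 1]]], members[i, 2])
          r <- recs[[cls]][[mkey]]
          if (is.null(r)) next
          bundle$names <- unique(c(bundle$names, r$name))
          for (f in c("formula", "inchi_key", "molecular_weight"))
            if (is.na(bundle[[f]]) && !is.na(r[[f]])) bundle[[f]] <- r[[f]]
          bundle$ec_numbers <- unique(c(bundle$ec_numbers, r$ec_numbers))
        }
        props[[as.character(next_u)]] <- bundle
      }
      u <- u_of_root[[root]]
      db <- sub("\\|.*$", "", key)
      id <- sub("^[^|]*\\|", "", key)
      aliases <- if (db == "chebi") c(id, paste0("CHEBI:", id)) else id
      for (a in aliases) if (is.null(id_map[[a]])) id_map[[a]] <- u
    }
    pre <- if (cls == "metabolite") "met" else "reac"
    mapper[[paste0(pre, "_id2u")]] <- id_map
    mapper[[paste0(pre, "_props")]] <- props
    mapper[[paste0("n_", pre)]] <- next_u
  }

  proton <- integer()
  for (u in ls(mapper$met_props)) {
    b <- mapper$met_props[[u]]
    if ((!is.na(b$formula) && b$formula == "H") ||
        any(normalize_met_name(b$names) %in% PROTON_NAMES))
      proton <- c(proton, b$universal_id)
  }
  mapper$proton_ids <- sort(proton)
  class(mapper) <- "gem_mapper"
  mapper
}

#' @export
print.gem_mapper <- function(x, ...) {
  cat("<gem_mapper> universal identifier mapper\n")
  cat("  databases (precedence): ", paste(x$precedence, collapse = " > "),
      "\n", sep = "")
  cat("  metabolites: ", length(ls(x$met_id2u)), " native ids -> ",
      x$n_met, " universal ids\n", sep = "")
  cat("  reactions:   ", length(ls(x$reac_id2u)), " native ids -> ",
      x$n_reac, " universal ids\n", sep = "")
  cat("  proton/hydrogen universal ids: ",
      if (length(x$proton_ids)) paste(x$proton_ids, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}
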