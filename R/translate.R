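# Namespace translation and MIRIAM-style annotation extension.

DB_MET_REGISTRY <- c(metanetx = "metanetx.chemical",
                     modelseed = "seed.compound",
                     bigg = "bigg.metabolite",
                     kegg = "kegg.compound",
                     chebi = "chebi")
DB_REAC_REGISTRY <- c(metanetx = "metanetx.reaction",
                      modelseed = "seed.reaction",
                      bigg = "bigg.reaction",
                      kegg = "kegg.reaction",
                      chebi = "chebi")

# Target-database member ids of an entity, lexicographically sorted.
target_members <- function(u, entity_class, target, mapper) {
  props <- get_properties(u, entity_class, mapper)
  if (is.null(props)) return(character())
  sort(props$member_ids[[target]])
}

#' Translate a model into another database namespace
#'
#' Renames every metabolite and reaction whose universal entity contains at
#' least one member id of the target database to that member id (plus the
#' compartment suffix for metabolites, e.g. `"cpd00027_c"`). Entities with
#' no target member keep their id and are reported as untranslatable. When
#' several target ids are available the lexicographically smallest is used
#' and the rest reported; when a rename would collide with one already
#' made, the later entity keeps its original id and is reported as
#' ambiguous. Reaction ids are translated only when the original id is
#' recognized by the reaction mapper. Stoichiometry, bounds, GPRs and the
#' objective are unchanged; the operation is idempotent for a fixed target.
#'
#' @param model a [gem_model()].
#' @param target target database: `"metanetx"`, `"modelseed"`, `"bigg"`,
#'   `"kegg"` or `"chebi"`.
#' @param mapper a `gem_mapper`.
#' @return a list with elements `model` (the translated `gem_model`) and
#'   `report`, itself holding one entry per entity class with `translated`
#'   (count), `untranslatable` (ids left unchanged) and `ambiguous`
#'   (list of id -> unused candidate target ids).
#' @export
translate_model <- function(model, target, mapper) {
  target <- tolower(target)
  if (!target %in% GEM_DATABASES)
    stop("unknown target database '", target, "'; supported: ",
         paste(GEM_DATABASES, collapse = ", "), call. = FALSE)

  met_ren <- character(0)
  met_report <- list(translated = 0L, untranslatable = character(),
                     ambiguous = list())
  taken <- character()
  for (m in model$metabolites) {
    u <- met_universal(m, mapper)
    members <- if (is.null(u)) character() else
      target_members(u, "metabolite", target, mapper)
    if (length(members) == 0) {
      met_report$untranslatable <- c(met_report$untranslatable, m$id)
      taken <- c(taken, m$id)
      next
    }
    code <- normalize_compartment(m$compartment)
    cands <- paste0(members, "_", code)
    free <- cands[!(cands %in% taken)]
    if (length(free) == 0) {
      met_report$ambiguous[[m$id]] <- cands
      taken <- c(taken, m$id)
      next
    }
    new_id <- free[1]
    if (length(members) > 1)
      met_report$ambiguous[[m$id]] <- setdiff(cands, new_id)
    met_ren[m$id] <- new_id
    taken <- c(taken, new_id)
    met_report$translated <- met_report$translated + 1L
  }
  # entities renamed despite extra candidates count as translated, so the
  # partition below only separates renamed / no-target / collision
  met_report$ambiguous <-
    met_report$ambiguous[setdiff(names(met_report$ambiguous),
                                 names(met_ren))]

  reac_ren <- character(0)
  reac_report <- list(translated = 0L, untranslatable = character(),
                      ambiguous = list())
  rtaken <- character()
  for (r in model$reactions) {
    u <- map_to_universal(r$id, "reaction", mapper)
    members <- if (is.null(u)) character() else
      target_members(u, "reaction", target, mapper)
    if (length(members) == 0) {
      reac_report$untranslatable <- c(reac_report$untranslatable, r$id)
      rtaken <- c(rtaken, r$id)
      next
    }
    free <- members[!(members %in% rtaken)]
    if (length(free) == 0) {
      reac_report$ambiguous[[r$id]] <- members
      rtaken <- c(rtaken, r$id)
      next
    }
    new_id <- free[1]
    if (length(members) > 1)
      reac_report$ambiguous[[r$id]] <- setdiff(members, new_id)
    reac_ren[r$id] <- new_id
    rtaken <- c(rtaken, new_id)
    reac_report$translated <- reac_report$translated + 1L
  }
  reac_report$ambiguous <-
    reac_report$ambiguous[setdiff(names(reac_report$ambiguous),
                                  names(reac_ren))]

  mets <- lapply(model$metabolites, function(m) {
    if (!is.na(met_ren[m$id])) m$id <- unname(met_ren[m$id])
    m
  })
  rxns <- lapply(model$reactions, function(r) {
    if (!is.na(reac_ren[r$id])) r$id <- unname(reac_ren[r$id])
    hit <- names(r$participants) %in% names(met_ren)
    if (any(hit))
      names(r$participants)[hit] <-
        unname(met_ren[names(r$participants)[hit]])
    r
  })
  obj <- model$objective
  hit <- names(obj$coefficients) %in% names(reac_ren)
  if (any(hit))
    names(obj$coefficients)[hit] <-
      unname(reac_ren[names(obj$coefficients)[hit]])
  out <- gem_model(model$id, metabolites = mets, reactions = rxns,
                   objective = obj, compartments = model$compartments)
  list(model = out,
       report = structure(list(metabolites = met_report,
                               reactions = reac_report),
                          class = "gem_translation_report"))
}

#' @export
print.gem_translation_report <- function(x, ...) {
  for (cls in names(x)) {
    r <- x[[cls]]
    cat(cls, ": ", r$translated, " translated, ",
        length(r$untranslatable), " untranslatable, ",
        length(r$ambiguous), " ambiguous\n", sep = "")
  }
  invisible(x)
}

#' Extend model annotations from the universal mapper
#'
#' For every metabolite and reaction recognized by the mapper, adds all
#' member ids of its universal entity as identifiers.org-style annotations
#' (registry prefix to id list, serialized as MIRIAM `bqbiol:is` CVTerms in
#' SBML output). Existing annotations are preserved and duplicates removed;
#' running the operation twice changes nothing.
#'
#' @param model a [gem_model()].
#' @param mapper a `gem_mapper`.
#' @return the annotated `gem_model`.
#' @export
extend_annotations <- function(model, mapper) {
  annotate_one <- function(entity, u, registry_map, cls) {
    props <- if (is.null(u)) NULL else get_properties(u, cls, mapper)
    if (is.null(props)) return(entity)
    for (db in names(props$member_ids)) {
      reg <- registry_map[[db]]
      ids <- props$member_ids[[db]]
      if (db == "chebi") ids <- paste0("CHEBI:", ids)
      entity$annotations[[reg]] <-
        unique(c(entity$annotations[[reg]], ids))
    }
    entity
  }
  mets <- lapply(model$metabolites, function(m)
    annotate_one(m, met_universal(m, mapper), DB_MET_REGISTRY,
                 "metabolite"))
  rxns <- lapply(model$reactions, function(r)
    annotate_one(r, map_to_universal(r$id, "reaction", mapper),
                 DB_REAC_REGISTRY, "reaction"))
  gem_model(model$id, metabolites = mets, reactions = rxns,
            objective = model$objective,
            compartments = model$compartments)
}
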