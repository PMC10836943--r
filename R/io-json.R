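# COBRA JSON reader and writer.

model_to_cobra_list <- function(model) {
  mets <- lapply(model$metabolites, function(m) {
    out <- list(id = m$id, compartment = m$compartment)
    if (!is.na(m$name)) out$name <- m$name
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    if (length(m$annotations)) out$annotation <- m$annotations
    out
  })
  obj <- model$objective$coefficients
  rxns <- lapply(model$reactions, function(r) {
    out <- list(id = r$id,
                metabolites = as.list(r$participants),
                lower_bound = r$lower_bound,
                upper_bound = r$upper_bound,
                gene_reaction_rule = r$gpr)
    if (!is.na(r$name)) out$name <- r$name
    if (!is.na(obj[r$id])) out$objective_coefficient <- unname(obj[r$id])
    if (length(r$annotations)) out$annotation <- r$annotations
    out
  })
  genes <- lapply(model_genes(model), function(g) list(id = g, name = g))
  list(id = model$id,
       version = "1",
       objective_direction = model$objective$direction,
       metabolites = unname(mets),
       reactions = unname(rxns),
       genes = genes,
       compartments = as.list(model$compartments))
}

write_cobra_json <- function(model, path) {
  jsonlite::write_json(model_to_cobra_list(model), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

json_annotations <- function(x) {
  if (is.null(x)) return(list())
  out <- list()
  for (reg in names(x)) {
    v <- x[[reg]]
    if (is.list(v)) v <- unlist(v, use.names = FALSE)
    out[[reg]] <- as.character(v)
  }
  out
}

read_cobra_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop("not a readable COBRA JSON file: ", path, " (",
                       conditionMessage(e), ")", call. = FALSE))
  if (is.null(x$metabolites) || is.null(x$reactions))
    stop("COBRA JSON file lacks metabolites/reactions lists: ", path,
         call. = FALSE)
  mets <- lapply(x$metabolites, function(m) {
    gem_metabolite(m$id,
                   name = if (is.null(m$name)) NA_character_ else m$name,
                   compartment = if (is.null(m$compartment) ||
                                     !nzchar(m$compartment)) "c"
                     else m$compartment,
                   formula = if (is.null(m$formula)) NA_character_ else
                     m$formula,
                   charge = if (is.null(m$charge)) NA_integer_ else
                     as.integer(m$charge),
                   annotations = json_annotations(m$annotation))
  })
  obj <- numeric()
  rxns <- lapply(x$reactions, function(r) {
    participants <- vapply(r$metabolites, as.numeric, 0)
    if (!is.null(r$objective_coefficient) &&
        r$objective_coefficient != 0)
      obj[r$id] <<- as.numeric(r$objective_coefficient)
    gem_reaction(r$id,
                 participants = participants,
                 name = if (is.null(r$name)) NA_character_ else r$name,
                 lower_bound = if (is.null(r$lower_bound)) -1000 else
                   as.numeric(r$lower_bound),
                 upper_bound = if (is.null(r$upper_bound)) 1000 else
                   as.numeric(r$upper_bound),
                 gpr = if (is.null(r$gene_reaction_rule)) "" else
                   r$gene_reaction_rule,
                 annotations = json_annotations(r$annotation))
  })
  comps <- character()
  for (code in names(x$compartments))
    comps[code] <- as.character(x$compartments[[code]])
  direction <- if (identical(x$objective_direction, "min")) "min" else "max"
  gem_model(if (is.null(x$id)) "model" else x$id,
            metabolites = mets, reactions = rxns,
            objective = list(coefficients = obj, direction = direction),
            compartments = comps)
}
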