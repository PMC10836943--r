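#' In-memory genome-scale metabolic model
#'
#' A `gem_model` is a neutral container for a genome-scale metabolic model
#' (GEM): an ordered collection of metabolites, an ordered collection of
#' reactions, an objective (a set of reaction/coefficient pairs with a
#' direction) and a compartment table. It is the common currency of all
#' readers, writers and the merging algorithm in this package.
#'
#' @param id model identifier.
#' @param metabolites list of metabolite entries built with [gem_metabolite()].
#' @param reactions list of reaction entries built with [gem_reaction()].
#' @param objective named numeric vector of objective coefficients keyed by
#'   reaction id, or a list with elements `coefficients` (named numeric) and
#'   `direction` (`"max"` or `"min"`).
#' @param compartments named character vector mapping compartment codes to
#'   display names (e.g. `c(c = "cytosol")`).
#'
#' @return An object of class `gem_model`.
#' @examples
#' m <- gem_model("toy",
#'   metabolites = list(
#'     gem_metabolite("a_c", compartment = "c"),
#'     gem_metabolite("b_c", compartment = "c")),
#'   reactions = list(
#'     gem_reaction("r1", participants = c(a_c = -1, b_c = 1))),
#'   objective = c(r1 = 1))
#' m
#' @export
gem_model <- function(id, metabolites = list(), reactions = list(),
                      objective = numeric(), compartments = character()) {
  if (is.numeric(objective)) {
    objective <- list(coefficients = objective, direction = "max")
  }
  if (is.null(objective$direction)) objective$direction <- "max"
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(
    id = as.character(id),
    metabolites = metabolites,
    reactions = reactions,
    objective = objective,
    compartments = compartments
  ), class = "gem_model")
  validate_gem_model(m)
  m
}

#' @rdname gem_model
#' @param name display name (optional).
#' @param compartment compartment code of the metabolite.
#' @param formula chemical formula (optional).
#' @param charge integer charge (optional).
#' @param annotations named list mapping identifiers.org registry prefixes
#'   (e.g. `"kegg.compound"`) to character vectors of external identifiers.
#' @export
gem_metabolite <- function(id, name = NA_character_, compartment = "c",
                           formula = NA_character_, charge = NA_integer_,
                           annotations = list()) {
  stopifnot(nzchar(id), nzchar(compartment))
  list(id = as.character(id), name = as.character(name),
       compartment = as.character(compartment),
       formula = as.character(formula),
       charge = as.integer(charge),
       annotations = annotations)
}

#' @rdname gem_model
#' @param participants named numeric vector of stoichiometric coefficients
#'   keyed by metabolite id; negative coefficients are reactants, positive
#'   products. Zero coefficients are dropped.
#' @param lower_bound,upper_bound flux bounds.
#' @param gpr gene-protein-reaction rule as a boolean string over gene ids
#'   (`"and"`/`"or"`, parentheses allowed); `""` means no rule.
#' @export
gem_reaction <- function(id, participants, name = NA_character_,
                         lower_bound = -1000, upper_bound = 1000,
                         gpr = "", annotations = list()) {
  stopifnot(nzchar(id))
  participants <- participants[participants != 0]
  # stored in metabolite-id order: participant order is not semantic, and a
  # fixed order keeps serialized files byte-stable across formats
  if (length(participants))
    participants <- participants[order(names(participants),
                                       method = "radix")]
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound", call. = FALSE)
  list(id = as.character(id), name = as.character(name),
       participants = participants,
       lower_bound = as.numeric(lower_bound),
       upper_bound = as.numeric(upper_bound),
       gpr = as.character(gpr), annotations = annotations)
}

validate_gem_model <- function(m) {
  met_ids <- names(m$metabolites)
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  rxn_ids <- names(m$reactions)
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  for (r in m$reactions) {
    missing <- setdiff(names(r$participants), met_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  obj_missing <- setdiff(names(m$objective$coefficients), rxn_ids)
  if (length(obj_missing))
    stop("objective references unknown reactions: ",
         paste(obj_missing, collapse = ", "), call. = FALSE)
  invisible(m)
}

#' Reactant and product sets of a reaction
#'
#' Partition a reaction's participants by the sign of their stoichiometric
#' coefficient: negative coefficients are reactants, positive are products.
#'
#' @param r a reaction entry from a [gem_model()].
#' @return character vector of metabolite ids.
#' @export
reactants_of <- function(r) names(r$participants)[r$participants < 0]

#' @rdname reactants_of
#' @export
products_of <- function(r) names(r$participants)[r$participants > 0]

#' @export
print.gem_model <- function(x, ...) {
  cat("<gem_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "   reactions: ", length(x$reactions), "\n", sep = "")
  obj <- x$objective$coefficients
  if (length(obj)) {
    cat("  objective (", x$objective$direction, "): ",
        paste0(names(obj), " [", format(obj), "]", collapse = ", "),
        "\n", sep = "")
  } else cat("  objective: none\n")
  if (length(x$compartments))
    cat("  compartments: ",
        paste0(names(x$compartments), " (", x$compartments, ")",
               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gem_model <- function(object, ...) {
  rev <- vapply(object$reactions,
                function(r) r$lower_bound < 0 && r$upper_bound > 0, TRUE)
  out <- list(id = object$id,
              n_metabolites = length(object$metabolites),
              n_reactions = length(object$reactions),
              n_reversible = sum(rev),
              n_genes = length(model_genes(object)),
              compartments = sort(unique(vapply(object$metabolites,
                                                `[[`, "", "compartment"))))
  class(out) <- "summary.gem_model"
  out
}

#' @export
print.summary.gem_model <- function(x, ...) {
  cat("GEM '", x$id, "': ", x$n_metabolites, " metabolites, ",
      x$n_reactions, " reactions (", x$n_reversible, " reversible), ",
      x$n_genes, " genes\n", sep = "")
  cat("compartments:", paste(x$compartments, collapse = ", "), "\n")
  invisible(x)
}

# All gene tokens appearing in the model's GPR strings.
model_genes <- function(m) {
  toks <- unlist(lapply(m$reactions, function(r) gpr_genes(r$gpr)),
                 use.names = FALSE)
  sort(unique(toks))
}
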