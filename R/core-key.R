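# Internal merging namespace: compartment codes, mergem ids, reaction keys.

# Canonical short codes for common compartment spellings. Unrecognized
# compartments pass through lower-cased, so foreign codes still compare
# equal between models that share them.
COMPARTMENT_CODES <- c(
  "cytosol" = "c", "cytoplasm" = "c", "cytoplasmic" = "c",
  "extracellular" = "e", "extracellular space" = "e",
  "extra-organism" = "e", "extraorganism" = "e", "external" = "e",
  "periplasm" = "p", "periplasmic space" = "p",
  "mitochondria" = "m", "mitochondrion" = "m", "mitochondrial" = "m",
  "boundary" = "b",
  "nucleus" = "n", "golgi" = "g", "golgi apparatus" = "g",
  "endoplasmic reticulum" = "r", "vacuole" = "v", "peroxisome" = "x",
  "lysosome" = "l", "chloroplast" = "h"
)

#' Normalize a compartment label to a short code
#'
#' Maps common compartment spellings and suffixed codes to one-letter codes
#' used inside mergem ids: `"cytosol"`, `"c0"` and `"[c]"` all become
#' `"c"`; `"boundary"` becomes `"b"`. Unrecognized labels are returned
#' lower-cased.
#'
#' @param raw compartment label or code.
#' @return canonical short code (character scalar).
#' @examples
#' normalize_compartment("c0")
#' normalize_compartment("Extracellular")
#' @export
normalize_compartment <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  x <- gsub("^\\[|\\]$", "", x)          # "[c]" -> "c"
  if (!is.na(COMPARTMENT_CODES[x])) return(unname(COMPARTMENT_CODES[x]))
  if (grepl("^[a-z][0-9]+$", x)) return(substr(x, 1, 1))  # "c0" -> "c"
  x
}

# Annotation registries tried, in order, when a metabolite's own id is not
# in the mapper; mirrors the database precedence order.
ANNOTATION_LOOKUP_ORDER <- c("metanetx.chemical", "seed.compound",
                             "bigg.metabolite", "kegg.compound", "chebi")

# Universal id of a metabolite entry: its id first, then its annotation ids
# in fixed registry order (remaining registries alphabetically); first hit
# wins. NULL when nothing is known.
met_universal <- function(m, mapper) {
  u <- map_to_universal(m$id, "metabolite", mapper)
  if (!is.null(u)) return(u)
  regs <- names(m$annotations)
  regs <- c(intersect(ANNOTATION_LOOKUP_ORDER, regs),
            sort(setdiff(regs, ANNOTATION_LOOKUP_ORDER)))
  for (reg in regs) {
    for (a in m$annotations[[reg]]) {
      u <- map_to_universal(as.character(a), "metabolite", mapper)
      if (!is.null(u)) return(u)
    }
  }
  NULL
}

#' Internal merging id of a metabolite
#'
#' Computes the candidate mergem id `"mergem_<universal>_<compartment>"`
#' for a metabolite: the universal id is resolved from the metabolite's own
#' id, falling back to its annotation ids in fixed registry order, and the
#' compartment code is normalized with [normalize_compartment()]. When no
#' universal id is known the metabolite's original id is returned. During
#' merging a candidate can additionally be rejected when another metabolite
#' of the same model already claims it; this function reports the
#' conflict-free candidate.
#'
#' @param m a metabolite entry ([gem_metabolite()]).
#' @param mapper a `gem_mapper`.
#' @return a character id, and attribute `"universal"` carrying the integer
#'   universal id when one was found.
#' @export
mergem_id <- function(m, mapper) {
  u <- met_universal(m, mapper)
  if (is.null(u)) return(m$id)
  structure(paste0("mergem_", u, "_", normalize_compartment(m$compartment)),
            universal = u)
}

new_reaction_key <- function(ids, values, exact) {
  pairs <- unique(data.frame(id = ids, value = values,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$id, pairs$value), , drop = FALSE]
  structure(list(id = pairs$id, value = pairs$value, exact = exact),
            class = "reaction_key")
}

#' Reaction key of a reaction
#'
#' Builds the set of (mergem id, signed integer) pairs that identifies a
#' reaction by its participants. In default mode the integer is -1 for
#' reactants and 1 for products; in exact-stoichiometry mode it is the
#' signed stoichiometric coefficient (rounded to 6 decimals). Metabolites
#' listed in `omit` — protons/hydrogen and boundary-compartment metabolites
#' during merging — are left out unless `include_protons` is set; if
#' omission would empty the key, the unfiltered key is used instead so that
#' proton-only exchange reactions do not all collapse onto one empty key.
#'
#' @param r a reaction entry ([gem_reaction()]).
#' @param exact_stoichiometry use signed coefficients instead of -1/1.
#' @param include_protons keep omitted metabolites in the key.
#' @param translated_ids optional named character vector mapping participant
#'   metabolite ids to their mergem ids; participants absent from it keep
#'   their own id.
#' @param omit metabolite ids (pre-translation) to leave out of the key.
#' @return an object of class `reaction_key`.
#' @examples
#' r <- gem_reaction("R", c(mergem_23_c = -1, mergem_45_c = -1,
#'                          mergem_67_c = 1))
#' reaction_key(r)
#' @export
reaction_key <- function(r, exact_stoichiometry = FALSE,
                         include_protons = FALSE, translated_ids = NULL,
                         omit = character()) {
  mets <- names(r$participants)
  if (length(mets) == 0)
    stop("reaction '", r$id, "' has no participants", call. = FALSE)
  keep <- if (include_protons) rep(TRUE, length(mets)) else !(mets %in% omit)
  if (!any(keep)) keep <- rep(TRUE, length(mets))   # empty-key fallback
  mets <- mets[keep]
  coefs <- unname(r$participants[keep])
  ids <- vapply(mets, function(mid) {
    if (!is.null(translated_ids) && !is.na(translated_ids[mid]))
      unname(translated_ids[mid]) else mid
  }, "")
  values <- if (exact_stoichiometry) round(coefs, 6) else sign(coefs)
  new_reaction_key(ids, values, exact_stoichiometry)
}

#' Reverse of a reaction key
#'
#' Negates every signed integer in the key: a reaction and its reverse have
#' the same metabolites with opposite pairings, and
#' `reverse_key(reverse_key(k))` equals `k`.
#'
#' @param k a `reaction_key`.
#' @return a `reaction_key`.
#' @export
reverse_key <- function(k) new_reaction_key(k$id, -k$value, k$exact)

# Canonical string form used for hashing in the key registry.
key_string <- function(k) {
  paste(paste0(k$id, "=", format(k$value, trim = TRUE, scientific = FALSE)),
        collapse = ";")
}

#' @export
print.reaction_key <- function(x, ...) {
  cat("<reaction_key", if (x$exact) " (exact stoichiometry)", "> {",
      paste0("(", x$id, ", ", x$value, ")", collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' @export
format.reaction_key <- function(x, ...) key_string(x)
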