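# Universal-id lookup and property retrieval.

# Namespace prefixes recognized (and stripped) when looking up a raw id.
NAMESPACE_PREFIXES <- c(
  "bigg.metabolite:", "bigg.reaction:", "kegg.compound:", "kegg.reaction:",
  "seed.compound:", "seed.reaction:", "metanetx.chemical:",
  "metanetx.reaction:", "chebi:", "CHEBI:"
)

# Trailing compartment tags recognized when looking up a raw id:
# "_c", "_c0", "[c]" style suffixes with a single lowercase code letter.
strip_compartment_tag <- function(id) {
  out <- character()
  if (grepl("_[a-z][0-9]?$", id)) out <- c(out, sub("_[a-z][0-9]?$", "", id))
  if (grepl("\\[[a-zA-Z][0-9]?\\]$", id))
    out <- c(out, sub("\\[[a-zA-Z][0-9]?\\]$", "", id))
  out
}

strip_namespace_prefix <- function(id) {
  for (p in NAMESPACE_PREFIXES) {
    if (startsWith(tolower(id), tolower(p)))
      return(substring(id, nchar(p) + 1L))
  }
  character()
}

# Ordered candidate spellings tried against the mapper tables: the raw id
# verbatim; with SBML "M_"/"R_" prefix stripped; with a recognized trailing
# compartment tag stripped; with a namespace prefix stripped. First hit wins.
id_lookup_candidates <- function(raw_id) {
  base <- raw_id
  cands <- base
  if (grepl("^[MR]_", base)) {
    base2 <- substring(base, 3)
    cands <- c(cands, base2)
  } else base2 <- NULL
  for (b in c(base, base2))
    cands <- c(cands, strip_compartment_tag(b))
  for (b in unique(cands))
    cands <- c(cands, strip_namespace_prefix(b))
  # prefix-stripped forms may still carry a compartment tag
  for (b in unique(cands))
    cands <- c(cands, strip_compartment_tag(b))
  unique(cands[nzchar(cands)])
}

#' Map a raw identifier to its universal id
#'
#' Looks a raw metabolite or reaction identifier up in the mapper, trying in
#' order: the id verbatim; with an SBML-style `"M_"`/`"R_"` prefix stripped;
#' with a recognized trailing compartment tag stripped (`"_c"`, `"[c]"`,
#' `"_c0"`, ...); with a namespace prefix stripped (`"bigg.metabolite:"`,
#' `"kegg.compound:"`, `"seed.compound:"`, `"metanetx.chemical:"`,
#' `"chebi:"`). The first known variant wins.
#'
#' @param raw_id identifier as found in a model or database.
#' @param entity_class `"metabolite"` or `"reaction"`.
#' @param mapper a [build_universal_mapper()] result.
#' @return integer universal id, or `NULL` when no variant is known
#'   (absence is a valid result, not an error).
#' @export
map_to_universal <- function(raw_id, entity_class = c("metabolite",
                                                      "reaction"), mapper) {
  entity_class <- match.arg(entity_class)
  if (is.null(raw_id) || length(raw_id) != 1 || is.na(raw_id) ||
      !nzchar(raw_id)) return(NULL)
  tab <- if (entity_class == "metabolite") mapper$met_id2u else
    mapper$reac_id2u
  for (cand in id_lookup_candidates(raw_id)) {
    u <- tab[[cand]]
    if (!is.null(u)) return(u)
  }
  NULL
}

#' Consolidated properties of a mapped entity
#'
#' Returns the consolidated property bundle (names, formula, molecular
#' weight, InChI key, EC numbers) of a universal entity, together with all
#' of its member native ids grouped by database.
#'
#' @param id a raw identifier string (resolved via [map_to_universal()]) or
#'   an integer universal id.
#' @inheritParams map_to_universal
#' @return a list with elements `universal_id`, `names`, `formula`,
#'   `molecular_weight`, `inchi_key`, `ec_numbers` and `member_ids`
#'   (a named list, one character vector per database), or `NULL` when
#'   the id is unknown.
#' @export
get_properties <- function(id, entity_class = c("metabolite", "reaction"),
                           mapper) {
  entity_class <- match.arg(entity_class)
  u <- if (is.numeric(id)) as.integer(id) else
    map_to_universal(id, entity_class, mapper)
  if (is.null(u)) return(NULL)
  props <- if (entity_class == "metabolite") mapper$met_props else
    mapper$reac_props
  props[[as.character(u)]]
}

is_proton_universal <- function(u, mapper) {
  !is.null(u) && u %in% mapper$proton_ids
}
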