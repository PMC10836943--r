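# SBML Level 3 Version 1 + FBC v2 reader and writer (built on xml2).
#
# Internal ids are namespace-clean: the conventional "M_"/"R_"/"G_" SBML
# prefixes are stripped on read and restored on write. Characters that are
# not legal in an SBML SId are escaped as "__uXXXX__" (hex codepoint) on
# write and restored on read, so ids like "HEX1∼" survive a round trip.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_escape <- function(id) {
  chars <- strsplit(id, "")[[1]]
  bad <- !grepl("^[A-Za-z0-9_]$", chars)
  if (!any(bad)) return(id)
  chars[bad] <- vapply(chars[bad], function(ch)
    sprintf("__u%04x__", utf8ToInt(ch)), "")
  paste(chars, collapse = "")
}

sbml_unescape <- function(id) {
  while (grepl("__u[0-9a-f]{4,6}__", id)) {
    m <- regmatches(id, regexpr("__u[0-9a-f]{4,6}__", id))
    code <- strtoi(sub("^__u([0-9a-f]+)__$", "\\1", m), 16L)
    id <- sub("__u[0-9a-f]{4,6}__", intToUtf8(code), id, fixed = FALSE)
  }
  id
}

sbml_sid <- function(prefix, id) paste0(prefix, sbml_escape(id))
sbml_unsid <- function(prefix, sid) {
  if (startsWith(sid, prefix)) sid <- substring(sid, nchar(prefix) + 1L)
  sbml_unescape(sid)
}

bound_param_id <- function(value) {
  s <- format(value, trim = TRUE, scientific = FALSE)
  s <- gsub("-", "m", s, fixed = TRUE)
  s <- gsub(".", "p", s, fixed = TRUE)
  paste0("bnd_", s)
}

miriam_uri <- function(registry, id)
  paste0("https://identifiers.org/", registry, "/", id)

parse_miriam_uri <- function(uri) {
  # "https://identifiers.org/kegg.compound/C00031",
  # "http://identifiers.org/chebi/CHEBI:17634" or
  # "https://identifiers.org/CHEBI:17634"
  m <- regmatches(uri, regexec(
    "identifiers\\.org/([^/]+)/(.+)$", uri))[[1]]
  if (length(m) == 3) return(c(registry = m[2], id = m[3]))
  m <- regmatches(uri, regexec(
    "identifiers\\.org/([^/:]+):(.+)$", uri))[[1]]
  if (length(m) == 3)
    return(c(registry = tolower(m[2]), id = paste0(m[2], ":", m[3])))
  NULL
}

xml_quote <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

add_annotation_node <- function(parent, about, annotations) {
  if (length(annotations) == 0) return(invisible())
  lis <- unlist(lapply(names(annotations), function(reg)
    vapply(annotations[[reg]], function(id)
      paste0("<rdf:li rdf:resource=\"",
             xml_quote(miriam_uri(reg, id)), "\"/>"), "")))
  snippet <- paste0(
    "<annotation>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">",
    "<rdf:Description rdf:about=\"#", xml_quote(about), "\">",
    "<bqbiol:is><rdf:Bag>", paste(lis, collapse = ""),
    "</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>")
  xml2::xml_add_child(parent, xml2::read_xml(snippet))
  invisible()
}

read_annotations <- function(node) {
  out <- list()
  lis <- xml2::xml_find_all(
    node, "./*[local-name()='annotation']//*[local-name()='li']")
  for (li in lis) {
    uri <- xml2::xml_attr(li, "resource")
    if (is.na(uri)) next
    parsed <- parse_miriam_uri(uri)
    if (is.null(parsed)) next
    out[[parsed[["registry"]]]] <-
      unique(c(out[[parsed[["registry"]]]], parsed[["id"]]))
  }
  out
}

gpr_to_fbc <- function(parent, ast) {
  if (is.character(ast)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_sid("G_", ast))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
    for (a in ast$args) gpr_to_fbc(node, a)
  }
  invisible()
}

fbc_to_gpr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef")
    return(sbml_unsid("G_", xml2::xml_attr(node, "geneProduct")))
  kids <- xml2::xml_children(node)
  args <- lapply(kids, fbc_to_gpr)
  args <- args[!vapply(args, is.null, TRUE)]
  if (name %in% c("and", "or")) {
    if (length(args) == 1) return(args[[1]])
    return(list(op = name, args = args))
  }
  if (length(args) == 1) return(args[[1]])
  NULL
}

write_sbml <- function(model, path) {
  num <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  root <- xml2::xml_new_root(
    "sbml", "xmlns" = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(root, "model",
                               id = sbml_escape(model$id),
                               "fbc:strict" = "false")

  comps <- model$compartments
  met_comps <- unique(vapply(model$metabolites, `[[`, "", "compartment"))
  for (code in setdiff(met_comps, names(comps)))
    comps[code] <- code
  if (length(comps)) {
    lc <- xml2::xml_add_child(mnode, "listOfCompartments")
    for (code in names(comps)) {
      xml2::xml_add_child(lc, "compartment", id = sbml_escape(code),
                          name = comps[[code]], constant = "true")
    }
  }

  if (length(model$metabolites)) {
    ls_ <- xml2::xml_add_child(mnode, "listOfSpecies")
    for (m in model$metabolites) {
      sid <- sbml_sid("M_", m$id)
      attrs <- list(id = sid, compartment = sbml_escape(m$compartment),
                    hasOnlySubstanceUnits = "false",
                    boundaryCondition = "false", constant = "false")
      if (!is.na(m$name)) attrs$name <- m$name
      if (!is.na(m$formula)) attrs$"fbc:chemicalFormula" <- m$formula
      if (!is.na(m$charge)) attrs$"fbc:charge" <- as.character(m$charge)
      sp <- do.call(xml2::xml_add_child, c(list(ls_, "species"), attrs))
      add_annotation_node(sp, sid, m$annotations)
    }
  }

  bounds <- sort(unique(unlist(lapply(model$reactions, function(r)
    c(r$lower_bound, r$upper_bound)))))
  if (length(bounds)) {
    lp <- xml2::xml_add_child(mnode, "listOfParameters")
    for (v in bounds) {
      xml2::xml_add_child(lp, "parameter", id = bound_param_id(v),
                          value = num(v), constant = "true")
    }
  }

  genes <- model_genes(model)
  if (length(model$reactions)) {
    lr <- xml2::xml_add_child(mnode, "listOfReactions")
    for (r in model$reactions) {
      sid <- sbml_sid("R_", r$id)
      attrs <- list(id = sid,
                    reversible = tolower(r$lower_bound < 0),
                    fast = "false",
                    "fbc:lowerFluxBound" = bound_param_id(r$lower_bound),
                    "fbc:upperFluxBound" = bound_param_id(r$upper_bound))
      if (!is.na(r$name)) attrs$name <- r$name
      rn <- do.call(xml2::xml_add_child, c(list(lr, "reaction"), attrs))
      add_annotation_node(rn, sid, r$annotations)
      react <- r$participants[r$participants < 0]
      prod <- r$participants[r$participants > 0]
      if (length(react)) {
        lrt <- xml2::xml_add_child(rn, "listOfReactants")
        for (mid in names(react)) {
          xml2::xml_add_child(lrt, "speciesReference",
                              species = sbml_sid("M_", mid),
                              stoichiometry = num(-react[[mid]]),
                              constant = "true")
        }
      }
      if (length(prod)) {
        lpd <- xml2::xml_add_child(rn, "listOfProducts")
        for (mid in names(prod)) {
          xml2::xml_add_child(lpd, "speciesReference",
                              species = sbml_sid("M_", mid),
                              stoichiometry = num(prod[[mid]]),
                              constant = "true")
        }
      }
      ast <- gpr_parse(r$gpr)
      if (!is.null(ast)) {
        gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
        gpr_to_fbc(gpa, ast)
      }
    }
  }

  obj <- model$objective$coefficients
  if (length(obj)) {
    lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj1")
    on <- xml2::xml_add_child(
      lo, "fbc:objective", "fbc:id" = "obj1",
      "fbc:type" = if (identical(model$objective$direction, "min"))
        "minimize" else "maximize")
    lf <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
    for (rid in names(obj)) {
      xml2::xml_add_child(lf, "fbc:fluxObjective",
                          "fbc:reaction" = sbml_sid("R_", rid),
                          "fbc:coefficient" = num(obj[[rid]]))
    }
  }

  if (length(genes)) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = sbml_sid("G_", g), "fbc:label" = g)
    }
  }

  xml2::write_xml(root, path)
  invisible(path)
}

find_all_local <- function(node, name)
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("not a readable SBML file: ", path, " (", conditionMessage(e),
         ")", call. = FALSE))
  mnode <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(mnode, "xml_missing"))
    stop("SBML file has no <model> element: ", path, call. = FALSE)
  model_id <- xml2::xml_attr(mnode, "id")
  if (is.na(model_id)) model_id <- "model"

  comps <- character()
  for (cn in find_all_local(mnode, "compartment")) {
    code <- sbml_unescape(xml2::xml_attr(cn, "id"))
    nm <- xml2::xml_attr(cn, "name")
    comps[code] <- if (is.na(nm)) code else nm
  }

  params <- numeric()
  for (pn in find_all_local(mnode, "parameter")) {
    params[xml2::xml_attr(pn, "id")] <-
      as.numeric(xml2::xml_attr(pn, "value"))
  }

  mets <- list()
  for (sn in find_all_local(mnode, "species")) {
    sid <- xml2::xml_attr(sn, "id")
    if (is.na(sid))
      stop("SBML species without id in ", path, call. = FALSE)
    charge <- suppressWarnings(as.integer(xml2::xml_attr(sn, "charge")))
    mets[[length(mets) + 1L]] <- gem_metabolite(
      sbml_unsid("M_", sid),
      name = xml2::xml_attr(sn, "name"),
      compartment = sbml_unescape(xml2::xml_attr(sn, "compartment")),
      formula = xml2::xml_attr(sn, "chemicalFormula"),
      charge = charge,
      annotations = read_annotations(sn))
  }

  rxns <- list()
  for (rn in find_all_local(mnode, "reaction")) {
    sid <- xml2::xml_attr(rn, "id")
    participants <- numeric()
    for (sr in xml2::xml_find_all(
      rn, "./*[local-name()='listOfReactants']/*")) {
      mid <- sbml_unsid("M_", xml2::xml_attr(sr, "species"))
      participants[mid] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(
      rn, "./*[local-name()='listOfProducts']/*")) {
      mid <- sbml_unsid("M_", xml2::xml_attr(sr, "species"))
      participants[mid] <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && !is.na(params[lb_ref])) params[[lb_ref]]
      else if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && !is.na(params[ub_ref])) params[[ub_ref]]
      else 1000
    gpa <- xml2::xml_find_first(
      rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      ast <- fbc_to_gpr(gpa)
      gpr_deparse(ast)
    }
    rxns[[length(rxns) + 1L]] <- gem_reaction(
      sbml_unsid("R_", sid),
      participants = participants,
      name = xml2::xml_attr(rn, "name"),
      lower_bound = lb, upper_bound = ub, gpr = gpr,
      annotations = read_annotations(rn))
  }

  obj <- numeric()
  direction <- "max"
  active <- xml2::xml_attr(
    xml2::xml_find_first(mnode, ".//*[local-name()='listOfObjectives']"),
    "activeObjective")
  for (on in find_all_local(mnode, "objective")) {
    oid <- xml2::xml_attr(on, "id")
    if (!is.na(active) && !is.na(oid) && oid != active) next
    direction <- if (identical(xml2::xml_attr(on, "type"), "minimize"))
      "min" else "max"
    for (fo in find_all_local(on, "fluxObjective")) {
      rid <- sbml_unsid("R_", xml2::xml_attr(fo, "reaction"))
      obj[rid] <- as.numeric(xml2::xml_attr(fo, "coefficient"))
    }
    break
  }

  gem_model(sbml_unescape(model_id), metabolites = mets, reactions = rxns,
            objective = list(coefficients = obj, direction = direction),
            compartments = comps)
}
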