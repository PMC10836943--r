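# The merging algorithm: template absorption, model absorption, objective
# assignment, Jaccard matrix, id reversion.
#
# The merge runs over a mutable state environment holding the growing
# merged model, the source maps mu (metabolites) and rho (reactions), the
# reversion map sigma (mergem id -> original id of the first model using
# it), and the key registry psi (key string -> merged reaction id).

new_merge_state <- function(mapper, exact_stoichiometry, include_protons,
                            n_models) {
  state <- new.env(parent = emptyenv())
  state$mapper <- mapper
  state$exact <- exact_stoichiometry
  state$include_protons <- include_protons
  state$n_models <- n_models
  state$mets <- list()
  state$rxns <- list()
  state$compartments <- character()
  state$mu <- new.env(parent = emptyenv())
  state$rho <- new.env(parent = emptyenv())
  state$sigma <- new.env(parent = emptyenv())
  state$psi <- new.env(parent = emptyenv())
  state$psi_exact <- new.env(parent = emptyenv())
  state$model_ids <- character(n_models)
  state
}

add_source <- function(env, key, index, original_id) {
  entry <- c(as.character(index), original_id)
  cur <- env[[key]]
  if (is.null(cur)) { env[[key]] <- list(entry); return(invisible()) }
  for (e in cur) if (identical(e, entry)) return(invisible())
  env[[key]] <- c(cur, list(entry))
  invisible()
}

# Per-model mergem-id map (theta): original metabolite id -> key id used in
# reaction keys (the mergem id when a universal id exists, else the
# original id).
model_theta <- function(model, mapper) {
  out <- character(0)
  for (m in model$metabolites) out[m$id] <- mergem_id(m, mapper)
  out
}

# Metabolite ids (pre-translation) omitted from reaction keys: protons /
# hydrogen (by universal id) and boundary-compartment metabolites.
model_key_omissions <- function(model, theta, mapper) {
  omit <- character()
  for (m in model$metabolites) {
    code <- normalize_compartment(m$compartment)
    is_proton <- grepl("^mergem_", theta[m$id]) &&
      is_proton_universal(as.integer(sub("^mergem_([0-9]+)_.*$", "\\1",
                                         theta[m$id])), mapper)
    if (is_proton || code == "b") omit <- c(omit, m$id)
  }
  omit
}

register_reaction_keys <- function(state, rid, rxn, theta, omit) {
  k <- reaction_key(rxn, exact_stoichiometry = state$exact,
                    include_protons = state$include_protons,
                    translated_ids = theta, omit = omit)
  ks <- key_string(k)
  if (is.null(state$psi[[ks]])) state$psi[[ks]] <- rid
  # exact-stoichiometry key kept alongside, used when reusing a merged
  # objective reaction is only safe on identical coefficients
  ke <- reaction_key(rxn, exact_stoichiometry = TRUE,
                     include_protons = state$include_protons,
                     translated_ids = theta, omit = omit)
  kes <- key_string(ke)
  if (is.null(state$psi_exact[[kes]])) state$psi_exact[[kes]] <- rid
  k
}

# Step 1: copy every template metabolite and reaction; translatable
# metabolites are renamed to their mergem id (the original id is stored in
# sigma) unless an earlier template metabolite already claimed that mergem
# id, in which case the original id is retained untranslated.
absorb_template <- function(template, state) {
  state$model_ids[1] <- template$id
  state$compartments <- template$compartments
  mapper <- state$mapper
  theta <- model_theta(template, mapper)
  rmap <- character(0)
  for (m in template$metabolites) {
    cand <- theta[m$id]
    translated <- grepl("^mergem_", cand) && is.null(state$mets[[cand]])
    new_id <- if (translated) cand else m$id
    if (translated) state$sigma[[cand]] <- m$id
    mm <- m
    mm$id <- new_id
    state$mets[[new_id]] <- mm
    add_source(state$mu, new_id, 1L, m$id)
    rmap[m$id] <- new_id
  }
  omit <- model_key_omissions(template, theta, mapper)
  for (r in template$reactions) {
    rr <- r
    names(rr$participants) <- unname(rmap[names(r$participants)])
    state$rxns[[r$id]] <- rr
    add_source(state$rho, r$id, 1L, r$id)
    register_reaction_keys(state, r$id, r, theta, omit)
  }
  state$rmaps <- list(rmap)
  state$thetas <- list(theta)
  invisible(state)
}

# Rename participants, collapsing any duplicates created by substitution.
rename_participants <- function(participants, map) {
  ids <- vapply(names(participants), function(x)
    if (!is.na(map[x])) unname(map[x]) else x, "")
  coefs <- tapply(unname(participants), ids, sum)
  coefs <- coefs[coefs != 0]
  out <- as.numeric(coefs)
  names(out) <- names(coefs)
  out
}

merge_annotations <- function(a, b) {
  for (reg in names(b)) a[[reg]] <- unique(c(a[[reg]], b[[reg]]))
  a
}

unique_reaction_id <- function(id, state) {
  while (!is.null(state$rxns[[id]])) id <- paste0(id, "\u223c")
  id
}

# Step 2: merge one non-template model. Metabolites go through the branch
# ladder (same id; same mergem id claimed by this model / another model /
# with a translatable alternative present here; fresh translation), then
# non-objective reactions are matched by forward or reverse key.
absorb_model <- function(model, index, state) {
  state$model_ids[index] <- model$id
  mapper <- state$mapper
  theta <- model_theta(model, mapper)
  rmap <- character(0)
  # per-reaction participant overrides for the same-model substitution case
  overrides <- list()
  new_comp <- setdiff(names(model$compartments), names(state$compartments))
  state$compartments <- c(state$compartments,
                          model$compartments[new_comp])

  for (m in model$metabolites) {
    cand <- theta[m$id]
    has_mergem <- grepl("^mergem_", cand)
    if (!is.null(state$mets[[m$id]])) {
      # same original id already present: source-map update only
      add_source(state$mu, m$id, index, m$id)
      rmap[m$id] <- m$id
    } else if (has_mergem && !is.null(state$mets[[cand]])) {
      sig <- state$sigma[[cand]]
      claimed_by_this_model <- any(vapply(state$mu[[cand]], function(e)
        e[1] == as.character(index), TRUE))
      if (!is.null(sig) && m$id != sig &&
          !is.null(model$metabolites[[sig]])) {
        # this model also contains the metabolite whose original id seeded
        # the mergem id: keep the original id so both survive
        mm <- m
        state$mets[[m$id]] <- mm
        add_source(state$mu, m$id, index, m$id)
        rmap[m$id] <- m$id
      } else if (claimed_by_this_model) {
        # a metabolite of this same model already claimed the mergem id:
        # substitute per reaction, except where the reaction also contains
        # the claiming metabolite (substitution would corrupt stoichiometry)
        claimer <- NULL
        for (e in state$mu[[cand]])
          if (e[1] == as.character(index)) claimer <- e[2]
        kept <- FALSE
        for (r in model$reactions) {
          if (!(m$id %in% names(r$participants))) next
          if (!is.null(claimer) && claimer %in% names(r$participants)) {
            kept <- TRUE
          } else {
            ov <- overrides[[r$id]]
            if (is.null(ov)) ov <- character(0)
            ov[m$id] <- cand
            overrides[[r$id]] <- ov
          }
        }
        if (kept) {
          mm <- m
          state$mets[[m$id]] <- mm
          add_source(state$mu, m$id, index, m$id)
          rmap[m$id] <- m$id
        } else {
          # substituted everywhere (or participates nowhere): identified
          # with the claiming merged metabolite
          add_source(state$mu, cand, index, m$id)
          rmap[m$id] <- cand
        }
      } else {
        # claimed by an earlier model: identify with it
        add_source(state$mu, cand, index, m$id)
        rmap[m$id] <- cand
      }
    } else {
      new_id <- if (has_mergem) cand else m$id
      if (has_mergem) state$sigma[[cand]] <- m$id
      mm <- m
      mm$id <- new_id
      state$mets[[new_id]] <- mm
      add_source(state$mu, new_id, index, m$id)
      rmap[m$id] <- new_id
    }
  }

  omit <- model_key_omissions(model, theta, mapper)
  obj_rxns <- names(model$objective$coefficients)
  for (r in model$reactions) {
    if (r$id %in% obj_rxns) next      # objective reactions handled in step 3
    k <- reaction_key(r, exact_stoichiometry = state$exact,
                      include_protons = state$include_protons,
                      translated_ids = theta, omit = omit)
    hit <- state$psi[[key_string(k)]]
    if (is.null(hit)) hit <- state$psi[[key_string(reverse_key(k))]]
    if (!is.null(hit)) {
      add_source(state$rho, hit, index, r$id)
      tgt <- state$rxns[[hit]]
      tgt$gpr <- gpr_or_merge(tgt$gpr, r$gpr)
      tgt$annotations <- merge_annotations(tgt$annotations, r$annotations)
      state$rxns[[hit]] <- tgt
    } else {
      new_id <- unique_reaction_id(r$id, state)
      rr <- r
      rr$id <- new_id
      pmap <- rmap
      ov <- overrides[[r$id]]
      if (!is.null(ov)) pmap[names(ov)] <- ov
      rr$participants <- rename_participants(r$participants, pmap)
      if (length(rr$participants) == 0) {
        warning("reaction '", r$id, "' lost all participants after ",
                "metabolite substitution; keeping original participants",
                call. = FALSE)
        rr$participants <- rename_participants(r$participants, rmap)
      }
      state$rxns[[new_id]] <- rr
      add_source(state$rho, new_id, index, r$id)
      register_reaction_keys(state, new_id, r, theta, omit)
    }
  }
  state$rmaps[[index]] <- rmap
  state$thetas[[index]] <- theta
  invisible(state)
}

# Step 3. Either copy one model's objective reactions, or build a single
# merged objective reaction in which each precursor's stoichiometry is the
# running mean over the objective reactions containing it (delta counters
# per metabolite and side).
assign_objective <- function(models, choice, state) {
  if (identical(choice, "merge")) return(merge_objectives(models, state))
  i <- as.integer(choice)
  if (is.na(i) || i < 1 || i > length(models))
    stop("objective choice must be \"merge\" or a model index in 1..",
         length(models), call. = FALSE)
  model <- models[[i]]
  coefs <- model$objective$coefficients
  obj <- numeric(0)
  for (rid in names(coefs)) {
    merged_id <- if (i == 1L) rid else {
      # the reaction was skipped during step 2; add it now with translated
      # participants (unless the template already carries this id)
      existing <- state$rxns[[rid]]
      from_same <- !is.null(existing) &&
        any(vapply(state$rho[[rid]], function(e)
          e[1] == as.character(i) && e[2] == rid, TRUE))
      if (from_same) rid else {
        new_id <- unique_reaction_id(rid, state)
        rr <- model$reactions[[rid]]
        rr$id <- new_id
        rr$participants <- rename_participants(rr$participants,
                                               state$rmaps[[i]])
        state$rxns[[new_id]] <- rr
        new_id
      }
    }
    add_source(state$rho, merged_id, i, rid)
    obj[merged_id] <- unname(coefs[rid])
  }
  state$objective <- list(coefficients = obj,
                          direction = model$objective$direction)
  invisible(state)
}

merge_objectives <- function(models, state) {
  reactants <- numeric(0)   # magnitudes per merged metabolite id
  products <- numeric(0)
  delta_t <- numeric(0)
  delta_p <- numeric(0)
  sources <- list()
  for (i in seq_along(models)) {
    model <- models[[i]]
    rmap <- state$rmaps[[i]]
    for (rid in names(model$objective$coefficients)) {
      r <- model$reactions[[rid]]
      if (is.null(r)) next
      sources[[length(sources) + 1L]] <- c(as.character(i), rid)
      for (mid in names(r$participants)) {
        coef <- r$participants[[mid]]
        key <- if (!is.na(rmap[mid])) unname(rmap[mid]) else mid
        if (coef < 0) {
          if (is.na(reactants[key])) {
            reactants[key] <- -coef
            delta_t[key] <- 1
          } else {
            reactants[key] <- (delta_t[key] * reactants[key] + (-coef)) /
              (delta_t[key] + 1)
            delta_t[key] <- delta_t[key] + 1
          }
        } else {
          if (is.na(products[key])) {
            products[key] <- coef
            delta_p[key] <- 1
          } else {
            products[key] <- (delta_p[key] * products[key] + coef) /
              (delta_p[key] + 1)
            delta_p[key] <- delta_p[key] + 1
          }
        }
      }
    }
  }
  participants <- numeric(0)
  for (key in union(names(reactants), names(products))) {
    v <- 0
    if (!is.na(products[key])) v <- v + products[key]
    if (!is.na(reactants[key])) v <- v - reactants[key]
    if (v != 0) participants[key] <- v
  }
  if (length(participants) == 0)
    stop("no objective reactions found in any input model", call. = FALSE)
  robj <- gem_reaction("merged_objective", participants = participants,
                       name = "merged objective",
                       lower_bound = 0, upper_bound = 1000)
  # the averaged reaction may coincide exactly with an existing reaction
  # (e.g. identical biomass functions); reuse it rather than duplicating
  theta_merged <- merged_theta(state)
  omit <- merged_key_omissions(state)
  ke <- reaction_key(robj, exact_stoichiometry = TRUE,
                     include_protons = state$include_protons,
                     translated_ids = theta_merged, omit = omit)
  hit <- state$psi_exact[[key_string(ke)]]
  obj_id <- if (!is.null(hit)) hit else {
    state$rxns[["merged_objective"]] <- robj
    "merged_objective"
  }
  for (s in sources) add_source(state$rho, obj_id, s[1], s[2])
  state$objective <- list(coefficients = stats::setNames(1, obj_id),
                          direction = "max")
  invisible(state)
}

# Key-space ids for metabolites of the merged model itself (used when
# matching the merged objective reaction against the key registry).
merged_theta <- function(state) {
  out <- character(0)
  for (m in state$mets) out[m$id] <- mergem_id(m, state$mapper)
  out
}

merged_key_omissions <- function(state) {
  omit <- character()
  theta <- merged_theta(state)
  for (m in state$mets) {
    code <- normalize_compartment(m$compartment)
    is_proton <- grepl("^mergem_", theta[m$id]) &&
      is_proton_universal(as.integer(sub("^mergem_([0-9]+)_.*$", "\\1",
                                         theta[m$id])), state$mapper)
    if (is_proton || code == "b") omit <- c(omit, m$id)
  }
  omit
}

#' Jaccard distance between two sets
#'
#' `1 - |A intersect B| / |A union B|`: 0 for identical sets, 1 for
#' disjoint non-empty sets. Two empty sets are identical, so their
#' distance is defined as 0.
#'
#' @param a,b vectors treated as sets.
#' @return a number in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  un <- length(union(a, b))
  if (un == 0) return(0)
  1 - length(intersect(a, b)) / un
}

source_sets <- function(env, n) {
  sets <- rep(list(character()), n)
  for (key in ls(env)) {
    for (e in env[[key]]) {
      i <- as.integer(e[1])
      sets[[i]] <- c(sets[[i]], key)
    }
  }
  lapply(sets, unique)
}

# Step 4. n x n matrix: metabolite distances above the diagonal, reaction
# distances below, zeros on the diagonal. Sets are the merged entities
# traced back to each input model through mu / rho.
compute_jaccard_matrix <- function(state) {
  n <- state$n_models
  met_sets <- source_sets(state$mu, n)
  reac_sets <- source_sets(state$rho, n)
  jm <- matrix(0, n, n, dimnames = list(state$model_ids, state$model_ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) jm[i, j] <- jaccard_distance(met_sets[[i]], met_sets[[j]])
      if (i > j) jm[i, j] <- jaccard_distance(reac_sets[[i]],
                                              reac_sets[[j]])
    }
  }
  jm
}

pair_stats <- function(state) {
  n <- state$n_models
  met_sets <- source_sets(state$mu, n)
  reac_sets <- source_sets(state$rho, n)
  common <- function(sets) {
    cnt <- matrix(0L, n, n, dimnames = list(state$model_ids,
                                            state$model_ids))
    pct <- matrix(NA_real_, n, n, dimnames = dimnames(cnt))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      cnt[i, j] <- length(intersect(sets[[i]], sets[[j]]))
      un <- length(union(sets[[i]], sets[[j]]))
      pct[i, j] <- if (un == 0) 100 else 100 * cnt[i, j] / un
    }
    list(common = cnt, percent = pct)
  }
  list(metabolites = common(met_sets), reactions = common(reac_sets))
}

# Step 5. Rename every mergem-id metabolite back to the original id stored
# in sigma (the first model that used it); rename in reactions and mu too.
revert_ids <- function(state) {
  ren <- character(0)
  used <- names(state$mets)[!grepl("^mergem_", names(state$mets))]
  for (mid in names(state$mets)) {
    if (!grepl("^mergem_", mid)) next
    orig <- state$sigma[[mid]]
    if (is.null(orig)) orig <- sub("^mergem_", "m_", mid)  # untracked guard
    while (orig %in% used) orig <- paste0(orig, "\u223c")
    ren[mid] <- orig
    used <- c(used, orig)
  }
  # apply renames
  if (length(ren)) {
    mets <- state$mets
    names(mets) <- vapply(names(mets), function(x)
      if (!is.na(ren[x])) unname(ren[x]) else x, "")
    for (i in seq_along(mets)) mets[[i]]$id <- names(mets)[i]
    state$mets <- mets
    for (rid in names(state$rxns)) {
      p <- state$rxns[[rid]]$participants
      hit <- names(p) %in% names(ren)
      if (any(hit)) {
        names(p)[hit] <- unname(ren[names(p)[hit]])
        state$rxns[[rid]]$participants <- p
      }
    }
    for (key in names(ren)) {
      entries <- state$mu[[key]]
      rm(list = key, envir = state$mu)
      state$mu[[unname(ren[key])]] <- entries
    }
  }
  invisible(state)
}

sources_as_list <- function(env) {
  keys <- sort(ls(env))
  out <- lapply(keys, function(k) {
    m <- do.call(rbind, env[[k]])
    data.frame(model = as.integer(m[, 1]), id = m[, 2],
               stringsAsFactors = FALSE)
  })
  names(out) <- keys
  out
}

#' Merge genome-scale metabolic models
#'
#' Merges two or more GEMs, possibly using different identifier namespaces,
#' into a single model. The first model is the template: all of its
#' metabolites and reactions are guaranteed present in the result.
#' Metabolites are translated into an internal common namespace (mergem
#' ids: universal id + compartment code) so that equivalent metabolites
#' from different namespaces unify; reactions are matched by their keys
#' (forward or reverse); matched reactions keep the first-encountered
#' reaction's id, bounds and stoichiometry while GPRs are OR-combined and
#' annotations unioned. After merging, internal ids are reverted to the
#' original id of the first model that used each metabolite.
#'
#' @param models list of two or more [gem_model()] objects, or file paths
#'   readable by [read_model()]. The first is the template.
#' @param objective `"merge"` (default) to average all input objective
#'   reactions into a single `merged_objective` reaction (each precursor's
#'   stoichiometry is the mean over the objective reactions containing it),
#'   or a model index whose objective is copied.
#' @param exact_stoichiometry match reactions only when participant
#'   stoichiometries agree (coefficients compared after rounding to 6
#'   decimals).
#' @param include_protons keep protons/hydrogen and boundary metabolites in
#'   reaction keys (by default they are ignored, which improves matching
#'   across database conventions).
#' @param mapper a `gem_mapper` from [build_universal_mapper()] or
#'   [load_mapper()].
#' @return an object of class `gem_merge` with elements `merged` (the
#'   merged `gem_model`), `mu` and `rho` (per merged metabolite/reaction,
#'   a data frame of the input models and original ids containing it),
#'   `jaccard` (the n x n Jaccard distance matrix: metabolite distances
#'   above the diagonal, reaction distances below) and `stats` (per-pair
#'   common-entity counts and percentages).
#' @examples
#' mapper <- fixture_mapper()
#' pair <- make_toy_models("cross_namespace")
#' res <- merge_gems(pair, mapper = mapper)
#' res$jaccard
#' @export
merge_gems <- function(models, objective = "merge",
                       exact_stoichiometry = FALSE,
                       include_protons = FALSE, mapper) {
  models <- lapply(models, function(m)
    if (inherits(m, "gem_model")) m else read_model(m))
  if (length(models) < 2)
    stop("at least two models are required for merging", call. = FALSE)
  if (missing(mapper) || !inherits(mapper, "gem_mapper"))
    stop("a 'gem_mapper' must be supplied (see build_universal_mapper(), ",
         "load_mapper() or fixture_mapper())", call. = FALSE)
  state <- new_merge_state(mapper, exact_stoichiometry, include_protons,
                           length(models))
  absorb_template(models[[1]], state)
  for (i in seq_along(models)[-1]) absorb_model(models[[i]], i, state)
  assign_objective(models, objective, state)
  jm <- compute_jaccard_matrix(state)
  stats <- pair_stats(state)
  revert_ids(state)
  merged <- gem_model(paste0("merged_", models[[1]]$id),
                      metabolites = unname(state$mets),
                      reactions = unname(state$rxns),
                      objective = state$objective,
                      compartments = state$compartments)
  structure(list(merged = merged,
                 mu = sources_as_list(state$mu),
                 rho = sources_as_list(state$rho),
                 jaccard = jm,
                 stats = stats),
            class = "gem_merge")
}

#' @export
print.gem_merge <- function(x, ...) {
  cat("<gem_merge> of ", nrow(x$jaccard), " models\n", sep = "")
  cat("  merged model: ", length(x$merged$metabolites), " metabolites, ",
      length(x$merged$reactions), " reactions\n", sep = "")
  cat("  Jaccard distance matrix (metabolites above, reactions below):\n")
  print(round(x$jaccard, 3))
  invisible(x)
}

#' @export
summary.gem_merge <- function(object, ...) {
  n <- nrow(object$jaccard)
  cat("Merged", n, "models into", length(object$merged$metabolites),
      "metabolites and", length(object$merged$reactions), "reactions\n")
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    cat(sprintf(
      "  %s vs %s: %d common metabolites (%.1f%%), %d common reactions (%.1f%%)\n",
      rownames(object$jaccard)[i], rownames(object$jaccard)[j],
      object$stats$metabolites$common[i, j],
      object$stats$metabolites$percent[i, j],
      object$stats$reactions$common[i, j],
      object$stats$reactions$percent[i, j]))
  }
  invisible(object)
}
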