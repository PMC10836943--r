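# Shared fixtures and independent oracles.

test_mapper <- local({
  mapper <- NULL
  function() {
    if (is.null(mapper)) mapper <<- fixture_mapper()
    mapper
  }
})

# Brute-force oracle for cross-reference merging: replays entity records
# and xref pairs sequentially over a plain list of member sets, applying
# the skip rule literally ("the target id must not already be linked to a
# different id of the source database"). Returns the partition as a sorted
# list of sorted "db|id" member vectors.
replay_partition <- function(entities, pairs) {
  groups <- list()          # each: character vector of "db|id"
  find_group <- function(key) {
    for (g in seq_along(groups)) if (key %in% groups[[g]]) return(g)
    NA_integer_
  }
  add_entity <- function(db, id) {
    key <- paste0(db, "|", id)
    if (is.na(find_group(key))) groups[[length(groups) + 1L]] <<- key
  }
  for (e in entities) add_entity(e[1], e[2])
  for (p in pairs) {
    add_entity(p[1], p[2])    # source db, id
    add_entity(p[3], p[4])    # target db, id
    ks <- paste0(p[1], "|", p[2])
    kt <- paste0(p[3], "|", p[4])
    gs <- find_group(ks)
    gt <- find_group(kt)
    if (gs == gt) next
    target_members <- groups[[gt]]
    dbs <- sub("\\|.*$", "", target_members)
    ids <- sub("^[^|]*\\|", "", target_members)
    if (any(dbs == p[1] & ids != p[2])) next       # skip rule
    groups[[gs]] <- c(groups[[gs]], groups[[gt]])
    groups[[gt]] <- NULL
  }
  parts <- lapply(groups, sort)
  parts[order(vapply(parts, `[`, "", 1))]
}

# Partition of a built mapper in the same canonical form.
mapper_partition <- function(mapper, entity_class = "metabolite") {
  props <- if (entity_class == "metabolite") mapper$met_props else
    mapper$reac_props
  parts <- lapply(ls(props), function(u) {
    b <- props[[u]]
    sort(unlist(lapply(names(b$member_ids), function(db)
      paste0(db, "|", b$member_ids[[db]])), use.names = FALSE))
  })
  parts[order(vapply(parts, `[`, "", 1))]
}

# Canonical reaction key: lexicographic min of the key and its reverse.
canonical_key <- function(r, theta, omit, exact = FALSE) {
  k <- reaction_key(r, exact_stoichiometry = exact,
                    translated_ids = theta, omit = omit)
  min(format(k), format(reverse_key(k)))
}

# Brute-force merged-reaction count: distinct canonical keys, where every
# template reaction counts and a later model's non-objective reaction
# counts only when its canonical key is new.
oracle_reaction_count <- function(models, mapper, exact = FALSE) {
  count <- 0L
  seen <- character()
  for (i in seq_along(models)) {
    model <- models[[i]]
    theta <- character()
    omit <- character()
    for (m in model$metabolites) {
      mid <- mergem_id(m, mapper)
      theta[m$id] <- mid
      u <- attr(mid, "universal")
      if ((!is.null(u) && u %in% mapper$proton_ids) ||
          normalize_compartment(m$compartment) == "b")
        omit <- c(omit, m$id)
    }
    obj <- names(model$objective$coefficients)
    for (r in model$reactions) {
      if (i > 1 && r$id %in% obj) next
      ck <- canonical_key(r, theta, omit, exact)
      if (i == 1) {
        count <- count + 1L
        seen <- c(seen, ck)
      } else if (!(ck %in% seen)) {
        count <- count + 1L
        seen <- c(seen, ck)
      }
    }
  }
  count
}

all_scenarios <- c("same_namespace_overlap", "cross_namespace",
                   "reversed_reaction", "nh2_nh3_conflict",
                   "proton_exchange", "objective_merge",
                   "stoichiometry_mismatch")
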