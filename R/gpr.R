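# Gene-protein-reaction (GPR) boolean strings.
#
# GPRs are stored as normalized boolean strings with explicit parentheses;
# genes are opaque tokens. A tiny recursive-descent parser turns a string
# into a nested list AST (list(op = "and"|"or", args = ...) or a gene
# character scalar), used for SBML fbc serialization and for OR-merging
# matched reactions.

gpr_tokenize <- function(s) {
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_parse <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
  toks <- gpr_tokenize(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end in '", s, "'",
                       call. = FALSE)
    if (t == "(") {
      take()
      e <- parse_or()
      if (is.na(peek()) || take() != ")")
        stop("GPR parse error: missing ')' in '", s, "'", call. = FALSE)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("GPR parse error: unexpected '", t, "' in '", s, "'",
           call. = FALSE)
    take()
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("GPR parse error: trailing tokens in '", s, "'", call. = FALSE)
  out
}

gpr_deparse <- function(ast) {
  if (is.null(ast)) return("")
  if (is.character(ast)) return(ast)
  parts <- vapply(ast$args, function(a) {
    d <- gpr_deparse(a)
    if (is.character(a)) d else paste0("(", d, ")")
  }, "")
  paste(parts, collapse = paste0(" ", ast$op, " "))
}

# Canonical string form: parsed and re-serialized, so equivalent spacing /
# case variants of the same expression compare equal as strings.
gpr_normalize <- function(s) gpr_deparse(gpr_parse(s))

gpr_genes <- function(s) {
  ast <- gpr_parse(s)
  walk <- function(a) {
    if (is.null(a)) return(character())
    if (is.character(a)) return(a)
    unlist(lapply(a$args, walk), use.names = FALSE)
  }
  unique(walk(ast))
}

# OR-combination of two GPRs, deduplicated at the disjunct level: each
# distinct rule appears once in the combined disjunction.
gpr_or_merge <- function(a, b) {
  a <- gpr_normalize(a)
  b <- gpr_normalize(b)
  if (!nzchar(a)) return(b)
  if (!nzchar(b)) return(a)
  disjuncts <- function(s) {
    ast <- gpr_parse(s)
    if (is.list(ast) && identical(ast$op, "or"))
      vapply(ast$args, gpr_deparse, "")
    else s
  }
  all_d <- unique(c(disjuncts(a), disjuncts(b)))
  if (length(all_d) == 1L) return(all_d)
  paste(paste0("(", all_d, ")"), collapse = " or ")
}
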