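# COBRA MATLAB (.mat) reader and writer.
#
# No MAT-file bindings exist for R in this stack, so this implements the
# MAT-file level-5 container directly (little-endian, uncompressed) for the
# subset needed by COBRA structs: double arrays, char arrays, cell arrays
# of strings, sparse double matrices and scalar structs. The reader also
# copes with small-data elements and UTF-8/UTF-16 char data as written by
# other COBRA tools; compressed elements are not supported.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L
MI_COMPRESSED <- 15L; MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_SPARSE <- 5L
MX_DOUBLE <- 6L; MX_INT32 <- 12L

raw_i32 <- function(x)
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
raw_f64 <- function(x)
  writeBin(as.double(x), raw(), size = 8, endian = "little")
raw_u16 <- function(x)
  writeBin(as.integer(x), raw(), size = 2, endian = "little")

pad8 <- function(r) {
  rem <- length(r) %% 8
  if (rem == 0) r else c(r, raw(8 - rem))
}

mat_elt <- function(type, payload)
  c(raw_i32(type), raw_i32(length(payload)), pad8(payload))

mat_flags <- function(class, nzmax = 0)
  mat_elt(MI_UINT32, c(raw_i32(class), raw_i32(nzmax)))

mat_dims <- function(d) mat_elt(MI_INT32, raw_i32(d))

mat_name <- function(name)
  mat_elt(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0))

mat_sparse <- function(i, j, x, nrow, ncol) {
  ord <- order(j, i)
  i <- i[ord]; j <- j[ord]; x <- x[ord]
  jc <- integer(ncol + 1)
  for (col in j) jc[col + 1L] <- jc[col + 1L] + 1L
  structure(list(ir = i - 1L, jc = cumsum(jc), pr = x,
                 dims = c(nrow, ncol)), class = "mat_sparse_array")
}

# Full miMATRIX element (tag included) for one R value.
mat_array_raw <- function(value, name = "") {
  if (inherits(value, "mat_sparse_array")) {
    nz <- max(1L, length(value$pr))
    payload <- c(mat_flags(MX_SPARSE, nz), mat_dims(value$dims),
                 mat_name(name),
                 mat_elt(MI_INT32, raw_i32(value$ir)),
                 mat_elt(MI_INT32, raw_i32(value$jc)),
                 mat_elt(MI_DOUBLE, raw_f64(value$pr)))
  } else if (is.integer(value)) {
    payload <- c(mat_flags(MX_INT32), mat_dims(c(length(value), 1L)),
                 mat_name(name), mat_elt(MI_INT32, raw_i32(value)))
  } else if (is.numeric(value)) {
    payload <- c(mat_flags(MX_DOUBLE), mat_dims(c(length(value), 1L)),
                 mat_name(name), mat_elt(MI_DOUBLE, raw_f64(value)))
  } else if (is.character(value) && length(value) == 1) {
    codes <- utf8ToInt(value)
    payload <- c(mat_flags(MX_CHAR), mat_dims(c(1L, length(codes))),
                 mat_name(name), mat_elt(MI_UINT16, raw_u16(codes)))
  } else if (is.list(value) && is.null(names(value))) {
    cells <- unlist(lapply(value, mat_array_raw))
    if (is.null(cells)) cells <- raw(0)
    payload <- c(mat_flags(MX_CELL), mat_dims(c(length(value), 1L)),
                 mat_name(name), cells)
  } else if (is.list(value)) {
    fields <- names(value)
    name_bytes <- unlist(lapply(fields, function(f) {
      b <- charToRaw(f)
      c(b, raw(32 - length(b)))
    }))
    if (is.null(name_bytes)) name_bytes <- raw(0)
    payload <- c(mat_flags(MX_STRUCT), mat_dims(c(1L, 1L)),
                 mat_name(name),
                 mat_elt(MI_INT32, raw_i32(32L)),
                 mat_elt(MI_INT8, name_bytes),
                 unlist(lapply(unname(value), mat_array_raw)))
  } else stop("unsupported MAT value of class ", class(value)[1],
              call. = FALSE)
  mat_elt(MI_MATRIX, payload)
}

write_mat5 <- function(vars, path) {
  desc <- sprintf("MATLAB 5.0 MAT-file, created by gemmerge on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  if (length(hdr) > 116) hdr <- hdr[1:116]
  hdr <- c(hdr, rep(charToRaw(" "), 116 - length(hdr)))
  hdr <- c(hdr, raw(8), raw_u16(strtoi("0100", 16L)), charToRaw("IM"))
  body <- unlist(lapply(names(vars), function(nm)
    mat_array_raw(vars[[nm]], nm)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(body, con)
  invisible(path)
}

## --- Reader -----------------------------------------------------------------

mat_cursor <- function(buf) {
  env <- new.env(parent = emptyenv())
  env$buf <- buf
  env$pos <- 1L
  env
}

cur_left <- function(cur) length(cur$buf) - cur$pos + 1L

cur_take <- function(cur, n) {
  out <- cur$buf[seq.int(cur$pos, length.out = n)]
  cur$pos <- cur$pos + n
  out
}

cur_int <- function(cur, size, n = 1L, signed = TRUE) {
  readBin(cur_take(cur, size * n), "integer", n = n, size = size,
          endian = "little", signed = signed)
}

# Reads one data element: list(type, data raw). Handles small data elements.
read_element <- function(cur) {
  head <- cur_take(cur, 4L)
  words <- readBin(head, "integer", n = 2, size = 2, endian = "little",
                   signed = FALSE)
  if (words[2] != 0) {                 # small data element
    type <- words[1]
    size <- words[2]
    data <- cur_take(cur, 4L)[seq_len(size)]
    return(list(type = type, data = data))
  }
  type <- readBin(head, "integer", n = 1, size = 4, endian = "little")
  size <- cur_int(cur, 4L)
  data <- if (size > 0) cur_take(cur, size) else raw(0)
  pad <- (8 - size %% 8) %% 8
  if (pad > 0 && cur_left(cur) >= pad) cur_take(cur, pad)
  list(type = type, data = data)
}

numeric_payload <- function(elt) {
  d <- elt$data
  switch(as.character(elt$type),
         "9" = readBin(d, "double", n = length(d) / 8, size = 8,
                       endian = "little"),
         "7" = readBin(d, "double", n = length(d) / 4, size = 4,
                       endian = "little"),
         "5" = readBin(d, "integer", n = length(d) / 4, size = 4,
                       endian = "little"),
         "6" = readBin(d, "integer", n = length(d) / 4, size = 4,
                       endian = "little"),
         "3" = readBin(d, "integer", n = length(d) / 2, size = 2,
                       endian = "little"),
         "4" = readBin(d, "integer", n = length(d) / 2, size = 2,
                       endian = "little", signed = FALSE),
         "1" = readBin(d, "integer", n = length(d), size = 1,
                       endian = "little"),
         "2" = readBin(d, "integer", n = length(d), size = 1,
                       endian = "little", signed = FALSE),
         "12" = , "13" = {
           # 64-bit integers, exact up to 2^53
           w <- readBin(d, "integer", n = length(d) / 4, size = 4,
                        endian = "little")
           lo <- w[seq(1, length(w), by = 2)]
           hi <- w[seq(2, length(w), by = 2)]
           lo <- ifelse(lo < 0, lo + 2^32, lo)
           hi * 2^32 + lo
         },
         stop("unsupported MAT numeric element type ", elt$type,
              call. = FALSE))
}

char_payload <- function(elt) {
  d <- elt$data
  if (length(d) == 0) return("")
  switch(as.character(elt$type),
         "16" = rawToChar(d),                               # miUTF8
         "4" = , "17" = intToUtf8(readBin(d, "integer", n = length(d) / 2,
                                          size = 2, endian = "little",
                                          signed = FALSE)),
         "1" = , "2" = rawToChar(d),
         stop("unsupported MAT char element type ", elt$type,
              call. = FALSE))
}

parse_matrix <- function(data) {
  cur <- mat_cursor(data)
  flags <- read_element(cur)
  fw <- readBin(flags$data, "integer", n = 2, size = 4, endian = "little")
  class <- bitwAnd(fw[1], 255L)
  nzmax <- fw[2]
  dims_elt <- read_element(cur)
  dims <- readBin(dims_elt$data, "integer",
                  n = length(dims_elt$data) / 4, size = 4,
                  endian = "little")
  name_elt <- read_element(cur)
  name <- if (length(name_elt$data)) rawToChar(name_elt$data) else ""
  value <-
    if (class == MX_CHAR) {
      char_payload(read_element(cur))
    } else if (class == MX_CELL) {
      n <- prod(dims)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        sub <- read_element(cur)
        out[[i]] <- parse_matrix(sub$data)$value
      }
      out
    } else if (class == MX_STRUCT) {
      flen <- numeric_payload(read_element(cur))
      fnames_elt <- read_element(cur)
      nfields <- length(fnames_elt$data) %/% flen
      fields <- vapply(seq_len(nfields), function(i) {
        b <- fnames_elt$data[seq.int((i - 1) * flen + 1,
                                     length.out = flen)]
        rawToChar(b[b != as.raw(0)])
      }, "")
      out <- vector("list", nfields)
      names(out) <- fields
      for (i in seq_len(nfields)) {
        sub <- read_element(cur)
        out[[i]] <- parse_matrix(sub$data)$value
      }
      out
    } else if (class == MX_SPARSE) {
      ir <- numeric_payload(read_element(cur))
      jc <- numeric_payload(read_element(cur))
      pr <- numeric_payload(read_element(cur))
      n <- min(length(ir), length(pr), nzmax)
      structure(list(ir = as.integer(ir[seq_len(n)]), jc = as.integer(jc),
                     pr = as.numeric(pr[seq_len(n)]), dims = dims),
                class = "mat_sparse_array")
    } else {
      # numeric classes (double and all integer widths)
      numeric_payload(read_element(cur))
    }
  list(name = name, value = value)
}

read_mat5 <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 128)
    stop("not a MAT-file (too short): ", path, call. = FALSE)
  endian <- rawToChar(buf[127:128])
  if (endian == "MI")
    stop("big-endian MAT-files are not supported: ", path, call. = FALSE)
  if (endian != "IM")
    stop("not a MAT-file level 5: ", path, call. = FALSE)
  cur <- mat_cursor(buf)
  cur$pos <- 129L
  vars <- list()
  while (cur_left(cur) >= 8) {
    elt <- read_element(cur)
    if (elt$type == MI_COMPRESSED) {
      data <- tryCatch(memDecompress(elt$data, type = "gzip"),
                       error = function(e)
                         stop("compressed MAT element could not be ",
                              "decompressed: ", path, call. = FALSE))
      sub <- read_element(mat_cursor(data))
      parsed <- parse_matrix(sub$data)
    } else if (elt$type == MI_MATRIX) {
      parsed <- parse_matrix(elt$data)
    } else next
    nm <- if (nzchar(parsed$name)) parsed$name else
      paste0("var", length(vars) + 1L)
    vars[[nm]] <- parsed$value
  }
  vars
}

## --- COBRA struct conversion ------------------------------------------------

annotations_to_tokens <- function(ann) {
  if (length(ann) == 0) return("")
  paste(unlist(lapply(names(ann), function(reg)
    paste0(reg, "=", ann[[reg]]))), collapse = ";")
}

tokens_to_annotations <- function(s) {
  out <- list()
  if (is.null(s) || !nzchar(s)) return(out)
  for (tok in strsplit(s, ";", fixed = TRUE)[[1]]) {
    reg <- sub("=.*$", "", tok)
    id <- sub("^[^=]*=", "", tok)
    if (nzchar(reg) && nzchar(id)) out[[reg]] <- c(out[[reg]], id)
  }
  out
}

str_or_empty <- function(x) if (is.na(x)) "" else x

model_to_cobra_struct <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  met_ids <- names(mets)
  i <- integer(); j <- integer(); x <- numeric()
  for (col in seq_along(rxns)) {
    p <- rxns[[col]]$participants
    rows <- match(names(p), met_ids)
    i <- c(i, rows); j <- c(j, rep(col, length(p))); x <- c(x, unname(p))
  }
  obj <- model$objective$coefficients
  cvec <- vapply(names(rxns), function(rid)
    if (!is.na(obj[rid])) unname(obj[rid]) else 0, 0)
  comps <- model$compartments
  codes <- unique(vapply(mets, `[[`, "", "compartment"))
  for (code in setdiff(codes, names(comps))) comps[code] <- code
  list(
    description = model$id,
    mets = unname(lapply(mets, `[[`, "id")),
    metNames = unname(lapply(mets, function(m) str_or_empty(m$name))),
    metFormulas = unname(lapply(mets, function(m)
      str_or_empty(m$formula))),
    metCharges = unname(vapply(mets, function(m)
      if (is.na(m$charge)) NaN else as.numeric(m$charge), 0)),
    metComps = as.integer(match(vapply(mets, `[[`, "", "compartment"),
                                names(comps))),
    metMiriam = unname(lapply(mets, function(m)
      annotations_to_tokens(m$annotations))),
    comps = as.list(names(comps)),
    compNames = as.list(unname(comps)),
    rxns = unname(lapply(rxns, `[[`, "id")),
    rxnNames = unname(lapply(rxns, function(r) str_or_empty(r$name))),
    grRules = unname(lapply(rxns, `[[`, "gpr")),
    rxnMiriam = unname(lapply(rxns, function(r)
      annotations_to_tokens(r$annotations))),
    S = mat_sparse(i, j, x, length(mets), length(rxns)),
    lb = unname(vapply(rxns, `[[`, 0, "lower_bound")),
    ub = unname(vapply(rxns, `[[`, 0, "upper_bound")),
    c = unname(cvec),
    b = rep(0, length(mets)),
    osenseStr = model$objective$direction,
        genes = lapply(model_genes(model), identity)
  )
}

cobra_cell <- function(s, field, n) {
  v <- s[[field]]
  if (is.null(v)) return(rep("", n))
  out <- vapply(v, function(x)
    if (is.character(x) && length(x) == 1) x else "", "")
  length(out) <- n
  out[is.na(out)] <- ""
  out
}

met_compartment_from_id <- function(id) {
  m <- regmatches(id, regexec("\\[([A-Za-z][0-9]?)\\]$", id))[[1]]
  if (length(m) == 2) return(m[2])
  m <- regmatches(id, regexec("_([a-z][0-9]?)$", id))[[1]]
  if (length(m) == 2) return(m[2])
  "c"
}

participants_from_S <- function(S, col, met_ids) {
  if (inherits(S, "mat_sparse_array")) {
    from <- S$jc[col] + 1L
    to <- S$jc[col + 1L]
    if (to < from) return(numeric(0))
    idx <- seq.int(from, to)
    stats::setNames(S$pr[idx], met_ids[S$ir[idx] + 1L])
  } else {
    m <- matrix(S, nrow = length(met_ids))
    v <- m[, col]
    stats::setNames(v[v != 0], met_ids[v != 0])
  }
}

cobra_struct_to_model <- function(s, id = "model") {
  if (is.null(s$mets) || is.null(s$rxns) || is.null(s$S))
    stop("MAT struct lacks COBRA fields mets/rxns/S", call. = FALSE)
  met_ids <- vapply(s$mets, as.character, "")
  rxn_ids <- vapply(s$rxns, as.character, "")
  nm <- length(met_ids); nr <- length(rxn_ids)
  met_names <- cobra_cell(s, "metNames", nm)
  met_formulas <- cobra_cell(s, "metFormulas", nm)
  comp_codes <- if (!is.null(s$comps)) cobra_cell(s, "comps",
                                                  length(s$comps))
    else character()
  met_comps <- if (!is.null(s$metComps) && is.numeric(s$metComps) &&
                   length(comp_codes)) {
    idx <- as.integer(s$metComps)
    ifelse(idx >= 1 & idx <= length(comp_codes), comp_codes[idx], "c")
  } else vapply(met_ids, met_compartment_from_id, "")
  met_miriam <- cobra_cell(s, "metMiriam", nm)
  charges <- if (!is.null(s$metCharges)) as.numeric(s$metCharges) else
    rep(NaN, nm)
  mets <- lapply(seq_len(nm), function(k) {
    gem_metabolite(met_ids[k],
                   name = if (nzchar(met_names[k])) met_names[k] else
                     NA_character_,
                   compartment = met_comps[k],
                   formula = if (nzchar(met_formulas[k])) met_formulas[k]
                     else NA_character_,
                   charge = if (is.nan(charges[k])) NA_integer_ else
                     as.integer(charges[k]),
                   annotations = tokens_to_annotations(met_miriam[k]))
  })
  lb <- if (!is.null(s$lb)) as.numeric(s$lb) else rep(-1000, nr)
  ub <- if (!is.null(s$ub)) as.numeric(s$ub) else rep(1000, nr)
  grs <- cobra_cell(s, "grRules", nr)
  rxn_names <- cobra_cell(s, "rxnNames", nr)
  rxn_miriam <- cobra_cell(s, "rxnMiriam", nr)
  rxns <- lapply(seq_len(nr), function(k) {
    gem_reaction(rxn_ids[k],
                 participants = participants_from_S(s$S, k, met_ids),
                 name = if (nzchar(rxn_names[k])) rxn_names[k] else
                   NA_character_,
                 lower_bound = lb[k], upper_bound = ub[k],
                 gpr = grs[k],
                 annotations = tokens_to_annotations(rxn_miriam[k]))
  })
  obj <- numeric()
  if (!is.null(s$c)) {
    cv <- as.numeric(s$c)
    for (k in which(cv != 0)) obj[rxn_ids[k]] <- cv[k]
  }
  comps <- character()
  if (!is.null(s$comps)) {
    codes <- cobra_cell(s, "comps", length(s$comps))
    nms <- cobra_cell(s, "compNames", length(s$comps))
    for (k in seq_along(codes))
      if (nzchar(codes[k]))
        comps[codes[k]] <- if (nzchar(nms[k])) nms[k] else codes[k]
  }
  direction <- if (!is.null(s$osenseStr) &&
                   identical(as.character(s$osenseStr), "min")) "min"
    else "max"
  mid <- if (!is.null(s$description) && nzchar(as.character(s$description)))
    as.character(s$description) else id
  gem_model(mid, metabolites = mets, reactions = rxns,
            objective = list(coefficients = obj, direction = direction),
            compartments = comps)
}

write_cobra_mat <- function(model, path) {
  var <- gsub("[^A-Za-z0-9_]", "_", model$id)
  if (!grepl("^[A-Za-z]", var)) var <- paste0("m_", var)
  vars <- stats::setNames(list(model_to_cobra_struct(model)), var)
  write_mat5(vars, path)
}

read_cobra_mat <- function(path) {
  vars <- read_mat5(path)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (is.list(v) && !is.null(names(v)) && "S" %in% names(v))
      return(cobra_struct_to_model(v, id = nm))
  }
  stop("no COBRA model struct found in MAT-file: ", path, call. = FALSE)
}
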