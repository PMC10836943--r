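#' Read a genome-scale metabolic model
#'
#' Reads a GEM from SBML (Level 3, FBC v2), COBRA JSON or COBRA MATLAB
#' format into a [gem_model()]. Annotations are captured as
#' registry-to-identifier lists (identifiers.org prefixes), the objective
#' from the FBC objective or the COBRA objective coefficients.
#'
#' @param path file path.
#' @param format `"sbml"`, `"json"` or `"mat"`; inferred from the file
#'   extension when omitted (`.xml`/`.sbml`, `.json`, `.mat`).
#' @return a `gem_model`.
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path))
    stop("model file does not exist: ", path, call. = FALSE)
  format <- resolve_format(path, format)
  switch(format,
         sbml = read_sbml(path),
         json = read_cobra_json(path),
         mat = read_cobra_mat(path))
}

#' Write a genome-scale metabolic model
#'
#' Writes a [gem_model()] to SBML, COBRA JSON or COBRA MATLAB format.
#' `read_model(write_model(m, path))` preserves ids, stoichiometries,
#' bounds, GPR strings, annotations and the objective. Writing is atomic:
#' the file is assembled in a temporary sibling and renamed into place.
#'
#' @param model a `gem_model`.
#' @inheritParams read_model
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "gem_model"))
  validate_gem_model(model)
  format <- resolve_format(path, format)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(unlink(tmp), add = TRUE)
  switch(format,
         sbml = write_sbml(model, tmp),
         json = write_cobra_json(model, tmp),
         mat = write_cobra_mat(model, tmp))
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (!is.null(format))
    return(match.arg(tolower(format), c("sbml", "json", "mat")))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xml = , sbml = "sbml",
         json = "json",
         mat = "mat",
         stop("cannot infer model format from extension '", ext,
              "'; pass format = \"sbml\", \"json\" or \"mat\"",
              call. = FALSE))
}
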