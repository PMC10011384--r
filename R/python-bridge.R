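#' @keywords internal
"_PACKAGE"

# Bridge to the packaged RDKit helper. One subprocess call handles a whole
# batch of molecules; RDKit import dominates the cost, so callers should
# batch aggressively.

molprep_script <- function() {
  path <- system.file("python", "molprep.py", package = "hbhydro")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is not yet installed flat
    path <- system.file("inst", "python", "molprep.py", package = "hbhydro")
  }
  path
}

#' Locate the Python interpreter used for molecule preparation
#'
#' The interpreter is taken from option `hbhydro.python`, then the
#' `HBHYDRO_PYTHON` environment variable, then `python` on `PATH`. It must
#' have RDKit importable.
#'
#' @return Path to the interpreter.
#' @export
find_python <- function() {
  cand <- getOption("hbhydro.python", "")
  if (!nzchar(cand)) cand <- Sys.getenv("HBHYDRO_PYTHON", "")
  if (!nzchar(cand)) cand <- Sys.which("python")
  if (!nzchar(cand)) {
    stop("configuration error: no Python interpreter found; set ",
         "options(hbhydro.python=) or HBHYDRO_PYTHON", call. = FALSE)
  }
  unname(cand)
}

# Run the helper on a list of molecule entries. Returns the parsed response
# list, one element per input entry, order preserved.
run_molprep <- function(entries, seed = 1L, embed = TRUE, minimise = TRUE,
                        preserve = FALSE, layout2d = FALSE) {
  stopifnot(length(entries) >= 1)
  req <- list(molecules = entries, seed = as.integer(seed), embed = embed,
              minimise = minimise, preserve = preserve, layout2d = layout2d)
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- suppressWarnings(
    system2(find_python(), shQuote(molprep_script()),
            stdout = TRUE, stderr = TRUE, stdin = infile)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("molecule preparation helper failed (is RDKit installed for ",
         find_python(), "?):\n", paste(out, collapse = "\n"), call. = FALSE)
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE),
    error = function(e) stop("unparseable helper output: ",
                             conditionMessage(e), call. = FALSE))
  parsed$molecules
}
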