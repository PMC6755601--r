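#' Locate the Python interpreter used for SMILES handling
#'
#' Substructure enumeration, canonicalization and ring perception are
#' delegated to RDKit through an external Python process. The interpreter is
#' resolved, in order, from the option `minhashfp.python`, the environment
#' variable `MINHASHFP_PYTHON`, and `python` on the PATH.
#'
#' @return Path to the Python executable.
#' @export
find_python <- function() {
  py <- getOption("minhashfp.python", "")
  if (!nzchar(py)) py <- Sys.getenv("MINHASHFP_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("No Python interpreter found; set option 'minhashfp.python' or ",
         "the MINHASFP_PYTHON environment variable.", call. = FALSE)
  }
  unname(py)
}

helper_script <- function() {
  path <- system.file("python", "shingling.py", package = "minhashfp")
  if (!nzchar(path)) stop("bundled shingling helper not found", call. = FALSE)
  path
}

# One batched round trip to the RDKit helper: request in, parsed JSON out.
run_chem_helper <- function(request) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  errfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA)
  status <- suppressWarnings(system2(
    find_python(), shQuote(helper_script()),
    stdin = infile, stdout = outfile, stderr = errfile
  ))
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(errfile, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("chemistry helper failed (exit ", status, "): ", msg, call. = FALSE)
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}
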