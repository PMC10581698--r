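# Bridge to the msprime/tskit coalescent simulation backend.
#
# The genealogy sampler is delegated to msprime (run as a subprocess through
# the bundled inst/python/coalsim.py driver); this package owns simulation
# configuration, site ascertainment, error injection and label handling.
# Data is exchanged as JSON in the session temporary directory.

backend_python <- function() {
  p <- Sys.getenv("TMRCANET_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p))
    stop_tmrcanet("no python interpreter found on PATH (needed for the msprime simulation backend)",
                  "tmrcanet_backend_error")
  p
}

backend_script <- function() {
  s <- system.file("python", "coalsim.py", package = "tmrcanet")
  if (!nzchar(s))
    stop_tmrcanet("bundled coalsim.py not found; is the package installed?",
                  "tmrcanet_backend_error")
  s
}

run_backend <- function(cfg) {
  infile <- tempfile("coalsim_cfg_", fileext = ".json")
  outfile <- tempfile("coalsim_out_", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(cfg, infile, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  res <- suppressWarnings(system2(backend_python(),
                                  c(backend_script(), infile, outfile),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(outfile))
    stop_tmrcanet(paste0("simulation backend failed:\n",
                         paste(res, collapse = "\n")),
                  "tmrcanet_backend_error")
  jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
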