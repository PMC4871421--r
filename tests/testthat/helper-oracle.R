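# Bridge to the statsmodels oracle (oracle_var.py). One python process can
# serve many tasks; inputs go through CSV, results come back as JSON.

oracle_available <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", "import statsmodels"), stdout = FALSE,
            stderr = FALSE) == 0
}

# tasks: list of lists with fields id, kind ("var"/"adf"), data (matrix or
# vector), and kind-specific parameters (k, H, variant, max_lags).
run_oracle <- function(tasks) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  spec <- list(tasks = lapply(tasks, function(t) {
    csv <- file.path(dir, paste0(t$id, ".csv"))
    utils::write.csv(as.data.frame(t$data), csv, row.names = FALSE)
    c(list(csv = csv), t[setdiff(names(t), "data")])
  }))
  spec_path <- file.path(dir, "spec.json")
  out_path <- file.path(dir, "out.json")
  jsonlite::write_json(spec, spec_path, auto_unbox = TRUE, digits = NA)
  status <- system2("python",
                    c(testthat::test_path("oracle_var.py"), spec_path, out_path),
                    stdout = FALSE, stderr = "")
  if (status != 0) stop("statsmodels oracle call failed")
  jsonlite::read_json(out_path, simplifyVector = TRUE)
}

# Convert statsmodels (H+1) x K x K nested list-array into R's array layout.
oracle_array <- function(a) {
  a <- as.array(a)
  stopifnot(length(dim(a)) == 3L)
  a
}
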