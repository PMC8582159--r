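# One default-phantom pipeline run (the package's reference conditions),
# computed once per test session and shared by the tests that inspect it.
default_run_dir <- function() {
  dir <- file.path(tempdir(), "abclust-default-run")
  marker <- file.path(dir, "provenance.json")
  if (!file.exists(marker))
    run_pipeline(list(out_dir = dir, seed = 42L, log_level = "quiet"))
  dir
}

default_run_features <- function() {
  utils::read.table(file.path(default_run_dir(), "features.tsv"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

default_run_phantom <- function() file.path(default_run_dir(), "phantom")
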