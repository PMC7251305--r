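# Shared setup for the numbered analysis scripts: seed parsing and the
# results directory layout. Every script can be run standalone, in
# order, from the repository root:
#   Rscript analysis/01_simulate.R [--seed 1]
suppressMessages(library(symdyad))

parse_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- match("--seed", args)
  if (!is.na(i)) as.integer(args[i + 1L]) else default
}

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

read_cohort_series <- function(dir = file.path("results", "cohort")) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                                  simplifyVector = TRUE)
  lapply(seq_along(manifest$subjects), function(s) {
    list(subject_id = manifest$subjects[s], outcome = manifest$outcomes[s],
         series = load_block_series(
           file.path(dir, paste0("series_", manifest$subjects[s], ".csv"))))
  })
}
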