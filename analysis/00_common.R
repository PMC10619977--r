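# Shared setup for the numbered analysis scripts: load the package, fix the
# master seed, and point all outputs at results/. Each script sources this
# file first and can be run on its own from the repository root:
#
#   Rscript analysis/01_simulate_ensembles.R
#
# Scripts 02 and 03 consume artifacts written by 01; everything else is
# self-contained. All randomness flows from MASTER_SEED via derive_seed().

suppressPackageStartupMessages(library(allokit))

MASTER_SEED <- 1
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

res_path <- function(...) file.path(RESULTS_DIR, ...)

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
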