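# Shared option parsing for the numbered analysis drivers. Each driver is
# run as e.g.
#   Rscript analysis/01_simulate.R --seed 1 --dir results/run
# and operates on the installed package only (no sourcing of R/).

suppressPackageStartupMessages(library(froglight))

parse_opts <- function(args = commandArgs(trailingOnly = TRUE)) {
  get <- function(flag, default) {
    i <- match(flag, args)
    if (is.na(i) || i == length(args)) default else args[i + 1]
  }
  list(seed = as.integer(get("--seed", "1")),
       dir = get("--dir", "results/run"),
       n_draws = as.integer(get("--draws", "1000")))
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}
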