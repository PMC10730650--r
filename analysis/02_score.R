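#!/usr/bin/env Rscript
# Stage 2: score colour observations to species lightness and fit the
# inter-observer calibration.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
opts <- parse_opts()

world <- read_world(file.path(opts$dir, "world"))
scored <- score_world(world)
write_table(scored$species_colour, file.path(opts$dir, "species_colour.csv"))
cal <- scored$calibration
write_json(list(slope = cal$slope, intercept = cal$intercept,
                se_slope = cal$se_slope, r_squared = cal$r_squared,
                n = cal$n),
           file.path(opts$dir, "calibration_fit.json"))
cat(sprintf("scored %d species; calibration slope %.3f (R2 %.3f, n %d)\n",
            nrow(scored$species_colour), cal$slope, cal$r_squared, cal$n))
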