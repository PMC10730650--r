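#!/usr/bin/env Rscript
# Stage 5: standardised effect sizes of colour-lightness mean pairwise
# distance against realm-pool null models.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
opts <- parse_opts()

world <- read_world(file.path(opts$dir, "world"))
traits <- read.csv(file.path(opts$dir, "decomposition.csv"))
asm <- assemble_world(world, traits)
ses <- diversity_world(world, traits, asm, n_draws = opts$n_draws,
                       seed = opts$seed)
write_table(ses, file.path(opts$dir, "ses.csv"))
cat(sprintf("SES for %d assemblages: mean %.3f, sd %.3f\n",
            nrow(ses), mean(ses$ses, na.rm = TRUE),
            sd(ses$ses, na.rm = TRUE)))
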