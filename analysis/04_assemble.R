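#!/usr/bin/env Rscript
# Stage 4: apply the water and coverage filters, build assemblage trait
# summaries and species-level range environments.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
opts <- parse_opts()

world <- read_world(file.path(opts$dir, "world"))
traits <- read.csv(file.path(opts$dir, "decomposition.csv"))
asm <- assemble_world(world, traits)
write_table(asm$summaries, file.path(opts$dir, "assemblage_summaries.csv"))
write_table(asm$species_env, file.path(opts$dir, "species_environment.csv"))
cat(sprintf("%d of %d assemblages included (%d water cells excluded)\n",
            sum(asm$summaries$included), nrow(asm$summaries),
            sum(!asm$cells$included)))
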