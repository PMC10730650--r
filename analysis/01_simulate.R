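#!/usr/bin/env Rscript
# Stage 1: simulate the default synthetic world and write the input bundle.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
opts <- parse_opts()

config <- world_config(seed = opts$seed)
dir.create(opts$dir, recursive = TRUE, showWarnings = FALSE)
write_json(unclass(config), file.path(opts$dir, "config.json"))
world <- simulate_world(config)
write_world(world, file.path(opts$dir, "world"))
cat(sprintf("world: %d cells (%d land), %d ranged species, %d observed\n",
            world$manifest$n_cells, world$manifest$n_cells_land,
            world$manifest$n_species_ranged,
            world$manifest$n_species_observed))
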