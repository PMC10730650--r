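#!/usr/bin/env Rscript
# Stage 3: graft colour-scored species missing from the tree, fit Pagel's
# lambda and the phylogenetic mixed-model decomposition (P and S).

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
opts <- parse_opts()

world <- read_world(file.path(opts$dir, "world"))
species_colour <- read.csv(file.path(opts$dir, "species_colour.csv"))
dec <- decompose_world(world, species_colour,
                       graft_seed = froglight:::stage_seed(opts$seed, 5L))
write_table(dec$traits, file.path(opts$dir, "decomposition.csv"))
write_json(list(lambda_colour = dec$lambda$lambda,
                mu = dec$lynch$mu,
                sigma2_phylo = dec$lynch$sigma2_phylo,
                sigma2_resid = dec$lynch$sigma2_resid,
                iterations = dec$lynch$iterations,
                converged = dec$lynch$converged),
           file.path(opts$dir, "decomposition_info.json"))
cat(sprintf("lambda = %.3f; sigma2 P/S = %.1f/%.1f over %d species\n",
            dec$lambda$lambda, dec$lynch$sigma2_phylo,
            dec$lynch$sigma2_resid, dec$lynch$n))
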