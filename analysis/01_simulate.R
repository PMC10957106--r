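#!/usr/bin/env Rscript
# Stage 1: synthetic study system. Simulates a dated birth-death phylogeny,
# Brownian precipitation niches (MAP, mm/yr), a two-state Mk history, a
# longitudinal precipitation landscape with monthly layers, and occurrence
# records drawn around each species' niche optimum.
source("analysis/00_config.R")

dat <- simulate_dataset(CFG)
ape::write.tree(dat$tree, file.path(RESULTS, "tree.nwk"))
write.csv(dat$landscape$occurrences, file.path(RESULTS, "occurrences.csv"),
          row.names = FALSE)
cells <- dat$landscape$cells
cells$dsl <- apply(dat$landscape$monthly, 1, dry_season_length)
write.csv(cells, file.path(RESULTS, "cells_climate.csv"), row.names = FALSE)
ex <- CFG$landscape_extent
ncol_g <- length(unique(cells$lon)); nrow_g <- length(unique(cells$lat))
m <- matrix(cells$map, nrow_g, ncol_g, byrow = TRUE)[nrow_g:1, ]
write_ascii_grid(m, file.path(RESULTS, "map_grid.asc"),
                 xll = ex[1], yll = ex[3], cellsize = 0.5)
write.csv(data.frame(taxon = names(dat$tip_states_mk),
                     state = dat$tip_states_mk),
          file.path(RESULTS, "tip_states_mk.csv"), row.names = FALSE)
true_states <- data.frame(node = seq_along(dat$states),
                          value = unname(dat$states))
write.csv(true_states, file.path(RESULTS, "true_node_states.csv"),
          row.names = FALSE)
cat("simulated", ape::Ntip(dat$tree), "species,",
    nrow(dat$landscape$occurrences), "occurrences over",
    nrow(cells), "cells\n")
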