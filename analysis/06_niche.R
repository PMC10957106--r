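#!/usr/bin/env Rscript
# Stage 6: precipitation-niche evolution. Phylogenetic signal (Pagel's
# lambda) of MAP and DSL, ML ancestral states, niche-shift detection under
# the 1200/1800-mm categories with the 250-mm minimum change, and per-5-Ma
# shift fractions.
source("analysis/00_config.R")

tree <- ape::read.tree(file.path(RESULTS, "tree.nwk"))
occ <- read.csv(file.path(RESULTS, "occurrences.csv"))
cells <- read.csv(file.path(RESULTS, "cells_climate.csv"))
clim <- data.frame(lon = cells$lon, lat = cells$lat, MAP = cells$map,
                   DSL = cells$dsl)
med <- species_climate_summary(occ, clim)
map_vals <- setNames(med$MAP, med$taxon)[tree$tip.label]
dsl_vals <- setNames(med$DSL, med$taxon)[tree$tip.label]

ps_map <- pagels_lambda(tree, map_vals)
ps_dsl <- pagels_lambda(tree, dsl_vals)
cat(sprintf("Pagel's lambda: MAP %.3f (p = %.2g), DSL %.3f (p = %.2g)\n",
            ps_map$lambda_hat, ps_map$p_value,
            ps_dsl$lambda_hat, ps_dsl$p_value))

asr <- ancestral_states_bm(tree, map_vals)
write.csv(asr, file.path(RESULTS, "ancestral_map.csv"), row.names = FALSE)
shifts <- detect_niche_shifts(tree, asr$estimate, niche_category_spec("MAP"))
write.csv(shifts, file.path(RESULTS, "niche_shifts.csv"), row.names = FALSE)
bins <- shifts_per_time_bin(shifts, tree, bin_width = 5)
write.csv(bins, file.path(RESULTS, "shift_bins.csv"), row.names = FALSE)
cat(nrow(shifts), "niche shifts;",
    sum(bins$n_splits), "splits across", nrow(bins), "bins\n")
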