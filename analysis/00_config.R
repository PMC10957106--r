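# Shared settings for the analysis scripts. Everything downstream derives
# from this seed, so the whole workflow is reproducible end to end.
library(phyloturn)
SEED <- 20260921L
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)
CFG <- sim_config(n_tips = 80, trait_sigma2 = 5e3, root_state = 1800,
                  spatial_noise_deg = 0.2, seed = SEED)
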