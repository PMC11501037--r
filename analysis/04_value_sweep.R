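#!/usr/bin/env Rscript
# Model-based prediction I: simulate each profile's fitted agents while
# the reward difference between sides (delta-V) varies over
# {-1, 0, 1, 2, 3} (one side fixed at value 1), and run the attribution
# study that asks which latent variable carries the between-profile
# descriptor differences.

library(forageRL)

seed <- 20240601L
fits <- read.csv("results/fits.csv")
comp <- read.csv("results/composition.csv")
cf <- merge(fits[, c("mouse_id", "alpha", "beta", "chi")],
            comp[, c("mouse_id", "nearest")], by = "mouse_id")
names(cf)[names(cf) == "nearest"] <- "label"

sw <- delta_v_sweep(split(cf, cf$label), dv_grid = c(-1, 0, 1, 2, 3),
                    n_replicates = 100, seed = derive_seed(seed, 4))
write.csv(sw$summary, "results/sweep_summary.csv", row.names = FALSE)

pref <- sw$summary[sw$summary$descriptor == "pref", ]
cat("Mean preference for the varying-value side by group and delta-V:\n")
print(reshape(pref[, c("group", "dv", "mean")], idvar = "group",
              timevar = "dv", direction = "wide"), row.names = FALSE)
cat("\n(Trackers follow value; Explorers respond weakly; Non-Switchers\n")
cat("stay near 0.5 in preference but entrench on one side instead.)\n\n")

modes <- c("own", "shuffle_alpha", "shuffle_beta", "shuffle_chi",
           "random_triplet")
rows <- lapply(modes, function(md) {
  res <- attribution_study(cf, md, seed = derive_seed(seed, 5))
  data.frame(mode = md, separation = descriptor_separation(res$per_animal))
})
attr_tab <- do.call(rbind, rows)
attr_tab$vs_own <- attr_tab$separation / attr_tab$separation[1]
write.csv(attr_tab, "results/attribution.csv", row.names = FALSE)
cat("Between-archetype descriptor separation by attribution mode:\n")
print(attr_tab, row.names = FALSE)
cat("\nWrote results/sweep_summary.csv, attribution.csv\n")
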