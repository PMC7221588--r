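#!/usr/bin/env Rscript
# Operating characteristics of the BDM branch test, measured by simulation:
# the null P distribution (is the nominal 0.05 level honest?) and the power
# curve over the radical-replacement tilt beta. Radical/conservative
# contrasts are approximate by construction, so the null rejection rate is
# reported as a measurement, not asserted to equal the nominal level.

library(bdmshift)

tr <- shifted_family_tree()
cfg <- sim_config(phy = tr, L = 450L, seed = 1)

nc <- null_calibration(cfg, replicates = 100L, seed = 1)
cat(sprintf("null (beta = 0): %d replicates; fraction P < 0.05 = %.3f; P < 0.01 = %.3f\n",
            length(nc$p_values), nc$frac_below_05, nc$frac_below_01))
write.table(data.frame(replicate = seq_along(nc$p_values), P = nc$p_values),
            "results/null_p_values.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

pc <- power_curve(cfg, beta_grid = c(0, 3, 10), replicates = 100L, seed = 1)
print(pc)
write.table(pc, "results/power_curve.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("median P should fall and the rejection fraction rise as beta grows\n")
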