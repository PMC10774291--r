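#!/usr/bin/env Rscript
# Stage 2: classify per-snapshot suitability for dense shelf water transport.
#
# Three conditions on the shelf region (wet cells shallower than 200 m):
# negative cross-shore bottom density gradient, region-mean potential energy
# anomaly above 5 J/m^3, and gravitational stratification beating wind
# mixing unless the wind is onshore (225-315 deg). Writes the per-snapshot
# series and the monthly suitability percentages.

library(kelpDSWT)

fields <- load_fields("results/scenario.nc")
states <- classify_dswt(fields)
monthly <- monthly_suitability(states)

out <- states
out$time <- format(out$time)
write.csv(out, "results/dswt_series.csv", row.names = FALSE)
write.csv(monthly, "results/monthly_suitability.csv", row.names = FALSE)

cat(sprintf("suitable %.1f%% of %d snapshots overall\n",
            100 * mean(states$suitable), nrow(states)))
print(monthly)
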