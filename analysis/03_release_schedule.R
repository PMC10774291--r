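#!/usr/bin/env Rscript
# Stage 3: turn the kelp probability map and the seasonal detrital
# production curve into a daily particle-release schedule.
#
# Daily counts apportion a 10,000-particle budget by largest remainder over
# the production-weighted days of 2017 (elevated March-August, peaking
# March-May); positions are drawn probability-proportionally from the kelp
# raster, uniform within each chosen cell.

library(kelpDSWT)

fields <- load_fields("results/scenario.nc")
kelp <- attr(fields, "kelp_prob")

schedule <- build_schedule(kelp, fields$grid, total = 10000,
                           year = 2017, seed = 2L)
print(schedule)

write.csv(schedule$days, "results/schedule_days.csv", row.names = FALSE)
write.csv(schedule$positions, "results/release_positions.csv", row.names = FALSE)

monthly <- tapply(schedule$days$count, format(schedule$days$date, "%m"), sum)
cat("releases per month:\n"); print(monthly)
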