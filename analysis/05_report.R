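#!/usr/bin/env Rscript
# Condense the evaluation into the headline contrasts: dynamic vs static
# (LSTM vs RF), temporal order (LSTM vs LSTM_perm), and vegetation
# interannual information (LSTM vs LSTM_msc / LSTM_annual), plus the
# site-centered residual seasonal curves per forest type.
#
# Usage: Rscript analysis/05_report.R

library(fluxmem)

ds <- read_dataset("results/dataset")
ev <- read.csv("results/evaluation.csv")

sc <- ev[ev$stratum_type == "all" & ev$metric == "nse", ]
wide <- reshape(sc[, c("setup", "scale", "member_mean")],
                idvar = "setup", timevar = "scale", direction = "wide")
names(wide) <- sub("member_mean.", "", names(wide))
wide <- wide[order(-wide$seasonal_cycle), ]
cat("NSE by set-up and scale (ensemble-member mean):\n")
print(wide, row.names = FALSE, digits = 3)

lstm <- wide[wide$setup == "LSTM", ]
for (other in c("RF", "LSTM_perm", "LSTM_msc", "LSTM_annual")) {
  o <- wide[wide$setup == other, ]
  cat(sprintf("LSTM - %-11s seasonal ΔNSE = %+.3f, interannual ΔNSE = %+.3f\n",
              other,
              lstm$seasonal_cycle - o$seasonal_cycle,
              lstm$interannual_anomalies - o$interannual_anomalies))
}

cv <- readRDS("results/cv_lstm.rds")
curves <- do.call(rbind, lapply(c("deciduous", "evergreen"), function(ft) {
  cbind(forest_type = ft,
        residual_seasonal_curve(cv$predictions, ds$sites, forest_type = ft,
                                member_preds = cv$member_preds))
}))
write.csv(curves, "results/residual_curves.csv", row.names = FALSE)
cat("wrote results/residual_curves.csv (site-centered residuals by aligned month)\n")
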