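#!/usr/bin/env Rscript

# Stage 5: diurnal structure, time budgets, and episode comparisons.

library(divechaos)

feats <- utils::read.csv("results/window_features.csv",
                         stringsAsFactors = FALSE)
feats$window_start <- as.POSIXct(feats$window_start,
                                 format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
labels <- utils::read.csv("results/window_labels.csv",
                          stringsAsFactors = FALSE)
labels$window_start <- as.POSIXct(labels$window_start,
                                  format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
attr(labels, "tag_map") <- sort(unique(labels$tag[!is.na(labels$tag)]))

budget <- time_budget(labels)
budget_hc <- time_budget(labels, min_confidence = 0.9)
utils::write.csv(budget, "results/time_budget.csv", row.names = FALSE)
utils::write.csv(budget_hc, "results/time_budget_high_confidence.csv",
                 row.names = FALSE)
cat("time budget (all assigned windows):\n")
print(budget)
cat(sprintf("dive bouts (deep + shallow): %.0f%% of windows\n",
            100 * sum(budget$fraction[budget$tag %in%
                                        c("deep-bout", "shallow-bout")])))

part <- daypart_partition(labels, bin_h = 3)
utils::write.csv(part, "results/daypart_partition.csv", row.names = FALSE)

for (feat in c("Ek_med", "L_med", "lyap", "period_s")) {
  tab <- diurnal_percentiles(feats$window_start, feats[[feat]], bin_h = 3)
  utils::write.csv(tab, sprintf("results/diurnal_%s.csv", feat),
                   row.names = FALSE)
}
ek <- utils::read.csv("results/diurnal_Ek_med.csv")
cat(sprintf("median E_k is lowest in the %02d:00-%02d:00 bin\n",
            ek$bin_start_h[which.min(ek$P50)],
            ek$bin_start_h[which.min(ek$P50)] + 3))

dn <- day_night_ecdf(feats$window_start, feats$Ek_med)
cat(sprintf("day/night E_k eCDF max gap: %.3f (n_day %d, n_night %d)\n",
            dn$max_gap, dn$n_day, dn$n_night))

cum <- cumulative_tag_count(labels, "near-surface-shallow")
utils::write.csv(
  transform(cum, window_start = format(window_start, "%Y-%m-%dT%H:%M:%SZ")),
  "results/cumulative_near_surface.csv", row.names = FALSE)

mid <- labels$window_start[1] + as.numeric(
  diff(range(labels$window_start)), units = "secs") / 2
ba <- before_after_median(feats$window_start, feats$L_med, mid,
                          span_days = 3, seed = 1)
cat(sprintf(paste0("median window L before vs after mid-record: ",
                   "%.1f vs %.1f m (diff %.1f, CI %.1f..%.1f)\n"),
            ba$median_before, ba$median_after, ba$difference,
            ba$ci[1], ba$ci[2]))
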