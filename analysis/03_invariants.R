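#!/usr/bin/env Rscript

# Stage 3: sliding-window attractor invariants.
#
# Each 30-min window (10-min step) of the embedded record yields the
# median distance from the origin L, the median phase-space kinetic
# energy E_k, the Rosenstein maximum Lyapunov exponent, the
# Grassberger-Procaccia correlation dimension, and the dominant wavelet
# period of the window.

library(divechaos)

rec <- regularize(read_depth_record("results/depth_record.csv"))
par <- jsonlite::read_json("results/embedding_params.json")

feats <- sliding_features(rec, par$tau_s, par$m)
out <- feats
out$window_start <- format(out$window_start, "%Y-%m-%dT%H:%M:%SZ")
utils::write.csv(out, "results/window_features.csv", row.names = FALSE)

per <- round(feats$period_s[is.finite(feats$period_s)])
per <- per[per < max(per)]  # drop the unresolved longest-voice windows
dom <- as.numeric(names(sort(table(per), decreasing = TRUE))[1])
cat(sprintf("%d windows of %g s every %g s\n", nrow(feats), 1800, 600))
cat(sprintf("modal window dominant period: %.1f min\n", dom / 60))
cat(sprintf("L_med quartiles: %.0f / %.0f / %.0f m\n",
            stats::quantile(feats$L_med, 0.25), stats::median(feats$L_med),
            stats::quantile(feats$L_med, 0.75)))
cat(sprintf("windows with failed estimators: %d of %d\n",
            sum(!stats::complete.cases(
              feats[, c("L_med", "Ek_med", "lyap", "dim")])), nrow(feats)))
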