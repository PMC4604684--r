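#!/usr/bin/env Rscript
# Group comparisons of the per-animal waveform summaries (two-tailed
# unpaired Student t-tests), percent changes, and a ratio t-test on
# simulated ratiometric expression data.

suppressPackageStartupMessages(library(pulsewave))

src <- "results/waveform_metrics.csv"
stopifnot(file.exists(src)) # run analysis/02_waveform_metrics.R first
pa <- utils::read.csv(src)
ctrl <- pa[pa$group == "control", ]
case <- pa[pa$group == "case", ]

rows <- lapply(c("sbp", "dbp", "pp", "map", "aix", "dn_pressure", "tau_s",
                 "hr_bpm"), function(m) {
  t <- group_t_test(case[[m]], ctrl[[m]])
  data.frame(metric = m, mean_case = t$mean_a, mean_control = t$mean_b,
             pct_change = percent_change(t$mean_b, t$mean_a),
             t = t$t, df = t$df, p = t$p)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/group_statistics.csv", row.names = FALSE)
print(transform(tab, pct_change = round(pct_change, 1), t = round(t, 2),
                p = signif(p, 3)), row.names = FALSE)

# ratiometric expression surrogate: case/control band-intensity ratios of a
# phosphorylation readout across 6 independent blots, true ratio 1.5
set.seed(20260921)
ratios <- exp(log(1.5) + rnorm(6, 0, 0.2))
rt <- ratio_t_test(ratios)
message(sprintf("ratio t-test: mean ratio %.3f, 95%% CI [%.3f, %.3f], p = %.4f (n = %d)",
                rt$mean_ratio, rt$ci[1], rt$ci[2], rt$p, rt$n))
write_results_json(rt[c("mean_ratio", "ci", "p", "n")],
                   "results/ratio_t_test.json")
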