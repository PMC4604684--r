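#!/usr/bin/env Rscript
# Fit per-animal 4-parameter logistic curves to the simulated pressor
# dose-response tables and compare Emax and ED50 between groups.

suppressPackageStartupMessages(library(pulsewave))

src <- "results/simulated/dose_response.csv"
stopifnot(file.exists(src)) # run analysis/01_simulate.R first
tab <- utils::read.csv(src)

fits <- lapply(split(tab, tab$animal_id), function(d) {
  f <- fit_4pl(d$dose_ug_per_kg, d$response_mmHg)
  f$group <- d$group[1]
  f
})
per_animal <- do.call(rbind, lapply(names(fits), function(id) {
  f <- fits[[id]]
  data.frame(animal_id = id, group = f$group,
             bottom = f$coef[["bottom"]], emax = f$coef[["emax"]],
             ed50 = f$coef[["ed50"]], hill = f$coef[["hill"]],
             converged = f$converged)
}))
dir.create("results", showWarnings = FALSE)
utils::write.csv(per_animal, "results/dose_response_fits.csv",
                 row.names = FALSE)

ctrl <- fits[vapply(fits, function(f) f$group == "control", logical(1))]
case <- fits[vapply(fits, function(f) f$group == "case", logical(1))]
cmp <- compare_fits(case, ctrl)
for (parm in c("emax", "ed50")) {
  t <- cmp[[parm]]$test
  message(sprintf("%s: case %.1f vs control %.1f (t = %.2f, df = %g, p = %.3g)",
                  toupper(parm), t$mean_a, t$mean_b, t$t, t$df, t$p))
}
write_results_json(list(
  emax = cmp$emax$test[c("t", "df", "p", "mean_a", "mean_b")],
  ed50 = cmp$ed50$test[c("t", "df", "p", "mean_a", "mean_b")]),
  "results/dose_response_comparison.json")
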