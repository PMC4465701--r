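#!/usr/bin/env Rscript
# Stage 2: regressions of the published per-community structure indices on
# habitat type and latitude, with two-set variation partitioning. Inputs are
# the transcribed survey summary shipped with the package (12 Brazilian
# snake communities, NRI/NTI computed against 500-km regional pools).
library(commphy)

dir.create("results", showWarnings = FALSE)
sv <- snake_survey()
design <- sv[, c("habitat_forest", "latitude")]

f_nri <- ols_fit(sv$NRI, design)
f_nti <- ols_fit(sv$NTI, design)
cat("NRI ~ habitat + latitude: "); print(f_nri)
cat("NTI ~ habitat + latitude: "); print(f_nti)

vp_nri <- varpart_two(sv$NRI, data.frame(latitude = sv$latitude),
                      data.frame(habitat = sv$habitat_forest))
cat("\nNRI variation partitioning (latitude | habitat):\n")
print(vp_nri)

out <- data.frame(
  response = c("NRI", "NTI"),
  r_squared = c(f_nri$r_squared, f_nti$r_squared),
  adj_r_squared = c(f_nri$adj_r_squared, f_nti$adj_r_squared),
  F = c(f_nri$F, f_nti$F), df1 = 2, df2 = 9,
  p = c(f_nri$p, f_nti$p))
write_result_csv(out, "results/survey_regressions.csv",
                 meta = list(latitude_convention = "absolute decimal degrees south",
                             habitat_coding = "forest=1"))
write_result_csv(
  data.frame(fraction = names(vp_nri$raw), raw = unname(vp_nri$raw),
             adjusted = unname(vp_nri$adjusted)),
  "results/survey_varpart_nri.csv",
  meta = list(set1 = "latitude", set2 = "habitat"))

cat(sprintf(paste0(
  "\nSummary: habitat and latitude jointly explain %.1f%% of NRI variation\n",
  "(adjusted %.1f%%); latitude uniquely accounts for %.0f%% (adjusted form)\n",
  "and habitat for %.0f%%. NTI shows no such structure (R2 = %.3f, p = %.2f).\n",
  "Communities at higher latitude and in non-forest habitat are the more\n",
  "phylogenetically clustered ones.\n"),
  100 * f_nri$r_squared, 100 * f_nri$adj_r_squared,
  100 * vp_nri$adjusted["a"], 100 * vp_nri$adjusted["c"],
  f_nti$r_squared, f_nti$p))
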