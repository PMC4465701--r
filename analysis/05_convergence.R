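#!/usr/bin/env Rscript
# Stage 5: trait convergence and niche-conservatism tests on the synthetic
# metacommunity: community-weighted matrix T on the optimal trait subset,
# rho(TE) with 9,999 species-level permutations, rho(PT), the partial
# rho(TE.P) with 999 permutations, and the d-separation verdict.
library(commphy)

inp <- "results/synthetic"
tree <- read_phylogeny(file.path(inp, "phylogeny.nwk"))
mc <- read_composition(file.path(inp, "composition.csv"))
traits <- read_traits(file.path(inp, "traits.csv"))

set.seed(303)
tr <- derive_robustness(traits)
B_hat <- standardize_traits(tr)
mp <- build_matrix_P(tree, mc)

best <- optimal_trait_subset(B_hat, mc)
cat("trait subset maximizing convergence:", paste(best$subset, collapse = ", "),
    sprintf("(rho = %.3f over %d candidate subsets)\n", best$rho,
            best$n_evaluated))

te <- permutation_test_TE(B_hat, mc, best$subset, n_perm = 9999)
pt <- rho_PT(mp, B_hat, mc, best$subset, n_perm = 9999)
tep <- rho_TE_given_P(mp, B_hat, mc, best$subset, n_perm = 999)
cat("rho(TE)   "); print(te)
cat("rho(PT)   "); print(pt)
cat("rho(TE.P) "); print(tep)
verdict <- dsep_verdict(te, tep)
cat("d-separation verdict:", verdict, "\n")

write_result_csv(
  data.frame(test = c("rho_TE", "rho_PT", "rho_TE_given_P"),
             rho = c(te$rho, pt$rho, tep$rho),
             p = c(te$p, pt$p, tep$p),
             n_perm = c(te$n_perm, pt$n_perm, tep$n_perm)),
  file.path(inp, "convergence.csv"),
  meta = list(seed = 303, subset = paste(best$subset, collapse = "+"),
              verdict = verdict))
cat(sprintf(paste0(
  "Community trait structure follows habitat (rho(TE) = %.3f, p = %.3g);\n",
  "whether it survives control for phylogeny-weighted composition\n",
  "(rho(TE.P) = %.3f, p = %.3g) decides between filtering on convergent\n",
  "traits and phylogenetic niche conservatism.\n"),
  te$rho, te$p, tep$rho, tep$p))
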