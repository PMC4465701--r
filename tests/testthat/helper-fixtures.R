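# small fixed trees used across tests
balanced4 <- function() ape::read.tree(text = "((A,B),(C,D));")
pectinate3 <- function() ape::read.tree(text = "(A,(B,C));")
star_tree <- function(n = 3) {
  ape::read.tree(text = paste0("(", paste(LETTERS[seq_len(n)], collapse = ","),
                               ");"))
}

# independent exhaustive NRI/NTI oracle: enumerate every richness-sized
# subset of the pool, population-sd convention; written with plain loops so
# it shares no code path with the package
oracle_structure_z <- function(species, pool_D, metric = "mpd") {
  met <- function(sp) {
    sub <- pool_D[sp, sp, drop = FALSE]
    if (metric == "mpd") {
      tot <- 0; np <- 0
      for (i in seq_along(sp)[-1]) for (j in seq_len(i - 1)) {
        tot <- tot + sub[i, j]; np <- np + 1
      }
      tot / np
    } else {
      mins <- numeric(length(sp))
      for (i in seq_along(sp)) mins[i] <- min(sub[i, -i])
      mean(mins)
    }
  }
  obs <- met(species)
  subsets <- utils::combn(rownames(pool_D), length(species), simplify = FALSE)
  vals <- vapply(subsets, met, numeric(1))
  mu <- mean(vals)
  sdv <- sqrt(sum((vals - mu)^2) / length(vals))
  -(obs - mu) / sdv
}

# small two-habitat metacommunity over a given species set
toy_metacommunity <- function(species, n_sites = 4,
                              habitat = rep(c("forest", "non_forest"),
                                            length.out = n_sites),
                              seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n_sites, length(species),
              dimnames = list(paste0("s", seq_len(n_sites)), species))
  for (i in seq_len(n_sites))
    m[i, sample(length(species),
                min(length(species), max(2, rpois(1, length(species) / 2))))] <- 1L
  m <- m[, colSums(m) > 0, drop = FALSE]
  metacommunity(m, habitat, seq(3, 30, length.out = n_sites))
}

# minimal valid trait table values for n species
toy_traits <- function(species, seed = 1) {
  set.seed(seed)
  vals <- as.data.frame(matrix(rexp(length(species) * 8) + 0.5,
                               ncol = 8,
                               dimnames = list(NULL, c("SVL", "TL", "CAM",
                                                       "HL", "HW", "HH",
                                                       "VS", "SS"))))
  trait_table(vals, species)
}
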