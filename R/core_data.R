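#' Read a rooted phylogeny from a newick file
#'
#' Reads a newick tree (polytomies allowed) and validates it for downstream
#' community-phylogenetics use. All analyses in this package measure
#' phylogenetic distance by node counting, so branch lengths, if present, are
#' retained on the returned object but never used; the object is flagged
#' accordingly.
#'
#' @param path Path to a newick file containing a single rooted tree.
#' @return An [ape::read.tree()] `"phylo"` object with attribute
#'   `branch_lengths_used = FALSE`. Tip labels are whitespace-trimmed and
#'   spaces are normalized to underscores (the newick convention), so they
#'   match species names in composition and trait tables.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("phylogeny file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_phylogeny(tree)
}

#' Validate a phylogeny object
#'
#' @param tree A `"phylo"` object.
#' @return The tree, tip labels normalized, with `branch_lengths_used` attr.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  tree$tip.label <- normalize_species(tree$tip.label)
  if (length(tree$tip.label) < 2) stop("phylogeny must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  # the basal node of the parsed newick is taken as the root; a basal
  # polytomy is a rooted polytomy (node counting needs no root branch)
  # every internal node must have >= 2 children (no unbranched knuckles)
  kids <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  internal <- (length(tree$tip.label) + 1):max(tree$edge)
  if (any(kids[internal] < 2)) stop("internal node with a single child")
  attr(tree, "branch_lengths_used") <- FALSE
  tree
}

# species-name normalization: trim, spaces -> underscores (newick convention)
normalize_species <- function(x) {
  gsub(" ", "_", trimws(as.character(x)))
}

#' Parse latitudes given in decimal degrees or degree-minute strings
#'
#' Site coordinates are stored as absolute decimal degrees (all supported
#' study regions are in the southern hemisphere; regressions are invariant to
#' the sign, but a single convention is fixed and recorded in output headers).
#' Strings like `"3 deg 6 min S"` (written with the degree sign) or `"24 deg 32 min S"` are converted exactly with
#' minutes/60 (and seconds/3600 when present).
#'
#' @param x Character or numeric vector of latitudes.
#' @return Numeric vector of absolute decimal degrees.
#' @examples
#' parse_latitude("24\u00b032'S")  # 24.5333...
#' @export
parse_latitude <- function(x) {
  if (is.numeric(x)) return(abs(x))
  out <- vapply(as.character(x), function(s) {
    s0 <- trimws(s)
    suppressWarnings(v <- as.numeric(s0))
    if (!is.na(v)) return(abs(v))
    # split on degree sign and any of the quote characters in common use
    parts <- strsplit(s0, "[\u00b0'\u2019\"\u201d\u2033\u2032]+")[[1]]
    parts <- parts[nzchar(trimws(parts))]
    hemi <- grepl("[SNWE]$", trimws(parts[length(parts)]))
    if (hemi) parts[length(parts)] <- gsub("[SNWE]", "", parts[length(parts)])
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    nums <- suppressWarnings(as.numeric(parts))
    if (any(is.na(nums)) || length(nums) < 1 || length(nums) > 3)
      stop("cannot parse coordinate: ", s)
    abs(nums[1]) + (if (length(nums) > 1) nums[2] / 60 else 0) +
      (if (length(nums) > 2) nums[3] / 3600 else 0)
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Construct a metacommunity object
#'
#' A metacommunity couples a sites x species presence/absence matrix with
#' per-site metadata (habitat class and latitude) and, optionally, per-site
#' regional species pools — the universes used for the randomization nulls.
#'
#' @param presence Sites x species matrix or data frame of 0/1.
#' @param habitat Character vector per site, `"forest"` or `"non_forest"`.
#' @param latitude Numeric or degree-minute character vector per site.
#' @param pools Optional named list mapping site name to a character vector of
#'   pool species; each site's present species must be contained in its pool.
#' @return An object of class `"metacommunity"`: a list with elements
#'   `presence` (integer matrix, sites in rows), `sites` (data frame with
#'   `site`, `habitat`, `latitude`), and `pools` (list or `NULL`).
#' @export
metacommunity <- function(presence, habitat, latitude, pools = NULL) {
  m <- as.matrix(presence)
  if (is.null(rownames(m))) rownames(m) <- paste0("site", seq_len(nrow(m)))
  colnames(m) <- normalize_species(colnames(m))
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(!m %in% c(0, 1)))
    stop("non-binary presence value in composition matrix")
  storage.mode(m) <- "integer"
  if (anyDuplicated(rownames(m))) stop("duplicate site names")
  if (any(rowSums(m) < 1)) {
    stop("empty site(s): ", paste(rownames(m)[rowSums(m) < 1], collapse = ", "))
  }
  if (any(colSums(m) < 1)) {
    stop("species never observed at any site: ",
         paste(colnames(m)[colSums(m) < 1], collapse = ", "))
  }
  habitat <- as.character(habitat)
  if (length(habitat) != nrow(m) || !all(habitat %in% c("forest", "non_forest")))
    stop("habitat must be one of 'forest'/'non_forest' per site")
  latitude <- parse_latitude(latitude)
  if (length(latitude) != nrow(m)) stop("latitude length mismatch")
  if (!is.null(pools)) {
    pools <- lapply(pools, normalize_species)
    if (!all(rownames(m) %in% names(pools)))
      stop("pools missing for site(s): ",
           paste(setdiff(rownames(m), names(pools)), collapse = ", "))
    for (s in rownames(m)) {
      pres <- colnames(m)[m[s, ] == 1]
      extra <- setdiff(pres, pools[[s]])
      if (length(extra))
        stop("site ", s, " has present species outside its pool: ",
             paste(extra, collapse = ", "))
    }
  }
  structure(list(
    presence = m,
    sites = data.frame(site = rownames(m), habitat = habitat,
                       latitude = latitude, stringsAsFactors = FALSE),
    pools = pools
  ), class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("metacommunity:", nrow(x$presence), "sites x", ncol(x$presence),
      "species; richness", paste(range(rowSums(x$presence)), collapse = "-"),
      "\n")
  cat("habitat:", paste(sprintf("%s=%d", names(table(x$sites$habitat)),
                                table(x$sites$habitat)), collapse = ", "),
      "| latitude", paste(sprintf("%.2f", range(x$sites$latitude)),
                          collapse = "-"), "\u00b0S\n")
  if (!is.null(x$pools)) cat("regional pools: sizes",
                             paste(range(lengths(x$pools)), collapse = "-"), "\n")
  invisible(x)
}

#' Read a sites x species composition table with site metadata
#'
#' The composition CSV holds one row per site: a `site` column, then one 0/1
#' column per species. Habitat and latitude come either from columns named
#' `habitat`/`latitude` in the same file or from a companion metadata CSV with
#' columns `site`, `habitat`, `latitude` (latitude may be decimal or a
#' degree-minute string).
#'
#' @param path Composition CSV.
#' @param metadata_path Optional companion metadata CSV.
#' @param pools Optional named list of pool membership (site -> species).
#' @return A [metacommunity()] object.
#' @export
read_composition <- function(path, metadata_path = NULL, pools = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site" %in% names(df)) stop("composition CSV needs a 'site' column")
  meta_cols <- intersect(c("habitat", "latitude"), names(df))
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    if (!all(c("site", "habitat", "latitude") %in% names(md)))
      stop("metadata CSV needs columns site, habitat, latitude")
    md <- md[match(df$site, md$site), ]
    if (any(is.na(md$site))) stop("metadata missing for some sites")
    habitat <- md$habitat; latitude <- md$latitude
  } else {
    if (length(meta_cols) < 2)
      stop("no metadata file given and habitat/latitude columns absent")
    habitat <- df$habitat; latitude <- df$latitude
  }
  sp_cols <- setdiff(names(df), c("site", "habitat", "latitude"))
  m <- as.matrix(df[, sp_cols, drop = FALSE])
  rownames(m) <- df$site
  metacommunity(m, habitat, latitude, pools = pools)
}

#' Write a metacommunity composition table (with metadata columns)
#' @param mc A metacommunity.
#' @param path Output CSV path.
#' @export
write_composition <- function(mc, path) {
  df <- data.frame(site = rownames(mc$presence),
                   habitat = mc$sites$habitat, latitude = mc$sites$latitude,
                   mc$presence, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-site regional pool membership
#'
#' Long-format CSV with columns `site` and `species`, one row per pool member.
#' @param path CSV path.
#' @return Named list site -> character vector of species.
#' @export
read_pools <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "species") %in% names(df)))
    stop("pool CSV needs columns site, species")
  split(normalize_species(df$species), df$site)
}

# the eight measured morphometric traits, in canonical order
TRAIT_NAMES <- c("SVL", "TL", "CAM", "HL", "HW", "HH", "VS", "SS")

#' Read a species x traits table
#'
#' Expects one row per species and the eight morphometric trait columns:
#' snout-vent length (SVL), tail length (TL), circumference around midbody
#' (CAM), head length (HL), head width (HW), head height (HH) — species-mean
#' lengths in mm — plus ventral (VS) and subcaudal (SS) scale counts
#' (species means, so possibly non-integer). All values must be strictly
#' positive.
#'
#' @param path CSV with a `species` column plus the 8 trait columns.
#' @return A data frame of class `"trait_table"`, species as row names, input
#'   order preserved.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("trait CSV needs a 'species' column")
  trait_table(df[, setdiff(names(df), "species"), drop = FALSE],
              species = df$species)
}

#' Construct a trait table
#' @param values Data frame / matrix of trait values (columns = traits).
#' @param species Character vector of species names (row order).
#' @return `"trait_table"` data frame.
#' @export
trait_table <- function(values, species) {
  df <- as.data.frame(values)
  missing_cols <- setdiff(TRAIT_NAMES, names(df))
  if (length(missing_cols))
    stop("missing trait column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c(TRAIT_NAMES, "robustness"))
  if (length(extra)) stop("unknown trait column(s): ", paste(extra, collapse = ", "))
  species <- normalize_species(species)
  if (anyDuplicated(species)) stop("duplicate species in trait table")
  num <- df[, intersect(names(df), c(TRAIT_NAMES))]
  if (any(!vapply(num, is.numeric, logical(1)))) stop("non-numeric trait value")
  if (any(as.matrix(num) <= 0, na.rm = TRUE) || any(is.na(num)))
    stop("trait values must be strictly positive and non-missing")
  rownames(df) <- species
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write a trait table
#' @param traits A trait_table.
#' @param path Output CSV path.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(data.frame(species = rownames(traits), traits,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Cross-validate a phylogeny, metacommunity and (optional) trait table
#'
#' Species observed in communities but absent from the tree are fatal (no
#' distance can be computed for them); tree tips never observed are only a
#' warning, as are species lacking trait data — trait analyses are later
#' restricted to sites with complete coverage, and this report lists the
#' affected sites.
#'
#' @param phylogeny A `"phylo"` tree.
#' @param mc A metacommunity.
#' @param traits Optional trait_table.
#' @return A data frame of class `"validation_report"` with columns
#'   `severity` (`"fatal"`/`"warning"`), `category`, `item`, `detail`.
#'   Zero rows means fully consistent.
#' @export
validate_dataset <- function(phylogeny, mc, traits = NULL) {
  rep <- list()
  add <- function(severity, category, item, detail = "") {
    rep[[length(rep) + 1]] <<- data.frame(severity = severity,
                                          category = category, item = item,
                                          detail = detail,
                                          stringsAsFactors = FALSE)
  }
  tips <- normalize_species(phylogeny$tip.label)
  comm_sp <- colnames(mc$presence)
  for (sp in setdiff(comm_sp, tips))
    add("fatal", "species_not_on_tree", sp,
        paste("sites:", paste(rownames(mc$presence)[mc$presence[, sp] == 1],
                              collapse = ";")))
  for (sp in setdiff(tips, comm_sp))
    add("warning", "tip_never_observed", sp)
  if (!is.null(mc$pools)) {
    pool_sp <- unique(unlist(mc$pools))
    for (sp in setdiff(pool_sp, tips))
      add("fatal", "pool_species_not_on_tree", sp)
  }
  if (!is.null(traits)) {
    lack <- setdiff(comm_sp, rownames(traits))
    for (sp in lack) {
      affected <- rownames(mc$presence)[mc$presence[, sp] == 1]
      add("warning", "species_without_traits", sp,
          paste("sites:", paste(affected, collapse = ";")))
    }
  }
  out <- if (length(rep)) do.call(rbind, rep) else
    data.frame(severity = character(), category = character(),
               item = character(), detail = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("validation: OK (no issues)\n")
  } else {
    cat("validation:", sum(x$severity == "fatal"), "fatal,",
        sum(x$severity == "warning"), "warning issue(s)\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Sites usable for trait-based analyses
#'
#' Sites where every present species has trait data; trait convergence tests
#' are run on this subset only.
#' @param mc A metacommunity.
#' @param traits A trait_table.
#' @return Character vector of site names.
#' @export
trait_covered_sites <- function(mc, traits) {
  covered <- colnames(mc$presence) %in% rownames(traits)
  rownames(mc$presence)[rowSums(mc$presence[, !covered, drop = FALSE]) == 0]
}

#' Restrict a metacommunity to a subset of sites
#' @param mc A metacommunity.
#' @param sites Character vector of site names to keep.
#' @return A metacommunity on those sites (species never present are dropped).
#' @export
subset_sites <- function(mc, sites) {
  keep <- rownames(mc$presence) %in% sites
  m <- mc$presence[keep, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  metacommunity(m, mc$sites$habitat[keep], mc$sites$latitude[keep],
                pools = if (is.null(mc$pools)) NULL else mc$pools[rownames(m)])
}

#' Analysis configuration
#'
#' Bundles the randomization/permutation counts, seed and the z threshold used
#' across the pipeline. The seed is recorded in every output header.
#'
#' @param n_randomizations_structure Tip-label randomizations for NRI/NTI
#'   nulls (default 9999).
#' @param n_permutations_convergence Permutations for rho(TE)/rho(PT)
#'   (default 9999).
#' @param n_permutations_dsep Permutations for the partial rho(TE.P) test
#'   (default 999).
#' @param seed Integer RNG seed.
#' @param z_threshold Two-sided significance threshold on NRI/NTI (1.96).
#' @param alpha Significance level for permutation tests / verdicts.
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(n_randomizations_structure = 9999,
                            n_permutations_convergence = 9999,
                            n_permutations_dsep = 999,
                            seed = 1L, z_threshold = 1.96, alpha = 0.05) {
  stopifnot(n_randomizations_structure >= 1, n_permutations_convergence >= 1,
            n_permutations_dsep >= 1)
  structure(list(n_randomizations_structure = as.integer(n_randomizations_structure),
                 n_permutations_convergence = as.integer(n_permutations_convergence),
                 n_permutations_dsep = as.integer(n_permutations_dsep),
                 seed = as.integer(seed), z_threshold = z_threshold,
                 alpha = alpha),
            class = "analysis_config")
}

#' Write a result table as CSV with a metadata header
#'
#' Every result file begins with comment lines recording the seed and
#' parameter values, so a run can be reproduced from its outputs alone.
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list of metadata values recorded as `# key: value` lines.
#' @export
write_result_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a result CSV written by [write_result_csv()]
#' @param path CSV path.
#' @return Data frame; metadata header returned as attribute `"meta"`.
#' @export
read_result_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^# ", "", l)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}
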