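#' Simulate a Yule (pure-birth) tree topology
#'
#' Grows a rooted binary topology by uniform random lineage splitting and
#' labels the tips `sp001 ... spNNN`. Branch lengths are not generated:
#' the analysis operates on branch-length-free classifications. (The
#' random-join construction used here draws from the same distribution
#' over labelled topologies as sequential uniform lineage splitting.)
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed; the same seed yields the same Newick string.
#' @return A `phylo` with `n_species` tips and `n_species - 1` internal
#'   nodes, no branch lengths.
#' @export
simulate_yule_topology <- function(n_species, seed) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("`n_species` must be at least 2")
  if (missing(seed)) stop("`seed` is mandatory")
  tr <- withr::with_seed(seed, ape::rcoal(n_species))
  tr$edge.length <- NULL
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Simulate a trait under Brownian motion on a topology
#'
#' Performs a Brownian walk over the tree with unit-length edges: each
#' child value is its parent's value plus a `Normal(0, sigma_between^2)`
#' innovation, starting from 0 at the root. This produces inter-specific
#' values with phylogenetic signal; it is a fixture generator, not an
#' inference model.
#'
#' @param tree A `phylo`.
#' @param sigma_between Innovation standard deviation per edge (> 0).
#' @param seed Integer seed.
#' @return Named numeric vector: tip label -> trait value.
#' @export
simulate_bm_trait <- function(tree, sigma_between, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(sigma_between) || sigma_between <= 0)
    stop("`sigma_between` must be > 0")
  if (missing(seed)) stop("`seed` is mandatory")
  n <- ape::Ntip(tree)
  ed <- ape::reorder.phylo(tree, "cladewise")$edge
  withr::with_seed(seed, {
    val <- numeric(n + tree$Nnode)  # root = 0
    steps <- stats::rnorm(nrow(ed), 0, sigma_between)
    for (e in seq_len(nrow(ed)))
      val[ed[e, 2]] <- val[ed[e, 1]] + steps[e]
    stats::setNames(val[seq_len(n)], tree$tip.label)
  })
}

#' Add within-species population replicates around species values
#'
#' For species `s` with `r_s` requested populations, draws `r_s` values
#' from `Normal(mu_s, sigma_within^2)` and records them as populations
#' `p1 ... pr`. A species with a single population copies its value
#' exactly.
#'
#' @param species_values Named numeric vector: species -> mean value.
#' @param design Named integer vector: species -> number of populations
#'   (>= 1). Species of `species_values` missing from `design` get 1.
#' @param sigma_within Within-species standard deviation (>= 0).
#' @param seed Integer seed.
#' @param metric Metric name recorded in the table (default `"trait"`).
#' @return A `trait_table` with one row per species x population.
#' @export
add_population_replicates <- function(species_values, design, sigma_within,
                                      seed, metric = "trait") {
  if (is.null(names(species_values)))
    stop("`species_values` must be named by species")
  if (!is.numeric(sigma_within) || sigma_within < 0)
    stop("`sigma_within` must be >= 0")
  if (missing(seed)) stop("`seed` is mandatory")
  counts <- stats::setNames(rep(1L, length(species_values)),
                            names(species_values))
  if (!missing(design) && length(design)) {
    if (is.null(names(design))) stop("`design` must be named by species")
    if (any(design < 1)) stop("population counts must be >= 1")
    counts[names(design)] <- as.integer(design)
  }
  rows <- withr::with_seed(seed, {
    do.call(rbind, lapply(names(species_values), function(sp) {
      r <- counts[[sp]]
      mu <- species_values[[sp]]
      vals <- if (r == 1L) mu else stats::rnorm(r, mu, sigma_within)
      data.frame(metric = metric, species = sp,
                 population = paste0("p", seq_len(r)), value = vals)
    }))
  })
  as_trait_table(rows)
}

# Expected nested-variance shares for tips x_sp = mu_s + e_sp, e iid
# N(0, sw2), species s carrying r_s tips, n = sum r_s, m species:
#   E[within SS / n]  = sw2 * (n - m) / n
#   E[between SS / n] = Var_n(mu, tip-weighted) + sw2 * (m - 1) / n
# Solving within / (within + between) = w for sw2 gives the calibration
# used by simulate_scenario(); w must stay below (n - m) / (n - 1).
.solve_sigma_within <- function(w, v_mu, n, m) {
  if (w == 0) return(0)
  a <- (n - m) / n
  b <- (m - 1) / n
  denom <- a * (1 - w) - w * b
  if (denom <= 0)
    stop("within-share w = ", w, " is not attainable with this design ",
         "(must be < ", signif(a / (a + b), 4), ")")
  sqrt(w * v_mu / denom)
}

#' Simulate a complete analysis scenario with a known within-species share
#'
#' Builds a species tree (Yule topology), Brownian inter-specific trait
#' values, and within-species replicates calibrated so that the expected
#' within-species share of the total sum of squares equals
#' `within_share`. The calibration solves the nested-variance expectation
#' for `sigma_within` given the realized variance of the species values,
#' accounting for the inflation of the between-species sum of squares by
#' sampling noise in the population means.
#'
#' @param n_species Number of species (default 15).
#' @param n_populations Populations per replicated species: a single
#'   integer (balanced design) or a named vector per species (default 4).
#' @param n_replicated How many species carry replicates (default: all).
#' @param within_share Target expected within-species variance share `w`
#'   in \[0, 1) (default 0.3).
#' @param sigma_between Brownian innovation sd (default 1).
#' @param seed Integer seed.
#' @param metric Metric name for the generated table.
#' @return Object of class `scenario`: list with `species_tree`,
#'   `enlarged`, `table`, `tip_values` (named by enlarged-tree tip),
#'   `true_within_share`, `sigma_between`, `sigma_within`, `seed`.
#' @export
simulate_scenario <- function(n_species = 15, n_populations = 4,
                              n_replicated = NULL, within_share = 0.3,
                              seed, sigma_between = 1, metric = "trait") {
  if (missing(seed)) stop("`seed` is mandatory")
  if (within_share < 0 || within_share >= 1)
    stop("`within_share` must lie in [0, 1)")
  tr <- simulate_yule_topology(n_species, seed)
  mu <- simulate_bm_trait(tr, sigma_between, seed + 1L)

  sp <- tr$tip.label
  if (is.null(n_replicated)) n_replicated <- n_species
  n_replicated <- min(n_replicated, n_species)
  replicated <- sp[seq_len(n_replicated)]
  counts <- stats::setNames(rep(1L, n_species), sp)
  if (length(n_populations) == 1L && is.null(names(n_populations))) {
    counts[replicated] <- as.integer(n_populations)
  } else {
    counts[names(n_populations)] <- as.integer(n_populations)
  }
  if (any(counts[replicated] < 2L))
    stop("replicated species need at least 2 populations")

  n <- sum(counts)
  m <- n_species
  mu_tipwise <- rep(unname(mu[sp]), counts[sp])
  v_mu <- .varn(mu_tipwise)
  sigma_within <- .solve_sigma_within(within_share, v_mu, n, m)

  table <- add_population_replicates(mu, counts, sigma_within,
                                     seed + 2L, metric = metric)
  reps <- lapply(sp[counts[sp] >= 2L],
                 function(s) paste0(s, "@p", seq_len(counts[[s]])))
  names(reps) <- sp[counts[sp] >= 2L]
  enlarged <- enlarge_with_replicates(tr, reps)

  tip_values <- numeric(0)
  for (i in seq_len(nrow(table))) {
    s <- table$species[i]
    lab <- if (counts[[s]] >= 2L) paste0(s, "@", table$population[i]) else s
    tip_values[lab] <- table$value[i]
  }
  structure(
    list(species_tree = tr, enlarged = enlarged, table = table,
         tip_values = tip_values, true_within_share = within_share,
         sigma_between = sigma_between, sigma_within = sigma_within,
         seed = seed),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Synthetic scenario:", ape::Ntip(x$species_tree), "species,",
      length(x$tip_values), "measurements,",
      length(x$enlarged$artificial_nodes), "replicated species\n")
  cat("  target within-species share =", x$true_within_share,
      " (sigma_within =", signif(x$sigma_within, 4), ")\n")
  invisible(x)
}

#' Write a ready-to-run example dataset
#'
#' Emits the Newick tree and CSV trait table of a synthetic scenario in
#' the formats the analysis pipeline consumes. The default replication
#' design mirrors the shape of published butterfly dispersal compilations:
#' 18 species, 8 of them with 3-6 populations.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_species,n_replicated,within_share Passed to
#'   [simulate_scenario()].
#' @return Named character vector with the `tree` and `traits` paths.
#' @export
write_fixture_dataset <- function(dir, seed, n_species = 18,
                                  n_replicated = 8, within_share = 0.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pops <- withr::with_seed(seed, {
    tmp <- simulate_yule_topology(n_species, seed)
    stats::setNames(sample(3:6, n_replicated, replace = TRUE),
                    tmp$tip.label[seq_len(n_replicated)])
  })
  sc <- simulate_scenario(n_species = n_species, n_populations = pops,
                          n_replicated = n_replicated,
                          within_share = within_share, seed = seed)
  tree_path <- file.path(dir, "tree.nwk")
  traits_path <- file.path(dir, "traits.csv")
  write_newick(sc$species_tree, tree_path)
  write_trait_table(sc$table, traits_path)
  c(tree = tree_path, traits = traits_path)
}
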