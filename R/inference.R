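.new_test_result <- function(statistic_name, observed, null_sample, p_value,
                             alternative, seed) {
  structure(
    list(statistic_name = statistic_name,
         observed = observed,
         null_sample = null_sample,
         n_perm = length(null_sample),
         p_value = p_value,
         alternative = alternative,
         seed = seed),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test for ", x$statistic_name, "\n",
      "  observed = ", format(x$observed), "\n",
      "  n_perm = ", x$n_perm, ", alternative = ", x$alternative,
      ", seed = ", x$seed, "\n",
      "  p-value = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

# (r + 1) / (N + 1) permutation p-value; ties at the observed value are
# counted into the tail (tolerance guards against float-order noise).
.perm_p <- function(null_sample, observed, tail = c("less", "greater")) {
  tail <- match.arg(tail)
  tol <- 1e-12 * max(1, abs(observed))
  r <- if (tail == "less") sum(null_sample <= observed + tol)
       else sum(null_sample >= observed - tol)
  (r + 1) / (length(null_sample) + 1)
}

.check_tip_values <- function(tree, tip_values) {
  missing_tips <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing_tips))
    stop("missing trait values for tip(s): ",
         paste(missing_tips, collapse = ", "))
  as.numeric(tip_values[tree$tip.label])
}

#' Trait conservation test (statistic S_c)
#'
#' Tests whether intra-specific trait variability is lower than expected
#' when intra- and inter-specific variation are exchangeable. The observed
#' S_c (sum of artificial-node contributions) is compared against a null
#' sample obtained by jointly permuting the trait values across *all* tips
#' of the enlarged tree, so values are exchanged among species and among
#' populations alike; the permutations alter the node diversities `d_k`
#' while the tip proportions `p_k` stay fixed. The alternative is `less`:
#' trait conservation within species shows up as an unusually small S_c.
#'
#' @param enlarged An `enlarged_phylo` with at least one artificial node.
#' @param tip_values Named numeric vector of (typically standardized)
#'   trait values, one per tip.
#' @param n_perm Number of permutations (>= 1; 1000 in routine use).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `perm_test` with `p_value = (#\{S_c^perm <= S_c^obs\} + 1) / (n_perm + 1)`.
#' @export
conservation_test <- function(enlarged, tip_values, n_perm = 1000, seed) {
  stopifnot(inherits(enlarged, "enlarged_phylo"))
  if (length(enlarged$artificial_nodes) == 0L)
    stop("test undefined: the enlarged tree has no artificial nodes")
  if (missing(seed)) stop("`seed` is mandatory")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("`n_perm` must be at least 1")

  x <- .check_tip_values(enlarged$tree, tip_values)
  dec <- decompose_diversity(enlarged, tip_values)
  obs <- sc_statistic(dec)$value

  plan <- attr(dec, "plan")
  art_idx <- match(enlarged$artificial_nodes, plan$nodes)
  art_tips <- plan$node_tips[art_idx]
  n <- plan$n
  null_sample <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      xp <- x[sample.int(n)]
      s <- 0
      for (idx in art_tips)
        s <- s + length(idx) / n * .varn(xp[idx])
      s
    }, numeric(1))
  })
  p <- .perm_p(null_sample, obs, "less")
  .new_test_result("S_c", obs, null_sample, p, "less", seed)
}

#' Skewness-to-root test (statistic S_3)
#'
#' Tests whether trait diversity is concentrated at root-ward (most
#' tip-distant) nodes of the tree. The observed S_3 (contribution-weighted
#' mean depth rank) is compared two-sidedly against the null sample from
#' joint permutation of all tip values; the two-sided p-value doubles the
#' smaller tail, capped at 1.
#'
#' @param enlarged An `enlarged_phylo` (artificial nodes optional) or a
#'   plain `phylo`.
#' @param tip_values Named numeric vector of trait values, one per tip.
#' @param ranks A `depth_ranks` for the tree (see [depth_ranks()]).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_test` with alternative `"two-sided"`.
#' @export
skewness_to_root_test <- function(enlarged, tip_values, ranks,
                                  n_perm = 1000, seed) {
  if (inherits(enlarged, "phylo")) {
    enlarged <- structure(
      list(tree = enlarged, artificial_nodes = integer(0),
           species_of_tip = stats::setNames(enlarged$tip.label,
                                            enlarged$tip.label)),
      class = "enlarged_phylo")
  }
  stopifnot(inherits(enlarged, "enlarged_phylo"))
  if (missing(seed)) stop("`seed` is mandatory")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("`n_perm` must be at least 1")

  x <- .check_tip_values(enlarged$tree, tip_values)
  dec <- decompose_diversity(enlarged, tip_values)
  if (attr(dec, "total") <= 0)
    stop("undefined statistic: total diversity is 0")
  obs <- s3_statistic(dec, ranks)$value

  plan <- attr(dec, "plan")
  r <- as.numeric(ranks)[match(plan$nodes, names(ranks))]
  if (any(is.na(r)))
    stop("`ranks` must cover every internal node")
  n <- plan$n
  null_sample <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      xp <- x[sample.int(n)]
      ev <- .plan_nu(plan, xp)
      tot <- sum(ev$nu)
      if (tot <= 0) return(NA_real_)
      sum(ev$nu / tot * r)
    }, numeric(1))
  })
  null_sample <- null_sample[!is.na(null_sample)]
  p_low <- .perm_p(null_sample, obs, "less")
  p_high <- .perm_p(null_sample, obs, "greater")
  p <- min(1, 2 * min(p_low, p_high))
  .new_test_result("S_3", obs, null_sample, p, "two-sided", seed)
}

# Abouheif proximity matrix: a_ij is the product, over the internal nodes
# on the path between tips i and j, of 1 / (number of direct descendants
# of that node); a_ii = 0.
.abouheif_proximity <- function(tree) {
  n <- ape::Ntip(tree)
  nchildren <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      internal <- path[path > n]
      A[i, j] <- A[j, i] <- prod(1 / nchildren[internal])
    }
  }
  dimnames(A) <- list(tree$tip.label, tree$tip.label)
  A
}

.cmean_from_A <- function(A, z, W) {
  # Moran form: C = (n / W) * (z' A z) / (z' z), z centered
  n <- length(z)
  (n / W) * as.numeric(crossprod(z, A %*% z)) / sum(z^2)
}

#' Abouheif's C_mean phylogenetic-signal statistic
#'
#' Measures whether closely related species carry similar trait values.
#' Uses the Moran autocorrelation form with Abouheif's path-product
#' proximities: `a_ij` is the product over the internal nodes on the
#' tip-to-tip path of one over the number of direct descendants of that
#' node (zero diagonal, no row normalization).
#'
#' @param tree A `phylo` whose tips are species.
#' @param species_values Named numeric vector: species -> trait value
#'   (typically the mean over that species' populations).
#' @return The C_mean value (a scalar).
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' abouheif_cmean(tr, c(A = 0, B = 2, C = 4, D = 6))  # 2/15
#' @export
abouheif_cmean <- function(tree, species_values) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 3L) stop("need at least 3 species")
  x <- .check_tip_values(tree, species_values)
  if (max(x) == min(x)) stop("degenerate input: constant trait values")
  A <- .abouheif_proximity(tree)
  W <- sum(A)
  .cmean_from_A(A, x - mean(x), W)
}

#' Permutation test for Abouheif's C_mean
#'
#' Upper-tailed test of phylogenetic signal: the species values are
#' permuted across the tips and the observed C_mean is compared with the
#' permutation distribution, `p = (#\{C >= C_obs\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams abouheif_cmean
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_test` with alternative `"greater"`.
#' @export
abouheif_test <- function(tree, species_values, n_perm = 1000, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (missing(seed)) stop("`seed` is mandatory")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("`n_perm` must be at least 1")
  if (ape::Ntip(tree) < 3L) stop("need at least 3 species")
  x <- .check_tip_values(tree, species_values)
  if (max(x) == min(x)) stop("degenerate input: constant trait values")
  A <- .abouheif_proximity(tree)
  W <- sum(A)
  obs <- .cmean_from_A(A, x - mean(x), W)
  n <- length(x)
  null_sample <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      z <- x[sample.int(n)]
      .cmean_from_A(A, z - mean(z), W)
    }, numeric(1))
  })
  p <- .perm_p(null_sample, obs, "greater")
  .new_test_result("C_mean", obs, null_sample, p, "greater", seed)
}

#' Hochberg step-up adjusted p-values
#'
#' Family-wise error control by Hochberg's step-up procedure:
#' `adjusted_(i) = min over j >= i of ((m - j + 1) * p_(j))`, capped at 1,
#' returned in the input order. Delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' hochberg_adjust(c(0.01, 0.02, 0.30))
#' @export
hochberg_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "hochberg")
}

#' Write a test result as JSON
#'
#' @param result A `perm_test`.
#' @param path Output path.
#' @param p_adjusted Optional adjusted p-value to include.
#' @return `path`, invisibly.
#' @export
write_test_json <- function(result, path, p_adjusted = NULL) {
  stopifnot(inherits(result, "perm_test"))
  out <- list(statistic_name = result$statistic_name,
              observed = result$observed,
              n_perm = result$n_perm,
              seed = result$seed,
              alternative = result$alternative,
              p_value = result$p_value)
  if (!is.null(p_adjusted)) out$p_adjusted <- p_adjusted
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
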