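#' Rao quadratic entropy of a set of trait values
#'
#' The quadratic entropy of `n` equally weighted units is the mean pairwise
#' dissimilarity `sum_ij d_ij / n^2`. For a single quantitative trait the
#' dissimilarity is the half squared difference `d_ij = (x_i - x_j)^2 / 2`,
#' under which the index reduces exactly to the variance with divisor `n`.
#' A precomputed dissimilarity matrix may be supplied instead, keeping the
#' index open to multi-trait extensions.
#'
#' @param values Numeric vector (ignored when `dis` is given, except for
#'   its length).
#' @param dis Optional symmetric dissimilarity matrix with zero diagonal.
#' @return The quadratic entropy (a non-negative scalar).
#' @examples
#' quadratic_entropy(c(0, 2, 4, 6))  # 5, the divisor-n variance
#' @export
quadratic_entropy <- function(values, dis = NULL) {
  if (is.null(dis)) {
    x <- as.numeric(values)
    n <- length(x)
    if (n < 1L) stop("empty value list")
    if (any(!is.finite(x))) stop("values must be finite")
    if (n == 1L) return(0)
    dis <- outer(x, x, function(a, b) (a - b)^2 / 2)
  } else {
    stopifnot(is.matrix(dis), nrow(dis) == ncol(dis))
    n <- nrow(dis)
    if (n < 1L) stop("empty dissimilarity matrix")
  }
  sum(dis) / n^2
}

# divisor-n variance; the single-trait closed form of quadratic_entropy()
.varn <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

# Precomputed index structure so a decomposition can be re-evaluated
# cheaply for permuted tip values: for every internal node, the tip index
# set under it and under each of its children.
.decomp_plan <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  under <- .tips_under(tree)
  nodes <- (n + 1L):(n + m)
  children <- lapply(nodes, function(k) tree$edge[tree$edge[, 1] == k, 2])
  list(
    n = n,
    nodes = nodes,
    node_tips = under[nodes],
    child_tips = lapply(children, function(ch) under[ch]),
    tip_label = tree$tip.label
  )
}

# nu_k for every internal node given tip values in tip-index order.
# d_k = QE(tips under k) - sum_j (n_j/n_k) QE(tips under child j);
# tiny negative d_k from cancellation is clamped, larger ones are bugs.
.plan_nu <- function(plan, x, clamp_tol = 1e-12) {
  nu <- numeric(length(plan$nodes))
  p <- numeric(length(plan$nodes))
  d <- numeric(length(plan$nodes))
  for (i in seq_along(plan$nodes)) {
    idx <- plan$node_tips[[i]]
    nk <- length(idx)
    qk <- .varn(x[idx])
    within <- 0
    for (cidx in plan$child_tips[[i]]) {
      if (length(cidx) > 1L)
        within <- within + length(cidx) / nk * .varn(x[cidx])
    }
    dk <- qk - within
    tol <- clamp_tol * max(1, abs(qk))
    if (dk < 0) {
      if (dk < -tol)
        stop("internal inconsistency: negative node diversity d_k = ", dk)
      dk <- 0
    }
    d[i] <- dk
    p[i] <- nk / plan$n
    nu[i] <- p[i] * dk
  }
  list(p = p, d = d, nu = nu)
}

#' Decompose trait diversity among the internal nodes of a phylogeny
#'
#' Partitions the quadratic entropy of the tip values additively among the
#' internal nodes. The contribution of node `k` is `nu_k = p_k * d_k`,
#' where `d_k` is the diversity in trait values among the clades descending
#' from `k` (the quadratic entropy of all tips under `k` minus the
#' size-weighted quadratic entropies within each child clade) and `p_k` is
#' the proportion of tips descending from `k`. The contributions telescope:
#' their sum equals the quadratic entropy of all tip values. On an enlarged
#' tree the tips under artificial nodes are populations, so those nodes
#' carry the intra-specific part of the diversity.
#'
#' @param tree A `phylo` or `enlarged_phylo`.
#' @param tip_values Named numeric vector: tip label -> trait value. Every
#'   tip must be covered.
#' @return Object of class `node_decomposition`: a data.frame with one row
#'   per internal node (`node`, `n_tips`, `p`, `d`, `nu`, `is_artificial`)
#'   and attributes `total` (the summed contributions) and `tree`.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' decompose_diversity(tr, c(A = 0, B = 2, C = 4, D = 6))
#' @export
decompose_diversity <- function(tree, tip_values) {
  artificial <- integer(0)
  if (inherits(tree, "enlarged_phylo")) {
    artificial <- tree$artificial_nodes
    tree <- tree$tree
  }
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L) stop("need at least 2 tips")
  if (is.null(names(tip_values)))
    stop("`tip_values` must be named by tip label")
  missing_tips <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing_tips))
    stop("missing trait values for tip(s): ",
         paste(missing_tips, collapse = ", "))
  x <- as.numeric(tip_values[tree$tip.label])
  if (any(!is.finite(x))) stop("tip values must be finite")

  plan <- .decomp_plan(tree)
  ev <- .plan_nu(plan, x)
  out <- data.frame(
    node = plan$nodes,
    n_tips = vapply(plan$node_tips, length, integer(1)),
    p = ev$p,
    d = ev$d,
    nu = ev$nu,
    is_artificial = plan$nodes %in% artificial
  )
  structure(out,
            total = sum(ev$nu),
            tree = tree,
            plan = plan,
            class = c("node_decomposition", "data.frame"))
}

#' Total diversity of a decomposition
#' @param dec A `node_decomposition`.
#' @return The sum of node contributions (equals the tips' quadratic entropy).
#' @export
total_diversity <- function(dec) {
  stopifnot(inherits(dec, "node_decomposition"))
  attr(dec, "total")
}

#' Intra-specific diversity statistic S_c
#'
#' The sum of node contributions `nu_k = p_k * d_k` over the artificial
#' (intra-specific) nodes. When the tip values are standardized to unit
#' total variance, `S_c` is the proportion of trait variance attributable
#' to intra-specific variation; it equals the within-species share of the
#' total sum of squares, with species weighted by their number of
#' populations.
#'
#' @param dec A `node_decomposition`.
#' @param artificial_nodes Node ids of the artificial nodes. Defaults to
#'   the ones flagged in `dec` (present when it was computed from an
#'   `enlarged_phylo`).
#' @return Object of class `sc_statistic`: list with `value` and
#'   `artificial_contributions` (named by node id).
#' @export
sc_statistic <- function(dec, artificial_nodes = NULL) {
  stopifnot(inherits(dec, "node_decomposition"))
  if (is.null(artificial_nodes)) {
    artificial_nodes <- dec$node[dec$is_artificial]
  }
  bad <- setdiff(artificial_nodes, dec$node)
  if (length(bad))
    stop("not internal nodes of the decomposition: ", paste(bad, collapse = ", "))
  sel <- dec$node %in% artificial_nodes
  contrib <- stats::setNames(dec$nu[sel], dec$node[sel])
  structure(list(value = sum(contrib), artificial_contributions = contrib),
            class = "sc_statistic")
}

#' @export
print.sc_statistic <- function(x, ...) {
  cat("S_c =", format(x$value), "(", length(x$artificial_contributions),
      "artificial node(s) )\n")
  invisible(x)
}

#' Skewness-to-root statistic S_3
#'
#' The contribution-weighted mean of the tipward depth ranks of the
#' internal nodes: `S_3 = sum_k (nu_k / total) * rank_k`, with ranks in
#' \[0, 1\] and 0 assigned to the most tip-distant (root-most) nodes (see
#' [depth_ranks()]). Small values indicate trait diversity concentrated at
#' root-ward nodes; values near 1 indicate diversity held by close-to-tip
#' nodes.
#'
#' @param dec A `node_decomposition`.
#' @param ranks A `depth_ranks` object covering every node with `nu > 0`.
#' @return Object of class `s3_statistic`: list with `value`.
#' @export
s3_statistic <- function(dec, ranks) {
  stopifnot(inherits(dec, "node_decomposition"))
  total <- attr(dec, "total")
  if (total <= 0)
    stop("undefined statistic: total diversity is 0")
  r <- as.numeric(ranks)[match(dec$node, names(ranks))]
  need <- dec$nu > 0
  if (any(need & is.na(r)))
    stop("missing depth rank for contributing node(s): ",
         paste(dec$node[need & is.na(r)], collapse = ", "))
  r[is.na(r)] <- 0  # zero-contribution nodes: rank irrelevant
  structure(list(value = sum(dec$nu / total * r)), class = "s3_statistic")
}

#' @export
print.s3_statistic <- function(x, ...) {
  cat("S_3 =", format(x$value), "\n")
  invisible(x)
}

#' Write a node decomposition as TSV
#'
#' One row per internal node with columns `node_id`, `clade_tips`
#' (comma-joined tip labels), `p`, `d`, `nu`, `is_artificial` and, when
#' `ranks` is supplied, `rank`.
#'
#' @param dec A `node_decomposition`.
#' @param path Output path.
#' @param ranks Optional `depth_ranks`.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(dec, path, ranks = NULL) {
  stopifnot(inherits(dec, "node_decomposition"))
  tree <- attr(dec, "tree")
  plan <- attr(dec, "plan")
  out <- data.frame(
    node_id = dec$node,
    clade_tips = vapply(plan$node_tips,
                        function(i) paste(tree$tip.label[i], collapse = ","),
                        character(1)),
    p = dec$p, d = dec$d, nu = dec$nu,
    is_artificial = dec$is_artificial
  )
  if (!is.null(ranks))
    out$rank <- as.numeric(ranks)[match(out$node_id, names(ranks))]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
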