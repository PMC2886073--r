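#' Parse a Newick string into a branch-length-free phylogeny
#'
#' Reads a rooted phylogeny in Newick format and returns an [ape::phylo]
#' object carrying topology and tip labels only. The trees this package
#' works with are classifications without branch lengths; any branch
#' lengths present in the input are discarded with a warning and no
#' downstream computation ever reads them. Unary (single-child) internal
#' nodes are suppressed, tip labels are trimmed of surrounding whitespace,
#' and duplicate tip labels are rejected.
#'
#' @param text Newick string (semicolon-terminated). Exactly one tree.
#' @param file Optionally, path to a file containing the Newick string
#'   (mutually exclusive with `text`).
#' @return An object of class `phylo` with no `edge.length` component.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("`text` must be a single non-empty character string")
  .check_newick_syntax(text)
  tr <- withCallingHandlers(
    ape::read.tree(text = text),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(tr))
    stop("malformed Newick string: could not be parsed")
  if (inherits(tr, "multiPhylo"))
    stop("expected exactly one tree, found ", length(tr))
  if (!is.null(tr$edge.length)) {
    warning("branch lengths present in input; discarded (trees are treated as branch-length-free)")
    tr$edge.length <- NULL
  }
  tr$tip.label <- trimws(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- trimws(tr$node.label)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tr$tip.label)))
    stop("empty tip label found")
  if (ape::Ntip(tr) < 2L)
    stop("a tree must have at least 2 tips (single-tip trees carry no internal structure)")
  tr <- ape::collapse.singles(tr)
  tr
}

# Cheap structural pre-check so that the common malformations are reported
# with a character position; ape's own parser is the authority otherwise.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick string: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L)
    stop("malformed Newick string: ", depth, " unclosed '(' (first at position ",
         which(chars == "(")[1], ")")
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick string: missing terminating ';' at position ",
         nchar(text))
  invisible(TRUE)
}

#' Write a phylogeny as a Newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if given the string is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Prune a phylogeny to a set of tips
#'
#' Keeps exactly the named tips, suppressing the internal nodes left with a
#' single child so that the relative topology among the kept tips is
#' preserved. Mirrors the usual step of cutting a large classification down
#' to the species for which trait data exist.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo`.
#' @examples
#' tr <- parse_newick("((A,B),(C,(D,E)));")
#' write_newick(prune_to_taxa(tr, c("A", "C", "D")))
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(trimws(as.character(keep)))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L)
    stop("at least 2 tips must be kept, got ", length(keep))
  pruned <- ape::keep.tip(tree, keep)
  pruned$edge.length <- NULL
  pruned
}

.escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Graft within-species replicates as virtual sister-taxa
#'
#' For every species with two or more replicate measurements, the species
#' tip is replaced in place by an artificial internal node whose children
#' are one virtual tip per replicate (population). Species with a single
#' replicate remain ordinary tips. The artificial nodes are the carriers of
#' intra-specific diversity in the decomposition.
#'
#' @param tree A `phylo` whose tips are species names.
#' @param replicates Named list: species name -> character vector of virtual
#'   tip labels (one per population). Species with one label are left as
#'   ordinary tips (label unchanged). All listed species must be tips of
#'   `tree`; the virtual labels must be globally unique.
#' @return An object of class `enlarged_phylo`: a list with components
#'   `tree` (the enlarged `phylo`), `artificial_nodes` (named integer
#'   vector of node ids, names = species), and `species_of_tip` (named
#'   character vector mapping every tip label of the enlarged tree to its
#'   species).
#' @examples
#' tr <- parse_newick("(A,B);")
#' enl <- enlarge_with_replicates(tr, list(A = c("a1", "a2", "a3")))
#' write_newick(enl$tree)
#' @export
enlarge_with_replicates <- function(tree, replicates) {
  stopifnot(inherits(tree, "phylo"))
  if (length(replicates) == 0L || is.null(names(replicates))) {
    replicates <- stats::setNames(list(), character(0))
  }
  if (any(!nzchar(names(replicates))))
    stop("`replicates` must be a fully named list (species -> population labels)")
  bad <- names(replicates)[lengths(replicates) == 0L]
  if (length(bad))
    stop("empty replicate list for species: ", paste(bad, collapse = ", "))
  missing_sp <- setdiff(names(replicates), tree$tip.label)
  if (length(missing_sp))
    stop("replicated species not found among tips: ",
         paste(missing_sp, collapse = ", "))
  multi <- names(replicates)[lengths(replicates) >= 2L]
  all_new <- unlist(replicates[multi], use.names = FALSE)
  reserved <- grepl("[():,;\\[\\]]", all_new)
  if (any(reserved))
    stop("virtual tip labels contain Newick-reserved characters: ",
         paste(unique(all_new[reserved]), collapse = ", "))
  untouched <- setdiff(tree$tip.label, multi)
  labels_after <- c(untouched, all_new)
  if (anyDuplicated(labels_after)) {
    dup <- unique(labels_after[duplicated(labels_after)])
    stop("virtual tip labels collide with existing labels: ",
         paste(dup, collapse = ", "))
  }

  nwk <- ape::write.tree(tree)
  for (sp in multi) {
    sub <- paste0("(", paste(replicates[[sp]], collapse = ","), ")")
    pat <- paste0("(?<=[(,])", .escape_regex(sp), "(?=[,);])")
    stopifnot(grepl(pat, nwk, perl = TRUE))
    nwk <- sub(pat, sub, nwk, perl = TRUE)
  }
  enl <- ape::read.tree(text = nwk)
  enl$edge.length <- NULL

  art <- integer(0)
  if (length(multi)) {
    art <- vapply(multi, function(sp) ape::getMRCA(enl, replicates[[sp]]),
                  integer(1))
  }
  species_of_tip <- stats::setNames(enl$tip.label, enl$tip.label)
  for (sp in multi) species_of_tip[replicates[[sp]]] <- sp
  for (sp in setdiff(names(replicates), multi)) {
    # single-replicate species keep their tip; it still belongs to sp
    species_of_tip[sp] <- sp
  }
  structure(
    list(tree = enl, artificial_nodes = art, species_of_tip = species_of_tip),
    class = "enlarged_phylo"
  )
}

#' @export
print.enlarged_phylo <- function(x, ...) {
  cat("Enlarged phylogeny:", ape::Ntip(x$tree), "tips,",
      x$tree$Nnode, "internal nodes,",
      length(x$artificial_nodes), "artificial node(s)\n")
  if (length(x$artificial_nodes))
    cat("  replicated species:", paste(names(x$artificial_nodes), collapse = ", "), "\n")
  invisible(x)
}

#' Collapse the artificial nodes of an enlarged tree back to species tips
#'
#' Inverse of [enlarge_with_replicates()]: every artificial node is replaced
#' by a single tip labelled with its species name.
#'
#' @param enlarged An `enlarged_phylo`.
#' @return A `phylo` whose tips are species.
#' @export
collapse_artificial <- function(enlarged) {
  stopifnot(inherits(enlarged, "enlarged_phylo"))
  tr <- enlarged$tree
  for (sp in names(enlarged$artificial_nodes)) {
    reps <- names(enlarged$species_of_tip)[enlarged$species_of_tip == sp]
    keep1 <- reps[1]
    tr <- ape::drop.tip(tr, setdiff(reps, keep1), collapse.singles = TRUE)
    tr$tip.label[tr$tip.label == keep1] <- sp
  }
  tr$edge.length <- NULL
  tr
}

# max edge-count distance from each node to its descendant tips
.node_tip_depths <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  depth <- numeric(n + m)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    chi <- po$edge[e, 2]
    depth[par] <- max(depth[par], depth[chi] + 1)
  }
  depth
}

# tip indices (of `tree`) under every node, as a list indexed by node id
.tips_under <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  under <- vector("list", n + m)
  for (i in seq_len(n)) under[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    chi <- po$edge[e, 2]
    under[[par]] <- c(under[[par]], under[[chi]])
  }
  under
}

#' Tip-distance ranks of internal nodes, measured on a reference tree
#'
#' Internal nodes of an enlarged (or plain) tree are ordered by their
#' topological distance to the tips *in a reference classification* (for
#' the motivating application: the complete tree from which the analysis
#' tree was pruned). The depth of a node is the maximum edge-count distance
#' to any of its descendant tips in the reference tree, taken at the
#' reference node spanning the same species. Nodes are ranked by decreasing
#' depth (average ranks for ties) and mapped affinely onto \[0, 1\]: 0 for
#' the deepest (most tip-distant, root-most) node, 1 for the shallowest.
#' Artificial nodes sit below original species tips and receive rank 1 by
#' convention. Measuring depth on the reference tree avoids artefacts of
#' unbalanced pruning.
#'
#' @param reference A `phylo`: the reference classification. Its tips must
#'   include every species spanned by the analysis tree.
#' @param enlarged An `enlarged_phylo` (or a plain `phylo`, in which case
#'   there are no artificial nodes and tips are their own species).
#' @return Object of class `depth_ranks`: a numeric vector of ranks in
#'   \[0, 1\] named by internal node id of the analysis tree, with the raw
#'   reference depths in `attr(, "depth")`.
#' @export
depth_ranks <- function(reference, enlarged) {
  stopifnot(inherits(reference, "phylo"))
  if (inherits(enlarged, "phylo")) {
    enlarged <- structure(
      list(tree = enlarged,
           artificial_nodes = integer(0),
           species_of_tip = stats::setNames(enlarged$tip.label, enlarged$tip.label)),
      class = "enlarged_phylo"
    )
  }
  stopifnot(inherits(enlarged, "enlarged_phylo"))
  tr <- enlarged$tree
  n <- ape::Ntip(tr)
  nodes <- (n + 1L):(n + tr$Nnode)
  ref_depth <- .node_tip_depths(reference)
  under <- .tips_under(tr)
  is_art <- nodes %in% enlarged$artificial_nodes

  depth <- rep(NA_real_, length(nodes))
  for (i in seq_along(nodes)) {
    if (is_art[i]) next
    sp <- unique(unname(enlarged$species_of_tip[tr$tip.label[under[[nodes[i]]]]]))
    missing_sp <- setdiff(sp, reference$tip.label)
    if (length(missing_sp))
      stop("internal node ", nodes[i], " cannot be mapped to the reference tree; ",
           "species absent: ", paste(missing_sp, collapse = ", "))
    ref_node <- if (length(sp) >= 2L) ape::getMRCA(reference, sp)
                else match(sp, reference$tip.label)
    depth[i] <- ref_depth[ref_node]
  }

  rk <- rep(NA_real_, length(nodes))
  ord <- which(!is_art)
  if (length(ord)) {
    r <- rank(-depth[ord], ties.method = "average")
    if (max(r) > min(r)) {
      rk[ord] <- (r - min(r)) / (max(r) - min(r))
    } else {
      rk[ord] <- 0  # single depth class: treat as deepest
    }
  }
  rk[is_art] <- 1
  structure(stats::setNames(rk, nodes), depth = stats::setNames(depth, nodes),
            class = "depth_ranks")
}

#' @export
print.depth_ranks <- function(x, ...) {
  cat("Depth ranks for", length(x), "internal nodes (0 = most tip-distant):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
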