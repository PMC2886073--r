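# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct variance
# algebra, and naive recursion.

# all permutations of 1..n as a matrix (n! rows); recursion, no packages
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# divisor-n variance, written out
varn_oracle <- function(x) sum((x - sum(x) / length(x))^2) / length(x)

# quadratic entropy by literal double sum over pairs
qe_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + (x[i] - x[j])^2 / 2
  s / n^2
}

# within-species share of the total sum of squares, straight from a
# grouping vector -- the tree-free S_c oracle
within_share_oracle <- function(values, species) {
  groups <- split(values, species)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  sst <- sum((values - mean(values))^2)
  ssw / sst
}

# random rooted tree with polytomies: collapse random internal edges of a
# random binary topology
random_polytomy_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rcoal(n)
    tr$edge.length <- rep(1, nrow(tr$edge))
    internal <- which(tr$edge[, 2] > ape::Ntip(tr))
    if (length(internal)) {
      zap <- internal[stats::runif(length(internal)) < 0.3]
      tr$edge.length[zap] <- 0
      tr <- ape::di2multi(tr, tol = 0.5)
    }
    tr$edge.length <- NULL
    tr$tip.label <- sprintf("t%02d", seq_len(ape::Ntip(tr)))
    tr
  })
}

# exact permutation-test p-values by full enumeration (identity included)
exact_perm_p_sc <- function(enlarged, tip_values, tail = "less") {
  x <- as.numeric(tip_values[enlarged$tree$tip.label])
  sp <- enlarged$species_of_tip[enlarged$tree$tip.label]
  stat <- function(v) within_share_oracle(v, sp)
  obs <- stat(x)
  P <- all_perms(length(x))
  stats <- apply(P, 1, function(p) stat(x[p]))
  if (tail == "less") mean(stats <= obs + 1e-12) else mean(stats >= obs - 1e-12)
}

exact_perm_p_cmean <- function(tree, species_values) {
  x <- as.numeric(species_values[tree$tip.label])
  obs <- abouheif_cmean(tree, stats::setNames(x, tree$tip.label))
  P <- all_perms(length(x))
  stats <- apply(P, 1, function(p)
    abouheif_cmean(tree, stats::setNames(x[p], tree$tip.label)))
  mean(stats >= obs - 1e-12)
}

# standardized tip values of a scenario (S_c share scale)
scenario_z <- function(sc) {
  stats::setNames(standardize(sc$tip_values)$scaled, names(sc$tip_values))
}
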