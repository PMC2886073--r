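test_that("conservation test agrees with exhaustive enumeration", {
  enl <- enlarge_with_replicates(parse_newick("(A,(C,D));"),
                                 list(A = c("a1", "a2")))
  z <- setNames(standardize(c(0, 2, 4, 6))$scaled, c("a1", "a2", "C", "D"))
  # only the unordered pair landing under the artificial node matters:
  # pair variances {1,4,9,1,4,1}/10, so Pr(S_c <= obs) = 3/6
  p_exact <- exact_perm_p_sc(enl, z)
  expect_equal(p_exact, 0.5)

  res <- conservation_test(enl, z, n_perm = 2000, seed = 42)
  expect_equal(res$alternative, "less")
  expect_equal(res$n_perm, 2000)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 2001)

  # determinism: same seed, same inputs -> identical result
  res2 <- conservation_test(enl, z, n_perm = 2000, seed = 42)
  expect_identical(res$null_sample, res2$null_sample)
  expect_identical(res$p_value, res2$p_value)

  # left-tail boundary: observed at the attainable minimum keeps p at the
  # smallest value the tie structure allows, never 0
  zmin <- setNames(standardize(c(0, 0.1, 4, -6))$scaled, c("a1", "a2", "C", "D"))
  resb <- conservation_test(enl, zmin, n_perm = 500, seed = 1)
  expect_gte(resb$p_value, 1 / 501)
  expect_equal(resb$p_value,
               (sum(resb$null_sample <= resb$observed + 1e-12) + 1) / 501)

  expect_error(conservation_test(enl, z, n_perm = 0, seed = 1), "n_perm")
  plain <- enlarge_with_replicates(parse_newick("((A,B),(C,D));"), list())
  expect_error(conservation_test(plain, c(A = 1, B = 2, C = 3, D = 4),
                                 seed = 1),
               "no artificial nodes")
})

test_that("skewness-to-root test doubles the smaller tail, capped at 1", {
  # diversity forced entirely to the root (subtrees internally constant):
  # observed S_3 = 0 and the lower tail is extreme once the tree is large
  # enough that permutations rarely re-sort the two blocks
  bal <- ape::stree(16, type = "balanced")
  bal$edge.length <- NULL
  rk16 <- depth_ranks(bal, bal)
  zb <- setNames(rep(c(-1, 1), each = 8), bal$tip.label)
  res <- skewness_to_root_test(bal, zb, rk16, n_perm = 199, seed = 5)
  expect_equal(res$observed, 0)
  expect_equal(res$alternative, "two-sided")
  expect_lte(res$p_value, 0.05)

  # the reported p is exactly the doubled smaller tail from the null sample
  sc <- simulate_scenario(n_species = 8, n_populations = 3,
                          within_share = 0.4, seed = 77)
  zz <- scenario_z(sc)
  rks <- depth_ranks(sc$species_tree, sc$enlarged)
  r2 <- skewness_to_root_test(sc$enlarged, zz, rks, n_perm = 299, seed = 9)
  p_low <- (sum(r2$null_sample <= r2$observed + 1e-12) + 1) / (r2$n_perm + 1)
  p_high <- (sum(r2$null_sample >= r2$observed - 1e-12) + 1) / (r2$n_perm + 1)
  expect_equal(r2$p_value, min(1, 2 * min(p_low, p_high)))
  r3 <- skewness_to_root_test(sc$enlarged, zz, rks, n_perm = 299, seed = 9)
  expect_identical(r2$null_sample, r3$null_sample)

  tr4 <- parse_newick("((A,B),(C,D));")
  expect_error(skewness_to_root_test(tr4, c(A = 1, B = 1, C = 1, D = 1),
                                     depth_ranks(tr4, tr4),
                                     n_perm = 99, seed = 1),
               "total diversity is 0")
})

test_that("abouheif C_mean matches hand computations and closed forms", {
  tr <- parse_newick("((A,B),(C,D));")
  # within-cherry proximity 1/2, cross 1/8 -> C_mean = 2/15
  expect_equal(abouheif_cmean(tr, c(A = 0, B = 2, C = 4, D = 6)), 2 / 15)

  # breaking cherry concordance lowers the statistic
  c_disc <- abouheif_cmean(tr, c(A = 0, B = 6, C = 2, D = 4))
  expect_lt(c_disc, 2 / 15)

  # star tree: all proximities equal -> Moran's I closed form -1/(n-1)
  for (n in c(4, 6, 9)) {
    star <- parse_newick(paste0("(", paste0("t", 1:n, collapse = ","), ");"))
    vals <- setNames(withr::with_seed(n, rnorm(n)), paste0("t", 1:n))
    expect_equal(abouheif_cmean(star, vals), -1 / (n - 1), tolerance = 1e-12)
  }

  expect_error(abouheif_cmean(tr, c(A = 1, B = 1, C = 1, D = 1)), "constant")
  expect_error(abouheif_cmean(parse_newick("(A,B);"), c(A = 1, B = 2)),
               "at least 3")
})

test_that("abouheif permutation test is upper-tailed, exact-consistent, reproducible", {
  tr <- parse_newick("((A,B),((C,D),E));")
  vals <- c(A = 0.1, B = 0.3, C = 2.2, D = 2.5, E = 1.9)
  p_exact <- exact_perm_p_cmean(tr, vals)
  res <- abouheif_test(tr, vals, n_perm = 2000, seed = 11)
  expect_equal(res$alternative, "greater")
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 2001)
  res2 <- abouheif_test(tr, vals, n_perm = 2000, seed = 11)
  expect_identical(res$null_sample, res2$null_sample)
})

test_that("abouheif test has power for clade-clustered traits", {
  # 32-tip balanced tree; tips within each size-4 subtree share a mean
  bal <- ape::stree(32, type = "balanced")
  bal$edge.length <- NULL
  rej <- withr::with_seed(123, {
    vapply(1:100, function(i) {
      mu <- rep(rnorm(8), each = 4)
      vals <- setNames(mu + rnorm(32, sd = 0.2), bal$tip.label)
      abouheif_test(bal, vals, n_perm = 199, seed = 20000 + i)$p_value
    }, numeric(1))
  })
  expect_gte(mean(rej <= 0.05), 0.95)
})

test_that("permutation tests hold their nominal level under exchangeability", {
  # S_3 type-I at alpha = 0.05; conservation and abouheif are covered by
  # the acceptance suite at full replication
  tr <- simulate_yule_topology(10, seed = 31)
  enl <- enlarge_with_replicates(
    tr, setNames(lapply(tr$tip.label[1:4], function(s) paste0(s, "@p", 1:3)),
                 tr$tip.label[1:4]))
  rks <- depth_ranks(tr, enl)
  labs <- enl$tree$tip.label
  # permutation seeds drawn from the outer stream, not sequential constants
  pvals <- withr::with_seed(99, {
    vapply(1:400, function(i) {
      z <- setNames(rnorm(length(labs)), labs)
      skewness_to_root_test(enl, z, rks, n_perm = 199,
                            seed = sample.int(2^31 - 2, 1))$p_value
    }, numeric(1))
  })
  rate <- mean(pvals <= 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("conservation test gains power as the within-species share shrinks", {
  pvals <- vapply(1:200, function(i) {
    sc <- simulate_scenario(n_species = 15, n_populations = 4,
                            within_share = 0.02, seed = 60000 + i)
    conservation_test(sc$enlarged, scenario_z(sc), n_perm = 199,
                      seed = 70000 + i)$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.8)
})

test_that("hochberg adjustment reproduces step-up arithmetic and monotonicity", {
  expect_equal(hochberg_adjust(c(0.01, 0.02, 0.30)), c(0.03, 0.04, 0.30))
  expect_equal(hochberg_adjust(0.2), 0.2)
  expect_equal(hochberg_adjust(rep(1, 4)), rep(1, 4))
  expect_error(hochberg_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  for (seed in 1:20) {
    p <- withr::with_seed(seed, runif(sample(2:10, 1)))
    adj <- hochberg_adjust(p)
    expect_true(all(adj >= p))               # never decreases
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order preserved
    expect_true(all(adj <= 1))
  }
})

test_that("test results serialize to JSON with their metadata", {
  tr <- parse_newick("((A,B),((C,D),E));")
  res <- abouheif_test(tr, c(A = 0, B = 1, C = 5, D = 6, E = 3),
                       n_perm = 99, seed = 2)
  path <- tempfile(fileext = ".json")
  write_test_json(res, path, p_adjusted = min(1, res$p_value * 3))
  out <- jsonlite::read_json(path)
  expect_equal(out$statistic_name, "C_mean")
  expect_equal(out$n_perm, 99)
  expect_equal(out$seed, 2)
  expect_equal(out$p_value, res$p_value)
  expect_equal(out$p_adjusted, min(1, res$p_value * 3))
})
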