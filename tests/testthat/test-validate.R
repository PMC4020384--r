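test_that("site pattern enumeration is lexicographic and complete", {
  nt <- state_space("nucleotide")
  p3 <- enumerate_site_patterns(3, nt)
  expect_equal(nrow(p3), 64)
  p2aa <- enumerate_site_patterns(2, state_space("amino_acid"))
  expect_equal(nrow(p2aa), 400)
  p4 <- enumerate_site_patterns(4, nt)
  expect_equal(nrow(p4), 256)
  expect_equal(rownames(p4)[1], "AAAA")
  expect_equal(rownames(p4)[256], "TTTT")
  expect_error(enumerate_site_patterns(4, state_space("codon")), "cap")
})

test_that("pruning probabilities obey limits and normalize", {
  tr0 <- parse_tree("((A:0,B:0):0,C:0);")
  expect_equal(pattern_probability(tr0, hky(1), "AAA"), 0.25,
               tolerance = 1e-12)
  expect_equal(pattern_probability(tr0, hky(1), "AAC"), 0, tolerance = 1e-12)

  set.seed(19)
  tr <- tree3()
  pats <- enumerate_site_patterns(3, state_space("nucleotide"))
  for (spec in list(hky(4), rand_gtr(), tn93(3, 7, c(.2, .3, .1, .4)))) {
    pr <- pattern_probability(tr, spec, pats, site_rate_model(0.7, 4, 0.2))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(sum(pr), 1, tolerance = 1e-8)
  }
})

test_that("pruning equals the exhaustive summation oracle", {
  tr <- tree3()
  Q <- build_rate_matrix(hky(4))
  # brute force: sum over root and internal states of pi * product of P entries
  P_ab <- transition_probabilities(Q, 0.3)   # internal -> A and B
  P_i <- transition_probabilities(Q, 0.2)    # root -> internal
  P_c <- transition_probabilities(Q, 0.5)    # root -> C
  brute <- function(a, b, c) {
    tot <- 0
    for (r in 1:4) for (i in 1:4) {
      tot <- tot + 0.25 * P_i[r, i] * P_ab[i, a] * P_ab[i, b] * P_c[r, c]
    }
    tot
  }
  pats <- enumerate_site_patterns(3, Q$space)
  pr <- pattern_probability(tr, Q, pats)
  idx <- matrix(match(pats, Q$space$states), ncol = 3)
  oracle <- mapply(brute, idx[, 1], idx[, 2], idx[, 3])
  expect_lt(max(abs(pr - oracle)), 1e-10)
})

test_that("pruning matches phangorn likelihoods on a 4-taxon tree", {
  tr <- parse_tree("((A:0.2,B:0.35):0.15,(C:0.4,D:0.1):0.2);")
  kappa <- 4; shape <- 0.5
  Q <- build_rate_matrix(hky(kappa))
  pats <- enumerate_site_patterns(4, Q$space)
  pr <- pattern_probability(tr, Q, pats, site_rate_model(shape, 4))

  # independent route: phangorn's pml on an alignment holding each pattern once
  m <- t(pats)
  rownames(m) <- c("A", "B", "C", "D")
  dat <- phangorn::phyDat(m, type = "DNA")
  phy <- ape::unroot(tr$phy)
  fit <- phangorn::pml(phy, dat, bf = rep(0.25, 4),
                       Q = c(1, kappa, 1, 1, kappa, 1), k = 4, shape = shape)
  expect_equal(as.numeric(stats::logLik(fit)), sum(log(pr)), tolerance = 1e-4)
})

test_that("marginalizing one tip reduces to the smaller tree", {
  Q <- build_rate_matrix(gtr(1:6, c(.1, .2, .3, .4)))
  tr <- tree3()
  pats2 <- enumerate_site_patterns(2, Q$space)
  # sum over C of P(a, b, c) vs 2-tip tree (A:0.3,B:0.3) below a stationary root
  tr2 <- parse_tree("(A:0.3,B:0.3);")
  for (k in sample(nrow(pats2), 4)) {
    a <- pats2[k, 1]; b <- pats2[k, 2]
    full <- sum(pattern_probability(
      tr, Q, cbind(rep(a, 4), rep(b, 4), Q$space$states)))
    reduced <- pattern_probability(tr2, Q, c(a, b))
    expect_equal(full, reduced, tolerance = 1e-8)
  }
})

test_that("chi-squared goodness of fit pools small cells and matches hand values", {
  exact <- chisq_goodness_of_fit(c(30, 30, 40), c(0.3, 0.3, 0.4))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 1)

  g <- chisq_goodness_of_fit(c(60, 40), c(0.5, 0.5))
  expect_equal(g$statistic, 4)
  expect_equal(g$df, 1)
  expect_equal(g$p_value, 0.04550026, tolerance = 1e-6)

  # cells with expected < 5 are pooled into one class
  gp <- chisq_goodness_of_fit(c(50, 46, 3, 1), c(0.5, 0.46, 0.03, 0.01))
  expect_equal(gp$n_classes, 3)
  expect_error(chisq_goodness_of_fit(c(3, 1), c(0.75, 0.25)), "2 classes")
})

test_that("mean pairwise amino-acid distance handles gaps and errors", {
  expect_equal(mean_pairwise_aa_distance(c(a = "MKLV", b = "MKLV")), 0)
  expect_equal(mean_pairwise_aa_distance(c(a = "MKMK", b = "MKAA")), 0.5)
  expect_equal(mean_pairwise_aa_distance(c(a = "M-KK", b = "MAKA")), 1 / 3)
  # a fully gapped pair is excluded; remaining pairs still count
  expect_equal(mean_pairwise_aa_distance(c(a = "M---", b = "-AAA", c = "MAAA")),
               mean(c(0, 0)))
  expect_error(mean_pairwise_aa_distance(c(a = "M-", b = "-A")), "comparable")
})
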