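test_that("HKY reduces to Jukes-Cantor and carries the ts/tv bias", {
  Q <- build_rate_matrix(hky(1))
  off <- Q$Q[row(Q$Q) != col(Q$Q)]
  expect_equal(off, rep(1 / 3, 12), tolerance = 1e-12)

  Q4 <- build_rate_matrix(hky(4))
  expect_equal(Q4$Q["A", "G"] / Q4$Q["A", "C"], 4, tolerance = 1e-12)
  expect_equal(Q4$Q["C", "T"] / Q4$Q["C", "G"], 4, tolerance = 1e-12)
})

test_that("generators are normalized and rows sum to zero", {
  specs <- list(hky(4), tn93(2, 5), gtr(1:6, freq = c(.1, .2, .3, .4)),
                gy94(0.3, 2), mg94(1, 0.4, kappa = 3),
                empirical_aa("WAG"))
  for (s in specs) {
    Q <- build_rate_matrix(s)
    expect_lt(max(abs(rowSums(Q$Q))), 1e-10)
    expect_equal(-sum(Q$freq * diag(Q$Q)), 1, tolerance = 1e-10)
    expect_true(all(Q$Q[row(Q$Q) != col(Q$Q)] >= 0))
  }
})

test_that("codon models obey the single-position change structure", {
  cs <- state_space("codon")
  expect_equal(cs$size, 61)
  Q1 <- build_rate_matrix(gy94(omega = 1, kappa = 1))
  # all allowed single-position changes share one rate under omega=kappa=1
  expect_equal(Q1$Q["AAA", "ACA"], Q1$Q["AAA", "AGA"], tolerance = 1e-12)
  # multi-position changes are forbidden for any parameters
  Qx <- build_rate_matrix(gy94(omega = 7, kappa = 3))
  expect_identical(Qx$Q["AAA", "ACC"], 0)
  # omega scales nonsynonymous (AAA lys -> ACA thr), not synonymous (AAA -> AAG lys)
  Qw <- build_rate_matrix(gy94(omega = 0.5, kappa = 1))
  raw_ratio <- (Qw$Q["AAA", "ACA"] / Qw$Q["AAA", "AAG"]) /
    (Q1$Q["AAA", "ACA"] / Q1$Q["AAA", "AAG"])
  expect_equal(raw_ratio, 0.5, tolerance = 1e-12)
  # MG94 targets nucleotide frequencies, not codon frequencies
  Qm <- build_rate_matrix(mg94(alpha = 1, beta = 0.5,
                               nuc_freq = c(.1, .2, .3, .4)))
  expect_identical(Qm$Q["AAA", "ACC"], 0)
  expect_equal(Qm$Q["AAA", "AAC"] / Qm$Q["AAA", "AAG"],
               (0.5 * 0.2) / (1 * 0.3), tolerance = 1e-12)
})

test_that("transition probabilities match closed forms and a series oracle", {
  Q <- build_rate_matrix(hky(1))
  expect_equal(transition_probabilities(Q, 0), diag(4),
               ignore_attr = TRUE)
  P <- transition_probabilities(Q, 0.1)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-0.4 / 3), tolerance = 1e-10)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)

  set.seed(5)
  R <- rand_sparse_general(5)
  Qg <- build_rate_matrix(general_ctmc(R))
  Pg <- transition_probabilities(Qg, 0.7)
  expect_lt(max(abs(Pg - expm_series(Qg$Q * 0.7))), 1e-8)
  expect_error(transition_probabilities(Q, -1), "distance")
})

test_that("Chapman-Kolmogorov holds for random models and distances", {
  set.seed(17)
  for (rep in 1:5) {
    Q <- build_rate_matrix(rand_gtr())
    d <- stats::runif(2, 0.05, 2)
    lhs <- transition_probabilities(Q, sum(d))
    rhs <- transition_probabilities(Q, d[1]) %*%
      transition_probabilities(Q, d[2])
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
  Qg <- build_rate_matrix(general_ctmc(rand_sparse_general(4)))
  lhs <- transition_probabilities(Qg, 1.1)
  rhs <- transition_probabilities(Qg, 0.4) %*% transition_probabilities(Qg, 0.7)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("detailed balance holds for reversible families", {
  set.seed(23)
  specs <- list(hky(4, c(.1, .2, .3, .4)), tn93(2, 6, c(.4, .1, .3, .2)),
                rand_gtr(), gy94(0.2, 3), empirical_aa("LG"))
  for (s in specs) {
    Q <- build_rate_matrix(s)
    F <- Q$freq * Q$Q           # pi_i q_ij
    expect_lt(max(abs(F - t(F))), 1e-10)
  }
})

test_that("model family reductions agree", {
  f <- c(.15, .35, .3, .2)
  expect_equal(build_rate_matrix(tn93(3.2, 3.2, f))$Q,
               build_rate_matrix(hky(3.2, f))$Q, tolerance = 1e-12)
  # GTR with unit exchangeabilities = frequency-only (F81-like) model
  Q <- build_rate_matrix(gtr(rep(1, 6), f))$Q
  for (j in 1:4) expect_equal(diff(range(Q[-j, j])), 0, tolerance = 1e-12)
})

test_that("stationary distributions are recovered", {
  expect_equal(unname(stationary_distribution(build_rate_matrix(hky(1)))),
               rep(0.25, 4), tolerance = 1e-10)
  f <- c(.1, .2, .3, .4)
  expect_equal(unname(stationary_distribution(build_rate_matrix(gtr(1:6, f)))),
               f, tolerance = 1e-8)
  # non-reversible 3-state cycle: cross-check against long-time behaviour
  R <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  R[1, 2] <- 1; R[2, 3] <- 2; R[3, 1] <- 4
  Q <- build_rate_matrix(general_ctmc(R))
  pi <- stationary_distribution(Q)
  expect_lt(max(abs(as.vector(pi %*% Q$Q))), 1e-10)
  Pinf <- transition_probabilities(Q, 500)
  expect_equal(unname(Pinf[1, ]), unname(pi), tolerance = 1e-8)
})

test_that("reducible generators are reported with unreachable states", {
  R <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  R[1, 2] <- R[2, 1] <- 1      # block {a,b}
  R[3, 4] <- R[4, 3] <- 1      # block {c,d}
  Q <- build_rate_matrix(general_ctmc(R, freq = rep(0.25, 4)))
  expect_error(stationary_distribution(Q), "reducible")
})

test_that("empirical amino-acid matrices load with published frequencies", {
  for (nm in c("Dayhoff", "JTT", "BLOSUM62", "WAG", "LG")) {
    Q <- build_rate_matrix(empirical_aa(nm))
    expect_equal(dim(Q$Q), c(20, 20))
    expect_equal(sum(Q$freq), 1, tolerance = 1e-9)
    expect_equal(unname(stationary_distribution(Q)), unname(Q$freq),
                 tolerance = 1e-8)
  }
  # frequency override changes the build frequencies
  Qu <- build_rate_matrix(empirical_aa("LG", freq = rep(0.05, 20)))
  expect_equal(unname(Qu$freq), rep(0.05, 20))
})

test_that("paml-style rate files round-trip the exchange matrix", {
  dat <- evosim:::.empirical_aa_data("WAG")
  tf <- tempfile(fileext = ".dat")
  s <- dat$exchangeabilities
  lines <- vapply(2:20, function(i) {
    paste(format(s[i, 1:(i - 1)], digits = 10), collapse = " ")
  }, character(1))
  writeLines(c(lines, "", paste(format(dat$freq, digits = 10), collapse = " ")),
             tf)
  got <- read_paml_rates(tf)
  expect_equal(got$exchangeabilities, s, tolerance = 1e-8)
  expect_equal(got$freq, dat$freq, tolerance = 1e-8)
})

test_that("invalid specifications fail loudly", {
  expect_error(build_rate_matrix(hky(2, freq = c(.5, .5))), "length")
  expect_error(hky(-1), "kappa")
  expect_error(gtr(1:5), "6 non-negative")
  expect_error(general_ctmc(matrix(0, 3, 3)), "all-zero")
  expect_error(build_rate_matrix(gy94(1), state_space("nucleotide")),
               "state space")
})
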