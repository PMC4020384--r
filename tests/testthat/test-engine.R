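test_that("root sequences follow the equilibrium distribution", {
  expect_equal(sample_root_sequence(c(1, 0, 0, 0), 5), rep(1L, 5))

  set.seed(9)
  Qjc <- build_rate_matrix(hky(1))
  s <- sample_root_sequence(Qjc, 100000)
  for (i in 1:4) {
    expect_lt(abs(mean(s == i) - 0.25), 3 * sqrt(0.25 * 0.75 / 100000))
  }

  # explicit root sequences pass through verbatim, bad states error
  tr <- parse_tree("(A:1,B:1);")
  p <- partition(4, tr, hky(1), root_sequence = "ACGT")
  expect_equal(p$root_sequence, 1:4)
  expect_error(partition(4, tr, hky(1), root_sequence = "ACGX"), "alphabet")
})

test_that("zero-length branches copy the parent sequence", {
  tr <- parse_tree("((A:0,B:0):0,C:0);")
  sim <- simulate_partition(partition(200, tr, hky(4)))
  root <- sim$states[4, ]
  for (node in c(1, 2, 3, 5)) expect_equal(sim$states[node, ], root)
})

test_that("long branches saturate to the stationary distribution", {
  set.seed(12)
  tr <- parse_tree("(A:25,B:25);")           # tip-to-tip distance 50
  aln <- simulate_alignment(partition(20000, tr, hky(1)), seed = 4)
  m <- as.matrix(aln)
  expect_lt(abs(mean(m[1, ] == m[2, ]) - 0.25),
            3 * sqrt(0.25 * 0.75 / 20000))

  # simulating from equilibrium stays at equilibrium (single branch, d=100)
  f <- c(.1, .2, .3, .4)
  tr1 <- parse_tree("(A:100,B:0);")
  aln1 <- simulate_alignment(partition(30000, tr1, gtr(rep(1, 6), f)), seed = 5)
  tipA <- strsplit(aln1$seqs[["A"]], "")[[1]]
  for (i in 1:4) {
    expect_lt(abs(mean(tipA == c("A", "C", "G", "T")[i]) - f[i]),
              3 * sqrt(f[i] * (1 - f[i]) / 30000))
  }
})

test_that("simulated pattern frequencies match pruning probabilities", {
  tr <- tree3()
  sm <- site_rate_model(0.5, 4)
  Q <- build_rate_matrix(hky(4))
  pats <- enumerate_site_patterns(3, Q$space)
  probs <- pattern_probability(tr, Q, pats, site_model = sm)
  aln <- simulate_alignment(partition(50000, tr, Q, site_model = sm), seed = 2)
  gof <- chisq_goodness_of_fit(pattern_counts(aln, pats), probs)
  expect_gt(gof$p_value, 0.01)
})

test_that("multi-partition alignments concatenate, pad and reproduce", {
  trABC <- parse_tree("((A:0.3,B:0.3):0.2,C:0.5);")
  trAB <- parse_tree("(A:0.4,B:0.4);")
  p1 <- partition(30, trABC, hky(4))
  p2 <- partition(20, trAB, gtr(1:6, c(.1, .2, .3, .4)))
  aln <- simulate_alignment(list(p1, p2), seed = 6)
  expect_equal(dim(aln), c(3, 50))
  # taxon C is absent from partition 2: gaps across exactly those columns
  expect_equal(substr(aln$seqs[["C"]], 31, 50), strrep("-", 20))
  expect_false(grepl("-", substr(aln$seqs[["C"]], 1, 30)))

  # same seed, byte-identical FASTA
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(simulate_alignment(list(p1, p2), seed = 6), f1)
  write_fasta(simulate_alignment(list(p1, p2), seed = 6), f2)
  expect_identical(readLines(f1), readLines(f2))

  # partition independence: adding p2 does not perturb p1's columns
  alone <- simulate_alignment(p1, seed = 6)
  expect_equal(substr(aln$seqs[["A"]], 1, 30), alone$seqs[["A"]])
})

test_that("codon partitions emit triplets or translations", {
  tr <- parse_tree("(A:0.05,B:0.05);")
  p <- partition(40, tr, gy94(0.5, 2))
  aln <- simulate_alignment(p, seed = 3)
  expect_equal(dim(aln)[2], 120)
  expect_equal(aln$alphabet, "nucleotide")
  alnaa <- simulate_alignment(p, seed = 3, translate = TRUE)
  expect_equal(dim(alnaa)[2], 40)
  expect_identical(translate_codons(aln$seqs[["A"]]), alnaa$seqs[["A"]])
})

test_that("ancestral sequences are emitted with node labels", {
  tr <- tree3()
  res <- simulate_alignment(partition(25, tr, hky(2)), seed = 10,
                            keep_ancestral = TRUE)
  expect_named(res, c("tips", "ancestral"))
  expect_equal(length(res$ancestral$seqs), 2)      # Nnode of a 3-tip tree
  expect_setequal(names(res$ancestral$seqs), c("node4", "node5"))
  expect_equal(nchar(res$ancestral$seqs[[1]]), 25)
})

test_that("epoch simulation demands time-calibrated trees", {
  em <- epoch_model(1, list(hky(1), hky(4)))
  tr_sub <- parse_tree("(A:0.5,B:0.5);")          # substitution units
  expect_error(partition(10, tr_sub, em), "time-calibrated")
  tr_time <- parse_tree("(A:0.5,B:0.5);", tip_heights = c(A = 0, B = 0))
  expect_s3_class(partition(10, tr_time, em), "partition")
})

test_that("clock rates and invariant sites propagate into pattern space", {
  # strict non-unit clock plus gamma+invariant mixture, simulate vs pruning
  tr <- tree3()
  Q <- build_rate_matrix(tn93(2, 5, c(.3, .2, .2, .3)))
  sm <- site_rate_model(alpha = 1, categories = 4, p_inv = 0.3)
  pats <- enumerate_site_patterns(3, Q$space)
  probs <- pattern_probability(tr, Q, pats, site_model = sm, clock_rate = 0.7)
  p <- partition(40000, tr, Q, site_model = sm,
                 clock = clock_model("strict", rate = 0.7))
  aln <- simulate_alignment(p, seed = 77)
  gof <- chisq_goodness_of_fit(pattern_counts(aln, pats), probs)
  expect_gt(gof$p_value, 0.01)
})
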