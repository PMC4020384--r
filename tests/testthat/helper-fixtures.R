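# Shared fixtures and independent oracles, built in code.

tree3 <- function() parse_tree("((A:0.3,B:0.3):0.2,C:0.5);")

rand_gtr <- function() {
  gtr(stats::runif(6, 0.3, 3),
      freq = as.vector(prop.table(stats::runif(4, 0.5, 2))))
}

rand_sparse_general <- function(n = 5, p_zero = 0.4) {
  repeat {
    R <- matrix(stats::runif(n * n, 0.2, 2), n, n)
    R[stats::runif(n * n) < p_zero] <- 0
    diag(R) <- 0
    if (all(rowSums(R) > 0) && all(colSums(R) > 0)) break
  }
  dimnames(R) <- list(paste0("S", 1:n), paste0("S", 1:n))
  R
}

# truncated Taylor-series matrix exponential: independent oracle for expm
expm_series <- function(M, kmax = 60) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(kmax)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

# observed site-pattern counts of an alignment, in pattern-matrix order
pattern_counts <- function(aln, pats) {
  m <- as.matrix(aln)
  obs <- table(factor(apply(m, 2, paste, collapse = ""),
                      levels = rownames(pats)))
  as.integer(obs)
}
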