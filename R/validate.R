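#' Enumerate all site patterns
#'
#' Lists every possible tip-state configuration for `n_tips` tips over a
#' state space, in lexicographic order (first tip varies slowest).
#'
#' @param n_tips Number of tips.
#' @param space A [state_space()].
#' @param cap Refuse to enumerate more than this many patterns.
#' @return Character matrix, one row per pattern and one column per tip;
#'   rownames are the concatenated pattern strings.
#' @examples
#' nrow(enumerate_site_patterns(3, state_space("nucleotide")))  # 64
#' @export
enumerate_site_patterns <- function(n_tips, space = state_space("nucleotide"),
                                    cap = 1e6) {
  stopifnot(inherits(space, "state_space"), n_tips >= 1)
  n_pat <- space$size^n_tips
  if (n_pat > cap) {
    stop("would enumerate ", format(n_pat), " patterns (cap ", format(cap),
         "); sample patterns instead")
  }
  idx <- vector("list", n_tips)
  for (j in seq_len(n_tips)) {
    idx[[j]] <- rep(rep(space$states, each = space$size^(n_tips - j)),
                    times = space$size^(j - 1))
  }
  m <- do.call(cbind, idx)
  rownames(m) <- apply(m, 1, paste, collapse = "")
  m
}

#' Exact site-pattern probability by pruning
#'
#' Computes the probability of observing a tip-state pattern under a
#' substitution process on a tree, by the Felsenstein pruning recursion:
#' tip partials are indicator vectors, internal partials multiply the
#' children's partials propagated through the branch transition
#' matrices, and the root partial is dotted with the root frequencies.
#' Rate mixtures are averaged over categories; the invariant-sites
#' category contributes only to constant patterns.
#'
#' @param tree A [timetree].
#' @param subst A [subst_spec], `"rate_matrix"` or [epoch_model()].
#' @param pattern Character vector of tip states in `tree` tip order
#'   (or a single string for single-character alphabets), or a pattern
#'   matrix from [enumerate_site_patterns()] for several at once.
#' @param site_model A [site_rate_model()].
#' @param clock_rate Strict clock rate applied to every branch, or a
#'   vector of per-branch multipliers named by child node id (e.g. from
#'   [sample_branch_rates()]).
#' @return Probability (vector, for a pattern matrix); sums to 1 over
#'   all patterns.
#' @export
pattern_probability <- function(tree, subst, pattern,
                                site_model = site_rate_model(),
                                clock_rate = 1) {
  stopifnot(inherits(tree, "timetree"))
  if (inherits(subst, "subst_spec")) subst <- build_rate_matrix(subst)
  epochal <- inherits(subst, "epoch_model")
  space <- subst$space
  n <- space$size
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)

  if (is.character(pattern) && is.null(dim(pattern))) {
    if (length(pattern) == 1 && n_tip > 1 && nchar(pattern) == n_tip) {
      pattern <- strsplit(pattern, "")[[1]]
    }
    pattern <- matrix(pattern, nrow = 1)
  }
  if (ncol(pattern) != n_tip) {
    stop("pattern has ", ncol(pattern), " states but the tree has ",
         n_tip, " tips")
  }
  pat_idx <- matrix(match(pattern, space$states), nrow = nrow(pattern))
  if (anyNA(pat_idx)) stop("pattern contains states outside the alphabet")

  po <- .postorder_edges(phy)
  brates <- if (length(clock_rate) == 1) {
    stats::setNames(rep(clock_rate, nrow(po$edge)),
                    po$edge[, 2])
  } else clock_rate

  tab <- site_model$table
  n_pat <- nrow(pattern)
  total <- numeric(n_pat)
  root <- n_tip + 1L
  root_freq <- if (epochal) .epoch_root_freq(subst) else subst$freq

  children <- split(seq_len(nrow(po$edge)), po$edge[, 1])

  for (ci in seq_len(nrow(tab))) {
    rate <- tab$rate[ci]; prob <- tab$prob[ci]
    if (rate == 0) {
      ## invariant category: only constant patterns have mass
      const <- apply(pat_idx, 1, function(v) length(unique(v)) == 1)
      contrib <- numeric(n_pat)
      contrib[const] <- root_freq[pat_idx[const, 1]]
      total <- total + prob * contrib
      next
    }
    ## per-edge transition matrices for this category
    Ps <- vector("list", nrow(po$edge))
    for (e in seq_len(nrow(po$edge))) {
      r <- brates[as.character(po$edge[e, 2])]
      Ps[[e]] <- if (epochal) {
        branch_transition_matrix(subst, tree$heights[po$edge[e, 1]],
                                 tree$heights[po$edge[e, 2]], r * rate)
      } else {
        transition_probabilities(subst, r * rate * po$length[e])
      }
    }
    for (pi in seq_len(n_pat)) {
      partial <- matrix(NA_real_, n_tip + phy$Nnode, n)
      for (tp in seq_len(n_tip)) {
        partial[tp, ] <- 0
        partial[tp, pat_idx[pi, tp]] <- 1
      }
      ## postorder: all children of a node appear before it
      done <- c(rep(TRUE, n_tip), rep(FALSE, phy$Nnode))
      for (e in seq_len(nrow(po$edge))) {
        par <- po$edge[e, 1]
        if (done[par]) next
        kids <- children[[as.character(par)]]
        if (any(!done[po$edge[kids, 2]])) next
        v <- rep(1, n)
        for (ke in kids) v <- v * as.vector(Ps[[ke]] %*% partial[po$edge[ke, 2], ])
        partial[par, ] <- v
        done[par] <- TRUE
      }
      total[pi] <- total[pi] + prob * sum(root_freq * partial[root, ])
    }
  }
  unname(total)
}

#' Pearson chi-squared goodness of fit to expected pattern probabilities
#'
#' Classes whose expected count falls below `min_expected` are pooled
#' into a single class (the classical small-cell rule), then
#' `X^2 = sum (O - E)^2 / E` is referred to the chi-squared distribution
#' with `classes - 1` degrees of freedom.
#'
#' @param observed Observed counts.
#' @param expected Expected probabilities (summing to 1) or expected
#'   counts.
#' @param min_expected Pooling threshold for expected counts.
#' @return List with `statistic`, `df`, `p_value`, `n_classes`.
#' @examples
#' chisq_goodness_of_fit(c(60, 40), c(0.5, 0.5))  # X2 = 4, p ~ 0.0455
#' @export
chisq_goodness_of_fit <- function(observed, expected, min_expected = 5) {
  n <- sum(observed)
  if (n <= 0) stop("no observations")
  if (length(observed) != length(expected)) {
    stop("'observed' and 'expected' must have equal length")
  }
  E <- if (abs(sum(expected) - 1) < 1e-6) expected * n else expected
  if (abs(sum(E) - n) > 1e-6 * n) {
    stop("expected probabilities must sum to 1 (or counts to n)")
  }
  small <- E < min_expected
  O <- observed
  if (any(small)) {
    O <- c(observed[!small], sum(observed[small]))
    E <- c(E[!small], sum(E[small]))
  }
  keep <- E > 0
  O <- O[keep]; E <- E[keep]
  if (length(E) < 2) stop("fewer than 2 classes after pooling")
  stat <- sum((O - E)^2 / E)
  df <- length(E) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_classes = length(E))
}

#' Mean pairwise amino-acid p-distance
#'
#' Averages, over all unordered row pairs, the proportion of differing
#' positions among columns where neither row has a gap.  Pairs with no
#' comparable columns are excluded (all pairs excluded is an error).
#'
#' @param a An [alignment()] of amino-acid rows, or a character vector of
#'   equal-length strings.
#' @return Mean p-distance in `[0, 1]`.
#' @examples
#' mean_pairwise_aa_distance(c(x = "MKMK", y = "MKAA"))  # 0.5
#' @export
mean_pairwise_aa_distance <- function(a) {
  seqs <- if (inherits(a, "alignment")) a$seqs else a
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1) stop("rows must have equal length")
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  n <- nrow(m)
  dists <- numeric(0)
  for (i in seq_len(n - 1)) {
    gi <- m[i, ] != "-"
    for (j in (i + 1):n) {
      ok <- gi & m[j, ] != "-"
      nc <- sum(ok)
      if (nc == 0) next
      dists <- c(dists, sum(m[i, ok] != m[j, ok]) / nc)
    }
  }
  if (!length(dists)) stop("no pair has comparable (gap-free) columns")
  mean(dists)
}
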