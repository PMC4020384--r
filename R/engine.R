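#' Simulation partition
#'
#' A partition is the unit of simulation: a number of sites evolving
#' along one tree under one substitution process (homogeneous or epoch),
#' one site-rate mixture and one clock.  Codon partitions count codon
#' columns (`n_sites` codons = `3 * n_sites` nucleotide columns in the
#' output).
#'
#' @param n_sites Number of sites (>= 1).
#' @param tree A [timetree].
#' @param subst A [subst_spec], a built `"rate_matrix"`, or an
#'   [epoch_model()].
#' @param site_model A [site_rate_model()].
#' @param clock A [clock_model()].
#' @param root_sequence Optional explicit root states: character vector
#'   of state labels of length `n_sites` (or a single string for
#'   single-character alphabets, or a nucleotide string of length
#'   `3 * n_sites` for codon spaces).
#' @param name Optional partition label.
#' @return A `"partition"` object.
#' @export
partition <- function(n_sites, tree, subst,
                      site_model = site_rate_model(),
                      clock = clock_model("strict"),
                      root_sequence = NULL, name = NULL) {
  stopifnot(n_sites >= 1, inherits(tree, "timetree"))
  if (inherits(subst, "subst_spec")) subst <- build_rate_matrix(subst)
  if (!inherits(subst, "rate_matrix") && !inherits(subst, "epoch_model")) {
    stop("'subst' must be a subst_spec, rate_matrix or epoch_model")
  }
  if (inherits(subst, "epoch_model") && !tree$time_units) {
    stop("epoch models need a time-calibrated tree ",
         "(branch lengths in substitution units carry no height information)")
  }
  space <- subst$space
  if (!is.null(root_sequence)) {
    root_sequence <- .parse_state_string(root_sequence, space, n_sites)
  }
  structure(list(n_sites = as.integer(n_sites), tree = tree, subst = subst,
                 site_model = site_model, clock = clock,
                 root_sequence = root_sequence, name = name, space = space),
            class = "partition")
}

.parse_state_string <- function(x, space, n_sites) {
  if (length(x) == 1 && nchar(x) > 1 && space$size > 0) {
    w <- if (space$kind == "codon") 3L else nchar(space$states[1])
    if (nchar(x) != n_sites * w) {
      stop("root sequence has ", nchar(x), " characters, expected ",
           n_sites * w)
    }
    x <- substring(x, seq(1, nchar(x), w), seq(w, nchar(x), w))
  }
  if (length(x) != n_sites) {
    stop("root sequence has ", length(x), " states, expected ", n_sites)
  }
  idx <- match(x, space$states)
  if (anyNA(idx)) {
    stop("root sequence contains states outside the model alphabet: ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Sample a root sequence from the equilibrium distribution
#'
#' Draws i.i.d. states from the model's equilibrium frequencies; epoch
#' models draw from the stationary distribution of the *oldest* epoch,
#' where the root lives.
#'
#' @param subst A `"rate_matrix"` or [epoch_model()] (a [subst_spec] is
#'   built on the fly), or a bare frequency vector to draw from directly.
#' @param n_sites Number of states to draw.
#' @return Integer vector of state indices (into `subst$space$states`).
#' @export
sample_root_sequence <- function(subst, n_sites) {
  if (inherits(subst, "subst_spec")) subst <- build_rate_matrix(subst)
  freq <- if (inherits(subst, "epoch_model")) {
    .epoch_root_freq(subst)
  } else if (is.numeric(subst)) {
    if (any(subst < 0) || abs(sum(subst) - 1) > 1e-6) {
      stop("frequency vector must be non-negative and sum to 1")
    }
    subst
  } else {
    subst$freq
  }
  sample.int(length(freq), n_sites, replace = TRUE, prob = freq)
}

#' Simulate one partition
#'
#' Pre-order Monte Carlo simulation: the root sequence is drawn from the
#' equilibrium distribution (or taken from the partition's explicit root
#' sequence), then each node is visited parents-first and every site's
#' child state is sampled from the row of the branch transition matrix
#' indexed by the parent state.  The branch distance for a site is
#' `clock multiplier x site rate x branch duration`; epoch branches use
#' [branch_transition_matrix()] with the site rate folded into every
#' segment.  Transition matrices are computed once per (branch, site
#' category).
#'
#' @param p A [partition()].
#' @return List with `states` (node x site integer matrix of state
#'   indices, rows indexed by ape node number), `site_rates`,
#'   `branch_rates`, `tree`, `space`.
#' @export
simulate_partition <- function(p) {
  stopifnot(inherits(p, "partition"))
  tree <- p$tree
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)
  n_nodes <- n_tip + phy$Nnode
  root <- n_tip + 1L
  n_sites <- p$n_sites
  space <- p$space
  epochal <- inherits(p$subst, "epoch_model")

  site <- sample_site_rates(p$site_model, n_sites)
  brates <- sample_branch_rates(tree, p$clock)

  states <- matrix(NA_integer_, n_nodes, n_sites)
  states[root, ] <- if (is.null(p$root_sequence)) {
    sample_root_sequence(p$subst, n_sites)
  } else {
    p$root_sequence
  }

  pre <- .preorder_edges(phy)
  cats <- sort(unique(site$category))
  cat_rate <- vapply(cats, function(cc) site$rate[match(cc, site$category)],
                     numeric(1))

  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    len <- pre$length[e]
    r <- brates[as.character(ch)]
    for (ci in seq_along(cats)) {
      idx <- which(site$category == cats[ci])
      if (!length(idx)) next
      rate <- cat_rate[ci]
      if (rate == 0 || len * r == 0) {
        states[ch, idx] <- states[par, idx]   # invariant sites / zero branch
        next
      }
      P <- if (epochal) {
        branch_transition_matrix(p$subst, tree$heights[par],
                                 tree$heights[ch], r * rate)
      } else {
        transition_probabilities(p$subst, r * rate * len)
      }
      parent_states <- states[par, idx]
      for (s in unique(parent_states)) {
        sel <- idx[parent_states == s]
        states[ch, sel] <- sample.int(space$size, length(sel),
                                      replace = TRUE, prob = P[s, ])
      }
    }
  }
  list(states = states, site_rates = site, branch_rates = brates,
       tree = tree, space = space)
}

#' Multiple sequence alignment container
#'
#' Rows are taxa, columns characters; a taxon absent from a partition is
#' padded with `-` across exactly that partition's columns.
#'
#' @param seqs Named character vector of equal-width sequence strings.
#' @param alphabet `"nucleotide"`, `"amino_acid"` or `"general"`.
#' @param partitions Data frame with columns `partition`, `start`, `end`
#'   (1-based column ranges); defaults to a single partition.
#' @return An object of class `"alignment"`.
#' @export
alignment <- function(seqs, alphabet = "nucleotide", partitions = NULL) {
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) stop("all rows must have equal length")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by taxon")
  }
  if (is.null(partitions)) {
    partitions <- data.frame(partition = "p1", start = 1L,
                             end = unique(widths))
  }
  structure(list(seqs = seqs, alphabet = alphabet, partitions = partitions),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$seqs), "taxa x", nchar(x$seqs[1]),
      x$alphabet, "columns,", nrow(x$partitions), "partition(s)\n")
  invisible(x)
}

#' @export
as.matrix.alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$seqs), ""))
  rownames(m) <- names(x$seqs)
  m
}

#' @export
dim.alignment <- function(x) c(length(x$seqs), nchar(x$seqs[[1]]))

## integer state rows -> character strings for a set of node rows
.states_to_strings <- function(states, rows, space) {
  labs <- space$states
  apply(states[rows, , drop = FALSE], 1, function(v) {
    paste(labs[v], collapse = "")
  })
}

#' Simulate a multi-partition alignment
#'
#' Simulates each partition independently (with per-partition seeds
#' derived from `seed` by a fixed counter scheme, so adding partitions
#' never perturbs earlier ones), concatenates the columns in the given
#' order, and gap-pads taxa missing from a partition.  Codon partitions
#' are emitted as nucleotide triplets unless `translate = TRUE`.
#'
#' @param partitions A [partition()] or list of them.
#' @param seed Optional integer seed; identical seeds give
#'   byte-identical output.
#' @param keep_ancestral Also return the internal-node sequences
#'   (labelled `node<k>` by ape node number) as a second alignment.
#' @param translate Emit amino-acid translations for codon partitions.
#' @return An [alignment()]; with `keep_ancestral = TRUE`, a list with
#'   elements `tips` and `ancestral`.
#' @examples
#' tr <- parse_tree("((A:0.2,B:0.2):0.1,C:0.3);")
#' a <- simulate_alignment(partition(50, tr, hky(2)), seed = 1)
#' dim(a)
#' @export
simulate_alignment <- function(partitions, seed = NULL,
                               keep_ancestral = FALSE, translate = FALSE) {
  if (inherits(partitions, "partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1,
            all(vapply(partitions, inherits, TRUE, "partition")))

  taxa <- character(0)
  for (p in partitions) taxa <- union(taxa, p$tree$phy$tip.label)

  blocks <- vector("list", length(partitions))
  anc_blocks <- vector("list", length(partitions))
  part_tab <- NULL
  col0 <- 0L
  for (i in seq_along(partitions)) {
    p <- partitions[[i]]
    if (!is.null(seed)) set.seed(.partition_seed(seed, i))
    sim <- simulate_partition(p)
    tips <- seq_len(ape::Ntip(p$tree$phy))
    seqs <- .states_to_strings(sim$states, tips, p$space)
    names(seqs) <- p$tree$phy$tip.label
    if (p$space$kind == "codon" && translate) {
      seqs <- vapply(seqs, translate_codons, character(1))
    }
    width <- nchar(seqs[[1]])
    gap_row <- strrep("-", width)
    rows <- vapply(taxa, function(tx) {
      if (tx %in% names(seqs)) seqs[[tx]] else gap_row
    }, character(1))
    blocks[[i]] <- rows
    if (keep_ancestral) {
      internals <- (ape::Ntip(p$tree$phy) + 1L):(ape::Ntip(p$tree$phy) +
                                                   p$tree$phy$Nnode)
      anc <- .states_to_strings(sim$states, internals, p$space)
      if (p$space$kind == "codon" && translate) {
        anc <- vapply(anc, translate_codons, character(1))
      }
      names(anc) <- paste0("node", internals)
      anc_blocks[[i]] <- anc
    }
    part_tab <- rbind(part_tab, data.frame(
      partition = if (is.null(p$name)) paste0("p", i) else p$name,
      start = col0 + 1L, end = col0 + width))
    col0 <- col0 + width
  }

  seqs <- vapply(seq_along(taxa), function(j) {
    paste(vapply(blocks, `[[`, character(1), j), collapse = "")
  }, character(1))
  names(seqs) <- taxa
  alphabet <- .alignment_alphabet(partitions, translate)
  aln <- alignment(seqs, alphabet, part_tab)
  if (!keep_ancestral) return(aln)

  anc_names <- unique(unlist(lapply(anc_blocks, names)))
  anc_seqs <- vapply(anc_names, function(nm) {
    paste(vapply(seq_along(anc_blocks), function(i) {
      b <- anc_blocks[[i]]
      w <- part_tab$end[i] - part_tab$start[i] + 1L
      if (nm %in% names(b)) b[[nm]] else strrep("-", w)
    }, character(1)), collapse = "")
  }, character(1))
  list(tips = aln,
       ancestral = alignment(anc_seqs, alphabet, part_tab))
}

## fixed counter-based per-partition seed split (stays below 2^31)
.partition_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

.alignment_alphabet <- function(partitions, translate) {
  kinds <- vapply(partitions, function(p) p$space$kind, character(1))
  kinds[kinds == "codon"] <- if (translate) "amino_acid" else "nucleotide"
  if (length(unique(kinds)) == 1) unique(kinds) else "general"
}
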