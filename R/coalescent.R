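#' Demographic models for coalescent simulation
#'
#' Constant population size or exponential growth.  `theta` is the
#' product of effective population size and generation time, expressed
#' directly in tree time units, so that for two contemporaneous lineages
#' the expected pairwise coalescent time equals `theta`.  Under
#' exponential growth the population looking back in time is
#' `N(h) = theta * exp(-growth * h)` at height `h` (`growth = 0` reduces
#' to the constant model; `growth < 0`, a population shrinking toward the
#' present, can leave lineages uncoalesced with positive probability,
#' in which case waiting times of `Inf` are returned).
#'
#' @param kind `"constant"` or `"exponential"`.
#' @param theta Population size parameter (> 0), in tree time units.
#' @param growth Growth rate per time unit (exponential model only).
#' @return A `"demographic_model"` object.
#' @export
demographic_model <- function(kind = c("constant", "exponential"),
                              theta, growth = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0) {
    stop("'theta' must be a single positive number")
  }
  if (!is.finite(growth)) stop("'growth' must be finite")
  structure(list(kind = kind, theta = theta, growth = growth),
            class = "demographic_model")
}

#' Waiting time to the next coalescence
#'
#' Draws the height of the next coalescent event among `k` active
#' lineages, starting the clock at `start_height`.  The waiting time `W`
#' satisfies `P(W > w) = exp(-integral_0^w k(k-1) / (2 N(start + s)) ds)`;
#' for the constant model this is exponential with rate
#' `k(k-1) / (2 theta)`, for exponential growth the integrated intensity
#' is inverted in closed form.
#'
#' @param k Number of active lineages (>= 2).
#' @param start_height Height at which the waiting period starts.
#' @param demo A [demographic_model()].
#' @return Height of the proposed coalescence (possibly `Inf` for
#'   improper declining-population models).
#' @export
draw_coalescent_time <- function(k, start_height, demo) {
  if (!inherits(demo, "demographic_model")) {
    stop("'demo' must be a demographic_model")
  }
  if (k < 2) stop("need at least 2 active lineages (k >= 2)")
  pair_rate <- k * (k - 1) / 2
  E <- stats::rexp(1)
  g <- if (demo$kind == "constant") 0 else demo$growth
  if (g == 0) {
    return(start_height + E * demo$theta / pair_rate)
  }
  ## intensity at height h: pair_rate * exp(g h) / theta; integrate from
  ## start to start + w and solve for w
  arg <- exp(g * start_height) + g * demo$theta * E / pair_rate
  if (arg <= 0) return(Inf)   # g < 0: bounded cumulative intensity
  log(arg) / g
}

#' Simulate a coalescent genealogy
#'
#' Generates a binary rooted genealogy for a (possibly heterochronous)
#' set of taxa under the standard serial-sample coalescent: going
#' backwards in time, lineages become active at their sampling heights;
#' among `k` active lineages coalescences are proposed from the
#' demographic model's intensity, and a proposal past the next sampling
#' height is discarded in favour of activating that sample first
#' (restarting the waiting process from the sampling height).  Merging
#' pairs are chosen uniformly at random.
#'
#' @param taxa A [taxon_set()] (or data frame with `name`, `height`)
#'   of at least 2 taxa.
#' @param demo A [demographic_model()].
#' @return A time-calibrated [timetree] with tips at their sampling
#'   heights.
#' @examples
#' set.seed(1)
#' tr <- simulate_genealogy(taxon_set(c("A", "B", "C")),
#'                          demographic_model("constant", theta = 1))
#' root_height(tr) > 0
#' @export
simulate_genealogy <- function(taxa, demo) {
  if (!inherits(taxa, "taxon_set")) taxa <- taxon_set(taxa$name, taxa$height)
  n <- nrow(taxa)
  if (n < 2) stop("need at least 2 taxa")

  ## pending samples sorted by height; node ids: tips 1..n (taxa order)
  ord <- order(taxa$height)
  pend_id <- ord
  pend_h <- taxa$height[ord]

  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  heights <- numeric(n_nodes)
  heights[seq_len(n)] <- taxa$height

  active <- integer(0)
  t_cur <- pend_h[1]
  next_internal <- 0L                  # counts internals created (1..n-1)
  internal_id <- function(j) n + 1L + (n - 1L - j)  # creation j -> ape id, root = n+1

  repeat {
    ## activate all pending samples at the current height
    while (length(pend_id) && pend_h[1] <= t_cur + 1e-12) {
      active <- c(active, pend_id[1])
      pend_id <- pend_id[-1]; pend_h <- pend_h[-1]
    }
    k <- length(active)
    if (!length(pend_id) && k == 1L) break
    if (k < 2) {
      ## wait for the next sample
      t_cur <- pend_h[1]
      next
    }
    t_prop <- draw_coalescent_time(k, t_cur, demo)
    if (length(pend_id) && t_prop > pend_h[1]) {
      t_cur <- pend_h[1]              # activate first, restart waiting
      next
    }
    if (!is.finite(t_prop)) {
      stop("coalescent process is improper under this demographic model ",
           "(lineages fail to coalesce)")
    }
    pick <- sample.int(k, 2L)
    next_internal <- next_internal + 1L
    anc <- internal_id(next_internal)
    heights[anc] <- t_prop
    parent[active[pick]] <- anc
    active <- c(active[-pick], anc)
    t_cur <- t_prop
  }

  edge_child <- setdiff(seq_len(n_nodes), n + 1L)
  edge <- cbind(parent[edge_child], edge_child)
  phy <- list(edge = edge,
              edge.length = heights[edge[, 1]] - heights[edge[, 2]],
              tip.label = taxa$name,
              Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  timetree(phy, heights, time_units = TRUE)
}

#' Rescale a time tree to a target root height
#'
#' Multiplies all node heights (hence branch lengths) by
#' `target / root_height(tree)`.  Used to condition simulated genealogies
#' on a realized age of the most recent common ancestor.
#'
#' @param tree A [timetree].
#' @param target Desired root height (> 0).
#' @return The rescaled tree.
#' @export
rescale_tree <- function(tree, target) {
  stopifnot(inherits(tree, "timetree"), target > 0)
  f <- target / root_height(tree)
  phy <- tree$phy
  phy$edge.length <- phy$edge.length * f
  timetree(phy, tree$heights * f, tree$time_units)
}
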