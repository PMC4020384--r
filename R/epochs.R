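#' Time-heterogeneous (epoch) substitution model
#'
#' Partitions evolutionary history into height intervals, each governed
#' by its own substitution specification over one shared state space:
#' `specs[[1]]` applies on `[0, boundaries[1])`, `specs[[i + 1]]` on
#' `[boundaries[i], boundaries[i + 1])`, and the last spec beyond the
#' final boundary.
#'
#' Two normalization conventions are available.  With
#' `normalize = "each"` (default) every epoch's generator is scaled to
#' one expected substitution per site per distance unit, so the clock
#' rate applies unchanged in every epoch and only the *character* of
#' substitution (e.g. the synonymous/nonsynonymous mix) varies through
#' time.  With `normalize = "first"` only the youngest epoch is
#' normalized and older epochs reuse its scaling constant, so a model
#' change back in time also changes the realized overall substitution
#' rate.
#'
#' @param boundaries Strictly increasing positive heights (`m` values).
#' @param specs List of `m + 1` [subst_spec] objects sharing one state
#'   space.
#' @param space Optional shared [state_space()]; inferred from the first
#'   spec when omitted.
#' @param normalize `"each"` or `"first"` (see Details).
#' @return An `"epoch_model"`.
#' @examples
#' em <- epoch_model(c(10, 50), list(gy94(1, 2), gy94(0.1, 2), gy94(0.01, 2)))
#' @export
epoch_model <- function(boundaries, specs, space = NULL,
                        normalize = c("each", "first")) {
  normalize <- match.arg(normalize)
  boundaries <- as.numeric(boundaries)
  if (length(specs) != length(boundaries) + 1) {
    stop("need one more spec (", length(boundaries) + 1,
         ") than boundaries (", length(boundaries), ")")
  }
  if (any(boundaries <= 0) || any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing and > 0")
  }
  if (is.null(space)) space <- .spec_space(specs[[1]])
  gens <- lapply(specs, .build_generator, space = space)
  sizes <- vapply(gens, function(g) g$space$size, numeric(1))
  if (length(unique(sizes)) != 1) stop("epoch specs must share one state space")
  scale <- if (normalize == "each") {
    vapply(gens, `[[`, numeric(1), "rate")
  } else {
    rep(gens[[1]]$rate, length(gens))
  }
  mats <- mapply(function(g, s) {
    .finalize_rate_matrix(g$Q / s, g$freq, g$space, s, g$reversible)
  }, gens, scale, SIMPLIFY = FALSE)
  structure(list(boundaries = boundaries, matrices = mats, specs = specs,
                 space = space, normalize = normalize),
            class = "epoch_model")
}

#' @export
print.epoch_model <- function(x, ...) {
  cat("epoch_model:", length(x$matrices), "epochs over", x$space$kind,
      "states; boundaries at", paste(x$boundaries, collapse = ", "),
      "; normalize =", x$normalize, "\n")
  invisible(x)
}

## epoch index for a height (0-based interval lookup)
.epoch_index <- function(em, h) findInterval(h, em$boundaries) + 1L

#' Transition matrix across a branch under an epoch model
#'
#' Cuts the branch `[child_height, parent_height]` at every epoch
#' boundary it crosses and composes the per-segment matrix exponentials
#' chronologically — the oldest segment is the leftmost factor — so that
#' `P[i, j]` is the probability that a parent in state `i` leaves a child
#' in state `j`.  The per-segment distance is
#' `rate * (segment duration)`.
#'
#' @param epochs An [epoch_model()].
#' @param parent_height,child_height Branch endpoint heights
#'   (`parent_height >= child_height >= 0`).
#' @param rate Combined rate multiplier (clock rate x site rate) applied
#'   to every segment.
#' @return Row-stochastic matrix over the epoch state space.
#' @export
branch_transition_matrix <- function(epochs, parent_height, child_height,
                                     rate = 1) {
  stopifnot(inherits(epochs, "epoch_model"))
  if (child_height < 0 || parent_height < 0) stop("heights must be >= 0")
  if (parent_height < child_height) {
    stop("parent_height must be >= child_height")
  }
  n <- epochs$space$size
  if (parent_height == child_height) {
    P <- diag(n)
    dimnames(P) <- list(epochs$space$states, epochs$space$states)
    return(P)
  }
  cuts <- epochs$boundaries[epochs$boundaries > child_height &
                            epochs$boundaries < parent_height]
  pts <- c(child_height, cuts, parent_height)
  P <- diag(n)
  for (s in seq_len(length(pts) - 1L)) {     # young -> old
    lo <- pts[s]; hi <- pts[s + 1L]
    e <- .epoch_index(epochs, (lo + hi) / 2)
    Pseg <- .mat_exp(epochs$matrices[[e]], rate * (hi - lo))
    P <- Pseg %*% P                          # oldest factor ends leftmost
  }
  dimnames(P) <- list(epochs$space$states, epochs$space$states)
  .clean_stochastic(P)
}

## stationary distribution of the oldest epoch (root state distribution)
.epoch_root_freq <- function(epochs) {
  last <- epochs$matrices[[length(epochs$matrices)]]
  if (last$reversible) last$freq else stationary_distribution(last)
}
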