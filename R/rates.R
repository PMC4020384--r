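#' Discrete-gamma site rate categories
#'
#' Discretizes a Gamma(`alpha`, `alpha`) distribution (mean 1) into `k`
#' equal-probability categories, each category's rate being the mean of
#' the distribution within its quantile bin (Yang's mean method).  When a
#' proportion `p_inv` of invariant sites is included, the gamma category
#' rates are divided by `1 - p_inv` so the full mixture (invariant
#' category at rate 0) keeps mean rate 1 — the molecular clock alone then
#' sets the time scale.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of gamma categories (>= 1).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return Data frame with columns `category` (0 = invariant), `rate`,
#'   `prob`; `sum(rate * prob) == 1`.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, k, p_inv = 0) {
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (p_inv < 0 || p_inv >= 1) stop("'p_inv' must be in [0, 1)")
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                      rate = alpha)
  ## E[X; X in bin] for X ~ Gamma(a, a): pgamma(x, a + 1, a) since mean = 1
  mass <- diff(stats::pgamma(qb, shape = alpha + 1, rate = alpha))
  rates <- mass * k / (1 - p_inv)
  out <- data.frame(category = seq_len(k), rate = rates,
                    prob = rep((1 - p_inv) / k, k))
  if (p_inv > 0) {
    out <- rbind(data.frame(category = 0, rate = 0, prob = p_inv), out)
  }
  out
}

#' Site rate mixture model
#'
#' Combines discrete-gamma rate heterogeneity (optional) with a
#' proportion of invariant sites.  With `alpha = NULL` and `p_inv = 0`
#' every site evolves at rate 1.
#'
#' @param alpha Gamma shape, or `NULL` for no gamma variation.
#' @param categories Number of gamma categories (ignored when
#'   `alpha = NULL`).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return A `"site_rate_model"` with the category table (see
#'   [discrete_gamma_rates()]).
#' @export
site_rate_model <- function(alpha = NULL, categories = 4, p_inv = 0) {
  if (p_inv < 0 || p_inv >= 1) stop("'p_inv' must be in [0, 1)")
  tab <- if (is.null(alpha)) {
    out <- data.frame(category = 1, rate = 1 / (1 - p_inv),
                      prob = 1 - p_inv)
    if (p_inv > 0) {
      out <- rbind(data.frame(category = 0, rate = 0, prob = p_inv), out)
    }
    out
  } else {
    discrete_gamma_rates(alpha, categories, p_inv)
  }
  structure(list(alpha = alpha,
                 categories = if (is.null(alpha)) 1L else as.integer(categories),
                 p_inv = p_inv, table = tab),
            class = "site_rate_model")
}

#' @export
print.site_rate_model <- function(x, ...) {
  cat("site_rate_model:",
      if (is.null(x$alpha)) "uniform rates"
      else paste0("gamma(alpha=", x$alpha, ", k=", x$categories, ")"),
      if (x$p_inv > 0) paste0("+ p_inv=", x$p_inv) else "", "\n")
  invisible(x)
}

#' Sample per-site rates from a mixture
#'
#' Each site is independently assigned the invariant category (rate 0)
#' with probability `p_inv`, otherwise one of the equal-probability gamma
#' categories.
#'
#' @param model A [site_rate_model()].
#' @param n_sites Number of sites (>= 1).
#' @return List with `rate` and `category` vectors of length `n_sites`
#'   (category 0 = invariant).
#' @export
sample_site_rates <- function(model, n_sites) {
  stopifnot(inherits(model, "site_rate_model"), n_sites >= 1)
  tab <- model$table
  idx <- sample.int(nrow(tab), n_sites, replace = TRUE, prob = tab$prob)
  list(rate = tab$rate[idx], category = tab$category[idx])
}

#' Molecular clock models
#'
#' Maps time units to expected substitutions per site.  The strict clock
#' multiplies every branch by one rate (default 1, so trees in
#' substitution units are passed through unchanged).  The uncorrelated
#' relaxed clocks draw independent per-branch scalers from a lognormal or
#' inverse-Gaussian distribution parameterized by its *real-space* mean
#' `mean` and spread `stdev` (lognormal: `stdev` is the standard
#' deviation of the log rate; inverse-Gaussian: `stdev` is the real-space
#' standard deviation, shape `lambda = mean^3 / stdev^2`).  `stdev = 0`
#' collapses either relaxed clock to a strict clock at rate `mean`.
#'
#' @param kind `"strict"`, `"lognormal"` or `"inverse_gaussian"`.
#' @param rate Strict clock rate (> 0), substitutions/site/time unit.
#' @param mean,stdev Mean and spread of the relaxed-clock scaler
#'   distribution.
#' @return A `"clock_model"`.
#' @export
clock_model <- function(kind = c("strict", "lognormal", "inverse_gaussian"),
                        rate = 1, mean = 1, stdev = 0) {
  kind <- match.arg(kind)
  if (kind == "strict") {
    if (rate <= 0) stop("'rate' must be > 0")
  } else {
    if (mean <= 0) stop("'mean' must be > 0")
    if (stdev < 0) stop("'stdev' must be >= 0")
  }
  structure(list(kind = kind, rate = rate, mean = mean, stdev = stdev),
            class = "clock_model")
}

#' Sample per-branch clock rate multipliers
#'
#' @param tree A [timetree].
#' @param clock A [clock_model()] (default: strict clock, rate 1).
#' @return Numeric vector with one multiplier per edge of `tree$phy`
#'   (in `tree$phy$edge` row order), named by child node id.
#' @export
sample_branch_rates <- function(tree, clock = clock_model("strict")) {
  stopifnot(inherits(tree, "timetree"), inherits(clock, "clock_model"))
  n_edge <- nrow(tree$phy$edge)
  r <- switch(clock$kind,
    strict = rep(clock$rate, n_edge),
    lognormal = {
      if (clock$stdev == 0) rep(clock$mean, n_edge)
      else stats::rlnorm(n_edge,
                         meanlog = log(clock$mean) - clock$stdev^2 / 2,
                         sdlog = clock$stdev)
    },
    inverse_gaussian = {
      if (clock$stdev == 0) rep(clock$mean, n_edge)
      else .rinvgauss(n_edge, mu = clock$mean,
                      lambda = clock$mean^3 / clock$stdev^2)
    }
  )
  names(r) <- tree$phy$edge[, 2]
  r
}

## Michael-Schucany-Haas inverse-Gaussian sampler
.rinvgauss <- function(n, mu, lambda) {
  y <- stats::rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}
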