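#' Substitution model specifications
#'
#' Constructors for the parametric and empirical substitution models.
#' Each returns a lightweight specification object (class `"subst_spec"`)
#' that [build_rate_matrix()] turns into a normalized CTMC generator.
#'
#' * `hky(kappa, freq)`: Hasegawa-Kishino-Yano; one transition/transversion
#'   bias `kappa`.
#' * `tn93(kappa1, kappa2, freq)`: Tamura-Nei; separate purine (`A<->G`)
#'   and pyrimidine (`C<->T`) transition biases.  `tn93(k, k)` equals
#'   `hky(k)`.
#' * `gtr(rates, freq)`: general time-reversible; six exchangeabilities in
#'   the order `AC, AG, AT, CG, CT, GT`.
#' * `gy94(omega, kappa, freq)`: Goldman-Yang codon model; `omega` is the
#'   nonsynonymous/synonymous rate ratio (dN/dS), `kappa` the
#'   transition/transversion ratio.  Codon frequencies default to uniform
#'   over the sense codons; `codon_freq_f1x4()` / `codon_freq_f3x4()`
#'   derive them from nucleotide composition.
#' * `mg94(alpha, beta, kappa, nuc_freq)`: Muse-Gaut codon model;
#'   synonymous rate `alpha`, nonsynonymous rate `beta`, target-nucleotide
#'   frequencies, and an optional transition/transversion extension
#'   (`kappa = NULL` disables it).
#' * `empirical_aa(name, freq)`: empirical amino-acid exchange matrices
#'   Dayhoff, JTT, BLOSUM62, WAG or LG, with the published equilibrium
#'   frequencies unless overridden.
#' * `general_ctmc(rates, freq)`: arbitrary (possibly sparse and
#'   non-reversible) off-diagonal rate table over a general state space,
#'   e.g. for discrete phylogeographic traits.
#'
#' @param kappa,kappa1,kappa2 Transition/transversion bias parameters
#'   (> 0).
#' @param freq Equilibrium frequency vector over the model's state space
#'   (non-negative, summing to one).  Defaults: uniform for nucleotide and
#'   codon models, the published frequencies for empirical amino-acid
#'   models, the stationary distribution of the rate table for
#'   `general_ctmc`.
#' @param rates For `gtr`: six exchangeabilities; for `general_ctmc`: a
#'   square numeric matrix of off-diagonal instantaneous rates whose
#'   dimnames name the states (diagonal ignored).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param alpha,beta Synonymous and nonsynonymous rates of MG94 (>= 0).
#' @param nuc_freq Nucleotide frequencies (A, C, G, T) used by MG94 for
#'   the target nucleotide of each change.
#' @param name Empirical matrix name: `"Dayhoff"`, `"JTT"`, `"BLOSUM62"`,
#'   `"WAG"` or `"LG"`.
#' @param genetic_code Genetic code for codon models (see
#'   [state_space()]).
#' @return A `"subst_spec"` object.
#' @seealso [build_rate_matrix()], [transition_probabilities()]
#' @examples
#' build_rate_matrix(hky(kappa = 4))
#' @name subst_spec
NULL

.new_spec <- function(model, params, freq = NULL, kind, genetic_code = NULL) {
  structure(
    list(model = model, params = params, freq = freq, kind = kind,
         genetic_code = genetic_code),
    class = "subst_spec"
  )
}

#' @rdname subst_spec
#' @export
hky <- function(kappa, freq = rep(0.25, 4)) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0)
  .new_spec("HKY", list(kappa = kappa), freq, "nucleotide")
}

#' @rdname subst_spec
#' @export
tn93 <- function(kappa1, kappa2, freq = rep(0.25, 4)) {
  stopifnot(kappa1 > 0, kappa2 > 0)
  .new_spec("TN93", list(kappa1 = kappa1, kappa2 = kappa2), freq, "nucleotide")
}

#' @rdname subst_spec
#' @export
gtr <- function(rates, freq = rep(0.25, 4)) {
  if (length(rates) != 6 || any(rates < 0)) {
    stop("GTR needs 6 non-negative exchangeabilities (AC, AG, AT, CG, CT, GT)")
  }
  .new_spec("GTR", list(rates = as.numeric(rates)), freq, "nucleotide")
}

#' @rdname subst_spec
#' @export
gy94 <- function(omega, kappa = 1, freq = NULL,
                 genetic_code = Biostrings::GENETIC_CODE) {
  stopifnot(omega >= 0, kappa > 0)
  .new_spec("GY94", list(omega = omega, kappa = kappa), freq, "codon",
            genetic_code)
}

#' @rdname subst_spec
#' @export
mg94 <- function(alpha, beta, kappa = NULL, nuc_freq = rep(0.25, 4),
                 genetic_code = Biostrings::GENETIC_CODE) {
  stopifnot(alpha >= 0, beta >= 0, is.null(kappa) || kappa > 0)
  if (length(nuc_freq) != 4 || any(nuc_freq < 0)) {
    stop("nuc_freq must be 4 non-negative values (A, C, G, T)")
  }
  nuc_freq <- nuc_freq / sum(nuc_freq)
  .new_spec("MG94",
            list(alpha = alpha, beta = beta, kappa = kappa,
                 nuc_freq = nuc_freq),
            NULL, "codon", genetic_code)
}

#' @rdname subst_spec
#' @export
empirical_aa <- function(name = c("Dayhoff", "JTT", "BLOSUM62", "WAG", "LG"),
                         freq = NULL) {
  name <- match.arg(name)
  .new_spec("EmpiricalAA", list(name = name), freq, "amino_acid")
}

#' @rdname subst_spec
#' @export
general_ctmc <- function(rates, freq = NULL) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates) || nrow(rates) < 2) {
    stop("'rates' must be a square matrix over >= 2 states")
  }
  if (is.null(rownames(rates))) {
    rownames(rates) <- colnames(rates) <- paste0("S", seq_len(nrow(rates)))
  }
  off <- rates; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(rowSums(off) == 0)) {
    stop("all-zero rate row(s): ",
         paste(rownames(rates)[rowSums(off) == 0], collapse = ", "))
  }
  .new_spec("General", list(rates = rates), freq, "general")
}

## Published empirical exchangeabilities and frequencies, PAML
## (ARNDCQEGHILKMFPSTWYV) order, provided through phangorn's model library.
.empirical_aa_data <- function(name) {
  pname <- switch(name, BLOSUM62 = "Blosum62", name)
  loader <- utils::getFromNamespace("getModelAA", "phangorn")
  env <- new.env()
  local_get <- function() {
    loader(pname, bf = TRUE, Q = TRUE)
    list(Q = Q, bf = bf)
  }
  dat <- local_get()
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- dat$Q
  s <- s + t(s)
  freq <- as.numeric(dat$bf)
  freq <- freq / sum(freq)
  labels <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  dimnames(s) <- list(labels, labels)
  list(exchangeabilities = s, freq = freq)
}

#' Read an empirical exchange matrix in PAML dat-file layout
#'
#' Parses the common plain-text layout for empirical amino-acid models: 19
#' rows of whitespace-separated lower-triangle exchangeabilities followed
#' by a line of 20 equilibrium frequencies (comments and blank lines after
#' the frequencies are ignored).  States are taken in
#' `ARNDCQEGHILKMFPSTWYV` order.
#'
#' @param file Path to the text file.
#' @return A list with `exchangeabilities` (symmetric 20 x 20 matrix) and
#'   `freq` (length-20 frequency vector).
#' @export
read_paml_rates <- function(file) {
  txt <- readLines(file, warn = FALSE)
  nums <- suppressWarnings(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 190 + 20) {
    stop("expected 190 exchangeabilities plus 20 frequencies, found ",
         length(nums), " numbers")
  }
  ## dat files list the lower triangle row by row; fill via the transpose
  s <- matrix(0, 20, 20)
  s[upper.tri(s)] <- nums[1:190]
  s <- t(s)
  s <- s + t(s)
  freq <- nums[191:210]
  labels <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  dimnames(s) <- list(labels, labels)
  list(exchangeabilities = s, freq = freq / sum(freq))
}

#' Codon frequencies from nucleotide composition
#'
#' `codon_freq_f1x4()` builds sense-codon frequencies proportional to the
#' product of one shared nucleotide frequency vector across the three
#' codon positions; `codon_freq_f3x4()` uses separate per-position
#' vectors.  Both renormalize over the sense codons of the space.
#'
#' @param nuc_freq Length-4 (F1x4) nucleotide frequencies (A, C, G, T).
#' @param pos_freq 3 x 4 matrix (F3x4) of per-position frequencies.
#' @param space A codon [state_space()].
#' @return Frequency vector over `space$states`.
#' @export
codon_freq_f1x4 <- function(nuc_freq, space = state_space("codon")) {
  codon_freq_f3x4(rbind(nuc_freq, nuc_freq, nuc_freq), space)
}

#' @rdname codon_freq_f1x4
#' @export
codon_freq_f3x4 <- function(pos_freq, space = state_space("codon")) {
  stopifnot(space$kind == "codon")
  pos_freq <- as.matrix(pos_freq)
  if (!all(dim(pos_freq) == c(3, 4)) || any(pos_freq < 0)) {
    stop("pos_freq must be a non-negative 3 x 4 matrix (rows = positions)")
  }
  pos_freq <- sweep(pos_freq, 1, rowSums(pos_freq), "/")
  nt <- c("A", "C", "G", "T")
  f <- vapply(space$states, function(cod) {
    b <- strsplit(cod, "")[[1]]
    pos_freq[1, match(b[1], nt)] * pos_freq[2, match(b[2], nt)] *
      pos_freq[3, match(b[3], nt)]
  }, numeric(1))
  unname(f / sum(f))
}

## Infer the default state space for a spec.
.spec_space <- function(spec) {
  switch(spec$kind,
    nucleotide = state_space("nucleotide"),
    amino_acid = state_space("amino_acid"),
    codon = state_space("codon", genetic_code = spec$genetic_code),
    general = state_space("general",
                          states = rownames(spec$params$rates))
  )
}

.check_freq <- function(freq, n, tol = 1e-9) {
  if (length(freq) != n) {
    stop("frequency vector has length ", length(freq), ", state space has ",
         n, " states")
  }
  if (any(freq < 0)) stop("frequencies must be >= 0")
  if (abs(sum(freq) - 1) > 1e-6) stop("frequencies must sum to 1")
  freq / sum(freq)
}

## Unnormalized generator + build frequencies for a spec.  Returns
## list(Q = generator with diagonal set, freq, rate = -sum(pi * diag),
##      reversible).
.build_generator <- function(spec, space = NULL) {
  if (is.null(space)) space <- .spec_space(spec)
  if (!inherits(space, "state_space")) stop("'space' must be a state_space")
  if (spec$kind != space$kind &&
      !(spec$kind == "general" && space$kind == "general")) {
    stop("model '", spec$model, "' needs a ", spec$kind,
         " state space, got ", space$kind)
  }
  n <- space$size
  st <- space$states

  if (spec$model %in% c("HKY", "TN93", "GTR")) {
    freq <- .check_freq(spec$freq, 4)
    R <- matrix(0, 4, 4, dimnames = list(st, st))
    if (spec$model == "GTR") {
      r <- spec$params$rates
      R[1, 2] <- R[2, 1] <- r[1] # AC
      R[1, 3] <- R[3, 1] <- r[2] # AG
      R[1, 4] <- R[4, 1] <- r[3] # AT
      R[2, 3] <- R[3, 2] <- r[4] # CG
      R[2, 4] <- R[4, 2] <- r[5] # CT
      R[3, 4] <- R[4, 3] <- r[6] # GT
    } else {
      k_pur <- if (spec$model == "HKY") spec$params$kappa else spec$params$kappa1
      k_pyr <- if (spec$model == "HKY") spec$params$kappa else spec$params$kappa2
      R[] <- 1
      diag(R) <- 0
      R[1, 3] <- R[3, 1] <- k_pur # A<->G
      R[2, 4] <- R[4, 2] <- k_pyr # C<->T
    }
    Q <- R * rep(freq, each = 4)
    reversible <- TRUE
  } else if (spec$model == "GY94") {
    freq <- if (is.null(spec$freq)) rep(1 / n, n) else .check_freq(spec$freq, n)
    meta <- .codon_change_table(space)
    Q <- matrix(0, n, n, dimnames = list(st, st))
    w <- rep(1, nrow(meta$pairs))
    w[meta$is_transition] <- w[meta$is_transition] * spec$params$kappa
    w[!meta$is_synonymous] <- w[!meta$is_synonymous] * spec$params$omega
    Q[meta$pairs] <- w * freq[meta$pairs[, 2]]
    reversible <- TRUE
  } else if (spec$model == "MG94") {
    meta <- .codon_change_table(space)
    nuc_freq <- spec$params$nuc_freq
    Q <- matrix(0, n, n, dimnames = list(st, st))
    w <- ifelse(meta$is_synonymous, spec$params$alpha, spec$params$beta)
    if (!is.null(spec$params$kappa)) {
      w[meta$is_transition] <- w[meta$is_transition] * spec$params$kappa
    }
    Q[meta$pairs] <- w * nuc_freq[meta$target_nt]
    ## stationary/build frequencies: product of position-wise nucleotide
    ## frequencies restricted to sense codons (detailed balance holds)
    freq <- codon_freq_f1x4(nuc_freq, space)
    reversible <- TRUE
  } else if (spec$model == "EmpiricalAA") {
    dat <- .empirical_aa_data(spec$params$name)
    freq <- if (is.null(spec$freq)) dat$freq else .check_freq(spec$freq, 20)
    Q <- dat$exchangeabilities * rep(freq, each = 20)
    dimnames(Q) <- list(st, st)
    reversible <- TRUE
  } else if (spec$model == "General") {
    Q <- spec$params$rates
    if (nrow(Q) != n) stop("rate table size != state space size")
    dimnames(Q) <- list(st, st)
    diag(Q) <- 0
    freq <- if (is.null(spec$freq)) {
      Qtmp <- Q; diag(Qtmp) <- -rowSums(Qtmp)
      .stationary_of(Qtmp, st)
    } else .check_freq(spec$freq, n)
    reversible <- FALSE
  } else {
    stop("unknown model: ", spec$model)
  }

  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freq * diag(Q))
  if (rate <= 0) stop("degenerate model: zero total substitution rate")
  list(Q = Q, freq = freq, rate = rate, reversible = reversible,
       space = space)
}

## Single-nucleotide codon change bookkeeping (cached per genetic code).
.codon_cache <- new.env(parent = emptyenv())
.codon_change_table <- function(space) {
  key <- paste(space$states, collapse = "")
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  n <- space$size
  chars <- do.call(rbind, strsplit(space$states, ""))
  pairs <- NULL; is_ts <- NULL; is_syn <- NULL; target <- NULL
  nt <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    diffs <- chars != rep(chars[i, ], each = n)
    ndiff <- rowSums(diffs)
    js <- which(ndiff == 1)
    for (j in js) {
      pos <- which(diffs[j, ])
      pairs <- rbind(pairs, c(i, j))
      is_ts <- c(is_ts, .is_transition(chars[i, pos], chars[j, pos]))
      is_syn <- c(is_syn, space$aa[i] == space$aa[j])
      target <- c(target, match(chars[j, pos], nt))
    }
  }
  res <- list(pairs = pairs, is_transition = is_ts, is_synonymous = is_syn,
              target_nt = target)
  .codon_cache[[key]] <- res
  res
}

#' Build a normalized CTMC rate matrix
#'
#' Turns a model specification into a generator `Q` scaled so that one
#' unit of evolutionary distance equals one expected substitution per
#' site: `-sum(pi_i * Q_ii) = 1` with `pi` the build frequencies.  Branch
#' lengths passed to [transition_probabilities()] are therefore in
#' expected substitutions per site.
#'
#' @param spec A [subst_spec] object.
#' @param space Optional [state_space()]; inferred from the spec when
#'   omitted.
#' @return An object of class `"rate_matrix"`: list with `Q` (normalized
#'   generator), `freq` (build frequencies), `space`, `rate_constant`
#'   (the pre-normalization rate), `reversible`.
#' @examples
#' Q <- build_rate_matrix(hky(kappa = 1))    # Jukes-Cantor
#' transition_probabilities(Q, 0.1)
#' @export
build_rate_matrix <- function(spec, space = NULL) {
  g <- .build_generator(spec, space)
  .finalize_rate_matrix(g$Q / g$rate, g$freq, g$space, g$rate, g$reversible,
                        spec)
}

.finalize_rate_matrix <- function(Q, freq, space, rate_constant, reversible,
                                  spec = NULL) {
  obj <- list(Q = Q, freq = freq, space = space,
              rate_constant = rate_constant, reversible = reversible,
              spec = spec)
  obj$decomp <- .decompose_generator(Q, freq, reversible)
  structure(obj, class = "rate_matrix")
}

## Eigen machinery: symmetrized decomposition for reversible generators
## (real spectrum guaranteed); NULL signals the dense-expm route.
.decompose_generator <- function(Q, freq, reversible) {
  if (!reversible || any(freq <= 0)) return(NULL)
  d <- sqrt(freq)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U = e$vectors / d,          # diag(1/d) %*% V
       Uinv = t(e$vectors) * rep(d, each = length(d)))  # t(V) %*% diag(d)
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("rate_matrix:", if (!is.null(x$spec)) x$spec$model else "generator",
      "over", x$space$size, x$space$kind, "states",
      if (x$reversible) "(reversible)" else "(non-reversible)", "\n")
  invisible(x)
}

#' Finite-time transition probabilities
#'
#' Computes `P = exp(Q * distance)` for a built rate matrix.  Reversible
#' generators use their cached symmetrized eigen-decomposition; general
#' (possibly non-reversible or defective) generators fall back to the
#' dense matrix exponential of \pkg{Matrix}.  Rows are cleaned to lie in
#' `[0, 1]` and renormalized to sum to one.
#'
#' @param Q A `"rate_matrix"` from [build_rate_matrix()].
#' @param distance Evolutionary distance in expected substitutions per
#'   site (>= 0, finite).
#' @return Row-stochastic matrix `P` with `P[i, j]` the probability of
#'   ending in state `j` after `distance`, starting from `i`.
#' @export
transition_probabilities <- function(Q, distance) {
  if (!inherits(Q, "rate_matrix")) stop("'Q' must be a rate_matrix")
  if (!is.numeric(distance) || length(distance) != 1 || is.na(distance) ||
      !is.finite(distance) || distance < 0) {
    stop("'distance' must be a single finite number >= 0")
  }
  if (anyNA(Q$Q)) stop("NaN/NA in generator")
  n <- nrow(Q$Q)
  if (distance == 0) {
    P <- diag(n)
    dimnames(P) <- dimnames(Q$Q)
    return(P)
  }
  P <- .mat_exp(Q, distance)
  .clean_stochastic(P)
}

.mat_exp <- function(Q, distance) {
  if (!is.null(Q$decomp)) {
    d <- Q$decomp
    P <- d$U %*% (exp(d$values * distance) * d$Uinv)
    dimnames(P) <- dimnames(Q$Q)
    P
  } else {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q$Q * distance)))
    dimnames(P) <- dimnames(Q$Q)
    P
  }
}

.clean_stochastic <- function(P) {
  P[P < 0] <- 0
  P[P > 1] <- 1
  P / rowSums(P)
}

.stationary_of <- function(Q, labels = rownames(Q)) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- as.vector(qr.solve(A, b))
  pi[abs(pi) < 1e-14] <- 0
  if (any(pi < -1e-8)) stop("stationary solve produced negative entries")
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  names(pi) <- labels
  pi
}

## strong connectivity of the support digraph of Q (off-diagonal > 0)
.unreachable_states <- function(Q) {
  n <- nrow(Q)
  adj <- Q > 0
  diag(adj) <- FALSE
  reach <- function(A) {
    seen <- rep(FALSE, n)
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  fwd <- reach(adj)
  bwd <- reach(t(adj))
  which(!(fwd & bwd))
}

#' Stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by direct linear algebra.  For
#' reversible builds this reproduces the build frequencies; for general
#' models it is the long-run state distribution.
#'
#' @param Q A `"rate_matrix"`.
#' @return Named frequency vector.
#' @export
stationary_distribution <- function(Q) {
  if (!inherits(Q, "rate_matrix")) stop("'Q' must be a rate_matrix")
  bad <- .unreachable_states(Q$Q)
  if (length(bad)) {
    stop("generator is reducible; states not in the recurrent communicating class: ",
         paste(Q$space$states[bad], collapse = ", "))
  }
  .stationary_of(Q$Q, Q$space$states)
}
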