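#' Configuration for the deep-time saturation study
#'
#' A scripted simulation experiment for rapidly-evolving pathogens under
#' increasingly strong purifying selection back in time: GY94 codon
#' substitution with the nonsynonymous/synonymous ratio omega stepping
#' down through a schedule of height intervals (an epoch model), a
#' strict clock, and heterochronous constant-size coalescent genealogies.
#' The defaults follow a log-linear omega decay — omega = 1.0 in the
#' most recent 10 years, then 0.2, 0.1, 0.02, 0.01, 0.002 on successive
#' intervals and 0.001 beyond 5000 years — with a clock of 3e-3 codon
#' substitutions/codon site/year and 50 taxa sampled evenly over 25
#' years.
#'
#' @param omega Omega value per epoch, youngest first (`m + 1` values).
#' @param boundaries Epoch boundary heights in years (`m` values).
#' @param clock_rate Codon substitutions per codon site per year.
#' @param kappa GY94 transition/transversion ratio.
#' @param n_taxa Number of sampled taxa per genealogy.
#' @param sampling_window Tips are sampled evenly over `[0, window]`
#'   years before the present.
#' @param theta Constant population size parameter(s) (Ne x generation
#'   time, years); one genealogy set per level.
#' @param replicates Replicates per theta level.
#' @param n_codons Codon columns per simulated alignment.
#' @param condition_root_height When non-`NULL`, every genealogy is
#'   rescaled to this root height (in years) before sequence simulation,
#'   conditioning the replicate set on a common age of the most recent
#'   common ancestor.
#' @param normalize Epoch normalization convention (see
#'   [epoch_model()]).
#' @return An `"epoch_study_config"`.
#' @export
epoch_study_config <- function(omega = c(1.0, 0.2, 0.1, 0.02, 0.01, 0.002, 0.001),
                               boundaries = c(10, 50, 100, 500, 1000, 5000),
                               clock_rate = 3e-3,
                               kappa = 2,
                               n_taxa = 50,
                               sampling_window = 25,
                               theta = c(1, 5, 10, 50, 100, 500, 1000),
                               replicates = 100,
                               n_codons = 500,
                               condition_root_height = NULL,
                               normalize = c("each", "first")) {
  if (length(omega) != length(boundaries) + 1) {
    stop("need one more omega value (", length(omega),
         ") than boundaries (", length(boundaries), ")")
  }
  stopifnot(clock_rate >= 0, n_taxa >= 2, replicates >= 1, n_codons >= 1)
  structure(list(omega = omega, boundaries = boundaries,
                 clock_rate = clock_rate, kappa = kappa, n_taxa = n_taxa,
                 sampling_window = sampling_window, theta = theta,
                 replicates = replicates, n_codons = n_codons,
                 condition_root_height = condition_root_height,
                 normalize = match.arg(normalize)),
            class = "epoch_study_config")
}

#' Run the deep-time saturation study
#'
#' For every theta level and replicate: simulate a heterochronous
#' constant-size coalescent genealogy, optionally rescale it to the
#' conditioning root height, simulate codons under the omega-epoch GY94
#' process with the configured strict clock, translate to amino acids
#' and record the gap-excluding mean pairwise amino-acid p-distance.
#'
#' @param cfg An [epoch_study_config()].
#' @param seed Optional integer seed (per-replicate seeds are derived
#'   from it).
#' @return Data frame with one row per replicate: `theta`, `replicate`,
#'   `tmrca_sim` (realized root height before conditioning), `tmrca`
#'   (root height actually used) and `mean_aa_distance`.
#' @export
run_epoch_study <- function(cfg = epoch_study_config(), seed = NULL) {
  stopifnot(inherits(cfg, "epoch_study_config"))
  taxa <- taxon_set(
    sprintf("taxon%02d", seq_len(cfg$n_taxa)),
    seq(0, cfg$sampling_window, length.out = cfg$n_taxa)
  )
  specs <- lapply(cfg$omega, function(w) gy94(omega = w, kappa = cfg$kappa))
  em <- epoch_model(cfg$boundaries, specs, normalize = cfg$normalize)
  clock <- if (cfg$clock_rate > 0) {
    clock_model("strict", rate = cfg$clock_rate)
  } else NULL

  rows <- vector("list", length(cfg$theta) * cfg$replicates)
  k <- 0L
  for (th in cfg$theta) {
    demo <- demographic_model("constant", theta = th)
    for (rep_i in seq_len(cfg$replicates)) {
      k <- k + 1L
      if (!is.null(seed)) set.seed(.partition_seed(seed, k))
      tr <- simulate_genealogy(taxa, demo)
      t_sim <- root_height(tr)
      if (!is.null(cfg$condition_root_height)) {
        tr <- rescale_tree(tr, cfg$condition_root_height)
      }
      d <- if (cfg$clock_rate == 0) {
        0   # no substitutions: all sequences identical
      } else {
        p <- partition(cfg$n_codons, tr, em, clock = clock)
        aln <- simulate_alignment(p, translate = TRUE)
        mean_pairwise_aa_distance(aln)
      }
      rows[[k]] <- data.frame(theta = th, replicate = rep_i,
                              tmrca_sim = t_sim, tmrca = root_height(tr),
                              mean_aa_distance = d)
    }
  }
  do.call(rbind, rows)
}

#' Summarize an epoch study by theta level
#'
#' @param tab Output of [run_epoch_study()].
#' @return Data frame with per-theta means of tMRCA and amino-acid
#'   distance.
#' @export
summarize_epoch_study <- function(tab) {
  agg <- stats::aggregate(tab[c("tmrca", "mean_aa_distance")],
                          by = list(theta = tab$theta), FUN = mean)
  names(agg)[2:3] <- c("mean_tmrca", "mean_aa_distance")
  agg
}
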