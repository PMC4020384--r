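#' Discrete state spaces for substitution processes
#'
#' A state space enumerates the labels a continuous-time Markov chain
#' (CTMC) substitution process acts on: the four nucleotides, the twenty
#' amino acids, the sense codons of a genetic code, or an arbitrary set of
#' discrete trait labels (e.g. phylogeographic locations).
#'
#' Nucleotides are always ordered `A, C, G, T`.  Amino acids follow the
#' conventional `ARNDCQEGHILKMFPSTWYV` ordering used by substitution-matrix
#' files.  Codon spaces enumerate triplets in lexicographic order and
#' exclude the stop codons of the chosen genetic code (61 sense codons for
#' the standard code), the usual convention for GY94/MG94-type models.
#'
#' @param kind One of `"nucleotide"`, `"amino_acid"`, `"codon"`,
#'   `"general"`.
#' @param states Character vector of state labels; required for
#'   `"general"`, ignored otherwise.
#' @param genetic_code Named character vector mapping codons to one-letter
#'   amino acids, as returned by [Biostrings::getGeneticCode()]; used only
#'   for codon spaces.  Defaults to the standard code.
#' @return An object of class `"state_space"`: a list with elements
#'   `kind`, `states`, `size`, and, for codon spaces, `aa` (the encoded
#'   amino acid per codon).
#' @examples
#' state_space("nucleotide")
#' cs <- state_space("codon")
#' cs$size  # 61
#' @export
state_space <- function(kind = c("nucleotide", "amino_acid", "codon", "general"),
                        states = NULL,
                        genetic_code = Biostrings::GENETIC_CODE) {
  kind <- match.arg(kind)
  if (kind == "nucleotide") {
    states <- c("A", "C", "G", "T")
    aa <- NULL
  } else if (kind == "amino_acid") {
    states <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    aa <- NULL
  } else if (kind == "codon") {
    nt <- c("A", "C", "G", "T")
    cod <- as.vector(t(outer(
      as.vector(t(outer(nt, nt, paste0))), nt, paste0
    )))
    cod <- sort(cod)
    aa_all <- unname(genetic_code[cod])
    if (anyNA(aa_all)) {
      stop("genetic_code does not cover all 64 codons")
    }
    keep <- aa_all != "*"
    states <- cod[keep]
    aa <- aa_all[keep]
  } else {
    if (is.null(states) || length(states) < 2) {
      stop("a 'general' state space needs >= 2 state labels")
    }
    states <- as.character(states)
    aa <- NULL
  }
  if (anyDuplicated(states)) stop("state labels must be unique")
  structure(
    list(kind = kind, states = states, size = length(states), aa = aa),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("state_space:", x$kind, "with", x$size, "states\n")
  if (x$size <= 24) cat(" ", paste(x$states, sep = "", collapse = " "), "\n")
  invisible(x)
}

## nucleotide transition (vs transversion) indicator for a pair of bases
.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}
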