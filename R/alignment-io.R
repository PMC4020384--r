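#' Write and read alignments
#'
#' `write_fasta()` writes one record per taxon with 80-column line
#' wrapping; `read_fasta()` reads it back losslessly.  `write_nexus()`
#' emits a NEXUS `DATA` block declaring `NTAX`, `NCHAR`, `DATATYPE` and
#' `GAP=-`; `read_nexus_alignment()` reads it back.  Round trips preserve
#' names, order and characters exactly.
#'
#' @param a An [alignment()] (or named character vector of sequences).
#' @param file Output path.
#' @param interleave Write the NEXUS matrix interleaved.
#' @return `write_*` return `file` invisibly; readers return an
#'   [alignment()].
#' @export
write_fasta <- function(a, file) {
  seqs <- if (inherits(a, "alignment")) a$seqs else a
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = file, width = 80L)
  invisible(file)
}

#' @rdname write_fasta
#' @param alphabet Alphabet tag attached to the alignment read back in.
#' @export
read_fasta <- function(file, alphabet = "nucleotide") {
  x <- Biostrings::readBStringSet(file)
  alignment(stats::setNames(as.character(x), names(x)), alphabet)
}

#' @rdname write_fasta
#' @export
write_nexus <- function(a, file, interleave = FALSE) {
  stopifnot(inherits(a, "alignment"))
  datatype <- switch(a$alphabet,
                     nucleotide = "DNA",
                     amino_acid = "PROTEIN",
                     "STANDARD")
  nm <- names(a$seqs)
  quoted <- ifelse(grepl("[ \t]", nm), paste0("'", nm, "'"), nm)
  ntax <- length(a$seqs)
  nchar_ <- nchar(a$seqs[[1]])
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("BEGIN DATA;")
  w("\tDIMENSIONS NTAX=", ntax, " NCHAR=", nchar_, ";")
  w("\tFORMAT DATATYPE=", datatype, " MISSING=? GAP=-",
    if (interleave) " INTERLEAVE=YES" else "", ";")
  w("\tMATRIX")
  pad <- max(nchar(quoted)) + 2L
  if (interleave) {
    for (s in seq(1, nchar_, 80L)) {
      for (j in seq_len(ntax)) {
        w("\t", formatC(quoted[j], width = -pad),
          substr(a$seqs[[j]], s, min(s + 79L, nchar_)))
      }
      w("")
    }
  } else {
    for (j in seq_len(ntax)) {
      w("\t", formatC(quoted[j], width = -pad), a$seqs[[j]])
    }
  }
  w("\t;")
  w("END;")
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_nexus_alignment <- function(file, alphabet = "nucleotide") {
  x <- ape::read.nexus.data(file)
  seqs <- vapply(x, function(v) toupper(paste(v, collapse = "")), character(1))
  alignment(seqs, alphabet)
}

#' Translate codons to amino acids
#'
#' Translates a nucleotide string (length divisible by 3) under a genetic
#' code; all-gap codons `---` become `-`.  Stop codons are an error: the
#' simulator's codon state space excludes them, so their presence
#' indicates data that was not produced under a sense-codon model.
#'
#' @param seq Nucleotide character string.
#' @param genetic_code Named codon-to-amino-acid map (see
#'   [state_space()]).
#' @return Amino-acid string of one third the input length.
#' @examples
#' translate_codons("ATGAAA")  # "MK"
#' @export
translate_codons <- function(seq, genetic_code = Biostrings::GENETIC_CODE) {
  n <- nchar(seq)
  if (n %% 3 != 0) {
    stop("sequence length ", n, " is not divisible by 3 (partial codon)")
  }
  if (n == 0) return("")
  cods <- substring(toupper(seq), seq(1, n, 3), seq(3, n, 3))
  out <- character(length(cods))
  is_gap <- cods == "---"
  out[is_gap] <- "-"
  aa <- unname(genetic_code[cods[!is_gap]])
  if (anyNA(aa)) {
    stop("untranslatable codon(s): ",
         paste(unique(cods[!is_gap][is.na(aa)]), collapse = ", "))
  }
  if (any(aa == "*")) {
    stop("stop codon(s) encountered: ",
         paste(unique(cods[!is_gap][aa == "*"]), collapse = ", "))
  }
  out[!is_gap] <- aa
  paste(out, collapse = "")
}
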