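# Thin wrappers around the ViennaRNA command-line folding engine.
# MFE values are engine- and version-dependent, so the engine identity is
# exposed via folding_engine() and recorded in pipeline run manifests.

folding_binary <- function(tool = c("RNAfold", "RNAduplex")) {
  tool <- match.arg(tool)
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop(tool, " was not found on the PATH. Install ViennaRNA or point PATH ",
         "at an installation providing ", tool, ".", call. = FALSE)
  }
  path
}

#' Identity string of the configured RNA folding engine
#'
#' @return character scalar, e.g. `"RNAfold 2.7.2"`.
#' @export
folding_engine <- function() {
  out <- suppressWarnings(system2(folding_binary("RNAfold"), "--version",
                                  stdout = TRUE, stderr = TRUE))
  trimws(out[1L])
}

#' Predict the minimum-free-energy secondary structure of RNA sequences
#'
#' Folds each sequence with the configured engine and returns the single MFE
#' structure in dot-bracket notation together with its free energy. Input may
#' be in the DNA alphabet; `T` is treated as `U`.
#'
#' @param sequences character vector of sequences (A/C/G/T or A/C/G/U).
#' @return data.frame with columns `sequence`, `structure` (dot-bracket,
#'   same length as the sequence) and `mfe` (kcal/mol, `<= 0`).
#' @examples
#' \dontrun{fold_rna("GGGGAAAACCCC")}
#' @export
fold_rna <- function(sequences) {
  if (!length(sequences)) {
    return(data.frame(sequence = character(0), structure = character(0),
                      mfe = numeric(0), stringsAsFactors = FALSE))
  }
  stopifnot(is.character(sequences), all(nzchar(sequences)))
  rna <- dna2rna(toupper(sequences))
  out <- system2(folding_binary("RNAfold"), c("--noPS"),
                 input = rna, stdout = TRUE, stderr = FALSE)
  if (length(out) != 2L * length(sequences)) {
    stop("RNAfold returned an unexpected number of lines (",
         length(out), " for ", length(sequences), " sequences)")
  }
  res <- out[seq(2L, length(out), by = 2L)]
  m <- regmatches(res, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", res))
  mfe <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  structure <- sub("\\s*\\(\\s*-?[0-9.]+\\)\\s*$", "", res)
  if (any(nchar(structure) != nchar(sequences))) {
    stop("RNAfold structure length does not match input sequence length")
  }
  data.frame(sequence = as.character(sequences), structure = structure,
             mfe = mfe, stringsAsFactors = FALSE)
}

#' Minimum free energy of an intermolecular RNA duplex
#'
#' Computes the hybridization MFE of paired sequences (both given 5'->3')
#' with the duplex engine. Vectorized over pairs.
#'
#' @param seq1,seq2 character vectors of equal length (DNA or RNA alphabet).
#' @return numeric vector of duplex MFEs (kcal/mol).
#' @export
duplex_mfe <- function(seq1, seq2) {
  stopifnot(length(seq1) == length(seq2))
  if (!length(seq1)) return(numeric(0))
  inp <- as.vector(rbind(dna2rna(toupper(seq1)), dna2rna(toupper(seq2))))
  out <- system2(folding_binary("RNAduplex"), stdout = TRUE, stderr = FALSE,
                 input = inp)
  out <- out[nzchar(trimws(out))]
  if (length(out) != length(seq1)) {
    stop("RNAduplex returned ", length(out), " results for ",
         length(seq1), " pairs")
  }
  m <- regmatches(out, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}
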