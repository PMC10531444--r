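#' @importFrom stats cor predict quantile sd setNames
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

# IUPAC degenerate nucleotide codes (DNA alphabet; U is mapped to T upstream)
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#' @param x character scalar over ACGTN
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_pyrimidine <- function(b) b %in% c("C", "T")

# longest contiguous C/T run in a character sequence
longest_pyr_run <- function(x) {
  ch <- seq_chars(x)
  if (length(ch) == 0L) return(0L)
  r <- rle(ch %in% c("C", "T"))
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

assert_acgt <- function(x, what = "sequence") {
  ch <- seq_chars(x)
  bad <- which(!ch %in% BASES)
  if (length(bad) > 0L) {
    stop(sprintf("non-ACGT base '%s' at position %d of %s",
                 ch[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(x)
}

# stable content hash used to tie feature vectors/tables to a registry
registry_hash <- function(names) rlang::hash(as.character(names))
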