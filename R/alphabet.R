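#' Standard amino-acid alphabets
#'
#' One-letter codes for the 20 standard amino acids (\code{aa_standard}) and
#' the extended alphabet including the unknown-residue placeholder \code{"X"}
#' (\code{aa_extended}). All propensity tables in this package are indexed by
#' these alphabets; \code{"X"} is excluded from Wc/Wt/St and from occurrence
#' frequencies, but pair tables carry X rows so that totals remain auditable.
#'
#' @format Character vectors of length 20 and 21.
#' @export
aa_standard <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname aa_standard
#' @export
aa_extended <- c(aa_standard, "X")

# Canonical key for an unordered amino-acid type pair, e.g. "A:L".
pair_key <- function(a1, a2) {
  lo <- ifelse(a1 <= a2, a1, a2)
  hi <- ifelse(a1 <= a2, a2, a1)
  paste(lo, hi, sep = ":")
}

# All unordered pairs over an alphabet, as a data frame (aa1 <= aa2).
all_unordered_pairs <- function(alphabet = aa_extended) {
  idx <- which(upper.tri(diag(length(alphabet)), diag = TRUE), arr.ind = TRUE)
  data.frame(aa1 = alphabet[pmin(idx[, 1], idx[, 2])],
             aa2 = alphabet[pmax(idx[, 1], idx[, 2])],
             stringsAsFactors = FALSE)
}
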