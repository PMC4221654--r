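#' Simplify a secondary-structure assignment to three states
#'
#' Reduces DSSP-style codes to helix/sheet/coil: H, G, and I become helix
#' (H), E becomes sheet (E), everything else becomes coil (C). Then every
#' maximal helix run shorter than five residues and every maximal sheet run
#' shorter than three residues is reassigned to coil, and the helix and
#' sheet fractions are computed over the full residue count.
#'
#' @param codes character vector of per-residue codes (or a single string).
#'   Codes outside \{H,G,I,E,B,T,S,C,-\} are treated as coil with a warning.
#' @return object of class \code{"SimplifiedSS"}: list with \code{codes}
#'   (3-state vector), \code{helix_fraction}, \code{sheet_fraction}.
#' @export
simplify_ss <- function(codes) {
  if (length(codes) == 1L && nchar(codes) > 1L) {
    codes <- strsplit(codes, "")[[1]]
  }
  if (length(codes) == 0L) stop("empty secondary-structure assignment")
  known <- c("H", "G", "I", "E", "B", "T", "S", "C", "-", " ")
  if (any(!codes %in% known)) {
    warning("unknown secondary-structure code(s) treated as coil: ",
            paste(unique(codes[!codes %in% known]), collapse = ", "))
  }
  ss <- ifelse(codes %in% c("H", "G", "I"), "H",
               ifelse(codes == "E", "E", "C"))
  r <- rle(ss)
  r$values[r$values == "H" & r$lengths < 5L] <- "C"
  r$values[r$values == "E" & r$lengths < 3L] <- "C"
  ss <- inverse.rle(r)
  structure(list(codes = ss,
                 helix_fraction = mean(ss == "H"),
                 sheet_fraction = mean(ss == "E")),
            class = "SimplifiedSS")
}

#' Assign a structural class from simplified secondary structure
#'
#' Applies composition thresholds to the helix and sheet fractions:
#' more than 15\% helix and less than 10\% sheet gives alpha; less than
#' 15\% helix and more than 10\% sheet gives beta; less than 15\% helix and
#' less than 10\% sheet gives alpha+beta. A domain matching none of these
#' (all inequalities are strict, so boundary values fall through) is
#' unassigned and excluded from downstream re-ranking.
#'
#' The printed alpha+beta rule selects domains poor in both secondary
#' structures, which is unusual for that label; \code{rule = "both_rich"}
#' swaps in the conventional variant (more than 15\% helix and more than
#' 10\% sheet).
#'
#' @param ss a \code{SimplifiedSS} from \code{\link{simplify_ss}} (a raw code
#'   vector or string is simplified first).
#' @param rule \code{"printed"} (default) or \code{"both_rich"}.
#' @return one of \code{"alpha"}, \code{"beta"}, \code{"alpha_beta"},
#'   \code{"unassigned"}.
#' @export
assign_class <- function(ss, rule = c("printed", "both_rich")) {
  rule <- match.arg(rule)
  if (!inherits(ss, "SimplifiedSS")) ss <- simplify_ss(ss)
  h <- ss$helix_fraction
  e <- ss$sheet_fraction
  if (h > 0.15 && e < 0.10) return("alpha")
  if (h < 0.15 && e > 0.10) return("beta")
  ab <- if (rule == "printed") h < 0.15 && e < 0.10 else h > 0.15 && e > 0.10
  if (ab) return("alpha_beta")
  "unassigned"
}
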