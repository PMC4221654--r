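#' Per-domain contact participation counts
#'
#' For each amino-acid type a, counts the residues of that type that form at
#' least one contact site (\code{Ic}) and all residues of that type
#' (\code{Iw}). Residues of unknown type are tallied under \code{"X"}.
#'
#' @param domain a \code{Domain}.
#' @param map the \code{ContactMap} built from this domain.
#' @return object of class \code{"DomainContactSummary"}: list with
#'   \code{domain_id}, \code{class_label}, \code{topology_label}, and named
#'   integer vectors \code{Ic} and \code{Iw} over the 21-letter alphabet.
#' @export
summarize_domain <- function(domain, map) {
  if (map$domain_id != domain$domain_id) {
    stop("contact map was built from domain '", map$domain_id,
         "', not '", domain$domain_id, "'")
  }
  deg <- contact_degree(map)
  Iw <- table(factor(domain$aa, levels = aa_extended))
  Ic <- table(factor(domain$aa[deg >= 1L], levels = aa_extended))
  structure(list(domain_id = domain$domain_id,
                 class_label = domain$class_label,
                 topology_label = domain$topology_label,
                 Ic = stats::setNames(as.integer(Ic), aa_extended),
                 Iw = stats::setNames(as.integer(Iw), aa_extended)),
            class = "DomainContactSummary")
}

# Unweighted mean over proteins of the per-protein ratio Ic/Iw, restricted
# to proteins that contain the amino acid. Shared by Wc and Wt.
propensity_from_summaries <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  out <- data.frame(aa = aa_standard, W = NA_real_, sd = NA_real_,
                    N = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(aa_standard)) {
    a <- aa_standard[k]
    ratios <- unlist(lapply(summaries, function(s) {
      if (s$Iw[[a]] > 0L) s$Ic[[a]] / s$Iw[[a]] else NULL
    }))
    out$N[k] <- length(ratios)
    if (length(ratios) > 0L) {
      out$W[k] <- mean(ratios)
      out$sd[k] <- if (length(ratios) > 1L) stats::sd(ratios) else 0
    }
  }
  out
}

#' Class contact propensity Wc
#'
#' For every standard amino-acid type a, Wc is the unweighted mean over the
#' proteins of a class of the per-protein fraction of type-a residues that
#' form at least one contact site. Each protein that contains the amino acid
#' contributes one ratio; proteins lacking it contribute nothing. The
#' standard deviation of the per-protein ratios is reported alongside.
#'
#' @param summaries list of \code{DomainContactSummary} objects (one class).
#' @return data frame with columns \code{aa}, \code{Wc}, \code{sd}, \code{N}
#'   (number of proteins containing the amino acid). \code{Wc} is \code{NA}
#'   for types absent from every protein (undefined, not zero).
#' @export
compute_Wc <- function(summaries) {
  out <- propensity_from_summaries(summaries)
  names(out)[names(out) == "W"] <- "Wc"
  out
}

#' Topology contact propensity Wt
#'
#' Identical to \code{\link{compute_Wc}} but computed over the proteins of a
#' single topology instead of a whole class.
#'
#' @param summaries list of \code{DomainContactSummary} objects (one
#'   topology).
#' @return data frame with columns \code{aa}, \code{Wt}, \code{sd}, \code{N}.
#' @export
compute_Wt <- function(summaries) {
  out <- propensity_from_summaries(summaries)
  names(out)[names(out) == "W"] <- "Wt"
  out
}

#' Amino-acid occurrence frequencies in a class
#'
#' Counts residues over all domains and normalizes to sum 1 over the 20
#' standard types; \code{"X"} placeholders are excluded from numerator and
#' denominator.
#'
#' @param domains list of \code{Domain} objects.
#' @return named numeric vector over \code{aa_standard} summing to 1.
#' @export
compute_frequencies <- function(domains) {
  stopifnot(length(domains) >= 1L)
  aa <- unlist(lapply(domains, function(d) d$aa))
  aa <- aa[aa != "X"]
  if (length(aa) == 0L) stop("no standard amino acids in the domain set")
  counts <- table(factor(aa, levels = aa_standard))
  stats::setNames(as.numeric(counts) / sum(counts), aa_standard)
}

#' Pair contact frequencies fp for a class
#'
#' For every unordered amino-acid type pair (a1, a2), \code{Jc} counts the
#' contact sites formed between residues of those types across all domains
#' of the class (each contact counted once; homotypic pairs once per
#' contact), and \code{fp = Jc / Jw} where \code{Jw} is the total number of
#' contact sites in the class. Pairs involving \code{"X"} are reported under
#' X rows; by default they count toward \code{Jw} (the literal total number
#' of contact sites), so that fp sums to 1 over the full 21-letter pair
#' alphabet.
#'
#' @param maps list of \code{ContactMap} objects.
#' @param domains list of the matching \code{Domain} objects (same order).
#' @param class_label label stored in the table.
#' @param include_x_in_total logical; when FALSE, contacts involving X are
#'   dropped from \code{Jw} as well, so fp sums to 1 over non-X pairs.
#' @return object of class \code{"PairFrequencyTable"}: data frame with
#'   columns \code{aa1}, \code{aa2}, \code{Jc}, \code{fp}, plus attributes
#'   \code{Jw} and \code{class_label}. \code{fp} is \code{NA} throughout if
#'   \code{Jw} is 0.
#' @export
compute_fp <- function(maps, domains, class_label = NA_character_,
                       include_x_in_total = TRUE) {
  stopifnot(length(maps) == length(domains))
  tab <- all_unordered_pairs(aa_extended)
  keys <- pair_key(tab$aa1, tab$aa2)
  Jc <- stats::setNames(integer(length(keys)), keys)
  Jw <- 0L
  for (m in seq_along(maps)) {
    map <- maps[[m]]; dom <- domains[[m]]
    if (map$domain_id != dom$domain_id) {
      stop("maps and domains are not aligned at position ", m)
    }
    if (nrow(map$pairs) == 0L) next
    a1 <- dom$aa[map$pairs[, 1]]
    a2 <- dom$aa[map$pairs[, 2]]
    has_x <- a1 == "X" | a2 == "X"
    Jw <- Jw + if (include_x_in_total) nrow(map$pairs) else sum(!has_x)
    k <- pair_key(a1, a2)
    cnt <- table(k)
    Jc[names(cnt)] <- Jc[names(cnt)] + as.integer(cnt)
  }
  tab$Jc <- unname(Jc)
  if (Jw > 0L) {
    tab$fp <- tab$Jc / Jw
  } else {
    warning("no contact sites in class; fp undefined")
    tab$fp <- NA_real_
  }
  attr(tab, "Jw") <- Jw
  attr(tab, "class_label") <- class_label
  class(tab) <- c("PairFrequencyTable", "data.frame")
  tab
}

#' Normalized pair contact frequencies fpn
#'
#' Divides each pair's fp by the product of the occurrence frequencies of
#' its two amino acids in the class: \code{fpn = fp / (f_a1 * f_a2)}. Rows
#' involving \code{"X"} and rows where a frequency is zero while fp is zero
#' are reported as \code{NA} (undefined, not zero); a zero frequency with a
#' positive fp is an inconsistency and raises an error.
#'
#' @param fp_table a \code{PairFrequencyTable} from \code{\link{compute_fp}}.
#' @param frequencies named frequency vector from
#'   \code{\link{compute_frequencies}}.
#' @return the table with an \code{fpn} column appended.
#' @export
compute_fpn <- function(fp_table, frequencies) {
  stopifnot(all(c("aa1", "aa2", "fp") %in% names(fp_table)))
  f1 <- frequencies[fp_table$aa1]
  f2 <- frequencies[fp_table$aa2]
  denom <- unname(f1 * f2)
  bad <- !is.na(fp_table$fp) & fp_table$fp > 0 &
    (is.na(denom) | denom == 0) &
    fp_table$aa1 != "X" & fp_table$aa2 != "X"
  if (any(bad)) {
    stop("pair(s) with positive fp but zero occurrence frequency: ",
         paste(pair_key(fp_table$aa1[bad], fp_table$aa2[bad]),
               collapse = ", "))
  }
  fpn <- fp_table$fp / denom
  fpn[is.na(denom) | denom == 0] <- NA_real_
  fpn[fp_table$aa1 == "X" | fp_table$aa2 == "X"] <- NA_real_
  fp_table$fpn <- fpn
  fp_table
}

#' Topology divergence St
#'
#' Root-mean-square (N-1 normalized) deviation between a topology's Wt
#' profile and its class's Wc profile, over the amino-acid types present in
#' the topology (X excluded, maximum 20 types). A small St means the
#' topology's contact behaviour represents its class well.
#'
#' @param wt_table data frame from \code{\link{compute_Wt}} for the topology.
#' @param wc_table data frame from \code{\link{compute_Wc}} for the class
#'   containing it.
#' @return list with \code{St} (NA with a warning when fewer than 2 types are
#'   present) and \code{n_types}.
#' @export
compute_St <- function(wt_table, wc_table) {
  stopifnot(identical(wt_table$aa, wc_table$aa))
  present <- wt_table$N >= 1L & !is.na(wt_table[[2]])
  n <- sum(present)
  if (n < 2L) {
    warning("St undefined: fewer than 2 amino-acid types present in topology")
    return(list(St = NA_real_, n_types = n))
  }
  diffs <- wt_table[[2]][present] - wc_table[[2]][present]
  if (anyNA(diffs)) {
    stop("class Wc undefined for a type present in the topology")
  }
  list(St = sqrt(sum(diffs^2) / (n - 1)), n_types = n)
}
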