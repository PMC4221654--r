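#' Empirical pair frequency inside a candidate top set
#'
#' Computes Jc / K where Jc is the number of pairs in the top set whose
#' unordered amino-acid type pair matches the candidate's. The candidate's
#' own occurrence is counted or not according to \code{include}; the
#' denominator is always the target set size K, never the current top-set
#' size.
#'
#' @param top_keys character vector of canonical type-pair keys (see
#'   \code{pair_key}) of the pairs currently in the top set, or a list of
#'   2-character vectors \code{c(a1, a2)}.
#' @param pair length-2 character vector with the candidate's amino-acid
#'   types; must not contain \code{"X"}.
#' @param K target top-set size (the constant denominator).
#' @param include logical; count the candidate's own occurrence.
#' @param candidate_in_top logical; whether the candidate is currently a
#'   member of the top set (TRUE during the removal pass, FALSE during the
#'   addition pass).
#' @return the empirical frequency, a real number >= 0.
#' @export
compute_domain_pair_fp <- function(top_keys, pair, K, include = TRUE,
                                   candidate_in_top = TRUE) {
  if (any(pair == "X")) stop("pairs containing X are never evaluated")
  if (is.list(top_keys)) {
    top_keys <- vapply(top_keys, function(p) pair_key(p[1], p[2]),
                       character(1))
  }
  key <- pair_key(pair[1], pair[2])
  jc <- sum(top_keys == key)
  jc_others <- if (candidate_in_top) max(jc - 1L, 0L) else jc
  (jc_others + as.integer(include)) / K
}

#' Normalized empirical pair frequency inside a candidate top set
#'
#' The value of \code{\link{compute_domain_pair_fp}} divided by the product
#' of the domain occurrence frequencies of the candidate's two amino acids.
#'
#' @inheritParams compute_domain_pair_fp
#' @param f_ad named numeric vector of per-type occurrence frequencies in
#'   the domain; both of the candidate's types must have positive frequency.
#' @return the normalized empirical frequency.
#' @export
compute_domain_pair_fpn <- function(top_keys, pair, K, f_ad, include = TRUE,
                                    candidate_in_top = TRUE) {
  denom <- unname(f_ad[pair[1]] * f_ad[pair[2]])
  if (is.na(denom) || denom <= 0) {
    stop("zero occurrence frequency for amino acid(s) in pair ",
         pair_key(pair[1], pair[2]))
  }
  compute_domain_pair_fp(top_keys, pair, K, include, candidate_in_top) / denom
}

#' Re-rank contact scores against class pair frequencies
#'
#' Post-processes per-residue-pair contact scores (e.g., direct information
#' from direct coupling analysis) so that the composition of the top K pairs
#' better matches the contact pair frequencies of the domain's structural
#' class. The procedure:
#'
#' \enumerate{
#'   \item Pairs are sorted by score (descending; ties by (i, j)); the first
#'     K form the top set, the remainder the rest set.
#'   \item Removal pass: walking the top set from the lowest score upward,
#'     each pair's empirical frequency in the top set is computed twice over
#'     the constant denominator K - counting the pair itself (inc) and not
#'     (exc). If dropping the pair brings the empirical frequency closer to
#'     the class value, the pair is moved to the removal set; counts update
#'     immediately so later decisions see the shrunken top set.
#'   \item Addition pass: walking the rest set from the highest score
#'     downward, a pair is appended to the end of the top set when including
#'     it brings the empirical frequency closer to the class value, until
#'     the top set holds K pairs or the rest set is exhausted.
#'   \item Backfill: while the top set still holds fewer than K pairs, the
#'     most recently removed pairs are appended back (last removed first).
#' }
#'
#' Pairs containing an \code{"X"} residue are never evaluated or moved: those
#' in the initial top set simply stay there. In \code{mode = "fpn"} the
#' empirical and class frequencies are both normalized by amino-acid
#' occurrence frequency products (class frequencies from the table's
#' \code{fpn} column; empirical ones by the domain's own frequencies).
#'
#' @param scores data frame with columns \code{i}, \code{j}, \code{score}
#'   (deduplicated unordered pairs, as from \code{\link{read_score_table}}).
#' @param aa character vector of the domain's amino-acid sequence
#'   (one-letter codes), or a \code{Domain}.
#' @param class_table a \code{PairFrequencyTable} for the domain's class,
#'   with an \code{fp} column (and \code{fpn} for \code{mode = "fpn"}).
#' @param mode \code{"fp"} or \code{"fpn"}.
#' @param K target set size; the default 200 matches the standard evaluation
#'   depth of 200 top-ranked contacts.
#' @param live_update logical; when FALSE the removal pass decides against
#'   the counts frozen at pass start (sensitivity variant).
#' @return data frame with columns \code{i}, \code{j}, \code{score},
#'   \code{status} (\code{"kept"}, \code{"added"}, or \code{"backfilled"}),
#'   ordered: retained pairs in score order, then additions in acceptance
#'   order, then backfills.
#' @export
rerank <- function(scores, aa, class_table, mode = c("fp", "fpn"), K = 200,
                   live_update = TRUE) {
  mode <- match.arg(mode)
  if (inherits(aa, "Domain")) aa <- aa$aa
  aa[!aa %in% aa_extended] <- "X"
  stopifnot(is.data.frame(scores),
            all(c("i", "j", "score") %in% names(scores)))
  if (anyDuplicated(paste(pmin(scores$i, scores$j),
                          pmax(scores$i, scores$j)))) {
    stop("duplicate unordered pairs in score table")
  }
  if (max(scores$i, scores$j) > length(aa)) {
    stop("score table references residues beyond the sequence length")
  }
  if (is.null(class_table)) stop("a class pair-frequency table is required")
  value_col <- if (mode == "fpn") "fpn" else "fp"
  if (!value_col %in% names(class_table)) {
    stop("class table lacks a '", value_col, "' column")
  }

  cls <- stats::setNames(class_table[[value_col]],
                         pair_key(class_table$aa1, class_table$aa2))
  cls[is.na(cls)] <- 0
  cls_get <- function(k) if (k %in% names(cls)) cls[[k]] else 0

  f_ad <- NULL
  if (mode == "fpn") {
    aa_std <- aa[aa != "X"]
    if (length(aa_std) == 0L) stop("domain sequence is all X")
    f_ad <- stats::setNames(
      as.numeric(table(factor(aa_std, levels = aa_standard))) /
        length(aa_std), aa_standard)
  }

  ord <- order(-scores$score, scores$i, scores$j)
  scores <- scores[ord, , drop = FALSE]
  m <- nrow(scores)
  if (K > m) {
    warning("K (", K, ") exceeds the number of scored pairs (", m,
            "); top set is the full input")
  }
  k_top <- min(K, m)
  a1 <- aa[scores$i]
  a2 <- aa[scores$j]
  key <- pair_key(a1, a2)
  is_x <- a1 == "X" | a2 == "X"

  # normalized class-vs-empirical distance; in fpn mode the empirical Jc/K
  # is divided by the domain frequency product
  pair_denom <- if (mode == "fpn") {
    d <- f_ad[a1] * f_ad[a2]
    if (any(!is_x & (is.na(d) | d <= 0))) {
      stop("zero domain frequency for amino acid(s) in a scored non-X pair")
    }
    unname(d)
  } else rep(1, m)

  in_top <- c(rep(TRUE, k_top), rep(FALSE, m - k_top))
  tally <- table(key[in_top])
  jc <- stats::setNames(as.integer(tally), names(tally))
  jc_get <- function(k) if (k %in% names(jc)) jc[[k]] else 0L

  status <- rep(NA_character_, m)
  status[in_top] <- "kept"
  rmv <- integer(0)  # row indices in removal order

  # removal pass: ascending score over the initial top set
  frozen <- jc
  for (r in rev(seq_len(k_top))) {
    if (is_x[r]) next
    base <- if (live_update) jc_get(key[r]) else
      if (key[r] %in% names(frozen)) frozen[[key[r]]] else 0L
    # pair r is still counted in `base` under live update; under the frozen
    # variant `base` is the pass-start count, which also includes it
    fp_inc <- (base / K) / pair_denom[r]
    fp_exc <- ((base - 1L) / K) / pair_denom[r]
    target <- cls_get(key[r])
    if (abs(fp_inc - target) > abs(fp_exc - target)) {
      in_top[r] <- FALSE
      status[r] <- NA_character_
      rmv <- c(rmv, r)
      jc[key[r]] <- jc_get(key[r]) - 1L
    }
  }

  # addition pass: descending score over the rest set
  n_top <- sum(in_top)
  if (m > k_top) {
    for (r in (k_top + 1L):m) {
      if (n_top >= K) break
      if (is_x[r]) next
      base <- jc_get(key[r])  # candidate not in top set
      fp_exc <- (base / K) / pair_denom[r]
      fp_inc <- ((base + 1L) / K) / pair_denom[r]
      target <- cls_get(key[r])
      if (!(abs(fp_inc - target) > abs(fp_exc - target))) {
        in_top[r] <- TRUE
        status[r] <- "added"
        jc[key[r]] <- base + 1L
        n_top <- n_top + 1L
      }
    }
  }

  # backfill: latest removed first, appended at the end
  backfilled <- integer(0)
  while (n_top < K && length(rmv) > 0L) {
    r <- rmv[length(rmv)]
    rmv <- rmv[-length(rmv)]
    backfilled <- c(backfilled, r)
    status[r] <- "backfilled"
    in_top[r] <- TRUE
    n_top <- n_top + 1L
  }

  kept_rows <- which(in_top & status == "kept")
  added_rows <- which(status == "added")
  out_rows <- c(kept_rows, added_rows, backfilled)
  out <- scores[out_rows, c("i", "j", "score"), drop = FALSE]
  out$status <- status[out_rows]
  rownames(out) <- NULL
  out
}
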