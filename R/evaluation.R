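#' Structural truth contact map for evaluation
#'
#' Builds the reference contact map used to score predictions, by default at
#' the standard evaluation setting of cutoff 8 Angstrom and separation 10.
#'
#' @param domain a \code{Domain}.
#' @param cutoff distance cutoff in Angstrom.
#' @param separation minimum sequence separation.
#' @return a \code{ContactMap}.
#' @export
truth_map <- function(domain, cutoff = 8, separation = 10) {
  build_contact_map(domain, contact_params(cutoff, separation))
}

#' True-positive-rate curve of a ranked prediction
#'
#' For each n from 1 up to \code{n_max} (or the number of available
#' predictions, whichever is smaller), the TP rate is the fraction of the
#' first n ranked pairs that are true contacts. Predicted pairs count as
#' true only at exact (i, j) identity.
#'
#' @param predicted matrix or data frame whose first two columns are the
#'   predicted residue pairs in rank order (best first), deduplicated.
#' @param truth a \code{ContactMap} with the reference contacts.
#' @param n_max maximum prediction depth (default 200).
#' @return object of class \code{"TPRateCurve"}: data frame with columns
#'   \code{n} and \code{tp_rate}.
#' @export
tp_curve <- function(predicted, truth, n_max = 200) {
  pred <- as.matrix(predicted[, 1:2, drop = FALSE])
  pi <- pmin(pred[, 1], pred[, 2])
  pj <- pmax(pred[, 1], pred[, 2])
  pkey <- paste(pi, pj)
  if (anyDuplicated(pkey)) stop("duplicate pairs in prediction list")
  tkey <- paste(truth$pairs[, 1], truth$pairs[, 2])
  n_eff <- min(n_max, length(pkey))
  if (n_eff == 0L) {
    out <- data.frame(n = integer(0), tp_rate = numeric(0))
  } else {
    hits <- cumsum(pkey[seq_len(n_eff)] %in% tkey)
    out <- data.frame(n = seq_len(n_eff), tp_rate = hits / seq_len(n_eff))
  }
  class(out) <- c("TPRateCurve", "data.frame")
  out
}

#' Mean TP-rate curve over domains
#'
#' Averages per-domain TP-rate curves (unweighted) at each prediction depth
#' n. Domains whose curves are truncated before n contribute only where
#' their curve is defined.
#'
#' @param curves list of \code{TPRateCurve} objects.
#' @param n_max maximum depth of the output curve.
#' @return data frame of class \code{"TPRateCurve"} with columns \code{n},
#'   \code{tp_rate}, and \code{n_domains} (curves contributing at each n).
#' @export
mean_tp_curve <- function(curves, n_max = 200) {
  stopifnot(length(curves) >= 1L)
  n_top <- min(n_max, max(vapply(curves, nrow, integer(1))))
  if (n_top == 0L) stop("all curves are empty")
  acc <- numeric(n_top)
  cnt <- integer(n_top)
  for (cv in curves) {
    k <- min(nrow(cv), n_top)
    if (k == 0L) next
    acc[1:k] <- acc[1:k] + cv$tp_rate[1:k]
    cnt[1:k] <- cnt[1:k] + 1L
  }
  out <- data.frame(n = seq_len(n_top), tp_rate = acc / pmax(cnt, 1L),
                    n_domains = cnt)
  out$tp_rate[cnt == 0L] <- NA_real_
  class(out) <- c("TPRateCurve", "data.frame")
  out
}

#' Plot a TP-rate curve
#'
#' @param x a \code{TPRateCurve}.
#' @param ... further arguments passed to \code{plot.default}.
#' @export
plot.TPRateCurve <- function(x, ...) {
  plot(x$n, x$tp_rate, type = "l", xlab = "top-ranked contacts",
       ylab = "mean TP rate", ylim = c(0, 1), ...)
  invisible(x)
}
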