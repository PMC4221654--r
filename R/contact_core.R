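#' Contact definition parameters
#'
#' A contact site is an unordered residue pair whose Cbeta-Cbeta distance is
#' no greater than \code{cutoff} and whose sequence separation |i - j| is at
#' least \code{separation} (adjacent residues have separation 1).
#'
#' @param cutoff maximum Cbeta-Cbeta distance in Angstrom; must be positive.
#'   Sweeps in this package typically cover 6-12 A.
#' @param separation minimum sequence separation (residues); must be >= 1.
#'   Typical sweeps cover 1-15.
#' @return an object of class \code{"ContactParams"}.
#' @export
contact_params <- function(cutoff, separation) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive distance in Angstrom")
  }
  if (!is.numeric(separation) || length(separation) != 1L || separation < 1) {
    stop("separation must be a single integer >= 1")
  }
  structure(list(cutoff = as.numeric(cutoff),
                 separation = as.integer(separation)),
            class = "ContactParams")
}

#' Build the contact map of a domain
#'
#' Returns exactly the unordered residue pairs (i < j) whose representative
#' Cbeta atoms lie within \code{params$cutoff} Angstrom and whose sequence
#' separation is at least \code{params$separation}. Residues without a
#' representative coordinate never appear in any pair.
#'
#' @param domain a \code{Domain}.
#' @param params a \code{ContactParams} (or a list with \code{cutoff} and
#'   \code{separation}).
#' @param separation_strict logical; when TRUE the separation predicate is
#'   |i - j| > separation instead of >=, for comparison with tools that use
#'   the strict convention.
#' @return object of class \code{"ContactMap"}: list with \code{domain_id},
#'   \code{cutoff}, \code{separation}, \code{n_residues}, and \code{pairs},
#'   an m x 2 integer matrix with \code{pairs[,1] < pairs[,2]}.
#' @export
build_contact_map <- function(domain, params, separation_strict = FALSE) {
  ok <- stats::complete.cases(domain$cbeta)
  idx <- which(ok)
  if (length(idx) < 2L) {
    warning("domain '", domain$domain_id,
            "' has fewer than 2 residues with coordinates; empty contact map")
    return(new_contact_map(domain, params, matrix(integer(0), 0, 2)))
  }
  xyz <- domain$cbeta[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  si <- domain$seq_index[idx]
  sep <- abs(outer(si, si, "-"))
  keep_sep <- if (separation_strict) sep > params$separation else
    sep >= params$separation
  hit <- which(upper.tri(d) & d <= params$cutoff & keep_sep, arr.ind = TRUE)
  pairs <- cbind(idx[hit[, 1]], idx[hit[, 2]])
  if (nrow(pairs) > 0L) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  new_contact_map(domain, params, pairs)
}

new_contact_map <- function(domain, params, pairs) {
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("i", "j")
  structure(list(domain_id = domain$domain_id,
                 cutoff = params$cutoff,
                 separation = params$separation,
                 n_residues = n_residues(domain),
                 pairs = pairs),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat("ContactMap", x$domain_id, "-", nrow(x$pairs), "contacts (cutoff",
      x$cutoff, "A, separation", x$separation, ")\n")
  invisible(x)
}

#' Contact degree of a residue
#'
#' The contact degree of a residue is the number of contact sites it
#' participates in.
#'
#' @param map a \code{ContactMap}.
#' @param i residue sequence index; when missing, the full degree vector over
#'   all residues of the domain is returned.
#' @return integer degree (or integer vector).
#' @export
contact_degree <- function(map, i) {
  deg <- tabulate(c(map$pairs[, 1], map$pairs[, 2]), nbins = map$n_residues)
  if (missing(i)) return(deg)
  if (i < 1L || i > map$n_residues) stop("residue index out of range")
  deg[i]
}

#' Average contact degree over a set of domains
#'
#' Pools the contact degrees of all residues of all domains (degree-0
#' residues included) and reports their mean and standard deviation. Because
#' it is ambiguous whether spread should be taken over residues or over
#' proteins, both are reported: \code{sd} over pooled residues and
#' \code{sd_domains} over per-domain means.
#'
#' @param domains list of \code{Domain} objects.
#' @param params a \code{ContactParams}.
#' @return list with \code{mean}, \code{sd} (over residues),
#'   \code{sd_domains} (over per-domain mean degrees), and
#'   \code{n_residues}.
#' @export
average_contact_degree <- function(domains, params) {
  stopifnot(length(domains) > 0L)
  degs <- lapply(domains, function(d)
    contact_degree(suppressWarnings(build_contact_map(d, params))))
  pooled <- unlist(degs)
  per_dom <- vapply(degs, mean, numeric(1))
  list(mean = mean(pooled),
       sd = if (length(pooled) > 1L) stats::sd(pooled) else 0,
       sd_domains = if (length(per_dom) > 1L) stats::sd(per_dom) else 0,
       n_residues = length(pooled))
}

#' Sweep average contact degree over a parameter grid
#'
#' @param domains list of \code{Domain} objects.
#' @param cutoffs numeric vector of cutoff distances (Angstrom).
#' @param separations integer vector of minimum separations.
#' @return data frame with one row per (cutoff, separation) cell and columns
#'   \code{cutoff}, \code{separation}, \code{mean}, \code{sd},
#'   \code{sd_domains}.
#' @export
sweep_average_degree <- function(domains, cutoffs, separations) {
  stopifnot(length(cutoffs) > 0L, length(separations) > 0L)
  grid <- expand.grid(separation = separations, cutoff = cutoffs)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    acd <- average_contact_degree(
      domains, contact_params(grid$cutoff[r], grid$separation[r]))
    data.frame(cutoff = grid$cutoff[r], separation = grid$separation[r],
               mean = acd$mean, sd = acd$sd, sd_domains = acd$sd_domains)
  })
  do.call(rbind, res)
}

#' Fit a power law y = a * x^b
#'
#' Parameters are estimated by ordinary least squares on log-transformed
#' data; the goodness of fit R-squared is computed on the original (linear)
#' scale against the back-transformed curve a * x^b.
#'
#' @param x positive predictor values (at least 3).
#' @param y positive response values.
#' @return object of class \code{"PowerFit"}: list with \code{a}, \code{b},
#'   \code{r_squared}, and \code{fitted}.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("power-law fit needs at least 3 points")
  if (any(x <= 0) || any(y <= 0)) {
    stop("power-law fit requires strictly positive x and y")
  }
  fit <- stats::lm(log(y) ~ log(x))
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  yhat <- a * x^b
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < .Machine$double.eps^0.5) 1 else -Inf
  } else 1 - ss_res / ss_tot
  structure(list(a = a, b = b, r_squared = r2, fitted = yhat),
            class = "PowerFit")
}

#' @export
print.PowerFit <- function(x, ...) {
  cat(sprintf("PowerFit: y = %.4g * x^%.4g  (R-squared %.4f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}
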