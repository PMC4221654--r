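# Independent oracles: deliberately naive transcriptions of the definitions,
# kept free of the package's own code paths.

# Build a bare Domain from explicit coordinates and types.
toy_domain <- function(coords, aa, id = "toy") {
  contactprop:::new_domain(domain_id = id, aa = aa,
                           cbeta = matrix(coords, ncol = 3, byrow = TRUE))
}

# O(n^2) contact scan: explicit loop over i, vectorized only over j.
brute_contacts <- function(domain, cutoff, separation, strict = FALSE) {
  xyz <- domain$cbeta
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1)) {
    if (anyNA(xyz[i, ])) next
    js <- (i + 1):n
    ok <- !apply(is.na(xyz[js, , drop = FALSE]), 1, any)
    d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
    sep <- js - i
    hit <- ok & d <= cutoff & (if (strict) sep > separation else sep >= separation)
    if (any(hit)) out <- rbind(out, cbind(i, js[hit]))
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  unname(out)
}

pairs_as_keys <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  sort(paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
}

# Direct transcription of the class propensity: unweighted mean over the
# proteins containing the amino acid of (#in-contact / #total).
oracle_W <- function(domains, maps, a) {
  ratios <- c()
  for (k in seq_along(domains)) {
    aa <- domains[[k]]$aa
    iw <- sum(aa == a)
    if (iw == 0) next
    touched <- unique(c(maps[[k]]$pairs))
    ic <- sum(aa[touched] == a)
    ratios <- c(ratios, ic / iw)
  }
  if (length(ratios) == 0) NA_real_ else mean(ratios)
}

# Direct tally of pair contact frequencies: every contact counted once under
# its unordered type pair; Jw = all contacts.
oracle_fp <- function(domains, maps, a1, a2, include_x_in_total = TRUE) {
  jc <- 0L; jw <- 0L
  for (k in seq_along(domains)) {
    aa <- domains[[k]]$aa
    prs <- maps[[k]]$pairs
    if (nrow(prs) == 0) next
    t1 <- aa[prs[, 1]]; t2 <- aa[prs[, 2]]
    keep <- if (include_x_in_total) rep(TRUE, length(t1)) else
      t1 != "X" & t2 != "X"
    jw <- jw + sum(keep)
    jc <- jc + sum((t1 == a1 & t2 == a2) | (t1 == a2 & t2 == a1))
  }
  if (jw == 0) NA_real_ else jc / jw
}

oracle_St <- function(wt, wc, present) {
  d <- wt[present] - wc[present]
  sqrt(sum(d^2) / (sum(present) - 1))
}

# Independent transcription of the re-ranking procedure (steps b-e).
# Pairs live in plain lists; Jc is recounted from scratch at every decision.
oracle_rerank <- function(scores, aa, class_values, K, mode = "fp",
                          f_ad = NULL) {
  cls <- function(a1, a2) {
    k <- paste(sort(c(a1, a2)), collapse = ":")
    if (k %in% names(class_values) && !is.na(class_values[[k]]))
      class_values[[k]] else 0
  }
  ord <- order(-scores$score, scores$i, scores$j)
  rows <- lapply(ord, function(r) list(i = scores$i[r], j = scores$j[r],
                                       score = scores$score[r],
                                       a1 = aa[scores$i[r]],
                                       a2 = aa[scores$j[r]]))
  k_top <- min(K, length(rows))
  top <- rows[seq_len(k_top)]
  rest <- if (length(rows) > k_top) rows[(k_top + 1):length(rows)] else list()
  rmv <- list()
  count_jc <- function(top, a1, a2) {
    want <- sort(c(a1, a2))
    sum(vapply(top, function(p) identical(sort(c(p$a1, p$a2)), want),
               logical(1)))
  }
  emp <- function(jc, a1, a2) {
    v <- jc / K
    if (mode == "fpn") v <- v / (f_ad[[a1]] * f_ad[[a2]])
    v
  }
  # removal pass, lowest score first
  for (p in rev(top)) {
    if (p$a1 == "X" || p$a2 == "X") next
    pos <- which(vapply(top, function(q) q$i == p$i && q$j == p$j,
                        logical(1)))
    jc_inc <- count_jc(top, p$a1, p$a2)
    t <- cls(p$a1, p$a2)
    inc <- emp(jc_inc, p$a1, p$a2)
    exc <- emp(jc_inc - 1, p$a1, p$a2)
    if (abs(inc - t) > abs(exc - t)) {
      rmv[[length(rmv) + 1]] <- top[[pos]]
      top <- top[-pos]
    }
  }
  # addition pass, highest score first
  for (p in rest) {
    if (length(top) >= K) break
    if (p$a1 == "X" || p$a2 == "X") next
    jc_exc <- count_jc(top, p$a1, p$a2)
    t <- cls(p$a1, p$a2)
    inc <- emp(jc_exc + 1, p$a1, p$a2)
    exc <- emp(jc_exc, p$a1, p$a2)
    if (!(abs(inc - t) > abs(exc - t))) {
      top[[length(top) + 1]] <- p
    }
  }
  # backfill, latest removed first
  while (length(top) < K && length(rmv) > 0) {
    top[[length(top) + 1]] <- rmv[[length(rmv)]]
    rmv[[length(rmv)]] <- NULL
  }
  do.call(rbind, lapply(top, function(p)
    data.frame(i = p$i, j = p$j, score = p$score)))
}

# Small ensemble of mixed-geometry domains for property tests.
random_domains <- function(n_domains, seed0 = 1, n_min = 10, n_max = 60) {
  lapply(seq_len(n_domains), function(k) {
    geom <- c("coil", "helix", "hairpin")[1 + (k %% 3)]
    n <- n_min + ((7 * k + seed0) %% (n_max - n_min + 1))
    make_domain(geom, n = n, seed = seed0 + k)
  })
}
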