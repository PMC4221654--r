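# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Reference amino-acid compositions for the generators
#'
#' \code{aa_composition_natural} approximates the overall frequencies of the
#' 20 standard amino acids in known protein sequences.
#' \code{aa_composition_buried} restricts it to the hydrophobic residues
#' (V, I, L, F, M, W, Y, C) found at packed strand and core positions;
#' \code{aa_composition_exposed} restricts it to polar and charged residues
#' (D, E, K, N, Q, S, G, P) typical of turns and solvent-exposed loops.
#' Sampling strand positions from the buried set and loop positions from the
#' exposed set stratifies composition by burial completely - an idealization
#' of the hydrophobic-core enrichment seen in real structures - and is what
#' gives generated ensembles their class-consistent amino-acid pair bias at
#' contact positions.
#'
#' @format Named numeric vectors over \code{aa_standard}, each summing to 1.
#' @export
aa_composition_natural <- local({
  f <- c(A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.014, Q = 0.039,
         E = 0.067, G = 0.071, H = 0.023, I = 0.059, L = 0.097, K = 0.058,
         M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.054, W = 0.011,
         Y = 0.029, V = 0.069)
  (f / sum(f))[aa_standard]
})

#' @rdname aa_composition_natural
#' @export
aa_composition_buried <- local({
  set <- c("V", "I", "L", "F", "M", "W", "Y", "C")
  f <- aa_composition_natural[set]
  f / sum(f)
})

#' @rdname aa_composition_natural
#' @export
aa_composition_exposed <- local({
  set <- c("D", "E", "K", "N", "Q", "S", "G", "P")
  f <- aa_composition_natural[set]
  f / sum(f)
})

sample_sequence <- function(n, composition, x_rate = 0) {
  aa <- sample(names(composition), n, replace = TRUE, prob = composition)
  if (x_rate > 0) aa[stats::runif(n) < x_rate] <- "X"
  aa
}

#' Generate an idealized alpha-helix domain
#'
#' Places residues on an ideal alpha-helix (rise 1.5 Angstrom per residue,
#' 100 degree turn, Calpha radius 2.3 Angstrom) with the Cbeta
#' representative at a fixed radial offset. Because consecutive turns are
#' only ~5.4 Angstrom apart along the axis, an isolated straight helix has
#' (i, i+3/i+4) contacts but essentially none at separation 10 and cutoff
#' 8 Angstrom.
#'
#' @param n number of residues (>= 4).
#' @param seed RNG seed for the amino-acid sequence.
#' @param composition named frequency vector over \code{aa_standard}.
#' @param x_rate probability of replacing a residue by the unknown type X.
#' @return a \code{Domain} with an additional \code{ca} coordinate matrix.
#' @export
make_helix <- function(n, seed = 1, composition = aa_composition_natural,
                       x_rate = 0) {
  if (n < 4L) stop("a helix needs at least 4 residues")
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  z <- (seq_len(n) - 1) * 1.5
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), z)
  cb <- cbind(3.3 * cos(theta), 3.3 * sin(theta), z - 0.5)
  aa <- with_seed(seed, sample_sequence(n, composition, x_rate))
  finish_synthetic(sprintf("helix_n%d_s%d", n, seed), aa, ca, cb)
}

#' Generate an idealized antiparallel beta-hairpin domain
#'
#' Two extended strands of \code{n_per_strand} residues run antiparallel at
#' a fixed inter-strand distance, joined by a loop of \code{turn_len}
#' residues arcing away from the strands. Registered cross-strand residue
#' pairs have Cbeta distance equal to \code{gap} and sequence separation of
#' at least \code{turn_len + 1}, so with the default loop length all
#' registered pairs survive a separation-10 filter. Strand positions draw
#' from \code{strand_composition} (the buried, hydrophobic alphabet by
#' default) and loop positions from \code{turn_composition} (the exposed,
#' polar alphabet), so the ensemble's true contacts carry the
#' hydrophobic-pair bias that class pair-frequency tables pick up.
#'
#' @param n_per_strand residues per strand (>= 3).
#' @param gap inter-strand Cbeta distance in Angstrom (> 0); 5 by default,
#'   comfortably inside an 8 Angstrom cutoff.
#' @param seed RNG seed for the amino-acid sequence.
#' @param turn_len loop length in residues (default 12).
#' @param strand_composition,turn_composition frequency vectors for strand
#'   and loop positions.
#' @param x_rate probability of replacing a residue by X.
#' @return a \code{Domain} with an additional \code{ca} matrix and a
#'   \code{registered_pairs} attribute listing the cross-strand pairs at
#'   exact register.
#' @export
make_hairpin <- function(n_per_strand, gap = 5, seed = 1, turn_len = 12,
                         strand_composition = aa_composition_buried,
                         turn_composition = aa_composition_exposed,
                         x_rate = 0) {
  if (n_per_strand < 3L) stop("a strand needs at least 3 residues")
  if (gap <= 0) stop("inter-strand gap must be positive")
  n1 <- n_per_strand; t <- turn_len
  x1 <- 3.4 * (seq_len(n1) - 1)
  s1 <- cbind(x1, 0, 0)
  # loop: ellipse arc from strand-1 end to strand-2 start, bulging in +x
  th <- pi * seq_len(t) / (t + 1)
  r_x <- max(gap, 3.4 * (t + 1) / pi)
  turn <- cbind(3.4 * (n1 - 1) + r_x * sin(th),
                gap / 2 - (gap / 2) * cos(th), 0)
  s2 <- cbind(3.4 * (rev(seq_len(n1)) - 1), gap, 0)
  ca <- rbind(s1, turn, s2)
  cb <- ca + matrix(rep(c(0, 0, 1.2), each = nrow(ca)), ncol = 3)
  n <- nrow(ca)
  aa <- with_seed(seed, {
    c(sample_sequence(n1, strand_composition, x_rate),
      sample_sequence(t, turn_composition, x_rate),
      sample_sequence(n1, strand_composition, x_rate))
  })
  dom <- finish_synthetic(sprintf("hairpin_n%d_s%d", n_per_strand, seed),
                          aa, ca, cb)
  i <- seq_len(n1)
  attr(dom, "registered_pairs") <- cbind(i = i, j = 2L * n1 + t + 1L - i)
  dom
}

#' Generate a random extended-coil domain
#'
#' A self-avoiding random walk with a 3.8 Angstrom step; new positions are
#' rejected when closer than 3.5 Angstrom to any previous residue. Cbeta
#' representatives sit at a random unit offset of 1.5 Angstrom from the
#' walk.
#'
#' @param n number of residues (>= 2).
#' @param seed RNG seed (geometry and sequence).
#' @param composition frequency vector over \code{aa_standard}.
#' @param x_rate probability of replacing a residue by X.
#' @return a \code{Domain} with an additional \code{ca} matrix.
#' @export
make_coil <- function(n, seed = 1, composition = aa_composition_natural,
                      x_rate = 0) {
  if (n < 2L) stop("a coil needs at least 2 residues")
  with_seed(seed, {
    ca <- matrix(0, n, 3)
    for (r in 2:n) {
      for (try in 1:200) {
        u <- stats::rnorm(3)
        step <- 3.8 * u / sqrt(sum(u^2))
        cand <- ca[r - 1, ] + step
        d2 <- rowSums((ca[seq_len(r - 1), , drop = FALSE] -
                         matrix(cand, r - 1, 3, byrow = TRUE))^2)
        if (all(d2 >= 3.5^2)) break
      }
      ca[r, ] <- cand
    }
    off <- matrix(stats::rnorm(3 * n), n, 3)
    off <- 1.5 * off / sqrt(rowSums(off^2))
    cb <- ca + off
    aa <- sample_sequence(n, composition, x_rate)
    finish_synthetic(sprintf("coil_n%d_s%d", n, seed), aa, ca, cb)
  })
}

#' Generate a synthetic domain of a chosen geometry
#'
#' Dispatcher over \code{\link{make_helix}}, \code{\link{make_hairpin}}
#' (\code{n} residues total across strands and a 12-residue loop),
#' \code{\link{make_coil}}, and \code{"mixed"} (a helix followed by a coil
#' of roughly equal length).
#'
#' @param geometry one of \code{"helix"}, \code{"hairpin"}, \code{"coil"},
#'   \code{"mixed"}.
#' @param n total residue count.
#' @param seed RNG seed.
#' @param ... passed on to the specific generator.
#' @return a \code{Domain}.
#' @export
make_domain <- function(geometry = c("helix", "hairpin", "coil", "mixed"),
                        n, seed = 1, ...) {
  geometry <- match.arg(geometry)
  switch(geometry,
    helix = make_helix(n, seed, ...),
    hairpin = make_hairpin(max(3L, (n - 12L) %/% 2L), seed = seed, ...),
    coil = make_coil(n, seed, ...),
    mixed = {
      n1 <- max(4L, n %/% 2L)
      h <- make_helix(n1, seed, ...)
      cl <- make_coil(max(2L, n - n1), seed + 1L, ...)
      shift <- matrix(h$ca[n1, ] + c(0, 0, 5), nrow(cl$ca), 3, byrow = TRUE)
      finish_synthetic(sprintf("mixed_n%d_s%d", n, seed),
                       c(h$aa, cl$aa),
                       rbind(h$ca, cl$ca + shift),
                       rbind(h$cbeta, cl$cbeta + shift))
    })
}

finish_synthetic <- function(id, aa, ca, cb) {
  cb[aa == "G", ] <- ca[aa == "G", ]  # glycine: Calpha is the representative
  dom <- new_domain(domain_id = id, aa = aa, cbeta = cb)
  dom$ca <- ca
  dom
}

#' Generate per-pair scores with known ground truth
#'
#' True contacts receive scores drawn from N(signal_mean, signal_sd) and all
#' other pairs from N(noise_mean, noise_sd), emulating a contact predictor
#' whose output separates the two populations imperfectly.
#'
#' @param truth a \code{ContactMap} with the true contacts.
#' @param all_pairs m x 2 matrix of the pairs to score; defaults to every
#'   unordered pair of the domain at the truth map's separation or more.
#' @param signal_mean,signal_sd score distribution for true contacts.
#' @param noise_mean,noise_sd score distribution for non-contacts.
#' @param seed RNG seed.
#' @return data frame with columns \code{i}, \code{j}, \code{score}.
#' @export
make_scores <- function(truth, all_pairs = NULL, signal_mean = 1,
                        signal_sd = 0.25, noise_mean = 0, noise_sd = 0.25,
                        seed = 1) {
  if (signal_sd < 0 || noise_sd < 0) stop("score spreads must be >= 0")
  if (is.null(all_pairs)) {
    n <- truth$n_residues
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- idx[, 2] - idx[, 1] >= truth$separation
    all_pairs <- cbind(idx[keep, 1], idx[keep, 2])
  }
  i <- pmin(all_pairs[, 1], all_pairs[, 2])
  j <- pmax(all_pairs[, 1], all_pairs[, 2])
  tkey <- paste(truth$pairs[, 1], truth$pairs[, 2])
  is_true <- paste(i, j) %in% tkey
  score <- with_seed(seed, {
    s <- stats::rnorm(length(i), noise_mean, noise_sd)
    s[is_true] <- stats::rnorm(sum(is_true), signal_mean, signal_sd)
    s
  })
  data.frame(i = i, j = j, score = score)
}

#' Generate a 3-state secondary-structure string
#'
#' Produces a string of H/E/C whose post-simplification helix and sheet
#' fractions match the request to within 1/n: helix runs are at least 5
#' residues and sheet runs at least 3, so no run is lost to
#' \code{\link{simplify_ss}}.
#'
#' @param helix_frac,sheet_frac requested fractions (each >= 0, sum <= 1).
#' @param n string length.
#' @param seed RNG seed (block order).
#' @return a character string of length \code{n}.
#' @export
make_ss_string <- function(helix_frac, sheet_frac, n, seed = 1) {
  if (helix_frac < 0 || sheet_frac < 0 || helix_frac + sheet_frac > 1) {
    stop("fractions must be >= 0 and sum to at most 1")
  }
  h <- round(helix_frac * n)
  e <- round(sheet_frac * n)
  if (h > 0 && h < 5) stop("infeasible: ", h, " helix residues cannot form ",
                           "a run of at least 5")
  if (e > 0 && e < 3) stop("infeasible: ", e, " sheet residues cannot form ",
                           "a run of at least 3")
  if (h + e > n) stop("requested fractions exceed the string length")
  split_runs <- function(total, min_len, pref) {
    runs <- integer(0)
    while (total >= pref + min_len) {
      runs <- c(runs, pref)
      total <- total - pref
    }
    if (total > 0) runs <- c(runs, total)
    runs
  }
  blocks <- c(lapply(split_runs(h, 5L, 8L), function(l) rep("H", l)),
              lapply(split_runs(e, 3L, 5L), function(l) rep("E", l)))
  coil_total <- n - h - e
  with_seed(seed, {
    if (length(blocks) > 1L) blocks <- blocks[sample(length(blocks))]
    nb <- length(blocks)
    coil_each <- if (nb > 0L) diff(round(seq(0, coil_total,
                                             length.out = nb + 2L))) else
      coil_total
    out <- character(0)
    if (nb == 0L) {
      out <- rep("C", coil_total)
    } else {
      for (b in seq_len(nb)) {
        out <- c(out, rep("C", coil_each[b]), blocks[[b]])
      }
      out <- c(out, rep("C", coil_total - sum(coil_each[seq_len(nb)])))
    }
    paste(out, collapse = "")
  })
}

#' Write a synthetic domain as a PDB file
#'
#' Emits CA and CB records (CA only for glycine) so that the file
#' round-trips through \code{\link{read_structure}}.
#'
#' @param domain a synthetic \code{Domain} carrying a \code{ca} matrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_synthetic_pdb <- function(domain, path) {
  if (is.null(domain$ca)) stop("domain carries no Calpha coordinates")
  n <- n_residues(domain)
  resid3 <- bio3d::aa123(domain$aa)
  has_cb <- domain$aa != "G"
  coords <- resno <- resid <- elety <- vector("list", n)
  for (r in seq_len(n)) {
    xyz <- if (has_cb[r]) rbind(domain$ca[r, ], domain$cbeta[r, ]) else
      domain$ca[r, , drop = FALSE]
    coords[[r]] <- xyz
    k <- nrow(xyz)
    resno[[r]] <- rep(r, k)
    resid[[r]] <- rep(resid3[r], k)
    elety[[r]] <- c("CA", "CB")[seq_len(k)]
  }
  xyz <- do.call(rbind, coords)
  bio3d::write.pdb(pdb = NULL, file = path, xyz = as.vector(t(xyz)),
                   resno = unlist(resno), resid = unlist(resid),
                   elety = unlist(elety), chain = rep("A", nrow(xyz)))
  invisible(path)
}
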