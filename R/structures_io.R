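#' Read a protein domain from a PDB file
#'
#' Parses coordinate records with \pkg{bio3d} and reduces each polymeric
#' residue to a single contact representative: the CB atom, or the CA atom
#' when no CB exists (always the case for glycine). Residues with neither
#' atom keep their place in the sequence but carry no coordinate and are
#' excluded from all contact computations. Alternate locations are resolved
#' to the highest-occupancy conformer; insertion-coded residues are kept in
#' file order.
#'
#' Residues are renumbered 1..n consecutively in file order so that sequence
#' separation arithmetic is gap-free; the author numbering is kept in
#' \code{pdb_resno}. Set \code{honor_gaps = TRUE} to instead derive internal
#' indices from the author numbering, so that chain breaks inflate the
#' separation between flanking residues.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier (single character). \code{NULL} selects the
#'   first chain in the file.
#' @param residue_range optional length-2 integer vector of author residue
#'   numbers \code{c(first, last)} to retain.
#' @param honor_gaps logical; derive sequence indices from author numbering
#'   instead of consecutive renumbering.
#' @return An object of class \code{"Domain"}: a list with elements
#'   \code{domain_id}, \code{aa} (one-letter codes, \code{"X"} for
#'   non-standard residues), \code{cbeta} (n x 3 matrix, NA rows where no
#'   representative atom exists), \code{pdb_resno}, and optional
#'   \code{class_label}, \code{topology_label}, \code{ss}.
#' @export
read_structure <- function(path, chain = NULL, residue_range = NULL,
                           honor_gaps = FALSE) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)

  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found in ", path,
         " (available: ", paste(chains, collapse = ", "), ")")
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (!is.null(residue_range)) {
    atoms <- atoms[atoms$resno >= residue_range[1] &
                   atoms$resno <= residue_range[2], , drop = FALSE]
  }

  # residue identity: author number + insertion code, in file order
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  rid <- paste(atoms$resno, ins, sep = "|")
  rid_order <- unique(rid)

  n <- length(rid_order)
  aa <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  resno <- integer(n)

  for (r in seq_len(n)) {
    rows <- atoms[rid == rid_order[r], , drop = FALSE]
    aa[r] <- bio3d::aa321(rows$resid[1])
    resno[r] <- rows$resno[1]
    rep_atom <- pick_representative(rows)
    if (is.null(rep_atom)) {
      warning("residue ", rows$resid[1], " ", rows$resno[1],
              " has neither CB nor CA; excluded from contacts")
    } else {
      xyz[r, ] <- unname(as.numeric(rep_atom[c("x", "y", "z")]))
    }
  }

  seq_index <- if (honor_gaps) resno - resno[1] + 1L else seq_len(n)

  new_domain(domain_id = paste0(basename(path), "_", chain),
             aa = aa, cbeta = xyz, pdb_resno = resno,
             seq_index = seq_index)
}

# Highest-occupancy CB (or CA fallback) among possibly multiple altlocs.
pick_representative <- function(rows) {
  for (elety in c("CB", "CA")) {
    cand <- rows[rows$elety == elety, , drop = FALSE]
    if (nrow(cand) == 0L) next
    if (nrow(cand) > 1L) {
      occ <- cand$o
      occ[is.na(occ)] <- 1
      cand <- cand[which.max(occ), , drop = FALSE]
    }
    return(cand[1, ])
  }
  NULL
}

new_domain <- function(domain_id, aa, cbeta, pdb_resno = seq_along(aa),
                       seq_index = seq_along(aa), class_label = NULL,
                       topology_label = NULL, ss = NULL) {
  stopifnot(length(aa) == nrow(cbeta))
  bad <- !aa %in% aa_extended
  if (any(bad)) {
    aa[bad] <- "X"
  }
  structure(list(domain_id = domain_id, aa = aa, cbeta = cbeta,
                 pdb_resno = pdb_resno, seq_index = as.integer(seq_index),
                 class_label = class_label, topology_label = topology_label,
                 ss = ss),
            class = "Domain")
}

#' @export
print.Domain <- function(x, ...) {
  cat("Domain", x$domain_id, "-", length(x$aa), "residues,",
      sum(stats::complete.cases(x$cbeta)), "with coordinates\n")
  if (!is.null(x$class_label)) cat("  class:", x$class_label, "\n")
  invisible(x)
}

#' Number of residues in a domain
#' @param domain a \code{Domain}.
#' @return integer residue count.
#' @export
n_residues <- function(domain) length(domain$aa)

#' Read a secondary-structure assignment
#'
#' Reads either a DSSP output file or a plain text file holding one
#' secondary-structure letter per residue (whitespace and line breaks
#' ignored). DSSP blank codes (loop) are returned as \code{"-"}; chain-break
#' markers (\code{"!"} residues) are skipped.
#'
#' @param path path to the file.
#' @param format \code{"auto"} (DSSP if the file contains a DSSP residue
#'   header), \code{"dssp"}, or \code{"text"}.
#' @param domain optional \code{Domain}; when given, the code count must
#'   equal the residue count or an error naming both lengths is raised.
#' @return character vector of per-residue codes over
#'   \{H,G,I,E,B,T,S,C,-\}.
#' @export
read_secondary_structure <- function(path, format = c("auto", "dssp", "text"),
                                     domain = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^  #  RESIDUE", lines))) "dssp" else "text"
  }
  codes <- if (format == "dssp") parse_dssp_codes(lines) else {
    strsplit(gsub("[[:space:]]", "", paste(lines, collapse = "")), "")[[1]]
  }
  if (!is.null(domain) && length(codes) != n_residues(domain)) {
    stop("secondary structure has ", length(codes), " codes but domain '",
         domain$domain_id, "' has ", n_residues(domain), " residues")
  }
  codes
}

parse_dssp_codes <- function(lines) {
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a DSSP file: residue header not found")
  body <- lines[(hdr[1] + 1L):length(lines)]
  aa_col <- substr(body, 14, 14)
  body <- body[aa_col != "!" & nzchar(trimws(body))]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  ss
}

#' Attach a secondary-structure string to a domain
#'
#' @param domain a \code{Domain}.
#' @param codes character vector of per-residue codes (or a single string).
#' @return the domain with \code{ss} set.
#' @export
attach_ss <- function(domain, codes) {
  if (length(codes) == 1L && nchar(codes) > 1L) {
    codes <- strsplit(codes, "")[[1]]
  }
  if (length(codes) != n_residues(domain)) {
    stop("secondary structure has ", length(codes), " codes but domain '",
         domain$domain_id, "' has ", n_residues(domain), " residues")
  }
  domain$ss <- codes
  domain
}

#' Read a per-pair contact score table
#'
#' Expects three tab-separated columns: residue index i, residue index j,
#' score. Pairs are stored in canonical unordered form with \code{i < j};
#' rows with \code{i == j}, duplicate unordered pairs, or non-numeric scores
#' are rejected.
#'
#' @param path path to a TSV file; lines starting with \code{#} are headers.
#' @return data frame with columns \code{i}, \code{j}, \code{score}.
#' @export
read_score_table <- function(path) {
  tab <- read_table(path)
  if (ncol(tab) < 3L) stop("score table needs 3 columns (i, j, score)")
  names(tab)[1:3] <- c("i", "j", "score")
  i <- suppressWarnings(as.integer(tab$i))
  j <- suppressWarnings(as.integer(tab$j))
  score <- suppressWarnings(as.numeric(tab$score))
  if (anyNA(i) || anyNA(j)) stop("non-integer residue index in score table")
  if (anyNA(score)) stop("non-numeric score in score table")
  if (any(i == j)) stop("self-pair (i == j) in score table")
  ii <- pmin(i, j); jj <- pmax(i, j)
  key <- paste(ii, jj)
  if (anyDuplicated(key)) {
    stop("duplicate unordered pair(s) in score table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  data.frame(i = ii, j = jj, score = score)
}

#' Write records to a tab-separated table
#'
#' Writes a deterministic TSV with a single \code{#}-prefixed header row.
#' Numeric columns are written with full double precision so that a
#' \code{write_table}/\code{read_table} round trip reproduces the values.
#'
#' @param records a data frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(records), collapse = "\t")), con)
  if (nrow(records) > 0L) {
    cols <- lapply(records, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a tab-separated table written by \code{write_table}
#'
#' @param path path to the TSV file.
#' @return data frame; column types are inferred.
#' @export
read_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- NULL
  if (startsWith(lines[1], "#")) {
    header <- strsplit(sub("^#\\s*", "", lines[1]), "\t")[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      replicate(length(header), character(0), simplify = FALSE), header))
    return(out)
  }
  out <- utils::read.table(text = lines, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!is.null(header) && length(header) == ncol(out)) names(out) <- header
  out
}
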