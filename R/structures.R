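STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Parse a protein structure from PDB or mmCIF
#'
#' Hydrogens, waters and HETATM records are excluded; among alternate
#' locations the highest-occupancy conformer of each atom is kept (ties
#' broken alphabetically by altloc id); residues left without heavy atoms
#' are dropped, as are chains with no standard amino acid residues.
#'
#' @param path Structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param model Model number to read (default 1, the first model).
#' @return Object of class `structure3d`: `atoms` (data frame with chain,
#'   resno, resid, elety, elesy, x, y, z, o), `chains` (per chain: `resno`
#'   vector and one-letter `seq`), `to_query` (`NULL` until
#'   [map_to_query()] is run), `source` (the file path).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            model = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif"
    else "pdb"
  }
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- substr(trimws(at$elety[
    is.na(elesy) | elesy == ""]), 1, 1)
  at <- at[!(toupper(trimws(elesy)) %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("no heavy protein atoms in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep the highest-occupancy conformer per atom site
  at$.ord <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[at$resid %in% STANDARD_AA3, , drop = FALSE]
  if (!nrow(at)) stop("no protein chain found in ", path)
  at <- at[order(at$chain, at$resno, at$insert, at$.ord), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resid = at$resid, elety = trimws(at$elety),
                      elesy = toupper(trimws(at$elesy)),
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      stringsAsFactors = FALSE)
  chains <- list()
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    resno <- unique(sub$resno)
    resid3 <- sub$resid[match(resno, sub$resno)]
    seq1 <- bio3d::aa321(resid3)
    seq1[is.na(seq1)] <- "X"
    chains[[ch]] <- list(resno = resno, seq = paste(seq1, collapse = ""))
  }
  out <- list(atoms = atoms, chains = chains, to_query = NULL,
              source = path)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d chains, %d residues, %d heavy atoms (%s)\n",
              length(x$chains),
              sum(vapply(x$chains, function(c) length(c$resno), integer(1))),
              nrow(x$atoms), x$source))
  if (!is.null(x$to_query)) cat("  mapped to query coordinates\n")
  invisible(x)
}

#' Map structure residues to ungapped-query coordinates
#'
#' Aligns each chain sequence globally to the query (match +1, mismatch 0,
#' gap open -5, gap extend -1) and records, for every aligned residue, the
#' corresponding query position. Chains aligning with less than
#' `min_identity` identity over aligned columns are rejected, since a
#' near-random alignment almost certainly indicates the wrong chain or
#' query.
#'
#' @param structure A [parse_structure()] object.
#' @param query_seq Ungapped query sequence (character string).
#' @param min_identity Identity floor over aligned columns (default 0.15).
#' @return The structure with `to_query` filled: per chain, a named
#'   integer vector from residue number to query position.
#' @export
map_to_query <- function(structure, query_seq, min_identity = 0.15) {
  stopifnot(inherits(structure, "structure3d"), nchar(query_seq) > 0)
  letters21 <- c(AA_ALPHABET[1:20], "X")
  submat <- matrix(0, 21, 21, dimnames = list(letters21, letters21))
  diag(submat) <- 1
  submat["X", "X"] <- 0
  to_query <- list()
  for (ch in names(structure$chains)) {
    cs <- structure$chains[[ch]]
    if (!nchar(cs$seq)) stop("empty chain sequence for chain ", ch)
    pa <- Biostrings::pairwiseAlignment(
      pattern = cs$seq, subject = query_seq, type = "global",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    pi <- 0L
    si <- 0L
    map <- integer(0)
    nmatch <- 0L
    naligned <- 0L
    for (k in seq_along(ap)) {
      if (ap[k] != "-") pi <- pi + 1L
      if (as_[k] != "-") si <- si + 1L
      if (ap[k] != "-" && as_[k] != "-") {
        naligned <- naligned + 1L
        if (ap[k] == as_[k]) nmatch <- nmatch + 1L
        map[as.character(cs$resno[pi])] <- si
      }
    }
    if (naligned == 0L || nmatch / naligned < min_identity)
      stop(sprintf(
        "chain %s aligns to the query with identity %.1f%% (< %.0f%%); refusing the mapping",
        ch, if (naligned) 100 * nmatch / naligned else 0,
        100 * min_identity))
    to_query[[ch]] <- map
  }
  structure$to_query <- to_query
  structure
}

#' Experimental contact sets from a mapped structure
#'
#' A pair of residues is in contact when the minimum distance over their
#' heavy-atom pairs is within the cutoff: 8 angstroms within a chain, 10
#' between chains. Contacts are reported in ungapped-query coordinates
#' with `i < j`; interchain contacts of a homo-oligomer collapse onto the
#' same query coordinate system and are reported separately.
#'
#' @param structure A [map_to_query()]-mapped structure.
#' @param intra_cutoff Intrachain heavy-atom cutoff in angstroms (default 8).
#' @param inter_cutoff Interchain cutoff in angstroms (default 10).
#' @param min_separation Minimum `j - i` for intrachain contacts
#'   (default 1, i.e. all non-self pairs).
#' @return Object of class `contact_sets`: `intra` and `inter`
#'   data frames (`i`, `j`), `L` (largest mapped query position), `id`.
#' @export
contact_map <- function(structure, intra_cutoff = 8, inter_cutoff = 10,
                        min_separation = 1) {
  stopifnot(inherits(structure, "structure3d"))
  if (is.null(structure$to_query))
    stop("structure is not mapped; run map_to_query() first")
  at <- structure$atoms
  qpos <- rep(NA_integer_, nrow(at))
  for (ch in names(structure$to_query)) {
    m <- structure$to_query[[ch]]
    sel <- at$chain == ch
    qpos[sel] <- unname(m[as.character(at$resno[sel])])
  }
  keep <- !is.na(qpos)
  at <- at[keep, , drop = FALSE]
  qpos <- qpos[keep]
  if (!nrow(at)) stop("no mapped residues")
  XYZ <- as.matrix(at[, c("x", "y", "z")])
  D2 <- outer(rowSums(XYZ^2), rowSums(XYZ^2), "+") - 2 * tcrossprod(XYZ)
  D2[D2 < 0] <- 0
  same_chain <- outer(at$chain, at$chain, "==")
  ut <- upper.tri(D2)

  collect <- function(sel) {
    idx <- which(sel, arr.ind = TRUE)
    if (!nrow(idx)) return(data.frame(i = integer(0), j = integer(0)))
    a <- qpos[idx[, 1]]
    b <- qpos[idx[, 2]]
    df <- data.frame(i = pmin(a, b), j = pmax(a, b))
    df <- df[df$j > df$i, , drop = FALSE]
    df <- unique(df)
    df[order(df$i, df$j), , drop = FALSE]
  }
  intra <- collect(ut & same_chain & D2 <= intra_cutoff^2)
  intra <- intra[intra$j - intra$i >= min_separation, , drop = FALSE]
  inter <- collect(ut & !same_chain & D2 <= inter_cutoff^2)
  rownames(intra) <- rownames(inter) <- NULL
  out <- list(intra = intra, inter = inter,
              L = max(qpos), id = structure$source)
  class(out) <- "contact_sets"
  out
}

#' Combine two conformations' contacts into a dual-fold map
#'
#' The common set is the exact intersection of the two intrachain contact
#' sets; each fold's unique set is the set difference. Interchain contacts
#' are kept per fold. Fold labels remain provisional (`a` first, `b`
#' second) until [determine_dominant()] is applied.
#'
#' @param map_a,map_b [contact_map()] results for the two conformations.
#' @param ids Identifiers for the two source structures.
#' @return Object of class `dual_fold_map` with fields `unique_a`,
#'   `unique_b`, `common`, `inter_a`, `inter_b`, `source_ids`, `L`,
#'   `dominant_id` (`NA` until determined).
#' @export
build_dual_fold_map <- function(map_a, map_b,
                                ids = c(map_a$id, map_b$id)) {
  stopifnot(inherits(map_a, "contact_sets"),
            inherits(map_b, "contact_sets"))
  keyify <- function(df) paste(df$i, df$j)
  ka <- keyify(map_a$intra)
  kb <- keyify(map_b$intra)
  out <- list(unique_a = map_a$intra[!(ka %in% kb), , drop = FALSE],
              unique_b = map_b$intra[!(kb %in% ka), , drop = FALSE],
              common = map_a$intra[ka %in% kb, , drop = FALSE],
              inter_a = map_a$inter, inter_b = map_b$inter,
              source_ids = ids, L = max(map_a$L, map_b$L),
              dominant_id = NA_character_)
  rownames(out$unique_a) <- rownames(out$unique_b) <-
    rownames(out$common) <- NULL
  class(out) <- "dual_fold_map"
  out
}

#' @export
print.dual_fold_map <- function(x, ...) {
  cat(sprintf(
    "dual_fold_map [%s vs %s]: %d/%d unique, %d common, %d/%d interchain (L %d)\n",
    x$source_ids[1], x$source_ids[2], nrow(x$unique_a), nrow(x$unique_b),
    nrow(x$common), nrow(x$inter_a), nrow(x$inter_b), x$L))
  if (!is.na(x$dominant_id)) cat("  dominant fold:", x$dominant_id, "\n")
  invisible(x)
}

# unique + interchain contacts of one fold ("a" or "b")
fold_contacts <- function(map, side) {
  u <- if (side == "a") map$unique_a else map$unique_b
  ic <- if (side == "a") map$inter_a else map$inter_b
  unique(rbind(u[, c("i", "j")], ic[, c("i", "j")]))
}

#' Identify the dominant fold from deep-alignment predictions
#'
#' The dominant conformation is the one whose unique contacts (including
#' its interchain contacts) overlap more of the pairs predicted from the
#' deepest (superfamily) alignment, within a Chebyshev tolerance box. The
#' label carries no energetic meaning. Ties go to the first fold with a
#' warning.
#'
#' @param dualmap A [build_dual_fold_map()] object.
#' @param deepest_run_pairs Predicted pairs from the superfamily alignment
#'   only (`data.frame` with `i`, `j`).
#' @param tol Overlap tolerance in residues (default 2).
#' @return The dominant fold's source id (character scalar).
#' @export
determine_dominant <- function(dualmap, deepest_run_pairs, tol = 2) {
  stopifnot(inherits(dualmap, "dual_fold_map"))
  p <- as.data.frame(deepest_run_pairs)
  na <- sum(pairs_overlap(p, fold_contacts(dualmap, "a"), tol))
  nb <- sum(pairs_overlap(p, fold_contacts(dualmap, "b"), tol))
  if (na == nb)
    warning("equal overlap with both folds; labelling fold '",
            dualmap$source_ids[1], "' dominant")
  if (nb > na) dualmap$source_ids[2] else dualmap$source_ids[1]
}

#' Categorize predicted contacts against a dual-fold map
#'
#' Each predicted pair is assigned to exactly one category with precedence
#' common > dominant > alternative > unobserved: a pair within the
#' tolerance box of a contact shared by both folds carries no
#' fold-discriminating information and must not inflate either unique
#' count. Interchain contacts count toward their fold's unique set.
#' Experimental common contacts are exact intersections; the tolerance
#' applies only to predicted-vs-experimental overlap.
#'
#' @param predictions Predicted pairs (`data.frame` with `i`, `j`; extra
#'   columns carried through), e.g. [filtered_pairs()] output.
#' @param dualmap A [build_dual_fold_map()] object.
#' @param tol Overlap tolerance in residues (default 2).
#' @param dominant_id Dominant fold id; defaults to `dualmap$dominant_id`
#'   (set it with [determine_dominant()]).
#' @return Object of class `categorized_predictions`: data frames
#'   `dominant`, `alternative`, `common`, `unobserved` partitioning the
#'   predictions, plus `dominant_fold_id` and `n`.
#' @export
categorize_predictions <- function(predictions, dualmap, tol = 2,
                                   dominant_id = dualmap$dominant_id) {
  stopifnot(inherits(dualmap, "dual_fold_map"))
  if (is.na(dominant_id))
    stop("dominant fold not determined; run determine_dominant() first")
  if (!dominant_id %in% dualmap$source_ids)
    stop("dominant_id must be one of the map's source ids")
  p <- as.data.frame(predictions)
  dom_side <- if (dominant_id == dualmap$source_ids[1]) "a" else "b"
  alt_side <- if (dom_side == "a") "b" else "a"
  in_common <- pairs_overlap(p, dualmap$common, tol)
  in_dom <- pairs_overlap(p, fold_contacts(dualmap, dom_side), tol)
  in_alt <- pairs_overlap(p, fold_contacts(dualmap, alt_side), tol)
  cat_ <- rep("unobserved", nrow(p))
  cat_[in_alt] <- "alternative"
  cat_[in_dom] <- "dominant"
  cat_[in_common] <- "common"
  out <- list(dominant = p[cat_ == "dominant", , drop = FALSE],
              alternative = p[cat_ == "alternative", , drop = FALSE],
              common = p[cat_ == "common", , drop = FALSE],
              unobserved = p[cat_ == "unobserved", , drop = FALSE],
              dominant_fold_id = dominant_id, n = nrow(p))
  class(out) <- "categorized_predictions"
  out
}

#' @export
print.categorized_predictions <- function(x, ...) {
  cat(sprintf(
    "categorized_predictions (dominant = %s): %d dominant, %d alternative, %d common, %d unobserved\n",
    x$dominant_fold_id, nrow(x$dominant), nrow(x$alternative),
    nrow(x$common), nrow(x$unobserved)))
  invisible(x)
}
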