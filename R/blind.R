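#' Collapse 8-state secondary structure to 3 states
#'
#' Standard reduction: H, G, I (helices) to `H`; E, B (strands/bridges) to
#' `E`; everything else (T, S, P, blank, `-`, `~`, C) to coil `C`.
#'
#' @param eight_state_string Character string over the DSSP 8-state
#'   alphabet (a 3-state string passes through unchanged).
#' @return Character string over `{H, E, C}` of the same length.
#' @export
simplify_ss <- function(eight_state_string) {
  if (!nchar(eight_state_string)) return("")
  ch <- strsplit(eight_state_string, "")[[1]]
  out <- character(length(ch))
  out[ch %in% c("H", "G", "I")] <- "H"
  out[ch %in% c("E", "B")] <- "E"
  coil <- ch %in% c("T", "S", "P", " ", "-", "~", "C")
  out[coil] <- "C"
  bad <- which(out == "")
  if (length(bad))
    stop("unknown secondary structure code: '", ch[bad[1]], "'")
  paste(out, collapse = "")
}

#' Read a DSSP annotation file
#'
#' Parses the classic DSSP output: the residue table that follows the
#' `#  RESIDUE` header, taking the residue number, chain and the 8-state
#' code from its fixed column. Chain-break records are skipped.
#'
#' @param path DSSP file path.
#' @param chain Optional chain id to restrict to.
#' @return List: `resno`, `chain`, `ss8` (vector) and `ss3` (collapsed
#'   string from [simplify_ss()]).
#' @export
read_dssp <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file (no residue table header): ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  brk <- substr(body, 14, 14) == "!"
  body <- body[!brk]
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  ch <- substr(body, 12, 12)
  ss8 <- substr(body, 17, 17)
  ok <- !is.na(resno)
  resno <- resno[ok]; ch <- ch[ok]; ss8 <- ss8[ok]
  if (!is.null(chain)) {
    sel <- ch == chain
    resno <- resno[sel]; ch <- ch[sel]; ss8 <- ss8[sel]
  }
  if (!length(resno)) stop("no residues parsed from ", path)
  list(resno = resno, chain = ch, ss8 = ss8,
       ss3 = simplify_ss(paste(ss8, collapse = "")))
}

#' Regions where two structures disagree between helix and strand
#'
#' A position is an alpha/beta difference when one string has `H` and the
#' other `E` there. Every window of length at least `min_len` whose
#' alpha/beta-difference density is at least `min_frac` marks its
#' positions; overlapping marked windows are merged into maximal spans,
#' and each span is trimmed to its outermost difference positions (so a
#' reported region never starts or ends on an agreeing residue). The
#' comparison is symmetric in its two arguments.
#'
#' @param ss_a,ss_b Equal-length 3-state strings in query coordinates.
#' @param min_len Minimum window length (default 15 residues).
#' @param min_frac Minimum difference density in the window (default 0.5).
#' @return `data.frame` with columns `start`, `end` (possibly 0 rows).
#' @export
find_divergent_regions <- function(ss_a, ss_b, min_len = 15,
                                   min_frac = 0.5) {
  if (nchar(ss_a) != nchar(ss_b))
    stop("secondary structure strings differ in length (",
         nchar(ss_a), " vs ", nchar(ss_b), ")")
  a <- strsplit(ss_a, "")[[1]]
  b <- strsplit(ss_b, "")[[1]]
  n <- length(a)
  d <- (a == "H" & b == "E") | (a == "E" & b == "H")
  if (n < min_len || !any(d))
    return(data.frame(start = integer(0), end = integer(0)))
  S <- c(0, cumsum(d))
  mark <- logical(n)
  for (s in seq_len(n - min_len + 1)) {
    for (e in (s + min_len - 1):n) {
      if ((S[e + 1] - S[s]) >= min_frac * (e - s + 1)) mark[s:e] <- TRUE
    }
  }
  if (!any(mark)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(mark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- data.frame(start = starts[r$values], end = ends[r$values])
  for (k in seq_len(nrow(spans))) {
    inside <- which(d[spans$start[k]:spans$end[k]]) + spans$start[k] - 1L
    spans$start[k] <- min(inside)
    spans$end[k] <- max(inside)
  }
  spans
}

#' Coevolutionary corroboration of two predicted structures
#'
#' Builds the dual-fold map of the two predicted structures and counts,
#' for each, the density-filtered clusters (of at least `min_cluster`
#' members) with at least one member overlapping that structure's unique
#' contacts (interchain included) within the tolerance box. A structure is
#' corroborated when at least one such cluster exists. Identical predicted
#' structures have empty unique sets and are never corroborated.
#'
#' @param contacts_a,contacts_b [contact_map()] results for the two
#'   predicted structures.
#' @param filtered A [dbscan_filter()] result over ACE predictions.
#' @param tol Overlap tolerance in residues (default 2).
#' @param min_cluster Minimum cluster size considered (default 3).
#' @return Object of class `corroboration`: `n_clusters_a`,
#'   `n_clusters_b`, `corroborated_a`, `corroborated_b`, `map` (the
#'   dual-fold map of the two predictions).
#' @export
corroborate <- function(contacts_a, contacts_b, filtered, tol = 2,
                        min_cluster = 3) {
  stopifnot(inherits(filtered, "filtered_predictions"))
  dm <- build_dual_fold_map(contacts_a, contacts_b, ids = c("a", "b"))
  ua <- fold_contacts(dm, "a")
  ub <- fold_contacts(dm, "b")
  na <- nb <- 0L
  for (cl in filtered$clusters) {
    if (length(cl) < min_cluster) next
    mem <- filtered$pairs[cl, c("i", "j")]
    if (nrow(ua) && any(pairs_overlap(mem, ua, tol))) na <- na + 1L
    if (nrow(ub) && any(pairs_overlap(mem, ub, tol))) nb <- nb + 1L
  }
  out <- list(n_clusters_a = na, n_clusters_b = nb,
              corroborated_a = na > 0L, corroborated_b = nb > 0L,
              map = dm)
  class(out) <- "corroboration"
  out
}

#' @export
print.corroboration <- function(x, ...) {
  cat(sprintf(
    "corroboration: structure a %s (%d clusters), structure b %s (%d clusters)\n",
    if (x$corroborated_a) "supported" else "unsupported", x$n_clusters_a,
    if (x$corroborated_b) "supported" else "unsupported", x$n_clusters_b))
  invisible(x)
}

#' Clusters carrying signal unexplained by either predicted structure
#'
#' Density-filtered clusters of at least `min_size` members whose mean
#' sequence separation is at least `min_separation` and none of whose
#' members overlaps (within the tolerance box) any contact of either
#' predicted structure. Such clusters are candidate alternative-fold
#' signal, but multimeric interfaces can mimic them, so downstream calls
#' carry an ambiguity flag.
#'
#' @param filtered A [dbscan_filter()] result.
#' @param contacts_a,contacts_b [contact_map()] results for the two
#'   predicted structures.
#' @param min_size Minimum cluster size (default 5).
#' @param min_separation Minimum mean `j - i` of members (default 6).
#' @param tol Overlap tolerance in residues (default 2).
#' @return List of member `data.frame`s, one per qualifying cluster.
#' @export
alternative_signal_clusters <- function(filtered, contacts_a, contacts_b,
                                        min_size = 5, min_separation = 6,
                                        tol = 2) {
  stopifnot(inherits(filtered, "filtered_predictions"))
  ref <- unique(rbind(contacts_a$intra[, c("i", "j")],
                      contacts_a$inter[, c("i", "j")],
                      contacts_b$intra[, c("i", "j")],
                      contacts_b$inter[, c("i", "j")]))
  out <- list()
  for (cl in filtered$clusters) {
    if (length(cl) < min_size) next
    mem <- filtered$pairs[cl, , drop = FALSE]
    if (mean(mem$j - mem$i) < min_separation) next
    if (nrow(ref) && any(pairs_overlap(mem[, c("i", "j")], ref, tol)))
      next
    out[[length(out) + 1L]] <- mem
  }
  out
}

#' Blind fold-switch call from two predicted structures
#'
#' Classification rules: Category 1 when the two predicted structures
#' diverge (a helix/strand-divergent region exists) and both are
#' corroborated by coevolution clusters; when exactly one is corroborated
#' the call is still Category 1 but flagged low-confidence (partial
#' corroboration). Category 2 when the predictions agree (no divergent
#' region) but at least one coevolution cluster carries signal unexplained
#' by either structure; flagged for multimer ambiguity, since an
#' oligomeric interface can mimic alternative-fold signal. Everything else
#' -- coevolutionary evidence for one conformation only -- is a single
#' fold.
#'
#' @param ss_a,ss_b 3-state secondary structure strings of the two
#'   predicted structures, in query coordinates (collapse DSSP output
#'   with [simplify_ss()] first).
#' @param corroboration A [corroborate()] result.
#' @param alt_signal_clusters Output of [alternative_signal_clusters()].
#' @param min_len,min_frac Divergence-rule parameters (defaults 15, 0.5).
#' @return Object of class `blind_call`: `category` (one of `category1`,
#'   `category2`, `single_fold`), `divergent_regions`, `corroboration`,
#'   `n_alt_signal_clusters`, `flags`.
#' @export
classify_blind <- function(ss_a, ss_b, corroboration,
                           alt_signal_clusters = list(),
                           min_len = 15, min_frac = 0.5) {
  stopifnot(inherits(corroboration, "corroboration"))
  div <- find_divergent_regions(ss_a, ss_b, min_len, min_frac)
  flags <- character(0)
  if (nrow(div) > 0) {
    both <- corroboration$corroborated_a && corroboration$corroborated_b
    one <- xor(corroboration$corroborated_a, corroboration$corroborated_b)
    if (both) {
      category <- "category1"
    } else if (one) {
      category <- "category1"
      flags <- c(flags, "low_confidence_partial_corroboration")
    } else {
      category <- "single_fold"
    }
  } else if (length(alt_signal_clusters) > 0) {
    category <- "category2"
    flags <- c(flags, "multimer_ambiguity")
  } else {
    category <- "single_fold"
  }
  out <- list(category = category, divergent_regions = div,
              corroboration = corroboration,
              n_alt_signal_clusters = length(alt_signal_clusters),
              flags = flags)
  class(out) <- "blind_call"
  out
}

#' @export
print.blind_call <- function(x, ...) {
  cat(sprintf("blind_call: %s (%d divergent regions, %d unexplained clusters)\n",
              x$category, nrow(x$divergent_regions),
              x$n_alt_signal_clusters))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' One-call blind fold-switch prediction
#'
#' Convenience wrapper chaining the blind pipeline: density-filter the
#' ACE predictions (radius chosen by [optimize_eps()] against the union
#' of the two predicted structures' contacts unless `eps` is given),
#' corroborate each predicted structure, collect unexplained clusters and
#' classify.
#'
#' @param contacts_a,contacts_b [contact_map()] results of the two
#'   predicted structures.
#' @param ss_a,ss_b Their 3-state secondary structure strings.
#' @param predictions ACE predicted pairs (`data.frame` with `i`, `j`).
#' @param eps DBSCAN radius; `NULL` (default) optimizes over `eps_grid`.
#' @param eps_grid,tol,min_samples See [optimize_eps()].
#' @param min_alt_size,min_alt_separation See
#'   [alternative_signal_clusters()].
#' @return A [classify_blind()] `blind_call`.
#' @export
blind_predict <- function(contacts_a, contacts_b, ss_a, ss_b, predictions,
                          eps = NULL, eps_grid = 1:15, tol = 2,
                          min_samples = 3, min_alt_size = 5,
                          min_alt_separation = 6) {
  ref <- unique(rbind(contacts_a$intra[, c("i", "j")],
                      contacts_a$inter[, c("i", "j")],
                      contacts_b$intra[, c("i", "j")],
                      contacts_b$inter[, c("i", "j")]))
  if (is.null(eps))
    eps <- optimize_eps(predictions[, c("i", "j")], ref, eps_grid, tol,
                        baseline_count = 0, min_samples)$eps
  filt <- dbscan_filter(predictions, eps, min_samples)
  corr <- corroborate(contacts_a, contacts_b, filt, tol, min_samples)
  alt <- alternative_signal_clusters(filt, contacts_a, contacts_b,
                                     min_alt_size, min_alt_separation,
                                     tol)
  classify_blind(ss_a, ss_b, corr, alt)
}

#' Positions forming only dominant-fold coevolved pairs
#'
#' Positions that take part in at least one dominant-category predicted
#' pair and in no alternative-category pair. These are the columns whose
#' masking (see [mask_columns_to_alanine()]) weakens the dominant fold's
#' coevolutionary signature while leaving positions shared by both folds
#' untouched.
#'
#' @param categorized A [categorize_predictions()] object.
#' @return Sorted integer vector of query positions.
#' @export
dominant_only_positions <- function(categorized) {
  stopifnot(inherits(categorized, "categorized_predictions"))
  pos_dom <- unique(c(categorized$dominant$i, categorized$dominant$j))
  pos_alt <- unique(c(categorized$alternative$i,
                      categorized$alternative$j))
  sort(setdiff(pos_dom, pos_alt))
}
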