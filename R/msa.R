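#' Query-anchored multiple sequence alignment
#'
#' An `msa` object stores an alignment as a character matrix of single
#' upper-case residues (gap = `-`), together with the index of the query
#' row and a column map giving, for every alignment column, the position of
#' that column in the ungapped query sequence (`NA` where the query has a
#' gap). All coordinates downstream of this module (coupling scores,
#' contact maps, categorized predictions) are 1-based positions in the
#' ungapped query, so column filtering never invalidates pair indices.
#'
#' @param ali Character matrix, one row per sequence, single characters.
#' @param labels Character vector of row identifiers.
#' @param query Integer row index of the query sequence.
#' @return An object of class `msa` with fields `ali`, `labels`, `query`,
#'   `column_map` and `query_full` (the ungapped query as a string).
#' @export
new_msa <- function(ali, labels, query = 1L) {
  stopifnot(is.matrix(ali), is.character(ali))
  if (length(labels) != nrow(ali))
    stop("labels must match the number of rows")
  query <- as.integer(query)
  if (query < 1L || query > nrow(ali)) stop("query row index out of range")
  qrow <- ali[query, ]
  nongap <- qrow != "-"
  column_map <- rep(NA_integer_, ncol(ali))
  column_map[nongap] <- seq_len(sum(nongap))
  dimnames(ali) <- NULL
  x <- list(ali = ali, labels = labels, query = query,
            column_map = column_map,
            query_full = paste(qrow[nongap], collapse = ""))
  class(x) <- "msa"
  validate_msa(x)
  x
}

validate_msa <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (nrow(x$ali) < 1L) stop("msa must contain at least one row")
  cm <- x$column_map[!is.na(x$column_map)]
  if (length(cm) && any(diff(cm) <= 0))
    stop("column_map must be strictly increasing over query columns")
  q <- x$ali[x$query, !is.na(x$column_map)]
  if (!identical(paste(q, collapse = ""),
                 paste(strsplit(x$query_full, "")[[1]][cm], collapse = "")))
    stop("column_map inconsistent with the query sequence")
  invisible(x)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (query: %s, length %d)\n",
              nrow(x$ali), ncol(x$ali), x$labels[x$query],
              nchar(x$query_full)))
  invisible(x)
}

#' Number of rows of an alignment
#' @param msa An [new_msa()] object.
#' @return Integer row count.
#' @export
msa_depth <- function(msa) nrow(msa$ali)

# Subset an msa by rows and/or columns, preserving query anchoring.
msa_subset <- function(msa, rows = NULL, cols = NULL) {
  ali <- msa$ali
  labels <- msa$labels
  query <- msa$query
  cmap <- msa$column_map
  if (!is.null(rows)) {
    if (!(query %in% rows)) stop("the query row cannot be removed")
    ali <- ali[rows, , drop = FALSE]
    labels <- labels[rows]
    query <- match(msa$query, rows)
  }
  if (!is.null(cols)) {
    ali <- ali[, cols, drop = FALSE]
    cmap <- cmap[cols]
  }
  x <- list(ali = ali, labels = labels, query = as.integer(query),
            column_map = cmap, query_full = msa$query_full)
  class(x) <- "msa"
  x
}

normalize_residues <- function(s) {
  s <- toupper(s)
  gsub("[.~]", "-", s)
}

parse_fasta_blocks <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found in ", path)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    if (starts[k] > ends[k]) return("")
    paste(lines[starts[k]:ends[k]], collapse = "")
  }, character(1))
  seqs <- gsub("\\s", "", seqs)
  list(labels = labels, seqs = seqs)
}

parse_stockholm <- function(lines, path) {
  seqs <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || grepl("^#", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line in ", path, ": ", ln)
    nm <- parts[1]
    seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[nm] else "", parts[2])
  }
  if (!length(seqs)) stop("no sequences found in Stockholm file ", path)
  list(labels = names(seqs), seqs = unname(seqs))
}

#' Read an alignment from FASTA, A3M or Stockholm
#'
#' A3M lowercase characters are insertion states relative to the query
#' coordinate system and are removed (together with `.` insert gaps), after
#' which all rows must have equal length. `.` and `~` are read as gaps in
#' all formats.
#'
#' @param path File path.
#' @param format One of `"fasta"`, `"a3m"`, `"stockholm"`.
#' @param query_label Label of the query row; default `NULL` takes the
#'   first sequence. Must match exactly one row.
#' @return An [new_msa()] object with the query row identified.
#' @export
read_msa <- function(path, format = c("fasta", "a3m", "stockholm"),
                     query_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(format,
    fasta = parse_fasta_blocks(lines, path),
    a3m = parse_fasta_blocks(lines, path),
    stockholm = parse_stockholm(lines, path))
  seqs <- parsed$seqs
  if (format == "a3m") {
    # lowercase = insertion relative to the query; '.' pads inserts
    seqs <- gsub("[a-z.]", "", seqs)
  }
  seqs <- normalize_residues(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("rows of ", path, " do not align: lengths ",
         paste(unique(lens), collapse = ", "))
  if (any(lens == 0L)) stop("empty sequences in ", path)
  ali <- do.call(rbind, strsplit(seqs, ""))
  query <- 1L
  if (!is.null(query_label)) {
    hit <- which(parsed$labels == query_label)
    if (length(hit) == 0L) stop("query label not found: ", query_label)
    if (length(hit) > 1L) stop("query label is ambiguous: ", query_label)
    query <- hit
  }
  new_msa(ali, parsed$labels, query)
}

#' Write an alignment to FASTA or A3M
#'
#' The query row is written first so that round-trips through external
#' tools keep the alignment query-anchored. No insertion states are
#' emitted, so the A3M output is plain aligned FASTA.
#'
#' @param msa An [new_msa()] object.
#' @param path Output path.
#' @param format `"fasta"` or `"a3m"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  ord <- c(msa$query, setdiff(seq_len(nrow(msa$ali)), msa$query))
  out <- character(0)
  for (r in ord) {
    out <- c(out, paste0(">", msa$labels[r]),
             paste(msa$ali[r, ], collapse = ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Per-row sequence identity to the query
#'
#' Identity is counted over columns where the query is non-gap: the number
#' of columns at which the row carries the same (non-gap) residue as the
#' query, divided by the number of non-gap query columns. Columns where the
#' query is gapped are ignored entirely. The query row scores exactly 1.
#'
#' @param msa An [new_msa()] object.
#' @return Numeric vector of identity fractions, one per row.
#' @export
qid_to_query <- function(msa) {
  qcols <- which(!is.na(msa$column_map))
  q <- msa$ali[msa$query, qcols]
  denom <- length(qcols)
  if (denom == 0L) stop("query has no residues")
  sub <- msa$ali[, qcols, drop = FALSE]
  hits <- sweep(sub, 2L, q, "==") & sub != "-"
  out <- rowSums(hits) / denom
  out[msa$query] <- 1.0
  unname(out)
}

#' Prune an alignment by identity to the query
#'
#' Retains rows whose [qid_to_query()] identity is at least
#' `threshold_percent`/100. The query row is always retained.
#'
#' @param msa An [new_msa()] object.
#' @param threshold_percent Identity threshold in percent (0-100).
#' @return A pruned [new_msa()] object.
#' @export
prune_by_qid <- function(msa, threshold_percent) {
  stopifnot(threshold_percent >= 0, threshold_percent <= 100)
  qid <- qid_to_query(msa)
  keep <- which(qid >= threshold_percent / 100 |
                  seq_along(qid) == msa$query)
  msa_subset(msa, rows = keep)
}

#' Build nested subfamily alignments over a grid of identity thresholds
#'
#' One pruned alignment per threshold; thresholds yielding identical row
#' sets are collapsed to a single entry (labelled with the smallest such
#' threshold), and thresholds reproducing the full superfamily row set are
#' absorbed into the superfamily entry.
#'
#' @param msa Superfamily alignment.
#' @param thresholds Identity grid in percent; default 1 to 50 by 1.
#' @return An object of class `nested_msas` with fields `superfamily`,
#'   `subfamilies` (list of `list(threshold=, msa=)`) and `thresholds`.
#' @export
make_nested_msas <- function(msa, thresholds = 1:50) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 100))
  thresholds <- sort(unique(thresholds))
  qid <- qid_to_query(msa)
  n <- length(qid)
  subfam <- list()
  seen <- character(0)
  all_key <- paste(seq_len(n), collapse = ",")
  for (t in thresholds) {
    keep <- which(qid >= t / 100 | seq_len(n) == msa$query)
    key <- paste(keep, collapse = ",")
    if (key == all_key || key %in% seen) next
    seen <- c(seen, key)
    subfam[[length(subfam) + 1L]] <-
      list(threshold = t, msa = msa_subset(msa, rows = keep))
  }
  out <- list(superfamily = msa, subfamilies = subfam,
              thresholds = thresholds)
  class(out) <- "nested_msas"
  out
}

#' @export
print.nested_msas <- function(x, ...) {
  cat(sprintf("nested_msas: superfamily depth %d, %d distinct subfamily MSAs\n",
              msa_depth(x$superfamily), length(x$subfamilies)))
  for (s in x$subfamilies)
    cat(sprintf("  qid >= %2d%%: depth %d\n", s$threshold,
                msa_depth(s$msa)))
  invisible(x)
}

#' Remove gap-rich rows, then gap-rich columns
#'
#' Rows with gap fraction above `seq_gap_max` are removed first (never the
#' query row); columns with gap fraction above `col_gap_max` over the
#' remaining rows are removed second. The order matters and is fixed:
#' removing rows first changes which columns survive. The column map is
#' updated so pair coordinates stay valid in query space.
#'
#' @param msa An [new_msa()] object.
#' @param seq_gap_max Maximum tolerated per-row gap fraction (default 0.25).
#' @param col_gap_max Maximum tolerated per-column gap fraction (default 0.75).
#' @return A filtered [new_msa()] object.
#' @export
filter_gaps <- function(msa, seq_gap_max = 0.25, col_gap_max = 0.75) {
  gaps <- msa$ali == "-"
  rowfrac <- rowMeans(gaps)
  keep_rows <- which(rowfrac <= seq_gap_max | seq_along(rowfrac) == msa$query)
  m <- msa_subset(msa, rows = keep_rows)
  colfrac <- colMeans(m$ali == "-")
  keep_cols <- which(colfrac <= col_gap_max)
  if (length(keep_cols) == 0L) stop("all columns removed by gap filter")
  msa_subset(m, cols = keep_cols)
}

#' Is an alignment deep enough for coevolutionary analysis?
#'
#' Alignments shallower than five times the query length are considered
#' too shallow for reliable coupling inference.
#'
#' @param msa An [new_msa()] object.
#' @param query_length Length of the query; defaults to the ungapped query
#'   length stored in the alignment.
#' @return `TRUE` iff depth >= 5 * query_length.
#' @export
depth_sufficient <- function(msa, query_length = nchar(msa$query_full)) {
  stopifnot(query_length > 0)
  msa_depth(msa) >= 5 * query_length
}

#' Mutate selected query columns to alanine across an alignment
#'
#' Used to suppress the coevolutionary signature of one fold before
#' structure prediction: every listed column is set to `A` in every row
#' except (by default) the query row. Gaps are preserved.
#'
#' @param msa An [new_msa()] object.
#' @param query_positions Positions in the ungapped query to mask; each
#'   must be present in the current column map.
#' @param keep_query Leave the query row untouched (default `TRUE`).
#' @return The masked [new_msa()] object.
#' @export
mask_columns_to_alanine <- function(msa, query_positions, keep_query = TRUE) {
  if (!length(query_positions)) return(msa)
  cols <- match(query_positions, msa$column_map)
  if (anyNA(cols))
    stop("query positions not present in column map: ",
         paste(query_positions[is.na(cols)], collapse = ", "))
  rows <- seq_len(nrow(msa$ali))
  if (keep_query) rows <- setdiff(rows, msa$query)
  for (cc in cols) {
    v <- msa$ali[rows, cc]
    v[v != "-"] <- "A"
    msa$ali[rows, cc] <- v
  }
  msa
}
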