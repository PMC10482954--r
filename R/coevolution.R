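#' Per-alignment coupling scores for residue pairs
#'
#' A `prediction_run` holds the residue-pair coupling scores produced by
#' one inference method on one alignment: raw scores plus within-run
#' z-scores, in ungapped-query coordinates with `i < j`.
#'
#' @param pairs `data.frame` with columns `i`, `j`, `raw` (and optionally
#'   `z`; if absent the run is not yet standardized).
#' @param method_tag Free-text method identifier.
#' @param msa_depth Row count of the source alignment.
#' @param depth_fraction `msa_depth` divided by the superfamily depth.
#' @return An object of class `prediction_run`.
#' @export
new_prediction_run <- function(pairs, method_tag = "mi-apc",
                               msa_depth = NA_integer_,
                               depth_fraction = 1.0) {
  stopifnot(is.data.frame(pairs), all(c("i", "j", "raw") %in% names(pairs)))
  if (nrow(pairs) && any(pairs$j <= pairs$i))
    stop("pairs must satisfy i < j")
  if (!is.na(depth_fraction) &&
      (depth_fraction <= 0 || depth_fraction > 1))
    stop("depth_fraction must lie in (0, 1]")
  x <- list(pairs = pairs, method_tag = method_tag,
            msa_depth = as.integer(msa_depth),
            depth_fraction = depth_fraction)
  class(x) <- "prediction_run"
  x
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("prediction_run [%s]: %d pairs, depth %s (fraction %.3g)\n",
              x$method_tag, nrow(x$pairs), x$msa_depth, x$depth_fraction))
  invisible(x)
}

# Integer-code the query-anchored columns of an alignment over AA_ALPHABET.
# Non-standard letters are coded as gap (21).
msa_to_int <- function(msa) {
  qcols <- which(!is.na(msa$column_map))
  sub <- msa$ali[, qcols, drop = FALSE]
  codes <- match(sub, AA_ALPHABET)
  codes[is.na(codes)] <- length(AA_ALPHABET)
  X <- matrix(as.integer(codes), nrow = nrow(sub), ncol = ncol(sub))
  list(X = X, qpos = msa$column_map[qcols])
}

#' Built-in coupling scorer: APC-corrected mutual information
#'
#' Computes mutual information between every pair of query-anchored
#' columns over the 21-letter alphabet (20 amino acids + gap) with a
#' uniformly spread additive pseudocount, then applies the average product
#' correction (APC): `score(a,b) = MI(a,b) - mean_a(MI) * mean_b(MI) /
#' mean(MI)`, with the means taken over the scored (separation-filtered)
#' pair set. This stand-in scorer exists so the pipeline runs end-to-end
#' without external inference engines; scores from those engines are
#' imported with [load_external_scores()].
#'
#' @param msa A gap-filtered [new_msa()] object with at least two rows.
#' @param min_separation Minimum query-coordinate separation `j - i` for a
#'   pair to be scored (default 6).
#' @param pseudocount Total prior mass spread over the joint alphabet
#'   (default 1).
#' @param method_tag Label stored in the run (default `"mi-apc"`).
#' @return A z-scored [new_prediction_run()].
#' @export
score_mi_apc <- function(msa, min_separation = 6, pseudocount = 1,
                         method_tag = "mi-apc") {
  if (msa_depth(msa) < 2L)
    stop("insufficient data: coupling inference needs at least 2 sequences")
  enc <- msa_to_int(msa)
  C <- ncol(enc$X)
  if (C < 2L) stop("fewer than two query-anchored columns")
  MI <- .pair_mi(enc$X, length(AA_ALPHABET), pseudocount)
  sep <- outer(enc$qpos, enc$qpos, function(a, b) b - a)
  elig <- upper.tri(MI) & sep >= min_separation
  if (!any(elig)) stop("no column pairs pass the separation filter")
  eligs <- elig | t(elig)
  npart <- rowSums(eligs)
  msum <- rowSums(MI * eligs)
  colmean <- ifelse(npart > 0, msum / npart, 0)
  grand <- mean(MI[elig])
  apc <- MI - outer(colmean, colmean) / grand
  idx <- which(elig, arr.ind = TRUE)
  pairs <- data.frame(i = enc$qpos[idx[, 1]], j = enc$qpos[idx[, 2]],
                      raw = apc[elig])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  run <- new_prediction_run(pairs, method_tag = method_tag,
                            msa_depth = msa_depth(msa))
  zscore_run(run)
}

#' Standardize a run's raw scores to z-scores
#'
#' Population (not sample) standard deviation over all scored pairs of the
#' run: the run is treated as the complete population of scores, so within
#' a run z-scores have mean 0 and standard deviation 1.
#'
#' @param run A [new_prediction_run()].
#' @return The run with a `z` column added (raw scores preserved).
#' @export
zscore_run <- function(run) {
  stopifnot(inherits(run, "prediction_run"))
  x <- run$pairs$raw
  if (length(x) < 2L) stop("z-scoring needs at least 2 scored pairs")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) {
    warning("zero variance among raw scores; all z-scores set to 0")
    run$pairs$z <- rep(0, length(x))
  } else {
    run$pairs$z <- (x - mu) / sdev
  }
  run
}

#' Import externally produced coupling scores
#'
#' Reads scores from a coevolution inference engine run outside this
#' package (e.g. a Markov-random-field or language-model method). Two
#' formats are supported: `pair_list`, a whitespace/tab-separated file with
#' a `# zero_based` or `# one_based` header line followed by `i j score`
#' rows in query coordinates, and `matrix`, a plain numeric grid with one
#' row per query-anchored alignment column. Matrix entries `(i,j)` and
#' `(j,i)` are averaged; diagonal and short-range pairs are dropped.
#'
#' @param path Score file path.
#' @param format `"pair_list"` or `"matrix"`.
#' @param msa The alignment the scores were computed from (supplies the
#'   column map and dimension checks).
#' @param min_separation Minimum `j - i` separation retained (default 6).
#' @param method_tag Label stored in the run (default `"external"`).
#' @return A z-scored [new_prediction_run()].
#' @export
load_external_scores <- function(path, format = c("pair_list", "matrix"),
                                 msa, min_separation = 6,
                                 method_tag = "external") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  L <- nchar(msa$query_full)
  if (format == "pair_list") {
    if (!length(lines) || !grepl("^#\\s*(zero_based|one_based)\\s*$",
                                 lines[1]))
      stop("pair_list file must start with a '# zero_based' or ",
           "'# one_based' header: ", path)
    offset <- if (grepl("zero_based", lines[1])) 1L else 0L
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    if (!length(body)) stop("no score rows in ", path)
    rec <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(rec) != 3L)
    if (length(bad))
      stop("malformed score row at line ", bad[1] + 1L, " of ", path)
    mat <- matrix(unlist(rec), ncol = 3L, byrow = TRUE)
    suppressWarnings({
      ii <- as.integer(mat[, 1]) + offset
      jj <- as.integer(mat[, 2]) + offset
      sc <- as.numeric(mat[, 3])
    })
    bad <- which(is.na(ii) | is.na(jj) | is.na(sc))
    if (length(bad))
      stop("non-numeric value at line ", bad[1] + 1L, " of ", path)
    if (any(ii < 1L | ii > L | jj < 1L | jj > L))
      stop("pair index out of range 1..", L, " in ", path)
    i2 <- pmin(ii, jj)
    j2 <- pmax(ii, jj)
    df <- data.frame(i = i2, j = j2, raw = sc)
    df <- df[df$j - df$i >= 1L, , drop = FALSE]
    # average duplicate/mirrored entries
    key <- paste(df$i, df$j)
    agg <- tapply(df$raw, key, mean)
    ij <- do.call(rbind, strsplit(names(agg), " "))
    pairs <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                        raw = as.numeric(agg))
  } else {
    qcols <- which(!is.na(msa$column_map))
    K <- length(qcols)
    rows <- lines[nzchar(trimws(lines))]
    rec <- strsplit(trimws(rows), "\\s+")
    if (length(rec) != K)
      stop("matrix has ", length(rec), " rows but the alignment has ", K,
           " query-anchored columns: ", path)
    bad <- which(lengths(rec) != K)
    if (length(bad))
      stop("ragged matrix at line ", bad[1], " of ", path)
    suppressWarnings(M <- matrix(as.numeric(unlist(rec)), nrow = K,
                                 byrow = TRUE))
    if (anyNA(M)) {
      pos <- which(is.na(M), arr.ind = TRUE)[1, ]
      stop("non-numeric cell at row ", pos[1], ", column ", pos[2],
           " of ", path)
    }
    S <- (M + t(M)) / 2
    qpos <- msa$column_map[qcols]
    idx <- which(upper.tri(S), arr.ind = TRUE)
    pairs <- data.frame(i = qpos[idx[, 1]], j = qpos[idx[, 2]],
                        raw = S[idx])
  }
  pairs <- pairs[pairs$j - pairs$i >= min_separation, , drop = FALSE]
  if (!nrow(pairs)) stop("no pairs pass the separation filter in ", path)
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  run <- new_prediction_run(pairs, method_tag = method_tag,
                            msa_depth = msa_depth(msa))
  if (nrow(pairs) >= 2L) zscore_run(run)
  else {
    run$pairs$z <- rep(0, nrow(pairs))
    run
  }
}

#' Write a prediction run as a one-based pair list
#'
#' @param run A [new_prediction_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "prediction_run"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# one_based", con)
  utils::write.table(run$pairs[, c("i", "j", "raw")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
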