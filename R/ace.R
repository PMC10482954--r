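#' Superpose prediction runs from nested alignments onto one contact map
#'
#' Each residue pair receives the mean z-score over the runs in which it
#' was scored (runs not scoring a pair contribute nothing for that pair,
#' so subfamily-only signals are not diluted by zero-filling), the number
#' of supporting runs, and the smallest depth fraction among supporting
#' runs. The `cap` most probable pairs by mean z-score are retained, with
#' a deterministic tie-break: higher support, then lower `i`, then lower
#' `j`.
#'
#' @param runs List of [new_prediction_run()] objects sharing query
#'   coordinates.
#' @param L Query length.
#' @param cap Retention cap; default `floor(15 * L / 2)`.
#' @return An object of class `superposition` with fields `pairs` (all
#'   aggregated pairs), `retained` (top-`cap`), `L`, `cap`, `n_runs`.
#' @export
superpose_runs <- function(runs, L, cap = floor(15 * L / 2)) {
  if (!length(runs)) stop("empty run list")
  if (!all(vapply(runs, inherits, logical(1), "prediction_run")))
    stop("runs must be prediction_run objects")
  dts <- lapply(runs, function(r) {
    data.table::data.table(i = r$pairs$i, j = r$pairs$j, z = r$pairs$z,
                           df = r$depth_fraction)
  })
  dt <- data.table::rbindlist(dts)
  i <- j <- z <- df <- NULL # appease R CMD check
  agg <- dt[, list(mean_z = mean(z), support = .N,
                   shallowest_fraction = min(df)), by = list(i, j)]
  data.table::setorder(agg, -mean_z, -support, i, j)
  pairs <- as.data.frame(agg)
  retained <- utils::head(pairs, cap)
  out <- list(pairs = pairs, retained = retained, L = L, cap = cap,
              n_runs = length(runs))
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d runs, %d pairs, %d retained (cap %d, L %d)\n",
              x$n_runs, nrow(x$pairs), nrow(x$retained), x$cap, x$L))
  invisible(x)
}

#' Density-based denoising of predicted contacts (DBSCAN)
#'
#' Standard DBSCAN on the points `(i, j)` of the contact-map half-plane
#' under Euclidean distance. A core point has at least `min_samples`
#' points (itself included) within radius `eps`; clusters are the
#' connected components of core points under eps-adjacency, grown in input
#' order; a non-core point with a core neighbour joins the cluster of its
#' first core neighbour in input order (a deterministic border rule);
#' remaining points are noise.
#'
#' @param pairs `data.frame` or matrix with columns `i`, `j` (extra
#'   columns are carried through).
#' @param eps Neighbourhood radius (> 0).
#' @param min_samples Minimum points to define a cluster (default 3).
#' @return An object of class `filtered_predictions`: `pairs` with a
#'   `cluster` column (0 = noise), `clusters` (list of row-index vectors),
#'   `noise` (row indices), `eps`, `min_samples`.
#' @export
dbscan_filter <- function(pairs, eps, min_samples = 3) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stop("pairs must be nonempty")
  stopifnot(eps > 0, all(c("i", "j") %in% names(pairs)))
  n <- nrow(pairs)
  P <- cbind(pairs$i, pairs$j)
  D <- as.matrix(stats::dist(P))
  adj <- D <= eps
  core <- rowSums(adj) >= min_samples
  label <- integer(n)
  cid <- 0L
  for (p in seq_len(n)) {
    if (!core[p] || label[p] != 0L) next
    cid <- cid + 1L
    queue <- p
    label[p] <- cid
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[q, ] & core & label == 0L)
      label[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  for (p in which(!core)) {
    cn <- which(adj[p, ] & core)
    if (length(cn)) label[p] <- label[cn[1]]
  }
  pairs$cluster <- label
  clusters <- split(seq_len(n), label)
  clusters <- unname(clusters[names(clusters) != "0"])
  out <- list(pairs = pairs, clusters = clusters,
              noise = which(label == 0L), eps = eps,
              min_samples = min_samples)
  class(out) <- "filtered_predictions"
  out
}

#' @export
print.filtered_predictions <- function(x, ...) {
  cat(sprintf(
    "filtered_predictions: %d clusters, %d clustered / %d noise (eps %.3g, min %d)\n",
    length(x$clusters), sum(x$pairs$cluster > 0), length(x$noise),
    x$eps, x$min_samples))
  invisible(x)
}

#' Pairs surviving density filtering
#' @param filtered A [dbscan_filter()] result.
#' @return `data.frame` of clustered pairs (noise removed).
#' @export
filtered_pairs <- function(filtered) {
  stopifnot(inherits(filtered, "filtered_predictions"))
  filtered$pairs[filtered$pairs$cluster > 0L, , drop = FALSE]
}

# TRUE for each row of pairs lying within a Chebyshev box of +/- tol
# residues of any reference pair. Both sides are i < j normalized.
pairs_overlap <- function(pairs, reference, tol = 2) {
  pairs <- as.data.frame(pairs)
  reference <- as.data.frame(reference)
  if (!nrow(pairs)) return(logical(0))
  if (!nrow(reference)) return(rep(FALSE, nrow(pairs)))
  M <- max(pairs$i, pairs$j, reference$i, reference$j) + tol
  mask <- matrix(FALSE, M, M)
  for (r in seq_len(nrow(reference))) {
    ri <- reference$i[r]; rj <- reference$j[r]
    xi <- max(1L, ri - tol):min(M, ri + tol)
    xj <- max(1L, rj - tol):min(M, rj + tol)
    mask[xi, xj] <- TRUE
  }
  mask[cbind(pairs$i, pairs$j)]
}

#' Choose the DBSCAN radius from an ROC over a reference contact set
#'
#' For each radius in `eps_grid`, the retained pairs are density-filtered
#' and split into true positives (within a Chebyshev box of `tol` residues
#' of any reference contact) and false positives. Moving up the grid, the
#' marginal slope `dTP/dFP` between consecutive radii is computed
#' (`dFP = 0` counts as +Inf when TP grows, 0 otherwise). The selected
#' radius is the largest one whose incoming slope exceeds 1 while the next
#' step's slope falls below 1 (more noise than signal would be gained by
#' growing further). The radius may not be so stringent that fewer
#' contacts survive than `baseline_count` (the deep-alignment-only
#' retention): if it is, the smallest radius satisfying the baseline is
#' used instead, falling back to the largest grid value with a warning.
#'
#' @param pairs Retained predicted pairs (`data.frame` with `i`, `j`).
#' @param reference_contacts Reference contacts (`data.frame` with `i`, `j`).
#' @param eps_grid Strictly increasing candidate radii (default 1:15).
#' @param tol Overlap tolerance in residues (default 2).
#' @param baseline_count Minimum number of surviving contacts (default 0).
#' @param min_samples Minimum cluster size (default 3).
#' @return List of class `eps_roc`: `eps` (chosen radius) and `roc`
#'   (per-radius table of TP, FP, kept count and slope).
#' @export
optimize_eps <- function(pairs, reference_contacts, eps_grid = 1:15,
                         tol = 2, baseline_count = 0, min_samples = 3) {
  if (!length(eps_grid)) stop("empty eps grid")
  if (is.unsorted(eps_grid, strictly = TRUE))
    stop("eps_grid must be strictly increasing")
  K <- length(eps_grid)
  TP <- FP <- kept <- numeric(K)
  for (k in seq_len(K)) {
    f <- dbscan_filter(pairs, eps_grid[k], min_samples)
    kp <- filtered_pairs(f)
    kept[k] <- nrow(kp)
    ov <- pairs_overlap(kp, reference_contacts, tol)
    TP[k] <- sum(ov)
    FP[k] <- kept[k] - TP[k]
  }
  slope <- rep(NA_real_, K)
  for (k in seq_len(K)[-1]) {
    dtp <- TP[k] - TP[k - 1]
    dfp <- FP[k] - FP[k - 1]
    slope[k] <- if (dfp == 0) {
      if (dtp > 0) Inf else 0
    } else dtp / dfp
  }
  cand <- integer(0)
  for (k in seq_len(K)[-1]) {
    if (is.na(slope[k]) || slope[k] <= 1) next
    if (k == K || slope[k + 1] < 1) cand <- c(cand, k)
  }
  pick_baseline <- function() {
    ok <- which(kept >= baseline_count)
    if (length(ok)) return(ok[1])
    warning("no radius reaches the baseline contact count; ",
            "using the largest grid value")
    K
  }
  if (length(cand)) {
    sel <- max(cand)
    if (kept[sel] < baseline_count) sel <- pick_baseline()
  } else {
    sel <- pick_baseline()
  }
  out <- list(eps = eps_grid[sel],
              roc = data.frame(eps = eps_grid, TP = TP, FP = FP,
                               kept = kept, slope = slope))
  class(out) <- "eps_roc"
  out
}

#' @export
print.eps_roc <- function(x, ...) {
  cat("eps_roc: chosen eps =", x$eps, "\n")
  print(x$roc)
  invisible(x)
}

# All experimental contacts of a dual-fold map as one reference set.
all_map_contacts <- function(map) {
  stopifnot(inherits(map, "dual_fold_map"))
  parts <- list(map$unique_a, map$unique_b, map$common,
                map$inter_a, map$inter_b)
  parts <- parts[vapply(parts, NROW, integer(1)) > 0]
  if (!length(parts)) return(data.frame(i = integer(0), j = integer(0)))
  unique(do.call(rbind, lapply(parts, function(p) p[, c("i", "j")])))
}

#' Run the full alternative-contact-enhancement pipeline
#'
#' Orchestrates: per-alignment gap filtering, coupling inference on the
#' superfamily and every nested subfamily alignment with every scorer,
#' per-run z-scoring, superposition with 15L/2 retention, ROC-based radius
#' choice against the reference contacts, and density filtering. A
#' superfamily-only baseline (3L/2 retention, the standard single-run
#' practice) is computed alongside for comparison and supplies the
#' baseline count of the radius optimizer.
#'
#' @param nested A [make_nested_msas()] object whose superfamily alignment
#'   passes [depth_sufficient()].
#' @param scorers Named list of scoring functions
#'   `function(msa, min_separation)` returning a z-scored run; default the
#'   built-in [score_mi_apc()].
#' @param reference_map A [build_dual_fold_map()] object (or plain
#'   `data.frame` of contacts) supplying the ROC reference.
#' @param min_separation Minimum pair separation (default 6).
#' @param eps_grid Candidate DBSCAN radii (default 1:15).
#' @param tol Overlap tolerance in residues (default 2).
#' @param min_samples Minimum cluster size (default 3).
#' @param seq_gap_max,col_gap_max Gap-filter thresholds (defaults 0.25,
#'   0.75).
#' @return Object of class `ace_result`: `superposition`, `filtered`,
#'   `eps` (the `eps_roc`), `superfamily_retained` (baseline top-3L/2
#'   pairs), `runs` (per-run metadata), `L`, `config`.
#' @export
run_ace <- function(nested, scorers = list("mi-apc" = score_mi_apc),
                    reference_map, min_separation = 6, eps_grid = 1:15,
                    tol = 2, min_samples = 3, seq_gap_max = 0.25,
                    col_gap_max = 0.75) {
  stopifnot(inherits(nested, "nested_msas"))
  L <- nchar(nested$superfamily$query_full)
  if (!depth_sufficient(nested$superfamily, L))
    stop(sprintf(
      "superfamily alignment too shallow for analysis: depth %d < 5L = %d",
      msa_depth(nested$superfamily), 5L * L))
  ref <- if (inherits(reference_map, "dual_fold_map"))
    all_map_contacts(reference_map) else as.data.frame(reference_map)

  msas <- c(list(list(threshold = 0, msa = nested$superfamily)),
            nested$subfamilies)
  super_f <- filter_gaps(nested$superfamily, seq_gap_max, col_gap_max)
  super_depth <- msa_depth(super_f)

  runs <- list()
  meta <- list()
  super_runs <- list()
  for (entry in msas) {
    m <- filter_gaps(entry$msa, seq_gap_max, col_gap_max)
    if (msa_depth(m) < 2L) next
    for (tag in names(scorers)) {
      r <- scorers[[tag]](m, min_separation = min_separation)
      r$method_tag <- tag
      r$depth_fraction <- msa_depth(m) / super_depth
      runs[[length(runs) + 1L]] <- r
      meta[[length(meta) + 1L]] <-
        data.frame(threshold = entry$threshold, method = tag,
                   depth = msa_depth(m),
                   depth_fraction = r$depth_fraction)
      if (entry$threshold == 0) super_runs[[length(super_runs) + 1L]] <- r
    }
  }
  if (!length(runs)) stop("no alignment produced a usable run")

  sup <- superpose_runs(runs, L, cap = floor(15 * L / 2))
  sup0 <- superpose_runs(super_runs, L, cap = floor(3 * L / 2))
  baseline_count <- nrow(sup0$retained)

  opt <- optimize_eps(sup$retained[, c("i", "j")], ref, eps_grid, tol,
                      baseline_count, min_samples)
  filt <- dbscan_filter(sup$retained, opt$eps, min_samples)

  out <- list(superposition = sup, filtered = filt, eps = opt,
              superfamily_retained = sup0$retained,
              runs = do.call(rbind, meta), L = L,
              config = list(min_separation = min_separation,
                            eps_grid = eps_grid, tol = tol,
                            min_samples = min_samples,
                            cap = floor(15 * L / 2),
                            baseline_cap = floor(3 * L / 2),
                            seq_gap_max = seq_gap_max,
                            col_gap_max = col_gap_max,
                            scorers = names(scorers)))
  class(out) <- "ace_result"
  out
}

#' @export
print.ace_result <- function(x, ...) {
  cat(sprintf(
    "ace_result: L=%d, %d runs, %d retained, eps=%.3g, %d clusters, %d noise\n",
    x$L, nrow(x$runs), nrow(x$superposition$retained), x$eps$eps,
    length(x$filtered$clusters), length(x$filtered$noise)))
  invisible(x)
}
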