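lchoose_safe <- function(n, k) {
  if (k < 0 || k > n || n < 0) return(-Inf)
  lchoose(n, k)
}

#' One-tailed hypergeometric enrichment p-value for subfamily contacts
#'
#' Evaluates the probability of obtaining at least the observed number of
#' additional correct contacts from the subfamily alignments, given the
#' concomitant incorrect ones, by direct summation of the hypergeometric
#' series in log-space (log-gamma binomials):
#' \deqn{p = \sum_{i=0}^{N_{ns}}
#'   \frac{\binom{N_{exp}-N_{ps}}{N_{pd}+i}\,\binom{N_{noise}-N_{nsup}}{N_{ns}-i}}
#'        {\binom{(N_{exp,tot}-N_{ps})+(N_{noise,tot}-N_{nsup})}{N_{pd}+N_{ns}}}}
#' where \eqn{N_{exp}} is the number of unique experimental contacts from
#' both conformations, \eqn{N_{ps}}/\eqn{N_{nsup}} the unique
#' correct/incorrect superfamily-only predictions, \eqn{N_{pd}}/\eqn{N_{ns}}
#' the unique correct/incorrect subfamily predictions not already made by
#' the superfamily, and \eqn{N_{noise} = L^2 - N_{exp}} with `L` the
#' maximum experimental sequence length (the squared form, although pairs
#' are unordered, is retained as the test's definition). Terms with
#' impossible binomial arguments contribute zero.
#'
#' @param n_exp Unique experimental contacts from both conformations.
#' @param n_pred_super Unique correct superfamily-only predictions.
#' @param n_pred_sub Unique correct subfamily predictions excluding the
#'   superfamily's.
#' @param n_noise_super Unique incorrect superfamily-only predictions.
#' @param n_noise_sub Unique incorrect subfamily predictions excluding the
#'   superfamily's.
#' @param L Maximum sequence length of an experimentally determined
#'   structure.
#' @param n_exp_total,n_noise_total Denominator totals; they default to
#'   `n_exp` and `n_noise` and exist only because the test names them
#'   separately.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(n_exp, n_pred_super, n_pred_sub,
                             n_noise_super, n_noise_sub, L,
                             n_exp_total = n_exp, n_noise_total = NULL) {
  counts <- c(n_exp, n_pred_super, n_pred_sub, n_noise_super,
              n_noise_sub, L)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("all counts must be non-negative integers")
  if (n_pred_super > n_exp)
    stop("n_pred_super cannot exceed n_exp")
  n_noise <- L^2 - n_exp
  if (n_noise < 0) stop("L^2 must be at least n_exp")
  if (is.null(n_noise_total)) n_noise_total <- n_noise
  if (n_noise_super > n_noise) stop("n_noise_super cannot exceed n_noise")
  A <- n_exp - n_pred_super
  B <- n_noise - n_noise_super
  Dn <- (n_exp_total - n_pred_super) + (n_noise_total - n_noise_super)
  k <- n_pred_sub + n_noise_sub
  ldenom <- lchoose_safe(Dn, k)
  if (!is.finite(ldenom))
    stop("impossible denominator: cannot draw ", k, " from ", Dn)
  lt <- vapply(0:n_noise_sub, function(i) {
    lchoose_safe(A, n_pred_sub + i) + lchoose_safe(B, n_noise_sub - i)
  }, numeric(1))
  p <- exp(logsumexp(lt) - ldenom)
  min(p, 1)
}

#' Epps-Singleton two-sample test
#'
#' Compares two samples through their empirical characteristic functions
#' evaluated at points `t` scaled by the semi-interquartile range of the
#' pooled sample. The statistic is a quadratic form in the difference of
#' the cos/sin moment vectors, with a biased covariance estimate and the
#' published small-sample correction when both samples are below 25
#' observations; the p-value comes from the asymptotic chi-squared
#' distribution with degrees of freedom equal to the rank of the
#' covariance. Valid for discrete and continuous data.
#'
#' @param x,y Numeric samples, each with at least 5 observations.
#' @param t Evaluation points for the characteristic function (default
#'   `c(0.4, 0.8)`).
#' @return An object of class `htest` with `statistic`, `parameter` (df)
#'   and `p.value`.
#' @export
epps_singleton <- function(x, y, t = c(0.4, 0.8)) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  nx <- length(x)
  ny <- length(y)
  if (nx < 5 || ny < 5)
    stop("each sample needs at least 5 observations")
  if (any(t <= 0)) stop("t must be positive")
  sigma <- stats::IQR(c(x, y), type = 7) / 2
  if (sigma == 0)
    stop("degenerate samples: pooled interquartile range is zero")
  ts <- t / sigma
  gmat <- function(v) {
    rbind(do.call(rbind, lapply(ts, function(s) cos(s * v))),
          do.call(rbind, lapply(ts, function(s) sin(s * v))))
  }
  gx <- gmat(x)
  gy <- gmat(y)
  n <- nx + ny
  cov_b <- function(g) {
    m <- rowMeans(g)
    tcrossprod(g - m) / ncol(g)
  }
  est_cov <- (n / nx) * cov_b(gx) + (n / ny) * cov_b(gy)
  sv <- svd(est_cov)
  tolr <- max(dim(est_cov)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tolr
  r <- sum(pos)
  if (r < 2 * length(t))
    warning("estimated covariance matrix is rank deficient; ",
            "consider different evaluation points t")
  dinv <- ifelse(pos, 1 / sv$d, 0)
  pinv <- sv$v %*% (dinv * t(sv$u))
  d <- rowMeans(gx) - rowMeans(gy)
  w <- n * drop(t(d) %*% pinv %*% d)
  if (max(nx, ny) < 25)
    w <- w / (1 + n^(-0.45) + 10.1 * (nx^(-1.7) + ny^(-1.7)))
  p <- stats::pchisq(w, df = r, lower.tail = FALSE)
  structure(list(statistic = c(W2 = w), parameter = c(df = r),
                 p.value = p,
                 method = "Epps-Singleton two-sample test",
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Fraction of predictions not matching the dominant conformation
#'
#' Alternative plus unobserved predictions over all predictions. For a
#' single-fold protein the alternative set is empty by construction, so
#' this reduces to the unobserved fraction.
#'
#' @param categorized A [categorize_predictions()] object.
#' @return Fraction in \[0, 1\].
#' @export
nondominant_fraction <- function(categorized) {
  stopifnot(inherits(categorized, "categorized_predictions"))
  if (categorized$n == 0)
    stop("no predictions: non-dominant fraction undefined")
  (nrow(categorized$alternative) + nrow(categorized$unobserved)) /
    categorized$n
}

#' Percent increase of contact counts over the deep-alignment baseline
#'
#' @param count_super_only Contact count from the superfamily-only
#'   analysis (must be at least 1; a zero baseline is undefined and
#'   returns `NA` with a warning so it can be reported separately).
#' @param count_ace Contact count after enhancement.
#' @return Percent increase, `100 * (ace - super) / super`.
#' @export
amplification <- function(count_super_only, count_ace) {
  stopifnot(count_super_only >= 0, count_ace >= 0)
  if (count_super_only == 0) {
    warning("zero baseline count: amplification undefined")
    return(NA_real_)
  }
  100 * (count_ace - count_super_only) / count_super_only
}

#' Depth-fraction bin of a pruned alignment
#'
#' Alignment depths are normalized by the superfamily depth and floored
#' into 0.05-wide bins labelled by their lower edge; a fraction of exactly
#' 1 maps to the top bin, 0.95.
#'
#' @param msa_depth Depth of the pruned alignment (vectorized).
#' @param superfamily_depth Depth of the unpruned superfamily alignment.
#' @return Bin lower edge(s) in `{0.00, 0.05, ..., 0.95}`.
#' @export
depth_bin <- function(msa_depth, superfamily_depth) {
  stopifnot(all(msa_depth > 0), all(msa_depth <= superfamily_depth))
  pmin(floor(20 * msa_depth / superfamily_depth) / 20, 0.95)
}

#' Cumulative contact counts and z-scores by depth-fraction bin
#'
#' For one protein family: per contact category, the cumulative count at
#' bin `b` is the size of the union of that category's contacts over all
#' alignments whose depth bin is at least `b` (so the shallowest bin 0.00
#' accumulates every alignment). Counts are converted to z-scores over the
#' twenty bins (population standard deviation; a flat profile gives all
#' zeros), making enhancement comparable across families with very
#' different raw contact counts.
#'
#' @param per_msa_sets List over alignments; each element a named list of
#'   contact `data.frame`s (`i`, `j`) per category, or a single
#'   `data.frame` (treated as category `"contacts"`).
#' @param depths Integer vector of alignment depths, parallel to
#'   `per_msa_sets`.
#' @param superfamily_depth Depth of the superfamily alignment.
#' @return Object of class `enhancement_profile`: `bins`, `counts` (bins x
#'   categories), `z` (same shape), `categories`.
#' @export
enhancement_profile <- function(per_msa_sets, depths, superfamily_depth) {
  if (length(per_msa_sets) != length(depths))
    stop("per_msa_sets and depths must have equal length")
  sets <- lapply(per_msa_sets, function(s) {
    if (is.data.frame(s)) list(contacts = s) else s
  })
  cats <- unique(unlist(lapply(sets, names)))
  if (is.null(cats) || !length(cats)) stop("no contact categories found")
  b <- depth_bin(depths, superfamily_depth)
  if (length(unique(b)) < 2L)
    stop("fewer than two populated depth bins: profile has zero variance")
  bins <- seq(0, 0.95, by = 0.05)
  counts <- matrix(0L, nrow = length(bins), ncol = length(cats),
                   dimnames = list(sprintf("%.2f", bins), cats))
  for (bi in seq_along(bins)) {
    sel <- which(b >= bins[bi])
    for (cat_ in cats) {
      pool <- lapply(sets[sel], function(s) {
        df <- s[[cat_]]
        if (is.null(df) || !nrow(df)) NULL else df[, c("i", "j")]
      })
      pool <- pool[!vapply(pool, is.null, logical(1))]
      counts[bi, cat_] <- if (length(pool))
        nrow(unique(do.call(rbind, pool))) else 0L
    }
  }
  z <- apply(counts, 2, function(v) {
    sdev <- sqrt(mean((v - mean(v))^2))
    if (sdev == 0) rep(0, length(v)) else (v - mean(v)) / sdev
  })
  rownames(z) <- rownames(counts)
  out <- list(bins = bins, counts = counts, z = z, categories = cats)
  class(out) <- "enhancement_profile"
  out
}

#' @export
print.enhancement_profile <- function(x, ...) {
  cat("enhancement_profile over bins 0.00-0.95:\n")
  print(x$counts)
  invisible(x)
}

#' Median per-bin z-scores across a cohort of families
#'
#' @param profiles List of [enhancement_profile()] objects.
#' @return Matrix of median z-scores, bins x categories (categories
#'   present in every profile).
#' @export
profile_medians <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1),
                       "enhancement_profile")))
  cats <- Reduce(intersect, lapply(profiles, function(p) p$categories))
  if (!length(cats)) stop("profiles share no contact category")
  bins <- profiles[[1]]$bins
  out <- sapply(cats, function(cat_) {
    apply(sapply(profiles, function(p) p$z[, cat_]), 1, stats::median)
  })
  rownames(out) <- sprintf("%.2f", bins)
  out
}
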