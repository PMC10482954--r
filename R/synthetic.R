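#' Specification of a synthetic protein family with planted couplings
#'
#' Describes the ground-truth generator: a superfamily alignment in which
#' dominant-fold couplings are shared by every sequence, while
#' alternative-fold couplings are carried only by a high-identity clade
#' (the fold-switching subfamily). Planted pairs are laid out as small
#' contact clusters (an anchor column against a short run of consecutive
#' columns), mirroring the patch structure of real contact maps. Planted
#' columns are two-state columns; outside the clade the two sides of an
#' alternative pair are sampled with a mild compensating anti-correlation
#' so that the pooled superfamily joint distribution factorizes -- the
#' textbook picture of subfamily-specific coevolution invisible at
#' superfamily scale.
#'
#' @param L Query length (default 100).
#' @param n_super Superfamily depth including the query (default 2000;
#'   must be at least 5L so the depth rule holds).
#' @param clade_fraction Fraction of rows in the high-identity clade
#'   (default 0.15).
#' @param n_dominant,n_alternative Numbers of planted dominant /
#'   alternative pairs (defaults 8 and 8).
#' @param coupling_strength Probability that a planted pair in an active
#'   row draws jointly from its coupled-state table (default 0.9).
#' @param background_identity,clade_identity Expected identity to the
#'   query outside planted columns (defaults 0.35 and 0.8).
#' @param min_separation Minimum sequence separation of planted pairs
#'   (default 6).
#' @param group_size Pairs per planted contact cluster (default 4).
#' @param seed RNG seed (default 7).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(L = 100, n_super = 2000, clade_fraction = 0.15,
                           n_dominant = 8, n_alternative = 8,
                           coupling_strength = 0.9,
                           background_identity = 0.35,
                           clade_identity = 0.8, min_separation = 6,
                           group_size = 4, seed = 7) {
  stopifnot(L >= 20, n_super >= 5 * L,
            clade_fraction > 0, clade_fraction < 1,
            n_dominant >= 0, n_alternative >= 0,
            coupling_strength >= 0, coupling_strength <= 1,
            background_identity > 0, clade_identity > background_identity,
            clade_identity <= 1, min_separation >= 1, group_size >= 1)
  phi <- clade_fraction * coupling_strength
  theta <- (0.5 - phi - 0.5 * clade_fraction * (1 - coupling_strength)) /
    (1 - clade_fraction)
  if (theta < 0 || theta > 1)
    stop("infeasible clade_fraction/coupling_strength combination")
  out <- list(L = L, n_super = n_super, clade_fraction = clade_fraction,
              n_dominant = n_dominant, n_alternative = n_alternative,
              coupling_strength = coupling_strength,
              background_identity = background_identity,
              clade_identity = clade_identity,
              min_separation = min_separation, group_size = group_size,
              seed = seed, theta = theta)
  class(out) <- "synthetic_spec"
  out
}

# Place planted contact clusters on disjoint columns. Each group couples
# one anchor column c0 with a run of `size` consecutive columns starting
# at r0 >= c0 + min_sep, producing `size` planted pairs (c0, r0+t).
place_groups <- function(L, n_pairs, group_size, min_sep, used) {
  groups <- list()
  remaining <- n_pairs
  guard <- 0L
  while (remaining > 0L) {
    size <- min(group_size, remaining)
    guard <- guard + 1L
    if (guard > 10000L)
      stop("could not place planted pairs: sequence too short for the ",
           "requested layout")
    c0 <- sample.int(L - min_sep - size, 1)
    r0 <- c0 + min_sep + sample.int(L - c0 - min_sep - size + 1, 1) - 1L
    cols <- c(c0, r0:(r0 + size - 1L))
    if (any(cols %in% used) || max(cols) > L) next
    used <- c(used, cols)
    groups[[length(groups) + 1L]] <-
      list(anchor = c0, run = r0:(r0 + size - 1L),
           pairs = data.frame(i = c0, j = r0:(r0 + size - 1L)))
    remaining <- remaining - size
  }
  list(groups = groups, used = used)
}

#' Generate a synthetic protein family with known ground truth
#'
#' Draws a uniformly random query, mutates it i.i.d. per row to hit the
#' clade or background identity in expectation, and overrides the planted
#' columns: dominant clusters are coupled (with probability
#' `coupling_strength`) in every row, alternative clusters only within
#' the clade; outside the clade the alternative columns remain two-state
#' but are sampled so the pooled superfamily distribution of each planted
#' alternative pair factorizes. Deterministic given the seed; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `msa` (an [new_msa()] object, query first) and
#'   `truth` (planted `dominant_pairs`, `alternative_pairs`, `clade_rows`,
#'   `groups`, and the generating [synthetic_spec()]).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    L <- spec$L
    n <- spec$n_super
    gs <- spec$group_size
    placed_d <- place_groups(L, spec$n_dominant, gs,
                             spec$min_separation, integer(0))
    placed_a <- place_groups(L, spec$n_alternative, gs,
                             spec$min_separation, placed_d$used)
    dom_groups <- placed_d$groups
    alt_groups <- placed_a$groups

    qcode <- sample.int(20, L, replace = TRUE)
    n_clade <- max(1L, round(spec$clade_fraction * (n - 1L)))
    clade_rows <- seq.int(2L, 1L + n_clade)
    bg_rows <- setdiff(seq_len(n)[-1L], clade_rows)

    ident <- numeric(n)
    ident[clade_rows] <- spec$clade_identity
    ident[bg_rows] <- spec$background_identity

    M <- matrix(0L, nrow = n, ncol = L)
    M[1L, ] <- qcode
    for (r in seq_len(n)[-1L]) {
      keep <- stats::runif(L) < ident[r]
      k <- sample.int(19L, L, replace = TRUE)
      other <- k + (k >= qcode)
      M[r, ] <- ifelse(keep, qcode, other)
    }

    # two-state tables: state 1 = query residue, state 2 = a fixed other
    state2 <- function(cols) {
      k <- sample.int(19L, length(cols), replace = TRUE)
      k + (k >= qcode[cols])
    }
    set_state <- function(rows, cols, z, s2) {
      # z: per-row state (1/2); s2: per-col state-2 codes
      for (ci in seq_along(cols)) {
        M[rows, cols[ci]] <<- ifelse(z == 1L, qcode[cols[ci]], s2[ci])
      }
    }
    s <- spec$coupling_strength
    for (g in dom_groups) {
      cols <- c(g$anchor, g$run)
      s2 <- state2(cols)
      rows <- seq_len(n)[-1L]
      coupled <- stats::runif(length(rows)) < s
      zc <- sample.int(2L, sum(coupled), replace = TRUE)
      set_state(rows[coupled], cols, zc, s2)
      if (any(!coupled)) {
        for (ci in seq_along(cols)) {
          zi <- sample.int(2L, sum(!coupled), replace = TRUE)
          M[rows[!coupled], cols[ci]] <-
            ifelse(zi == 1L, qcode[cols[ci]], s2[ci])
        }
      }
    }
    for (g in alt_groups) {
      cols <- c(g$anchor, g$run)
      s2 <- state2(cols)
      coupled <- stats::runif(length(clade_rows)) < s
      zc <- sample.int(2L, sum(coupled), replace = TRUE)
      set_state(clade_rows[coupled], cols, zc, s2)
      if (any(!coupled)) {
        for (ci in seq_along(cols)) {
          zi <- sample.int(2L, sum(!coupled), replace = TRUE)
          M[clade_rows[!coupled], cols[ci]] <-
            ifelse(zi == 1L, qcode[cols[ci]], s2[ci])
        }
      }
      # background: anchor and run stay two-state but the pooled joint
      # factorizes (mild anti-correlation compensating the clade)
      u <- sample.int(2L, length(bg_rows), replace = TRUE)
      same <- stats::runif(length(bg_rows)) < spec$theta
      v <- ifelse(same, u, 3L - u)
      set_state(bg_rows, g$anchor, u, s2[1L])
      set_state(bg_rows, g$run, v, s2[-1L])
    }

    ali <- matrix(AA_ALPHABET[M], nrow = n, ncol = L)
    labels <- c("query",
                sprintf("clade_%04d", seq_along(clade_rows)),
                sprintf("bg_%05d", seq_along(bg_rows)))
    msa <- new_msa(ali, labels, query = 1L)
    truth <- list(
      dominant_pairs = do.call(rbind, lapply(dom_groups, `[[`, "pairs")),
      alternative_pairs = if (length(alt_groups))
        do.call(rbind, lapply(alt_groups, `[[`, "pairs"))
      else data.frame(i = integer(0), j = integer(0)),
      clade_rows = clade_rows, groups = list(dominant = dom_groups,
                                             alternative = alt_groups),
      spec = spec)
    list(msa = msa, truth = truth)
  })
}

#' Construct a contact set object from plain pair tables
#'
#' Utility for building [contact_map()]-compatible objects from planted
#' ground truth or externally supplied contact lists.
#'
#' @param intra Intrachain contacts (`data.frame` with `i`, `j`).
#' @param inter Interchain contacts (default none).
#' @param L Query length; defaults to the largest index present.
#' @param id Identifier.
#' @return A `contact_sets` object.
#' @export
as_contact_sets <- function(intra,
                            inter = data.frame(i = integer(0),
                                               j = integer(0)),
                            L = NULL, id = "contacts") {
  intra <- as.data.frame(intra)[, c("i", "j")]
  inter <- as.data.frame(inter)
  if (nrow(inter)) inter <- inter[, c("i", "j")]
  if (is.null(L))
    L <- max(c(intra$i, intra$j, inter$i, inter$j, 1L))
  out <- list(intra = intra, inter = inter, L = L, id = id)
  class(out) <- "contact_sets"
  out
}

#' Random disjoint dual-fold contact sets with requested sizes
#'
#' Emits two synthetic structures' intrachain contact sets sharing
#' `n_common` contacts, with `n_dominant` unique to fold a and
#' `n_alternative` unique to fold b, plus the assembled dual-fold map. No
#' 3-D coordinates are attempted: the sets are used directly by
#' categorization and statistics tests.
#'
#' @param L Query length.
#' @param n_dominant,n_alternative,n_common Category sizes.
#' @param seed RNG seed (default 1).
#' @param min_separation Minimum `j - i` (default 2).
#' @return List: `contacts_a`, `contacts_b` (`contact_sets`), `map`
#'   (`dual_fold_map`).
#' @export
generate_toy_dualfold <- function(L, n_dominant, n_alternative, n_common,
                                  seed = 1, min_separation = 2) {
  with_local_seed(seed, {
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    idx <- idx[idx[, 2] - idx[, 1] >= min_separation, , drop = FALSE]
    need <- n_dominant + n_alternative + n_common
    if (need > nrow(idx))
      stop("requested ", need, " contacts but only ", nrow(idx),
           " pairs satisfy the separation constraint at L = ", L)
    pick <- idx[sample.int(nrow(idx), need), , drop = FALSE]
    df <- data.frame(i = pick[, 1], j = pick[, 2])
    dom <- df[seq_len(n_dominant), , drop = FALSE]
    alt <- df[n_dominant + seq_len(n_alternative), , drop = FALSE]
    com <- df[n_dominant + n_alternative + seq_len(n_common), ,
              drop = FALSE]
    ca <- as_contact_sets(rbind(dom, com), L = L, id = "foldA")
    cb <- as_contact_sets(rbind(alt, com), L = L, id = "foldB")
    list(contacts_a = ca, contacts_b = cb,
         map = build_dual_fold_map(ca, cb))
  })
}

#' Synthetic blind-prediction scenario emulating ACE output
#'
#' Builds the inputs the blind classification pipeline consumes: two
#' predicted structures' contact sets laid out as small patches (vertical
#' runs of adjacent pairs, as strand pairings appear on contact maps),
#' matching 3-state secondary structure strings, and a denoised-scale
#' prediction set containing one tight cluster per contact patch plus
#' scattered isolated noise pairs. In the dual-fold scenario the two
#' structures differ by unique patches and by a 20-residue helix/strand
#' divergent region; in the single-fold scenario they are identical. The
#' prediction set emulates the situation after superposition and density
#' filtering of a real family, where surviving clusters sit on true
#' contacts and residual noise is sparse.
#'
#' @param L Query length (default 100).
#' @param dual Generate a fold-switching family (`TRUE`) or single-fold
#'   (`FALSE`).
#' @param n_unique Unique contact patches per fold (default 3).
#' @param n_common Patches common to both folds (default 2).
#' @param patch_len Pairs per patch (default 6).
#' @param n_noise Isolated noise pairs in the prediction set (default 30).
#' @param seed RNG seed.
#' @return List: `ss_a`, `ss_b`, `contacts_a`, `contacts_b`,
#'   `predictions` (`data.frame` of pairs), `truth`.
#' @export
generate_blind_family <- function(L = 100, dual = TRUE, n_unique = 3,
                                  n_common = 2, patch_len = 6,
                                  n_noise = 30, seed = 1) {
  stopifnot(L >= 60)
  with_local_seed(seed, {
    min_sep <- 6L
    placed <- list()
    too_close <- function(i, j, pts, d) {
      any(abs(pts$i - i) <= d & abs(pts$j - j) <= d)
    }
    all_pts <- data.frame(i = integer(0), j = integer(0))
    place_patch <- function() {
      repeat {
        i0 <- sample.int(L - min_sep - patch_len, 1)
        j0 <- i0 + min_sep +
          sample.int(L - i0 - min_sep - patch_len + 1, 1) - 1L
        pts <- data.frame(i = i0, j = j0:(j0 + patch_len - 1L))
        if (!nrow(all_pts) ||
            !any(vapply(seq_len(nrow(pts)), function(k)
              too_close(pts$i[k], pts$j[k], all_pts, 8L), logical(1)))) {
          all_pts <<- rbind(all_pts, pts)
          return(pts)
        }
      }
    }
    n_a <- if (dual) n_unique else 0L
    n_b <- if (dual) n_unique else 0L
    patches_a <- if (n_a) lapply(seq_len(n_a), function(k) place_patch())
    patches_b <- if (n_b) lapply(seq_len(n_b), function(k) place_patch())
    patches_c <- lapply(seq_len(max(n_common, 1L)), function(k)
      place_patch())
    if (!dual) {
      # single fold: every patch belongs to the one (shared) structure
      patches_c <- c(patches_c,
                     lapply(seq_len(n_unique), function(k) place_patch()))
    }
    bind <- function(lst) if (length(lst)) unique(do.call(rbind, lst))
      else data.frame(i = integer(0), j = integer(0))
    com <- bind(patches_c)
    ua <- bind(patches_a)
    ub <- bind(patches_b)
    ca <- as_contact_sets(rbind(ua, com), L = L, id = "predictedA")
    cb <- as_contact_sets(rbind(ub, com), L = L, id = "predictedB")

    predictions <- rbind(ua, ub, com)
    guard <- 0L
    while (n_noise > 0L && guard < 50000L) {
      guard <- guard + 1L
      i0 <- sample.int(L - min_sep, 1)
      j0 <- i0 + min_sep + sample.int(L - i0 - min_sep + 1, 1) - 1L
      if (too_close(i0, j0, predictions, 3L)) next
      predictions <- rbind(predictions, data.frame(i = i0, j = j0))
      n_noise <- n_noise - 1L
    }
    rownames(predictions) <- NULL

    base <- rep(c("H", "C", "E", "C"), length.out = 20)
    ss <- unlist(lapply(seq_len(ceiling(L / 10)), function(k)
      rep(base[(k - 1) %% 4 + 1], 10)))[seq_len(L)]
    ss_a <- ss
    ss_b <- ss
    if (dual) {
      d0 <- sample.int(L - 20L, 1)
      ss_a[d0:(d0 + 19L)] <- "H"
      ss_b[d0:(d0 + 19L)] <- "E"
    }
    list(ss_a = paste(ss_a, collapse = ""),
         ss_b = paste(ss_b, collapse = ""),
         contacts_a = ca, contacts_b = cb, predictions = predictions,
         truth = list(unique_a = ua, unique_b = ub, common = com,
                      dual = dual))
  })
}
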