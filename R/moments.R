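#' Central moments of depth profiles
#'
#' Treats each profile as a histogram with the intracortical depths `1..D` as
#' bins and the sampled intensities as frequencies, and computes the mean and
#' standard deviation of that depth distribution. With weights
#' `w_d = I_d / sum(I)`:
#' \deqn{\mu_1 = \sum_d w_d d, \qquad \mu_2 = \sqrt{\sum_d w_d (d - \mu_1)^2}}
#' `mu1` (center of gravity) measures whether signal balances toward the
#' superficial (low) or deep (high) cortex; `mu2` (conventionally called the
#' variance, reported as the standard deviation) measures profile flatness:
#' it is maximal for a uniform profile and zero for a single-depth
#' concentration. Both are invariant to scaling the profile by any positive
#' constant, so global intensity calibration is irrelevant.
#'
#' @param profiles Numeric vector (one profile) or matrix (profiles in rows),
#'   non-negative intensities.
#' @param negatives How to treat negative intensities: `"error"` (default)
#'   or `"clamp"` to zero. Ratio images can dip below zero at boundaries;
#'   clamping changes the moments, so it must be requested explicitly.
#' @param degenerate How to treat all-zero profiles after clamping:
#'   `"error"` (default) or `"na"`.
#' @return A tibble with one row per profile: `mu1`, `mu2`.
#' @export
profile_moments <- function(profiles, negatives = c("error", "clamp"),
                            degenerate = c("error", "na")) {
  negatives <- match.arg(negatives)
  degenerate <- match.arg(degenerate)
  p <- if (is.matrix(profiles)) profiles else matrix(profiles, nrow = 1L)
  storage.mode(p) <- "double"
  if (anyNA(p)) stop_domain("profiles contain missing values; mask them out first")
  if (any(p < 0)) {
    if (negatives == "error") {
      stop_domain("profiles contain negative intensities (use negatives = \"clamp\" to truncate)")
    }
    p[p < 0] <- 0
  }
  tot <- rowSums(p)
  if (any(tot <= 0)) {
    if (degenerate == "error") stop_domain("all-zero profile: moments are undefined")
  }
  d <- seq_len(ncol(p))
  mu1 <- as.vector(p %*% d) / tot
  mu2 <- sqrt(pmax(as.vector(p %*% d^2) / tot - mu1^2, 0))
  bad <- tot <= 0
  mu1[bad] <- NA_real_
  mu2[bad] <- NA_real_
  tibble::tibble(mu1 = mu1, mu2 = mu2)
}

#' Average depth profiles within parcels
#'
#' Parcel-level profiles are unweighted means over the parcel's masked-in
#' vertices (profiles are averaged first; moments are taken of the average,
#' matching the analysis convention). Excluded parcels and parcels left with
#' no valid vertex are omitted; the latter are reported in the
#' `dropped_parcels` attribute.
#'
#' @param profiles `laminar_profiles` or plain matrix (vertices x depths).
#' @param labels Integer/character vector of per-vertex parcel ids.
#' @param excluded_ids Parcel ids to drop from analysis (e.g. limbic areas).
#' @return Tibble with `parcel_id`, `n_vertices`, and depth columns
#'   `depth_1 .. depth_D`.
#' @export
parcel_mean_profiles <- function(profiles, labels, excluded_ids = NULL) {
  p <- unclass(profiles)
  mask <- attr(profiles, "mask") %||% rep(TRUE, nrow(p))
  if (length(labels) != nrow(p)) {
    stop_contract("`labels` must have one entry per profile row")
  }
  keep <- mask & !(labels %in% excluded_ids)
  if (!any(keep)) stop_contract("no analyzed parcels remain after exclusions")
  pk <- p[keep, , drop = FALSE]
  lk <- labels[keep]
  sums <- rowsum(pk, group = lk)
  counts <- as.vector(rowsum(rep(1, nrow(pk)), group = lk))
  ids <- rownames(sums)
  means <- sums / counts
  all_ids <- setdiff(unique(labels), excluded_ids)
  dropped <- setdiff(as.character(all_ids), ids)
  if (length(dropped)) {
    warning(sprintf("%d parcels had no valid vertices and were dropped: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- tibble::tibble(parcel_id = ids, n_vertices = counts)
  colnames(means) <- paste0("depth_", seq_len(ncol(means)))
  out <- dplyr::bind_cols(out, tibble::as_tibble(means))
  attr(out, "dropped_parcels") <- dropped
  out
}

#' Sliding-window mean profiles along age
#'
#' Averages subject profiles within overlapping age windows (default
#' 1.5-week windows with 50% overlap, i.e. window starts step by 0.75
#' weeks). Windows are half-open `[start, start + width)`; empty windows are
#' dropped.
#'
#' @param profiles Numeric matrix, subjects x depths.
#' @param ages Numeric vector of subject ages (weeks).
#' @param width Window width in weeks (default 1.5).
#' @param overlap Fractional overlap between consecutive windows in \[0, 1)
#'   (default 0.5).
#' @return Tibble with `window_start`, `window_center`, `n_subjects`, and
#'   depth columns.
#' @export
sliding_window_profiles <- function(profiles, ages, width = 1.5, overlap = 0.5) {
  profiles <- as.matrix(profiles)
  if (length(ages) != nrow(profiles)) stop_contract("`ages` must match profile rows")
  if (nrow(profiles) < 1L) stop_contract("at least one subject required")
  if (width <= 0) stop_domain("`width` must be positive")
  if (overlap < 0 || overlap >= 1) stop_domain("`overlap` must lie in [0, 1)")
  step <- width * (1 - overlap)
  starts <- seq(min(ages), max(ages), by = step)
  rows <- lapply(starts, function(s) {
    in_win <- ages >= s & ages < s + width
    if (!any(in_win)) return(NULL)
    m <- colMeans(profiles[in_win, , drop = FALSE])
    c(window_start = s, window_center = s + width / 2,
      n_subjects = sum(in_win), stats::setNames(m, paste0("depth_", seq_along(m))))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tibble::as_tibble(do.call(rbind, rows))
}

#' Moment-sorted profile bins
#'
#' Ranks profiles by one central moment, partitions the ranking into
#' near-equal-count bins preserving rank order, and averages each bin per
#' depth — the standard visualization of how profile shape covaries with a
#' moment across all participants and regions.
#'
#' @param profiles Numeric matrix, profiles x depths.
#' @param which_moment `"mu1"` or `"mu2"`.
#' @param n_bins Number of bins (default 100).
#' @return Tibble with `bin`, `n_profiles`, mean moment value `moment`, and
#'   depth columns.
#' @export
moment_sorted_bins <- function(profiles, which_moment = c("mu1", "mu2"),
                               n_bins = 100L) {
  which_moment <- match.arg(which_moment)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0L) stop_contract("no profiles supplied")
  mom <- profile_moments(profiles)[[which_moment]]
  ord <- order(mom)
  grp <- ceiling(seq_along(ord) * n_bins / length(ord))
  sums <- rowsum(profiles[ord, , drop = FALSE], group = grp)
  counts <- as.vector(table(grp))
  means <- sums / counts
  colnames(means) <- paste0("depth_", seq_len(ncol(means)))
  out <- tibble::tibble(bin = as.integer(rownames(sums)),
                        n_profiles = counts,
                        moment = as.vector(rowsum(mom[ord], group = grp)) / counts)
  dplyr::bind_cols(out, tibble::as_tibble(means))
}
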