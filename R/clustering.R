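#' Taxon abundance profiles as points
#'
#' Each taxon becomes one point whose coordinates are its relative
#' abundances across all samples (taxa are the objects being clustered, as
#' when module structure among families is sought). Optional z-scaling
#' standardizes each taxon profile.
#'
#' @param ft A `feature_table` in relative mode.
#' @param scale Z-scale each profile (row) to mean 0, SD 1?
#' @return Numeric matrix, taxa x samples.
#' @export
taxon_profiles <- function(ft, scale = FALSE) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$mode != "relative") abort("`taxon_profiles()` requires relative mode.")
  pts <- ft$values
  if (scale) {
    sds <- apply(pts, 1L, stats::sd)
    sds[sds == 0] <- 1
    pts <- (pts - rowMeans(pts)) / sds
  }
  pts
}

#' DBSCAN clustering with Euclidean distance
#'
#' Standard density-based clustering: a core point has at least `min_pts`
#' neighbors within `eps` (itself included); clusters are maximal
#' density-connected sets; border points join the first cluster that
#' discovers them, with points processed in fixed row order so runs are
#' deterministic. Unreachable points are noise.
#'
#' @param points Numeric matrix, one row per object (rows must be named).
#' @param eps Neighborhood radius (> 0).
#' @param min_pts Minimum neighborhood size for a core point (>= 1).
#' @return A `microrewire_modules` tibble: `taxon`, `module` (letters in
#'   discovery order, `NA` for noise), `is_core`, plus attributes `eps`,
#'   `min_pts`.
#' @export
dbscan_cluster <- function(points, eps, min_pts = 4L) {
  if (!is.matrix(points)) points <- as.matrix(points)
  assert_scalar_number(eps, "eps", positive = TRUE)
  assert_scalar_number(min_pts, "min_pts", positive = TRUE)
  n <- nrow(points)
  ids <- rownames(points) %||% as.character(seq_len(n))
  dm <- as.matrix(stats::dist(points))
  nbrs <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  label <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    label[i] <- cl
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      if (!core[p]) next
      for (q in nbrs[[p]]) {
        if (is.na(label[q])) label[q] <- cl
        if (!visited[q]) {
          visited[q] <- TRUE
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  out <- tibble(
    taxon = ids,
    module = module_letters(label),
    is_core = core
  )
  attr(out, "eps") <- eps
  attr(out, "min_pts") <- as.integer(min_pts)
  class(out) <- c("microrewire_modules", class(out))
  out
}

module_letters <- function(idx) {
  labs <- c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))
  ifelse(is.na(idx), NA_character_, labs[idx])
}

#' Sorted k-th nearest-neighbor distance profile
#'
#' The classic aid for choosing DBSCAN's `eps`: per-point distance to its
#' k-th nearest neighbor, sorted ascending. A knee in this curve separates
#' within-cluster from between-cluster scales.
#'
#' @param points Numeric matrix, one row per object.
#' @param k Neighbor rank (1 <= k < number of points).
#' @return Sorted numeric vector of k-th-NN distances.
#' @export
knn_distance_profile <- function(points, k) {
  if (!is.matrix(points)) points <- as.matrix(points)
  n <- nrow(points)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k >= n) {
    abort(sprintf("`k` must be in 1..%d.", n - 1L))
  }
  dm <- as.matrix(stats::dist(points))
  # sort(r)[1] is the self-distance 0; the k-th neighbor sits at k + 1
  kth <- apply(dm, 1L, function(r) sort(r)[k + 1L])
  sort(unname(kth))
}

#' Pick eps at the knee of a k-NN distance profile
#'
#' The knee is taken as the dense-to-sparse transition of the sorted
#' profile: the largest relative (log-scale) jump between consecutive
#' values. `eps` is the value on the dense side of that jump, so every
#' point of the dense regime is eps-reachable while the radius stays as
#' small as the dense regime allows. Relative rather than absolute jumps
#' are used because k-NN distances of abundance profiles span orders of
#' magnitude.
#'
#' @param profile Sorted ascending k-th-NN distances
#'   (from [knn_distance_profile()]).
#' @return The distance value at the knee.
#' @export
knee_eps <- function(profile) {
  n <- length(profile)
  if (n < 3L) return(profile[n])
  floor_ <- max(profile) * 1e-12
  lp <- log(pmax(profile, floor_))
  gaps <- diff(lp)
  if (max(gaps) <= 0) return(profile[n])
  profile[which.max(gaps)]
}

#' Cluster taxa into modules from a feature table
#'
#' Convenience wrapper: builds taxon profiles, selects `eps` at the knee of
#' the (min_pts - 1)-NN distance profile when `eps = "auto"`, and runs
#' DBSCAN.
#'
#' @param ft A `feature_table` in relative mode.
#' @param eps Neighborhood radius, or `"auto"` for the knee heuristic.
#' @param min_pts Minimum neighborhood size (default 4).
#' @param scale Z-scale profiles first?
#' @return A `microrewire_modules` tibble (see [dbscan_cluster()]); the
#'   `eps` attribute records the radius actually used.
#' @export
cluster_taxa <- function(ft, eps = "auto", min_pts = 4L, scale = FALSE) {
  pts <- taxon_profiles(ft, scale = scale)
  if (identical(eps, "auto")) {
    k <- max(1L, as.integer(min_pts) - 1L)
    eps <- knee_eps(knn_distance_profile(pts, k))
  }
  dbscan_cluster(pts, eps = eps, min_pts = min_pts)
}
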