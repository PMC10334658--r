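#' Shannon diversity of a relative-abundance vector
#'
#' `H = -sum(p_i * log(p_i))` over nonzero entries, in nats by default
#' (natural log, the usual ecology convention); other bases via `base`.
#'
#' @param p Non-negative vector summing to 1 (within 1e-9).
#' @param base Logarithm base.
#' @return Shannon entropy `H`.
#' @export
shannon <- function(p, base = exp(1)) {
  check_rel_vector(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Gini-Simpson diversity of a relative-abundance vector
#'
#' `D = 1 - sum(p_i^2)` by default (bounded in `[0, 1]`, matching the usual
#' boxplot scale); `inverse = TRUE` returns `1 / sum(p_i^2)` instead.
#'
#' @param p Non-negative vector summing to 1 (within 1e-9).
#' @param inverse Return inverse-Simpson instead of Gini-Simpson?
#' @return Simpson diversity.
#' @export
simpson <- function(p, inverse = FALSE) {
  check_rel_vector(p)
  s <- sum(p^2)
  if (inverse) 1 / s else 1 - s
}

check_rel_vector <- function(p) {
  if (!is.numeric(p) || !length(p)) abort("`p` must be a numeric vector.")
  if (any(p < 0)) abort("`p` must be non-negative.")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`p` must sum to 1 (got %.10g).", sum(p)))
  }
  invisible(p)
}

#' Per-sample alpha diversity table
#'
#' One row per sample with observed richness (taxa with abundance > 0),
#' Shannon entropy (nats) and Gini-Simpson index. Columns are renormalized
#' by their sums before index computation, so tables merged on shared taxa
#' without renormalization are handled consistently.
#'
#' @param ft A `feature_table` in relative mode.
#' @return A `microrewire_alpha` tibble: `sample_id`, `dataset`, `group`,
#'   `observed`, `shannon`, `simpson`.
#' @export
alpha_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$mode != "relative") abort("`alpha_table()` requires relative mode.")
  v <- sweep(ft$values, 2L, colSums(ft$values), "/")
  out <- tibble(
    sample_id = colnames(v),
    observed = unname(colSums(v > 0)),
    shannon = unname(apply(v, 2L, shannon)),
    simpson = unname(apply(v, 2L, simpson))
  )
  if (!is.null(ft$samples)) {
    out <- left_join(ft$samples, out, by = "sample_id")
  }
  class(out) <- c("microrewire_alpha", class(out))
  out
}

#' Group comparison of alpha-diversity indices
#'
#' Wilcoxon rank-sum test (case vs control) for each index in the alpha
#' table.
#'
#' @param records Output of [alpha_table()] with `group` present, or any
#'   data frame with a `group` column plus index columns.
#' @param indices Index columns to compare.
#' @return Tibble: `index`, `statistic` (rank-sum W), `p_value`.
#' @export
compare_alpha <- function(records,
                          indices = c("observed", "shannon", "simpson")) {
  records <- as_tibble(records)
  if (!"group" %in% names(records)) abort("`records` must have a `group` column.")
  x_idx <- records$group == "case"
  if (!any(x_idx) || !all(is.na(records$group) | records$group %in% c("case", "control"))) {
    abort("Groups must be 'case' and 'control'.")
  }
  if (!any(!x_idx)) abort("Both groups must be nonempty.")
  purrr::map_dfr(indices, function(ix) {
    w <- wilcoxon_rank_sum(records[[ix]][x_idx], records[[ix]][!x_idx])
    tibble(index = ix, statistic = w$statistic, p_value = w$p_value)
  })
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `BC_jk = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over taxa, computed on
#' relative abundances.
#'
#' @param ft A `feature_table` in relative mode with at least 2 samples.
#' @return A symmetric `dist`-backed `microrewire_dist` object (entries in
#'   `[0, 1]`, zero diagonal when expanded with `as.matrix()`).
#' @export
bray_curtis <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$mode != "relative") abort("`bray_curtis()` requires relative mode.")
  if (ncol(ft$values) < 2L) abort("Need at least 2 samples.")
  if (any(colSums(ft$values) == 0)) {
    abort(sprintf(
      "All-zero sample(s): %s (Bray-Curtis undefined).",
      paste(colnames(ft$values)[colSums(ft$values) == 0], collapse = ", ")
    ))
  }
  d <- vegan::vegdist(t(ft$values), method = "bray")
  class(d) <- c("microrewire_dist", class(d))
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical MDS: Gower double-centering of squared distances followed by an
#' eigendecomposition. Coordinates use positive-eigenvalue axes only;
#' negative eigenvalues are reported (no Lingoes/Cailliez correction).
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param k Number of axes to return (1..n-1).
#' @return A `microrewire_pcoa`: `points` (samples x axes), `eig` (all
#'   eigenvalues, descending), `prop_explained` (over positive eigenvalues).
#' @export
pcoa <- function(d, k = 2L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n - 1L) {
    abort(sprintf("`k` must be in 1..%d.", n - 1L))
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  pts <- fit$points
  if (ncol(pts) > length(pos)) pts <- pts[, seq_along(pos), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(
    list(points = pts, eig = eig,
         prop_explained = pmax(eig, 0) / sum(pos),
         sample_ids = attr(d, "Labels")),
    class = "microrewire_pcoa"
  )
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA (one-way, the group factor): pseudo-F
#' from total vs within-group sums of squared distances, with a permutation
#' p-value `( #{F_perm >= F_obs} + 1 ) / (nperm + 1)`. Delegates to
#' `vegan::adonis2()` under the given seed.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param nperm Number of label permutations.
#' @param seed Integer seed (required: permutations are stochastic).
#' @return A `microrewire_permanova`: `statistic` (pseudo-F), `r_squared`,
#'   `p_value`, `nperm`, `seed`, `n`.
#' @export
permanova <- function(d, groups, nperm = 999L, seed) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) abort("`groups` must have one label per sample.")
  tab <- table(groups)
  if (length(tab) < 2L) abort("Need at least 2 groups.")
  if (any(tab < 2L)) abort("Every group needs at least 2 samples.")
  if (missing(seed)) abort("`seed` is required for reproducible permutations.")
  assert_scalar_number(nperm, "nperm", positive = TRUE)
  df <- data.frame(group = groups)
  set.seed(seed)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = nperm)
  structure(
    list(statistic = fit$F[1L], r_squared = fit$R2[1L],
         p_value = fit$`Pr(>F)`[1L], nperm = as.integer(nperm),
         seed = as.integer(seed), n = n),
    class = "microrewire_permanova"
  )
}

#' Beta-dispersion (homogeneity of multivariate spread)
#'
#' Per-sample distance to its own group centroid in principal-coordinate
#' space, followed by a one-way ANOVA on those distances (delegates to
#' `vegan::betadisper()` with centroid type).
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param groups Group label per sample.
#' @return A `microrewire_dispersion`: `distances` tibble (`sample_id`,
#'   `group`, `distance`), `statistic` (ANOVA F), `p_value`.
#' @export
beta_dispersion <- function(d, groups) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) abort("`groups` must have one label per sample.")
  if (length(unique(groups)) < 2L) abort("Need at least 2 groups.")
  if (any(table(groups) < 2L)) {
    warn("A group has a single sample; its dispersion contribution is 0.")
  }
  bd <- vegan::betadisper(d, groups, type = "centroid")
  an <- stats::anova(bd)
  structure(
    list(
      distances = tibble(
        sample_id = attr(d, "Labels") %||% as.character(seq_len(n)),
        group = groups,
        distance = unname(bd$distances)
      ),
      statistic = an$`F value`[1L],
      p_value = an$`Pr(>F)`[1L]
    ),
    class = "microrewire_dispersion"
  )
}

#' @export
print.microrewire_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations, n = %d)\n",
    x$statistic, x$r_squared, x$p_value, x$nperm, x$n
  ))
  invisible(x)
}

#' @export
tidy.microrewire_permanova <- function(x, ...) {
  tibble(term = "group", statistic = x$statistic,
         r_squared = x$r_squared, p_value = x$p_value)
}

#' @export
glance.microrewire_permanova <- function(x, ...) {
  tibble(statistic = x$statistic, r_squared = x$r_squared,
         p_value = x$p_value, nperm = x$nperm, n = x$n)
}

#' @export
tidy.microrewire_pcoa <- function(x, ...) {
  as_tibble(x$points) |>
    mutate(sample_id = x$sample_ids, .before = 1L)
}
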