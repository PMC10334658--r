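#' Pearson correlation with a two-sided p-value
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a Student-t with
#' `n - 2` degrees of freedom; `|r| = 1` yields `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3L) abort("Need at least 3 paired observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation is undefined for a constant vector.")
  }
  r <- stats::cor(x, y)
  list(r = r, p_value = cor_p(r, n), n = n)
}

# two-sided p for a sample Pearson r at sample size n
cor_p <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(
    abs(r) >= 1, 0,
    2 * stats::pt(abs(r) * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2,
                  lower.tail = FALSE)
  )
  p
}

#' Per-condition Pearson co-occurrence network
#'
#' Tests every unordered pair of taxa for correlation of relative abundance
#' across the samples of one condition (datasets pooled). Taxa constant
#' within the condition are excluded with a notice. Non-significant
#' correlations are retained in the edge table but carry
#' `significant = FALSE` — downstream they count as absent (the
#' "transformed to zero" convention).
#'
#' @param ft A `feature_table` in relative mode with metadata.
#' @param condition `"case"` or `"control"`.
#' @param alpha Edge significance level.
#' @param adjust `"none"` (raw p, the default) or `"BH"` (one FDR family
#'   over all pairs at this level).
#' @return A `cooccurrence_network`: `edges` tibble (`taxon_a`, `taxon_b`,
#'   `r`, `p_value`, `q_value`, `significant`), `nodes`, `condition`,
#'   `alpha`, `adjust`, `n_samples`, `level`.
#' @export
condition_network <- function(ft, condition = c("case", "control"),
                              alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(ft, "feature_table"))
  condition <- arg_match(condition)
  adjust <- arg_match(adjust)
  if (ft$mode != "relative") abort("`condition_network()` requires relative mode.")
  if (is.null(ft$samples)) abort("Sample metadata must be attached.")
  sel <- ft$samples$group == condition
  n <- sum(sel)
  if (n < 4L) abort(sprintf("Condition '%s' has %d samples; need >= 4.", condition, n))
  if (n < 10L) warn(sprintf("Condition '%s' has only %d samples; correlations will be unstable.", condition, n))
  v <- ft$values[, sel, drop = FALSE]
  const <- apply(v, 1L, function(r) diff(range(r)) == 0)
  if (any(const)) {
    inform(sprintf("Excluding %d condition-constant taxa: %s",
                   sum(const), paste(rownames(v)[const], collapse = ", ")))
    v <- v[!const, , drop = FALSE]
  }
  taxa <- rownames(v)
  if (length(taxa) < 2L) abort("Fewer than 2 non-constant taxa; no pairs to test.")
  R <- stats::cor(t(v))
  idx <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[idx]
  p <- cor_p(r, n)
  q <- bh_adjust(p)
  sig <- if (adjust == "BH") q < alpha else p < alpha
  edges <- tibble(
    taxon_a = taxa[idx[, 1L]],
    taxon_b = taxa[idx[, 2L]],
    r = r, p_value = p, q_value = q, significant = sig
  )
  structure(
    list(edges = edges, nodes = taxa, condition = condition,
         alpha = alpha, adjust = adjust, n_samples = n, level = ft$level),
    class = "cooccurrence_network"
  )
}

#' Differential (rewired) network between two condition networks
#'
#' Compares the significant edge sets of the control (normal) and case
#' (disease) networks:
#' * significant in case only: **gained** interaction;
#' * significant in control only: **lost** interaction;
#' * significant in both with opposite signs of `r`: **changed_direction**.
#' Pairs significant in both with the same sign, or in neither, are not
#' rewired. A sign flip of a non-significant correlation is treated as
#' noise, so changed-direction requires significance in both conditions.
#' Nodes are the taxa with at least one rewired incident edge.
#'
#' @param net_control,net_case `cooccurrence_network`s at the same
#'   taxonomic level.
#' @return A `differential_network`: `edges` tibble (`taxon_a`, `taxon_b`,
#'   `class`, `r_control`, `r_case`), `nodes`, `level`.
#' @export
differential_network <- function(net_control, net_case) {
  stopifnot(inherits(net_control, "cooccurrence_network"),
            inherits(net_case, "cooccurrence_network"))
  if (!identical(net_control$level, net_case$level) &&
      !(is.na(net_control$level) && is.na(net_case$level))) {
    abort(sprintf("Networks are at different levels ('%s' vs '%s').",
                  net_control$level, net_case$level))
  }
  ec <- net_case$edges
  en <- net_control$edges
  kc <- pair_key(ec$taxon_a, ec$taxon_b)
  kn <- pair_key(en$taxon_a, en$taxon_b)
  keys <- union(kc[ec$significant], kn[en$significant])
  mi_c <- match(keys, kc)
  mi_n <- match(keys, kn)
  sig_c <- !is.na(mi_c) & ec$significant[ifelse(is.na(mi_c), 1L, mi_c)]
  sig_n <- !is.na(mi_n) & en$significant[ifelse(is.na(mi_n), 1L, mi_n)]
  r_c <- ifelse(is.na(mi_c), NA_real_, ec$r[ifelse(is.na(mi_c), 1L, mi_c)])
  r_n <- ifelse(is.na(mi_n), NA_real_, en$r[ifelse(is.na(mi_n), 1L, mi_n)])
  class_ <- dplyr::case_when(
    sig_c & !sig_n ~ "gained",
    sig_n & !sig_c ~ "lost",
    sig_c & sig_n & sign(r_c) != sign(r_n) ~ "changed_direction",
    TRUE ~ NA_character_
  )
  keep <- !is.na(class_)
  ab <- do.call(rbind, strsplit(keys[keep], "\r", fixed = TRUE))
  edges <- tibble(
    taxon_a = if (sum(keep)) ab[, 1L] else character(0),
    taxon_b = if (sum(keep)) ab[, 2L] else character(0),
    class = class_[keep],
    r_control = r_n[keep],
    r_case = r_c[keep]
  ) |>
    arrange(.data$taxon_a, .data$taxon_b)
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$taxon_a, edges$taxon_b))),
         level = net_case$level),
    class = "differential_network"
  )
}

#' Per-node rewiring degree
#'
#' Counts of incident rewired edges per taxon, split by class, sorted by
#' total descending with a stable taxon-name tiebreak.
#'
#' @param dnet A `differential_network`.
#' @return Tibble: `taxon`, `total`, `gained`, `lost`, `changed`.
#' @export
rewiring_degree <- function(dnet) {
  stopifnot(inherits(dnet, "differential_network"))
  e <- dnet$edges
  long <- bind_rows(
    tibble(taxon = e$taxon_a, class = e$class),
    tibble(taxon = e$taxon_b, class = e$class)
  )
  long |>
    group_by(.data$taxon) |>
    summarise(
      total = n(),
      gained = sum(.data$class == "gained"),
      lost = sum(.data$class == "lost"),
      changed = sum(.data$class == "changed_direction"),
      .groups = "drop"
    ) |>
    arrange(desc(.data$total), .data$taxon)
}

#' Degree-based hub calls
#'
#' Applies the level-specific degree cutoffs used to flag the most important
#' network nodes: degree >= 4 at the phylum level, degree > 15 at the genus
#' level; the family level has no established cutoff and requires
#' `family_cutoff` (interpreted as degree >= cutoff).
#'
#' @param ctable A centrality table ([centrality_table()]) or any data frame
#'   with `node` and `degree` columns.
#' @param level `"phylum"`, `"family"` or `"genus"`.
#' @param family_cutoff Degree cutoff for the family level.
#' @return Character vector of hub taxa.
#' @export
hub_nodes <- function(ctable, level = c("phylum", "family", "genus"),
                      family_cutoff = NULL) {
  level <- arg_match(level)
  ctable <- as_tibble(ctable)
  if (!all(c("node", "degree") %in% names(ctable))) {
    abort("`ctable` must have `node` and `degree` columns.")
  }
  keep <- switch(level,
    phylum = ctable$degree >= 4,
    genus = ctable$degree > 15,
    family = {
      if (is.null(family_cutoff)) {
        abort("No published family-level cutoff; set `family_cutoff`.")
      }
      ctable$degree >= family_cutoff
    }
  )
  ctable$node[keep]
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence_network> condition: %s | %d taxa, %d/%d significant pairs (alpha = %g, adjust = %s, n = %d)\n",
    x$condition, length(x$nodes), sum(x$edges$significant),
    nrow(x$edges), x$alpha, x$adjust, x$n_samples
  ))
  invisible(x)
}

#' @export
print.differential_network <- function(x, ...) {
  tab <- table(factor(x$edges$class,
                      levels = c("gained", "lost", "changed_direction")))
  cat(sprintf(
    "<differential_network> %d nodes, %d rewired edges (gained %d, lost %d, changed %d)%s\n",
    length(x$nodes), nrow(x$edges), tab[["gained"]], tab[["lost"]],
    tab[["changed_direction"]],
    if (!is.na(x$level)) paste0(" [", x$level, "]") else ""
  ))
  invisible(x)
}

#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @export
tidy.differential_network <- function(x, ...) x$edges

#' @export
glance.differential_network <- function(x, ...) {
  tibble(
    nodes = length(x$nodes),
    edges = nrow(x$edges),
    gained = sum(x$edges$class == "gained"),
    lost = sum(x$edges$class == "lost"),
    changed_direction = sum(x$edges$class == "changed_direction"),
    level = x$level
  )
}

#' Compare a differential network with planted ground truth
#'
#' Precision/recall/F1 of the recovered gained, lost and changed-direction
#' edge sets against a `microrewire_truth`.
#'
#' @param dnet A `differential_network`.
#' @param truth A `microrewire_truth` (from [ground_truth()] or
#'   [simulate_microbiome()]).
#' @return Tibble: `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
edge_recovery <- function(dnet, truth) {
  stopifnot(inherits(dnet, "differential_network"),
            inherits(truth, "microrewire_truth"))
  one <- function(cls, truth_edges) {
    pred <- dnet$edges[dnet$edges$class == cls, ]
    pk <- pair_key(pred$taxon_a, pred$taxon_b)
    tk <- pair_key(truth_edges$taxon_a, truth_edges$taxon_b)
    tp <- length(intersect(pk, tk))
    fp <- length(setdiff(pk, tk))
    fn <- length(setdiff(tk, pk))
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
    tibble(class = cls, tp = tp, fp = fp, fn = fn,
           precision = prec, recall = rec, f1 = f1)
  }
  bind_rows(
    one("gained", truth$gained),
    one("lost", truth$lost),
    one("changed_direction", truth$changed)
  )
}

#' Adjusted Rand index between recovered and planted modules
#'
#' Restricted to the taxa carrying a planted module label; recovered noise
#' is treated as its own class. Delegates to
#' `mclust::adjustedRandIndex()`.
#'
#' @param assignment A `microrewire_modules` tibble (from
#'   [dbscan_cluster()] / [cluster_taxa()]).
#' @param truth A `microrewire_truth` with a `modules` map.
#' @return The adjusted Rand index.
#' @export
module_ari <- function(assignment, truth) {
  stopifnot(inherits(truth, "microrewire_truth"))
  if (is.null(truth$modules)) abort("Ground truth has no planted modules.")
  planted <- names(truth$modules)
  pred <- assignment$module[match(planted, assignment$taxon)]
  pred[is.na(pred)] <- "NOISE"
  mclust::adjustedRandIndex(pred, unname(truth$modules))
}
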