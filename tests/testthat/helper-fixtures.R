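# Shared fixtures and independent reference implementations used as oracles.
# Everything here is deliberately naive: plain loops straight from the
# definitions, sharing no code path with the package.

toy_counts <- function() {
  m <- matrix(c(2, 3, 5,
                4, 0, 6,
                0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus",
                                "Bacteria;Proteobacteria;Gamma;Pseudomonadales;Moraxellaceae;Moraxella",
                                "Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Lactococcus"),
                              c("S1", "S2", "S3")))
  feature_table(m, mode = "counts")
}

toy_meta <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    dataset = "D1",
    group = c("case", "control", "case")
  )
}

# small labelled relative table with metadata, both groups
toy_relative <- function(n_case = 6, n_control = 6, n_taxa = 5, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  m <- matrix(rexp(n_taxa * n) + 0.05, n_taxa, n,
              dimnames = list(sprintf("T%d", seq_len(n_taxa)),
                              sprintf("S%d", seq_len(n))))
  meta <- tibble::tibble(
    sample_id = colnames(m), dataset = "D1",
    group = rep(c("case", "control"), c(n_case, n_control))
  )
  to_relative(attach_metadata(feature_table(m, mode = "counts"), meta))
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# ---- graph oracles ---------------------------------------------------------

random_adjacency <- function(n, p = 0.35) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  A
}

adj_to_edges <- function(A) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  data.frame(from = rownames(A)[idx[, 1]], to = rownames(A)[idx[, 2]])
}

# all-pairs shortest paths, plain Floyd-Warshall
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# number of shortest paths between every pair, by dynamic programming on
# distance levels (independent of Brandes accumulation)
bf_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  diag(S) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, pred])
    }
  }
  S
}

bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  S <- bf_path_counts(A, D)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || S[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  if (n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  stats::setNames(bc, rownames(A))
}

bf_closeness <- function(A) {
  D <- bf_distances(A)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    out[v] <- if (length(d)) length(d) / sum(d) else 0
  }
  stats::setNames(out, rownames(A))
}

bf_clustering <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (i in seq_along(nb)) {
      for (j in seq_along(nb)) {
        if (i < j && A[nb[i], nb[j]] > 0) links <- links + 1
      }
    }
    out[v] <- 2 * links / (k * (k - 1))
  }
  stats::setNames(out, rownames(A))
}

bf_neighborhood_connectivity <- function(A) {
  deg <- rowSums(A > 0)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    out[v] <- if (length(nb)) mean(deg[nb]) else 0
  }
  stats::setNames(out, rownames(A))
}

# ---- DBSCAN reference ------------------------------------------------------

# definition-based reference: clusters are connected components of core
# points under eps-adjacency, ordered by their smallest core index (the
# order a sequential scan discovers them); a non-core point with a core
# neighbor joins the earliest-discovered such component, others are noise.
naive_dbscan <- function(points, eps, min_pts) {
  n <- nrow(points)
  dm <- as.matrix(stats::dist(points))
  core <- vapply(seq_len(n), function(i) sum(dm[i, ] <= eps) >= min_pts,
                 logical(1))
  comp <- rep(NA_integer_, n)
  cores <- which(core)
  seen <- logical(n)
  comps <- list()
  for (c0 in cores) {
    if (seen[c0]) next
    members <- c0
    frontier <- c0
    seen[c0] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        reach <- cores[dm[f, cores] <= eps & !seen[cores]]
        seen[reach] <- TRUE
        nxt <- c(nxt, reach)
      }
      members <- c(members, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  # discovery order == order of smallest core index, which the loop gives
  for (k in seq_along(comps)) comp[comps[[k]]] <- k
  label <- comp
  for (i in seq_len(n)) {
    if (core[i] || !is.na(label[i])) next
    near_comps <- stats::na.omit(unique(comp[cores[dm[i, cores] <= eps]]))
    if (length(near_comps)) label[i] <- min(near_comps)
  }
  label
}

# ---- misc oracles ----------------------------------------------------------

# closed-form BH step-up, straight from the definition
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sided Wilcoxon p by full enumeration of label assignments
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  mean_w <- n1 * length(y) / 2
  lower <- mean(stats <= obs)
  upper <- mean(stats >= obs)
  if (obs > mean_w) min(1, 2 * upper) else if (obs < mean_w) min(1, 2 * lower) else 1
}
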