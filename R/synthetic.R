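#' Specify a synthetic multi-study case-control microbiome experiment
#'
#' The generator is logistic-normal/multinomial: each sample draws a latent
#' Gaussian vector for its condition, squashes it through a softmax into
#' proportions, and draws multinomial counts at a dataset-specific depth.
#' This family lets arbitrary signed pairwise correlation be planted per
#' condition — which is exactly what gained / lost / changed-direction edge
#' ground truth requires — while still producing compositional counts.
#'
#' @param n_taxa Number of taxa.
#' @param datasets Tibble with columns `name`, `n_case`, `n_control`,
#'   `depth_min`, `depth_max` (per-sample sequencing depth is drawn
#'   log-uniformly within the dataset's range).
#' @param mu_case,mu_control Latent log-mean vectors, length `n_taxa`.
#' @param sigma_scale Latent log-SD vector (scalar recycled).
#' @param Sigma_case,Sigma_control Latent correlation matrices: symmetric,
#'   unit diagonal, positive semi-definite (smallest eigenvalue >= -1e-8).
#' @param modules Optional named character vector mapping taxon name to
#'   module id for planted profile modules (taxa absent are unclustered).
#' @param taxa Taxon names; defaults to `Genus01..`.
#' @param seed Master integer seed; per-dataset streams are derived from it
#'   by fixed offsets (`seed + 1009 * dataset_index`).
#'
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_taxa, datasets, mu_case, mu_control,
                           sigma_scale = 1, Sigma_case = NULL,
                           Sigma_control = NULL, modules = NULL,
                           taxa = NULL, seed = 1L) {
  assert_scalar_number(n_taxa, "n_taxa", positive = TRUE)
  datasets <- as_tibble(datasets)
  need <- c("name", "n_case", "n_control", "depth_min", "depth_max")
  miss <- setdiff(need, names(datasets))
  if (length(miss)) {
    abort(sprintf("`datasets` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(datasets$n_case < 0) || any(datasets$n_control < 0)) {
    abort("Group sizes must be >= 0.")
  }
  if (any(datasets$depth_min <= 0) || any(datasets$depth_max < datasets$depth_min)) {
    abort("Depths must satisfy 0 < depth_min <= depth_max.")
  }
  taxa <- taxa %||% sprintf("Genus%02d", seq_len(n_taxa))
  if (length(taxa) != n_taxa || anyDuplicated(taxa)) {
    abort("`taxa` must be `n_taxa` unique names.")
  }
  if (length(mu_case) != n_taxa || length(mu_control) != n_taxa) {
    abort("`mu_case` and `mu_control` must have length `n_taxa`.")
  }
  sigma_scale <- rep_len(sigma_scale, n_taxa)
  if (any(sigma_scale <= 0)) abort("`sigma_scale` must be positive.")
  Sigma_case <- Sigma_case %||% diag(n_taxa)
  Sigma_control <- Sigma_control %||% diag(n_taxa)
  validate_corr(Sigma_case, n_taxa, "Sigma_case")
  validate_corr(Sigma_control, n_taxa, "Sigma_control")
  if (!is.null(modules)) {
    if (is.null(names(modules)) || !all(names(modules) %in% taxa)) {
      abort("`modules` must be named by taxon names present in `taxa`.")
    }
  }
  structure(
    list(n_taxa = as.integer(n_taxa), datasets = datasets,
         mu_case = mu_case, mu_control = mu_control,
         sigma_scale = sigma_scale,
         Sigma_case = Sigma_case, Sigma_control = Sigma_control,
         modules = modules, taxa = taxa, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

validate_corr <- function(S, n, name) {
  if (!is.matrix(S) || nrow(S) != n || ncol(S) != n) {
    abort(sprintf("`%s` must be a %d x %d matrix.", name, n, n))
  }
  if (max(abs(S - t(S))) > 1e-12) abort(sprintf("`%s` must be symmetric.", name))
  if (max(abs(diag(S) - 1)) > 1e-12) abort(sprintf("`%s` must have unit diagonal.", name))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf("`%s` is not positive semi-definite (min eigenvalue %.3g).",
                  name, min(ev)))
  }
  invisible(S)
}

#' Simulate counts and ground truth from a synthetic spec
#'
#' For each sample: `z ~ MVN(mu_group, D S_group D)` with
#' `D = diag(sigma_scale)`, proportions `softmax(z)`, and counts
#' `multinomial(depth, proportions)`. Deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a counts-mode [feature_table()] with metadata
#'   attached, level `"genus"`) and `truth` (a `microrewire_truth`: planted
#'   differential taxa, per-condition signed edge sets, expected
#'   gained/lost/changed-direction pairs, and the module map).
#' @export
simulate_microbiome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  D <- diag(spec$sigma_scale, spec$n_taxa)
  cov_case <- D %*% spec$Sigma_case %*% D
  cov_control <- D %*% spec$Sigma_control %*% D

  blocks <- list()
  metas <- list()
  for (i in seq_len(nrow(spec$datasets))) {
    d <- spec$datasets[i, ]
    set.seed((spec$seed + 1009L * i) %% .Machine$integer.max)
    for (grp in c("case", "control")) {
      n <- if (grp == "case") d$n_case else d$n_control
      if (n == 0) next
      mu <- if (grp == "case") spec$mu_case else spec$mu_control
      cv <- if (grp == "case") cov_case else cov_control
      z <- MASS::mvrnorm(n, mu = mu, Sigma = cv, tol = 1e-6)
      z <- matrix(z, nrow = n)
      p <- exp(z - apply(z, 1L, max))
      p <- p / rowSums(p)
      depth <- round(exp(stats::runif(n, log(d$depth_min), log(d$depth_max))))
      cnt <- vapply(seq_len(n), function(s) {
        stats::rmultinom(1L, size = depth[s], prob = p[s, ])[, 1L]
      }, numeric(spec$n_taxa))
      ids <- sprintf("%s_%s_%03d", d$name, grp, seq_len(n))
      colnames(cnt) <- ids
      rownames(cnt) <- spec$taxa
      blocks[[length(blocks) + 1L]] <- cnt
      metas[[length(metas) + 1L]] <- tibble(
        sample_id = ids, dataset = d$name, group = grp
      )
    }
  }
  if (!length(blocks)) abort("Spec generates no samples.")
  values <- do.call(cbind, blocks)
  taxa <- tibble(taxon = spec$taxa, kingdom = "Bacteria",
                 phylum = NA_character_, class = NA_character_,
                 order = NA_character_, family = NA_character_,
                 genus = spec$taxa)
  taxa <- normalize_lineages(taxa)
  # genus is the informative rank here; keep kingdom+genus assigned
  taxa$phylum <- "SimPhylum"; taxa$class <- "SimClass"
  taxa$order <- "SimOrder"; taxa$family <- "SimFamily"
  taxa$genus <- spec$taxa
  ft <- feature_table(values, taxa = taxa,
                      samples = bind_rows(metas),
                      mode = "counts", level = "genus")
  list(table = ft, truth = ground_truth(spec))
}

#' Extract the planted ground truth of a synthetic spec
#'
#' Edge sets are the nonzero off-diagonal entries of the latent correlation
#' matrices; expected gained edges are those planted in case only, lost in
#' control only, changed-direction planted in both with opposite signs.
#'
#' @param spec A [synthetic_spec()].
#' @return A `microrewire_truth` list: `differential_taxa`, `edges_case`,
#'   `edges_control` (tibbles `taxon_a`, `taxon_b`, `r`), `gained`, `lost`,
#'   `changed`, `modules`.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  edges_of <- function(S) {
    idx <- which(upper.tri(S) & S != 0, arr.ind = TRUE)
    tibble(taxon_a = spec$taxa[idx[, 1L]],
           taxon_b = spec$taxa[idx[, 2L]],
           r = S[idx])
  }
  ec <- edges_of(spec$Sigma_case)
  en <- edges_of(spec$Sigma_control)
  kc <- pair_key(ec$taxon_a, ec$taxon_b)
  kn <- pair_key(en$taxon_a, en$taxon_b)
  gained <- ec[!kc %in% kn, c("taxon_a", "taxon_b")]
  lost <- en[!kn %in% kc, c("taxon_a", "taxon_b")]
  both <- intersect(kc, kn)
  sign_flip <- both[sign(ec$r[match(both, kc)]) != sign(en$r[match(both, kn)])]
  changed <- ec[match(sign_flip, kc), c("taxon_a", "taxon_b")]
  structure(
    list(
      differential_taxa = spec$taxa[spec$mu_case != spec$mu_control],
      edges_case = ec, edges_control = en,
      gained = gained, lost = lost, changed = changed,
      modules = spec$modules
    ),
    class = "microrewire_truth"
  )
}

#' Build a study-scale synthetic spec
#'
#' Emulates the integrated four-cohort design: case/control sizes
#' 245/231, 50/207, 27/26 and 25/24 (totals 347/488 at `scale = 1`), scaled
#' per dataset by `scale` and rounded. Defaults plant 64 genera; four
#' four-taxon profile modules at low-abundance mean levels with log-SD 0.3
#' and within-module latent correlation 0.98 in both conditions (tight
#' Euclidean profile clusters whose pairs form stable, never-rewired
#' edges); 10 case-only and 10 control-only
#' latent pairs at |r| = 0.8 with alternating signs; 2 changed-direction
#' pairs (+0.8 in case, -0.8 in control); and 8 differential taxa depleted
#' in the case group by a latent log-mean shift of 1.0. Latent means sit in
#' a narrow band (SD 0.5) so that no taxon dominates the composition and
#' softmax closure induces only weak spurious correlation. Per-dataset
#' depths are log-uniform around 5e4.
#'
#' @param scale Group-size multiplier in (0, 1].
#' @param seed Master seed (also drives the latent mean draw).
#' @param n_taxa Number of genera.
#' @param n_diff Number of planted differential taxa.
#' @param diff_shift Latent log-mean shift for differential taxa.
#' @param n_condition_edges Planted pairs unique to each condition.
#' @param n_changed Planted pairs with opposite signs across conditions.
#' @param planted_r Magnitude of planted latent correlations.
#' @param module_sizes Sizes of the planted modules.
#' @return A [synthetic_spec()].
#' @export
make_paper_like_spec <- function(scale = 1, seed = 1L, n_taxa = 64L,
                                 n_diff = 8L, diff_shift = 1.0,
                                 n_condition_edges = 10L, n_changed = 2L,
                                 planted_r = 0.8,
                                 module_sizes = c(4L, 4L, 4L, 4L)) {
  assert_scalar_number(scale, "scale", positive = TRUE)
  if (scale > 1) abort("`scale` must be in (0, 1].")
  base <- tibble(
    name = paste0("D", 1:4),
    n_case = c(245L, 50L, 27L, 25L),
    n_control = c(231L, 207L, 26L, 24L),
    depth_min = c(3e4, 2e4, 4e4, 2.5e4),
    depth_max = c(6e4, 5e4, 8e4, 1e5)
  )
  base$n_case <- as.integer(round(scale * base$n_case))
  base$n_control <- as.integer(round(scale * base$n_control))
  if (any(base$n_case < 1L) || any(base$n_control < 1L)) {
    abort("`scale` yields an empty group in at least one dataset.")
  }

  n_mod_taxa <- sum(module_sizes)
  need <- n_mod_taxa + 2L * (2L * n_condition_edges) + 2L * n_changed
  if (need > n_taxa) {
    abort(sprintf("Need at least %d taxa for the requested plant; got %d.",
                  need, n_taxa))
  }
  taxa <- sprintf("Genus%02d", seq_len(n_taxa))

  set.seed(seed)
  mu <- stats::rnorm(n_taxa, 0, 0.5)
  # moderate log-SD keeps share distributions light-tailed enough for the
  # Pearson edge test's t reference to stay calibrated
  sigma <- rep(0.5, n_taxa)

  # planted modules: a shared low-abundance latent mean, reduced log-SD and
  # near-unit within-module correlation make mates' profiles almost
  # coincident in Euclidean space. The within-module correlation must be
  # planted in BOTH conditions (module pairs become stable, same-sign
  # edges, so they never enter the rewired classes), and module abundance
  # levels are kept low so block co-movement has a negligible softmax
  # footprint on the other taxa.
  mod_ids <- LETTERS[seq_along(module_sizes)]
  mod_levels <- seq(-0.5, -2, length.out = length(module_sizes))
  modules <- character(0)
  pos <- 1L
  Sc <- diag(n_taxa); Sn <- diag(n_taxa)
  for (m in seq_along(module_sizes)) {
    members <- pos:(pos + module_sizes[m] - 1L)
    mu[members] <- mod_levels[m]
    sigma[members] <- 0.3
    Sc[members, members] <- 0.98
    Sn[members, members] <- 0.98
    diag(Sc)[members] <- 1; diag(Sn)[members] <- 1
    modules <- c(modules, stats::setNames(rep(mod_ids[m], length(members)),
                                          taxa[members]))
    pos <- pos + module_sizes[m]
  }

  plant_pairs <- function(S, k, start) {
    signs <- rep_len(c(1, -1), k)
    for (j in seq_len(k)) {
      a <- start + 2L * (j - 1L); b <- a + 1L
      S[a, b] <- S[b, a] <- signs[j] * planted_r
    }
    S
  }
  case_start <- n_mod_taxa + 1L
  ctrl_start <- case_start + 2L * n_condition_edges
  chg_start <- ctrl_start + 2L * n_condition_edges
  Sc <- plant_pairs(Sc, n_condition_edges, case_start)
  Sn <- plant_pairs(Sn, n_condition_edges, ctrl_start)
  for (j in seq_len(n_changed)) {
    a <- chg_start + 2L * (j - 1L); b <- a + 1L
    Sc[a, b] <- Sc[b, a] <- planted_r
    Sn[a, b] <- Sn[b, a] <- -planted_r
  }

  mu_control <- mu
  mu_case <- mu
  if (n_diff > 0L) {
    # tumor-depleted taxa: a downward case shift mirrors the reduced
    # diversity of the disease state and keeps shifted taxa from acquiring
    # large compositional footprints in either condition
    diff_idx <- case_start:(case_start + n_diff - 1L)
    mu_case[diff_idx] <- mu_case[diff_idx] - diff_shift
  }

  synthetic_spec(
    n_taxa = n_taxa, datasets = base,
    mu_case = mu_case, mu_control = mu_control,
    sigma_scale = sigma, Sigma_case = Sc, Sigma_control = Sn,
    modules = if (length(modules)) modules else NULL,
    taxa = taxa, seed = seed
  )
}

#' Write ground truth to JSON
#'
#' @param truth A `microrewire_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "microrewire_truth"))
  out <- list(
    differential_taxa = truth$differential_taxa,
    edges_case = truth$edges_case,
    edges_control = truth$edges_control,
    gained = truth$gained, lost = truth$lost, changed = truth$changed,
    modules = as.list(truth$modules %||% stats::setNames(list(), character(0)))
  )
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
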