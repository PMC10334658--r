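#' Assemble and validate a pipeline configuration
#'
#' The configuration is a flat list (or a YAML file of one) naming either
#' input tables plus metadata or a synthetic design, the taxonomic levels to
#' analyze, and the tuning knobs of every stage. Unspecified keys take
#' documented defaults.
#'
#' @param ... Configuration keys (see Details), or a single named list.
#' @param path Optional YAML file to read keys from; explicit arguments
#'   override file values.
#'
#' @details Recognized keys:
#' * `tables`, `metadata`: character vectors of feature-table TSV paths and
#'   one metadata TSV (columns sample_id, dataset, group). Mutually
#'   exclusive with `synthetic`.
#' * `synthetic`: list with `scale` and optional generator overrides, run
#'   through [make_paper_like_spec()].
#' * `levels`: ranks to analyze (default `"genus"`).
#' * `alpha`: edge significance level (default 0.05); `adjust`: `"none"` or
#'   `"BH"` (default `"none"`).
#' * `permanova_nperm` (default 999), `seed` (required).
#' * `dbscan_eps` (`"auto"` or number), `dbscan_min_pts` (default 4),
#'   `dbscan_scale` (default FALSE).
#' * `hub_family_cutoff`: optional family-level degree cutoff.
#' * `renormalize`, `drop_unclassified` (default FALSE).
#' * `out_dir`: output directory (required for [run_pipeline()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
    cfg <- yaml::read_yaml(path)
  }
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  cfg[names(dots)] <- dots
  defaults <- list(
    levels = "genus", alpha = 0.05, adjust = "none",
    permanova_nperm = 999L, dbscan_eps = "auto", dbscan_min_pts = 4L,
    dbscan_scale = FALSE, hub_family_cutoff = NULL,
    renormalize = FALSE, drop_unclassified = FALSE
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  }
  has_files <- !is.null(cfg$tables)
  has_synth <- !is.null(cfg$synthetic)
  if (has_files == has_synth) {
    abort("Exactly one of `tables` or `synthetic` must be given.")
  }
  if (has_files) {
    if (is.null(cfg$metadata)) abort("`metadata` path is required with `tables`.")
    for (p in c(cfg$tables, cfg$metadata)) {
      if (!file.exists(p)) abort(sprintf("Input path does not exist: %s", p))
    }
  }
  if (is.null(cfg$seed)) abort("`seed` is required (stochastic stages are seeded).")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates merge, diversity, differential abundance, module clustering,
#' per-condition networks, differential-network classification, centralities
#' and exports for each requested level, writing TSV/SIF/JSON artifacts into
#' `out_dir` and returning a run manifest. Identical configuration and seed
#' produce byte-identical outputs.
#'
#' @param cfg A [pipeline_config()] (or a list/YAML path coercible to one).
#' @param force Overwrite existing outputs?
#' @return The manifest (also written as `manifest.json`): per-level counts
#'   of taxa, significant differential taxa, modules, significant edges per
#'   condition, and rewired edges per class.
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  if (is.null(cfg$out_dir)) abort("`out_dir` is required.")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  truth <- NULL
  base_tables <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      args <- cfg$synthetic
      args$seed <- args$seed %||% cfg$seed
      spec <- do.call(make_paper_like_spec, args)
      sim <- simulate_microbiome(spec)
      truth <- sim$truth
      list(sim$table)
    } else {
      meta <- readr::read_tsv(cfg$metadata, show_col_types = FALSE, progress = FALSE)
      lapply(cfg$tables, function(p) {
        attach_metadata(read_feature_table(p), meta)
      })
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("microrewire")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    levels = list()
  )
  if (!is.null(cfg$tables)) {
    manifest$input_digests <- as.list(tools::md5sum(c(cfg$tables, cfg$metadata)))
  }

  for (level in cfg$levels) {
    lv <- stage(paste0("merge[", level, "]"), {
      rel <- lapply(base_tables, function(t) {
        to_relative(collapse_taxa(t, level,
                                  drop_unclassified = isTRUE(cfg$drop_unclassified)))
      })
      merge_shared(rel, level, renormalize = isTRUE(cfg$renormalize))
    })
    inform(sprintf("[%s] %d shared taxa, %d samples", level,
                   nrow(lv$values), ncol(lv$values)))

    out <- function(name) file.path(cfg$out_dir, sprintf("%s_%s.tsv", name, level))
    check_clobber <- function(p) {
      if (file.exists(p) && !force) {
        abort(sprintf("Output exists (use force = TRUE): %s", p))
      }
      p
    }

    alpha <- stage("alpha_diversity", alpha_table(lv))
    alpha_tests <- stage("alpha_tests", compare_alpha(alpha))
    readr::write_tsv(alpha, check_clobber(out("alpha")), progress = FALSE)

    d <- stage("bray_curtis", bray_curtis(lv))
    ord <- stage("pcoa", pcoa(d, k = 2L))
    perm <- stage("permanova",
                  permanova(d, lv$samples$group,
                            nperm = cfg$permanova_nperm, seed = cfg$seed))
    disp <- stage("beta_dispersion", beta_dispersion(d, lv$samples$group))
    readr::write_tsv(tidy(ord), check_clobber(out("pcoa")), progress = FALSE)
    stats_tbl <- bind_rows(
      alpha_tests |> mutate(test = paste0("wilcoxon_", .data$index)) |>
        select("test", "statistic", "p_value"),
      tibble(test = "permanova", statistic = perm$statistic,
             p_value = perm$p_value),
      tibble(test = "beta_dispersion_anova", statistic = disp$statistic,
             p_value = disp$p_value)
    )
    readr::write_tsv(stats_tbl, check_clobber(out("stats")), progress = FALSE)

    da <- stage("differential_abundance", diff_abundance_table(lv, level))
    readr::write_tsv(da, check_clobber(out("diffabund")), progress = FALSE)

    mods <- stage("clustering",
                  cluster_taxa(lv, eps = cfg$dbscan_eps,
                               min_pts = cfg$dbscan_min_pts,
                               scale = isTRUE(cfg$dbscan_scale)))
    mods_out <- mods |>
      mutate(module = ifelse(is.na(.data$module), "NOISE", .data$module))
    readr::write_tsv(mods_out, check_clobber(out("modules")), progress = FALSE)

    net_case <- stage("network_case",
                      condition_network(lv, "case", alpha = cfg$alpha,
                                        adjust = cfg$adjust))
    net_control <- stage("network_control",
                         condition_network(lv, "control", alpha = cfg$alpha,
                                           adjust = cfg$adjust))
    readr::write_tsv(net_case$edges, check_clobber(out("edges_case")), progress = FALSE)
    readr::write_tsv(net_control$edges, check_clobber(out("edges_control")),
                     progress = FALSE)
    dnet <- stage("differential_network",
                  differential_network(net_control, net_case))
    inform(sprintf(
      "[%s] case edges %d, control edges %d, rewired %d (%d nodes)",
      level, sum(net_case$edges$significant),
      sum(net_control$edges$significant), nrow(dnet$edges), length(dnet$nodes)
    ))

    counts <- glance(dnet)
    lvl_manifest <- list(
      taxa = nrow(lv$values), samples = ncol(lv$values),
      significant_taxa = sum(da$significant),
      modules = length(unique(stats::na.omit(mods$module))),
      edges_case = sum(net_case$edges$significant),
      edges_control = sum(net_control$edges$significant),
      rewired_edges = counts$edges, rewired_nodes = counts$nodes,
      gained = counts$gained, lost = counts$lost,
      changed_direction = counts$changed_direction,
      dbscan_eps = attr(mods, "eps")
    )
    if (nrow(dnet$edges)) {
      ct <- stage("centrality", centrality_table(dnet))
      readr::write_tsv(ct, check_clobber(out("centrality")), progress = FALSE)
      rd <- rewiring_degree(dnet)
      readr::write_tsv(rd, check_clobber(out("rewiring_degree")), progress = FALSE)
      stage("export", export_network(
        dnet, ct,
        sif = file.path(cfg$out_dir, sprintf("network_%s.sif", level)),
        edge_attr = out("edge_attributes"),
        node_attr = out("node_attributes"),
        force = force
      ))
      if (level %in% c("phylum", "genus") ||
          (level == "family" && !is.null(cfg$hub_family_cutoff))) {
        lvl_manifest$hubs <- hub_nodes(ct, level,
                                       family_cutoff = cfg$hub_family_cutoff)
      }
    }
    manifest$levels[[level]] <- lvl_manifest
  }

  if (!is.null(truth)) {
    # store the basename only: the manifest must not embed the output path
    manifest$ground_truth_file <- "truth.json"
    write_truth(truth, file.path(cfg$out_dir, "truth.json"))
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Export a differential network for Cytoscape
#'
#' Writes a SIF edge file (`A pp B` lines), an edge-attribute TSV carrying
#' the rewiring class and per-condition correlations, and a node-attribute
#' TSV with the centrality table, all in stable sorted order.
#'
#' @param dnet A `differential_network`.
#' @param ctable Its [centrality_table()].
#' @param sif,edge_attr,node_attr Output paths.
#' @param force Overwrite existing files?
#' @return Invisible named vector of the written paths.
#' @export
export_network <- function(dnet, ctable, sif, edge_attr, node_attr,
                           force = FALSE) {
  stopifnot(inherits(dnet, "differential_network"))
  if (!nrow(dnet$edges)) abort("Cannot export an empty network.")
  for (p in c(sif, edge_attr, node_attr)) {
    if (file.exists(p) && !force) {
      abort(sprintf("Output exists (use force = TRUE): %s", p))
    }
  }
  e <- arrange(dnet$edges, .data$taxon_a, .data$taxon_b)
  writeLines(sprintf("%s pp %s", e$taxon_a, e$taxon_b), sif)
  readr::write_tsv(e, edge_attr, progress = FALSE)
  readr::write_tsv(as_tibble(ctable), node_attr, progress = FALSE)
  invisible(c(sif = sif, edge_attr = edge_attr, node_attr = node_attr))
}

#' Read a SIF edge file back into an edge tibble
#'
#' @param path SIF file with `nodeA relation nodeB` lines.
#' @return Tibble: `taxon_a`, `relation`, `taxon_b`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  parts <- strsplit(readLines(path), " ", fixed = TRUE)
  tibble(
    taxon_a = vapply(parts, `[[`, character(1), 1L),
    relation = vapply(parts, `[[`, character(1), 2L),
    taxon_b = vapply(parts, `[[`, character(1), 3L)
  )
}
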