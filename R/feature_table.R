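#' Construct a taxon-by-sample feature table
#'
#' A `feature_table` is the pipeline's universal currency: a non-negative
#' taxa x samples abundance matrix together with per-taxon taxonomy lineages
#' and per-sample metadata (`dataset`, `group`). Values are either raw
#' `counts` or per-sample `relative` frequencies (each sample column summing
#' to 1).
#'
#' @param values Numeric matrix, taxa in rows, samples in columns. Row names
#'   are taxon labels, column names are sample ids.
#' @param taxa Optional tibble of per-taxon lineages with a `taxon` column and
#'   any of the rank columns `kingdom`, `phylum`, `class`, `order`, `family`,
#'   `genus`. If omitted, lineages are parsed from the row names when they
#'   look like semicolon-separated lineage strings (Greengenes-style
#'   `k__...; p__...` prefixes are understood).
#' @param samples Optional tibble of sample metadata with columns
#'   `sample_id`, `dataset`, `group` (`group` in `"case"`/`"control"`).
#'   May be attached later with [attach_metadata()].
#' @param mode `"counts"` or `"relative"`.
#' @param level Taxonomic rank the rows represent, if known (set by
#'   [collapse_taxa()]).
#'
#' @return A `feature_table` object.
#' @seealso [read_feature_table()], [collapse_taxa()], [to_relative()],
#'   [merge_shared()]
#' @export
feature_table <- function(values, taxa = NULL, samples = NULL,
                          mode = c("counts", "relative"), level = NA_character_) {
  mode <- arg_match(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (taxa x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have taxon row names and sample column names.")
  }
  dup_t <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_t)) {
    abort(sprintf("Duplicate taxon label(s): %s", paste(dup_t, collapse = ", ")))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    abort(sprintf("Duplicate sample id(s): %s", paste(dup_s, collapse = ", ")))
  }
  if (anyNA(values)) abort("`values` must not contain missing cells.")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "Negative abundance at taxon '%s', sample '%s'.",
      rownames(values)[bad[[1L]]], colnames(values)[bad[[2L]]]
    ))
  }
  if (mode == "relative") {
    cs <- colSums(values)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off)) {
      abort(sprintf(
        "Relative-mode columns must sum to 1; sample '%s' sums to %.6g.",
        colnames(values)[off[[1L]]], cs[off[[1L]]]
      ))
    }
  }
  taxa <- build_taxa_tibble(rownames(values), taxa)
  if (!is.null(samples)) {
    samples <- validate_sample_meta(samples, colnames(values))
  }
  structure(
    list(values = values, taxa = taxa, samples = samples,
         mode = mode, level = level),
    class = "feature_table"
  )
}

build_taxa_tibble <- function(labels, taxa) {
  if (is.null(taxa)) {
    return(parse_lineage(labels))
  }
  taxa <- as_tibble(taxa)
  if (!"taxon" %in% names(taxa)) abort("`taxa` must have a `taxon` column.")
  if (!setequal(taxa$taxon, labels) || nrow(taxa) != length(labels)) {
    abort("`taxa$taxon` must match the value matrix row names exactly.")
  }
  taxa <- taxa[match(labels, taxa$taxon), , drop = FALSE]
  for (r in tax_ranks()) {
    if (!r %in% names(taxa)) taxa[[r]] <- NA_character_
  }
  normalize_lineages(taxa[, c("taxon", tax_ranks())])
}

#' Parse taxonomy lineage strings into rank columns
#'
#' Understands plain semicolon-separated lineages (`Bacteria;Firmicutes;...`)
#' and Greengenes-style prefixed ones (`k__Bacteria; p__Firmicutes; ...`).
#' Labels without a semicolon carry no lineage (all ranks unassigned).
#'
#' @param labels Character vector of taxon labels.
#' @return Tibble with columns `taxon` plus the six ranks kingdom..genus.
#' @export
parse_lineage <- function(labels) {
  ranks <- tax_ranks()
  parts <- strsplit(labels, ";", fixed = TRUE)
  mat <- matrix(NA_character_, length(labels), length(ranks),
                dimnames = list(NULL, ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) < 2L && !grepl(";", labels[[i]], fixed = TRUE)) next
    p <- sub("^[kpcofgs]__", "", p)
    p <- p[seq_len(min(length(p), length(ranks)))]
    p[p == ""] <- NA_character_
    mat[i, seq_along(p)] <- p
  }
  out <- as_tibble(mat)
  out <- tibble(taxon = labels, !!!out)
  normalize_lineages(out)
}

# enforce: once a rank is unassigned, all deeper ranks are unassigned
normalize_lineages <- function(taxa) {
  ranks <- tax_ranks()
  m <- as.matrix(taxa[, ranks])
  m[!is.na(m) & m == ""] <- NA_character_
  for (j in seq_along(ranks)[-1]) {
    m[is.na(m[, j - 1L]), j] <- NA_character_
  }
  taxa[, ranks] <- as_tibble(m)
  taxa
}

validate_sample_meta <- function(meta, sample_ids) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "dataset", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(sprintf("Metadata is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) {
    abort(sprintf("Metadata lists sample(s) more than once: %s",
                  paste(dup, collapse = ", ")))
  }
  absent <- setdiff(sample_ids, meta$sample_id)
  if (length(absent)) {
    abort(sprintf("Sample(s) missing from metadata: %s",
                  paste(absent, collapse = ", ")))
  }
  meta <- meta[match(sample_ids, meta$sample_id), need]
  bad <- setdiff(unique(meta$group), c("case", "control"))
  if (length(bad)) {
    abort(sprintf(
      "Unknown group label(s): %s (allowed: case, control).",
      paste(bad, collapse = ", ")
    ))
  }
  meta$dataset <- as.character(meta$dataset)
  meta
}

#' Read a feature table from TSV or BIOM-JSON
#'
#' The TSV dialect is the canonical interchange format: first column taxon
#' labels (optionally full lineage strings), header row sample ids,
#' tab-separated numeric cells. BIOM (JSON flavor) is read through the
#' biomformat package when available.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @return A `feature_table` in counts mode, input ordering preserved.
#' @export
read_feature_table <- function(path, format = c("tsv", "biom")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "biom") {
    return(read_feature_table_biom(path))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    abort(sprintf("Duplicate sample id(s) in header: %s",
                  paste(dup_s, collapse = ", ")))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        name_repair = "minimal", progress = FALSE)
  labels <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    abort(sprintf(
      "Invalid cell value '%s' at row %d (taxon '%s'), column %d (sample '%s').",
      raw[i, j], i, labels[i], j, sample_ids[j]
    ))
  }
  dimnames(num) <- list(labels, sample_ids)
  feature_table(num, mode = "counts")
}

read_feature_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("Reading BIOM files requires the 'biomformat' package.")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  storage.mode(m) <- "double"
  obs <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  taxa <- NULL
  if (!is.null(obs) && is.data.frame(obs) && ncol(obs) >= 1L) {
    lin <- apply(obs, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
    taxa <- parse_lineage(unname(lin))
    taxa$taxon <- rownames(m)
  }
  feature_table(m, taxa = taxa, mode = "counts")
}

#' Attach sample metadata to a feature table
#'
#' @param ft A `feature_table`.
#' @param meta Data frame with columns `sample_id`, `dataset`, `group`
#'   (`group` must be `"case"` or `"control"`); every sample in `ft` must
#'   appear exactly once.
#' @return The feature table with metadata bound, rows of `meta` reordered to
#'   the sample order of `ft`.
#' @export
attach_metadata <- function(ft, meta) {
  stopifnot(inherits(ft, "feature_table"))
  ft$samples <- validate_sample_meta(meta, colnames(ft$values))
  ft
}

#' Collapse a feature table to a taxonomic rank
#'
#' Sums counts of all taxa sharing the same lineage at `level`. Taxa
#' unassigned at `level` are pooled under a single `"unclassified"` label so
#' per-sample totals are conserved; set `drop_unclassified = TRUE` to exclude
#' them instead. Labels duplicated across different parent lineages are
#' disambiguated with the full lineage prefix.
#'
#' @param ft A `feature_table` in counts mode whose taxa carry lineages.
#' @param level One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param drop_unclassified Drop the pooled unclassified row?
#' @return A `feature_table` in counts mode at `level`.
#' @export
collapse_taxa <- function(ft, level, drop_unclassified = FALSE) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$mode != "counts") abort("`collapse_taxa()` requires a counts-mode table.")
  ranks <- tax_ranks()
  if (!is.character(level) || length(level) != 1L || !level %in% ranks) {
    abort(sprintf("`level` must be one of: %s", paste(ranks, collapse = ", ")))
  }
  idx <- match(level, ranks)
  up <- ranks[seq_len(idx)]
  lin <- ft$taxa
  label <- lin[[level]]
  unassigned <- is.na(label)
  key <- ifelse(
    unassigned,
    "\runclassified",
    apply(as.matrix(lin[, up, drop = FALSE]), 1L, paste, collapse = ";")
  )
  first <- !duplicated(key)
  ord_keys <- key[first]
  vals <- rowsum(ft$values, group = key, reorder = FALSE)
  vals <- vals[match(ord_keys, rownames(vals)), , drop = FALSE]

  out_label <- ifelse(is.na(label[first]), "unclassified", label[first])
  # same level name under different parents -> disambiguate with full prefix
  dup <- out_label %in% out_label[duplicated(out_label)]
  out_label[dup] <- gsub("^\r", "", ord_keys[dup])
  rownames(vals) <- out_label

  new_taxa <- lin[first, c("taxon", up), drop = FALSE]
  new_taxa$taxon <- out_label
  for (r in setdiff(ranks, up)) new_taxa[[r]] <- NA_character_
  new_taxa[[level]][is.na(new_taxa[[level]])] <- "unclassified"
  new_taxa <- new_taxa[, c("taxon", ranks)]

  if (drop_unclassified) {
    keep <- out_label != "unclassified"
    vals <- vals[keep, , drop = FALSE]
    new_taxa <- new_taxa[keep, , drop = FALSE]
  }
  out <- feature_table(vals, taxa = new_taxa, samples = ft$samples,
                       mode = "counts", level = level)
  out
}

#' Convert counts to per-sample relative frequencies
#'
#' @param ft A `feature_table` in counts mode with no all-zero sample.
#' @return The table in relative mode; each column sums to 1.
#' @export
to_relative <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$mode != "counts") {
    abort("`to_relative()` expects a counts-mode table (already relative).")
  }
  cs <- colSums(ft$values)
  zero <- which(cs == 0)
  if (length(zero)) {
    abort(sprintf("All-zero sample(s): %s",
                  paste(colnames(ft$values)[zero], collapse = ", ")))
  }
  ft$values <- sweep(ft$values, 2L, cs, "/")
  ft$mode <- "relative"
  ft
}

#' Merge multiple relative-frequency tables on their shared taxa
#'
#' Mirrors the multi-study integration step: tables collapsed to the same
#' rank are restricted to the intersection of their taxon sets and their
#' samples concatenated. By default values are NOT renormalized after the
#' restriction, so each sample keeps its original proportions; pass
#' `renormalize = TRUE` to rescale columns to sum to 1.
#'
#' @param tables List of `feature_table`s in relative mode, all at `level`.
#' @param level Taxonomic rank the tables are collapsed to.
#' @param renormalize Rescale each sample over the shared taxa?
#' @return A merged `feature_table` in relative mode (`renormalize = FALSE`
#'   leaves column sums below 1; the object then carries
#'   `attr(, "renormalized") = FALSE`).
#' @export
merge_shared <- function(tables, level, renormalize = FALSE) {
  if (!is.list(tables) || !length(tables) ||
      !all(vapply(tables, inherits, logical(1), "feature_table"))) {
    abort("`tables` must be a non-empty list of feature_table objects.")
  }
  for (t in tables) {
    if (t$mode != "relative") abort("All tables must be in relative mode.")
    if (is.na(t$level) || t$level != level) {
      abort(sprintf("All tables must be collapsed to level '%s'.", level))
    }
  }
  all_ids <- unlist(lapply(tables, function(t) colnames(t$values)))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup)) {
    abort(sprintf("Colliding sample id(s) across tables: %s",
                  paste(dup, collapse = ", ")))
  }
  shared <- Reduce(intersect, lapply(tables, function(t) rownames(t$values)))
  if (!length(shared)) abort("No taxa are shared by all tables.")
  vals <- do.call(cbind, lapply(tables, function(t) {
    t$values[shared, , drop = FALSE]
  }))
  metas <- lapply(tables, function(t) t$samples)
  samples <- if (all(!vapply(metas, is.null, logical(1)))) bind_rows(metas) else NULL
  taxa <- tables[[1L]]$taxa
  taxa <- taxa[match(shared, taxa$taxon), , drop = FALSE]
  if (renormalize) {
    vals <- sweep(vals, 2L, colSums(vals), "/")
    out <- feature_table(vals, taxa = taxa, samples = samples,
                         mode = "relative", level = level)
  } else {
    # column sums < 1 are expected here: proportions are kept as measured,
    # so build unchecked and flag relative mode afterwards
    out <- feature_table(vals, taxa = taxa, samples = samples,
                         mode = "counts", level = level)
    out$mode <- "relative"
  }
  attr(out, "renormalized") <- renormalize
  out
}

#' Write a feature table (and its metadata) to TSV
#'
#' @param ft A `feature_table`.
#' @param path Output TSV path for the abundance matrix.
#' @param meta_path Optional sidecar TSV path for the sample metadata.
#' @return `ft`, invisibly.
#' @export
write_feature_table <- function(ft, path, meta_path = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  df <- tibble(taxon = rownames(ft$values)) |>
    dplyr::bind_cols(as_tibble(ft$values, .name_repair = "minimal"))
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(meta_path)) {
    if (is.null(ft$samples)) abort("No sample metadata to write.")
    readr::write_tsv(ft$samples, meta_path, progress = FALSE)
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d taxa x %d samples [%s mode%s]\n",
    nrow(x$values), ncol(x$values), x$mode,
    if (!is.na(x$level)) paste0(", level: ", x$level) else ""
  ))
  if (!is.null(x$samples)) {
    tab <- table(x$samples$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat("  datasets:", paste(unique(x$samples$dataset), collapse = ", "), "\n")
  } else {
    cat("  (no sample metadata attached)\n")
  }
  invisible(x)
}

#' Tidy a feature table into long form
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `sample_id`, `abundance` plus
#'   `dataset`/`group` when metadata is attached.
#' @export
tidy.feature_table <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "sample_id", values_to = "abundance")
  if (!is.null(x$samples)) {
    out <- left_join(out, x$samples, by = "sample_id")
  }
  out
}

#' Extract the abundance matrix of a feature table
#'
#' @param ft A `feature_table`.
#' @return The numeric taxa x samples matrix.
#' @export
ft_values <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  ft$values
}

#' Extract the sample metadata of a feature table
#'
#' @param ft A `feature_table`.
#' @return A tibble with `sample_id`, `dataset`, `group`, or `NULL`.
#' @export
ft_samples <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  ft$samples
}
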