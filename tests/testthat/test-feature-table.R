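test_that("TSV round-trip preserves shape, order and values", {
  path <- write_tsv_fixture(c(
    "taxon\tS1\tS2",
    "A\t1\t2",
    "B\t0\t3",
    "C\t4\t0"
  ))
  ft <- read_feature_table(path)
  expect_equal(dim(ft$values), c(3L, 2L))
  expect_equal(rownames(ft$values), c("A", "B", "C"))
  expect_equal(colnames(ft$values), c("S1", "S2"))
  expect_equal(unname(ft$values[, "S2"]), c(2, 3, 0))
  expect_equal(ft$mode, "counts")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, out)
  expect_equal(ft_values(read_feature_table(out)), ft$values)
})

test_that("reader rejects malformed tables with informative errors", {
  dup <- write_tsv_fixture(c("taxon\tS1\tS1", "A\t1\t2"))
  expect_error(read_feature_table(dup), "S1")

  neg <- write_tsv_fixture(c("taxon\tS1\tS2", "A\t1\t2", "B\t-2\t3"))
  expect_error(read_feature_table(neg), "row 2.*B.*column 1.*S1")

  txt <- write_tsv_fixture(c("taxon\tS1", "A\tx"))
  expect_error(read_feature_table(txt), "'x'")

  expect_error(read_feature_table("no/such/file.tsv"), "not found")
})

test_that("metadata attachment validates coverage and labels", {
  ft <- toy_counts()
  ft2 <- attach_metadata(ft, toy_meta())
  expect_equal(ft2$samples$group, c("case", "control", "case"))

  expect_error(attach_metadata(ft, toy_meta()[1:2, ]), "S3")
  bad <- toy_meta(); bad$group[1] <- "tumour"
  expect_error(attach_metadata(ft, bad), "tumour")
  dup <- toy_meta()[c(1, 1, 2, 3), ]
  expect_error(attach_metadata(ft, dup), "more than once")
})

test_that("collapse sums counts at the requested rank and conserves totals", {
  ft <- attach_metadata(toy_counts(), toy_meta())
  fam <- collapse_taxa(ft, "family")
  # Streptococcus + Lactococcus share Streptococcaceae
  expect_equal(unname(fam$values["Streptococcaceae", ]), c(2, 4, 6))
  expect_equal(colSums(fam$values), colSums(ft$values))
  expect_equal(fam$level, "family")

  phy <- collapse_taxa(ft, "phylum")
  expect_setequal(rownames(phy$values), c("Firmicutes", "Proteobacteria"))
  # idempotence: collapsing a collapsed table is the identity
  expect_equal(ft_values(collapse_taxa(phy, "phylum")), phy$values)

  expect_error(collapse_taxa(ft, "species"), "level")
})

test_that("taxa unassigned at the rank pool under unclassified", {
  m <- matrix(c(2, 3,
                5, 1,
                1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("Bacteria;Firmicutes;;;;",
                                "Bacteria",
                                "Bacteria;Firmicutes;B;L;S;Gemella"),
                              c("S1", "S2")))
  ft <- feature_table(m)
  gen <- collapse_taxa(ft, "genus")
  expect_equal(unname(gen$values["unclassified", ]), c(7, 4))
  expect_equal(colSums(gen$values), colSums(m))
  dropped <- collapse_taxa(ft, "genus", drop_unclassified = TRUE)
  expect_equal(rownames(dropped$values), "Gemella")
})

test_that("duplicate rank names under different parents are disambiguated", {
  m <- matrix(1:4, 2, 2,
              dimnames = list(c("Bacteria;Firmicutes;C1;O1;F1;Shared",
                                "Bacteria;Proteobacteria;C2;O2;F2;Shared"),
                              c("S1", "S2")))
  gen <- collapse_taxa(feature_table(m), "genus")
  expect_equal(nrow(gen$values), 2L)
  expect_true(all(grepl("Shared", rownames(gen$values))))
  expect_false(anyDuplicated(rownames(gen$values)) > 0)
})

test_that("to_relative normalizes columns and guards its mode", {
  ft <- toy_counts()
  rel <- to_relative(ft)
  expect_equal(unname(colSums(rel$values)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(rel$values[, "S1"]), c(2, 4, 0) / 6)
  expect_error(to_relative(rel), "already relative")

  zero <- feature_table(matrix(c(1, 2, 0, 0), 2, 2,
                               dimnames = list(c("A", "B"), c("S1", "S2"))))
  expect_error(to_relative(zero), "S2")
})

test_that("merge_shared intersects taxa, keeps samples, flags renormalization", {
  mk <- function(taxa, samples, seed) {
    set.seed(seed)
    m <- matrix(rexp(length(taxa) * length(samples)) + 0.1,
                length(taxa), dimnames = list(taxa, samples))
    ft <- to_relative(feature_table(m))
    ft$level <- "genus"
    ft$taxa$genus <- taxa
    ft
  }
  t1 <- mk(c("A", "B", "C"), c("S1", "S2"), 1)
  t2 <- mk(c("B", "C", "D"), c("S3", "S4"), 2)
  mg <- merge_shared(list(t1, t2), "genus")
  expect_setequal(rownames(mg$values), c("B", "C"))
  expect_equal(colnames(mg$values), c("S1", "S2", "S3", "S4"))
  # proportions kept as measured: column sums below 1
  expect_true(all(colSums(mg$values) < 1))
  mg2 <- merge_shared(list(t1, t2), "genus", renormalize = TRUE)
  expect_equal(unname(colSums(mg2$values)), rep(1, 4), tolerance = 1e-12)

  # taxon set is order-insensitive; single table is the identity
  mg_rev <- merge_shared(list(t2, t1), "genus")
  expect_setequal(rownames(mg_rev$values), rownames(mg$values))
  expect_equal(ft_values(merge_shared(list(t1), "genus")), t1$values)

  t3 <- mk(c("X", "Y"), c("S5", "S6"), 3)
  expect_error(merge_shared(list(t1, t3), "genus"), "shared")
  t4 <- mk(c("A", "B"), c("S1", "S9"), 4)
  expect_error(merge_shared(list(t1, t4), "genus"), "S1")
})

test_that("lineage parsing handles greengenes prefixes and truncation", {
  lin <- parse_lineage(c("k__Bacteria; p__Firmicutes; c__; o__; f__; g__",
                         "Bacteria;Proteobacteria",
                         "PlainLabel"))
  expect_equal(lin$phylum, c("Firmicutes", "Proteobacteria", NA))
  expect_true(all(is.na(lin$class[1])))
  # once unassigned, deeper ranks stay unassigned
  expect_true(all(is.na(as.matrix(lin[3, c("kingdom", "phylum", "genus")]))))
})

test_that("BIOM JSON tables are read when biomformat is available", {
  skip_if_not_installed("biomformat")
  m <- matrix(c(5, 0, 3, 7), 2, 2,
              dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
  b <- biomformat::make_biom(m)
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  ft <- read_feature_table(path, format = "biom")
  expect_equal(unname(ft$values), unname(m))
  expect_equal(rownames(ft$values), rownames(m))
})
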