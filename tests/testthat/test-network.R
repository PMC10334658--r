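test_that("pearson with p matches hand computation and cor.test", {
  expect_equal(pearson_with_p(1:4, 2 * (1:4) + 1)$r, 1)
  expect_equal(pearson_with_p(1:4, 2 * (1:4) + 1)$p_value, 0)

  got <- pearson_with_p(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(got$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)

  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    ct <- cor.test(x, y)
    got <- pearson_with_p(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("condition networks test all pairs and drop constant taxa", {
  set.seed(52)
  n <- 30
  x <- rnorm(n)
  m <- rbind(T1 = x - min(x) + 0.5,
             T2 = 2 * (x - min(x) + 0.5),    # exactly dependent on T1
             T3 = rexp(n) + 0.2,
             T4 = rep(0.3, n))               # constant
  colnames(m) <- paste0("S", seq_len(n))
  meta <- tibble::tibble(sample_id = colnames(m), dataset = "D1",
                         group = rep(c("case", "control"), each = n / 2))
  rel <- to_relative(attach_metadata(feature_table(m), meta))
  # T4 is constant pre-normalization but not after; rebuild by hand
  v <- m / rep(colSums(m), each = 4)
  rel$values <- v

  expect_message(
    net <- condition_network(rel, "case", alpha = 0.05),
    NA
  )
  expect_equal(nrow(net$edges), choose(4, 2))
  e12 <- net$edges[net$edges$taxon_a == "T1" & net$edges$taxon_b == "T2", ]
  expect_true(e12$significant)
  expect_gt(e12$r, 0.99)

  # a condition-constant taxon is excluded from tested pairs
  v2 <- v; v2["T3", meta$group == "case"] <- 0.25
  v2 <- sweep(v2, 2, colSums(v2), "/")
  v2["T3", meta$group == "case"] <- v2["T3", meta$group == "case"][1]
  rel2 <- rel; rel2$values <- v2
  expect_message(net2 <- condition_network(rel2, "case"), "T3")
  expect_false("T3" %in% c(net2$edges$taxon_a, net2$edges$taxon_b))

  expect_error(condition_network(rel, "case", alpha = 0.05, adjust = "BY"))
})

test_that("rewiring classification follows the gained/lost/changed rules", {
  mk_net <- function(edges, condition) {
    structure(list(edges = edges, nodes = c("A", "B", "C", "D"),
                   condition = condition, alpha = 0.05, adjust = "none",
                   n_samples = 50, level = "genus"),
              class = "cooccurrence_network")
  }
  edges <- function(r_ab, sig_ab, r_cd, sig_cd, r_ac, sig_ac) {
    tibble::tibble(
      taxon_a = c("A", "C", "A"), taxon_b = c("B", "D", "C"),
      r = c(r_ab, r_cd, r_ac), p_value = ifelse(c(sig_ab, sig_cd, sig_ac), 0.001, 0.5),
      q_value = NA_real_, significant = c(sig_ab, sig_cd, sig_ac)
    )
  }
  control <- mk_net(edges(0.6, TRUE,  0.5, TRUE, 0.5, TRUE), "control")
  case <- mk_net(edges(0.1, FALSE, -0.5, TRUE, 0.7, TRUE), "case")
  dn <- differential_network(control, case)
  cls <- setNames(dn$edges$class, paste(dn$edges$taxon_a, dn$edges$taxon_b))
  expect_equal(unname(cls["A B"]), "lost")
  expect_equal(unname(cls["C D"]), "changed_direction")
  expect_false("A C" %in% names(cls))   # significant both, same sign

  # gained: significant in case only
  control2 <- mk_net(edges(0.1, FALSE, 0.5, TRUE, 0.5, TRUE), "control")
  case2 <- mk_net(edges(0.6, TRUE, 0.5, TRUE, 0.5, TRUE), "case")
  dn2 <- differential_network(control2, case2)
  expect_equal(dn2$edges$class, "gained")
  expect_equal(dn2$nodes, c("A", "B"))

  # swapping the inputs exchanges gained and lost, fixes changed_direction
  dn_swap <- differential_network(case, control)
  cls_swap <- setNames(dn_swap$edges$class,
                       paste(dn_swap$edges$taxon_a, dn_swap$edges$taxon_b))
  expect_equal(unname(cls_swap["A B"]), "gained")
  expect_equal(unname(cls_swap["C D"]), "changed_direction")

  lvl <- case; lvl$level <- "phylum"
  expect_error(differential_network(control, lvl), "different levels")
})

test_that("classes partition rewired edges on random networks", {
  set.seed(53)
  for (i in 1:30) {
    taxa <- paste0("T", 1:8)
    pairs <- t(combn(taxa, 2))
    mk <- function(cond) {
      structure(list(
        edges = tibble::tibble(
          taxon_a = pairs[, 1], taxon_b = pairs[, 2],
          r = runif(nrow(pairs), -1, 1), p_value = runif(nrow(pairs)),
          q_value = NA_real_, significant = runif(nrow(pairs)) < 0.4
        ),
        nodes = taxa, condition = cond, alpha = 0.05, adjust = "none",
        n_samples = 30, level = "genus"
      ), class = "cooccurrence_network")
    }
    ctrl <- mk("control"); cs <- mk("case")
    dn <- differential_network(ctrl, cs)
    expect_false(anyDuplicated(paste(dn$edges$taxon_a, dn$edges$taxon_b)) > 0)
    expect_true(all(dn$edges$class %in% c("gained", "lost", "changed_direction")))
    # every rewired pair has exactly one class and matches the rule
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    kc <- key(cs$edges$taxon_a, cs$edges$taxon_b)
    kn <- key(ctrl$edges$taxon_a, ctrl$edges$taxon_b)
    for (j in seq_len(nrow(dn$edges))) {
      k <- key(dn$edges$taxon_a[j], dn$edges$taxon_b[j])
      sc <- cs$edges$significant[match(k, kc)]
      sn <- ctrl$edges$significant[match(k, kn)]
      expected <- if (sc && !sn) "gained" else if (!sc && sn) "lost"
        else "changed_direction"
      expect_equal(dn$edges$class[j], expected)
    }
    # handshake lemma on rewiring degrees
    rd <- rewiring_degree(dn)
    expect_equal(sum(rd$total), 2 * nrow(dn$edges))
    expect_equal(rd$total, rd$gained + rd$lost + rd$changed)
    expect_true(all(diff(rd$total) <= 0))
  }
})

test_that("planted pairs reach significance with high power", {
  set.seed(54)
  hits <- vapply(1:20, function(i) {
    n <- 200
    z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.8, 0.8, 1), 2))
    pearson_with_p(z[, 1], z[, 2])$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("hub calls honor the published degree cutoffs", {
  ct <- tibble::tibble(node = paste0("T", 1:5), degree = c(3, 4, 15, 16, 21))
  expect_setequal(hub_nodes(ct, "phylum"), c("T2", "T3", "T4", "T5"))
  expect_setequal(hub_nodes(ct, "genus"), c("T4", "T5"))
  expect_false("T3" %in% hub_nodes(ct, "genus"))  # degree 15 excluded at genus
  expect_error(hub_nodes(ct, "family"), "family_cutoff")
  expect_setequal(hub_nodes(ct, "family", family_cutoff = 15), c("T3", "T4", "T5"))
})
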