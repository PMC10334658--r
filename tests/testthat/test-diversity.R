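test_that("shannon and simpson match hand-evaluated cases", {
  expect_equal(shannon(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(shannon(rep(0.25, 4), base = 2), 2, tolerance = 1e-12)

  expect_equal(simpson(rep(0.25, 4)), 0.75)
  expect_equal(simpson(1), 0)
  expect_equal(simpson(c(0.5, 0.5)), 0.5)
  expect_equal(simpson(rep(0.25, 4), inverse = TRUE), 4)

  expect_error(shannon(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon(c(0.3, 0.3)), "sum to 1")

  # permutation invariance in taxa
  set.seed(1)
  p <- rexp(8); p <- p / sum(p)
  o <- sample(8)
  expect_equal(shannon(p), shannon(p[o]))
  expect_equal(simpson(p), simpson(p[o]))
})

test_that("alpha table counts strictly positive taxa per sample", {
  ft <- toy_relative()
  ft$values[1, 1] <- 0
  ft$values[, 1] <- ft$values[, 1] / sum(ft$values[, 1])
  at <- alpha_table(ft)
  expect_equal(nrow(at), ncol(ft$values))
  expect_equal(at$observed[at$sample_id == "S1"], 4)
  # entropy bound given observed richness
  expect_true(all(at$shannon <= log(at$observed) + 1e-12))
  expect_true(all(at$simpson >= 0 & at$simpson <= 1 - 1 / at$observed + 1e-12))
})

test_that("alpha group comparison delegates to the rank-sum test", {
  at <- alpha_table(toy_relative(seed = 5))
  res <- compare_alpha(at)
  expect_equal(res$index, c("observed", "shannon", "simpson"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # identical groups give p = 1
  rec <- tibble::tibble(group = rep(c("case", "control"), each = 3),
                        observed = rep(c(3, 4, 5), 2),
                        shannon = rep(1, 6), simpson = rep(c(0.5, 0.6, 0.7), 2))
  res2 <- compare_alpha(rec)
  expect_true(all(res2$p_value > 0.99))

  # fully separated tiny samples: exact two-sided p = 2 / choose(4, 2)
  rec3 <- tibble::tibble(group = c("case", "case", "control", "control"),
                         shannon = c(1, 2, 3, 4))
  res3 <- compare_alpha(rec3, indices = "shannon")
  expect_equal(res3$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("bray-curtis matches the formula and its metric properties", {
  m <- matrix(c(0.5, 0, 0.5,
                0, 0.5, 0.5), 3, 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  ft <- feature_table(m, mode = "relative")
  d <- as.matrix(bray_curtis(ft))
  expect_equal(d["S1", "S2"], 0.5)

  # identical columns -> 0; disjoint supports -> 1
  m2 <- matrix(c(0, 1, 0, 1, 1, 0), 2, 3,
               dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  d2 <- as.matrix(bray_curtis(feature_table(m2, mode = "relative")))
  expect_equal(d2["S1", "S2"], 0)
  expect_equal(d2["S1", "S3"], 1)

  ft3 <- toy_relative(seed = 7)
  d3 <- as.matrix(bray_curtis(ft3))
  expect_equal(d3, t(d3))
  expect_true(all(diag(d3) == 0))
  expect_true(all(d3 >= 0 & d3 <= 1))
})

test_that("pcoa reproduces classical MDS geometry", {
  # collinear points 0, 1, 2 on a line
  D <- as.dist(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3))
  fit <- pcoa(D, k = 2)
  expect_equal(fit$eig[1], 2, tolerance = 1e-9)
  expect_equal(fit$eig[2:3], c(0, 0), tolerance = 1e-9)
  expect_equal(sort(abs(fit$points[, 1])), c(0, 1, 1), tolerance = 1e-9)

  # Euclidean-embeddable distances are reproduced exactly
  set.seed(3)
  X <- matrix(rnorm(6 * 3), 6, 3)
  D2 <- dist(X)
  fit2 <- pcoa(D2, k = 5)
  expect_equal(as.matrix(dist(fit2$points)), as.matrix(D2), tolerance = 1e-8,
               ignore_attr = TRUE)

  # equidistant triangle: two equal positive eigenvalues
  D3 <- as.dist(matrix(1, 3, 3) - diag(3))
  fit3 <- pcoa(D3, k = 2)
  expect_equal(fit3$eig[1], fit3$eig[2], tolerance = 1e-9)
  expect_gt(fit3$eig[2], 0)

  expect_error(pcoa(D, k = 3), "`k`")
})

test_that("pcoa recovers known coordinates up to rotation", {
  set.seed(11)
  X <- matrix(rnorm(10 * 2), 10, 2)
  fit <- pcoa(dist(X), k = 2)
  # procrustes residual after optimal rotation/translation is ~0
  pr <- vegan::procrustes(X, fit$points, symmetric = FALSE)
  expect_lt(max(abs(pr$Yrot + matrix(pr$translation, 10, 2, byrow = TRUE) - X)),
            1e-6)
})

test_that("permanova separates planted clusters and ignores sample order", {
  set.seed(2)
  X <- rbind(matrix(rnorm(10 * 3), 10, 3),
             matrix(rnorm(10 * 3, mean = 100), 10, 3))
  rownames(X) <- paste0("S", 1:20)
  d <- dist(X)
  g <- rep(c("a", "b"), each = 10)
  fit <- permanova(d, g, nperm = 999, seed = 7)
  expect_lte(fit$p_value, 0.005)
  expect_gt(fit$statistic, 50)
  expect_true(fit$r_squared > 0 && fit$r_squared < 1)

  # permuting sample order (with labels) leaves F unchanged
  o <- sample(20)
  fit2 <- permanova(as.dist(as.matrix(d)[o, o]), g[o], nperm = 99, seed = 7)
  expect_equal(fit2$statistic, fit$statistic, tolerance = 1e-10)

  expect_error(permanova(d, rep("a", 20), nperm = 99, seed = 1), "2 groups")
  expect_error(permanova(d, g, nperm = 99), "seed")
})

test_that("beta dispersion flags a diffuse group and respects symmetry", {
  set.seed(4)
  tight <- matrix(rnorm(50 * 3, sd = 0.1), 50, 3)
  diffuse <- matrix(rnorm(50 * 3, sd = 2), 50, 3)
  X <- rbind(tight, diffuse)
  rownames(X) <- paste0("S", 1:100)
  g <- rep(c("tight", "diffuse"), each = 50)
  bd <- beta_dispersion(dist(X), g)
  expect_lt(bd$p_value, 0.05)
  expect_gt(mean(bd$distances$distance[g == "diffuse"]),
            mean(bd$distances$distance[g == "tight"]))

  # mirror-image groups have equal dispersion
  set.seed(5)
  A <- matrix(rnorm(20 * 2), 20, 2)
  X2 <- rbind(A, -A)
  rownames(X2) <- paste0("S", 1:40)
  bd2 <- beta_dispersion(dist(X2), rep(c("a", "b"), each = 20))
  expect_gt(bd2$p_value, 0.9)
})
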