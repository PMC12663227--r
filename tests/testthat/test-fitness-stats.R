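test_that("germination success reproduces the counting arithmetic", {
  expect_equal(germination_success(0, 96)$estimate, 0)
  expect_equal(germination_success(138, 151)$estimate, 0.914, tolerance = 5e-4)
  expect_equal(germination_success(80, 92)$estimate, 0.870, tolerance = 5e-4)
  expect_error(germination_success(5, 4), "germinated")
})

test_that("Wilson intervals always contain the point estimate", {
  g <- c(0, 1, 5, 48, 96)
  ci <- germination_success(g, rep(96, 5))
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  expect_true(all(ci$lower >= 0 & ci$upper <= 1))
})

test_that("fitness index is the product, commutative and bounded", {
  expect_equal(fitness_index(0, 0.7), 0)
  expect_equal(fitness_index(1, 1), 1)
  expect_equal(fitness_index(0.5, 0.2), 0.1)
  x <- seq(0, 1, 0.25)
  expect_equal(fitness_index(x, rev(x)), fitness_index(rev(x), x))
  expect_error(fitness_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("median gate splits loads into B+ and B++ halves", {
  g <- gate_by_load(1:10)
  expect_identical(g$b_plus, 1:5)
  expect_identical(g$b_plusplus, 6:10)
  # odd count: median element goes to B+
  g9 <- gate_by_load(c(5, 1, 9, 3, 7, 2, 8, 4, 6))
  expect_identical(sort(g9$b_plus), c(1, 2, 3, 4, 5))
  # partition property
  expect_identical(sort(c(g9$index_b_plus, g9$index_b_plusplus)), 1:9)
  # degenerate all-equal input is flagged but still balanced
  ge <- gate_by_load(rep(2, 6))
  expect_true(ge$degenerate)
  expect_identical(length(ge$b_plus), 3L)
  # simulated log-normal loads: B++ mean exceeds B+ mean
  set.seed(19)
  gl <- gate_by_load(rlnorm(200, log(1000), 0.5))
  expect_gt(mean(gl$b_plusplus), mean(gl$b_plus))
})

test_that("normalization to negative spores is a plain ratio", {
  expect_equal(normalize_to_negative(0.3, 0.3), 1)
  expect_equal(normalize_to_negative(0, 0.4), 0)
  expect_equal(normalize_to_negative(0.26, 0.52), 0.5)
  expect_error(normalize_to_negative(0.2, 0), "> 0")
})

test_that("retention summaries count positives per storage day", {
  r <- retention_summary(c(0, 0, 7, 7, 7), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$fraction_retained[r$day == 0], 1)
  expect_equal(r$fraction_retained[r$day == 7], 1 / 3, tolerance = 1e-12)
  all_neg <- retention_summary(rep(1, 4), rep(FALSE, 4))
  expect_equal(all_neg$fraction_retained, 0)
})

test_that("identical groups are not significant under Mann-Whitney/BH", {
  x <- c(1, 2, 3, 4, 5, 6)
  gc <- group_compare(c(x, x), rep(c("a", "b"), each = 6), "mann-whitney")
  expect_gt(min(gc$pairwise$p_adj), 0.05)
  expect_identical(unname(gc$letters["a"]), unname(gc$letters["b"]))
})

test_that("small-sample Mann-Whitney p equals full rank-permutation enumeration", {
  set.seed(20)
  for (rep in 1:5) {
    x <- round(runif(4), 3) * 100
    y <- round(runif(4), 3) * 100 + sample(c(0, 30), 1)
    gc <- group_compare(c(x, y), rep(c("a", "b"), each = 4), "mann-whitney")
    expect_equal(gc$pairwise$p, mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("a shifted group is isolated by Kruskal-Wallis/Dunn letters", {
  set.seed(21)
  vals <- c(rnorm(15, 0), rnorm(15, 0.2), rnorm(15, 0), rnorm(15, 6))
  grp <- rep(c("g1", "g2", "g3", "g4"), each = 15)
  gc <- group_compare(vals, grp, "kruskal-dunn")
  expect_lt(gc$omnibus$p, 0.05)
  shifted <- gc$letters["g4"]
  others <- gc$letters[c("g1", "g2", "g3")]
  # g4 shares no letter with any other group
  expect_true(all(vapply(others, function(l)
    !any(strsplit(shifted, "")[[1]] %in% strsplit(l, "")[[1]]), logical(1))))
  # Kruskal-Wallis omnibus agrees with stats::kruskal.test
  expect_equal(gc$omnibus$p, kruskal.test(vals, factor(grp))$p.value)
})

test_that("Dunn z statistics match a direct rank computation with ties", {
  vals <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 10, 11, 12)
  grp <- rep(c("a", "b", "c"), each = 4)
  gc <- group_compare(vals, grp, "kruskal-dunn")
  r <- rank(vals)
  n <- length(vals)
  ties <- table(r)
  corr <- sum(ties^3 - ties) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - corr) * (1 / 4 + 1 / 4))
  z_ab <- (mean(r[grp == "a"]) - mean(r[grp == "b"])) / se
  got <- gc$pairwise$statistic[gc$pairwise$group1 == "a" &
                               gc$pairwise$group2 == "b"]
  expect_equal(got, z_ab, tolerance = 1e-12)
  expect_equal(gc$pairwise$p_adj, pmin(1, gc$pairwise$p * 3))
})

test_that("p-values are invariant under within-group permutation and BH is monotone", {
  set.seed(22)
  x <- rnorm(10); y <- rnorm(10, 1)
  vals <- c(x, y); grp <- rep(c("a", "b"), each = 10)
  p1 <- group_compare(vals, grp, "mann-whitney")$pairwise$p
  perm <- c(sample(1:10), 10 + sample(1:10))
  p2 <- group_compare(vals[perm], grp, "mann-whitney")$pairwise$p
  expect_equal(p1, p2, tolerance = 1e-12)
  p <- c(0.001, 0.02, 0.04, 0.3, 0.9)
  expect_true(all(diff(p.adjust(p, "BH")) >= 0))
  # groups below two observations are excluded with a warning
  expect_warning(
    gc <- group_compare(c(x, y, 3), c(grp, "c"), "mann-whitney"), "excluding")
  expect_identical(nrow(gc$pairwise), 1L)
})

test_that("enrichment fractions reproduce the printed percentages", {
  expect_equal(enrichment_fraction(20, 591)$percent, 3.4)
  expect_equal(enrichment_fraction(401, 21522)$percent, 1.9)
  expect_equal(enrichment_fraction(0, 10)$percent, 0)
  # hypergeometric tail agrees with the one-sided Fisher test
  e <- enrichment_fraction(20, 591, hits_bg = 401, total_bg = 21522)
  f <- fisher.test(matrix(c(20, 571, 401 - 20, 21522 - 401 - 571), 2),
                   alternative = "greater")
  expect_equal(e$p_hyper, f$p.value, tolerance = 1e-6)
  expect_error(enrichment_fraction(5, 4), "hits")
})
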