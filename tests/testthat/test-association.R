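test_that("Pearson correlation and t-based p-value match their anchors", {
  x <- c(1, 2, 3, 4)
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)
  res <- pearson_with_p(x, c(1, -1, -1, 1))  # orthogonal to centered x
  expect_equal(res$r, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # explicit t transform reproduced by hand
  set.seed(8)
  a <- rnorm(25); b <- 0.4 * a + rnorm(25)
  res <- pearson_with_p(a, b)
  tt <- res$r * sqrt((25 - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tt), df = 23))
})

test_that("t-based p-value agrees with a permutation null", {
  set.seed(15)
  x <- rnorm(20)
  y <- 0.3 * x + rnorm(20)
  res <- pearson_with_p(x, y)
  p_perm <- perm_pvalue_pearson(x, y, n_perm = 1e5)
  expect_lt(abs(res$p - p_perm), 0.02)
})

test_that("input contract of the correlation tests is enforced", {
  expect_error(pearson_with_p(1:5, 1:4), class = "icubench_bad_input")
  expect_error(pearson_with_p(1:2, 1:2), class = "icubench_too_few")
  expect_error(pearson_with_p(rep(1, 5), 1:5),
               class = "icubench_constant_input")
  expect_error(spearman_with_p(rep(1, 5), 1:5),
               class = "icubench_constant_input")
})

test_that("Spearman correlation is rank-based with mean ranks for ties", {
  x <- c(0.3, 1.1, 2.7, 3.9, 5)
  expect_equal(spearman_with_p(x, exp(x))$r, 1)   # monotone transform
  expect_equal(spearman_with_p(x, -x)$r, -1)      # reversal
  # hand-ranked oracle with tied x: ranks (1, 2.5, 2.5, 4)
  res <- spearman_with_p(c(1, 2, 2, 3), c(10, 20, 30, 40))
  rx <- c(1, 2.5, 2.5, 4); ry <- 1:4
  expect_equal(res$r, sum((rx - 2.5) * (ry - 2.5)) /
                 sqrt(sum((rx - 2.5)^2) * sum((ry - 2.5)^2)))
  # definitional identity: spearman == pearson on ranks
  set.seed(44)
  for (i in 1:5) {
    a <- sample(1:8, 12, replace = TRUE)
    b <- rnorm(12)
    expect_equal(spearman_with_p(a, b)$r, pearson_with_p(rank(a), rank(b))$r)
  }
})

test_that("exact permutation Spearman p-value is available for tiny samples", {
  set.seed(5)
  x <- rnorm(6); y <- rnorm(6)
  res <- spearman_with_p(x, y, exact = TRUE)
  expect_gte(res$p, 0)
  expect_lte(res$p, 1)
  # strictly monotone pair: only reversals/identity reach |rho| = 1
  res <- spearman_with_p(1:5, (1:5)^3, exact = TRUE)
  expect_equal(res$p, 2 / factorial(5))
  expect_error(spearman_with_p(rnorm(12), rnorm(12), exact = TRUE),
               class = "icubench_too_large")
})

test_that("Pearson test is symmetric and affine-invariant", {
  set.seed(26)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(pearson_with_p(x, y), pearson_with_p(y, x))
  expect_equal(pearson_with_p(3 * x + 2, y)$r, pearson_with_p(x, y)$r)
  expect_equal(pearson_with_p(x, 0.5 * y - 1)$p, pearson_with_p(x, y)$p)
})

fake_indicator_table <- function(n_icus = 12, subgroups = c("all", "CAP"),
                                 seed = 61) {
  set.seed(seed)
  tab <- tidyr::expand_grid(icu_id = sprintf("icu_%02d", seq_len(n_icus)),
                            subgroup = subgroups)
  n <- nrow(tab)
  tab$SMR <- exp(rnorm(n, 0, 0.2)); tab$SRR <- exp(rnorm(n, 0, 0.3))
  tab$SLOSR <- exp(rnorm(n, 0, 0.1))
  tab$n_mortality <- tab$n_los <- 200L
  tab$n_risk_set <- 150L
  class(tab) <- c("indicator_table", class(tab))
  tab
}

test_that("pairwise association sweep yields subgroup x pair results", {
  tab <- fake_indicator_table(subgroups = c("all", "CAP", "sepsis"))
  res <- pairwise_indicator_associations(tab, "pearson")
  expect_equal(nrow(res), 3 * 3)
  expect_setequal(unique(res$pair), c("SMR-SRR", "SMR-SLOSR", "SLOSR-SRR"))
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$significant, res$p < 0.01)
  # alpha only moves the flag, not the coefficients
  res05 <- pairwise_indicator_associations(tab, "pearson", alpha = 0.05)
  expect_equal(res05$r, res$r)
  expect_equal(res05$p, res$p)
  expect_equal(res05$significant, res05$p < 0.05)
  # spearman route
  ressp <- pairwise_indicator_associations(tab, "spearman")
  expect_equal(ressp$r[1],
               pearson_with_p(rank(tab$SMR[tab$subgroup == "all"]),
                              rank(tab$SRR[tab$subgroup == "all"]))$r)
})

test_that("missing indicator cells use pairwise-complete deletion", {
  tab <- fake_indicator_table(n_icus = 10, subgroups = "all")
  tab$SRR[3] <- NA
  res <- pairwise_indicator_associations(tab, "pearson")
  expect_equal(res$n_icus[res$pair == "SMR-SRR"], 9)
  expect_equal(res$n_icus[res$pair == "SMR-SLOSR"], 10)
  pts <- scatter_export(tab, "SMR-SRR", "all")
  expect_equal(nrow(pts), 9)
  expect_false(tab$icu_id[3] %in% pts$icu_id)
  pts2 <- scatter_export(tab, "SMR-SLOSR", "all")
  expect_equal(nrow(pts2), 10)
})

test_that("subgroups with too few or constant indicators are omitted with warnings", {
  tab <- fake_indicator_table(n_icus = 3, subgroups = "all")
  tab$SMR[1:2] <- NA
  w <- capture_warnings(res <- pairwise_indicator_associations(tab))
  expect_match(w, "fewer than 3", all = FALSE)
  tab2 <- fake_indicator_table(n_icus = 8, subgroups = "all")
  tab2$SLOSR <- 1
  w2 <- capture_warnings(res2 <- pairwise_indicator_associations(tab2))
  expect_match(w2, "constant", all = FALSE)
  expect_setequal(res2$pair, "SMR-SRR")
})

test_that("scatter export validates its arguments and round-trips CSV", {
  tab <- fake_indicator_table()
  expect_error(scatter_export(tab, "SMR-XYZ", "all"),
               class = "icubench_bad_pair")
  expect_error(scatter_export(tab, "SMR-SRR", "nope"),
               class = "icubench_bad_subgroup")
  pts <- scatter_export(tab, "SMR-SLOSR", "all")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(pts, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(pts))
})

test_that("association report pivots to one subgroup row with pair columns", {
  tab <- fake_indicator_table(subgroups = c("all", "CAP"))
  rep <- association_report(pairwise_indicator_associations(tab))
  expect_equal(nrow(rep), 2)
  expect_true(all(c("SMR-SRR_r", "SMR-SRR_p", "SMR-SLOSR_r",
                    "SLOSR-SRR_p") %in% names(rep)))
})
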