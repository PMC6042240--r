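test_that("correlation handles self, reflection and the hand oracle", {
  x <- setNames(c(1, 2, 3, 5, 8), paste0("s", 1:5))
  expect_equal(correlate_scores(x, x)$r, 1)
  expect_equal(correlate_scores(x, -x)$r, -1)
  # hand oracle: x=(1,2,3), y=(1,2,4) -> cov 1.5, sds 1 and sqrt(7/3)
  a <- setNames(c(1, 2, 3), paste0("s", 1:3))
  b <- setNames(c(1, 2, 4), paste0("s", 1:3))
  expect_equal(correlate_scores(a, b)$r, 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
})

test_that("correlation pairs by sample id and counts dropped pairs", {
  x <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  y <- setNames(c(8, 6, NA, 2, 0), paste0("s", c(4, 3, 2, 1, 9)))
  res <- correlate_scores(x, y)
  expect_equal(res$n, 3L)
  expect_equal(res$n_dropped, 1L)
  expect_equal(res$r, cor(c(1, 3, 4), c(2, 6, 8)), tolerance = 1e-12)

  expect_error(correlate_scores(x[1:2], y), "fewer than 3")
  expect_error(correlate_scores(setNames(rep(1, 4), names(x)), x),
               "zero variance")
  expect_error(correlate_scores(unname(x), y), "named")
})

test_that("Pearson is affine-equivariant; Spearman is monotone-invariant", {
  set.seed(12)
  x <- setNames(rnorm(20), paste0("s", 1:20))
  y <- setNames(x + rnorm(20), names(x))
  base_p <- correlate_scores(x, y, "pearson")$r
  expect_equal(correlate_scores(3 * x + 7, y, "pearson")$r, base_p,
               tolerance = 1e-12)
  expect_equal(correlate_scores(-x, y, "pearson")$r, -base_p,
               tolerance = 1e-12)
  base_s <- correlate_scores(x, y, "spearman")$r
  expect_equal(correlate_scores(exp(x), y, "spearman")$r, base_s,
               tolerance = 1e-12)
})

test_that("group comparison uses the exact rank-sum extremes", {
  ids <- paste0("s", 1:10)
  s <- setNames(c(1:5, 11:15), ids)
  annot <- sample_annotation(data.frame(
    sample_id = ids, group = "case",
    subtype = rep(c("limited", "diffuse"), each = 5)))
  res <- compare_groups(s, annot, split_by = "subtype")
  # complete separation at 5+5: two-sided exact p = 2 / choose(10, 5)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(sort(res$n_per_group), c(5L, 5L))

  # identical multisets sit at the null centre of the rank-sum statistic
  s2 <- setNames(c(1:5, 1:5), ids)
  res2 <- suppressWarnings(compare_groups(s2, annot, split_by = "subtype"))
  expect_equal(res2$statistic, 5 * 5 / 2)

  # p is invariant under any common monotone transform of the scores
  res3 <- compare_groups(exp(s / 4), annot, split_by = "subtype")
  expect_equal(res3$p_value, res$p_value, tolerance = 1e-12)
})

test_that("group comparison demands exactly two nonempty groups", {
  ids <- paste0("s", 1:6)
  s <- setNames(rnorm(6), ids)
  annot3 <- sample_annotation(data.frame(
    sample_id = ids, group = "case",
    subtype = c("limited", "diffuse", "overlap", "limited", "diffuse",
                "overlap")))
  expect_error(compare_groups(s, annot3, split_by = "subtype"),
               "exactly 2.*diffuse, limited, overlap")
  annot1 <- sample_annotation(data.frame(sample_id = ids, group = "case",
                                         duration_class = "early"))
  expect_error(compare_groups(s, annot1, split_by = "duration_class"),
               "exactly 2")
})

test_that("cohort summary reproduces printed clinical percentages", {
  annot <- sample_annotation(data.frame(
    sample_id = paste0("p", 1:36), group = "case",
    mrss = c(rep(17, 35), NA),
    subtype = rep(c("diffuse", "limited", "overlap"), c(30, 5, 1)),
    duration_class = rep(c("early", "late"), c(12, 24))))
  cs <- summarize_cohort(annot)
  sub <- cs$categorical$subtype
  expect_equal(sub$pct[sub$level == "diffuse"], 83.3)
  expect_equal(sub$pct[sub$level == "limited"], 13.9)
  dur <- cs$categorical$duration_class
  expect_equal(dur$pct[dur$level == "early"], 33.3)
  expect_equal(dur$pct[dur$level == "late"], 66.7)
  expect_equal(cs$continuous$mrss$n, 35L)
  expect_equal(cs$continuous$mrss$mean, 17)
})

test_that("cohort percentages always sum to ~100, with missing as a category", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    annot <- sample_annotation(data.frame(
      sample_id = paste0("s", seq_len(n)),
      group = sample(c("control", "case"), n, TRUE),
      subtype = sample(c("diffuse", "limited", "overlap", "n/a"), n, TRUE)))
    cs <- summarize_cohort(annot)
    for (tab in cs$categorical) {
      expect_lt(abs(sum(tab$pct) - 100), 0.1 * nrow(tab) + 1e-9)
      expect_equal(sum(tab$count), n)
    }
  }
  one <- summarize_cohort(sample_annotation(data.frame(
    sample_id = "s1", group = "case", subtype = "diffuse")))
  expect_equal(one$categorical$subtype$pct, 100)
})

test_that("metabolic panel follows the printed formulas", {
  p <- compute_metabolic_panel(glucose = 100, insulin = 4, leptin = 6,
                               adiponectin = 3)
  expect_equal(p$homa_ir, 1)
  expect_equal(p$leptin_adiponectin_ratio, 2)
  expect_equal(compute_metabolic_panel(100, 0)$homa_ir, 0)
  expect_warning(z <- compute_metabolic_panel(90, 5, leptin = 6,
                                              adiponectin = 0),
                 "undefined")
  expect_true(is.na(z$leptin_adiponectin_ratio))
  expect_equal(z$homa_ir, 90 * 5 / 400)
  expect_error(compute_metabolic_panel(-1, 5), "nonnegative")
})
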