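test_that("coefficient of variation follows the sample-SD definition", {
  # hand oracle: values (1,2,3,10): mean 4, sample SD sqrt(50/3) -> CV 1.0206
  vals <- rbind(c(1, 2, 3, 10),
                c(5, 5, 5, 5))
  x <- tiny_matrix(vals)
  annot <- tiny_annot(colnames(x), c("control", "control", "case", "case"))
  sig <- signature_def(rownames(x), c(1L, 1L))
  res <- filter_signature_genes(x, annot, sig, cv_min = 0.5, fdr_max = 1)
  expect_equal(res$cv[1], sqrt(50 / 3) / 4, tolerance = 1e-12)
  expect_equal(res$cv[2], 0)
  expect_false(res$kept[2])        # constant gene: CV 0, never kept
  expect_true(res$cv[1] > 0.5)
})

test_that("filter applies the CV AND FDR conjunction with BH over tested genes", {
  set.seed(42)
  n <- 40
  vals <- rbind(matrix(rnorm(20 * n, mean = 2), 20, n),  # null genes
                matrix(rnorm(5 * n, mean = 2), 5, n))
  vals[21:25, 21:n] <- vals[21:25, 21:n] + 5             # shifted in cases
  x <- tiny_matrix(vals)
  annot <- tiny_annot(colnames(x), rep(c("control", "case"), each = 20))
  sig <- signature_def(rownames(x), rep(1L, 25))
  res <- filter_signature_genes(x, annot, sig, cv_min = 0.0, fdr_max = 0.05)
  expect_true(all(res$kept[21:25]))
  # q-values are the monotone BH transform of the p-values
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  # permissive thresholds keep every tested non-degenerate gene
  all_kept <- filter_signature_genes(x, annot, sig, cv_min = 0,
                                     fdr_max = 1 + 1e-9)
  expect_true(all(all_kept$kept))
})

test_that("filter handles degenerate genes and bad designs", {
  vals <- rbind(c(-1, 1, -1, 1), c(1, 2, 3, 4))
  x <- tiny_matrix(vals)
  annot <- tiny_annot(colnames(x), c("control", "control", "case", "case"))
  sig <- signature_def(rownames(x), c(1L, 1L))
  res <- filter_signature_genes(x, annot, sig)
  expect_true(is.na(res$cv[1]))                 # zero mean -> CV undefined
  expect_match(res$reason[1], "zero mean")
  expect_false(res$kept[1])

  one_ctrl <- tiny_annot(colnames(x), c("control", "case", "case", "case"))
  expect_error(filter_signature_genes(x, one_ctrl, sig), "at least 2")

  sig_extra <- signature_def(c(rownames(x), "ghost"), c(1L, 1L, 1L))
  expect_warning(res2 <- filter_signature_genes(x, annot, sig_extra),
                 "absent")
  expect_equal(nrow(res2), 2L)
  expect_equal(attr(res2, "missing_genes"), "ghost")
})

test_that("control reference holds control-only means and n-1 SDs", {
  vals <- rbind(c(1, 3, 100), c(2, 2, 50))
  x <- tiny_matrix(vals)
  annot <- tiny_annot(colnames(x), c("control", "control", "case"))
  expect_warning(ref <- build_control_reference(x, annot, rownames(x)),
                 NA)
  expect_equal(ref$gene_id, "g1")               # g2 has zero control SD
  expect_equal(ref$mean_ctr, 2)
  expect_equal(ref$sd_ctr, sqrt(2))
  expect_equal(attr(ref, "excluded")$gene_id, "g2")
  expect_match(attr(ref, "excluded")$reason, "zero control SD")

  expect_error(build_control_reference(x, annot, "g2"),
               "no scoreable genes")

  # control-only matrix: reference means are the per-gene row means
  set.seed(1)
  xc <- tiny_matrix(matrix(rnorm(12), 3, 4))
  ac <- tiny_annot(colnames(xc), rep("control", 4))
  refc <- build_control_reference(xc, ac, rownames(xc))
  expect_equal(refc$mean_ctr, unname(rowMeans(unclass(xc))))
})

test_that("toy worked example matches the hand-computed z-sum", {
  # g1 (k=+1, controls 1,3), g2 (k=-1, controls 0,2); case (g1=4, g2=-1)
  vals <- rbind(c(1, 3, 4), c(0, 2, -1))
  x <- tiny_matrix(vals)
  annot <- tiny_annot(colnames(x), c("control", "control", "case"))
  sig <- signature_def(c("g1", "g2"), c(1L, -1L))
  ref <- build_control_reference(x, annot, c("g1", "g2"))
  sv <- compute_signature_score(x, annot, sig, ref)
  expect_equal(sv$raw_score, c(0, 0, 2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(attr(sv, "control_mean_raw"), 0)
  expect_equal(sv$score[3], 2 * sqrt(2), tolerance = 1e-12)
})

test_that("vectorized score equals the double-loop oracle on random problems", {
  set.seed(99)
  for (rep in 1:25) {
    prob <- random_score_problem(sample(2:10, 1), sample(5:10, 1), 3)
    sv <- compute_signature_score(prob$x, prob$annot, prob$sig, prob$ref)
    oracle <- score_oracle(prob$x, prob$annot, prob$sig, prob$ref)
    expect_equal(sv$score, unname(oracle[sv$sample_id]),
                 tolerance = 1e-10)
  }
})

test_that("controls are centred at zero and k-flips negate every score", {
  set.seed(5)
  prob <- random_score_problem(6, 9, 4)
  sv <- compute_signature_score(prob$x, prob$annot, prob$sig, prob$ref)
  expect_equal(mean(sv$score[sv$group == "control"]), 0, tolerance = 1e-12)

  flipped <- signature_def(prob$sig$gene_id, -prob$sig$k)
  sv2 <- compute_signature_score(prob$x, prob$annot, flipped, prob$ref)
  expect_equal(sv2$raw_score, -sv$raw_score, tolerance = 1e-12)
  expect_equal(sv2$score, -sv$score, tolerance = 1e-12)

  none <- compute_signature_score(prob$x, prob$annot, prob$sig, prob$ref,
                                  normalize = "none")
  expect_equal(none$score, none$raw_score)
})

test_that("scores are invariant to per-gene affine rescaling of the input", {
  set.seed(13)
  prob <- random_score_problem(5, 8, 3)
  sv <- compute_signature_score(prob$x, prob$annot, prob$sig, prob$ref)
  vals <- unclass(prob$x)
  vals[2, ] <- 7.3 + vals[2, ] * 2.9     # shift + positive scale, all samples
  x2 <- tiny_matrix(vals, rownames(prob$x), colnames(prob$x))
  ref2 <- build_control_reference(x2, prob$annot, rownames(x2))
  sv2 <- compute_signature_score(x2, prob$annot, prob$sig, ref2)
  expect_equal(sv2$score, sv$score, tolerance = 1e-8)
})

test_that("raising a gene in one case sample moves its score by k's sign", {
  set.seed(21)
  prob <- random_score_problem(4, 8, 3)
  sig <- signature_def(prob$sig$gene_id, c(1L, 1L, -1L, -1L))
  sv <- compute_signature_score(prob$x, prob$annot, sig, prob$ref)
  for (g in c(1, 3)) {
    vals <- unclass(prob$x)
    vals[g, 8] <- vals[g, 8] + 2
    xb <- tiny_matrix(vals, rownames(prob$x), colnames(prob$x))
    svb <- compute_signature_score(xb, prob$annot, sig, prob$ref)
    if (sig$k[g] == 1L) expect_gt(svb$score[8], sv$score[8])
    else expect_lt(svb$score[8], sv$score[8])
    # a case-sample perturbation leaves every other sample's score alone
    expect_equal(svb$score[-8], sv$score[-8], tolerance = 1e-12)
  }
})

test_that("scoring rejects inconsistent inputs", {
  prob <- random_score_problem(3, 6, 3)
  bad_annot <- prob$annot[-1, ]
  expect_error(compute_signature_score(prob$x, bad_annot, prob$sig,
                                       prob$ref), "absent from annotation")
  sig_short <- signature_def(prob$sig$gene_id[1], prob$sig$k[1])
  expect_error(compute_signature_score(prob$x, prob$annot, sig_short,
                                       prob$ref), "direction weight")
  ref_empty <- prob$ref[0, ]
  expect_error(compute_signature_score(prob$x, prob$annot, prob$sig,
                                       ref_empty), "empty retained")
})
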