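# shared fixture builders; everything is generated in code

tiny_matrix <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, gene_ids = genes, sample_ids = samples)
}

tiny_annot <- function(sample_ids, groups, mrss = NA_real_) {
  sample_annotation(data.frame(sample_id = sample_ids, group = groups,
                               mrss = mrss, stringsAsFactors = FALSE))
}

# random small scoring problem: matrix + annotation + signature + reference
random_score_problem <- function(n_genes, n_samples, n_ctrl) {
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  x <- tiny_matrix(vals)
  annot <- tiny_annot(colnames(x),
                      rep(c("control", "case"),
                          c(n_ctrl, n_samples - n_ctrl)))
  sig <- signature_def(rownames(x),
                       sample(c(1L, -1L), n_genes, replace = TRUE))
  ref <- build_control_reference(x, annot, rownames(x))
  list(x = x, annot = annot, sig = sig, ref = ref)
}

# independent double-loop oracle for the direction-weighted z-sum score
score_oracle <- function(x, annot, sig, ref) {
  kmap <- setNames(sig$k, sig$gene_id)
  raw <- numeric(ncol(x))
  names(raw) <- colnames(x)
  for (s in seq_len(ncol(x))) {
    acc <- 0
    for (i in seq_len(nrow(ref))) {
      g <- ref$gene_id[i]
      acc <- acc + kmap[[g]] *
        (unclass(x)[g, s] - ref$mean_ctr[i]) / ref$sd_ctr[i]
    }
    raw[s] <- acc
  }
  ctrl <- annot$sample_id[annot$group == "control"]
  raw - mean(raw[names(raw) %in% ctrl])
}

# brute-force Pearson chi-square on a contingency table
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# rank-then-Pearson Spearman oracle (average ranks for ties)
spearman_oracle <- function(a, b) {
  stats::cor(rank(a, ties.method = "average"),
             rank(b, ties.method = "average"), method = "pearson")
}

# build a cluster_assignment by hand (for contingency tests)
manual_assignment <- function(sample_ids, clusters) {
  structure(list(assignment = data.frame(sample_id = sample_ids,
                                         cluster = clusters,
                                         stringsAsFactors = FALSE),
                 n_clusters = length(unique(clusters)),
                 distance_name = "manual", linkage_name = "manual",
                 panel_genes = character(0)),
            class = "cluster_assignment")
}
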