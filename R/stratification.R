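#' Hierarchically cluster samples on a gene panel
#'
#' Samples are clustered on the panel genes after per-gene z-scoring
#' over all samples. The default geometry is the transcriptome-heatmap
#' convention: distance = 1 - Pearson correlation between sample
#' profiles, average linkage; both are configurable. The tree is cut to
#' exactly `n_clusters` and labels are renumbered 1..k by decreasing
#' cluster size (ties broken by the smallest member sample id), so the
#' labelling is deterministic.
#'
#' Panel genes absent from the matrix, and genes with zero variance
#' across samples, are dropped with a warning. In the fully degenerate
#' case where every panel gene is constant (all samples identical over
#' the panel) an all-zero distance matrix is used so the cut is still
#' deterministic.
#'
#' @param x an [expression_matrix()].
#' @param panel character vector of panel gene ids.
#' @param n_clusters number of clusters (default 3; must not exceed the
#'   number of samples).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage an [stats::hclust()] agglomeration method, default
#'   `"average"`.
#' @return a list of class `cluster_assignment`: `assignment`
#'   (data.frame sample_id, cluster), `n_clusters`, `distance_name`,
#'   `linkage_name`, `panel_genes` (genes actually used).
#' @export
cluster_samples <- function(x, panel, n_clusters = 3L,
                            distance = c("correlation", "euclidean"),
                            linkage = "average") {
  distance <- match.arg(distance)
  panel <- as.character(panel)
  absent <- setdiff(panel, rownames(x))
  if (length(absent) > 0L) {
    warning(sprintf("%d panel gene(s) absent from matrix, dropped",
                    length(absent)), call. = FALSE)
  }
  panel <- intersect(panel, rownames(x))
  if (length(panel) == 0L) stop("panel empty after dropping absent genes",
                                call. = FALSE)
  n <- ncol(x)
  if (n_clusters < 1L || n_clusters > n) {
    stop("n_clusters must be between 1 and the number of samples",
         call. = FALSE)
  }
  vals <- unclass(x)[panel, , drop = FALSE]
  sdv <- apply(vals, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning(sprintf("%d zero-variance panel gene(s) dropped", sum(sdv == 0)),
            call. = FALSE)
  }
  used <- panel[sdv > 0]
  if (length(used) == 0L) {
    # all samples identical over the panel: zero geometry, deterministic cut
    d <- stats::as.dist(matrix(0, n, n,
                               dimnames = list(colnames(x), colnames(x))))
    used <- character(0)
  } else {
    z <- (vals[used, , drop = FALSE] - rowMeans(vals[used, , drop = FALSE])) /
      sdv[sdv > 0]
    if (distance == "correlation") {
      if (length(used) < 2L) {
        stop("correlation distance needs at least 2 non-constant panel genes; use euclidean",
             call. = FALSE)
      }
      cm <- suppressWarnings(stats::cor(z))
      if (anyNA(cm)) {
        stop("sample profile(s) constant over the panel: correlation distance undefined",
             call. = FALSE)
      }
      d <- stats::as.dist(1 - cm)
    } else {
      d <- stats::dist(t(z))
    }
  }
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = n_clusters)
  labels <- .renumber_clusters(labels, colnames(x))
  structure(list(assignment = data.frame(sample_id = colnames(x),
                                         cluster = unname(labels),
                                         stringsAsFactors = FALSE),
                 n_clusters = as.integer(n_clusters),
                 distance_name = distance,
                 linkage_name = linkage,
                 panel_genes = used),
            class = "cluster_assignment")
}

# relabel 1..k by decreasing size; ties by smallest member sample id
.renumber_clusters <- function(labels, sample_ids) {
  sizes <- table(labels)
  min_id <- vapply(names(sizes), function(l) {
    min(sample_ids[labels == as.integer(l)])
  }, character(1))
  ord <- order(-as.integer(sizes), min_id)
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  stats::setNames(as.integer(remap[as.character(labels)]), sample_ids)
}

#' Chi-square test of cluster-by-group association
#'
#' Builds the clusters x diagnosis-groups contingency table and applies
#' the Pearson chi-square test without continuity correction, with
#' (r-1)(c-1) degrees of freedom — the test used to ask whether
#' unsupervised transcriptome clusters discriminate cases from
#' controls. Expected counts below 5 trigger a warning but do not
#' block the test.
#'
#' @param assignment a [cluster_samples()] result.
#' @param annot a [sample_annotation()] covering every clustered sample.
#' @return a list of class `contingency_result`: `table` (clusters x
#'   groups), `chi_square`, `df`, `p_value`, `expected`.
#' @export
cluster_group_chisq <- function(assignment, annot) {
  annot <- sample_annotation(annot)
  df <- assignment$assignment
  idx <- match(df$sample_id, annot$sample_id)
  if (anyNA(idx)) {
    stop("clustered sample(s) absent from annotation: ",
         paste(utils::head(df$sample_id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  group <- annot$group[idx]
  missing_grp <- setdiff(.valid_groups, unique(group))
  if (length(missing_grp) > 0L) {
    stop("group(s) entirely absent: ", paste(missing_grp, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(cluster = df$cluster, group = factor(group, .valid_groups))
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("expected count(s) below 5 in the contingency table",
            call. = FALSE)
  }
  structure(list(table = tab,
                 chi_square = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 expected = res$expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.3f, df = %d, p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
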