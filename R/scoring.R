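#' Filter signature genes by variability and differential expression
#'
#' Applies the two-part signature filter: a gene is retained when its
#' coefficient of variation across all samples exceeds `cv_min` AND its
#' case-vs-control differential-expression q-value (Benjamini-Hochberg,
#' adjusted over exactly the tested signature genes) is below `fdr_max`.
#' CV is sd/|mean| over all samples (cases and controls pooled), sample
#' sd with divisor n-1. The differential test defaults to a two-sided
#' Welch two-sample t-test on the input scale; a Wilcoxon rank-sum test
#' can be substituted.
#'
#' Signature genes absent from the matrix are skipped and recorded; a
#' gene whose overall mean is exactly zero has an undefined CV and is
#' dropped with a reason rather than raising an error. A gene constant
#' within both groups carries no evidence against the null and is
#' assigned p = 1.
#'
#' @param x an [expression_matrix()].
#' @param annot a [sample_annotation()] covering the matrix samples.
#' @param signature a [signature_def()].
#' @param cv_min CV threshold (default 0.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return a data.frame of class `filter_result` with one row per tested
#'   gene: `gene_id`, `k`, `cv`, `p_value`, `q_value`, `kept`, `reason`;
#'   attributes `cv_min`, `fdr_max`, `test`, `missing_genes`.
#' @export
filter_signature_genes <- function(x, annot, signature,
                                   cv_min = 0.5, fdr_max = 0.05,
                                   test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  annot <- sample_annotation(annot)
  idx <- .match_samples(x, annot)
  ctrl <- colnames(x)[annot$group[idx] == "control"]
  case <- colnames(x)[annot$group[idx] == "case"]
  if (length(ctrl) < 2L || length(case) < 2L) {
    stop(sprintf("need at least 2 samples per group (control: %d, case: %d)",
                 length(ctrl), length(case)), call. = FALSE)
  }
  present <- signature$gene_id %in% rownames(x)
  missing_genes <- signature$gene_id[!present]
  if (length(missing_genes) > 0L) {
    warning(sprintf("%d signature gene(s) absent from matrix, skipped: %s",
                    length(missing_genes),
                    paste(utils::head(missing_genes, 5L), collapse = ", ")),
            call. = FALSE)
  }
  sig <- signature[present, , drop = FALSE]
  if (nrow(sig) == 0L) {
    stop("no signature genes present in the matrix", call. = FALSE)
  }
  vals <- unclass(x)[sig$gene_id, , drop = FALSE]
  m <- rowMeans(vals)
  s <- apply(vals, 1L, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / abs(m))
  p <- vapply(seq_len(nrow(vals)), function(i) {
    a <- vals[i, case]
    b <- vals[i, ctrl]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # no within-group variability: the location test is undefined;
      # when the group means also coincide there is no evidence at all
      if (mean(a) == mean(b)) return(1.0)
      return(0.0)
    }
    if (test == "welch") {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  kept <- !is.na(cv) & cv > cv_min & q < fdr_max
  reason <- rep(NA_character_, nrow(sig))
  reason[is.na(cv)] <- "CV undefined (zero mean)"
  reason[!is.na(cv) & cv <= cv_min] <- "CV below threshold"
  fail_fdr <- !is.na(cv) & cv > cv_min & q >= fdr_max
  reason[fail_fdr] <- "FDR above threshold"
  out <- data.frame(gene_id = sig$gene_id, k = sig$k, cv = cv,
                    p_value = p, q_value = q, kept = kept,
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "cv_min") <- cv_min
  attr(out, "fdr_max") <- fdr_max
  attr(out, "test") <- test
  attr(out, "missing_genes") <- missing_genes
  class(out) <- c("filter_result", "data.frame")
  out
}

#' Build a control reference (per-gene control mean and SD)
#'
#' The standardization baseline of the signature score: per-gene mean
#' and sample standard deviation (divisor n-1) computed over control
#' samples only. Genes with zero control SD are excluded and reported,
#' never imputed, because the z-score is undefined for them.
#'
#' @param x an [expression_matrix()].
#' @param annot a [sample_annotation()].
#' @param genes gene ids to include (must be present in the matrix).
#' @return a data.frame of class `control_reference` with columns
#'   `gene_id`, `mean_ctr`, `sd_ctr`; excluded genes in attribute
#'   `excluded` (data.frame gene_id, reason).
#' @export
build_control_reference <- function(x, annot, genes) {
  annot <- sample_annotation(annot)
  idx <- .match_samples(x, annot)
  ctrl <- colnames(x)[annot$group[idx] == "control"]
  if (length(ctrl) < 2L) {
    stop("need at least 2 control samples to build a reference",
         call. = FALSE)
  }
  genes <- as.character(genes)
  absent <- setdiff(genes, rownames(x))
  if (length(absent) > 0L) {
    stop("requested gene(s) absent from matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  vals <- unclass(x)[genes, ctrl, drop = FALSE]
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1L, stats::sd)
  zero <- sdv == 0
  excluded <- data.frame(gene_id = genes[zero],
                         reason = rep("zero control SD", sum(zero)),
                         stringsAsFactors = FALSE)
  if (all(zero)) stop("no scoreable genes: every requested gene has zero control SD",
                      call. = FALSE)
  out <- data.frame(gene_id = genes[!zero], mean_ctr = mu[!zero],
                    sd_ctr = sdv[!zero], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "control_samples") <- ctrl
  class(out) <- c("control_reference", "data.frame")
  out
}

#' Compute the per-sample direction-weighted signature score
#'
#' For each sample the raw score is the sum over retained signature
#' genes of `k_i * (expr_i - mean_ctr_i) / sd_ctr_i`, i.e. a per-gene
#' z-score against the control reference, weighted by the gene's
#' direction k (+1 induced, -1 suppressed) and summed. Scores are then
#' normalized to the mean of the controls by subtracting the mean raw
#' score of the control samples, so controls are centred at zero.
#'
#' @param x an [expression_matrix()].
#' @param annot a [sample_annotation()]; every matrix sample must be
#'   annotated.
#' @param signature a [signature_def()] providing the k weight for every
#'   scored gene.
#' @param reference a [build_control_reference()] result; its genes
#'   define the retained gene set and must be a subset of the matrix and
#'   of the signature.
#' @param normalize `"subtract"` (default; centre on the control mean)
#'   or `"none"` (report raw sums).
#' @return a data.frame of class `score_vector` with columns
#'   `sample_id`, `group`, `raw_score`, `score` (the normalized score);
#'   attributes `control_mean_raw`, `genes_used`, `genes_dropped`,
#'   `normalize`.
#' @export
compute_signature_score <- function(x, annot, signature, reference,
                                    normalize = c("subtract", "none")) {
  normalize <- match.arg(normalize)
  annot <- sample_annotation(annot)
  idx <- .match_samples(x, annot)
  genes <- reference$gene_id
  if (length(genes) == 0L) stop("empty retained gene set", call. = FALSE)
  absent <- setdiff(genes, rownames(x))
  if (length(absent) > 0L) {
    stop("reference gene(s) absent from matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  kmap <- stats::setNames(signature$k, signature$gene_id)
  no_k <- setdiff(genes, names(kmap))
  if (length(no_k) > 0L) {
    stop("scored gene(s) without a direction weight in the signature: ",
         paste(utils::head(no_k, 5L), collapse = ", "), call. = FALSE)
  }
  k <- as.numeric(kmap[genes])
  z <- (unclass(x)[genes, , drop = FALSE] - reference$mean_ctr) /
    reference$sd_ctr
  raw <- as.numeric(colSums(z * k))
  names(raw) <- colnames(x)
  ctrl <- annot$group[idx] == "control"
  if (!any(ctrl)) stop("no control samples to normalize against",
                       call. = FALSE)
  control_mean_raw <- mean(raw[ctrl])
  score <- if (normalize == "subtract") raw - control_mean_raw else raw
  out <- data.frame(sample_id = colnames(x), group = annot$group[idx],
                    raw_score = raw, score = score, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "control_mean_raw") <- control_mean_raw
  attr(out, "genes_used") <- genes
  attr(out, "genes_dropped") <- attr(reference, "excluded")
  attr(out, "normalize") <- normalize
  attr(out, "signature") <- attr(signature, "name")
  class(out) <- c("score_vector", "data.frame")
  out
}

# every matrix sample must appear in the annotation; returns the row
# index of annot for each matrix column, in column order
.match_samples <- function(x, annot) {
  idx <- match(colnames(x), annot$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) in matrix absent from annotation: ",
         paste(utils::head(colnames(x)[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  idx
}
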