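#' Correlate a score vector with another score or clinical covariate
#'
#' Pairs two per-sample vectors by sample id, drops pairs with a
#' missing value (counting them), and reports the correlation
#' coefficient with a two-sided p-value (t-approximation for Pearson;
#' the rank method used by [stats::cor.test()] for Spearman). Pearson
#' is the default for score-score and score-MRSS associations.
#'
#' @param x,y [compute_signature_score()] results, or numeric vectors
#'   named by sample id.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a list of class `association_result`: `method`, `r`,
#'   `p_value`, `n` (complete pairs), `n_dropped`.
#' @export
correlate_scores <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- .as_named_scores(x, "x")
  y <- .as_named_scores(y, "y")
  common <- intersect(names(x), names(y))
  if (length(common) == 0L) stop("no samples shared between x and y",
                                 call. = FALSE)
  xv <- x[common]
  yv <- y[common]
  keep <- !is.na(xv) & !is.na(yv)
  n_dropped <- sum(!keep)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3L) {
    stop("fewer than 3 complete pairs after dropping missing values",
         call. = FALSE)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in x or y: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = method,
                                         alternative = "two.sided",
                                         exact = FALSE))
  structure(list(method = method,
                 r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = length(xv),
                 n_dropped = n_dropped),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s R = %.3f, p = %.3g, n = %d\n", x$method, x$r,
              x$p_value, x$n))
  invisible(x)
}

.as_named_scores <- function(v, what) {
  if (inherits(v, "score_vector")) {
    return(stats::setNames(v$score, v$sample_id))
  }
  if (is.data.frame(v) && all(c("sample_id", "score") %in% colnames(v))) {
    return(stats::setNames(v$score, v$sample_id))
  }
  if (is.numeric(v)) {
    if (is.null(names(v))) {
      stop(what, " must be named by sample id (or be a score_vector)",
           call. = FALSE)
    }
    return(v)
  }
  stop(what, " must be a score_vector or a named numeric vector",
       call. = FALSE)
}

#' Compare scores between two clinical subgroups
#'
#' Splits the scored samples by an annotation field (e.g. disease
#' subtype or disease-duration class), requires exactly two nonempty
#' groups after dropping "n/a" entries, and applies the two-sided
#' Wilcoxon-Mann-Whitney rank-sum test — the conventional
#' distribution-free two-group comparison for pathway scores.
#'
#' @param scores a [compute_signature_score()] result or named numeric
#'   vector.
#' @param annot a [sample_annotation()].
#' @param split_by annotation column to split on: `"subtype"`,
#'   `"duration_class"` or `"group"`.
#' @param groups optional pair of category labels to compare; samples in
#'   other categories are excluded (e.g. `c("diffuse", "limited")` when
#'   a third subtype is present).
#' @return a list of class `group_comparison_result`: `group_labels`,
#'   `n_per_group`, `statistic` (rank-sum W), `p_value`, `method`.
#' @export
compare_groups <- function(scores, annot,
                           split_by = c("subtype", "duration_class",
                                        "group"),
                           groups = NULL) {
  split_by <- match.arg(split_by)
  annot <- sample_annotation(annot)
  s <- .as_named_scores(scores, "scores")
  idx <- match(names(s), annot$sample_id)
  if (anyNA(idx)) {
    stop("scored sample(s) absent from annotation", call. = FALSE)
  }
  lab <- annot[[split_by]][idx]
  keep <- !is.na(lab) & lab != "n/a" & !is.na(s)
  if (!is.null(groups)) {
    if (length(groups) != 2L) stop("groups must name exactly 2 categories",
                                   call. = FALSE)
    keep <- keep & lab %in% groups
  }
  s <- s[keep]
  lab <- lab[keep]
  cats <- sort(unique(lab))
  if (length(cats) != 2L) {
    stop("need exactly 2 nonempty groups to compare; found: ",
         if (length(cats)) paste(cats, collapse = ", ") else "none",
         call. = FALSE)
  }
  a <- s[lab == cats[1L]]
  b <- s[lab == cats[2L]]
  wt <- suppressWarnings(stats::wilcox.test(a, b,
                                            alternative = "two.sided"))
  structure(list(group_labels = cats,
                 n_per_group = c(length(a), length(b)),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = "Wilcoxon-Mann-Whitney"),
            class = "group_comparison_result")
}

#' @export
print.group_comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d), W = %g, p = %.3g\n",
              x$method, x$group_labels[1L], x$n_per_group[1L],
              x$group_labels[2L], x$n_per_group[2L], x$statistic,
              x$p_value))
  invisible(x)
}

#' Summarize a cohort annotation table
#'
#' Counts and percentages (one decimal) for each categorical field, and
#' mean +/- SD for continuous fields (MRSS, plus any extra numeric
#' columns such as age). Missing values form their own category, so
#' category percentages always sum to 100 (up to rounding).
#'
#' @param annot a [sample_annotation()] (extra columns are summarized
#'   too: character/factor columns as categories, numeric as mean/SD).
#' @return a list of class `cohort_summary`: `n_total`, `categorical`
#'   (named list of data.frames with level, count, pct), `continuous`
#'   (named list with mean, sd, n).
#' @export
summarize_cohort <- function(annot) {
  annot <- sample_annotation(annot)
  if (nrow(annot) == 0L) stop("annotation table is empty", call. = FALSE)
  n_total <- nrow(annot)
  skip <- "sample_id"
  categorical <- list()
  continuous <- list()
  for (col in setdiff(colnames(annot), skip)) {
    v <- annot[[col]]
    if (is.numeric(v)) {
      ok <- !is.na(v)
      continuous[[col]] <- list(mean = if (any(ok)) mean(v[ok]) else NA_real_,
                                sd = if (sum(ok) > 1L) stats::sd(v[ok]) else NA_real_,
                                n = sum(ok))
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "missing"
      tab <- table(v)
      categorical[[col]] <- data.frame(
        level = names(tab),
        count = as.integer(tab),
        pct = round(100 * as.integer(tab) / n_total, 1L),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(n_total = n_total, categorical = categorical,
                 continuous = continuous),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort of %d samples\n", x$n_total))
  for (nm in names(x$categorical)) {
    tab <- x$categorical[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s %d (%.1f%%)", tab$level, tab$count,
                              tab$pct), collapse = ", ")))
  }
  for (nm in names(x$continuous)) {
    s <- x$continuous[[nm]]
    cat(sprintf("  %s: %.1f +/- %.1f (n = %d)\n", nm, s$mean, s$sd, s$n))
  }
  invisible(x)
}

#' Compute a metabolic panel (HOMA-IR and leptin/adiponectin ratio)
#'
#' HOMA-IR (homeostatic model assessment of insulin resistance) is
#' `glucose * insulin / 400`, with glucose in mg/dL and insulin in
#' uU/mL as supplied. The leptin/adiponectin ratio, a marker of adipose
#' tissue health, is defined only for adiponectin > 0; when adiponectin
#' is zero the ratio is reported as NA and HOMA-IR is still computed.
#'
#' @param glucose,insulin nonnegative fasting serum values.
#' @param leptin,adiponectin nonnegative adipokine levels (optional,
#'   `NA` by default).
#' @return a list of class `metabolic_panel` with the inputs plus
#'   `homa_ir` and `leptin_adiponectin_ratio`.
#' @export
compute_metabolic_panel <- function(glucose, insulin, leptin = NA_real_,
                                    adiponectin = NA_real_) {
  for (v in list(glucose = glucose, insulin = insulin)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("glucose and insulin must be single nonnegative numbers",
           call. = FALSE)
    }
  }
  if (!is.na(leptin) && leptin < 0) stop("leptin must be nonnegative",
                                         call. = FALSE)
  if (!is.na(adiponectin) && adiponectin < 0) {
    stop("adiponectin must be nonnegative", call. = FALSE)
  }
  homa_ir <- glucose * insulin / 400
  ratio <- NA_real_
  if (!is.na(leptin) && !is.na(adiponectin)) {
    if (adiponectin > 0) {
      ratio <- leptin / adiponectin
    } else {
      warning("adiponectin is 0: leptin/adiponectin ratio undefined",
              call. = FALSE)
    }
  }
  structure(list(glucose = glucose, insulin = insulin, leptin = leptin,
                 adiponectin = adiponectin, homa_ir = homa_ir,
                 leptin_adiponectin_ratio = ratio),
            class = "metabolic_panel")
}
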