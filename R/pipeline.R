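#' Build and validate a pipeline run configuration
#'
#' Collects all inputs and stage parameters of a full
#' filter -> score -> cluster -> associate run. Inputs may be given as
#' file paths (TSV matrix/annotation/signatures, GMT gene sets) or as
#' in-memory objects; referenced files are checked at validation time.
#'
#' @param matrix an [expression_matrix()] or path to a matrix TSV.
#' @param annot a [sample_annotation()] or path to an annotation TSV.
#' @param signatures a named list of [signature_def()] objects or file
#'   paths; the first (or `primary`) signature is the one filtered and
#'   used as the clustering panel.
#' @param primary name of the primary signature (default: the first).
#' @param gene_sets optional [gene_set_collection()] or GMT path, for
#'   the coexpression-module stage.
#' @param anchor optional anchor gene id; when given together with
#'   `gene_sets`, a coexpression module is derived.
#' @param module_sets set names to intersect the module with (default:
#'   all).
#' @param cv_min,fdr_max signature filter thresholds (defaults 0.5,
#'   0.05).
#' @param apply_filter apply the CV/FDR filter to the primary signature
#'   (default TRUE); when FALSE all signature genes are scored.
#' @param test differential test for the filter (`"welch"` or
#'   `"wilcoxon"`).
#' @param normalize score normalization mode (`"subtract"` or
#'   `"none"`).
#' @param r_threshold,max_candidates coexpression-module parameters
#'   (defaults 0.5, 400).
#' @param n_clusters,distance,linkage clustering parameters (defaults
#'   3, correlation, average).
#' @param cor_method correlation method for the association stage
#'   (default `"pearson"`).
#' @param out_dir optional output directory; when given, all stage
#'   outputs plus a JSON report are written there.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, annot, signatures, primary = NULL,
                            gene_sets = NULL, anchor = NULL,
                            module_sets = NULL,
                            cv_min = 0.5, fdr_max = 0.05,
                            apply_filter = TRUE,
                            test = "welch",
                            normalize = "subtract",
                            r_threshold = 0.5, max_candidates = 400L,
                            n_clusters = 3L, distance = "correlation",
                            linkage = "average",
                            cor_method = "pearson",
                            out_dir = NULL) {
  for (p in c(if (is.character(matrix)) matrix,
              if (is.character(annot)) annot,
              unlist(Filter(is.character, signatures)),
              if (is.character(gene_sets)) gene_sets)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (length(signatures) == 0L) stop("at least one signature is required",
                                     call. = FALSE)
  if (is.null(names(signatures)) || any(names(signatures) == "")) {
    stop("signatures must be a named list", call. = FALSE)
  }
  if (is.null(primary)) primary <- names(signatures)[1L]
  if (!primary %in% names(signatures)) {
    stop("primary signature '", primary, "' not among the signatures",
         call. = FALSE)
  }
  stopifnot(cv_min >= 0, fdr_max > 0, fdr_max <= 1,
            r_threshold >= -1, r_threshold <= 1,
            max_candidates >= 1, n_clusters >= 1)
  structure(list(matrix = matrix, annot = annot, signatures = signatures,
                 primary = primary, gene_sets = gene_sets,
                 anchor = anchor, module_sets = module_sets,
                 params = list(cv_min = cv_min, fdr_max = fdr_max,
                               apply_filter = apply_filter, test = test,
                               normalize = normalize,
                               r_threshold = r_threshold,
                               max_candidates = as.integer(max_candidates),
                               n_clusters = as.integer(n_clusters),
                               distance = distance, linkage = linkage,
                               cor_method = cor_method),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; file
#' paths are resolved relative to the YAML file's directory.
#'
#' @param path path to the YAML config.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  cfg$matrix <- rel(cfg$matrix)
  cfg$annot <- rel(cfg$annot)
  cfg$gene_sets <- rel(cfg$gene_sets)
  if (!is.null(cfg$signatures)) cfg$signatures <- lapply(cfg$signatures, rel)
  do.call(pipeline_config, cfg)
}

#' Run the full scoring, stratification and association pipeline
#'
#' Executes, in order: the CV/FDR filter on the primary signature;
#' control-reference construction and per-sample score computation for
#' every signature; hierarchical clustering of samples on the primary
#' panel with a chi-square test of cluster-by-group association; the
#' optional anchor-gene coexpression module; pairwise score-score
#' correlations and each score's correlation with MRSS; and two-group
#' score comparisons by disease subtype (diffuse vs limited) and
#' duration class. Any stage failure aborts the run naming the stage.
#' The run is fully deterministic: identical config and inputs give an
#' identical report.
#'
#' @param config a [pipeline_config()] or path to a YAML config file.
#' @return a list of class `run_report` echoing the parameters and
#'   holding every stage result; written (with TSV side outputs) to
#'   `out_dir` as `report.json` when an output directory is configured.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  x <- stage("load_matrix", {
    if (is.character(config$matrix)) read_expression_matrix(config$matrix)
    else config$matrix
  })
  annot <- stage("load_annotation", {
    if (is.character(config$annot)) read_sample_annotation(config$annot)
    else sample_annotation(config$annot)
  })
  sigs <- stage("load_signatures", {
    lapply(stats::setNames(names(config$signatures),
                           names(config$signatures)), function(nm) {
      s <- config$signatures[[nm]]
      if (is.character(s)) read_signature(s, name = nm) else s
    })
  })
  gsets <- stage("load_gene_sets", {
    gs <- config$gene_sets
    if (is.character(gs)) read_gmt(gs) else gs
  })
  p <- config$params

  filter_res <- NULL
  panels <- lapply(sigs, function(s) s$gene_id)
  if (isTRUE(p$apply_filter)) {
    filter_res <- stage("filter", {
      filter_signature_genes(x, annot, sigs[[config$primary]],
                             cv_min = p$cv_min, fdr_max = p$fdr_max,
                             test = p$test)
    })
    panels[[config$primary]] <- filter_res$gene_id[filter_res$kept]
    if (length(panels[[config$primary]]) == 0L) {
      stop("stage 'filter' failed: no primary-signature genes survive the filter",
           call. = FALSE)
    }
  }

  scores <- stage("score", {
    lapply(stats::setNames(names(sigs), names(sigs)), function(nm) {
      genes <- intersect(panels[[nm]], rownames(x))
      ref <- build_control_reference(x, annot, genes)
      compute_signature_score(x, annot, sigs[[nm]], ref,
                              normalize = p$normalize)
    })
  })

  clustering <- stage("cluster", {
    cl <- cluster_samples(x, panels[[config$primary]],
                          n_clusters = p$n_clusters,
                          distance = p$distance, linkage = p$linkage)
    list(assignment = cl, contingency = cluster_group_chisq(cl, annot))
  })

  module <- NULL
  if (!is.null(config$anchor)) {
    module <- stage("module", {
      derive_module(x, config$anchor, gene_sets = gsets,
                    set_names = config$module_sets,
                    r_threshold = p$r_threshold,
                    max_candidates = p$max_candidates)
    })
  }

  associations <- stage("associate", {
    out <- list()
    nms <- names(scores)
    if (length(nms) > 1L) {
      for (i in seq_len(length(nms) - 1L)) {
        for (j in seq((i + 1L), length(nms))) {
          key <- paste(nms[i], nms[j], sep = "_vs_")
          out[[key]] <- correlate_scores(scores[[nms[i]]],
                                         scores[[nms[j]]],
                                         method = p$cor_method)
        }
      }
    }
    if (any(!is.na(annot$mrss))) {
      mrss <- stats::setNames(annot$mrss, annot$sample_id)
      for (nm in nms) {
        out[[paste0(nm, "_vs_mrss")]] <-
          correlate_scores(scores[[nm]], mrss, method = p$cor_method)
      }
    }
    out
  })

  comparisons <- stage("compare_groups", {
    out <- list()
    prim <- scores[[config$primary]]
    if (all(c("diffuse", "limited") %in% annot$subtype)) {
      out$limited_vs_diffuse <- compare_groups(
        prim, annot, split_by = "subtype",
        groups = c("diffuse", "limited"))
    }
    if (all(c("early", "late") %in% annot$duration_class)) {
      out$early_vs_late <- compare_groups(
        prim, annot, split_by = "duration_class",
        groups = c("early", "late"))
    }
    out
  })

  score_summary <- lapply(scores, function(sv) {
    lapply(split(sv$score, sv$group), function(v) {
      list(n = length(v), mean = mean(v), sd = stats::sd(v))
    })
  })
  genes_in <- vapply(sigs, nrow, integer(1))
  genes_scored <- vapply(scores, function(sv) length(attr(sv, "genes_used")),
                         integer(1))

  report <- structure(list(
    package_version = as.character(utils::packageVersion("fibrosig")),
    parameters = p,
    primary_signature = config$primary,
    gene_counts = list(signature_genes_in = as.list(genes_in),
                       genes_scored = as.list(genes_scored)),
    filter = filter_res,
    scores = scores,
    score_summary = score_summary,
    clustering = clustering,
    module = module,
    associations = associations,
    group_comparisons = comparisons),
    class = "run_report")

  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$scores)) {
    utils::write.table(report$scores[[nm]],
                       file.path(out_dir, paste0("scores_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$filter)) {
    utils::write.table(report$filter,
                       file.path(out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$clustering$assignment$assignment,
                     file.path(out_dir, "cluster_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    package_version = report$package_version,
    parameters = report$parameters,
    primary_signature = report$primary_signature,
    gene_counts = report$gene_counts,
    n_genes_kept = if (!is.null(report$filter)) sum(report$filter$kept),
    score_summary = report$score_summary,
    contingency_table = matrix(
      as.integer(report$clustering$contingency$table),
      nrow = nrow(report$clustering$contingency$table),
      dimnames = dimnames(report$clustering$contingency$table)),
    chi_square = report$clustering$contingency$chi_square,
    chi_square_df = report$clustering$contingency$df,
    chi_square_p = report$clustering$contingency$p_value,
    module_genes = if (!is.null(report$module)) report$module$module_genes,
    associations = lapply(report$associations, function(a) {
      list(method = a$method, r = a$r, p_value = a$p_value, n = a$n)
    }),
    group_comparisons = lapply(report$group_comparisons, function(g) {
      list(groups = g$group_labels, n = g$n_per_group,
           statistic = g$statistic, p_value = g$p_value)
    }))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("fibrosig run report (v%s)\n", x$package_version))
  cat(sprintf("  primary signature: %s (%d genes scored)\n",
              x$primary_signature,
              x$gene_counts$genes_scored[[x$primary_signature]]))
  cat(sprintf("  clusters: %d, chi-square = %.2f (p = %.3g)\n",
              x$clustering$assignment$n_clusters,
              x$clustering$contingency$chi_square,
              x$clustering$contingency$p_value))
  for (nm in names(x$associations)) {
    a <- x$associations[[nm]]
    cat(sprintf("  %s: R = %.3f (p = %.3g, n = %d)\n", nm, a$r,
                a$p_value, a$n))
  }
  for (nm in names(x$group_comparisons)) {
    g <- x$group_comparisons[[nm]]
    cat(sprintf("  %s: p = %.3g\n", nm, g$p_value))
  }
  invisible(x)
}
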