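#' Derive an anchor-gene coexpression module
#'
#' The "orthogonal" module construction: every other gene is correlated
#' with the anchor gene across all samples by Spearman rank correlation
#' (average ranks for ties); genes with r strictly above `r_threshold`
#' (positive side only — no absolute value) form the candidate pool,
#' truncated to the `max_candidates` highest-r genes when more qualify
#' (ties broken by gene id, ascending). The module is the intersection
#' of the candidates with the union of the selected pathway gene sets;
#' the anchor itself is never a module member.
#'
#' @param x an [expression_matrix()].
#' @param anchor anchor gene id (must be in the matrix and non-constant).
#' @param gene_sets optional [gene_set_collection()]; when `NULL` the
#'   module equals the candidate list.
#' @param set_names names of sets to intersect with (default: all sets
#'   in `gene_sets`).
#' @param r_threshold Spearman threshold, default 0.5.
#' @param max_candidates candidate-pool cap, default 400.
#' @return a list of class `coexpression_module`: `anchor_gene`,
#'   `r_threshold`, `candidates` (data.frame gene_id, spearman_r, sorted
#'   by decreasing r), `module_genes`, `pathway_sets_used`.
#' @export
derive_module <- function(x, anchor, gene_sets = NULL, set_names = NULL,
                          r_threshold = 0.5, max_candidates = 400L) {
  if (!anchor %in% rownames(x)) {
    stop("anchor gene '", anchor, "' not in matrix", call. = FALSE)
  }
  a <- unclass(x)[anchor, ]
  if (stats::sd(a) == 0) {
    stop("anchor gene '", anchor,
         "' is constant: rank correlation undefined", call. = FALSE)
  }
  others <- setdiff(rownames(x), anchor)
  r <- suppressWarnings(
    as.numeric(stats::cor(a, t(unclass(x)[others, , drop = FALSE]),
                          method = "spearman")))
  names(r) <- others
  qual <- !is.na(r) & r > r_threshold
  cand_ids <- others[qual]
  cand_r <- r[qual]
  # deterministic truncation: top r first, ties by gene id ascending
  ord <- order(-cand_r, cand_ids)
  cand_ids <- cand_ids[ord]
  cand_r <- cand_r[ord]
  if (length(cand_ids) > max_candidates) {
    cand_ids <- cand_ids[seq_len(max_candidates)]
    cand_r <- cand_r[seq_len(max_candidates)]
  }
  if (length(cand_ids) == 0L) {
    warning("no genes exceed the coexpression threshold; empty module",
            call. = FALSE)
  }
  sets_used <- character(0)
  if (is.null(gene_sets)) {
    module <- cand_ids
  } else {
    if (is.null(set_names)) set_names <- names(gene_sets)
    unknown <- setdiff(set_names, names(gene_sets))
    if (length(unknown) > 0L) {
      stop("unknown gene set(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sets_used <- set_names
    pathway_genes <- unique(unlist(gene_sets[set_names], use.names = FALSE))
    module <- cand_ids[cand_ids %in% pathway_genes]
  }
  structure(list(anchor_gene = anchor,
                 r_threshold = r_threshold,
                 candidates = data.frame(gene_id = cand_ids,
                                         spearman_r = unname(cand_r),
                                         stringsAsFactors = FALSE),
                 module_genes = module,
                 pathway_sets_used = sets_used),
            class = "coexpression_module")
}

#' @export
print.coexpression_module <- function(x, ...) {
  cat(sprintf("coexpression module anchored on %s: %d candidates (r > %g), %d module genes\n",
              x$anchor_gene, nrow(x$candidates), x$r_threshold,
              length(x$module_genes)))
  invisible(x)
}
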