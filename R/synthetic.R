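#' Configure the synthetic expression cohort generator
#'
#' The generator emulates the statistical structure the pipeline is
#' designed to detect: gene blocks loading on latent per-sample axes
#' with planted pairwise axis correlations, a case-vs-control mean
#' shift on one or more axes, a clinical severity covariate (MRSS)
#' linearly tied to one axis, and unstructured background genes. The
#' defaults mirror a skin-biopsy study design of 22 controls and 70
#' cases with a 43-gene anchor signature, two correlated partner axes
#' (one strongly positive, one strongly negative), and MRSS driven by
#' the anchor axis.
#'
#' The default inter-axis correlation between the two partner axes
#' (pparg, tgfb) is the product of their correlations with the anchor
#' axis (0.9 * -0.8 = -0.72), i.e. the two partners are conditionally
#' independent given the anchor; this is the weakest assumption that
#' keeps the default correlation matrix positive semidefinite.
#'
#' @param n_control,n_case group sizes (defaults 22 and 70).
#' @param block_sizes named integer vector of genes per block; a block
#'   named `"background"` carries no axis (defaults: ncor 43, pparg 30,
#'   tgfb 30, background 400).
#' @param axis_correlation symmetric correlation matrix over the
#'   non-background blocks (unit diagonal, positive semidefinite).
#'   Default: corr(ncor, pparg) = 0.9, corr(ncor, tgfb) = -0.8,
#'   corr(pparg, tgfb) = -0.72.
#' @param group_shift named numeric vector of case-group mean offsets on
#'   the latent axes (default `c(ncor = -1)`).
#' @param loading per-block gene loading on its axis; a scalar or a
#'   named vector (default 1).
#' @param noise_sd SD of the independent per-gene noise (default 1).
#' @param mrss_axis axis driving MRSS in cases (default `"ncor"`).
#' @param mrss_slope,mrss_intercept,mrss_noise_sd,mrss_floor linear MRSS
#'   model for cases: `max(floor, intercept + slope * axis + noise)`;
#'   defaults -5, 15, 5, 0, giving a clinically plausible 0-51-range
#'   severity score anticorrelated with the anchor axis.
#' @param flip_fraction fraction of each axis block's genes emitted with
#'   direction k = -1 (their loadings negated), to exercise the
#'   sign-weight machinery (default 0).
#' @param seed integer RNG seed; generation is fully reproducible.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_control = 22L, n_case = 70L,
                             block_sizes = c(ncor = 43L, pparg = 30L,
                                             tgfb = 30L, background = 400L),
                             axis_correlation = NULL,
                             group_shift = c(ncor = -1),
                             loading = 1,
                             noise_sd = 1,
                             mrss_axis = "ncor",
                             mrss_slope = -5,
                             mrss_intercept = 15,
                             mrss_noise_sd = 5,
                             mrss_floor = 0,
                             flip_fraction = 0,
                             seed = 1L) {
  if (n_control < 1L || n_case < 1L) stop("group sizes must be >= 1",
                                          call. = FALSE)
  if (is.null(names(block_sizes)) || any(names(block_sizes) == "")) {
    stop("block_sizes must be named", call. = FALSE)
  }
  if (any(block_sizes < 1L)) stop("block sizes must be >= 1", call. = FALSE)
  axes <- setdiff(names(block_sizes), "background")
  if (length(axes) == 0L) stop("need at least one non-background block",
                               call. = FALSE)
  if (is.null(axis_correlation)) {
    axis_correlation <- diag(length(axes))
    dimnames(axis_correlation) <- list(axes, axes)
    for (pair in list(c("ncor", "pparg", 0.9), c("ncor", "tgfb", -0.8),
                      c("pparg", "tgfb", -0.72))) {
      if (all(pair[1:2] %in% axes)) {
        axis_correlation[pair[[1L]], pair[[2L]]] <-
          axis_correlation[pair[[2L]], pair[[1L]]] <-
          as.numeric(pair[[3L]])
      }
    }
  }
  axis_correlation <- as.matrix(axis_correlation)
  if (is.null(dimnames(axis_correlation))) {
    dimnames(axis_correlation) <- list(axes, axes)
  }
  if (!identical(sort(rownames(axis_correlation)), sort(axes))) {
    stop("axis_correlation must be named by the non-background blocks",
         call. = FALSE)
  }
  axis_correlation <- axis_correlation[axes, axes, drop = FALSE]
  if (any(abs(diag(axis_correlation) - 1) > 1e-12)) {
    stop("axis_correlation must have unit diagonal", call. = FALSE)
  }
  if (any(abs(axis_correlation - t(axis_correlation)) > 1e-12)) {
    stop("axis_correlation must be symmetric", call. = FALSE)
  }
  ev <- eigen(axis_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("axis_correlation is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  if (noise_sd <= 0 || mrss_noise_sd <= 0) {
    stop("noise SDs must be > 0", call. = FALSE)
  }
  if (flip_fraction < 0 || flip_fraction > 1) {
    stop("flip_fraction must be in [0, 1]", call. = FALSE)
  }
  if (length(loading) == 1L && is.null(names(loading))) {
    loading <- stats::setNames(rep(as.numeric(loading), length(axes)), axes)
  }
  missing_l <- setdiff(axes, names(loading))
  if (length(missing_l) > 0L) {
    stop("loading missing for block(s): ",
         paste(missing_l, collapse = ", "), call. = FALSE)
  }
  shift <- stats::setNames(rep(0, length(axes)), axes)
  if (length(group_shift) > 0L) {
    unknown <- setdiff(names(group_shift), axes)
    if (length(unknown) > 0L) {
      stop("group_shift names unknown axis(es): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    shift[names(group_shift)] <- as.numeric(group_shift)
  }
  structure(list(n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 block_sizes = block_sizes,
                 axes = axes,
                 axis_correlation = axis_correlation,
                 group_shift = shift,
                 loading = loading[axes],
                 noise_sd = as.numeric(noise_sd),
                 mrss_axis = mrss_axis,
                 mrss_slope = as.numeric(mrss_slope),
                 mrss_intercept = as.numeric(mrss_intercept),
                 mrss_noise_sd = as.numeric(mrss_noise_sd),
                 mrss_floor = as.numeric(mrss_floor),
                 flip_fraction = as.numeric(flip_fraction),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic expression cohort
#'
#' Draws per-sample latent axis values from a multivariate normal with
#' the configured correlation matrix, adds the case-group shift, and
#' builds each gene as `loading * axis + N(0, noise_sd)` (background
#' genes are pure noise). Case samples receive an MRSS
#' `max(floor, intercept + slope * axis + N(0, mrss_noise_sd))` on the
#' configured axis, plus disease subtype and duration-class labels at
#' realistic cohort frequencies (diffuse 30:limited 5:overlap 1;
#' early 1:late 2); controls carry no MRSS. Generation is byte-for-byte
#' reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_dataset`: `matrix`
#'   (an [expression_matrix()]), `annot` (a [sample_annotation()]),
#'   `truth` (data.frame sample_id + one column per latent axis),
#'   `signatures` (named list of [signature_def()], one per axis block,
#'   k = +1 except for flipped genes), `gene_sets`
#'   (a [gene_set_collection()] with one set per block), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_control + config$n_case
  axes <- config$axes
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(config$n_control)),
                  sprintf("case_%02d", seq_len(config$n_case)))
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))

  lat <- MASS::mvrnorm(n, mu = rep(0, length(axes)),
                       Sigma = config$axis_correlation)
  lat <- matrix(lat, nrow = n, ncol = length(axes),
                dimnames = list(sample_ids, axes))
  is_case <- group == "case"
  for (a in axes) lat[is_case, a] <- lat[is_case, a] + config$group_shift[a]

  blocks <- names(config$block_sizes)
  gene_rows <- list()
  signatures <- list()
  sets <- list()
  for (b in blocks) {
    size <- config$block_sizes[[b]]
    ids <- sprintf("%s_g%03d", b, seq_len(size))
    noise <- matrix(stats::rnorm(size * n, sd = config$noise_sd),
                    nrow = size, ncol = n)
    if (b == "background") {
      vals <- noise
    } else {
      k <- rep(1L, size)
      n_flip <- floor(config$flip_fraction * size)
      if (n_flip > 0L) k[sample.int(size, n_flip)] <- -1L
      loadings <- config$loading[[b]] * k
      vals <- outer(loadings, lat[, b]) + noise
      signatures[[b]] <- signature_def(ids, k, name = b)
    }
    rownames(vals) <- ids
    gene_rows[[b]] <- vals
    sets[[b]] <- ids
  }
  mat <- do.call(rbind, gene_rows)
  colnames(mat) <- sample_ids

  mrss <- rep(NA_real_, n)
  if (config$mrss_axis %in% axes) {
    mrss[is_case] <- pmax(config$mrss_floor,
                          config$mrss_intercept +
                            config$mrss_slope * lat[is_case, config$mrss_axis] +
                            stats::rnorm(sum(is_case),
                                         sd = config$mrss_noise_sd))
  }
  subtype <- rep("n/a", n)
  subtype[is_case] <- sample(c("diffuse", "limited", "overlap"),
                             sum(is_case), replace = TRUE,
                             prob = c(30, 5, 1) / 36)
  duration <- rep("n/a", n)
  duration[is_case] <- sample(c("early", "late"), sum(is_case),
                              replace = TRUE, prob = c(1, 2) / 3)
  annot <- sample_annotation(data.frame(sample_id = sample_ids,
                                        group = group, mrss = mrss,
                                        subtype = subtype,
                                        duration_class = duration,
                                        stringsAsFactors = FALSE))
  truth <- data.frame(sample_id = sample_ids, lat, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(matrix = expression_matrix(mat,
                                            scale_note = "synthetic latent-factor"),
                 annot = annot,
                 truth = truth,
                 signatures = signatures,
                 gene_sets = gene_set_collection(sets),
                 config = config),
            class = "synthetic_dataset")
}

#' Extract the realized latent axis values of a synthetic cohort
#'
#' The per-sample latent values are the recovery target for the
#' downstream signature score.
#'
#' @param dataset a [simulate_cohort()] result.
#' @param axis axis name (a non-background block).
#' @return numeric vector named by sample id.
#' @export
truth_axis_scores <- function(dataset, axis) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!axis %in% colnames(dataset$truth)[-1L]) {
    stop("unknown axis '", axis, "'; available: ",
         paste(colnames(dataset$truth)[-1L], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(dataset$truth[[axis]], dataset$truth$sample_id)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the expression matrix and annotation as TSV, one two-column
#' signature file per axis block, a GMT with every block as a set, and
#' the latent truth table.
#'
#' @param dataset a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(dataset$matrix, file.path(dir, "matrix.tsv"))
  write_sample_annotation(dataset$annot, file.path(dir, "annotation.tsv"))
  for (nm in names(dataset$signatures)) {
    write_signature(dataset$signatures[[nm]],
                    file.path(dir, paste0("signature_", nm, ".tsv")))
  }
  write_gmt(dataset$gene_sets, file.path(dir, "blocks.gmt"))
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
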