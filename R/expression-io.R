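#' Construct an expression matrix
#'
#' A thin validated wrapper around a numeric genes-by-samples matrix.
#' Values are taken as-is on the input scale (typically log-like
#' continuous intensities); no transform is applied internally. The
#' provenance of the scale is recorded in `scale_note` so downstream
#' reports can state what was scored.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers
#'   (default: `colnames(values)`).
#' @param scale_note free-text tag describing the expression scale
#'   (e.g. `"log2 intensity"`); the package never guesses the scale.
#' @return a numeric matrix of class `expr_matrix` with dimnames set and
#'   a `scale_note` attribute.
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale_note = "unspecified") {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of gene_ids does not match number of rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of sample_ids does not match number of columns", call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0L) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0L) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "scale_note") <- as.character(scale_note)[1L]
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), attr(x, "scale_note")))
  invisible(x)
}

#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' the body must be fully numeric (missing values are a hard error —
#' the scoring formula has no missing-data rule). Row and column order
#' are preserved.
#'
#' @param path path to the file.
#' @param delimiter field delimiter, default tab.
#' @param scale_note stored on the returned object, see
#'   [expression_matrix()].
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   scale_note = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty expression matrix in ", path, call. = FALSE)
  }
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric expression value '%s' at row %d (gene '%s'), column '%s'",
      body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
      gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]), call. = FALSE)
  }
  expression_matrix(num, gene_ids = gene_ids, sample_ids = sample_ids,
                    scale_note = scale_note)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written at full double precision so a write/read
#' round-trip reproduces the matrix exactly to printed precision.
#'
#' @param x an `expr_matrix` (or plain named numeric matrix).
#' @param path output path.
#' @param delimiter field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  df <- data.frame(gene_id = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# -- sample annotations -------------------------------------------------

.valid_groups <- c("control", "case")
.valid_subtypes <- c("diffuse", "limited", "overlap", "n/a")
.valid_durations <- c("early", "late", "n/a")

#' Validate (and normalize) a sample annotation table
#'
#' The table must carry `sample_id` and `group` (control/case); optional
#' clinical columns are `mrss` (modified Rodnan skin score, >= 0 or NA),
#' `subtype` (diffuse/limited/overlap/"n/a") and `duration_class`
#' (early/late/"n/a"). Absent optional columns are filled with NA /
#' "n/a".
#'
#' @param annot a data.frame.
#' @return the validated data.frame (class `sample_annotation`).
#' @export
sample_annotation <- function(annot) {
  annot <- as.data.frame(annot, stringsAsFactors = FALSE)
  req <- c("sample_id", "group")
  miss <- setdiff(req, colnames(annot))
  if (length(miss) > 0L) {
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  annot$sample_id <- as.character(annot$sample_id)
  dup <- unique(annot$sample_id[duplicated(annot$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample id(s) in annotation: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  annot$group <- as.character(annot$group)
  bad <- setdiff(unique(annot$group), .valid_groups)
  if (length(bad) > 0L) {
    stop("unknown group value(s): ", paste(bad, collapse = ", "),
         "; expected control/case", call. = FALSE)
  }
  if (!"mrss" %in% colnames(annot)) annot$mrss <- NA_real_
  annot$mrss <- suppressWarnings(as.numeric(annot$mrss))
  if (any(!is.na(annot$mrss) & annot$mrss < 0)) {
    stop("mrss must be nonnegative", call. = FALSE)
  }
  for (col in c("subtype", "duration_class")) {
    if (!col %in% colnames(annot)) annot[[col]] <- "n/a"
    annot[[col]] <- as.character(annot[[col]])
    annot[[col]][is.na(annot[[col]]) | annot[[col]] == ""] <- "n/a"
  }
  bad <- setdiff(unique(annot$subtype), .valid_subtypes)
  if (length(bad) > 0L) {
    stop("unknown subtype value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(annot$duration_class), .valid_durations)
  if (length(bad) > 0L) {
    stop("unknown duration_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(annot) <- c("sample_annotation", "data.frame")
  annot
}

#' Read a sample annotation table (TSV)
#'
#' @param path path to a tab-separated table with header
#'   `sample_id, group[, mrss, subtype, duration_class]`.
#' @return a `sample_annotation` data.frame.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample_annotation(utils::read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Write a sample annotation table (TSV)
#' @param annot a `sample_annotation` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# -- signature definitions ----------------------------------------------

#' Construct a signature definition
#'
#' A signature is a named list of genes with per-gene direction weights
#' k in {+1, -1}: +1 for genes induced by the pathway of interest, -1
#' for suppressed genes.
#'
#' @param gene_id character vector of unique gene ids.
#' @param k integer vector of direction weights, each +1 or -1.
#' @param name signature name.
#' @return a data.frame of class `signature_def` with columns
#'   `gene_id`, `k` and a `name` attribute.
#' @export
signature_def <- function(gene_id, k, name = "signature") {
  gene_id <- as.character(gene_id)
  k <- as.integer(k)
  if (length(gene_id) == 0L) stop("signature is empty", call. = FALSE)
  if (length(gene_id) != length(k)) {
    stop("gene_id and k lengths differ", call. = FALSE)
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene(s) in signature: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(k %in% c(1L, -1L))) {
    stop("direction weight k must be +1 or -1", call. = FALSE)
  }
  out <- data.frame(gene_id = gene_id, k = k, stringsAsFactors = FALSE)
  attr(out, "name") <- as.character(name)[1L]
  class(out) <- c("signature_def", "data.frame")
  out
}

#' Read a two-column signature file
#'
#' Columns are gene and direction. Direction tokens `induced`, `+1`, `1`
#' map to k = +1 and `suppressed`, `-1` map to k = -1 (the convention
#' used for direction-weighted pathway scores).
#'
#' @param path path to a tab-separated two-column file. A header line is
#'   detected and skipped when its second field is not a direction token.
#' @param name signature name (default: the file name without extension).
#' @return a `signature_def`.
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (length(readLines(path, warn = FALSE)) == 0L) {
    stop("signature file is empty: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("signature file is empty or not two-column: ", path, call. = FALSE)
  }
  # header detection: first row's direction field not a known token
  if (!.is_direction_token(tab[1L, 2L])) {
    if (nrow(tab) == 1L) {
      stop("signature file has no data rows: ", path, call. = FALSE)
    }
    tab <- tab[-1L, , drop = FALSE]
  }
  k <- vapply(tab[[2L]], .parse_direction, integer(1), USE.NAMES = FALSE)
  signature_def(tab[[1L]], k, name = name)
}

.is_direction_token <- function(token) {
  tolower(trimws(token)) %in% c("induced", "suppressed", "+1", "1", "-1",
                                "−1")
}

.parse_direction <- function(token) {
  t <- tolower(trimws(token))
  if (t %in% c("induced", "+1", "1")) return(1L)
  if (t %in% c("suppressed", "-1", "−1")) return(-1L)
  stop("unknown direction token: '", token,
       "' (expected induced/suppressed/+1/-1)", call. = FALSE)
}

#' Write a signature definition as two-column TSV
#' @param signature a `signature_def`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(signature[, c("gene_id", "k")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- GMT gene sets ------------------------------------------------------

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene ids per set).
#' @param descriptions optional character vector of per-set descriptions.
#' @return a named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L) stop("gene-set collection is empty", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every gene set needs a name", call. = FALSE)
  }
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup) > 0L) {
    stop("duplicate set name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("gene set(s) with no genes: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  attr(sets, "descriptions") <- stats::setNames(descriptions, names(sets))
  class(sets) <- "gene_set_collection"
  sets
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene order is
#' preserved; duplicate genes within a line are collapsed with a
#' warning.
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(fields)), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate gene(s) %s collapsed",
                      fields[1L],
                      paste(unique(genes[duplicated(genes)]), collapse = ", ")),
              call. = FALSE)
      genes <- genes[!duplicated(genes)]
    }
    sets[[fields[1L]]] <- genes
    desc <- c(desc, fields[2L])
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection to GMT
#' @param sets a `gene_set_collection` (or named list of gene vectors).
#' @param path output path.
#' @param descriptions optional per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = attr(sets, "descriptions")) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
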