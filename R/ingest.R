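#' Parse a sample column header into group and replicate
#'
#' Column headers of the expression matrix encode the sample group and its
#' replicate number as `<GROUP><replicate>`, e.g. `STOMACH1` or
#' `SALIVARY_GLAND3`. The replicate index is the maximal trailing run of
#' decimal digits; everything before it is the group label.
#'
#' @param header A single non-empty column name.
#' @return A list with elements `group` (character) and `replicate` (integer).
#' @examples
#' parse_column_name("STOMACH1")
#' parse_column_name("SALIVARY_GLAND3")
#' @export
parse_column_name <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  if (is.na(header) || !nzchar(header)) {
    stop("empty column header", call. = FALSE)
  }
  m <- regmatches(header, regexpr("[0-9]+$", header))
  if (length(m) == 0L) {
    stop(sprintf("column '%s' has no trailing replicate number", header),
         call. = FALSE)
  }
  group <- sub("[0-9]+$", "", header)
  if (!nzchar(group)) {
    stop(sprintf("column '%s' has no group label before the replicate number",
                 header), call. = FALSE)
  }
  list(group = group, replicate = as.integer(m))
}

#' Read a wide-format expression CSV
#'
#' The file has one row per gene; the first column (named `gene` or `Symbol`)
#' holds unique gene symbols and every remaining column is one replicate of
#' one sample group, named as parsed by [parse_column_name()]. Values must be
#' non-negative; empty cells are treated as missing observations. Every group
#' must have at least two replicate columns (required for SEM and ANOVA).
#'
#' @param path Path to the CSV file.
#' @return An `expr_matrix` object: a list with `values` (numeric matrix,
#'   genes x samples), `genes`, `columns` (tibble of sample column, group,
#'   replicate) and `groups` (group labels in column order).
#' @export
read_expression_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("expression file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2L) {
    stop("expression CSV needs a gene column plus at least one sample column",
         call. = FALSE)
  }
  id_col <- names(raw)[1L]
  if (!id_col %in% c("gene", "Symbol")) {
    stop(sprintf(
      "first column must be the gene identifier ('gene' or 'Symbol'), got '%s'",
      id_col), call. = FALSE)
  }
  genes <- raw[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate gene symbol(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }

  sample_names <- names(raw)[-1L]
  parsed <- lapply(sample_names, parse_column_name)
  columns <- tibble::tibble(
    column = sample_names,
    group = vapply(parsed, `[[`, character(1), "group"),
    replicate = vapply(parsed, `[[`, integer(1), "replicate")
  )
  if (anyDuplicated(columns[c("group", "replicate")])) {
    bad <- columns$column[duplicated(columns[c("group", "replicate")])]
    stop(sprintf("duplicate group/replicate column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  reps_per_group <- table(columns$group)
  if (any(reps_per_group < 2L)) {
    stop(sprintf("group(s) with a single replicate: %s",
                 paste(names(reps_per_group)[reps_per_group < 2L], collapse = ", ")),
         call. = FALSE)
  }

  values <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_names),
                   dimnames = list(genes, sample_names))
  for (j in seq_along(sample_names)) {
    cell <- raw[[j + 1L]]
    blank <- is.na(cell) | !nzchar(trimws(cell))
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!blank & (is.na(num) | !is.finite(num)))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' at gene %s, column %s",
                   cell[bad[1L]], genes[bad[1L]], sample_names[j]),
           call. = FALSE)
    }
    neg <- which(!blank & num < 0)
    if (length(neg) > 0L) {
      stop(sprintf("negative value %s at gene %s, column %s",
                   cell[neg[1L]], genes[neg[1L]], sample_names[j]),
           call. = FALSE)
    }
    num[blank] <- NA_real_
    values[, j] <- num
  }

  structure(
    list(values = values, genes = genes, columns = columns,
         groups = unique(columns$group)),
    class = "expr_matrix"
  )
}

#' Write an expression matrix back to CSV
#'
#' Inverse of [read_expression_csv()]: reproduces the wide layout with the
#' original column names, `gene` as the identifier column, and full numeric
#' precision so a read/write round trip is exact.
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- tibble::as_tibble(expr$values, rownames = NA)
  out <- tibble::tibble(gene = expr$genes)
  for (cn in colnames(expr$values)) out[[cn]] <- unname(expr$values[, cn])
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a gene annotation CSV
#'
#' The file has one row per (gene, GO term) with columns `geneLink`, `GO`,
#' `Symbol` and `description` in any order. Rows sharing a symbol are
#' aggregated: GO terms are unioned, the link and description are taken from
#' the first row, and the Entrez ID is the part of the link after `?term=`.
#' Rows with an empty symbol are skipped with a warning.
#'
#' @param path Path to the CSV file.
#' @return An `annotation_table`: a tibble with one row per symbol and
#'   columns `symbol`, `gene_link`, `entrez_id`, `description`, `go_terms`
#'   (list column of character vectors).
#' @export
read_annotation_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("geneLink", "GO", "Symbol", "description")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("annotation CSV missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  empty_sym <- is.na(raw$Symbol) | !nzchar(trimws(raw$Symbol))
  if (any(empty_sym)) {
    warning(sprintf("skipping %d annotation row(s) with empty Symbol",
                    sum(empty_sym)), call. = FALSE)
    raw <- raw[!empty_sym, , drop = FALSE]
  }

  first_desc <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) "" else x[1L]
  }
  ann <- raw |>
    dplyr::group_by(symbol = .data$Symbol) |>
    dplyr::summarise(
      gene_link = first_desc(.data$geneLink),
      description = first_desc(.data$description),
      go_terms = list(unique(stats::na.omit(.data$GO))),
      n_desc = dplyr::n_distinct(stats::na.omit(.data$description)),
      .groups = "drop"
    )
  if (any(ann$n_desc > 1L)) {
    warning(sprintf(
      "symbol(s) with conflicting descriptions (first row kept): %s",
      paste(ann$symbol[ann$n_desc > 1L], collapse = ", ")), call. = FALSE)
  }
  ann$n_desc <- NULL
  ann$entrez_id <- ifelse(
    grepl("?term=", ann$gene_link, fixed = TRUE),
    sub(".*\\?term=", "", ann$gene_link), ""
  )
  ann <- ann[c("symbol", "gene_link", "entrez_id", "description", "go_terms")]
  class(ann) <- c("annotation_table", class(ann))
  ann
}

#' Merge expression data with annotations into one dataset
#'
#' Joins on the gene symbol (case-sensitive exact match). Every expression
#' gene appears exactly once, in input order; genes without an annotation get
#' an empty description, link and GO set. Annotation-only symbols are dropped
#' and their count reported as a message.
#'
#' @param expr An `expr_matrix` from [read_expression_csv()].
#' @param annot An `annotation_table` from [read_annotation_csv()], or `NULL`.
#' @return An `expr_dataset`: a list with `expr`, `annot` and `genes` (a
#'   tibble of merged per-gene records: symbol, description, gene_link,
#'   entrez_id, go_terms).
#' @export
merge_annotations <- function(expr, annot = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(annot)) {
    annot <- tibble::tibble(
      symbol = character(), gene_link = character(), entrez_id = character(),
      description = character(), go_terms = list()
    )
    class(annot) <- c("annotation_table", class(annot))
  }
  stopifnot(inherits(annot, "annotation_table"))

  idx <- match(expr$genes, annot$symbol)
  unmatched_annot <- sum(!annot$symbol %in% expr$genes)
  if (unmatched_annot > 0L) {
    message(sprintf("%d annotation symbol(s) without expression data dropped",
                    unmatched_annot))
  }
  genes <- tibble::tibble(
    symbol = expr$genes,
    description = ifelse(is.na(idx), "", annot$description[pmax(idx, 1L)]),
    gene_link = ifelse(is.na(idx), "", annot$gene_link[pmax(idx, 1L)]),
    entrez_id = ifelse(is.na(idx), "", annot$entrez_id[pmax(idx, 1L)]),
    go_terms = lapply(idx, function(i) {
      if (is.na(i)) character(0) else annot$go_terms[[i]]
    })
  )
  structure(list(expr = expr, annot = annot, genes = genes),
            class = "expr_dataset")
}

#' Read expression and annotation files into a dataset
#'
#' Convenience wrapper: [read_expression_csv()] + [read_annotation_csv()] +
#' [merge_annotations()].
#'
#' @param expression_path Wide-format expression CSV.
#' @param annotation_path Optional annotation CSV; `NULL` for none.
#' @return An `expr_dataset`.
#' @export
read_dataset <- function(expression_path, annotation_path = NULL) {
  expr <- read_expression_csv(expression_path)
  annot <- if (is.null(annotation_path)) NULL else read_annotation_csv(annotation_path)
  merge_annotations(expr, annot)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d groups: %s)\n",
              nrow(x$values), ncol(x$values), length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' @export
print.expr_dataset <- function(x, ...) {
  n_ann <- sum(nzchar(x$genes$description) | lengths(x$genes$go_terms) > 0)
  cat(sprintf("<expr_dataset> %d genes (%d annotated), groups: %s\n",
              nrow(x$genes), n_ann, paste(x$expr$groups, collapse = ", ")))
  invisible(x)
}
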