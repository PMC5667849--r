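#' Construct a transcript filter query
#'
#' A query bundles the six browsing criteria: free-text search over gene
#' symbols, descriptions and GO terms (the three text facets are OR-combined
#' with one another), plus numeric facets for expression range, fold change
#' against a reference group, and a maximum ANOVA q-value (AND-combined).
#' An all-empty query selects every gene.
#'
#' @param symbols,description_terms,go_terms Optional character vectors of
#'   search terms (case-insensitive substring match).
#' @param expr_range Optional numeric `c(lo, hi)`, in expression units,
#'   applied to the maximum group mean of each gene; `0 <= lo <= hi`.
#' @param fc_ref Optional reference group name for the fold-change facet.
#' @param min_fold Minimum fold change (>= 1); a gene survives if some group
#'   differs from the reference by at least this factor in either direction.
#'   Only used when `fc_ref` is given.
#' @param max_q Optional maximum ANOVA q-value, in (0, 1].
#' @return A `filter_query` object.
#' @export
filter_query <- function(symbols = NULL, description_terms = NULL,
                         go_terms = NULL, expr_range = NULL,
                         fc_ref = NULL, min_fold = 1, max_q = NULL) {
  if (!is.null(expr_range)) {
    stopifnot(length(expr_range) == 2L, is.numeric(expr_range))
    if (is.na(expr_range[1]) || expr_range[1] > expr_range[2]) {
      stop("expression range must satisfy lo <= hi", call. = FALSE)
    }
  }
  if (!is.null(fc_ref)) stopifnot(is.character(fc_ref), length(fc_ref) == 1L)
  if (min_fold < 1) stop("min_fold must be >= 1", call. = FALSE)
  if (!is.null(max_q)) {
    stopifnot(is.numeric(max_q), length(max_q) == 1L)
    if (max_q <= 0 || max_q > 1) stop("max_q must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(symbols = symbols, description_terms = description_terms,
         go_terms = go_terms, expr_range = expr_range,
         fc_ref = fc_ref, min_fold = min_fold, max_q = max_q),
    class = "filter_query"
  )
}

# case-insensitive literal substring match of any term in each element of x
.contains_any <- function(x, terms) {
  x_low <- tolower(x)
  terms_low <- tolower(terms)
  hit <- rep(FALSE, length(x))
  for (t in terms_low) hit <- hit | grepl(t, x_low, fixed = TRUE)
  hit
}

#' Filter genes by symbol search terms
#'
#' @param ds An `expr_dataset` or `stats_table`.
#' @param terms Character vector of search terms; a gene survives when its
#'   symbol contains any term (case-insensitive substring).
#' @return Character vector of surviving gene symbols, dataset order.
#' @export
filter_by_symbol <- function(ds, terms) {
  stopifnot(length(terms) > 0)
  g <- .dataset_genes(ds)
  g$symbol[.contains_any(g$symbol, terms)]
}

#' Filter genes by description search terms
#'
#' Genes with an empty description never match.
#'
#' @inheritParams filter_by_symbol
#' @return Character vector of surviving gene symbols, dataset order.
#' @export
filter_by_description <- function(ds, terms) {
  stopifnot(length(terms) > 0)
  g <- .dataset_genes(ds)
  g$symbol[nzchar(g$description) & .contains_any(g$description, terms)]
}

#' Filter genes by GO-term search terms
#'
#' A gene survives when at least one of its GO annotations contains any of
#' the search terms (case-insensitive substring). Unannotated genes never
#' match.
#'
#' @inheritParams filter_by_symbol
#' @return Character vector of surviving gene symbols, dataset order.
#' @export
filter_by_go <- function(ds, terms) {
  stopifnot(length(terms) > 0)
  g <- .dataset_genes(ds)
  hit <- vapply(g$go_terms, function(gos) {
    length(gos) > 0 && any(.contains_any(gos, terms))
  }, logical(1))
  g$symbol[hit]
}

.dataset_genes <- function(ds) {
  if (inherits(ds, "expr_dataset")) return(ds$genes)
  if (inherits(ds, "stats_table")) return(ds$annotation)
  stop("expected an expr_dataset or stats_table", call. = FALSE)
}

#' Filter genes by expression level
#'
#' A gene survives when the maximum of its group means lies inside
#' `[lo, hi]` — i.e. the gene is expressed at a level in that range in at
#' least its most expressed group.
#'
#' @param stats A `stats_table`.
#' @param lo,hi Expression-unit bounds, `0 <= lo <= hi` (`hi` may be `Inf`).
#' @return Character vector of surviving gene symbols, table order.
#' @export
filter_by_expression_range <- function(stats, lo = 0, hi = Inf) {
  stopifnot(inherits(stats, "stats_table"), lo >= 0, lo <= hi)
  mx <- .max_group_mean(stats)
  stats$genes[!is.na(mx) & mx >= lo & mx <= hi]
}

.max_group_mean <- function(stats) {
  agg <- stats::aggregate(mean ~ gene, data = stats$summary, FUN = max,
                          na.action = stats::na.omit)
  agg$mean[match(stats$genes, agg$gene)]
}

#' Filter genes by fold change against a reference group
#'
#' A gene survives when some non-reference group's mean differs from the
#' reference group's mean by at least `min_fold` in either direction, fold
#' changes computed as `(mean_a + eps) / (mean_ref + eps)` with the table's
#' pseudocount.
#'
#' @param stats A `stats_table`.
#' @param ref_group Reference group name (must exist in the table).
#' @param min_fold Minimum fold change, >= 1.
#' @return Character vector of surviving gene symbols, table order.
#' @export
filter_by_fold_change <- function(stats, ref_group, min_fold) {
  stopifnot(inherits(stats, "stats_table"))
  if (!ref_group %in% stats$groups) {
    stop(sprintf("unknown reference group '%s'; valid groups: %s",
                 ref_group, paste(stats$groups, collapse = ", ")),
         call. = FALSE)
  }
  if (min_fold < 1) stop("min_fold must be >= 1", call. = FALSE)
  eps <- stats$eps
  ref <- stats$summary[stats$summary$group == ref_group, ]
  ref_mean <- ref$mean[match(stats$genes, ref$gene)]
  hit <- rep(FALSE, length(stats$genes))
  for (g in setdiff(stats$groups, ref_group)) {
    gm <- stats$summary[stats$summary$group == g, ]
    m <- gm$mean[match(stats$genes, gm$gene)]
    fc <- (m + eps) / (ref_mean + eps)
    hit <- hit | (!is.na(fc) & (fc >= min_fold | fc <= 1 / min_fold))
  }
  stats$genes[hit]
}

#' Filter genes by maximum ANOVA q-value
#'
#' Genes flagged degenerate by the ANOVA (zero within-group variance with
#' separated means) are excluded, with a message.
#'
#' @param stats A `stats_table`.
#' @param max_q Threshold in (0, 1].
#' @return Character vector of surviving gene symbols, table order.
#' @export
filter_by_qvalue <- function(stats, max_q) {
  stopifnot(inherits(stats, "stats_table"))
  if (max_q <= 0 || max_q > 1) stop("max_q must be in (0, 1]", call. = FALSE)
  an <- stats$anova[match(stats$genes, stats$anova$gene), ]
  if (any(an$degenerate)) {
    message(sprintf("%d degenerate gene(s) excluded from the q-value filter",
                    sum(an$degenerate)))
  }
  stats$genes[!an$degenerate & !is.na(an$q) & an$q <= max_q]
}

#' Apply a composite filter query
#'
#' The three text facets (symbol, description, GO) form one search facet: a
#' gene passes it by matching ANY active text criterion. The numeric facets
#' (expression range, fold change, q-value) are each applied as an AND.
#' Survivors are ordered by ANOVA q ascending with alphabetical tie-break,
#' the order also used for the heatmap's leading rows.
#'
#' @param ds An `expr_dataset` (carries the annotation text fields).
#' @param stats The matching `stats_table`.
#' @param query A [filter_query()].
#' @return A `filter_result`: list with `genes` (ordered survivors) and
#'   `counts` (named survivor count after each applied facet).
#' @export
apply_query <- function(ds, stats, query = filter_query()) {
  stopifnot(inherits(stats, "stats_table"), inherits(query, "filter_query"))
  survivors <- stats$genes
  counts <- c(input = length(survivors))

  text_active <- !is.null(query$symbols) || !is.null(query$description_terms) ||
    !is.null(query$go_terms)
  if (text_active) {
    hits <- character(0)
    if (!is.null(query$symbols)) {
      hits <- union(hits, filter_by_symbol(ds, query$symbols))
    }
    if (!is.null(query$description_terms)) {
      hits <- union(hits, filter_by_description(ds, query$description_terms))
    }
    if (!is.null(query$go_terms)) {
      hits <- union(hits, filter_by_go(ds, query$go_terms))
    }
    survivors <- intersect(survivors, hits)
    counts <- c(counts, text = length(survivors))
  }
  if (!is.null(query$expr_range)) {
    survivors <- intersect(
      survivors,
      filter_by_expression_range(stats, query$expr_range[1], query$expr_range[2]))
    counts <- c(counts, expression = length(survivors))
  }
  if (!is.null(query$fc_ref)) {
    survivors <- intersect(
      survivors, filter_by_fold_change(stats, query$fc_ref, query$min_fold))
    counts <- c(counts, fold_change = length(survivors))
  }
  if (!is.null(query$max_q)) {
    survivors <- intersect(survivors, filter_by_qvalue(stats, query$max_q))
    counts <- c(counts, qvalue = length(survivors))
  }

  an <- stats$anova[match(survivors, stats$anova$gene), ]
  ord <- order(an$q, survivors, na.last = TRUE, method = "radix")
  structure(list(genes = survivors[ord], counts = counts),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d surviving gene(s)\n", length(x$genes)))
  chain <- paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " > ")
  cat(" ", chain, "\n")
  invisible(x)
}

#' Serialize a filter query to a flat list (YAML/JSON-ready)
#'
#' @param query A `filter_query`.
#' @return A plain named list with `NULL` facets omitted.
#' @export
query_to_list <- function(query) {
  stopifnot(inherits(query, "filter_query"))
  out <- unclass(query)
  out[!vapply(out, is.null, logical(1))]
}

#' Rebuild a filter query from a flat list
#'
#' @param x A named list as produced by [query_to_list()] or read from a
#'   YAML/JSON config.
#' @return A `filter_query`.
#' @export
query_from_list <- function(x) {
  do.call(filter_query, x[names(x) %in% names(formals(filter_query))])
}
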