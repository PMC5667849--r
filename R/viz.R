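#' @importFrom rlang .data
NULL

new_figure_bundle <- function(plot, table, kind, options = list()) {
  structure(list(plot = plot, table = table,
                 meta = c(list(kind = kind), options)),
            class = "figure_bundle")
}

#' @export
print.figure_bundle <- function(x, ...) {
  cat(sprintf("<figure_bundle> %s: %d plotted row(s)\n",
              x$meta$kind, nrow(x$table)))
  invisible(x)
}

#' Dot plot of group means with SEM error bars
#'
#' One panel per gene; x = sample groups in input order, y = group mean with
#' +/- SEM error bars. All panels share one y-axis range so expression
#' levels are comparable across genes.
#'
#' @param stats A `stats_table`.
#' @param genes Character vector of gene symbols to plot (at most 25).
#' @return A `figure_bundle`; `$table` has one row per plotted point with
#'   columns `gene`, `group`, `mean`, `sem`, `ymin`, `ymax`.
#' @export
dot_plot <- function(stats, genes) {
  stopifnot(inherits(stats, "stats_table"), length(genes) > 0)
  missing <- setdiff(genes, stats$genes)
  if (length(missing) > 0) {
    stop(sprintf("gene(s) not in stats table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(genes) > 25L) {
    stop(sprintf(
      "%d genes requested; dot plots are capped at 25 panels - filter first",
      length(genes)), call. = FALSE)
  }
  tab <- stats$summary[stats$summary$gene %in% genes, ]
  tab <- tab[order(match(tab$gene, genes), match(tab$group, stats$groups)), ]
  sem0 <- ifelse(is.na(tab$sem), 0, tab$sem)
  tab <- tibble::tibble(
    gene = tab$gene, group = tab$group, mean = tab$mean, sem = tab$sem,
    ymin = tab$mean - sem0, ymax = tab$mean + sem0
  )
  ylim <- c(min(0, tab$ymin, na.rm = TRUE), max(tab$ymax, na.rm = TRUE))
  p <- ggplot2::ggplot(tab, ggplot2::aes(
         x = factor(.data$group, levels = stats$groups), y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax), width = 0.2) +
    ggplot2::geom_point(size = 2, colour = "#377eb8") +
    ggplot2::facet_wrap(~ factor(gene, levels = genes)) +
    ggplot2::coord_cartesian(ylim = ylim) +
    ggplot2::labs(x = NULL, y = "expression") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  new_figure_bundle(p, tab, "dot_plot", list(shared_ylim = ylim))
}

#' Volcano plot for one pairwise contrast
#'
#' Per gene: x = log2 fold change of `group_a` vs `group_b`, y = -log10 of
#' the contrast's q-value. Genes with q = 0 are drawn at the largest finite
#' y plus 10 percent.
#'
#' @param stats A `stats_table`.
#' @param group_a,group_b Two distinct group names forming a stored contrast.
#' @return A `figure_bundle`; `$table` has columns `gene`, `log2fc`, `q`,
#'   `neg_log10_q`, `capped`.
#' @export
volcano_plot <- function(stats, group_a, group_b) {
  stopifnot(inherits(stats, "stats_table"))
  if (group_a == group_b) {
    stop("volcano plot needs two distinct groups", call. = FALSE)
  }
  pw <- stats$pairwise
  sub <- pw[pw$group_a == group_a & pw$group_b == group_b, ]
  flip <- FALSE
  if (nrow(sub) == 0L) {
    sub <- pw[pw$group_a == group_b & pw$group_b == group_a, ]
    flip <- TRUE
  }
  if (nrow(sub) == 0L) {
    stop(sprintf("no stored contrast between '%s' and '%s'",
                 group_a, group_b), call. = FALSE)
  }
  lfc <- if (flip) -sub$log2fc else sub$log2fc
  y <- -log10(sub$q)
  finite_max <- suppressWarnings(max(y[is.finite(y)], na.rm = TRUE))
  if (!is.finite(finite_max)) finite_max <- 1
  capped <- is.infinite(y)
  y[capped] <- finite_max * 1.1
  tab <- tibble::tibble(gene = sub$gene, log2fc = lfc, q = sub$q,
                        neg_log10_q = y, capped = capped)
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, .data$neg_log10_q)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#444444") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = sprintf("log2 fold change (%s vs %s)", group_a, group_b),
                  y = "-log10 q") +
    ggplot2::theme_bw()
  new_figure_bundle(p, tab, "volcano_plot",
                    list(group_a = group_a, group_b = group_b))
}

#' Gene-difference plot against a reference transcript
#'
#' For each gene g and group s the log2 difference from the reference gene,
#' d(g, s) = log2((mean_gs + eps) / (mean_ref,s + eps)), is plotted as a dot
#' coloured on a blue (up) - yellow (no difference) - red (down) diverging
#' scale. Panels are ordered by the similarity score S(g) = mean over groups
#' of |d(g, s)|: ascending for `"most"` similar, descending for `"least"`.
#'
#' @param stats A `stats_table`.
#' @param ref_gene Reference gene symbol.
#' @param order `"most"` or `"least"` similar first.
#' @param genes Optional subset of genes to compare (default: all).
#' @param max_panels Number of panels kept after sorting (default 25).
#' @return A `figure_bundle`; `$table` has columns `gene`, `group`, `d`
#'   (log2 difference) and `similarity` (S(g)).
#' @export
difference_plot <- function(stats, ref_gene, order = c("most", "least"),
                            genes = NULL, max_panels = 25L) {
  stopifnot(inherits(stats, "stats_table"))
  order <- match.arg(order)
  if (!ref_gene %in% stats$genes) {
    stop(sprintf("unknown reference gene '%s'", ref_gene), call. = FALSE)
  }
  if (is.null(genes)) genes <- stats$genes
  eps <- stats$eps
  summ <- stats$summary
  ref <- summ[summ$gene == ref_gene, ]
  ref_mean <- ref$mean[match(stats$groups, ref$group)]

  sub <- summ[summ$gene %in% genes, ]
  d <- log2((sub$mean + eps) /
            (ref_mean[match(sub$group, stats$groups)] + eps))
  tab <- tibble::tibble(gene = sub$gene, group = sub$group, d = d)
  sim <- stats::aggregate(abs(d) ~ gene, data = tab, FUN = mean)
  names(sim) <- c("gene", "similarity")
  tab$similarity <- sim$similarity[match(tab$gene, sim$gene)]

  ord_genes <- sim$gene[order(sim$similarity, sim$gene,
                              decreasing = c(order == "least", FALSE),
                              method = "radix")]
  ord_genes <- utils::head(ord_genes, max_panels)
  tab <- tab[tab$gene %in% ord_genes, ]
  tab <- tab[order(match(tab$gene, ord_genes), match(tab$group, stats$groups)), ]

  lim <- max(abs(tab$d), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  p <- ggplot2::ggplot(tab, ggplot2::aes(
         x = factor(.data$group, levels = stats$groups), y = .data$d,
         colour = .data$d)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient2(low = "#d73027", mid = "#ffffbf",
                                    high = "#4575b4", midpoint = 0,
                                    limits = c(-lim, lim)) +
    ggplot2::facet_wrap(~ factor(gene, levels = ord_genes)) +
    ggplot2::labs(x = NULL, y = sprintf("log2 difference vs %s", ref_gene),
                  colour = "log2 diff") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  new_figure_bundle(p, tab, "difference_plot",
                    list(ref_gene = ref_gene, order = order))
}

#' Heatmap display options
#'
#' @param normalize One of `"none"`, `"rows"`, `"columns"`: z-score across
#'   transcripts (rows) or samples (columns) after any log transform.
#' @param cluster_rows,cluster_cols Hierarchically cluster (Euclidean
#'   distance, complete linkage) and reorder rows/columns.
#' @param log_transform Apply `log2(x + eps)` before normalization.
#' @param max_rows Keep only the leading `max_rows` genes of the incoming
#'   order (default 50).
#' @return A `heatmap_options` list.
#' @export
heatmap_options <- function(normalize = c("none", "rows", "columns"),
                            cluster_rows = FALSE, cluster_cols = FALSE,
                            log_transform = FALSE, max_rows = 50L) {
  normalize <- match.arg(normalize)
  stopifnot(max_rows >= 1)
  structure(list(normalize = normalize, cluster_rows = cluster_rows,
                 cluster_cols = cluster_cols, log_transform = log_transform,
                 max_rows = as.integer(max_rows)),
            class = "heatmap_options")
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Expression heatmap of group means
#'
#' Transcripts as rows, sample groups as columns, colour from black (low)
#' to yellow (high). Pipeline: (1) truncate to the leading `max_rows` genes
#' of the incoming order (use [apply_query()]'s q-ascending order for the
#' canonical "first fifty"); (2) optional `log2(x + eps)`; (3) optional row
#' or column z-scoring; (4) optional hierarchical clustering (Euclidean,
#' complete linkage) reordering rows/columns.
#'
#' @param stats A `stats_table`.
#' @param genes Ordered character vector of gene symbols.
#' @param opts A [heatmap_options()] list.
#' @return A `figure_bundle`; `$table` is long format with columns `gene`,
#'   `group`, `value` (the displayed number) plus the final `row_order` /
#'   `col_order` ranks.
#' @export
expression_heatmap <- function(stats, genes, opts = heatmap_options()) {
  stopifnot(inherits(stats, "stats_table"), length(genes) > 0)
  genes <- utils::head(genes, opts$max_rows)
  summ <- stats$summary[stats$summary$gene %in% genes, ]
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(stats$groups),
              dimnames = list(genes, stats$groups))
  m[cbind(match(summ$gene, genes), match(summ$group, stats$groups))] <- summ$mean

  if (opts$log_transform) m <- log2(m + stats$eps)
  if (opts$normalize == "rows") {
    m <- t(apply(m, 1, .zscore))
    dimnames(m) <- list(genes, stats$groups)
  } else if (opts$normalize == "columns") {
    m <- apply(m, 2, .zscore)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(genes, stats$groups))
    rownames(m) <- genes
  }

  row_ord <- seq_len(nrow(m))
  col_ord <- seq_len(ncol(m))
  if (isTRUE(opts$cluster_rows) && nrow(m) > 1L) {
    row_ord <- stats::hclust(stats::dist(m, method = "euclidean"),
                             method = "complete")$order
  }
  if (isTRUE(opts$cluster_cols) && ncol(m) > 1L) {
    col_ord <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                             method = "complete")$order
  }
  m <- m[row_ord, col_ord, drop = FALSE]

  tab <- tibble::tibble(
    gene = rep(rownames(m), times = ncol(m)),
    group = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    row_order = rep(seq_len(nrow(m)), times = ncol(m)),
    col_order = rep(seq_len(ncol(m)), each = nrow(m))
  )
  p <- ggplot2::ggplot(tab, ggplot2::aes(
         x = factor(.data$group, levels = colnames(m)),
         y = factor(.data$gene, levels = rev(rownames(m))),
         fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "yellow",
                                 na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  new_figure_bundle(p, tab, "heatmap", list(options = opts))
}

#' Transcript-level principal component analysis
#'
#' Builds the genes x groups matrix of `log2(mean + eps)`, centers each
#' group column across genes (no variance scaling), and decomposes it by
#' SVD. The scatter shows gene scores on the first two principal components
#' with percent variance explained on the axes; a companion bar panel shows
#' the PC1/PC2 loadings per group. Sign convention: within each component
#' the largest-magnitude loading is made positive.
#'
#' @param stats A `stats_table`.
#' @param genes Character vector of at least 3 gene symbols.
#' @return A `figure_bundle`; `$table` holds the gene scores (`gene`,
#'   `PC1`, `PC2`); `$meta` carries `loadings` (groups x PCs),
#'   `var_explained` (percent, all PCs) and the full `scores` matrix.
#' @export
pca_plot <- function(stats, genes) {
  stopifnot(inherits(stats, "stats_table"))
  genes <- intersect(genes, stats$genes)
  if (length(genes) < 3L) {
    stop("PCA needs at least 3 genes", call. = FALSE)
  }
  if (length(stats$groups) < 2L) {
    stop("PCA needs at least 2 groups", call. = FALSE)
  }
  summ <- stats$summary[stats$summary$gene %in% genes, ]
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(stats$groups),
              dimnames = list(genes, stats$groups))
  m[cbind(match(summ$gene, genes), match(summ$group, stats$groups))] <- summ$mean
  m <- log2(m + stats$eps)
  centered <- scale(m, center = TRUE, scale = FALSE)

  sv <- svd(centered)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  # deterministic sign: largest-|loading| entry of each PC is positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- stats$groups
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  rownames(scores) <- genes
  colnames(scores) <- colnames(loadings)
  var_explained <- 100 * sv$d^2 / sum(sv$d^2)

  tab <- tibble::tibble(gene = genes,
                        PC1 = scores[, 1],
                        PC2 = if (ncol(scores) >= 2) scores[, 2] else 0)
  scatter <- ggplot2::ggplot(tab, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#377eb8") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", var_explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  if (length(var_explained) >= 2) var_explained[2] else 0)) +
    ggplot2::theme_bw()
  load_tab <- tibble::tibble(
    group = rep(stats$groups, 2),
    component = rep(c("PC1", "PC2"), each = length(stats$groups)),
    loading = c(loadings[, 1],
                if (ncol(loadings) >= 2) loadings[, 2] else rep(0, nrow(loadings)))
  )
  bars <- ggplot2::ggplot(load_tab, ggplot2::aes(
           x = factor(.data$group, levels = stats$groups), y = .data$loading)) +
    ggplot2::geom_col(fill = "#984ea3") +
    ggplot2::facet_wrap(~ component, ncol = 1) +
    ggplot2::labs(x = NULL, y = "loading") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  p <- patchwork::wrap_plots(scatter, bars, widths = c(2, 1))
  new_figure_bundle(p, tab, "pca_plot",
                    list(loadings = loadings, scores = scores,
                         var_explained = var_explained,
                         centered = centered))
}

#' Render a figure bundle to PNG (and optionally its table to CSV)
#'
#' @param fig A `figure_bundle`.
#' @param path Output PNG path.
#' @param width,height Plot size in inches.
#' @param dpi Raster resolution (> 0).
#' @param table_csv Optional path; when given, the bundle's data table is
#'   written there as CSV.
#' @return `path`, invisibly.
#' @export
render_png <- function(fig, path, width = 8, height = 6, dpi = 150,
                       table_csv = NULL) {
  stopifnot(inherits(fig, "figure_bundle"))
  if (!is.numeric(dpi) || dpi <= 0) stop("dpi must be > 0", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("output directory does not exist: %s", dir), call. = FALSE)
  }
  grDevices::png(path, width = width, height = height, units = "in",
                 res = dpi, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  print(fig$plot)
  if (!is.null(table_csv)) readr::write_csv(fig$table, table_csv)
  invisible(path)
}
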