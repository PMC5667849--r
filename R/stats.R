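#' Per-group mean and standard error per gene
#'
#' For every gene and sample group, the arithmetic mean of the observed
#' replicates and the standard error of the mean, sem = s / sqrt(n) with s
#' the sample standard deviation (n - 1 denominator). Missing cells are
#' excluded from n; a gene/group left with fewer than two observed
#' replicates is flagged (`defined = FALSE`) and its sem is `NA`.
#'
#' @param ds An `expr_dataset`.
#' @return A tibble with columns `gene`, `group`, `n`, `mean`, `sem`,
#'   `defined`, one row per gene/group, groups in input column order.
#' @export
group_summary <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  v <- ds$expr$values
  cols <- ds$expr$columns
  out <- lapply(ds$expr$groups, function(g) {
    sub <- v[, cols$column[cols$group == g], drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[n == 0] <- NA_real_
    ss <- rowSums((sub - mu)^2, na.rm = TRUE)
    sem <- sqrt(ss / pmax(n - 1, 1)) / sqrt(n)
    sem[n < 2] <- NA_real_
    tibble::tibble(gene = rownames(v), group = g, n = as.integer(n),
                   mean = unname(mu), sem = unname(sem), defined = n >= 2)
  })
  dplyr::bind_rows(out)
}

# Rowwise one-way ANOVA components from a genes x samples matrix and a
# group factor. Returns F, dfs, p and a degeneracy flag per gene.
.row_anova <- function(v, group) {
  group <- as.character(group)
  groups <- unique(group)
  k <- length(groups)
  n_obs <- rowSums(!is.na(v))
  grand <- rowMeans(v, na.rm = TRUE)

  ss_between <- rep(0, nrow(v))
  ss_within <- rep(0, nrow(v))
  for (g in groups) {
    sub <- v[, group == g, drop = FALSE]
    n_g <- rowSums(!is.na(sub))
    m_g <- rowMeans(sub, na.rm = TRUE)
    m_g[n_g == 0] <- 0
    ss_between <- ss_between + n_g * (m_g - grand)^2
    ss_within <- ss_within + rowSums((sub - m_g)^2, na.rm = TRUE)
  }
  df1 <- k - 1L
  df2 <- n_obs - k
  ms_b <- ss_between / df1
  ms_w <- ss_within / df2

  f <- ms_b / ms_w
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  degenerate <- rep(FALSE, nrow(v))

  # zero within-group variance: p collapses to 0 or 1 by the between term
  tol <- 1e-12
  zero_w <- ms_w <= tol * pmax(ms_b, 1)
  both_zero <- zero_w & ms_b <= tol
  f[both_zero] <- 0
  p[both_zero] <- 1
  sep <- zero_w & !both_zero
  f[sep] <- Inf
  p[sep] <- 0
  degenerate[sep] <- TRUE

  undefined <- df2 < 1
  p[undefined] <- NA_real_
  f[undefined] <- NA_real_
  degenerate[undefined] <- TRUE

  tibble::tibble(F = unname(f), df_between = df1, df_within = unname(df2),
                 p = unname(p), degenerate = unname(degenerate))
}

#' Experiment-wide one-way ANOVA per gene
#'
#' Standard fixed-effects one-way ANOVA across all sample groups on the raw
#' expression values: F = MS_between / MS_within with df (k - 1, N - k),
#' upper-tail p from the F distribution, and q from Benjamini-Hochberg
#' adjustment across all genes. Degenerate genes (zero within-group variance
#' with separated means) get p = 0 and are flagged; genes with all values
#' equal get F = 0, p = 1.
#'
#' @param ds An `expr_dataset`.
#' @return A tibble with columns `gene`, `F`, `df_between`, `df_within`,
#'   `p`, `q`, `degenerate`.
#' @export
anova_per_gene <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (length(ds$expr$groups) < 2L) {
    stop("ANOVA needs at least two sample groups", call. = FALSE)
  }
  res <- .row_anova(ds$expr$values, ds$expr$columns$group)
  res <- dplyr::bind_cols(tibble::tibble(gene = ds$expr$genes), res)
  res$q <- bh_qvalues(res$p)
  res[c("gene", "F", "df_between", "df_within", "p", "q", "degenerate")]
}

# Welch t test and log2 fold change for one ordered pair of groups,
# vectorized over genes. eps is the fold-change pseudocount.
.row_welch <- function(v, cols, a, ref, eps) {
  stat_one <- function(g) {
    sub <- v[, cols$column[cols$group == g], drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    s2 <- rowSums((sub - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    s2[n < 2] <- NA_real_
    list(n = n, m = m, s2 = s2)
  }
  x <- stat_one(a)
  y <- stat_one(ref)

  se2 <- x$s2 / x$n + y$s2 / y$n
  t <- (x$m - y$m) / sqrt(se2)
  df <- se2^2 / ((x$s2 / x$n)^2 / (x$n - 1) + (y$s2 / y$n)^2 / (y$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degenerate <- rep(FALSE, nrow(v))

  zero_var <- !is.na(se2) & se2 == 0
  eq <- zero_var & x$m == y$m
  t[eq] <- 0; df[eq] <- x$n[eq] + y$n[eq] - 2; p[eq] <- 1
  ne <- zero_var & x$m != y$m
  t[ne] <- sign(x$m[ne] - y$m[ne]) * Inf
  df[ne] <- x$n[ne] + y$n[ne] - 2
  p[ne] <- 0
  degenerate[ne] <- TRUE

  tibble::tibble(
    gene = rownames(v), group_a = a, group_b = ref,
    log2fc = unname(log2((x$m + eps) / (y$m + eps))),
    t = unname(t), df = unname(df), p = unname(p),
    degenerate = unname(degenerate)
  )
}

#' Pairwise differential-expression tests for all group pairs
#'
#' For every unordered pair of sample groups, a Welch t test (unequal
#' variances, Welch-Satterthwaite df) per gene on the replicates, plus the
#' log2 fold change of the group means with pseudocount `eps` added to both
#' numerator and denominator. q-values are Benjamini-Hochberg adjusted
#' across genes within each contrast.
#'
#' @param ds An `expr_dataset`.
#' @param eps Fold-change pseudocount in expression units (default 1).
#' @return A tibble with columns `gene`, `group_a`, `group_b`, `log2fc`,
#'   `t`, `df`, `p`, `q`, `degenerate`; S * (S - 1) / 2 contrasts for S
#'   groups, pairs in input group order.
#' @export
pairwise_tests <- function(ds, eps = 1) {
  stopifnot(inherits(ds, "expr_dataset"), eps >= 0)
  groups <- ds$expr$groups
  if (length(groups) < 2L) {
    stop("pairwise tests need at least two sample groups", call. = FALSE)
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    out <- .row_welch(ds$expr$values, ds$expr$columns, pr[1L], pr[2L], eps)
    out$q <- bh_qvalues(out$p)
    out
  })
  dplyr::bind_rows(res)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: on the sorted p-values,
#' q_(i) = min over j >= i of p_(j) * m / j, clipped at 1 and mapped back to
#' the input order. `NA`/`NaN` p-values propagate and do not count toward m.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q[is.nan(p)] <- NaN
  q
}

#' Build the per-gene statistics lookup table
#'
#' Composes [group_summary()], [anova_per_gene()] and [pairwise_tests()]
#' into the lookup table reused by all filtering and plotting: per-gene
#' group means and SEMs, experiment-wide ANOVA F/p/q, and per-contrast
#' log2 fold changes and q-values.
#'
#' @param ds An `expr_dataset`.
#' @param eps Fold-change pseudocount in expression units (default 1).
#' @return A `stats_table`: a list with `genes`, `groups`, `summary`,
#'   `anova`, `pairwise`, `eps` and the source dataset annotation.
#' @export
build_stats_table <- function(ds, eps = 1) {
  stopifnot(inherits(ds, "expr_dataset"))
  structure(
    list(
      genes = ds$expr$genes,
      groups = ds$expr$groups,
      summary = group_summary(ds),
      anova = anova_per_gene(ds),
      pairwise = pairwise_tests(ds, eps = eps),
      eps = eps,
      annotation = ds$genes
    ),
    class = "stats_table"
  )
}

#' @export
print.stats_table <- function(x, ...) {
  cat(sprintf(
    "<stats_table> %d genes, %d groups, %d pairwise contrast(s), eps = %g\n",
    length(x$genes), length(x$groups),
    nrow(x$pairwise) / max(length(x$genes), 1L), x$eps))
  invisible(x)
}

# Wide one-row-per-gene layout of the lookup table, the persisted interface:
# avg_<GROUP>, sem_<GROUP>, anova_F/p/q, log2fc_<A>_vs_<B>, q_<A>_vs_<B>.
# full = TRUE appends the internal columns (n, t, df, pairwise p) needed for
# an exact reload.
stats_table_wide <- function(stats, full = FALSE) {
  stopifnot(inherits(stats, "stats_table"))
  wide <- tibble::tibble(gene = stats$genes)
  for (g in stats$groups) {
    sub <- stats$summary[stats$summary$group == g, ]
    m <- match(stats$genes, sub$gene)
    wide[[paste0("avg_", g)]] <- sub$mean[m]
    wide[[paste0("sem_", g)]] <- sub$sem[m]
    if (full) wide[[paste0("n_", g)]] <- sub$n[m]
  }
  an <- stats$anova[match(stats$genes, stats$anova$gene), ]
  wide$anova_F <- an$F
  wide$anova_p <- an$p
  wide$anova_q <- an$q
  contrasts <- unique(stats$pairwise[c("group_a", "group_b")])
  for (i in seq_len(nrow(contrasts))) {
    a <- contrasts$group_a[i]; b <- contrasts$group_b[i]
    sub <- stats$pairwise[stats$pairwise$group_a == a & stats$pairwise$group_b == b, ]
    m <- match(stats$genes, sub$gene)
    ab <- sprintf("%s_vs_%s", a, b)
    wide[[paste0("log2fc_", ab)]] <- sub$log2fc[m]
    wide[[paste0("q_", ab)]] <- sub$q[m]
    if (full) {
      wide[[paste0("t_", ab)]] <- sub$t[m]
      wide[[paste0("df_", ab)]] <- sub$df[m]
      wide[[paste0("p_", ab)]] <- sub$p[m]
    }
  }
  wide
}

# full-precision decimal rendering that survives a readr round trip,
# including Inf/NaN and empty-for-NA
.format_full <- function(x) {
  if (is.integer(x)) return(ifelse(is.na(x), "", as.character(x)))
  vapply(x, function(v) {
    if (is.nan(v)) "NaN"
    else if (is.na(v)) ""
    else if (is.infinite(v)) ifelse(v > 0, "Inf", "-Inf")
    else sprintf("%.17g", v)
  }, character(1))
}

#' Persist a statistics lookup table
#'
#' Writes the wide per-gene CSV (`stats_table.csv`) plus a JSON sidecar
#' (`stats_table.json`) holding the pseudocount, the group order, replicate
#' counts and MD5 hashes of the source files, so [load_or_build_stats()]
#' can skip recomputation when the inputs are unchanged. Numbers are written
#' at full double precision so a save/load round trip is exact.
#'
#' @param stats A `stats_table`.
#' @param dir Output directory (created if needed).
#' @param input_paths Optional character vector of source-file paths to hash.
#' @return The CSV path, invisibly.
#' @export
save_stats_table <- function(stats, dir, input_paths = character()) {
  stopifnot(inherits(stats, "stats_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "stats_table.csv")
  wide <- stats_table_wide(stats, full = TRUE)
  out <- wide
  for (nm in names(wide)) {
    if (is.numeric(wide[[nm]])) out[[nm]] <- .format_full(wide[[nm]])
  }
  readr::write_csv(out, csv_path, na = "")
  hashes <- if (length(input_paths) > 0) {
    as.list(tools::md5sum(input_paths))
  } else list()
  meta <- list(
    eps = stats$eps,
    groups = as.list(stats$groups),
    input_hashes = hashes,
    degenerate_anova = as.list(stats$anova$gene[stats$anova$degenerate]),
    degenerate_pairwise = lapply(seq_len(sum(stats$pairwise$degenerate)),
      function(i) {
        row <- stats$pairwise[stats$pairwise$degenerate, ][i, ]
        list(gene = row$gene, group_a = row$group_a, group_b = row$group_b)
      }),
    annotation = list(
      symbol = stats$annotation$symbol,
      description = stats$annotation$description,
      gene_link = stats$annotation$gene_link,
      entrez_id = stats$annotation$entrez_id,
      go_terms = stats$annotation$go_terms
    )
  )
  jsonlite::write_json(meta, file.path(dir, "stats_table.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv_path)
}

#' Load a persisted statistics lookup table
#'
#' @param dir Directory written by [save_stats_table()].
#' @return A `stats_table`.
#' @export
load_stats_table <- function(dir) {
  csv_path <- file.path(dir, "stats_table.csv")
  json_path <- file.path(dir, "stats_table.json")
  if (!file.exists(csv_path) || !file.exists(json_path)) {
    stop(sprintf("no persisted stats table under %s", dir), call. = FALSE)
  }
  wide <- readr::read_csv(csv_path, progress = FALSE, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  for (nm in setdiff(names(wide), "gene")) wide[[nm]] <- as.numeric(wide[[nm]])
  meta <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  groups <- vapply(meta$groups, as.character, character(1))
  genes <- wide$gene
  k <- length(groups)

  summ <- dplyr::bind_rows(lapply(groups, function(g) {
    n <- as.integer(wide[[paste0("n_", g)]])
    tibble::tibble(gene = genes, group = g, n = n,
                   mean = wide[[paste0("avg_", g)]],
                   sem = wide[[paste0("sem_", g)]],
                   defined = n >= 2L)
  }))
  deg_anova <- vapply(meta$degenerate_anova, as.character, character(1))
  n_tot <- rowSums(sapply(groups, function(g) as.integer(wide[[paste0("n_", g)]])))
  anova <- tibble::tibble(
    gene = genes, F = wide$anova_F,
    df_between = k - 1L, df_within = as.integer(n_tot) - k,
    p = wide$anova_p, q = wide$anova_q,
    degenerate = genes %in% deg_anova
  )

  deg_pw <- meta$degenerate_pairwise
  deg_key <- vapply(deg_pw, function(d)
    paste(d$gene, d$group_a, d$group_b, sep = "\r"), character(1))
  fc_cols <- grep("^log2fc_.+_vs_.+$", names(wide), value = TRUE)
  pairwise <- dplyr::bind_rows(lapply(fc_cols, function(cn) {
    ab <- sub("^log2fc_", "", cn)
    cand <- groups[vapply(groups, function(g) startsWith(ab, paste0(g, "_vs_")),
                          logical(1))]
    a <- cand[which.max(nchar(cand))]
    b <- sub(paste0("^", a, "_vs_"), "", ab)
    tibble::tibble(
      gene = genes, group_a = a, group_b = b,
      log2fc = wide[[cn]],
      t = wide[[paste0("t_", ab)]], df = wide[[paste0("df_", ab)]],
      p = wide[[paste0("p_", ab)]], q = wide[[paste0("q_", ab)]],
      degenerate = paste(genes, a, b, sep = "\r") %in% deg_key
    )
  }))

  ann <- meta$annotation
  as_chr0 <- function(x) vapply(x, function(v) {
    if (is.null(v)) "" else as.character(v)
  }, character(1))
  annotation <- tibble::tibble(
    symbol = as_chr0(ann$symbol),
    description = as_chr0(ann$description),
    gene_link = as_chr0(ann$gene_link),
    entrez_id = as_chr0(ann$entrez_id),
    go_terms = lapply(ann$go_terms, function(g)
      vapply(g, as.character, character(1)))
  )

  structure(
    list(genes = genes, groups = groups, summary = summ, anova = anova,
         pairwise = pairwise, eps = meta$eps[[1]], annotation = annotation),
    class = "stats_table"
  )
}

#' Build the lookup table, or reload it when inputs are unchanged
#'
#' Compares MD5 hashes of the input files with those recorded in the sidecar
#' of a previously saved table; on a match the saved table is reloaded, on a
#' mismatch (or no cache) the table is rebuilt and saved with a notice.
#'
#' @param expression_path Expression CSV path.
#' @param annotation_path Annotation CSV path, or `NULL`.
#' @param cache_dir Directory for the persisted table.
#' @param eps Fold-change pseudocount.
#' @return A list with `stats` (the `stats_table`) and `cache_hit` (logical).
#' @export
load_or_build_stats <- function(expression_path, annotation_path, cache_dir,
                                eps = 1) {
  paths <- c(expression_path, if (!is.null(annotation_path)) annotation_path)
  json_path <- file.path(cache_dir, "stats_table.json")
  if (file.exists(json_path)) {
    meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    stored <- unlist(meta$input_hashes)
    current <- tools::md5sum(paths)
    if (length(stored) == length(current) &&
        all(names(stored) == names(current)) &&
        all(stored == current) &&
        identical(as.numeric(meta$eps), as.numeric(eps))) {
      return(list(stats = load_stats_table(cache_dir), cache_hit = TRUE))
    }
    message("stats cache out of date; recomputing")
  }
  ds <- read_dataset(expression_path, annotation_path)
  stats <- build_stats_table(ds, eps = eps)
  save_stats_table(stats, cache_dir, input_paths = paths)
  list(stats = stats, cache_hit = FALSE)
}
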