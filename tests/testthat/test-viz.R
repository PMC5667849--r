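test_that("dot plot table carries means with SEM bars on a shared y range", {
  st <- demo_stats()
  fig <- dot_plot(st, c("A1BG", "A2M"))
  a1bg <- fig$table[fig$table$gene == "A1BG", ]
  expect_equal(a1bg$group, c("STOMACH", "SALIVARY_GLAND"))
  expect_equal(a1bg$mean, c(260.6667, 374.6667), tolerance = 1e-6)
  expect_equal(a1bg$sem, c(13.87243, 80.85859), tolerance = 1e-6)
  expect_equal(a1bg$ymax, a1bg$mean + a1bg$sem, tolerance = 1e-12)
  # shared scale: the common upper limit is the largest mean + sem anywhere
  expect_equal(fig$meta$shared_ylim[2], max(fig$table$ymax))
  expect_s3_class(fig$plot, "ggplot")

  # zero SEM collapses the error bar without failing
  ds <- tiny_dataset(matrix(c(5, 5, 5, 1, 2, 3), nrow = 1))
  fig2 <- dot_plot(build_stats_table(ds), "G01")
  expect_equal(fig2$table$ymin[1], fig2$table$ymax[1])
})

test_that("dot plot rejects unknown genes and more than 25 panels", {
  sim <- simulate_expr_dataset(sim_config(n_genes = 30, seed = 5))
  st <- build_stats_table(sim$ds)
  expect_error(dot_plot(st, sim$truth$gene[1:26]), "25")
  expect_error(dot_plot(demo_stats(), "NOSUCH"), "NOSUCH")
})

test_that("volcano coordinates equal the stored contrast statistics", {
  st <- demo_stats()
  fig <- volcano_plot(st, "STOMACH", "SALIVARY_GLAND")
  pw <- st$pairwise
  m <- match(fig$table$gene, pw$gene)
  expect_equal(fig$table$log2fc, pw$log2fc[m], tolerance = 0)
  ok <- !fig$table$capped
  expect_equal(fig$table$neg_log10_q[ok], -log10(pw$q[m][ok]), tolerance = 0)

  flipped <- volcano_plot(st, "SALIVARY_GLAND", "STOMACH")
  expect_equal(flipped$table$log2fc, -fig$table$log2fc, tolerance = 0)
  expect_equal(flipped$table$neg_log10_q, fig$table$neg_log10_q, tolerance = 0)
  expect_error(volcano_plot(st, "STOMACH", "STOMACH"), "distinct")
})

test_that("volcano caps q = 0 genes at 110% of the largest finite height", {
  ds <- tiny_dataset(matrix(c(3, 3, 3, 9, 9, 9,
                              10, 12, 14, 11, 12, 15,
                              1, 5, 2, 8, 3, 9), nrow = 3, byrow = TRUE))
  st <- build_stats_table(ds)
  fig <- volcano_plot(st, "ALPHA", "BETA")
  capped <- fig$table[fig$table$capped, ]
  expect_equal(capped$gene, "G01")
  finite_max <- max(fig$table$neg_log10_q[!fig$table$capped])
  expect_equal(capped$neg_log10_q, finite_max * 1.1, tolerance = 1e-12)
})

test_that("difference plot scores similarity as mean absolute log2 difference", {
  sim <- simulate_expr_dataset(sim_config(n_genes = 20, seed = 15))
  st <- build_stats_table(sim$ds, eps = 0)
  ref <- st$genes[1]
  fig <- difference_plot(st, ref, "most")
  # the reference itself: all differences zero, sorted first
  expect_equal(fig$table$gene[1], ref)
  ref_rows <- fig$table[fig$table$gene == ref, ]
  expect_true(all(ref_rows$d == 0))
  expect_equal(unique(ref_rows$similarity), 0)

  least <- difference_plot(st, ref, "least")
  most_order <- unique(fig$table$gene)
  sims <- vapply(most_order, function(g)
    fig$table$similarity[fig$table$gene == g][1], numeric(1))
  expect_true(all(diff(sims) >= 0))
  expect_equal(unique(least$table$gene)[1],
               most_order[which.max(sims)])
  expect_error(difference_plot(st, "NOSUCH"), "NOSUCH")
})

test_that("a gene at exactly twice the reference sits at d = 1 everywhere", {
  base <- c(10, 12, 14, 20, 22, 24)
  ds <- tiny_dataset(rbind(base, 2 * base, c(7, 3, 9, 1, 8, 2)),
                     genes = c("REF", "DOUBLE", "NOISE"))
  st <- build_stats_table(ds, eps = 0)
  fig <- difference_plot(st, "REF", "most")
  dbl <- fig$table[fig$table$gene == "DOUBLE", ]
  expect_equal(dbl$d, c(1, 1), tolerance = 1e-12)
  expect_equal(unique(dbl$similarity), 1, tolerance = 1e-12)
  # the scaled copy ranks nearer the reference than the independent gene
  ord <- unique(fig$table$gene)
  expect_lt(which(ord == "DOUBLE"), which(ord == "NOISE"))
})

test_that("heatmap truncates to max_rows and z-scores rows on request", {
  sim <- simulate_expr_dataset(sim_config(n_genes = 60, seed = 25))
  ds <- sim$ds
  st <- build_stats_table(ds)
  ordered <- apply_query(ds, st, filter_query())$genes
  fig <- expression_heatmap(st, ordered)
  expect_equal(length(unique(fig$table$gene)), 50L)
  expect_setequal(unique(fig$table$gene), ordered[1:50])

  fig2 <- expression_heatmap(st, ordered,
                             heatmap_options(normalize = "rows"))
  for (g in unique(fig2$table$gene)[1:5]) {
    vals <- fig2$table$value[fig2$table$gene == g]
    expect_equal(mean(vals), 0, tolerance = 1e-12)
    expect_equal(sd(vals), 1, tolerance = 1e-12)
  }
  fig3 <- expression_heatmap(st, ordered[1:10],
                             heatmap_options(normalize = "columns"))
  for (grp in unique(fig3$table$group)) {
    vals <- fig3$table$value[fig3$table$group == grp]
    expect_equal(mean(vals), 0, tolerance = 1e-12)
    expect_equal(sd(vals), 1, tolerance = 1e-12)
  }
  # constant row z-scores to all zeros rather than NaN
  cds <- tiny_dataset(matrix(c(5, 5, 5, 5, 5, 5,
                               1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE))
  cst <- build_stats_table(cds)
  figc <- expression_heatmap(cst, cst$genes, heatmap_options(normalize = "rows"))
  expect_equal(figc$table$value[figc$table$gene == "G01"], c(0, 0))
})

test_that("heatmap log transform and clustering behave as documented", {
  sim <- simulate_expr_dataset(sim_config(n_genes = 12, seed = 35))
  st <- build_stats_table(sim$ds)
  plain <- expression_heatmap(st, st$genes)
  logged <- expression_heatmap(st, st$genes, heatmap_options(log_transform = TRUE))
  key <- paste(plain$table$gene, plain$table$group)
  key_log <- paste(logged$table$gene, logged$table$group)
  expect_equal(logged$table$value[match(key, key_log)],
               log2(plain$table$value + st$eps), tolerance = 1e-12)

  # two identical rows end up adjacent after complete-linkage clustering
  base <- c(10, 11, 12, 30, 31, 32)
  ds <- tiny_dataset(rbind(base, c(500, 490, 510, 100, 90, 110), base,
                           c(1, 2, 1, 2, 1, 2)),
                     genes = c("TWIN_A", "FAR", "TWIN_B", "LOW"))
  cst <- build_stats_table(ds)
  fig <- expression_heatmap(cst, cst$genes, heatmap_options(cluster_rows = TRUE))
  rows <- unique(fig$table[order(fig$table$row_order), c("gene", "row_order")])
  pos <- match(c("TWIN_A", "TWIN_B"), rows$gene)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("heatmap normalization and clustering commute with gene relabeling", {
  sim <- simulate_expr_dataset(sim_config(n_genes = 8, seed = 45))
  st <- build_stats_table(sim$ds)
  opts <- heatmap_options(normalize = "rows", cluster_rows = TRUE,
                          log_transform = FALSE)
  fig <- expression_heatmap(st, st$genes, opts)
  # relabel: reverse the gene names everywhere in the table
  st2 <- st
  relab <- stats::setNames(rev(st$genes), st$genes)
  st2$genes <- unname(relab[st$genes])
  st2$summary$gene <- unname(relab[st$summary$gene])
  st2$anova$gene <- unname(relab[st$anova$gene])
  st2$pairwise$gene <- unname(relab[st$pairwise$gene])
  st2$annotation$symbol <- unname(relab[st$annotation$symbol])
  fig2 <- expression_heatmap(st2, st2$genes, opts)
  got <- fig2$table
  got$gene <- names(relab)[match(got$gene, relab)]
  key <- function(t) t[order(t$gene, t$group), c("gene", "group", "value")]
  expect_equal(key(got), key(fig$table), tolerance = 1e-12)
})

test_that("PCA variance shares, orthogonality and reconstruction hold", {
  sim <- simulate_expr_dataset(sim_config(n_genes = 40, n_groups = 4, seed = 55))
  st <- build_stats_table(sim$ds)
  fig <- pca_plot(st, st$genes)
  ve <- fig$meta$var_explained
  expect_equal(sum(ve), 100, tolerance = 1e-9)
  expect_true(all(diff(ve) <= 1e-9))
  scores <- fig$meta$scores
  load <- fig$meta$loadings
  gram <- crossprod(scores)
  expect_equal(gram[upper.tri(gram)], rep(0, length(gram[upper.tri(gram)])),
               tolerance = 1e-6)
  expect_equal(colSums(load^2), rep(1, ncol(load)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # full-rank reconstruction of the centered matrix
  recon <- scores %*% t(load)
  expect_lt(max(abs(recon - fig$meta$centered)), 1e-8)
  # deterministic sign: dominant loading of each PC is positive
  for (j in seq_len(ncol(load))) {
    expect_gte(load[which.max(abs(load[, j])), j], 0)
  }
  expect_error(pca_plot(st, st$genes[1:2]), "3 genes")
})

test_that("a rank-one expression pattern loads entirely on PC1", {
  profile <- c(1, 2, 4)
  vals <- t(sapply(c(1, 2, 4, 8), function(s) rep(s * profile, each = 2)))
  cols <- stats::setNames(lapply(seq_len(6), function(j) vals[, j]),
                          c("AA1", "AA2", "BB1", "BB2", "CC1", "CC2"))
  p <- write_expr_fixture(cols, sprintf("R%d", 1:4))
  ds <- suppressMessages(read_dataset(p))
  st <- build_stats_table(ds, eps = 0)
  fig <- pca_plot(st, st$genes)
  expect_equal(fig$meta$var_explained[1], 100, tolerance = 1e-9)
})

test_that("figures render to valid PNG files with deterministic tables", {
  st <- demo_stats()
  fig <- dot_plot(st, "A1BG")
  dir <- tempfile("figs"); dir.create(dir)
  png1 <- file.path(dir, "a.png"); csv1 <- file.path(dir, "a.csv")
  png2 <- file.path(dir, "b.png"); csv2 <- file.path(dir, "b.csv")
  render_png(fig, png1, table_csv = csv1)
  render_png(fig, png2, table_csv = csv2)
  expect_true(file.exists(png1))
  expect_gt(file.size(png1), 0)
  magic <- readBin(png1, "raw", n = 8)
  expect_identical(magic, as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  expect_identical(readLines(csv1), readLines(csv2))
  expect_error(render_png(fig, png1, dpi = 0), "dpi")
  expect_error(render_png(fig, file.path(dir, "no/such/dir/x.png")), "directory")
})
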