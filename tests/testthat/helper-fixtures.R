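# shared fixture builders; everything is generated in code at test time

demo_dataset <- function() {
  suppressMessages(read_dataset(demo_path("demo_expression.csv"),
                                demo_path("demo_annotation.csv")))
}

demo_stats <- function(eps = 1) build_stats_table(demo_dataset(), eps = eps)

# write a wide expression CSV from a named list of per-column values
write_expr_fixture <- function(cols, genes, path = tempfile(fileext = ".csv")) {
  df <- tibble::tibble(gene = genes)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]
  readr::write_csv(df, path, na = "")
  path
}

# a tiny two-group, three-replicate dataset built from a genes x 6 matrix
tiny_dataset <- function(values, genes = sprintf("G%02d", seq_len(nrow(values))),
                         groups = c("ALPHA", "BETA")) {
  stopifnot(ncol(values) == 6)
  cols <- stats::setNames(
    lapply(seq_len(6), function(j) values[, j]),
    c(paste0(groups[1], 1:3), paste0(groups[2], 1:3)))
  path <- write_expr_fixture(cols, genes)
  suppressMessages(read_dataset(path))
}

# a two-group dataset from explicit replicate vectors (any replicate count)
two_group_dataset <- function(x, y, genes = "G01",
                              groups = c("ALPHA", "BETA")) {
  cols <- c(stats::setNames(as.list(x), paste0(groups[1], seq_along(x))),
            stats::setNames(as.list(y), paste0(groups[2], seq_along(y))))
  suppressMessages(read_dataset(write_expr_fixture(cols, genes)))
}

# exhaustive two-group permutation p-value for the one-way ANOVA F statistic
perm_anova_p <- function(x, y) {
  obs <- c(x, y)
  n <- length(x)
  f_stat <- function(a, b) {
    gm <- mean(c(a, b))
    ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
    ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    (ssb / 1) / (ssw / (length(a) + length(b) - 2))
  }
  f_obs <- f_stat(x, y)
  idx <- utils::combn(length(obs), n)
  f_perm <- apply(idx, 2, function(i) f_stat(obs[i], obs[-i]))
  mean(f_perm >= f_obs - 1e-12)
}

# independent Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
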