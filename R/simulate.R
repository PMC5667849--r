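#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the lookup table
#' assumes: replicated sample groups with per-gene location shifts. Each
#' gene gets a baseline log2 expression `b ~ Normal(mu0, tau)`; a fraction
#' `de_fraction` of genes are differentially expressed, receiving a `+effect`
#' log2 shift in one randomly chosen group. Replicates are drawn lognormal,
#' `2^(b + shift + Normal(0, sigma))`, or negative binomial with matching
#' mean and dispersion `phi`.
#'
#' @param n_genes Number of genes (> 0).
#' @param n_groups Number of sample groups (>= 2).
#' @param n_reps Replicates per group (>= 2).
#' @param de_fraction Fraction of differentially expressed genes, in [0, 1].
#' @param effect Planted log2 fold change (>= 0).
#' @param base_mean Baseline location mu0, log2 scale.
#' @param base_spread Baseline spread tau, log2 scale (>= 0).
#' @param noise Within-group replicate noise sigma, log2 scale (> 0).
#' @param distribution `"lognormal"` or `"nbinom"`.
#' @param dispersion Negative-binomial dispersion phi (> 0), used only for
#'   `"nbinom"`.
#' @param seed Integer RNG seed; every draw is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500L, n_groups = 4L, n_reps = 3L,
                       de_fraction = 0.1, effect = 2, base_mean = 6,
                       base_spread = 2, noise = 0.25,
                       distribution = c("lognormal", "nbinom"),
                       dispersion = 0.1, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n_genes >= 1, n_groups >= 2, n_reps >= 2,
            de_fraction >= 0, de_fraction <= 1,
            effect >= 0, base_spread >= 0, noise > 0, dispersion > 0)
  structure(list(n_genes = as.integer(n_genes), n_groups = as.integer(n_groups),
                 n_reps = as.integer(n_reps), de_fraction = de_fraction,
                 effect = effect, base_mean = base_mean,
                 base_spread = base_spread, noise = noise,
                 distribution = distribution, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# fixed synthetic GO vocabulary; the planted-pathway term marks DE genes
.sim_go_vocab <- c(
  "synthetic kinase activity", "synthetic membrane transport",
  "synthetic DNA binding", "synthetic oxidoreductase activity",
  "synthetic ribosome biogenesis", "synthetic signal transduction",
  "synthetic cytoskeleton organization", "synthetic lipid metabolism",
  "synthetic ion channel activity", "synthetic transcription regulation"
)
.sim_planted_term <- "synthetic planted pathway response"

#' Simulate an expression dataset with known ground truth
#'
#' Produces the two input tables in the exact dialects the ingest module
#' reads — a wide expression data frame (`gene`, `<GROUP><rep>` columns) and
#' a long annotation data frame (`geneLink`, `GO`, `Symbol`, `description`)
#' — plus a truth table flagging the differentially expressed genes, their
#' affected group and the true log2 effect. DE genes all carry a designated
#' planted-pathway GO term; every gene gets 1-6 synthetic GO terms.
#'
#' @param cfg A [sim_config()].
#' @return A list with tibbles `expression`, `annotation`, `truth`, and the
#'   `config` used.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes; nk <- cfg$n_groups; nr <- cfg$n_reps
  genes <- sprintf("SYNG%04d", seq_len(ng))
  # group labels must be digit-free so <GROUP><replicate> headers parse back
  suffix <- do.call(paste0, expand.grid(LETTERS, c("", LETTERS))[c(2, 1)])
  groups <- paste0("GRP", suffix[seq_len(nk)])

  n_de <- round(cfg$de_fraction * ng)
  de_idx <- if (n_de > 0) sample.int(ng, n_de) else integer(0)
  affected <- rep(NA_character_, ng)
  affected[de_idx] <- sample(groups, n_de, replace = TRUE)

  baseline <- stats::rnorm(ng, cfg$base_mean, cfg$base_spread)
  shift <- matrix(0, nrow = ng, ncol = nk, dimnames = list(genes, groups))
  if (n_de > 0) {
    shift[cbind(de_idx, match(affected[de_idx], groups))] <- cfg$effect
  }

  values <- matrix(NA_real_, nrow = ng, ncol = nk * nr)
  colnames(values) <- as.vector(t(outer(groups, seq_len(nr), paste0)))
  for (k in seq_len(nk)) {
    mu_log2 <- baseline + shift[, k]
    for (r in seq_len(nr)) {
      col <- (k - 1L) * nr + r
      if (cfg$distribution == "lognormal") {
        values[, col] <- 2^(mu_log2 + stats::rnorm(ng, 0, cfg$noise))
      } else {
        mu <- 2^mu_log2
        values[, col] <- stats::rnbinom(ng, mu = mu, size = 1 / cfg$dispersion)
      }
    }
  }

  expression <- tibble::tibble(gene = genes)
  for (cn in colnames(values)) expression[[cn]] <- unname(values[, cn])

  n_terms <- sample.int(6, ng, replace = TRUE)
  annotation <- dplyr::bind_rows(lapply(seq_len(ng), function(i) {
    terms <- sample(.sim_go_vocab, n_terms[i])
    if (i %in% de_idx) terms <- unique(c(.sim_planted_term, terms))
    tibble::tibble(
      geneLink = sprintf("https://www.ncbi.nlm.nih.gov/gene/?term=%d",
                         900000L + i),
      GO = terms,
      Symbol = genes[i],
      description = sprintf("synthetic gene %d", i)
    )
  }))

  truth <- tibble::tibble(
    gene = genes,
    is_de = seq_len(ng) %in% de_idx,
    affected_group = ifelse(is.na(affected), "", affected),
    true_log2fc = ifelse(is.na(affected), 0, cfg$effect)
  )
  list(expression = expression, annotation = annotation, truth = truth,
       config = cfg)
}

#' Load a simulated dataset straight into an `expr_dataset`
#'
#' Convenience for tests and scripts: writes the simulated tables to a
#' temporary directory and runs them through the ingest readers, so the
#' simulated data take the exact same path as user data.
#'
#' @param cfg A [sim_config()].
#' @param dir Directory for the intermediate CSVs (default: a fresh tempdir).
#' @return A list with `ds` (`expr_dataset`), `truth`, `paths` and `config`.
#' @export
simulate_expr_dataset <- function(cfg = sim_config(), dir = tempfile("sim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(cfg)
  paths <- c(expression = file.path(dir, "sim_expression.csv"),
             annotation = file.path(dir, "sim_annotation.csv"),
             truth = file.path(dir, "sim_truth.csv"))
  readr::write_csv(sim$expression, paths[["expression"]])
  readr::write_csv(sim$annotation, paths[["annotation"]])
  readr::write_csv(sim$truth, paths[["truth"]])
  ds <- read_dataset(paths[["expression"]], paths[["annotation"]])
  list(ds = ds, truth = sim$truth, paths = paths, config = cfg)
}

#' Power and realized FDR of differential-expression calls
#'
#' Compares ANOVA q-value calls at a threshold against the simulator's
#' ground truth: power is the fraction of truly DE genes called, realized
#' FDR the fraction of called genes that are null.
#'
#' @param stats A `stats_table` built from a simulated dataset.
#' @param truth The matching truth tibble (`gene`, `is_de`, ...).
#' @param q_threshold Call a gene DE when its ANOVA q <= this value.
#' @return A list with `power`, `fdr`, `n_called`, `n_true`.
#' @export
recovery_report <- function(stats, truth, q_threshold = 0.05) {
  stopifnot(inherits(stats, "stats_table"))
  if (!setequal(stats$genes, truth$gene)) {
    stop("stats table and truth table cover different gene sets",
         call. = FALSE)
  }
  an <- stats$anova
  is_de <- truth$is_de[match(an$gene, truth$gene)]
  called <- !is.na(an$q) & an$q <= q_threshold
  n_called <- sum(called)
  n_true <- sum(is_de)
  power <- if (n_true == 0) NA_real_ else sum(called & is_de) / n_true
  fdr <- if (n_called == 0) 0 else sum(called & !is_de) / n_called
  list(power = power, fdr = fdr, n_called = n_called, n_true = n_true)
}
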