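#' Specification for a synthetic single-cell count matrix
#'
#' Describes a cluster-structured gamma-Poisson (negative binomial) count
#' simulation with dropout, used to exercise the full clustering pipeline
#' without any external dataset. Per-gene base means are drawn log-normal;
#' each cluster up-regulates a random subset of genes (its differentially
#' expressed set) by a multiplicative fold change; counts are over-dispersed
#' gamma-Poisson draws; technical dropout is modelled as independent
#' Bernoulli zero-masking on top of sampling.
#'
#' @param n_cells Number of cells (rows) to simulate.
#' @param n_genes Number of genes (columns) to simulate.
#' @param n_clusters Number of ground-truth clusters K.
#' @param de_fraction Fraction of genes differentially expressed per cluster,
#'   in \[0, 1\].
#' @param log_fold_change Positive log2 fold change applied to each cluster's
#'   DE genes; 0 gives a single shared mean vector (no cluster signal).
#' @param dropout_rate Target fraction of entries forced to zero by the
#'   dropout mask, in \[0, 1).
#' @param dispersion Positive gamma-Poisson over-dispersion phi; the count
#'   variance is mu + phi * mu^2.
#' @param seed Integer seed; identical specs produce bit-identical output.
#'
#' @return An object of class `"synthetic_spec"`.
#' @seealso [generate_counts()]
#' @export
synthetic_spec <- function(n_cells, n_genes, n_clusters,
                           de_fraction = 0.2, log_fold_change = 1,
                           dropout_rate = 0.3, dispersion = 0.3, seed = 0L) {
  .check(.is_count(n_cells) && n_cells >= 1, "invalid n_cells: must be a positive integer")
  .check(.is_count(n_genes) && n_genes >= 1, "invalid n_genes: must be a positive integer")
  .check(.is_count(n_clusters) && n_clusters >= 1, "invalid n_clusters: must be a positive integer")
  .check(n_clusters <= n_cells, "invalid n_clusters: must not exceed n_cells")
  .check(is.numeric(de_fraction) && de_fraction >= 0 && de_fraction <= 1,
         "invalid de_fraction: must lie in [0, 1]")
  .check(!(n_clusters > 1 && de_fraction * n_genes < 1),
         "invalid de_fraction: de_fraction * n_genes must be >= 1 when n_clusters > 1")
  .check(is.numeric(log_fold_change) && log_fold_change >= 0,
         "invalid log_fold_change: must be nonnegative")
  .check(is.numeric(dropout_rate) && dropout_rate >= 0 && dropout_rate < 1,
         "invalid dropout_rate: must lie in [0, 1)")
  .check(is.numeric(dispersion) && dispersion > 0, "invalid dispersion: must be positive")
  .check(.is_count(seed), "invalid seed: must be an integer")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters), de_fraction = de_fraction,
                 log_fold_change = log_fold_change, dropout_rate = dropout_rate,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a cluster-structured synthetic count matrix
#'
#' Draws a cells x genes nonnegative integer matrix from the gamma-Poisson
#' model described in [synthetic_spec()], together with its ground-truth
#' cluster labels. Cells are assigned to the K clusters in near-equal
#' proportions (every cluster is non-empty). Per-cell library-size factors
#' are log-normal so that totals vary realistically across cells.
#'
#' @param spec A `"synthetic_spec"` object.
#' @return A list with elements:
#'   * `counts` — n_cells x n_genes integer matrix with cell/gene dimnames;
#'   * `labels` — integer vector in 1..K, one label per cell;
#'   * `masked_fraction` — realized fraction of entries zeroed by the dropout
#'     mask (counted against the pre-mask draw).
#' @export
generate_counts <- function(spec) {
  .check(inherits(spec, "synthetic_spec"), "spec must be created by synthetic_spec()")
  n <- spec$n_cells; g <- spec$n_genes; K <- spec$n_clusters
  with_seed(spec$seed, {
    labels <- sample(rep_len(seq_len(K), n))
    base_mean <- exp(rnorm(g, mean = 0, sd = 1))
    fold <- matrix(1, nrow = K, ncol = g)
    if (K > 1 && spec$log_fold_change > 0) {
      n_de <- max(1L, round(spec$de_fraction * g))
      for (k in seq_len(K)) {
        de <- sample.int(g, n_de)
        fold[k, de] <- 2^spec$log_fold_change
      }
    }
    size_factor <- exp(rnorm(n, mean = 0, sd = 0.3))
    mu <- (size_factor %o% base_mean) * fold[labels, , drop = FALSE]
    shape <- 1 / spec$dispersion
    lambda <- matrix(rgamma(n * g, shape = shape, rate = shape / pmax(mu, 1e-12)),
                     nrow = n, ncol = g)
    counts <- matrix(rpois(n * g, lambda), nrow = n, ncol = g)
    masked <- 0
    if (spec$dropout_rate > 0) {
      mask <- matrix(runif(n * g) < spec$dropout_rate, nrow = n, ncol = g)
      counts[mask] <- 0L
      masked <- mean(mask)
    }
    dimnames(counts) <- list(paste0("cell_", seq_len(n)), paste0("gene_", seq_len(g)))
    list(counts = counts, labels = labels, masked_fraction = masked)
  })
}

#' Generate a pair of partitions differing by controlled noise
#'
#' Produces a balanced random partition of `n` items into `K` groups and a
#' perturbed copy in which `floor(noise * n)` positions are reassigned to a
#' label drawn uniformly from 1..K (a reassignment may collide with the
#' original label). Used as a fixture for agreement-metric tests.
#'
#' @param n Number of items.
#' @param K Number of groups, `1 <= K <= n`.
#' @param noise Fraction of positions to reassign, in \[0, 1\].
#' @param seed Integer seed.
#' @return A list with `a` and `b` (integer label vectors) and `reassigned`,
#'   the indices that were redrawn in `b`.
#' @export
generate_partition_pair <- function(n, K, noise = 0, seed = 0L) {
  .check(.is_count(n) && n >= 1, "invalid n: must be a positive integer")
  .check(.is_count(K) && K >= 1 && K <= n, "invalid K: must satisfy 1 <= K <= n")
  .check(is.numeric(noise) && noise >= 0 && noise <= 1, "invalid noise: must lie in [0, 1]")
  with_seed(seed, {
    a <- sample(rep_len(seq_len(K), n))
    b <- a
    m <- floor(noise * n)
    idx <- integer(0)
    if (m > 0) {
      idx <- sort(sample.int(n, m))
      b[idx] <- sample.int(K, m, replace = TRUE)
    }
    list(a = a, b = b, reassigned = idx)
  })
}

#' Write a generated count matrix to disk
#'
#' Emits the matrix in dense CSV form (cells x genes, header of gene ids,
#' first column of cell ids) and/or as a 10x-style Matrix Market triplet
#' directory (`matrix.mtx` stored genes x cells, with `barcodes.tsv` and
#' `features.tsv`), plus the labels as a one-column CSV, so that the
#' package's readers can be exercised round-trip.
#'
#' @param sim Output of [generate_counts()].
#' @param dir Output directory (created if missing).
#' @param format `"csv"`, `"mtx"`, or both.
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(sim, dir, format = c("csv", "mtx")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("csv" %in% format) {
    p <- file.path(dir, "counts.csv")
    write_counts_csv(sim$counts, p)
    paths <- c(paths, p)
  }
  if ("mtx" %in% format) {
    write_counts_mtx(sim$counts, dir)
    paths <- c(paths, file.path(dir, "matrix.mtx"))
  }
  lp <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(cell_id = rownames(sim$counts), label = sim$labels),
                   lp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, lp))
}
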