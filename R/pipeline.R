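# End-to-end orchestration of the four pipeline stages: preprocessing ->
# cell graph -> MLP encoder (+ optional standardization) -> GAT autoencoder
# -> k-means initialization -> self-optimizing refinement -> hard labels.

#' Configuration for a full pipeline run
#'
#' A master seed deterministically derives per-stage seeds, so a single
#' integer reproduces the whole run.
#'
#' @param K Number of clusters (required, >= 2).
#' @param standardize Standardize the encoder output before the attention
#'   stage? (The two modes of the method; default `TRUE`.)
#' @param seed Master seed.
#' @param preprocessing Named list of [preprocess()] arguments.
#' @param graph Named list of [build_cell_graph()] arguments
#'   (`knn_k`, `k_ne`, `alpha`, `order`, `negative_policy`, `symmetrize`).
#' @param encoder Named list of [encoder_config()] arguments.
#' @param gat Named list of [gat_config()] arguments (minus `input_dim`,
#'   which is set from the encoder).
#' @param cluster Named list of refinement arguments: `lambda_kld`,
#'   `update_interval`, `tol`, `max_epochs`, `n_restarts`,
#'   `final_kmeans` (run a terminal k-means on the refined latent instead
#'   of taking argmax-of-Q labels; default `FALSE`).
#' @return A `"scea_config"` object.
#' @export
scea_config <- function(K, standardize = TRUE, seed = 0L,
                        preprocessing = list(), graph = list(),
                        encoder = list(), gat = list(), cluster = list()) {
  .check(!missing(K) && .is_count(K) && K >= 2, "K is required and must be an integer >= 2")
  .check(.is_count(seed), "seed must be an integer")
  structure(list(K = as.integer(K), standardize = isTRUE(standardize),
                 seed = as.integer(seed), preprocessing = preprocessing,
                 graph = graph, encoder = encoder, gat = gat,
                 cluster = cluster),
            class = "scea_config")
}

#' Run the full clustering pipeline
#'
#' Executes preprocessing, graph construction + denoising, two-stage
#' non-linear dimension reduction, and self-optimizing clustering, and
#' returns hard labels plus a manifest recording configuration, per-stage
#' dimensions, filter report, loss traces, and (when truth labels are
#' supplied) ARI/NMI.
#'
#' @param X Raw cells x genes count matrix, or a path: a `.csv`/`.tsv` file
#'   or a Matrix Market triplet directory.
#' @param config A [scea_config()].
#' @param labels_true Optional ground-truth labels (vector, or named by
#'   cell id) for evaluation.
#' @param out_dir Optional output directory; when given, writes
#'   `labels.csv` and `manifest.json`.
#' @param verbose Print per-stage progress to stderr?
#' @return A list with `labels` (integer vector named by cell id),
#'   `manifest`, and the intermediate objects `graph`, `encoder_state`,
#'   `gat_state`, `latent`, `Q`.
#' @export
run_scea <- function(X, config, labels_true = NULL, out_dir = NULL,
                     verbose = FALSE) {
  .check(inherits(config, "scea_config"), "config must be an scea_config")
  say <- function(...) if (verbose) message("[scea] ", ...)
  t_stage <- function() proc.time()[["elapsed"]]
  timings <- list()

  if (is.character(X)) {
    X <- if (dir.exists(X)) read_counts_mtx(X) else read_counts_csv(X)
  }
  X <- as_expression_matrix(X)
  dims <- list(input = dim(X))
  if (!is.null(labels_true) && is.null(names(labels_true))) {
    .check(length(labels_true) == nrow(X),
           "labels_true length (", length(labels_true),
           ") does not match input cell count (", nrow(X), ")")
    names(labels_true) <- rownames(X)
  }

  say("preprocessing ", nrow(X), " x ", ncol(X))
  t0 <- t_stage()
  prep <- do.call(preprocess, c(list(X = X), config$preprocessing))
  timings$preprocessing <- t_stage() - t0
  dims$preprocessed <- dim(prep$matrix)
  .check(nrow(prep$matrix) >= config$K,
         "fewer cells after QC (", nrow(prep$matrix), ") than clusters K (",
         config$K, ")")

  say("building cell graph")
  t0 <- t_stage()
  graph <- do.call(build_cell_graph,
                   c(list(X = prep$matrix, K = config$K), config$graph))
  timings$cell_graph <- t_stage() - t0

  say("pretraining MLP encoder")
  t0 <- t_stage()
  enc_args <- config$encoder
  if (is.null(enc_args$seed)) enc_args$seed <- derive_seed(config$seed, 1L)
  enc_cfg <- do.call(encoder_config, enc_args)
  enc_state <- pretrain_encoder(prep$matrix, enc_cfg)
  E <- encode(enc_state, prep$matrix)
  if (config$standardize) E <- standardize(E)
  timings$mlp_encoder <- t_stage() - t0
  dims$embedding <- dim(E)

  say("training graph attention autoencoder")
  t0 <- t_stage()
  gat_args <- config$gat
  gat_args$input_dim <- ncol(E)
  if (is.null(gat_args$seed)) gat_args$seed <- derive_seed(config$seed, 2L)
  gat_cfg <- do.call(gat_config, gat_args)
  gat_fit <- train_gat_autoencoder(E, graph, gat_cfg)
  timings$gat_autoencoder <- t_stage() - t0
  dims$latent <- dim(gat_fit$latent)

  say("clustering (k-means init + refinement)")
  t0 <- t_stage()
  cl_args <- config$cluster
  n_restarts <- if (is.null(cl_args$n_restarts)) 10 else cl_args$n_restarts
  km <- kmeans_init(gat_fit$latent, config$K,
                    seed = derive_seed(config$seed, 3L),
                    n_restarts = n_restarts)
  ref <- refine(gat_fit$state, E, graph, km$centers,
                lambda_kld = if (is.null(cl_args$lambda_kld)) 1 else cl_args$lambda_kld,
                update_interval = if (is.null(cl_args$update_interval)) 20 else cl_args$update_interval,
                tol = if (is.null(cl_args$tol)) 0.001 else cl_args$tol,
                max_epochs = if (is.null(cl_args$max_epochs)) 200 else cl_args$max_epochs,
                learning_rate = if (is.null(cl_args$learning_rate)) 1e-4 else cl_args$learning_rate)
  labels <- ref$labels
  if (isTRUE(cl_args$final_kmeans)) {
    labels <- kmeans_init(ref$latent, config$K,
                          seed = derive_seed(config$seed, 4L),
                          n_restarts = n_restarts)$labels
  }
  names(labels) <- rownames(prep$matrix)
  timings$clustering <- t_stage() - t0

  manifest <- list(
    config = unclass_recursive(config),
    dimensions = dims,
    filter_report = unclass(prep$report),
    encoder_loss_trace = enc_state$loss_trace,
    gat_loss_trace = gat_fit$state$loss_trace,
    refinement_epochs = nrow(ref$trace),
    kmeans_init_inertia = km$inertia,
    timings_sec = timings)

  if (!is.null(labels_true)) {
    truth <- align_truth(labels_true, names(labels))
    manifest$metrics <- metrics_report(truth, labels)
    manifest$metrics_kmeans_init <- metrics_report(truth, km$labels)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(cell_id = names(labels), cluster = labels),
                     file.path(out_dir, "labels.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }

  list(labels = labels, manifest = manifest, graph = graph,
       encoder_state = enc_state, gat_state = ref$state,
       latent = ref$latent, Q = ref$Q, kmeans_init = km)
}

# Match ground-truth labels to predicted cell ids: by name when named,
# else by order.
align_truth <- function(labels_true, cell_ids) {
  if (!is.null(names(labels_true)) && !is.null(cell_ids)) {
    missing_ids <- setdiff(cell_ids, names(labels_true))
    .check(length(missing_ids) == 0,
           "truth labels missing for cells: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    labels_true[cell_ids]
  } else {
    .check(length(labels_true) == length(cell_ids),
           "truth labels length (", length(labels_true),
           ") does not match cell count (", length(cell_ids), ")")
    labels_true
  }
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Evaluate predicted labels against ground truth
#'
#' Reads both label sets (paths to CSV files, or vectors), matches cells by
#' id when both carry ids (so row order does not matter), and returns the
#' metrics report.
#'
#' @param pred Predicted labels: a CSV path (`cell_id,cluster` or one
#'   column) or a vector (optionally named by cell id).
#' @param truth Ground-truth labels in the same forms.
#' @param normalization NMI normalization (see [nmi()]).
#' @return A metrics report list (see [metrics_report()]).
#' @export
evaluate <- function(pred, truth, normalization = c("mean", "sum_log_k")) {
  normalization <- match.arg(normalization)
  if (is.character(pred) && length(pred) == 1 && file.exists(pred))
    pred <- read_labels_csv(pred)
  if (is.character(truth) && length(truth) == 1 && file.exists(truth))
    truth <- read_labels_csv(truth)
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    missing_ids <- setdiff(names(pred), names(truth))
    .check(length(missing_ids) == 0, "truth labels missing for cells: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    truth <- truth[names(pred)]
  } else {
    .check(length(pred) == length(truth),
           "label vectors differ in length (", length(pred), " vs ",
           length(truth), ")")
  }
  metrics_report(truth, pred, normalization)
}
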