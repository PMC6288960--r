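#' Run configuration for the end-to-end pipeline
#'
#' @param k,m Word length and Markov order; a missing one is filled via
#'   the k = m + 2 pairing (real-data scale defaults to k = 12, m = 10;
#'   the synthetic desk preset uses k = 8, m = 2).
#' @param measure Dissimilarity measure (default `"d2star"`).
#' @param strand Strand policy for k-mer counting.
#' @param bases Optional fixed base total: every sample is down-sampled to
#'   it before profiling (`NULL` = use all reads).
#' @param K_values K values for the KNN evaluation.
#' @param train_size Training-set size for the split evaluation (default
#'   n - 1, i.e. leave-one-out).
#' @param n_splits Number of train/test splits.
#' @param B_permutations Label permutations for the WMW test.
#' @param B_bootstrap Reference-panel bootstraps for RC.
#' @param n_subsets,subset_bases Disjoint read subsets for NC (NC is
#'   skipped when `subset_bases` is NULL).
#' @param seed Master seed; stages derive sub-seeds via [stage_seed()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(k = 12L, m = 10L, measure = "d2star",
                       strand = "both", bases = NULL, K_values = 1:10,
                       train_size = NULL, n_splits = 100,
                       B_permutations = 1e4, B_bootstrap = 1000,
                       n_subsets = 10, subset_bases = NULL, seed = 1L) {
  km <- resolve_k_m(k, m)
  structure(c(km, list(measure = measure, strand = strand, bases = bases,
                       K_values = K_values, train_size = train_size,
                       n_splits = n_splits,
                       B_permutations = B_permutations,
                       B_bootstrap = B_bootstrap, n_subsets = n_subsets,
                       subset_bases = subset_bases, seed = as.integer(seed))),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full geographic-sourcing pipeline
#'
#' Reads to profiles to dissimilarity matrix to classification, statistics
#' and confidence scores, with every output written to `out_dir`:
#' the matrix (PHYLIP + TSV), nearest-neighbor links, the KNN accuracy
#' table, per-continent and pooled permutation WMW tests, PCoA coordinates
#' and eigenvalues, the great-circle correlation summary, per-query
#' predictions with RC (and NC when read subsets are configured), and a
#' JSON manifest of the configuration. Samples whose metadata continent is
#' `"UNKNOWN"` are treated as queries: they are excluded from the reference
#' panel, the evaluation and the tests, and classified against it.
#'
#' Stage failures abort with an error naming the stage; outputs written so
#' far are kept next to an `INCOMPLETE` marker file.
#'
#' @param read_sets Named list of [read_set()] objects (references and
#'   queries).
#' @param meta Metadata data.frame (see [read_metadata()]) covering all
#'   samples.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`matrix`,
#'   `nn_links`, `accuracy`, `permtests`, `pcoa`, `geocorr`,
#'   `predictions`).
#' @export
run_pipeline <- function(read_sets, meta, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.create(file.path(out_dir, "INCOMPLETE"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ids <- vapply(read_sets, `[[`, character(1), "sample_id")
  names(read_sets) <- ids
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss))
    stop("pipeline stage 'metadata' failed: samples missing from metadata: ",
         paste(miss, collapse = ", "))
  labels <- stats::setNames(meta$continent[match(ids, meta$sample_id)], ids)
  ref_ids <- ids[labels[ids] != "UNKNOWN"]
  query_ids <- setdiff(ids, ref_ids)

  if (!is.null(config$bases)) {
    read_sets <- stage("downsample", lapply(read_sets, function(rs)
      downsample_reads(rs, config$bases,
                       seed = stage_seed(config$seed,
                                         paste0("downsample_", rs$sample_id)))))
  }

  features <- stage("profiles", lapply(read_sets, compute_features,
                                       k = config$k, m = config$m,
                                       measure = config$measure,
                                       strand = config$strand))
  dm <- stage("matrix", pairwise_matrix(features))
  write_matrix(dm, file.path(out_dir, "matrix.phylip"), "phylip")
  write_matrix(dm, file.path(out_dir, "matrix.tsv"), "tsv")

  ref_labels <- labels[ref_ids]
  nn <- stage("nn_links", nn_link_table(dm$values[ref_ids, ref_ids],
                                        ref_labels))
  write_tsv(nn, file.path(out_dir, "nn_links.tsv"))

  train_size <- if (is.null(config$train_size)) length(ref_ids) - 1L
    else config$train_size
  acc <- stage("crossval", evaluate_splits(
    dm$values[ref_ids, ref_ids], ref_labels, train_size = train_size,
    K_values = config$K_values, n_splits = config$n_splits,
    seed = stage_seed(config$seed, "splits"),
    bases = if (is.null(config$bases)) NA else config$bases))
  write_tsv(acc, file.path(out_dir, "accuracy.tsv"))

  groups <- c(unique(unname(ref_labels)), "ALL")
  permtests <- stage("permtest", lapply(groups, function(g)
    permutation_test(dm$values[ref_ids, ref_ids], ref_labels, group = g,
                     B = config$B_permutations,
                     seed = stage_seed(config$seed, paste0("perm_", g)))))
  write_tsv(data.frame(group = groups,
                       W_observed = vapply(permtests, `[[`, 0, "W_observed"),
                       p_value = vapply(permtests, `[[`, 0, "p_value"),
                       B = config$B_permutations),
            file.path(out_dir, "permtest.tsv"))

  pc <- stage("pcoa", pcoa_analysis(dm$values[ref_ids, ref_ids], r = 3))
  write_tsv(data.frame(sample_id = ref_ids, pc$coordinates),
            file.path(out_dir, "pcoa_coords.tsv"))
  write_tsv(data.frame(eigenvalue = pc$eigenvalues),
            file.path(out_dir, "pcoa_eigenvalues.tsv"))

  gc <- stage("geocorr", geo_correlation(dm$values[ref_ids, ref_ids],
                                         meta))
  write_tsv(data.frame(pearson_r = gc$pearson_r, r_squared = gc$r_squared,
                       spearman_rho = gc$spearman_rho,
                       n_pairs = gc$n_pairs),
            file.path(out_dir, "geocorr.tsv"))

  predictions <- NULL
  if (length(query_ids)) {
    predictions <- stage("queries", do.call(rbind, lapply(
      query_ids, function(q) {
        pred <- knn_predict(dm, ref_labels, q, K = min(config$K_values))
        rc <- reference_confidence(
          dm, ref_labels, q, K_values = c(1, 3), B = config$B_bootstrap,
          seed = stage_seed(config$seed, paste0("rc_", q)))
        nc <- NA_real_
        if (!is.null(config$subset_bases)) {
          nc_res <- ngs_confidence(
            read_sets[[q]], features[ref_ids], ref_labels,
            K = min(config$K_values), n_subsets = config$n_subsets,
            subset_bases = config$subset_bases,
            seed = stage_seed(config$seed, paste0("nc_", q)),
            strand = config$strand)
          nc <- nc_res$NC
        }
        data.frame(sample_id = q, predicted = pred$predicted,
                   RC_K1 = unname(rc$RC["1"]), RC_K3 = unname(rc$RC["3"]),
                   NC = nc)
      })))
    write_tsv(predictions, file.path(out_dir, "predictions.tsv"))
  }

  manifest <- c(unclass(config),
                list(n_samples = length(ids), n_references = length(ref_ids),
                     n_queries = length(query_ids),
                     package_version = as.character(
                       utils::packageVersion("kmergeo"))))
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  file.remove(file.path(out_dir, "INCOMPLETE"))
  invisible(list(matrix = dm, nn_links = nn, accuracy = acc,
                 permtests = permtests, pcoa = pc, geocorr = gc,
                 predictions = predictions))
}
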