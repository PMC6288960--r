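#' K-nearest-neighbor majority vote on a distance vector
#'
#' Deterministic tie handling: candidate neighbors are ordered by ascending
#' distance with ties broken by ascending sample id; vote ties go to the
#' tied label owning the single nearest neighbor, then to the tied label
#' with the smallest summed neighbor distance, then alphabetically.
#'
#' @param ids Candidate ids (duplicates allowed, e.g. bootstrap resamples;
#'   a duplicate can occupy several of the K slots).
#' @param dists Distances to the query, parallel to `ids`.
#' @param labels Named vector mapping sample id to class label.
#' @param K Number of neighbors.
#' @return List with `predicted`, `neighbor_ids`, `neighbor_distances`,
#'   `votes` (named integer vector).
#' @export
knn_vote <- function(ids, dists, labels, K) {
  if (K < 1) stop("K must be >= 1")
  if (length(ids) < K)
    stop("K = ", K, " exceeds the number of candidates (", length(ids), ")")
  ord <- order(dists, ids)
  top <- ord[seq_len(K)]
  nb_ids <- ids[top]
  nb_dist <- dists[top]
  nb_lab <- unname(labels[nb_ids])
  votes <- sort(table(nb_lab), decreasing = TRUE)
  tied <- names(votes)[votes == votes[1]]
  if (length(tied) > 1L) {
    # nearest neighbor among the tied labels decides
    nd <- vapply(tied, function(l) min(nb_dist[nb_lab == l]), numeric(1))
    tied <- tied[nd == min(nd)]
    if (length(tied) > 1L) {
      sd <- vapply(tied, function(l) sum(nb_dist[nb_lab == l]), numeric(1))
      tied <- tied[sd == min(sd)]
    }
    tied <- sort(tied)
  }
  list(predicted = tied[1], neighbor_ids = nb_ids,
       neighbor_distances = nb_dist,
       votes = as.integer(votes)[order(names(votes))] |>
         stats::setNames(sort(names(votes))))
}

#' Predict a sample's continent of origin by KNN
#'
#' Finds the K training samples with the smallest dissimilarity to the
#' query in a precomputed matrix and predicts by majority vote.
#'
#' @param dm A `dissim_matrix` (or plain symmetric matrix with dimnames).
#' @param train_labels Named vector mapping training sample ids to
#'   continent labels; the query must not be among them.
#' @param query_id Id of the query sample (a row of `dm`).
#' @param K Number of neighbors.
#' @return As [knn_vote()], plus `query_id` and `K`.
#' @export
knn_predict <- function(dm, train_labels, query_id, K) {
  values <- if (inherits(dm, "dissim_matrix")) dm$values else dm
  if (!query_id %in% rownames(values)) stop("query not in matrix: ", query_id)
  train_ids <- names(train_labels)
  train_ids <- setdiff(train_ids, query_id)
  missing <- setdiff(train_ids, colnames(values))
  if (length(missing))
    stop("training ids not in matrix: ", paste(missing, collapse = ", "))
  res <- knn_vote(train_ids, values[query_id, train_ids], train_labels, K)
  c(list(query_id = query_id, K = K), res)
}

#' KNN accuracy over random train/test splits
#'
#' Splits the labeled samples into training and test sets uniformly at
#' random (unstratified), predicts every test sample for each K, and
#' averages accuracy over splits.
#'
#' @param dm A `dissim_matrix` or plain symmetric matrix.
#' @param labels Named continent labels for all samples in `dm`.
#' @param train_size Training-set size (1 <= train_size < n). With
#'   `train_size = n - 1` every split is leave-one-out.
#' @param K_values Integer vector of K values to evaluate.
#' @param n_splits Number of random splits.
#' @param seed Integer seed (recorded in the output).
#' @param bases Optional base-total annotation column.
#' @return Data.frame with columns `bases`, `train_size`, `K`, `accuracy`
#'   (mean over splits), `n_splits`, `seed`.
#' @export
evaluate_splits <- function(dm, labels, train_size, K_values = 1:10,
                            n_splits = 100, seed = 1, bases = NA) {
  values <- if (inherits(dm, "dissim_matrix")) dm$values else dm
  ids <- names(labels)
  n <- length(ids)
  stopifnot(train_size >= 1, train_size < n)
  if (any(K_values > train_size))
    stop("K exceeds training size")
  acc <- matrix(0, n_splits, length(K_values))
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      train <- sample(ids, train_size)
      test <- setdiff(ids, train)
      correct <- matrix(FALSE, length(test), length(K_values))
      for (ti in seq_along(test)) {
        d <- values[test[ti], train]
        ord <- order(d, train)
        for (ki in seq_along(K_values)) {
          pred <- knn_vote(train, d, labels, K_values[ki])$predicted
          correct[ti, ki] <- pred == labels[[test[ti]]]
        }
      }
      acc[s, ] <- colMeans(correct)
    }
  })
  data.frame(bases = bases, train_size = train_size, K = K_values,
             accuracy = colMeans(acc), n_splits = n_splits, seed = seed)
}

#' Nearest-neighbor link table
#'
#' For every sample, the two most similar other samples and whether they
#' share the sample's continent — a tabular stand-in for the circular link
#' plots used to visualize reference panels.
#'
#' @param dm A `dissim_matrix` or plain symmetric matrix.
#' @param labels Named continent labels.
#' @return Data.frame with columns `sample_id`, `top1_id`, `top2_id`,
#'   `top1_dist`, `top2_dist`, `top1_same_continent`,
#'   `top2_same_continent`; attribute `top1_same_fraction` holds the
#'   summary fraction of samples whose nearest neighbor shares their
#'   continent.
#' @export
nn_link_table <- function(dm, labels) {
  values <- if (inherits(dm, "dissim_matrix")) dm$values else dm
  ids <- names(labels)
  stopifnot(length(ids) >= 3)
  rows <- lapply(ids, function(id) {
    others <- setdiff(ids, id)
    d <- values[id, others]
    ord <- order(d, others)
    data.frame(sample_id = id,
               top1_id = others[ord[1]], top2_id = others[ord[2]],
               top1_dist = d[ord[1]], top2_dist = d[ord[2]],
               top1_same_continent = labels[[others[ord[1]]]] == labels[[id]],
               top2_same_continent = labels[[others[ord[2]]]] == labels[[id]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "top1_same_fraction") <- mean(out$top1_same_continent)
  out
}

#' Reference-confidence (RC) of a KNN prediction
#'
#' Bootstraps the reference panel: B resamples of the reference ids with
#' replacement (duplicates kept as distinct votes, so a sample drawn twice
#' can occupy two of the K slots), a KNN prediction per resample, and
#' RC(K) = the fraction of resample predictions that agree with the
#' prediction using the full original panel.
#'
#' @param dm A `dissim_matrix` or plain symmetric matrix containing the
#'   query and all references.
#' @param labels Named continent labels of the reference samples (the query
#'   is excluded automatically if present).
#' @param query_id Query sample id.
#' @param K_values K values to evaluate (default 1 and 3).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `query_id`, `full_prediction` (per K), `RC` (named by
#'   K), `B`.
#' @export
reference_confidence <- function(dm, labels, query_id, K_values = c(1, 3),
                                 B = 1000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  values <- if (inherits(dm, "dissim_matrix")) dm$values else dm
  ref_ids <- setdiff(names(labels), query_id)
  d <- values[query_id, ref_ids]
  names(d) <- ref_ids
  full <- vapply(K_values, function(K)
    knn_vote(ref_ids, d, labels, K)$predicted, character(1))
  names(full) <- as.character(K_values)
  agree <- matrix(0, B, length(K_values))
  with_seed(seed, {
    for (b in seq_len(B)) {
      boot <- sample(ref_ids, length(ref_ids), replace = TRUE)
      for (ki in seq_along(K_values)) {
        pred <- knn_vote(boot, d[boot], labels, K_values[ki])$predicted
        agree[b, ki] <- pred == full[ki]
      }
    }
  })
  rc <- colMeans(agree)
  names(rc) <- as.character(K_values)
  list(query_id = query_id, full_prediction = full, RC = rc, B = B)
}

#' NGS-confidence (NC) of a KNN prediction
#'
#' Quantifies the sensitivity of a prediction to which reads were
#' sequenced: the query's reads are split into disjoint subsets of a fixed
#' base total, the full profile-dissimilarity-KNN pipeline is rerun per
#' subset, and NC is the fraction of subsets predicting the modal label.
#' A modal tie is broken by the label of the subset with the smallest
#' nearest-neighbor distance.
#'
#' @param query_reads A [read_set()] for the query sample.
#' @param ref_features List of `sample_features` for the reference panel
#'   (see [compute_features()]), all with one measure/k/m.
#' @param ref_labels Named continent labels of the references.
#' @param K Number of neighbors.
#' @param n_subsets Number of disjoint read subsets (fewer are used, with a
#'   warning, if the reads run out).
#' @param subset_bases Base total per subset.
#' @param seed Integer seed for the read partition.
#' @param strand Strand policy for the subset profiles.
#' @return List with `query_id`, `predictions` (one per subset), `modal`,
#'   `NC`, `n_subsets_used`.
#' @export
ngs_confidence <- function(query_reads, ref_features, ref_labels, K = 1,
                           n_subsets = 10, subset_bases, seed = 1,
                           strand = "both") {
  parts <- partition_reads(query_reads, n_subsets, subset_bases, seed)
  if (length(parts) == 0)
    stop("insufficient data: no read subset of ", subset_bases,
         " bases could be formed")
  k <- ref_features[[1]]$k
  m <- ref_features[[1]]$m
  measure <- ref_features[[1]]$measure
  ref_ids <- vapply(ref_features, `[[`, character(1), "sample_id")
  preds <- character(length(parts))
  min_d <- numeric(length(parts))
  for (i in seq_along(parts)) {
    qf <- compute_features(parts[[i]], k = k, m = m, measure = measure,
                           strand = strand)
    d <- drop(cross_dissimilarity(list(qf), ref_features))
    names(d) <- ref_ids
    preds[i] <- knn_vote(ref_ids, d, ref_labels, K)$predicted
    min_d[i] <- min(d)
  }
  tab <- table(preds)
  modal_set <- names(tab)[tab == max(tab)]
  if (length(modal_set) > 1L) {
    # modal tie: the tied label whose subset has the smallest 1NN distance
    cand <- which(preds %in% modal_set)
    modal <- preds[cand[which.min(min_d[cand])]]
  } else modal <- modal_set
  list(query_id = query_reads$sample_id, predictions = preds,
       modal = modal, NC = unname(max(tab)) / length(preds),
       n_subsets_used = length(parts))
}
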