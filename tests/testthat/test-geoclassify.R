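# small labeled matrix: distances from one query to labeled references
query_matrix <- function(dists, labels) {
  ids <- c("q", names(dists))
  v <- matrix(0.5, length(ids), length(ids), dimnames = list(ids, ids))
  v["q", names(dists)] <- dists
  v[names(dists), "q"] <- dists
  diag(v) <- 0
  list(values = v, labels = stats::setNames(labels, names(dists)))
}

test_that("KNN majority vote and tie rules are deterministic", {
  qm <- query_matrix(c(A1 = 0.1, A2 = 0.2, B1 = 0.3),
                     c("A", "A", "B"))
  pred <- knn_predict(qm$values, qm$labels, "q", K = 2)
  expect_equal(pred$predicted, "A")
  expect_equal(unname(pred$votes["A"]), 2L)
  expect_equal(pred$neighbor_ids, c("A1", "A2"))

  pred <- knn_predict(qm$values, qm$labels, "q", K = 3)
  expect_equal(pred$predicted, "A")  # votes A:2, B:1

  # vote tie at K=2: nearest neighbor's label wins
  qm <- query_matrix(c(B1 = 0.1, A1 = 0.2), c("B", "A"))
  expect_equal(knn_predict(qm$values, qm$labels, "q", K = 2)$predicted, "B")

  # equal-distance neighbors: id order breaks the selection tie
  qm <- query_matrix(c(A1 = 0.2, B1 = 0.2, B2 = 0.4), c("A", "B", "B"))
  pred <- knn_predict(qm$values, qm$labels, "q", K = 1)
  expect_equal(pred$neighbor_ids, "A1")

  # still-tied votes fall back to smallest summed distance
  qm <- query_matrix(c(A1 = 0.2, B1 = 0.2, A2 = 0.3, B2 = 0.35),
                     c("A", "B", "A", "B"))
  expect_equal(knn_predict(qm$values, qm$labels, "q", K = 4)$predicted, "A")

  expect_error(knn_predict(qm$values, qm$labels, "q", K = 9), "exceeds")
  expect_error(knn_predict(qm$values, qm$labels, "zz", K = 1),
               "not in matrix")
})

test_that("KNN is invariant to sample relabeling and row order", {
  labels <- stats::setNames(rep(c("NA", "EU", "AS"), each = 4),
                            sprintf("s%02d", 1:12))
  set.seed(9)
  v <- separated_matrix(labels, 0.1, 0.9) +
    matrix(stats::runif(144, 0, 0.05), 12, 12)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  p1 <- knn_predict(v, labels[-1], "s01", K = 3)
  # permute rows/columns
  perm <- sample(rownames(v))
  p2 <- knn_predict(v[perm, perm], labels[-1], "s01", K = 3)
  expect_equal(p1$predicted, p2$predicted)
  expect_equal(p1$neighbor_ids, p2$neighbor_ids)
  # rename every sample consistently
  ren <- stats::setNames(sprintf("t%02d", 1:12), rownames(v))
  v3 <- v
  dimnames(v3) <- list(ren[rownames(v)], ren[colnames(v)])
  lab3 <- stats::setNames(labels[-1], ren[names(labels[-1])])
  p3 <- knn_predict(v3, lab3, ren[["s01"]], K = 3)
  expect_equal(p3$predicted, p1$predicted)
})

test_that("split evaluation recovers separation and chance levels", {
  labels <- stats::setNames(rep(c("NA", "EU", "AS"), each = 6),
                            sprintf("s%02d", 1:18))
  v <- separated_matrix(labels)
  acc <- evaluate_splits(v, labels, train_size = 12, K_values = c(1, 3),
                         n_splits = 10, seed = 2)
  expect_equal(acc$accuracy, c(1, 1))

  # shuffled labels on an unstructured matrix: ~ chance (1/3)
  set.seed(10)
  n <- 18
  v2 <- matrix(stats::runif(n * n, 0.4, 0.6), n, n,
               dimnames = dimnames(v))
  v2 <- (v2 + t(v2)) / 2
  diag(v2) <- 0
  acc2 <- evaluate_splits(v2, labels, train_size = 12, K_values = 1,
                          n_splits = 60, seed = 3)
  expect_gt(acc2$accuracy, 1 / 3 - 0.15)
  expect_lt(acc2$accuracy, 1 / 3 + 0.15)

  # train_size = n - 1 is leave-one-out: matches the nn-link logic at K=1
  acc3 <- evaluate_splits(v, labels, train_size = 17, K_values = 1,
                          n_splits = 20, seed = 4)
  nn <- nn_link_table(v, labels)
  expect_equal(acc3$accuracy, attr(nn, "top1_same_fraction"))
})

test_that("nearest-neighbor links report ordered neighbors and summary", {
  labels <- stats::setNames(rep(c("NA", "EU", "AS"), each = 3),
                            sprintf("s%d", 1:9))
  v <- separated_matrix(labels)
  nn <- nn_link_table(v, labels)
  expect_true(all(nn$top1_same_continent))
  expect_equal(attr(nn, "top1_same_fraction"), 1)
  expect_true(all(nn$top1_dist <= nn$top2_dist))

  # one sample pulled away from its class and towards another: its top-1
  # flips, everyone else keeps a closer within-class neighbor
  v2 <- v
  v2["s1", setdiff(names(labels)[labels == "NA"], "s1")] <- 0.95
  v2[setdiff(names(labels)[labels == "NA"], "s1"), "s1"] <- 0.95
  v2["s1", "s4"] <- v2["s4", "s1"] <- 0.5
  nn2 <- nn_link_table(v2, labels)
  expect_equal(attr(nn2, "top1_same_fraction"), (9 - 1) / 9)
})

test_that("reference confidence is 1 under separation, < 1 at a margin", {
  labels <- stats::setNames(rep(c("NA", "EU", "AS"), each = 8),
                            sprintf("s%02d", 1:24))
  v <- separated_matrix(labels)
  ids <- c("q", names(labels))
  vq <- matrix(0.9, 25, 25, dimnames = list(ids, ids))
  vq[-1, -1] <- v
  vq["q", names(labels)[labels == "EU"]] <- 0.1
  vq[names(labels)[labels == "EU"], "q"] <- 0.1
  diag(vq) <- 0
  rc <- reference_confidence(vq, labels, "q", K_values = c(1, 3), B = 100,
                             seed = 5)
  # a bootstrap panel can in principle lose nearly all of one continent,
  # so demand exact agreement at K=1 and near-total agreement at K=3
  expect_equal(unname(rc$RC[["1"]]), 1)
  expect_gte(rc$RC[["3"]], 0.95)
  expect_equal(unname(rc$full_prediction), c("EU", "EU"))

  # borderline query: jittered distances straddling two continents
  set.seed(6)
  vq["q", ] <- vq[, "q"] <- 0.9
  na_ids <- names(labels)[labels == "NA"]
  eu_ids <- names(labels)[labels == "EU"]
  vq["q", c(na_ids, eu_ids)] <- stats::runif(16, 0.4, 0.6)
  vq[c(na_ids, eu_ids), "q"] <- vq["q", c(na_ids, eu_ids)]
  diag(vq) <- 0
  rc2 <- reference_confidence(vq, labels, "q", K_values = 1, B = 200,
                              seed = 7)
  expect_lt(rc2$RC[["1"]], 1)

  expect_error(reference_confidence(vq, labels, "q", B = 0), "B must be")
})

test_that("NGS confidence reruns the pipeline on disjoint read subsets", {
  cfg <- desk_config(3)
  pop <- simulate_samples(modifyList_cfg(cfg, n_individuals = 3L))
  refs <- lapply(names(pop$genomes), function(id)
    sequence_reads(pop$genomes[[id]], 100, 200000, 0.001,
                   seed = stage_seed(3, id), sample_id = id))
  ref_feats <- lapply(refs, compute_features, k = 6, m = 2,
                      measure = "d2star")
  labels <- stats::setNames(pop$meta$continent, pop$meta$sample_id)
  query <- sequence_reads(pop$genomes[["EU_01"]], 100, 450000, 0.001,
                          seed = 99, sample_id = "query")
  nc <- ngs_confidence(query, ref_feats, labels, K = 1, n_subsets = 3,
                       subset_bases = 150000, seed = 8)
  expect_equal(nc$NC, 1)
  expect_equal(nc$modal, "EU")
  expect_equal(nc$n_subsets_used, 3)

  expect_error(ngs_confidence(query, ref_feats, labels, n_subsets = 2,
                              subset_bases = 1e7, seed = 1),
               "insufficient")
})
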