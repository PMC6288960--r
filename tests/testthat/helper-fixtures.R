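# shared fixtures, generated in code

# random read set over ACGT
random_read_set <- function(n_reads, read_len, seed, id = "rand") {
  set.seed(seed)
  reads <- vapply(seq_len(n_reads), function(i)
    paste(sample(c("A", "C", "G", "T"), read_len, replace = TRUE),
          collapse = ""), character(1))
  read_set(reads, sample_id = id)
}

# random kmer_profile (counts drawn over the full 4^k alphabet)
random_profile <- function(k, seed, id = "p") {
  set.seed(seed)
  counts <- as.numeric(rpois(4^k, lambda = 3))
  if (sum(counts) == 0) counts[1] <- 1
  structure(list(k = as.integer(k), counts = counts, N = sum(counts),
                 sample_id = id),
            class = "kmer_profile")
}

# block matrix with constant within-group and between-group dissimilarity
separated_matrix <- function(labels, intra = 0.1, inter = 0.9) {
  ids <- names(labels)
  n <- length(ids)
  v <- matrix(inter, n, n, dimnames = list(ids, ids))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    v[idx, idx] <- intra
  }
  diag(v) <- 0
  v
}

# the desk-scale synthetic preset used across the deeper checks
desk_config <- function(seed, ...) {
  sim_config(genome_length = 200000L, n_individuals = 12L,
             delta_continental = 0.02, delta_individual = 0.002,
             read_length = 100L, bases_per_sample = 200000L,
             error_rate = 0.001, seed = seed, ...)
}

# tweak fields of a sim_config while keeping its class
modifyList_cfg <- function(cfg, ...) {
  upd <- list(...)
  for (n in names(upd)) cfg[[n]] <- upd[[n]]
  cfg
}

# one full desk-preset run (simulation, features, d2* matrix), memoized per
# seed because several deep checks reuse the same panels
.desk_cache <- new.env(parent = emptyenv())
desk_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  cfg <- desk_config(seed)
  sim <- simulate_read_sets(cfg)
  features <- lapply(sim$read_sets, compute_features, k = 8, m = 2,
                     measure = "d2star")
  dm <- pairwise_matrix(features)
  labels <- stats::setNames(sim$meta$continent, sim$meta$sample_id)
  out <- list(cfg = cfg, sim = sim, features = features, dm = dm,
              labels = labels)
  .desk_cache[[key]] <- out
  out
}

# leave-one-out 1NN accuracy from a (possibly rectangular) distance matrix:
# rows = queries, columns = references sharing the query ids
loo_1nn_accuracy <- function(values, labels) {
  ids <- rownames(values)
  correct <- vapply(ids, function(id) {
    others <- setdiff(colnames(values), id)
    pred <- knn_vote(others, values[id, others], labels, K = 1)$predicted
    pred == labels[[id]]
  }, logical(1))
  mean(correct)
}
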