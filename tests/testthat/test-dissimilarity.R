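# profiles with prescribed counts, for closed-form cases
make_profile <- function(counts, k, id = "p") {
  full <- numeric(4^k)
  full[seq_along(counts)] <- counts
  names(full) <- kmergeo:::all_kmers(k)
  structure(list(k = as.integer(k), counts = full, N = sum(full),
                 sample_id = id),
            class = "kmer_profile")
}

# order-0 model with prescribed base probabilities
make_model0 <- function(p4, id = "m") {
  trans <- matrix(p4, nrow = 1, dimnames = list("", c("A","C","G","T")))
  structure(list(m = 0L, trans = trans, initial = c(1), sample_id = id),
            class = "markov_model")
}

test_that("frequency-based distances match closed forms", {
  # f_x = (.5,.5,0), f_y = (.25,.25,.5) over three words
  x <- make_profile(c(2, 2, 0), k = 1)
  y <- make_profile(c(1, 1, 2), k = 1)
  expect_equal(manhattan_dissimilarity(x, y), 1.0)
  expect_equal(euclid_dissimilarity(x, y), sqrt(2 * 0.0625 + 0.25))

  expect_equal(manhattan_dissimilarity(x, x), 0)
  expect_equal(euclid_dissimilarity(x, x), 0)

  # disjoint supports: total variation bound x2 / point masses
  a <- make_profile(c(3, 0), k = 1)
  b <- make_profile(c(0, 7), k = 1)
  expect_equal(manhattan_dissimilarity(a, b), 2)
  expect_equal(euclid_dissimilarity(a, b), sqrt(2))

  # d2 cosine arithmetic
  x2 <- make_profile(c(1, 1), k = 1)
  y2 <- make_profile(c(1, 0), k = 1)
  expect_equal(d2_dissimilarity(x2, y2), 0.5 * (1 - 1 / sqrt(2)))
  expect_equal(d2_dissimilarity(a, b), 0.5)  # orthogonal
  expect_equal(d2_dissimilarity(x2, x2), 0)

  empty <- make_profile(c(0, 0), k = 1)
  expect_error(manhattan_dissimilarity(x, empty), "undefined")
  expect_error(d2_dissimilarity(x, empty), "undefined")
  expect_error(manhattan_dissimilarity(x, make_profile(1, k = 2)),
               "different k")
})

test_that("d2* and d2s are 0 at identity and 1 at anti-correlation", {
  rs <- random_read_set(20, 50, seed = 51)
  kp <- count_kmers(rs, 3)
  mm <- fit_markov(rs, 1)
  expect_equal(d2star_dissimilarity(kp, mm, kp, mm), 0, tolerance = 1e-12)
  expect_equal(d2s_dissimilarity(kp, mm, kp, mm), 0, tolerance = 1e-12)

  # uniform order-0 background, N = 8, expectation 2 per word:
  # centered X = (2,-2,0,0), centered Y = (-2,2,0,0) = -X
  m0 <- make_model0(c(0.25, 0.25, 0.25, 0.25))
  x <- make_profile(c(4, 0, 2, 2), k = 1)
  y <- make_profile(c(0, 4, 2, 2), k = 1)
  expect_equal(d2star_dissimilarity(x, m0, y, m0), 1)
  expect_equal(d2s_dissimilarity(x, m0, y, m0), 1)
})

test_that("CVTree composition vectors use the plug-in expectation", {
  rs <- random_read_set(20, 60, seed = 61)
  trip <- lapply(3:1, function(k) count_kmers(rs, k))
  expect_equal(cvtree_dissimilarity(trip[[1]], trip[[2]], trip[[3]],
                                    trip[[1]], trip[[2]], trip[[3]]),
               0, tolerance = 1e-12)

  # per-word oracle evaluation on a second sample
  rs2 <- random_read_set(20, 60, seed = 62)
  trip2 <- lapply(3:1, function(k) count_kmers(rs2, k))
  got <- cvtree_dissimilarity(trip[[1]], trip[[2]], trip[[3]],
                              trip2[[1]], trip2[[2]], trip2[[3]])
  want <- oracle_measures(rs$reads, rs2$reads, k = 3, m = 1)$cvtree
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("all six measures match the brute-force oracle on random pairs", {
  for (seed in 1:3) {
    rs_x <- random_read_set(10, 60, seed = 100 + seed, id = "x")
    rs_y <- random_read_set(10, 60, seed = 200 + seed, id = "y")
    k <- c(3, 4, 3)[seed]
    m <- c(0, 1, 2)[seed]
    got <- package_measures(rs_x, rs_y, k, m)
    want <- oracle_measures(rs_x$reads, rs_y$reads, k, m)
    for (meas in names(want)) {
      expect_equal(got[[meas]], want[[meas]], tolerance = 1e-9,
                   label = sprintf("%s (k=%d, m=%d)", meas, k, m))
    }
  }
})

test_that("measures respect their metric identities and bounds", {
  set.seed(71)
  for (i in 1:20) {
    x <- random_profile(3, seed = 300 + i)
    y <- random_profile(3, seed = 400 + i)
    z <- random_profile(3, seed = 500 + i)
    expect_equal(manhattan_dissimilarity(x, y),
                 manhattan_dissimilarity(y, x), tolerance = 1e-12)
    expect_lte(manhattan_dissimilarity(x, y), 2)
    expect_lte(euclid_dissimilarity(x, y), sqrt(2))
    d2v <- d2_dissimilarity(x, y)
    expect_gte(d2v, 0); expect_lte(d2v, 1)
    # triangle inequality for the true metrics
    expect_lte(manhattan_dissimilarity(x, z),
               manhattan_dissimilarity(x, y) + manhattan_dissimilarity(y, z)
               + 1e-12)
    expect_lte(euclid_dissimilarity(x, z),
               euclid_dissimilarity(x, y) + euclid_dissimilarity(y, z)
               + 1e-12)
  }
})

test_that("expected d2* grows with substitution divergence", {
  deltas <- c(0.001, 0.01, 0.05, 0.1)
  means <- sapply(seq_along(deltas), function(di) {
    mean(sapply(1:5, function(s) {
      g <- simulate_root_genome(50000, seed = 900 + s)
      g2 <- evolve_sequence(g, deltas[di], seed = 950 + 10 * di + s)
      rs1 <- sequence_reads(g, 100, 50000, seed = 980 + s, sample_id = "a")
      rs2 <- sequence_reads(g2, 100, 50000, seed = 990 + s, sample_id = "b")
      f1 <- compute_features(rs1, k = 6, m = 2, measure = "d2star")
      f2 <- compute_features(rs2, k = 6, m = 2, measure = "d2star")
      pairwise_matrix(list(f1, f2))$values[1, 2]
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("pairwise matrices are symmetric and agree with direct calls", {
  sets <- lapply(1:4, function(i) random_read_set(15, 60, seed = 700 + i,
                                                  id = paste0("s", i)))
  dm <- dissimilarity_matrix(sets, k = 3, m = 1, measure = "d2star")
  expect_true(isSymmetric(unname(dm$values)))
  expect_equal(unname(diag(dm$values)), rep(0, 4))
  f2 <- compute_features(sets[[2]], k = 3, m = 1, measure = "d2star")
  f3 <- compute_features(sets[[3]], k = 3, m = 1, measure = "d2star")
  direct <- d2star_dissimilarity(f2$profile, f2$model, f3$profile, f3$model)
  expect_equal(dm$values[2, 3], direct, tolerance = 1e-12)

  # two identical samples: all-zero matrix
  twin <- read_set(sets[[1]]$reads, "twin")
  dm2 <- dissimilarity_matrix(list(sets[[1]], twin), k = 3, m = 1)
  expect_equal(max(abs(dm2$values)), 0, tolerance = 1e-12)
})

test_that("matrix files round-trip in PHYLIP and TSV dialects", {
  tmp <- withr::local_tempdir()
  sets <- lapply(1:3, function(i) random_read_set(10, 50, seed = 800 + i,
                                                  id = paste0("s", i)))
  dm <- dissimilarity_matrix(sets, k = 3, m = 1)
  for (fmt in c("phylip", "tsv")) {
    p <- file.path(tmp, paste0("m.", fmt))
    write_matrix(dm, p, fmt)
    back <- read_matrix(p, fmt)
    expect_equal(back$sample_ids, dm$sample_ids)
    expect_equal(back$values, dm$values, tolerance = 1e-9)
  }
  # the two dialects parse to the same matrix
  a <- read_matrix(file.path(tmp, "m.phylip"), "phylip")
  b <- read_matrix(file.path(tmp, "m.tsv"), "tsv")
  expect_equal(a$values, b$values, tolerance = 1e-12)

  bad <- file.path(tmp, "bad.phylip")
  writeLines(c("    3", "s1  0 0.5", "s2  0.5 0"), bad)
  expect_error(read_matrix(bad, "phylip"), "malformed")
})
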