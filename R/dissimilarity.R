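#' Alignment-free dissimilarity measures between k-mer profiles
#'
#' Six measures over profiles of the same word length k. `manhattan`,
#' `euclid` and `d2` act on relative k-mer frequencies; `d2star` and `d2s`
#' first center counts by their expectation under each sample's own Markov
#' background model; `cvtree` centers by a (k-1)/(k-2)-mer plug-in
#' expectation. The correlation-type measures (`d2`, `d2star`, `d2s`,
#' `cvtree`) are mapped to `[0, 1]` as (1 - correlation)/2, so 0 means
#' identical profiles and 1 perfect anti-correlation.
#'
#' @param x,y `kmer_profile` objects of equal k with N > 0.
#' @return A non-negative dissimilarity.
#' @name dissimilarity-measures
NULL

check_pair <- function(x, y) {
  stopifnot(inherits(x, "kmer_profile"), inherits(y, "kmer_profile"))
  if (x$k != y$k) stop("profiles have different k: ", x$k, " vs ", y$k)
  if (x$N == 0 || y$N == 0)
    stop("undefined measure: empty k-mer profile (N = 0)")
}

#' @rdname dissimilarity-measures
#' @export
manhattan_dissimilarity <- function(x, y) {
  check_pair(x, y)
  sum(abs(x$counts / x$N - y$counts / y$N))
}

#' @rdname dissimilarity-measures
#' @export
euclid_dissimilarity <- function(x, y) {
  check_pair(x, y)
  sqrt(sum((x$counts / x$N - y$counts / y$N)^2))
}

#' @rdname dissimilarity-measures
#' @export
d2_dissimilarity <- function(x, y) {
  check_pair(x, y)
  nx <- sqrt(sum(x$counts^2))
  ny <- sqrt(sum(y$counts^2))
  if (nx == 0 || ny == 0) stop("undefined measure: zero-norm profile")
  0.5 * (1 - sum(x$counts * y$counts) / (nx * ny))
}

#' @rdname dissimilarity-measures
#' @param mx,my `markov_model` objects (same order m) fitted on the same
#'   samples as `x` and `y`.
#' @param px,py Optional precomputed [word_probabilities()] vectors for
#'   `mx`/`my` at word length `x$k` (recomputed when missing).
#' @details For `d2star`, words with zero background probability in either
#'   sample are excluded from the cross term and from both self-normalizers;
#'   there are no pseudocounts. For `d2s`, terms with both centered counts
#'   zero are skipped.
#' @export
d2star_dissimilarity <- function(x, mx, y, my, px = NULL, py = NULL) {
  check_pair(x, y)
  stopifnot(inherits(mx, "markov_model"), inherits(my, "markov_model"))
  if (mx$m != my$m) stop("models have different order m")
  if (mx$m > x$k) stop("model order m exceeds profile k")
  if (is.null(px)) px <- word_probabilities(mx, x$k)
  if (is.null(py)) py <- word_probabilities(my, y$k)
  keep <- px > 0 & py > 0
  if (!any(keep))
    stop("undefined measure: no word with positive background probability ",
         "in both samples")
  xc <- x$counts[keep] - x$N * px[keep]
  yc <- y$counts[keep] - y$N * py[keep]
  denom <- sqrt(x$N * px[keep] * y$N * py[keep])
  D2 <- sum(xc * yc / denom)
  nx <- sqrt(sum(xc^2 / (x$N * px[keep])))
  ny <- sqrt(sum(yc^2 / (y$N * py[keep])))
  if (nx == 0 || ny == 0) stop("undefined measure: zero d2* normalizer")
  0.5 * (1 - D2 / (nx * ny))
}

#' @rdname dissimilarity-measures
#' @export
d2s_dissimilarity <- function(x, mx, y, my, px = NULL, py = NULL) {
  check_pair(x, y)
  stopifnot(inherits(mx, "markov_model"), inherits(my, "markov_model"))
  if (mx$m != my$m) stop("models have different order m")
  if (is.null(px)) px <- word_probabilities(mx, x$k)
  if (is.null(py)) py <- word_probabilities(my, y$k)
  xc <- x$counts - x$N * px
  yc <- y$counts - y$N * py
  r <- sqrt(xc^2 + yc^2)
  keep <- r > 0
  if (!any(keep)) stop("undefined measure: all centered counts zero")
  xc <- xc[keep]; yc <- yc[keep]; r <- r[keep]
  D2 <- sum(xc * yc / r)
  nx <- sqrt(sum(xc^2 / r))
  ny <- sqrt(sum(yc^2 / r))
  if (nx == 0 || ny == 0) stop("undefined measure: zero d2s normalizer")
  0.5 * (1 - D2 / (nx * ny))
}

# composition-vector entry a_w = (X_w - E_w)/E_w with the plug-in
# expectation E_w = X(prefix) * X(suffix) / X(middle); 0 where E_w = 0
cvtree_vector <- function(kp, kp1, kp2) {
  k <- kp$k
  i <- 0:(4^k - 1)
  prefix <- i %/% 4L + 1L           # first k-1 bases
  suffix <- i %% 4^(k - 1) + 1L     # last  k-1 bases
  middle <- (i %/% 4L) %% 4^(k - 2) + 1L  # central k-2 bases
  E <- ifelse(kp2$counts[middle] > 0,
              kp1$counts[prefix] * kp1$counts[suffix] / kp2$counts[middle],
              0)
  ifelse(E > 0, (kp$counts - E) / E, 0)
}

#' @rdname dissimilarity-measures
#' @param x1,x2,y1,y2 Companion profiles of word lengths k-1 and k-2 for
#'   the same samples as `x` and `y` (CVTree's plug-in expectation).
#' @export
cvtree_dissimilarity <- function(x, x1, x2, y, y1, y2) {
  check_pair(x, y)
  stopifnot(x1$k == x$k - 1L, x2$k == x$k - 2L,
            y1$k == y$k - 1L, y2$k == y$k - 2L)
  if (x$k < 2) stop("cvtree requires k >= 2")
  a <- cvtree_vector(x, x1, x2)
  b <- cvtree_vector(y, y1, y2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined measure: zero composition-vector norm")
  0.5 * (1 - sum(a * b) / (na * nb))
}

MEASURES <- c("manhattan", "euclid", "d2", "cvtree", "d2star", "d2s")

#' Precompute per-sample features for a dissimilarity measure
#'
#' Builds, once per sample, everything a pairwise measure needs: the k-mer
#' profile, and depending on the measure the Markov model with its word
#' probabilities (`d2star`, `d2s`) or the (k-1)/(k-2)-mer companion
#' profiles (`cvtree`). Doing this up front makes the n x n matrix loop a
#' pure vector computation.
#'
#' @param rs A [read_set()].
#' @param k Word length.
#' @param m Markov order (background-adjusted measures). If only one of
#'   `k`/`m` is given the other defaults via the k = m + 2 pairing.
#' @param measure One of "d2star", "d2s", "cvtree", "d2", "euclid",
#'   "manhattan".
#' @param strand Strand policy, see [count_kmers()].
#' @return An object of class `sample_features`.
#' @export
compute_features <- function(rs, k = NULL, m = NULL,
                             measure = c("d2star", "d2s", "cvtree", "d2",
                                         "euclid", "manhattan"),
                             strand = c("both", "forward")) {
  measure <- match.arg(measure)
  strand <- match.arg(strand)
  km <- resolve_k_m(k, m)
  k <- km$k; m <- km$m
  f <- list(sample_id = rs$sample_id, k = k, m = m, measure = measure,
            profile = count_kmers(rs, k, strand))
  if (measure %in% c("d2star", "d2s")) {
    f$model <- fit_markov(rs, m, strand)
    f$p <- word_probabilities(f$model, k)
    f$centered <- f$profile$counts - f$profile$N * f$p
    if (measure == "d2star") {
      # the standardized vector X~_w / sqrt(N p_w) makes the pair loop a
      # plain inner product when every word has positive background
      # probability in both samples
      f$pos <- f$p > 0
      u <- numeric(length(f$p))
      u[f$pos] <- f$centered[f$pos] / sqrt(f$profile$N * f$p[f$pos])
      f$u <- u
      f$u_norm2 <- sum(u^2)
    }
  } else if (measure == "cvtree") {
    f$profile_k1 <- count_kmers(rs, k - 1L, strand)
    f$profile_k2 <- count_kmers(rs, k - 2L, strand)
    f$cv <- cvtree_vector(f$profile, f$profile_k1, f$profile_k2)
    f$cv_norm <- sqrt(sum(f$cv^2))
  } else {
    f$freq <- f$profile$counts / f$profile$N
    if (measure == "d2") {
      cn <- sqrt(sum(f$profile$counts^2))
      if (cn == 0) stop("undefined measure: zero-norm profile")
      f$cn <- f$profile$counts / cn
    }
  }
  structure(f, class = "sample_features")
}

#' Resolve the k / m pairing
#'
#' Background-adjusted measures perform well with word length two above the
#' Markov order, so a missing k defaults to m + 2 and a missing m to k - 2
#' (floored at 0).
#'
#' @param k,m Integers or NULL.
#' @return A list with both `k` and `m` filled in.
#' @export
resolve_k_m <- function(k = NULL, m = NULL) {
  if (is.null(k) && is.null(m)) stop("supply at least one of k, m")
  if (is.null(k)) k <- m + 2L
  if (is.null(m)) m <- max(k - 2L, 0L)
  if (m > k) stop("m must not exceed k")
  list(k = as.integer(k), m = as.integer(m))
}

# pairwise measure from precomputed features; algebraically identical to
# the exported per-pair functions (asserted in the test suite)
pair_dissimilarity <- function(fx, fy) {
  stopifnot(fx$measure == fy$measure)
  switch(fx$measure,
    manhattan = sum(abs(fx$freq - fy$freq)),
    euclid = sqrt(sum((fx$freq - fy$freq)^2)),
    d2 = 0.5 * (1 - sum(fx$cn * fy$cn)),
    d2star = {
      if (all(fx$pos) && all(fy$pos)) {
        nx <- sqrt(fx$u_norm2); ny <- sqrt(fy$u_norm2)
        if (nx == 0 || ny == 0) stop("undefined measure: zero d2* normalizer")
        0.5 * (1 - sum(fx$u * fy$u) / (nx * ny))
      } else {
        d2star_dissimilarity(fx$profile, fx$model, fy$profile, fy$model,
                             px = fx$p, py = fy$p)
      }
    },
    d2s = {
      r <- sqrt(fx$centered^2 + fy$centered^2)
      keep <- r > 0
      if (!any(keep)) stop("undefined measure: all centered counts zero")
      xc <- fx$centered[keep]; yc <- fy$centered[keep]; r <- r[keep]
      nx <- sqrt(sum(xc^2 / r)); ny <- sqrt(sum(yc^2 / r))
      if (nx == 0 || ny == 0) stop("undefined measure: zero d2s normalizer")
      0.5 * (1 - sum(xc * yc / r) / (nx * ny))
    },
    cvtree = {
      if (fx$cv_norm == 0 || fy$cv_norm == 0)
        stop("undefined measure: zero composition-vector norm")
      0.5 * (1 - sum(fx$cv * fy$cv) / (fx$cv_norm * fy$cv_norm))
    })
}

#' Pairwise dissimilarity matrix
#'
#' @param features List of `sample_features` (see [compute_features()]),
#'   all with the same measure, k and m.
#' @return An object of class `dissim_matrix`: list with `sample_ids`,
#'   `values` (symmetric matrix, zero diagonal), `measure`, `k`, `m`.
#' @export
pairwise_matrix <- function(features) {
  stopifnot(length(features) >= 2)
  ids <- vapply(features, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicated sample ids")
  n <- length(features)
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pair_dissimilarity(features[[i]], features[[j]])
      values[i, j] <- v
      values[j, i] <- v
    }
  }
  structure(list(sample_ids = ids, values = values,
                 measure = features[[1]]$measure,
                 k = features[[1]]$k, m = features[[1]]$m),
            class = "dissim_matrix")
}

#' Rectangular query-versus-reference dissimilarities
#'
#' Computes the dissimilarity of each query sample to each reference
#' sample, e.g. for classifying external samples against a fixed reference
#' panel, or test samples whose reads were perturbed.
#'
#' @param query_features,ref_features Lists of `sample_features`.
#' @return Numeric matrix, rows = queries, columns = references.
#' @export
cross_dissimilarity <- function(query_features, ref_features) {
  qids <- vapply(query_features, `[[`, character(1), "sample_id")
  rids <- vapply(ref_features, `[[`, character(1), "sample_id")
  out <- matrix(0, length(qids), length(rids),
                dimnames = list(qids, rids))
  for (i in seq_along(qids)) {
    for (j in seq_along(rids)) {
      out[i, j] <- pair_dissimilarity(query_features[[i]],
                                      ref_features[[j]])
    }
  }
  out
}

#' End-to-end dissimilarity matrix from read sets
#'
#' Convenience wrapper: [compute_features()] per sample, then
#' [pairwise_matrix()].
#'
#' @inheritParams compute_features
#' @param read_sets List of [read_set()] objects.
#' @return A `dissim_matrix`.
#' @export
dissimilarity_matrix <- function(read_sets, k = NULL, m = NULL,
                                 measure = "d2star", strand = "both") {
  features <- lapply(read_sets, compute_features, k = k, m = m,
                     measure = measure, strand = strand)
  pairwise_matrix(features)
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("dissim_matrix: %d samples, measure=%s, k=%d, m=%s\n",
              length(x$sample_ids), x$measure, x$k,
              if (is.null(x$m) || is.na(x$m)) "-" else x$m))
  invisible(x)
}

#' Write / read a dissimilarity matrix
#'
#' Two dialects: `"phylip"` (square matrix: n on the first line, then one
#' label plus n values per row) and `"tsv"` (header row of ids, then label
#' plus values). `read_matrix(write_matrix(dm))` reproduces values to at
#' least 1e-9.
#'
#' @param dm A `dissim_matrix`.
#' @param path File path.
#' @param format `"phylip"` or `"tsv"`.
#' @return `path` invisibly (write); a `dissim_matrix` (read).
#' @export
write_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dm, "dissim_matrix"))
  v <- format(dm$values, digits = 15, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "phylip") {
    writeLines(sprintf("%5d", length(dm$sample_ids)), con)
    for (i in seq_along(dm$sample_ids)) {
      writeLines(paste(c(dm$sample_ids[i], v[i, ]), collapse = "  "), con)
    }
  } else {
    writeLines(paste(c("sample_id", dm$sample_ids), collapse = "\t"), con)
    for (i in seq_along(dm$sample_ids)) {
      writeLines(paste(c(dm$sample_ids[i], v[i, ]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_matrix
#' @param measure,k,m Metadata to attach on read (the files store values
#'   and labels only).
#' @export
read_matrix <- function(path, format = c("phylip", "tsv"),
                        measure = "d2star", k = NA_integer_,
                        m = NA_integer_) {
  format <- match.arg(format)
  if (format == "phylip") {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    if (is.na(n) || length(lines) < n + 1L)
      stop("malformed PHYLIP matrix: ", path)
    ids <- character(n)
    values <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
      if (length(parts) != n + 1L)
        stop("malformed PHYLIP row ", i, ": expected ", n, " values")
      ids[i] <- parts[1]
      values[i, ] <- as.numeric(parts[-1])
    }
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(values) != ncol(values))
      stop("malformed TSV matrix: not square")
    if (!identical(colnames(values), ids))
      stop("malformed TSV matrix: row/column labels differ")
    mode(values) <- "numeric"
  }
  if (anyNA(values)) stop("non-numeric entries in matrix file: ", path)
  dimnames(values) <- list(ids, ids)
  structure(list(sample_ids = ids, values = values, measure = measure,
                 k = k, m = m),
            class = "dissim_matrix")
}
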