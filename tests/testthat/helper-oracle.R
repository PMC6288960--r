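# independent brute-force oracle: explicit window loops, map-based counts
# and chain-rule word probabilities; shares no code with the package paths
# it checks

oracle_revcomp <- function(r) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", r), "")[[1]]), collapse = "")
}

# word -> count map (environment) from explicit window loops; windows with
# N are skipped and never span reads
oracle_counts <- function(reads, k, strand = "both") {
  if (strand == "both")
    reads <- c(reads, vapply(reads, oracle_revcomp, character(1)))
  cnt <- new.env(parent = emptyenv())
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(r, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      prev <- if (is.null(cnt[[w]])) 0 else cnt[[w]]
      cnt[[w]] <- prev + 1
    }
  }
  cnt
}

oracle_lookup <- function(env, w) if (is.null(env[[w]])) 0 else env[[w]]

# m-th order model as plain lookup tables
oracle_markov <- function(reads, m, strand = "both") {
  c_hi <- oracle_counts(reads, m + 1, strand)
  trans <- new.env(parent = emptyenv())
  for (w in ls(c_hi)) {
    u <- substr(w, 1, m)
    tot <- sum(vapply(c("A", "C", "G", "T"), function(a)
      oracle_lookup(c_hi, paste0(u, a)), numeric(1)))
    trans[[w]] <- c_hi[[w]] / tot
  }
  if (m == 0) {
    q <- new.env(parent = emptyenv())
    q[["."]] <- 1  # empty context
  } else {
    c_m <- oracle_counts(reads, m, strand)
    tot <- sum(vapply(ls(c_m), function(w) c_m[[w]], numeric(1)))
    q <- new.env(parent = emptyenv())
    for (w in ls(c_m)) q[[w]] <- c_m[[w]] / tot
  }
  list(m = m, trans = trans, q = q)
}

oracle_word_prob <- function(model, w) {
  m <- model$m
  p <- if (m == 0) 1 else oracle_lookup(model$q, substr(w, 1, m))
  if (p == 0) return(0)
  k <- nchar(w)
  if (k > m) {
    for (i in (m + 1):k) {
      p <- p * oracle_lookup(model$trans, substr(w, i - m, i))
      if (p == 0) return(0)
    }
  }
  p
}

oracle_all_words <- function(k) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

# all six measures by explicit loops over every word of length k
oracle_measures <- function(reads_x, reads_y, k, m, strand = "both") {
  words <- oracle_all_words(k)
  cx <- oracle_counts(reads_x, k, strand)
  cy <- oracle_counts(reads_y, k, strand)
  X <- vapply(words, function(w) oracle_lookup(cx, w), numeric(1))
  Y <- vapply(words, function(w) oracle_lookup(cy, w), numeric(1))
  NX <- sum(X); NY <- sum(Y)
  fx <- X / NX; fy <- Y / NY

  manhattan <- sum(abs(fx - fy))
  euclid <- sqrt(sum((fx - fy)^2))
  d2 <- 0.5 * (1 - sum(X * Y) / (sqrt(sum(X^2)) * sqrt(sum(Y^2))))

  mx <- oracle_markov(reads_x, m, strand)
  my <- oracle_markov(reads_y, m, strand)
  px <- vapply(words, function(w) oracle_word_prob(mx, w), numeric(1))
  py <- vapply(words, function(w) oracle_word_prob(my, w), numeric(1))
  xt <- X - NX * px
  yt <- Y - NY * py

  num <- den_x <- den_y <- 0
  for (i in seq_along(words)) {
    if (px[i] > 0 && py[i] > 0) {
      num <- num + xt[i] * yt[i] / sqrt(NX * px[i] * NY * py[i])
      den_x <- den_x + xt[i]^2 / (NX * px[i])
      den_y <- den_y + yt[i]^2 / (NY * py[i])
    }
  }
  d2star <- 0.5 * (1 - num / (sqrt(den_x) * sqrt(den_y)))

  num <- den_x <- den_y <- 0
  for (i in seq_along(words)) {
    r <- sqrt(xt[i]^2 + yt[i]^2)
    if (r > 0) {
      num <- num + xt[i] * yt[i] / r
      den_x <- den_x + xt[i]^2 / r
      den_y <- den_y + yt[i]^2 / r
    }
  }
  d2s <- 0.5 * (1 - num / (sqrt(den_x) * sqrt(den_y)))

  cx1 <- oracle_counts(reads_x, k - 1, strand)
  cx2 <- oracle_counts(reads_x, k - 2, strand)
  cy1 <- oracle_counts(reads_y, k - 1, strand)
  cy2 <- oracle_counts(reads_y, k - 2, strand)
  cv <- function(w, ck, c1, c2) {
    mid <- oracle_lookup(c2, substr(w, 2, nchar(w) - 1))
    if (mid == 0) return(0)
    E <- oracle_lookup(c1, substr(w, 1, nchar(w) - 1)) *
      oracle_lookup(c1, substr(w, 2, nchar(w))) / mid
    if (E == 0) return(0)
    (oracle_lookup(ck, w) - E) / E
  }
  a <- vapply(words, function(w) cv(w, cx, cx1, cx2), numeric(1))
  b <- vapply(words, function(w) cv(w, cy, cy1, cy2), numeric(1))
  cvtree <- 0.5 * (1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2))))

  lapply(list(manhattan = manhattan, euclid = euclid, d2 = d2,
              d2star = d2star, d2s = d2s, cvtree = cvtree), as.numeric)
}

# package-side values for the same pair, via the feature path
package_measures <- function(rs_x, rs_y, k, m, strand = "both") {
  out <- list()
  for (meas in c("manhattan", "euclid", "d2", "d2star", "d2s", "cvtree")) {
    fx <- compute_features(rs_x, k = k, m = m, measure = meas,
                           strand = strand)
    fy <- compute_features(rs_y, k = k, m = m, measure = meas,
                           strand = strand)
    out[[meas]] <- pairwise_matrix(list(fx, fy))$values[1, 2]
  }
  out
}
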