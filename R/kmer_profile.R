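#' Count k-mers in a read set
#'
#' Counts occurrences of all 4^k DNA words. Windows are taken within reads
#' only (never spanning read boundaries) and any window containing an N (or
#' other ambiguity code) is skipped. With `strand = "both"` the counts of
#' every read's reverse complement are added, symmetrizing the profile over
#' strand sampling.
#'
#' @param rs A [read_set()].
#' @param k Word length (>= 1). Counts are stored densely over all 4^k
#'   words, so k is practical up to about 12.
#' @param strand `"both"` (default) or `"forward"`.
#' @return An object of class `kmer_profile`: a list with `k`, `counts`
#'   (named numeric vector over all 4^k words in lexicographic order), `N`
#'   (total occurrences) and `sample_id`.
#' @export
count_kmers <- function(rs, k, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  stopifnot(inherits(rs, "read_set"))
  if (!is.numeric(k) || k < 1) stop("k must be a positive integer")
  k <- as.integer(k)
  x <- Biostrings::DNAStringSet(rs$reads)
  counts <- Biostrings::oligonucleotideFrequency(x, width = k,
                                                 simplify.as = "collapsed")
  if (strand == "both") {
    counts <- counts + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(x), width = k,
      simplify.as = "collapsed")
  }
  counts <- as.numeric(counts)
  names(counts) <- all_kmers(k)
  structure(list(k = k, counts = counts, N = sum(counts),
                 sample_id = rs$sample_id),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile '%s': k=%d, N=%g occurrences, %d/%d words seen\n",
              x$sample_id, x$k, x$N, sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

#' Fit an m-th order Markov background model
#'
#' Transition probabilities P(a|u) are maximum-likelihood estimates
#' C(ua) / sum_b C(ub) from within-read (m+1)-mer counts (ambiguous windows
#' skipped; strand policy as in [count_kmers()]). Initial context
#' probabilities q(u) are normalized m-mer counts. For m = 0 the model is
#' the single-nucleotide frequency distribution with q = 1 for the empty
#' context. Contexts never observed get zero-probability transitions.
#'
#' @param rs A [read_set()].
#' @param m Markov order (>= 0).
#' @param strand `"both"` (default) or `"forward"`.
#' @return An object of class `markov_model`: a list with `m`, `trans`
#'   (4^m x 4 matrix of P(a|u), rows = contexts in lexicographic order),
#'   `initial` (length-4^m vector q(u)) and `sample_id`.
#' @export
fit_markov <- function(rs, m, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  stopifnot(inherits(rs, "read_set"))
  if (!is.numeric(m) || m < 0) stop("m must be a non-negative integer")
  m <- as.integer(m)
  cts <- count_kmers(rs, m + 1L, strand = strand)$counts
  if (sum(cts) == 0)
    stop("model-fit error: no usable window of length ", m + 1L)
  trans_counts <- matrix(cts, nrow = 4^m, ncol = 4, byrow = TRUE)
  rs_tot <- rowSums(trans_counts)
  trans <- trans_counts / ifelse(rs_tot > 0, rs_tot, 1)
  trans[rs_tot == 0, ] <- 0
  rownames(trans) <- all_kmers(m)
  colnames(trans) <- DNA_BASES
  if (m == 0L) {
    initial <- c(1)
    names(initial) <- ""
  } else {
    m_cts <- count_kmers(rs, m, strand = strand)$counts
    initial <- m_cts / sum(m_cts)
  }
  structure(list(m = m, trans = trans, initial = initial,
                 sample_id = rs$sample_id),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model '%s': order m=%d, %d contexts observed\n",
              x$sample_id, x$m, sum(rowSums(x$trans) > 0)))
  invisible(x)
}

#' Probability of a single word under a Markov background model
#'
#' Chain rule: p_w = q(w_1..w_m) * prod_i P(w_i | w_(i-m)..w_(i-1)). Any
#' missing (never observed) context or transition yields p_w = 0.
#'
#' @param mm A [fit_markov()] model.
#' @param w A word over A/C/G/T of length >= m.
#' @return The probability p_w.
#' @export
word_probability <- function(mm, w) {
  stopifnot(inherits(mm, "markov_model"))
  k <- nchar(w)
  if (k < mm$m) stop("word shorter than the model order m = ", mm$m)
  chars <- strsplit(toupper(w), "")[[1]]
  code <- match(chars, DNA_BASES) - 1L
  if (anyNA(code)) stop("word must be over A/C/G/T: ", w)
  m <- mm$m
  p <- if (m == 0L) 1 else {
    u <- sum(code[seq_len(m)] * 4^((m - 1):0)) + 1L
    unname(mm$initial[u])
  }
  if (k > m) {
    for (i in (m + 1L):k) {
      ctx <- if (m == 0L) 1L
        else sum(code[(i - m):(i - 1L)] * 4^((m - 1):0)) + 1L
      p <- p * mm$trans[ctx, code[i] + 1L]
    }
  }
  unname(p)
}

#' Probabilities of all 4^k words under a Markov background model
#'
#' Vectorized chain-rule evaluation: the length-l word probabilities are
#' extended one base at a time, reusing the fact that the transition
#' context of word i (0-based code) is `i mod 4^m`.
#'
#' @param mm A [fit_markov()] model.
#' @param k Word length (>= m).
#' @return Named numeric vector of p_w over all 4^k words in lexicographic
#'   order.
#' @export
word_probabilities <- function(mm, k) {
  stopifnot(inherits(mm, "markov_model"))
  m <- mm$m
  if (k < m) stop("k must be >= the model order m = ", m)
  p <- as.numeric(mm$initial)  # over 4^m contexts
  if (k > m) {
    for (l in m:(k - 1L)) {
      # p has length 4^l, indexed by 0-based word code i; appending base a
      # gives child code 4*i + a, whose transition context is the last m
      # bases of the parent, i.e. i mod 4^m
      ctx <- (seq_along(p) - 1L) %% (4^m)
      ext <- matrix(0, nrow = 4, ncol = length(p))
      for (a in 0:3) {
        ext[a + 1L, ] <- p * mm$trans[cbind(ctx + 1L, a + 1L)]
      }
      p <- as.numeric(ext)  # column-major: child 4i+a lands at slot 4i+a
    }
  }
  names(p) <- all_kmers(k)
  p
}

#' Background-centered k-mer counts
#'
#' Subtracts the expected count under the background model from the
#' observed count: X~_w = X_w - N * p_w for every word.
#'
#' @param kp A [count_kmers()] profile.
#' @param mm A [fit_markov()] model with m <= kp$k.
#' @return Named numeric vector over all 4^k words.
#' @export
centered_counts <- function(kp, mm) {
  stopifnot(inherits(kp, "kmer_profile"), inherits(mm, "markov_model"))
  if (mm$m > kp$k) stop("model order m exceeds profile k")
  kp$counts - kp$N * word_probabilities(mm, kp$k)
}

#' Write / read a k-mer profile as TSV
#'
#' Plain two-column table (word, count); zero-count words are omitted.
#'
#' @param kp A `kmer_profile`.
#' @param path Output path.
#' @return `path` invisibly (write); a `kmer_profile` (read).
#' @export
write_profile <- function(kp, path) {
  stopifnot(inherits(kp, "kmer_profile"))
  nz <- kp$counts > 0
  df <- data.frame(word = names(kp$counts)[nz], count = kp$counts[nz])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s k=%d", kp$sample_id, kp$k), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# sample_id=", header)) stop("not a profile file: ", path)
  sample_id <- sub("^# sample_id=(\\S+) k=\\d+$", "\\1", header)
  k <- as.integer(sub("^.* k=(\\d+)$", "\\1", header))
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  counts <- numeric(4^k)
  names(counts) <- all_kmers(k)
  counts[df$word] <- df$count
  structure(list(k = k, counts = counts, N = sum(counts),
                 sample_id = sample_id),
            class = "kmer_profile")
}
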