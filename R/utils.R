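#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded package functions never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Combines the master seed with a stage tag by a fixed integer hash
#' (a 32-bit multiplicative scheme over the tag's character codes), so each
#' pipeline stage draws from its own reproducible stream and can be rerun
#' in isolation.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage tag, e.g. "simulate" or "splits".
#' @return A non-negative integer below 2^31.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(master_seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# integer encoding of DNA: A=0, C=1, G=2, T=3 (lexicographic)
DNA_BASES <- c("A", "C", "G", "T")

# all 4^k words in lexicographic order; k small (<= 12); memoized because
# profile construction asks for the same k over and over
.kmer_cache <- new.env(parent = emptyenv())
all_kmers <- function(k) {
  if (k == 0L) return("")
  key <- as.character(k)
  if (!is.null(.kmer_cache[[key]])) return(.kmer_cache[[key]])
  idx <- 0:(4^k - 1)
  out <- rep("", length(idx))
  for (pos in seq_len(k)) {
    digit <- (idx %/% 4^(k - pos)) %% 4
    out <- paste0(out, DNA_BASES[digit + 1])
  }
  .kmer_cache[[key]] <- out
  out
}
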