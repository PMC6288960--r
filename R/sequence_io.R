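#' Construct a read set
#'
#' A read set holds the shotgun reads of one sample as plain uppercase
#' character strings over the alphabet A, C, G, T, N, together with the
#' total number of sequenced bases. Reads never span records: every
#' downstream k-mer window is taken within a single read.
#'
#' @param reads Character vector of DNA reads. Case is normalized to upper;
#'   any IUPAC ambiguity code other than A/C/G/T is replaced by N.
#' @param sample_id Sample identifier.
#' @return An object of class `read_set` with elements `sample_id`, `reads`
#'   and `total_bases`.
#' @export
read_set <- function(reads = character(), sample_id = "sample") {
  reads <- toupper(as.character(reads))
  reads <- gsub("[^ACGTN]", "N", reads)
  structure(
    list(sample_id = as.character(sample_id), reads = reads,
         total_bases = sum(nchar(reads))),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d reads, %d bases\n",
              x$sample_id, length(x$reads), x$total_bases))
  invisible(x)
}

#' Read shotgun reads from FASTA or FASTQ
#'
#' Reads all records of a (possibly gzip-compressed) FASTA or FASTQ file in
#' file order. FASTQ quality strings are discarded: no quality filtering is
#' applied. Reads containing N are kept; N handling happens at k-mer
#' counting time.
#'
#' @param path Path to the sequence file.
#' @param format One of `"auto"` (detect from the file extension), `"fasta"`
#'   or `"fastq"`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extensions.
#' @return A [read_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq"
      else if (grepl("\\.(fa|fasta|fna|ffn)$", base, ignore.case = TRUE)) "fasta"
      else stop("cannot detect format from extension of: ", path)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(gz|bgz)$", "", basename(path), ignore.case = TRUE)
    sample_id <- sub("\\.[^.]*$", "", sample_id)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e))
  )
  if (length(seqs) == 0L) warning("no reads found in ", path)
  read_set(as.character(seqs), sample_id = sample_id)
}

#' Write a read set to FASTA or FASTQ
#'
#' @param rs A [read_set()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param format `"fasta"` or `"fastq"`. FASTQ records carry a constant
#'   placeholder quality ("I") since the simulator does not model qualities.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(rs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(rs, "read_set"))
  x <- Biostrings::DNAStringSet(rs$reads)
  names(x) <- sprintf("%s_read%d", rs$sample_id, seq_along(rs$reads))
  compress <- grepl("\\.gz$", path)
  if (format == "fastq") {
    q <- Biostrings::BStringSet(vapply(nchar(rs$reads), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = compress)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta",
                                compress = compress)
  }
  invisible(path)
}

#' Down-sample a read set to a fixed base total
#'
#' Whole reads are drawn uniformly at random without replacement until the
#' running base total first reaches or exceeds `target_bases`; no read is
#' trimmed, so the output total lies in `[target_bases, target_bases + max
#' read length)`. Deterministic given `seed`.
#'
#' @param rs A [read_set()].
#' @param target_bases Positive target base total; must not exceed
#'   `rs$total_bases`.
#' @param seed Integer seed.
#' @return A [read_set()] containing the selected reads.
#' @export
downsample_reads <- function(rs, target_bases, seed) {
  stopifnot(inherits(rs, "read_set"), target_bases >= 1)
  if (target_bases > rs$total_bases)
    stop("insufficient data: target_bases (", target_bases,
         ") exceeds available bases (", rs$total_bases, ")")
  ord <- with_seed(seed, sample.int(length(rs$reads)))
  len <- nchar(rs$reads)[ord]
  n_take <- which(cumsum(len) >= target_bases)[1L]
  out <- read_set(rs$reads[ord[seq_len(n_take)]], sample_id = rs$sample_id)
  out
}

#' Partition a read set into disjoint fixed-size subsets
#'
#' Reads are shuffled once, then consumed greedily: each part accumulates
#' whole reads until its total first reaches `part_bases`. Parts are
#' pairwise disjoint by read identity. If the pool is exhausted before
#' `n_parts` full parts are formed, fewer parts are returned with a warning.
#'
#' @param rs A [read_set()].
#' @param n_parts Number of parts requested.
#' @param part_bases Base total per part.
#' @param seed Integer seed.
#' @return A list of [read_set()] objects (at most `n_parts`).
#' @export
partition_reads <- function(rs, n_parts, part_bases, seed) {
  stopifnot(inherits(rs, "read_set"), n_parts >= 1, part_bases >= 1)
  if (part_bases > rs$total_bases)
    stop("insufficient data: part_bases (", part_bases,
         ") exceeds available bases (", rs$total_bases, ")")
  ord <- with_seed(seed, sample.int(length(rs$reads)))
  len <- nchar(rs$reads)[ord]
  parts <- list()
  i <- 1L
  while (length(parts) < n_parts && i <= length(ord)) {
    acc <- 0L
    first <- i
    while (i <= length(ord) && acc < part_bases) {
      acc <- acc + len[i]
      i <- i + 1L
    }
    if (acc >= part_bases) {
      idx <- ord[first:(i - 1L)]
      parts[[length(parts) + 1L]] <-
        read_set(rs$reads[idx],
                 sample_id = sprintf("%s_part%d", rs$sample_id,
                                     length(parts) + 1L))
    }
  }
  if (length(parts) < n_parts)
    warning("read pool exhausted: returning ", length(parts), " of ",
            n_parts, " requested parts")
  parts
}

#' Assign a continent label from country or longitude
#'
#' Samples from the United States or Canada are labeled `NA` (North
#' America). Otherwise samples west of 60 degrees E longitude are labeled
#' `EU` and samples at or east of it `AS`. The country check takes
#' precedence, so North American samples are recognized at any longitude.
#'
#' @param country Free-text country name, or `NA`.
#' @param longitude Longitude in degrees, east positive, or `NA`.
#' @return One of `"NA"`, `"EU"`, `"AS"`.
#' @export
assign_continent <- function(country = NA, longitude = NA) {
  na_countries <- c("usa", "us", "united states", "united states of america",
                    "canada")
  if (!is.na(country) && nzchar(trimws(country))) {
    if (tolower(trimws(country)) %in% na_countries) return("NA")
  }
  if (!is.na(longitude)) {
    return(if (longitude < 60) "EU" else "AS")
  }
  if (is.na(country) || !nzchar(trimws(country)))
    stop("cannot assign continent: neither country nor longitude available")
  # country given but not NA-listed, and no longitude to fall back on
  stop("cannot assign continent for country '", country,
       "' without a longitude")
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with header columns `sample_id`, `country`,
#' `latitude`, `longitude`, `continent`. A blank continent is derived via
#' [assign_continent()]; the literal string "UNKNOWN" marks query samples.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `sample_id`, `country`, `latitude`,
#'   `longitude`, `continent` (one of "NA", "EU", "AS", "UNKNOWN").
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA?", ""))
  # the continent code "NA" collides with R's missing marker, so the file is
  # parsed with "" as the only NA string and literal NA restored by hand
  need <- c("sample_id", "country", "latitude", "longitude", "continent")
  if (!all(need %in% names(meta)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  meta <- meta[, need]
  meta$continent <- as.character(meta$continent)
  blank <- is.na(meta$continent) | meta$continent == ""
  for (i in which(blank)) {
    meta$continent[i] <- assign_continent(meta$country[i], meta$longitude[i])
  }
  bad <- !meta$continent %in% c("NA", "EU", "AS", "UNKNOWN")
  if (any(bad))
    stop("invalid continent labels: ",
         paste(unique(meta$continent[bad]), collapse = ", "))
  meta
}

#' Write a sample metadata table
#'
#' @param meta Data.frame as returned by [read_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
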