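BASE_CODES <- utf8ToInt("ACGT")  # A=65 C=67 G=71 T=84
N_CODE <- utf8ToInt("N")

#' Simulation configuration for the synthetic three-continent design
#'
#' Bundles every parameter of the population and shotgun-read generator.
#' The defaults are a desk-scale stand-in for a reference panel of woody
#' plants sampled on three continents: a 200 kb genome, 12 individuals per
#' continent diverging 2% from the common root per continental branch and
#' 0.2% per individual branch, 100 bp reads to a 200 kb per-sample total,
#' and a 0.1% per-base sequencing error rate.
#'
#' With `ibd = TRUE` the continental branch lengths are made proportional
#' to the geometry of the continent centers (the three-point split of the
#' pairwise great-circle distances), so expected sequence divergence scales
#' with geographic distance — an isolation-by-distance scenario.
#'
#' @param genome_length Root genome length L in bases.
#' @param n_individuals Individuals per continent.
#' @param delta_continental Per-site substitution probability on each
#'   root-to-continent branch (with `ibd = TRUE`, the half of the largest
#'   center-to-center divergence; other branches scale down).
#' @param delta_individual Per-site substitution probability on each
#'   continent-to-individual branch.
#' @param read_length Read length in bases.
#' @param bases_per_sample Total sequenced bases per sample.
#' @param error_rate Per-base sequencing substitution probability.
#' @param gc_content GC fraction of the root genome.
#' @param continent_names,continent_centers Continent labels and their
#'   (lat, lon) centers.
#' @param within_spread_km Standard deviation (km) of individual sampling
#'   locations around their continent center.
#' @param ibd Isolation-by-distance branch scaling (see above).
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L,
                       n_individuals = 12L,
                       delta_continental = 0.02,
                       delta_individual = 0.002,
                       read_length = 100L,
                       bases_per_sample = 200000L,
                       error_rate = 0.001,
                       gc_content = 0.5,
                       continent_names = c("NA", "EU", "AS"),
                       continent_centers = list(c(40, -95), c(48, 10),
                                                c(45, 125)),
                       within_spread_km = 300,
                       ibd = FALSE,
                       seed = 1L) {
  stopifnot(delta_continental >= 0, delta_continental <= 1,
            delta_individual >= 0, delta_individual <= 1,
            error_rate >= 0, error_rate <= 1,
            gc_content >= 0, gc_content <= 1,
            genome_length >= read_length,
            length(continent_names) == length(continent_centers))
  if (delta_individual >= delta_continental && delta_continental > 0)
    warning("delta_individual >= delta_continental: continents will not ",
            "be separable")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a root genome
#'
#' I.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param L Genome length.
#' @param gc_content GC fraction.
#' @param seed Integer seed.
#' @return A DNA string of length L.
#' @export
simulate_root_genome <- function(L, gc_content = 0.5, seed = 1) {
  stopifnot(L >= 1)
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  with_seed(seed, intToUtf8(sample(BASE_CODES, L, replace = TRUE, prob = p)))
}

# mutate codes in place: each position hit independently with prob delta,
# substitute drawn uniformly from the 3 alternative bases; N untouched
mutate_codes <- function(s, delta) {
  if (delta <= 0) return(s)
  hit <- which(stats::runif(length(s)) < delta & s != N_CODE)
  if (length(hit)) {
    old <- match(s[hit], BASE_CODES) - 1L
    new <- (old + sample.int(3L, length(hit), replace = TRUE)) %% 4L
    s[hit] <- BASE_CODES[new + 1L]
  }
  s
}

#' Evolve a sequence by independent substitutions
#'
#' Each site is substituted independently with probability `delta`; the
#' replacement base is uniform over the three alternatives (no
#' transition/transversion bias). Length is preserved; no indels.
#'
#' @param seq DNA string.
#' @param delta Per-site substitution probability.
#' @param seed Integer seed.
#' @return The mutated DNA string.
#' @export
evolve_sequence <- function(seq, delta, seed = 1) {
  stopifnot(delta >= 0, delta <= 1)
  with_seed(seed, intToUtf8(mutate_codes(utf8ToInt(seq), delta)))
}

# three-point split: branch length b_i from pairwise distances D so that
# b_i + b_j = D[i,j] exactly for three leaves of a star tree
star_branches <- function(D) {
  n <- nrow(D)
  stopifnot(n == 3)
  b <- numeric(3)
  for (i in 1:3) {
    jk <- setdiff(1:3, i)
    b[i] <- (D[i, jk[1]] + D[i, jk[2]] - D[jk[1], jk[2]]) / 2
  }
  pmax(b, 0)
}

#' Simulate continental populations
#'
#' A star phylogeny: the root genome evolves once per continent (branch
#' substitution probability `delta_continental`, or distance-scaled
#' branches under `ibd`), then once per individual within each continent
#' (`delta_individual`). Individual sampling coordinates are scattered
#' around the continent centers with a Gaussian spread of
#' `within_spread_km`.
#'
#' @param cfg A [sim_config()].
#' @return List with `genomes` (named list of DNA strings), `meta`
#'   (data.frame: sample_id, country, latitude, longitude, continent),
#'   `ancestors` (continental ancestor genomes), `root`.
#' @export
simulate_samples <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  root <- simulate_root_genome(cfg$genome_length, cfg$gc_content,
                               stage_seed(cfg$seed, "root"))
  nc <- length(cfg$continent_names)
  if (cfg$ibd) {
    centers <- do.call(rbind, cfg$continent_centers)
    D <- matrix(0, nc, nc)
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      D[i, j] <- D[j, i] <- great_circle(centers[i, 1], centers[i, 2],
                                         centers[j, 1], centers[j, 2])
    }
    b <- star_branches(D)
    # largest pairwise divergence pinned at 2 * delta_continental
    deltas <- b * 2 * cfg$delta_continental / max(D)
  } else {
    deltas <- rep(cfg$delta_continental, nc)
  }
  genomes <- list()
  ancestors <- list()
  meta <- list()
  for (ci in seq_len(nc)) {
    cont <- cfg$continent_names[ci]
    anc <- evolve_sequence(root, deltas[ci],
                           stage_seed(cfg$seed, paste0("continent_", cont)))
    ancestors[[cont]] <- anc
    center <- cfg$continent_centers[[ci]]
    for (ii in seq_len(cfg$n_individuals)) {
      id <- sprintf("%s_%02d", cont, ii)
      genomes[[id]] <- evolve_sequence(
        anc, cfg$delta_individual, stage_seed(cfg$seed, paste0("ind_", id)))
      xy <- with_seed(stage_seed(cfg$seed, paste0("coord_", id)),
                      stats::rnorm(2, sd = cfg$within_spread_km))
      lat <- center[1] + xy[1] / 111.32
      lon <- center[2] + xy[2] / (111.32 * cos(center[1] * pi / 180))
      meta[[id]] <- data.frame(sample_id = id, country = "synthetic",
                               latitude = lat, longitude = lon,
                               continent = cont)
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  list(genomes = genomes, meta = meta, ancestors = ancestors, root = root)
}

#' Simulate shotgun reads from a genome
#'
#' Read start positions are uniform over the genome, the strand is chosen
#' uniformly (reverse complement with probability 1/2), a per-base
#' substitution error is applied, and reads accumulate until the total
#' first reaches `bases_per_sample`.
#'
#' @param genome DNA string.
#' @param read_length Read length in bases.
#' @param bases_per_sample Target base total.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param sample_id Sample id for the returned [read_set()].
#' @return A [read_set()].
#' @export
sequence_reads <- function(genome, read_length, bases_per_sample,
                           error_rate = 0, seed = 1, sample_id = "sample") {
  L <- nchar(genome)
  stopifnot(read_length <= L, read_length >= 1, bases_per_sample >= 1)
  n_reads <- ceiling(bases_per_sample / read_length)
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    flip <- stats::runif(n_reads) < 0.5
    if (any(flip)) {
      reads[flip] <- vapply(reads[flip], function(r)
        intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", r)))), character(1),
        USE.NAMES = FALSE)
    }
    if (error_rate > 0) {
      s <- mutate_codes(utf8ToInt(paste(reads, collapse = "")), error_rate)
      big <- intToUtf8(s)
      ends <- cumsum(nchar(reads))
      reads <- substring(big, c(1L, ends[-length(ends)] + 1L), ends)
    }
    read_set(reads, sample_id = sample_id)
  })
}

#' Inject additional substitution errors into a read set
#'
#' Every non-N base is independently substituted with probability `rate`,
#' uniformly over the three alternatives; read count and lengths are
#' preserved. Models additional sequencing error on top of whatever error
#' the reads already carry (applied sequentially, so error processes
#' compose).
#'
#' @param rs A [read_set()].
#' @param rate Per-base substitution probability (default 0.05).
#' @param seed Integer seed.
#' @return A [read_set()] with the same structure and mutated bases.
#' @export
inject_errors <- function(rs, rate = 0.05, seed = 1) {
  stopifnot(inherits(rs, "read_set"), rate >= 0, rate <= 1)
  if (rate == 0 || rs$total_bases == 0) return(rs)
  with_seed(seed, {
    s <- mutate_codes(utf8ToInt(paste(rs$reads, collapse = "")), rate)
    big <- intToUtf8(s)
    ends <- cumsum(nchar(rs$reads))
    read_set(substring(big, c(1L, ends[-length(ends)] + 1L), ends),
             sample_id = rs$sample_id)
  })
}

#' Simulate a full set of per-sample read sets
#'
#' [simulate_samples()] followed by [sequence_reads()] for every
#' individual, each stage under its own sub-seed of `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `read_sets` (named list of [read_set()]), `meta`,
#'   `genomes`.
#' @export
simulate_read_sets <- function(cfg) {
  pop <- simulate_samples(cfg)
  read_sets <- lapply(names(pop$genomes), function(id) {
    sequence_reads(pop$genomes[[id]], cfg$read_length,
                   cfg$bases_per_sample, cfg$error_rate,
                   seed = stage_seed(cfg$seed, paste0("reads_", id)),
                   sample_id = id)
  })
  names(read_sets) <- names(pop$genomes)
  list(read_sets = read_sets, meta = pop$meta, genomes = pop$genomes)
}
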