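#' Wilcoxon-Mann-Whitney U for inter exceeding intra
#'
#' U = number of (intra, inter) pairs with inter > intra, ties counted one
#' half. Computed by the rank-sum identity; equals the naive double loop.
#'
#' @param intra,inter Non-empty numeric vectors of within-group and
#'   between-group dissimilarities.
#' @return The U statistic, in `[0, length(intra) * length(inter)]`.
#' @export
wmw_statistic <- function(intra, inter) {
  if (length(intra) == 0 || length(inter) == 0)
    stop("both intra and inter must be non-empty")
  r <- rank(c(intra, inter))
  n2 <- length(inter)
  sum(r[length(intra) + seq_len(n2)]) - n2 * (n2 + 1) / 2
}

# upper-triangle pair values of a dissimilarity matrix split into
# intra/inter for one continent (or pooled over all) under given labels
pair_partition <- function(v, li, lj, group) {
  if (group == "ALL") {
    groups <- unique(c(li, lj))
    intra <- c(); inter <- c()
    for (g in groups) {
      p <- pair_partition(v, li, lj, g)
      intra <- c(intra, p$intra)
      inter <- c(inter, p$inter)
    }
    return(list(intra = intra, inter = inter))
  }
  in_i <- li == group
  in_j <- lj == group
  list(intra = v[in_i & in_j], inter = v[xor(in_i, in_j)])
}

#' Permutation WMW test of intra- versus inter-continental dissimilarity
#'
#' Tests whether within-continent dissimilarities are smaller than
#' dissimilarities from that continent to the others. The observed U
#' (direction: inter exceeding intra) is compared with its distribution
#' under B random permutations of the sample labels (labels are permuted
#' jointly; matrix entries are untouched, preserving the dependence among
#' pairs sharing a sample). For `group = "ALL"` the per-continent pair
#' partitions are pooled, so each between-continent pair contributes to
#' both continents it touches.
#'
#' The p-value uses the add-one estimator (1 + #\{U_perm >= U_obs\}) /
#' (B + 1); permutation ties count against rejection.
#'
#' @param dm A `dissim_matrix` or plain symmetric matrix.
#' @param labels Named continent labels for all samples.
#' @param group One continent label, or `"ALL"`.
#' @param B Number of label permutations.
#' @param seed Integer seed.
#' @return List of class `perm_test` with `group`, `W_observed`,
#'   `p_value`, `B`, `seed`.
#' @export
permutation_test <- function(dm, labels, group = "ALL", B = 1e4, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  values <- if (inherits(dm, "dissim_matrix")) dm$values else dm
  ids <- names(labels)
  lab <- unname(unlist(labels[ids]))
  n <- length(ids)
  if (group != "ALL" && sum(lab == group) < 2)
    stop("degenerate grouping: fewer than 2 samples labeled ", group)
  if (length(unique(lab)) < 2)
    stop("degenerate grouping: a single continent label")
  ut <- which(upper.tri(values[ids, ids]), arr.ind = TRUE)
  v <- values[ids, ids][ut]
  iu <- ut[, 1]; ju <- ut[, 2]
  obs_p <- pair_partition(v, lab[iu], lab[ju], group)
  if (length(obs_p$intra) == 0 || length(obs_p$inter) == 0)
    stop("degenerate grouping: empty intra or inter pair set")
  W_obs <- wmw_statistic(obs_p$intra, obs_p$inter)
  count <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      lp <- sample(lab)
      pp <- pair_partition(v, lp[iu], lp[ju], group)
      W <- wmw_statistic(pp$intra, pp$inter)
      if (W >= W_obs) count <- count + 1L
    }
  })
  structure(list(group = group, W_observed = W_obs,
                 p_value = (1 + count) / (B + 1), B = B, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation WMW test (%s): W = %g, p = %.4g (B = %d)\n",
              x$group, x$W_observed, x$p_value, x$B))
  invisible(x)
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric MDS: Gower double-centering of the squared
#' dissimilarities followed by eigendecomposition (via [ape::pcoa()]).
#' Coordinates are returned for positive eigenvalues only; negative
#' eigenvalues are reported, not corrected.
#'
#' @param dm A `dissim_matrix` or plain symmetric matrix.
#' @param r Number of coordinate axes to return (capped at the number of
#'   positive eigenvalues).
#' @return List of class `pcoa_result` with `coordinates` (n x r),
#'   `eigenvalues` (all, descending), `variance_explained` (fractions of
#'   the positive-eigenvalue mass, one per returned axis), `n_negative`.
#' @export
pcoa_analysis <- function(dm, r = 3) {
  values <- if (inherits(dm, "dissim_matrix")) dm$values else dm
  if (!isSymmetric(unname(values), tol = 1e-8))
    stop("PCoA requires a symmetric dissimilarity matrix")
  fit <- ape::pcoa(stats::as.dist(values))
  eig <- fit$values$Eigenvalues
  pos <- eig[eig > 0]
  r_use <- min(r, ncol(fit$vectors))
  coords <- fit$vectors[, seq_len(r_use), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(r_use))
  rownames(coords) <- rownames(values)
  structure(list(coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 variance_explained = pos[seq_len(r_use)] / sum(pos),
                 n_negative = sum(eig < 0)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes (%.1f%% of variance), %d negative eigenvalues dropped\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$variance_explained), x$n_negative))
  invisible(x)
}

EARTH_RADIUS_KM <- 6371.0088  # IUGG mean Earth radius

#' Great-circle distance between geographic points
#'
#' Haversine formula on a sphere of radius 6371.0088 km (IUGG mean),
#' via [geosphere::distHaversine()]. Vectorized over points.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (latitude in
#'   `[-90, 90]`, longitude in `(-180, 180]`).
#' @return Distance(s) in kilometers.
#' @export
great_circle <- function(lat1, lon1, lat2, lon2) {
  coords <- c(lat1, lon1, lat2, lon2)
  if (anyNA(coords)) stop("missing coordinates")
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Correlation of dissimilarity with great-circle distance
#'
#' Pearson and Spearman correlations over all n(n-1)/2 sample pairs of
#' (dissimilarity, great-circle distance between sampling locations) — the
#' isolation-by-distance signal.
#'
#' @param dm A `dissim_matrix` or plain symmetric matrix.
#' @param meta Data.frame with columns `sample_id`, `latitude`,
#'   `longitude` covering every sample in `dm`.
#' @return List of class `geo_correlation` with `pearson_r`, `r_squared`,
#'   `spearman_rho`, `n_pairs`, and the paired vectors `dissimilarity`
#'   and `distance_km`.
#' @export
geo_correlation <- function(dm, meta) {
  values <- if (inherits(dm, "dissim_matrix")) dm$values else dm
  ids <- rownames(values)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(ids[is.na(idx)], collapse = ", "))
  lat <- meta$latitude[idx]
  lon <- meta$longitude[idx]
  bad <- is.na(lat) | is.na(lon)
  if (any(bad))
    stop("missing coordinates for: ", paste(ids[bad], collapse = ", "))
  ut <- which(upper.tri(values), arr.ind = TRUE)
  diss <- values[ut]
  dist_km <- great_circle(lat[ut[, 1]], lon[ut[, 1]],
                          lat[ut[, 2]], lon[ut[, 2]])
  if (stats::sd(diss) == 0 || stats::sd(dist_km) == 0) {
    warning("degenerate input: constant dissimilarity or distance; ",
            "correlation undefined")
    pearson <- NA_real_
    spearman <- NA_real_
  } else {
    pearson <- stats::cor(diss, dist_km, method = "pearson")
    spearman <- stats::cor(diss, dist_km, method = "spearman")
  }
  structure(list(pearson_r = pearson, r_squared = pearson^2,
                 spearman_rho = spearman, n_pairs = length(diss),
                 dissimilarity = diss, distance_km = dist_km),
            class = "geo_correlation")
}

#' @export
print.geo_correlation <- function(x, ...) {
  cat(sprintf("geo_correlation over %d pairs: Pearson R = %.3f (R^2 = %.3f), Spearman rho = %.3f\n",
              x$n_pairs, x$pearson_r, x$r_squared, x$spearman_rho))
  invisible(x)
}
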