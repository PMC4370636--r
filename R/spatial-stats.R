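#' Great-circle distance (haversine, spherical earth R = 6371 km)
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in signed decimal degrees
#'   (vectorized).
#' @return Distance(s) in km.
#' @export
#' @examples
#' geodesic_km(0, 0, 1, 0)  # ~111.19
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range", call. = FALSE)
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Pairwise great-circle distance matrix for a site table
#'
#' @param sites Data.frame with columns `site`, `lat`, `lon` (see
#'   [read_sites()]).
#' @return Symmetric km matrix with site dimnames.
#' @export
geodesic_matrix <- function(sites) {
  sites <- check_sites(sites)
  n <- nrow(sites)
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    geodesic_km(sites$lat[i], sites$lon[i], sites$lat[j], sites$lon[j]))
  diag(d) <- 0
  dimnames(d) <- list(sites$site, sites$site)
  d
}

#' Equal-count distance classes
#'
#' Sorts pair distances ascending and splits them into `k` consecutive
#' classes of (as near as possible) equal pair counts — the "equal number
#' of pairs per class" correlogram convention. A remainder r puts one extra
#' pair in each of the first r classes. Ties are kept adjacent by a stable
#' sort on (distance, pair index).
#'
#' @param distances Numeric vector of pair distances.
#' @param k Number of classes (default 6).
#' @return A list: `class` (integer assignment per input pair), `centroid`
#'   (mean member distance per class), `size` (pairs per class), `breaks`
#'   (max member distance per class).
#' @export
equal_count_classes <- function(distances, k = 6) {
  n <- length(distances)
  if (k <= 0 || k > n)
    stop("k must be in 1..number of pairs", call. = FALSE)
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ord <- order(distances, seq_len(n))  # stable on ties
  cls <- integer(n)
  cls[ord] <- rep(seq_len(k), times = sizes)
  list(
    class = cls,
    centroid = as.numeric(tapply(distances, cls, mean)),
    size = as.integer(table(cls)),
    breaks = as.numeric(tapply(distances, cls, max))
  )
}

#' Moran's I spatial autocorrelation coefficient
#'
#' I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
#' with S0 the sum of all weights. Positive values indicate that connected
#' sites hold similar values (spatial aggregation), negative values the
#' opposite. The expectation under no autocorrelation is -1/(n-1).
#'
#' @param values Site-indexed numeric vector (not all equal).
#' @param weights Symmetric nonnegative matrix, zero diagonal, not all zero.
#' @return Moran's I (dimensionless).
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  stopifnot(is.matrix(weights), nrow(weights) == n, ncol(weights) == n)
  if (n < 3) stop("need at least 3 sites", call. = FALSE)
  xc <- values - mean(values)
  den <- sum(xc^2)
  if (den < .Machine$double.eps)
    stop("Moran's I undefined: zero variance in values", call. = FALSE)
  s0 <- sum(weights)
  if (s0 <= 0) stop("all-zero weight matrix", call. = FALSE)
  (n / s0) * sum(weights * outer(xc, xc)) / den
}

#' Moran's I correlogram over equal-count distance classes
#'
#' For each of `k` equal-count great-circle distance classes, binary
#' within-class weights (w_ij = 1 iff the pair falls in the class) define a
#' Moran's I; a permutation test shuffles the value vector across sites and
#' compares |I - E[I]| to the permuted values (two-sided rank p with
#' add-one smoothing, E[I] = -1/(n-1)).
#'
#' @param values Numeric vector, one value per site (in `sites` order).
#' @param sites Site table with `lat`/`lon`, or a precomputed symmetric
#'   distance matrix.
#' @param k Number of distance classes.
#' @param n_perm Permutations per class (default 999).
#' @param seed Integer seed.
#' @param row_standardize Use row-standardized weights instead of the
#'   default binary weights.
#' @return A data.frame with one row per class: `centroid_km`, `n_pairs`,
#'   `I`, `p`, and `defined` (FALSE when every involved site is isolated in
#'   that class).
#' @export
correlogram <- function(values, sites, k = 6, n_perm = 999, seed = 1,
                        row_standardize = FALSE) {
  d <- if (is.matrix(sites)) sites else geodesic_matrix(sites)
  n <- nrow(d)
  if (n < 4) stop("need at least 4 sites", call. = FALSE)
  stopifnot(length(values) == n)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  cl <- equal_count_classes(d[ut], k)
  e_i <- -1 / (n - 1)
  out <- lapply(seq_len(k), function(g) {
    w <- matrix(0, n, n)
    sel <- ut[cl$class == g, , drop = FALSE]
    w[sel] <- 1
    w[sel[, 2:1, drop = FALSE]] <- 1
    if (row_standardize) {
      rs <- rowSums(w)
      w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
    }
    involved <- rowSums(w) > 0
    if (!any(involved))
      return(data.frame(class = g, centroid_km = cl$centroid[g],
                        n_pairs = cl$size[g], I = NA_real_, p = NA_real_,
                        defined = FALSE))
    i_obs <- morans_i(values, w)
    perm <- with_seed(derive_seed(seed, paste0("class:", g)), {
      vapply(seq_len(n_perm), function(r)
        morans_i(sample(values), w), numeric(1))
    })
    p <- (1 + sum(abs(perm - e_i) >= abs(i_obs - e_i))) / (n_perm + 1)
    data.frame(class = g, centroid_km = cl$centroid[g], n_pairs = cl$size[g],
               I = i_obs, p = p, defined = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PCNM spatial eigenvector filters
#'
#' Principal coordinates of neighbour matrices: the inter-site distance
#' matrix is truncated at `t` (entries > t replaced by 4t), the truncated
#' matrix is double-centered (-D^2/2, Gower centering) and
#' eigen-decomposed; the eigenvectors with positive eigenvalues are the
#' spatial filters, ordered by descending eigenvalue. Filters associated
#' with large eigenvalues describe broad-scale spatial structure and are
#' used as regression covariates to absorb spatial autocorrelation.
#'
#' @param sites Site table or symmetric distance matrix (km).
#' @param truncation Threshold t in km, or `"auto"` for the largest edge of
#'   the minimum spanning tree of the distance matrix (the standard choice,
#'   keeping the connection graph connected).
#' @param tol Relative eigenvalue tolerance for "positive".
#' @return A list: `vectors` (site x filter matrix, unit-norm columns),
#'   `values` (positive eigenvalues, descending), `truncation` (km). Empty
#'   filter set (with a warning) when no positive eigenvalue exists.
#' @export
pcnm_filters <- function(sites, truncation = "auto", tol = 1e-9) {
  d <- if (is.matrix(sites)) sites else geodesic_matrix(sites)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 sites", call. = FALSE)
  if (max(d) <= 0) stop("all sites coincident", call. = FALSE)
  t <- if (identical(truncation, "auto")) max(mst_edges(d)) else truncation
  dt <- d
  dt[dt > t] <- 4 * t
  diag(dt) <- 0
  a <- -0.5 * dt^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) {
    warning("no positive PCNM eigenvalues; empty filter set")
    return(list(vectors = matrix(numeric(0), n, 0), values = numeric(0),
                truncation = t))
  }
  vec <- e$vectors[, keep, drop = FALSE]
  colnames(vec) <- paste0("pcnm", seq_len(ncol(vec)))
  if (!is.null(rownames(d))) rownames(vec) <- rownames(d)
  list(vectors = vec, values = e$values[keep], truncation = t)
}

# minimum spanning tree edge lengths (Prim), for the auto truncation
mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  edges <- numeric(0)
  while (!all(in_tree)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges <- c(edges, best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  edges
}

#' Read a site table from CSV
#'
#' Columns: `site`, `lat`, `lon`, `substrate` (sedimentary / crystalline /
#' inselberg) and any number of named climate covariates.
#'
#' @param file CSV path.
#' @return Validated data.frame.
#' @export
read_sites <- function(file) {
  check_sites(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @keywords internal
check_sites <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("site", "lat", "lon") %in% names(sites)))
  if (anyDuplicated(sites$site))
    stop("duplicate site ids", call. = FALSE)
  if (any(abs(sites$lat) > 90) || any(abs(sites$lon) > 180))
    stop("coordinates out of range", call. = FALSE)
  if ("substrate" %in% names(sites)) {
    bad <- setdiff(unique(sites$substrate),
                   c("sedimentary", "crystalline", "inselberg"))
    if (length(bad))
      stop("unknown substrate class: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  sites
}
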