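#' Mean pairwise phylogenetic distance (MPD)
#'
#' Unweighted mean of patristic distances over all unordered pairs of the
#' sampled species; a tree-wide measure emphasising deep relationships.
#'
#' @param sample Character vector of species names (>= 2, no duplicates).
#' @param dist Patristic matrix from [patristic_matrix()].
#' @return MPD in the units of `dist` (My for dated trees).
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' mpd(c("A", "B", "C"), patristic_matrix(tr))  # 10/3
mpd <- function(sample, dist) {
  sample <- check_sample(sample, dist)
  sub <- dist[sample, sample]
  mean(sub[upper.tri(sub)])
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean over sampled species of the patristic distance to the nearest other
#' sampled species; a tip-level measure emphasising recent relationships.
#'
#' @inheritParams mpd
#' @return MNTD in the units of `dist`.
#' @export
mntd <- function(sample, dist) {
  sample <- check_sample(sample, dist)
  sub <- dist[sample, sample]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

check_sample <- function(sample, dist) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) sample <- unique(sample)
  if (length(sample) < 2L)
    stop("metric undefined for fewer than 2 species", call. = FALSE)
  missing <- setdiff(sample, rownames(dist))
  if (length(missing))
    stop("species not in distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sample
}

#' Standardized effect size of MPD or MNTD under tip-label randomization
#'
#' The null model reshuffles taxa labels across the tips of the pool
#' phylogeny, which for an incidence sample is equivalent to drawing a
#' uniform random subset of the pool of the same richness. SES =
#' (observed - null mean) / null SD, with the sample (n-1) SD.
#'
#' @param metric `"mpd"` or `"mntd"`.
#' @param sample Character vector of sampled species.
#' @param pool A `phylo` pool tree, or a precomputed patristic matrix whose
#'   row names define the randomization pool.
#' @param n_perm Number of null permutations (the study default is 1000).
#' @param seed Integer seed for the permutation stream.
#' @return A list with `observed`, `null_mean`, `null_sd`, `ses`, `p`
#'   (one-sided lower rank p with add-one smoothing), `n_perm` and
#'   `degenerate` (TRUE when the null has zero spread, e.g. sample = pool;
#'   `ses` is then NA rather than a number).
#' @export
ses_metric <- function(metric = c("mpd", "mntd"), sample, pool,
                       n_perm = 1000, seed = 1) {
  metric <- match.arg(metric)
  fn <- if (metric == "mpd") mpd else mntd
  dist <- if (inherits(pool, "phylo")) patristic_matrix(pool) else pool
  sample <- check_sample(sample, dist)
  pool_names <- rownames(dist)
  k <- length(sample)
  if (k > length(pool_names))
    stop("sample larger than pool", call. = FALSE)
  observed <- fn(sample, dist)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      fn(sample(pool_names, k), dist)
    }, numeric(1))
  })
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  degenerate <- !is.finite(null_sd) || null_sd < .Machine$double.eps^0.5
  list(
    metric = metric,
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = if (degenerate) NA_real_ else (observed - null_mean) / null_sd,
    p = (1 + sum(null <= observed)) / (n_perm + 1),
    n_perm = n_perm,
    degenerate = degenerate
  )
}

#' NRI/NTI table for a set of communities
#'
#' Net Relatedness Index (NRI = -SES of MPD) and Nearest Taxon Index
#' (NTI = -SES of MNTD) per site, with significance flags at the two-sided
#' normal threshold: index > 1.96 flags phylogenetic clustering, index
#' < -1.96 flags overdispersion.
#'
#' Per-site null streams are derived from `seed` and the site id
#' ([derive_seed()]), so results do not depend on site order.
#'
#' @param comm Site-by-species incidence matrix (0/1) with site row names
#'   and species column names; see [read_community()].
#' @param pool Pool `phylo` tree or patristic matrix. By default the full
#'   supplied tree is the randomization pool; set `restrict_pool = TRUE` to
#'   shuffle only among the species present in `comm` (e.g. a growth-form
#'   subset).
#' @param n_perm Null permutations per site and metric.
#' @param seed Master seed.
#' @param restrict_pool Restrict the randomization pool to `colnames(comm)`.
#' @return A data.frame with one row per site: richness, observed MPD/MNTD,
#'   null means/SDs, `nri`, `nti`, and logical `nri_sig`, `nti_sig`.
#' @export
nri_nti_table <- function(comm, pool, n_perm = 1000, seed = 1,
                          restrict_pool = FALSE) {
  comm <- check_community(comm)
  dist <- if (inherits(pool, "phylo")) patristic_matrix(pool) else pool
  missing <- setdiff(colnames(comm), rownames(dist))
  if (length(missing))
    stop("community species missing from pool: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (restrict_pool)
    dist <- dist[colnames(comm), colnames(comm)]
  res <- lapply(rownames(comm), function(site) {
    spp <- colnames(comm)[comm[site, ] > 0]
    s_mpd <- ses_metric("mpd", spp, dist, n_perm,
                        derive_seed(seed, paste0("mpd:", site)))
    s_mntd <- ses_metric("mntd", spp, dist, n_perm,
                         derive_seed(seed, paste0("mntd:", site)))
    data.frame(
      site = site, richness = length(spp),
      mpd_obs = s_mpd$observed, mpd_null_mean = s_mpd$null_mean,
      mpd_null_sd = s_mpd$null_sd,
      mntd_obs = s_mntd$observed, mntd_null_mean = s_mntd$null_mean,
      mntd_null_sd = s_mntd$null_sd,
      nri = -s_mpd$ses, nti = -s_mntd$ses,
      n_perm = n_perm, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$nri_sig <- !is.na(out$nri) & abs(out$nri) > 1.96
  out$nti_sig <- !is.na(out$nti) & abs(out$nti) > 1.96
  rownames(out) <- NULL
  out
}

#' @keywords internal
check_community <- function(comm) {
  if (is.data.frame(comm)) comm <- as.matrix(comm)
  stopifnot(is.matrix(comm))
  if (is.null(rownames(comm)) || is.null(colnames(comm)))
    stop("community matrix needs site row names and species column names",
         call. = FALSE)
  if (!all(comm %in% c(0, 1)))
    stop("community matrix must be 0/1 incidence", call. = FALSE)
  empty_sp <- colSums(comm) == 0
  if (any(empty_sp))
    comm <- comm[, !empty_sp, drop = FALSE]
  poor <- rowSums(comm) < 2
  if (any(poor))
    stop("sites with fewer than 2 species: ",
         paste(rownames(comm)[poor], collapse = ", "), call. = FALSE)
  comm
}

#' Read a site-by-species incidence matrix from CSV
#'
#' First column is the site id; remaining columns are species incidences.
#'
#' @param file CSV path.
#' @return Incidence matrix with site row names.
#' @export
read_community <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "numeric"
  check_community(m)
}

#' Read a long-format (site, species) occurrence list into a matrix
#'
#' @param file CSV with columns `site` and `species`.
#' @return Incidence matrix.
#' @export
read_community_long <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "species") %in% names(df)))
  m <- unclass(table(df$site, df$species))
  m[m > 1] <- 1
  check_community(as.matrix(m))
}

#' Write a community matrix as CSV
#' @param comm Incidence matrix.
#' @param file Output path.
#' @export
write_community <- function(comm, file) {
  df <- data.frame(site = rownames(comm), comm, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}
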