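#' Simulate an ultrametric pure-birth (Yule) pool phylogeny
#'
#' Stands in for a dated regional megatree: tips are a species pool, depths
#' are equal (ultrametric), branch lengths in arbitrary time units.
#' Tip names `sp001`, `sp002`, ... are deterministic; the same seed gives
#' byte-identical newick output.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate (default 1; scales depth only).
#' @return A `phylo`.
#' @export
simulate_yule_tree <- function(n_tips, seed = 1, birth = 1) {
  if (n_tips < 2) stop("need at least 2 tips", call. = FALSE)
  tree <- with_seed(derive_seed(seed, "yule"),
                    ape::rphylo(n_tips, birth = birth, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree$node.label <- sprintf("n%03d", seq_len(tree$Nnode))
  tree
}

#' Evolve a discrete trait (life form) along a phylogeny
#'
#' Symmetric (equal-rates) Markov evolution from a uniformly drawn root
#' state. Low rates produce clade-structured (conserved) states — the
#' regime the phylogenetic-signal test is designed to detect.
#'
#' @param tree Dated `phylo`.
#' @param n_states Number of states (default 5, labelled with the Raunkiaer
#'   life forms when `n_states == 5`).
#' @param rate Transition rate per unit branch length.
#' @param seed Integer seed.
#' @return Named character vector: tip -> state.
#' @export
evolve_discrete_trait <- function(tree, n_states = 5, rate = 0.1, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    stop("tree must have positive total branch length", call. = FALSE)
  labels <- if (n_states == 5) LIFE_FORMS else paste0("state", seq_len(n_states))
  states <- with_seed(derive_seed(seed, "disc"), {
    root <- sample.int(n_states, 1)
    as.character(ape::rTraitDisc(tree, model = "ER", k = n_states,
                                 rate = rate, states = labels,
                                 root.value = root))
  })
  stats::setNames(states, tree$tip.label)
}

#' Evolve a continuous niche optimum by Brownian motion
#'
#' @param tree Dated `phylo`.
#' @param sigma Trait SD per square-root unit time.
#' @param seed Integer seed.
#' @return Named numeric vector: tip -> niche optimum (environment units).
#' @export
evolve_continuous_niche <- function(tree, sigma = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  with_seed(derive_seed(seed, "bm"),
            ape::rTraitCont(tree, model = "BM", sigma = sigma,
                            root.value = 0))
}

#' Assemble site communities from a species pool
#'
#' Three assembly rules: `neutral` draws a uniform random subset per site;
#' `filtering` draws from the species whose niche optimum lies within
#' `tolerance` of the site environment (topping up with the
#' nearest-optimum species when too few qualify) — with a conserved niche
#' this induces phylogenetic clustering; `repulsion` greedily picks species
#' maximizing the minimum patristic distance within the growing sample,
#' inducing overdispersion.
#'
#' @param pool Pool `phylo`.
#' @param niche Named species -> optimum vector (required for `filtering`).
#' @param sites Site table; for `filtering`, must have an `env` column.
#' @param mode `"neutral"`, `"filtering"` or `"repulsion"`.
#' @param richness Species per site (>= 2, <= pool size).
#' @param tolerance Niche half-width for `filtering` (environment units).
#' @param seed Integer master seed (per-site streams derived from it).
#' @return Incidence matrix (sites x pool species).
#' @export
assemble_communities <- function(pool, niche = NULL, sites,
                                 mode = c("neutral", "filtering", "repulsion"),
                                 richness = 10, tolerance = 1, seed = 1) {
  mode <- match.arg(mode)
  tips <- pool$tip.label
  if (richness < 2 || richness > length(tips))
    stop("richness must be in 2..pool size", call. = FALSE)
  if (mode == "filtering") {
    stopifnot(!is.null(niche), "env" %in% names(sites))
    niche <- niche[tips]
    if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  }
  dmat <- if (mode == "repulsion") patristic_matrix(pool) else NULL
  comm <- matrix(0L, nrow(sites), length(tips),
                 dimnames = list(sites$site, tips))
  for (i in seq_len(nrow(sites))) {
    chosen <- with_seed(derive_seed(seed, paste0("site:", sites$site[i])), {
      switch(mode,
        neutral = sample(tips, richness),
        filtering = {
          dev <- abs(niche - sites$env[i])
          cand <- tips[dev <= tolerance]
          if (length(cand) >= richness) sample(cand, richness)
          else unique(c(cand, tips[order(dev)]))[seq_len(richness)]
        },
        repulsion = {
          sel <- sample(tips, 1)
          while (length(sel) < richness) {
            rest <- setdiff(tips, sel)
            mind <- apply(dmat[rest, sel, drop = FALSE], 1L, min)
            sel <- c(sel, rest[which.max(mind)])
          }
          sel
        })
    })
    comm[i, chosen] <- 1L
  }
  comm
}

#' Simulate a site table with spatially autocorrelated covariates
#'
#' Coordinates are uniform on a square of side `extent_km` centred on the
#' Caatinga (8 S, 39 W). Each climate covariate is one draw from a
#' zero-mean Gaussian process with exponential covariance exp(-d/range)
#' (dense Cholesky with 1e-8 diagonal jitter), scaled to a realistic mean
#' and SD. Edaphic classes are assigned from spatially blocked regions
#' (k-means on coordinates), and two deliberately collinear precipitation
#' summaries are included to exercise VIF screening. The `env` column is a
#' standardized copy of `precip_driest`, the filtering axis used by
#' [assemble_communities()].
#'
#' @param n_sites Number of sites (>= 4).
#' @param extent_km Side of the study square (default 800, the scale of the
#'   study region).
#' @param autocorr_range_km Exponential decay range of the covariate
#'   Gaussian process (default 200 km, matching short-distance-class
#'   autocorrelation).
#' @param seed Integer seed.
#' @return Site table: `site`, `lat`, `lon`, `substrate`, `annual_temp`
#'   (deg C), `annual_precip` (mm), `precip_driest`, `precip_wettest`
#'   (mm), `precip_seasonality` (dimensionless), `env`.
#' @export
simulate_sites <- function(n_sites, extent_km = 800,
                           autocorr_range_km = 200, seed = 1) {
  if (n_sites < 4) stop("need at least 4 sites", call. = FALSE)
  lat0 <- -8; lon0 <- -39
  km_per_deg <- 6371 * pi / 180
  with_seed(derive_seed(seed, "sites"), {
    x <- stats::runif(n_sites, -extent_km / 2, extent_km / 2)
    y <- stats::runif(n_sites, -extent_km / 2, extent_km / 2)
    lat <- lat0 + y / km_per_deg
    lon <- lon0 + x / (km_per_deg * cos(lat0 * pi / 180))
    d <- as.matrix(stats::dist(cbind(x, y)))
    sigma <- exp(-d / autocorr_range_km) + diag(1e-8, n_sites)
    l <- chol(sigma)
    gp <- function() as.numeric(t(l) %*% stats::rnorm(n_sites))
    temp <- 25 + 2 * gp()
    precip <- 800 + 200 * gp()
    driest <- pmax(0, 30 + 15 * gp())
    wettest <- 0.5 * precip + 50 * stats::rnorm(n_sites)  # collinear on purpose
    seasonality <- 60 - 0.04 * driest * 10 + 5 * stats::rnorm(n_sites)
    blocks <- stats::kmeans(cbind(x, y), centers = min(3, n_sites))$cluster
    data.frame(
      site = sprintf("site%03d", seq_len(n_sites)),
      lat = lat, lon = lon,
      substrate = c("sedimentary", "crystalline", "inselberg")[
        ((blocks - 1) %% 3) + 1],
      annual_temp = temp, annual_precip = precip,
      precip_driest = driest, precip_wettest = wettest,
      precip_seasonality = seasonality,
      env = as.numeric(scale(driest)),
      stringsAsFactors = FALSE
    )
  })
}

#' Emit a complete synthetic toy study to a directory
#'
#' Writes the file set the pipeline reads: pool tree (newick), ages file
#' (a random subset of true internal node ages), life-form table,
#' community matrix and site table. Same seed, same bytes.
#'
#' @param dir Output directory (created if missing).
#' @param n_tips Pool size.
#' @param n_sites Number of sites.
#' @param richness Species per site.
#' @param mode Assembly rule (see [assemble_communities()]).
#' @param trait_rate Discrete trait transition rate.
#' @param niche_sigma Brownian niche SD.
#' @param tolerance Filtering niche tolerance.
#' @param seed Master seed.
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_study <- function(dir, n_tips = 100, n_sites = 20, richness = 12,
                           mode = "filtering", trait_rate = 0.05,
                           niche_sigma = 1, tolerance = 0.8, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_yule_tree(n_tips, seed)
  sites <- simulate_sites(n_sites, seed = seed)
  traits <- evolve_discrete_trait(tree, rate = trait_rate, seed = seed)
  niche_raw <- evolve_continuous_niche(tree, sigma = niche_sigma, seed = seed)
  niche <- as.numeric(scale(niche_raw))
  names(niche) <- names(niche_raw)
  comm <- assemble_communities(tree, niche, sites, mode = mode,
                               richness = richness, tolerance = tolerance,
                               seed = seed)
  ages_all <- node_ages(tree)
  idx <- with_seed(derive_seed(seed, "ages"),
                   sort(sample(tree$Nnode - 1L,
                               max(1L, tree$Nnode %/% 10))) + 1L)
  ages <- data.frame(name = tree$node.label[idx],
                     age = ages_all[ape::Ntip(tree) + idx])
  paths <- list(
    tree = file.path(dir, "pool_tree.nwk"),
    ages = file.path(dir, "node_ages.txt"),
    traits = file.path(dir, "life_forms.csv"),
    communities = file.path(dir, "communities.csv"),
    sites = file.path(dir, "sites.csv")
  )
  write_newick(tree, paths$tree)
  utils::write.table(ages, paths$ages, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.csv(data.frame(species = names(traits),
                              final_category = unname(traits)),
                   paths$traits, row.names = FALSE, quote = FALSE)
  write_community(comm, paths$communities)
  utils::write.csv(sites, paths$sites, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
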