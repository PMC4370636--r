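#' Build a pipeline run configuration
#'
#' Defaults are the study constants: 1000 null permutations for SES, 999
#' trait reshuffles for the signal test, 6 equal-count distance classes,
#' root age 137 My, and the growth-form split rule (phanerophytes are
#' woody; the other four Raunkiaer states are herbaceous).
#'
#' @param tree,ages,communities,traits,sites Input file paths (newick,
#'   phylocom-style ages, and CSVs; `ages` may be `NULL`).
#' @param n_perm SES permutations per site and metric.
#' @param n_rand Signal-test reshuffles.
#' @param k Distance classes for the correlogram.
#' @param alpha_cor Significance level for correlogram classes.
#' @param alpha_model Significance level for ANCOVA flags.
#' @param root_age Root age in My for dating.
#' @param climate_terms Climate covariate column names in the site table.
#' @param n_filters Number of leading PCNM filters carried into the ANCOVA
#'   (the broad-scale first filter by default).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tree, communities, traits, sites, ages = NULL,
                       n_perm = 1000, n_rand = 999, k = 6,
                       alpha_cor = 0.05, alpha_model = 0.10,
                       root_age = 137,
                       climate_terms = c("annual_temp", "annual_precip",
                                         "precip_driest"),
                       n_filters = 1, seed = 1) {
  cfg <- list(tree = tree, ages = ages, communities = communities,
              traits = traits, sites = sites,
              n_perm = n_perm, n_rand = n_rand, k = k,
              alpha_cor = alpha_cor, alpha_model = alpha_model,
              root_age = root_age, climate_terms = climate_terms,
              n_filters = n_filters, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Split a community matrix into woody and herbaceous partitions
#'
#' Woody = phanerophytes; herbaceous = therophytes, cryptophytes,
#' hemicryptophytes and chamaephytes. Sites falling below 2 species in a
#' partition are dropped from that partition with a warning (the metrics
#' are undefined there).
#'
#' @param comm Incidence matrix.
#' @param traits Named species -> life-form vector covering every community
#'   species.
#' @return A list with elements `woody` and `herbaceous` (either may have
#'   fewer sites than the input).
#' @export
split_growth_forms <- function(comm, traits) {
  missing <- setdiff(colnames(comm), names(traits))
  if (length(missing))
    stop("species without a life form: ", paste(missing, collapse = ", "),
         call. = FALSE)
  forms <- traits[colnames(comm)]
  take <- function(keep, label) {
    sub <- comm[, keep, drop = FALSE]
    ok <- rowSums(sub) >= 2
    if (!all(ok))
      warning("sites dropped from ", label, " partition (< 2 species): ",
              paste(rownames(sub)[!ok], collapse = ", "))
    sub[ok, colSums(sub) > 0, drop = FALSE]
  }
  list(woody = take(forms == "phanerophyte", "woody"),
       herbaceous = take(forms != "phanerophyte", "herbaceous"))
}

#' Run the full community-phylogenetics pipeline
#'
#' Stages: read and reconcile inputs; date the pool tree; NRI/NTI tables
#' for all species and the woody/herbaceous partitions; life-form signal
#' test; Moran's I correlograms for each index and climate covariate; PCNM
#' filters; VIF screen of the climate covariates; ANCOVA per index; and
#' climate-vs-edaphic variance partitioning per index. All tables are
#' written as CSV to `out_dir` together with a manifest recording every
#' setting and seed, which suffices to re-execute the run identically.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of all stage results.
#' @export
run_all <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message("[caatphylo] ", ...)

  log_line("stage: load inputs")
  tree <- read_newick(cfg$tree)
  ages <- if (!is.null(cfg$ages)) read_age_table(cfg$ages)
  comm <- read_community(cfg$communities)
  traits <- read_life_forms(cfg$traits)
  sites <- read_sites(cfg$sites)

  unknown <- setdiff(colnames(comm), tree$tip.label)
  if (length(unknown))
    stop("stage 'reconcile' failed; community species not in tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  comm <- comm[sites$site, , drop = FALSE]

  log_line("stage: date tree (root age ", cfg$root_age, " My)")
  dated <- date_tree(tree, ages, root_age = cfg$root_age)
  write_newick(dated, file.path(out_dir, "dated_tree.nwk"))
  dist <- patristic_matrix(dated)

  log_line("stage: NRI/NTI (", cfg$n_perm, " permutations)")
  parts <- split_growth_forms(comm, traits)
  div_of <- function(m, label) {
    if (nrow(m) == 0L) {
      log_line("partition '", label, "' has no analysable site; skipped")
      return(NULL)
    }
    nri_nti_table(m, dist, cfg$n_perm, derive_seed(cfg$seed, label))
  }
  div <- Filter(Negate(is.null), list(
    all = div_of(comm, "all"),
    woody = div_of(parts$woody, "woody"),
    herbaceous = div_of(parts$herbaceous, "herbaceous")
  ))
  div_tab <- merge_div_tables(div, sites)
  utils::write.csv(div_tab, file.path(out_dir, "diversity_indices.csv"),
                   row.names = FALSE, quote = FALSE)

  log_line("stage: life-form signal test (", cfg$n_rand, " reshuffles)")
  pool_states <- traits[tree$tip.label[tree$tip.label %in% names(traits)]]
  sig <- signal_test(prune_to_taxa(dated, names(pool_states)), pool_states,
                     n_rand = cfg$n_rand,
                     seed = derive_seed(cfg$seed, "signal"))
  utils::write.csv(
    data.frame(observed = sig$observed, null_median = sig$null_median,
               null_min = sig$null_min, null_max = sig$null_max,
               n_rand = sig$n_rand, p = sig$p),
    file.path(out_dir, "signal_test.csv"), row.names = FALSE, quote = FALSE)

  log_line("stage: correlograms (", cfg$k, " classes)")
  dmat <- geodesic_matrix(sites)
  corr_vars <- c(
    stats::setNames(
      lapply(c("nri_all", "nri_woody", "nri_herbaceous",
               "nti_all", "nti_woody", "nti_herbaceous"),
             function(v) div_tab[[v]]),
      c("nri_all", "nri_woody", "nri_herbaceous",
        "nti_all", "nti_woody", "nti_herbaceous")),
    stats::setNames(lapply(cfg$climate_terms, function(v) sites[[v]]),
                    cfg$climate_terms))
  corr <- lapply(names(corr_vars), function(v) {
    x <- corr_vars[[v]]
    if (is.null(x) || anyNA(x)) return(NULL)  # partition dropped a site
    cg <- correlogram(x, dmat, k = cfg$k, seed = derive_seed(cfg$seed, v))
    cbind(variable = v, cg)
  })
  corr <- do.call(rbind, corr)
  utils::write.csv(corr, file.path(out_dir, "correlograms.csv"),
                   row.names = FALSE, quote = FALSE)

  log_line("stage: PCNM filters")
  filt <- pcnm_filters(dmat)
  filt_tab <- data.frame(site = sites$site, filt$vectors)
  utils::write.csv(filt_tab, file.path(out_dir, "pcnm_filters.csv"),
                   row.names = FALSE, quote = FALSE)

  log_line("stage: VIF screen")
  vif <- vif_screen(sites[, cfg$climate_terms, drop = FALSE])
  utils::write.csv(vif$steps, file.path(out_dir, "vif_screen.csv"),
                   row.names = FALSE, quote = FALSE)

  log_line("stage: ANCOVA + variance partition")
  fvec <- filt$vectors[, seq_len(min(cfg$n_filters, ncol(filt$vectors))),
                       drop = FALSE]
  anc <- list(); part <- list()
  for (v in c("nri_all", "nri_woody", "nri_herbaceous",
              "nti_all", "nti_woody", "nti_herbaceous")) {
    y <- div_tab[[v]]
    if (is.null(y) || anyNA(y)) next
    anc[[v]] <- ancova(y, sites, vif$retained, filter = fvec[, 1],
                       alpha = cfg$alpha_model)
    part[[v]] <- variance_partition(
      y, sites[, vif$retained, drop = FALSE], edaphic_dummies(sites))
  }
  anc_tab <- do.call(rbind, lapply(names(anc), function(v)
    cbind(index = v, anc[[v]]$coefficients)))
  utils::write.csv(anc_tab, file.path(out_dir, "ancova.csv"),
                   row.names = FALSE, quote = FALSE)
  part_tab <- do.call(rbind, lapply(names(part), function(v)
    data.frame(index = v, climate = part[[v]]$a, edaphic = part[[v]]$c,
               shared = part[[v]]$b, unexplained = part[[v]]$d,
               adj_r2 = part[[v]]$r2_full)))
  utils::write.csv(part_tab, file.path(out_dir, "variance_partition.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- c(
    sprintf("input_tree: %s", cfg$tree),
    sprintf("input_ages: %s", cfg$ages %||% ""),
    sprintf("input_communities: %s", cfg$communities),
    sprintf("input_traits: %s", cfg$traits),
    sprintf("input_sites: %s", cfg$sites),
    sprintf("n_perm: %d", cfg$n_perm),
    sprintf("n_rand: %d", cfg$n_rand),
    sprintf("k_classes: %d", cfg$k),
    sprintf("alpha_cor: %g", cfg$alpha_cor),
    sprintf("alpha_model: %g", cfg$alpha_model),
    sprintf("root_age: %g", cfg$root_age),
    sprintf("climate_terms: %s", paste(cfg$climate_terms, collapse = ",")),
    sprintf("n_filters: %d", cfg$n_filters),
    sprintf("seed: %d", cfg$seed)
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  log_line("done: ", out_dir)
  invisible(list(dated_tree = dated, diversity = div_tab, signal = sig,
                 correlograms = corr, filters = filt, vif = vif,
                 ancova = anc, partition = part))
}

# wide per-site table joining the three partitions' indices
merge_div_tables <- function(div, sites) {
  out <- data.frame(site = sites$site,
                    substrate = sites$substrate %||% NA,
                    stringsAsFactors = FALSE)
  for (p in names(div)) {
    m <- match(out$site, div[[p]]$site)
    out[[paste0("nri_", p)]] <- div[[p]]$nri[m]
    out[[paste0("nti_", p)]] <- div[[p]]$nti[m]
  }
  out
}

#' The published 13-site Caatinga tables (packaged fixture)
#'
#' Site coordinates and substrate classes together with the printed per-site
#' NRI/NTI values for all, woody and herbaceous species. These printed
#' tables are the only desk-scale inputs of the original study (the raw
#' floristic lists were never deposited), and suffice to recompute its
#' spatial-autocorrelation analysis.
#'
#' @return A data.frame with one row per site: `site`, `municipality`,
#'   `substrate`, `lat`, `lon`, `nri_all`, `nri_wood`, `nri_herb`,
#'   `nti_all`, `nti_wood`, `nti_herb`.
#' @export
caatinga_tables <- function() {
  f <- system.file("extdata", "caatinga_sites.csv", package = "caatphylo",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
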