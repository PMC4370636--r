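#' @keywords internal
LIFE_FORMS <- c("phanerophyte", "chamaephyte", "hemicryptophyte",
                "cryptophyte", "therophyte")

#' Harmonize a raw life-form label into the five Raunkiaer categories
#'
#' Source floras report growth habits outside the five classical Raunkiaer
#' states (bud position in the dry season). The harmonization rules are:
#' aerophytes, epiphytes and hemiparasites become phanerophytes; cacti and
#' succulents become phanerophytes when the adult plant is tall, else
#' chamaephytes; climbers become therophytes when they senesce in the dry
#' season, otherwise phanerophytes (tall) or chamaephytes (short). Labels
#' already in the five-state vocabulary pass through.
#'
#' @param raw Raw label (case-insensitive): one of the five final states or
#'   aerophyte, epiphyte, hemiparasite, succulent, cactus, climber.
#' @param size_class `"tall"` or `"short"`; required for cactus/succulent
#'   and for non-senescent climbers.
#' @param senescent_dry_season Logical; required for climbers.
#' @return One of the five Raunkiaer categories.
#' @export
harmonize_life_form <- function(raw, size_class = NULL,
                                senescent_dry_season = NULL) {
  raw <- tolower(trimws(raw))
  if (raw %in% LIFE_FORMS) return(raw)
  if (raw %in% c("aerophyte", "epiphyte", "hemiparasite"))
    return("phanerophyte")
  if (raw %in% c("cactus", "succulent")) {
    if (is.null(size_class))
      stop("'", raw, "' needs a size_class ('tall'/'short')", call. = FALSE)
    return(if (match.arg(size_class, c("tall", "short")) == "tall")
      "phanerophyte" else "chamaephyte")
  }
  if (raw == "climber") {
    if (is.null(senescent_dry_season))
      stop("'climber' needs senescent_dry_season (TRUE/FALSE)", call. = FALSE)
    if (isTRUE(senescent_dry_season)) return("therophyte")
    if (is.null(size_class))
      stop("non-senescent 'climber' needs a size_class", call. = FALSE)
    return(if (match.arg(size_class, c("tall", "short")) == "tall")
      "phanerophyte" else "chamaephyte")
  }
  stop("unknown life-form label: '", raw, "'", call. = FALSE)
}

#' Resolve conflicting life-form reports for one species
#'
#' When different surveys assign different forms to one species, the form
#' with the *least protected* buds wins, i.e. the priority order
#' phanerophyte > chamaephyte > hemicryptophyte > cryptophyte > therophyte.
#'
#' @param reports Character vector of final-category reports.
#' @return The single resolved category.
#' @export
resolve_life_form <- function(reports) {
  reports <- unique(match.arg(tolower(reports), LIFE_FORMS, several.ok = TRUE))
  LIFE_FORMS[min(match(reports, LIFE_FORMS))]
}

#' Read a species life-form table
#'
#' CSV with columns `species`, `raw_label` and optional `size_class`,
#' `senescent_dry_season`, `final_category`. Raw labels are harmonized via
#' [harmonize_life_form()] unless a `final_category` is already present.
#' Ferns/lycophytes, exotics or genus-level records can be dropped at load
#' via `exclude`; the count of exclusions is reported with a message, since
#' downstream phylogenetic metrics are sensitive to such old or uncertain
#' records.
#'
#' @param file CSV path.
#' @param exclude Character vector of species names to drop.
#' @return Named character vector: species -> category.
#' @export
read_life_forms <- function(file, exclude = character()) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot("species" %in% names(df))
  if (length(exclude)) {
    n0 <- nrow(df)
    df <- df[!df$species %in% exclude, , drop = FALSE]
    message("excluded ", n0 - nrow(df), " species at load")
  }
  cat_of <- function(i) {
    if ("final_category" %in% names(df) && nzchar(df$final_category[i] %||% ""))
      return(tolower(df$final_category[i]))
    harmonize_life_form(
      df$raw_label[i],
      size_class = if ("size_class" %in% names(df) &&
                       nzchar(df$size_class[i] %||% "")) df$size_class[i],
      senescent_dry_season = if ("senescent_dry_season" %in% names(df))
        as.logical(df$senescent_dry_season[i])
    )
  }
  out <- vapply(seq_len(nrow(df)), cat_of, character(1))
  if (anyDuplicated(df$species)) {
    out <- tapply(out, df$species, resolve_life_form)
    out <- stats::setNames(as.character(out), names(out))
  } else {
    names(out) <- df$species
  }
  bad <- setdiff(unique(out), LIFE_FORMS)
  if (length(bad))
    stop("invalid final categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out
}

#' Minimum number of character-state changes on a tree (parsimony score)
#'
#' Exact minimum over all internal-state assignments for an unordered
#' multistate character, computed with Hartigan's dynamic program, which is
#' valid for multifurcating trees: at each internal node the children vote
#' for their optimal state sets; the node keeps the most-voted states and
#' adds (number of children - max votes) changes.
#'
#' @param tree A `phylo` (branch lengths not needed; polytomies fine).
#' @param states Named character (or factor) vector of tip states covering
#'   every tip.
#' @return Integer minimum change count.
#' @export
parsimony_changes <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  states <- stats::setNames(as.character(states), names(states))
  untyped <- setdiff(tree$tip.label, names(states))
  if (length(untyped))
    stop("tips without a state: ", paste(untyped, collapse = ", "),
         call. = FALSE)
  eng <- parsimony_engine(tree)
  eng(states[tree$tip.label])
}

# precompute the postorder traversal once; returns a scorer over tip-state
# vectors (in tree$tip.label order), so null reshuffles reuse the topology
parsimony_engine <- function(tree) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  depth <- integer(ntot)
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) {
      depth[ch] <- depth[v] + 1L
      queue <- c(queue, ch[ch > ntip])
    }
  }
  internal <- root:ntot
  ord <- internal[order(depth[internal], decreasing = TRUE)]
  kids_ord <- lapply(as.character(ord), function(v) kids[[v]])
  nkids <- lengths(kids_ord)

  function(tip_states) {
    alphabet <- unique(tip_states)
    sets <- matrix(FALSE, ntot, length(alphabet))
    sets[cbind(seq_len(ntip), match(tip_states, alphabet))] <- TRUE
    changes <- 0L
    for (i in seq_along(ord)) {
      votes <- colSums(sets[kids_ord[[i]], , drop = FALSE])
      mx <- max(votes)
      sets[ord[i], ] <- votes == mx
      changes <- changes + nkids[i] - mx
    }
    as.integer(changes)
  }
}

#' Fixed-tree, character-reshuffle test of phylogenetic signal
#'
#' Tests whether a discrete trait (here, Raunkiaer life form) shows fewer
#' parsimony state changes on the phylogeny than expected if states were
#' distributed at random: the observed minimum change count is compared to
#' a null distribution obtained by uniformly permuting the tip states
#' (preserving the state multiset). Significantly few changes indicate
#' phylogenetic niche conservatism.
#'
#' @inheritParams parsimony_changes
#' @param n_rand Number of random reshuffles (default 999).
#' @param seed Integer seed.
#' @return A list: `observed`, `null_median`, `null_min`, `null_max`,
#'   `n_rand`, `p` = (1 + #\{null <= observed\}) / (n_rand + 1), and the
#'   full `null` vector.
#' @export
signal_test <- function(tree, states, n_rand = 999, seed = 1) {
  states <- stats::setNames(as.character(states), names(states))
  if (length(unique(states[tree$tip.label])) < 2L)
    stop("signal test undefined for a single-state trait", call. = FALSE)
  observed <- parsimony_changes(tree, states)
  tip_states <- states[tree$tip.label]
  eng <- parsimony_engine(tree)
  null <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) eng(sample(tip_states)),
           integer(1))
  })
  list(
    observed = observed,
    null_median = stats::median(null),
    null_min = min(null),
    null_max = max(null),
    n_rand = n_rand,
    p = (1 + sum(null <= observed)) / (n_rand + 1),
    null = null
  )
}
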