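#' Parse a newick string into a phylogeny
#'
#' Trees are represented throughout the package as [ape::read.tree()] `phylo`
#' objects: tips are the species pool, branch lengths are in millions of
#' years (My) once dated, and internal node labels carry the names used by
#' age-constraint tables. Polytomies and inner labels are preserved.
#'
#' @param text A single rooted newick statement terminated by `;`.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("newick text must be a single non-empty string", call. = FALSE)
  text <- trimws(text)
  if (!grepl(";\\s*$", text))
    stop("newick statement must end with ';'", call. = FALSE)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at position ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("unbalanced '(': ", depth, " unclosed at end of string", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || inherits(tree, "multiPhylo"))
    stop("malformed newick string", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("empty tip name in newick string", call. = FALSE)
  tree
}

#' Read a newick tree from a file
#'
#' @param file Path to a `.nwk` file holding one tree.
#' @return A `phylo` object.
#' @export
read_newick <- function(file) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Serialize a phylogeny to newick
#'
#' Labels are written unquoted; branch lengths use full precision so that
#' `parse_newick(write_newick(t))` round-trips topology and lengths.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if given the string is also written to it.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Prune a phylogeny to a set of tips
#'
#' Internal nodes left with a single child are collapsed and their branch
#' lengths summed, so patristic distances among the retained tips are
#' unchanged. Node labels of retained nodes survive the collapse.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip names to keep (at least 2).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(taxa) < 2L)
    stop("need at least 2 tips to prune to", call. = FALSE)
  ape::keep.tip(tree, taxa)
}

#' Read a node-age constraint table
#'
#' Two whitespace-delimited columns (node name, age in My), the dialect of
#' phylocom-style `ages` files. Lines starting with `#` are ignored.
#'
#' @param file Path to the ages file.
#' @return A data.frame with columns `name` and `age`.
#' @export
read_age_table <- function(file) {
  raw <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("name", "age"),
                           colClasses = c("character", "numeric"))
  validate_age_table(raw)
}

#' @keywords internal
validate_age_table <- function(ages) {
  stopifnot(is.data.frame(ages), all(c("name", "age") %in% names(ages)))
  if (anyDuplicated(ages$name))
    stop("duplicate node names in age table", call. = FALSE)
  if (any(!is.finite(ages$age)) || any(ages$age <= 0))
    stop("ages must be finite and > 0", call. = FALSE)
  ages[c("name", "age")]
}

#' Date a phylogeny by even placement of undated nodes
#'
#' Produces a pseudo-chronogram from a topology plus a set of internal-node
#' age constraints, in the manner of branch-length adjustment (BLADJ): the
#' root is fixed at `root_age`, nodes named in `ages` keep their given ages,
#' tips are age 0, and every other internal node is placed so that the node
#' ages along the path from its nearest dated ancestor to its nearest dated
#' descendant (or tip) are evenly spaced by node count. This minimizes
#' variance in branch lengths subject to the constraints.
#'
#' Nodes are assigned in order of increasing node depth and become anchors
#' for the nodes below them, so ages are non-increasing root-to-tip and no
#' negative branch lengths can arise from consistent constraints. When an
#' undated node has several equally near dated descendants the largest age
#' (the most constraining) is used.
#'
#' @param tree A `phylo`; internal node labels identify constrainable nodes.
#' @param ages A data.frame with columns `name`, `age` (My), or `NULL` for
#'   root-only calibration.
#' @param root_age Age of the root in My. The default 137 is the stem age
#'   commonly used for the eudicots.
#' @return The tree with branch lengths `age(parent) - age(child)` and a
#'   `node.age` attribute holding all node ages (tips first, ape order).
#' @export
date_tree <- function(tree, ages = NULL, root_age = 137) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  root <- ntip + 1L
  if (!is.null(ages)) {
    ages <- validate_age_table(ages)
    if (is.null(tree$node.label) && nrow(ages))
      ages <- ages[0L, ]
    else
      ages <- ages[ages$name %in% tree$node.label, , drop = FALSE]
  } else {
    ages <- data.frame(name = character(), age = numeric())
  }

  age <- rep(NA_real_, ntot)
  fixed <- logical(ntot)
  age[seq_len(ntip)] <- 0
  fixed[seq_len(ntip)] <- TRUE
  age[root] <- root_age
  fixed[root] <- TRUE
  if (nrow(ages)) {
    idx <- ntip + match(ages$name, tree$node.label)
    age[idx] <- ages$age
    fixed[idx] <- TRUE
    if (any(ages$age > root_age))
      stop("age constraint exceeds root age: ",
           paste(ages$name[ages$age > root_age], collapse = ", "),
           call. = FALSE)
  }

  parent <- integer(ntot)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent[root] <- 0L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  kids <- vector("list", ntot)
  kids[as.integer(names(children))] <- children

  # constraint consistency: each fixed node must be <= its nearest fixed ancestor
  for (v in which(fixed)) {
    if (v == root) next
    a <- parent[v]
    while (a != 0L && !fixed[a]) a <- parent[a]
    if (a != 0L && !is.na(age[a]) && age[v] > age[a])
      stop("age constraint violation: node age ", age[v],
           " exceeds dated ancestor age ", age[a], call. = FALSE)
  }

  # node depth (edges from root) for the top-down sweep
  depth <- integer(ntot)
  ord <- integer(0)
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in kids[[v]]) {
      depth[w] <- depth[v] + 1L
      queue <- c(queue, w)
    }
  }

  fixed0 <- fixed  # the original constraint set anchors the downward search
  nearest_fixed_below <- function(v) {
    # BFS down among original constraints; returns c(steps, age);
    # tie at equal depth -> max age (the most constraining)
    lev <- kids[[v]]
    steps <- 1L
    while (length(lev)) {
      hit <- lev[fixed0[lev]]
      if (length(hit)) return(c(steps, max(age[hit])))
      lev <- unlist(kids[lev], use.names = FALSE)
      steps <- steps + 1L
    }
    stop("internal error: no fixed descendant found")  # tips are fixed
  }

  # max constrained age strictly below each node (monotonicity floor)
  maxfix_below <- rep(-Inf, ntot)
  for (v in rev(ord)) {
    for (w in kids[[v]])
      maxfix_below[v] <- max(maxfix_below[v],
                             if (fixed0[w]) age[w] else maxfix_below[w])
  }

  for (v in ord) {
    if (fixed[v]) next
    # parent is already assigned (top-down sweep), so it is the anchor;
    # sequential anchoring reproduces even node-count spacing along chains
    down <- nearest_fixed_below(v)
    interp <- age[parent[v]] -
      (age[parent[v]] - down[2L]) / (down[1L] + 1)
    age[v] <- max(interp, maxfix_below[v])
    fixed[v] <- TRUE
  }

  bl <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  if (any(bl < -1e-9))
    stop("negative branch length produced; inconsistent age constraints",
         call. = FALSE)
  bl[bl < 0] <- 0
  tree$edge.length <- bl
  attr(tree, "node.age") <- age
  tree
}

#' Node ages of a dated phylogeny
#'
#' @param tree A `phylo` returned by [date_tree()], or any tree with branch
#'   lengths (ages are then distances below the maximum root-to-tip depth).
#' @return Numeric vector of ages (tips first, then internal nodes in ape
#'   numbering).
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ag <- attr(tree, "node.age")
  if (!is.null(ag)) return(ag)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Patristic distance matrix
#'
#' Tip-to-tip path lengths (the sum of branch lengths along the path, i.e.
#' twice the divergence time for an ultrametric tree).
#'
#' @param tree A `phylo` with all branch lengths set.
#' @return A symmetric matrix with zero diagonal, dimnames = tip labels.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have all branch lengths set (date it first)",
         call. = FALSE)
  ape::cophenetic.phylo(tree)
}
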