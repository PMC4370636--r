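# shared fixtures and independent brute-force oracles

# the 3-tip worked tree: d(A,B)=2, d(A,C)=d(B,C)=4
worked_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

# brute-force MPD/MNTD by explicit double loops
mpd_brute <- function(sample, dist) {
  s <- 0; np <- 0
  for (i in seq_along(sample)) for (j in seq_along(sample)) {
    if (i < j) { s <- s + dist[sample[i], sample[j]]; np <- np + 1 }
  }
  s / np
}
mntd_brute <- function(sample, dist) {
  mins <- vapply(seq_along(sample), function(i) {
    best <- Inf
    for (j in seq_along(sample)) if (j != i)
      best <- min(best, dist[sample[i], sample[j]])
    best
  }, numeric(1))
  mean(mins)
}

# exhaustive parsimony: minimum changes over all internal-state assignments
parsimony_exhaustive <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  alphabet <- sort(unique(as.character(states)))
  m <- tree$Nnode
  tip_idx <- match(states[tree$tip.label], alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_along(alphabet)), m)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tip_idx, grid[r, ])
    best <- min(best, sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]]))
  }
  best
}

# naive Moran's I straight from the formula
morans_i_naive <- function(x, w) {
  n <- length(x); xb <- mean(x)
  num <- 0; s0 <- 0
  for (i in 1:n) for (j in 1:n) {
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
    s0 <- s0 + w[i, j]
  }
  (n / s0) * num / sum((x - xb)^2)
}

# random site table on a small square (plain, no spatial structure)
random_sites <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(site = paste0("s", seq_len(n)),
             lat = runif(n, -10, -5), lon = runif(n, -42, -36),
             substrate = sample(c("sedimentary", "crystalline", "inselberg"),
                                n, replace = TRUE),
             stringsAsFactors = FALSE)
}
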