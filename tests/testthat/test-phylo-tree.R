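test_that("newick parsing keeps topology, lengths, polytomies and labels", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))

  tr2 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr2), 3L)
  expect_equal(tr2$Nnode, 2L)

  poly <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(ape::Ntip(poly), 3L)
  expect_equal(poly$Nnode, 1L)

  lab <- parse_newick("((A:1,B:1)n1:1,C:2)root;")
  expect_true("n1" %in% lab$node.label)
})

test_that("malformed newick is rejected with a positional message", {
  expect_error(parse_newick("((A:1,B:1:);"), "unbalanced")
  expect_error(parse_newick("(A:1,B:1));"), "position")
  expect_error(parse_newick(""), "non-empty")
  expect_error(parse_newick("(A:1,A:1);"), "duplicate")
  expect_error(parse_newick("(A:1,B:1)"), ";")
})

test_that("newick round-trips are isomorphic with equal branch lengths", {
  for (txt in c("(A:1,B:1);", "(A:1,B:1,C:1);")) {
    back <- parse_newick(write_newick(parse_newick(txt)))
    expect_true(ape::all.equal.phylo(parse_newick(txt), back,
                                     use.edge.length = TRUE))
  }
  set.seed(42)
  big <- ape::rtree(100)
  back <- parse_newick(write_newick(big))
  expect_true(ape::all.equal.phylo(big, back, use.edge.length = FALSE))
  expect_equal(sort(patristic_matrix(back)[big$tip.label, big$tip.label]),
               sort(patristic_matrix(big)), tolerance = 1e-9)
})

test_that("pruning collapses degree-2 nodes, summing branch lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  d <- patristic_matrix(pr)
  expect_equal(d["A", "C"], 4)
  expect_equal(ape::Ntip(pr), 2L)

  same <- prune_to_taxa(tr, c("A", "B", "C"))
  expect_true(ape::all.equal.phylo(tr, same, use.edge.length = TRUE))

  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
})

test_that("prune-then-distance equals distance-then-subselect", {
  set.seed(7)
  tr <- ape::rtree(50)
  full <- patristic_matrix(tr)
  for (k in c(2, 5, 10)) {
    taxa <- sample(tr$tip.label, k)
    sub <- patristic_matrix(prune_to_taxa(tr, taxa))[taxa, taxa]
    expect_equal(sub, full[taxa, taxa], tolerance = 1e-10)
  }
  # exhaustive over all subsets of size <= 5 on a small tree
  small <- ape::rtree(8)
  fs <- patristic_matrix(small)
  for (k in 2:5) {
    subsets <- utils::combn(small$tip.label, k)
    for (c_i in seq_len(ncol(subsets))) {
      taxa <- subsets[, c_i]
      sub <- patristic_matrix(prune_to_taxa(small, taxa))[taxa, taxa]
      expect_equal(sub, fs[taxa, taxa], tolerance = 1e-10)
    }
  }
})

test_that("even-spacing dating matches hand-worked chains", {
  # root(10) -> n1 -> tips : n1 midway at 5
  tr <- parse_newick("((A:1,B:1)n1:1,C:2)r;")
  dt <- date_tree(tr, NULL, root_age = 10)
  ag <- node_ages(dt)
  expect_equal(unname(ag[ape::Ntip(tr) + 2L]), 5)
  # root(9) -> n1 -> {n2,n3} -> tips : ages 6 then 3
  tr2 <- parse_newick("(((A:1,B:1)n2:1,(C:1,D:1)n3:1)n1:1,E:3)r;")
  ag2 <- node_ages(date_tree(tr2, NULL, root_age = 9))
  nl <- match(c("n1", "n2", "n3"), tr2$node.label)
  expect_equal(unname(ag2[ape::Ntip(tr2) + nl]), c(6, 3, 3))
})

test_that("dating preserves constraints and orders ages root-to-tip", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- ape::rphylo(30, 1, 0)
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
    true_age <- node_ages(tr)
    pick <- sort(sample(2:tr$Nnode, 5))
    ages <- data.frame(name = tr$node.label[pick],
                       age = true_age[ape::Ntip(tr) + pick])
    root_age <- true_age[ape::Ntip(tr) + 1L]
    dt <- date_tree(tr, ages, root_age = root_age)
    ag <- node_ages(dt)
    # constrained nodes keep their ages exactly
    expect_equal(unname(ag[ape::Ntip(tr) + pick]), ages$age, tolerance = 1e-12)
    expect_equal(unname(ag[ape::Ntip(tr) + 1L]), root_age)
    expect_true(all(ag[seq_len(ape::Ntip(tr))] == 0))
    # ages non-increasing along every edge; lengths consistent
    expect_true(all(ag[dt$edge[, 1]] - ag[dt$edge[, 2]] >= -1e-9))
    expect_true(all(dt$edge.length >= 0))
    # idempotent under the same constraint set
    dt2 <- date_tree(dt, ages, root_age = root_age)
    expect_equal(node_ages(dt2), ag, tolerance = 1e-12)
  }
})

test_that("dating rejects inconsistent constraints", {
  tr <- parse_newick("(((A:1,B:1)n2:1,C:1)n1:1,D:1)r;")
  expect_error(date_tree(tr, data.frame(name = "n1", age = 200),
                         root_age = 137), "root")
  expect_error(
    date_tree(tr, data.frame(name = c("n1", "n2"), age = c(5, 9)),
              root_age = 137), "violation")
})

test_that("patristic distances are path sums on the worked tree", {
  d <- patristic_matrix(worked_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  # ultrametric: root-spanning pairs at 2T
  ul <- simulate_yule_tree(20, seed = 3)
  T <- max(node_ages(ul))
  du <- patristic_matrix(ul)
  left <- ape::extract.clade(ul, ul$edge[1, 2])$tip.label
  if (length(left) < 20) {
    right <- setdiff(ul$tip.label, left)
    expect_equal(unname(du[left[1], right[1]]), 2 * T, tolerance = 1e-9)
  }
  undated <- ape::rtree(5)
  undated$edge.length <- NULL
  expect_error(patristic_matrix(undated), "branch length")
})
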