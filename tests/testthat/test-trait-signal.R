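test_that("life-form harmonization follows the reclassification rules", {
  expect_equal(harmonize_life_form("epiphyte"), "phanerophyte")
  expect_equal(harmonize_life_form("aerophyte"), "phanerophyte")
  expect_equal(harmonize_life_form("hemiparasite"), "phanerophyte")
  expect_equal(harmonize_life_form("therophyte"), "therophyte")
  expect_equal(harmonize_life_form("Chamaephyte"), "chamaephyte")
  expect_equal(harmonize_life_form("cactus", size_class = "tall"),
               "phanerophyte")
  expect_equal(harmonize_life_form("succulent", size_class = "short"),
               "chamaephyte")
  expect_equal(harmonize_life_form("climber", senescent_dry_season = TRUE),
               "therophyte")
  expect_equal(harmonize_life_form("climber", size_class = "tall",
                                   senescent_dry_season = FALSE),
               "phanerophyte")
  expect_error(harmonize_life_form("cactus"), "size_class")
  expect_error(harmonize_life_form("climber"), "senescent")
  expect_error(harmonize_life_form("lichen"), "unknown")
})

test_that("conflicting reports resolve to the least protected buds", {
  expect_equal(resolve_life_form(c("chamaephyte", "phanerophyte")),
               "phanerophyte")
  expect_equal(resolve_life_form(c("therophyte", "cryptophyte")),
               "cryptophyte")
  expect_equal(resolve_life_form("therophyte"), "therophyte")
})

test_that("life-form reader harmonizes, resolves and excludes", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeLines(c(
    "species,raw_label,size_class,senescent_dry_season",
    "Aspidosperma_p,phanerophyte,,",
    "Tillandsia_l,epiphyte,,",
    "Pilosocereus_g,cactus,tall,",
    "Ipomoea_a,climber,,TRUE",
    "Mimosa_t,chamaephyte,,",
    "Mimosa_t,phanerophyte,,",
    "Selaginella_c,therophyte,,"), f)
  expect_message(lf <- read_life_forms(f, exclude = "Selaginella_c"),
                 "excluded 1")
  expect_equal(unname(lf["Tillandsia_l"]), "phanerophyte")
  expect_equal(unname(lf["Pilosocereus_g"]), "phanerophyte")
  expect_equal(unname(lf["Ipomoea_a"]), "therophyte")
  expect_equal(unname(lf["Mimosa_t"]), "phanerophyte")  # least protected
  expect_false("Selaginella_c" %in% names(lf))
})

test_that("parsimony change counts match hand-worked topologies", {
  st <- c(A = "x", B = "x", C = "y", D = "y")
  expect_equal(parsimony_changes(parse_newick("((A,B),(C,D));"), st), 1L)
  expect_equal(parsimony_changes(parse_newick("((A,C),(B,D));"), st), 2L)
  expect_equal(parsimony_changes(parse_newick("((A,B),(C,D));"),
                                 c(A = "x", B = "x", C = "x", D = "x")), 0L)
  # polytomy: 3 same + 1 different = 1 change
  expect_equal(parsimony_changes(parse_newick("(A,B,C,D);"),
                                 c(A = "x", B = "x", C = "x", D = "y")), 1L)
  expect_error(parsimony_changes(parse_newick("((A,B),(C,D));"),
                                 c(A = "x", B = "x", C = "y")), "D")
})

test_that("Hartigan parsimony equals exhaustive enumeration on small trees", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    if (rep %% 3 == 0) tr <- ape::di2multi(tr, tol = 0.6)  # make polytomies
    k <- sample(2:5, 1)
    st <- setNames(sample(letters[1:k], n, replace = TRUE), tr$tip.label)
    if (length(unique(st)) == 1) next
    expect_equal(parsimony_changes(tr, st),
                 parsimony_exhaustive(tr, st),
                 info = paste("rep", rep))
  }
})

test_that("parsimony count matches phangorn's Sankoff score", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (rep in 1:10) {
    tr <- ape::rtree(20)
    forms <- c("phanerophyte", "chamaephyte", "hemicryptophyte",
               "cryptophyte", "therophyte")
    st <- setNames(sample(forms, 20, replace = TRUE), tr$tip.label)
    pd <- phangorn::phyDat(matrix(st, ncol = 1,
                                  dimnames = list(names(st), NULL)),
                           type = "USER", levels = sort(unique(st)))
    expect_equal(parsimony_changes(tr, st),
                 as.integer(phangorn::parsimony(tr, pd, method = "sankoff")))
  }
})

test_that("parsimony is invariant to child order and rerooting", {
  set.seed(23)
  tr <- ape::rtree(12)
  st <- setNames(sample(c("x", "y", "z"), 12, replace = TRUE), tr$tip.label)
  base <- parsimony_changes(tr, st)
  expect_equal(parsimony_changes(ape::ladderize(tr), st), base)
  expect_equal(parsimony_changes(ape::ladderize(tr, right = FALSE), st), base)
  for (tip in sample(tr$tip.label, 4))
    expect_equal(parsimony_changes(
      ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE), st),
      base)
})

test_that("signal test flags clade-structured traits and sizes its null", {
  tr <- ape::stree(32, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  # perfect clade structure: one state per quarter of the tree
  st <- setNames(rep(c("a", "b", "c", "d"), each = 8), tr$tip.label)
  res <- signal_test(tr, st, n_rand = 999, seed = 7)
  expect_equal(res$observed, 3L)
  expect_lte(res$p, 0.01)
  expect_equal(length(res$null), 999L)
  expect_gte(res$null_min, res$observed)
  expect_error(signal_test(tr, setNames(rep("a", 32), tr$tip.label)),
               "single-state")
})

test_that("mean parsimony changes rise with the trait change rate", {
  tr <- simulate_yule_tree(40, seed = 6)
  rates <- c(0.02, 0.2, 2) / max(node_ages(tr))
  means <- vapply(rates, function(r) {
    mean(vapply(1:30, function(i) {
      st <- evolve_discrete_trait(tr, n_states = 5, rate = r, seed = 1000 + i)
      if (length(unique(st)) < 2) 0L else parsimony_changes(tr, st)
    }, integer(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
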