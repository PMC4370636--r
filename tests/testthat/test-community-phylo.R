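test_that("MPD and MNTD match hand-worked values on the 3-tip tree", {
  d <- patristic_matrix(worked_tree())
  expect_equal(mpd(c("A", "B"), d), 2)
  expect_equal(mntd(c("A", "B"), d), 2)
  expect_equal(mpd(c("A", "B", "C"), d), 10 / 3)
  expect_equal(mntd(c("A", "B", "C"), d), 8 / 3)
  expect_error(mpd("A", d), "fewer than 2")
})

test_that("MPD/MNTD equal brute-force double loops and picante", {
  skip_if_not_installed("picante")
  set.seed(5)
  tr <- ape::rtree(20)
  d <- patristic_matrix(tr)
  for (rep in 1:20) {
    spp <- sample(tr$tip.label, 6)
    expect_equal(mpd(spp, d), mpd_brute(spp, d), tolerance = 1e-12)
    expect_equal(mntd(spp, d), mntd_brute(spp, d), tolerance = 1e-12)
    comm <- matrix(as.integer(tr$tip.label %in% spp), 1,
                   dimnames = list("s1", tr$tip.label))
    expect_equal(mpd(spp, d), unname(picante::mpd(comm, d)),
                 tolerance = 1e-12)
    expect_equal(mntd(spp, d), unname(picante::mntd(comm, d)),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to species order and extra matrix taxa", {
  set.seed(9)
  tr <- ape::rtree(15)
  d <- patristic_matrix(tr)
  spp <- sample(tr$tip.label, 5)
  expect_equal(mpd(spp, d), mpd(rev(spp), d))
  expect_equal(mntd(spp, d), mntd(sample(spp), d))
  dsub <- d[spp, spp]
  expect_equal(mpd(spp, d), mpd(spp, dsub))
  expect_equal(mntd(spp, d), mntd(spp, dsub))
  # MNTD <= MPD always (nearest <= average)
  for (rep in 1:200) {
    s <- sample(tr$tip.label, sample(2:10, 1))
    expect_lte(mntd(s, d), mpd(s, d) + 1e-12)
  }
})

test_that("exhaustive SES on the worked tree gives -2/sqrt(3)", {
  d <- patristic_matrix(worked_tree())
  # all C(3,2) = 3 equally likely null samples under label reshuffling
  null <- apply(utils::combn(rownames(d), 2), 2, mpd, dist = d)
  expect_equal(sort(null), c(2, 4, 4))
  ses_exact <- (2 - mean(null)) / sd(null)
  expect_equal(ses_exact, -2 / sqrt(3), tolerance = 1e-12)
  # Monte-Carlo null mean agrees within 3 MC standard errors
  mc <- ses_metric("mpd", c("A", "B"), worked_tree(), n_perm = 4000, seed = 2)
  se_null <- sd(null) / sqrt(mc$n_perm)
  expect_lt(abs(mc$null_mean - mean(null)), 3 * se_null)
  expect_false(mc$degenerate)
})

test_that("Monte-Carlo SES converges to the exhaustive-null SES", {
  # pool of 8 tips, samples of 4: all C(8,4) = 70 equally likely null draws
  tr <- simulate_yule_tree(8, seed = 44)
  d <- patristic_matrix(tr)
  spp <- tr$tip.label[c(1, 3, 5, 7)]
  null <- apply(utils::combn(tr$tip.label, 4), 2, mpd, dist = d)
  ses_exh <- (mpd(spp, d) - mean(null)) / sd(null)
  mc <- ses_metric("mpd", spp, tr, n_perm = 4000, seed = 3)
  expect_lt(abs(mc$null_mean - mean(null)), 3 * sd(null) / sqrt(4000))
  expect_lt(abs(mc$ses - ses_exh), 0.1)
})

test_that("sample = entire pool yields a degenerate null, not a number", {
  tr <- worked_tree()
  r <- ses_metric("mpd", c("A", "B", "C"), tr, n_perm = 50, seed = 1)
  expect_true(r$degenerate)
  expect_true(is.na(r$ses))
})

test_that("SES is reproducible under a fixed seed", {
  tr <- simulate_yule_tree(30, seed = 4)
  a <- ses_metric("mntd", tr$tip.label[1:8], tr, n_perm = 100, seed = 99)
  b <- ses_metric("mntd", tr$tip.label[1:8], tr, n_perm = 100, seed = 99)
  expect_identical(a, b)
})

test_that("clade communities read as clustered, spread ones as overdispersed", {
  tr <- simulate_yule_tree(64, seed = 21)
  d <- patristic_matrix(tr)
  root_kids <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1L, 2]
  clade <- ape::extract.clade(tr, root_kids[1])$tip.label
  skip_if(length(clade) < 8 || length(clade) > 56)
  clade <- clade[1:8]
  # one representative per scattered lineage: greedy max-min picks
  spread <- tr$tip.label[1]
  while (length(spread) < 8) {
    rest <- setdiff(tr$tip.label, spread)
    spread <- c(spread,
                rest[which.max(apply(d[rest, spread, drop = FALSE], 1, min))])
  }
  comm <- rbind(
    clustered = as.integer(tr$tip.label %in% clade),
    dispersed = as.integer(tr$tip.label %in% spread))
  colnames(comm) <- tr$tip.label
  tab <- nri_nti_table(comm, tr, n_perm = 300, seed = 8)
  expect_gt(tab$nri[tab$site == "clustered"], 0)
  expect_lt(tab$nri[tab$site == "dispersed"], 0)
  # flags are definitionally tied to the 1.96 threshold
  expect_equal(tab$nri_sig, abs(tab$nri) > 1.96)
  expect_equal(tab$nti_sig, abs(tab$nti) > 1.96)
})

test_that("per-site results are independent of site order", {
  tr <- simulate_yule_tree(40, seed = 13)
  set.seed(3)
  comm <- matrix(0L, 4, 40, dimnames = list(paste0("s", 1:4), tr$tip.label))
  for (i in 1:4) comm[i, sample(40, 10)] <- 1L
  t1 <- nri_nti_table(comm, tr, n_perm = 60, seed = 5)
  t2 <- nri_nti_table(comm[4:1, ], tr, n_perm = 60, seed = 5)
  expect_equal(t1[order(t1$site), ], t2[order(t2$site), ],
               ignore_attr = TRUE)
})

test_that("community readers validate and round-trip", {
  tr <- simulate_yule_tree(10, seed = 2)
  set.seed(2)
  comm <- matrix(0L, 3, 10, dimnames = list(paste0("s", 1:3), tr$tip.label))
  for (i in 1:3) comm[i, sample(10, 4)] <- 1L
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_community(comm, f)
  back <- read_community(f)
  expect_equal(back[, colnames(comm)[colSums(comm) > 0]],
               comm[, colSums(comm) > 0])
  bad <- comm; bad[1, ] <- 0L
  expect_error(caatphylo:::check_community(bad), "fewer than 2")
  expect_error(nri_nti_table(
    matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("spX", "spY"))), tr),
    "missing from pool")
})
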