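test_that("node distances follow the scaled root-to-leaf node counts", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  nd <- computeNd(tr)
  expect_equal(nd[c("D", "C", "A", "B")], c(D = 0, C = 0.5, A = 1, B = 1))
  expect_warning(nd0 <- computeNd(ape::read.tree(text = "((A,B),(C,D));")),
                 "equally deep")
  expect_true(all(nd0 == 0))
  expect_error(computeNd(ape::unroot(ape::rtree(5))), "rooted")
})

test_that("node distances match an independent path-count oracle", {
  withr::with_seed(31, {
    tr <- ape::rtree(50)
  })
  nd <- computeNd(tr)
  # oracle: unit branch lengths, root-to-tip distance via ape
  tr2 <- ape::compute.brlen(tr, 1)
  d <- ape::node.depth.edgelength(tr2)[seq_len(50)]
  names(d) <- tr$tip.label
  oracle <- (d - min(d)) / (max(d) - min(d))
  expect_equal(nd[names(oracle)], oracle)
  expect_true(all(nd >= 0 & nd <= 1))
})

test_that("the molecular clock converts nd to geological age", {
  expect_equal(clockAge(0), 3.814)
  expect_equal(round(clockAge(0.020), 1), 3.7)
  expect_equal(round(clockAge(0.126), 1), 3.3)
  fsf <- clockSpec("FSF")
  expect_equal(clockAge(0, fsf), 3.628)
  # strictly decreasing in nd
  ages <- clockAge(seq(0, 1, 0.1))
  expect_true(all(diff(ages) <= 0))
  expect_warning(a1 <- clockAge(1, clockSpec("FSF")), "clamped")
  expect_equal(a1, 0)   # the FSF clock crosses zero before nd = 1
  expect_error(clockAge(1.2), "\\[0, 1\\]")
  expect_error(clockSpec(slope = 1, intercept = 0), "negative")
})

test_that("age-group tables partition the 20 amino acids", {
  g123 <- ageGroups()
  expect_identical(lengths(g123), c(`1` = 3L, `2` = 8L, `3` = 9L))
  gabc <- expansionGroups()
  expect_identical(lengths(gabc), c(A = 5L, B = 7L, C = 8L))
  ghte <- exchangeGroups()
  expect_identical(lengths(ghte), c(H = 5L, T = 8L, E = 7L))
  for (g in list(g123, gabc, ghte))
    expect_setequal(unlist(g), aminoAcids())
  entries <- data.frame(aa = c("Y", "K", "G", "B"))
  lab <- assignGroups(entries)
  expect_identical(lab$group123, c("1", "2", "3", "unassigned"))
  expect_identical(lab$groupABC, c("C", "C", "A", "unassigned"))
  # duplicated assignment is a table-validation error
  bad <- ageGroups(); bad$`2` <- c(bad$`2`, "Y")
  expect_error(assignGroups(entries, tables = list(group123 = bad,
                                                   groupABC = expansionGroups())),
               "more than one group")
})

test_that("timelines combine nd, clock age and group labels", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  tl <- buildTimeline(tr, aa = c(A = "Y", B = "K", C = "G", D = "L"))
  expect_equal(tl$nd, sort(tl$nd))
  expect_equal(tl$ageGy, clockAge(tl$nd))
  expect_identical(tl$group123[tl$domainId == "D"], "1")
})

test_that("coevolution regression recovers exact and noisy slopes", {
  pts <- data.frame(nd = c(0.1, 0.2, 0.4, 0.8), s = c(0.2, 0.4, 0.8, 1.6))
  fit <- coevolutionRegression(pts, throughOrigin = TRUE)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r2, 1)
  withr::with_seed(17, {
    x <- runif(20, 0.05, 1)
    noisy <- data.frame(nd = x, s = 1.5 * x + rnorm(20, 0, 0.1))
  })
  f2 <- coevolutionRegression(noisy, throughOrigin = TRUE)
  expect_lt(abs(f2$slope - 1.5), 3 * f2$slopeSe)
  expect_equal(f2$df, c(1, 19))
  f3 <- coevolutionRegression(noisy, throughOrigin = FALSE)
  expect_equal(f3$df, c(1, 18))
  # duplicating every point leaves the slope unchanged
  dup <- rbind(noisy, noisy)
  expect_equal(coevolutionRegression(dup)$slope, f2$slope)
  expect_error(coevolutionRegression(data.frame(nd = c(1, 1, 1),
                                                s = c(1, 2, 3))),
               "identical")
})

test_that("end-to-end census recovery: encode, search, root, nd", {
  cfg <- simulationConfig(nDomains = 25, nProteomes = 12, noiseSd = 0.3,
                          seed = 4)
  sim <- simulateCensus(cfg)
  cm <- encodeCharacters(sim$census)
  res <- searchMP(cm, "hillclimb", seed = 4, nStarts = 1L, maxTrees = 1L)
  nd <- computeNd(lundbergRoot(res$trees[[1]], cm))
  rho <- stats::cor(sim$truth$birthRank[names(nd)], nd, method = "spearman")
  expect_gt(rho, 0.8)
})
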