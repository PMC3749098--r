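test_that("hydropathy means reproduce the scale's arithmetic", {
  kd <- kyteDoolittle()
  expect_equal(round(mean(kd), 2), -0.49)
  expect_length(kd, 20)
  editing <- c("S", "L", "P", "K", "M", "I", "V", "A", "T", "F")
  expect_equal(kdMean(editing), 1.2)
  top14 <- c("LL", "AL", "AA", "LA", "EL", "LE", "LK", "EE", "VL", "AE",
             "GS", "LG", "GL", "EA")
  expect_equal(round(kdMean(top14), 2), 0.93)
  expect_error(kdMean(character(0)), "nonempty")
  expect_error(kdMean(c("A", "U")), "unknown")
})

test_that("dipeptide counting is overlapping and conserves L - 1", {
  ct <- dipeptideCounts("ALA")
  expect_equal(unname(ct$dipep[c("AL", "LA")]), c(1, 1))
  expect_equal(sum(ct$dipep), 2)
  expect_equal(unname(dipeptideCounts("LLLL")$dipep["LL"]), 3)
  # ambiguous residues are tallied separately
  cx <- dipeptideCounts("AXLA")
  expect_equal(cx$ambiguous, 2)
  expect_equal(sum(cx$dipep) + cx$ambiguous, 3)
  withr::with_seed(5, {
    s <- paste(sample(c(aminoAcids(), "X"), 300, TRUE), collapse = "")
  })
  cs <- dipeptideCounts(s)
  expect_equal(sum(cs$dipep) + cs$ambiguous, 299)
  expect_equal(sum(cs$aa) + cs$aaAmbiguous, 300)
  expect_error(dipeptideCounts(""), "nonempty")
  expect_error(dipeptideCounts("AB"), "unknown")
})

test_that("culling drops short, multi-domain, gappy and redundant sequences", {
  rec <- data.frame(
    id = paste0("s", 1:5),
    residues = c(strrep("A", 20),                  # too short
                 paste(rep("ACDEFGHIKL", 10), collapse = ""),
                 paste(rep("ACDEFGHIKL", 10), collapse = ""),  # duplicate
                 paste(rep("MNPQRSTVWY", 8), collapse = ""),
                 paste(rep("LVIMFYWQEK", 9), collapse = "")),
    nDomains = c(1L, 1L, 1L, 2L, 1L),
    unassignedRun = c(0L, 0L, 0L, 0L, 31L),
    stringsAsFactors = FALSE)
  out <- cullSequences(rec)
  expect_identical(sort(out$id), c("s2"))  # s1 short, s3 dup, s4 multi, s5 gappy
  # sliding identity catches shifted copies
  a <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  b <- substr(a, 6, 95)
  out2 <- cullSequences(data.frame(id = c("a", "b"), residues = c(a, b),
                                   stringsAsFactors = FALSE))
  expect_identical(out2$id, "a")
})

test_that("profiles pool per-family frequencies and order heat maps", {
  rec <- data.frame(id = c("x", "y", "z"),
                    residues = c("AA", "ALAL", "VGVGVG"),
                    ffId = c("f1", "f1", "f2"), nd = c(0.1, 0.1, 0.6),
                    stringsAsFactors = FALSE)
  pr <- buildProfiles(rec)
  expect_equal(nrow(pr$families), 2)
  expect_equal(sum(pr$aaFreq["f1", ]), 1)
  expect_equal(unname(pr$aaFreq["f1", "A"]), 4 / 6)
  expect_equal(unname(pr$dipepFreq["f1", "AA"]), 1 / 4)
  expect_identical(sort(colnames(pr$aaHeatmap)), aminoAcids())
  expect_identical(rownames(pr$aaHeatmap), c("f1", "f2"))  # nd ascending
  # global mean frequency decreasing across heat-map columns
  expect_true(all(diff(colMeans(pr$aaHeatmap)) <= 0))
  recBad <- rec; recBad$nd[2] <- NA
  expect_error(buildProfiles(recBad), "without nd")
})

test_that("hypergeometric tail matches closed form and exhaustive enumeration", {
  expect_equal(codechron:::.hypergeomTail(3, 5, 10, 3),
               choose(5, 3) / choose(10, 3))
  # full-support tail is 1
  expect_equal(codechron:::.hypergeomTail(0, 5, 10, 3), 1)
  # enumeration oracle for N <= 12: draw n of N labelled items, M successes
  enumTail <- function(k, M, N, n) {
    draws <- utils::combn(N, n)
    mean(apply(draws, 2, function(d) sum(d <= M)) >= k)
  }
  for (cse in list(c(2, 4, 10, 5), c(3, 6, 12, 6), c(1, 3, 8, 4),
                   c(4, 5, 11, 7))) {
    expect_equal(codechron:::.hypergeomTail(cse[1], cse[2], cse[3], cse[4]),
                 enumTail(cse[1], cse[2], cse[3], cse[4]),
                 tolerance = 1e-12)
  }
  # and against the standard distribution function
  expect_equal(codechron:::.hypergeomTail(7, 40, 100, 20),
               phyper(6, 40, 60, 20, lower.tail = FALSE))
})

test_that("ancient-set selection honors both cutoff conventions", {
  rec <- data.frame(id = 1:3, nd = c(0.1, 0.2, 0.3))
  expect_identical(ancientRecords(rec)$id, 1L)            # strict < 0.2
  expect_identical(ancientRecords(rec, inclusive = TRUE)$id, 1:2)
})

test_that("enrichment applies the strict proportion filter", {
  anc <- data.frame(residues = "ALAL", stringsAsFactors = FALSE)
  all <- data.frame(residues = c("ALAL", "ALAL"), stringsAsFactors = FALSE)
  res <- hypergeomEnrichment(anc, all)
  # identical composition: k/n == M/N for every item, nothing is tested
  expect_true(all(is.na(res$p[res$k > 0])))
  expect_false(any(res$enriched))
  # consistency guard
  expect_error(hypergeomEnrichment(all, anc), "consistency")
})

test_that("group contrast expectation approaches the product of marginals", {
  withr::with_seed(8, {
    recs <- data.frame(residues = replicate(3, paste(
      sample(aminoAcids(), 150, TRUE), collapse = "")))
  })
  res <- groupSetContrast(recs, nPermutations = 200, seed = 2)
  ch <- unlist(strsplit(recs$residues, ""))
  gOf <- stats::setNames(rep(names(ageGroups()), lengths(ageGroups())),
                         unlist(ageGroups()))
  pg <- prop.table(table(gOf[ch]))
  closed <- as.vector(outer(pg, pg))  # product of marginal group frequencies
  names(closed) <- as.vector(outer(names(pg), names(pg), paste, sep = "-"))
  expect_equal(res$expectedProp[names(closed)], closed, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(res$df, 8)
  expect_true(res$chisq >= 0 && res$p >= 0 && res$p <= 1)
})

test_that("dipeptide networks weight edges by joining dipeptide types", {
  g <- dipeptideNetwork(c("AL", "LA", "AG"))
  expect_setequal(igraph::V(g)$name, c("A", "G", "L"))
  eid <- igraph::get_edge_ids(g, c("A", "L"))
  expect_equal(igraph::E(g)$weight[eid], 2)
  expect_equal(igraph::E(g)$weight[igraph::get_edge_ids(g, c("A", "G"))], 1)
  # self-pair becomes a self-loop
  g2 <- dipeptideNetwork("LL")
  expect_equal(igraph::ecount(g2), 1)
  expect_true(igraph::which_loop(g2))
  expect_error(dipeptideNetwork(character(0)), "nonempty")
})
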