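OMEGA <- "\u03a9"

test_that("region classification is total and length-preserving", {
  expect_equal(classifyRegions("HGIEBTS "),
               paste0("HHHEETT", OMEGA))
  expect_equal(classifyRegions("hgi"), "HHH")  # case-insensitive
  expect_equal(classifyRegions("    "), strrep(OMEGA, 4))
  withr::with_seed(3, {
    s <- paste(sample(c("H", "G", "I", "E", "B", "T", "S", " "), 100, TRUE),
               collapse = "")
  })
  expect_equal(nchar(classifyRegions(s)), 100)
  expect_error(classifyRegions("HXH"), "position 2")
})

test_that("DSSP files and simplified annotations both parse", {
  # classic layout: chain at column 12, summary letter at column 17
  ss <- c("H", "H", "T", " ", "E")
  resLines <- sprintf("%5d%5d %1s %1s  %1s", 1:5, 1:5, "A", "G", ss)
  lines <- c("==== Secondary Structure Definition ====", "HEADER line",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC", resLines)
  p <- tempfile()
  writeLines(lines, p)
  parsed <- parseDssp(p)
  expect_identical(unname(parsed["A"]), "HHT E")
  # simplified two-column round trip
  p2 <- tempfile()
  writeLines(c("id\tstructure", "s1\tHHT E", "s2\tEEE"), p2)
  parsed2 <- parseDssp(p2)
  expect_identical(unname(parsed2), c("HHT E", "EEE"))
  expect_identical(names(parsed2), c("s1", "s2"))
  p3 <- tempfile(); writeLines("just some text", p3)
  expect_error(parseDssp(p3), "malformed")
})

test_that("exact Mann-Whitney p matches enumeration over label assignments", {
  # {1,2,3} vs {4,5,6}: U = 0, one-sided p = 1/20
  expect_equal(codechron:::.mannWhitney(1:3, 4:6, "less"), 0.05)
  # enumeration oracle for combined n <= 12
  enumP <- function(x, y) {
    pooled <- c(x, y)
    U <- function(a, b) sum(outer(a, b, ">"))   # pairs with x above y
    obs <- U(x, y)
    picks <- utils::combn(length(pooled), length(x))
    stat <- apply(picks, 2, function(ix) U(pooled[ix], pooled[-ix]))
    mean(stat <= obs)   # one-sided: x tends to be smaller
  }
  withr::with_seed(9, {
    for (rep in 1:4) {
      vals <- sample(1:100, 11)   # distinct values: exact case, no ties
      x <- vals[1:5]; y <- vals[6:11]
      expect_equal(codechron:::.mannWhitney(x, y, "less"), enumP(x, y))
    }
  })
})

test_that("region bias flags planted loop avoidance", {
  rec <- loopAvoidanceRecords()
  res <- regionBiasTest("AL", rec)
  omegaRow <- res[res$class == paste(OMEGA, OMEGA, sep = "-"), ]
  expect_lt(omegaRow$p, 0.05)
  expect_identical(omegaRow$direction, "-")
  hhRow <- res[res$class == "H-H", ]
  expect_identical(hhRow$direction, "+")
  # enriched set = all dipeptides: identical samples, no direction
  allDip <- unique(unlist(lapply(rec$residues, function(s) {
    ch <- strsplit(s, "")[[1]]
    paste0(ch[-length(ch)], ch[-1])
  })))
  res2 <- suppressMessages(regionBiasTest(allDip, rec))
  done <- !is.na(res2$p)
  expect_true(all(res2$p[done] > 0.95))
  expect_true(all(res2$direction[done] == ""))
})

test_that("turn-boundary ratio counts boundary vs other loop dipeptides", {
  # structure: T O O O O O O with enriched pairs placed by hand
  rec <- list(residues = "ALALALAL",
              structure = "T       ")
  # pairs: positions 1..7; classes: T-O, O-O x6; all pairs enriched
  out <- tOmegaRatio(rec, c("AL", "LA"))
  expect_equal(out$nBoundary, 1)
  expect_equal(out$nOtherLoop, 6)
  expect_equal(out$r, 1 / 6)
  out2 <- tOmegaRatio(list(residues = "ALALALALA",
                           structure = "T   T    "), c("AL", "LA"))
  expect_equal(out2$nBoundary + out2$nOtherLoop, 8)
  # no loop dipeptides at all: undefined and flagged
  out3 <- tOmegaRatio(list(residues = "ALAL", structure = "HHHH"),
                      c("AL", "LA"))
  expect_false(out3$defined)
  expect_true(is.nan(out3$r))
  # r invariant to non-loop content changes
  a <- tOmegaRatio(list(residues = "ALALHH", structure = "T   HH"), "AL")
  b <- tOmegaRatio(list(residues = "ALALEE", structure = "T   EE"), "AL")
  expect_equal(a$r, b$r)
  expect_error(tOmegaRatio(list(residues = "AL", structure = NA), "AL"),
               "no structure")
})

test_that("exchange-group ANOVA matches textbook sums of squares", {
  groups <- exchangeGroups()
  withr::with_seed(21, {
    recs <- do.call(rbind, lapply(1:8, function(i) {
      res <- paste(sample(aminoAcids(), 60, TRUE), collapse = "")
      data.frame(residues = res, structure = strrep("H", 60),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- exchangeGroupAnalysis(recs, groups)
  expect_true("H" %in% names(out))
  # independent recomputation of the per-sequence frequencies and F
  freq <- t(vapply(recs$residues, function(s) {
    ch <- strsplit(s, "")[[1]]
    gr <- vapply(names(groups), function(g) mean(ch %in% groups[[g]]), 0)
    gr / sum(gr)
  }, numeric(3)))
  v <- as.vector(freq)
  f <- factor(rep(colnames(freq), each = nrow(freq)))
  gm <- mean(v)
  ssb <- sum(tapply(v, f, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(v, f, function(z) sum((z - mean(z))^2)))
  Fhand <- (ssb / 2) / (ssw / (length(v) - 3))
  expect_equal(out$H$F, Fhand)
  expect_equal(out$H$n, 8)
})

test_that("separated exchange groups earn distinct letters, identical ones share", {
  groups <- exchangeGroups()
  # widely separated: sequences dominated by one group per letter class
  recs <- do.call(rbind, lapply(1:6, function(i) {
    res <- paste0(strrep("L", 30 + i), strrep("S", 10), strrep("Y", 5))
    data.frame(residues = res, structure = strrep("H", 45 + i),
               stringsAsFactors = FALSE)
  }))
  out <- exchangeGroupAnalysis(recs, groups)
  expect_gt(out$H$F, 100)
  expect_true(length(unique(out$H$letters)) == 3)
  # identical frequencies: F = 0 and one shared letter
  base <- paste(rep(vapply(groups, `[`, "", 1), 10), collapse = "")
  recs2 <- data.frame(residues = rep(base, 4),
                      structure = rep(strrep("T", nchar(base)), 4),
                      stringsAsFactors = FALSE)
  out2 <- exchangeGroupAnalysis(recs2, groups)
  expect_equal(out2$T$F, 0)
  expect_true(all(out2$T$letters == "a"))
  # a group absent from the data is a degenerate input
  recs3 <- data.frame(residues = "LLLL", structure = "HHHH",
                      stringsAsFactors = FALSE)
  expect_error(exchangeGroupAnalysis(recs3, groups), "absent")
})
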