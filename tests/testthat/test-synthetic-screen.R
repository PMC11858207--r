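test_that("screen generation is a pure function of its spec", {
  spec <- screenSpec(nDecoys = 50, nActives = 5, seed = 42)
  a <- genScreen(spec)
  b <- genScreen(spec)
  expect_identical(scoreValues(a$scores), scoreValues(b$scores))
  expect_identical(a$kd, b$kd)
  expect_identical(a$active, b$active)
  c_ <- genScreen(screenSpec(nDecoys = 50, nActives = 5, seed = 43))
  expect_false(identical(scoreValues(a$scores), scoreValues(c_$scores)))
  # calling the generator must not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(genScreen(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("screen matrix has the advertised shape and category tags", {
  sc <- genScreen(screenSpec(nDecoys = 30, nActives = 4, seed = 1))
  expect_s4_class(sc$scores, "ScoreMatrix")
  expect_identical(dim(scoreValues(sc$scores)), c(34L, 6L))
  expect_identical(as.integer(table(structureCategory(sc$scores))[
    c("apoE3", "free-apoE4", "holo-apoE4")]), c(2L, 2L, 2L))
  expect_identical(sum(sc$active), 4L)
})

test_that("invalid screen specs fail naming the offending field", {
  expect_error(screenSpec(nDecoys = -1), "nDecoys")
  expect_error(screenSpec(holoCoupling = 1.2), "holoCoupling")
  expect_error(screenSpec(freeCoupling = -2), "freeCoupling")
  expect_error(screenSpec(kdRangeUm = c(10, 1)), "kdRangeUm")
  expect_error(screenSpec(nDecoys = 1, nActives = 0), "at least 2")
})

test_that("zero coupling leaves columns uncorrelated with activity", {
  sc <- genScreen(screenSpec(nDecoys = 180, nActives = 20,
                             holoCoupling = 0, freeCoupling = 0,
                             seed = 11))
  z <- sc$activity
  m <- scoreValues(sc$scores)
  # permutation oracle: 95% null bound of |spearman| on this sample size
  set.seed(99)
  nullAbs <- replicate(500, abs(cor(z, sample(m[, 1]), method = "spearman")))
  bound <- quantile(nullAbs, 0.995)
  for (j in seq_len(ncol(m))) {
    expect_lt(abs(cor(z, m[, j], method = "spearman")), bound)
  }
})

test_that("Kd values below the detection floor are censored as bounds", {
  sc <- genScreen(screenSpec(nDecoys = 100, nActives = 40,
                             kdRangeUm = c(0.5, 1000),
                             detectionFloorUm = 5, seed = 2))
  censored <- sc$kd$censor == "below"
  expect_gt(sum(censored), 0)
  expect_true(all(sc$kd$kd_text[censored] == "<5"))
  expect_true(all(sc$kd$kd_um[censored] == 5))
  expect_true(all(sc$kd$censor %in% c("none", "below")))
})

test_that("coupled screens give actives better consensus ranks than decoys", {
  sc <- genScreen(screenSpec(nDecoys = 990, nActives = 10,
                             holoCoupling = 0.9, freeCoupling = -0.9,
                             seed = 7))
  ct <- buildConsensusTable(sc$scores)
  act <- ct$consensus_rank[sc$active[ct$ligand_id]]
  dec <- ct$consensus_rank[!sc$active[ct$ligand_id]]
  expect_lt(median(act), median(dec))
  expect_lt(wilcox.test(act, dec, alternative = "less")$p.value, 0.01)
})
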