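test_that("score ranking follows the docking convention with average ties", {
  expect_equal(rankScores(c(-9.1, -8.5, -9.1)), c(1.5, 3, 1.5))
  expect_equal(rankScores(c(0.9, 0.2, 0.5), "higher_better"), c(1, 3, 2))
  set.seed(17)
  for (rep_ in 1:20) {
    v <- rnorm(sample(2:40, 1))
    r <- rankScores(v)
    n <- length(v)
    expect_equal(sum(r), n * (n + 1) / 2)  # rank conservation, ties included
    expect_setequal(rankScores(sample(v)), r)
  }
  expect_error(rankScores(c(1, NA)), "non-finite")
  expect_error(rankScores(numeric()), "at least one")
})

test_that("the consensus score is the holo/free rank ratio", {
  expect_equal(consensusScore(c(61, 25), c(519, 505)), 43 / 512)
  expect_equal(consensusScore(c(7, 7), c(7, 7)), 1)
  # scale invariance and strict monotonicity
  set.seed(5)
  for (rep_ in 1:10) {
    h <- runif(2, 1, 1000); f <- runif(2, 1, 1000); c_ <- runif(1, 0.1, 9)
    expect_equal(consensusScore(c_ * h, c_ * f), consensusScore(h, f))
    expect_gt(consensusScore(h + c(1, 0), f), consensusScore(h, f))
    expect_lt(consensusScore(h, f + c(0, 1)), consensusScore(h, f))
  }
  expect_error(consensusScore(c(0, 1), c(1, 2)), "positive")
})

test_that("the published rank matrix reproduces the printed consensus order", {
  ct <- buildConsensusTable(knownLigandRanks())
  expect_identical(ct$ligand_id[order(ct$consensus_score)],
                   expectedConsensusOrder)
  expect_identical(order(ct$consensus_score), order(ct$consensus_rank))
  expect_equal(ct$avg_holo_rank[ct$ligand_id == "155557185"], 43)
  expect_equal(ct$avg_free_rank[ct$ligand_id == "155557185"], 512)
})

test_that("degenerate and malformed consensus inputs are handled", {
  m <- matrix(c(2, 3, 4, 5, 6, 7), 1,
              dimnames = list("solo", names(apoescreen:::SYNTH_CATEGORIES)))
  sm <- ScoreMatrix(m, apoescreen:::SYNTH_CATEGORIES, valueKind = "rank")
  expect_equal(buildConsensusTable(sm)$consensus_rank, 1)
  m2 <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  sm2 <- ScoreMatrix(m2, c(S1 = "apoE3", S2 = "free-apoE4"),
                     valueKind = "rank")
  expect_error(buildConsensusTable(sm2), "holo-apoE4")
})

test_that("correlation diagnostics agree with textbook formulas", {
  sm <- knownLigandRanks()
  kd <- knownLigandKd()
  v <- kd$kd_um[match(ligandIds(sm), kd$ligand_id)]  # bounds at face value
  ranks <- scoreValues(sm)

  pearsonOracle <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  spearmanOracle <- function(x, y) pearsonOracle(rank(x), rank(y))
  kendallOracle <- function(x, y) {
    n <- length(x); num <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
      num <- num + a * b
      tx <- tx + (a != 0); ty <- ty + (b != 0)
    }
    num / sqrt(tx * ty)  # tau-b
  }
  for (method in c("pearson", "spearman", "kendall")) {
    d <- correlationDiagnostics(sm, kd, method = method)
    oracle <- switch(method, pearson = pearsonOracle,
                     spearman = spearmanOracle, kendall = kendallOracle)
    for (j in colnames(ranks)) {
      expect_equal(unname(d$per_structure[j]),
                   unname(oracle(ranks[, j], v)),
                   tolerance = 1e-12, label = paste(method, j))
    }
    expect_identical(d$method, method)
    expect_identical(d$n_used, 8L)
  }
})

test_that("perfect concordance and reversal hit the correlation bounds", {
  m <- matrix(c(1:5, 5:1, 1:5, 1:5, 1:5, 1:5), 5,
              dimnames = list(letters[1:5],
                              names(apoescreen:::SYNTH_CATEGORIES)))
  sm <- ScoreMatrix(m, apoescreen:::SYNTH_CATEGORIES, valueKind = "rank")
  kd <- data.frame(ligand_id = letters[1:5], kd_um = c(1, 5, 20, 80, 400),
                   censor = "none", stringsAsFactors = FALSE)
  d <- correlationDiagnostics(sm, kd, method = "spearman")
  expect_equal(unname(d$per_structure["APOE3-1"]), 1)
  expect_equal(unname(d$per_structure["APOE3-2"]), -1)
})

test_that("censored-Kd policies change which ligands enter the diagnostics", {
  sm <- knownLigandRanks()
  kd <- knownLigandKd()
  expect_identical(correlationDiagnostics(sm, kd, kdPolicy = "drop")$n_used,
                   6L)
  expect_identical(
    correlationDiagnostics(sm, kd, kdPolicy = "substitute")$n_used, 8L)
  expect_identical(
    correlationDiagnostics(sm, kd, kdPolicy = "midpoint")$n_used, 8L)
  expect_error(correlationDiagnostics(sm, kd[1:2, ], kdPolicy = "drop"),
               "at least 3")
})

test_that("enrichment reports counts, factors and the all-actives fraction", {
  entries <- data.frame(ligand_id = sprintf("L%04d", 1:1258),
                        consensus_rank = 1:1258,
                        stringsAsFactors = FALSE)
  actives <- entries$ligand_id[c(6, 9, 11, 14, 21)]
  e <- enrichment(entries, actives, topFraction = 0.02)
  expect_equal(e$min_fraction_containing_all_actives, 21 / 1258)
  expect_identical(e$n_actives_in_top, 5L)
  expect_equal(e$enrichment_factor, 1 / 0.02)
  expect_error(enrichment(entries, actives, topFraction = 0), "topFraction")
  expect_error(enrichment(entries, "NOPE", 0.1), "NOPE")
})

test_that("enrichment factor is centred on 1 under random ranking", {
  n <- 400; nActives <- 20; topFraction <- 0.1
  ids <- sprintf("L%03d", 1:n)
  actives <- ids[1:nActives]
  set.seed(123)
  efs <- replicate(1000, {
    entries <- data.frame(ligand_id = ids, consensus_rank = sample(n),
                          stringsAsFactors = FALSE)
    enrichment(entries, actives, topFraction)$enrichment_factor
  })
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se)
})

test_that("shape-query combination keeps the strongest query match", {
  t1 <- data.frame(ligand_id = c("a", "b"), score = c(0.9, 0.5))
  t2 <- data.frame(ligand_id = c("a", "b"), score = c(0.1, 0.5))
  hl <- combineShapeQueries(list(q1 = t1, q2 = t2))
  expect_identical(hl$ligand_id, c("a", "b"))
  expect_equal(hl$combined_score, c(0.9, 0.5))
  # single query: order preserved
  single <- combineShapeQueries(list(q = t1))
  expect_identical(single$ligand_id, c("a", "b"))
  # invariance under query order permutation
  set.seed(12)
  tabs <- lapply(1:3, function(i) {
    data.frame(ligand_id = sprintf("m%02d", 1:30),
               score = round(runif(30, 0, 2), 3))
  })
  names(tabs) <- paste0("q", 1:3)
  a <- combineShapeQueries(tabs)
  b <- combineShapeQueries(rev(tabs))
  expect_identical(a$ligand_id, b$ligand_id)
  expect_equal(a$combined_score, b$combined_score)
  # disjoint ligand sets
  t3 <- data.frame(ligand_id = c("x", "y"), score = c(1, 2))
  expect_error(combineShapeQueries(list(t1, t3)), "union")
  u <- combineShapeQueries(list(q1 = t1, q3 = t3), mode = "union")
  expect_setequal(u$ligand_id, c("a", "b", "x", "y"))
})

test_that("hit-list intersection recovers the single common screening hit", {
  hl <- screeningHitLists()
  common <- intersectHitLists(hl$docking, hl$shape, n = 25)
  expect_identical(common$ligand_id, "193679")
  expect_identical(common$pos_a, 4L)
  expect_identical(common$pos_b, 7L)
  self <- intersectHitLists(hl$docking, hl$docking, 25)
  expect_identical(self$ligand_id,
                   hl$docking$ligand_id[order(hl$docking$rank)])
  expect_identical(nrow(intersectHitLists(c("a", "b"), c("c", "d"), 2)), 0L)
  expect_error(intersectHitLists(c("a"), c("b", "c"), 2), "exceeds")
})

test_that("Kd triage keeps ligands bound below threshold on all proteins", {
  fb <- flavonoidBindingTable()
  others <- fb[fb$name != "Isobavachin", ]
  binders <- kdTriage(others, 100, proteins = c("ApoE3", "ApoE4"))
  expect_setequal(binders, c("14236566", "513197"))  # Bavachin, Isoxanthohumol
  # the top hit itself also passes when included
  all_ <- kdTriage(fb, 100, proteins = c("ApoE3", "ApoE4"))
  expect_true("193679" %in% all_)
  expect_identical(kdTriage(fb[0, ], 100), character())
  nb <- data.frame(ligand_id = "x", protein = "ApoE4", kd_um = NA_real_,
                   censor = "no_binding", stringsAsFactors = FALSE)
  expect_identical(kdTriage(nb, 1e6), character())
})
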