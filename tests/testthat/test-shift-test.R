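test_that("the permutation statistic hits its documented extremes", {
  # fully separated samples: every difference has one sign
  r <- shiftStatistic(rnorm(200), rnorm(200) + 100, seed = 1)
  expect_equal(r$stat, 0)
  expect_equal(r$p_value, 0)
  # elementwise-identical vectors: degenerate no-evidence case
  r2 <- shiftStatistic(rep(2, 50), rep(2, 50), seed = 1)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$p_value, min(1, 2 * r2$stat))
  # identical distributions: p near 1
  set.seed(4)
  x <- rnorm(1000)
  r3 <- shiftStatistic(x, sample(x), seed = 2)
  expect_gt(r3$p_value, 0.8)
  expect_error(shiftStatistic(1:5, 1:4), "equal length")
  expect_error(shiftStatistic(1:5, 1:5, nRepeats = 0), "nRepeats")
})

test_that("p-values lie on the discrete grid the statistic implies", {
  set.seed(9)
  for (i in 1:5) {
    n <- 50
    r <- shiftStatistic(rnorm(n), rnorm(n, 1), nRepeats = 20)
    onGrid <- abs(r$p_value * n * 20 / 2 -
                  round(r$p_value * n * 20 / 2)) < 1e-9
    expect_true(onGrid || r$p_value == 1)
    expect_gte(r$stat, 0); expect_lte(r$stat, 0.5)
  }
})

test_that("BH adjustment equals the closed-form step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(1.0), 1.0)
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bhAdjust(p)
    expect_equal(q, bhOracle(p))
    expect_true(all(q >= p - 1e-12))
    # permutation invariance
    o <- sample(length(p))
    expect_equal(bhAdjust(p[o]), q[o])
  }
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("type-I error is controlled and power grows with the shift", {
  # null: identical sampling distributions in both conditions
  p0 <- simulateShiftP(100, 400, 0, seed = 21)
  expect_lte(mean(p0 < 0.05), 0.07)
  expect_lte(mean(p0 < 0.01), 0.03)
  # detection rate is non-decreasing in the shift size; large shifts are
  # always caught (the minority-sign statistic needs ~2.8 sd to separate)
  rates <- vapply(c(0, 1, 2, 3, 4), function(d)
    mean(simulateShiftP(40, 400, d, seed = 30 + d) < 0.05), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[[5]], 1)
})

test_that("planted shifts beyond the separation threshold are recovered exactly", {
  pl <- makePlantedSamples(nNull = 50, nShifted = 10, nSamples = 500,
                           shiftSdUnits = 4, seed = 3)
  res <- testFluxShifts(pl$low, pl$high, seed = 4)
  hits <- res$reaction_id[res$significant]
  expect_setequal(intersect(hits, pl$shifted), pl$shifted)
  expect_lte(length(setdiff(hits, pl$shifted)), 1)
  expect_true(all(res$direction[res$reaction_id %in% pl$shifted] == "up"))
})

test_that("testFluxShifts is deterministic, honours alpha, and skips unshared reactions", {
  pl <- makePlantedSamples(nNull = 10, nShifted = 5, nSamples = 200,
                           shiftSdUnits = 4, seed = 6)
  a <- testFluxShifts(pl$low, pl$high, seed = 11)
  b <- testFluxShifts(pl$low, pl$high, seed = 11)
  expect_identical(a, b)
  # identical sample sets: no reaction can be significant
  same <- testFluxShifts(pl$low, pl$low, seed = 11)
  expect_equal(sum(same$significant), 0L)
  expect_true(all(same$p_value == 1))
  # alpha = 0 switches everything off
  none <- testFluxShifts(pl$low, pl$high, alpha = 0, seed = 11)
  expect_equal(sum(none$significant), 0L)
  # a reaction missing from one side is skipped and reported
  trimmed <- new("FluxSampleSet",
                 samples = samples(pl$high)[, -1, drop = FALSE],
                 meta = sampleMeta(pl$high))
  res <- testFluxShifts(pl$low, trimmed, seed = 11)
  expect_identical(attr(res, "skipped"), colnames(samples(pl$low))[1])
  # disjoint reaction sets cannot be compared
  other <- samples(pl$high)
  colnames(other) <- paste0("x_", seq_len(ncol(other)))
  expect_error(testFluxShifts(pl$low,
                              new("FluxSampleSet", samples = other,
                                  meta = list()), seed = 1),
               "share no reactions")
})

test_that("group summaries count shifted reactions against whole groups", {
  # seven pigment reactions, three shifted up; one extra unannotated group
  mets <- data.frame(id = paste0("m", 1:8, "_c"), name = paste0("m", 1:8),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- c(lapply(1:7, function(i)
    list(id = paste0("P", i), stoichiometry = setNames(-1, paste0("m", i, "_c")),
         lower_bound = 0, upper_bound = 1, gpr = paste0("g", i),
         subsystem = "pigment biosynthesis")),
    list(list(id = "T1", stoichiometry = c(m8_c = -1), lower_bound = 0,
              upper_bound = 1, gpr = "", subsystem = "transport")))
  model <- cnflux:::buildModel(mets, rxns, "P1")
  cmap <- buildCategoryMap(unique(subsystems(model)))
  results <- data.frame(
    reaction_id = c(paste0("P", 1:7), "T1"),
    stat = 0, p_value = 0.01, q_value = c(rep(0.01, 3), rep(0.5, 4), 0.01),
    direction = "up",
    significant = c(rep(TRUE, 3), rep(FALSE, 4), TRUE),
    stringsAsFactors = FALSE)
  gs <- summarizeGroups(results, model, cmap)
  pig <- gs[gs$group == "pigments", ]
  expect_equal(pig$n_reactions_in_group, 7L)
  expect_equal(pig$n_up, 3L)
  expect_equal(pig$pct_up, 100 * 3 / 7, tolerance = 1e-9)
  # T1 is significant but has no GPR: dropped under the gene filter
  expect_equal(gs$n_up[gs$group == "transport"], 0L)
  gsAll <- summarizeGroups(results, model, cmap, geneAssociatedOnly = FALSE)
  expect_equal(gsAll$n_up[gsAll$group == "transport"], 1L)
  # zero significant results: all percentages zero
  results0 <- results; results0$significant <- FALSE
  gs0 <- summarizeGroups(results0, model, cmap)
  expect_true(all(gs0$pct_up == 0 & gs0$pct_down == 0))
})

test_that("sampling and expression hit sets are compared per subsystem", {
  toy <- makeToyModel()
  # disjoint: no shared reactions anywhere
  tab <- compareHitSets("CFIX", "gNASM", toy)
  expect_true(all(tab$n_shared == 0))
  expect_equal(tab$n_sampling_only[tab$subsystem == "carbon fixation"], 1L)
  expect_equal(tab$n_de_only[tab$subsystem == "nitrogen metabolism"], 1L)
  # identical: everything shared
  tab2 <- compareHitSets(c("TAGS", "DM_tag_c"), "gTAG", toy)
  expect_true(all(tab2$n_sampling_only == 0 & tab2$n_de_only == 0))
  expect_equal(sum(tab2$n_shared), 2L)
})
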