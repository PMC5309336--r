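test_that("the toy model is feasible and its breakpoint follows the stoichiometry", {
  toy <- makeToyModel()
  expect_equal(optimizeModel(toyAt(3.0, 0.5))@objectiveValue, 0.5,
               tolerance = 1e-9)
  # the breakpoint ratio is cPerBiomass / nPerBiomass by construction
  toy4 <- makeToyModel(cPerBiomass = 4)
  res <- cnSweep(toy4, scenarioSpec("cn_sweep",
                                    carbonGrid = seq(0.2, 4, by = 0.2),
                                    nitrogenBase = 0.5))
  expect_equal(res@breakpointCNRatio, 4, tolerance = 0.2 / 0.5 + 1e-9)
  # carbon audit: every optimal solution closes the atom balance exactly
  sol <- parsimoniousFBA(toyAt(4.5, 0.5))
  v <- sol@fluxes
  expect_equal(6 * v[["BOF"]] + 5 * v[["DM_dmsp_c"]] + 50 * v[["DM_tag_c"]] +
               7 * v[["DM_chryso_c"]], 4.5, tolerance = 1e-9)
  expect_equal(v[["BOF"]] + v[["DM_no3_c"]], 0.5, tolerance = 1e-9)
})

test_that("closing every carbon sink makes over-breakpoint uptake infeasible", {
  toy <- makeToyModel(includeDemands = "DM_no3_c")
  sol <- optimizeModel(toyAt(4.5, 0.5, open = "DM_no3_c", model = toy))
  expect_identical(sol@status, "infeasible")
  # below the breakpoint the same model grows fine
  sol2 <- optimizeModel(toyAt(2.4, 0.5, open = "DM_no3_c", model = toy))
  expect_identical(sol2@status, "optimal")
})

test_that("planted sample fixtures have the advertised shape and determinism", {
  pl <- makePlantedSamples(nNull = 50, nShifted = 10, nSamples = 100,
                           shiftSdUnits = 2, seed = 3)
  expect_equal(ncol(samples(pl$low)), 60L)
  expect_equal(ncol(samples(pl$high)), 60L)
  expect_length(pl$shifted, 10L)
  expect_true(all(pl$shifted %in% colnames(samples(pl$high))))
  pl2 <- makePlantedSamples(nNull = 50, nShifted = 10, nSamples = 100,
                            shiftSdUnits = 2, seed = 3)
  expect_identical(samples(pl$low), samples(pl2$low))
  expect_identical(samples(pl$high), samples(pl2$high))
  # zero planted shift: both conditions share a distribution, detection ~ alpha
  pl0 <- makePlantedSamples(nNull = 0, nShifted = 40, nSamples = 400,
                            shiftSdUnits = 0, seed = 5)
  res <- testFluxShifts(pl0$low, pl0$high, seed = 6)
  expect_lte(mean(res$p_value < 0.05), 0.07)
  # lognormal base draws positive fluxes
  plog <- makePlantedSamples(nNull = 5, nShifted = 0, nSamples = 50,
                             baseDistribution = "lognormal", seed = 7)
  expect_true(all(samples(plog$low) > 0))
})

test_that("planted clusters realise targets, ground truth and planted enrichment", {
  toy <- makeToyModel()
  tg <- matrix(0, 3, 3); tg[1, 2] <- tg[2, 1] <- 1
  pc <- makePlantedClusters(toy, nClusters = 3, overlapTargets = tg, seed = 2)
  expect_equal(pc$componentSizes, c(2, 1))
  expect_equal(nrow(pc$edges), 1L)
  expect_setequal(pc$edges[1, ], c("cluster_01", "cluster_02"))
  # the augmented model reproduces the planted product sets through GPRs
  sets <- clusterMetaboliteSets(pc$clusters, pc$model, side = "products")
  expect_identical(lapply(sets, sort), lapply(pc$productSets, sort))
  # overlap targets achieved within the documented tolerance
  pcJ <- makePlantedClusters(toy, nClusters = 4,
                             overlapTargets = {
                               m <- matrix(0, 4, 4)
                               m[1, 2] <- m[2, 1] <- 0.95
                               m[3, 4] <- m[4, 3] <- 0.5
                               m
                             }, seed = 9)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_equal(jac(pcJ$productSets[[1]], pcJ$productSets[[2]]), 0.95,
               tolerance = 0.02)
  expect_equal(jac(pcJ$productSets[[3]], pcJ$productSets[[4]]), 0.5,
               tolerance = 0.02)
  # planted terms are recoverable by the enrichment machinery
  enr <- enrichClusters(pc$clusters, pc$geneTerms)
  for (cl in names(pc$plantedTerms)) {
    hit <- enr[enr$cluster == cl & enr$term == pc$plantedTerms[[cl]], ]
    expect_true(hit$significant)
    expect_identical(hit$direction, "enriched")
  }
  # determinism
  pc2 <- makePlantedClusters(toy, nClusters = 3, overlapTargets = tg, seed = 2)
  expect_identical(pc$productSets, pc2$productSets)
  expect_identical(pc$geneTerms, pc2$geneTerms)
  # an impossible overlap demand errors with the limit stated
  tooMuch <- matrix(0.98, 3, 3); diag(tooMuch) <- 0
  expect_error(makePlantedClusters(toy, nClusters = 3,
                                   overlapTargets = tooMuch, seed = 1),
               "unachievable")
})
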