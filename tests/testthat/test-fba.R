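test_that("the simplex core handles degenerate, infeasible and unbounded LPs", {
  # max x1 + x2 s.t. x1 - x2 = 0 in [0,1]^2 -> (1,1)
  r <- simplexSolver(c(1, 1), matrix(c(1, -1), 1), 0, c(0, 0), c(1, 1),
                     maximize = TRUE)
  expect_equal(r$objective, 2)
  # degenerate vertex: x1 + x2 = 1, x1 - x2 = 1 -> (1, 0)
  r2 <- simplexSolver(c(0, 1), matrix(c(1, 1, 1, -1), 2, byrow = TRUE),
                      c(1, 1), c(0, 0), c(10, 10))
  expect_equal(r2$x, c(1, 0))
  # infeasible: x1 = 2 outside [0, 1]
  r3 <- simplexSolver(1, matrix(1, 1, 1), 2, 0, 1)
  expect_identical(r3$status, "infeasible")
  # unbounded: max x1 with x1 = x2, both unbounded above
  r4 <- simplexSolver(c(1, 0), matrix(c(1, -1), 1), 0, c(0, 0), c(Inf, Inf),
                      maximize = TRUE)
  expect_identical(r4$status, "unbounded")
})

test_that("toy FBA matches the closed-form min(C/6, N) growth law", {
  toy <- makeToyModel()
  for (uc in seq(0.6, 6, length.out = 5)) {
    for (un in seq(0.1, 1, length.out = 5)) {
      sol <- optimizeModel(toyAt(uc, un, model = toy))
      expect_identical(sol@status, "optimal")
      expect_equal(sol@objectiveValue, toyGrowthOracle(uc, un),
                   tolerance = 1e-9)
    }
  }
  # hand LP anchors: carbon-limited and nitrogen-limited regimes
  expect_equal(optimizeModel(toyAt(1.2, 0.5))@objectiveValue, 0.2)
  expect_equal(optimizeModel(toyAt(4.5, 0.5))@objectiveValue, 0.5)
})

test_that("optimal solutions are mass-balanced and honest about status", {
  toy <- makeToyModel()
  sol <- optimizeModel(toyAt(2.4, 0.5))
  S <- as.matrix(stoichiometry(toy))
  expect_lt(max(abs(S %*% sol@fluxes)), 1e-6)
  # all exchanges blocked: nothing can grow
  blocked <- applyConstraints(toy, constraintSet(character(), numeric(),
                                                 numeric()),
                              blockOthers = TRUE)
  expect_equal(optimizeModel(blocked)@objectiveValue, 0)
  # carbon forced in with every sink closed: infeasible, reported not thrown
  m <- toyAt(4.5, 0.5, open = character())
  sol2 <- optimizeModel(m)
  expect_identical(sol2@status, "infeasible")
  expect_identical(parsimoniousFBA(m)@status, "infeasible")
})

test_that("parsimonious FBA keeps the optimum and picks the frugal sink", {
  toy <- makeToyModel()
  # scenario-3 style: DMSP closed, storage routes open, excess carbon 1.5
  m <- toyAt(4.5, 0.5, open = c("DM_no3_c", "DM_tag_c", "DM_chryso_c"))
  fba <- optimizeModel(m)
  p <- parsimoniousFBA(m)
  expect_equal(p@objectiveValue, fba@objectiveValue, tolerance = 1e-9)
  expect_equal(unname(p@fluxes[["DM_tag_c"]]), 1.5 / 50, tolerance = 1e-9)
  expect_equal(unname(p@fluxes[["DM_chryso_c"]]), 0, tolerance = 1e-9)
  # exactly at the breakpoint no demand carries flux
  p2 <- parsimoniousFBA(toyAt(3.0, 0.5,
                              open = c("DM_dmsp_c", "DM_no3_c", "DM_tag_c",
                                       "DM_chryso_c")))
  expect_equal(unname(p2@fluxes[c("DM_dmsp_c", "DM_no3_c", "DM_tag_c",
                                  "DM_chryso_c")]),
               rep(0, 4), tolerance = 1e-9)
})

test_that("FVA brackets fluxes correctly with the objective free or fixed", {
  m <- toyAt(4.5, 0.5)
  # objective free: at most all carbon leaves via DMSP (4.5/5); at least the
  # excess over what nitrogen-capped biomass can fix ((4.5 - 3)/5)
  fv <- fluxVariability(m, "DM_dmsp_c", fixObjectiveFraction = 0)
  expect_equal(fv$v_min, 0.3, tolerance = 1e-9)
  expect_equal(fv$v_max, 0.9, tolerance = 1e-9)
  # objective fixed at optimum: DMSP is pinned to exactly the excess carbon
  fv1 <- fluxVariability(m, "DM_dmsp_c", fixObjectiveFraction = 1)
  expect_equal(fv1$v_min, 0.3, tolerance = 1e-9)
  expect_equal(fv1$v_max, 0.3, tolerance = 1e-9)
  # biomass itself pinned at its optimum
  fvB <- fluxVariability(m, "BOF", fixObjectiveFraction = 1)
  expect_equal(fvB$v_min, 0.5, tolerance = 1e-9)
  expect_equal(fvB$v_max, 0.5, tolerance = 1e-9)
  # a demand whose precursor route is closed cannot carry flux
  m2 <- applyConstraints(m, constraintSet("CHRYS", 0, 0))
  fv0 <- fluxVariability(m2, "DM_chryso_c")
  expect_equal(c(fv0$v_min, fv0$v_max), c(0, 0))
  expect_error(fluxVariability(m, "nope"), "unknown")
})

test_that("pruning removes blocked branches, keeps the optimum, and is idempotent", {
  # closing the TAG demand strands TAGS and the tag_c metabolite
  m <- toyAt(3.0, 0.5, open = c("DM_dmsp_c", "DM_no3_c", "DM_chryso_c"))
  before <- optimizeModel(m)@objectiveValue
  pr <- pruneBlocked(m)
  expect_setequal(pr$removedReactions, c("TAGS", "DM_tag_c"))
  expect_identical(pr$removedMetabolites, "tag_c")
  expect_equal(optimizeModel(pr$model)@objectiveValue, before,
               tolerance = 1e-9)
  pr2 <- pruneBlocked(pr$model)
  expect_length(pr2$removedReactions, 0)
  expect_length(pr2$removedMetabolites, 0)
})
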