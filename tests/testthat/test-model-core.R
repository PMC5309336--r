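test_that("toy model has the documented shape and a valid S matrix", {
  toy <- makeToyModel()
  expect_equal(nReactions(toy), 14L)
  expect_equal(nMetabolites(toy), 10L)
  S <- stoichiometry(toy)
  expect_equal(dim(S), c(10L, 14L))
  expect_identical(rownames(S), metaboliteIds(toy))
  expect_identical(colnames(S), reactionIds(toy))
  # exchange columns carry exactly one nonzero
  for (ex in exchangeReactions(toy))
    expect_equal(sum(S[, ex] != 0), 1)
  expect_identical(objectiveId(toy), "BOF")
})

test_that("GPR tokenisation extracts mentioned genes regardless of structure", {
  expect_setequal(gprGenes("gA and (gB or gC)"), c("gA", "gB", "gC"))
  expect_setequal(gprGenes("(g1 or g2) and (g1 or g3)"), c("g1", "g2", "g3"))
  expect_identical(gprGenes(""), character(0))
  expect_identical(gprGenes(NA_character_), character(0))
})

test_that("constraints are applied, validated and idempotent", {
  toy <- makeToyModel()
  cs <- constraintSet(c("EX_hco3_e", "EX_no3_e", "DM_tag_c"),
                      c(-1.57, -0.535, 0), c(-1.57, -0.535, 0))
  m <- applyConstraints(toy, cs)
  b <- reactionBounds(m)
  expect_equal(b$lower_bound[b$id == "EX_hco3_e"], -1.57)
  expect_equal(b$upper_bound[b$id == "EX_hco3_e"], -1.57)
  expect_equal(b$lower_bound[b$id == "EX_no3_e"], -0.535)
  # idempotence
  expect_identical(applyConstraints(m, cs)@reactions, m@reactions)
  # empty set is the identity
  empty <- constraintSet(character(), numeric(), numeric())
  expect_identical(applyConstraints(toy, empty)@reactions, toy@reactions)
  # blockOthers closes exchanges not named in the set
  m2 <- applyConstraints(toy, constraintSet("EX_hco3_e", -3.14, -3.14),
                         blockOthers = TRUE)
  b2 <- reactionBounds(m2)
  expect_equal(b2$lower_bound[b2$id == "EX_no3_e"], 0)
  expect_equal(b2$upper_bound[b2$id == "EX_no3_e"], 0)
  expect_equal(b2$lower_bound[b2$id == "EX_hco3_e"], -3.14)
  # internal reactions untouched by blockOthers
  expect_equal(b2$upper_bound[b2$id == "CFIX"], 1000)
  # errors
  expect_error(applyConstraints(toy, constraintSet("nope", 0, 1)), "nope")
  csBad <- constraintSet("EX_hco3_e", 0, 1)
  csBad$lb <- 2
  expect_error(applyConstraints(toy, csBad), "lower bound")
  expect_error(constraintSet("x", 1, 0), "lower bound")
})

test_that("reaction sides follow the sign convention, reversibility and currency filter", {
  toy <- makeToyModel()
  # irreversible fixation: substrates negative, products positive
  side <- reactionSides(toy, "CFIX")
  expect_setequal(side$substrates, c("h_c", "hco3_c"))
  expect_identical(side$products, "cfix_c")
  # the proton is currency, bicarbonate is not
  side2 <- reactionSides(toy, "CFIX", dropCurrency = TRUE)
  expect_identical(side2$substrates, "hco3_c")
  # reversible exchange contributes its metabolite to both sides
  side3 <- reactionSides(toy, "EX_hco3_e")
  expect_identical(side3$substrates, side3$products)
  expect_identical(side3$substrates, "hco3_e")
  expect_error(reactionSides(toy, "missing"), "unknown reaction")
})

test_that("gene-to-reaction mapping uses bare GPR mention", {
  toy <- makeToyModel()
  m <- mapGenesToReactions(toy, c("gTAG", "gBOF", "absent"))
  expect_setequal(m$gTAG, c("TAGS", "DM_tag_c"))
  expect_identical(m$gBOF, "BOF")
  expect_identical(m$absent, character(0))
  expect_identical(mapGenesToReactions(toy, character(0)), setNames(list(), character(0)))
  # an "and" GPR associates the reaction with every mentioned gene
  mets <- data.frame(id = "x_c", name = "x", compartment = "c",
                     stringsAsFactors = FALSE)
  rxn <- list(list(id = "R1", stoichiometry = c(x_c = -1), lower_bound = 0,
                   upper_bound = 1, gpr = "gA and gB", subsystem = "s"))
  mini <- cnflux:::buildModel(mets, rxn, "R1")
  mm <- mapGenesToReactions(mini, c("gA", "gB"))
  expect_identical(mm$gA, "R1")
  expect_identical(mm$gB, "R1")
})

test_that("currency matching is compartment-agnostic on base ids", {
  toy <- makeToyModel()
  cur <- isCurrency(toy)
  expect_true(cur[["h_c"]])
  expect_false(cur[["hco3_c"]])
  expect_false(cur[["hco3_e"]])
})
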