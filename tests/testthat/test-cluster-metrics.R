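test_that("the category map encodes the canonical carbon/nitrogen split", {
  cm <- buildCategoryMap(c("urea cycle", "Calvin-Benson cycle",
                           "tricarboxylic acid cycle", "photosynthesis",
                           "made-up subsystem"))
  expect_identical(cm@macro[["urea cycle"]], "nitrogen")
  expect_identical(cm@macro[["Calvin-Benson cycle"]], "carbon")
  expect_setequal(cm@macro[["tricarboxylic acid cycle"]],
                  c("carbon", "nitrogen"))
  expect_identical(cm@macro[["made-up subsystem"]], character(0))
  expect_identical(unname(cm@display[["made-up subsystem"]]), "unmapped")
  expect_identical(unname(cm@display[["photosynthesis"]]), "energy")
})

test_that("enrichment p-values equal the direct hypergeometric tail sums", {
  # the worked 2x2: 8 of 10 cluster genes carry a term held by 40 of 1214
  universe <- sprintf("g%04d", 1:1214)
  carriers <- universe[1:40]
  clusters <- list(c1 = c(carriers[1:8], universe[100:101]))
  geneTerms <- setNames(rep(list("T"), 40), carriers)
  rec <- enrichClusters(clusters, geneTerms, universe = universe)
  expect_equal(rec$p_value, hyperOverOracle(8, 40, 10, 1214),
               tolerance = 1e-12)
  expect_identical(rec$direction, "enriched")
  # randomised tables: min tail matches the summation oracle exactly
  set.seed(8)
  for (i in 1:50) {
    N <- sample(40:200, 1)
    uni <- sprintf("u%03d", seq_len(N))
    K <- sample(5:30, 1)
    n <- sample(5:30, 1)
    cl <- list(c = sample(uni, n))
    gt <- setNames(rep(list("T"), K), sample(uni, K))
    r <- enrichClusters(cl, gt, universe = uni)
    k <- length(intersect(cl$c, names(gt)))
    expect_equal(r$p_value,
                 min(hyperOverOracle(k, K, n, N), hyperUnderOracle(k, K, n, N)),
                 tolerance = 1e-12)
    expect_equal(r$k, k)
  }
})

test_that("a cluster equal to the universe is never enriched; outsiders error", {
  uni <- sprintf("g%02d", 1:40)
  gt <- setNames(rep(list("T"), 10), uni[1:10])
  recs <- enrichClusters(list(all = uni), gt, universe = uni)
  expect_true(all(!recs$significant))
  expect_error(enrichClusters(list(c = c(uni[1], "stranger")), gt,
                              universe = uni), "stranger")
})

test_that("carbon/nitrogen flags follow significant terms through the macro map", {
  cm <- buildCategoryMap(c("photosynthesis", "tricarboxylic acid cycle",
                           "urea cycle"))
  recs <- data.frame(
    cluster = c("a", "a", "b", "c"),
    term = c("photosynthesis", "urea cycle", "tricarboxylic acid cycle",
             "photosynthesis"),
    q_value = c(0.01, 0.2, 0.01, 0.9),
    stringsAsFactors = FALSE)
  flags <- flagCNClusters(recs, cm)
  expect_identical(flags$a, "carbon")            # urea cycle not significant
  expect_setequal(flags$b, c("carbon", "nitrogen"))
  expect_identical(flags$c, character(0))
  # set identity: |C| + |N| - |both| = |C or N|
  nC <- sum(vapply(flags, function(f) "carbon" %in% f, logical(1)))
  nN <- sum(vapply(flags, function(f) "nitrogen" %in% f, logical(1)))
  nBoth <- sum(vapply(flags, function(f) all(c("carbon", "nitrogen") %in% f),
                      logical(1)))
  nAny <- sum(vapply(flags, length, integer(1)) > 0)
  expect_equal(nC + nN - nBoth, nAny)
})

test_that("cluster metabolite sets respect GPRs, sides and the currency filter", {
  toy <- makeToyModel()
  sets <- clusterMetaboliteSets(list(bof = "gBOF", none = "gUnknown"),
                                toy, side = "substrates")
  # biomass consumes fixed carbon and organic nitrogen; no currency listed
  expect_setequal(sets$bof, c("cfix_c", "orgN_c"))
  expect_identical(sets$none, character(0))
  # the proton consumed by fixation is currency and is dropped by default
  s2 <- clusterMetaboliteSets(list(fix = "gCFIX"), toy, side = "substrates")
  expect_setequal(s2$fix, "hco3_c")
  s2all <- clusterMetaboliteSets(list(fix = "gCFIX"), toy,
                                 side = "substrates", dropCurrency = FALSE)
  expect_setequal(s2all$fix, c("hco3_c", "h_c"))
  # a reversible reaction contributes to both sides
  sEx <- clusterMetaboliteSets(list(e = "gEXC"), toy, side = "products")
  expect_identical(sEx$e, "hco3_e")
})

test_that("connectivity edges reproduce brute-force Jaccard with a strict threshold", {
  # identical sets connect, the 9/10 boundary case does not
  sets <- list(a = letters[1:10], b = letters[1:10], c = letters[1:9],
               d = LETTERS[1:5])
  g <- connectivityGraph(sets, threshold = 0.9)
  ed <- igraph::as_data_frame(g)
  expect_equal(nrow(ed), 1L)
  expect_setequal(unlist(ed[, c("from", "to")]), c("a", "b"))
  expect_equal(ed$weight, 1.0)
  # a-c score is exactly 0.9 and must NOT produce an edge
  expect_equal(length(intersect(sets$a, sets$c)) /
               length(union(sets$a, sets$c)), 0.9)
  # disjoint sets score zero; empty sets stay isolated vertices
  g2 <- connectivityGraph(list(x = "m1", y = "m2", z = character(0)), 0.9)
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 3)
  # randomised fixtures against the brute-force oracle
  for (seed in 1:10) {
    set.seed(seed)
    pool <- sprintf("met%02d", 1:30)
    rsets <- lapply(1:8, function(i) sample(pool, sample(3:20, 1)))
    names(rsets) <- paste0("c", 1:8)
    thr <- runif(1, 0.2, 0.95)
    got <- igraph::as_data_frame(connectivityGraph(rsets, thr))
    want <- jaccardEdgesOracle(rsets, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      gotPairs <- apply(got[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))
      wantPairs <- apply(want, 1, function(r) paste(sort(r), collapse = "|"))
      expect_setequal(gotPairs, wantPairs)
    }
  }
  # permutation invariance in cluster order
  gFwd <- connectivityGraph(sets, 0.5)
  gRev <- connectivityGraph(rev(sets), 0.5)
  pairs <- function(g) {
    e <- igraph::as_data_frame(g)
    sort(unname(apply(e[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))))
  }
  expect_identical(pairs(gFwd), pairs(gRev))
  # the "sum" denominator caps scores at 0.5
  gSum <- connectivityGraph(sets, 0.45, denominator = "sum")
  expect_true(all(igraph::E(gSum)$weight <= 0.5))
})

test_that("graph topology reports components and normalised betweenness", {
  g <- connectivityGraph(list(a = "x", b = "x", c = "y", d = "y"), 0.5)
  topo <- graphTopology(g)
  expect_equal(topo$componentSizes, c(2, 2))
  expect_true(all(topo$betweenness == 0))
  # path a-b-c: the middle node carries the single shortest path
  gp <- connectivityGraph(list(a = c("p", "q"), b = c("q", "r"),
                               c = c("r", "s")), 0.3)
  tp <- graphTopology(gp)
  expect_equal(unname(tp$betweenness[["b"]]), 1)
  expect_equal(tp$componentSizes, 3)
})
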