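# Directed modularity, module detection, betweenness, hub ranking,
# region-set centrality.

test_that("directed modularity matches the double-loop oracle on random
           graphs", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    W <- matrix(rexp(n * n), n, n) * (matrix(runif(n * n), n, n) < 0.6)
    diag(W) <- 0
    if (sum(W) == 0) next
    comm <- sample(1:3, n, replace = TRUE)
    g <- runif(1, 0.5, 2)
    expect_equal(directedModularity(W, comm, g),
                 oracleModularity(W, comm, g), tolerance = 1e-12)
  }
})

test_that("one community at gamma 1 scores exactly zero; reciprocal pairs
           score one half", {
  set.seed(2)
  W <- matrix(runif(49), 7, 7); diag(W) <- 0
  expect_equal(directedModularity(W, rep(1, 7), 1), 0, tolerance = 1e-14)
  Wp <- matrix(0, 4, 4)
  Wp[1, 2] <- Wp[2, 1] <- Wp[3, 4] <- Wp[4, 3] <- 1
  expect_equal(directedModularity(Wp, c(1, 1, 2, 2), 1), 0.5)
})

test_that("modularity is non-increasing in gamma at a fixed partition", {
  set.seed(5)
  W <- matrix(rexp(36), 6, 6); diag(W) <- 0
  comm <- c(1, 1, 2, 2, 3, 3)
  gs <- seq(0.25, 3, by = 0.25)
  qs <- vapply(gs, function(g) directedModularity(W, comm, g), numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("module detection recovers planted blocks and never loses to a
           trivial partition", {
  cfg <- simConfig(seed = 8, withinDensity = 0.5, betweenDensity = 0.05)
  dens <- makeDensity(cfg)
  det <- detectModules(dens$density, gamma = 1, seed = 3)
  expect_equal(ariIndex(det$membership, dens$blocks), 1)
  W <- weightMatrix(dens$density)
  expect_gte(det$Q, directedModularity(W, seq_len(nrow(W)), 1) - 1e-12)
  expect_gte(det$Q, directedModularity(W, rep(1, nrow(W)), 1) - 1e-12)
  # complete uniform digraph: no split improves on one community
  Wu <- matrix(1, 6, 6); diag(Wu) <- 0
  du <- detectModules(Wu, gamma = 1, seed = 1)
  expect_identical(du$n_modules, 1L)
  expect_equal(du$Q, 0, tolerance = 1e-12)
})

test_that("two disconnected blocks partition exactly, with the closed-form
           modularity", {
  # zero between-block density: Q at gamma 1 for the block partition is
  # 1 - sum((block weight / m)^2)
  set.seed(6)
  B1 <- matrix(runif(16, 0.5, 1), 4, 4); diag(B1) <- 0
  B2 <- matrix(runif(16, 0.5, 1), 4, 4); diag(B2) <- 0
  W <- rbind(cbind(B1, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), B2))
  m <- sum(W)
  closed <- 1 - (sum(B1) / m)^2 - (sum(B2) / m)^2
  blocks <- rep(1:2, each = 4)
  expect_equal(directedModularity(W, blocks, 1), closed, tolerance = 1e-12)
  for (s in 1:5) {
    det <- detectModules(W, gamma = 1, seed = s, restarts = 4)
    expect_equal(ariIndex(det$membership, blocks), 1)
  }
})

test_that("detection is deterministic given a seed", {
  cfg <- simConfig(seed = 8)
  W <- weightMatrix(makeDensity(cfg)$density)
  d1 <- detectModules(W, gamma = 1.3, seed = 42)
  d2 <- detectModules(W, gamma = 1.3, seed = 42)
  expect_identical(d1, d2)
})

test_that("betweenness matches the path-enumeration oracle on random
           digraphs", {
  set.seed(17)
  for (rep in 1:25) {
    n <- 6
    W <- matrix(rexp(n * n), n, n) * (matrix(runif(n * n), n, n) < 0.5)
    diag(W) <- 0
    ct <- betweennessCentrality(W)
    expect_equal(ct$betweenness, oracleBetweenness(W), tolerance = 1e-9,
                 info = paste("rep", rep))
  }
})

test_that("path graph and complete graph betweenness follow the contract", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 3] <- 1
  rownames(W) <- colnames(W) <- c("A", "B", "C")
  ct <- betweennessCentrality(W)
  expect_equal(ct$betweenness[ct$acronym == "B"], 1)
  expect_equal(ct$betweenness[ct$acronym != "B"], c(0, 0))
  expect_equal(ct$betweenness_norm[ct$acronym == "B"], 0.5)
  Wc <- matrix(1, 5, 5); diag(Wc) <- 0
  expect_true(all(betweennessCentrality(Wc)$betweenness == 0))
  # fewer than 3 nodes: all zeros by contract
  expect_true(all(betweennessCentrality(matrix(1, 2, 2))$betweenness == 0))
})

test_that("global rescaling of W changes no modularity, partition,
           betweenness or ranking", {
  cfg <- simConfig(seed = 19, bridgeRegion = "PH")
  W <- weightMatrix(makeDensity(cfg)$density)
  part <- rep(1:4, length.out = nrow(W))
  for (c in c(0.001, 7, 1e4)) {
    expect_equal(directedModularity(W, part, 1.2),
                 directedModularity(c * W, part, 1.2),
                 tolerance = 1e-12)
    d1 <- detectModules(W, 1, seed = 2)
    d2 <- detectModules(c * W, 1, seed = 2)
    expect_identical(d1$membership, d2$membership)
    expect_equal(d1$Q, d2$Q, tolerance = 1e-9)
    b1 <- betweennessCentrality(W); b2 <- betweennessCentrality(c * W)
    expect_equal(b1$betweenness, b2$betweenness, tolerance = 1e-9)
    expect_identical(b1$rank, b2$rank)
  }
})

test_that("hub ranking averages brains, breaks ties alphabetically", {
  ct <- data.frame(
    brain_id = rep(c("b1", "b2"), each = 3),
    condition = "ZT0-4",
    acronym = rep(c("B", "A", "C"), 2),
    betweenness = c(4, 4, 1, 6, 6, 3),
    betweenness_norm = 0, rank = 0)
  hk <- rankHubs(ct, 3)
  expect_identical(hk$acronym, c("A", "B", "C"))  # A and B tie at 5
  expect_equal(hk$mean_betweenness, c(5, 5, 2))
  expect_identical(hk$rank, 1:3)
  full <- rankHubs(ct, 3)
  expect_identical(sort(full$rank), 1:3)
  expect_error(rankHubs(ct, 9), "exceeds")
})

test_that("region-set centrality averages members per brain then per
           condition", {
  ct <- data.frame(
    brain_id = rep(c("b1", "b2"), each = 4),
    condition = rep(c("ZT0-4", "ZT0-4"), each = 4),
    acronym = rep(c("A", "B", "C", "D"), 2),
    betweenness = c(1, 3, 10, 20, 3, 5, 10, 20))
  sc <- setCentrality(ct, c("A", "B"))
  expect_equal(sc$per_brain$set_mean, c(2, 4))
  expect_equal(sc$per_condition$mean, 3)
  expect_equal(sc$per_condition$sd, sd(c(2, 4)))
  single <- setCentrality(ct, "C")
  expect_equal(single$per_brain$set_mean, c(10, 10))
  all4 <- setCentrality(ct, c("A", "B", "C", "D"))
  expect_equal(all4$per_brain$set_mean,
               c(mean(c(1, 3, 10, 20)), mean(c(3, 5, 10, 20))))
  expect_warning(setCentrality(ct, c("A", "ZZZ")), "ZZZ")
  expect_error(setCentrality(ct, "ZZZ"), "none of the region-set")
})

test_that("a planted bridge region dominates betweenness", {
  cfg <- simConfig(seed = 23, bridgeRegion = "PH")
  db <- makeDensity(cfg)
  ct <- betweennessCentrality(weightMatrix(db$density))
  expect_identical(ct$acronym[ct$rank == 1], "PH")
})

test_that("internal ARI agrees with mclust's adjusted Rand index", {
  skip_if_not_installed("mclust")
  set.seed(33)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ariIndex(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(ariIndex(1:5, c(2, 2, 3, 3, 1)) , ariIndex(1:5, c(2, 2, 3, 3, 1)))
  expect_equal(ariIndex(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})
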