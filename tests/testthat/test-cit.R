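test_that("fisherZTest reproduces the hand-computed partial correlation", {
  # construct exact sample correlations r_xy=0.5, r_xm=0.6, r_ym=0.6
  n <- 50
  Q <- orthoBasis(n, 3)
  M <- Q[, 1]
  X <- 0.6 * Q[, 1] + sqrt(1 - 0.36) * Q[, 2]
  a <- (0.5 - 0.36) / sqrt(1 - 0.36)
  Y <- 0.6 * Q[, 1] + a * Q[, 2] + sqrt(1 - 0.36 - a^2) * Q[, 3]
  expect_equal(cor(X, Y), 0.5, tolerance = 1e-12)
  expect_equal(cor(X, M), 0.6, tolerance = 1e-12)
  f <- fisherZTest(X, Y, M)
  expect_equal(f$r_partial, (0.5 - 0.36) / (1 - 0.36), tolerance = 1e-10)
  expect_equal(f$r_partial, 0.21875, tolerance = 1e-10)
  expect_equal(f$w, 0.5 * log(1.21875 / 0.78125), tolerance = 1e-10)
  expect_equal(f$w, 0.22234294, tolerance = 1e-6)
  expect_equal(f$sigma, 1 / sqrt(n - 1 - 3))
  expect_equal(f$p_value, 2 * (1 - pnorm(abs(f$z_score))), tolerance = 1e-12)
  # strict n-3 convention restores the plain denominator
  expect_equal(fisherZTest(X, Y, M, strict_n3 = TRUE)$sigma, 1 / sqrt(n - 3))
})

test_that("residual-regression and recursive-formula routes agree", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    M <- rnorm(n)
    X <- 0.5 * M + rnorm(n)
    Y <- 0.5 * M + 0.3 * X + rnorm(n)
    expect_equal(fisherZTest(X, Y, M)$r_partial,
                 ivccc:::.partialCorRecursive(X, Y, M), tolerance = 1e-10)
  }
})

test_that("fisherZTest is symmetric and reduces to Pearson marginally", {
  set.seed(12)
  X <- rnorm(30); Y <- rnorm(30); M <- rnorm(30)
  a <- fisherZTest(X, Y, M); b <- fisherZTest(Y, X, M)
  expect_identical(a$r_partial, b$r_partial)
  expect_identical(a$p_value, b$p_value)
  m <- fisherZTest(X, Y)
  expect_equal(m$r_partial, cor(X, Y), tolerance = 1e-12)
  expect_equal(m$sigma, 1 / sqrt(30 - 3))
})

test_that("fisherZTest flags saturation and rejects degenerate input", {
  X <- rnorm(20)
  f <- fisherZTest(X, 2 * X + 1)
  expect_true(f$saturated)
  expect_equal(f$p_value, 0)
  expect_error(fisherZTest(rep(1, 20), rnorm(20)), "zero-variance")
  expect_error(fisherZTest(rnorm(5), rnorm(5), matrix(rnorm(10), 5)),
               "n >=")
  # conditioning set that explains X exactly
  M <- rnorm(20)
  expect_error(fisherZTest(M, rnorm(20), M), "exactly")
})

test_that("coexpression is 1 on identical genes and 0 on flat genes", {
  set.seed(13)
  m <- rbind(ga = rpois(40, 20), gb = 0, gc = rpois(40, 20))
  m <- rbind(m, gd = m["ga", ])
  colnames(m) <- paste0("c", 1:40)
  meta <- data.frame(cell_id = colnames(m),
                     sample_id = rep(c("s1", "s2"), each = 20),
                     patient_id = "p1",
                     timepoint = rep(c("pre", "post"), each = 20),
                     cell_type = "T")
  cm <- CellMatrix(m, meta)
  expect_equal(coexpression(cm, "ga", "ga", "T"), 1, tolerance = 1e-12)
  r <- coexpression(cm, "ga", "gb", "T")
  expect_equal(as.numeric(r), 0)
  expect_true(isTRUE(attr(r, "degenerate")))
  expect_error(coexpression(cm, "ga", "nope", "T"), "not in matrix")
  expect_error(coexpression(cm, "ga", "gc", "T", min_cells = 100), "fewer")
  # complex subunits are min-combined: pairing with its own min is perfect
  expect_equal(coexpression(cm, c("ga", "gd"), "ga", "T"), 1,
               tolerance = 1e-12)
})

test_that("screenLR requires marginal dependence before claiming mediation", {
  set.seed(14)
  n <- 15
  Z <- rep(c(0, 1), each = n)
  pats <- rep(paste0("p", 1:n), 2)
  # X and Y marginally independent; ligand/receptor well expressed
  vs <- cbind(x = rnorm(2 * n, 10), lig = rnorm(2 * n, 10))
  vr <- cbind(y = rnorm(2 * n, 10), rec = rnorm(2 * n, 10))
  pbS <- makePB(vs, pats, Z, "T"); pbR <- makePB(vr, pats, Z, "M")
  iv <- data.frame(x_gene = "x", y_gene = "y", passes = TRUE)
  lr <- data.frame(ligand = "lig", receptor = "rec", source = "s")
  # a CellMatrix carrying these gene names for the co-expression step
  m <- matrix(rpois(4 * 60, 30), 4, 60,
              dimnames = list(c("x", "lig", "y", "rec"), paste0("c", 1:60)))
  meta <- data.frame(cell_id = colnames(m), sample_id = "s1",
                     patient_id = "p1", timepoint = "pre", cell_type = "T")
  meta$cell_type <- rep(c("T", "M"), each = 30)
  cmx <- CellMatrix(m, meta)
  out <- screenLR(iv, lr, pbS, pbR, cmx)
  expect_equal(nrow(out), 1)
  expect_false(out$mediates)
  expect_gt(out$p_marginal, 0.05)
  expect_error(screenLR(iv, lr[0, ], pbS, pbR, cmx), "empty LR database")
})

test_that("screenLR skips LR pairs with unmeasured genes and logs it", {
  set.seed(15)
  n <- 10
  Z <- rep(c(0, 1), each = n)
  pats <- rep(paste0("p", 1:n), 2)
  x <- Z + rnorm(2 * n); lig <- x + rnorm(2 * n, 0, 0.2)
  y <- lig + rnorm(2 * n, 0, 0.2)
  vs <- cbind(x = x - min(x), lig = lig - min(lig))
  vr <- cbind(y = y - min(y), rec = rep(5, 2 * n) + runif(2 * n, 0, 0.1))
  pbS <- makePB(vs, pats, Z, "T"); pbR <- makePB(vr, pats, Z, "M")
  iv <- data.frame(x_gene = "x", y_gene = "y", passes = TRUE)
  lr <- data.frame(ligand = c("lig", "ghost"), receptor = c("rec", "rec"),
                   source = "s")
  m <- matrix(rpois(4 * 60, 30), 4, 60,
              dimnames = list(c("x", "lig", "y", "rec"), paste0("c", 1:60)))
  meta <- data.frame(cell_id = colnames(m),
                     sample_id = "s1", patient_id = "p1",
                     timepoint = "pre",
                     cell_type = rep(c("T", "M"), each = 30))
  cmx <- CellMatrix(m, meta)
  expect_message(out <- screenLR(iv, lr, pbS, pbR, cmx), "skipping 1")
  expect_equal(nrow(out), 1)
  expect_identical(out$ligand, "lig")
})
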