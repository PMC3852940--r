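# Random-forest occurrence modeling: AUC, cross-validation, permutation
# importance, partial dependence, raster prediction.

test_that("AUC matches exhaustive pairwise counting on worked examples", {
  # (0.9 P, 0.8 A, 0.4 P, 0.3 A): 3 concordant pairs of 4 -> 0.75
  sc <- c(0.9, 0.8, 0.4, 0.3)
  lb <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(aucMW(sc, lb), 0.75)
  expect_equal(aucMW(sc, lb), bruteForceAUC(sc, lb))
  # error-free ranking
  expect_equal(aucMW(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  # all scores tied: every pair counts one half
  expect_equal(aucMW(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(aucMW(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC equals the pairwise-counting oracle on random instances", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(4:150, 1)
    sc <- if (i %% 2) rnorm(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
    lb <- c(TRUE, FALSE, runif(n - 2) < 0.5)   # both classes guaranteed
    expect_equal(aucMW(sc, lb), bruteForceAUC(sc, lb))
  }
})

test_that("forest fitting uses vote-fraction probabilities and validates input", {
  set.seed(15)
  depth <- c(runif(50, 1000, 2000), runif(50, 0, 1000))
  y <- depth > 1000
  pred <- data.frame(depth = depth)
  m <- fitOccurrenceModel(y, pred, seed = 1)
  p <- predictPresence(m, pred)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(aucMW(p, y), 1.0)        # separable toy: resubstitution AUC 1
  expect_equal(m@forest$ntree, 500)
  expect_error(fitOccurrenceModel(rep(TRUE, 10),
                                  data.frame(x = rnorm(10))),
               "degenerate")
  expect_error(fitOccurrenceModel(y, pred[, 0, drop = FALSE]), "no predictors")
  predNA <- pred; predNA$depth[1] <- NA
  expect_error(fitOccurrenceModel(y, predNA), "missing")
})

test_that("repeated cross-validation is seeded, stratified and averaged", {
  w <- syntheticWorld(42)
  a <- w$areas[["warm-proxy"]]
  cv1 <- repeatedCV(a$labels, a$pred, k = 5, repeats = 2, seed = 3,
                    ntree = 100)
  cv2 <- repeatedCV(a$labels, a$pred, k = 5, repeats = 2, seed = 3,
                    ntree = 100)
  expect_identical(foldAUCs(cv1), foldAUCs(cv2))
  expect_equal(nrow(foldAUCs(cv1)), 10)
  expect_equal(cvAUC(cv1), mean(foldAUCs(cv1)$auc))
  # every fold of every repeat tests on both classes
  for (fold in cv1@folds)
    for (f in unique(fold))
      expect_gt(length(unique(a$labels[fold == f])), 1)
  expect_error(repeatedCV(rep(c(TRUE, FALSE), c(4, 40)),
                          data.frame(x = rnorm(44)), k = 10),
               "smaller k")
})

test_that("leave-one-out on a separable toy pools to AUC 1", {
  set.seed(16)
  depth <- c(runif(10, 1200, 2000), runif(10, 0, 800))
  y <- rep(c(TRUE, FALSE), each = 10)
  # k = n: singleton test folds, so only pooled scoring is defined
  cv <- repeatedCV(y, data.frame(depth = depth), k = 20, repeats = 1,
                   seed = 1, ntree = 200, scoring = "pooled")
  expect_equal(cvAUC(cv), 1.0)
  expect_true(all(is.na(foldAUCs(cv)$auc)))
  expect_error(repeatedCV(y, data.frame(depth = depth), k = 20,
                          repeats = 1, seed = 1, scoring = "average"),
               "smaller k")
})

test_that("permutation importance ranks the causal predictor above noise", {
  w <- syntheticWorld(42)
  a <- w$areas[["warm-proxy"]]
  set.seed(99)
  pred <- cbind(a$pred,
                noise_a = rnorm(nrow(a$pred)),
                noise_b = runif(nrow(a$pred)))
  cv <- repeatedCV(a$labels, pred, k = 5, repeats = 1, seed = 4,
                   ntree = 150, keepModels = TRUE)
  imp <- permutationImportance(cv, pred, a$labels,
                               predictorNames = c("salinity_bottom_min",
                                                  "noise_a", "noise_b"),
                               nPerm = 5, seed = 4)
  impOf <- function(v) imp$importance[imp$predictor == v]
  expect_gt(impOf("salinity_bottom_min"), impOf("noise_a"))
  expect_gt(impOf("salinity_bottom_min"), impOf("noise_b"))
  expect_lt(abs(impOf("noise_a")), 0.02)
  expect_true(all(imp$sd >= 0))
  expect_error(permutationImportance(cv, pred, a$labels,
                                     predictorNames = "nope"),
               "not in model")
  cvNo <- repeatedCV(a$labels, pred, k = 5, repeats = 1, seed = 4,
                     ntree = 50)
  expect_error(permutationImportance(cvNo, pred, a$labels), "keepModels")
})

test_that("permuting a constant predictor contributes exactly zero", {
  set.seed(17)
  n <- 120
  pred <- data.frame(x = rnorm(n), const = rep(1, n))
  y <- pred$x > 0
  cv <- repeatedCV(y, pred, k = 4, repeats = 1, seed = 2, ntree = 100,
                   keepModels = TRUE)
  imp <- permutationImportance(cv, pred, y, predictorNames = "const",
                               nPerm = 3, seed = 2)
  expect_equal(imp$importance, 0)
  expect_equal(imp$sd, 0)
})

test_that("partial dependence holds other covariates at their means", {
  registerS3method("predict", "constantForest",
                   function(object, newdata, type = "prob", ...)
                     matrix(0.5, nrow(newdata), 2,
                            dimnames = list(NULL, c("absence", "presence"))),
                   envir = asNamespace("stats"))
  stub <- new("ModelBundle", forest = structure(list(ntree = 1L),
                                                class = "constantForest"),
              predictors = c("x", "z"), subarea = "toy",
              classPrior = c(0.5, 0.5), seed = 1L)
  tab <- data.frame(x = rnorm(40), z = rnorm(40))
  pd <- partialDependence(stub, "x", tab, nGrid = 25)
  expect_true(all(pd$probability == 0.5))        # constant model, flat curve
  expect_true(all(diff(pd$value) > 0))
  expect_equal(range(pd$value), range(tab$x))
  expect_error(partialDependence(stub, "missing", tab), "not in model")
  tab0 <- data.frame(x = rep(1, 10), z = rnorm(10))
  expect_warning(pd0 <- partialDependence(stub, "x", tab0), "zero-variance")
  expect_equal(nrow(pd0), 1)
})

test_that("partial dependence recovers a monotone salinity response", {
  w <- syntheticWorld(42)
  a <- w$areas[["warm-proxy"]]
  m <- fitOccurrenceModel(a$labels, a$pred, seed = 5, ntree = 300)
  pd <- partialDependence(m, "salinity_bottom_min", a$pred)
  expect_true(all(pd$probability >= 0 & pd$probability <= 1))
  expect_true(all(diff(pd$value) > 0))
  # low-salinity end predicts much lower presence than the high end
  expect_gt(mean(tail(pd$probability, 10)), mean(head(pd$probability, 10)) + 0.3)
  # the averaged variant is also monotone in the large
  pdA <- partialDependence(m, "salinity_bottom_min", a$pred, nGrid = 30,
                           average = TRUE)
  expect_gt(mean(tail(pdA$probability, 5)), mean(head(pdA$probability, 5)))
})

test_that("raster prediction propagates nodata and matches point prediction", {
  w <- syntheticWorld(42)
  a <- w$areas[["warm-proxy"]]
  m <- fitOccurrenceModel(a$labels, a$pred, seed = 6, ntree = 100)
  st <- w$env$stack
  surf <- predictRaster(m, st)
  v <- gridValues(surf)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_identical(is.na(v), is.na(gridValues(st[["depth"]])))
  # cell-center point prediction equals the raster value at that cell
  i <- 30L; j <- 40L
  pt <- data.frame(lon = gridOrigin(st)[1] + (j - 1) * cellSize(st),
                   lat = gridOrigin(st)[2] - (i - 1) * cellSize(st))
  ext <- extractAtPoints(st, pt)
  expect_equal(predictPresence(m, ext), v[i, j])
  # a stack missing a model predictor is a named error
  small <- GridStack(st[["depth"]])
  expect_error(predictRaster(m, small), "salinity_bottom_min")
})
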