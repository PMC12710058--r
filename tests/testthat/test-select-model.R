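# Mutual information, feature selection, ensembles, metrics, SHAP.

test_that("mutual information has the expected information-theoretic anchors", {
  set.seed(1)
  x <- rnorm(2000)
  expect_equal(mutual_information(x, x, bins = 8), 3, tolerance = 1e-9)
  y <- rnorm(2000)
  # plug-in bias of the 8x8 joint at n = 2000 stays well under 0.05 bits
  expect_lt(mutual_information(x, y, bins = 8), 0.05)
  # 2x2 perfectly dependent joint mass {(0,0): .5, (1,1): .5} -> 1 bit
  a <- rep(c(0, 1), each = 500)
  expect_equal(mutual_information(a, a, bins = 2), 1, tolerance = 1e-9)
  expect_warning(mi0 <- mutual_information(rep(1, 100), rnorm(100)), "constant")
  expect_equal(mi0, 0)
})

test_that("MI is symmetric and invariant under monotone transforms", {
  set.seed(2)
  x <- rnorm(500); y <- x + rnorm(500)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_equal(mutual_information(exp(x), y^3 + 2 * y),
               mutual_information(x, y))
})

fake_mi_table <- function(values) {
  fn <- feature_names()
  m <- matrix(rep(values, length.out = length(fn) * 3), length(fn), 3,
              dimnames = list(fn, PHYSIO_TARGETS))
  m
}

test_that("typical-feature ranking respects cells and tie rules", {
  m <- fake_mi_table(0.5)
  ranked <- rank_typical_features(m)
  expect_equal(nrow(ranked), 2 * 3 * 3 * 2)  # 18 cells x 2 features
  # all-equal MI -> lexicographically first two of each cell
  cell <- ranked[ranked$source == "fluorescence" &
                   ranked$dim == "1D-Parallel" & ranked$target == "P_max", ]
  flu_par <- sort(grep("^((Fv/Fm)|NPQ|qP|qL|qN|Y)", feature_names(), value = TRUE))
  flu_par <- sort(flu_par[grepl("/1D-Parallel/", flu_par)])
  expect_equal(cell$feature, flu_par[1:2])
})

test_that("key-feature selection applies the substitution rule", {
  # no overlap: plain top-2 per target
  m <- fake_mi_table(0.1)
  fn <- rownames(m)
  m[fn[1], "P_max"] <- 3; m[fn[2], "P_max"] <- 2.9
  m[fn[3], "REC"] <- 3;  m[fn[4], "REC"] <- 2.9
  m[fn[5], "Chl_a+b"] <- 3; m[fn[6], "Chl_a+b"] <- 2.9
  keys <- select_key_features(m)
  expect_equal(sort(keys$feature), sort(fn[1:6]))
  expect_equal(nrow(keys), 6)
  # overlap: fn[1] best for both P_max and Chl; Chl has the larger MI, so
  # P_max substitutes its third-ranked feature
  m2 <- fake_mi_table(0.1)
  m2[fn[1], "P_max"] <- 2.207; m2[fn[2], "P_max"] <- 2.18
  m2[fn[7], "P_max"] <- 2.1    # third-ranked substitute
  m2[fn[3], "REC"] <- 3;  m2[fn[4], "REC"] <- 2.9
  m2[fn[1], "Chl_a+b"] <- 2.345; m2[fn[6], "Chl_a+b"] <- 2.3
  keys2 <- select_key_features(m2)
  expect_equal(length(unique(keys2$feature)), 6)
  chl <- keys2[keys2$target == "Chl_a+b", ]
  expect_true(fn[1] %in% chl$feature)
  pm <- keys2[keys2$target == "P_max", ]
  expect_false(fn[1] %in% pm$feature)
  expect_true(fn[7] %in% pm$feature)
})

make_regression_data <- function(n = 180, p = 6, seed = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  list(X = X, y_lin = drop(X %*% c(3, -2, 1, 0.5, 0, 0)))
}

test_that("tuned XGB recovers a noise-free nonlinear-capable target", {
  d <- make_regression_data(seed = 0)
  b <- tune_and_train(d$X, d$y_lin, "XGB", seed = 0)
  held <- b$validation
  r2 <- evaluate_regression(d$y_lin[held],
                            predict(b, d$X[held, , drop = FALSE]))$r2
  expect_gte(r2, 0.95)
  # determinism of the tuning contract
  b2 <- tune_and_train(d$X, d$y_lin, "XGB", seed = 0)
  expect_identical(c(b$n_estimators, b$max_depth),
                   c(b2$n_estimators, b2$max_depth))
  expect_equal(predict(b, d$X[held, ]), predict(b2, d$X[held, ]))
})

test_that("RF on a pure-noise target shows no held-out skill", {
  d <- make_regression_data(seed = 1)
  set.seed(99)
  y_noise <- rnorm(nrow(d$X))
  b <- tune_and_train(d$X, y_noise, "RF", seed = 1,
                      n_grid = c(100L), depth_grid = c(3L))
  held <- b$validation
  r2 <- evaluate_regression(y_noise[held], predict(b, d$X[held, ]))$r2
  expect_lte(r2, 0.2)
})

test_that("AdaBoost trains, predicts and beats the mean on signal", {
  d <- make_regression_data(seed = 2)
  b <- tune_and_train(d$X, d$y_lin, "AB", seed = 2,
                      n_grid = c(50L), depth_grid = c(4L))
  held <- b$validation
  r2 <- evaluate_regression(d$y_lin[held], predict(b, d$X[held, ]))$r2
  expect_gte(r2, 0.7)
  expect_error(train_ensemble(d$X, rep(1, nrow(d$X)), "AB"), "degenerate")
})

test_that("regression metrics match the printed formulas", {
  expect_equal(evaluate_regression(1:5, 1:5), list(r2 = 1, rmse = 0))
  y <- c(1, 2, 3, 4)
  expect_equal(evaluate_regression(y, rep(mean(y), 4))$r2, 0)
  m <- evaluate_regression(c(0, 1, 2), c(0, 1, 3))
  expect_equal(m$rmse, 0.5774, tolerance = 1e-4)
  expect_equal(m$r2, 0.5)
  expect_warning(evaluate_regression(c(2, 2), c(1, 2)), "zero-variance")
})

test_that("classification metrics match the contingency formulas", {
  perfect <- evaluate_classification(c(0:4, 0:4), c(0:4, 0:4))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$kappa, 1)
  # 2-class chance agreement: confusion [[25,25],[25,25]]
  yt <- rep(c(0, 0, 1, 1), each = 25)
  yp <- rep(c(0, 1, 0, 1), each = 25)
  chance <- evaluate_classification(yt, yp, classes = 0:1)
  expect_equal(chance$acc, 50)
  expect_equal(chance$kappa, 0)
  # confusion [[40,10],[5,45]] -> ACC 85 %, kappa 0.70
  yt2 <- c(rep(0, 50), rep(1, 50))
  yp2 <- c(rep(0, 40), rep(1, 10), rep(0, 5), rep(1, 45))
  m2 <- evaluate_classification(yt2, yp2, classes = 0:1)
  expect_equal(m2$acc, 85)
  expect_equal(m2$kappa, 0.70)
})

test_that("classification metrics equal brute-force evaluation on random labels", {
  set.seed(31)
  for (k in 1:100) {
    yt <- sample(0:4, 40, replace = TRUE)
    yp <- sample(0:4, 40, replace = TRUE)
    got <- evaluate_classification(yt, yp)
    want <- oracle_classification(yt, yp, 0:4)
    expect_equal(got$acc, want$acc, tolerance = 1e-12)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
  }
})

test_that("predict_risk combines the two models through the CDRI rule", {
  # stub models with controllable constant predictions
  stub <- function(value, feats) {
    structure(list(value = value, feature_names = feats), class = "stub_model")
  }
  predict.stub_model <- function(object, newdata, ...)
    rep(object$value, nrow(newdata))
  registerS3method("predict", "stub_model", predict.stub_model)
  X <- data.frame(a = 1:3, b = 4:6)
  r0 <- predict_risk(stub(4.5, c("a", "b")), stub(0, c("a", "b")), X)
  expect_equal(unique(r0$level), 0L)
  r3 <- predict_risk(stub(1.0, c("a", "b")), stub(650, c("a", "b")), X)
  expect_equal(unique(r3$cdri), 0)
  expect_equal(unique(r3$level), 3L)
  expect_error(predict_risk(stub(1, c("a", "b")), stub(1, c("a", "c")), X),
               "different feature sets")
})

test_that("exact Shapley attributions are additive and rank the signal", {
  set.seed(77)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 4] <- 0                       # zero-variance feature
  y <- 2 * X[, 1] + rnorm(n, 0, 0.05)
  mdl <- train_ensemble(X, y, "XGB", n_estimators = 100, max_depth = 3,
                        seed = 3)
  ex <- explain(mdl, X[1:20, ], background = X)
  expect_equal(ex$ranking$feature[1], "f1")
  # local additivity: base + sum(phi) = prediction
  recon <- ex$base_value + rowSums(ex$shap)
  expect_equal(recon, ex$prediction, tolerance = 1e-6)
  expect_equal(ex$prediction, unname(predict(mdl, X[1:20, ])),
               tolerance = 1e-9)
  expect_lt(max(abs(ex$shap[, "f4"])), 1e-9)
  expect_error(explain(structure(list(), class = "lm"), X), "tree-ensemble")
})
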