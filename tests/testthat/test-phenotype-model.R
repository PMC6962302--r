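test_that("derive_traits computes the premature-birth score and reference Z-scores", {
  ph <- data.frame(sample = c("a", "b", "c"), group = "case",
                   gestational_age = c(39, 37, 42))
  out <- derive_traits(ph)
  expect_equal(out$premature_birth, c(0, 2, -3)) # term, pre-term, post-term

  # Z from a reference table, linearly interpolated in gestational age
  ref <- list(birth_weight = data.frame(
    sex = rep(c("m", "f"), each = 3),
    gestational_age = rep(c(36, 38, 40), 2),
    mean = c(2600, 3000, 3400, 2500, 2900, 3300),
    sd = rep(c(400, 450, 500), 2)
  ))
  ph2 <- data.frame(sample = c("s1", "s2"), group = "case",
                    gestational_age = c(38, 39), sex = c("m", "f"),
                    birth_weight = c(3000, 2650))
  out2 <- derive_traits(ph2, reference = ref)
  expect_equal(out2$birth_weight_z[1], 0)
  expect_equal(out2$birth_weight_z[2], (2650 - 3100) / 475)
  ph_bad <- data.frame(sample = "x", group = "case", gestational_age = 30,
                       sex = "m", birth_weight = 1500)
  expect_error(derive_traits(ph_bad, reference = ref), "outside reference")
})

test_that("select_features unions significant features deterministically", {
  ms <- data.frame(feature = c("m1", "m2", "m3"),
                   significant = c(TRUE, FALSE, TRUE))
  es <- data.frame(feature = c("e1", "e2"), significant = c(FALSE, TRUE))
  expect_equal(select_features(ms, es), c("m1", "m3", "e2"))
  es0 <- data.frame(feature = "e1", significant = FALSE)
  ms0 <- data.frame(feature = "m1", significant = FALSE)
  expect_error(select_features(ms0, es0), "threshold")
})

test_that("stratified_split respects group ratios, rounding and the seed", {
  ids <- sprintf("S%02d", 1:36)
  grp <- rep(c("control", "case"), c(8, 28))
  sp <- stratified_split(ids, grp, seed = 5)
  # round(2/3 * 8) = 5 controls, round(2/3 * 28) = 19 cases in training
  expect_equal(sum(sp$train %in% ids[1:8]), 5)
  expect_equal(sum(sp$train %in% ids[9:36]), 19)
  expect_equal(sort(c(sp$train, sp$test)), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(ids, grp, seed = 5))
  expect_false(identical(sp, stratified_split(ids, grp, seed = 6)))
  expect_error(stratified_split(ids, grp, ratio = 0.999, seed = 1), "empty")
  expect_error(stratified_split(c("a", "b"), c("x", "y"), seed = 1),
               "at least 2")
})

test_that("SMOTE synthesizes convex minority combinations until balance", {
  # two minority points on a segment: synthetic coordinates are (l, l)
  x <- rbind(matrix(rep(c(0, 1), each = 2), 2, 2, byrow = FALSE),
             matrix(5 + runif(12), 6, 2))
  x[1, ] <- c(0, 0); x[2, ] <- c(1, 1)
  rownames(x) <- paste0("s", 1:8)
  y <- factor(rep(c("min", "maj"), c(2, 6)), levels = c("min", "maj"))
  aug <- suppressWarnings(smote_augment(x, y, k = 1, seed = 3))
  synth <- aug$x[aug$synthetic, , drop = FALSE]
  expect_equal(nrow(synth), 4) # 6 - 2
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)
  expect_true(all(synth >= 0 & synth <= 1))
  expect_equal(as.character(aug$y[aug$synthetic]), rep("min", 4))

  # 5 vs 15: ten synthetic samples restore 1:1 balance
  set.seed(4)
  x2 <- matrix(rnorm(20 * 3), 20, 3,
               dimnames = list(paste0("s", 1:20), NULL))
  x2[1:5, ] <- x2[1:5, ] - 6 # separate the minority cluster
  y2 <- factor(rep(c("a", "b"), c(5, 15)))
  aug2 <- smote_augment(x2, y2, k = 4, seed = 9)
  expect_equal(sum(aug2$synthetic), 10)
  expect_equal(unname(table(aug2$y)["a"]), 15L)

  # every synthetic point's nearest original neighbor is minority-class
  orig <- x2
  synth2 <- aug2$x[aug2$synthetic, , drop = FALSE]
  for (i in seq_len(nrow(synth2))) {
    d <- sqrt(rowSums((orig - matrix(synth2[i, ], 20, 3, byrow = TRUE))^2))
    expect_equal(as.character(y2[which.min(d)]), "a")
  }

  expect_error(smote_augment(x2[c(1, 6:20), ], factor(rep(c("a", "b"), c(1, 15))),
                             k = 1, seed = 1), "at least 2")
})

test_that("regression SMOTE interpolates targets with the shared lambda", {
  set.seed(5)
  x <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  y <- rnorm(12)
  grp <- rep(c("control", "case"), c(4, 8))
  aug <- suppressWarnings(smote_augment(x, y, group = grp, k = 3, seed = 2))
  expect_equal(sum(aug$synthetic), 4)
  # each synthetic sample lies on a segment between two minority samples
  # and its target uses the same interpolation weight
  xm <- x[1:4, ]; ym <- y[1:4]
  for (i in which(aug$synthetic)) {
    found <- FALSE
    for (a in 1:4) for (b in 1:4) {
      if (a == b) next
      dv <- xm[b, ] - xm[a, ]
      lam <- if (abs(dv[1]) > 1e-12) (aug$x[i, 1] - xm[a, 1]) / dv[1] else NA
      if (!is.na(lam) && lam >= 0 && lam <= 1 &&
          all(abs(xm[a, ] + lam * dv - aug$x[i, ]) < 1e-9) &&
          abs(ym[a] + lam * (ym[b] - ym[a]) - aug$y[i]) < 1e-9) {
        found <- TRUE
      }
    }
    expect_true(found)
  }
})

test_that("grid-search training is deterministic and solves separable data", {
  set.seed(21)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  rownames(x) <- paste0("s", 1:40)
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- train_trait_model(x, y, "classification", cv_folds = 4, seed = 3)
  expect_equal(max(fit$cv_results$cv_metric), 1)
  fit2 <- train_trait_model(x, y, "classification", cv_folds = 4, seed = 3)
  expect_identical(fit$best_params, fit2$best_params)
  ev <- evaluate_model(fit, x, y)
  expect_equal(ev$metric, 1)
  expect_true(all(c("prob_case", "predicted") %in% names(ev$predictions)))
})

test_that("pure-noise features give chance-level test accuracy", {
  set.seed(22)
  x <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(paste0("s", 1:60), NULL))
  y <- factor(rep(c("a", "b"), each = 30))
  itr <- c(1:20, 31:50); ite <- c(21:30, 51:60)
  fit <- train_trait_model(x[itr, ], y[itr], "classification", seed = 4)
  ev <- evaluate_model(fit, x[ite, ], y[ite])
  # binomial band around 0.5 at n = 20 (majority rate 0.5)
  expect_gte(ev$metric, 0.15)
  expect_lte(ev$metric, 0.85)
})

test_that("evaluate_model reports correlations and flags degenerate predictions", {
  set.seed(23)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(paste0("s", 1:30), NULL))
  y <- x %*% c(1, -1, 0.5, 0) + rnorm(30, 0, 0.1)
  fit <- train_trait_model(x[1:20, ], y[1:20], "regression", seed = 5)
  ev <- evaluate_model(fit, x[21:30, ], y[21:30])
  expect_gt(ev$metric, 0.9)
  expect_lt(ev$p.value, 0.01)
  # constant predictions: undefined correlation, flagged not valued
  constant_fit <- fit
  constant_fit$model <- structure(list(), class = "constant_pred")
  # simulate via a y_test with zero variance instead
  ev2 <- evaluate_model(fit, x[21:30, ], rep(1, 10))
  expect_true(ev2$failed)
  expect_true(is.na(ev2$metric))
})

test_that("permutation importance isolates the informative feature", {
  set.seed(24)
  n <- 40
  x <- cbind(signal = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  y <- factor(rep(c("a", "b"), each = n / 2))
  fit <- train_trait_model(x, y, "classification", seed = 6)
  imp <- permutation_importance(fit, x, y, n_repeats = 10, seed = 7)
  expect_equal(imp$percent[imp$feature == "signal"], 100)
  expect_lt(max(imp$percent[imp$feature != "signal"]), 50)
  expect_true(all(imp$raw >= 0))
  # invariant to test-sample order
  perm <- sample(n)
  imp2 <- permutation_importance(fit, x[perm, ], y[perm], n_repeats = 10,
                                 seed = 7)
  expect_equal(imp$raw, imp2$raw, tolerance = 1e-9)
  expect_error(permutation_importance(fit, x[1, , drop = FALSE], y[1]),
               "at least 2")
})

test_that("importance network applies include/label/supplementary thresholds", {
  imps <- list(
    group = data.frame(feature = c("f1", "f2", "f3"), raw = c(1, 2, 3),
                       percent = c(5, 55, 100)),
    birth_weight_z = data.frame(feature = c("f1", "f2", "f3"),
                                raw = c(3, 0, 1), percent = c(85, 0, 30))
  )
  net <- build_importance_network(imps)
  # edges: (f2, group), (f3, group), (f1, bw), (f3, bw) -- percent >= 10
  expect_equal(nrow(net$edges), 4)
  expect_equal(nrow(net$edges), sum(sapply(imps, function(i) sum(i$percent >= 10))))
  labf <- net$nodes$labeled[net$nodes$type == "feature"]
  names(labf) <- net$nodes$id[net$nodes$type == "feature"]
  expect_true(labf[["f1"]]) # 85 >= 80
  expect_true(labf[["f3"]]) # 100
  expect_false(labf[["f2"]]) # max 55
  expect_equal(sort(unique(net$supplementary$feature)), c("f1", "f2", "f3"))
  # all importances below the include threshold: only trait nodes remain
  low <- lapply(imps, function(i) { i$percent <- i$percent / 50; i })
  net0 <- build_importance_network(low)
  expect_equal(nrow(net0$edges), 0)
  expect_true(all(net0$nodes$type == "trait"))
})

test_that("network files are written in SIF and GraphML form", {
  imps <- list(group = data.frame(feature = "f1", raw = 1, percent = 90))
  net <- build_importance_network(imps)
  sif <- tempfile(fileext = ".sif"); gml <- tempfile(fileext = ".graphml")
  write_network(net, sif, gml)
  expect_equal(readLines(sif), "f1\tpredicts\tgroup")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$importance_percent, 90)
  unlink(c(sif, gml))
})

test_that("test-set hygiene: the fitted model never sees test samples", {
  set.seed(25)
  x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(paste0("s", 1:30), NULL))
  y <- factor(rep(c("a", "b"), each = 15))
  itr <- c(1:10, 16:25)
  # training with or without the test rows present in the frame is identical
  f1 <- train_trait_model(x[itr, ], y[itr], "classification", seed = 8)
  x_copy <- x[itr, ]
  f2 <- train_trait_model(x_copy, y[itr], "classification", seed = 8)
  expect_identical(f1$best_params, f2$best_params)
  expect_equal(predict(f1$model, x[-itr, ]), predict(f2$model, x[-itr, ]))
})
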