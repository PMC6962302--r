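#' Derive modeling traits from raw phenotypes
#'
#' Adds the premature-birth score (39 minus gestational age in weeks;
#' values above 2 indicate pre-term birth, at or below -3 post-term) and,
#' when Z-scores are not already present, computes growth Z-scores
#' `(value - ref_mean) / ref_sd` from a user-supplied reference table,
#' interpolated linearly in gestational age per sex.
#'
#' @param phenotypes `data.frame` with at least `sample`, `group`,
#'   `gestational_age`; optionally `birth_weight_z` /
#'   `head_circumference_z`, or raw `birth_weight` / `head_circumference`
#'   plus `sex` for Z-derivation.
#' @param reference Optional named list of reference tables, one per raw
#'   measure (e.g. `list(birth_weight = data.frame(sex, gestational_age,
#'   mean, sd))`).
#' @return The phenotype table with `premature_birth` and any derivable
#'   Z-score columns added.
#' @export
derive_traits <- function(phenotypes, reference = NULL) {
  if (!"gestational_age" %in% names(phenotypes)) {
    stop("`gestational_age` column is required")
  }
  phenotypes$premature_birth <- 39 - phenotypes$gestational_age

  for (measure in c("birth_weight", "head_circumference")) {
    zcol <- paste0(measure, "_z")
    if (zcol %in% names(phenotypes)) next
    if (!measure %in% names(phenotypes)) next
    ref <- reference[[measure]]
    if (is.null(ref)) {
      stop(sprintf("raw `%s` present but no reference table supplied", measure))
    }
    z <- numeric(nrow(phenotypes))
    for (i in seq_len(nrow(phenotypes))) {
      sx <- phenotypes$sex[i]
      ga <- phenotypes$gestational_age[i]
      sub <- ref[ref$sex == sx, ]
      if (ga < min(sub$gestational_age) || ga > max(sub$gestational_age)) {
        stop(sprintf("gestational age %.1f of sample %s outside reference range",
                     ga, phenotypes$sample[i]))
      }
      m <- stats::approx(sub$gestational_age, sub$mean, ga)$y
      s <- stats::approx(sub$gestational_age, sub$sd, ga)$y
      z[i] <- (phenotypes[[measure]][i] - m) / s
    }
    phenotypes[[zcol]] <- z
  }
  phenotypes
}

#' The four modeled phenotypic traits
#'
#' Case-control group membership (classification, accuracy metric) and
#' three continuous severity traits (regression, Pearson correlation
#' metric): premature birth, birth-weight Z and head-circumference Z.
#'
#' @return `data.frame` with columns `name`, `task`, `metric`.
#' @export
trait_specs <- function() {
  data.frame(
    name = c("group", "premature_birth", "birth_weight_z",
             "head_circumference_z"),
    task = c("classification", "regression", "regression", "regression"),
    metric = c("accuracy", "pearson_r", "pearson_r", "pearson_r"),
    stringsAsFactors = FALSE
  )
}

#' Select model features from the differential screens
#'
#' The union of significant features across both omics layers, in
#' deterministic order (methylation table order, then expression).
#'
#' @param meth_stats,expr_stats `feature_stats` tables.
#' @return Character vector of feature ids; errors when empty (advising a
#'   look at the screen thresholds).
#' @export
select_features <- function(meth_stats, expr_stats) {
  sel <- c(meth_stats$feature[meth_stats$significant],
           expr_stats$feature[expr_stats$significant])
  if (!length(sel)) {
    stop("no significant features selected; review the Levene/q thresholds")
  }
  unique(sel)
}

#' Stratified train/test split
#'
#' Allocates `round(ratio * n_g)` samples of each group to the training
#' set, preserving the case-control ratio; deterministic given the seed.
#'
#' @param sample_ids Character vector of sample ids.
#' @param groups Group label per sample.
#' @param ratio Training fraction (default 2/3).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
stratified_split <- function(sample_ids, groups, ratio = 2 / 3, seed = 1L) {
  stopifnot(length(sample_ids) == length(groups))
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  with_seed(seed, {
    train <- unlist(lapply(names(tab), function(g) {
      ids <- sample_ids[groups == g]
      n_train <- round(ratio * length(ids))
      sample(ids, n_train)
    }), use.names = FALSE)
    test <- setdiff(sample_ids, train)
    if (!length(test)) stop("test set is empty; lower `ratio`")
    if (!length(train)) stop("training set is empty; raise `ratio`")
    list(train = sort(train), test = sort(test))
  })
}

#' SMOTE oversampling of the minority group
#'
#' Classification: each synthetic sample is `x + lambda * (x_nn - x)` with
#' `lambda ~ Uniform(0,1)` and `x_nn` one of the `k` nearest minority
#' neighbors (Euclidean) of a minority sample `x`, generated until the
#' classes are balanced. For continuous targets the same interpolation is
#' applied within the minority *group* (case samples) and the target is
#' interpolated with the same lambda (SMOTER-style — an interpretation,
#' since the original technique is defined for class labels). Test data
#' must never pass through here.
#'
#' @param x Numeric matrix, samples x features (training set only).
#' @param y Factor (classification) or numeric target (regression).
#' @param group For numeric `y`: group label per sample defining the
#'   minority group to oversample.
#' @param k Number of nearest neighbors (default 5; lowered with a warning
#'   when the minority is too small).
#' @param seed Integer seed.
#' @return List with augmented `x`, `y`, `group`, and `synthetic` flag per
#'   row.
#' @export
smote_augment <- function(x, y, group = NULL, k = 5, seed = 1L) {
  x <- as.matrix(x)
  classification <- is.factor(y) || is.character(y)
  strata <- if (classification) as.character(y) else {
    if (is.null(group)) stop("`group` is required for continuous targets")
    as.character(group)
  }
  tab <- sort(table(strata))
  if (length(tab) != 2) stop("exactly two classes/groups are supported")
  minority <- names(tab)[1]
  n_min <- tab[[1]]
  n_needed <- tab[[2]] - tab[[1]]
  if (n_min < 2) stop("minority class must have at least 2 samples")
  if (k >= n_min) {
    warning(sprintf("k lowered from %d to %d (minority size)", k, n_min - 1))
    k <- n_min - 1
  }
  if (n_needed == 0) {
    return(list(x = x, y = y, group = group,
                synthetic = rep(FALSE, nrow(x))))
  }
  idx_min <- which(strata == minority)
  xm <- x[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  if (k == 1) nn <- matrix(nn, ncol = 1)

  with_seed(seed, {
    base_i <- rep_len(seq_len(n_min), n_needed)
    nn_pick <- vapply(base_i, function(i) nn[i, sample.int(k, 1)], integer(1))
    lambda <- stats::runif(n_needed)
    synth_x <- xm[base_i, , drop = FALSE] +
      lambda * (xm[nn_pick, , drop = FALSE] - xm[base_i, , drop = FALSE])
    rownames(synth_x) <- sprintf("synth%03d", seq_len(n_needed))

    if (classification) {
      y_new <- factor(c(as.character(y), rep(minority, n_needed)),
                      levels = levels(factor(y)))
      group_new <- NULL
    } else {
      ym <- y[idx_min]
      y_new <- c(y, ym[base_i] + lambda * (ym[nn_pick] - ym[base_i]))
      group_new <- c(group, rep(minority, n_needed))
    }
    list(
      x = rbind(x, synth_x),
      y = y_new,
      group = group_new,
      synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_needed))
    )
  })
}

default_svm_grid <- function(task, n_features) {
  g0 <- 1 / n_features
  if (task == "classification") {
    lin <- expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100),
                       gamma = g0, stringsAsFactors = FALSE)
    rbf <- expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                       gamma = g0 * c(0.5, 1, 2), stringsAsFactors = FALSE)
    grid <- rbind(lin, rbf)
    grid$epsilon <- NA_real_
    return(grid)
  }
  # regression: epsilon down to 0.01 -- traits live on the Z-score scale,
  # where a wide tube swallows the within-group signal (0.5 never won in
  # calibration and is dropped, as are redundant cost points)
  lin <- expand.grid(kernel = "linear", cost = c(0.1, 1, 10),
                     gamma = g0, stringsAsFactors = FALSE)
  rbf <- expand.grid(kernel = "radial", cost = c(1, 10, 100),
                     gamma = g0 * c(0.5, 1, 2), stringsAsFactors = FALSE)
  merge(rbind(lin, rbf), data.frame(epsilon = c(0.01, 0.1)), by = NULL)
}

make_cv_folds <- function(y, cv_folds, classification, max_redraw = 20) {
  n <- length(y)
  for (attempt in seq_len(max_redraw)) {
    if (classification) {
      folds <- integer(n)
      for (lev in levels(y)) {
        idx <- which(y == lev)
        folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(cv_folds), n))
    }
    if (!classification) return(folds)
    degenerate <- any(vapply(seq_len(cv_folds), function(f) {
      length(unique(y[folds != f])) < 2
    }, logical(1)))
    if (!degenerate) return(folds)
    warning("degenerate CV fold (single class); fold assignment re-drawn")
  }
  stop("could not build non-degenerate folds")
}

.model_metric <- function(pred, truth, classification) {
  if (classification) {
    mean(as.character(pred) == as.character(truth))
  } else {
    if (stats::sd(pred) == 0 || stats::sd(truth) == 0) return(NA_real_)
    stats::cor(pred, truth)
  }
}

#' Train a support-vector model for one trait by grid-search CV
#'
#' For each grid point the k-fold cross-validated metric (accuracy for
#' classification, Pearson r for regression; folds stratified for
#' classification) is computed on the training set; the best point (first
#' in grid order on ties — deterministic) is refit on the full training
#' set. The margin solver is an exchangeable component (`e1071::svm`);
#' the grid loop, fold assignment, scoring and refit live here.
#' Classification models expose sigmoid-calibrated class probabilities.
#'
#' @param x Numeric matrix, samples x features (augmented training set).
#' @param y Factor or numeric response.
#' @param task `"classification"` or `"regression"`.
#' @param grid `data.frame` with columns `kernel`, `cost`, `gamma`,
#'   `epsilon`; default [default_svm_grid()].
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed (controls fold assignment).
#' @return List of class `trait_model`: fitted `model`, `task`,
#'   `best_params`, `cv_results`, `features`.
#' @export
train_trait_model <- function(x, y, task = c("classification", "regression"),
                              grid = NULL, cv_folds = 5, seed = 1L) {
  task <- match.arg(task)
  x <- as.matrix(x)
  classification <- task == "classification"
  if (classification) y <- factor(y)
  if (is.null(grid)) grid <- default_svm_grid(task, ncol(x))
  if (!nrow(grid)) stop("empty hyperparameter grid")

  fit_one <- function(xi, yi, par) {
    args <- list(x = xi, y = yi, kernel = par$kernel, cost = par$cost,
                 gamma = par$gamma, scale = FALSE,
                 probability = classification)
    if (!classification && !is.na(par$epsilon)) args$epsilon <- par$epsilon
    args$type <- if (classification) "C-classification" else "eps-regression"
    do.call(e1071::svm, args)
  }

  with_seed(seed, {
    folds <- make_cv_folds(if (classification) y else as.numeric(y),
                           cv_folds, classification)
    cv_score <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      par <- grid[gi, ]
      scores <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        if (sum(!tr) == 0 || length(unique(as.character(y[tr]))) < 2 &&
            classification) return(NA_real_)
        fit <- fit_one(x[tr, , drop = FALSE], y[tr], par)
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
        .model_metric(pred, y[!tr], classification)
      }, numeric(1))
      cv_score[gi] <- mean(scores, na.rm = TRUE)
    }
    cv_score[is.nan(cv_score)] <- -Inf
    best <- which.max(cv_score)
    final <- fit_one(x, y, grid[best, ])
    structure(list(
      model = final, task = task,
      best_params = grid[best, , drop = FALSE],
      cv_results = cbind(grid, cv_metric = cv_score),
      features = colnames(x),
      levels = if (classification) levels(y) else NULL
    ), class = "trait_model")
  })
}

#' @export
print.trait_model <- function(x, ...) {
  bp <- x$best_params
  cat(sprintf("trait_model [%s]: %s kernel, cost %g (CV metric %.3f)\n",
              x$task, bp$kernel, bp$cost,
              max(x$cv_results$cv_metric, na.rm = TRUE)))
  invisible(x)
}

#' Evaluate a trait model on the untouched test set
#'
#' Accuracy (classification, with per-sample calibrated case
#' probabilities) or Pearson r with its two-sided p-value (regression).
#' Constant predictions make r undefined; this is reported as a failure
#' flag rather than a value.
#'
#' @param fit A [train_trait_model()] result.
#' @param x_test,y_test Test features and response (never used in training
#'   or augmentation).
#' @return List with `metric`, `p.value` (regression), `predictions`
#'   (`data.frame`), `failed`.
#' @export
evaluate_model <- function(fit, x_test, y_test) {
  x_test <- as.matrix(x_test)
  if (!nrow(x_test)) stop("test set is empty")
  if (fit$task == "classification") {
    pred <- stats::predict(fit$model, x_test, probability = TRUE)
    prob <- attr(pred, "probabilities")
    case_col <- if ("case" %in% colnames(prob)) "case" else colnames(prob)[1]
    preds <- data.frame(
      sample = rownames(x_test) %||% seq_len(nrow(x_test)),
      actual = as.character(y_test),
      predicted = as.character(pred),
      prob_case = prob[, case_col],
      stringsAsFactors = FALSE
    )
    list(metric = mean(preds$predicted == preds$actual),
         p.value = NA_real_, predictions = preds, failed = FALSE)
  } else {
    pred <- as.numeric(stats::predict(fit$model, x_test))
    preds <- data.frame(
      sample = rownames(x_test) %||% seq_len(nrow(x_test)),
      actual = as.numeric(y_test), predicted = pred,
      stringsAsFactors = FALSE
    )
    if (stats::sd(pred) == 0 || stats::sd(y_test) == 0) {
      return(list(metric = NA_real_, p.value = NA_real_,
                  predictions = preds, failed = TRUE))
    }
    ct <- stats::cor.test(pred, as.numeric(y_test))
    list(metric = unname(ct$estimate), p.value = ct$p.value,
         predictions = preds, failed = FALSE)
  }
}

#' Permutation feature importance on the test set
#'
#' The importance of a feature is the mean drop of the test metric
#' (accuracy or Pearson r) over `n_repeats` shufflings of that feature's
#' test column, all other columns untouched. Negative means are floored
#' at zero, then scaled to percent of the maximum importance (all zeros
#' stay zero).
#'
#' @param fit A [train_trait_model()] result.
#' @param x_test,y_test Test data.
#' @param n_repeats Permutations per feature (default 20).
#' @param seed Integer seed.
#' @return `data.frame` with `feature`, `raw`, `percent`.
#' @export
permutation_importance <- function(fit, x_test, y_test, n_repeats = 20,
                                   seed = 1L) {
  x_test <- as.matrix(x_test)
  if (nrow(x_test) < 2) stop("need at least 2 test samples")
  classification <- fit$task == "classification"
  metric_of <- function(xm) {
    pred <- stats::predict(fit$model, xm)
    m <- .model_metric(if (classification) pred else as.numeric(pred),
                       if (classification) y_test else as.numeric(y_test),
                       classification)
    if (is.na(m)) 0 else m
  }
  baseline <- metric_of(x_test)
  # permutations are drawn in a canonical sample order (sorted row names)
  # so the result does not depend on how the test rows happen to be sorted
  canon <- if (!is.null(rownames(x_test))) {
    order(rownames(x_test))
  } else {
    seq_len(nrow(x_test))
  }
  with_seed(seed, {
    raw <- vapply(seq_len(ncol(x_test)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x_test
        idx <- sample.int(nrow(xp))
        xp[canon, j] <- xp[canon[idx], j]
        baseline - metric_of(xp)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    raw <- pmax(raw, 0)
    pct <- if (max(raw) > 0) 100 * raw / max(raw) else raw
    data.frame(feature = colnames(x_test), raw = raw, percent = pct,
               stringsAsFactors = FALSE)
  })
}

#' Build the feature-trait importance network
#'
#' Bipartite graph linking each omics feature to each trait for which its
#' permutation importance reaches `include_threshold` percent. Feature
#' nodes whose best importance reaches `label_threshold` are flagged for
#' labeling; a supplementary table lists features at or above
#' `supplementary_threshold` for any trait.
#'
#' @param importances Named list, trait name -> `data.frame` from
#'   [permutation_importance()].
#' @param include_threshold Minimum percent importance for an edge
#'   (default 10).
#' @param label_threshold Percent importance from which a feature node is
#'   labeled (default 80).
#' @param supplementary_threshold Cutoff of the supplementary list
#'   (default 50).
#' @return List of class `importance_network`: `nodes` (`id`, `type`,
#'   `labeled`), `edges` (`feature`, `trait`, `importance_percent`),
#'   `supplementary`.
#' @export
build_importance_network <- function(importances, include_threshold = 10,
                                     label_threshold = 80,
                                     supplementary_threshold = 50) {
  stopifnot(is.list(importances), length(names(importances)) > 0)
  edges <- do.call(rbind, lapply(names(importances), function(tr) {
    imp <- importances[[tr]]
    keep <- imp$percent >= include_threshold
    if (!any(keep)) return(NULL)
    data.frame(feature = imp$feature[keep], trait = tr,
               importance_percent = imp$percent[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(feature = character(), trait = character(),
                        importance_percent = numeric(),
                        stringsAsFactors = FALSE)
  }
  feat <- unique(edges$feature)
  labeled <- vapply(feat, function(f) {
    any(edges$importance_percent[edges$feature == f] >= label_threshold)
  }, logical(1))
  nodes <- data.frame(id = names(importances), type = "trait",
                      labeled = TRUE, stringsAsFactors = FALSE)
  if (length(feat)) {
    nodes <- rbind(nodes, data.frame(id = feat, type = "feature",
                                     labeled = unname(labeled),
                                     stringsAsFactors = FALSE))
  }
  supp <- do.call(rbind, lapply(names(importances), function(tr) {
    imp <- importances[[tr]]
    keep <- imp$percent >= supplementary_threshold
    if (!any(keep)) return(NULL)
    data.frame(feature = imp$feature[keep], trait = tr,
               importance_percent = imp$percent[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(supp)) {
    supp <- edges[0, ]
  }
  structure(list(nodes = nodes, edges = edges, supplementary = supp),
            class = "importance_network")
}

#' @export
print.importance_network <- function(x, ...) {
  cat(sprintf(
    "importance_network: %d feature nodes (%d labeled), %d trait nodes, %d edges\n",
    sum(x$nodes$type == "feature"),
    sum(x$nodes$labeled & x$nodes$type == "feature"),
    sum(x$nodes$type == "trait"), nrow(x$edges)
  ))
  invisible(x)
}
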