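# Vectorized per-row two-group screens. These reproduce, row by row, what
# levene_test() and student_t_test() return; equality is asserted in the
# test suite.

row_pooled_t <- function(x, ia, ib) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(x[, ia, drop = FALSE])
  mb <- rowMeans(x[, ib, drop = FALSE])
  ssa <- rowSums((x[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((x[, ib, drop = FALSE] - mb)^2)
  df <- na + nb - 2
  sp2 <- (ssa + ssb) / df
  tval <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  zero <- sp2 <= 0
  equal <- abs(ma - mb) < .Machine$double.eps^0.5
  tval[zero & equal] <- 0
  tval[zero & !equal] <- NA_real_
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p[zero & equal] <- 1
  list(t = tval, p = p, df = df, degenerate = zero & !equal,
       mean_a = ma, mean_b = mb)
}

row_levene <- function(x, ia, ib, center = "mean") {
  ctr_fun <- if (center == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  za <- abs(x[, ia, drop = FALSE] - ctr_fun(x[, ia, drop = FALSE]))
  zb <- abs(x[, ib, drop = FALSE] - ctr_fun(x[, ib, drop = FALSE]))
  na <- length(ia); nb <- length(ib)
  n <- na + nb
  mza <- rowMeans(za); mzb <- rowMeans(zb)
  gm <- (na * mza + nb * mzb) / n
  ssb <- na * (mza - gm)^2 + nb * (mzb - gm)^2
  ssw <- rowSums((za - mza)^2) + rowSums((zb - mzb)^2)
  w <- (n - 2) * ssb / ssw
  p <- stats::pf(w, 1, n - 2, lower.tail = FALSE)
  flat <- ssw <= 0
  p[flat & ssb <= 0] <- 1
  w[flat & ssb <= 0] <- 0
  p[flat & ssb > 0] <- 0
  w[flat & ssb > 0] <- Inf
  list(w = w, p = p)
}

#' Differential screen of one omics layer
#'
#' Applies, per feature, the mean-centered Levene variance-homogeneity test
#' and the pooled two-sided Student t-test between the two groups, adjusts
#' the t-test p-values into Benjamini-Hochberg q-values across all tested
#' features of the layer, and flags as significant only features passing
#' the conjunctive gate: Levene p >= `alpha_levene` AND q < `q_threshold`.
#' Fold-change is the ratio of group means (case over control); for
#' methylation a delta of group mean betas is also reported.
#'
#' @param x An [omics_matrix()] (features x samples).
#' @param groups Character/factor of group labels per sample (exactly two
#'   levels present).
#' @param case,control The labels of the case and control groups. Defaults
#'   recognise `"case"`/`"control"`; otherwise supply them explicitly.
#' @param alpha_levene Levene gate level (default 0.05).
#' @param q_threshold FDR threshold on q-values (default 0.05).
#' @param levene_center `"mean"` (default) or `"median"`.
#' @return A `data.frame` of class `feature_stats` with columns `feature`,
#'   `layer`, `levene_p`, `t_stat`, `p_value`, `q_value`, `fold_change`,
#'   `delta_mean`, `significant`, `degenerate`. Features with missing
#'   values are excluded (recorded in the `dropped` attribute).
#' @export
run_differential <- function(x, groups,
                             case = "case", control = "control",
                             alpha_levene = 0.05, q_threshold = 0.05,
                             levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  groups <- as.character(groups)
  if (length(groups) != ncol(x)) {
    stop("`groups` must have one label per sample column")
  }
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two group labels must be present")
  if (!case %in% lev || !control %in% lev) {
    # fall back to treating the rarer group as control
    tabg <- sort(table(groups))
    control <- names(tabg)[1]
    case <- names(tabg)[2]
  }
  ia <- which(groups == case)
  ib <- which(groups == control)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs at least 2 samples")
  }

  keep <- !apply(x, 1, anyNA)
  dropped <- rownames(x)[!keep]
  if (length(dropped)) {
    message(sprintf("run_differential: dropping %d feature(s) with missing values",
                    length(dropped)))
  }
  xm <- x[keep, , drop = FALSE]

  tt <- row_pooled_t(xm, ia, ib)
  lv <- row_levene(xm, ia, ib, center = levene_center)
  q <- bh_adjust(tt$p)

  fc <- ifelse(abs(tt$mean_b) > 0, tt$mean_a / tt$mean_b, NA_real_)
  res <- data.frame(
    feature = rownames(xm),
    layer = omics_layer(x),
    levene_p = lv$p,
    t_stat = tt$t,
    p_value = tt$p,
    q_value = q,
    fold_change = fc,
    delta_mean = tt$mean_a - tt$mean_b,
    degenerate = tt$degenerate,
    stringsAsFactors = FALSE
  )
  res$significant <- !is.na(res$q_value) & !res$degenerate &
    res$levene_p >= alpha_levene & res$q_value < q_threshold
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  attr(res, "case") <- case
  attr(res, "control") <- control
  class(res) <- c("feature_stats", "data.frame")
  res
}

#' Genes altered in both omics layers
#'
#' Intersects the significant features of the methylation and expression
#' screens at the gene level: a gene qualifies when it has at least one
#' significant methylation site AND at least one significant transcript.
#' Per layer the significant/total feature counts and a majority direction
#' label (hypo/hypermethylated, under/overexpressed, from the sign of the
#' mean-difference of significant features) are reported.
#'
#' @param meth_stats,expr_stats `feature_stats` tables from
#'   [run_differential()] for the two layers.
#' @param feature_gene_map `data.frame` with columns `feature` and `gene`.
#' @return `data.frame` of class `cross_omics` with one row per overlapping
#'   gene and list-columns `meth_sig_features` / `expr_sig_features`
#'   carrying the contributing feature ids.
#' @export
cross_omics_overlap <- function(meth_stats, expr_stats, feature_gene_map) {
  map <- feature_gene_map
  stopifnot(all(c("feature", "gene") %in% names(map)))

  gene_of <- function(stats) {
    sig <- stats$feature[stats$significant]
    missing <- setdiff(sig, map$feature)
    if (length(missing)) {
      warning(sprintf("%d significant feature(s) absent from the gene map; ignored",
                      length(missing)))
    }
    map$gene[match(stats$feature, map$feature)]
  }
  gm <- gene_of(meth_stats)
  ge <- gene_of(expr_stats)

  sig_m <- unique(gm[meth_stats$significant & !is.na(gm)])
  sig_e <- unique(ge[expr_stats$significant & !is.na(ge)])
  genes <- sort(intersect(sig_m, sig_e))

  rows <- lapply(genes, function(g) {
    mi <- which(gm == g & !is.na(gm))
    ei <- which(ge == g & !is.na(ge))
    msig <- meth_stats[mi, ][meth_stats$significant[mi], ]
    esig <- expr_stats[ei, ][expr_stats$significant[ei], ]
    data.frame(
      gene = g,
      n_meth_sig = nrow(msig), n_meth_total = length(mi),
      n_expr_sig = nrow(esig), n_expr_total = length(ei),
      meth_direction = if (sum(sign(msig$delta_mean)) >= 0) "hypermethylated" else "hypomethylated",
      expr_direction = if (sum(sign(esig$delta_mean)) >= 0) "overexpressed" else "underexpressed",
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene = character(), n_meth_sig = integer(), n_meth_total = integer(),
    n_expr_sig = integer(), n_expr_total = integer(),
    meth_direction = character(), expr_direction = character(),
    stringsAsFactors = FALSE
  )
  out$meth_sig_features <- lapply(genes, function(g) {
    meth_stats$feature[meth_stats$significant & !is.na(gm) & gm == g]
  })
  out$expr_sig_features <- lapply(genes, function(g) {
    expr_stats$feature[expr_stats$significant & !is.na(ge) & ge == g]
  })
  class(out) <- c("cross_omics", "data.frame")
  out
}

#' Methylation-expression correlation for overlap genes
#'
#' For each gene altered in both layers, Pearson correlation across all
#' samples between the mean beta of its significant methylation sites and
#' the mean intensity of its significant transcripts, with the two-sided
#' t-based p-value; significant at `alpha`.
#'
#' @param overlap Output of [cross_omics_overlap()].
#' @param methylome,transcriptome The corresponding [omics_matrix()] objects.
#' @param alpha Significance level for `r_significant` (default 0.05).
#' @return `overlap` augmented with columns `r`, `r_p`, `r_significant`
#'   (`r` is `NA` and flagged when either mean profile has zero variance).
#' @export
meth_expr_correlation <- function(overlap, methylome, transcriptome,
                                  alpha = 0.05) {
  if (ncol(methylome) < 3) stop("at least 3 samples are required")
  n <- nrow(overlap)
  r <- rp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mfeat <- overlap$meth_sig_features[[i]]
    efeat <- overlap$expr_sig_features[[i]]
    if (!length(mfeat) || !length(efeat)) next
    mv <- colMeans(methylome[mfeat, , drop = FALSE])
    ev <- colMeans(transcriptome[efeat, , drop = FALSE])
    if (stats::sd(mv) == 0 || stats::sd(ev) == 0) next
    ct <- stats::cor.test(mv, ev, method = "pearson")
    r[i] <- unname(ct$estimate)
    rp[i] <- ct$p.value
  }
  overlap$r <- r
  overlap$r_p <- rp
  overlap$r_significant <- !is.na(rp) & rp < alpha
  overlap
}

#' Kendall concordance between two differential screens
#'
#' Used to check that the screen is not driven by a confounder: the screen
#' is re-run on a restricted subset (e.g. cases with high gestational age
#' only) and the per-feature t statistics of the full and restricted
#' screens are compared by Kendall's tau-b.
#'
#' @param stats_full,stats_subset `feature_stats` tables sharing a feature
#'   universe.
#' @param on Column to correlate, default `"t_stat"`.
#' @return List with `tau` and `p.value`.
#' @export
kendall_concordance <- function(stats_full, stats_subset, on = "t_stat") {
  shared <- intersect(stats_full$feature, stats_subset$feature)
  if (length(shared) < 2) stop("fewer than 2 shared features")
  a <- stats_full[[on]][match(shared, stats_full$feature)]
  b <- stats_subset[[on]][match(shared, stats_subset$feature)]
  ok <- is.finite(a) & is.finite(b)
  ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "kendall"))
  list(tau = unname(ct$estimate), p.value = ct$p.value)
}

#' Hierarchical clustering of samples on significant features
#'
#' Rows (features) are z-scored, samples are clustered by complete-linkage
#' agglomeration on Euclidean distances, and a two-cluster cut is reported
#' -- the unsupervised check that significant features separate cases from
#' controls.
#'
#' @param x Numeric matrix (features x samples), typically an
#'   [omics_matrix()] restricted to significant features.
#' @param k Number of clusters for the reported cut (default 2).
#' @return List with the `hclust` object (`tree`), `leaf_order` (sample ids
#'   in dendrogram order) and `clusters` (named cut assignment).
#' @export
hcluster_order <- function(x, k = 2) {
  if (anyNA(x)) stop("matrix contains missing values")
  if (ncol(x) < 2 || nrow(x) < 1) stop("need >= 2 samples and >= 1 feature")
  z <- x - rowMeans(x)
  sds <- apply(x, 1, stats::sd)
  sds[sds == 0] <- 1
  z <- z / sds
  tree <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                        method = "complete")
  list(
    tree = tree,
    leaf_order = colnames(x)[tree$order],
    clusters = stats::cutree(tree, k = min(k, ncol(x)))
  )
}
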