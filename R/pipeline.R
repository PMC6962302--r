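#' Pipeline configuration
#'
#' One structured object driving the whole analysis: input/output paths,
#' the screening thresholds, the text-mining parameters and the modeling
#' parameters, all seeded from one master seed (each stage derives its own
#' sub-seed via [derive_seed()]).
#'
#' @param out_dir Output directory for all stage files.
#' @param data_dir Directory holding `methylome.tsv`, `transcriptome.tsv`,
#'   `phenotypes.tsv`, `feature_gene_map.tsv`, `corpus.jsonl` (defaults to
#'   `file.path(out_dir, "data")`, where the simulate stage writes them).
#' @param sim A [sim_config()] used by the simulate stage.
#' @param alpha_levene,q_threshold Screen thresholds (defaults 0.05/0.05).
#' @param high_ga_cutoff Gestational-age cutoff (weeks) of the restricted
#'   concordance subset (default 37).
#' @param lsa_k LSA components (capped at the matrix rank; default 50 at
#'   synthetic scale).
#' @param k_clusters k-means clusters (default 4 at synthetic scale;
#'   capped at the number of annotated genes).
#' @param top_m Summary terms per cluster (default 10).
#' @param min_df Term document-frequency pruning threshold (default 2).
#' @param train_ratio Training fraction of the stratified split (default
#'   2/3).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param cv_folds Grid-search CV folds (default 5).
#' @param n_repeats Permutation-importance repeats (default 20).
#' @param include_threshold,label_threshold,supplementary_threshold
#'   Network thresholds in percent (defaults 10/80/50).
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            data_dir = file.path(out_dir, "data"),
                            sim = sim_config(),
                            alpha_levene = 0.05, q_threshold = 0.05,
                            high_ga_cutoff = 37,
                            lsa_k = 50, k_clusters = 4, top_m = 10,
                            min_df = 2,
                            train_ratio = 2 / 3, smote_k = 5,
                            cv_folds = 5, n_repeats = 20,
                            include_threshold = 10, label_threshold = 80,
                            supplementary_threshold = 50,
                            seed = 1L) {
  stopifnot(alpha_levene > 0, alpha_levene < 1,
            q_threshold > 0, q_threshold < 1,
            include_threshold >= 0, include_threshold <= 100,
            label_threshold >= 0, label_threshold <= 100,
            train_ratio > 0, train_ratio < 1)
  cfg <- as.list(environment())
  cfg$sim$seed <- derive_seed(seed, "simulate")
  structure(cfg, class = "pipeline_config")
}

read_stage_inputs <- function(cfg, need = c("matrices", "phenotypes",
                                            "map", "corpus")) {
  d <- cfg$data_dir
  req <- function(fname) {
    p <- file.path(d, fname)
    if (!file.exists(p)) {
      stop(sprintf("missing input %s; run the simulate stage (or point data_dir at existing study files)", p))
    }
    p
  }
  out <- list()
  if ("matrices" %in% need) {
    out$methylome <- read_omics_matrix(req("methylome.tsv"), "methylation")
    out$transcriptome <- read_omics_matrix(req("transcriptome.tsv"), "expression")
  }
  if ("phenotypes" %in% need) {
    out$phenotypes <- utils::read.delim(req("phenotypes.tsv"),
                                        stringsAsFactors = FALSE)
  }
  if ("map" %in% need) {
    out$map <- utils::read.delim(req("feature_gene_map.tsv"),
                                 stringsAsFactors = FALSE)
  }
  if ("corpus" %in% need) {
    out$corpus <- read_corpus_jsonl(req("corpus.jsonl"))
  }
  out
}

#' Run the simulate stage
#'
#' Generates the synthetic study and corpus and writes them under
#' `data_dir`.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, counts for the run report.
#' @export
stage_simulate <- function(cfg) {
  study <- simulate_omics_cohort(cfg$sim)
  corpus <- simulate_annotation_corpus(cfg$sim)
  write_study(study, cfg$data_dir, corpus = corpus)
  invisible(list(
    n_samples = nrow(study$phenotypes),
    n_meth_features = nrow(study$methylome),
    n_expr_features = nrow(study$transcriptome),
    n_genes = length(corpus$docs)
  ))
}

#' Run the differential stage
#'
#' Screens both layers, writes the per-feature statistics, the cross-omics
#' overlap with methylation-expression correlations, the sample dendrogram
#' orders, and the gestational-age-restricted Kendall concordance check.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, counts/statistics for the run report.
#' @export
stage_diff <- function(cfg) {
  inp <- read_stage_inputs(cfg, c("matrices", "phenotypes", "map"))
  grp <- inp$phenotypes$group
  ms <- run_differential(inp$methylome, grp,
                         alpha_levene = cfg$alpha_levene,
                         q_threshold = cfg$q_threshold)
  es <- run_differential(inp$transcriptome, grp,
                         alpha_levene = cfg$alpha_levene,
                         q_threshold = cfg$q_threshold)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(ms), file.path(cfg$out_dir, "meth_stats.tsv"))
  write_tsv(as.data.frame(es), file.path(cfg$out_dir, "expr_stats.tsv"))

  ov <- cross_omics_overlap(ms, es, inp$map)
  ov <- meth_expr_correlation(ov, inp$methylome, inp$transcriptome)
  ov_flat <- ov
  ov_flat$meth_sig_features <- vapply(ov$meth_sig_features, paste,
                                      character(1), collapse = ",")
  ov_flat$expr_sig_features <- vapply(ov$expr_sig_features, paste,
                                      character(1), collapse = ",")
  write_tsv(as.data.frame(ov_flat), file.path(cfg$out_dir, "overlap.tsv"))

  # confounder check: drop low-gestational-age cases and compare t-stats
  keep <- inp$phenotypes$group == "control" |
    inp$phenotypes$gestational_age >= cfg$high_ga_cutoff
  conc <- list(meth = NULL, expr = NULL)
  if (sum(keep & grp == "case") >= 2) {
    ms_sub <- run_differential(
      omics_matrix(unclass(inp$methylome)[, keep, drop = FALSE], "methylation"),
      grp[keep], alpha_levene = cfg$alpha_levene, q_threshold = cfg$q_threshold)
    es_sub <- run_differential(
      omics_matrix(unclass(inp$transcriptome)[, keep, drop = FALSE], "expression"),
      grp[keep], alpha_levene = cfg$alpha_levene, q_threshold = cfg$q_threshold)
    conc$meth <- kendall_concordance(ms, ms_sub)
    conc$expr <- kendall_concordance(es, es_sub)
  }

  hc <- list()
  for (layer in c("meth", "expr")) {
    st <- if (layer == "meth") ms else es
    mat <- if (layer == "meth") inp$methylome else inp$transcriptome
    sig <- st$feature[st$significant]
    if (length(sig) >= 1) {
      ord <- hcluster_order(unclass(mat)[sig, , drop = FALSE])
      hc[[layer]] <- ord
      write_tsv(
        data.frame(sample = names(ord$clusters), cluster = ord$clusters,
                   position = match(names(ord$clusters), ord$leaf_order)),
        file.path(cfg$out_dir, sprintf("hcluster_%s.tsv", layer))
      )
    }
  }

  invisible(list(
    n_sig_meth = sum(ms$significant), n_sig_expr = sum(es$significant),
    n_tested_meth = nrow(ms), n_tested_expr = nrow(es),
    n_overlap_genes = nrow(ov),
    n_overlap_r_significant = sum(ov$r_significant, na.rm = TRUE),
    kendall = conc
  ))
}

#' Run the text-mining stage
#'
#' Restricts the corpus to significant genes (when screen outputs exist;
#' otherwise uses the whole corpus), builds the tf-idf matrix, fits the
#' LSA, clusters genes and writes the cluster report.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, counts for the run report.
#' @export
stage_textmine <- function(cfg) {
  inp <- read_stage_inputs(cfg, c("corpus", "map"))
  stats_path <- file.path(cfg$out_dir, "meth_stats.tsv")
  docs <- inp$corpus$docs
  if (file.exists(stats_path)) {
    ms <- utils::read.delim(stats_path, stringsAsFactors = FALSE)
    es <- utils::read.delim(file.path(cfg$out_dir, "expr_stats.tsv"),
                            stringsAsFactors = FALSE)
    sig_feat <- c(ms$feature[ms$significant], es$feature[es$significant])
    sig_genes <- unique(inp$map$gene[inp$map$feature %in% sig_feat])
    docs <- docs[names(docs) %in% sig_genes]
    if (length(docs) < 2) {
      stop("fewer than 2 significant genes have annotations; run `diff` first or check thresholds")
    }
  }
  tm <- build_term_matrix(docs, min_df = cfg$min_df)
  k <- min(cfg$lsa_k, min(dim(tm$M)))
  lsa <- fit_lsa(tm, k)
  kc <- min(cfg$k_clusters, length(lsa$genes))
  labels <- cluster_genes(lsa, kc, seed = derive_seed(cfg$seed, "textmine"))
  rep <- summarize_clusters(lsa, labels, top_m = cfg$top_m)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_term_matrix(tm, file.path(cfg$out_dir, "term_matrix.tsv"),
                    file.path(cfg$out_dir, "vocabulary.tsv"))
  write_tsv(data.frame(gene = names(labels), cluster = as.integer(labels)),
            file.path(cfg$out_dir, "gene_clusters.tsv"))
  write_tsv(rep$terms, file.path(cfg$out_dir, "cluster_terms.tsv"))
  invisible(list(
    n_annotated_genes = length(tm$total_terms),
    n_terms = nrow(tm$M),
    lsa_k = k, retained_variance = lsa$retained_variance,
    n_clusters = nrow(rep$sizes)
  ))
}

#' Run the prediction stage
#'
#' Selects significant features, splits samples with stratification,
#' standardizes on training statistics, SMOTE-augments the training set,
#' grid-search trains one SVM per trait on a shared split, evaluates on
#' the untouched test set and computes permutation importances.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, per-trait metrics for the run report.
#' @export
stage_predict <- function(cfg) {
  inp <- read_stage_inputs(cfg, c("matrices", "phenotypes"))
  ms <- utils::read.delim(file.path(cfg$out_dir, "meth_stats.tsv"),
                          stringsAsFactors = FALSE)
  es <- utils::read.delim(file.path(cfg$out_dir, "expr_stats.tsv"),
                          stringsAsFactors = FALSE)
  if (!nrow(ms)) stop("empty meth_stats.tsv; run the diff stage first")
  feats <- select_features(ms, es)
  ph <- derive_traits(inp$phenotypes)

  xall <- t(rbind(unclass(inp$methylome)[intersect(feats, rownames(inp$methylome)), ,
                                         drop = FALSE],
                  unclass(inp$transcriptome)[intersect(feats, rownames(inp$transcriptome)), ,
                                             drop = FALSE]))
  sp <- stratified_split(ph$sample, ph$group, ratio = cfg$train_ratio,
                         seed = derive_seed(cfg$seed, "split"))
  itr <- match(sp$train, ph$sample)
  ite <- match(sp$test, ph$sample)
  xtr <- xall[itr, , drop = FALSE]
  xte <- xall[ite, , drop = FALSE]
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xtr <- scale(xtr, mu, sdv)
  xte <- scale(xte, mu, sdv)

  specs <- trait_specs()
  models <- list(); evals <- list(); imps <- list()
  for (i in seq_len(nrow(specs))) {
    tr_name <- specs$name[i]
    task <- specs$task[i]
    seed_t <- derive_seed(cfg$seed, paste0("model_", tr_name))
    if (task == "classification") {
      y_tr <- factor(ph$group[itr], levels = c("control", "case"))
      aug <- smote_augment(xtr, y_tr, k = cfg$smote_k, seed = seed_t)
      fit <- train_trait_model(aug$x, aug$y, task, cv_folds = cfg$cv_folds,
                               seed = seed_t)
      ev <- evaluate_model(fit, xte, ph$group[ite])
    } else {
      y_tr <- ph[[tr_name]][itr]
      aug <- smote_augment(xtr, y_tr, group = ph$group[itr],
                           k = cfg$smote_k, seed = seed_t)
      fit <- train_trait_model(aug$x, aug$y, task, cv_folds = cfg$cv_folds,
                               seed = seed_t)
      ev <- evaluate_model(fit, xte, ph[[tr_name]][ite])
    }
    imp <- permutation_importance(fit, xte,
                                  if (task == "classification")
                                    ph$group[ite] else ph[[tr_name]][ite],
                                  n_repeats = cfg$n_repeats, seed = seed_t)
    models[[tr_name]] <- fit
    evals[[tr_name]] <- ev
    imps[[tr_name]] <- imp
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(do.call(rbind, lapply(names(models), function(nm) {
    bp <- models[[nm]]$best_params
    data.frame(trait = nm, task = models[[nm]]$task, kernel = bp$kernel,
               cost = bp$cost, gamma = bp$gamma, epsilon = bp$epsilon,
               metric = evals[[nm]]$metric, p_value = evals[[nm]]$p.value,
               stringsAsFactors = FALSE)
  })), file.path(cfg$out_dir, "trait_models.tsv"))
  write_tsv(do.call(rbind, lapply(names(evals), function(nm) {
    pr <- evals[[nm]]$predictions
    if (!"prob_case" %in% names(pr)) pr$prob_case <- NA_real_
    cbind(trait = nm, pr)
  })), file.path(cfg$out_dir, "predictions.tsv"))
  write_tsv(do.call(rbind, lapply(names(imps), function(nm) {
    cbind(trait = nm, imps[[nm]])
  })), file.path(cfg$out_dir, "importance.tsv"))

  invisible(list(
    n_features = ncol(xall),
    train = sp$train, test = sp$test,
    metrics = lapply(evals, function(e) list(metric = e$metric,
                                             p.value = e$p.value))
  ))
}

#' Run the network stage
#'
#' Builds the feature-trait importance network from `importance.tsv` and
#' writes SIF, GraphML and the supplementary high-importance table.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, counts for the run report.
#' @export
stage_network <- function(cfg) {
  imp_path <- file.path(cfg$out_dir, "importance.tsv")
  if (!file.exists(imp_path)) {
    stop(sprintf("missing %s; run the predict stage first", imp_path))
  }
  imp <- utils::read.delim(imp_path, stringsAsFactors = FALSE)
  imps <- split(imp[, c("feature", "raw", "percent")], imp$trait)
  net <- build_importance_network(
    imps,
    include_threshold = cfg$include_threshold,
    label_threshold = cfg$label_threshold,
    supplementary_threshold = cfg$supplementary_threshold
  )
  write_network(net, file.path(cfg$out_dir, "network.sif"),
                file.path(cfg$out_dir, "network.graphml"))
  write_tsv(net$supplementary,
            file.path(cfg$out_dir, "importance_supplementary.tsv"))
  invisible(list(
    n_feature_nodes = sum(net$nodes$type == "feature"),
    n_labeled = sum(net$nodes$labeled & net$nodes$type == "feature"),
    n_edges = nrow(net$edges)
  ))
}

#' Run the full pipeline
#'
#' simulate (optional) -> differential -> text-mining -> models ->
#' network, writing every stage output plus a JSON run report with the
#' derived sub-seeds, per-stage counts and model metrics.
#'
#' @param cfg A [pipeline_config()].
#' @param simulate Run the simulate stage first (default `TRUE`; set
#'   `FALSE` to analyze existing files under `data_dir`).
#' @return The run report, invisibly; also written to
#'   `file.path(out_dir, "run_report.json")`.
#' @export
run_pipeline <- function(cfg, simulate = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("placmine")),
    master_seed = cfg$seed,
    sub_seeds = list(
      simulate = cfg$sim$seed,
      textmine = derive_seed(cfg$seed, "textmine"),
      split = derive_seed(cfg$seed, "split"),
      models = lapply(stats::setNames(nm = trait_specs()$name), function(nm)
        derive_seed(cfg$seed, paste0("model_", nm)))
    )
  )
  if (simulate) {
    message("stage simulate")
    report$simulate <- stage_simulate(cfg)
  }
  message("stage diff")
  report$diff <- stage_diff(cfg)
  message(sprintf("  significant: %d methylation sites, %d transcripts; %d overlap genes",
                  report$diff$n_sig_meth, report$diff$n_sig_expr,
                  report$diff$n_overlap_genes))
  message("stage textmine")
  report$textmine <- stage_textmine(cfg)
  message(sprintf("  %d genes, %d terms, %d clusters",
                  report$textmine$n_annotated_genes, report$textmine$n_terms,
                  report$textmine$n_clusters))
  message("stage predict")
  report$predict <- stage_predict(cfg)
  message("stage network")
  report$network <- stage_network(cfg)
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
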