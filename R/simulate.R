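#' Simulation configuration for a synthetic IUGR case-control study
#'
#' Bundles every knob of the synthetic cohort and corpus generators. The
#' defaults encode the study conditions the generator emulates: an 8
#' control / 28 IUGR placenta cohort with gestational ages 38.7 +/- 0.7 vs
#' 34.0 +/- 3.9 weeks, birth-weight Z-scores -0.07 +/- 0.89 vs
#' -2.02 +/- 0.75 and head-circumference Z-scores 0.22 +/- 0.49 vs
#' -1.30 +/- 0.86, planted differential CpGs with a hypomethylation bias,
#' planted differential transcripts with balanced direction, a
#' gestational-age mixture creating two IUGR sub-clusters, traits linear in
#' a subset of planted features, and a topic-structured abstract corpus.
#'
#' @param n_control,n_case Group sizes (default 8 / 28).
#' @param n_meth_features,n_expr_features Features per layer (default 2000
#'   each, a desk-scale stand-in for array-scale matrices).
#' @param n_diff_meth,n_diff_expr Planted differential feature counts
#'   (default 200 CpGs / 120 transcripts).
#' @param hypometh_fraction Fraction of planted CpGs shifted downward in
#'   cases (default 0.75, a global-hypomethylation bias).
#' @param delta_beta Planted beta-scale mean shift (default 0.4).
#' @param log2fc Planted expression log2 fold-change (default 1.5).
#' @param meth_noise_sd,expr_noise_sd Residual SD on the logit-beta and
#'   log2-intensity scales (default 0.5 each).
#' @param ga_control_mean,ga_control_sd,ga_case_mean,ga_case_sd Gestational
#'   age moments in weeks (defaults 38.7/0.7 and 34.0/3.9).
#' @param ga_coupling Logit-scale shift distinguishing the two IUGR
#'   sub-clusters on trait-signal features (default 0.3).
#' @param trait_signal_features Number of planted features per layer that
#'   carry the trait signal and the sub-cluster structure (default 40).
#' @param trait_r2 Within-group fraction of trait variance explained by the
#'   trait-signal features (default 0.6).
#' @param bw_control,bw_case,hc_control,hc_case Length-2 `c(mean, sd)`
#'   vectors of the birth-weight and head-circumference Z-score moments.
#' @param n_overlap_genes Number of genes planted in both layers (default
#'   6); these carry the cross-layer coupling.
#' @param n_genes Genes in the map/corpus (default 200).
#' @param n_topics Latent topics of the corpus (default 4).
#' @param abstracts_per_gene_range Inclusive integer range for the number
#'   of abstracts per gene (default `c(8, 15)`).
#' @param vocab_size Number of distinct pseudo-stems (default 120).
#' @param topic_mix Probability that a content token is drawn from the
#'   gene's topic pool rather than the background pool (default 0.7).
#' @param coupling_sd SD of the shared per-sample latent coupling the
#'   methylation and expression of genes planted in both layers (default
#'   0.35; drives the planted anti-correlation).
#' @param seed Master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_control = 8, n_case = 28,
                       n_meth_features = 2000, n_expr_features = 2000,
                       n_diff_meth = 200, n_diff_expr = 120,
                       hypometh_fraction = 0.75,
                       delta_beta = 0.4, log2fc = 1.5,
                       meth_noise_sd = 0.5, expr_noise_sd = 0.5,
                       ga_control_mean = 38.7, ga_control_sd = 0.7,
                       ga_case_mean = 34.0, ga_case_sd = 3.9,
                       ga_coupling = 0.3,
                       trait_signal_features = 40, trait_r2 = 0.6,
                       bw_control = c(-0.07, 0.89), bw_case = c(-2.02, 0.75),
                       hc_control = c(0.22, 0.49), hc_case = c(-1.30, 0.86),
                       n_overlap_genes = 6,
                       n_genes = 200, n_topics = 4,
                       abstracts_per_gene_range = c(8, 15),
                       vocab_size = 120, topic_mix = 0.7,
                       coupling_sd = 0.35,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_control", "n_case", "n_meth_features", "n_expr_features",
              "n_diff_meth", "n_diff_expr", "trait_signal_features",
              "n_overlap_genes", "n_genes", "n_topics", "vocab_size")
  for (nm in counts) {
    if (cfg[[nm]] < 0 || cfg[[nm]] != round(cfg[[nm]])) {
      stop(sprintf("`%s` must be a nonnegative integer", nm))
    }
  }
  if (n_control + n_case < 4) stop("n_control + n_case must be >= 4")
  if (n_diff_meth > n_meth_features) stop("n_diff_meth exceeds n_meth_features")
  if (n_diff_expr > n_expr_features) stop("n_diff_expr exceeds n_expr_features")
  if (hypometh_fraction < 0 || hypometh_fraction > 1) {
    stop("hypometh_fraction must lie in [0, 1]")
  }
  if (delta_beta < 0 || log2fc < 0) stop("effect sizes must be nonnegative")
  if (delta_beta >= 1) stop("delta_beta must be < 1 (beta scale)")
  if (vocab_size < n_topics) stop("vocab_size must be >= n_topics")
  if (length(abstracts_per_gene_range) != 2 ||
      abstracts_per_gene_range[1] > abstracts_per_gene_range[2] ||
      abstracts_per_gene_range[1] < 1) {
    stop("abstracts_per_gene_range must be an increasing positive pair")
  }
  if (trait_r2 < 0 || trait_r2 > 1) stop("trait_r2 must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d control / %d case; %d CpGs (%d planted), %d probes (%d planted); %d genes, %d topics; seed %d\n",
    x$n_control, x$n_case, x$n_meth_features, x$n_diff_meth,
    x$n_expr_features, x$n_diff_expr, x$n_genes, x$n_topics, x$seed
  ))
  invisible(x)
}

gene_symbols <- function(n) sprintf("G%04d", seq_len(n))

# Gestational-age mixture for the case group: two components (an early
# severe and a near-term mild sub-cluster) whose pooled mean and SD match
# the configured case moments. Component SDs are fixed at 2.0 and 1.0
# weeks; the separation is solved from the target SD.
case_ga_components <- function(mean, sd) {
  s1 <- 2.0; s2 <- 1.0
  extra <- sd^2 - 0.5 * (s1^2 + s2^2)
  half <- if (extra > 0) sqrt(extra) else 0.1
  list(means = c(mean - half, mean + half), sds = c(s1, s2))
}

#' Simulate a synthetic case-control omics study
#'
#' Generates a full study with known planted structure. Null methylation
#' features are logit-normal around a feature-specific baseline shared by
#' both groups; planted CpGs shift the case-group mean by `+-delta_beta`
#' on the beta scale (a `hypometh_fraction` of them downward). Expression
#' is log2-normal with planted `+-log2fc` shifts of balanced direction.
#' Case gestational ages come from a two-component mixture and the
#' trait-signal features are shifted oppositely in the two components, so
#' hierarchical clustering of planted features yields gestational-age
#' separated IUGR sub-clusters. Birth-weight and head-circumference
#' Z-scores are linear in the trait-signal features plus noise, with group
#' moments matching the configured cohort description. Genes planted in
#' both layers share a latent sample effect inducing a negative
#' methylation-expression correlation.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_study` with elements `methylome`,
#'   `transcriptome` ([omics_matrix()]), `phenotypes` (`data.frame`),
#'   `feature_gene_map`, `truth` (planted feature ids with directions,
#'   trait features, overlap genes, GA components) and `config`. The
#'   corpus is generated separately by [simulate_annotation_corpus()].
#' @export
simulate_omics_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_control + cfg$n_case
    samples <- sprintf("S%02d", seq_len(n))
    group <- rep(c("control", "case"), c(cfg$n_control, cfg$n_case))
    is_case <- group == "case"

    # --- gestational age -------------------------------------------------
    ga <- numeric(n)
    ga[!is_case] <- stats::rnorm(cfg$n_control, cfg$ga_control_mean,
                                 cfg$ga_control_sd)
    comp <- rep(NA_integer_, n)
    mix <- case_ga_components(cfg$ga_case_mean, cfg$ga_case_sd)
    comp[is_case] <- rep_len(c(1L, 2L), cfg$n_case)[sample(cfg$n_case)]
    ga[is_case] <- stats::rnorm(cfg$n_case, mix$means[comp[is_case]],
                                mix$sds[comp[is_case]])
    ga <- pmin(pmax(ga, 24), 42)

    # --- gene map (blockwise feature -> gene) ----------------------------
    genes <- gene_symbols(cfg$n_genes)
    meth_ids <- sprintf("cg%06d", seq_len(cfg$n_meth_features))
    expr_ids <- sprintf("PR%06d", seq_len(cfg$n_expr_features))
    # block allocation so planted features concentrate on the first genes
    meth_gene <- genes[pmin(ceiling(seq_len(cfg$n_meth_features) /
                                      (cfg$n_meth_features / cfg$n_genes)),
                            cfg$n_genes)]
    expr_gene <- genes[pmin(ceiling(seq_len(cfg$n_expr_features) /
                                      (cfg$n_expr_features / cfg$n_genes)),
                            cfg$n_genes)]

    planted_m <- seq_len(cfg$n_diff_meth)
    # expression planting overlaps only the tail of the methylation-planted
    # genes (n_overlap_genes shared), then extends into fresh genes, so the
    # study has meth-only, expr-only and dual-layer genes -- and the
    # trait-signal features (drawn from the non-shared ends) stay clear of
    # the cross-layer coupling noise
    g_m_planted <- unique(meth_gene[planted_m])
    n_ov <- min(cfg$n_overlap_genes, length(g_m_planted))
    start_gene <- if (n_ov > 0) {
      match(g_m_planted[length(g_m_planted) - n_ov + 1], genes)
    } else {
      length(g_m_planted) + 1
    }
    cand_genes <- genes[seq(min(start_gene, cfg$n_genes), cfg$n_genes)]
    cand_genes <- c(cand_genes, setdiff(genes, cand_genes))
    cand_idx <- unlist(lapply(cand_genes, function(g) which(expr_gene == g)))
    planted_e <- sort(cand_idx[seq_len(cfg$n_diff_expr)])
    overlap_genes <- intersect(unique(meth_gene[planted_m]),
                               unique(expr_gene[planted_e]))

    # --- planted directions ---------------------------------------------
    # hypermethylated features first: the leading (trait-signal) genes are
    # hypermethylated, the tail -- including the dual-layer genes -- is
    # hypomethylated, giving the configured global hypomethylation bias
    n_hypo <- round(cfg$hypometh_fraction * cfg$n_diff_meth)
    dir_m <- rep(-1, cfg$n_diff_meth)
    if (cfg$n_diff_meth > 0) dir_m[seq_len(cfg$n_diff_meth - n_hypo)] <- 1
    # expression: overlap genes overexpressed (mirroring the hypomethylated/
    # overexpressed pattern), remaining planted probes alternate direction
    dir_e <- rep(1, cfg$n_diff_expr)
    if (cfg$n_diff_expr > 0) {
      in_overlap <- expr_gene[planted_e] %in% overlap_genes
      dir_e[!in_overlap] <- rep_len(c(1, -1), sum(!in_overlap))
      k_rest <- sum(!in_overlap)
      # keep overall directions roughly balanced
      n_up_needed <- floor(cfg$n_diff_expr / 2) - sum(in_overlap)
      if (k_rest > 0) {
        dir_e[!in_overlap] <- c(rep(1, max(0, n_up_needed)),
                                rep(-1, k_rest - max(0, n_up_needed)))
      }
    }

    # --- methylation matrix (logit-normal) -------------------------------
    mu_m <- stats::rnorm(cfg$n_meth_features, 0, 1.5)
    # planted baselines sit symmetric about 0.5 (hypermethylated features
    # start low and end high, hypomethylated the reverse) so the planted
    # shift leaves the beta-scale variance unchanged between groups and
    # the Levene gate sees homogeneous variances
    base_beta_planted <- 0.5 - dir_m * cfg$delta_beta / 2 +
      stats::runif(cfg$n_diff_meth, -0.03, 0.03)
    mu_m[planted_m] <- stats::qlogis(base_beta_planted)
    logit_meth <- matrix(mu_m, cfg$n_meth_features, n) +
      matrix(stats::rnorm(cfg$n_meth_features * n, 0, cfg$meth_noise_sd),
             cfg$n_meth_features, n)

    if (cfg$n_diff_meth > 0) {
      target <- pmin(pmax(base_beta_planted + dir_m * cfg$delta_beta,
                          0.02), 0.98)
      delta_logit <- stats::qlogis(target) - stats::qlogis(base_beta_planted)
      logit_meth[planted_m, is_case] <-
        logit_meth[planted_m, is_case, drop = FALSE] + delta_logit
      # sub-cluster structure: trait-signal features shifted oppositely in
      # the two gestational-age components (severe component more extreme)
      tsf_m <- planted_m[seq_len(min(cfg$trait_signal_features,
                                     cfg$n_diff_meth))]
      comp_sign <- ifelse(comp[is_case] == 1L, 1, -1)
      shift <- outer(sign(delta_logit[match(tsf_m, planted_m)]),
                     comp_sign) * cfg$ga_coupling
      logit_meth[tsf_m, is_case] <-
        logit_meth[tsf_m, is_case, drop = FALSE] + shift
    } else {
      tsf_m <- integer(0)
    }

    # --- expression matrix (log2-normal) ---------------------------------
    mu_e <- stats::rnorm(cfg$n_expr_features, 8, 1.5)
    log2_expr <- matrix(mu_e, cfg$n_expr_features, n) +
      matrix(stats::rnorm(cfg$n_expr_features * n, 0, cfg$expr_noise_sd),
             cfg$n_expr_features, n)
    if (cfg$n_diff_expr > 0) {
      log2_expr[planted_e, is_case] <-
        log2_expr[planted_e, is_case, drop = FALSE] + dir_e * cfg$log2fc
      n_tsf_e <- min(cfg$trait_signal_features, cfg$n_diff_expr)
      tsf_e <- planted_e[seq(to = cfg$n_diff_expr, length.out = n_tsf_e)]
      comp_sign <- ifelse(comp[is_case] == 1L, 1, -1)
      # severe component more extreme in the planted direction
      shift_e <- outer(dir_e[match(tsf_e, planted_e)], comp_sign) *
        cfg$ga_coupling
      log2_expr[tsf_e, is_case] <-
        log2_expr[tsf_e, is_case, drop = FALSE] + shift_e
    }

    # --- cross-layer coupling for overlap genes --------------------------
    if (length(overlap_genes) && cfg$coupling_sd > 0) {
      for (g in overlap_genes) {
        u <- stats::rnorm(n, 0, cfg$coupling_sd)
        mrows <- planted_m[meth_gene[planted_m] == g]
        erows <- planted_e[expr_gene[planted_e] == g]
        # anti-correlated coupling: methylation up <-> expression down
        logit_meth[mrows, ] <- logit_meth[mrows, , drop = FALSE] +
          rep(u, each = length(mrows))
        log2_expr[erows, ] <- log2_expr[erows, , drop = FALSE] -
          rep(u, each = length(erows))
      }
    }

    beta <- stats::plogis(logit_meth)
    dimnames(beta) <- list(meth_ids, samples)
    # the transcriptome is emitted on the normalized log2-intensity scale
    # (the standard container for expression arrays); values stay positive
    expr <- pmax(log2_expr, 0.01)
    dimnames(expr) <- list(expr_ids, samples)

    # --- traits linear in trait-signal features --------------------------
    # severity score: projection of each sample onto the planted effect
    # direction of the trait-signal CpGs (more extreme -> more severe)
    sev <- if (length(tsf_m)) {
      colSums(logit_meth[tsf_m, , drop = FALSE] *
                -dir_m[match(tsf_m, planted_m)]) / length(tsf_m)
    } else {
      stats::rnorm(n)
    }
    z_within <- numeric(n)
    for (g in c(FALSE, TRUE)) {
      idx <- is_case == g
      z_within[idx] <- as.numeric(scale(sev[idx]))
    }
    make_trait <- function(mom_control, mom_case) {
      mu <- ifelse(is_case, mom_case[1], mom_control[1])
      sdv <- ifelse(is_case, mom_case[2], mom_control[2])
      eps <- stats::rnorm(n)
      # higher severity score -> lower growth Z-score
      mu + sdv * (-sqrt(cfg$trait_r2) * z_within +
                    sqrt(1 - cfg$trait_r2) * eps)
    }
    bw_z <- make_trait(cfg$bw_control, cfg$bw_case)
    hc_z <- make_trait(cfg$hc_control, cfg$hc_case)

    phenotypes <- data.frame(
      sample = samples,
      group = group,
      gestational_age = ga,
      premature_birth = 39 - ga,
      birth_weight_z = bw_z,
      head_circumference_z = hc_z,
      stringsAsFactors = FALSE
    )

    truth <- list(
      meth = data.frame(
        feature = meth_ids[planted_m],
        direction = if (cfg$n_diff_meth) dir_m else numeric(0),
        stringsAsFactors = FALSE
      ),
      expr = data.frame(
        feature = expr_ids[planted_e],
        direction = if (cfg$n_diff_expr) dir_e else numeric(0),
        stringsAsFactors = FALSE
      ),
      trait_features_meth = meth_ids[tsf_m],
      trait_features_expr = if (cfg$n_diff_expr > 0) {
        n_tsf_e <- min(cfg$trait_signal_features, cfg$n_diff_expr)
        expr_ids[planted_e[seq(to = cfg$n_diff_expr, length.out = n_tsf_e)]]
      } else character(0),
      overlap_genes = overlap_genes,
      ga_component = stats::setNames(comp, samples)
    )

    structure(list(
      methylome = omics_matrix(beta, "methylation"),
      transcriptome = omics_matrix(expr, "expression"),
      phenotypes = phenotypes,
      feature_gene_map = data.frame(
        feature = c(meth_ids, expr_ids),
        gene = c(meth_gene, expr_gene),
        layer = rep(c("methylation", "expression"),
                    c(cfg$n_meth_features, cfg$n_expr_features)),
        stringsAsFactors = FALSE
      ),
      truth = truth,
      config = cfg
    ), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d samples (%d control / %d case); %d CpGs, %d probes; %d planted CpGs, %d planted probes, %d overlap genes\n",
    nrow(x$phenotypes), sum(x$phenotypes$group == "control"),
    sum(x$phenotypes$group == "case"),
    nrow(x$methylome), nrow(x$transcriptome),
    nrow(x$truth$meth), nrow(x$truth$expr), length(x$truth$overlap_genes)
  ))
  invisible(x)
}
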