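test_that("porter_stem reproduces the canonical step examples", {
  pairs <- c(
    caresses = "caress", ponies = "poni", ties = "ti", caress = "caress",
    cats = "cat", feed = "feed", agreed = "agre", plastered = "plaster",
    bled = "bled", motoring = "motor", sing = "sing", troubled = "troubl",
    sized = "size", hopping = "hop", tanned = "tan", falling = "fall",
    hissing = "hiss", fizzed = "fizz", failing = "fail", filing = "file",
    happy = "happi", sky = "sky", relational = "relat",
    conditional = "condit", rational = "ration", connection = "connect",
    connections = "connect", running = "run", flying = "fly",
    university = "univers", probability = "probabl",
    generalization = "gener", oscillators = "oscil",
    controlling = "control", roll = "roll"
  )
  expect_equal(porter_stem(names(pairs)), unname(pairs))
})

test_that("preprocess_text lowercases, filters and stems", {
  expect_equal(preprocess_text("the"), character(0))
  expect_equal(preprocess_text(""), character(0))
  # punctuation stripped, short words and stop words dropped, stems applied
  toks <- preprocess_text("Placental growth; the placentas are GROWING!")
  expect_equal(toks, c("placent", "growth", "placenta", "grow"))
  # no token of length <= 3 and no stop word survives
  txt <- "We saw that the cell is a very small unit of life in biology"
  out <- preprocess_text(txt)
  expect_false(any(out %in% stopwords_en))
  # two passes reach a fixpoint
  once <- preprocess_text(paste(out, collapse = " "))
  twice <- preprocess_text(paste(once, collapse = " "))
  expect_identical(once, twice)
})

test_that("tf-idf matches a hand-computed three-document worksheet", {
  # summaries (already clean stems, unigrams only):
  #   d1: alpha alpha beta      -> 3 terms
  #   d2: alpha gamma           -> 2 terms
  #   d3: gamma gamma gamma beta -> 4 terms
  # df: alpha 2, beta 2, gamma 2 -> idf = log2(3/2) for every term
  docs <- list(d1 = "alphaq alphaq betaq", d2 = "alphaq gammaq",
               d3 = "gammaq gammaq gammaq betaq")
  # use pseudo-words long enough to survive filtering and stable under
  # stemming
  tm <- build_term_matrix(docs, ngram_orders = 1, normalize = "none",
                          min_df = 1)
  idf <- log2(3 / 2)
  M <- as.matrix(tm$M)
  expect_equal(M["alphaq", "d1"], 2 / 3 * idf, tolerance = 1e-12)
  expect_equal(M["betaq", "d1"], 1 / 3 * idf, tolerance = 1e-12)
  expect_equal(M["gammaq", "d1"], 0)
  expect_equal(M["alphaq", "d2"], 1 / 2 * idf, tolerance = 1e-12)
  expect_equal(M["gammaq", "d3"], 3 / 4 * idf, tolerance = 1e-12)
  expect_equal(tm$n_docs, 3)
  expect_equal(unname(tm$doc_freq[match(c("alphaq", "betaq", "gammaq"),
                                        tm$vocab)]), c(2, 2, 2))
})

test_that("idf closed forms hold: ubiquitous terms vanish, |D|=8 df=2 gives 2", {
  docs <- as.list(c(sprintf("common%d", 1:8)))
  names(docs) <- paste0("d", 1:8)
  docs <- lapply(seq_along(docs), function(i) {
    # "everyq" occurs in all 8 docs; "rareq" in exactly 2
    base <- "everyq filler"
    if (i <= 2) base <- paste(base, "rareq")
    paste(base, sprintf("uniq%daaa", i))
  })
  names(docs) <- paste0("d", 1:8)
  tm <- build_term_matrix(docs, ngram_orders = 1, normalize = "none",
                          min_df = 1)
  M <- as.matrix(tm$M)
  expect_true(all(M["everyq", ] == 0)) # idf = log2(8/8) = 0
  i_rare <- match("rareq", tm$vocab)
  expect_equal(unname(tm$doc_freq[i_rare]), 2)
  # tf in d1 = 1/4 terms, idf = log2(8/2) = 2
  expect_equal(M["rareq", "d1"], 1 / 4 * 2, tolerance = 1e-12)
})

test_that("n-gram streams share one tf denominator and L2 columns are unit", {
  docs <- list(g1 = "alphaq betaq gammaq deltaq", g2 = "betaq gammaq alphaq")
  tm <- build_term_matrix(docs, ngram_orders = 1:3, normalize = "none",
                          min_df = 1)
  # g1: 4 unigrams + 3 bigrams + 2 trigrams = 9 terms
  expect_equal(unname(tm$total_terms["g1"]), 9)
  M <- as.matrix(tm$M)
  expect_equal(M["alphaq_betaq_gammaq", "g1"], 1 / 9 * 1, tolerance = 1e-12)

  tm2 <- build_term_matrix(docs, ngram_orders = 1:3, normalize = "l2",
                           min_df = 1)
  nrm <- sqrt(Matrix::colSums(tm2$M^2))
  expect_equal(unname(nrm), c(1, 1), tolerance = 1e-12)
})

test_that("empty-after-preprocessing documents are discarded with a message", {
  docs <- list(g1 = "alphaq betaq alphaq", g2 = "the and of is",
               g3 = "gammaq betaq")
  expect_message(tm <- build_term_matrix(docs, ngram_orders = 1, min_df = 1),
                 "discarding 1 gene")
  expect_equal(colnames(tm$M), c("g1", "g3"))
})

test_that("LSA retained variance matches the Gram-matrix eigen oracle", {
  set.seed(14)
  X <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(paste0("t", 1:50), paste0("g", 1:20)))
  tm <- list(M = X, vocab = rownames(X))
  class(tm) <- "term_matrix"
  ev <- sort(eigen(crossprod(X), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  for (k in c(1, 5, 20)) {
    model <- fit_lsa(tm, k)
    expect_equal(model$retained_variance, sum(ev[seq_len(k)]) / sum(ev),
                 tolerance = 1e-8)
  }
  # full-rank reconstruction
  model <- fit_lsa(tm, 20)
  recon <- model$loadings %*% t(model$scores)
  expect_equal(unname(recon), unname(X), tolerance = 1e-8)
  expect_equal(model$retained_variance, 1, tolerance = 1e-12)

  # rank-1 input at k = 1 retains everything
  R1 <- outer(rnorm(30), rnorm(6))
  dimnames(R1) <- list(paste0("t", 1:30), paste0("g", 1:6))
  tm1 <- structure(list(M = R1, vocab = rownames(R1)), class = "term_matrix")
  expect_equal(fit_lsa(tm1, 1)$retained_variance, 1, tolerance = 1e-12)
  expect_warning(fit_lsa(tm1, 3), "rank")
})

test_that("k-means recovers well-separated planted clusters exactly", {
  set.seed(15)
  scores <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
                  matrix(rnorm(12, 5, 0.1), 6, 2))
  rownames(scores) <- paste0("g", 1:12)
  model <- structure(list(scores = scores,
                          loadings = diag(2), vocab = c("a", "b")),
                     class = "lsa_model")
  labels <- cluster_genes(model, 2, seed = 1)
  expect_equal(length(unique(labels[1:6])), 1)
  expect_equal(length(unique(labels[7:12])), 1)
  expect_true(labels[1] != labels[12])
  # the 2-partition found is the global optimum: brute-force over all
  # balanced and unbalanced splits of 12 points
  wcss_of <- function(assign) {
    sum(sapply(unique(assign), function(c_i) {
      pts <- scores[assign == c_i, , drop = FALSE]
      sum(scale(pts, scale = FALSE)^2)
    }))
  }
  best <- Inf
  for (mask in 1:(2^11)) {
    assign <- c(1, as.integer(intToBits(mask))[1:11] + 1)
    if (length(unique(assign)) == 2) best <- min(best, wcss_of(assign))
  }
  expect_equal(unname(attr(labels, "wcss")), best, tolerance = 1e-9)

  # k = 1: WCSS equals the total sum of squares
  lab1 <- cluster_genes(model, 1, seed = 1)
  expect_equal(unname(attr(lab1, "wcss")),
               sum(scale(scores, scale = FALSE)^2), tolerance = 1e-9)
  # determinism
  expect_identical(as.integer(cluster_genes(model, 2, seed = 7)),
                   as.integer(cluster_genes(model, 2, seed = 7)))
})

test_that("cluster summaries rank topic stems and never surface idf-0 terms", {
  cfg <- small_config(seed = 61, n_topics = 2, n_genes = 24,
                      abstracts_per_gene_range = c(4, 6))
  corpus <- simulate_annotation_corpus(cfg)
  tm <- build_term_matrix(corpus$docs, ngram_orders = 1)
  model <- fit_lsa(tm, min(20, min(dim(tm$M))))
  labels <- cluster_genes(model, 2, seed = 2)
  rep <- summarize_clusters(model, labels, top_m = 10)
  expect_equal(sum(rep$sizes$size), length(corpus$docs))
  expect_equal(sum(rep$sizes$fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(subset(rep$terms, cluster == 1)$weight) <= 1e-12))
  expect_true(all(rep$terms$weight > 0))
  # ubiquitous terms (idf 0 -> zero row) cannot be summary terms
  zero_terms <- tm$vocab[Matrix::rowSums(tm$M != 0) == 0]
  expect_false(any(rep$terms$term %in% zero_terms))
  # summaries draw from the matching planted topic pool
  ari <- adjusted_rand(labels, corpus$topic_truth[names(labels)])
  expect_gt(ari, 0.8)
  for (c_i in rep$sizes$cluster) {
    top <- subset(rep$terms, cluster == c_i)$term[1:5]
    genes_c <- names(labels)[labels == c_i]
    major_topic <- as.integer(names(which.max(
      table(corpus$topic_truth[genes_c]))))
    in_pool <- mean(top %in% corpus$topic_pools[[major_topic]])
    expect_gt(in_pool, 0.5)
  }
})

test_that("removing one gene's abstracts only touches its column and df counts", {
  docs <- list(g1 = "alphaq betaq", g2 = "betaq gammaq deltaq",
               g3 = "alphaq gammaq", g4 = "deltaq betaq epsilq")
  tm_full <- build_term_matrix(docs, ngram_orders = 1, normalize = "none",
                               min_df = 1)
  tm_drop <- build_term_matrix(docs[-2], ngram_orders = 1, normalize = "none",
                               min_df = 1)
  shared_terms <- intersect(tm_full$vocab, tm_drop$vocab)
  for (g in c("g1", "g3", "g4")) {
    tf_full <- as.matrix(tm_full$M)[shared_terms, g] /
      log2(tm_full$n_docs / tm_full$doc_freq[match(shared_terms, tm_full$vocab)])
    tf_drop <- as.matrix(tm_drop$M)[shared_terms, g] /
      log2(tm_drop$n_docs / tm_drop$doc_freq[match(shared_terms, tm_drop$vocab)])
    tf_full[is.nan(tf_full)] <- 0
    tf_drop[is.nan(tf_drop)] <- 0
    expect_equal(tf_full, tf_drop, tolerance = 1e-12)
  }
})
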