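ngram_tokens <- function(tokens, orders = 1:3) {
  n <- length(tokens)
  out <- list()
  for (k in orders) {
    if (n >= k) {
      if (k == 1) {
        out[[length(out) + 1]] <- tokens
      } else {
        idx <- seq_len(n - k + 1)
        mat <- vapply(0:(k - 1), function(o) tokens[idx + o], character(length(idx)))
        if (length(idx) == 1) mat <- matrix(mat, nrow = 1)
        out[[length(out) + 1]] <- apply(mat, 1, paste, collapse = "_")
      }
    }
  }
  unlist(out, use.names = FALSE)
}

#' Build the tf-idf term matrix over gene summaries
#'
#' Each gene's abstracts are preprocessed and concatenated into one "gene
#' summary" token stream; the vocabulary is all unigrams, bigrams and
#' trigrams (by default) over that stream. Term frequency is the count of
#' a term in the summary divided by the total number of terms (of all
#' orders) in the summary; inverse document frequency is
#' `log2(|D| / df_i)` with `|D|` the number of gene summaries and `df_i`
#' the number of summaries containing term i, so a term present in every
#' summary gets weight zero. Each gene column of the tf-idf matrix is then
#' length-normalized (L2 by default).
#'
#' @param docs A `gene_doc_set` (from [simulate_annotation_corpus()] or
#'   [read_corpus_jsonl()]) or a named list of character vectors of
#'   abstracts per gene.
#' @param ngram_orders Integer vector of n-gram orders (default `1:3`).
#' @param normalize Column normalization: `"l2"` (default), `"l1"` or
#'   `"none"`.
#' @param min_df Terms in fewer than `min_df` summaries are pruned after
#'   weighting (default 2); set 1 to keep everything.
#' @param stopword_list Passed to [preprocess_text()].
#' @return List of class `term_matrix`: sparse matrix `M` (terms x genes,
#'   tf-idf), `vocab`, `doc_freq`, `n_docs`, `total_terms` per gene. Genes
#'   whose summaries are empty after preprocessing are discarded with a
#'   message (annotation-free).
#' @export
build_term_matrix <- function(docs, ngram_orders = 1:3,
                              normalize = c("l2", "l1", "none"),
                              min_df = 2, stopword_list = stopwords_en) {
  normalize <- match.arg(normalize)
  if (inherits(docs, "gene_doc_set")) docs <- docs$docs
  if (is.null(names(docs))) stop("`docs` must be a named list of abstracts")
  docs <- docs[lengths(docs) > 0]

  streams <- lapply(docs, function(abst) {
    ngram_tokens(preprocess_text(abst, stopword_list), ngram_orders)
  })
  empty <- lengths(streams) == 0
  if (any(empty)) {
    message(sprintf("discarding %d gene(s) with empty summaries: %s",
                    sum(empty), paste(names(streams)[empty], collapse = ", ")))
    streams <- streams[!empty]
  }
  if (length(streams) < 2) stop("need at least 2 non-empty gene summaries")

  total_terms <- lengths(streams)
  vocab <- sort(unique(unlist(streams, use.names = FALSE)))
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  doc_hits <- vector("list", length(streams))
  for (j in seq_along(streams)) {
    tab <- table(streams[[j]])
    ids <- match(names(tab), vocab)
    trip_i <- c(trip_i, ids)
    trip_j <- c(trip_j, rep(j, length(ids)))
    trip_x <- c(trip_x, as.numeric(tab) / total_terms[j])
    doc_hits[[j]] <- ids
  }
  df <- tabulate(unlist(doc_hits), nbins = length(vocab))
  n_docs <- length(streams)
  idf <- log2(n_docs / df)

  M <- Matrix::sparseMatrix(
    i = trip_i, j = trip_j, x = trip_x * idf[trip_i],
    dims = c(length(vocab), n_docs),
    dimnames = list(vocab, names(streams))
  )
  M <- Matrix::drop0(M)

  if (min_df > 1) {
    keep <- df >= min_df
    M <- M[keep, , drop = FALSE]
    vocab_kept <- vocab[keep]
    df_kept <- df[keep]
  } else {
    vocab_kept <- vocab
    df_kept <- df
  }

  if (normalize != "none") {
    nrm <- if (normalize == "l2") {
      sqrt(Matrix::colSums(M^2))
    } else {
      Matrix::colSums(abs(M))
    }
    nrm[nrm == 0] <- 1
    M <- M %*% Matrix::Diagonal(ncol(M), 1 / nrm)
    dimnames(M) <- list(vocab_kept, names(streams))
  }

  structure(list(
    M = M, vocab = vocab_kept, doc_freq = df_kept, n_docs = n_docs,
    total_terms = total_terms, normalize = normalize
  ), class = "term_matrix")
}

#' @export
print.term_matrix <- function(x, ...) {
  cat(sprintf("term_matrix: %d terms x %d genes (%s-normalized tf-idf)\n",
              nrow(x$M), ncol(x$M), x$normalize))
  invisible(x)
}

#' Latent semantic analysis of a term matrix
#'
#' Truncated singular value decomposition of the tf-idf matrix. Genes are
#' embedded as the k-dimensional rows of `V_k %*% diag(d_k)`; the retained
#' variance is the sum of squared retained singular values over the
#' squared Frobenius norm of the input.
#'
#' @param term_matrix A [build_term_matrix()] result.
#' @param k Number of components, `1 <= k <= min(n_terms, n_docs)`; values
#'   beyond the numerical rank retain all variance (with a warning).
#' @return List of class `lsa_model`: `k`, `singular_values`, `loadings`
#'   (terms x k), `scores` (genes x k), `retained_variance`.
#' @export
fit_lsa <- function(term_matrix, k) {
  M <- as.matrix(term_matrix$M)
  if (k < 1 || k > min(dim(M))) stop("k must lie in [1, min(n_terms, n_docs)]")
  sv <- svd(M)
  tot <- sum(sv$d^2)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (k > rank) {
    warning(sprintf("k = %d exceeds numerical rank %d; variance fully retained",
                    k, rank))
  }
  d_k <- sv$d[seq_len(k)]
  retained <- if (tot > 0) sum(d_k^2) / tot else 1
  scores <- sv$v[, seq_len(k), drop = FALSE] %*% diag(d_k, k)
  rownames(scores) <- colnames(M)
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(M)
  structure(list(
    k = k, singular_values = sv$d, loadings = loadings, scores = scores,
    retained_variance = retained, vocab = rownames(M), genes = colnames(M)
  ), class = "lsa_model")
}

#' @export
print.lsa_model <- function(x, ...) {
  cat(sprintf("lsa_model: %d components over %d genes, %.1f%% variance retained\n",
              x$k, length(x$genes), 100 * x$retained_variance))
  invisible(x)
}

# k-means++ seeding followed by Lloyd iterations; an emptied cluster is
# re-seeded from the point farthest from its assigned center.
.kmeans_lloyd <- function(x, k, max_iter = 100) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    for (c_i in 2:k) {
      d2 <- apply(x, 1, function(p) {
        min(rowSums((centers[seq_len(c_i - 1), , drop = FALSE] -
                       matrix(p, c_i - 1, ncol(x), byrow = TRUE))^2))
      })
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[c_i, ] <- x[sample.int(n, 1, prob = prob), ]
    }
  }
  assign_pts <- function(centers) {
    d <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    max.col(-d, ties.method = "first")
  }
  lab <- assign_pts(centers)
  for (it in seq_len(max_iter)) {
    for (c_i in seq_len(k)) {
      if (!any(lab == c_i)) {
        dist_own <- rowSums((x - centers[lab, , drop = FALSE])^2)
        centers[c_i, ] <- x[which.max(dist_own), ]
        lab[which.max(dist_own)] <- c_i
      }
    }
    for (c_i in seq_len(k)) {
      centers[c_i, ] <- colMeans(x[lab == c_i, , drop = FALSE])
    }
    new_lab <- assign_pts(centers)
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  wcss <- sum(rowSums((x - centers[lab, , drop = FALSE])^2))
  list(labels = lab, centers = centers, wcss = wcss)
}

#' Cluster genes in LSA space
#'
#' Lloyd's k-means with k-means++ initialization and `n_init` restarts on
#' the gene LSA coordinates; the restart with the lowest within-cluster
#' sum of squares wins, and the result is deterministic given the seed.
#'
#' @param model An [fit_lsa()] model.
#' @param k_clusters Number of clusters, at most the number of genes.
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts (default 10).
#' @return Named integer vector gene -> cluster id, with attributes
#'   `wcss` and `centers`.
#' @export
cluster_genes <- function(model, k_clusters, seed = 1L, n_init = 10) {
  x <- model$scores
  if (k_clusters > nrow(x)) stop("k_clusters exceeds the number of genes")
  if (k_clusters < 1) stop("k_clusters must be >= 1")
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- .kmeans_lloyd(x, k_clusters)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    out <- stats::setNames(best$labels, rownames(x))
    attr(out, "wcss") <- best$wcss
    attr(out, "centers") <- best$centers
    out
  })
}

#' Summarize clusters by their most specific terms
#'
#' Each cluster center (mean gene coordinate in LSA space) is projected
#' back to term space through the component loadings; the `top_m` terms
#' with the largest positive back-projected weight summarize the cluster,
#' ready for word-cloud rendering. A term occurring in every summary has
#' idf 0 and can never appear.
#'
#' @param model An [fit_lsa()] model.
#' @param labels Cluster assignment from [cluster_genes()].
#' @param top_m Number of terms per cluster (default 10; truncated at the
#'   vocabulary size).
#' @return List of class `cluster_report`: `assignments`, `sizes`
#'   (`data.frame` cluster/size/fraction), `terms` (`data.frame` cluster,
#'   rank, term, weight with nonnegative weights sorted descending).
#' @export
summarize_clusters <- function(model, labels, top_m = 10) {
  stopifnot(length(labels) == nrow(model$scores))
  top_m <- min(top_m, length(model$vocab))
  cl_ids <- sort(unique(labels))
  sizes <- data.frame(
    cluster = cl_ids,
    size = as.integer(table(factor(labels, levels = cl_ids))),
    stringsAsFactors = FALSE
  )
  sizes$fraction <- sizes$size / length(labels)

  term_rows <- lapply(cl_ids, function(c_i) {
    center <- colMeans(model$scores[labels == c_i, , drop = FALSE])
    w <- as.numeric(model$loadings %*% center)
    ord <- order(w, decreasing = TRUE)
    ord <- ord[w[ord] > 1e-12][seq_len(min(top_m, sum(w > 1e-12)))]
    if (!length(ord)) return(NULL)
    data.frame(cluster = c_i, rank = seq_along(ord),
               term = model$vocab[ord], weight = w[ord],
               stringsAsFactors = FALSE)
  })
  structure(list(
    assignments = labels,
    sizes = sizes,
    terms = do.call(rbind, term_rows)
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d clusters over %d genes (sizes %s)\n",
              nrow(x$sizes), length(x$assignments),
              paste(x$sizes$size, collapse = "/")))
  invisible(x)
}
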