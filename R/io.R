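# Plain-text interchange: TSV matrices/tables, JSON-lines corpora,
# sparse-triplet term matrices, SIF/GraphML networks, JSON run reports.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an omics matrix as TSV
#'
#' Features in rows (first column `feature`), one column per sample.
#' @param x An [omics_matrix()].
#' @param path Output path.
#' @export
write_omics_matrix <- function(x, path) {
  df <- data.frame(feature = rownames(x), as.data.frame(unclass(x)[, ]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an omics matrix from TSV
#'
#' @param path TSV written by [write_omics_matrix()].
#' @param layer `"methylation"` or `"expression"`.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, layer) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  omics_matrix(m, layer)
}

#' Write a gene-abstract corpus as JSON lines
#'
#' One record per gene: `{"gene": symbol, "abstracts": [...]}` (and the
#' latent topic when known).
#' @param corpus A `gene_doc_set`.
#' @param path Output path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(corpus$docs)) {
    rec <- list(gene = g, abstracts = corpus$docs[[g]])
    if (!is.null(corpus$topic_truth)) rec$topic <- unname(corpus$topic_truth[[g]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a gene-abstract corpus from JSON lines
#'
#' @param path File written by [write_corpus_jsonl()] (or any JSONL with
#'   `gene` and `abstracts` fields).
#' @return A `gene_doc_set`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  docs <- lapply(recs, function(r) as.character(r$abstracts))
  names(docs) <- vapply(recs, function(r) r$gene, character(1))
  topics <- vapply(recs, function(r) {
    if (is.null(r$topic)) NA_integer_ else as.integer(r$topic)
  }, integer(1))
  structure(list(
    docs = docs,
    topic_truth = if (all(is.na(topics))) NULL else
      stats::setNames(topics, names(docs)),
    topic_pools = NULL
  ), class = "gene_doc_set")
}

#' Write a term matrix as sparse triplets plus vocabulary
#'
#' @param tm A [build_term_matrix()] result.
#' @param triplet_path TSV of `(term_index, gene_index, value)` triplets.
#' @param vocab_path TSV of `(term_index, term, doc_freq)`.
#' @export
write_term_matrix <- function(tm, triplet_path, vocab_path) {
  trip <- Matrix::summary(tm$M)
  write_tsv(data.frame(term_index = trip$i, gene_index = trip$j,
                       value = trip$x), triplet_path)
  write_tsv(data.frame(term_index = seq_along(tm$vocab), term = tm$vocab,
                       doc_freq = tm$doc_freq), vocab_path)
  invisible(triplet_path)
}

#' Export the importance network as SIF and GraphML
#'
#' SIF lines read `feature predicts trait`; the GraphML carries the edge
#' attribute `importance_percent` and node attributes `type` and
#' `labeled`, ready for Cytoscape-style viewers.
#'
#' @param net An [build_importance_network()] result.
#' @param sif_path,graphml_path Output paths (either may be `NULL`).
#' @export
write_network <- function(net, sif_path = NULL, graphml_path = NULL) {
  if (!is.null(sif_path)) {
    lines <- if (nrow(net$edges)) {
      sprintf("%s\tpredicts\t%s", net$edges$feature, net$edges$trait)
    } else {
      # isolated trait nodes
      net$nodes$id[net$nodes$type == "trait"]
    }
    writeLines(lines, sif_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      if (nrow(net$edges)) net$edges[, c("feature", "trait")] else
        data.frame(from = character(), to = character()),
      directed = FALSE, vertices = net$nodes
    )
    if (nrow(net$edges)) {
      igraph::E(g)$importance_percent <- net$edges$importance_percent
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(net)
}

#' Write all files of a synthetic study
#'
#' Emits `methylome.tsv`, `transcriptome.tsv`, `phenotypes.tsv`,
#' `feature_gene_map.tsv`, `corpus.jsonl` (when a corpus is attached) and
#' `truth.json` into a directory.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @param corpus Optional `gene_doc_set` to write alongside.
#' @export
write_study <- function(study, dir, corpus = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_matrix(study$methylome, file.path(dir, "methylome.tsv"))
  write_omics_matrix(study$transcriptome, file.path(dir, "transcriptome.tsv"))
  write_tsv(study$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_tsv(study$feature_gene_map, file.path(dir, "feature_gene_map.tsv"))
  if (!is.null(corpus)) {
    write_corpus_jsonl(corpus, file.path(dir, "corpus.jsonl"))
  }
  truth <- study$truth
  truth$ga_component <- as.list(truth$ga_component)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
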