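# Pseudo-stem construction for the synthetic corpus: pronounceable
# consonant-vowel words long enough to survive the short-word filter, with
# surface variants (plural / -ed / -ing) that Porter-stem back to one
# canonical stem, so the corpus exercises the whole preprocessing chain.

.syllables <- function(rng_n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(sample(cons, rng_n, TRUE), sample(vow, rng_n, TRUE))
}

.make_vocab <- function(vocab_size, stopword_list) {
  words <- character(0)
  guard <- 0
  while (length(words) < vocab_size && guard < 200) {
    guard <- guard + 1
    cand <- vapply(seq_len(vocab_size * 2), function(i) {
      paste(.syllables(sample(3:4, 1)), collapse = "")
    }, character(1))
    cand <- cand[nchar(cand) > 3 & !cand %in% stopword_list]
    stems <- porter_stem(cand)
    keep <- nchar(stems) > 3 & !duplicated(stems) &
      !stems %in% porter_stem(words)
    words <- unique(c(words, cand[keep]))
  }
  words[seq_len(vocab_size)]
}

.surface_variants <- function(word) {
  base_stem <- porter_stem(word)
  cands <- c(word, paste0(word, "s"), paste0(word, "ed"), paste0(word, "ing"))
  ok <- porter_stem(cands) == base_stem & nchar(cands) > 3
  cands[ok]
}

#' Simulate a topic-structured gene-abstract corpus
#'
#' Assigns each gene one latent topic and generates its abstracts as bags
#' of pseudo-words: each content token comes from the gene's topic-specific
#' term pool with probability `topic_mix`, otherwise from a shared
#' background pool. Tokens are emitted as surface variants (plural, -ed,
#' -ing forms) of canonical stems, interleaved with stop words, short
#' words and punctuation, so the downstream preprocessing stages do real
#' work. Abstract counts per gene are uniform on
#' `abstracts_per_gene_range`.
#'
#' @param config A [sim_config()]; uses `n_genes`, `n_topics`,
#'   `vocab_size`, `topic_mix`, `abstracts_per_gene_range` and `seed`.
#' @return List of class `gene_doc_set` with `docs` (named list: gene
#'   symbol -> character vector of abstracts), `topic_truth` (named
#'   integer vector), and `topic_pools` (canonical stems per topic).
#' @export
simulate_annotation_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_topics < 1) stop("n_topics must be >= 1")
  with_seed(derive_seed(cfg$seed, "corpus"), {
    genes <- gene_symbols(cfg$n_genes)
    topic <- stats::setNames(rep_len(seq_len(cfg$n_topics), cfg$n_genes)[
      sample(cfg$n_genes)], genes)

    vocab <- .make_vocab(cfg$vocab_size, stopwords_en)
    n_bg <- max(1, round(0.4 * length(vocab)))
    bg_pool <- vocab[seq_len(n_bg)]
    rest <- vocab[-seq_len(n_bg)]
    if (length(rest) < cfg$n_topics) stop("vocab too small for topic pools")
    topic_pool <- split(rest, rep_len(seq_len(cfg$n_topics), length(rest)))

    variants <- lapply(vocab, .surface_variants)
    names(variants) <- vocab

    fillers <- c("the", "of", "and", "in", "was", "were", "with", "for",
                 "we", "is", "are", "to", "by", "an", "a", "on", "at",
                 "gene", "cell", "role") # last three are > 3 chars, kept
    punct <- c(",", ".", ";", ":")

    gen_abstract <- function(g) {
      n_tok <- sample(40:80, 1)
      from_topic <- stats::runif(n_tok) < cfg$topic_mix
      pool_words <- ifelse(from_topic,
                           sample(topic_pool[[topic[[g]]]], n_tok, TRUE),
                           sample(bg_pool, n_tok, TRUE))
      words <- vapply(pool_words, function(w) {
        v <- variants[[w]]
        v[sample.int(length(v), 1)]
      }, character(1), USE.NAMES = FALSE)
      n_fill <- max(1, round(0.2 * n_tok))
      words <- append(words, sample(fillers, n_fill, TRUE),
                      after = sample(n_tok, 1))
      idx <- sample(length(words), 3)
      words[idx] <- paste0(words[idx], sample(punct, 3, TRUE))
      paste(words, collapse = " ")
    }

    docs <- lapply(genes, function(g) {
      n_abs <- sample(cfg$abstracts_per_gene_range[1]:
                        cfg$abstracts_per_gene_range[2], 1)
      vapply(seq_len(n_abs), function(i) gen_abstract(g), character(1))
    })
    names(docs) <- genes

    structure(list(
      docs = docs,
      topic_truth = topic,
      topic_pools = lapply(topic_pool, porter_stem)
    ), class = "gene_doc_set")
  })
}

#' @export
print.gene_doc_set <- function(x, ...) {
  cat(sprintf("gene_doc_set: %d genes, %d abstracts, %d topics\n",
              length(x$docs), sum(lengths(x$docs)),
              length(unique(x$topic_truth))))
  invisible(x)
}
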