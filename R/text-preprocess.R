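# Standard English stop-word list (snowball-style function words).
stopwords_en <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
  "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
  "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
  "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
  "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
  "being", "have", "has", "had", "having", "do", "does", "did", "doing",
  "would", "should", "could", "ought", "a", "an", "the", "and", "but",
  "if", "or", "because", "as", "until", "while", "of", "at", "by", "for",
  "with", "about", "against", "between", "into", "through", "during",
  "before", "after", "above", "below", "to", "from", "up", "down", "in",
  "out", "on", "off", "over", "under", "again", "further", "then", "once",
  "here", "there", "when", "where", "why", "how", "all", "any", "both",
  "each", "few", "more", "most", "other", "some", "such", "no", "nor",
  "not", "only", "own", "same", "so", "than", "too", "very", "can",
  "will", "just", "also", "may", "might", "must", "shall", "upon",
  "within", "without", "among", "however", "therefore", "thus", "although",
  "whereas", "moreover", "furthermore", "respectively", "whether", "since",
  "toward", "towards", "via", "per", "versus"
)

#' Preprocess raw abstract text into stemmed tokens
#'
#' Lowercases, strips punctuation and digits, drops tokens of three
#' characters or fewer, removes stop words, and Porter-stems the
#' remainder -- the normalization applied to every abstract before term
#' extraction.
#'
#' @param raw Character vector of raw text (elements are concatenated into
#'   one token stream).
#' @param stopword_list Character vector of stop words (default: a standard
#'   English list shipped with the package).
#' @return Character vector of stems (empty for empty input).
#' @examples
#' preprocess_text("Placental growth; the placentas are GROWING!")
#' @export
preprocess_text <- function(raw, stopword_list = stopwords_en) {
  if (!length(raw)) return(character(0))
  txt <- tolower(paste(raw, collapse = " "))
  txt <- gsub("[^a-z]+", " ", txt)
  tokens <- strsplit(trimws(txt), "\\s+")[[1]]
  tokens <- tokens[nchar(tokens) > 3]
  tokens <- tokens[!tokens %in% stopword_list]
  if (!length(tokens)) return(character(0))
  porter_stem(tokens)
}
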