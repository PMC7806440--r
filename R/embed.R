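#' Tokenize free text into lowercase word tokens
#'
#' Lowercases and splits on runs of non-alphanumeric characters; empty
#' fragments are dropped and stopwords are retained. This is the English
#' counterpart of the morphological-analysis step used for languages without
#' whitespace word boundaries: for English, morpheme segmentation degenerates
#' to plain word tokenization.
#'
#' @param text Character vector.
#' @return A list of character vectors, one per input element.
#' @examples
#' tokenize("Metformin vs. placebo")[[1]]
#' @export
tokenize <- function(text) {
  text <- tolower(as.character(text))
  out <- strsplit(text, "[^[:alnum:]]+")
  purrr::map(out, function(x) x[nzchar(x)])
}

article_tokens <- function(corpus) {
  # title and abstract concatenated: title carries the strongest topic signal
  tokenize(paste(corpus$title, corpus$abstract))
}

#' Build the embedding vocabulary
#'
#' Selects the `max_vocab` most frequent tokens over all articles (title and
#' abstract), ordered by descending corpus frequency with lexicographic
#' tie-break. Stopwords are deliberately kept: the query vector subtracts the
#' screened-irrelevant mean, which cancels shared background vocabulary.
#'
#' @param corpus A screening corpus.
#' @param max_vocab Vocabulary cap (default 1000).
#' @return A tibble of class `screen_vocabulary` with columns `word`, `freq`.
#' @export
build_vocabulary <- function(corpus, max_vocab = 1000) {
  stopifnot(max_vocab >= 1)
  corpus <- as_corpus(corpus)
  if (nrow(corpus) == 0) {
    abort("corpus is empty", class = "citescreen_validation_error")
  }
  toks <- unlist(article_tokens(corpus), use.names = FALSE)
  if (length(toks) == 0) {
    abort("corpus contains no tokens", class = "citescreen_validation_error")
  }
  tab <- table(toks)
  vocab <- tibble::tibble(word = names(tab), freq = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$word) |>
    head(max_vocab)
  class(vocab) <- c("screen_vocabulary", class(tibble::tibble()))
  vocab
}

#' Embedding hyperparameters
#'
#' @param dim Embedding dimension (300 is the conventional size for this
#'   corpus scale).
#' @param negative Number of negative samples per observed pair (5; useful
#'   range for small corpora is 5-20).
#' @param max_vocab Vocabulary cap (1000 most frequent words).
#' @param epochs Training passes over the corpus.
#' @param window Maximum skip-gram context window; the effective window per
#'   position is sampled uniformly from `1:window` as in word2vec.
#' @param alpha,min_alpha Initial and final learning rate (linear decay).
#' @param joint If `TRUE` (default) document and word vectors are trained
#'   simultaneously against a shared output layer; if `FALSE`, word vectors
#'   are trained first and document vectors fitted afterwards against the
#'   frozen output layer.
#' @param seed Integer seed for the trainer's internal RNG. Training is
#'   single-threaded and bit-reproducible given the seed.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(dim = 300, negative = 5, max_vocab = 1000,
                             epochs = 40, window = 5, alpha = 0.025,
                             min_alpha = 1e-4, joint = TRUE, seed = 1) {
  stopifnot(dim >= 1, negative >= 1, max_vocab >= 2, epochs >= 1,
            window >= 1, alpha > 0, min_alpha > 0, alpha >= min_alpha)
  structure(list(dim = as.integer(dim), negative = as.integer(negative),
                 max_vocab = as.integer(max_vocab),
                 epochs = as.integer(epochs), window = as.integer(window),
                 alpha = alpha, min_alpha = min_alpha, joint = isTRUE(joint),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Train word and document embeddings
#'
#' Trains word vectors with a skip-gram negative-sampling objective and
#' document vectors with the distributed bag-of-words paragraph-vector
#' objective (PV-DBOW), jointly by default. Out-of-vocabulary tokens are
#' removed before training, mirroring the vocabulary cap; an article whose
#' token sequence is empty after that still receives a (zero) document
#' vector.
#'
#' @param corpus A screening corpus.
#' @param vocab Optional vocabulary from [build_vocabulary()]; built from the
#'   corpus at `config$max_vocab` when omitted.
#' @param config An [embedding_config()].
#' @return A list of class `embedding_model` with elements `W` (n x dim word
#'   matrix, rownames = words), `D` (m x dim document matrix, rownames =
#'   article ids), `vocab` and `config`.
#' @export
train_embeddings <- function(corpus, vocab = NULL,
                             config = embedding_config()) {
  corpus <- as_corpus(corpus)
  stopifnot(inherits(config, "embedding_config"))
  if (is.null(vocab)) vocab <- build_vocabulary(corpus, config$max_vocab)
  toks <- article_tokens(corpus)
  idx <- purrr::map(toks, function(x) {
    i <- match(x, vocab$word)
    as.integer(i[!is.na(i)])
  })
  if (sum(purrr::map_int(idx, length) > 0) < 2) {
    abort("need at least 2 articles with in-vocabulary tokens to train",
          class = "citescreen_training_error")
  }
  fit <- cpp_train_embeddings(idx, as.numeric(vocab$freq), config$dim,
                              config$negative, config$epochs, config$window,
                              config$alpha, config$min_alpha,
                              as.numeric(config$seed), config$joint)
  W <- fit$W
  D <- fit$D
  rownames(W) <- vocab$word
  rownames(D) <- corpus$id
  structure(list(W = W, D = D, vocab = vocab, config = config),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("# embedding model: %d documents x %d words, dim %d\n",
              nrow(x$D), nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Compute the sentence-word feature matrix
#'
#' The feature matrix is the product `D %*% t(W)`: an m x n matrix whose rows
#' are article feature vectors expressed in word coordinates. Similarity
#' structure of the embeddings survives the product by linearity, and no
#' dimensionality reduction is applied - the column count stays at the
#' vocabulary size.
#'
#' @param model An `embedding_model`.
#' @return An m x n numeric matrix with article ids as rownames and words as
#'   colnames.
#' @export
feature_matrix <- function(model) {
  stopifnot(inherits(model, "embedding_model"))
  F <- model$D %*% t(model$W)
  if (!all(is.finite(F))) {
    abort("feature matrix contains non-finite entries",
          class = "citescreen_internal_error")
  }
  F
}

#' Cosine similarity of two vectors
#'
#' Returns `NA` (the "undefined" sentinel) when either vector has zero norm;
#' callers rank undefined scores below every defined score.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`, or `NA`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    abort("vectors differ in length", class = "citescreen_validation_error")
  }
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}
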