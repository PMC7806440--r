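#' Configuration for the synthetic labelled corpus generator
#'
#' The generator draws each article's tokens from a unigram mixture: a
#' Zipf-like background distribution shared by every article, plus a topic
#' distribution over `topic_size` reserved words that only relevant articles
#' use. `delta` is the topic weight - the probability that a relevant
#' article's token is drawn from the topic distribution instead of the
#' background. `delta = 0` makes labels statistically independent of text;
#' `delta = 1` makes every relevant-article token a topic word.
#'
#' Defaults emulate the shape of real title/abstract screening corpora:
#' roughly 1200 distinct words, abstracts of about 150 tokens, and a small
#' dedicated topic vocabulary.
#'
#' @param m Total number of articles.
#' @param P Number of relevant articles, `2 <= P <= m`.
#' @param vocab_size Total distinct words (background + topic).
#' @param topic_size Words reserved for the relevant topic.
#' @param delta Topic weight in relevant articles, in `[0, 1]`.
#' @param len_mean,len_sd Token-count distribution per article
#'   (positive-truncated normal).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(m, P, vocab_size = 1200, topic_size = 100,
                         delta = 0.8, len_mean = 150, len_sd = 40,
                         seed = 1) {
  if (!(P >= 2 && P <= m)) {
    abort("need 2 <= P <= m", class = "citescreen_validation_error")
  }
  if (!(topic_size >= 1 && topic_size < vocab_size)) {
    abort("need 1 <= topic_size < vocab_size",
          class = "citescreen_validation_error")
  }
  if (!(delta >= 0 && delta <= 1)) {
    abort("delta must lie in [0, 1]", class = "citescreen_validation_error")
  }
  if (!(len_mean > 0)) {
    abort("len_mean must be positive", class = "citescreen_validation_error")
  }
  structure(list(m = as.integer(m), P = as.integer(P),
                 vocab_size = as.integer(vocab_size),
                 topic_size = as.integer(topic_size), delta = delta,
                 len_mean = len_mean, len_sd = len_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic labelled screening corpus
#'
#' Produces `m` articles, `P` of them labelled relevant, whose token streams
#' follow the mixture described in [synth_config()]. The title is the first
#' 8 tokens of the article's stream and the abstract the remainder, so
#' titles and abstracts share the topic signal. Ids are zero-padded so
#' lexicographic order equals generation order. Relevant labels are assigned
#' to a random subset of positions.
#'
#' @param config A [synth_config()].
#' @return A [screening corpus][as_corpus].
#' @examples
#' corpus <- generate_corpus(synth_config(m = 50, P = 5, seed = 42))
#' glance(corpus)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_bg <- config$vocab_size - config$topic_size
  bg_words <- sprintf("bg%04d", seq_len(n_bg))
  topic_words <- sprintf("topic%03d", seq_len(config$topic_size))
  # Zipf rank-frequency (exponent 1) so a vocabulary cap actually bites
  bg_p <- (1 / seq_len(n_bg))
  bg_p <- bg_p / sum(bg_p)
  tp_p <- (1 / seq_len(config$topic_size))
  tp_p <- tp_p / sum(tp_p)

  rel_rows <- sort(sample.int(config$m, config$P))
  rows <- vector("list", config$m)
  for (i in seq_len(config$m)) {
    len <- 0
    while (len < 1) len <- round(rnorm(1, config$len_mean, config$len_sd))
    relevant <- i %in% rel_rows
    if (relevant && config$delta > 0) {
      from_topic <- stats::runif(len) < config$delta
    } else {
      from_topic <- rep(FALSE, len)
    }
    toks <- character(len)
    n_t <- sum(from_topic)
    if (n_t > 0) {
      toks[from_topic] <- sample(topic_words, n_t, replace = TRUE, prob = tp_p)
    }
    if (n_t < len) {
      toks[!from_topic] <- sample(bg_words, len - n_t, replace = TRUE,
                                  prob = bg_p)
    }
    n_title <- min(8, len)
    rows[[i]] <- tibble::tibble(
      id = sprintf("art%06d", i),
      title = paste(toks[seq_len(n_title)], collapse = " "),
      abstract = if (len > n_title)
        paste(toks[(n_title + 1):len], collapse = " ") else "",
      label = if (relevant) "relevant" else "irrelevant"
    )
  }
  as_corpus(dplyr::bind_rows(rows))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Benchmark corpus shapes
#'
#' Eight generator configurations whose (relevant, total) article counts
#' span the range typical of published clinical systematic-review screening
#' tasks: 138 to 6935 records with 5 to 20 includes each. Useful as a
#' standard battery for exercising the full pipeline at realistic shapes.
#'
#' @param delta Topic weight shared by all eight configurations.
#' @return A list of eight [synth_config()] objects.
#' @export
benchmark_configs <- function(delta = 0.8) {
  shapes <- list(c(6, 410), c(12, 560), c(17, 5644), c(20, 6935),
                 c(11, 830), c(5, 5839), c(5, 138), c(5, 2389))
  purrr::imap(shapes, function(s, i) {
    synth_config(m = s[2], P = s[1], delta = delta, seed = 100L + i)
  })
}
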