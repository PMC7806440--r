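#' Initialise the query vector from two seed articles
#'
#' The query starts as the mean of the feature-matrix rows of the two
#' known-relevant seed articles.
#'
#' @param F Feature matrix from [feature_matrix()] (rownames are article ids).
#' @param corpus The labelled corpus the matrix was built from.
#' @param seed_pair Character vector of two distinct relevant article ids.
#' @return A numeric query vector of length `ncol(F)`.
#' @export
init_query <- function(F, corpus, seed_pair) {
  corpus <- as_corpus(corpus)
  check_seed_pair(corpus, seed_pair)
  colMeans(F[seed_pair, , drop = FALSE])
}

check_seed_pair <- function(corpus, seed_pair) {
  if (length(seed_pair) != 2) {
    abort("seed_pair must contain exactly 2 article ids",
          class = "citescreen_validation_error")
  }
  if (seed_pair[1] == seed_pair[2]) {
    abort("seed articles must be distinct",
          class = "citescreen_validation_error")
  }
  lab <- corpus$label[match(seed_pair, corpus$id)]
  if (anyNA(lab)) {
    abort("seed id not present in corpus",
          class = "citescreen_validation_error")
  }
  if (any(lab != "relevant")) {
    abort("both seed articles must be labelled relevant",
          class = "citescreen_validation_error")
  }
  invisible(TRUE)
}

#' Recompute the query vector from accumulated feedback
#'
#' The query is the mean of the feature rows of all screened-relevant
#' articles minus the mean over all screened-irrelevant articles; the second
#' term is omitted while no irrelevant article has been screened yet.
#'
#' @param F Feature matrix.
#' @param screened_relevant,screened_irrelevant Character vectors of article
#'   ids screened so far, by revealed label.
#' @return A numeric query vector of length `ncol(F)`.
#' @export
update_query <- function(F, screened_relevant, screened_irrelevant = character()) {
  if (length(screened_relevant) == 0) {
    abort("at least one screened relevant article is required",
          class = "citescreen_validation_error")
  }
  q <- colMeans(F[screened_relevant, , drop = FALSE])
  if (length(screened_irrelevant) > 0) {
    q <- q - colMeans(F[screened_irrelevant, , drop = FALSE])
  }
  q
}

#' Score unscreened articles against the query
#'
#' @param F Feature matrix.
#' @param q Query vector of length `ncol(F)`.
#' @param unscreened Character vector of article ids still unscreened.
#' @return A named numeric vector of cosine similarities (`NA` = undefined,
#'   when either the query or the article row has zero norm).
#' @export
score_unscreened <- function(F, q, unscreened) {
  if (length(q) != ncol(F)) {
    abort("query length does not match feature-matrix columns",
          class = "citescreen_validation_error")
  }
  if (length(unscreened) == 0) return(stats::setNames(numeric(0), character(0)))
  sub <- F[unscreened, , drop = FALSE]
  qn <- sqrt(sum(q * q))
  rn <- sqrt(rowSums(sub * sub))
  s <- as.numeric(sub %*% q)
  out <- ifelse(qn == 0 | rn == 0, NA_real_, s / (qn * rn))
  stats::setNames(out, unscreened)
}

#' Pick the article to read next
#'
#' The article with the highest defined score; ties and the all-undefined
#' case fall back to the lexicographically smallest id, making the loop
#' fully deterministic.
#'
#' @param scores Named numeric score vector (`NA` = undefined).
#' @return A single article id.
#' @export
select_next <- function(scores) {
  if (length(scores) == 0) {
    abort("no unscreened articles to select from",
          class = "citescreen_validation_error")
  }
  defined <- !is.na(scores)
  if (!any(defined)) return(min(names(scores)))
  top <- scores[defined]
  cand <- names(top)[top == max(top)]
  min(cand)
}

#' Simulate one retrospective screening run
#'
#' Runs the relevance-feedback loop: seed with two relevant articles, score
#' every unscreened article by cosine similarity to the query vector, read
#' the top-ranked article, reveal its true label, recompute the query
#' (mean of screened-relevant rows minus mean of screened-irrelevant rows),
#' and repeat until every relevant article has been read (or an optional
#' reading budget is exhausted). No classifier is trained on top of the
#' feature vectors; the query vector itself is the model of relevance.
#'
#' @param F Feature matrix from [feature_matrix()].
#' @param corpus Fully labelled corpus (no `unknown` labels) with at least
#'   two relevant articles.
#' @param seed_pair Two distinct relevant article ids.
#' @param budget Optional maximum total reads (including the two seeds).
#' @param keep_scores Keep the full pre-selection score snapshot of every
#'   post-seed step (needed by [auroc_trace()]); costs one `steps x m`
#'   matrix of memory.
#' @return A `screening_trace`: the ordered read log with revealed labels
#'   and selection scores. The two seeds are steps 1 and 2.
#' @examples
#' corpus <- generate_corpus(synth_config(m = 60, P = 4, seed = 7))
#' model <- train_embeddings(corpus, config = embedding_config(
#'   dim = 16, epochs = 5, seed = 7))
#' F <- feature_matrix(model)
#' seeds <- relevant_seed_pairs(corpus)[1, ]
#' trace <- run_screening(F, corpus, c(seeds$seed1, seeds$seed2))
#' glance(trace)
#' @export
run_screening <- function(F, corpus, seed_pair, budget = NULL,
                          keep_scores = TRUE) {
  corpus <- as_corpus(corpus)
  if (any(corpus$label == "unknown")) {
    abort("retrospective simulation requires a fully labelled corpus",
          class = "citescreen_validation_error")
  }
  if (sum(corpus$label == "relevant") < 2) {
    abort("at least 2 relevant articles are required",
          class = "citescreen_validation_error")
  }
  if (!identical(sort(rownames(F)), sort(corpus$id))) {
    abort("feature-matrix rownames do not match corpus ids",
          class = "citescreen_validation_error")
  }
  F <- F[corpus$id, , drop = FALSE]
  check_seed_pair(corpus, seed_pair)
  if (is.null(budget)) {
    budget <- -1L
  } else {
    stopifnot(budget >= 2)
    budget <- as.integer(budget)
  }
  seed_rows <- match(seed_pair, corpus$id)
  id_rank <- as.integer(rank(corpus$id, ties.method = "first"))
  res <- cpp_run_screening(F, corpus$label == "relevant",
                           as.integer(seed_rows), budget, keep_scores,
                           id_rank)
  ord <- res$order
  steps <- tibble::tibble(
    step = seq_along(ord),
    id = corpus$id[ord],
    label = corpus$label[ord],
    score = ifelse(is.nan(res$score), NA_real_, res$score)
  )
  history <- res$history
  if (!is.null(history)) {
    colnames(history) <- corpus$id
    rownames(history) <- as.character(seq_len(nrow(history)) + 2L)
  }
  new_trace(steps,
            m = nrow(corpus), P = sum(corpus$label == "relevant"),
            seed_pair = seed_pair,
            stop_reason = c("all_relevant_found",
                            "budget_exhausted")[res$stop_reason],
            history = history,
            labels = stats::setNames(corpus$label, corpus$id))
}

new_trace <- function(steps, m, P, seed_pair, stop_reason, history = NULL,
                      labels = NULL) {
  structure(list(steps = steps, m = m, P = P, seed_pair = seed_pair,
                 stop_reason = stop_reason, history = history,
                 labels = labels),
            class = "screening_trace")
}

#' Build a screening trace from a recorded reading order
#'
#' Turns a retrospective reading log (for example, a human screener's actual
#' reading order, or a hypothetical one) into a `screening_trace` so that the
#' same evaluation functions - [recall_curve()], [reading_ratio()],
#' [wss_at()] - apply to it. Scores are unavailable and recorded as `NA`.
#'
#' @param corpus Fully labelled corpus.
#' @param order_ids Article ids in the order they were read. Must be unique;
#'   may be a prefix of the corpus (screening stopped early).
#' @return A `screening_trace` with `stop_reason = "all_relevant_found"` if
#'   the log contains every relevant article, `"budget_exhausted"` otherwise.
#' @export
manual_trace <- function(corpus, order_ids) {
  corpus <- as_corpus(corpus)
  order_ids <- as.character(order_ids)
  if (anyDuplicated(order_ids) > 0) {
    abort("reading order contains duplicate ids",
          class = "citescreen_validation_error")
  }
  pos <- match(order_ids, corpus$id)
  if (anyNA(pos)) {
    abort(paste0("ids not present in corpus: ",
                 paste(order_ids[is.na(pos)], collapse = ", ")),
          class = "citescreen_validation_error")
  }
  P <- sum(corpus$label == "relevant")
  labels <- corpus$label[pos]
  steps <- tibble::tibble(step = seq_along(order_ids), id = order_ids,
                          label = labels, score = NA_real_)
  found_all <- sum(labels == "relevant") == P && P > 0
  new_trace(steps, m = nrow(corpus), P = P, seed_pair = NULL,
            stop_reason = if (found_all) "all_relevant_found"
                          else "budget_exhausted",
            labels = stats::setNames(corpus$label, corpus$id))
}

#' Enumerate all seed pairs of relevant articles
#'
#' All `choose(P, 2)` unordered pairs of relevant ids, in lexicographic
#' order - the trial set of an exhaustive seed-pair sweep.
#'
#' @param corpus Labelled corpus with `P >= 2` relevant articles.
#' @return A tibble with columns `seed1`, `seed2` (seed1 < seed2).
#' @export
relevant_seed_pairs <- function(corpus) {
  corpus <- as_corpus(corpus)
  rel <- relevant_ids(corpus)
  if (length(rel) < 2) {
    abort("need at least 2 relevant articles to form seed pairs",
          class = "citescreen_validation_error")
  }
  pairs <- combn(rel, 2)
  tibble::tibble(seed1 = pairs[1, ], seed2 = pairs[2, ])
}

#' @export
print.screening_trace <- function(x, ...) {
  cat(sprintf(
    "# screening trace: %d reads of %d articles (%d relevant), stop: %s\n",
    nrow(x$steps), x$m, x$P, x$stop_reason))
  if (!is.null(x$seed_pair)) {
    cat(sprintf("# seeds: %s, %s\n", x$seed_pair[1], x$seed_pair[2]))
  }
  print(x$steps, ...)
  invisible(x)
}
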