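#' Build a screening corpus from a data frame
#'
#' A screening corpus is a tibble with one row per bibliographic record and
#' columns `id`, `title`, `abstract` and `label`. The label records the
#' screening ground truth: `"relevant"` (included by the review), `"irrelevant"`
#' (retrieved by the search but excluded) or `"unknown"` (not yet screened;
#' permitted at the I/O level so prospective use is possible, but rejected by
#' [run_screening()]).
#'
#' Label values are normalised case-insensitively; the aliases `include`,
#' `included` and `correct` map to `relevant`, and `exclude`, `excluded` and
#' `incorrect` map to `irrelevant`. Missing or empty labels become `unknown`.
#'
#' @param x A data frame with columns `id`, `title`, `abstract` and optionally
#'   `label` (absent means all `unknown`).
#' @return A tibble of class `screen_corpus`, preserving input row order.
#' @examples
#' corpus <- as_corpus(data.frame(
#'   id = c("a", "b"), title = c("t1", "t2"),
#'   abstract = c("first abstract", "second abstract"),
#'   label = c("include", "exclude")
#' ))
#' glance(corpus)
#' @export
as_corpus <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("id", "title", "abstract")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "citescreen_format_error")
  }
  out <- tibble::tibble(
    id = as.character(x$id),
    title = dplyr::coalesce(as.character(x$title), ""),
    abstract = dplyr::coalesce(as.character(x$abstract), ""),
    label = normalise_labels(if ("label" %in% names(x)) x$label else NULL,
                             nrow(x))
  )
  validate_corpus(out)
}

normalise_labels <- function(label, n) {
  if (is.null(label)) return(rep("unknown", n))
  raw <- tolower(trimws(as.character(label)))
  raw[is.na(raw) | raw == ""] <- "unknown"
  map <- c(
    relevant = "relevant", include = "relevant", included = "relevant",
    correct = "relevant", "1" = "relevant", "true" = "relevant",
    irrelevant = "irrelevant", exclude = "irrelevant",
    excluded = "irrelevant", incorrect = "irrelevant", "0" = "irrelevant",
    "false" = "irrelevant", unknown = "unknown"
  )
  bad <- setdiff(unique(raw), names(map))
  if (length(bad) > 0) {
    abort(paste0("unrecognised label value(s): ", paste(bad, collapse = ", ")),
          class = "citescreen_validation_error")
  }
  unname(map[raw])
}

validate_corpus <- function(corpus) {
  if (any(is.na(corpus$id) | corpus$id == "")) {
    abort("every article must have a non-empty id",
          class = "citescreen_validation_error")
  }
  dup <- corpus$id[duplicated(corpus$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate article id(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "citescreen_validation_error")
  }
  bad <- any(!validUTF8(corpus$id) | !validUTF8(corpus$title) |
               !validUTF8(corpus$abstract))
  if (bad) {
    abort("corpus text contains bytes that are not valid UTF-8",
          class = "citescreen_validation_error")
  }
  class(corpus) <- c("screen_corpus", class(tibble::tibble()))
  corpus
}

#' Attach relevance labels from a list of included ids
#'
#' Marks the listed ids `relevant` and every other article `irrelevant`,
#' mirroring how ground truth is derived retrospectively: the relevant set is
#' the set of articles the finished review actually included.
#'
#' @param corpus A screening corpus.
#' @param relevant_ids Character vector of article ids to label relevant.
#' @return The corpus with labels replaced.
#' @export
attach_labels <- function(corpus, relevant_ids) {
  corpus <- as_corpus(corpus)
  relevant_ids <- as.character(relevant_ids)
  unknown_ids <- setdiff(relevant_ids, corpus$id)
  if (length(unknown_ids) > 0) {
    abort(paste0("relevant_ids not present in corpus: ",
                 paste(unknown_ids, collapse = ", ")),
          class = "citescreen_validation_error")
  }
  corpus$label <- ifelse(corpus$id %in% relevant_ids, "relevant", "irrelevant")
  validate_corpus(corpus)
}

#' @export
glance.screen_corpus <- function(x, ...) {
  tibble::tibble(
    m = nrow(x),
    n_relevant = sum(x$label == "relevant"),
    n_irrelevant = sum(x$label == "irrelevant"),
    n_unknown = sum(x$label == "unknown")
  )
}

relevant_ids <- function(corpus) sort(corpus$id[corpus$label == "relevant"])

#' @export
print.screen_corpus <- function(x, ...) {
  cat(sprintf("# screening corpus: %d articles (%d relevant, %d irrelevant, %d unknown)\n",
              nrow(x), sum(x$label == "relevant"),
              sum(x$label == "irrelevant"), sum(x$label == "unknown")))
  NextMethod()
}
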