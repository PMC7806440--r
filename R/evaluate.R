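#' Cumulative recall curve of a screening trace
#'
#' @param trace A `screening_trace`.
#' @return A tibble with one row per read: `reads`, `found` (cumulative
#'   relevant articles), `recall` = found / P.
#' @export
recall_curve <- function(trace) {
  stopifnot(inherits(trace, "screening_trace"))
  if (trace$P == 0) {
    abort("recall is undefined for a corpus with no relevant articles",
          class = "citescreen_validation_error")
  }
  found <- cumsum(trace$steps$label == "relevant")
  tibble::tibble(reads = trace$steps$step, found = found,
                 recall = found / trace$P)
}

#' Fraction of the corpus read at stop
#'
#' @param trace A `screening_trace`.
#' @return Reads divided by corpus size; `1 - reading_ratio` is the workload
#'   reduction at full recall.
#' @export
reading_ratio <- function(trace) {
  stopifnot(inherits(trace, "screening_trace"))
  if (trace$m == 0) {
    abort("empty corpus", class = "citescreen_validation_error")
  }
  nrow(trace$steps) / trace$m
}

#' Work saved over sampling at a recall level
#'
#' WSS@R compares prioritised screening with reading the corpus in random
#' order: `wss = (N - n_read) / N - (1 - R/100)`, where `n_read` is the
#' number of reads at which recall first reaches `R`% - concretely, the
#' first step at which at least `ceiling(R/100 * P)` relevant articles have
#' been read. No interpolation between steps is applied.
#'
#' @param trace A `screening_trace`.
#' @param recall_target Recall level R as a percent in `(0, 100]`; several
#'   may be given.
#' @return A tibble with columns `recall_target`, `n_read`, `wss`,
#'   `attained`. When the trace never reaches the target recall (possible
#'   under a reading budget), `n_read` and `wss` are `NA` and `attained` is
#'   `FALSE`.
#' @export
wss_at <- function(trace, recall_target = c(95, 100)) {
  stopifnot(inherits(trace, "screening_trace"))
  if (any(recall_target <= 0 | recall_target > 100)) {
    abort("recall_target must lie in (0, 100]",
          class = "citescreen_validation_error")
  }
  if (trace$P == 0) {
    abort("WSS is undefined for a corpus with no relevant articles",
          class = "citescreen_validation_error")
  }
  found <- cumsum(trace$steps$label == "relevant")
  N <- trace$m
  purrr::map_dfr(recall_target, function(R) {
    need <- ceiling(R / 100 * trace$P)
    hit <- which(found >= need)
    if (length(hit) == 0) {
      return(tibble::tibble(recall_target = R, n_read = NA_integer_,
                            wss = NA_real_, attained = FALSE))
    }
    n_read <- trace$steps$step[hit[1]]
    # computed as R/100 - n_read/N, the algebraically identical form of
    # (N - n_read)/N - (1 - R/100): it keeps WSS@100 bit-identical to
    # 1 - reading_ratio
    tibble::tibble(recall_target = R, n_read = n_read,
                   wss = R / 100 - n_read / N, attained = TRUE)
  })
}

#' Area under the ROC curve from scores and labels
#'
#' The Mann-Whitney formulation: the probability that a randomly chosen
#' relevant article outscores a randomly chosen irrelevant one, with ties
#' counted one half. Computed from midranks. Articles with undefined (`NA`)
#' scores are excluded; the result is `NA` unless at least one relevant and
#' one irrelevant article have defined scores.
#'
#' @param scores Numeric scores (`NA` = undefined).
#' @param labels Labels aligned with `scores`; anything equal to
#'   `"relevant"` (or `TRUE`) counts as the positive class.
#' @return AUROC in `[0, 1]`, or `NA`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels differ in length",
          class = "citescreen_validation_error")
  }
  pos <- if (is.logical(labels)) labels else labels == "relevant"
  keep <- !is.na(scores)
  scores <- scores[keep]
  pos <- pos[keep]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-step AUROC trajectory of a screening run
#'
#' At each post-seed step, the AUROC over the articles still unscreened at
#' that moment, using the scores the query assigned just before the step's
#' selection. Requires the trace to have been run with `keep_scores = TRUE`.
#' Steps where the unscreened pool is single-class (for example, once every
#' relevant article has been found) have undefined AUROC and are returned as
#' `NA`; aggregate summaries omit them.
#'
#' @param trace A `screening_trace` from [run_screening()].
#' @return A tibble with columns `step`, `n_unscreened`, `auroc`.
#' @export
auroc_trace <- function(trace) {
  stopifnot(inherits(trace, "screening_trace"))
  if (is.null(trace$history)) {
    abort("trace has no score snapshots; rerun with keep_scores = TRUE",
          class = "citescreen_validation_error")
  }
  H <- trace$history
  lab <- unname(trace$labels[colnames(H)])
  purrr::map_dfr(seq_len(nrow(H)), function(s) {
    x <- H[s, ]
    unscreened <- !(is.na(x) & !is.nan(x)) # NA (not NaN) marks screened
    sc <- x[unscreened]
    sc[is.nan(sc)] <- NA_real_
    tibble::tibble(step = s + 2L, n_unscreened = sum(unscreened),
                   auroc = auroc(sc, lab[unscreened]))
  })
}

#' Sweep every seed pair and aggregate
#'
#' Runs one screening simulation per unordered pair of relevant articles
#' (all `choose(P, 2)` of them) and aggregates work saved over sampling and
#' the final-step AUROC across pairs, together with the across-pair mean
#' cumulative recall curve and mean per-step AUROC trajectory.
#'
#' @param F Feature matrix.
#' @param corpus Fully labelled corpus with `P >= 2`.
#' @param budget Optional per-run reading budget.
#' @param keep_auroc Compute per-step AUROC trajectories (requires score
#'   snapshots; disable to save memory on very large corpora).
#' @return A `screening_sweep` object; see [tidy.screening_sweep()] and
#'   [glance.screening_sweep()].
#' @export
sweep_seed_pairs <- function(F, corpus, budget = NULL, keep_auroc = TRUE) {
  corpus <- as_corpus(corpus)
  pairs <- relevant_seed_pairs(corpus)
  m <- nrow(corpus)

  per_pair <- vector("list", nrow(pairs))
  recall_sum <- numeric(m)
  recall_sq <- numeric(m)
  auroc_acc <- list()

  for (i in seq_len(nrow(pairs))) {
    sp <- c(pairs$seed1[i], pairs$seed2[i])
    tr <- run_screening(F, corpus, sp, budget = budget,
                        keep_scores = keep_auroc)
    w <- wss_at(tr, c(95, 100))
    final_auc <- NA_real_
    if (keep_auroc) {
      at <- auroc_trace(tr)
      def <- at[!is.na(at$auroc), ]
      if (nrow(def) > 0) final_auc <- def$auroc[nrow(def)]
      auroc_acc[[i]] <- at
    }
    per_pair[[i]] <- tibble::tibble(
      seed1 = sp[1], seed2 = sp[2], reads = nrow(tr$steps),
      stop_reason = tr$stop_reason,
      n_read95 = w$n_read[1], wss95 = w$wss[1],
      n_read100 = w$n_read[2], wss100 = w$wss[2],
      auroc_final = final_auc
    )
    # recall extended to the full corpus length: after an all-found stop the
    # curve stays at 1
    rc <- recall_curve(tr)
    full <- c(rc$recall, rep(rc$recall[nrow(rc)], m - nrow(rc)))
    recall_sum <- recall_sum + full
    recall_sq <- recall_sq + full^2
  }

  n_pairs <- nrow(pairs)
  mean_recall <- recall_sum / n_pairs
  sd_recall <- sqrt(pmax(0, recall_sq / n_pairs - mean_recall^2) *
                      n_pairs / max(1, n_pairs - 1))
  recall_tbl <- tibble::tibble(reads = seq_len(m), mean_recall = mean_recall,
                               sd_recall = sd_recall)

  auroc_tbl <- NULL
  if (keep_auroc) {
    auroc_tbl <- dplyr::bind_rows(auroc_acc) |>
      dplyr::filter(!is.na(.data$auroc)) |>
      dplyr::group_by(.data$step) |>
      dplyr::summarise(mean_auroc = mean(.data$auroc),
                       sd_auroc = ifelse(dplyr::n() > 1, sd(.data$auroc), 0),
                       n_pairs = dplyr::n(), .groups = "drop")
  }

  structure(list(pairs = dplyr::bind_rows(per_pair), pair_count = n_pairs,
                 m = m, P = sum(corpus$label == "relevant"),
                 recall = recall_tbl, auroc_steps = auroc_tbl),
            class = "screening_sweep")
}

#' @export
print.screening_sweep <- function(x, ...) {
  cat(sprintf("# seed-pair sweep: %d pairs over %d articles (%d relevant)\n",
              x$pair_count, x$m, x$P))
  print(glance(x), ...)
  invisible(x)
}
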