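#' Tidy a screening trace
#'
#' One row per read, in reading order, augmented with the cumulative
#' quantities used for evaluation and export.
#'
#' @param x A `screening_trace`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `id`, `label`, `score`,
#'   `cum_relevant`, `cum_read`, `recall`, `fraction_read`.
#' @export
tidy.screening_trace <- function(x, ...) {
  cum_rel <- cumsum(x$steps$label == "relevant")
  dplyr::mutate(x$steps,
                cum_relevant = cum_rel,
                cum_read = x$steps$step,
                recall = cum_rel / x$P,
                fraction_read = x$steps$step / x$m)
}

#' One-row summary of a screening trace
#'
#' @param x A `screening_trace`.
#' @param ... Unused.
#' @return A tibble with reads, reading ratio, WSS at 95 and 100, and the
#'   stop reason.
#' @export
glance.screening_trace <- function(x, ...) {
  w <- wss_at(x, c(95, 100))
  tibble::tibble(
    m = x$m, P = x$P, reads = nrow(x$steps),
    reading_ratio = reading_ratio(x),
    n_read95 = w$n_read[1], wss95 = w$wss[1],
    n_read100 = w$n_read[2], wss100 = w$wss[2],
    stop_reason = x$stop_reason
  )
}

#' Per-seed-pair results of a sweep
#'
#' @param x A `screening_sweep`.
#' @param ... Unused.
#' @return A tibble with one row per seed pair: reads, WSS@95, WSS@100 and
#'   final-step AUROC.
#' @export
tidy.screening_sweep <- function(x, ...) x$pairs

#' Aggregate summary of a seed-pair sweep
#'
#' @param x A `screening_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with pair count and mean/sd/min/max of WSS@95,
#'   WSS@100 and the final-step AUROC across seed pairs.
#' @export
glance.screening_sweep <- function(x, ...) {
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) sd(v) else 0, min(v), max(v))
  }
  w95 <- agg(x$pairs$wss95)
  w100 <- agg(x$pairs$wss100)
  auc <- agg(x$pairs$auroc_final)
  tibble::tibble(
    pair_count = x$pair_count,
    wss95_mean = w95[1], wss95_sd = w95[2], wss95_min = w95[3],
    wss95_max = w95[4],
    wss100_mean = w100[1], wss100_sd = w100[2], wss100_min = w100[3],
    wss100_max = w100[4],
    auroc_mean = auc[1], auroc_sd = auc[2], auroc_min = auc[3],
    auroc_max = auc[4]
  )
}

#' Export a sweep summary as JSON
#'
#' @param x A `screening_sweep`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_json <- function(x, path) {
  stopifnot(inherits(x, "screening_sweep"))
  g <- glance(x)
  out <- list(
    pair_count = g$pair_count,
    wss95 = list(mean = g$wss95_mean, sd = g$wss95_sd, min = g$wss95_min,
                 max = g$wss95_max),
    wss100 = list(mean = g$wss100_mean, sd = g$wss100_sd, min = g$wss100_min,
                  max = g$wss100_max),
    auroc_final = list(mean = g$auroc_mean, sd = g$auroc_sd,
                       min = g$auroc_min, max = g$auroc_max)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
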