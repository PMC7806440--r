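# Fixture builders and independent reference implementations used across the
# suite. The references recompute everything from scratch with explicit loops
# and share no code with the package internals.

tmp_text_file <- function(lines, ext = "txt") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path, useBytes = TRUE)
  path
}

toy_corpus <- function(m = 6, P = 2, labels = NULL) {
  ids <- sprintf("a%02d", seq_len(m))
  if (is.null(labels)) {
    labels <- c(rep("relevant", P), rep("irrelevant", m - P))
  }
  as_corpus(data.frame(
    id = ids,
    title = paste("title", ids),
    abstract = paste("abstract text for", ids),
    label = labels
  ))
}

# random fully-labelled corpus plus a random dense feature matrix; used where
# the text itself is irrelevant (screening-loop and evaluation tests)
random_screening_problem <- function(m, n = 4, P = NULL) {
  if (is.null(P)) P <- sample(2:max(2, min(m, 5)), 1)
  ids <- sprintf("r%03d", seq_len(m))
  labels <- rep("irrelevant", m)
  labels[sample.int(m, P)] <- "relevant"
  corpus <- as_corpus(data.frame(id = ids, title = ids, abstract = ids,
                                 label = labels))
  F <- matrix(rnorm(m * n), nrow = m, dimnames = list(ids, NULL))
  list(corpus = corpus, F = F)
}

# --- naive reference for the screening loop --------------------------------
# Recomputes means and every cosine from scratch at each step, no caching,
# base loops only. Returns the ordered ids read.
reference_screening_order <- function(F, corpus, seed_pair) {
  ids <- corpus$id
  labels <- stats::setNames(corpus$label, ids)
  P <- sum(labels == "relevant")
  read <- as.character(seed_pair)
  cos_manual <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) NA_real_ else sum(u * v) / (nu * nv)
  }
  while (sum(labels[read] == "relevant") < P) {
    rel <- read[labels[read] == "relevant"]
    irr <- read[labels[read] == "irrelevant"]
    q <- rep(0, ncol(F))
    for (id in rel) q <- q + F[id, ] / length(rel)
    if (length(irr) > 0) {
      qi <- rep(0, ncol(F))
      for (id in irr) qi <- qi + F[id, ] / length(irr)
      q <- q - qi
    }
    unscreened <- setdiff(ids, read)
    scores <- vapply(unscreened, function(id) cos_manual(q, F[id, ]),
                     numeric(1))
    if (all(is.na(scores))) {
      pick <- sort(unscreened)[1]
    } else {
      best <- max(scores, na.rm = TRUE)
      pick <- sort(unscreened[!is.na(scores) & scores == best])[1]
    }
    read <- c(read, pick)
  }
  read
}

# --- brute-force AUROC ------------------------------------------------------
# Exhaustive pair counting: concordant pairs plus half of ties.
auroc_brute <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  pos <- (labels == "relevant")[keep]
  sp <- scores[pos]; sn <- scores[!pos]
  if (length(sp) == 0 || length(sn) == 0) return(NA_real_)
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}
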