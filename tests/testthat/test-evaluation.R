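test_that("recall curve counts cumulative relevant reads", {
  corpus <- toy_corpus(m = 10, P = 2)
  trace <- manual_trace(corpus, c("a01", "a02"))
  rc <- recall_curve(trace)
  expect_equal(rc$reads, c(1, 2))
  expect_equal(rc$recall, c(0.5, 1.0))

  # recall flat over irrelevant reads, monotone overall, 1 at an all-found stop
  corpus5 <- toy_corpus(m = 8, P = 3)
  trace5 <- manual_trace(corpus5, c("a01", "a04", "a05", "a02", "a03"))
  rc5 <- recall_curve(trace5)
  expect_equal(rc5$recall, c(1, 1, 1, 2, 3) / 3)
  expect_true(all(diff(rc5$recall) >= 0))
  expect_equal(rc5$recall[nrow(rc5)], 1)
})

test_that("reading ratio is reads over corpus size", {
  corpus <- toy_corpus(m = 10, P = 2)
  expect_equal(reading_ratio(manual_trace(corpus, c("a01", "a02"))), 0.2)
  full <- manual_trace(corpus, corpus$id)
  expect_equal(reading_ratio(full), 1.0)
})

test_that("WSS follows its formula at the worked and derived cases", {
  # corpus of 1000, all relevant found at the 200th read: 20% reading ratio,
  # 80% of the screening work avoided at full recall
  ids <- sprintf("art%04d", 1:1000)
  labels <- rep("irrelevant", 1000)
  labels[c(1:9, 1000)] <- "relevant"
  corpus <- as_corpus(data.frame(id = ids, title = ids, abstract = ids,
                                 label = labels))
  order_ids <- c(ids[1:9], ids[10:199], ids[1000])
  trace <- manual_trace(corpus, order_ids)
  expect_equal(reading_ratio(trace), 0.20)
  w <- wss_at(trace, 100)
  expect_equal(w$n_read, 200)
  expect_equal(w$wss, 0.80)

  # perfect ranking, N=100, P=20: 95% recall needs ceiling(19) = 19 reads
  ids2 <- sprintf("b%03d", 1:100)
  labels2 <- c(rep("relevant", 20), rep("irrelevant", 80))
  corpus2 <- as_corpus(data.frame(id = ids2, title = ids2, abstract = ids2,
                                  label = labels2))
  perfect <- manual_trace(corpus2, ids2[1:20])
  w95 <- wss_at(perfect, 95)
  expect_equal(w95$n_read, 19)
  expect_equal(w95$wss, (100 - 19) / 100 - 0.05)

  # worst case: target recall reached only at the very last read (n_read = N)
  labels3 <- c(rep("relevant", 2), rep("irrelevant", 98))
  corpus3 <- as_corpus(data.frame(id = ids2, title = ids2, abstract = ids2,
                                  label = labels3))
  worst <- manual_trace(corpus3, c(ids2[3:100], ids2[1:2]))
  expect_equal(wss_at(worst, 95)$n_read, 100)
  expect_equal(wss_at(worst, 95)$wss, -0.05)

  expect_error(wss_at(perfect, 0), class = "citescreen_validation_error")
  expect_error(wss_at(perfect, 101), class = "citescreen_validation_error")
})

test_that("unattained recall under a budget is flagged, not fabricated", {
  prob <- withr::with_seed(1, random_screening_problem(15, P = 4))
  sp <- relevant_seed_pairs(prob$corpus)[1, ]
  trace <- run_screening(prob$F, prob$corpus, c(sp$seed1, sp$seed2),
                         budget = 3)
  w <- wss_at(trace, 100)
  expect_false(w$attained)
  expect_true(is.na(w$wss))
})

test_that("AUROC matches exhaustive pair counting and handles ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.3), c("relevant", "irrelevant",
                                         "relevant")), 0.5)
  expect_equal(auroc(c(1, 1, 1), c("relevant", "irrelevant", "relevant")),
               0.5)
  expect_equal(auroc(c(5, 4, 1, 0), c("relevant", "relevant", "irrelevant",
                                      "irrelevant")), 1.0)
  expect_true(is.na(auroc(c(1, 2), c("relevant", "relevant"))))

  withr::with_seed(11, {
    for (rep in 1:50) {
      n <- sample(2:12, 1)
      scores <- sample(c(rnorm(n), round(rnorm(n), 1)), n) # some exact ties
      labels <- sample(c("relevant", "irrelevant"), n, replace = TRUE)
      expect_equal(auroc(scores, labels), auroc_brute(scores, labels))
    }
  })
})

test_that("per-step AUROC is computed over the unscreened pool", {
  # separable geometry: discrimination should be perfect at every step
  corpus <- toy_corpus(m = 6, P = 3)
  F <- matrix(c(1, 0,
                0.95, 0.05,
                0.9, 0.1,
                0, 1,
                0.05, 1,
                0.1, 1), nrow = 6, byrow = TRUE,
              dimnames = list(corpus$id, NULL))
  trace <- run_screening(F, corpus, c("a01", "a02"))
  at <- auroc_trace(trace)
  expect_equal(at$auroc[1], 1.0) # one relevant left, scored top
  expect_equal(at$n_unscreened[1], 4)

  # a single-class unscreened pool has undefined AUROC: here the lone
  # irrelevant article out-scores the last relevant and is read first
  mini <- toy_corpus(m = 4, P = 3)
  Fm <- matrix(c(1, 0,
                 1, 0,
                 0.5, 0.5,
                 0.99, 0.01), nrow = 4, byrow = TRUE,
               dimnames = list(mini$id, NULL))
  at_m <- auroc_trace(run_screening(Fm, mini, c("a01", "a02")))
  expect_false(is.na(at_m$auroc[1])) # mixed pool at step 3
  expect_true(is.na(at_m$auroc[2]))  # only the relevant article remains

  no_hist <- run_screening(F, corpus, c("a01", "a02"), keep_scores = FALSE)
  expect_error(auroc_trace(no_hist), class = "citescreen_validation_error")
})

test_that("per-step AUROC agrees with direct recomputation from snapshots", {
  prob <- withr::with_seed(3, random_screening_problem(14, P = 4))
  sp <- relevant_seed_pairs(prob$corpus)[2, ]
  trace <- run_screening(prob$F, prob$corpus, c(sp$seed1, sp$seed2))
  at <- auroc_trace(trace)
  H <- trace$history
  for (s in seq_len(nrow(H))) {
    x <- H[s, ]
    unscr <- !(is.na(x) & !is.nan(x))
    sc <- x[unscr]; sc[is.nan(sc)] <- NA
    lb <- unname(trace$labels[colnames(H)])[unscr]
    expect_equal(at$auroc[s], auroc_brute(sc, lb))
  }
})

test_that("sweeps cover every seed pair and aggregate order statistics", {
  prob <- withr::with_seed(8, random_screening_problem(18, P = 5))
  sw <- sweep_seed_pairs(prob$F, prob$corpus)
  expect_equal(sw$pair_count, choose(5, 2))
  expect_equal(nrow(tidy(sw)), 10)
  g <- glance(sw)
  expect_lte(g$wss95_min, g$wss95_mean)
  expect_lte(g$wss95_mean, g$wss95_max)
  expect_gte(g$wss95_sd, 0)
  # the mean recall curve is monotone and ends at 1
  expect_true(all(diff(sw$recall$mean_recall) >= -1e-12))
  expect_equal(sw$recall$mean_recall[nrow(sw$recall)], 1)

  # degenerate dispersion: identical runs give zero SD
  sep <- toy_corpus(m = 5, P = 3)
  Fsep <- matrix(c(1, 0, 1, 0, 1, 0, 0, 1, 0, 1), nrow = 5, byrow = TRUE,
                 dimnames = list(sep$id, NULL))
  gsep <- glance(sweep_seed_pairs(Fsep, sep))
  expect_equal(gsep$wss95_sd, 0)
})

test_that("sweep JSON export round-trips the aggregates", {
  prob <- withr::with_seed(5, random_screening_problem(12, P = 3))
  sw <- sweep_seed_pairs(prob$F, prob$corpus)
  path <- withr::local_tempfile(fileext = ".json")
  write_sweep_json(sw, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$pair_count, 3)
  expect_equal(back$wss95$mean, glance(sw)$wss95_mean)
})
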