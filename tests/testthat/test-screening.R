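test_that("query initialisation and update follow the feedback arithmetic", {
  corpus <- toy_corpus(m = 4, P = 2)
  F <- matrix(c(1, 0,
                0, 1,
                2, 0,
                0, 2), nrow = 4, byrow = TRUE,
              dimnames = list(corpus$id, NULL))
  q <- init_query(F, corpus, c("a01", "a02"))
  expect_equal(unname(q), c(0.5, 0.5))

  # identical rows: mean is idempotent
  F2 <- F; F2["a02", ] <- F2["a01", ]
  expect_equal(unname(init_query(F2, corpus, c("a01", "a02"))), c(1, 0))

  expect_error(init_query(F, corpus, c("a01", "a01")),
               class = "citescreen_validation_error")
  expect_error(init_query(F, corpus, c("a01", "a03")),
               class = "citescreen_validation_error") # a03 not relevant

  expect_equal(unname(update_query(F, "a03", "a04")), c(2, -2))
  expect_equal(unname(update_query(F, c("a03", "a04"))), c(1, 1))
  expect_error(update_query(F, character()),
               class = "citescreen_validation_error")
})

test_that("scoring and selection rank by cosine with deterministic ties", {
  ids <- c("a", "b", "z")
  F <- matrix(c(2, 0,
                0, 3,
                0, 0), nrow = 3, byrow = TRUE, dimnames = list(ids, NULL))
  s <- score_unscreened(F, c(1, 0), ids)
  expect_equal(s[["a"]], 1)
  expect_equal(s[["b"]], 0)
  expect_true(is.na(s[["z"]])) # zero-norm row -> undefined

  expect_equal(select_next(c(a = 0.9, b = 0.9, c = 0.1)), "a")
  expect_equal(select_next(c(z = 0.2)), "z")
  # undefined never outranks a defined score
  expect_equal(select_next(c(u = NA_real_, v = -0.5)), "v")
  expect_equal(select_next(c(u = NA_real_, t = NA_real_)), "t")
  expect_error(select_next(numeric(0)), class = "citescreen_validation_error")
  expect_length(score_unscreened(F, c(1, 0), character()), 0)
})

test_that("a hand-built separable problem is screened in the derived order", {
  # two seed relevants at [1,0], a third relevant near them, two irrelevant
  # articles near [0,1]: the third relevant must be read at step 3 and the
  # run must stop there
  corpus <- toy_corpus(m = 5, P = 3)
  F <- matrix(c(1, 0,
                1, 0,
                0.9, 0.1,
                0, 1,
                0.1, 1), nrow = 5, byrow = TRUE,
              dimnames = list(corpus$id, NULL))
  trace <- run_screening(F, corpus, c("a01", "a02"))
  expect_equal(nrow(trace$steps), 3)
  expect_equal(trace$steps$id, c("a01", "a02", "a03"))
  expect_equal(trace$stop_reason, "all_relevant_found")
  expect_equal(trace$steps$score[3],
               cosine_similarity(c(1, 0), c(0.9, 0.1)))
})

test_that("exhaustive and budgeted stops behave as contracted", {
  all_rel <- toy_corpus(m = 4, P = 4)
  F <- matrix(rnorm(8), nrow = 4, dimnames = list(all_rel$id, NULL))
  trace <- run_screening(F, all_rel, c("a01", "a02"))
  expect_equal(nrow(trace$steps), 4)
  expect_equal(trace$stop_reason, "all_relevant_found")

  prob <- withr::with_seed(42, random_screening_problem(12, P = 5))
  sp <- relevant_seed_pairs(prob$corpus)[1, ]
  budgeted <- run_screening(prob$F, prob$corpus, c(sp$seed1, sp$seed2),
                            budget = 3)
  expect_equal(nrow(budgeted$steps), 3)
  expect_equal(budgeted$stop_reason, "budget_exhausted")
})

test_that("zero feature matrix falls back to id-order reading", {
  corpus <- toy_corpus(m = 5, P = 3)
  F <- matrix(0, nrow = 5, ncol = 3, dimnames = list(corpus$id, NULL))
  trace <- run_screening(F, corpus, c("a02", "a03"))
  # all scores undefined at every step: remaining ids read lexicographically
  expect_equal(trace$steps$id, c("a02", "a03", "a01"))
  expect_true(all(is.na(trace$steps$score)))
})

test_that("unknown labels and bad seeds are rejected", {
  corpus <- toy_corpus(m = 4, P = 2,
                       labels = c("relevant", "relevant", "unknown",
                                  "irrelevant"))
  F <- matrix(rnorm(8), nrow = 4, dimnames = list(corpus$id, NULL))
  expect_error(run_screening(F, corpus, c("a01", "a02")),
               class = "citescreen_validation_error")
})

test_that("traces are deterministic and maintain the partition invariants", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      prob <- random_screening_problem(sample(6:15, 1))
      sp <- relevant_seed_pairs(prob$corpus)[1, ]
      t1 <- run_screening(prob$F, prob$corpus, c(sp$seed1, sp$seed2))
      t2 <- run_screening(prob$F, prob$corpus, c(sp$seed1, sp$seed2))
      expect_identical(t1$steps, t2$steps)
      # no article read twice, read count bounded by m
      expect_equal(anyDuplicated(t1$steps$id), 0)
      expect_lte(nrow(t1$steps), nrow(prob$corpus))
      # monotone recall reaching P at stop
      found <- cumsum(t1$steps$label == "relevant")
      expect_true(all(diff(found) >= 0))
      expect_equal(found[length(found)], t1$P)
    }
  })
})

test_that("screening matches the naive from-scratch reference implementation", {
  withr::with_seed(2024, {
    for (rep in 1:8) {
      prob <- random_screening_problem(sample(8:20, 1))
      pairs <- relevant_seed_pairs(prob$corpus)
      for (i in seq_len(nrow(pairs))) {
        sp <- c(pairs$seed1[i], pairs$seed2[i])
        got <- run_screening(prob$F, prob$corpus, sp, keep_scores = FALSE)
        want <- reference_screening_order(prob$F, prob$corpus, sp)
        expect_equal(got$steps$id, want)
      }
    }
  })
})

test_that("seed pairs enumerate all C(P,2) relevant pairs in order", {
  for (P in c(2, 5, 20)) {
    corpus <- toy_corpus(m = P + 3, P = P)
    pairs <- relevant_seed_pairs(corpus)
    expect_equal(nrow(pairs), choose(P, 2))
    expect_true(all(pairs$seed1 < pairs$seed2))
    expect_false(any(duplicated(pairs)))
  }
  expect_error(relevant_seed_pairs(toy_corpus(m = 4, P = 1)),
               class = "citescreen_validation_error")
})

test_that("manual traces classify their stop reason from the labels", {
  corpus <- toy_corpus(m = 6, P = 2)
  full <- manual_trace(corpus, c("a01", "a03", "a02"))
  expect_equal(full$stop_reason, "all_relevant_found")
  partial <- manual_trace(corpus, c("a01", "a03"))
  expect_equal(partial$stop_reason, "budget_exhausted")
  expect_error(manual_trace(corpus, c("a01", "a01")),
               class = "citescreen_validation_error")
  expect_error(manual_trace(corpus, "nope"),
               class = "citescreen_validation_error")
})
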