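# helper: build a minimal hand-made trace from a matrix of word-unit
# activations (rows follow the unit table constructed here)
fake_trace <- function(hist, words, align_idx, lex_words = unique(words),
                       word_id = lex_words[1], span_start = NULL,
                       n_phonemes = 3L) {
  spacing <- 6L
  wu <- tibble::tibble(
    word = words,
    align_idx = as.integer(align_idx),
    align_slice = as.integer(align_idx) * 3L,
    n_phonemes = n_phonemes,
    span_start = if (is.null(span_start)) as.integer(align_idx) * 3L else span_start,
    span_end = (if (is.null(span_start)) as.integer(align_idx) * 3L else span_start) +
      n_phonemes * spacing
  )
  structure(
    list(word_hist = hist, wunits = wu, words = lex_words,
         meta = list(word_id = word_id, noise_sd = 0, feedback_on = TRUE,
                     seed = 1L, n_cycles = ncol(hist))),
    class = "activation_trace"
  )
}

test_that("the Luce rule normalizes, is symmetric, and matches direct arithmetic", {
  expect_equal(luce_choice(0.37, k = 13), 1)
  expect_equal(luce_choice(c(0.4, 0.4), k = 13), c(0.5, 0.5))
  a <- c(0.2, 0.1, -0.05)
  direct <- exp(13 * a) / sum(exp(13 * a))  # unshifted arithmetic
  expect_equal(luce_choice(a, k = 13), direct, tolerance = 1e-12)
  expect_error(luce_choice(numeric(0)), "empty")
  expect_error(luce_choice(c(1, NaN)), "finite")
})

test_that("Luce probabilities are invariant to constant activation shifts", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(2:30, 1))
    k <- runif(1, 2, 20)
    shift <- runif(1, -50, 50)
    p <- luce_choice(a, k)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(luce_choice(a + shift, k), p, tolerance = 1e-9)
  }
  # extreme activations do not overflow thanks to the max shift
  expect_equal(sum(luce_choice(c(1000, 999), k = 20)), 1)
})

test_that("candidate selection filters by window and ranks by peak", {
  set.seed(9)
  n_units <- 120
  hist <- matrix(runif(n_units * 30, -0.3, 1), n_units, 30)
  words <- rep(paste0("w", 1:10), 12)
  align <- rep(0:11, each = 10)
  tr <- fake_trace(hist, words, align)
  dp <- decision_params(n_candidates = 15, candidate_slice_window = 10)
  sel <- select_candidates(tr, dp)
  expect_length(sel, 15)
  expect_true(all(tr$wunits$align_idx[sel] < 10))
  # brute force: sort all (unit, peak) pairs in the window
  eligible <- which(align < 10)
  peaks <- vapply(eligible, function(i) max(hist[i, ]), numeric(1))
  want <- eligible[order(-peaks)][1:15]
  expect_setequal(sel, want)
  # a unit dominating every cycle is ranked first
  hist2 <- hist
  hist2[7, ] <- 2
  expect_equal(select_candidates(fake_trace(hist2, words, align), dp)[1], 7L)
  # fewer units than requested: all are returned
  small <- fake_trace(hist[1:5, , drop = FALSE], words[1:5], align[1:5])
  expect_length(select_candidates(small, decision_params()), 5)
})

test_that("minimal-mode scoring implements the strict no-other-word rule", {
  # two words, one unit each; activations chosen so Luce(k=13) gives a
  # clean crossing pattern
  base <- matrix(-0.1, 2, 50)
  # no unit ever dominates: incorrect, no RT
  tr <- fake_trace(base, c("tgt", "cmp"), c(0, 0), word_id = "tgt")
  out <- score_trial(tr)
  expect_false(out$correct)
  expect_true(is.na(out$rt))

  # only the target crosses, from cycle 40 on
  h <- base
  h[1, 40:50] <- 0.9
  out <- score_trial(fake_trace(h, c("tgt", "cmp"), c(0, 0), word_id = "tgt"))
  expect_true(out$correct)
  expect_equal(out$rt, 40L)

  # a competitor crossing earlier voids the trial even if the target
  # crosses later
  h2 <- base
  h2[2, 10:15] <- 0.9
  h2[1, 40:50] <- 0.9
  out <- score_trial(fake_trace(h2, c("tgt", "cmp"), c(0, 0), word_id = "tgt"))
  expect_false(out$correct)

  # ... and a competitor crossing *after* the target also voids it
  h3 <- base
  h3[1, 20:24] <- 0.9
  h3[2, 40:45] <- 0.9
  out <- score_trial(fake_trace(h3, c("tgt", "cmp"), c(0, 0), word_id = "tgt"))
  expect_false(out$correct)

  expect_error(score_trial(fake_trace(base, c("tgt", "cmp"), c(0, 0)),
                           target_word_id = "absent"),
               "not in lexicon")
})

test_that("threshold crossings are monotone in the criterion", {
  # raising the threshold can only remove crossings: target hits and
  # competitor alarms are each non-increasing, and the RT of a trial that
  # stays correct never decreases. (Overall correctness itself is not
  # monotone under the strict no-other-word rule: a higher criterion can
  # silence a competitor's crossing and thereby rescue a trial.)
  set.seed(21)
  for (i in 1:15) {
    n_units <- 12
    hist <- matrix(runif(n_units * 40, -0.3, 1), n_units, 40)
    words <- rep(paste0("w", 1:4), 3)
    tr <- fake_trace(hist, words, rep(0:2, each = 4), word_id = "w1")
    # independent recomputation of the per-cycle choice probabilities
    dp0 <- decision_params()
    cand <- select_candidates(tr, dp0)
    R <- apply(hist[cand, ], 2, luce_choice, k = dp0$k)
    is_t <- words[cand] == "w1"
    prev <- NULL
    prev_hit <- prev_fa <- NULL
    for (thr in c(0.3, 0.5, 0.7, 0.9)) {
      out <- score_trial(tr, params = decision_params(threshold = thr))
      hit <- any(R[is_t, ] > thr)
      fa <- any(R[!is_t, ] > thr)
      expect_equal(out$correct, hit && !fa)
      if (!is.null(prev)) {
        expect_true(!hit || prev_hit)  # hits non-increasing
        expect_true(!fa || prev_fa)    # alarms non-increasing
        if (out$correct && prev$correct) expect_gte(out$rt, prev$rt)
      }
      prev <- out; prev_hit <- hit; prev_fa <- fa
    }
  }
})

test_that("fp98 legacy scoring sums the aligned target pair", {
  # target unit at alignment 0 and 1; competitor far away in time does not
  # enter the denominator, overlapping one does
  hist <- rbind(
    rep(c(0, 0.45), c(10, 20)),  # tgt align 0
    rep(c(0, 0.45), c(10, 20)),  # tgt align 1
    rep(0.1, 30),                # overlapping competitor
    rep(5, 30)                   # non-overlapping competitor (span elsewhere)
  )
  tr <- fake_trace(hist, c("tgt", "tgt", "cmp", "far"), c(0, 1, 0, 20),
                   word_id = "tgt",
                   span_start = c(0L, 3L, 0L, 60L))
  dp <- fp98_decision_params()
  out <- score_trial(tr, params = dp)
  # summed target activation 0.9 vs one competitor at -0.1: R > 0.9
  expect_true(out$correct)
  expect_equal(out$rt, 11L)
  # with "far" overlapping instead, its huge activation swamps the choice
  tr2 <- fake_trace(hist, c("tgt", "tgt", "cmp", "far"), c(0, 1, 0, 2),
                    word_id = "tgt",
                    span_start = c(0L, 3L, 0L, 6L))
  expect_false(score_trial(tr2, params = dp)$correct)
})

test_that("scoring modes agree when no competitor overlaps the target", {
  # single-word lexicon: trivially no overlapping competitors
  inv <- ortho_inventory()
  lex <- lexicon("pa", list(c("P", "A")), inv)
  tr <- run_trial("pa", lex, inv, tiny_params(), n_cycles = 30,
                  record_phonemes = FALSE)
  a <- score_trial(tr, params = decision_params())
  b <- score_trial(tr, params = fp98_decision_params())
  expect_equal(a$correct, b$correct)
})

test_that("calibration maximizes proportion correct over the grid", {
  lex <- mini_gang_lexicon()
  net <- build_network(lex)
  # one-point grid returns that point
  one <- calibrate_decision(lex, k_grid = 13, threshold_grid = 0.5,
                            network = net, n_cycles = 60)
  expect_equal(one$k, 13)
  expect_equal(one$threshold, 0.5)
  # small grid: the returned point attains the grid maximum, ties broken
  # toward smaller k then larger threshold
  cal <- calibrate_decision(lex, k_grid = c(5, 13), threshold_grid = c(0.3, 0.6),
                            network = net, n_cycles = 60)
  expect_equal(cal$prop_correct, max(cal$grid$prop_correct))
  top <- cal$grid[cal$grid$prop_correct == cal$prop_correct, ]
  expect_equal(cal$k, min(top$k))
  expect_equal(cal$threshold, max(top$threshold[top$k == cal$k]))
  expect_error(calibrate_decision(lex, k_grid = numeric(0), network = net),
               "empty")
})
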