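toy_results <- function() {
  # fixed 12-row table: 3 words x 2 feedback settings x 2 replicates at one
  # noise level
  tibble::tibble(
    word = rep(rep(c("w1", "w2", "w3"), each = 2), 2),
    sd = 0.5,
    feedback = rep(c(TRUE, FALSE), each = 6),
    replicate = rep(1:2, 6),
    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    rt = as.integer(c(40, 50, 60, 60, NA, NA,
                      45, 55, NA, 70, NA, NA)),
    seed = 1L
  )
}

test_that("condition summaries match hand computation", {
  res <- toy_results()
  s <- summarize_conditions(res)
  fb <- s[s$feedback == TRUE, ]
  # item accuracies with feedback: w1 = 1, w2 = 1, w3 = 0 -> mean 2/3
  expect_equal(fb$accuracy, 2 / 3)
  expect_equal(fb$se_accuracy, sd(c(1, 1, 0)) / sqrt(3))
  # item RTs over correct trials: w1 = 45, w2 = 60 -> mean 52.5
  expect_equal(fb$mean_rt, 52.5)
  expect_equal(fb$se_rt, sd(c(45, 60)) / sqrt(2))
  nf <- s[s$feedback == FALSE, ]
  # without feedback: w1 = 1, w2 = 0.5, w3 = 0
  expect_equal(nf$accuracy, 0.5)
  # RT averages over correct trials: w1 = (45 + 55) / 2 = 50, w2 = 70
  expect_equal(nf$mean_rt, 60)

  # all-correct two-trial cell: accuracy 1, mean rt 45
  simple <- tibble::tibble(
    word = c("a", "b"), sd = 0, feedback = TRUE, replicate = 1L,
    correct = TRUE, rt = c(40L, 50L), seed = 1L
  )
  s2 <- summarize_conditions(simple)
  expect_equal(s2$accuracy, 1)
  expect_equal(s2$mean_rt, 45)

  # zero-correct cell: accuracy 0, RT absent (NA, not 0)
  none <- tibble::tibble(
    word = paste0("w", 1:4), sd = 1.5, feedback = FALSE, replicate = 1L,
    correct = FALSE, rt = NA_integer_, seed = 1L
  )
  s3 <- summarize_conditions(none)
  expect_equal(s3$accuracy, 0)
  expect_true(is.na(s3$mean_rt))
})

test_that("item comparison classifies words and tallies the excluded", {
  res <- tibble::tibble(
    word = rep(c("a", "b", "c", "d", "e"), 2),
    sd = 0,
    feedback = rep(c(TRUE, FALSE), each = 5),
    replicate = 1L,
    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                TRUE, TRUE, TRUE, FALSE, TRUE),
    rt = as.integer(c(40, 50, 60, 30, NA,
                      45, 50, 55, NA, 33)),
    seed = 1L
  )
  cmp <- compare_items(res, at_sd = 0)
  expect_equal(cmp$n, 3)
  expect_equal(sort(cmp$items$word), c("a", "b", "c"))
  expect_equal(cmp$items$class[cmp$items$word == "a"], "faster_with")
  expect_equal(cmp$items$class[cmp$items$word == "b"], "equal")
  expect_equal(cmp$items$class[cmp$items$word == "c"], "faster_without")
  expect_equal(unname(cmp$percentages), rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(cmp$percentages), 100, tolerance = 0.1)
  # d correct only with feedback, e only without
  expect_equal(cmp$fb_only_correct, 1)
  expect_equal(cmp$nofb_only_correct, 1)
  expect_error(compare_items(res, at_sd = 0.25), "no trials")
})

test_that("item-comparison percentages match a brute-force recount", {
  set.seed(12)
  words <- paste0("w", 1:20)
  mk <- function(fb) tibble::tibble(
    word = words, sd = 0, feedback = fb, replicate = 1L,
    correct = runif(20) < 0.8,
    rt = sample(30:70, 20, replace = TRUE),
    seed = 1L
  )
  res <- dplyr::bind_rows(mk(TRUE), mk(FALSE))
  res$rt[!res$correct] <- NA_integer_
  cmp <- compare_items(res, at_sd = 0)
  # exhaustive recount
  on <- res[res$feedback & res$correct, ]
  off <- res[!res$feedback & res$correct, ]
  joint <- intersect(on$word, off$word)
  expect_equal(cmp$n, length(joint))
  nw <- sum(vapply(joint, function(w) {
    on$rt[on$word == w] < off$rt[off$word == w]
  }, logical(1)))
  expect_equal(unname(cmp$percentages["faster_with"]), 100 * nw / length(joint))
  expect_equal(sum(cmp$percentages), 100, tolerance = 0.1)
})

test_that("survivor subsets shrink with noise and reclassify the baseline items", {
  res <- dplyr::bind_rows(lapply(c(0, 0.5, 1), function(s) {
    tibble::tibble(
      word = rep(c("a", "b", "c", "d"), 2),
      sd = s,
      feedback = rep(c(TRUE, FALSE), each = 4),
      replicate = 1L,
      # c and d are the sd-0 faster_without items; d drops out at sd 1
      correct = c(TRUE, TRUE, TRUE, s < 1,
                  TRUE, TRUE, TRUE, TRUE),
      rt = as.integer(c(40, 50, 62, 55, 45, 50, 55 + 10 * s, 50)),
      seed = 1L
    )
  }))
  sv <- survivor_subsets(res)
  expect_equal(sort(sv$baseline_words), c("c", "d"))
  expect_equal(sv$summary$survivors, c(2, 2, 1))
  expect_true(all(diff(sv$summary$survivors) <= 0))
  # at sd 1 only c survives; with rt 65 vs 62 it is now faster with feedback
  expect_equal(sv$by_sd[["1"]]$items$word, "c")
  expect_equal(sv$by_sd[["1"]]$items$class, "faster_with")

  # empty baseline class -> empty subsets at every level, no error
  res2 <- res
  res2$rt[res2$sd == 0 & !res2$feedback] <- 99L
  sv2 <- suppressWarnings(survivor_subsets(res2))
  expect_equal(length(sv2$baseline_words), 0)
  expect_true(all(sv2$summary$survivors == 0))
})

test_that("gang reports match brute-force enumeration on random lexicons", {
  for (seed in c(2, 13)) {
    lex <- generate_synthetic_lexicon(
      synthetic_lexicon_spec(n_words = 30, n_gangs = 2, gang_size = 3,
                             n_onset_embeddings = 2, seed = seed))
    for (w in lex$word) expect_same_gangs(lex, w)
  }
  # symmetric consistency: every reported gang member shares the stated
  # mutual prefix with every co-member, and >= 2 phonemes with the target
  lex <- generate_synthetic_lexicon(
    synthetic_lexicon_spec(n_words = 40, n_gangs = 3, gang_size = 4,
                           n_onset_embeddings = 1, seed = 6))
  for (w in lex$word) {
    gr <- gang_report(lex, w)
    tp <- lex$phonemes[[match(w, lex$word)]]
    if (nrow(gr$gangs)) {
      for (i in seq_len(nrow(gr$gangs))) {
        mem <- gr$gangs$members[[i]]
        ph <- lapply(mem, function(m) lex$phonemes[[match(m, lex$word)]])
        for (pa in ph) {
          expect_gte(iatrace:::common_prefix_len(pa, tp), 2)
          for (pb in ph) {
            expect_gte(iatrace:::common_prefix_len(pa, pb),
                       gr$gangs$overlap_len[i])
          }
        }
      }
    }
  }
  # degenerate inputs
  one <- lexicon("solo", list(c("s", "o" = "a")))
  expect_equal(nrow(gang_report(one, "solo")$gangs), 0)
  expect_equal(gang_report(one, "solo")$cohort_size, 0)
})

test_that("architecture counts match the schematic and a graph enumeration", {
  # three phonemes, four words: IAM 7 nodes, comparison model 10
  expect_equal(count_architecture(P = 3, W = 4, L = 3, "iam")$nodes, 7)
  expect_equal(count_architecture(P = 3, W = 4, L = 3, "merge")$nodes, 10)
  # no words: only phoneme nodes, no excitatory connections in the IAM
  w0 <- count_architecture(P = 5, W = 0, L = 3, "iam")
  expect_equal(w0$nodes, 5)
  expect_equal(w0$excitatory, 0)

  # explicit graph enumeration oracle: P = 5 phonemes, W = 6 words of
  # length 3
  P <- 5; W <- 6; L <- 3
  edges_exc <- 0
  for (w in seq_len(W)) edges_exc <- edges_exc + L + L  # ff + fb per word
  got <- count_architecture(P, W, L, "iam")
  expect_equal(got$excitatory, edges_exc)
  expect_equal(count_architecture(P, W, L, "merge")$excitatory, edges_exc + P)
  expect_equal(got$inhibitory_paper, nrow(t(utils::combn(P, 2))) +
                 nrow(t(utils::combn(L, 2))))
  expect_equal(got$inhibitory_alt, nrow(t(utils::combn(P, 2))) +
                 nrow(t(utils::combn(W, 2))))
})

test_that("n-phone connection counts reproduce the printed values", {
  expect_equal(nphone_connections(40, 2), 1560)
  expect_equal(nphone_connections(40, 3), 62400)
  expect_equal(nphone_connections(40, 4), 2496000)
  expect_equal(nphone_connections(1, 5), 0)
  expect_error(nphone_connections(40, 1), "order")
})

test_that("unpruned response-computation cost multiplies out", {
  expect_equal(response_computation_cost(211, 33, 100), 146919300)
  expect_equal(response_computation_cost(4, 33, 100), 52800)
  expect_equal(response_computation_cost(0, 33, 100), 0)
})

test_that("plots build without evaluation errors", {
  res <- toy_results()
  s <- summarize_conditions(res)
  expect_s3_class(plot_accuracy(s), "ggplot")
  expect_s3_class(plot_rt(s), "ggplot")
  cmp <- compare_items(res, at_sd = 0.5)
  expect_s3_class(plot_item_comparison(cmp), "ggplot")
})
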