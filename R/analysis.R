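#' Condition-level accuracy and RT summary
#'
#' Collapses a trial table to one row per (noise sd, feedback) cell:
#' accuracy (proportion correct), mean RT over correct trials only, and
#' the standard error of each across items. A cell with no correct trial
#' reports `mean_rt = NA`, not zero. Failed trials (`correct = NA`) count
#' as errors.
#'
#' @param results a [run_batch()] result table.
#' @return a tibble with columns `sd`, `feedback`, `accuracy`,
#'   `se_accuracy`, `mean_rt`, `se_rt`, `n_items`.
#' @export
summarize_conditions <- function(results) {
  stopifnot(nrow(results) > 0)
  items <- results |>
    dplyr::group_by(.data$sd, .data$feedback, .data$word) |>
    dplyr::summarise(
      acc = mean(.data$correct %in% TRUE),
      rt = if (any(.data$correct %in% TRUE)) {
        mean(.data$rt[.data$correct %in% TRUE])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  items |>
    dplyr::group_by(.data$sd, .data$feedback) |>
    dplyr::summarise(
      accuracy = mean(.data$acc),
      se_accuracy = stats::sd(.data$acc) / sqrt(dplyr::n()),
      mean_rt = if (any(!is.na(.data$rt))) {
        mean(.data$rt, na.rm = TRUE)
      } else {
        NA_real_
      },
      se_rt = if (sum(!is.na(.data$rt)) > 1) {
        stats::sd(.data$rt, na.rm = TRUE) / sqrt(sum(!is.na(.data$rt)))
      } else {
        NA_real_
      },
      n_items = dplyr::n(),
      .groups = "drop"
    )
}

# per-item correctness and RT for one (sd, feedback) cell; an item counts
# as correct only when every replicate of the cell is correct
item_outcomes <- function(results, at_sd, fb) {
  results |>
    dplyr::filter(.data$sd == at_sd, .data$feedback == fb) |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(
      correct = all(.data$correct %in% TRUE),
      rt = if (all(.data$correct %in% TRUE)) mean(.data$rt) else NA_real_,
      .groups = "drop"
    )
}

#' Item-level feedback-advantage comparison at one noise level
#'
#' Restricts to the words recognized correctly under both feedback
#' settings, pairs their RTs, and classifies each word as `faster_with`
#' (feedback RT lower), `faster_without`, or `equal` (exact tie in
#' cycles), with the percentage of each class. Words correct under only
#' one setting are excluded from the paired comparison but tallied
#' separately so accuracy asymmetries stay visible.
#'
#' @param results a [run_batch()] result table containing both feedback
#'   settings at `at_sd`.
#' @param at_sd the noise sd to compare at (default 0).
#' @param words optional restriction to a subset of words (used by
#'   [survivor_subsets()]).
#' @return a list of class `item_comparison`: `items` (word,
#'   `rt_feedback`, `rt_nofeedback`, `class`), `percentages` (named,
#'   summing to 100 when any item qualifies), `n`, `fb_only_correct`,
#'   `nofb_only_correct`, `sd`.
#' @export
compare_items <- function(results, at_sd = 0, words = NULL) {
  sds <- unique(results$sd)
  if (!at_sd %in% sds) stop("no trials at sd = ", at_sd, call. = FALSE)
  if (!all(c(TRUE, FALSE) %in% unique(results$feedback))) {
    stop("both feedback settings are required", call. = FALSE)
  }
  on_tab <- item_outcomes(results, at_sd, TRUE)
  off_tab <- item_outcomes(results, at_sd, FALSE)
  both <- dplyr::inner_join(on_tab, off_tab, by = "word",
                            suffix = c("_feedback", "_nofeedback"))
  if (!is.null(words)) both <- both[both$word %in% words, , drop = FALSE]
  joint <- both[both$correct_feedback & both$correct_nofeedback, ]
  items <- tibble::tibble(
    word = joint$word,
    rt_feedback = joint$rt_feedback,
    rt_nofeedback = joint$rt_nofeedback,
    class = dplyr::case_when(
      joint$rt_feedback < joint$rt_nofeedback ~ "faster_with",
      joint$rt_feedback > joint$rt_nofeedback ~ "faster_without",
      TRUE ~ "equal"
    )
  )
  n <- nrow(items)
  if (n == 0) warning("no items correct under both feedback settings")
  pct <- vapply(c("faster_with", "faster_without", "equal"),
                function(cl) if (n) 100 * sum(items$class == cl) / n else 0,
                numeric(1))
  structure(
    list(
      items = items, percentages = pct, n = n,
      fb_only_correct = sum(both$correct_feedback & !both$correct_nofeedback),
      nofb_only_correct = sum(!both$correct_feedback & both$correct_nofeedback),
      sd = at_sd
    ),
    class = "item_comparison"
  )
}

#' @export
print.item_comparison <- function(x, ...) {
  cat("<item_comparison> sd ", x$sd, ": ", x$n, " items correct in both\n",
      sep = "")
  cat(sprintf("  faster with feedback %.1f%%, faster without %.1f%%, equal %.1f%%\n",
              x$percentages["faster_with"], x$percentages["faster_without"],
              x$percentages["equal"]))
  cat("  correct only with feedback: ", x$fb_only_correct,
      "; only without: ", x$nofb_only_correct, "\n", sep = "")
  invisible(x)
}

#' Track a baseline item class across increasing noise
#'
#' Takes the words in a given class at the lowest noise level (by default
#' the `faster_without` items at sd = 0 — those showing a feedback
#' disadvantage on clean input) and, at each higher noise level,
#' reclassifies the survivors: the baseline words still recognized
#' correctly under both feedback settings. Survivor counts can only
#' shrink as noise grows.
#'
#' @param results a [run_batch()] result table.
#' @param baseline_class item class defining the subset at the baseline sd.
#' @param baseline_sd noise level defining the subset (default the lowest).
#' @return a list of class `survivor_subsets`: `baseline_words`, `by_sd`
#'   (a named list of [compare_items()] results, one per sd at or above
#'   the baseline), and a `summary` tibble of per-sd survivor counts and
#'   class percentages.
#' @export
survivor_subsets <- function(results, baseline_class = "faster_without",
                             baseline_sd = min(results$sd)) {
  base <- compare_items(results, at_sd = baseline_sd)
  words <- base$items$word[base$items$class == baseline_class]
  sds <- sort(unique(results$sd))
  sds <- sds[sds >= baseline_sd]
  by_sd <- lapply(sds, function(s) {
    suppressWarnings(compare_items(results, at_sd = s, words = words))
  })
  names(by_sd) <- as.character(sds)
  summary <- dplyr::bind_rows(lapply(by_sd, function(cmp) {
    tibble::tibble(
      sd = cmp$sd, survivors = cmp$n,
      pct_faster_with = cmp$percentages["faster_with"],
      pct_faster_without = cmp$percentages["faster_without"],
      pct_equal = cmp$percentages["equal"]
    )
  }))
  structure(
    list(baseline_class = baseline_class, baseline_words = words,
         by_sd = by_sd, summary = summary),
    class = "survivor_subsets"
  )
}

#' Structural diagnostics of a target's competitor environment
#'
#' Reports, for one target word: the words onset-embedded in it (strict
#' prefixes of the target, like cow in couch) and the words it is itself
#' a strict onset prefix of; its cohort (words sharing the first
#' `cohort_len` phonemes); and the gang clusters within the cohort —
#' maximal sets of two or more cohort members whose mutual shared onset is
#' strictly longer than the onset they share with the target (the
#' clue vs. clock/clod/clot configuration, where mutual feedback to the
#' gang's shared unheard vowel lets the gang transiently out-activate the
#' target).
#'
#' @param lexicon a [lexicon()].
#' @param target a word of the lexicon.
#' @param cohort_len onset overlap defining the cohort (default 2).
#' @return a list of class `gang_report`: `target`, `embedded_in_target`,
#'   `target_embedded_in`, `cohort`, `cohort_size`, and `gangs` — a tibble
#'   with one row per gang (`prefix`, `size`, `overlap_len`,
#'   `target_overlap`, `members` list-column).
#' @export
gang_report <- function(lexicon, target, cohort_len = 2L) {
  ti <- match(target, lexicon$word)
  if (is.na(ti)) stop("target '", target, "' not in lexicon", call. = FALSE)
  tp <- lexicon$phonemes[[ti]]
  others <- setdiff(seq_len(nrow(lexicon)), ti)
  cpls <- vapply(others, function(i) {
    common_prefix_len(lexicon$phonemes[[i]], tp)
  }, integer(1))
  lens <- lexicon$n_phonemes[others]

  embedded_in_target <- lexicon$word[others[cpls == lens & lens < length(tp)]]
  target_embedded_in <- lexicon$word[others[cpls == length(tp) &
                                              lens > length(tp)]]
  coh_idx <- others[cpls >= cohort_len]
  cohort <- lexicon$word[coh_idx]

  gangs <- tibble::tibble(prefix = character(0), size = integer(0),
                          overlap_len = integer(0),
                          target_overlap = integer(0), members = list())
  if (length(coh_idx) >= 2) {
    # candidate gang prefixes: every onset prefix of every cohort member
    # longer than its overlap with the target
    cand <- list()
    for (i in coh_idx) {
      p <- lexicon$phonemes[[i]]
      if (length(p) <= cohort_len) next
      for (l in seq(cohort_len + 1L, length(p))) {
        pref <- p[seq_len(l)]
        if (common_prefix_len(pref, tp) >= l) next  # target shares it fully
        cand[[paste(pref, collapse = " ")]] <- pref
      }
    }
    hits <- list()
    for (key in names(cand)) {
      pref <- cand[[key]]
      l <- length(pref)
      mem <- coh_idx[vapply(coh_idx, function(i) {
        common_prefix_len(lexicon$phonemes[[i]], pref) >= l
      }, logical(1))]
      if (length(mem) >= 2) {
        hits[[key]] <- list(prefix = pref, members = sort(lexicon$word[mem]))
      }
    }
    if (length(hits)) {
      # keep the longest prefix per distinct member set
      mkey <- vapply(hits, function(h) paste(h$members, collapse = ","),
                     character(1))
      keep <- unlist(lapply(split(seq_along(hits), mkey), function(ii) {
        ii[which.max(vapply(hits[ii], function(h) length(h$prefix), integer(1)))]
      }), use.names = FALSE)
      keep <- sort(keep)
      gangs <- dplyr::bind_rows(lapply(hits[keep], function(h) {
        tibble::tibble(
          prefix = paste(h$prefix, collapse = " "),
          size = length(h$members),
          overlap_len = length(h$prefix),
          target_overlap = common_prefix_len(h$prefix, tp),
          members = list(h$members)
        )
      }))
    }
  }
  structure(
    list(target = target, embedded_in_target = embedded_in_target,
         target_embedded_in = target_embedded_in,
         cohort = cohort, cohort_size = length(cohort),
         cohort_len = as.integer(cohort_len), gangs = gangs),
    class = "gang_report"
  )
}

#' @export
print.gang_report <- function(x, ...) {
  cat("<gang_report> target '", x$target, "': cohort size ", x$cohort_size,
      ", ", nrow(x$gangs), " gang(s), ", length(x$embedded_in_target),
      " word(s) embedded at onset\n", sep = "")
  if (nrow(x$gangs)) {
    for (i in seq_len(nrow(x$gangs))) {
      cat("  gang /", x$gangs$prefix[i], "/ x", x$gangs$size[i],
          " (mutual ", x$gangs$overlap_len[i], ", target ",
          x$gangs$target_overlap[i], "): ",
          paste(x$gangs$members[[i]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Node and connection counts of interactive vs. autonomous architectures
#'
#' For `P` phonemes, `W` words and mean word length `L` (phonemes per
#' word): an interactive-activation model has `P + W` nodes and `2 W L`
#' excitatory connections (one feedforward and one feedback per
#' phoneme-word link); the autonomous comparison architecture adds a bank
#' of `P` phoneme decision nodes (`2 P + W` nodes) and `P` extra
#' excitatory connections. Lateral inhibitory connections are
#' `P(P-1)/2` within the phoneme layer plus a second pairwise term that
#' the source formula writes with `L`; since word-layer inhibition is
#' pairwise over words, the `W`-based reading is also computed, and both
#' are returned side by side (`inhibitory_paper` uses `L`,
#' `inhibitory_alt` uses `W`). Terms with fewer than two elements
#' contribute zero.
#'
#' @param P phoneme count (>= 1).
#' @param W word count (>= 0).
#' @param L mean word length in phonemes (> 0; may be fractional, in
#'   which case the pairwise term generalizes to `L(L-1)/2`).
#' @param model `"iam"` or `"merge"`.
#' @return a one-row tibble: `model`, `nodes`, `excitatory`,
#'   `inhibitory_paper`, `inhibitory_alt`.
#' @export
count_architecture <- function(P, W, L = 3, model = c("iam", "merge")) {
  model <- match.arg(model)
  stopifnot(P >= 1, W >= 0, L > 0)
  pair <- function(x) if (x < 2) 0 else x * (x - 1) / 2
  nodes <- if (model == "iam") P + W else 2 * P + W
  excitatory <- if (model == "iam") 2 * W * L else 2 * W * L + P
  tibble::tibble(
    model = model,
    nodes = nodes,
    excitatory = excitatory,
    inhibitory_paper = pair(P) + pair(L),
    inhibitory_alt = pair(P) + pair(W)
  )
}

#' Connections required to wire n-phone transitional probabilities
#'
#' An autonomous architecture that encodes n-phone statistics in its
#' phoneme layer needs `P^n - P^(n-1)` connections: 1,560 diphone
#' connections for 40 phonemes, 62,400 triphone connections, 2,496,000
#' quadraphone connections. (An interactive architecture gets the
#' equivalent sensitivity for free through lexical feedback.)
#'
#' @param P phoneme count (>= 1).
#' @param order n-phone order (>= 2).
#' @return connection count (numeric; exact for moderate P and order).
#' @export
nphone_connections <- function(P, order) {
  stopifnot(P >= 1)
  if (order < 2) stop("n-phone order must be at least 2", call. = FALSE)
  P^order - P^(order - 1)
}

#' Luce-rule evaluations needed without candidate pruning
#'
#' Computing response strength for every copy of every word against every
#' word at every cycle costs `W * W * copies * cycles` evaluations —
#' 146,919,300 for 211 words, 33 alignments and 100 cycles — which is why
#' scoring restricts the candidate pool.
#'
#' @param W word count.
#' @param copies reduplicated alignments per word.
#' @param cycles processing cycles.
#' @return evaluation count.
#' @export
response_computation_cost <- function(W, copies, cycles) {
  stopifnot(W >= 0, copies >= 0, cycles >= 0)
  W * W * copies * cycles
}
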