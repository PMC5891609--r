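#' Recognition-decision parameters
#'
#' Controls how word-layer activation traces are turned into recognition
#' judgments. Response probabilities come from the Luce choice rule
#' \deqn{R_i = e^{k a_i} / \sum_j e^{k a_j}}
#' computed per cycle over a fixed candidate pool: the `n_candidates` word
#' units with the highest peak activation among units aligned in the first
#' `candidate_slice_window` alignment slots. In `"minimal"` mode (the
#' default, k = 13, threshold = 0.5) a trial is correct only when some unit
#' of the target word crosses the threshold and no unit of any other word
#' ever does; RT is the first crossing cycle. `"fp98"` mode reproduces the
#' legacy scoring: the scored target activation is the sum of the
#' onset-aligned target unit and the unit at the next alignment slot,
#' competitors are the temporally overlapping units of other words, k = 20
#' and threshold = 0.9, and correctness requires only the target crossing.
#'
#' @param k choice-rule exponent gain.
#' @param threshold response-probability criterion.
#' @param n_candidates candidate-pool size.
#' @param candidate_slice_window alignment-slot cutoff for candidates.
#' @param mode `"minimal"` or `"fp98"`.
#' @return a list of class `decision_params`.
#' @export
decision_params <- function(k = 13, threshold = 0.5, n_candidates = 50L,
                            candidate_slice_window = 10L,
                            mode = c("minimal", "fp98")) {
  mode <- match.arg(mode)
  stopifnot(k > 0, threshold > 0, threshold < 1, n_candidates >= 1,
            candidate_slice_window >= 1)
  structure(
    list(k = k, threshold = threshold,
         n_candidates = as.integer(n_candidates),
         candidate_slice_window = as.integer(candidate_slice_window),
         mode = mode),
    class = "decision_params"
  )
}

#' @rdname decision_params
#' @param ... overrides passed to [decision_params()].
#' @export
fp98_decision_params <- function(...) {
  args <- utils::modifyList(list(k = 20, threshold = 0.9, mode = "fp98"),
                            list(...))
  do.call(decision_params, args)
}

#' Luce choice rule
#'
#' Converts candidate activations at one cycle into response
#' probabilities: `R_i = exp(k * a_i) / sum_j exp(k * a_j)`. Exponentials
#' are max-shifted for numerical stability (k times an activation can
#' exceed the range of `exp` for large k), which leaves the probabilities
#' unchanged — the rule is invariant to adding a constant to all
#' activations.
#'
#' @param activations numeric vector of candidate activations (finite).
#' @param k exponent gain.
#' @return numeric vector of probabilities summing to 1.
#' @export
luce_choice <- function(activations, k = 13) {
  if (!length(activations)) stop("empty candidate set", call. = FALSE)
  if (!all(is.finite(activations))) {
    stop("activations must be finite", call. = FALSE)
  }
  e <- exp(k * (activations - max(activations)))
  e / sum(e)
}

#' Select the candidate word units of a trial
#'
#' Among word units aligned within the first `candidate_slice_window`
#' alignment slots, returns (the indices of) the `n_candidates` units with
#' the highest peak activation over the trial; fewer if fewer exist. Ties
#' break toward the lower unit index, which is deterministic.
#'
#' @param trace an [run_trial()] result (or the reduced traces a batch
#'   records).
#' @param params a [decision_params()].
#' @return integer vector of row indices into `trace$wunits` /
#'   `trace$word_hist`.
#' @export
select_candidates <- function(trace, params = decision_params()) {
  hist <- trace$word_hist
  if (is.null(dim(hist))) hist <- matrix(hist, nrow = 1)
  if (!nrow(hist)) return(integer(0))
  eligible <- which(trace$wunits$align_idx < params$candidate_slice_window)
  if (!length(eligible)) return(integer(0))
  peaks <- apply(hist[eligible, , drop = FALSE], 1, max)
  sel <- eligible[order(-peaks, eligible)]
  utils::head(sel, params$n_candidates)
}

# per-cycle Luce probabilities for a matrix of candidate activations
# (rows = candidates, cols = cycles)
luce_series <- function(A, k) {
  shift <- apply(A, 2, max)
  E <- exp(k * sweep(A, 2, shift))
  sweep(E, 2, colSums(E), "/")
}

#' Score one trial
#'
#' Applies the decision rule of `params` to a trial's activation trace and
#' returns a one-row result: correctness, and RT (first threshold-crossing
#' cycle) when correct. Any reduplicated copy of the target word counts as
#' the target; in minimal mode any copy of any other word that ever
#' crosses the threshold — before or after the target — voids correctness.
#'
#' @param trace an [run_trial()] result.
#' @param target_word_id the intended word (defaults to the trial's input
#'   word).
#' @param params a [decision_params()].
#' @return a one-row tibble with columns `word`, `sd`, `feedback`,
#'   `replicate`, `correct`, `rt`, `seed`.
#' @export
score_trial <- function(trace, target_word_id = trace$meta$word_id,
                        params = decision_params()) {
  if (!target_word_id %in% trace$words) {
    stop("target '", target_word_id, "' not in lexicon", call. = FALSE)
  }
  hist <- trace$word_hist
  if (is.null(dim(hist))) hist <- matrix(hist, nrow = 1)
  if (params$mode == "minimal") {
    cand <- select_candidates(trace, params)
    correct <- FALSE
    rt <- NA_integer_
    if (length(cand)) {
      R <- luce_series(hist[cand, , drop = FALSE], params$k)
      is_target <- trace$wunits$word[cand] == target_word_id
      crossing <- R > params$threshold
      competitor_crossed <- any(crossing[!is_target, , drop = FALSE])
      target_cycles <- which(apply(crossing[is_target, , drop = FALSE], 2, any))
      if (length(target_cycles) && !competitor_crossed) {
        correct <- TRUE
        rt <- target_cycles[1]
      }
    }
  } else {
    # fp98 legacy: summed onset-aligned target pair vs. overlapping units
    tgt_rows <- which(trace$wunits$word == target_word_id &
                        trace$wunits$align_idx <= 1L)
    if (!length(tgt_rows)) {
      stop("trace does not record the onset-aligned target units",
           call. = FALSE)
    }
    span_end <- max(trace$wunits$span_end[tgt_rows])
    comp_rows <- which(trace$wunits$word != target_word_id &
                         trace$wunits$span_start < span_end)
    a_t <- colSums(hist[tgt_rows, , drop = FALSE])
    A <- rbind(a_t, hist[comp_rows, , drop = FALSE])
    R <- luce_series(A, params$k)
    target_cycles <- which(R[1, ] > params$threshold)
    correct <- length(target_cycles) > 0
    rt <- if (correct) target_cycles[1] else NA_integer_
  }
  tibble::tibble(
    word = target_word_id,
    sd = trace$meta$noise_sd,
    feedback = trace$meta$feedback_on,
    replicate = trace$meta$replicate %||% 1L,
    correct = correct,
    rt = as.integer(rt),
    seed = trace$meta$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the choice-rule constants
#'
#' Grid search for the (k, threshold) pair that maximizes proportion
#' correct — i.e. maximizes hits while the strict no-other-word rule
#' punishes false alarms — over noise-free, feedback-off trials of every
#' word in the lexicon. Traces are simulated once and re-scored for each
#' grid point. Ties break toward smaller k, then larger threshold.
#'
#' @param lexicon a [lexicon()].
#' @param inventory a [phoneme_inventory()].
#' @param params a [trace_params()].
#' @param k_grid numeric vector of k values (classically 2 to 20).
#' @param threshold_grid numeric vector of thresholds in (0.01, 0.99).
#' @param base a [decision_params()] supplying pool size, window and mode.
#' @param n_cycles cycles per trial.
#' @param network optional pre-built network.
#' @return a list with the winning `k`, `threshold`, `prop_correct`, the
#'   full `grid` tibble, and a `decision_params` object `best`. Warns when
#'   no grid point scores a single trial correct.
#' @export
calibrate_decision <- function(lexicon, inventory = trace_inventory(),
                               params = trace_params(),
                               k_grid = 2:20,
                               threshold_grid = seq(0.05, 0.95, by = 0.05),
                               base = decision_params(),
                               n_cycles = 100L, network = NULL) {
  if (!length(k_grid) || !length(threshold_grid)) {
    stop("empty calibration grid", call. = FALSE)
  }
  net <- if (is.null(network)) build_network(lexicon, inventory, params) else network
  traces <- lapply(lexicon$word, function(wd) {
    run_trial(wd, lexicon, inventory, params, noise_sd = 0,
              feedback_on = FALSE, n_cycles = n_cycles, network = net,
              record_phonemes = FALSE)
  })
  grid <- expand.grid(k = k_grid, threshold = threshold_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$prop_correct <- vapply(seq_len(nrow(grid)), function(i) {
    dp <- decision_params(k = grid$k[i], threshold = grid$threshold[i],
                          n_candidates = base$n_candidates,
                          candidate_slice_window = base$candidate_slice_window,
                          mode = base$mode)
    mean(vapply(traces, function(tr) score_trial(tr, params = dp)$correct,
                logical(1)))
  }, numeric(1))
  ord <- order(-grid$prop_correct, grid$k, -grid$threshold)
  best <- grid[ord[1], ]
  if (best$prop_correct == 0) {
    warning("no (k, threshold) setting yields any correct trial")
  }
  list(
    k = best$k, threshold = best$threshold,
    prop_correct = best$prop_correct,
    grid = tibble::as_tibble(grid),
    best = decision_params(k = best$k, threshold = best$threshold,
                           n_candidates = base$n_candidates,
                           candidate_slice_window = base$candidate_slice_window,
                           mode = base$mode)
  )
}
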