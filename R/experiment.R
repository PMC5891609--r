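#' Condition grid for a batch experiment
#'
#' The full study design crosses the noise grid with feedback on/off:
#' seven noise levels times two feedback settings = 14 batches, every word
#' of the lexicon used once as the target per batch, 100 cycles per trial.
#' Replicates per cell are configurable (the classical design ran each
#' word once per condition; replicates let stochastic cells be averaged).
#'
#' @param noise a [noise_spec()].
#' @param feedback logical vector of feedback settings.
#' @param replicates replicates per (word, noise, feedback) cell.
#' @param n_cycles cycles per trial.
#' @param master_seed integer master seed; per-trial streams derive from
#'   it via [trial_seed()].
#' @return a list of class `condition_grid`.
#' @export
condition_grid <- function(noise = noise_spec(), feedback = c(TRUE, FALSE),
                           replicates = 1L, n_cycles = 100L,
                           master_seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"), length(feedback) >= 1,
            replicates >= 1, n_cycles >= 1)
  structure(
    list(noise = noise, feedback = as.logical(feedback),
         replicates = as.integer(replicates),
         n_cycles = as.integer(n_cycles),
         master_seed = as.integer(master_seed)),
    class = "condition_grid"
  )
}

#' Run the full batch experiment over a lexicon
#'
#' Simulates every (word, noise sd, feedback, replicate) trial of the
#' grid and scores each with the decision rule. Trials are mutually
#' independent — each draws its noise from its own [trial_seed()] stream —
#' so the result table is identical whatever the execution order; the
#' engine exploits this by running trials through the shared network in
#' column batches. Noise-free input fields are compiled once per word and
#' cached; noisy fields are drawn fresh per trial.
#'
#' A trial whose simulation or scoring fails is recorded with
#' `correct = NA` (and a warning) rather than aborting the batch.
#'
#' @param lexicon a [lexicon()].
#' @param inventory a [phoneme_inventory()].
#' @param params a [trace_params()].
#' @param grid a [condition_grid()].
#' @param decision a [decision_params()].
#' @param network optional pre-built [build_network()] result.
#' @param chunk_size trials simulated per engine call (memory/speed
#'   trade-off; results do not depend on it).
#' @param progress print per-batch progress to stderr.
#' @return a tibble of class `result_table` with one row per trial:
#'   `word`, `sd`, `feedback`, `replicate`, `correct`, `rt`, `seed`.
#' @export
run_batch <- function(lexicon, inventory = trace_inventory(),
                      params = trace_params(), grid = condition_grid(),
                      decision = decision_params(), network = NULL,
                      chunk_size = 64L, progress = FALSE) {
  stopifnot(nrow(lexicon) >= 1)
  net <- if (is.null(network)) build_network(lexicon, inventory, params) else network
  sd_levels <- grid$noise$sd_levels

  plan <- expand.grid(
    word = lexicon$word,
    sd_index = seq_along(sd_levels),
    feedback = grid$feedback,
    replicate = seq_len(grid$replicates),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  plan$sd <- sd_levels[plan$sd_index]
  plan$seed <- mapply(trial_seed, plan$word, plan$sd_index, plan$feedback,
                      plan$replicate, MoreArgs = list(master_seed = grid$master_seed))

  # record enough alignments for either scoring mode
  span_align <- ceiling(max(lexicon$n_phonemes) * params$phoneme_spacing_slices /
                          params$unit_copy_spacing)
  rec_window <- max(decision$candidate_slice_window,
                    if (decision$mode == "fp98") span_align else 0L)
  record_w <- which(net$wunits$align_idx < rec_window)
  wunits_rec <- net$wunits[record_w, , drop = FALSE]

  fields <- lapply(lexicon$phonemes, compile_input, inventory = inventory,
                   params = net$params)
  names(fields) <- lexicon$word

  n_trials <- nrow(plan)
  chunks <- split(seq_len(n_trials),
                  ceiling(seq_len(n_trials) / chunk_size))
  rows <- vector("list", n_trials)
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    inputs <- vapply(idx, function(i) {
      f <- fields[[plan$word[i]]]
      if (plan$sd[i] > 0) {
        f <- with_local_seed(plan$seed[i], corrupt_input(f, plan$sd[i]))
      }
      as.numeric(f)
    }, numeric(net$n_f))
    res <- tryCatch(
      run_trials_engine(net, inputs, fb_mult = as.numeric(plan$feedback[idx]),
                        n_cycles = grid$n_cycles, record_w = record_w),
      error = function(e) e
    )
    for (jj in seq_along(idx)) {
      i <- idx[jj]
      row <- if (inherits(res, "error")) {
        NULL
      } else {
        trace <- structure(
          list(word_hist = res$whist[, , jj, drop = TRUE],
               wunits = wunits_rec, words = lexicon$word,
               params = net$params,
               meta = list(word_id = plan$word[i], noise_sd = plan$sd[i],
                           feedback_on = plan$feedback[i],
                           replicate = plan$replicate[i],
                           seed = plan$seed[i],
                           n_cycles = grid$n_cycles)),
          class = "activation_trace"
        )
        tryCatch(score_trial(trace, params = decision), error = function(e) NULL)
      }
      if (is.null(row)) {
        warning("trial failed: word ", plan$word[i], ", sd ", plan$sd[i],
                ", feedback ", plan$feedback[i], call. = FALSE)
        row <- tibble::tibble(
          word = plan$word[i], sd = plan$sd[i],
          feedback = plan$feedback[i], replicate = plan$replicate[i],
          correct = NA, rt = NA_integer_, seed = plan$seed[i]
        )
      }
      rows[[i]] <- row
    }
    if (progress) {
      message("chunk ", ci, "/", length(chunks), " (",
              length(idx), " trials)")
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("result_table", class(out))
  out
}

#' Read / write a result table
#'
#' Plain CSV serialization of the trial rows produced by [run_batch()].
#'
#' @param results a `result_table` tibble.
#' @param path file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   the tibble.
#' @export
write_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$feedback <- as.logical(df$feedback)
  df$correct <- as.logical(df$correct)
  out <- tibble::as_tibble(df)
  class(out) <- c("result_table", class(out))
  out
}
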