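#' Initialize a network state
#'
#' All feature, phoneme and word units start at their layer's resting
#' activation, with the cycle counter at zero.
#'
#' @param lexicon a [lexicon()].
#' @param inventory a [phoneme_inventory()].
#' @param params a [trace_params()].
#' @param network optional pre-built [build_network()] result (must match
#'   the other arguments); avoids rebuilding connection structure.
#' @return an object of class `trace_state` with elements `f`, `p`, `w`
#'   (activation vectors), `cycle`, and `network`.
#' @export
init_state <- function(lexicon, inventory = trace_inventory(),
                       params = trace_params(), network = NULL) {
  net <- if (is.null(network)) build_network(lexicon, inventory, params) else network
  p <- net$params
  structure(
    list(
      f = matrix(p$rest_feature, net$n_f, 1),
      p = matrix(p$rest_phoneme, net$n_pu, 1),
      w = matrix(p$rest_word, net$n_wu, 1),
      cycle = 0L,
      network = net
    ),
    class = "trace_state"
  )
}

#' @export
print.trace_state <- function(x, ...) {
  cat("<trace_state> cycle ", x$cycle, "; ", x$network$n_wu,
      " word units, max word activation ",
      if (x$network$n_wu) format(max(x$w), digits = 3) else "NA", "\n",
      sep = "")
  invisible(x)
}

# One synchronous update of all layers. Activation matrices have one
# column per trial; `input_masked` is the currently audible input
# (n_f x T), `fb_row` a 1 x T matrix of feedback multipliers (0 or 1).
# All net inputs are computed from the pre-update activations
# (double-buffered), inhibition is sourced only from positive activations,
# activation moves toward the saturation bound matching the sign of the
# net input, decays toward rest, and is clipped to [act_min, act_max].
step_core <- function(net, F, P, W, input_masked, fb_row) {
  pr <- net$params
  posF <- pmax(F, 0)
  posP <- pmax(P, 0)

  netF <- pr$excite_input_feature * input_masked
  if (pr$inhibit_feature > 0) {
    tot <- rowsum(posF, group = net$slice_of_frow, reorder = TRUE)
    netF <- netF - pr$inhibit_feature * (tot[net$slice_of_frow + 1L, , drop = FALSE] - posF)
  }

  netP <- as.matrix(net$M_fp %*% posF) -
    net$inh_p_scale * (as.matrix(net$S_p_t %*% (net$S_p %*% posP)) -
                         posP * net$len_p)
  if (net$n_wu > 0) {
    posW <- pmax(W, 0)
    netP <- netP + as.matrix(net$M_wp %*% posW) * fb_row[rep(1L, nrow(P)), , drop = FALSE]
    netW <- as.matrix(net$M_pw %*% posP) -
      net$inh_w_scale * (as.matrix(net$S_w_t %*% (net$S_w %*% posW)) -
                           posW * net$len_w)
  }

  apply_update <- function(a, net_in, decay, rest) {
    a2 <- a + pmax(net_in, 0) * (pr$act_max - a) +
      pmin(net_in, 0) * (a - pr$act_min) - decay * (a - rest)
    pmin(pmax(a2, pr$act_min), pr$act_max)
  }
  F2 <- apply_update(F, netF, pr$decay_feature, pr$rest_feature)
  P2 <- apply_update(P, netP, pr$decay_phoneme, pr$rest_phoneme)
  W2 <- if (net$n_wu > 0) {
    apply_update(W, netW, pr$decay_word, pr$rest_word)
  } else {
    W
  }
  if (anyNA(P2) || !all(is.finite(P2)) || (net$n_wu > 0 && !all(is.finite(W2)))) {
    stop("non-finite activations: parameter blow-up", call. = FALSE)
  }
  list(F = F2, P = P2, W = W2)
}

#' Advance a network state by one cycle
#'
#' @param state a [init_state()] result.
#' @param input an `input_field` matrix (or `NULL` for ambient silence).
#'   The caller decides how much of the field is audible; see [run_trial()]
#'   for incremental presentation.
#' @param feedback_on logical; when `FALSE` the word-to-phoneme feedback
#'   gain is treated as zero for this step.
#' @return the updated `trace_state` (cycle incremented).
#' @export
trace_step <- function(state, input = NULL, feedback_on = TRUE) {
  net <- state$network
  im <- if (is.null(input)) {
    matrix(0, net$n_f, 1)
  } else {
    matrix(as.numeric(input), net$n_f, 1)
  }
  res <- step_core(net, state$f, state$p, state$w, im,
                   matrix(as.numeric(feedback_on), 1, 1))
  state$f <- res$F
  state$p <- res$P
  state$w <- res$W
  state$cycle <- state$cycle + 1L
  state
}

# Batched trial engine: runs `ncol(inputs)` independent trials through the
# shared network. The input field of slice t becomes audible at cycle
# t + 1 and stays on (static memory trace). Word-unit history is recorded
# for the units in `record_w`, phoneme history optionally for all phoneme
# units.
run_trials_engine <- function(net, inputs, fb_mult, n_cycles,
                              record_w = seq_len(net$n_wu),
                              record_p = FALSE) {
  pr <- net$params
  tr <- ncol(inputs)
  stopifnot(length(fb_mult) == tr)
  F <- matrix(pr$rest_feature, net$n_f, tr)
  P <- matrix(pr$rest_phoneme, net$n_pu, tr)
  W <- matrix(pr$rest_word, net$n_wu, tr)
  fb_row <- matrix(fb_mult, 1, tr)
  whist <- array(NA_real_, c(length(record_w), n_cycles, tr))
  phist <- if (record_p) array(NA_real_, c(net$n_pu, n_cycles, tr)) else NULL
  im <- matrix(0, net$n_f, tr)
  audible <- net$slice_of_frow  # slice index of each input row
  for (cyc in seq_len(n_cycles)) {
    new_rows <- which(audible == cyc - 1L)
    if (length(new_rows)) im[new_rows, ] <- inputs[new_rows, , drop = FALSE]
    res <- step_core(net, F, P, W, im, fb_row)
    F <- res$F; P <- res$P; W <- res$W
    if (length(record_w)) whist[, cyc, ] <- W[record_w, , drop = FALSE]
    if (record_p) phist[, cyc, ] <- P
  }
  list(whist = whist, phist = phist, F = F, P = P, W = W)
}

#' Run one recognition trial
#'
#' Compiles the target word's input field, corrupts it with Gaussian noise
#' (deterministically, from `seed`), presents it incrementally (slice `t`
#' becomes audible at cycle `t + 1` and persists), and runs the network
#' for `n_cycles` synchronous updates, snapshotting word-layer (and
#' optionally phoneme-layer) activations each cycle.
#'
#' @param word_id a word of `lexicon`.
#' @param lexicon a [lexicon()].
#' @param inventory a [phoneme_inventory()].
#' @param params a [trace_params()].
#' @param noise_sd standard deviation of the per-element Gaussian input
#'   noise (0 for clean input).
#' @param feedback_on logical; `FALSE` zeroes lexical feedback.
#' @param seed integer seed for the trial's noise stream.
#' @param n_cycles number of update cycles.
#' @param network optional pre-built [build_network()] result.
#' @param record_phonemes keep per-cycle phoneme activations too.
#' @return an object of class `activation_trace`: `word_hist`
#'   (word units x cycles), optional `ph_hist`, the unit tables, and trial
#'   metadata.
#' @export
run_trial <- function(word_id, lexicon, inventory = trace_inventory(),
                      params = trace_params(), noise_sd = 0,
                      feedback_on = TRUE, seed = 1L, n_cycles = 100L,
                      network = NULL, record_phonemes = TRUE) {
  if (!word_id %in% lexicon$word) {
    stop("word '", word_id, "' not in lexicon", call. = FALSE)
  }
  net <- if (is.null(network)) build_network(lexicon, inventory, params) else network
  field <- compile_input(lexicon$phonemes[[match(word_id, lexicon$word)]],
                         inventory, net$params)
  noisy <- if (noise_sd > 0) {
    with_local_seed(seed, corrupt_input(field, noise_sd))
  } else {
    field
  }
  res <- run_trials_engine(net, matrix(as.numeric(noisy), ncol = 1),
                           fb_mult = as.numeric(feedback_on),
                           n_cycles = n_cycles, record_p = record_phonemes)
  structure(
    list(
      word_hist = res$whist[, , 1, drop = TRUE],
      ph_hist = if (record_phonemes) res$phist[, , 1, drop = TRUE] else NULL,
      wunits = net$wunits,
      punits = net$punits,
      words = net$lexicon$word,
      params = net$params,
      meta = list(word_id = word_id, noise_sd = noise_sd,
                  feedback_on = feedback_on, seed = as.integer(seed),
                  n_cycles = as.integer(n_cycles))
    ),
    class = "activation_trace"
  )
}

#' @export
print.activation_trace <- function(x, ...) {
  cat("<activation_trace> word '", x$meta$word_id, "', sd ",
      x$meta$noise_sd, ", feedback ", x$meta$feedback_on, ", ",
      x$meta$n_cycles, " cycles\n", sep = "")
  invisible(x)
}

#' Peak activation of a phoneme across all its reduplicated units
#'
#' Convenience accessor used by the gang-effect demonstration: the maximum
#' activation the given phoneme reaches in any copy at any cycle of a
#' trial.
#'
#' @param trace an [run_trial()] result with phoneme history.
#' @param phoneme a phoneme symbol.
#' @return a single number.
#' @export
peak_phoneme_activation <- function(trace, phoneme) {
  if (is.null(trace$ph_hist)) {
    stop("trace was recorded without phoneme history", call. = FALSE)
  }
  phoneme <- normalize_phonemes(phoneme)
  rows <- which(trace$punits$phoneme == phoneme)
  if (!length(rows)) stop("no such phoneme: ", phoneme, call. = FALSE)
  max(trace$ph_hist[rows, ])
}
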