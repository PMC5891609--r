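# Shared fixtures: synthetic orthogonal feature tables (so correctness of
# the dynamics is independent of the packaged feature values), a reduced
# geometry for fast engine tests, and independent brute-force oracles.

# inventory with orthogonal (identity) feature vectors
ortho_inventory <- function(symbols = c("P", "B", "A")) {
  phoneme_inventory(symbols, diag(length(symbols)))
}

# small trace geometry: 24 slices, phonemes every 3, copies every 3
tiny_params <- function(...) {
  trace_params(n_slices = 24L, phoneme_spacing_slices = 3L,
               unit_copy_spacing = 3L, feature_spread_slices = 5L, ...)
}

# ---------------------------------------------------------------------------
# Independent one-step oracle: plain loops over every unit, computing net
# input from first principles (receptive fields, lexical links, pairwise
# overlap-scaled inhibition) and applying the documented update equation.
# Unit ordering is taken from the network tables (labels only); all
# connectivity and arithmetic is recomputed here.
oracle_step <- function(lexicon, inventory, params, state_f, state_p,
                        state_w, input_field, feedback_on = TRUE) {
  ns <- params$n_slices
  half <- (params$feature_spread_slices - 1) / 2
  ramp <- function(d) 1 - abs(d) / (half + 1)
  feats <- inventory$features
  feats <- feats / ifelse(sqrt(rowSums(feats^2)) == 0, 1,
                          sqrt(rowSums(feats^2)))
  align <- seq(0, ns - 1, by = params$unit_copy_spacing)
  nph <- length(inventory$symbols)
  nfd <- ncol(feats)

  posF <- pmax(matrix(state_f, ns, nfd), 0)
  netF <- params$excite_input_feature * matrix(input_field, ns, nfd)

  # phoneme units
  pu <- expand.grid(ph = seq_len(nph), ai = seq_along(align))
  pu$slice <- align[pu$ai]
  n_pu <- nrow(pu)
  posP <- pmax(state_p, 0)
  netP <- numeric(n_pu)
  for (u in seq_len(n_pu)) {
    e <- 0
    for (d in -half:half) {
      t <- pu$slice[u] + d
      if (t < 0 || t > ns - 1) next
      for (k in seq_len(nfd)) {
        e <- e + ramp(d) * feats[pu$ph[u], k] * posF[t + 1, k]
      }
    }
    e <- e * params$excite_feature_phoneme
    inh <- 0
    span_u <- (pu$slice[u] - half):(pu$slice[u] + half)
    span_u <- span_u[span_u >= 0 & span_u <= ns - 1]
    for (v in seq_len(n_pu)) {
      if (v == u) next
      span_v <- (pu$slice[v] - half):(pu$slice[v] + half)
      span_v <- span_v[span_v >= 0 & span_v <= ns - 1]
      ov <- length(intersect(span_u, span_v))
      inh <- inh + ov * posP[v]
    }
    inh <- inh * params$inhibit_phoneme / params$feature_spread_slices
    netP[u] <- e - inh
  }

  # word units
  W <- nrow(lexicon)
  wu <- expand.grid(w = seq_len(W), ai = seq_along(align))
  wu$slice <- align[wu$ai]
  n_wu <- nrow(wu)
  posW <- pmax(state_w, 0)
  netW <- numeric(n_wu)
  pu_index <- function(ph, slice) {
    ai <- which(align == slice)
    if (!length(ai)) return(NA_integer_)
    (ai - 1) * nph + ph
  }
  spans_w <- lapply(seq_len(n_wu), function(u) {
    s <- wu$slice[u]
    e <- min(s + lexicon$n_phonemes[wu$w[u]] * params$phoneme_spacing_slices,
             ns) - 1
    s:e
  })
  for (u in seq_len(n_wu)) {
    phs <- match(lexicon$phonemes[[wu$w[u]]], inventory$symbols)
    e <- 0
    for (j in seq_along(phs)) {
      sl <- wu$slice[u] + (j - 1) * params$phoneme_spacing_slices
      if (sl > ns - 1) next
      pi <- pu_index(phs[j], sl)
      if (!is.na(pi)) e <- e + posP[pi]
    }
    e <- e * params$excite_phoneme_word
    inh <- 0
    for (v in seq_len(n_wu)) {
      if (v == u) next
      ov <- length(intersect(spans_w[[u]], spans_w[[v]]))
      inh <- inh + ov * posW[v]
    }
    inh <- inh * params$inhibit_word / params$phoneme_spacing_slices
    netW[u] <- e - inh
  }

  # feedback word -> phoneme
  if (feedback_on && params$feedback_word_phoneme > 0) {
    for (u in seq_len(n_wu)) {
      phs <- match(lexicon$phonemes[[wu$w[u]]], inventory$symbols)
      for (j in seq_along(phs)) {
        sl <- wu$slice[u] + (j - 1) * params$phoneme_spacing_slices
        if (sl > ns - 1) next
        pi <- pu_index(phs[j], sl)
        if (!is.na(pi)) {
          netP[pi] <- netP[pi] + params$feedback_word_phoneme * posW[u]
        }
      }
    }
  }

  upd <- function(a, net, decay, rest) {
    d <- if (net > 0) net * (params$act_max - a) else net * (a - params$act_min)
    min(max(a + d - decay * (a - rest), params$act_min), params$act_max)
  }
  list(
    f = mapply(upd, as.numeric(state_f), as.numeric(netF),
               MoreArgs = list(decay = params$decay_feature,
                               rest = params$rest_feature)),
    p = mapply(upd, as.numeric(state_p), netP,
               MoreArgs = list(decay = params$decay_phoneme,
                               rest = params$rest_phoneme)),
    w = if (n_wu) {
      mapply(upd, as.numeric(state_w), netW,
             MoreArgs = list(decay = params$decay_word,
                             rest = params$rest_word))
    } else {
      numeric(0)
    }
  )
}

# ---------------------------------------------------------------------------
# Independent gang-finding oracle: group cohort words by shared l-prefix,
# sweeping l from long to short, keeping groups of >= 2 whose prefix is
# shared with the target for fewer than l phonemes; one gang per distinct
# member set (the longest qualifying prefix wins).
oracle_gangs <- function(lexicon, target, cohort_len = 2) {
  tp <- lexicon$phonemes[[match(target, lexicon$word)]]
  cpl <- function(a, b) {
    n <- min(length(a), length(b)); i <- 0
    while (i < n && a[i + 1] == b[i + 1]) i <- i + 1
    i
  }
  idx <- which(lexicon$word != target &
                 vapply(lexicon$phonemes, cpl, numeric(1), b = tp) >= cohort_len)
  found <- list()
  if (length(idx) >= 2 && max(lexicon$n_phonemes[idx]) >= cohort_len + 1) {
    for (l in rev(seq(cohort_len + 1, max(lexicon$n_phonemes[idx])))) {
      withl <- idx[lexicon$n_phonemes[idx] >= l]
      if (length(withl) < 2) next
      keyv <- vapply(withl, function(i) {
        paste(lexicon$phonemes[[i]][1:l], collapse = " ")
      }, character(1))
      for (kk in unique(keyv)) {
        mem <- withl[keyv == kk]
        if (length(mem) < 2) next
        pref <- lexicon$phonemes[[mem[1]]][1:l]
        if (cpl(pref, tp) >= l) next
        mset <- paste(sort(lexicon$word[mem]), collapse = ",")
        if (is.null(found[[mset]])) {
          found[[mset]] <- list(members = sort(lexicon$word[mem]),
                                overlap_len = l,
                                target_overlap = cpl(pref, tp))
        }
      }
    }
  }
  found
}

expect_same_gangs <- function(lexicon, target) {
  got <- gang_report(lexicon, target)$gangs
  want <- oracle_gangs(lexicon, target)
  expect_equal(nrow(got), length(want))
  if (nrow(got)) {
    got_sets <- sort(vapply(got$members, paste, character(1), collapse = ","))
    expect_equal(got_sets, sort(names(want)))
    for (i in seq_len(nrow(got))) {
      key <- paste(got$members[[i]], collapse = ",")
      expect_equal(got$overlap_len[i], want[[key]]$overlap_len)
      expect_equal(got$target_overlap[i], want[[key]]$target_overlap)
    }
  }
}
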