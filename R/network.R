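#' Compile a phoneme string into an input field
#'
#' The input field is a `n_slices` by `n_features` matrix of continuous
#' feature values. Phoneme `j` (1-based) contributes its unit-normalized
#' feature vector as a triangular ramp centered at slice
#' `(j - 1) * phoneme_spacing_slices`, spread over
#' `feature_spread_slices` slices; overlapping contributions from adjacent
#' phonemes add. Slices outside the word carry the ambient (silence)
#' pattern, which is all-zero.
#'
#' @param phonemes character vector of inventory symbols (may be empty,
#'   giving an all-ambient field).
#' @param inventory a [phoneme_inventory()].
#' @param params a [trace_params()].
#' @return a matrix of class `input_field` (`n_slices` x `n_features`,
#'   slices as rows).
#' @export
compile_input <- function(phonemes, inventory = trace_inventory(),
                          params = trace_params()) {
  phonemes <- normalize_phonemes(as.character(phonemes))
  bad <- setdiff(phonemes, inventory$symbols)
  if (length(bad)) {
    stop("unknown phoneme symbol: ", bad[1], call. = FALSE)
  }
  half <- (params$feature_spread_slices - 1L) %/% 2L
  m <- length(phonemes)
  if (m > 0) {
    last_center <- (m - 1L) * params$phoneme_spacing_slices
    if (last_center + half > params$n_slices - 1L) {
      stop("word of ", m, " phonemes does not fit in ", params$n_slices,
           " slices", call. = FALSE)
    }
  }
  fnorm <- normalized_features(inventory)
  field <- matrix(0, nrow = params$n_slices, ncol = ncol(fnorm),
                  dimnames = list(NULL, colnames(fnorm)))
  ramp <- params$input_pattern_scale *
    (1 - abs(seq(-half, half)) / (half + 1L))
  for (j in seq_len(m)) {
    center <- (j - 1L) * params$phoneme_spacing_slices
    slices <- center + seq(-half, half)
    ok <- slices >= 0 & slices <= params$n_slices - 1L
    field[slices[ok] + 1L, ] <- field[slices[ok] + 1L, ] +
      ramp[ok] %o% fnorm[phonemes[j], ]
  }
  class(field) <- c("input_field", class(field))
  field
}

# feature rows scaled to unit L2 norm so every phoneme injects the same
# total input energy; keeps gain calibration independent of the table
normalized_features <- function(inventory) {
  f <- inventory$features
  nrm <- sqrt(rowSums(f^2))
  nrm[nrm == 0] <- 1
  f / nrm
}

#' Build the reduplicated interactive-activation network for a lexicon
#'
#' Constructs the unit tables and sparse connection structure once; the
#' result is reused across trials (the network depends only on the lexicon,
#' inventory and parameters, not on the input). Phoneme and word units are
#' tiled at every alignment (`unit_copy_spacing` slices apart). Lateral
#' inhibition within the phoneme and word layers scales with the temporal
#' overlap of the competing units and is evaluated through per-slice
#' activation masses, which is algebraically identical to an explicit
#' unit-by-unit overlap-weighted inhibition matrix.
#'
#' @param lexicon a [lexicon()] (may have zero rows: phoneme and feature
#'   layers only).
#' @param inventory a [phoneme_inventory()].
#' @param params a [trace_params()].
#' @return an object of class `trace_network`.
#' @export
build_network <- function(lexicon, inventory = trace_inventory(),
                          params = trace_params()) {
  ns <- params$n_slices
  align <- seq(0L, ns - 1L, by = params$unit_copy_spacing)
  n_align <- length(align)
  nph <- n_phonemes(inventory)
  nf_dim <- n_features(inventory)
  n_f <- ns * nf_dim
  half <- (params$feature_spread_slices - 1L) %/% 2L
  fnorm <- normalized_features(inventory)

  # --- phoneme units: index = (align_i - 1) * nph + ph ---------------------
  punits <- tibble::tibble(
    phoneme = rep(inventory$symbols, times = n_align),
    ph = rep(seq_len(nph), times = n_align),
    align_idx = rep(seq_len(n_align) - 1L, each = nph),
    align_slice = rep(align, each = nph)
  )
  n_pu <- nrow(punits)

  # feature -> phoneme: ramped, feature-weighted receptive field
  offs <- seq(-half, half)
  ramp <- 1 - abs(offs) / (half + 1L)
  ug <- expand.grid(u = seq_len(n_pu), o = seq_along(offs),
                    d = seq_len(nf_dim))
  sl <- punits$align_slice[ug$u] + offs[ug$o]
  wgt <- ramp[ug$o] * fnorm[cbind(punits$ph[ug$u], ug$d)] *
    params$excite_feature_phoneme
  keep <- sl >= 0 & sl <= ns - 1 & wgt != 0
  M_fp <- Matrix::sparseMatrix(
    i = ug$u[keep], j = (ug$d[keep] - 1L) * ns + sl[keep] + 1L,
    x = wgt[keep], dims = c(n_pu, n_f)
  )

  # phoneme coverage (for overlap-scaled lateral inhibition)
  pg <- expand.grid(u = seq_len(n_pu), o = seq_along(offs))
  psl <- punits$align_slice[pg$u] + offs[pg$o]
  pkeep <- psl >= 0 & psl <= ns - 1
  S_p <- Matrix::sparseMatrix(
    i = psl[pkeep] + 1L, j = pg$u[pkeep], x = 1, dims = c(ns, n_pu)
  )
  len_p <- Matrix::colSums(S_p)

  # --- word units: index = (align_i - 1) * W + w ---------------------------
  W <- nrow(lexicon)
  if (W > 0) {
    wunits <- tibble::tibble(
      word = rep(lexicon$word, times = n_align),
      w = rep(seq_len(W), times = n_align),
      n_phonemes = rep(lexicon$n_phonemes, times = n_align),
      align_idx = rep(seq_len(n_align) - 1L, each = W),
      align_slice = rep(align, each = W)
    )
    wunits$span_start <- wunits$align_slice
    wunits$span_end <- pmin(
      wunits$align_slice + wunits$n_phonemes * params$phoneme_spacing_slices,
      ns
    )  # exclusive
    n_wu <- nrow(wunits)

    # phoneme -> word (and word -> phoneme feedback, same topology)
    tri_i <- integer(0); tri_j <- integer(0)
    ph_idx <- lapply(lexicon$phonemes, function(p) {
      match(p, inventory$symbols)
    })
    maxlen <- max(lexicon$n_phonemes)
    for (j in seq_len(maxlen)) {
      has <- which(lexicon$n_phonemes >= j)
      phj <- vapply(ph_idx[has], function(v) v[j], integer(1))
      for (ai in seq_len(n_align)) {
        sl <- align[ai] + (j - 1L) * params$phoneme_spacing_slices
        if (sl > ns - 1L) next
        pa <- sl %/% params$unit_copy_spacing  # alignment index of that slice
        wu <- (ai - 1L) * W + has
        pu <- pa * nph + phj
        tri_i <- c(tri_i, wu)
        tri_j <- c(tri_j, pu)
      }
    }
    M_pw <- Matrix::sparseMatrix(i = tri_i, j = tri_j,
                                 x = params$excite_phoneme_word,
                                 dims = c(n_wu, n_pu))
    M_wp <- Matrix::sparseMatrix(i = tri_j, j = tri_i,
                                 x = params$feedback_word_phoneme,
                                 dims = c(n_pu, n_wu))

    # word coverage
    spans <- mapply(function(s, e) seq.int(s, e - 1L),
                    wunits$span_start, wunits$span_end, SIMPLIFY = FALSE)
    S_w <- Matrix::sparseMatrix(
      i = unlist(spans) + 1L,
      j = rep(seq_len(n_wu), times = lengths(spans)),
      x = 1, dims = c(ns, n_wu)
    )
    len_w <- Matrix::colSums(S_w)
  } else {
    wunits <- tibble::tibble(
      word = character(0), w = integer(0), n_phonemes = integer(0),
      align_idx = integer(0), align_slice = integer(0),
      span_start = integer(0), span_end = integer(0)
    )
    n_wu <- 0L
    M_pw <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(0L, n_pu))
    M_wp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(n_pu, 0L))
    S_w <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(ns, 0L))
    len_w <- numeric(0)
  }

  structure(
    list(
      lexicon = lexicon, inventory = inventory, params = params,
      n_slices = ns, align = align, n_align = n_align,
      n_f = n_f, n_pu = n_pu, n_wu = n_wu,
      punits = punits, wunits = wunits,
      M_fp = M_fp, M_pw = M_pw, M_wp = M_wp,
      S_p = S_p, S_w = S_w, S_p_t = Matrix::t(S_p), S_w_t = Matrix::t(S_w),
      len_p = len_p, len_w = len_w,
      inh_p_scale = params$inhibit_phoneme / params$feature_spread_slices,
      inh_w_scale = params$inhibit_word / params$phoneme_spacing_slices,
      slice_of_frow = rep(seq_len(ns) - 1L, times = nf_dim)
    ),
    class = "trace_network"
  )
}

#' @export
print.trace_network <- function(x, ...) {
  cat("<trace_network> ", nrow(x$lexicon), " words, ",
      n_phonemes(x$inventory), " phonemes, ", x$n_align, " alignments (",
      x$n_wu, " word units, ", x$n_pu, " phoneme units, ", x$n_f,
      " feature units)\n", sep = "")
  invisible(x)
}
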