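#' Interactive-activation network parameters
#'
#' Connection gains, decay/rest/bounds, and the reduplication geometry of
#' the simulator. The two parameters with study-specific values are
#' `inhibit_word` and `feedback_word_phoneme`: the standard setting uses
#' 0.030 for both, while the large-lexicon preset ([biglex_params()])
#' lowers them to 0.025 and 0.015. Setting `feedback_word_phoneme = 0`
#' defines the feedback-off (autonomous) model. The remaining defaults are
#' the package's canonical parameter set, shipped in file form at
#' `inst/extdata/params-default.txt`.
#'
#' Geometry: the input trace spans `n_slices` feature time slices;
#' successive phonemes are centered `phoneme_spacing_slices` apart; each
#' phoneme's feature pattern ramps linearly up and down over
#' `feature_spread_slices` slices; reduplicated phoneme and word units are
#' aligned every `unit_copy_spacing` slices (99/6/11/3 gives the classical
#' 33 alignments).
#'
#' @param excite_input_feature,excite_feature_phoneme,excite_phoneme_word
#'   bottom-up excitatory gains between adjacent layers.
#' @param feedback_word_phoneme top-down excitatory gain from word units to
#'   their constituent phoneme units; 0 disables lexical feedback.
#' @param inhibit_feature,inhibit_phoneme,inhibit_word lateral inhibition
#'   gains within each layer. Phoneme and word inhibition scale with the
#'   temporal overlap of the competing units.
#' @param decay_feature,decay_phoneme,decay_word per-cycle decay rates
#'   toward rest, in `[0, 1)`.
#' @param rest_feature,rest_phoneme,rest_word resting activations.
#' @param act_min,act_max activation bounds.
#' @param input_pattern_scale amplitude of the compiled input patterns.
#'   Noise is specified on the absolute input scale, so this anchors the
#'   signal-to-noise ratio of the noise grid; the default input gain
#'   (`excite_input_feature = 1 / input_pattern_scale`) compensates so
#'   clean-input dynamics are independent of it.
#' @param n_slices feature time slices in the trace.
#' @param phoneme_spacing_slices slices between successive input phonemes.
#' @param unit_copy_spacing slices between reduplicated unit alignments;
#'   must divide `phoneme_spacing_slices`.
#' @param feature_spread_slices temporal extent of one phoneme's feature
#'   pattern (odd).
#' @return a list of class `trace_params`.
#' @export
trace_params <- function(excite_input_feature = 0.25,
                         excite_feature_phoneme = 0.02,
                         excite_phoneme_word = 0.05,
                         feedback_word_phoneme = 0.03,
                         inhibit_feature = 0.0,
                         inhibit_phoneme = 0.04,
                         inhibit_word = 0.03,
                         decay_feature = 0.5,
                         decay_phoneme = 0.03,
                         decay_word = 0.05,
                         rest_feature = -0.1,
                         rest_phoneme = -0.1,
                         rest_word = -0.1,
                         act_min = -0.3,
                         act_max = 1.0,
                         input_pattern_scale = 4,
                         n_slices = 99L,
                         phoneme_spacing_slices = 6L,
                         unit_copy_spacing = 3L,
                         feature_spread_slices = 11L) {
  p <- list(
    excite_input_feature = excite_input_feature,
    excite_feature_phoneme = excite_feature_phoneme,
    excite_phoneme_word = excite_phoneme_word,
    feedback_word_phoneme = feedback_word_phoneme,
    inhibit_feature = inhibit_feature,
    inhibit_phoneme = inhibit_phoneme,
    inhibit_word = inhibit_word,
    decay_feature = decay_feature,
    decay_phoneme = decay_phoneme,
    decay_word = decay_word,
    rest_feature = rest_feature,
    rest_phoneme = rest_phoneme,
    rest_word = rest_word,
    act_min = act_min,
    act_max = act_max,
    input_pattern_scale = input_pattern_scale,
    n_slices = as.integer(n_slices),
    phoneme_spacing_slices = as.integer(phoneme_spacing_slices),
    unit_copy_spacing = as.integer(unit_copy_spacing),
    feature_spread_slices = as.integer(feature_spread_slices)
  )
  gains <- p[grep("^(excite|feedback|inhibit)", names(p))]
  if (any(unlist(gains) < 0)) stop("gains must be >= 0", call. = FALSE)
  decays <- unlist(p[grep("^decay", names(p))])
  if (any(decays < 0 | decays >= 1)) {
    stop("decay rates must lie in [0, 1)", call. = FALSE)
  }
  rests <- unlist(p[grep("^rest", names(p))])
  if (any(rests <= p$act_min) || any(rests >= p$act_max)) {
    stop("resting levels must lie strictly inside [act_min, act_max]",
         call. = FALSE)
  }
  if (p$input_pattern_scale <= 0) {
    stop("input_pattern_scale must be positive", call. = FALSE)
  }
  if (p$n_slices < 1 || p$phoneme_spacing_slices < 1 ||
      p$unit_copy_spacing < 1 || p$feature_spread_slices < 1) {
    stop("geometry values must be positive", call. = FALSE)
  }
  if (p$phoneme_spacing_slices %% p$unit_copy_spacing != 0) {
    stop("phoneme_spacing_slices must be a multiple of unit_copy_spacing",
         call. = FALSE)
  }
  if (p$feature_spread_slices %% 2 == 0) {
    stop("feature_spread_slices must be odd (symmetric ramp)", call. = FALSE)
  }
  structure(p, class = "trace_params")
}

#' Large-lexicon parameter preset
#'
#' The standard parameters with lexical inhibition lowered from 0.030 to
#' 0.025 and lexical feedback from 0.030 to 0.015 — the adjustment known to
#' improve performance when the lexicon grows to several hundred words.
#'
#' @param ... overrides passed on to [trace_params()].
#' @return a `trace_params` object.
#' @export
biglex_params <- function(...) {
  trace_params(inhibit_word = 0.025, feedback_word_phoneme = 0.015, ...)
}

#' @export
print.trace_params <- function(x, ...) {
  cat("<trace_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read / write a parameter file
#'
#' Flat key-value text format, one `name<TAB>value` pair per line, `#`
#' comments; keys match the [trace_params()] argument names. Values
#' round-trip exactly.
#'
#' @param path file path.
#' @return `read_params()` returns a `trace_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  vals <- lapply(toks, function(t) {
    if (length(t) != 2) stop("malformed parameter line: ",
                             paste(t, collapse = " "), call. = FALSE)
    stats::setNames(list(as.numeric(t[2])), t[1])
  })
  do.call(trace_params, unlist(vals, recursive = FALSE))
}

#' @rdname read_params
#' @param params a [trace_params()] object.
#' @export
write_params <- function(params, path) {
  lines <- vapply(names(params), function(nm) {
    sprintf("%s\t%s", nm, format(params[[nm]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a feature table
#'
#' Tab-separated table: first column phoneme symbol, remaining columns the
#' named feature dimensions. Used together with [phoneme_inventory()].
#'
#' @param path file path.
#' @return `read_feature_table()` returns a numeric matrix with phoneme
#'   rownames; `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "#",
                          quote = "", fileEncoding = "UTF-8")
  m <- as.matrix(df)
  rownames(m) <- normalize_phonemes(rownames(m))
  m
}

#' @rdname read_feature_table
#' @param features numeric matrix with phoneme rownames.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(phoneme = rownames(features), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
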