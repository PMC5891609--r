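#' Phoneme inventory
#'
#' An inventory pairs an ordered set of phoneme symbols with a matrix of
#' continuous feature values (one row per phoneme, one column per named
#' feature dimension). The feature rows define the input patterns the
#' simulator writes into the input field and the bottom-up weights of the
#' feature-to-phoneme connections. An optional ambient (silence) symbol
#' carries the pattern used outside the spoken word; by convention it is
#' all-zero.
#'
#' @param symbols character vector of phoneme labels (ASCII; see
#'   [normalize_phonemes()] for accepted aliases of the two non-ASCII
#'   symbols).
#' @param features numeric matrix with `length(symbols)` rows; row order
#'   matches `symbols`. All values must be finite.
#' @param ambient single symbol used for silence/boundary (default `"-"`);
#'   must not collide with `symbols`. Its feature pattern is all-zero.
#' @return an object of class `phoneme_inventory`.
#' @seealso [trace_inventory()] for the default 14-phoneme inventory.
#' @export
phoneme_inventory <- function(symbols, features, ambient = "-") {
  symbols <- as.character(symbols)
  stopifnot(length(symbols) >= 1, !anyDuplicated(symbols))
  features <- as.matrix(features)
  if (nrow(features) != length(symbols)) {
    stop("`features` must have one row per symbol", call. = FALSE)
  }
  if (!all(is.finite(features))) {
    stop("feature values must be finite", call. = FALSE)
  }
  if (ambient %in% symbols) {
    stop("ambient symbol collides with a phoneme symbol", call. = FALSE)
  }
  rownames(features) <- symbols
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  structure(
    list(symbols = symbols, features = features, ambient = ambient),
    class = "phoneme_inventory"
  )
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat(
    "<phoneme_inventory> ", length(x$symbols), " phonemes, ",
    ncol(x$features), " feature dimensions\n  ",
    paste(x$symbols, collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of phonemes / feature dimensions of an inventory
#' @param inventory a [phoneme_inventory()].
#' @return integer count.
#' @export
n_phonemes <- function(inventory) length(inventory$symbols)

#' @rdname n_phonemes
#' @export
n_features <- function(inventory) ncol(inventory$features)

# Canonical-style continuous feature table for the 14-phoneme inventory.
# Seven named dimensions loosely following the classical acoustic-phonetic
# set (power, vocalic, consonantal, voiced, diffuse, acute, burst); values
# in [0, 1], chosen so every phoneme has a distinct pattern and phonetically
# close segments (e.g. /p b/, /u ^/) have closer patterns than distant ones.
default_feature_table <- function() {
  dims <- c("pow", "voc", "cns", "voi", "dif", "acu", "bur")
  m <- rbind(
    p = c(0.20, 0.00, 1.00, 0.00, 0.80, 0.20, 1.00),
    b = c(0.30, 0.00, 1.00, 1.00, 0.80, 0.20, 0.80),
    t = c(0.20, 0.00, 1.00, 0.00, 0.90, 0.90, 1.00),
    d = c(0.30, 0.00, 1.00, 1.00, 0.90, 0.90, 0.80),
    k = c(0.20, 0.00, 1.00, 0.00, 0.20, 0.35, 1.00),
    g = c(0.30, 0.00, 1.00, 1.00, 0.20, 0.35, 0.80),
    s = c(0.40, 0.00, 0.80, 0.00, 0.90, 0.95, 0.30),
    S = c(0.40, 0.00, 0.80, 0.00, 0.60, 0.70, 0.30),
    r = c(0.70, 0.60, 0.50, 1.00, 0.40, 0.50, 0.00),
    l = c(0.70, 0.60, 0.50, 1.00, 0.55, 0.65, 0.00),
    a = c(1.00, 1.00, 0.00, 1.00, 0.10, 0.30, 0.00),
    i = c(1.00, 1.00, 0.00, 1.00, 1.00, 0.95, 0.00),
    u = c(1.00, 1.00, 0.00, 1.00, 0.70, 0.05, 0.00),
    "^" = c(0.90, 1.00, 0.00, 1.00, 0.40, 0.40, 0.00)
  )
  colnames(m) <- dims
  m
}

#' The default 14-phoneme inventory
#'
#' The classical TRACE-style phoneme set
#' /p b t d k g s ʃ r l a i u ˆ/, held internally with the ASCII
#' aliases `S` (for ʃ) and `^` (for ˆ). Feature values come from
#' the packaged seven-dimension table (see `inst/extdata/features-default.tsv`
#' for the same table in file form).
#'
#' @return a [phoneme_inventory()] with 14 phonemes.
#' @export
trace_inventory <- function() {
  phoneme_inventory(rownames(default_feature_table()),
                    default_feature_table())
}

#' Normalize phoneme symbols to their ASCII form
#'
#' The two non-ASCII inventory symbols are accepted on input and mapped to
#' their ASCII aliases: ʃ (esh) becomes `S` and ˆ / ʌ
#' (caret / wedge) become `^`. All other symbols pass through unchanged.
#'
#' @param x character vector of phoneme symbols.
#' @return character vector of the same length.
#' @export
normalize_phonemes <- function(x) {
  aliases <- c("S", "^", "^")
  names(aliases) <- c("\u0283", "\u02c6", "\u028c")
  hit <- x %in% names(aliases)
  x[hit] <- aliases[x[hit]]
  x
}

#' Substitution rules for out-of-inventory symbols
#'
#' Transcriptions from a general phonetic dictionary use a richer alphabet
#' than the 14-phoneme inventory. These rules map the recoverable symbols
#' onto inventory members before filtering: schwa to `^`, ash (æ) to
#' `a`, open o (ɔ) to `a`, and the vocalic liquids `L`/`R` to `l`/`r`.
#'
#' @param extra optional named character vector of additional mappings
#'   (names = source symbols, values = inventory symbols); entries override
#'   the defaults on name collision.
#' @return named character vector (class `substitution_rules`).
#' @export
substitution_rules <- function(extra = NULL) {
  rules <- c("^", "a", "a", "l", "r")
  # schwa, ash, open-o, vocalic l, vocalic r
  names(rules) <- c("\u0259", "\u00e6", "\u0254", "L", "R")
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)))
    rules[names(extra)] <- extra
  }
  class(rules) <- c("substitution_rules", class(rules))
  rules
}

#' Apply substitution rules to a phoneme sequence
#'
#' @param phonemes character vector of symbols.
#' @param rules a [substitution_rules()] mapping.
#' @return character vector with mapped symbols replaced and all symbols
#'   normalized to ASCII form.
#' @export
apply_substitutions <- function(phonemes, rules = substitution_rules()) {
  phonemes <- as.character(phonemes)
  hit <- phonemes %in% names(rules)
  phonemes[hit] <- unname(rules[phonemes[hit]])
  normalize_phonemes(phonemes)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
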