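#' Construct a lexicon
#'
#' A lexicon is a tibble with one row per word: `word` (unique id),
#' `phonemes` (list-column of phoneme symbol vectors) and `n_phonemes`.
#' Every symbol must belong to the inventory. Homophones — distinct words
#' with identical phoneme strings — are retained as separate entries;
#' under strict recognition scoring a homophone pair can never both stay
#' below threshold while the other crosses, so such items are unrecognizable
#' by construction (documented behavior).
#'
#' @param words character vector of unique word ids.
#' @param phonemes list of character vectors (or a character vector of
#'   space-separated symbol strings), parallel to `words`.
#' @param inventory a [phoneme_inventory()] used for validation.
#' @param name optional lexicon name.
#' @return a tibble of class `lexicon`.
#' @export
lexicon <- function(words, phonemes, inventory = trace_inventory(),
                    name = "lexicon") {
  words <- as.character(words)
  if (anyDuplicated(words)) {
    stop("duplicate word_id: ",
         paste(unique(words[duplicated(words)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.character(phonemes)) phonemes <- strsplit(phonemes, "[ \t]+")
  stopifnot(length(words) == length(phonemes))
  phonemes <- lapply(phonemes, function(p) normalize_phonemes(as.character(p)))
  for (i in seq_along(phonemes)) {
    bad <- setdiff(phonemes[[i]], inventory$symbols)
    if (length(bad)) {
      stop("unknown phoneme symbol ", paste(bad, collapse = " "),
           " in word '", words[i], "'", call. = FALSE)
    }
    if (!length(phonemes[[i]])) {
      stop("word '", words[i], "' has an empty transcription", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    word = words,
    phonemes = phonemes,
    n_phonemes = lengths(phonemes)
  )
  attr(out, "name") <- name
  class(out) <- c("lexicon", class(out))
  out
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon '", attr(x, "name"), "'> ", nrow(x), " words\n", sep = "")
  NextMethod()
}

#' Read a lexicon from a plain-text file
#'
#' One entry per line: a word id, then whitespace, then space-separated
#' phoneme symbols. `#` starts a comment; blank lines are skipped. The
#' ASCII aliases `S` and `^` and their non-ASCII originals are both
#' accepted.
#'
#' @param path file path.
#' @param inventory a [phoneme_inventory()].
#' @param name lexicon name; defaults to the file's base name.
#' @return a [lexicon()].
#' @export
read_lexicon <- function(path, inventory = trace_inventory(), name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  words <- character(0)
  phon <- list()
  for (i in keep) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) < 2) {
      stop("line ", i, ": expected a word id and at least one phoneme",
           call. = FALSE)
    }
    syms <- normalize_phonemes(toks[-1])
    bad <- setdiff(syms, inventory$symbols)
    if (length(bad)) {
      stop("line ", i, ": unknown phoneme symbol '", bad[1], "'",
           call. = FALSE)
    }
    if (toks[1] %in% words) {
      stop("line ", i, ": duplicate word_id '", toks[1], "'", call. = FALSE)
    }
    words <- c(words, toks[1])
    phon <- c(phon, list(syms))
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lexicon(words, phon, inventory, name = name)
}

#' Write a lexicon to the plain-text format read by [read_lexicon()]
#'
#' @param lex a [lexicon()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  lines <- vapply(seq_len(nrow(lex)), function(i) {
    paste(lex$word[i], paste(lex$phonemes[[i]], collapse = " "), sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a lexicon from a phonetic dictionary
#'
#' Emulates constructing a model lexicon by scanning a large electronic
#' dictionary: each transcription is passed through the substitution rules,
#' and the entry is retained exactly when every resulting symbol belongs to
#' the inventory. Entries containing unrecoverable segments (nasals, other
#' vowels, ...) are dropped. The operation is idempotent: running it on its
#' own output changes nothing.
#'
#' @param entries a data frame with columns `orthography` and
#'   `transcription` (space-separated phoneme symbols, any alphabet).
#' @param inventory a [phoneme_inventory()].
#' @param rules a [substitution_rules()] mapping.
#' @param name lexicon name.
#' @return a [lexicon()] of the retained entries, input order preserved;
#'   empty input gives an empty lexicon.
#' @export
build_from_dictionary <- function(entries, inventory = trace_inventory(),
                                  rules = substitution_rules(),
                                  name = "dictionary") {
  stopifnot(is.data.frame(entries),
            all(c("orthography", "transcription") %in% names(entries)))
  if (!nrow(entries)) {
    return(lexicon(character(0), list(), inventory, name = name))
  }
  phon <- lapply(strsplit(as.character(entries$transcription), "[ \t]+"),
                 apply_substitutions, rules = rules)
  keep <- vapply(phon, function(p) {
    length(p) > 0 && all(p %in% inventory$symbols)
  }, logical(1))
  ids <- make.unique(as.character(entries$orthography)[keep], sep = "_")
  lexicon(ids, phon[keep], inventory, name = name)
}

#' Convert a lexicon back to dictionary entries
#'
#' Convenience inverse of [build_from_dictionary()]: returns a tibble with
#' `orthography` and `transcription` columns.
#'
#' @param lex a [lexicon()].
#' @return a tibble.
#' @export
as_dictionary_entries <- function(lex) {
  tibble::tibble(
    orthography = lex$word,
    transcription = vapply(lex$phonemes, paste, character(1), collapse = " ")
  )
}

#' The four-word gang demonstration lexicon
#'
#' clue /k l u/ together with the gang clock /k l a k/, clod /k l a d/,
#' clot /k l a t/: the gang members share a three-phoneme onset with each
#' other but only two phonemes with clue, the structure under which mutual
#' lexical feedback to the unheard vowel lets the gang transiently suppress
#' the target.
#'
#' @param inventory a [phoneme_inventory()].
#' @return a [lexicon()] of four words.
#' @export
mini_gang_lexicon <- function(inventory = trace_inventory()) {
  lexicon(
    c("clue", "clock", "clod", "clot"),
    list(c("k", "l", "u"), c("k", "l", "a", "k"),
         c("k", "l", "a", "d"), c("k", "l", "a", "t")),
    inventory, name = "minigang"
  )
}

# longest common prefix length of two symbol vectors
common_prefix_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq)) neq[1] - 1L else n
}
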