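#' Specification for a synthetic lexicon
#'
#' Describes the structured random lexicons used for whole-lexicon
#' simulation studies when a canonical word list is not available. The
#' generator plants a controlled number of gang clusters (a short target
#' plus `gang_size` longer words that share `gang_shared_prefix_len` onset
#' phonemes with each other but only two with the target, mirroring the
#' clue/clock/clod/clot configuration) and onset-embedded pairs (one word a
#' strict prefix of another), then fills the remainder with words that are
#' guaranteed to introduce no further gangs or embeddings.
#'
#' @param n_words total number of words.
#' @param length_weights numeric vector of sampling weights over filler
#'   word lengths; names give the lengths. The default favors 3-5 phoneme
#'   words, the densest region of short English content words.
#' @param n_gangs number of planted gang clusters (each consumes
#'   `gang_size + 1` words).
#' @param gang_size words per gang, excluding the target.
#' @param gang_shared_prefix_len onset phonemes shared within a gang
#'   (must be at least 2; the target shares exactly two).
#' @param n_onset_embeddings number of planted embedded pairs (each
#'   consumes 2 words).
#' @param seed integer seed; the generator is deterministic given the spec.
#' @return a list of class `synthetic_lexicon_spec`.
#' @export
synthetic_lexicon_spec <- function(n_words = 100,
                                   length_weights = c("3" = 0.35, "4" = 0.3,
                                                      "5" = 0.2, "6" = 0.1,
                                                      "7" = 0.05),
                                   n_gangs = 5, gang_size = 3,
                                   gang_shared_prefix_len = 3,
                                   n_onset_embeddings = 5, seed = 1L) {
  stopifnot(n_words >= 0, n_gangs >= 0, gang_size >= 0,
            n_onset_embeddings >= 0, gang_shared_prefix_len >= 2,
            length(length_weights) >= 1, all(length_weights >= 0),
            sum(length_weights) > 0)
  if (is.null(names(length_weights))) {
    stop("`length_weights` must be named by word length", call. = FALSE)
  }
  structure(
    list(n_words = as.integer(n_words), length_weights = length_weights,
         n_gangs = as.integer(n_gangs), gang_size = as.integer(gang_size),
         gang_shared_prefix_len = as.integer(gang_shared_prefix_len),
         n_onset_embeddings = as.integer(n_onset_embeddings),
         seed = as.integer(seed)),
    class = "synthetic_lexicon_spec"
  )
}

# Roughly CV-alternating random word over the inventory; keeps strings
# pronounceable-looking so synthetic lexicons resemble the phonotactics of
# real short words rather than uniform symbol soup.
random_word_syms <- function(len, consonants, vowels) {
  syms <- character(len)
  is_vowel <- runif(1) < 0.25
  for (j in seq_len(len)) {
    pool <- if (is_vowel) vowels else consonants
    syms[j] <- sample(pool, 1)
    flip <- if (is_vowel) 0.85 else 0.7
    is_vowel <- if (runif(1) < flip) !is_vowel else is_vowel
  }
  syms
}

#' Generate a structured synthetic lexicon
#'
#' Deterministic given the spec (including its seed). The output contains
#' exactly the requested gang clusters and onset-embedded pairs and no
#' accidental ones: filler words never share three or more onset phonemes
#' with any other word and never stand in a prefix relation, and each
#' embedded pair's two-phoneme onset is unique to the pair, so
#' [gang_report()] run over the output finds precisely the planted
#' structure.
#'
#' @param spec a [synthetic_lexicon_spec()].
#' @param inventory a [phoneme_inventory()]; vowels are taken to be the
#'   phonemes with a dominant `voc` feature when present, else the last
#'   quarter of the inventory.
#' @return a [lexicon()] with `spec$n_words` words. Word ids encode their
#'   role: `g<i>t` (gang target), `g<i>m<j>` (gang member), `e<i>s`/`e<i>l`
#'   (embedded short/long), `w<i>` (filler).
#' @export
generate_synthetic_lexicon <- function(spec, inventory = trace_inventory()) {
  stopifnot(inherits(spec, "synthetic_lexicon_spec"))
  consumed <- spec$n_gangs * (spec$gang_size + 1L) + 2L * spec$n_onset_embeddings
  n_fill <- spec$n_words - consumed
  if (n_fill < 0) {
    stop("infeasible spec: gangs and embeddings require ", consumed,
         " words but n_words = ", spec$n_words, call. = FALSE)
  }
  if (spec$n_gangs > 0 && spec$gang_shared_prefix_len < 3) {
    stop("infeasible spec: a detectable gang needs a mutual prefix longer ",
         "than the two-phoneme cohort overlap (gang_shared_prefix_len >= 3)",
         call. = FALSE)
  }
  feats <- inventory$features
  if ("voc" %in% colnames(feats)) {
    vowels <- inventory$symbols[feats[, "voc"] >= 0.9]
  } else {
    vowels <- utils::tail(inventory$symbols, max(1, length(inventory$symbols) %/% 4))
  }
  consonants <- setdiff(inventory$symbols, vowels)
  if (!length(vowels)) vowels <- inventory$symbols
  if (!length(consonants)) consonants <- inventory$symbols
  gpl <- spec$gang_shared_prefix_len

  with_local_seed(spec$seed, {
    words <- character(0)
    phon <- list()
    keys <- character(0)      # full strings, for duplicate checks
    pre3 <- character(0)      # 3-phoneme onset keys in use
    pair_pre2 <- character(0) # 2-phoneme onsets reserved by embedded pairs
    gang_pre2 <- character(0) # 2-phoneme onsets reserved by gang clusters
    key <- function(p) paste(p, collapse = " ")

    add <- function(id, p) {
      words <<- c(words, id)
      phon <<- c(phon, list(p))
      keys <<- c(keys, key(p))
      if (length(p) >= 3) pre3 <<- c(pre3, key(p[1:3]))
    }
    sample_len <- function() {
      as.integer(sample(names(spec$length_weights), 1,
                        prob = spec$length_weights))
    }

    # --- gang clusters -----------------------------------------------------
    for (g in seq_len(spec$n_gangs)) {
      ok <- FALSE
      for (try in 1:2000) {
        prefix <- random_word_syms(gpl, consonants, vowels)
        if (gpl >= 3 && key(prefix[1:3]) %in% pre3) next
        # a cluster's two-phoneme onset is unique to it, so the cluster is
        # a gang only relative to its own designated target
        if (key(prefix[1:2]) %in% gang_pre2) next
        if (any(vapply(phon, function(p) common_prefix_len(p, prefix) >= 2,
                       logical(1)))) next
        # target diverges at position 3; shares exactly two with the gang
        alt <- setdiff(inventory$symbols, prefix[3])
        tgt <- c(prefix[1:2], sample(alt, 1),
                 if (gpl > 3) random_word_syms(gpl - 3L, consonants, vowels))
        tails <- sample(inventory$symbols, spec$gang_size)
        members <- lapply(tails, function(s) c(prefix, s))
        cand <- c(list(tgt), members)
        ck <- vapply(cand, key, character(1))
        c3 <- vapply(cand[lengths(cand) >= 3],
                     function(p) key(p[1:3]), character(1))
        if (anyDuplicated(ck) || any(ck %in% keys)) next
        if (key(tgt[1:3]) %in% c3[-1] || any(c3 %in% pre3)) next
        for (j in seq_along(members)) add(sprintf("g%dm%d", g, j), members[[j]])
        add(sprintf("g%dt", g), tgt)
        gang_pre2 <- c(gang_pre2, key(prefix[1:2]))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible spec: could not place gang cluster ", g,
                    call. = FALSE)
    }

    # --- onset-embedded pairs ---------------------------------------------
    for (e in seq_len(spec$n_onset_embeddings)) {
      ok <- FALSE
      for (try in 1:2000) {
        short <- random_word_syms(3L, consonants, vowels)
        if (key(short[1:3]) %in% pre3) next
        if (key(short[1:2]) %in% pair_pre2) next
        # pair onsets must be unique so the pair joins no cohort
        if (any(vapply(phon, function(p) common_prefix_len(p, short) >= 2,
                       logical(1)))) next
        long <- c(short, random_word_syms(1L + (runif(1) < 0.5),
                                          consonants, vowels))
        if (key(short) %in% keys || key(long) %in% keys) next
        add(sprintf("e%ds", e), short)
        add(sprintf("e%dl", e), long)
        pair_pre2 <- c(pair_pre2, key(short[1:2]))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible spec: could not place embedded pair ", e,
                    call. = FALSE)
    }

    # --- fillers: no new gangs, no new embeddings --------------------------
    for (i in seq_len(n_fill)) {
      ok <- FALSE
      for (try in 1:5000) {
        p <- random_word_syms(sample_len(), consonants, vowels)
        if (key(p) %in% keys) next
        if (length(p) >= 3 && key(p[1:3]) %in% pre3) next
        if (length(p) >= 2 && key(p[1:2]) %in% c(pair_pre2, gang_pre2)) next
        clash <- vapply(phon, function(q) {
          cpl <- common_prefix_len(p, q)
          cpl >= 3 || cpl == min(length(p), length(q))
        }, logical(1))
        if (any(clash)) next
        add(sprintf("w%d", i), p)
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible spec: could not place filler word ", i,
                    call. = FALSE)
    }

    lexicon(words, phon, inventory,
            name = sprintf("synthetic-%d-seed%d", spec$n_words, spec$seed))
  })
}
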