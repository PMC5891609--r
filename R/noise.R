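#' Noise specification
#'
#' The study grid corrupts every element of the input field with i.i.d.
#' zero-mean Gaussian noise, freshly drawn for each time step, at seven
#' standard deviations from 0 to 1.5 in steps of 0.25 — a range meant to
#' impede the model only slightly at one end and severely at the other.
#' Noisy inputs are not clipped; activations (not inputs) are bounded.
#'
#' @param sd_levels ordered numeric vector of noise standard deviations.
#' @param mean noise mean (0 in the study design).
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(sd_levels = seq(0, 1.5, by = 0.25), mean = 0) {
  stopifnot(all(sd_levels >= 0), !is.unsorted(sd_levels))
  structure(list(sd_levels = as.numeric(sd_levels), mean = as.numeric(mean)),
            class = "noise_spec")
}

#' Corrupt an input field with Gaussian noise
#'
#' Adds independent `N(mean, sd)` noise to every element, drawn from the
#' current RNG stream. Use [trial_seed()] (or any seeding discipline) to
#' make draws reproducible. `sd = 0` returns the input unchanged without
#' touching the RNG.
#'
#' @param x numeric vector or matrix (an input field, or one time-step
#'   row of one).
#' @param sd noise standard deviation (must be non-negative).
#' @param mean noise mean.
#' @return object of the same shape as `x`.
#' @export
corrupt_input <- function(x, sd, mean = 0) {
  if (!is.numeric(sd) || length(sd) != 1 || is.na(sd) || sd < 0) {
    stop("noise sd must be a single non-negative number", call. = FALSE)
  }
  if (sd == 0 && mean == 0) return(x)
  x + stats::rnorm(length(x), mean = mean, sd = sd)
}

#' Deterministic per-trial seed
#'
#' Maps a trial's identity — word, noise-level index, feedback setting and
#' replicate — plus the experiment master seed to a stream seed, via a
#' stable polynomial string hash. Trials therefore reproduce exactly under
#' a fixed master seed regardless of the order in which a batch executes
#' them.
#'
#' @param master_seed integer master seed of the experiment.
#' @param word_id word identifier.
#' @param sd_index 1-based index of the noise level in the grid.
#' @param feedback logical feedback setting.
#' @param replicate replicate number.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
trial_seed <- function(master_seed, word_id, sd_index, feedback,
                       replicate = 1L) {
  key <- paste(word_id, as.integer(sd_index), as.integer(as.logical(feedback)),
               as.integer(replicate), sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master_seed) + h) %% 2147483647)
}
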