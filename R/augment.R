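## Training-time augmentation operators. All are deterministic under a
## fixed R RNG state (pass `seed` or `set.seed()` upstream) and are applied
## only when building training data — inference is augmentation-free.

#' Augmentation policy
#'
#' @param brightness_range image brightness factors are drawn uniformly
#'   from this range (sub-interval of `(0, 1]`).
#' @param shuffle_reads permute read order?
#' @param coverage_downsample randomly thin coverage?
#' @param downsample_range kept-coverage fraction range used when thinning.
#' @param mnv_synthesis_rate fraction of substitution windows to augment
#'   with an adjacent second substitution.
#' @param rng_seed integer seed.
#' @return an `augment_policy`.
#' @export
augment_policy <- function(brightness_range = c(0.3, 1.0),
                           shuffle_reads = TRUE,
                           coverage_downsample = TRUE,
                           downsample_range = c(0.5, 1.0),
                           mnv_synthesis_rate = 0.2,
                           rng_seed = 1L) {
  stopifnot(length(brightness_range) == 2L,
            brightness_range[1] > 0, brightness_range[2] <= 1,
            brightness_range[1] <= brightness_range[2],
            mnv_synthesis_rate >= 0, mnv_synthesis_rate <= 1)
  structure(list(brightness_range = brightness_range,
                 shuffle_reads = shuffle_reads,
                 coverage_downsample = coverage_downsample,
                 downsample_range = downsample_range,
                 mnv_synthesis_rate = mnv_synthesis_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "augment_policy")
}

#' Scale image brightness
#'
#' Multiplies every pixel by `factor` (rounded half-up); zeros stay zero,
#' so the one-hot structure is preserved. Applied globally across the
#' three channels.
#'
#' @param image a `dnm_image` (or integer array).
#' @param factor scalar in `[0.3, 1]`.
#' @return image of the same type.
#' @export
random_brightness <- function(image, factor) {
  if (!is_scalar_number(factor) || factor < 0.3 || factor > 1) {
    stop2("brightness factor must be in [0.3, 1]")
  }
  out <- image
  out[] <- as.integer(round_half_up(as.numeric(image) * factor))
  out
}

#' Shuffle read order
#'
#' For a window, permutes each member's read slices; for an encoded image,
#' permutes the occupied rows within each channel (reads are
#' channel-specific, so permutations are drawn independently per channel).
#' The multiset of rows/reads is unchanged.
#'
#' @param x a `trio_window` or `dnm_image`.
#' @param seed optional RNG seed.
#' @return object of the same type.
#' @export
shuffle_reads <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "trio_window")) {
    for (role in TRIO_ROLES) {
      n <- length(x$reads[[role]])
      if (n > 1L) x$reads[[role]] <- x$reads[[role]][sample.int(n)]
    }
    return(x)
  }
  for (k in seq_len(dim(x)[3])) {
    occupied <- which(rowSums(x[, , k] != 0L) > 0L)
    if (length(occupied) > 1L) {
      x[occupied, , k] <- x[sample(occupied), , k]
    }
  }
  x
}

#' Randomly thin coverage
#'
#' Subsamples each member's reads without replacement to emulate
#' lower-coverage sequencing; at least one read is kept per non-empty
#' member. Survivor order is preserved.
#'
#' @param window a `trio_window`.
#' @param keep_fraction fraction of reads to keep, in `(0, 1]`.
#' @param seed optional RNG seed.
#' @return a `trio_window`.
#' @export
downsample_coverage <- function(window, keep_fraction, seed = NULL) {
  stopifnot(inherits(window, "trio_window"))
  if (!is_scalar_number(keep_fraction) || keep_fraction <= 0 ||
      keep_fraction > 1) {
    stop2("keep_fraction must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  for (role in TRIO_ROLES) {
    n <- length(window$reads[[role]])
    if (n == 0L) next
    k <- max(1L, as.integer(round_half_up(n * keep_fraction)))
    if (k < n) {
      window$reads[[role]] <- window$reads[[role]][sort(sample.int(n, k))]
    }
  }
  window
}

#' Synthesize an adjacent second substitution (MNV enrichment)
#'
#' Writes a second substitution into the reads at a window offset adjacent
#' to the variant, consistently per read: exactly the reads that carry the
#' alt allele also receive the adjacent change, in every member, so the
#' inheritance pattern (and hence the label) is preserved.
#'
#' @param window a substitution `trio_window`.
#' @param seed optional RNG seed.
#' @return a `trio_window` with the extra substitution applied.
#' @export
synthesize_mnv <- function(window, seed = NULL) {
  stopifnot(inherits(window, "trio_window"))
  if (window$variant_type != "substitution") {
    stop2("MNV synthesis applies to substitution windows only")
  }
  if (!is.null(seed)) set.seed(seed)
  vp <- window$variant_position
  offs <- vp + c(nchar(window$ref), -1L)      # right of the event, else left
  offs <- offs[offs >= window$window_start &
               offs < window$window_start + WINDOW_LEN]
  if (!length(offs)) stop2("variant at window edge: no free adjacent offset")
  target <- offs[[1]]
  alt1 <- substr(window$alt, 1L, 1L)
  new_base <- NULL
  for (role in TRIO_ROLES) {
    for (i in seq_along(window$reads[[role]])) {
      s <- window$reads[[role]][[i]]
      at_var <- which(!is.na(s$columns$ref_pos) &
                        s$columns$ref_pos == vp)
      if (!length(at_var) || s$columns$base[at_var[1]] != alt1) next
      at_tgt <- which(!is.na(s$columns$ref_pos) &
                        s$columns$ref_pos == target)
      if (!length(at_tgt)) next
      cur <- s$columns$base[at_tgt[1]]
      if (cur == GAP) next
      if (is.null(new_base)) new_base <- random_other_base(cur)
      if (new_base != cur) {
        window$reads[[role]][[i]]$columns$base[at_tgt[1]] <- new_base
      }
    }
  }
  window
}

#' Apply an augmentation policy to one simulated window
#'
#' Order: optional MNV synthesis (substitutions only), coverage thinning,
#' read shuffling. Brightness is an image-level operator; apply
#' [random_brightness()] after encoding.
#'
#' @param window a `trio_window`.
#' @param policy an [augment_policy()].
#' @return a `trio_window`.
#' @export
augment_window <- function(window, policy = augment_policy()) {
  if (window$variant_type == "substitution" &&
      stats::runif(1) < policy$mnv_synthesis_rate) {
    window <- synthesize_mnv(window)
  }
  if (policy$coverage_downsample) {
    window <- downsample_coverage(
      window, stats::runif(1, policy$downsample_range[1],
                           policy$downsample_range[2]))
  }
  if (policy$shuffle_reads) window <- shuffle_reads(window)
  window
}
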