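## Encode a trio read window as the fixed-size RGB intensity image the
## classifier consumes: rows = reads (capped at 160), columns = 41 genomic
## positions x 4 one-hot pixels (A,C,T,G), channels = child/father/mother.

#' Quality-to-intensity model
#'
#' Pixel intensity is `round(255 * min(1, bq/bq_cap) * min(1, mq/mq_cap))`:
#' monotone in both qualities and saturating at 255 once both caps are
#' reached. The caps default to common Illumina maxima (base quality 40,
#' mapping quality 60) and are configurable.
#'
#' @param base_quality_cap,mapping_quality_cap Phred caps (> 0).
#' @param max_intensity maximum pixel value (255).
#' @return an `intensity_model`.
#' @export
intensity_model <- function(base_quality_cap = 40, mapping_quality_cap = 60,
                            max_intensity = 255L) {
  stopifnot(base_quality_cap > 0, mapping_quality_cap > 0,
            max_intensity == 255L)
  structure(list(base_quality_cap = base_quality_cap,
                 mapping_quality_cap = mapping_quality_cap,
                 max_intensity = 255L),
            class = "intensity_model")
}

#' Pixel intensity for a base/mapping quality pair
#'
#' @param base_quality,mapping_quality Phred scores (>= 0; vectorized).
#' @param model an [intensity_model()].
#' @return integer intensities in `[0, 255]`.
#' @export
pixel_intensity <- function(base_quality, mapping_quality,
                            model = intensity_model()) {
  if (any(base_quality < 0) || any(mapping_quality < 0)) {
    stop2("qualities must be non-negative")
  }
  as.integer(round_half_up(
    255 * pmin(1, base_quality / model$base_quality_cap) *
      pmin(1, mapping_quality / model$mapping_quality_cap)
  ))
}

## Rasterization anchor: the read base aligned to the variant position is
## drawn in base block 20; every alignment column (including insertions,
## which have no reference position, and deletion gaps, which light no
## pixel but consume a block) shifts by one block from its neighbour. A
## read not covering the variant is anchored by the reference offset of its
## leftmost in-window aligned column.
slice_blocks <- function(slice, variant_position) {
  cols <- slice$columns
  n <- length(cols$base)
  anchor_idx <- which(!is.na(cols$ref_pos) & cols$ref_pos == variant_position)
  if (length(anchor_idx)) {
    anchor_idx <- anchor_idx[1]
    anchor_block <- WINDOW_FLANK
  } else {
    anchor_idx <- which(!is.na(cols$ref_pos))[1]
    anchor_block <- cols$ref_pos[anchor_idx] -
      (variant_position - WINDOW_FLANK)
  }
  blocks <- anchor_block + (seq_len(n) - anchor_idx)
  blocks
}

#' Encode the reads of one trio member as a single channel
#'
#' @param slices list of read slices (ordered per the extraction contract).
#' @param variant_position 0-based position of the variant's first base.
#' @param model an [intensity_model()].
#' @return integer matrix `160 x 164`.
#' @export
encode_member <- function(slices, variant_position,
                          model = intensity_model()) {
  mat <- matrix(0L, IMAGE_ROWS, IMAGE_COLS)
  n <- min(length(slices), IMAGE_ROWS)
  for (i in seq_len(n)) {
    s <- slices[[i]]
    blocks <- slice_blocks(s, variant_position)
    base <- s$columns$base
    lit <- base %in% BASES & blocks >= 0L & blocks < WINDOW_LEN
    if (!any(lit)) next
    colidx <- 4L * blocks[lit] + match(base[lit], BASES)  # 1-based column
    vals <- pixel_intensity(s$columns$qual[lit],
                            rep(s$mapping_quality, sum(lit)), model)
    mat[cbind(rep(i, length(colidx)), colidx)] <- vals
  }
  mat
}

#' Encode a trio window as a 160 x 164 x 3 intensity image
#'
#' Channels 1/2/3 hold the child/father/mother pileups; the variant's first
#' base occupies one-hot block index 20 (0-based), i.e. image columns
#' 81..84.
#'
#' @param window a `trio_window`.
#' @param model an [intensity_model()].
#' @return a `dnm_image`: integer array `160 x 164 x 3` with metadata
#'   attributes `contig`, `position` (1-based), `variant_type`.
#' @export
encode_trio <- function(window, model = intensity_model()) {
  stopifnot(inherits(window, "trio_window"))
  img <- array(0L, dim = c(IMAGE_ROWS, IMAGE_COLS, 3L))
  for (k in seq_along(TRIO_ROLES)) {
    img[, , k] <- encode_member(window$reads[[TRIO_ROLES[k]]],
                                window$variant_position, model)
  }
  structure(img, class = "dnm_image",
            contig = window$contig,
            position = window$variant_position + 1L,
            variant_type = window$variant_type)
}

#' @export
print.dnm_image <- function(x, ...) {
  cat(sprintf("<dnm_image> %s:%s (%s), %d x %d x %d, %d lit pixels\n",
              attr(x, "contig") %||% "?", attr(x, "position") %||% "?",
              attr(x, "variant_type") %||% "?",
              dim(x)[1], dim(x)[2], dim(x)[3], sum(x != 0L)))
  invisible(x)
}

#' Export an encoded image as PNG (lossless round-trip)
#'
#' @param image a `dnm_image`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Import a PNG written by [write_image_png()]
#'
#' @param path PNG path.
#' @return integer array `rows x cols x 3`.
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  storage.mode(arr) <- "double"
  array(as.integer(round_half_up(arr * 255)), dim = dim(arr))
}
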