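# 3D brightness/contrast balancing across sections: pluggable tissue-mask
# provider plus masked histogram matching to a high-contrast template
# section.

#' Classical tissue mask provider
#'
#' Deterministic threshold/morphology mask at a coarse pixel size: blocks
#' are tissue when their local texture (block standard deviation) exceeds a
#' floor and their mean intensity lies inside a plausible tissue range
#' (excluding dark substrate and saturated debris), followed by
#' morphological closing and opening. The mask interface also accepts
#' externally produced masks (e.g. from a learned model) in place of this
#' provider.
#'
#' @param section section image matrix (working pixel size).
#' @param pixel_size_nm pixel size of `section`.
#' @param config [pipeline_config()] (`mask_pixel_nm` sets the mask scale).
#' @param intensity_range plausible tissue mean range (gray levels).
#' @param texture_floor minimum block standard deviation.
#' @return list of class `tissue_mask`: `mask` (logical matrix at the mask
#'   scale), `pixel_size_nm`, `provenance` ("classical").
#' @export
classical_mask <- function(section, pixel_size_nm = 16, config = pipeline_config(),
                           intensity_range = c(30, 235), texture_floor = 4) {
  f <- max(1L, round(config$mask_pixel_nm / pixel_size_nm))
  mu <- block_reduce(section, f, mean)
  sdv <- block_reduce(section, f, stats::sd)
  m <- sdv > texture_floor & mu >= intensity_range[1] & mu <= intensity_range[2]
  if (any(m)) {
    k <- EBImage::makeBrush(3, "box")
    im <- EBImage::Image(t(m) * 1)
    im <- EBImage::opening(EBImage::closing(im, k), k)
    m <- t(as.matrix(im)) > 0.5
  }
  if (!any(m)) warning("tissue mask is empty")
  structure(list(mask = m, pixel_size_nm = f * pixel_size_nm,
                 provenance = "classical"),
            class = "tissue_mask")
}

# upsample a coarse mask to the section grid (nearest / block replication)
mask_at_section <- function(mask, section, pixel_size_nm = 16) {
  f <- max(1L, round(mask$pixel_size_nm / pixel_size_nm))
  m <- mask$mask
  big <- m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f), drop = FALSE]
  h <- nrow(section); w <- ncol(section)
  out <- matrix(FALSE, h, w)
  hh <- min(h, nrow(big)); ww <- min(w, ncol(big))
  out[seq_len(hh), seq_len(ww)] <- big[seq_len(hh), seq_len(ww)]
  out
}

#' Masked 256-bin histogram of a section
#'
#' Counts only pixels inside the tissue mask (upsampled to the section
#' grid).
#'
#' @param section section image.
#' @param mask a `tissue_mask` (or logical matrix at section resolution).
#' @param pixel_size_nm section pixel size.
#' @return integer vector of 256 counts summing to the masked pixel count.
#' @export
masked_histogram <- function(section, mask, pixel_size_nm = 16) {
  m <- if (inherits(mask, "tissue_mask"))
    mask_at_section(mask, section, pixel_size_nm) else mask
  if (!any(m)) stop("empty tissue mask")
  hist256(section[m])
}

# monotone gray mapping from source histogram to template histogram by CDF
# inversion; among target bins with equal cumulative mass the lowest
# intensity is chosen (empty-bin runs collapse to their first bin, which
# keeps self-matching an identity)
histogram_mapping <- function(src_hist, template_hist) {
  if (sum(src_hist > 0) < 2 || sum(template_hist > 0) < 2)
    stop("degenerate (single-bin) histogram")
  cs <- cumsum(src_hist) / sum(src_hist)
  ct <- cumsum(template_hist) / sum(template_hist)
  lo <- findInterval(cs - 1e-12, ct, left.open = TRUE) + 1L  # first ct >= cs
  cummax(pmin(lo, 256) - 1)                 # enforce monotonicity
}

#' Match a section's masked histogram to a template histogram
#'
#' Computes a monotone non-decreasing gray-level mapping from the section's
#' masked histogram onto the template histogram (masked-CDF inversion, ties
#' broken toward the lower intensity) and applies it to the whole section.
#' Sections already
#' matching the template change by at most about one gray level.
#'
#' @param section section image.
#' @param mask tissue mask (see [masked_histogram()]).
#' @param template_hist 256-bin histogram of the (manually selected,
#'   high-contrast) template section.
#' @param pixel_size_nm section pixel size.
#' @return list: `image` (corrected section), `mapping` (length-256 gray
#'   mapping).
#' @export
match_to_template <- function(section, mask, template_hist, pixel_size_nm = 16) {
  sh <- masked_histogram(section, mask, pixel_size_nm)
  map <- histogram_mapping(sh, template_hist)
  idx <- as.integer(round(pmin(pmax(section, 0), 255))) + 1L
  list(image = matrix(map[idx], nrow(section), ncol(section)), mapping = map)
}

#' Balance contrast across a stack by masked histogram matching
#'
#' @param sections list of section images.
#' @param template_index index of the high-contrast template section.
#' @param masks optional list of tissue masks (computed classically when
#'   NULL).
#' @param pixel_size_nm section pixel size.
#' @param config [pipeline_config()].
#' @return list of corrected sections.
#' @export
contrast_balance_stack <- function(sections, template_index = 1, masks = NULL,
                                   pixel_size_nm = 16, config = pipeline_config()) {
  if (is.null(masks))
    masks <- lapply(sections, classical_mask, pixel_size_nm = pixel_size_nm,
                    config = config)
  th <- masked_histogram(sections[[template_index]], masks[[template_index]],
                         pixel_size_nm)
  lapply(seq_along(sections), function(i)
    match_to_template(sections[[i]], masks[[i]], th, pixel_size_nm)$image)
}
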