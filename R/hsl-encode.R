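## HSL encoding of a per-locus expression profile over ordered sample
## points. Lightness carries the (log, background-subtracted, clamped)
## maximum intensity from white down to mid-grey; saturation the squared
## relative range ((max-min)/max)^2; hue the peak sample point over a
## 240-degree red-to-blue span, nudged up to half-way towards the larger
## neighbour in proportion to its relative intensity.

#' Encoding parameters
#'
#' @param n_samples number of ordered sample points per profile (>= 2).
#' @param background noise floor subtracted before the log; intensities at
#'   or below it display white. See [estimate_background()].
#' @param upper_clamp intensity cap; values at or above it display at the
#'   lightness floor. See [upper_clamp_value()].
#' @param hue_span_degrees hue range; the default 240 covers two-thirds of
#'   the colour wheel, red through the spectrum to blue.
#' @param lightness_floor lightness at/above the clamp (0.5 = mid-grey).
#' @param hue_mode `"spectrum"` (default) or `"two-colour"`, a linear ramp
#'   between two primaries usable under single-cone colour-vision
#'   deficiency.
#' @param two_colour_hues length-2 hue anchors used when
#'   `hue_mode = "two-colour"`.
#' @return an `EncodingParams` list.
#' @export
encoding_params <- function(n_samples, background = 0, upper_clamp,
                            hue_span_degrees = 240, lightness_floor = 0.5,
                            hue_mode = c("spectrum", "two-colour"),
                            two_colour_hues = c(0, 240)) {
  hue_mode <- match.arg(hue_mode)
  if (n_samples < 2L) stopf("n_samples must be >= 2")
  if (background < 0) stopf("background must be non-negative")
  if (upper_clamp <= background) stopf("upper_clamp must exceed background")
  if (hue_span_degrees <= 0 || hue_span_degrees > 360)
    stopf("hue_span_degrees must lie in (0, 360]")
  if (lightness_floor <= 0 || lightness_floor >= 1)
    stopf("lightness_floor must lie in (0, 1)")
  structure(list(n_samples = as.integer(n_samples),
                 background = background, upper_clamp = upper_clamp,
                 hue_span_degrees = hue_span_degrees,
                 lightness_floor = lightness_floor,
                 hue_mode = hue_mode, two_colour_hues = two_colour_hues),
            class = "EncodingParams")
}

#' Estimate the background noise floor from a normalised tile matrix
#'
#' Most of a bacterial genome is transcribed on one strand only, so the
#' less-expressed strand of each locus estimates non-specific signal. For
#' every tile the per-library average intensity of each strand is taken;
#' the background is twice the median (over tiles) of the smaller of the
#' two strand averages.
#'
#' @param matrix a normalised [tile_depth_matrix()] (both strands present).
#' @return non-negative scalar.
#' @export
estimate_background <- function(matrix) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  fwd <- rowMeans(matrix$depth$forward)
  rev <- rowMeans(matrix$depth$reverse)
  2 * stats::median(pmin(fwd, rev))
}

#' Upper display clamp from a normalised tile matrix
#'
#' The 99th percentile (linear interpolation between order statistics,
#' `quantile type = 7`) of tile intensities at the most-expressed sample
#' point — the library whose total normalised depth is largest — over both
#' strands. Caps the skewed long tail of strong expression so the log
#' lightness scale discriminates the majority of loci.
#'
#' @param matrix a normalised, replicate-merged [tile_depth_matrix()].
#' @param probs percentile, default 0.99.
#' @return positive scalar.
#' @export
upper_clamp_value <- function(matrix, probs = 0.99) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  totals <- library_sizes(matrix)
  top <- names(totals)[which.max(totals)]
  vals <- c(matrix$depth$forward[, top], matrix$depth$reverse[, top])
  unname(stats::quantile(vals, probs, type = 7))
}

#' Lightness channel
#'
#' `L = 1 - (1 - floor) * log(1 + I) / log(1 + range)` with
#' `I = clamp(max_intensity - background, 0, upper_clamp - background)`:
#' white (1) at or below background, the floor (mid-grey by default) at or
#' above the clamp, logarithmic in between. Monotone non-increasing in
#' intensity; any log base gives the same value.
#'
#' @param max_intensity profile maximum (non-negative; vectorised).
#' @param params an [encoding_params()].
#' @return lightness fraction(s) in `[lightness_floor, 1]`.
#' @export
lightness_channel <- function(max_intensity, params) {
  rng <- params$upper_clamp - params$background
  i <- clamp(max_intensity - params$background, 0, rng)
  1 - (1 - params$lightness_floor) * log1p(i) / log1p(rng)
}

#' Saturation channel
#'
#' `S = ((max - min) / max)^2`; 0 for a flat (or all-zero) profile, 1 when
#' the minimum is zero. The square usefully suppresses hue where the range
#' is under ~2-fold.
#'
#' @param profile non-negative numeric vector over sample points.
#' @return fraction in `[0, 1]`.
#' @export
saturation_channel <- function(profile) {
  mx <- max(profile)
  if (mx <= 0) return(0)
  ((mx - min(profile)) / mx)^2
}

#' Hue channel
#'
#' Anchor hue for peak index p (0-based) is `p/(n-1) * hue_span`; the hue
#' then shifts towards the larger neighbour by
#' `(neighbour/peak) * half inter-anchor spacing`, so it never crosses more
#' than half-way to the adjacent sample point. Endpoints shift only inward.
#' If two samples tie for the maximum, the earlier is the peak and the tie
#' partner pulls exactly half-way in its direction; equal nonzero
#' neighbours cancel (no shift). An all-zero profile returns hue 0 (the
#' colour is irrelevant because saturation is 0).
#'
#' @param profile non-negative numeric vector over sample points.
#' @param params an [encoding_params()] (uses `hue_span_degrees`,
#'   `hue_mode`, `two_colour_hues`).
#' @return hue in degrees, within `[0, 360)`.
#' @export
hue_channel <- function(profile, params) {
  n <- length(profile)
  mx <- max(profile)
  if (mx <= 0) return(0)
  p <- which.max(profile)                 # earliest maximal index
  frac <- hue_fraction(profile, p, n)
  if (params$hue_mode == "two-colour") {
    h <- params$two_colour_hues[1] +
      frac * diff(params$two_colour_hues[1:2])
  } else {
    h <- frac * params$hue_span_degrees
  }
  h %% 360
}

## peak position as a fraction of [0, 1] along the sample axis, including
## the half-spacing neighbour adjustment
hue_fraction <- function(profile, p, n) {
  spacing <- 1 / (n - 1)
  anchor <- (p - 1) * spacing
  mx <- profile[p]
  ties <- which(profile == mx)
  if (length(ties) > 1L)
    return(anchor + 0.5 * spacing * sign(ties[2] - p))
  left <- if (p > 1L) profile[p - 1L] else NA_real_
  right <- if (p < n) profile[p + 1L] else NA_real_
  shift <- 0
  if (!is.na(right) && (is.na(left) || right > left))
    shift <- (right / mx) * 0.5 * spacing
  else if (!is.na(left) && (is.na(right) || left > right))
    shift <- -(left / mx) * 0.5 * spacing
  anchor + shift
}

#' Encode a profile as an HSL colour
#'
#' @param profile non-negative numeric vector of length
#'   `params$n_samples`.
#' @param params an [encoding_params()].
#' @return an `HslColour`: list with `hue` (degrees in `[0,360)`),
#'   `saturation` and `lightness` (fractions).
#' @examples
#' p <- encoding_params(7, background = 2, upper_clamp = 100)
#' encode_profile(c(0, 1, 9, 40, 9, 1, 0), p)
#' @export
encode_profile <- function(profile, params) {
  stopifnot(inherits(params, "EncodingParams"))
  if (length(profile) != params$n_samples)
    stopf("profile has %d values; params declare %d sample points",
          length(profile), params$n_samples)
  if (any(profile < 0)) stopf("profile values must be non-negative")
  structure(list(hue = hue_channel(profile, params),
                 saturation = saturation_channel(profile),
                 lightness = lightness_channel(max(profile), params)),
            class = "HslColour")
}

#' @export
print.HslColour <- function(x, ...) {
  rgb <- hsl_to_rgb(x)
  cat(sprintf("HSL(%.1f, %.3f, %.3f) = RGB(%d, %d, %d)\n",
              x$hue, x$saturation, x$lightness, rgb[1], rgb[2], rgb[3]))
  invisible(x)
}

#' Convert HSL to 8-bit RGB
#'
#' Standard bi-hexcone HSL conversion, rounded half-up to integers.
#'
#' @param hsl an `HslColour` (or list with hue/saturation/lightness).
#' @return integer vector `c(r, g, b)` in `[0, 255]`.
#' @export
hsl_to_rgb <- function(hsl) {
  h <- (hsl$hue %% 360) / 60
  s <- hsl$saturation; l <- hsl$lightness
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- l - c / 2
  rgb1 <- switch(findInterval(h, 0:5, rightmost.closed = TRUE),
                 c(c, x, 0), c(x, c, 0), c(0, c, x),
                 c(0, x, c), c(x, 0, c), c(c, 0, x))
  as.integer(floor((rgb1 + m) * 255 + 0.5))
}

#' Invert the lightness map back to a clamped intensity
#'
#' Useful for checking the encoding: recovers
#' `clamp(max_intensity, background, upper_clamp)` from a lightness value.
#'
#' @param lightness value in `[lightness_floor, 1]`.
#' @param params an [encoding_params()].
#' @return intensity on the original scale.
#' @export
lightness_to_intensity <- function(lightness, params) {
  rng <- params$upper_clamp - params$background
  i <- expm1((1 - lightness) / (1 - params$lightness_floor) * log1p(rng))
  params$background + i
}

#' Encode every tile of a matrix
#'
#' Treats each library of a (normalised, replicate-merged) matrix as one
#' ordered sample point and encodes every (strand, tile) profile.
#'
#' @param matrix a [tile_depth_matrix()] whose libraries are the ordered
#'   sample points.
#' @param params an [encoding_params()] with matching `n_samples`; when
#'   missing, one is built with `background = estimate_background(matrix)`
#'   and `upper_clamp = upper_clamp_value(matrix)`.
#' @return data.frame: strand, tile, tile_start, H, S, L, R, G, B.
#' @export
encode_matrix <- function(matrix, params = NULL) {
  stopifnot(inherits(matrix, "TileDepthMatrix"))
  if (is.null(params)) {
    params <- encoding_params(length(matrix$libraries),
                              background = estimate_background(matrix),
                              upper_clamp = upper_clamp_value(matrix))
  }
  if (params$n_samples != length(matrix$libraries))
    stopf("params declare %d sample points; matrix has %d libraries",
          params$n_samples, length(matrix$libraries))
  ax <- matrix$axis
  one_strand <- function(strand) {
    d <- matrix$depth[[strand]]
    cols <- t(apply(d, 1, function(v) {
      hsl <- encode_profile(v, params)
      c(hsl$hue, hsl$saturation, hsl$lightness, hsl_to_rgb(hsl))
    }))
    data.frame(strand = strand, tile = seq_len(ax$n_tiles),
               tile_start = (seq_len(ax$n_tiles) - 1L) * ax$tile_size,
               H = cols[, 1], S = cols[, 2], L = cols[, 3],
               R = as.integer(cols[, 4]), G = as.integer(cols[, 5]),
               B = as.integer(cols[, 6]))
  }
  rbind(one_strand("forward"), one_strand("reverse"))
}

#' Write a colour table as TSV
#' @param colours data.frame from [encode_matrix()] or [render_genes()].
#' @param path output TSV path.
#' @export
write_colour_table <- function(colours, path) {
  num <- vapply(colours, is.double, logical(1))
  out <- colours
  out[num] <- lapply(colours[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
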