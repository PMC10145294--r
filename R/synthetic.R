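# Synthetic lodged-field mosaic generator.
#
# Emulates the statistics of a UAV orthomosaic of a paddy field containing
# lodged (flattened) patches among upright canopy: two vegetation classes
# with deliberately similar colours but different directional textures,
# plus a small fraction of bare ground / path pixels.  The index mask is
# exact ground truth by construction: class textures are applied strictly
# within their mask regions.  Labels: 0 = background, 1 = healthy canopy,
# 2 = lodging.

#' Configuration of the synthetic field generator
#'
#' @param height,width mosaic size in pixels.
#' @param lodging_fraction target fraction of all pixels labelled lodging
#'   (default 0.42, a heavily lodged field).
#' @param background_fraction approximate fraction of bare path pixels
#'   (default 0.04), laid out as one horizontal and one vertical strip.
#' @param patch_count approximate number of distinct lodging patches; sets
#'   the correlation length of the smooth random field whose upper level
#'   set becomes the lodging mask.
#' @param patch_scale patch length scale in pixels; overrides
#'   `patch_count` when given.
#' @param noise_sd standard deviation of per-pixel Gaussian image noise.
#' @param seed integer RNG seed; the same config generates bitwise
#'   identical mosaics.
#' @return a `field_config` object.
#' @export
field_config <- function(height = 1536L, width = 1536L,
                         lodging_fraction = 0.42,
                         background_fraction = 0.04,
                         patch_count = 24L, patch_scale = NULL,
                         noise_sd = 0.02, seed = 1L) {
  stopifnot(height >= 8L, width >= 8L,
            lodging_fraction >= 0, lodging_fraction <= 1,
            background_fraction >= 0, background_fraction < 0.5,
            patch_count >= 1L, noise_sd >= 0)
  if (is.null(patch_scale))
    patch_scale <- sqrt(height * width / patch_count)
  structure(list(height = as.integer(height), width = as.integer(width),
                 lodging_fraction = lodging_fraction,
                 background_fraction = background_fraction,
                 patch_count = as.integer(patch_count),
                 patch_scale = patch_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "field_config")
}

# Class appearance: means close between canopy and lodging on purpose
# (lodged straw is slightly brighter and yellower than upright canopy).
field_palette <- function() {
  list(background = c(0.45, 0.42, 0.38),
       healthy    = c(0.24, 0.42, 0.20),
       lodging    = c(0.31, 0.46, 0.25))
}

# Smooth unit-variance random field: a coarse Gaussian grid with cell size
# `scale` pixels, bilinearly upsampled to the mosaic size.
smooth_field <- function(h, w, scale) {
  gh <- max(2L, as.integer(ceiling(h / scale)) + 1L)
  gw <- max(2L, as.integer(ceiling(w / scale)) + 1L)
  g <- array(stats::rnorm(gh * gw), dim = c(gh, gw, 1L))
  bilinear_resize(g, h, w)[, , 1L]
}

#' Generate a synthetic lodged-field mosaic
#'
#' Healthy canopy gets a directional planting-row texture; lodging regions
#' (the upper level set of a smooth random field, thresholded so the
#' realised pixel fraction matches `lodging_fraction` exactly up to
#' rounding) get a flatter, brighter texture with a different orientation;
#' background strips get an untextured soil tone.  Image values are
#' quantised to 8 bits so PNG round trips are exact.
#'
#' @param config a [field_config()].
#' @return a `mosaic` object: list with `image` (`H x W x 3` in `[0, 1]`),
#'   `mask` (`H x W` integer, values 0/1/2) and `config`.
#' @export
generate_field <- function(config = field_config()) {
  stopifnot(inherits(config, "field_config"))
  set.seed(config$seed)
  h <- config$height; w <- config$width
  mask <- matrix(1L, h, w)

  # background strips (paths), one horizontal + one vertical
  if (config$background_fraction > 0) {
    bw <- max(1L, round(config$background_fraction * w / 2))
    bh <- max(1L, round(config$background_fraction * h / 2))
    x0 <- sample.int(w - bw, 1L)
    y0 <- sample.int(h - bh, 1L)
    mask[y0:(y0 + bh - 1L), ] <- 0L
    mask[, x0:(x0 + bw - 1L)] <- 0L
  }

  # lodging = upper level set of a smooth field over the vegetated area
  veg <- which(mask == 1L)
  target <- round(config$lodging_fraction * h * w)
  if (target > length(veg))
    stop("lodging_fraction ", config$lodging_fraction,
         " is unreachable: only ", length(veg), " of ", h * w,
         " pixels are vegetated")
  if (target > 0L) {
    f <- smooth_field(h, w, config$patch_scale)
    cut <- stats::quantile(f[veg], 1 - target / length(veg), names = FALSE)
    lodged <- veg[f[veg] >= cut]
    lodged <- lodged[seq_len(min(length(lodged), target))]
    mask[lodged] <- 2L
  }

  pal <- field_palette()
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # planting rows: strong narrow stripes for upright canopy
  rows_h <- 0.045 * sin(2 * pi * (0.23 * xx + 0.97 * yy) / 9)
  # flattened straw: broader, fainter stripes at a different angle
  rows_l <- 0.025 * sin(2 * pi * (0.91 * xx - 0.41 * yy) / 23)

  img <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) {
    plane <- matrix(pal$background[c], h, w)
    plane[mask == 1L] <- pal$healthy[c] + rows_h[mask == 1L]
    plane[mask == 2L] <- pal$lodging[c] + rows_l[mask == 2L]
    img[, , c] <- plane
  }
  if (config$noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = config$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255   # exact 8-bit PNG round trips

  structure(list(image = img, mask = mask, config = config),
            class = "mosaic")
}
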