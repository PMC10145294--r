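# Tiling and split protocol for large field mosaics.
#
# The mosaic is partitioned into three disjoint spatial regions
# (train/val/test bands) so no evaluation pixel is ever seen in training.
# Evaluation tiles are sampled without overlap inside their band;
# training tiles are sampled freely (overlaps allowed) inside the training
# band.  All origins are 0-based (x = column, y = row), top-left origin.

#' Split protocol configuration
#'
#' Defaults are desk-scale (small mosaic, 64-pixel tiles); the full
#' orthomosaic protocol (224-pixel tiles, thousands of crops) is reached
#' by passing larger values.
#'
#' @param crop_size tile side length in pixels.
#' @param ratios `(train, val, test)` area proportions, summing to 1;
#'   default `c(0.6, 0.2, 0.2)`.
#' @param n_eval_crops total number of non-overlapping evaluation tiles,
#'   split evenly between the validation and test bands.
#' @param n_train_crops number of (possibly overlapping) training tiles.
#' @param seed RNG seed for crop placement.
#' @return a `split_config` object.
#' @export
split_config <- function(crop_size = 64L, ratios = c(0.6, 0.2, 0.2),
                         n_eval_crops = 100L, n_train_crops = 200L,
                         seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-8, crop_size >= 1L,
            n_eval_crops >= 0L, n_train_crops >= 0L)
  structure(list(crop_size = as.integer(crop_size), ratios = ratios,
                 n_eval_crops = as.integer(n_eval_crops),
                 n_train_crops = as.integer(n_train_crops),
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Partition a mosaic into train/validation/test regions
#'
#' Contiguous vertical bands by default: spatially disjoint regions
#' covering the whole mosaic, with areas proportional to `ratios` (exact
#' up to one pixel column/row of rounding).
#'
#' @param dims `c(height, width)` of the mosaic, or a `mosaic` object.
#' @param ratios `(train, val, test)` proportions summing to 1.
#' @param orientation `"vertical"` (bands along the width) or
#'   `"horizontal"`.
#' @return data.frame with one row per split: `split`, `x`, `y` (0-based
#'   origin), `w`, `h`.
#' @export
partition_regions <- function(dims, ratios = c(0.6, 0.2, 0.2),
                              orientation = c("vertical", "horizontal")) {
  if (inherits(dims, "mosaic")) dims <- dim(dims$mask)
  orientation <- match.arg(orientation)
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  h <- dims[1]; w <- dims[2]
  extent <- if (orientation == "vertical") w else h
  edges <- round(cumsum(c(0, ratios)) * extent)
  sizes <- diff(edges)
  out <- data.frame(split = c("train", "val", "test"),
                    x = 0L, y = 0L, w = w, h = h,
                    stringsAsFactors = FALSE)
  if (orientation == "vertical") {
    out$x <- as.integer(edges[1:3]); out$w <- as.integer(sizes)
  } else {
    out$y <- as.integer(edges[1:3]); out$h <- as.integer(sizes)
  }
  out
}

crop_overlaps <- function(x1, y1, x2, y2, size) {
  abs(x1 - x2) < size & abs(y1 - y2) < size
}

#' Sample non-overlapping square crops inside a region
#'
#' Rejection sampling with bounded retries: candidate origins are drawn
#' uniformly; a candidate overlapping an accepted tile is rejected, and a
#' stalled packing is restarted from scratch a bounded number of times.
#' Dense requests (above roughly half the region area, where random
#' sequential packing jams) fall back to a randomised grid: row and
#' column offsets are drawn as order statistics of the available slack,
#' and `n` of the resulting disjoint cells are kept at random.
#'
#' @param region one row of [partition_regions()] (or any list with
#'   `x`, `y`, `w`, `h`).
#' @param n number of crops.
#' @param size crop side length in pixels.
#' @param seed RNG seed.
#' @return integer matrix `n x 2` (columns `x`, `y`) of 0-based origins in
#'   mosaic coordinates; tiles are pairwise disjoint and lie fully inside
#'   the region.
#' @export
sample_nonoverlapping_crops <- function(region, n, size, seed = 1L) {
  set.seed(seed)
  if (region$w < size || region$h < size)
    stop("region smaller than crop size")
  cap <- (region$w %/% size) * (region$h %/% size)
  if (n > cap)
    stop("region can hold at most ", cap, " disjoint ", size, "x", size,
         " tiles; ", n, " requested")
  density <- n * size^2 / (region$w * region$h)
  if (density <= 0.45) {
    max_tries <- max(200L * n, 1000L)
    for (restart in 1:25) {
      xs <- integer(0); ys <- integer(0)
      tries <- 0L
      while (length(xs) < n && tries < max_tries) {
        tries <- tries + 1L
        cx <- sample.int(region$w - size + 1L, 1L) - 1L + region$x
        cy <- sample.int(region$h - size + 1L, 1L) - 1L + region$y
        if (!any(crop_overlaps(xs, ys, cx, cy, size))) {
          xs <- c(xs, cx); ys <- c(ys, cy)
        }
      }
      if (length(xs) == n)
        return(cbind(x = xs, y = ys))
    }
  }
  # dense packing: jittered disjoint grid cells
  kx <- region$w %/% size
  ky <- region$h %/% size
  ox <- floor(sort(stats::runif(kx, 0, region$w - kx * size + 1)))
  oy <- floor(sort(stats::runif(ky, 0, region$h - ky * size + 1)))
  cells_x <- region$x + (seq_len(kx) - 1L) * size + as.integer(ox)
  cells_y <- region$y + (seq_len(ky) - 1L) * size + as.integer(oy)
  grid <- expand.grid(x = cells_x, y = cells_y)
  keep <- sample.int(nrow(grid), n)
  cbind(x = grid$x[keep], y = grid$y[keep])
}

#' Sample freely-overlapping square crops inside a region
#'
#' @inheritParams sample_nonoverlapping_crops
#' @return integer matrix `n x 2` of 0-based origins; overlaps permitted.
#' @export
sample_overlapping_crops <- function(region, n, size, seed = 1L) {
  set.seed(seed)
  if (region$w < size || region$h < size)
    stop("region smaller than crop size")
  cbind(x = sample.int(region$w - size + 1L, n, replace = TRUE) - 1L +
          region$x,
        y = sample.int(region$h - size + 1L, n, replace = TRUE) - 1L +
          region$y)
}

extract_tile <- function(mosaic, x, y, size) {
  ry <- (y + 1L):(y + size)
  rx <- (x + 1L):(x + size)
  list(image = mosaic$image[ry, rx, , drop = FALSE],
       mask = mosaic$mask[ry, rx, drop = FALSE])
}

#' Cut a mosaic into a train/val/test tile set
#'
#' Applies the full protocol: band partition per `ratios`, overlapping
#' training crops in the train band, and non-overlapping evaluation crops
#' split evenly between the validation and test bands.
#'
#' @param mosaic a [generate_field()] mosaic.
#' @param config a [split_config()].
#' @return a `tileset`: list of tiles (`image`, `mask`, `origin`,
#'   `split`) plus a `manifest` data.frame.
#' @export
make_tileset <- function(mosaic, config = split_config()) {
  stopifnot(inherits(mosaic, "mosaic"), inherits(config, "split_config"))
  # class-presence guarantee: if a vegetation class is missing from the
  # sampled tiles, resample with a shifted seed (bounded retries)
  for (try in 0:4) {
    ts <- make_tileset_once(mosaic, config, config$seed + 1000L * try)
    labs <- unlist(lapply(ts$tiles, function(t) unique(t$mask)))
    if (all(c(1L, 2L) %in% labs) || sum(mosaic$mask == 2L) == 0L)
      return(ts)
  }
  stop("could not sample tiles containing both vegetation classes")
}

make_tileset_once <- function(mosaic, config, seed) {
  regions <- partition_regions(dim(mosaic$mask), config$ratios)
  sz <- config$crop_size
  n_val <- config$n_eval_crops %/% 2L
  n_test <- config$n_eval_crops - n_val
  orig_train <- sample_overlapping_crops(regions[1, ], config$n_train_crops,
                                         sz, seed = seed)
  orig_val <- sample_nonoverlapping_crops(regions[2, ], n_val, sz,
                                          seed = seed + 1L)
  orig_test <- sample_nonoverlapping_crops(regions[3, ], n_test, sz,
                                           seed = seed + 2L)
  origins <- rbind(orig_train, orig_val, orig_test)
  split <- rep(c("train", "val", "test"),
               c(nrow(orig_train), nrow(orig_val), nrow(orig_test)))
  tiles <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    t <- extract_tile(mosaic, origins[i, 1], origins[i, 2], sz)
    t$origin <- origins[i, ]
    t$split <- split[i]
    tiles[[i]] <- t
  }
  manifest <- data.frame(id = sprintf("tile_%05d", seq_along(tiles)),
                         split = split,
                         x = origins[, 1], y = origins[, 2],
                         seed = seed,
                         stringsAsFactors = FALSE)
  structure(list(tiles = tiles, manifest = manifest,
                 crop_size = sz, config = config),
            class = "tileset")
}

tileset_split <- function(ts, split) {
  ts$tiles[ts$manifest$split == split]
}

# ---- augmentation --------------------------------------------------------

nearest_resize_mask <- function(mask, out_h, out_w) {
  h <- nrow(mask); w <- ncol(mask)
  yi <- if (out_h > 1) round(seq(0, h - 1, length.out = out_h)) + 1L else 1L
  xi <- if (out_w > 1) round(seq(0, w - 1, length.out = out_w)) + 1L else 1L
  mask[yi, xi, drop = FALSE]
}

#' Augment a tile
#'
#' Horizontal flip (image and mask together), bounded multiplicative
#' colour jitter (image only: global brightness and per-channel gains,
#' each within `1 +/- jitter`), and optional resizing (bilinear for the
#' image, nearest-neighbour for the mask so labels stay in {0, 1, 2}).
#'
#' @param tile list with `image` (`H x W x 3`) and `mask` (`H x W`).
#' @param flip logical; flip left-right.
#' @param jitter nonnegative jitter amplitude (0 disables).
#' @param resize_to optional `c(H, W)` output size.
#' @param seed optional RNG seed for the jitter draw.
#' @return augmented tile (same structure).
#' @export
augment_tile <- function(tile, flip = FALSE, jitter = 0,
                         resize_to = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- tile$image; mask <- tile$mask
  if (isTRUE(flip)) {
    img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (jitter > 0) {
    gains <- stats::runif(4L, 1 - jitter, 1 + jitter)
    img <- img * gains[1]
    for (c in 1:3) img[, , c] <- img[, , c] * gains[c + 1L]
    img <- pmin(pmax(img, 0), 1)
  }
  if (!is.null(resize_to)) {
    img <- bilinear_resize(img, resize_to[1], resize_to[2])
    mask <- nearest_resize_mask(mask, resize_to[1], resize_to[2])
  }
  tile$image <- img; tile$mask <- mask
  tile
}

# ---- tile set I/O --------------------------------------------------------

#' Write / read a tile set on disk
#'
#' Images are written as RGB PNG, masks as single-channel index PNG
#' (pixel value = class index), and the manifest as CSV.  Reading back a
#' written tile set reproduces it exactly (images are 8-bit quantised at
#' generation time).
#'
#' @param ts a `tileset`.
#' @param dir output directory (created if missing).
#' @return `write_tileset` returns `dir` invisibly; `read_tileset` returns
#'   a `tileset`.
#' @export
write_tileset <- function(ts, dir) {
  stopifnot(inherits(ts, "tileset"))
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(ts$tiles)) {
    id <- ts$manifest$id[i]
    png::writePNG(ts$tiles[[i]]$image,
                  file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(ts$tiles[[i]]$mask / 255,
                  file.path(dir, "masks", paste0(id, ".png")))
  }
  utils::write.csv(cbind(ts$manifest, crop_size = ts$crop_size),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_tileset
#' @export
read_tileset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  sz <- man$crop_size[1]
  tiles <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    ip <- file.path(dir, "images", paste0(man$id[i], ".png"))
    mp <- file.path(dir, "masks", paste0(man$id[i], ".png"))
    if (!file.exists(mp)) stop("missing mask file ", mp)
    if (!file.exists(ip)) stop("missing image file ", ip)
    img <- png::readPNG(ip)
    msk <- png::readPNG(mp)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    tiles[[i]] <- list(image = img,
                       mask = matrix(as.integer(round(msk * 255)),
                                     nrow(msk), ncol(msk)),
                       origin = c(x = man$x[i], y = man$y[i]),
                       split = man$split[i])
  }
  structure(list(tiles = tiles,
                 manifest = man[, c("id", "split", "x", "y", "seed")],
                 crop_size = sz, config = NULL),
            class = "tileset")
}
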