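#' Registered two-channel membrane image
#'
#' The two emission bands of a solvatochromic membrane probe recorded on the
#' same field: a blue band (500-540 nm) and a red band (630-735 nm). Both
#' arrays must be finite and of identical shape.
#'
#' @param blue,red 2-D numeric matrices of identical shape.
#' @param pixel_size_um optional pixel edge length in micrometres.
#' @param meta named list of annotations.
#' @return object of class `ImagePair`.
#' @export
image_pair <- function(blue, red, pixel_size_um = NULL, meta = list()) {
  blue <- as.matrix(blue); red <- as.matrix(red)
  if (!all(dim(blue) == dim(red)))
    stopf("blue (%s) and red (%s) images differ in shape",
          paste(dim(blue), collapse = "x"), paste(dim(red), collapse = "x"))
  if (any(!is.finite(blue)) || any(!is.finite(red)))
    stopf("image intensities must be finite")
  structure(list(blue = blue, red = red, pixel_size_um = pixel_size_um,
                 meta = as.list(meta)),
            class = "ImagePair")
}

#' Seed points for watershed segmentation
#'
#' Manually placed (or generator-supplied) seed pixels labelled `membrane`,
#' `interior` and `background`. Coordinates are 1-based `(row, col)` matrices,
#' matching R's matrix indexing; JSON seed files (see [read_seeds_json()]) use
#' 0-based coordinates and are converted on read.
#'
#' @param membrane,interior,background integer matrices with 2 columns
#'   (row, col); `membrane` must have at least one seed, the others may be
#'   `NULL`.
#' @return object of class `SeedSet`.
#' @export
seed_set <- function(membrane, interior = NULL, background = NULL) {
  as_coords <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- matrix(as.integer(round(as.matrix(x))), ncol = 2)
    if (nrow(x) == 0L) return(NULL)
    colnames(x) <- c("row", "col")
    x
  }
  membrane <- as_coords(membrane)
  if (is.null(membrane)) stopf("at least one membrane seed is required")
  structure(list(membrane = membrane, interior = as_coords(interior),
                 background = as_coords(background)),
            class = "SeedSet")
}

#' Read seeds from JSON
#'
#' Parses a seed file of the form
#' `{"membrane": [[r, c], ...], "interior": ..., "background": ...}` with
#' 0-based row/column coordinates and returns a 1-based [seed_set()].
#'
#' @param path JSON file.
#' @return a [seed_set()].
#' @export
read_seeds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grab <- function(k) {
    if (is.null(obj[[k]]) || !length(obj[[k]])) return(NULL)
    matrix(as.integer(obj[[k]]), ncol = 2) + 1L
  }
  seed_set(grab("membrane"), grab("interior"), grab("background"))
}

seed_label_matrix <- function(seeds, dims) {
  lab <- matrix(0L, dims[1], dims[2])
  put <- function(coords, value) {
    if (is.null(coords)) return()
    if (any(coords[, 1] < 1 | coords[, 1] > dims[1] |
            coords[, 2] < 1 | coords[, 2] > dims[2]))
      stopf("seed coordinates outside the %dx%d image", dims[1], dims[2])
    lab[coords] <<- value
  }
  put(seeds$membrane, 1L)
  put(seeds$interior, 2L)
  put(seeds$background, 3L)
  lab
}

#' Seeded watershed segmentation of the membrane
#'
#' Segments an image into membrane and non-membrane pixels by Meyer's
#' marker-based watershed on the inverted summed-channel intensity: the
#' bright membrane rim becomes a basin that the membrane seeds claim
#' directly, while interior and background seeds claim their own regions.
#' The flooding is fully deterministic; relief ties are broken by row-major
#' scan order (lowest index wins).
#'
#' @param pair an [image_pair()] (must not be constant).
#' @param seeds a [seed_set()] with at least one membrane seed.
#' @return object of class `SegmentationMask`: a logical membrane matrix with
#'   the full watershed label array (1 = membrane, 2 = interior,
#'   3 = background) in attribute `labels`.
#' @export
seeded_watershed_segment <- function(pair, seeds) {
  stopifnot(inherits(pair, "ImagePair"), inherits(seeds, "SeedSet"))
  total <- pair$blue + pair$red
  if (max(total) == min(total)) stopf("cannot segment an all-constant image")
  lab0 <- seed_label_matrix(seeds, dim(total))
  labels <- watershed_flood(-total, lab0)
  membrane <- labels == 1L
  if (!any(membrane)) stopf("segmentation produced no membrane pixels")
  structure(membrane, class = c("SegmentationMask", class(membrane)),
            labels = labels)
}

#' Per-pixel generalized polarization
#'
#' `GP = (blue - red) / (blue + red)`, computed where `blue + red > 0`;
#' other pixels are undefined and returned as `NA`. Inputs are expected to be
#' background-subtracted. GP lies in `[-1, 1]` wherever defined, is invariant
#' to a common scaling of both channels and antisymmetric under channel swap.
#'
#' @param blue,red numeric matrices of identical shape.
#' @return matrix of GP values with `NA` at invalid pixels.
#' @export
pixel_gp <- function(blue, red) {
  blue <- as.matrix(blue); red <- as.matrix(red)
  if (!all(dim(blue) == dim(red))) stopf("blue and red images differ in shape")
  total <- blue + red
  gp <- (blue - red) / total
  gp[total <= 0] <- NA_real_
  gp
}

#' Mean generalized polarization over a region
#'
#' Subtracts a per-channel scalar background, computes per-pixel GP and
#' averages it over the valid pixels of a region mask (typically the membrane
#' label from [seeded_watershed_segment()], or any user-supplied region mask
#' such as an organelle mask). Pixels whose background-subtracted channel sum
#' is `<= 0` are invalid and excluded.
#'
#' @param pair an [image_pair()].
#' @param mask logical matrix selecting region pixels (>= 1 must be `TRUE`).
#' @param background numeric length-2 `c(blue, red)` scalar background,
#'   e.g. from [estimate_background()]. Default `c(0, 0)`.
#' @return list with `mean_gp`, `n_pixels` (valid pixels averaged),
#'   `n_invalid` and `fraction_invalid`.
#' @export
mean_gp <- function(pair, mask, background = c(0, 0)) {
  stopifnot(inherits(pair, "ImagePair"))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(pair$blue))) stopf("mask shape differs from image")
  if (!any(mask)) stopf("mask selects no pixels")
  if (length(background) != 2L || any(!is.finite(background)))
    stopf("`background` must be two finite numbers c(blue, red)")
  gp <- pixel_gp(pair$blue - background[1], pair$red - background[2])
  vals <- gp[mask]
  n_invalid <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stopf("no valid pixels remain after background subtraction")
  list(mean_gp = mean(vals), n_pixels = length(vals), n_invalid = n_invalid,
       fraction_invalid = n_invalid / (length(vals) + n_invalid))
}

#' Estimate per-channel background from the segmentation
#'
#' Median intensity of the background-labelled watershed region in each
#' channel — a robust scalar background estimate for [mean_gp()].
#'
#' @param pair an [image_pair()].
#' @param segmentation a `SegmentationMask` from [seeded_watershed_segment()]
#'   whose label array contains background-labelled pixels.
#' @return numeric length-2 `c(blue, red)`.
#' @export
estimate_background <- function(pair, segmentation) {
  labels <- attr(segmentation, "labels")
  if (is.null(labels)) stopf("segmentation lacks a label array")
  bg <- labels == 3L
  if (!any(bg)) stopf("segmentation contains no background-labelled pixels")
  c(stats::median(pair$blue[bg]), stats::median(pair$red[bg]))
}

#' Segment-and-average convenience pipeline
#'
#' Runs [seeded_watershed_segment()], estimates the background from the
#' background-seeded region (when background seeds exist) and returns the
#' membrane mean GP.
#'
#' @param pair an [image_pair()].
#' @param seeds a [seed_set()].
#' @return the [mean_gp()] result with the mask in element `mask`.
#' @export
image_mean_gp <- function(pair, seeds) {
  mask <- seeded_watershed_segment(pair, seeds)
  background <- if (!is.null(seeds$background))
    estimate_background(pair, mask) else c(0, 0)
  out <- mean_gp(pair, mask, background = background)
  out$mask <- mask
  out$background <- background
  out
}

# ---------------------------------------------------------------------------
# image file I/O (16-bit grayscale TIFF per channel)

#' Read and write two-channel TIFF image pairs
#'
#' Each channel is stored as a single-channel TIFF; intensities are written
#' as 16-bit unsigned integers (values clamped to 0-65535) and read back as
#' raw counts. The channel order (blue, red) is fixed by the argument/manifest
#' position, never guessed from metadata.
#'
#' @param blue_path,red_path TIFF file paths.
#' @param pair an [image_pair()] (for writing).
#' @param meta annotations attached on read.
#' @return `read_image_pair()` returns an [image_pair()];
#'   `write_image_pair()` returns the paths invisibly.
#' @name image_io
NULL

#' @rdname image_io
#' @export
read_image_pair <- function(blue_path, red_path, meta = list()) {
  rd <- function(p) {
    if (!file.exists(p)) stopf("image file does not exist: %s", p)
    img <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.numeric(img), nrow = nrow(img))
  }
  image_pair(rd(blue_path), rd(red_path), meta = meta)
}

#' @rdname image_io
#' @export
write_image_pair <- function(pair, blue_path, red_path) {
  stopifnot(inherits(pair, "ImagePair"))
  wr <- function(img, p) {
    img <- pmin(pmax(round(img), 0), 65535)
    tiff::writeTIFF(img / 65535, p, bits.per.sample = 16)
  }
  wr(pair$blue, blue_path)
  wr(pair$red, red_path)
  invisible(c(blue_path, red_path))
}

#' Batch mean GP over an image manifest
#'
#' Processes a manifest of image pairs and seed files through the
#' segmentation + GP pipeline. Unreadable or failing entries are recorded as
#' failed rows (with the error message) and the run continues.
#'
#' @param manifest data.frame with columns `blue`, `red`, `seeds` (file
#'   paths); extra columns (e.g. group labels) are carried through.
#' @return data.frame with one row per manifest row: the manifest columns
#'   plus `mean_gp`, `n_pixels`, `status` and `error`.
#' @export
batch_image_gp <- function(manifest) {
  req <- c("blue", "red", "seeds")
  if (!all(req %in% names(manifest)))
    stopf("manifest must have columns %s", paste(req, collapse = ", "))
  if (nrow(manifest) == 0L) {
    out <- cbind(manifest,
                 data.frame(mean_gp = numeric(0), n_pixels = integer(0),
                            status = character(0), error = character(0)))
    return(out)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    res <- tryCatch({
      pair <- read_image_pair(manifest$blue[i], manifest$red[i])
      seeds <- read_seeds_json(manifest$seeds[i])
      g <- image_mean_gp(pair, seeds)
      data.frame(mean_gp = g$mean_gp, n_pixels = g$n_pixels,
                 status = "ok", error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(mean_gp = NA_real_, n_pixels = NA_integer_,
                 status = "failed", error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    cbind(manifest[i, , drop = FALSE], res, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
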