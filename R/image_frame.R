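#' Construct a 2-D image frame with physical pixel size
#'
#' An `image_frame` couples a grayscale intensity matrix with the physical
#' size of its (square) pixels, so that all spectral quantities downstream
#' can be expressed in physical units (cycles per micrometer) rather than
#' cycles per pixel. Intensities are non-negative and, for generated or
#' file-backed images, live in `[0, 1]`.
#'
#' @param intensities numeric matrix of non-negative intensities, at least
#'   16 x 16 pixels.
#' @param pixel_size_um micrometers per pixel (isotropic), positive.
#' @param source_id opaque identifier carried through scoring and reports.
#' @return An object of class `image_frame`: a list with elements
#'   `intensities`, `pixel_size_um` and `source_id`.
#' @examples
#' fr <- image_frame(matrix(runif(32 * 32), 32), pixel_size_um = 1.8)
#' dim(fr$intensities)
#' @export
image_frame <- function(intensities, pixel_size_um, source_id = "frame") {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (nrow(intensities) < 16L || ncol(intensities) < 16L)
    stop("image must be at least 16 x 16 pixels, got ",
         nrow(intensities), " x ", ncol(intensities))
  if (anyNA(intensities)) stop("'intensities' contains NA")
  if (min(intensities) < 0) stop("'intensities' must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(
    list(intensities = intensities,
         pixel_size_um = as.numeric(pixel_size_um),
         source_id = as.character(source_id)),
    class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_frame '%s'> %d x %d px @ %.3g um/px (%.3g x %.3g um)\n",
              x$source_id, d[1], d[2], x$pixel_size_um,
              d[1] * x$pixel_size_um, d[2] * x$pixel_size_um))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$intensities), max(x$intensities), mean(x$intensities)))
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$intensities)

is_image_frame <- function(x) inherits(x, "image_frame")

#' Construct a labeled image set
#'
#' Pairs a list of [image_frame()] objects with class labels in
#' `{"AWM", "NODAL"}` (atrial working myocardium vs. nodal tissue), the
#' containers produced by anatomical indexing of acquired images and by the
#' synthetic generator [generate_dataset()].
#'
#' @param images list of `image_frame` objects.
#' @param labels character vector of `"AWM"` / `"NODAL"`, one per image.
#' @param seed integer master seed when the set was generated synthetically,
#'   otherwise `NA`.
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, labels, seed = NA_integer_) {
  if (length(images) != length(labels))
    stop("'images' and 'labels' must have the same length (",
         length(images), " vs ", length(labels), ")")
  labels <- as.character(labels)
  bad <- which(!labels %in% c("AWM", "NODAL"))
  if (length(bad))
    stop("invalid label '", labels[bad[1]], "' at position ", bad[1],
         "; labels must be 'AWM' or 'NODAL'")
  ok <- vapply(images, is_image_frame, logical(1))
  if (length(ok) && !all(ok))
    stop("element ", which(!ok)[1], " of 'images' is not an image_frame")
  structure(list(images = images, labels = labels, seed = seed),
            class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$images)

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d images (%d AWM, %d NODAL)%s\n",
              length(x), sum(x$labels == "AWM"), sum(x$labels == "NODAL"),
              if (is.na(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' @export
`[.image_set` <- function(x, i) {
  image_set(x$images[i], x$labels[i], seed = x$seed)
}

#' Concatenate image sets
#' @param ... `image_set` objects.
#' @return A single `image_set`; the seed is kept only if all parts share it.
#' @export
c.image_set <- function(...) {
  parts <- list(...)
  seeds <- unique(vapply(parts, function(p) as.integer(p$seed), integer(1)))
  image_set(unlist(lapply(parts, `[[`, "images"), recursive = FALSE),
            unlist(lapply(parts, `[[`, "labels")),
            seed = if (length(seeds) == 1L) seeds else NA_integer_)
}
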