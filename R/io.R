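#' Quantize intensities to the 16-bit export grid
#'
#' Images are floating point in `[0, 1]` internally and 16-bit on disk.
#' Export truncates to the 65535-level grid (`floor(x * 65535) / 65535`),
#' matching the TIFF writer, so `quantize16()` predicts exactly what a
#' write/read round trip returns.
#'
#' @param x numeric vector or matrix in `[0, 1]`.
#' @return `x` snapped to the 16-bit grid.
#' @export
quantize16 <- function(x) floor(pmin(pmax(x, 0), 1) * 65535) / 65535

#' Write a labeled image set to disk
#'
#' Writes each frame as a 16-bit grayscale TIFF plus a sidecar labels CSV
#' with columns `filename`, `label`, `pixel_size_um`, `seed`. The CSV is
#' the authoritative carrier of the physical pixel size.
#'
#' @param set an [image_set()].
#' @param dir output directory, created if missing.
#' @param labels_csv name of the sidecar CSV inside `dir`.
#' @return The path of the labels CSV, invisibly.
#' @export
write_image_set <- function(set, dir, labels_csv = "labels.csv") {
  stopifnot(inherits(set, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(set)
  fn <- sprintf("img_%04d_%s.tif", seq_len(n), tolower(set$labels))
  for (i in seq_len(n))
    tiff::writeTIFF(pmin(pmax(set$images[[i]]$intensities, 0), 1),
                    file.path(dir, fn[i]), bits.per.sample = 16L)
  tab <- data.frame(
    filename = fn,
    label = set$labels,
    pixel_size_um = vapply(set$images, `[[`, numeric(1), "pixel_size_um"),
    seed = if (is.na(set$seed)) NA_integer_ else set$seed)
  path <- file.path(dir, labels_csv)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

read_gray_image <- function(path, row) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("labels CSV row ", row, ": unsupported image format '", ext,
         "' for file '", basename(path), "'"))
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] == 2L) return(m[, , 1])            # gray + alpha
    stop("labels CSV row ", row, ": image '", basename(path),
         "' is not monochrome (", dim(m)[3], " channels)")
  }
  m
}

#' Read a labeled image set from a directory and labels CSV
#'
#' Loads every image referenced in the labels CSV (columns `filename`,
#' `label`, and optionally `pixel_size_um` and `seed`) as a grayscale
#' [image_frame()]. Rows are processed in order of filename so the set is
#' deterministic regardless of CSV row order. Errors name the offending
#' 1-based CSV row.
#'
#' @param image_dir directory containing the image files.
#' @param labels_csv path to the labels CSV.
#' @param pixel_size_um fallback pixel size when the CSV has no
#'   `pixel_size_um` column.
#' @return An [image_set()].
#' @export
read_labeled_images <- function(image_dir, labels_csv,
                                pixel_size_um = NULL) {
  tab <- read.csv(labels_csv, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(image_set(list(), character(0)))
  stopifnot(all(c("filename", "label") %in% names(tab)))
  tab$.row <- seq_len(nrow(tab))
  tab <- tab[order(tab$filename), ]
  imgs <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    row <- tab$.row[k]
    if (!tab$label[k] %in% c("AWM", "NODAL"))
      stop("labels CSV row ", row, ": unknown label '", tab$label[k], "'")
    path <- file.path(image_dir, tab$filename[k])
    if (!file.exists(path))
      stop("labels CSV row ", row, ": file '", tab$filename[k],
           "' not found in '", image_dir, "'")
    px <- if ("pixel_size_um" %in% names(tab)) tab$pixel_size_um[k]
          else pixel_size_um
    if (is.null(px) || is.na(px))
      stop("labels CSV row ", row, ": no pixel size available ",
           "(no pixel_size_um column and no fallback given)")
    imgs[[k]] <- image_frame(read_gray_image(path, row), px,
                             source_id = tab$filename[k])
  }
  seed <- if ("seed" %in% names(tab) && !anyNA(tab$seed) &&
              length(unique(tab$seed)) == 1L)
    as.integer(tab$seed[1]) else NA_integer_
  image_set(imgs, tab$label, seed = seed)
}

#' Write and read I15 score tables
#'
#' CSV with columns `source_id`, `method`, `i15`, `label` (and
#' `degenerate` when present), the interchange format between the scoring
#' and ROC stages.
#'
#' @param scores a [score_set()] data frame.
#' @param path CSV path.
#' @return `write_scores` the path invisibly; `read_scores` the data frame.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source_id", "i15", "label") %in% names(tab)))
  tab
}
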