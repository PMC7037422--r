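as_pixel_matrix <- function(img) {
  if (inherits(img, "nuclei_image")) return(img$pixels)
  if (inherits(img, "Image")) return(EBImage::imageData(img))
  if (is.matrix(img)) return(img)
  stop("'img' must be a nuclei_image, an EBImage Image, or a matrix")
}

#' Count stained nuclei in a grayscale field
#'
#' Standard segmentation pipeline for Hoechst-type nuclear stains:
#' Gaussian smoothing, a global threshold (Otsu by default, computed on
#' the image rescaled to `[0, 1]` so the count is invariant to positive
#' intensity rescaling), connected-component labelling (8-connectivity),
#' and removal of components below `min_area`. Overlapping nuclei are not
#' split (no watershed): two blobs closer than the resolution of the
#' smoothed threshold merge into one count, a documented limitation.
#' Images use (row, col) indexing with the origin at the top-left.
#'
#' @param img a `nuclei_image` from [simulate_growth_images()], an
#'   `EBImage::Image`, or a numeric matrix.
#' @param smooth_sigma Gaussian smoothing radius in px.
#' @param min_area minimum component area in px.
#' @param threshold_rule `"otsu"` or an explicit numeric threshold on the
#'   rescaled `[0, 1]` intensities.
#' @return list: `count`, `labels` (integer label matrix), `threshold`.
#' @export
#' @examples
#' imgs <- simulate_growth_images(sample_condition(), day = 0,
#'                                default_generative_params(), n_fields = 1,
#'                                seed = 3, plating_per_field = 20)
#' count_nuclei(imgs[[1]])$count
#' imgs[[1]]$truth_count
count_nuclei <- function(img, smooth_sigma = 2, min_area = 20,
                         threshold_rule = "otsu") {
  px <- as_pixel_matrix(img)
  if (length(px) == 0) stop("empty image")
  if (any(!is.finite(px))) stop("non-finite pixel intensities")
  rng <- range(px)
  if (rng[2] > rng[1]) {
    px <- (px - rng[1]) / (rng[2] - rng[1])
  } else {
    return(list(count = 0L, labels = matrix(0L, nrow(px), ncol(px)),
                threshold = NA_real_))
  }
  im <- EBImage::Image(px)
  sm <- EBImage::gblur(im, sigma = smooth_sigma)
  thr <- if (identical(threshold_rule, "otsu")) {
    EBImage::otsu(sm, range = c(0, 1))
  } else {
    if (!is.numeric(threshold_rule) || !is.finite(threshold_rule))
      stop("'threshold_rule' must be \"otsu\" or a finite number")
    threshold_rule
  }
  mask <- sm > thr
  labels <- EBImage::bwlabel(mask)
  lab <- EBImage::imageData(labels)
  n <- max(lab)
  if (n > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(areas >= min_area)
    lab <- matrix(match(lab, keep, nomatch = 0L), nrow(lab), ncol(lab))
    n <- length(keep)
  }
  list(count = as.integer(n), labels = lab, threshold = thr)
}

#' Growth series from daily image sets
#'
#' Counts nuclei on every field of every day and reports per-day field
#' counts and their mean (the per-condition growth readout; typically
#' five fields per day). Missing days are simply absent from the series,
#' never interpolated.
#'
#' @param images_by_day named list: `images_by_day[["<day>"]]` is a list
#'   of images (any form accepted by [count_nuclei()]).
#' @param ... counting parameters passed to [count_nuclei()].
#' @return a `growth_series` data frame: `day`, `field`, `count`, plus a
#'   `mean_count` attribute-style summary accessible via
#'   [growth_means()].
#' @export
build_growth_series <- function(images_by_day, ...) {
  if (length(images_by_day) < 1) stop("at least one day of images is required")
  days <- as.numeric(names(images_by_day))
  if (any(is.na(days))) stop("'images_by_day' must be named by day")
  rows <- mapply(function(imgs, day) {
    if (length(imgs) < 1) stop("day ", day, " has no fields")
    counts <- vapply(imgs, function(im) count_nuclei(im, ...)$count, integer(1))
    data.frame(day = day, field = seq_along(imgs), count = counts)
  }, images_by_day, days, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$day, out$field), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("growth_series", "data.frame"))
}

#' @rdname build_growth_series
#' @param series a `growth_series`.
#' @return `growth_means()`: data frame of `day` and `mean_count`.
#' @export
growth_means <- function(series) {
  m <- aggregate(count ~ day, data = series, FUN = mean)
  names(m)[2] <- "mean_count"
  m[order(m$day), , drop = FALSE]
}

#' Growth inhibition of a treated series relative to control
#'
#' `1 - treated/control` at the requested day, using the per-day mean
#' counts: 0 for identical growth, 0.5 when the treated cell number is
#' halved, 1 for complete inhibition. Values below 0 (treated exceeding
#' control) are kept as is.
#'
#' @param treated,control `growth_series` objects containing `day`.
#' @param day the day at which to compare.
#' @return inhibition fraction.
#' @export
growth_inhibition <- function(treated, control, day) {
  mt <- growth_means(treated); mc <- growth_means(control)
  if (!(day %in% mt$day) || !(day %in% mc$day))
    stop("day ", day, " missing from one of the series")
  tr <- mt$mean_count[mt$day == day]
  ct <- mc$mean_count[mc$day == day]
  if (ct <= 0) stop("control count is zero at day ", day)
  1 - tr / ct
}

#' Write or read a nuclei image as 16-bit grayscale
#'
#' @param img a `nuclei_image` or matrix with intensities in `[0, 1]`.
#' @param path output path (`.tif` or `.png`).
#' @export
write_nuclei_image <- function(img, path) {
  px <- as_pixel_matrix(img)
  EBImage::writeImage(EBImage::Image(px), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_nuclei_image
#' @export
read_nuclei_image <- function(path) {
  im <- EBImage::readImage(path)
  px <- EBImage::imageData(im)
  if (length(dim(px)) > 2) px <- px[, , 1]
  structure(list(pixels = px, truth_count = NA_integer_,
                 centers = NULL, day = NA, field = NA),
            class = "nuclei_image")
}
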