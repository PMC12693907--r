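# Fruit image color pipeline: gray-world white balance, sRGB -> CIELAB a*
# extraction over a fruit mask, hue-based surface color ratios, five-level
# maturity grading, and LabelMe-style polygon mask rasterization.
#
# Images are numeric height x width x 3 arrays of 8-bit values (0..255),
# channel order R, G, B.

# sRGB (D65/2 deg) colorimetry constants. The RGB->XYZ matrix is the classic
# sRGB matrix; the reference white is its row sums so the gray axis maps to
# a* = 0 exactly.
RGB_XYZ <- matrix(c(0.412453, 0.357580, 0.180423,
                    0.212671, 0.715160, 0.072169,
                    0.019334, 0.119193, 0.950227), 3, 3, byrow = TRUE)
WHITE_XYZ <- rowSums(RGB_XYZ)
CIE_DELTA <- 6 / 29

assert_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("image must be a height x width x 3 array.")
  }
}

#' Gray-world automatic white balance
#'
#' Under the gray-world assumption the scene's average reflectance is
#' achromatic, so each channel is rescaled by `s_c = a_gray / a_c` where
#' `a_c` is the channel mean and `a_gray` the mean of the three channel
#' means. Channel means are exactly equal after scaling; the returned image
#' is clipped to \[0, 255\] and rounded (half-to-even) to stay 8-bit.
#'
#' @param image Height x width x 3 RGB array, values 0..255.
#' @return List with `image` (balanced 8-bit array) and `gains`, a one-row
#'   tibble with the channel means and gains.
#' @export
gray_world_balance <- function(image) {
  assert_rgb_image(image)
  a_r <- mean(image[, , 1]); a_g <- mean(image[, , 2]); a_b <- mean(image[, , 3])
  if (min(a_r, a_g, a_b) == 0) {
    abort("a channel mean is zero; gray-world gains undefined.",
          class = "ripecast_zero_channel")
  }
  a_gray <- (a_r + a_g + a_b) / 3
  s <- a_gray / c(a_r, a_g, a_b)
  out <- image
  for (c in 1:3) out[, , c] <- image[, , c] * s[c]
  out <- round(pmin(pmax(out, 0), 255))
  gains <- tibble::tibble(a_gray = a_gray, a_r = a_r, a_g = a_g, a_b = a_b,
                          s_r = s[1], s_g = s[2], s_b = s[3])
  list(image = out, gains = gains)
}

# Vectorized sRGB inverse companding on values scaled to [0, 1].
srgb_linearize <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

# CIE f(t): cube root above delta^3, linearized branch below.
cie_f <- function(t) {
  ifelse(t > CIE_DELTA^3, t^(1 / 3), t / (3 * CIE_DELTA^2) + 4 / 29)
}

# a* for matrices of 8-bit R, G, B values.
pixel_a_star <- function(r, g, b) {
  rl <- srgb_linearize(r / 255)
  gl <- srgb_linearize(g / 255)
  bl <- srgb_linearize(b / 255)
  x <- RGB_XYZ[1, 1] * rl + RGB_XYZ[1, 2] * gl + RGB_XYZ[1, 3] * bl
  y <- RGB_XYZ[2, 1] * rl + RGB_XYZ[2, 2] * gl + RGB_XYZ[2, 3] * bl
  500 * (cie_f(x / WHITE_XYZ[1]) - cie_f(y / WHITE_XYZ[2]))
}

#' CIELAB a* feature of a masked fruit
#'
#' Converts masked pixels from 8-bit sRGB to CIE XYZ (D65/2 deg) and computes
#' the red-green opponent coordinate `a* = 500 (f(X/Xn) - f(Y/Yn))` per
#' pixel. The fruit-level feature is the arithmetic mean over the mask, and
#' its normalized form is `a_n = (a* + 128) / 255`.
#'
#' @param image Height x width x 3 RGB array, values 0..255.
#' @param mask Logical height x width matrix with at least one `TRUE` pixel.
#' @return One-row tibble with `a_mean` and `a_norm`.
#' @export
rgb_to_a <- function(image, mask) {
  assert_rgb_image(image)
  if (!any(mask)) abort("empty fruit mask.", class = "ripecast_empty_mask")
  a <- pixel_a_star(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  a_mean <- mean(a)
  tibble::tibble(a_mean = a_mean, a_norm = (a_mean + 128) / 255)
}

#' Surface color ratios of a masked fruit
#'
#' Classifies each masked pixel as red, yellow, or green by HSV hue
#' (red: \[0, 25) or \[330, 360) degrees; yellow: \[25, 70); green:
#' \[70, 170)), with low-saturation pixels (`s < sat_min`) and out-of-band
#' hues left unclassified and redistributed proportionally over the three
#' classes. Intended to run on white-balanced images.
#'
#' @inheritParams rgb_to_a
#' @param sat_min Saturation below which a pixel is unclassified (default 0.15).
#' @return One-row tibble with `red`, `yellow`, `green` fractions summing
#'   to 1, plus `n_pixels` and `n_unclassified`.
#' @export
color_ratios <- function(image, mask, sat_min = 0.15) {
  assert_rgb_image(image)
  if (!any(mask)) abort("empty fruit mask.", class = "ripecast_empty_mask")
  hsv <- grDevices::rgb2hsv(rbind(image[, , 1][mask],
                                  image[, , 2][mask],
                                  image[, , 3][mask]), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  cls <- rep("other", length(hue))
  chrom <- sat >= sat_min
  cls[chrom & (hue < 25 | hue >= 330)] <- "red"
  cls[chrom & hue >= 25 & hue < 70] <- "yellow"
  cls[chrom & hue >= 70 & hue < 170] <- "green"
  counts <- c(red = sum(cls == "red"), yellow = sum(cls == "yellow"),
              green = sum(cls == "green"))
  if (sum(counts) == 0) {
    abort("no classifiable (chromatic) pixels inside the mask.",
          class = "ripecast_no_chromatic_pixels")
  }
  frac <- counts / sum(counts) # proportional redistribution of "other"
  tibble::tibble(red = frac[["red"]], yellow = frac[["yellow"]],
                 green = frac[["green"]], n_pixels = length(cls),
                 n_unclassified = sum(cls == "other"))
}

#' Five-level maturity grade from surface color fractions
#'
#' Grades per the red surface coverage bands of the five-level ripeness
#' standard: level 1 green/white-green (`red + yellow < 0.01`); level 2
#' transition (`red < 0.10`); level 3 early (`0.10 <= red < 0.40`); level 4
#' mid (`0.40 <= red < 0.70`); level 5 late (`red >= 0.70`). The published
#' bands leave 30-40% and 60-70% unassigned; contiguous half-open bins make
#' the grading total.
#'
#' @param red,yellow Numeric vectors of surface fractions in \[0, 1\].
#' @return Integer vector of maturity levels 1..5.
#' @export
grade_maturity <- function(red, yellow = 0) {
  stopifnot(length(yellow) %in% c(1L, length(red)))
  level <- ifelse(red + yellow < 0.01, 1L,
           ifelse(red < 0.10, 2L,
           ifelse(red < 0.40, 3L,
           ifelse(red < 0.70, 4L, 5L))))
  as.integer(level)
}

#' Rasterize a LabelMe-style polygon annotation to a fruit mask
#'
#' Reads the `shapes[[i]]$points` polygons of a LabelMe JSON annotation and
#' rasterizes their union over the pixel grid, treating pixel (row, col) as
#' the zero-based point (x = col - 1, y = row - 1) and including boundary
#' pixels.
#'
#' @param annotation Path to the annotation JSON, or a list already parsed
#'   from it.
#' @param height,width Image dimensions in pixels.
#' @param label If not `NULL`, only shapes with this label are used.
#' @return Logical height x width matrix with a `"polygons"` attribute
#'   holding the source vertices.
#' @export
read_polygon_mask <- function(annotation, height, width, label = NULL) {
  ann <- if (is.character(annotation)) {
    jsonlite::read_json(annotation, simplifyVector = FALSE)
  } else annotation
  shapes <- ann$shapes
  if (is.null(shapes) || length(shapes) == 0) {
    abort("annotation contains no shapes.", class = "ripecast_bad_annotation")
  }
  if (!is.null(label)) {
    shapes <- purrr::keep(shapes, ~ identical(.x$label, label))
  }
  mask <- matrix(FALSE, height, width)
  polys <- list()
  for (sh in shapes) {
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3) {
      abort("polygon needs at least 3 vertices.",
            class = "ripecast_bad_annotation")
    }
    if (polygon_area(pts[, 1], pts[, 2]) == 0) {
      abort("zero-area polygon in annotation.",
            class = "ripecast_bad_annotation")
    }
    polys <- c(polys, list(pts))
    mask <- mask | rasterize_polygon(pts, height, width)
  }
  if (!any(mask)) abort("mask is empty.", class = "ripecast_bad_annotation")
  attr(mask, "polygons") <- polys
  mask
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

rasterize_polygon <- function(pts, height, width) {
  xs <- rep(seq_len(width) - 1, each = height)
  ys <- rep(seq_len(height) - 1, times = width)
  inside <- pracma::inpolygon(xs, ys, pts[, 1], pts[, 2], boundary = TRUE)
  matrix(inside, height, width)
}

#' Read / write an 8-bit RGB image
#'
#' PNG always; JPEG reading if the jpeg package is installed.
#'
#' @param path Image path (.png, .jpg/.jpeg).
#' @return Height x width x 3 numeric array of 8-bit values.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      abort("reading JPEG requires the jpeg package.")
    }
    jpeg::readJPEG(path)
  } else {
    abort(sprintf("unsupported image format: %s", ext))
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' @rdname read_rgb_image
#' @param image Height x width x 3 array of 8-bit values.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Measure a batch of fruit images
#'
#' Runs white balance (optional), a* extraction, color ratios and maturity
#' grading for each image/mask pair, returning one observation row per
#' image — the per-image record consumed by the ripening and quality models.
#'
#' @param images List of RGB arrays (or paths).
#' @param masks List of logical masks (or annotation paths; then `heights`
#'   and `widths` are taken from each image).
#' @param ids Optional identifiers (default list index).
#' @param white_balance Apply [gray_world_balance()] first (default TRUE).
#' @return Tibble with columns `id`, `a_mean`, `a_norm`, `red`, `yellow`,
#'   `green`, `maturity_level`.
#' @export
measure_fruit_images <- function(images, masks, ids = NULL,
                                 white_balance = TRUE) {
  ids <- ids %||% seq_along(images)
  purrr::map2_dfr(seq_along(images), ids, function(i, id) {
    img <- images[[i]]
    if (is.character(img)) img <- read_rgb_image(img)
    mask <- masks[[i]]
    if (is.character(mask)) {
      mask <- read_polygon_mask(mask, dim(img)[1], dim(img)[2])
    }
    if (white_balance) img <- gray_world_balance(img)$image
    a <- rgb_to_a(img, mask)
    cr <- color_ratios(img, mask)
    tibble::tibble(id = id, a_mean = a$a_mean, a_norm = a$a_norm,
                   red = cr$red, yellow = cr$yellow, green = cr$green,
                   maturity_level = grade_maturity(cr$red, cr$yellow))
  })
}
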