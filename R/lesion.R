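# coerce EBImage returns back to a plain matrix
as_mask_matrix <- function(x) {
  m <- if (isTRUE(is.matrix(x))) x else EBImage::imageData(x)
  matrix(as.double(m > 0.5), nrow(m), ncol(m))
}

#' Convert an RGB raster to intensity
#'
#' Fundus lesion contrast lives mostly in the green channel, so the default
#' takes it directly; `"luminance"` uses the Rec. 601 weights.
#'
#' @param img `rows x cols x 3` array, or a matrix (returned unchanged).
#' @param method `"green"` or `"luminance"`.
#' @return Intensity matrix in `[0, 1]`.
#' @export
rgb_to_intensity <- function(img, method = c("green", "luminance")) {
  method <- match.arg(method)
  if (length(dim(img)) == 2) return(img)
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop_dim("expected rows x cols x 3 RGB array")
  if (method == "green") img[, , 2]
  else 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Generate a synthetic fundus-like raster with known lesions
#'
#' A smooth background with a gentle radial vignette and Gaussian pixel
#' noise, onto which circular lesions are painted: `"red"` lesions as dark
#' discs (intensity lowered by `contrast`), `"bright"` lesions as light
#' discs (raised by `contrast`). Exact per-kind ground-truth masks are
#' returned. Lesions of different kinds must not overlap.
#'
#' @param lesions `NULL` (background only) or a data frame with columns
#'   `row`, `col`, `radius`, `kind` (`"red"`/`"bright"`) and optionally
#'   `contrast` (default 0.3); each disc must lie within the image.
#' @param width,height Raster size in pixels.
#' @param background Base intensity.
#' @param vignette Radial darkening amplitude (quadratic toward the
#'   corners).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List with `image` (matrix in `[0,1]`), `masks` (logical `red` and
#'   `bright` truth masks) and the lesion table.
#' @export
synth_fundus <- function(lesions = NULL, width = 128, height = 128,
                         background = 0.55, vignette = 0.03,
                         noise_sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  cr <- (height + 1) / 2; cc <- (width + 1) / 2
  d2 <- ((rows - cr)^2 + (cols - cc)^2) / (cr^2 + cc^2)
  img <- background - vignette * d2 +
    matrix(stats::rnorm(height * width, sd = noise_sd), height, width)
  red <- bright <- matrix(FALSE, height, width)
  if (!is.null(lesions) && nrow(lesions) > 0) {
    if (!all(c("row", "col", "radius", "kind") %in% names(lesions)))
      stop_input("lesions needs columns row, col, radius, kind")
    if (is.null(lesions$contrast)) lesions$contrast <- 0.3
    for (i in seq_len(nrow(lesions))) {
      L <- lesions[i, ]
      if (L$row - L$radius < 1 || L$row + L$radius > height ||
          L$col - L$radius < 1 || L$col + L$radius > width)
        stop_input("lesion ", i, " does not fit inside the image")
      disc <- (rows - L$row)^2 + (cols - L$col)^2 <= L$radius^2
      if (L$kind == "red") {
        img[disc] <- img[disc] - L$contrast
        red <- red | disc
      } else if (L$kind == "bright") {
        img[disc] <- img[disc] + L$contrast
        bright <- bright | disc
      } else stop_input("unknown lesion kind: ", L$kind)
    }
    if (any(red & bright))
      stop_input("layout error: red and bright lesions overlap")
  }
  list(image = clamp(img, 0, 1),
       masks = list(red = red, bright = bright),
       lesions = lesions)
}

#' Polarity-aware binarization
#'
#' Thresholds the intensity image: `"dark"` polarity marks pixels strictly
#' below the threshold (candidate red lesions), `"bright"` marks pixels
#' strictly above it. The threshold comes from Otsu's criterion, or from an
#' intensity quantile: for the quantile method `q` is the tail mass on the
#' selected polarity's side (the `q`-quantile for dark, the `(1-q)`-quantile
#' for bright).
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @param polarity `"dark"` or `"bright"`.
#' @param method `"otsu"` or `"quantile"`.
#' @param q Tail mass in (0, 1) for the quantile method.
#' @return Logical mask.
#' @export
binarize_image <- function(image, polarity = c("dark", "bright"),
                           method = c("otsu", "quantile"), q = 0.05) {
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  if (method == "otsu") {
    if (stats::sd(as.vector(image)) < 1e-12)
      stop_input("degenerate threshold: constant image has no Otsu split")
    th <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    if (q <= 0 || q >= 1) stop_config("q must be in (0, 1)")
    th <- unname(stats::quantile(image, if (polarity == "dark") q else 1 - q))
  }
  if (polarity == "dark") image < th else image > th
}

# 8-connected component labeling: EBImage's 4-connected labeling plus a
# union-find merge of labels that touch diagonally
label_components <- function(mask) {
  m <- matrix(as.double(as.logical(mask)), nrow(mask), ncol(mask))
  lab <- as_label_matrix(EBImage::bwlabel(m))
  n <- max(lab)
  if (n == 0) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    r0 <- seq_len(nr - 1)
    c0 <- if (shift[2] == 1) seq_len(nc - 1) else 2:nc
    a <- lab[r0, c0]
    b <- lab[r0 + 1, c0 + shift[2]]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

as_label_matrix <- function(x) {
  m <- if (isTRUE(is.matrix(x))) x else EBImage::imageData(x)
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}

disc_brush <- function(radius) EBImage::makeBrush(2 * radius + 1, "disc")

#' Morphological mask refinement
#'
#' Closing (fills gaps) with a disc of `closing_radius`, then opening
#' (removes specks) with a disc of `opening_radius`, then removal of
#' 8-connected components smaller than `min_size` pixels. A radius of 0
#' skips the corresponding operation.
#'
#' @param mask Logical or 0/1 matrix.
#' @param closing_radius,opening_radius Disc structuring-element radii.
#' @param min_size Minimum surviving component area in pixels.
#' @return Logical mask.
#' @export
refine_mask <- function(mask, closing_radius = 2, opening_radius = 1,
                        min_size = 8) {
  if (closing_radius < 0 || opening_radius < 0)
    stop_config("radii must be >= 0")
  m <- matrix(as.double(as.logical(mask)), nrow(mask), ncol(mask))
  if (closing_radius > 0)
    m <- as_mask_matrix(EBImage::closing(m, disc_brush(closing_radius)))
  if (opening_radius > 0)
    m <- as_mask_matrix(EBImage::opening(m, disc_brush(opening_radius)))
  if (min_size > 1) {
    lab <- label_components(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      keep <- which(sizes >= min_size)
      m <- matrix(as.double(lab %in% keep & lab > 0), nrow(m), ncol(m))
    }
  }
  m > 0
}

#' Dilate a binary mask with a disc structuring element
#'
#' @param mask Logical or 0/1 matrix.
#' @param radius Disc radius (0 returns the mask unchanged).
#' @return Logical mask.
#' @export
dilate_mask <- function(mask, radius = 2) {
  if (radius == 0) return(mask > 0)
  m <- matrix(as.double(as.logical(mask)), nrow(mask), ncol(mask))
  as_mask_matrix(EBImage::dilate(m, disc_brush(radius))) > 0
}

# weighted border-pixel perimeter (straight 1, diagonal sqrt(2), corner
# (1+sqrt(2))/2), the standard 3x3 neighborhood-code estimator
perimeter_length <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- function(dr, dc) pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  interior <- m & core(-1, 0) & core(1, 0) & core(0, -1) & core(0, 1)
  border <- matrix(as.integer(m & !interior), nr, nc)
  bpad <- matrix(0L, nr + 2, nc + 2)
  bpad[2:(nr + 1), 2:(nc + 1)] <- border
  bcore <- function(dr, dc) bpad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  s4 <- bcore(-1, 0) + bcore(1, 0) + bcore(0, -1) + bcore(0, 1)
  sd8 <- bcore(-1, -1) + bcore(-1, 1) + bcore(1, -1) + bcore(1, 1)
  code <- 1L + 2L * s4 + 10L * sd8
  wtab <- numeric(50)
  wtab[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  wtab[c(21, 33) + 1] <- sqrt(2)
  wtab[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  sum(wtab[code[border == 1L] + 1])
}

#' Geometric features of mask components
#'
#' For every 8-connected component: area (pixel count), perimeter (weighted
#' border-pixel counting, diagonals sqrt(2)), border complexity
#' (`perimeter^2 / (4 * pi * area)`; 1 for a disc, larger for irregular
#' outlines), elongation (major/minor axis ratio of the second-moment
#' ellipse, >= 1; a per-pixel variance of 1/12 regularizes degenerate
#' single-pixel regions), centroid, and mean interior intensity when an
#' image is supplied.
#'
#' @param mask Logical or 0/1 matrix.
#' @param image Optional intensity matrix of the same shape.
#' @return Data frame with one row per component (zero rows for an empty
#'   mask).
#' @export
region_features <- function(mask, image = NULL) {
  lab <- label_components(mask)
  n <- max(lab)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), complexity = numeric(0),
                      elongation = numeric(0), mean_intensity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  if (n == 0) return(empty)
  out <- lapply(seq_len(n), function(k) {
    comp <- lab == k
    idx <- which(comp, arr.ind = TRUE)
    area <- nrow(idx)
    per <- perimeter_length(comp)
    cov <- stats::cov(idx) * (area - 1) / max(area, 1)
    if (area == 1) cov <- matrix(0, 2, 2)
    ev <- eigen(cov + diag(1 / 12, 2), symmetric = TRUE,
                only.values = TRUE)$values
    data.frame(label = k, area = area, perimeter = per,
               complexity = per^2 / (4 * pi * area),
               elongation = sqrt(max(ev) / min(ev)),
               mean_intensity = if (is.null(image)) NA_real_
                                else mean(image[comp]),
               centroid_row = mean(idx[, 1]),
               centroid_col = mean(idx[, 2]))
  })
  do.call(rbind, out)
}

#' Rule-based lesion screening
#'
#' The screening chain for one lesion kind: polarity-aware binarization
#' (`"red"` = dark, `"bright"` = light), morphological refinement (closing
#' then opening; sub-threshold components are kept at this stage so they can
#' be reported as rejected calls), geometric feature computation per
#' 8-connected component, and accept/reject filtering. A component is
#' accepted iff its area is at least `min_area`, its elongation at most
#' `max_elongation`, and its border complexity at most `max_complexity`;
#' a rejected call carries the first failed rule (`"too-small"`,
#' `"too-elongated"`, `"too-irregular"`).
#'
#' @param image Intensity matrix in `[0, 1]` (or RGB array; converted via
#'   the green channel).
#' @param kind `"red"` or `"bright"`.
#' @param min_area Minimum accepted area in pixels.
#' @param max_elongation Maximum accepted axis ratio.
#' @param max_complexity Maximum accepted border complexity.
#' @param closing_radius,opening_radius Refinement radii.
#' @param method,q Binarization method and quantile, see
#'   [binarize_image()].
#' @return List with `calls` (data frame: kind, geometry, accepted flag,
#'   rejection reason), `labels` (component label matrix) and
#'   `accepted_mask` (union of accepted components).
#' @export
screen_lesions <- function(image, kind = c("red", "bright"),
                           min_area = 8, max_elongation = 4,
                           max_complexity = 3,
                           closing_radius = 2, opening_radius = 1,
                           method = c("otsu", "quantile"), q = 0.05) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (length(dim(image)) == 3) image <- rgb_to_intensity(image)
  polarity <- if (kind == "red") "dark" else "bright"
  raw <- binarize_image(image, polarity, method, q)
  refined <- refine_mask(raw, closing_radius, opening_radius, min_size = 1)
  lab <- label_components(refined)
  feats <- region_features(refined, image)
  if (nrow(feats) == 0) {
    calls <- cbind(data.frame(kind = character(0)), feats,
                   accepted = logical(0), reason = character(0))
    return(list(calls = calls, labels = lab,
                accepted_mask = matrix(FALSE, nrow(image), ncol(image))))
  }
  reason <- rep("none", nrow(feats))
  reason[feats$complexity > max_complexity] <- "too-irregular"
  reason[feats$elongation > max_elongation] <- "too-elongated"
  reason[feats$area < min_area] <- "too-small"
  accepted <- reason == "none"
  calls <- cbind(data.frame(kind = kind, stringsAsFactors = FALSE),
                 feats, accepted = accepted, reason = reason)
  acc_mask <- matrix(lab %in% feats$label[accepted] & lab > 0,
                     nrow(lab), ncol(lab))
  list(calls = calls, labels = lab, accepted_mask = acc_mask)
}

#' Write screening calls to CSV
#'
#' @param screening Result of [screen_lesions()].
#' @param path CSV path.
#' @export
calls_to_csv <- function(screening, path) {
  utils::write.csv(screening$calls[, c("kind", "centroid_row", "centroid_col",
                                       "area", "elongation", "complexity",
                                       "accepted", "reason")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an image / write a binary mask as PNG
#'
#' Intensities are normalized to `[0, 1]` on load; masks are written as
#' single-channel 0/255 PNG.
#'
#' @param path File path.
#' @return `read_image`: intensity matrix (RGB converted via the green
#'   channel).
#' @export
read_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_config("the png package is required for image IO")
  img <- png::readPNG(path)
  img <- rgb_to_intensity(img)
  rng <- range(img)
  if (rng[2] > 1 || rng[1] < 0) img <- (img - rng[1]) / max(rng[2] - rng[1], 1e-12)
  img
}

#' @rdname read_image
#' @param mask Logical or 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_config("the png package is required for image IO")
  png::writePNG(matrix(as.double(as.logical(mask)), nrow(mask), ncol(mask)),
                path)
  invisible(path)
}
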