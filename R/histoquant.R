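# Histology quantification: steatosis as the area fraction of near-white
# lipid vacuoles on H&E-like sections, fibrosis as the area fraction of
# blue-dominant pixels on trichrome-like sections.

near_white_mask <- function(img, white_min = 0.9, sat_max = 0.08) {
  lo <- pmin(img[, , 1L], img[, , 2L], img[, , 3L])
  hi <- pmax(img[, , 1L], img[, , 2L], img[, , 3L])
  lo > white_min & (hi - lo) < sat_max
}

check_rgb <- function(image) {
  if (inherits(image, "synthetic_slide")) image <- image$image
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] < 3L)
    hep_stop("quantification", "expected an RGB array (height x width x 3)")
  image[, , 1:3, drop = FALSE]
}

#' Detect tissue on a stained slide image
#'
#' Tissue is everything that is not near-white background (high luminance,
#' low saturation), cleaned by a small morphological opening and with
#' interior holes filled — so unstained vacuoles enclosed by tissue count as
#' tissue area.
#'
#' @param image RGB array in `[0,1]` (height x width x 3), or a
#'   `synthetic_slide`.
#' @param white_min Minimum channel value for a background pixel.
#' @param sat_max Maximum channel spread for a background pixel.
#' @return Logical matrix: `TRUE` for tissue pixels.
#' @export
detect_tissue <- function(image, white_min = 0.9, sat_max = 0.08) {
  img <- check_rgb(image)
  fg <- !near_white_mask(img, white_min, sat_max)
  fg <- EBImage::opening(fg, EBImage::makeBrush(3L, shape = "disc")) > 0
  fg <- EBImage::fillHull(fg) > 0
  if (!any(fg))
    hep_stop("quantification", "no tissue detected on the image")
  fg
}

slide_quantification <- function(image_id, tissue_area, vacuole_area = NA,
                                 fibrosis_area = NA, n_vacuoles = NA,
                                 n_nuclei = NA, denominator_area = tissue_area) {
  structure(
    list(image_id = image_id, tissue_area = tissue_area,
         vacuole_area = vacuole_area, fibrosis_area = fibrosis_area,
         relative_steatosis = if (is.na(vacuole_area)) NA_real_
                              else vacuole_area / denominator_area,
         relative_fibrosis = if (is.na(fibrosis_area)) NA_real_
                             else fibrosis_area / denominator_area,
         n_vacuoles = n_vacuoles, n_nuclei = n_nuclei),
    class = "slide_quantification"
  )
}

#' @export
print.slide_quantification <- function(x, ...) {
  cat(sprintf("<slide_quantification> %s: tissue %d px", x$image_id,
              x$tissue_area))
  if (!is.na(x$relative_steatosis))
    cat(sprintf(", steatosis %.3f (%d vacuoles, %s nuclei)",
                x$relative_steatosis, x$n_vacuoles,
                if (is.na(x$n_nuclei)) "?" else x$n_nuclei))
  if (!is.na(x$relative_fibrosis))
    cat(sprintf(", fibrosis %.3f", x$relative_fibrosis))
  cat("\n")
  invisible(x)
}

#' Quantify steatosis on an H&E-like slide image
#'
#' Candidate vacuoles are near-white connected components inside the tissue
#' mask, filtered by equivalent radius (`sqrt(area/pi)` within
#' `[min_radius, max_radius]`) and circularity (`4*pi*A/P^2 >=
#' min_circularity`), which excludes vessels and tears. The steatosis
#' fraction is the retained vacuole area divided by the tissue area (default)
#' or by the whole image area. Hematoxylin-dark nuclei are counted for QC.
#'
#' @param image RGB array or `synthetic_slide`.
#' @param min_radius,max_radius Vacuole equivalent-radius bounds, pixels.
#' @param min_circularity Minimum circularity in `[0,1]`.
#' @param denominator `"tissue"` (default) or `"image"` — the area the
#'   vacuole area is normalized by.
#' @param image_id Identifier recorded in the output.
#' @param white_min,sat_max Background/vacuole color thresholds, see
#'   [detect_tissue()].
#' @return A `slide_quantification`; also carries the detected vacuole mask
#'   as attribute `vacuole_mask`.
#' @export
quantify_steatosis <- function(image, min_radius = 4, max_radius = 40,
                               min_circularity = 0.6,
                               denominator = c("tissue", "image"),
                               image_id = "slide", white_min = 0.9,
                               sat_max = 0.08) {
  denominator <- match.arg(denominator)
  img <- check_rgb(image)
  tissue <- detect_tissue(img, white_min, sat_max)
  cand <- near_white_mask(img, white_min, sat_max) & tissue
  lab <- EBImage::bwlabel(cand)
  vac_mask <- matrix(FALSE, nrow(tissue), ncol(tissue))
  n_keep <- 0L; vac_area <- 0
  if (max(lab) > 0L) {
    ft <- EBImage::computeFeatures.shape(lab)
    area <- ft[, "s.area"]
    perim <- pmax(ft[, "s.perimeter"], 1)
    radius <- sqrt(area / pi)
    circ <- pmin(4 * pi * area / perim^2, 1)
    keep <- which(radius >= min_radius & radius <= max_radius &
                    circ >= min_circularity)
    if (length(keep) > 0L) {
      vac_mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
      vac_area <- sum(area[keep])
      n_keep <- length(keep)
    }
  }
  # QC: count hematoxylin-dark blobs (nuclei)
  lum <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  nuc_lab <- EBImage::bwlabel(lum < 0.6 & tissue)
  n_nuclei <- if (max(nuc_lab) > 0L) {
    nf <- EBImage::computeFeatures.shape(nuc_lab)
    sum(nf[, "s.area"] >= 4)
  } else 0L
  denom <- if (denominator == "tissue") sum(tissue) else length(tissue)
  out <- slide_quantification(image_id, tissue_area = sum(tissue),
                              vacuole_area = vac_area, n_vacuoles = n_keep,
                              n_nuclei = n_nuclei, denominator_area = denom)
  attr(out, "vacuole_mask") <- vac_mask
  out
}

#' Quantify fibrosis on a trichrome-like slide image
#'
#' Fibrosis pixels are tissue pixels whose blue-dominance score — the blue
#' channel minus the larger of red and green — exceeds `blue_threshold`. The
#' fibrosis fraction is their area divided by the tissue area (default) or
#' the whole image area.
#'
#' @param image RGB array or `synthetic_slide`.
#' @param blue_threshold Blue-dominance threshold in `[0,1]`.
#' @param denominator `"tissue"` or `"image"`.
#' @param image_id Identifier recorded in the output.
#' @param white_min,sat_max Background thresholds, see [detect_tissue()].
#' @return A `slide_quantification`; carries the fibrosis mask as attribute
#'   `fibrosis_mask`.
#' @export
quantify_fibrosis <- function(image, blue_threshold = 0.2,
                              denominator = c("tissue", "image"),
                              image_id = "slide", white_min = 0.9,
                              sat_max = 0.08) {
  denominator <- match.arg(denominator)
  img <- check_rgb(image)
  tissue <- detect_tissue(img, white_min, sat_max)
  bluedom <- img[, , 3L] - pmax(img[, , 1L], img[, , 2L])
  fib <- tissue & bluedom > blue_threshold
  denom <- if (denominator == "tissue") sum(tissue) else length(tissue)
  out <- slide_quantification(image_id, tissue_area = sum(tissue),
                              fibrosis_area = sum(fib),
                              denominator_area = denom)
  attr(out, "fibrosis_mask") <- fib
  out
}

#' Read an RGB slide image (PNG or TIFF)
#' @param path Image file path; format picked by extension.
#' @return RGB array (height x width x 3) in `[0,1]`.
#' @export
read_slide_image <- function(path) {
  if (!file.exists(path)) hep_stop("quantification", "image not found: %s", path)
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}
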