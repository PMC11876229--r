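# Study-style image selection and cropping: manifest exclusions,
# Otsu-based breast segmentation, lesion-centered 512x512 crops, and
# seeded normal-tissue crops restricted to the bottom 80% of the breast's
# row extent (which removes the pectoral wedge in MLO views).
#
# Window coordinates reported by these functions are row/column, 0-based,
# half-open: a window (r0, c0) of side s covers rows r0..r0+s-1.

#' Read / write a manifest CSV
#'
#' Manifests are plain data frames with columns patient_id, image_id,
#' view, cancer, finding, density, image_path, mask_path, exclusion_flag,
#' in stable record order, with a free-text `provenance` attribute.
#'
#' @param path CSV path.
#' @return The manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      image_id = "character"))
  m$mask_path[is.na(m$mask_path)] <- ""
  validate_manifest(m)
  attr(m, "provenance") <- path
  m
}

#' @rdname read_manifest
#' @param manifest A manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  need <- c("patient_id", "image_id", "view", "cancer", "finding",
            "density", "image_path", "mask_path", "exclusion_flag")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$image_id))
    stop("image_id values must be unique", call. = FALSE)
  if (any(is.na(manifest$patient_id) | manifest$patient_id == ""))
    stop("every record needs a patient_id", call. = FALSE)
  bad <- setdiff(unique(manifest$exclusion_flag), EXCLUSION_FLAGS)
  if (length(bad))
    stop("unknown exclusion_flag value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  normal <- manifest$finding == "normal"
  if (any(manifest$cancer[normal] != 0))
    stop("normal findings cannot be cancer-positive", call. = FALSE)
  invisible(TRUE)
}

#' Apply the study's exclusion rules to a manifest
#'
#' Keeps exactly the records whose `exclusion_flag` is `"none"`, in the
#' original order, and reports the number removed per flag. Idempotent:
#' re-applying to the kept manifest removes nothing.
#'
#' @param manifest A manifest data frame.
#' @return List with `kept` (filtered manifest) and `report` (named
#'   integer counts per exclusion flag plus `kept`).
#' @export
apply_exclusions <- function(manifest) {
  if (nrow(manifest) == 0L) stop("manifest is empty", call. = FALSE)
  validate_manifest(manifest)
  flags <- factor(manifest$exclusion_flag, levels = EXCLUSION_FLAGS[-1])
  removed <- table(flags)
  kept <- manifest[manifest$exclusion_flag == "none", , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "provenance") <- attr(manifest, "provenance")
  report <- c(as.integer(removed), nrow(kept))
  names(report) <- c(EXCLUSION_FLAGS[-1], "kept")
  list(kept = kept, report = report)
}

#' Segment the breast area of a mammogram
#'
#' Binarizes the image with Otsu's threshold and takes the largest
#' connected foreground component as the breast area; the outline is its
#' boundary contour and `row_extent` the 0-based (top, bottom) rows it
#' spans.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @return An object of class `breast_segmentation`: list with
#'   `breast_mask` (logical matrix), `outline` (n x 2 matrix of 0-based
#'   row/col boundary pixels), and `row_extent`.
#' @export
segment_breast <- function(image) {
  if (diff(range(image)) == 0)
    stop("image is constant; cannot binarize", call. = FALSE)
  im <- EBImage::Image(image)
  thr <- EBImage::otsu(im, range = range(image))
  fg <- image > thr
  if (!any(fg)) stop("empty foreground after thresholding", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  biggest <- which.max(tab)
  mask <- matrix(as.integer(lab) == biggest, nrow(image), ncol(image))
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  # EBImage works x (col) first; convert to 0-based row/col
  outline <- cbind(row = oc[, 2], col = oc[, 1])
  rows <- which(rowSums(mask) > 0)
  structure(list(breast_mask = mask, outline = outline,
                 row_extent = c(top = min(rows) - 1L, bottom = max(rows) - 1L)),
            class = "breast_segmentation")
}

clamp_window <- function(center0, crop, n) {
  # 0-based start of a half-open window of length crop centered at center0
  start <- round(center0 - crop / 2)
  min(max(start, 0L), n - crop)
}

#' Lesion-centered square crop
#'
#' Crops a `crop` x `crop` window centered on the lesion mask's centroid,
#' clamped to the image bounds so the window never leaves the image, and
#' translates the mask into crop coordinates.
#'
#' @param image Numeric matrix, at least `crop` on each side.
#' @param mask Logical/0-1 matrix of the lesion, same size as `image`,
#'   nonempty.
#' @param crop Window side in pixels (default 512).
#' @return List with `image`, `mask` (both `crop` x `crop`) and `window`
#'   (0-based row/col of the window's top-left corner).
#' @export
crop_lesion_centered <- function(image, mask, crop = 512L) {
  mask <- mask != 0
  if (!any(mask)) stop("lesion mask is empty", call. = FALSE)
  if (nrow(image) < crop || ncol(image) < crop)
    stop("image smaller than the crop window", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  centroid0 <- colMeans(idx) - 1  # 0-based
  r0 <- clamp_window(centroid0[1] + 0.5, crop, nrow(image))
  c0 <- clamp_window(centroid0[2] + 0.5, crop, ncol(image))
  list(image = image[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop)],
       mask = mask[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop)],
       window = c(row = as.integer(r0), col = as.integer(c0)))
}

#' Random normal-tissue crop from the lower breast area
#'
#' Draws a seeded `crop` x `crop` window whose center lies inside the
#' breast mask and below the top 20% of the breast's row extent (the rule
#' that excludes the pectoral wedge in MLO views), with the window clamped
#' inside the image.
#'
#' @param image Numeric matrix.
#' @param seg A `breast_segmentation` of `image`.
#' @param crop Window side (default 512).
#' @param seed Integer seed for the uniform draw over admissible centers.
#' @return List with `image`, `window` (0-based top-left) and `center`
#'   (0-based row/col of the drawn center).
#' @export
crop_normal_region <- function(image, seg, crop = 512L, seed = 1L) {
  stopifnot(inherits(seg, "breast_segmentation"))
  H <- nrow(image); W <- ncol(image)
  if (H < crop || W < crop)
    stop("image smaller than the crop window", call. = FALSE)
  top <- seg$row_extent[["top"]]; bottom <- seg$row_extent[["bottom"]]
  row_cut <- top + 0.2 * (bottom - top)
  rr <- matrix(seq_len(H) - 1L, H, W)
  half <- crop / 2
  admissible <- seg$breast_mask & rr >= row_cut &
    rr >= half - 0.5 & rr <= H - half - 0.5 &
    matrix(seq_len(W) - 1L, H, W, byrow = TRUE) >= half - 0.5 &
    matrix(seq_len(W) - 1L, H, W, byrow = TRUE) <= W - half - 0.5
  cand <- which(admissible)
  if (!length(cand))
    stop("no admissible crop center in the lower breast area", call. = FALSE)
  withr::local_seed(seed)
  pos <- cand[sample.int(length(cand), 1L)]
  r <- (pos - 1L) %% H        # 0-based row
  cl <- (pos - 1L) %/% H      # 0-based col
  r0 <- clamp_window(r + 0.5, crop, H)
  c0 <- clamp_window(cl + 0.5, crop, W)
  list(image = image[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop)],
       window = c(row = as.integer(r0), col = as.integer(c0)),
       center = c(row = as.integer(r), col = as.integer(cl)))
}

#' Read a grayscale image file (PNG or TIFF)
#'
#' @param path Image path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_gray <- function(path) {
  x <- if (grepl("\\.tif{1,2}$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}
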