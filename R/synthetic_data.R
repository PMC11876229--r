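# Seeded synthetic mammogram phantoms: crops with a bright breast region
# over a dark background, fibroglandular texture (stronger in dense
# breasts), and lesion classes mass / calcification / distortion with
# ground-truth masks, grouped into synthetic patients with 1-2 images.
# Everything derives deterministically from (config, seed).

FINDINGS <- c("mass", "calcification", "distortion", "normal")
DENSITIES <- c("DB", "Not-DB")
EXCLUSION_FLAGS <- c("none", "phyllodes", "neurofibromatosis", "lymphedema",
                     "venous_port", "foreign_body", "artifact",
                     "lesion_unidentifiable")

#' Reference breakdown of the source mammography study population
#'
#' Per-finding and per-density image counts of the CMMD-based study
#' population that the synthetic generator's default mixture emulates
#' (cropped MLO images after exclusions: 1515 with and 1309 without
#' breast cancer, 2824 in total).
#'
#' @return A list with data frames `findings` (finding, cancer, not_cancer)
#'   and `density` (density, cancer, not_cancer).
#' @export
cmmd_reference_counts <- function() {
  list(
    findings = data.frame(
      finding = FINDINGS,
      cancer = c(954L, 508L, 53L, 0L),
      not_cancer = c(186L, 62L, 7L, 1054L)),
    density = data.frame(
      density = DENSITIES,
      cancer = c(1236L, 279L),
      not_cancer = c(1141L, 168L))
  )
}

#' Per-flag exclusion counts of the source study
#'
#' Radiologist-driven exclusions applied to the 2601 MLO images of the
#' source population, leaving 2436 analyzable images.
#'
#' @return Named integer vector over the seven exclusion flags.
#' @export
cmmd_exclusion_counts <- function() {
  c(phyllodes = 6L, neurofibromatosis = 2L, lymphedema = 1L,
    venous_port = 8L, foreign_body = 5L, artifact = 3L,
    lesion_unidentifiable = 140L)
}

#' Configuration of the synthetic phantom generator
#'
#' Defaults follow the source study's composition: the finding mixture and
#' per-finding cancer rates are the [cmmd_reference_counts()] proportions,
#' the density mixture is the study's dense-breast fraction, lesion-mask
#' area ranges are uniform ranges centered on the study's reported mean
#' area fractions (mass 20.7%, calcification 25.2%, distortion 57.5% of
#' the 512x512 crop), and exclusion-flag rates are the study's per-flag
#' empirical rates. Intensities live in \[0, 1\] (written as 16-bit gray).
#'
#' @param n_patients Number of synthetic patients (each contributes 1-2
#'   images).
#' @param finding_mix Named proportions over mass/calcification/
#'   distortion/normal, summing to 1.
#' @param density_mix Proportion of dense (DB) patients.
#' @param cancer_rate_per_finding Named probability of cancer given each
#'   lesion finding (normal is always 0).
#' @param image_size Crop side in pixels (default 512).
#' @param lesion_area_range Named list of `c(lo, hi)` mask-area fractions
#'   per lesion finding.
#' @param noise_sd Additive Gaussian pixel noise, in \[0, 1\] gray units.
#' @param exclusion_rates Named probabilities for the seven exclusion
#'   flags (their sum must be < 1).
#' @param seed Integer seed; identical config + seed reproduces the
#'   dataset bit for bit.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 50L,
                             finding_mix = c(mass = 1140, calcification = 570,
                                             distortion = 60, normal = 1054) / 2824,
                             density_mix = 2377 / 2824,
                             cancer_rate_per_finding = c(mass = 954 / 1140,
                                                         calcification = 508 / 570,
                                                         distortion = 53 / 60,
                                                         normal = 0),
                             image_size = 512L,
                             lesion_area_range = list(
                               mass = c(0.13, 0.28),
                               calcification = c(0.16, 0.34),
                               distortion = c(0.45, 0.70)),
                             noise_sd = 0.02,
                             exclusion_rates = c(phyllodes = 0, neurofibromatosis = 0,
                                                 lymphedema = 0, venous_port = 0,
                                                 foreign_body = 0, artifact = 0,
                                                 lesion_unidentifiable = 0),
                             seed = 1L) {
  if (abs(sum(finding_mix) - 1) > 1e-9)
    stop("finding_mix must sum to 1", call. = FALSE)
  if (!setequal(names(finding_mix), FINDINGS))
    stop("finding_mix must be named over ", paste(FINDINGS, collapse = "/"),
         call. = FALSE)
  if (density_mix < 0 || density_mix > 1)
    stop("density_mix must be a proportion", call. = FALSE)
  if (any(cancer_rate_per_finding < 0 | cancer_rate_per_finding > 1))
    stop("cancer rates must be probabilities", call. = FALSE)
  if (cancer_rate_per_finding[["normal"]] != 0)
    stop("normal images cannot carry cancer", call. = FALSE)
  if (!setequal(names(exclusion_rates), EXCLUSION_FLAGS[-1]))
    stop("exclusion_rates must cover the seven flags", call. = FALSE)
  if (sum(exclusion_rates) >= 1)
    stop("exclusion rates must sum to < 1", call. = FALSE)
  for (f in c("mass", "calcification", "distortion")) {
    r <- lesion_area_range[[f]]
    if (is.null(r) || length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2])
      stop("lesion_area_range[[", f, "]] must be an increasing pair in (0,1)",
           call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 finding_mix = finding_mix[FINDINGS],
                 density_mix = density_mix,
                 cancer_rate_per_finding = cancer_rate_per_finding[FINDINGS],
                 image_size = as.integer(image_size),
                 lesion_area_range = lesion_area_range,
                 noise_sd = noise_sd,
                 exclusion_rates = exclusion_rates[EXCLUSION_FLAGS[-1]],
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

record_seed <- function(config, index) {
  as.integer((config$seed %% 100000L) * 20011L + index * 7L) %% 2147483647L
}

#' Deterministic per-record metadata for a synthetic dataset
#'
#' Draws, under the config seed, the patient structure (1-2 images each),
#' per-patient density, per-image finding, cancer status and exclusion
#' flag. [generate_record()] and [build_dataset()] both derive from this
#' table, so the manifest and the images always agree.
#'
#' @param config A `synthetic_config`.
#' @return Data frame with one row per image: patient_id, image_id, view,
#'   cancer, finding, density, exclusion_flag.
#' @export
synthetic_manifest_skeleton <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::local_seed(config$seed)
  n_img_per_pat <- sample(1:2, config$n_patients, replace = TRUE)
  patient <- rep(sprintf("P%04d", seq_len(config$n_patients)), n_img_per_pat)
  n <- length(patient)
  dens_pat <- ifelse(stats::runif(config$n_patients) < config$density_mix,
                     "DB", "Not-DB")
  density <- rep(dens_pat, n_img_per_pat)
  finding <- sample(FINDINGS, n, replace = TRUE, prob = config$finding_mix)
  cancer <- as.integer(stats::runif(n) <
                         config$cancer_rate_per_finding[finding])
  u <- stats::runif(n)
  cum <- cumsum(config$exclusion_rates)
  flag_idx <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
  flag <- ifelse(flag_idx > length(cum), "none", names(cum)[pmin(flag_idx, length(cum))])
  data.frame(patient_id = patient,
             image_id = sprintf("I%05d", seq_len(n)),
             view = "MLO",
             cancer = cancer,
             finding = finding,
             density = density,
             exclusion_flag = flag,
             stringsAsFactors = FALSE)
}

# low-frequency Gaussian texture: coarse noise field upsampled bilinearly
smooth_noise <- function(size, scale, sd) {
  k <- max(2L, ceiling(size / scale))
  coarse <- matrix(stats::rnorm(k * k, 0, sd), k, k)
  as.matrix(EBImage::resize(EBImage::Image(coarse), w = size, h = size))
}

# breast region for a crop: large ellipse anchored past the lower-left,
# leaving a dark background corner at the top-right
crop_breast_mask <- function(S) {
  rr <- matrix(seq_len(S), S, S)
  cc <- matrix(seq_len(S), S, S, byrow = TRUE)
  ((rr - 1.05 * S) / (1.45 * S))^2 + ((cc - 0.05 * S) / (1.35 * S))^2 <= 1
}

render_mass <- function(S, frac, cancer, center) {
  rr <- matrix(seq_len(S), S, S) - center[1]
  cc <- matrix(seq_len(S), S, S, byrow = TRUE) - center[2]
  d <- sqrt(rr^2 + cc^2)
  th <- atan2(cc, rr)
  r0 <- sqrt(frac * S^2 / pi)
  ph <- stats::runif(3, 0, 2 * pi)
  wob <- 0.07 * sin(2 * th + ph[1]) + 0.05 * sin(3 * th + ph[2])
  if (cancer) {
    m <- sample(7:12, 1)
    wob <- wob + 0.28 * abs(sin(m / 2 * th + ph[3]))^9  # spicules
  }
  shape <- 1 + wob
  # one rescale pass so the realized mask area hits the drawn fraction
  mask <- d <= r0 * shape
  r0 <- r0 * sqrt(frac * S^2 / max(1, sum(mask)))
  mask <- d <= r0 * shape
  contrast <- if (cancer) 0.30 else 0.20
  bump <- contrast * exp(-(d / (r0 * shape))^2 * 1.8) * (d <= r0 * shape * 1.15)
  if (cancer) {  # thin radiating rays past the boundary
    m <- 9
    ray <- (abs(sin(m / 2 * th + ph[3]))^24) * (d < 1.7 * r0) * 0.12
    bump <- bump + ray
  }
  list(bump = bump, mask = mask)
}

render_calcification <- function(S, frac, cancer, center) {
  rr <- matrix(seq_len(S), S, S) - center[1]
  cc <- matrix(seq_len(S), S, S, byrow = TRUE) - center[2]
  d <- sqrt(rr^2 + cc^2)
  th <- atan2(cc, rr)
  rc <- sqrt(frac * S^2 / pi)
  ph <- stats::runif(2, 0, 2 * pi)
  shape <- 1 + 0.10 * sin(3 * th + ph[1]) + 0.06 * sin(5 * th + ph[2])
  mask <- d <= rc * shape
  rc <- rc * sqrt(frac * S^2 / max(1, sum(mask)))
  mask <- d <= rc * shape
  n_dot <- 10L + stats::rpois(1, 20)
  conc <- if (cancer) 1.8 else 0.9  # cancer: tight central cluster
  rd <- rc * stats::runif(n_dot)^conc
  td <- stats::runif(n_dot, 0, 2 * pi)
  dot_r <- stats::runif(n_dot, 1, 2.5) * S / 512
  bump <- 0.05 * exp(-(d / (rc * shape))^4)  # faint haze marks the extent
  for (i in seq_len(n_dot)) {
    dr <- center[1] + rd[i] * cos(td[i])
    dc <- center[2] + rd[i] * sin(td[i])
    dd2 <- (matrix(seq_len(S), S, S) - dr)^2 +
      (matrix(seq_len(S), S, S, byrow = TRUE) - dc)^2
    amp <- if (cancer) stats::runif(1, 0.35, 0.6) else stats::runif(1, 0.3, 0.4)
    bump <- bump + amp * exp(-dd2 / (2 * max(dot_r[i], 0.8)^2))
  }
  list(bump = bump, mask = mask)
}

# local radial swirl of the already-rendered texture inside a bounding
# box; the mask is the box (the source study uses boxes for distortion)
render_distortion <- function(img, S, frac, cancer, center) {
  side <- round(sqrt(frac) * S)
  r0 <- max(1L, min(S - side + 1L, round(center[1] - side / 2)))
  c0 <- max(1L, min(S - side + 1L, round(center[2] - side / 2)))
  rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
  sub <- img[rows, cols]
  n <- side
  rr <- matrix(seq_len(n), n, n) - (n + 1) / 2
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - (n + 1) / 2
  d <- sqrt(rr^2 + cc^2)
  sigma <- n / 4
  theta_max <- if (cancer) 1.3 else 0.55
  ang <- theta_max * exp(-d^2 / (2 * sigma^2))
  ca <- cos(ang); sa <- sin(ang)
  sr <- rr * ca - cc * sa + (n + 1) / 2
  sc <- rr * sa + cc * ca + (n + 1) / 2
  warped <- bilinear_sample(sub, sr, sc)
  if (cancer) {  # rays converging on the swirl centre
    th <- atan2(cc, rr)
    warped <- warped + 0.10 * (abs(sin(4 * th))^30) * (d < n / 2.2)
  }
  img[rows, cols] <- warped
  mask <- matrix(FALSE, S, S)
  mask[rows, cols] <- TRUE
  list(img = img, mask = mask)
}

# bilinear lookup of matrix m at fractional (row, col) coordinate arrays
bilinear_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0; i10 <- (c0 - 1) * H + r1
  i01 <- (c1 - 1) * H + r0; i11 <- (c1 - 1) * H + r1
  out <- m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
  matrix(out, H, W)
}

#' Generate one synthetic phantom crop with its mask and record
#'
#' Renders the `index`-th image of the dataset implied by `config`:
#' a breast region over dark background with fibroglandular texture
#' (higher mean and variance for dense breasts), plus the record's lesion.
#' Cancer-positive lesions differ systematically from benign ones
#' (spiculated vs smooth mass boundaries, tight irregular vs scattered
#' calcification clusters, strong vs mild architectural swirl), so a
#' classifier can in principle separate them. Deterministic in
#' (config, index).
#'
#' @param config A `synthetic_config`.
#' @param index 1-based image index into [synthetic_manifest_skeleton()].
#' @return List with `image` (matrix in [0,1]), `mask` (logical matrix, or
#'   NULL for normal findings) and `record` (one-row data frame).
#' @export
generate_record <- function(config, index) {
  skel <- synthetic_manifest_skeleton(config)
  if (index < 1L || index > nrow(skel))
    stop("index exceeds the ", nrow(skel), " images implied by config",
         call. = FALSE)
  rec <- skel[index, , drop = FALSE]
  withr::local_seed(record_seed(config, index))
  S <- config$image_size
  breast <- crop_breast_mask(S)
  dense <- rec$density == "DB"
  base_mu <- if (dense) 0.42 else 0.32
  amp <- if (dense) 0.14 else 0.07
  tex <- smooth_noise(S, S / 12, amp) + smooth_noise(S, S / 40, amp / 2)
  img <- 0.04 + matrix(0, S, S)
  img[breast] <- base_mu + tex[breast]
  mask <- NULL
  if (rec$finding != "normal") {
    frac <- stats::runif(1, config$lesion_area_range[[rec$finding]][1],
                         config$lesion_area_range[[rec$finding]][2])
    center <- c(S / 2, S / 2) + stats::runif(2, -0.04 * S, 0.04 * S)
    if (rec$finding == "mass") {
      les <- render_mass(S, frac, rec$cancer == 1L, center)
      img <- img + les$bump
      mask <- les$mask
    } else if (rec$finding == "calcification") {
      les <- render_calcification(S, frac, rec$cancer == 1L, center)
      img <- img + les$bump
      mask <- les$mask
    } else {
      les <- render_distortion(img, S, frac, rec$cancer == 1L, center)
      img <- les$img
      mask <- les$mask
    }
  }
  img <- img + matrix(stats::rnorm(S * S, 0, config$noise_sd), S, S)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, record = rec)
}

#' Generate a full-field synthetic mammogram with breast and pectoral masks
#'
#' A taller-than-wide MLO-style phantom: a breast region anchored to the
#' left edge over a dark background, a bright pectoral-muscle wedge in the
#' top rows of the breast, fibroglandular texture, and optionally a mass
#' lesion. Used to exercise breast segmentation and the normal-region
#' cropping rule.
#'
#' @param height,width Image size in pixels.
#' @param seed Integer seed.
#' @param dense Dense-breast texture?
#' @param wedge_frac Fraction of the breast's row extent covered by the
#'   pectoral wedge (from the top).
#' @param lesion Add a benign mass at a random in-breast location?
#' @return List with `image`, `breast_mask`, `pectoral_mask`, and
#'   `lesion_mask` (NULL unless `lesion`).
#' @export
synthetic_fullfield <- function(height = 1024L, width = 768L, seed = 1L,
                                dense = FALSE, wedge_frac = 0.15,
                                lesion = FALSE) {
  withr::local_seed(seed)
  H <- as.integer(height); W <- as.integer(width)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  breast <- ((rr - 0.45 * H) / (0.42 * H))^2 + (cc / (0.75 * W))^2 <= 1
  top <- min(rr[breast]); bottom <- max(rr[breast])
  wedge_rows <- top + wedge_frac * (bottom - top)
  pect <- breast & (rr <= wedge_rows) & (cc <= (wedge_rows - rr) * 1.2)
  base_mu <- if (dense) 0.42 else 0.32
  amp <- if (dense) 0.14 else 0.07
  tex <- smooth_noise(max(H, W), max(H, W) / 16, amp)[seq_len(H), seq_len(W)]
  img <- matrix(0.04, H, W)
  img[breast] <- base_mu + tex[breast]
  img[pect] <- img[pect] + 0.22
  lesion_mask <- NULL
  if (lesion) {
    cand <- which(breast & rr > wedge_rows + 0.1 * H & cc < 0.55 * W)
    pos <- cand[sample.int(length(cand), 1L)]
    center <- c((pos - 1) %% H + 1, (pos - 1) %/% H + 1)
    les <- render_mass(max(H, W), 0.01, FALSE, center)
    img <- img + les$bump[seq_len(H), seq_len(W)]
    lesion_mask <- les$mask[seq_len(H), seq_len(W)]
  }
  img <- pmin(pmax(img + matrix(stats::rnorm(H * W, 0, 0.015), H, W), 0), 1)
  list(image = img, breast_mask = breast, pectoral_mask = pect,
       lesion_mask = lesion_mask)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates every record implied by the config, writes images as 16-bit
#' grayscale TIFF and lesion masks as 8-bit 0/255 PNG, and writes the
#' manifest CSV (columns patient_id,image_id,view,cancer,finding,density,
#' image_path,mask_path,exclusion_flag).
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
build_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  skel <- synthetic_manifest_skeleton(config)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(msk_dir, showWarnings = FALSE)
  rows <- vector("list", nrow(skel))
  for (i in seq_len(nrow(skel))) {
    g <- generate_record(config, i)
    rec <- g$record
    ipath <- file.path("images", paste0(rec$image_id, ".tiff"))
    tiff::writeTIFF(g$image, file.path(out_dir, ipath), bits.per.sample = 16L)
    mpath <- ""
    if (!is.null(g$mask)) {
      mpath <- file.path("masks", paste0(rec$image_id, "_mask.png"))
      png::writePNG(g$mask * 1.0, file.path(out_dir, mpath))
    }
    rec$image_path <- ipath
    rec$mask_path <- mpath
    rows[[i]] <- rec[, c("patient_id", "image_id", "view", "cancer",
                         "finding", "density", "image_path", "mask_path",
                         "exclusion_flag")]
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "provenance") <- sprintf(
    "synthetic phantoms: %d patients, seed %d", config$n_patients, config$seed)
  invisible(manifest)
}

#' Generate an in-memory synthetic dataset
#'
#' Like [build_dataset()] but keeps images and masks in memory, which is
#' how the training and evaluation examples consume phantoms.
#'
#' @param config A `synthetic_config`.
#' @return List with `manifest` (data frame), `images` (named list of
#'   matrices, keyed by image_id) and `masks` (named list; NULL entries
#'   for normal findings).
#' @export
generate_dataset <- function(config) {
  skel <- synthetic_manifest_skeleton(config)
  images <- vector("list", nrow(skel))
  masks <- vector("list", nrow(skel))
  for (i in seq_len(nrow(skel))) {
    g <- generate_record(config, i)
    images[[i]] <- g$image
    masks[i] <- list(g$mask)  # keeps NULL entries for normal findings
  }
  names(images) <- skel$image_id
  names(masks) <- skel$image_id
  skel$image_path <- ""
  skel$mask_path <- ifelse(skel$finding == "normal", "", "<memory>")
  list(manifest = skel[, c("patient_id", "image_id", "view", "cancer",
                           "finding", "density", "image_path", "mask_path",
                           "exclusion_flag")],
       images = images, masks = masks)
}
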