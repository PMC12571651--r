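# Synthetic dual-view radiograph/report generator.
#
# Emulates the statistical structure the alignment pipeline assumes: each
# record carries a frontal and a lateral HU-valued view sharing one latent
# lesion whose geometry and intensity depend on the class, plus a
# templated report with Findings/Diagnosis sections naming the class.
# Lesions are Gaussian-profile ellipses on an air-like background with a
# soft-tissue thorax disc, so the standard chest window (1500/-500 HU)
# renders both anatomy and lesion contrast meaningfully.

# class table: keyword + lesion intensity/geometry per class
synthetic_classes <- function(n_classes = 8L) {
  base <- data.frame(
    keyword = c("pneumonia", "pneumothorax", "pleural effusion", "edema",
                "cardiomegaly", "atelectasis", "consolidation", "nodule"),
    peak_hu = c(150, -350, 250, 50, 350, 200, 300, 450),
    radius_frac = c(0.14, 0.20, 0.16, 0.22, 0.18, 0.10, 0.12, 0.06),
    eccentricity = c(1.4, 1.1, 1.8, 1.2, 1.3, 2.0, 1.5, 1.0),
    stringsAsFactors = FALSE)
  if (n_classes > nrow(base))
    stop("at most ", nrow(base), " synthetic classes are defined",
         call. = FALSE)
  base[seq_len(n_classes), ]
}

report_templates <- function() {
  c(paste("HISTORY: %s-year-old patient with cough and dyspnea.",
          "FINDINGS: %s seen in the %s lung field%s.",
          "IMPRESSION: findings consistent with %s."),
    paste("INDICATION: follow-up imaging requested.",
          "FINDINGS: there is %s involving the %s hemithorax%s.",
          "DIAGNOSIS: %s."),
    paste("FINDINGS: the %s zone demonstrates %s%s; heart size is normal.",
          "IMPRESSION: appearance most compatible with %s.",
          "RECOMMENDATION: clinical correlation advised."))
}

#' Synthetic dataset specification
#'
#' Defaults emulate the shape of a class-balanced retrieval pool:
#' 8 classes (the full-scale protocol uses 200 records per class; the
#' desk-scale test default is 8 per class), 224 x 224 pixel views on an
#' air-like background around -1000 HU with class-dependent lesion
#' intensities, all values inside `[-1024, 1000]` so the default chest
#' window captures the lesion band.
#'
#' @param n_classes number of classes (<= 8).
#' @param n_per_class records per class.
#' @param image_side image side in pixels.
#' @param hu_background mean background intensity (HU).
#' @param noise_sd pixel noise standard deviation (HU); 0 gives
#'   noise-free deterministic geometry.
#' @param lesion_contrast multiplier on class lesion amplitudes.
#' @param seed base seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 8L, n_per_class = 8L,
                           image_side = 224L, hu_background = -1000,
                           noise_sd = 20, lesion_contrast = 1,
                           seed = 1L) {
  stopifnot(n_classes >= 1L, n_per_class >= 1L, image_side >= 32L,
            noise_sd >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 image_side = as.integer(image_side),
                 hu_background = hu_background, noise_sd = noise_sd,
                 lesion_contrast = lesion_contrast,
                 classes = synthetic_classes(n_classes),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# gaussian-profile rotated ellipse on a grid, peak amplitude `amp`
lesion_profile <- function(side, cx, cy, sx, sy, theta, amp) {
  x <- matrix(seq_len(side), side, side, byrow = TRUE)
  y <- matrix(seq_len(side), side, side)
  xr <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
  yr <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
  amp * exp(-0.5 * ((xr / sx)^2 + (yr / sy)^2))
}

# deterministic frontal -> lateral reprojection of the lesion centre:
# the vertical coordinate is shared between views, the horizontal one is
# compressed toward the mid-depth line
lateral_reprojection <- function(cx, side) side / 2 + (cx - side / 2) * 0.55

#' Generate one synthetic dual-view record
#'
#' Draws class-conditioned lesion geometry (position, size, orientation,
#' amplitude), renders the frontal view, derives the lateral view by a
#' deterministic reprojection of the lesion (shared vertical coordinate,
#' depth-compressed horizontal coordinate) plus independent noise, and
#' fills a report template naming the class keyword. Deterministic per
#' `(class_id, seed)`.
#'
#' @param class_id class index in `1..spec$n_classes`.
#' @param spec a [synthetic_spec()].
#' @param seed record seed.
#' @return Object of class `view_pair`: `frontal` and `lateral`
#'   [radiograph()]s (HU units), `report`, `record_id`, `class_id`, and
#'   the latent `lesion` parameters.
#' @export
generate_record <- function(class_id, spec, seed) {
  if (class_id < 1L || class_id > spec$n_classes)
    stop("class_id must lie in 1..", spec$n_classes, call. = FALSE)
  cls <- spec$classes[class_id, ]
  S <- spec$image_side
  with_seed(mix_seed(spec$seed, seed, class_id), {
    # class-anchored lesion position: classes sit at distinct clock angles
    ang <- 2 * pi * (class_id - 1) / max(spec$n_classes, 2L) +
      runif(1, -0.25, 0.25)
    rad <- S * runif(1, 0.18, 0.28)
    cx <- S / 2 + rad * cos(ang)
    cy <- S / 2 + rad * sin(ang)
    sx <- S * cls$radius_frac * runif(1, 0.8, 1.2)
    sy <- sx * cls$eccentricity
    theta <- runif(1, 0, pi)
    amp <- spec$lesion_contrast * (cls$peak_hu - spec$hu_background) *
      runif(1, 0.85, 1.15)
    thorax <- lesion_profile(S, S / 2, S / 2, S * 0.32, S * 0.40, 0, 420)
    frontal <- spec$hu_background + thorax +
      lesion_profile(S, cx, cy, sx, sy, theta, amp)
    if (spec$noise_sd > 0)
      frontal <- frontal + matrix(rnorm(S * S, sd = spec$noise_sd), S, S)
    cxl <- lateral_reprojection(cx, S)
    lateral <- spec$hu_background +
      lesion_profile(S, S / 2, S / 2, S * 0.22, S * 0.40, 0, 420) +
      lesion_profile(S, cxl, cy, sx * 0.7, sy, theta, amp)
    if (spec$noise_sd > 0)
      lateral <- lateral + matrix(rnorm(S * S, sd = spec$noise_sd), S, S)
    clip <- function(M) pmin(pmax(M, -1024), 1000)
    side_word <- if (cx < S / 2) "left" else "right"
    tmpl <- sample(report_templates(), 1L)
    sev <- sample(c("", ", partially obscuring the costophrenic angle",
                    ", with adjacent volume loss"), 1L)
    report <- switch(match(tmpl, report_templates()),
      sprintf(tmpl, sample(35:85, 1L), cls$keyword, side_word, sev,
              cls$keyword),
      sprintf(tmpl, cls$keyword, side_word, sev, cls$keyword),
      sprintf(tmpl, side_word, cls$keyword, sev, cls$keyword))
    structure(list(
      frontal = radiograph(clip(frontal), "frontal", "HU"),
      lateral = radiograph(clip(lateral), "lateral", "HU"),
      report = report,
      record_id = sprintf("c%02d_s%09d", class_id, as.integer(seed)),
      class_id = as.integer(class_id),
      lesion = list(cx = cx, cy = cy, cx_lateral = cxl, sx = sx, sy = sy,
                    theta = theta, amp = amp)),
      class = "view_pair")
  })
}

#' Generate a class-balanced synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return List with `records` (length `n_classes * n_per_class`, grouped
#'   by class) and `manifest` data.frame (`record_id`, `class_id`,
#'   `report`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  records <- list()
  for (cl in seq_len(spec$n_classes))
    for (i in seq_len(spec$n_per_class))
      records[[length(records) + 1L]] <-
        generate_record(cl, spec, seed = mix_seed(spec$seed, "rec", cl, i))
  manifest <- data.frame(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    class_id = vapply(records, function(r) r$class_id, integer(1)),
    report = vapply(records, function(r) r$report, character(1)),
    stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}

#' Write a dataset manifest as JSON lines
#'
#' @param manifest manifest data.frame from [generate_dataset()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_manifest_jsonl <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(manifest)))
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
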