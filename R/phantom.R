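# Seeded synthetic MRI-like phantoms. Each image is an elliptical skull/brain
# mask with a bright rim, smooth low-frequency intensity texture and Gaussian
# noise; tumor classes add a superellipse lesion whose location prior, size
# range, contrast and edge sharpness are class-specific. Geometry is defined
# in coordinates relative to the image side, so any output resolution yields
# the same class structure. Intensities are emitted in [0, 255].

phantom_class_defs <- function(n_classes) {
  defs <- list(
    list(name = "no_lesion", lesion = FALSE),
    # anterior-left, small, high contrast, sharp edge
    list(name = "lesion_anterior", lesion = TRUE, cx = 0.35, cy = 0.35,
         jitter = 0.05, r_lo = 0.06, r_hi = 0.10, contrast = 0.35, soft = 0.15),
    # deep/central, large, moderate contrast, soft edge
    list(name = "lesion_central", lesion = TRUE, cx = 0.50, cy = 0.50,
         jitter = 0.04, r_lo = 0.10, r_hi = 0.16, contrast = 0.20, soft = 0.6),
    # posterior-right, small, very bright, sharp edge
    list(name = "lesion_posterior", lesion = TRUE, cx = 0.63, cy = 0.63,
         jitter = 0.05, r_lo = 0.05, r_hi = 0.08, contrast = 0.45, soft = 0.1))
  defs[seq_len(n_classes)]
}

#' Phantom generator configuration
#'
#' @param n_per_class images per class.
#' @param n_classes 2, 3 or 4 classes (class 0 is always lesion-free).
#' @param image_size square output resolution in pixels (default 224).
#' @param noise_sd additive Gaussian noise standard deviation on the `[0, 1]`
#'   intensity scale (default 0.03).
#' @param seed integer seed; the image stack is bitwise reproducible.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_per_class = 50L, n_classes = 4L, image_size = 224L,
                           noise_sd = 0.03, seed = 1L) {
  stopifnot(n_per_class >= 1, n_classes %in% 2:4, image_size >= 16,
            noise_sd >= 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

render_phantom <- function(s, def, noise_sd) {
  u <- (seq_len(s) - 0.5) / s
  gx <- matrix(u, s, s)                         # column coordinate
  gy <- matrix(u, s, s, byrow = TRUE)
  # brain ellipse with per-image jitter
  ax <- 0.38 + stats::runif(1, -0.02, 0.02)
  ay <- 0.45 + stats::runif(1, -0.02, 0.02)
  d2 <- ((gx - 0.5) / ax)^2 + ((gy - 0.5) / ay)^2
  brain <- d2 <= 1
  img <- matrix(0.02, s, s)
  # smooth texture: a few random low-frequency sinusoids
  tex <- matrix(0, s, s)
  for (i in 1:3) {
    fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi)
    tex <- tex + sin(2 * pi * fx * gx + ph[1]) * sin(2 * pi * fy * gy + ph[2])
  }
  img[brain] <- 0.45 + 0.05 * tex[brain]
  # skull rim
  rim <- d2 > 1 & d2 <= 1.18
  img[rim] <- 0.8
  if (isTRUE(def$lesion)) {
    cx <- def$cx + stats::runif(1, -def$jitter, def$jitter)
    cy <- def$cy + stats::runif(1, -def$jitter, def$jitter)
    r <- stats::runif(1, def$r_lo, def$r_hi)
    q <- stats::runif(1, 1.5, 3)                # superellipse exponent
    ecc <- stats::runif(1, 0.7, 1.3)            # eccentricity
    dist_le <- (abs((gx - cx) / (r * ecc)))^q + (abs((gy - cy) / r))^q
    # soft in [0,1]: 0 = hard edge, larger = smoother falloff
    blob <- 1 / (1 + exp((dist_le - 1) / max(def$soft, 0.02) * 8))
    img <- img + def$contrast * blob * brain
  }
  img <- img + stats::rnorm(s * s, sd = noise_sd)
  pmin(pmax(img, 0), 1) * 255
}

#' Generate a seeded synthetic phantom dataset
#'
#' @param cfg a [phantom_config].
#' @param out_dir optional directory; when given, images are also written as a
#'   `class_name/<id>.png` folder tree consumable by [load_folder_dataset()].
#' @return a `dataset_index` with in-memory images, balanced at
#'   `n_per_class` per class.
#' @export
generate_phantoms <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  defs <- phantom_class_defs(cfg$n_classes)
  records <- vector("list", cfg$n_classes * cfg$n_per_class)
  with_seed(cfg$seed, {
    i <- 0L
    for (k in seq_len(cfg$n_classes)) {
      for (j in seq_len(cfg$n_per_class)) {
        i <- i + 1L
        records[[i]] <- list(image = render_phantom(cfg$image_size, defs[[k]],
                                                    cfg$noise_sd),
                             label = k - 1L)
      }
    }
  })
  idx <- structure(list(records = records,
                        class_names = vapply(defs, `[[`, character(1), "name")),
                   class = "dataset_index")
  if (!is.null(out_dir)) write_dataset_tree(idx, out_dir)
  idx
}

#' Write a dataset as a class-per-subfolder PNG tree
#'
#' @param dataset a `dataset_index` with in-memory images.
#' @param out_dir output root directory.
#' @return `out_dir`, invisibly.
#' @export
write_dataset_tree <- function(dataset, out_dir) {
  counts <- integer(length(dataset$class_names))
  for (rec in dataset$records) {
    cls <- dataset$class_names[rec$label + 1L]
    dir.create(file.path(out_dir, cls), recursive = TRUE, showWarnings = FALSE)
    counts[rec$label + 1L] <- counts[rec$label + 1L] + 1L
    png::writePNG(rec$image / 255,
                  file.path(out_dir, cls, sprintf("%04d.png", counts[rec$label + 1L])))
  }
  invisible(out_dir)
}
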