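#' Configuration for a synthetic paired-phantom subject
#'
#' Describes one simulated PET acquisition: grid geometry matching a clinical
#' whole-body PET reconstruction (4.07 x 4.07 x 2 mm voxels by default), a
#' uniform soft-tissue background, ellipsoidal lesions with heterogeneous
#' uptake, an isotropic Gaussian point-spread function applied
#' post-reconstruction, and additive noise.
#'
#' Lesion heterogeneity is a log-normal texture: a Gaussian random field with
#' Gaussian-kernel correlation of length `texture_correlation_length_mm`,
#' scaled to log-scale standard deviation `texture_log_sd` and exponentiated,
#' so uptake stays positive. A correlation length of 0 disables texture
#' (uniform lesions).
#'
#' @param grid_shape integer triple, voxel counts per axis.
#' @param spacing_mm voxel spacing in mm.
#' @param background_suv uniform background SUV, >= 0.
#' @param n_lesions number of lesions to place.
#' @param lesion_radius_range_mm range the three ellipsoid semi-axes are
#'   drawn from (uniformly, independently), mm. The lower end must give a
#'   sphere of at least `min_lesion_volume_cm3` unless `allow_small = TRUE`.
#' @param lesion_mean_suv_range range of lesion mean SUV (uniform); keep the
#'   lower end above the segmentation threshold (SUV 3) so lesions are
#'   recoverable by thresholding.
#' @param texture_correlation_length_mm correlation length of the intra-lesion
#'   texture field, mm; 0 disables texture.
#' @param texture_log_sd log-scale standard deviation of the texture field.
#' @param psf_fwhm_mm full width at half maximum of the isotropic Gaussian
#'   point-spread function, mm (0 disables blurring).
#' @param noise_sd_suv standard deviation of additive Gaussian background
#'   noise, SUV; the final image is clamped at 0.
#' @param min_lesion_volume_cm3 includability threshold used for validation.
#' @param allow_small allow lesion radii below the includability threshold.
#' @param seed integer RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 48),
                           spacing_mm = c(4.07, 4.07, 2.0),
                           background_suv = 1.0,
                           n_lesions = 3,
                           lesion_radius_range_mm = c(8, 16),
                           lesion_mean_suv_range = c(5, 12),
                           texture_correlation_length_mm = 8,
                           texture_log_sd = 0.3,
                           psf_fwhm_mm = 6,
                           noise_sd_suv = 0.1,
                           min_lesion_volume_cm3 = 1.5,
                           allow_small = FALSE,
                           seed = 1L) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    background_suv = background_suv, n_lesions = as.integer(n_lesions),
    lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
    lesion_mean_suv_range = as.numeric(lesion_mean_suv_range),
    texture_correlation_length_mm = texture_correlation_length_mm,
    texture_log_sd = texture_log_sd, psf_fwhm_mm = psf_fwhm_mm,
    noise_sd_suv = noise_sd_suv, min_lesion_volume_cm3 = min_lesion_volume_cm3,
    allow_small = isTRUE(allow_small), seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(
    length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 4L),
    length(cfg$spacing_mm) == 3L, all(cfg$spacing_mm > 0),
    cfg$background_suv >= 0, cfg$n_lesions >= 0L,
    length(cfg$lesion_radius_range_mm) == 2L,
    cfg$lesion_radius_range_mm[1] <= cfg$lesion_radius_range_mm[2],
    cfg$lesion_radius_range_mm[1] > 0,
    length(cfg$lesion_mean_suv_range) == 2L,
    cfg$lesion_mean_suv_range[1] <= cfg$lesion_mean_suv_range[2],
    cfg$texture_correlation_length_mm >= 0, cfg$texture_log_sd >= 0,
    cfg$psf_fwhm_mm >= 0, cfg$noise_sd_suv >= 0
  )
  min_vol_mm3 <- 4 / 3 * pi * cfg$lesion_radius_range_mm[1]^3
  if (!cfg$allow_small && cfg$n_lesions > 0 &&
      min_vol_mm3 < cfg$min_lesion_volume_cm3 * 1000) {
    stop(sprintf(
      paste0("smallest possible lesion (%.2f cm^3) is below the ",
             "includability threshold %.2f cm^3; enlarge ",
             "`lesion_radius_range_mm` or set `allow_small = TRUE`"),
      min_vol_mm3 / 1000, cfg$min_lesion_volume_cm3
    ), call. = FALSE)
  }
  invisible(cfg)
}

#' Configuration for the retest acquisition
#'
#' The retest scan repeats the test scan with a known within-subject
#' variability: each lesion's uptake is scaled by an independent log-normal
#' factor with unit mean whose coefficient of variation is
#' `sqrt(2) * wcv_true_pct / 100`, so paired relative differences have
#' theoretical within-subject CV equal to `wcv_true_pct`. A systematic
#' multiplicative shift `bias_pct` emulates a tracer change between scans.
#'
#' @param wcv_true_pct injected within-subject coefficient of variation, %.
#' @param bias_pct systematic multiplicative uptake shift, % (0 = none).
#' @param redraw_noise if `TRUE`, background noise is re-sampled for the
#'   retest; if `FALSE` the identical noise realisation is reused.
#' @param seed integer RNG seed for the lesion factors (and fresh noise).
#' @return A `retest_config` list.
#' @export
retest_config <- function(wcv_true_pct = 10, bias_pct = 0,
                          redraw_noise = TRUE, seed = 2L) {
  stopifnot(wcv_true_pct >= 0, is.finite(bias_pct), bias_pct > -100)
  structure(
    list(
      wcv_true_pct = wcv_true_pct, bias_pct = bias_pct,
      redraw_noise = isTRUE(redraw_noise), seed = as.integer(seed)
    ),
    class = "retest_config"
  )
}

# Correlated log-normal texture field with unit mean, on an arbitrary grid.
texture_field <- function(dims, spacing_mm, corr_length_mm, log_sd, seed) {
  if (corr_length_mm <= 0 || log_sd <= 0) {
    return(array(1, dim = dims))
  }
  set.seed(seed)
  g <- array(stats::rnorm(prod(dims)), dim = dims)
  g <- gaussian_smooth(g, corr_length_mm / spacing_mm)
  g <- (g - mean(g)) / max(stats::sd(g), 1e-12)
  exp(log_sd * g - log_sd^2 / 2)
}

# Voxel-centre coordinates (mm) along each axis.
axis_centres <- function(n, spacing) (seq_len(n) - 0.5) * spacing

ellipsoid_support <- function(dims, spacing_mm, centre_mm, semi_axes_mm) {
  x <- axis_centres(dims[1], spacing_mm[1])
  y <- axis_centres(dims[2], spacing_mm[2])
  z <- axis_centres(dims[3], spacing_mm[3])
  dx2 <- ((x - centre_mm[1]) / semi_axes_mm[1])^2
  dy2 <- ((y - centre_mm[2]) / semi_axes_mm[2])^2
  dz2 <- ((z - centre_mm[3]) / semi_axes_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Deterministic rendering of one subject image from stored lesion parameters.
# `factors` scales each lesion's uptake (1 for the test scan).
render_phantom <- function(cfg, lesions, factors, noise_seed) {
  dims <- cfg$grid_shape
  img <- array(cfg$background_suv, dim = dims)
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    tex <- texture_field(
      dims = vapply(les$box, length, integer(1)),
      spacing_mm = cfg$spacing_mm,
      corr_length_mm = cfg$texture_correlation_length_mm,
      log_sd = cfg$texture_log_sd, seed = les$texture_seed
    )
    sub_sup <- crop_to_box(les$support, les$box)
    sub <- crop_to_box(img, les$box)
    sub[sub_sup] <- factors[i] * les$mean_suv * tex[sub_sup]
    img[les$box[[1]], les$box[[2]], les$box[[3]]] <- sub
  }
  if (cfg$psf_fwhm_mm > 0) {
    sigma_vox <- (cfg$psf_fwhm_mm / (2 * sqrt(2 * log(2)))) / cfg$spacing_mm
    img <- gaussian_smooth(img, sigma_vox)
  }
  if (cfg$noise_sd_suv > 0) {
    set.seed(noise_seed)
    img <- img + array(stats::rnorm(prod(dims), sd = cfg$noise_sd_suv), dim = dims)
  }
  img[img < 0] <- 0
  image_volume(img, cfg$spacing_mm)
}

#' Generate one synthetic test-scan subject
#'
#' Places non-overlapping ellipsoidal lesions by rejection sampling (at most
#' 1000 attempts per lesion), fills each with mean uptake times a positive
#' spatially correlated texture field, embeds them in a uniform background,
#' applies the Gaussian point-spread function, and adds noise. Masks are the
#' pre-blur ellipsoid supports. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return List with `image` (`image_volume`), `masks` (list of
#'   `lesion_mask`), and `truth` (`phantom_truth`: per-lesion analytic
#'   volume (mL), realised pre-blur mean uptake, centroid, plus the hidden
#'   state needed to re-render the subject for a retest scan).
#' @export
generate_subject <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  dims <- cfg$grid_shape
  extent <- dims * cfg$spacing_mm
  set.seed(cfg$seed)
  lesions <- list()
  centres <- matrix(numeric(0), ncol = 3)
  max_radii <- numeric(0)
  for (i in seq_len(cfg$n_lesions)) {
    semi <- stats::runif(3, cfg$lesion_radius_range_mm[1],
                         cfg$lesion_radius_range_mm[2])
    mean_suv <- stats::runif(1, cfg$lesion_mean_suv_range[1],
                             cfg$lesion_mean_suv_range[2])
    rmax <- max(semi)
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      ctr <- stats::runif(3, rmax + cfg$spacing_mm, extent - rmax - cfg$spacing_mm)
      if (nrow(centres) == 0L ||
          all(sqrt(rowSums(sweep(centres, 2, ctr)^2)) >
              max_radii + rmax + max(cfg$spacing_mm))) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "could not place lesion %d without overlap after 1000 attempts; reduce n_lesions or lesion radii", i
      ), call. = FALSE)
    }
    sup <- ellipsoid_support(dims, cfg$spacing_mm, ctr, semi)
    if (!any(sup)) {
      stop("lesion support is empty; radii are too small for the grid", call. = FALSE)
    }
    lesions[[i]] <- list(
      lesion_id = sprintf("lesion_%02d", i), centre_mm = ctr,
      semi_axes_mm = semi, mean_suv = mean_suv, support = sup,
      box = bounding_box(sup, pad = 0L),
      texture_seed = sample.int(.Machine$integer.max - 1L, 1)
    )
    centres <- rbind(centres, ctr)
    max_radii <- c(max_radii, rmax)
  }
  noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
  image <- render_phantom(cfg, lesions, factors = rep(1, length(lesions)),
                          noise_seed = noise_seed)
  masks <- lapply(lesions, function(l) {
    lesion_mask(l$support, cfg$spacing_mm, lesion_id = l$lesion_id)
  })
  # realised pre-blur mean uptake within each mask
  mean_uptake <- vapply(lesions, function(l) {
    tex <- texture_field(vapply(l$box, length, integer(1)), cfg$spacing_mm,
                         cfg$texture_correlation_length_mm, cfg$texture_log_sd,
                         l$texture_seed)
    mean(l$mean_suv * tex[crop_to_box(l$support, l$box)])
  }, numeric(1))
  tab <- data.frame(
    lesion_id = vapply(lesions, `[[`, character(1), "lesion_id"),
    volume_ml = vapply(lesions, function(l) {
      4 / 3 * pi * prod(l$semi_axes_mm) / 1000
    }, numeric(1)),
    mean_uptake = mean_uptake,
    centroid_x_mm = vapply(lesions, function(l) l$centre_mm[1], numeric(1)),
    centroid_y_mm = vapply(lesions, function(l) l$centre_mm[2], numeric(1)),
    centroid_z_mm = vapply(lesions, function(l) l$centre_mm[3], numeric(1)),
    stringsAsFactors = FALSE
  )
  truth <- structure(
    list(
      lesions = tab, wcv_true_pct = 0, bias_pct = 0, config = cfg,
      render_state = list(lesions = lesions, noise_seed = noise_seed)
    ),
    class = "phantom_truth"
  )
  list(image = image, masks = masks, truth = truth)
}

#' Generate the paired retest scan for a phantom subject
#'
#' Re-renders the subject with each lesion's uptake multiplied by
#' `(1 + bias_pct/100)` times a unit-mean log-normal factor whose coefficient
#' of variation is `sqrt(2) * wcv_true_pct / 100` (so the theoretical
#' within-subject CV of paired relative differences equals `wcv_true_pct`).
#' Lesion geometry and texture are identical to the test scan; background
#' noise is re-sampled or reused per `rcfg$redraw_noise`. Deterministic for
#' fixed seeds.
#'
#' @param image the test `image_volume` (used for validation only).
#' @param masks lesion masks from [generate_subject()].
#' @param truth `phantom_truth` from [generate_subject()].
#' @param rcfg a [retest_config()].
#' @return The retest `image_volume`, with the drawn per-lesion factors
#'   attached as attribute `"lesion_factors"`.
#' @export
generate_retest <- function(image, masks, truth, rcfg) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(rcfg, "retest_config"))
  cfg <- truth$config
  if (!identical(dim(image$values), cfg$grid_shape)) {
    stop("test image does not match the phantom configuration grid", call. = FALSE)
  }
  lesions <- truth$render_state$lesions
  n <- length(lesions)
  set.seed(rcfg$seed)
  if (rcfg$wcv_true_pct > 0 && n > 0) {
    cv <- sqrt(2) * rcfg$wcv_true_pct / 100
    s2 <- log(1 + cv^2)
    factors <- stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else {
    factors <- rep(1, n)
  }
  fresh_noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
  factors <- factors * (1 + rcfg$bias_pct / 100)
  noise_seed <- if (rcfg$redraw_noise) fresh_noise_seed else truth$render_state$noise_seed
  out <- render_phantom(cfg, lesions, factors = factors, noise_seed = noise_seed)
  attr(out, "lesion_factors") <- factors
  out
}

#' Write a paired test-retest phantom cohort to disk
#'
#' Generates `n_subjects` independent subjects plus their retest scans and
#' writes a dataset directory consumable by [run_pipeline()]:
#' `sub-XX/image_test.nii.gz`, `sub-XX/image_retest.nii.gz`,
#' `sub-XX/lesion_XX.nii.gz`, a `pairing.csv` table
#' (subject_id, lesion_id, test_path, retest_path, mask_path), the ground
#' truth as `truth.json` and the configuration as `config.yaml`.
#'
#' @param out_dir output directory; must not exist unless `force = TRUE`.
#' @param n_subjects number of subjects, >= 1.
#' @param group_label one of `"intratracer_A"`, `"intratracer_B"`,
#'   `"intertracer"`. When `rcfg` is not supplied, the intertracer group
#'   defaults to a systematic +10% uptake shift; intratracer groups to none.
#' @param cfg a [phantom_config()]; per-subject seeds are derived from
#'   `cfg$seed`.
#' @param rcfg a [retest_config()], or `NULL` for group defaults.
#' @param n_lesions_range optional integer pair; when given, each subject's
#'   lesion count is drawn uniformly from this range (overriding
#'   `cfg$n_lesions`).
#' @param force overwrite an existing directory.
#' @param compress write `.nii.gz` (default) or plain `.nii`.
#' @return Invisibly, a list with the pairing data frame and truth list.
#' @export
generate_cohort <- function(out_dir, n_subjects, group_label = "intratracer_A",
                            cfg = phantom_config(), rcfg = NULL,
                            n_lesions_range = NULL, force = FALSE,
                            compress = TRUE) {
  stopifnot(n_subjects >= 1)
  group_label <- match.arg(group_label,
                           c("intratracer_A", "intratracer_B", "intertracer"))
  if (is.null(rcfg)) {
    rcfg <- retest_config(
      wcv_true_pct = 10,
      bias_pct = if (group_label == "intertracer") 10 else 0,
      redraw_noise = TRUE, seed = cfg$seed + 1L
    )
  }
  if (dir.exists(out_dir)) {
    if (!force) {
      stop(sprintf("output directory '%s' exists; use force = TRUE to overwrite",
                   out_dir), call. = FALSE)
    }
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE)
  ext <- if (compress) ".nii.gz" else ".nii"
  set.seed(cfg$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  retest_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lesion_counts <- if (is.null(n_lesions_range)) {
    rep(cfg$n_lesions, n_subjects)
  } else {
    sample(seq(n_lesions_range[1], n_lesions_range[2]), n_subjects, replace = TRUE)
  }
  pairing <- list()
  truth_all <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("sub-%02d", s)
    cfg_s <- cfg
    cfg_s$seed <- subj_seeds[s]
    cfg_s$n_lesions <- lesion_counts[s]
    rcfg_s <- rcfg
    rcfg_s$seed <- retest_seeds[s]
    subj <- generate_subject(cfg_s)
    retest <- generate_retest(subj$image, subj$masks, subj$truth, rcfg_s)
    sdir <- file.path(out_dir, sid)
    dir.create(sdir)
    write_volume(subj$image, file.path(sdir, paste0("image_test", ext)))
    write_volume(retest, file.path(sdir, paste0("image_retest", ext)))
    for (m in subj$masks) {
      write_volume(m, file.path(sdir, paste0(m$lesion_id, ext)))
    }
    if (length(subj$masks) > 0) {
      pairing[[sid]] <- data.frame(
        subject_id = sid,
        lesion_id = vapply(subj$masks, `[[`, character(1), "lesion_id"),
        test_path = file.path(sid, paste0("image_test", ext)),
        retest_path = file.path(sid, paste0("image_retest", ext)),
        mask_path = file.path(sid, paste0(
          vapply(subj$masks, `[[`, character(1), "lesion_id"), ext
        )),
        stringsAsFactors = FALSE
      )
    }
    truth_all[[sid]] <- list(
      subject_id = sid, lesions = subj$truth$lesions,
      lesion_factors = as.numeric(attr(retest, "lesion_factors"))
    )
  }
  pairing_df <- if (length(pairing)) {
    do.call(rbind, c(pairing, list(make.row.names = FALSE)))
  } else {
    data.frame(subject_id = character(0), lesion_id = character(0),
               test_path = character(0), retest_path = character(0),
               mask_path = character(0))
  }
  utils::write.csv(pairing_df, file.path(out_dir, "pairing.csv"),
                   row.names = FALSE)
  truth_out <- list(
    group_label = group_label, wcv_true_pct = rcfg$wcv_true_pct,
    bias_pct = rcfg$bias_pct, subjects = unname(truth_all)
  )
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg_plain <- unclass(cfg)
  yaml::write_yaml(
    list(group_label = group_label, phantom = cfg_plain,
         retest = unclass(rcfg)),
    file.path(out_dir, "config.yaml")
  )
  invisible(list(pairing = pairing_df, truth = truth_out))
}
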