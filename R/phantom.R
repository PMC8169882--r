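#' Configuration of the synthetic anisotropic phantom
#'
#' Describes a multi-class 3D phantom that mimics, at desk scale, the size
#' hierarchy of the anatomy the segmentation task targets: one large
#' ellipsoidal blob (prostate-like, class 1), one thin tube along the slice
#' axis just posterior to the blob (external-urethral-sphincter-like,
#' class 2), and two small posterolateral tubes sharing a class
#' (neurovascular-bundle-like, class 3); class 0 is background.  The grid
#' is anisotropic: slice spacing is several times the in-plane spacing, as
#' in thick-slice axial MRI.
#'
#' Structure sizes are stored in voxel units; the defaults are derived from
#' `grid_size` so phantoms scale with the grid.  Per-class intensity means
#' and standard deviations plus a global additive noise sigma define the
#' gray-value model; the defaults keep every foreground class at least two
#' noise standard deviations away from the background mean so the task is
#' learnable by a small network while the thin tubes remain the hardest
#' targets.
#'
#' @param grid_size integer length-3 (W, H, D), all >= 8.
#' @param spacing voxel spacing in mm; default 1 x 1 x 3 preserves the
#'   anisotropy ratio that motivates the anisotropic network.
#' @param blob_semiaxes ellipsoid semi-axes of the blob, voxels.
#' @param eus_radius radius of the axial tube, voxels.
#' @param eus_gap gap between blob edge and tube centre along y, voxels.
#' @param nvb_radius radius of the two lateral tubes, voxels.
#' @param nvb_offset (x, y) offset of the lateral tubes from the blob
#'   centre, voxels.
#' @param tube_zspan fraction (lo, hi) of the slice range spanned by tubes.
#' @param class_means per-class intensity means (background, blob, axial
#'   tube, lateral tubes).
#' @param class_sds per-class intensity s.d. (tissue texture).
#' @param noise_sigma additive global Gaussian noise s.d.
#' @param jitter relative random jitter of centres/radii between cases (anatomical variability; organ sizes vary by tens of percent across subjects).
#' @return an object of class `segda_phantom_config`.
#' @export
phantom_config <- function(grid_size = c(64L, 64L, 16L),
                           spacing = c(1, 1, 3),
                           blob_semiaxes = NULL,
                           eus_radius = NULL,
                           eus_gap = NULL,
                           nvb_radius = NULL,
                           nvb_offset = NULL,
                           tube_zspan = c(0.15, 0.85),
                           class_means = c(0.20, 0.55, 0.85, 0.40),
                           class_sds = c(0.02, 0.02, 0.02, 0.02),
                           noise_sigma = 0.08,
                           jitter = 0.2) {
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 3L || any(grid_size < 8L)) {
    abort("`grid_size` must be three integers, all >= 8.", class = "segda_config_error")
  }
  if (any(spacing <= 0)) {
    abort("`spacing` must be positive.", class = "segda_config_error")
  }
  W <- grid_size[1]; H <- grid_size[2]; D <- grid_size[3]
  blob_semiaxes <- blob_semiaxes %||% c(0.22 * W, 0.17 * H, 0.28 * D)
  eus_radius <- eus_radius %||% max(1.6, 0.04 * W)
  eus_gap <- eus_gap %||% max(2, 0.05 * H)
  nvb_radius <- nvb_radius %||% max(1.2, 0.025 * W)
  nvb_offset <- nvb_offset %||% c(0.20 * W, 0.10 * H)
  cfg <- structure(
    list(grid_size = grid_size, spacing = as.numeric(spacing),
         blob_semiaxes = as.numeric(blob_semiaxes),
         eus_radius = eus_radius, eus_gap = eus_gap,
         nvb_radius = nvb_radius, nvb_offset = as.numeric(nvb_offset),
         tube_zspan = as.numeric(tube_zspan),
         class_means = as.numeric(class_means),
         class_sds = as.numeric(class_sds),
         noise_sigma = noise_sigma, jitter = jitter),
    class = "segda_phantom_config"
  )
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  W <- cfg$grid_size[1]; H <- cfg$grid_size[2]; D <- cfg$grid_size[3]
  ctr <- (cfg$grid_size - 1) / 2
  slack <- 1 + cfg$jitter
  if (any(cfg$blob_semiaxes * slack >= ctr + 0.5)) {
    abort("blob semi-axes do not fit inside the grid.", class = "segda_config_error")
  }
  y_eus <- ctr[2] + cfg$blob_semiaxes[2] + cfg$eus_gap
  if ((y_eus + cfg$eus_radius) * 1 >= H - 1) {
    abort("axial tube does not fit inside the grid.", class = "segda_config_error")
  }
  if (ctr[1] + cfg$nvb_offset[1] + cfg$nvb_radius >= W - 1 ||
      ctr[2] + cfg$nvb_offset[2] + cfg$nvb_radius >= H - 1) {
    abort("lateral tubes do not fit inside the grid.", class = "segda_config_error")
  }
  invisible(cfg)
}

#' Configuration of the source-to-target domain shift
#'
#' Parameterizes the appearance and shape change between the two synthetic
#' domains, emulating the shift between acquisition set-ups (e.g. an
#' endorectal coil compressing periprostatic tissue and altering contrast):
#' a smooth anterior-posterior compression field, a monotone gray-value
#' remap `v -> gain * v^gamma + offset`, and extra additive noise.
#'
#' With `deformation_amplitude = 0`, `gain = 1`, `offset = 0`, `gamma = 1`
#' and `extra_noise_sigma = 0` the shift is the identity and target cases
#' equal source cases bit for bit (for equal seeds).
#'
#' @param deformation_amplitude peak displacement as a fraction of the
#'   grid's y extent; must stay below ~0.3 so the per-slice displacement
#'   field remains invertible and structures stay inside the grid.
#' @param intensity_gain,intensity_offset linear part of the gray remap.
#' @param contrast_gamma exponent of the remap (applied to clipped
#'   non-negative intensities).
#' @param extra_noise_sigma additional Gaussian noise s.d. in the target
#'   domain.
#' @return an object of class `segda_shift_config`.
#' @export
domain_shift_config <- function(deformation_amplitude = 0.15,
                                intensity_gain = 0.7,
                                intensity_offset = 0.25,
                                contrast_gamma = 1.5,
                                extra_noise_sigma = 0.02) {
  if (deformation_amplitude < 0 || deformation_amplitude > 0.3) {
    abort("`deformation_amplitude` must lie in [0, 0.3] (invertibility).",
          class = "segda_config_error")
  }
  if (intensity_gain <= 0 || contrast_gamma <= 0) {
    abort("`intensity_gain` and `contrast_gamma` must be positive (monotone remap).",
          class = "segda_config_error")
  }
  structure(
    list(deformation_amplitude = deformation_amplitude,
         intensity_gain = intensity_gain,
         intensity_offset = intensity_offset,
         contrast_gamma = contrast_gamma,
         extra_noise_sigma = extra_noise_sigma),
    class = "segda_shift_config"
  )
}

# y-displacement field of the compression: smooth bump along y, slightly
# modulated along z.  Sampling semantics (pull-back): output (x,y,z) reads
# the source at y + disp.
shift_displacement <- function(dim, amplitude) {
  W <- dim[1]; H <- dim[2]; D <- dim[3]
  y <- (0:(H - 1)) / (H - 1)
  z <- (0:(D - 1)) / max(1, D - 1)
  bump <- sin(pi * y)                      # 0 at both y borders
  mod <- 1 + 0.2 * sin(2 * pi * z)         # mild through-slice variation
  disp <- outer(rep(1, W), outer(bump, mod)) * amplitude * (H - 1)
  array(disp, dim)
}

#' Generate one synthetic phantom case
#'
#' Builds the four-class label map and its gray-value volume for one case.
#' All randomness (structure jitter, texture, noise) is controlled by
#' `seed`, so equal arguments give bit-identical output.  For
#' `domain = "target"` the domain shift is applied consistently to the
#' image (linear interpolation / monotone remap / extra noise) and the
#' labels (nearest-neighbour warp by the same displacement field).
#'
#' @param config a [phantom_config()].
#' @param domain `"source"` or `"target"`.
#' @param shift a [domain_shift_config()]; only used for the target domain.
#' @param seed integer seed.
#' @return `list(volume =, labels =)`, a [volume()] / [label_map()] pair.
#' @export
generate_case <- function(config, domain = c("source", "target"),
                          shift = domain_shift_config(), seed = 1L) {
  domain <- match.arg(domain)
  validate_phantom_config(config)
  set.seed(seed)
  d <- config$grid_size
  W <- d[1]; H <- d[2]; D <- d[3]
  ctr <- (d - 1) / 2
  j <- function(x, rel = config$jitter) x * (1 + runif(length(x), -rel, rel))

  blob_c <- ctr + c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -0.5, 0.5)) *
    config$jitter * d
  blob_r <- j(config$blob_semiaxes)
  eus_c <- c(ctr[1] + runif(1, -1, 1) * config$jitter * W / 2,
             blob_c[2] + blob_r[2] + config$eus_gap)
  eus_r <- j(config$eus_radius)
  nvb_off <- j(config$nvb_offset)
  nvb_r <- j(config$nvb_radius)
  zspan <- round(config$tube_zspan * (D - 1))

  xs <- 0:(W - 1); ys <- 0:(H - 1); zs <- 0:(D - 1)
  X <- array(rep(xs, times = H * D), d)
  Y <- array(rep(rep(ys, each = W), times = D), d)
  Z <- array(rep(zs, each = W * H), d)

  lab <- array(0L, d)
  inside_blob <- ((X - blob_c[1]) / blob_r[1])^2 +
    ((Y - blob_c[2]) / blob_r[2])^2 +
    ((Z - blob_c[3]) / blob_r[3])^2 <= 1
  lab[inside_blob] <- 1L
  in_z <- Z >= zspan[1] & Z <= zspan[2]
  eus <- ((X - eus_c[1])^2 + (Y - eus_c[2])^2 <= eus_r^2) & in_z
  lab[eus] <- 2L
  nvb <- ((((X - (blob_c[1] - nvb_off[1]))^2 + (Y - (blob_c[2] + nvb_off[2]))^2) <= nvb_r^2) |
          (((X - (blob_c[1] + nvb_off[1]))^2 + (Y - (blob_c[2] + nvb_off[2]))^2) <= nvb_r^2)) & in_z
  lab[nvb] <- 3L

  if (length(unique(as.integer(lab))) < 4L) {
    abort("phantom structures do not all fit inside the grid.",
          class = "segda_config_error")
  }

  img <- array(config$class_means[lab + 1L], d) +
    array(rnorm(prod(d), 0, 1), d) * config$class_sds[lab + 1L] +
    array(rnorm(prod(d), 0, config$noise_sigma), d)

  if (domain == "target") {
    if (shift$deformation_amplitude > 0) {
      disp <- shift_displacement(d, shift$deformation_amplitude)
      img <- array(cpp_warp_y(as.numeric(img), d, as.numeric(disp),
                              mode = 0L, border = 1L, fill = 0), d)
      lab <- array(as.integer(cpp_warp_y(as.numeric(lab), d, as.numeric(disp),
                                         mode = 1L, border = 1L, fill = 0)), d)
    }
    if (shift$intensity_gain != 1 || shift$intensity_offset != 0 ||
        shift$contrast_gamma != 1) {
      img <- shift$intensity_gain * pmax(img, 0)^shift$contrast_gamma +
        shift$intensity_offset
    }
    if (shift$extra_noise_sigma > 0) {
      img <- img + array(rnorm(prod(d), 0, shift$extra_noise_sigma), d)
    }
  }

  list(volume = volume(img, config$spacing),
       labels = label_map(lab, config$spacing, n_classes = 4L))
}

#' Generate a synthetic cohort with train/val/test splits
#'
#' Builds `n_labeled` labeled and `m_unlabeled` unlabeled training cases,
#' `n_val` labeled validation cases and `n_test` labeled test cases, all
#' from one domain.  Case seeds are drawn once from `seed`, so two cohorts
#' with different seeds share the split structure but differ in voxel data.
#'
#' @param config a [phantom_config()].
#' @param shift a [domain_shift_config()].
#' @param n_labeled,m_unlabeled,n_val,n_test non-negative case counts.
#' @param domain `"source"` or `"target"`.
#' @param seed integer seed.
#' @return an object of class `segda_cohort`: a list with `cases` (each
#'   `list(case_id, volume, labels, split, domain, labeled)`; unlabeled
#'   cases carry `labels = NULL`) and a `manifest` tibble.
#' @export
generate_cohort <- function(config, shift = domain_shift_config(),
                            n_labeled = 5L, m_unlabeled = 10L,
                            n_val = 5L, n_test = 10L,
                            domain = c("source", "target"), seed = 1L) {
  domain <- match.arg(domain)
  counts <- c(n_labeled, m_unlabeled, n_val, n_test)
  if (any(counts < 0)) {
    abort("case counts must be non-negative.", class = "segda_usage_error")
  }
  set.seed(seed)
  n_total <- sum(counts)
  case_seeds <- sample.int(.Machine$integer.max, n_total)
  tag <- substr(domain, 1, 3)
  roles <- rep(c("train_labeled", "train_unlabeled", "val", "test"), counts)
  cases <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cs <- generate_case(config, domain = domain, shift = shift,
                        seed = case_seeds[i])
    role <- roles[i]
    labeled <- role != "train_unlabeled"
    cases[[i]] <- list(
      case_id = sprintf("%s-%s-%03d", tag, sub("_.*", "", role), i),
      volume = cs$volume,
      labels = if (labeled) cs$labels else NULL,
      split = sub("_.*", "", role),
      domain = domain,
      labeled = labeled
    )
  }
  names(cases) <- vapply(cases, `[[`, "", "case_id")
  manifest <- tibble(
    case_id = names(cases),
    image_path = NA_character_,
    label_path = NA_character_,
    split = vapply(cases, `[[`, "", "split"),
    domain = domain,
    labeled = vapply(cases, `[[`, TRUE, "labeled")
  )
  structure(list(cases = cases, manifest = manifest), class = "segda_cohort")
}

#' @export
print.segda_cohort <- function(x, ...) {
  cat(sprintf("<segda_cohort> %d cases\n", length(x$cases)))
  print(dplyr::count(x$manifest, .data$domain, .data$split, .data$labeled))
  invisible(x)
}

#' Select cases from a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param split optional split filter (`"train"`, `"val"`, `"test"`).
#' @param labeled optional logical filter.
#' @return list of case records.
#' @export
cohort_cases <- function(cohort, split = NULL, labeled = NULL) {
  keep <- rep(TRUE, length(cohort$cases))
  if (!is.null(split)) {
    keep <- keep & vapply(cohort$cases, `[[`, "", "split") %in% split
  }
  if (!is.null(labeled)) {
    keep <- keep & vapply(cohort$cases, `[[`, TRUE, "labeled") == labeled
  }
  unname(cohort$cases[keep])
}

#' Write a cohort to disk as NIfTI pairs plus a manifest CSV
#'
#' Each case is written as `<id>_img.nii.gz` and, when labeled,
#' `<id>_lab.nii.gz`; the manifest (`manifest.csv`) records paths, split,
#' domain and labeled status.
#'
#' @param cohort a `segda_cohort`.
#' @param dir destination directory (created if missing).
#' @return the manifest tibble with populated paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_along(cohort$cases)) {
    cs <- cohort$cases[[i]]
    ip <- file.path(dir, paste0(cs$case_id, "_img.nii.gz"))
    write_volume(cs$volume, ip)
    man$image_path[i] <- ip
    if (cs$labeled) {
      lp <- file.path(dir, paste0(cs$case_id, "_lab.nii.gz"))
      write_volume(cs$labels, lp)
      man$label_path[i] <- lp
    }
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`.
#' @param n_classes number of label classes.
#' @return a `segda_cohort`.
#' @export
read_cohort <- function(dir, n_classes = 4L) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  cases <- purrr::pmap(man, function(case_id, image_path, label_path, split,
                                     domain, labeled) {
    list(case_id = case_id,
         volume = read_volume(image_path),
         labels = if (isTRUE(labeled)) read_label_map(label_path, n_classes) else NULL,
         split = split, domain = domain, labeled = labeled)
  })
  names(cases) <- man$case_id
  structure(list(cases = cases, manifest = man), class = "segda_cohort")
}
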