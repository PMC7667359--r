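#' @title Synthetic lesion-phantom cohort
#' @description
#' Ellipsoid-based 3D lesion phantoms with known analytic volume, standing in
#' for real DWI infarct masks so that every downstream measurement and
#' evaluation stage can be tested against exact ground truth. Lesion shape is
#' a rotated ellipsoid whose radial surface may be perturbed by a smooth
#' mean-zero angular noise field (roughness) and by localized inward bites
#' (concavity), the latter giving the irregular, non-convex outline of real
#' infarcts for which diameter products are known to overestimate volume.
#' @name synthetic-cohort
NULL

# Fit log-normal meanlog/sdlog to a median and IQR by least squares on the
# 25th/50th/75th percentiles in log space.
fit_lognormal_quartiles <- function(median_ml, q25_ml, q75_ml) {
  if (!(q25_ml < median_ml && median_ml < q75_ml))
    stop("IQR bounds must straddle the median")
  z75 <- qnorm(0.75)
  list(
    meanlog = mean(log(c(q25_ml, median_ml, q75_ml))),
    sdlog = (log(q75_ml) - log(q25_ml)) / (2 * z75)
  )
}

# Smooth mean-zero angular noise field plus localized inward bites, frozen
# into the spec at construction time so rasterization is a pure function.
# The smooth field is a random combination of degree-2/3 Legendre polynomials
# in (v_j . u), each of which integrates to zero over the sphere.
make_surface_field <- function(seed, roughness, concavity,
                               n_modes = 6L, n_bites = 4L,
                               bite_halfangle_deg = 60) {
  with_seed(seed, {
    field <- list(roughness = roughness, concavity = concavity)
    if (roughness > 0) {
      v <- matrix(rnorm(3 * n_modes), nrow = 3)
      v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
      field$modes_v <- v
      field$modes_w <- rnorm(n_modes) / sqrt(n_modes)
      field$modes_deg <- rep_len(c(2L, 3L), n_modes)
    }
    if (concavity > 0) {
      b <- matrix(rnorm(3 * n_bites), nrow = 3)
      b <- sweep(b, 2, sqrt(colSums(b^2)), "/")
      field$bites_c <- b
      field$bites_d <- concavity * runif(n_bites, 0.6, 1)
      field$bites_t0 <- cos(bite_halfangle_deg * pi / 180)
    }
    field
  })
}

# Signed relative radial perturbation delta(u) for unit directions u (n x 3):
# surface radius is (1 + delta(u)) times the ellipsoid radius.
eval_surface_field <- function(field, u) {
  delta <- numeric(nrow(u))
  if (field$roughness > 0) {
    g <- numeric(nrow(u))
    for (j in seq_along(field$modes_w)) {
      t <- drop(u %*% field$modes_v[, j])
      p <- if (field$modes_deg[j] == 2L) (3 * t^2 - 1) / 2
           else (5 * t^3 - 3 * t) / 2
      g <- g + field$modes_w[j] * p
    }
    delta <- delta + field$roughness * g
  }
  if (field$concavity > 0) {
    t0 <- field$bites_t0
    for (m in seq_along(field$bites_d)) {
      s <- pmax(0, (drop(u %*% field$bites_c[, m]) - t0) / (1 - t0))
      delta <- delta - field$bites_d[m] * s^2
    }
  }
  delta
}

# Largest outward excursion of the field (bites are inward only); used to
# size the grid so the phantom can never be clipped.
field_outward_bound <- function(field) {
  if (field$roughness > 0) field$roughness * sum(abs(field$modes_w)) else 0
}

#' Specify a synthetic lesion phantom
#'
#' A rotated, optionally roughened ellipsoid on an anisotropic voxel grid.
#' The smooth roughness field is mean-zero over the sphere, so the expected
#' volume stays that of the base ellipsoid; concavity bites are strictly
#' inward, carving the surface the way real infarcts deviate from their
#' convex envelope.
#'
#' @param semi_axes three semi-axis lengths in mm `(row, col, slice)`, all
#'   positive, in the lesion's body frame.
#' @param orientation Euler angles in radians `c(about_slice, about_col,
#'   about_row)` applied in that order. The cohort sampler uses only the
#'   first (in-plane) angle by default, keeping slice cross-sections
#'   analytic.
#' @param spacing voxel spacing in mm `c(row, col, slice)`.
#' @param roughness amplitude (>= 0, dimensionless) of the smooth radial
#'   noise field; 0 gives an exact ellipsoid.
#' @param concavity depth (>= 0, dimensionless) of localized inward surface
#'   bites; 0 disables them.
#' @param grid_shape voxel counts per axis, or `NULL` to size the grid
#'   automatically around the lesion with a safety margin.
#' @param center lesion center in physical mm, or `NULL` for the grid center.
#' @param seed integer seed for the frozen surface noise field.
#' @param patient_id label.
#' @return An object of class `lesion_spec`; its `true_volume_ml` is the
#'   analytic ellipsoid volume `(4/3) * pi * prod(semi_axes) / 1000`.
#' @export
lesion_spec <- function(semi_axes, orientation = c(0, 0, 0),
                        spacing = c(1, 1, 5), roughness = 0, concavity = 0,
                        grid_shape = NULL, center = NULL, seed = 1L,
                        patient_id = "phantom") {
  semi_axes <- as.numeric(semi_axes)
  spacing <- as.numeric(spacing)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("`semi_axes` must be three positive lengths in mm")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive lengths in mm")
  if (roughness < 0 || concavity < 0)
    stop("`roughness` and `concavity` must be >= 0")
  field <- make_surface_field(seed, roughness, concavity)
  r_out <- max(semi_axes) * (1 + field_outward_bound(field))
  if (is.null(grid_shape)) {
    # centered grid with an odd voxel count: the lesion equator falls on a
    # slice center and a >= 2-voxel clearance guards the clipping check
    grid_shape <- 2L * ceiling(r_out / spacing) + 5L
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be three positive voxel counts")
  if (is.null(center)) center <- (grid_shape - 1) / 2 * spacing
  structure(
    list(
      semi_axes = semi_axes, orientation = as.numeric(orientation),
      spacing = spacing, roughness = roughness, concavity = concavity,
      grid_shape = grid_shape, center = as.numeric(center),
      seed = as.integer(seed), patient_id = as.character(patient_id),
      field = field,
      true_volume_ml = 4 / 3 * pi * prod(semi_axes) / 1000
    ),
    class = "lesion_spec"
  )
}

# Rotation matrix mapping body-frame to world-frame coordinates:
# R = R_slice(e1) %*% R_col(e2) %*% R_row(e3), axes = (row, col, slice).
rotation_matrix <- function(e) {
  cz <- cos(e[1]); sz <- sin(e[1])
  cy <- cos(e[2]); sy <- sin(e[2])
  cx <- cos(e[3]); sx <- sin(e[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)  # about slice axis
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)  # about col axis
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)  # about row axis
  Rz %*% Ry %*% Rx
}

#' Rasterize a lesion phantom onto its voxel grid
#'
#' A voxel belongs to the lesion iff its center, expressed in the lesion's
#' body frame, lies inside the (optionally perturbed) ellipsoid surface —
#' the center-point membership test that matches binary manual delineation.
#' Errors if the lesion touches the grid boundary, since a clipped phantom
#' would silently bias every volume downstream.
#'
#' @param spec a [lesion_spec].
#' @return A [lesion_image] with the spec's spacing and patient id.
#' @export
rasterize_lesion <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  n <- spec$grid_shape
  sp <- spec$spacing
  dx <- (seq_len(n[1]) - 1) * sp[1] - spec$center[1]
  dy <- (seq_len(n[2]) - 1) * sp[2] - spec$center[2]
  dz <- (seq_len(n[3]) - 1) * sp[3] - spec$center[3]
  R <- rotation_matrix(spec$orientation)
  # body-frame coordinates q = t(R) d are separable across the three axes
  q <- lapply(1:3, function(m)
    outer(outer(R[1, m] * dx, R[2, m] * dy, `+`), R[3, m] * dz, `+`))
  r2 <- (q[[1]] / spec$semi_axes[1])^2 + (q[[2]] / spec$semi_axes[2])^2 +
        (q[[3]] / spec$semi_axes[3])^2
  if (spec$roughness > 0 || spec$concavity > 0) {
    nrm <- sqrt(q[[1]]^2 + q[[2]]^2 + q[[3]]^2)
    nrm[nrm < 1e-12] <- 1e-12
    u <- cbind(as.vector(q[[1]] / nrm), as.vector(q[[2]] / nrm),
               as.vector(q[[3]] / nrm))
    delta <- array(eval_surface_field(spec$field, u), dim = n)
    inside <- sqrt(r2) <= 1 + delta
  } else {
    inside <- r2 <= 1
  }
  if (!any(inside)) stop("rasterized lesion is empty; grid or axes too small")
  if (any(inside[c(1, n[1]), , ]) || any(inside[, c(1, n[2]), ]) ||
      any(inside[, , c(1, n[3])]))
    stop("lesion clipped by grid boundary; enlarge `grid_shape`")
  lesion_image(inside, sp, spec$patient_id)
}

#' Configure a synthetic cohort
#'
#' Defaults emulate the reference multicenter DWI cohort: true lesion
#' volumes log-normal with median 26 ml and IQR 10.7–62.2 ml, slice
#' thickness drawn per patient from 2.5–5 mm, 1 mm in-plane resolution, and
#' a mix of exact ellipsoids and roughened/concave shapes.
#'
#' @param n_patients cohort size.
#' @param median_ml,iqr_ml target median and `c(q25, q75)` of the true
#'   lesion-volume distribution, in ml.
#' @param shape_mix fraction of patients whose lesion is an exact ellipsoid;
#'   the remainder get roughness and concavity drawn from the ranges below.
#' @param aspect_ratio_range range of the in-plane minor-to-major semi-axis
#'   ratio, sampled per patient.
#' @param z_aspect_range range of the through-plane-to-major semi-axis
#'   ratio. MCA-territory infarcts extend cranio-caudally about as far as
#'   in-plane; the default keeps the median lesion spanning on the order of
#'   8–11 slices, in line with the reference cohort's 8 (IQR 6–11).
#' @param roughness_range,concavity_range sampling ranges for the roughened
#'   fraction of the cohort.
#' @param in_plane_mm in-plane voxel size (mm); DWI protocols near 1–2 mm.
#' @param slice_thickness_choices per-patient slice thickness is drawn
#'   uniformly from this set (mm).
#' @param volume_limits_ml truncation bounds on sampled true volumes,
#'   keeping phantoms clinically plausible and grids bounded.
#' @param seed integer master seed for the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 238L,
                          median_ml = 26, iqr_ml = c(10.7, 62.2),
                          shape_mix = 0.3,
                          aspect_ratio_range = c(0.4, 0.95),
                          z_aspect_range = c(0.5, 1.1),
                          roughness_range = c(0.04, 0.12),
                          concavity_range = c(0.35, 0.65),
                          in_plane_mm = 1,
                          slice_thickness_choices = c(2.5, 3, 4, 5),
                          volume_limits_ml = c(0.5, 400),
                          seed = 1L) {
  if (n_patients < 1L) stop("`n_patients` must be >= 1")
  if (!(iqr_ml[1] < median_ml && median_ml < iqr_ml[2]))
    stop("IQR bounds must straddle the median")
  if (any(slice_thickness_choices <= 0)) stop("slice thickness must be positive")
  if (shape_mix < 0 || shape_mix > 1) stop("`shape_mix` must be in [0, 1]")
  structure(
    list(
      n_patients = as.integer(n_patients), median_ml = median_ml,
      iqr_ml = as.numeric(iqr_ml), shape_mix = shape_mix,
      aspect_ratio_range = as.numeric(aspect_ratio_range),
      z_aspect_range = as.numeric(z_aspect_range),
      roughness_range = as.numeric(roughness_range),
      concavity_range = as.numeric(concavity_range),
      in_plane_mm = in_plane_mm,
      slice_thickness_choices = as.numeric(slice_thickness_choices),
      volume_limits_ml = as.numeric(volume_limits_ml),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Sample a cohort of lesion phantom specifications
#'
#' Draws per-patient true volumes from the configured log-normal law, solves
#' the ellipsoid semi-axes from volume and sampled aspect ratios, applies a
#' random in-plane rotation, and assigns per-patient voxel spacing and shape
#' irregularity. Deterministic given the config seed.
#'
#' @param config a [cohort_config].
#' @return A list of [lesion_spec] objects of length `config$n_patients`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  par <- fit_lognormal_quartiles(config$median_ml, config$iqr_ml[1],
                                 config$iqr_ml[2])
  with_seed(config$seed, {
    n <- config$n_patients
    vol <- pmin(pmax(rlnorm(n, par$meanlog, par$sdlog),
                     config$volume_limits_ml[1]), config$volume_limits_ml[2])
    ar <- config$aspect_ratio_range
    zr <- config$z_aspect_range
    u1 <- runif(n, ar[1], ar[2])  # in-plane minor / major
    u2 <- runif(n, zr[1], zr[2])  # through-plane / major
    theta <- runif(n, 0, pi)
    th <- sample(config$slice_thickness_choices, n, replace = TRUE)
    rough <- runif(n) >= config$shape_mix
    rough_amp <- runif(n, config$roughness_range[1], config$roughness_range[2])
    conc_amp <- runif(n, config$concavity_range[1], config$concavity_range[2])
    lapply(seq_len(n), function(i) {
      # volume (ml -> mm^3) = (4/3) pi p^3 u1 u2 with p the major semi-axis
      p <- (vol[i] * 1000 * 3 / (4 * pi * u1[i] * u2[i]))^(1 / 3)
      lesion_spec(
        semi_axes = c(p, p * u1[i], p * u2[i]),
        orientation = c(theta[i], 0, 0),
        spacing = c(config$in_plane_mm, config$in_plane_mm, th[i]),
        roughness = if (rough[i]) rough_amp[i] else 0,
        concavity = if (rough[i]) conc_amp[i] else 0,
        seed = derive_seed(config$seed, i),
        patient_id = sprintf("P%04d", i)
      )
    })
  })
}

# Generating in-plane full axes (cm) at the widest slice. Analytic for
# in-plane-only rotations; otherwise measured brute-force from the mask.
true_inplane_axes_cm <- function(spec, image = NULL) {
  if (all(abs(spec$orientation[2:3]) < 1e-12) &&
      spec$roughness == 0 && spec$concavity == 0) {
    ax <- sort(2 * spec$semi_axes[1:2], decreasing = TRUE) / 10
    return(c(a = ax[1], b = ax[2]))
  }
  if (is.null(image)) image <- rasterize_lesion(spec)
  m <- select_measurement_slice(image, feret_fun = feret_diameter_brute)
  c(a = m$a_cm, b = m$b_cm)
}

#' Write a phantom cohort to disk
#'
#' Rasterizes each spec, writes one NIfTI mask per patient (spacing in the
#' header), and writes a catalog CSV pairing each mask with its analytic
#' true volume and the generating in-plane diameters at the widest slice.
#'
#' @param specs list of [lesion_spec] objects, e.g. from [sample_cohort()].
#' @param out_dir output directory (created if needed).
#' @return Path to the catalog CSV, invisibly. Catalog columns:
#'   `patient_id, mask_path, true_volume_ml, true_a_cm, true_b_cm,
#'   n_lesion_slices, slice_thickness_mm`.
#' @export
write_cohort <- function(specs, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- lapply(specs, function(spec) {
    img <- rasterize_lesion(spec)
    path <- file.path(out_dir, paste0(spec$patient_id, ".nii.gz"))
    write_lesion_image(img, path)
    ab <- true_inplane_axes_cm(spec, img)
    data.frame(
      patient_id = spec$patient_id, mask_path = basename(path),
      true_volume_ml = spec$true_volume_ml,
      true_a_cm = ab[["a"]], true_b_cm = ab[["b"]],
      n_lesion_slices = count_lesion_slices(img),
      slice_thickness_mm = spec$spacing[3],
      stringsAsFactors = FALSE
    )
  })
  catalog <- do.call(rbind, rows)
  catalog_path <- file.path(out_dir, "catalog.csv")
  write.csv(catalog, catalog_path, row.names = FALSE)
  invisible(catalog_path)
}
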