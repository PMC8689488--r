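# Phantoms are minimal-sufficient mussel-like scenes: an elliptical shell
# ring bright in CH1 (and, via bleed-through, in CH2), a dim tissue interior,
# circular ROS foci in CH2 only, an optional gut blob in CH3, Gaussian sensor
# noise, and signal distributed over z so that the per-pixel maximum over
# slices recovers the scene. Geometry (not texture) is what the area-based
# pipeline operators consume.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic phantom scene
#'
#' Default intensities mimic an 8-bit acquisition in which the shell
#' autofluorescence is balanced across CH1 and CH2 (bleed-through ratio
#' `shell_intensity_ch2 / shell_intensity_ch1 = 1`, the instrument's design),
#' ROS foci are bright against a dim tissue baseline, and sensor noise is
#' additive Gaussian.
#'
#' @param image_shape `(rows, cols)` of each slice.
#' @param n_slices number of z slices.
#' @param shell_axes outer ellipse semi-axes (px) of the shell footprint.
#' @param shell_rotation ellipse rotation (radians).
#' @param ring_thickness shell ring thickness (px).
#' @param shell_intensity_ch1,shell_intensity_ch2 mean ring intensity in CH1
#'   and CH2; their ratio is the bleed-through ratio.
#' @param tissue_intensity interior baseline intensity (CH2).
#' @param ros_fraction target true ROS area as a fraction of the shell
#'   footprint, in \[0, 1).
#' @param ros_object_count number of circular ROS foci.
#' @param ros_intensity focus intensity added over the tissue baseline (CH2).
#' @param gut_present render a CH3 gut blob.
#' @param gut_intensity CH3 blob intensity.
#' @param noise_sd additive Gaussian sigma per voxel; `noise_model` may be
#'   set to `"poisson"` for Poisson counts around the scene mean.
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @param bit_depth 8 or 16.
#' @param pixel_size optional physical pixel size (um/px) carried as
#'   metadata.
#' @param centre_jitter max random offset of the shell centre, as a fraction
#'   of the image's smaller dimension.
#' @param seed integer seed making the render deterministic.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(512L, 512L), n_slices = 5L,
                         shell_axes = c(160, 100), shell_rotation = 0,
                         ring_thickness = 12,
                         shell_intensity_ch1 = 200,
                         shell_intensity_ch2 = 200,
                         tissue_intensity = 20,
                         ros_fraction = 0.2, ros_object_count = 5L,
                         ros_intensity = 160,
                         gut_present = FALSE, gut_intensity = 150,
                         noise_sd = 5, noise_model = c("gaussian", "poisson"),
                         bit_depth = 8L, pixel_size = NULL,
                         centre_jitter = 0.05, seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32L),
            n_slices >= 1L, length(shell_axes) == 2L, all(shell_axes > 0),
            ring_thickness > 0, ring_thickness < min(shell_axes),
            shell_intensity_ch1 >= 0, shell_intensity_ch2 >= 0,
            tissue_intensity >= 0, ros_intensity >= 0,
            ros_fraction >= 0, ros_fraction < 1, ros_object_count >= 1L,
            noise_sd >= 0, centre_jitter >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_slices = as.integer(n_slices),
                 shell_axes = shell_axes, shell_rotation = shell_rotation,
                 ring_thickness = ring_thickness,
                 shell_intensity_ch1 = shell_intensity_ch1,
                 shell_intensity_ch2 = shell_intensity_ch2,
                 tissue_intensity = tissue_intensity,
                 ros_fraction = ros_fraction,
                 ros_object_count = as.integer(ros_object_count),
                 ros_intensity = ros_intensity,
                 gut_present = isTRUE(gut_present),
                 gut_intensity = gut_intensity,
                 noise_sd = noise_sd, noise_model = noise_model,
                 bit_depth = as.integer(bit_depth), pixel_size = pixel_size,
                 centre_jitter = centre_jitter, seed = seed),
            class = "phantom_spec")
}

# Rotated-ellipse membership on pixel-centre coordinates.
ellipse_mask <- function(shape, centre, axes, rotation = 0) {
  r <- seq_len(shape[1L]) - centre[1L]
  c_ <- seq_len(shape[2L]) - centre[2L]
  rr <- matrix(r, shape[1L], shape[2L])
  cc <- matrix(c_, shape[1L], shape[2L], byrow = TRUE)
  u <- rr * cos(rotation) + cc * sin(rotation)
  v <- -rr * sin(rotation) + cc * cos(rotation)
  (u / axes[1L])^2 + (v / axes[2L])^2 <= 1
}

draw_disc <- function(mask, centre, radius) {
  r0 <- max(1L, floor(centre[1L] - radius)); r1 <- min(nrow(mask), ceiling(centre[1L] + radius))
  c0 <- max(1L, floor(centre[2L] - radius)); c1 <- min(ncol(mask), ceiling(centre[2L] + radius))
  rr <- matrix(r0:r1 - centre[1L], r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1 - centre[2L], r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (rr^2 + cc^2 <= radius^2)
  mask
}

# Place circular foci (overlap allowed) inside the interior ellipse until the
# union area hits the target within 2% relative. A random configuration
# (unit-disc centre coordinates + radius multipliers) is drawn once per
# attempt and then only its global radius scale is iterated, so the area is a
# monotone function of the free parameter and the search converges; the
# rendered truth mask, not the disc algebra, is the contract.
place_ros_foci <- function(spec, centre, inner_axes, target,
                           max_attempts = 10L, max_scale_iter = 40L) {
  shape <- spec$image_shape
  n <- spec$ros_object_count
  rot <- spec$shell_rotation
  r_base <- sqrt(target / (n * pi))
  render_conf <- function(uv, mult, scale) {
    mask <- matrix(FALSE, shape[1L], shape[2L])
    for (i in seq_len(n)) {
      rad <- min(r_base * scale * mult[i], 0.95 * min(inner_axes))
      fit <- pmax(inner_axes - rad, 0.5)
      ctr <- centre + c(uv[i, 1L] * fit[1L] * cos(rot) -
                          uv[i, 2L] * fit[2L] * sin(rot),
                        uv[i, 1L] * fit[1L] * sin(rot) +
                          uv[i, 2L] * fit[2L] * cos(rot))
      mask <- draw_disc(mask, ctr, rad)
    }
    mask
  }
  for (attempt in seq_len(max_attempts)) {
    uv <- matrix(0, n, 2L)
    for (i in seq_len(n)) repeat {
      u <- runif(1, -1, 1); v <- runif(1, -1, 1)
      if (u^2 + v^2 <= 1) { uv[i, ] <- c(u, v); break }
    }
    mult <- runif(n, 0.75, 1.25)
    scale <- 1
    for (it in seq_len(max_scale_iter)) {
      mask <- render_conf(uv, mult, scale)
      area <- sum(mask)
      if (abs(area - target) <= 0.02 * target) return(mask)
      adj <- sqrt(target / max(area, 1))
      scale <- scale * max(min(adj, 1.5), 0.67)
    }
  }
  stop("ros_fraction ", spec$ros_fraction, " unachievable with ",
       n, " foci of feasible size (", max_attempts, " attempts)")
}

# Spread a 2-D scene over z so that max over slices recovers it exactly:
# every pixel's full intensity lands in one uniformly chosen slice.
spread_slices <- function(scene, n_slices) {
  shape <- dim(scene)
  zmap <- matrix(sample.int(n_slices, length(scene), replace = TRUE),
                 shape[1L], shape[2L])
  vox <- array(0, c(shape, n_slices))
  for (k in seq_len(n_slices)) vox[, , k] <- scene * (zmap == k)
  vox
}

#' Render a phantom z-stack with ground-truth masks
#'
#' Deterministic for a given `spec$seed`. ROS foci are placed inside the
#' shell footprint and resized until the rendered truth-ROS area is within 2%
#' (relative) of `ros_fraction x |truth shell|`. Noise is added independently
#' per channel, slice and voxel, then intensities are clipped to the bit
#' depth and rounded.
#'
#' @param spec a [phantom_spec].
#' @return list with `stack` (a [zstack]), `truth_shell` and `truth_ros`
#'   ([mask_image]s) and `true_fraction` (rendered, not requested).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$image_shape
    jit <- spec$centre_jitter * min(shape)
    centre <- shape / 2 + runif(2, -jit, jit)
    outer <- ellipse_mask(shape, centre, spec$shell_axes, spec$shell_rotation)
    inner_axes <- spec$shell_axes - spec$ring_thickness
    inner <- ellipse_mask(shape, centre, inner_axes, spec$shell_rotation)
    ring <- outer & !inner
    truth_shell <- mask_image(outer, role = "truth_shell")
    target <- round(spec$ros_fraction * sum(outer))
    ros <- if (target > 0)
      place_ros_foci(spec, centre, inner_axes, target)
    else matrix(FALSE, shape[1L], shape[2L])
    truth_ros <- mask_image(ros, role = "truth_ros")

    ch1_scene <- ring * spec$shell_intensity_ch1
    ch2_scene <- ring * spec$shell_intensity_ch2 +
      inner * spec$tissue_intensity + ros * spec$ros_intensity
    channels <- list(shell = spread_slices(ch1_scene, spec$n_slices),
                     ros = spread_slices(ch2_scene, spec$n_slices))
    if (spec$gut_present) {
      gut <- ellipse_mask(shape, centre, inner_axes * 0.45,
                          spec$shell_rotation)
      channels$gut <- spread_slices(gut * spec$gut_intensity, spec$n_slices)
    }
    top <- 2^spec$bit_depth - 1
    channels <- lapply(channels, function(vox) {
      noisy <- if (spec$noise_model == "poisson") {
        array(stats::rpois(length(vox), lambda = vox), dim(vox))
      } else if (spec$noise_sd > 0) {
        vox + array(rnorm(length(vox), 0, spec$noise_sd), dim(vox))
      } else vox
      round(pmin(pmax(noisy, 0), top))
    })
    list(stack = zstack(channels, pixel_size = spec$pixel_size,
                        bit_depth = spec$bit_depth),
         truth_shell = truth_shell, truth_ros = truth_ros,
         true_fraction = sum(ros) / sum(outer))
  })
}

#' The default emersion-stress experiment design
#'
#' Six treatments — an immersed control, a freeze-killed reference, and four
#' emersion treatments crossing duration (1 h, 20 h) with relative humidity
#' (high ~85%, moderate ~60%) — each replicated in 3 containers of 10
#' individuals. True mean ROS fractions follow the magnitudes the method was
#' developed against: a low control (~5%), stressed groups between 16% and
#' 38%, and a dead reference inside the stressed range.
#'
#' @param containers_per_treatment replicate containers per treatment.
#' @param individuals_per_container individuals imaged per container.
#' @param between_container_sd SD of container-level offsets of the true
#'   fraction (fraction scale).
#' @param within_container_sd SD of individual offsets within a container.
#' @param seed integer seed for the simulation stream.
#' @return an object of class `experiment_design`.
#' @export
default_design <- function(containers_per_treatment = 3L,
                           individuals_per_container = 10L,
                           between_container_sd = 0.02,
                           within_container_sd = 0.03,
                           seed = NULL) {
  experiment_design(
    treatments = data.frame(
      label = c("control", "dead", "em1h_highRH", "em1h_modRH",
                "em20h_highRH", "em20h_modRH"),
      mean_fraction = c(0.05, 0.30, 0.26, 0.38, 0.31, 0.16)),
    containers_per_treatment = containers_per_treatment,
    individuals_per_container = individuals_per_container,
    between_container_sd = between_container_sd,
    within_container_sd = within_container_sd, seed = seed)
}

#' Specify a treatment/container experiment design
#'
#' @param treatments `data.frame` with columns `label` and `mean_fraction`
#'   (true mean ROS fraction per treatment); optional per-treatment
#'   `between_sd` / `within_sd` columns override the shared SDs.
#' @inheritParams default_design
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(treatments, containers_per_treatment = 3L,
                              individuals_per_container = 10L,
                              between_container_sd = 0.02,
                              within_container_sd = 0.03, seed = NULL) {
  stopifnot(is.data.frame(treatments),
            all(c("label", "mean_fraction") %in% names(treatments)),
            nrow(treatments) >= 1L,
            all(treatments$mean_fraction >= 0),
            all(treatments$mean_fraction < 1),
            containers_per_treatment >= 1L, individuals_per_container >= 1L,
            between_container_sd >= 0, within_container_sd >= 0)
  if (anyDuplicated(treatments$label)) stop("duplicate treatment labels")
  if (is.null(treatments$between_sd))
    treatments$between_sd <- between_container_sd
  if (is.null(treatments$within_sd))
    treatments$within_sd <- within_container_sd
  structure(list(treatments = treatments,
                 containers_per_treatment = as.integer(containers_per_treatment),
                 individuals_per_container = as.integer(individuals_per_container),
                 seed = seed),
            class = "experiment_design")
}

#' Simulate a full treatment/container experiment of phantoms
#'
#' True per-individual ROS fractions are drawn hierarchically (treatment mean
#' -> Gaussian container offset -> Gaussian individual offset), truncated to
#' \[0, 0.99\] (truncation events are messaged), and one phantom is rendered
#' per individual with that fraction. Deterministic for a given
#' `design$seed`.
#'
#' @param design an [experiment_design].
#' @param phantom_base a [phantom_spec] whose geometry/noise settings are
#'   reused for every individual (its `ros_fraction` and `seed` are
#'   overridden).
#' @param render if `FALSE`, skip rendering and return only the truth table
#'   (useful for statistics-only simulations).
#' @param out_dir if non-`NULL`, write each stack as OME-TIFF plus
#'   `truth_table.csv` and `labels.csv` into this directory instead of
#'   keeping stacks in memory.
#' @return list with `truth` (`data.frame`: `individual_id`, `treatment`,
#'   `container`, `true_fraction`), `stacks` (named list of [zstack]s, or
#'   file paths when `out_dir` is used, or `NULL` when `render = FALSE`), and
#'   `design`.
#' @export
simulate_experiment <- function(design, phantom_base = phantom_spec(),
                                render = TRUE, out_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(phantom_base, "phantom_spec"))
  if (design$containers_per_treatment < 1L) stop("degenerate design")
  with_seed(design$seed, {
    tr <- design$treatments
    rows <- list()
    n_trunc <- 0L
    for (i in seq_len(nrow(tr))) {
      for (cj in seq_len(design$containers_per_treatment)) {
        c_off <- rnorm(1, 0, tr$between_sd[i])
        for (ind in seq_len(design$individuals_per_container)) {
          f <- tr$mean_fraction[i] + c_off + rnorm(1, 0, tr$within_sd[i])
          if (f < 0 || f > 0.99) n_trunc <- n_trunc + 1L
          f <- min(max(f, 0), 0.99)
          rows[[length(rows) + 1L]] <- data.frame(
            individual_id = sprintf("%s_c%d_i%02d", tr$label[i], cj, ind),
            treatment = tr$label[i],
            container = sprintf("%s_c%d", tr$label[i], cj),
            true_fraction = f)
        }
      }
    }
    truth <- do.call(rbind, rows)
    if (n_trunc > 0L)
      message(n_trunc, " simulated fraction(s) truncated to [0, 0.99]")
    stacks <- NULL
    if (render) {
      seeds <- sample.int(.Machine$integer.max - 1L, nrow(truth))
      stacks <- vector("list", nrow(truth))
      names(stacks) <- truth$individual_id
      for (r in seq_len(nrow(truth))) {
        sp <- phantom_base
        sp$ros_fraction <- truth$true_fraction[r]
        sp$seed <- seeds[r]
        ph <- render_phantom(sp)
        ph$stack$id <- truth$individual_id[r]
        stacks[[r]] <- ph$stack
      }
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        paths <- file.path(out_dir, paste0(truth$individual_id, ".ome.tiff"))
        for (r in seq_len(nrow(truth))) write_stack(stacks[[r]], paths[r])
        labels <- data.frame(file = basename(paths),
                             treatment = truth$treatment,
                             container = truth$container)
        write.csv(truth, file.path(out_dir, "truth_table.csv"),
                  row.names = FALSE)
        write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
        stacks <- paths
      }
    }
    list(truth = truth, stacks = stacks, design = design)
  })
}
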