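#' Per-channel maximum-intensity projection
#'
#' Collapses each channel of a z-stack to a 2-D image whose every pixel is
#' the maximum over slices. Idempotent on single-slice stacks and invariant
#' to slice-order permutation.
#'
#' @param stack a [zstack] with at least one slice.
#' @return a [projection_set].
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  ns <- n_slices(stack)
  if (ns < 1L) stop("degenerate stack: zero slices")
  images <- lapply(stack$channels, function(a) {
    do.call(pmax, lapply(seq_len(ns), function(k) a[, , k]))
  })
  projection_set(images, source = stack$id)
}

#' Estimate the CH2/CH1 shell gain
#'
#' The acquisition protocol balances the detectors so the shell
#' autofluorescence reads at the same level in CH1 and CH2; this estimates
#' the residual imbalance as the ratio of medians of the two channels over
#' fluorescing shell pixels. Because the shell ROI is the *filled* footprint
#' whose interior carries no CH1 signal, medians are taken over ROI pixels
#' with CH1 above Otsu within the ROI (the ring); when CH1 is constant over
#' the ROI, all ROI pixels are used.
#'
#' @param proj a [projection_set] with `shell` and `ros` channels.
#' @param shell_mask a [mask_image], the shell ROI.
#' @return scalar gain `g >= 0`; `g = 1` means balanced channels.
#' @export
equalize_shell_gain <- function(proj, shell_mask) {
  stopifnot(inherits(proj, "projection_set"))
  if (mask_area(shell_mask) == 0L) stop("empty shell mask")
  ch1 <- proj$images$shell
  ch2 <- proj$images$ros
  v1 <- ch1[shell_mask]
  bright <- if (max(v1) > min(v1)) shell_mask & (ch1 >= otsu_threshold(v1))
  else shell_mask
  m1 <- median(ch1[bright])
  if (m1 == 0)
    stop("unbalanceable acquisition: CH1 median is zero under the shell mask")
  median(ch2[bright]) / m1
}

#' Channel subtraction: remove non-specific shell signal from CH2
#'
#' Computes `max(0, CH2 - gain * CH1)` pixelwise in floating point; negative
#' differences are clipped to zero. With a gain-balanced acquisition
#' (`gain = 1`) and CH2 equal to the bleed-through copy of CH1, the result is
#' exactly the zero image.
#'
#' @param proj a [projection_set] with `shell` and `ros` channels.
#' @param gain scalar CH1 multiplier (default 1, the balanced design).
#' @return numeric matrix, the cleaned ROS image.
#' @export
subtract_channels <- function(proj, gain = 1.0) {
  stopifnot(inherits(proj, "projection_set"))
  ch1 <- proj$images$shell
  ch2 <- proj$images$ros
  if (is.null(ch1) || is.null(ch2))
    stop("projection set must contain 'shell' (CH1) and 'ros' (CH2)")
  if (!all(dim(ch1) == dim(ch2))) stop("CH1 and CH2 shapes differ")
  pmax(ch2 - gain * ch1, 0)
}

new_ros_quantification <- function(id, shell_mask, ros_mask, gain) {
  shell_px <- mask_area(shell_mask)
  ros_px <- mask_area(ros_mask)
  structure(list(
    individual_id = id,
    shell_area_px = shell_px,
    ros_area_px = ros_px,
    ros_percent = 100 * ros_px / shell_px,
    shell_threshold = attr(shell_mask, "threshold"),
    ros_threshold = attr(ros_mask, "threshold"),
    gain_factor = gain),
    class = "ros_quantification")
}

#' @export
print.ros_quantification <- function(x, ...) {
  cat(sprintf(
    "<ros_quantification%s> shell %d px, ROS %d px => %.2f%% ROS-positive\n",
    if (is.null(x$individual_id)) "" else paste0(" ", x$individual_id),
    x$shell_area_px, x$ros_area_px, x$ros_percent))
  cat(sprintf("  thresholds: shell %.4g, ros %s; gain %.4g\n",
              x$shell_threshold,
              if (is.na(x$ros_threshold)) "(none: no foreground)"
              else sprintf("%.4g", x$ros_threshold), x$gain_factor))
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

quantify_projection <- function(proj, params, id) {
  shell_mask <- with_stage("segment_shell",
                           segment_shell(proj$images$shell, params))
  gain <- if (params$equalize_gain)
    with_stage("equalize_shell_gain", equalize_shell_gain(proj, shell_mask))
  else params$gain
  sub <- with_stage("subtract_channels", subtract_channels(proj, gain))
  ros_mask <- with_stage("segment_ros", segment_ros(sub, shell_mask, params, reference = max(proj$images$ros)))
  q <- new_ros_quantification(id, shell_mask, ros_mask, gain)
  attr(q, "masks") <- list(shell = shell_mask, ros = ros_mask)
  q
}

#' Quantify the ROS-positive area fraction of one individual
#'
#' Runs the whole image chain: maximum-intensity projection, shell-footprint
#' segmentation from CH1, optional gain estimation, CH2 - gain x CH1
#' subtraction, ROS segmentation inside the shell ROI, and the per-individual
#' summary `ros_percent = 100 * |ros mask| / |shell mask|`. Stage failures
#' are reported with the failing stage named.
#'
#' @param stack a [zstack] with `shell` and `ros` channels.
#' @param params a [seg_params] configuration.
#' @param id identifier for the result (defaults to the stack id).
#' @return a `ros_quantification`: shell/ROS areas in pixels, `ros_percent`
#'   in \[0, 100\], and the thresholds and gain actually applied.
#' @export
quantify_individual <- function(stack, params = seg_params(), id = NULL) {
  stopifnot(inherits(stack, "zstack"))
  proj <- with_stage("max_projection", max_projection(stack))
  quantify_projection(proj, params, id %||% stack$id)
}

# Multi-individual frames: every sufficiently large component of the shell
# segmentation is treated as one individual, labelled id#k in scan order.
quantify_frame <- function(stack, params, id) {
  proj <- with_stage("max_projection", max_projection(stack))
  ch1 <- proj$images$shell
  if (max(ch1) <= min(ch1)) stop("[segment_shell] no shell found: constant image")
  thr <- if (params$shell_method == "fixed") {
    params$shell_threshold
  } else {
    t0 <- otsu_threshold(ch1)
    if (fisher_separation(as.numeric(ch1), t0) < params$min_separation)
      stop("[segment_shell] no shell found: ",
           "no threshold separates foreground from background")
    t0
  }
  mask <- fill_holes(binary_close(ch1 >= thr, params$close_radius))
  comps <- select_components(mask, params$min_component_size,
                             intensity = ch1, multi = TRUE)
  if (!length(comps))
    stop("[segment_shell] no shell found: no component of at least ",
         params$min_component_size, " px")
  lapply(seq_along(comps), function(k) {
    shell_mask <- mask_image(comps[[k]], role = "shell_roi")
    attr(shell_mask, "threshold") <- as.numeric(thr)
    gain <- if (params$equalize_gain)
      with_stage("equalize_shell_gain", equalize_shell_gain(proj, shell_mask))
    else params$gain
    sub <- with_stage("subtract_channels", subtract_channels(proj, gain))
    ros_mask <- with_stage("segment_ros", segment_ros(sub, shell_mask, params, reference = max(proj$images$ros)))
    q <- new_ros_quantification(paste0(id, "#", k), shell_mask, ros_mask, gain)
    attr(q, "masks") <- list(shell = shell_mask, ros = ros_mask)
    q
  })
}

#' Quantify a batch of stacks into a tidy experiment table
#'
#' Accepts file paths (TIFF/OME-TIFF) or in-memory [zstack] objects, joins
#' the per-individual results with treatment/container labels, and isolates
#' failures: a stack that cannot be read or quantified produces a failure
#' record, not an aborted batch.
#'
#' @param stacks character vector of file paths, or a list of [zstack]s.
#' @param params a [seg_params]; with `multi_individual = TRUE` every
#'   sufficiently large connected component in a frame yields its own row.
#' @param labels optional `data.frame` with columns `file` (or `id`),
#'   `treatment`, `container`, joined by file name / stack id.
#' @param mask_dir if non-`NULL`, write the shell and ROS masks of every
#'   successful quantification into this directory as 0/255 TIFFs.
#' @return a `data.frame` of class `experiment_table` with columns
#'   `individual_id`, `file`, `treatment`, `container`, `shell_area_px`,
#'   `ros_area_px`, `ros_percent`, `shell_threshold`, `ros_threshold`,
#'   `gain_factor`; failures as attribute `"failures"` (data.frame of
#'   `file`, `error`).
#' @export
quantify_batch <- function(stacks, params = seg_params(), labels = NULL,
                           mask_dir = NULL) {
  if (!is.null(mask_dir))
    dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(stacks) == 0L) stop("empty batch: no stacks to quantify")
  if (inherits(stacks, "zstack")) stacks <- list(stacks)
  nm <- if (is.character(stacks)) basename(stacks)
  else vapply(seq_along(stacks),
              function(i) stacks[[i]]$id %||% paste0("stack", i), character(1))
  rows <- list(); fails <- list()
  for (i in seq_along(stacks)) {
    res <- tryCatch({
      s <- if (is.character(stacks)) read_stack(stacks[[i]]) else stacks[[i]]
      if (params$multi_individual) quantify_frame(s, params, nm[i])
      else list(quantify_individual(s, params, id = nm[i]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(file = nm[i], error = conditionMessage(res))
    } else {
      for (q in res) {
        if (!is.null(mask_dir)) {
          m <- attr(q, "masks")
          safe <- gsub("[^A-Za-z0-9_.-]", "_", q$individual_id)
          write_mask(m$shell, file.path(mask_dir, paste0(safe, "_shell.tiff")))
          write_mask(m$ros, file.path(mask_dir, paste0(safe, "_ros.tiff")))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = q$individual_id, file = nm[i],
          shell_area_px = q$shell_area_px, ros_area_px = q$ros_area_px,
          ros_percent = q$ros_percent, shell_threshold = q$shell_threshold,
          ros_threshold = q$ros_threshold, gain_factor = q$gain_factor)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(0), file = character(0),
               shell_area_px = integer(0), ros_area_px = integer(0),
               ros_percent = numeric(0), shell_threshold = numeric(0),
               ros_threshold = numeric(0), gain_factor = numeric(0))
  if (!is.null(labels)) {
    key <- if ("file" %in% names(labels)) "file" else "id"
    idx <- match(tab$file, labels[[key]])
    tab$treatment <- labels$treatment[idx]
    tab$container <- labels$container[idx]
  } else {
    tab$treatment <- NA_character_
    tab$container <- NA_character_
  }
  ord <- c("individual_id", "file", "treatment", "container",
           "shell_area_px", "ros_area_px", "ros_percent",
           "shell_threshold", "ros_threshold", "gain_factor")
  tab <- tab[, ord]
  class(tab) <- c("experiment_table", "data.frame")
  attr(tab, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(file = character(0), error = character(0))
  tab
}
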