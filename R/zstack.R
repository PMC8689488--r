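# Channel-role convention: CH1 = shell autofluorescence (~410/20 nm, blue),
# CH2 = ROS stain (~510/20 nm, green), CH3 = gut autofluorescence (~660/20 nm,
# red). CH3 is carried through I/O and overlays but never quantified.
CHANNEL_ROLES <- c("shell", "ros", "gut")

#' Construct a multi-channel z-stack
#'
#' A `zstack` holds one 3-D intensity array per channel role, all with
#' identical `row x col x slice` dimensions. Channels are identified by role,
#' not wavelength: `"shell"` (CH1, shell autofluorescence), `"ros"` (CH2, the
#' ROS stain) and optionally `"gut"` (CH3). At least `shell` and `ros` must be
#' present for quantification; `gut` is pass-through only.
#'
#' Intensities are stored as non-negative numbers at the native bit depth of
#' the source (`bit_depth`, default 8); all downstream arithmetic is done in
#' floating point so that clipping only ever happens where the method defines
#' it (the channel subtraction).
#'
#' @param channels named list of 3-D numeric arrays (`row x col x slice`),
#'   names drawn from `c("shell", "ros", "gut")`.
#' @param pixel_size optional physical pixel size in micrometres per pixel.
#'   When absent, areas are reported in pixels and percent only.
#' @param bit_depth integer dynamic range of the source data (8 or 16).
#' @param axial_extent_um optional total axial extent of the stack in
#'   micrometres (metadata only).
#' @param id optional identifier carried into results.
#' @return an object of class `zstack`.
#' @export
zstack <- function(channels, pixel_size = NULL, bit_depth = 8L,
                   axial_extent_um = NULL, id = NULL) {
  if (!is.list(channels) || is.null(names(channels)))
    stop("channels must be a named list of 3-D arrays")
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         " (expected shell/ros/gut)")
  if (!all(c("shell", "ros") %in% names(channels)))
    stop("channels 'shell' (CH1) and 'ros' (CH2) are required")
  channels <- channels[intersect(CHANNEL_ROLES, names(channels))]
  dims <- lapply(channels, function(a) {
    if (length(dim(a)) != 3L) stop("each channel must be a 3-D array")
    dim(a)
  })
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) all(d == d0), logical(1))))
    stop("all channels must share identical row/col/slice dimensions")
  if (d0[3L] < 1L) stop("stack must have at least one slice")
  for (a in channels) {
    if (anyNA(a)) stop("intensities must be finite")
    if (min(a) < 0) stop("intensities must be non-negative")
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  top <- 2^bit_depth - 1
  if (max(vapply(channels, max, numeric(1))) > top)
    stop("intensities exceed 2^bit_depth - 1")
  structure(
    list(channels = channels, pixel_size = pixel_size,
         bit_depth = bit_depth, axial_extent_um = axial_extent_um, id = id),
    class = "zstack")
}

#' @export
dim.zstack <- function(x) dim(x$channels[[1L]])

#' Number of z slices in a stack
#' @param stack a [zstack].
#' @return integer slice count.
#' @export
n_slices <- function(stack) dim(stack)[3L]

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<zstack%s> %d x %d px, %d slice(s), channels: %s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              d[1L], d[2L], d[3L], paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  cat(sprintf("  bit depth: %d\n", x$bit_depth))
  invisible(x)
}

#' Construct a set of per-channel 2-D projections
#'
#' @param images named list of numeric matrices, one per channel role, all
#'   the same shape.
#' @param source identifier of the stack the projections derive from.
#' @return an object of class `projection_set`.
#' @export
projection_set <- function(images, source = NULL) {
  if (!is.list(images) || is.null(names(images)))
    stop("images must be a named list of matrices")
  d0 <- dim(images[[1L]])
  for (m in images) {
    if (!is.matrix(m)) stop("each projection must be a matrix")
    if (!all(dim(m) == d0)) stop("projections must share the same shape")
  }
  structure(list(images = images, source = source), class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<projection_set> %d x %d px, channels: %s\n",
              d[1L], d[2L], paste(names(x$images), collapse = ", ")))
  invisible(x)
}

MASK_ROLES <- c("shell_roi", "ros_positive", "truth_shell", "truth_ros")

#' Construct a binary mask image
#'
#' @param pixels logical matrix.
#' @param role one of `"shell_roi"`, `"ros_positive"`, `"truth_shell"`,
#'   `"truth_ros"`.
#' @return logical matrix of class `mask_image` with a `role` attribute.
#' @export
mask_image <- function(pixels, role) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("pixels must be a logical matrix")
  if (anyNA(pixels)) stop("mask must not contain NA")
  role <- match.arg(role, MASK_ROLES)
  structure(pixels, role = role, class = c("mask_image", "matrix", "array"))
}

#' Mask area in pixels
#' @param mask a [mask_image] (or plain logical matrix).
#' @return number of TRUE pixels.
#' @export
mask_area <- function(mask) sum(mask)

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image:%s> %d x %d px, area %d px\n",
              attr(x, "role"), nrow(x), ncol(x), mask_area(x)))
  invisible(x)
}
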