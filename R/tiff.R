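# Minimal baseline TIFF codec. Scope: uncompressed, single-sample grayscale,
# 8- or 16-bit unsigned, multi-page; little- or big-endian on read,
# little-endian one-strip-per-page on write; OME-XML channel metadata in the
# first page's ImageDescription. This subset is all the pipeline needs and is
# implemented here because no TIFF-capable R package is available at run time.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

u16le <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}
u32le <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
               v %/% 16777216))
}

# One 12-byte IFD entry; `value` is pre-encoded raw (<= 4 bytes, padded).
tiff_entry <- function(tag, type, count, value) {
  stopifnot(length(value) <= 4L)
  c(u16le(tag), u16le(type), u32le(count),
    value, raw(4L - length(value)))
}

# pages: list of numeric matrices (already integer-valued, in range).
write_tiff_pages <- function(pages, path, bit_depth, description = NULL) {
  bpp <- bit_depth %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16le(42L), u32le(8L)), con)
  pos <- 8
  npg <- length(pages)
  for (p in seq_len(npg)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    strip_len <- h * w * bpp
    desc <- if (p == 1L && !is.null(description)) {
      c(charToRaw(description), as.raw(0L))
    } else NULL
    ntags <- 10L + (!is.null(desc))
    ifd_len <- 2L + ntags * 12L + 4L
    desc_off <- pos + ifd_len
    strip_off <- desc_off + length(desc)
    next_off <- if (p < npg) strip_off + strip_len else 0
    ent <- list(
      tiff_entry(256L, 4L, 1L, u32le(w)),        # ImageWidth
      tiff_entry(257L, 4L, 1L, u32le(h)),        # ImageLength
      tiff_entry(258L, 3L, 1L, u16le(bit_depth)),# BitsPerSample
      tiff_entry(259L, 3L, 1L, u16le(1L)),       # Compression: none
      tiff_entry(262L, 3L, 1L, u16le(1L)))       # Photometric: BlackIsZero
    if (!is.null(desc))
      ent <- c(ent, list(tiff_entry(270L, 2L, length(desc), u32le(desc_off))))
    ent <- c(ent, list(
      tiff_entry(273L, 4L, 1L, u32le(strip_off)),  # StripOffsets
      tiff_entry(277L, 3L, 1L, u16le(1L)),         # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, u32le(h)),          # RowsPerStrip
      tiff_entry(279L, 4L, 1L, u32le(strip_len)),  # StripByteCounts
      tiff_entry(339L, 3L, 1L, u16le(1L))))        # SampleFormat: unsigned
    writeBin(c(u16le(ntags), unlist(ent), u32le(next_off)), con)
    if (!is.null(desc)) writeBin(desc, con)
    v <- as.integer(round(t(m)))  # TIFF strips are row-major
    if (bpp == 1L) writeBin(as.raw(v), con)
    else writeBin(as.raw(rbind(v %% 256L, v %/% 256L)), con)
    pos <- strip_off + strip_len
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("'", path, "' is not a TIFF file (truncated)")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little"
  else if (order_tag == "MM") "big"
  else stop("'", path, "' is not a TIFF file (bad byte-order mark)")
  rd <- function(off, size, n = 1L)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = FALSE, endian = endian)
  rd32 <- function(off, n = 1L) {  # unsigned 32-bit, returned as double
    b <- as.integer(raw[(off + 1L):(off + 4L * n)])
    dim(b) <- c(4L, n)
    if (endian == "big") b <- b[4:1, , drop = FALSE]
    as.numeric(b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ])
  }
  if (rd(2L, 2L) != 42L) stop("'", path, "' is not a TIFF file (bad magic)")
  ifd_off <- rd32(4L)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    nent <- rd(ifd_off, 2L)
    tags <- list()
    for (i in seq_len(nent)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd(e, 2L); type <- rd(e + 2L, 2L); count <- rd32(e + 4L)
      tsz <- TIFF_TYPE_SIZE[as.character(type)]
      if (is.na(tsz)) next  # skip rationals etc.
      off <- if (count * tsz <= 4L) e + 8L else rd32(e + 8L)
      val <- if (type == 2L) {
        bytes <- raw[(off + 1L):(off + count)]
        rawToChar(bytes[bytes != as.raw(0L)])
      } else if (type == 4L) rd32(off, count) else rd(off, tsz, count)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stop("TIFF page missing required tag ", tag)
      v
    }
    w <- need(256L); h <- need(257L)
    bits <- tags[["258"]] %||% 1L
    comp <- tags[["259"]] %||% 1L
    if (comp != 1L) stop("unsupported TIFF compression scheme ", comp)
    spp <- tags[["277"]] %||% 1L
    if (any(spp != 1L)) stop("only single-sample (grayscale) TIFF supported")
    if (!all(bits %in% c(8L, 16L)))
      stop("only 8- or 16-bit TIFF supported, found ", bits[1L])
    fmt <- tags[["339"]] %||% 1L
    if (any(fmt != 1L)) stop("only unsigned-integer TIFF samples supported")
    soff <- need(273L); scnt <- need(279L)
    data <- raw[unlist(mapply(function(o, n) (o + 1):(o + n), soff, scnt,
                              SIMPLIFY = FALSE))]
    bpp <- bits[1L] %/% 8L
    vals <- readBin(data, "integer", n = w * h, size = bpp, signed = FALSE,
                    endian = endian)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    if (is.null(description) && !is.null(tags[["270"]]))
      description <- tags[["270"]]
    attr(pages[[length(pages)]], "bits") <- bits[1L]
    ifd_off <- rd32(ifd_off + 2L + nent * 12L)
  }
  list(pages = pages, description = description)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ome_xml <- function(stack) {
  d <- dim(stack)
  roles <- names(stack$channels)
  ch <- paste0(sprintf('<Channel ID="Channel:0:%d" Name="%s"/>',
                       seq_along(roles) - 1L, roles), collapse = "")
  phys <- if (is.null(stack$pixel_size)) "" else
    sprintf(' PhysicalSizeX="%g" PhysicalSizeY="%g" PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm"',
            stack$pixel_size, stack$pixel_size)
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"%s><Pixels ID="Pixels:0" DimensionOrder="XYCZT" ',
    'Type="uint%d" SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="%d" SizeT="1"%s>',
    '%s</Pixels></Image></OME>'),
    if (is.null(stack$id)) "" else sprintf(' Name="%s"', stack$id),
    stack$bit_depth, d[2L], d[1L], length(roles), d[3L], phys, ch)
}

parse_ome <- function(description) {
  if (is.null(description) || !grepl("<OME", description, fixed = TRUE))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num_attr <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else as.numeric(v)
  }
  chn <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name")
  list(size_c = num_attr(px, "SizeC"), size_z = num_attr(px, "SizeZ"),
       dimension_order = xml2::xml_attr(px, "DimensionOrder"),
       physical_size = num_attr(px, "PhysicalSizeX"),
       image_name = xml2::xml_attr(xml2::xml_find_first(doc, ".//Image"),
                                   "Name"),
       channel_names = if (length(chn)) chn else NULL)
}

#' Read a multi-channel z-stack from TIFF / OME-TIFF
#'
#' Accepts two dialects: OME-TIFF whose first-page `ImageDescription` carries
#' OME-XML (`SizeC`/`SizeZ`, channel names, physical pixel size), and plain
#' multi-page TIFF with pages interleaved channel-fastest (page = z * C + c),
#' in which case the channel count and roles are taken from `channel_order`.
#' OME metadata, when present, overrides `channel_order`; a `channel_order`
#' whose length disagrees with the OME channel count is a format error.
#'
#' @param path TIFF file path.
#' @param channel_order character vector of channel roles in file order,
#'   drawn from `c("shell", "ros", "gut")`. Default assumes the CH1/CH2/CH3
#'   convention, truncated to the number of channels in the file when OME
#'   metadata states it.
#' @return a [zstack].
#' @export
read_stack <- function(path, channel_order = NULL) {
  tf <- read_tiff_pages(path)
  if (!length(tf$pages)) stop("'", path, "' contains no image pages")
  ome <- parse_ome(tf$description)
  npg <- length(tf$pages)
  if (!is.null(ome) && !is.null(ome$size_c)) {
    nc <- as.integer(ome$size_c)
    nz <- as.integer(ome$size_z %||% (npg / nc))
    if (!is.null(channel_order) && length(channel_order) != nc)
      stop(sprintf(
        "channel-count mismatch in '%s': declared %d channel(s), file has %d",
        path, length(channel_order), nc))
    roles <- ome$channel_names %||% CHANNEL_ROLES[seq_len(nc)]
    if (!all(roles %in% CHANNEL_ROLES)) roles <- CHANNEL_ROLES[seq_len(nc)]
    dim_order <- ome$dimension_order %||% "XYCZT"
  } else {
    if (is.null(channel_order))
      channel_order <- CHANNEL_ROLES[seq_len(min(3L, npg))]
    nc <- length(channel_order)
    roles <- channel_order
    nz <- npg / nc
    dim_order <- "XYCZT"
  }
  nz <- as.integer(round(nz))
  if (nc * nz != npg || nz < 1L)
    stop(sprintf(
      "channel-count mismatch in '%s': %d page(s) cannot hold %d channel(s)",
      path, npg, nc))
  page_of <- function(ci, zi) {
    if (startsWith(dim_order, "XYC")) (zi - 1L) * nc + ci
    else (ci - 1L) * nz + zi  # XYZCT
  }
  h <- nrow(tf$pages[[1L]]); w <- ncol(tf$pages[[1L]])
  channels <- lapply(seq_len(nc), function(ci) {
    a <- array(0, dim = c(h, w, nz))
    for (zi in seq_len(nz)) a[, , zi] <- tf$pages[[page_of(ci, zi)]]
    a
  })
  names(channels) <- roles
  zstack(channels,
         pixel_size = if (!is.null(ome)) ome$physical_size else NULL,
         bit_depth = attr(tf$pages[[1L]], "bits"),
         id = if (!is.null(ome) && !is.na(ome$image_name %||% NA))
           ome$image_name else NULL)
}

#' Write a z-stack as OME-TIFF
#'
#' Pages are written channel-fastest (`XYCZT`) with OME-XML metadata (channel
#' roles, stack geometry, physical pixel size when known) on the first page,
#' losslessly for integer intensities.
#'
#' @param stack a [zstack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack)
  pages <- vector("list", length(stack$channels) * d[3L])
  k <- 0L
  for (zi in seq_len(d[3L]))
    for (ci in seq_along(stack$channels)) {
      k <- k + 1L
      pages[[k]] <- stack$channels[[ci]][, , zi]
    }
  write_tiff_pages(pages, path, stack$bit_depth, description = ome_xml(stack))
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask a [mask_image] or logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_tiff_pages(list(ifelse(mask, 255, 0)), path, 8L)
  invisible(path)
}

#' Read a binary mask written by [write_mask]
#' @param path TIFF file path.
#' @param role mask role to assign, see [mask_image].
#' @return a [mask_image].
#' @export
read_mask <- function(path, role = "shell_roi") {
  tf <- read_tiff_pages(path)
  mask_image(tf$pages[[1L]] > 0, role = role)
}
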