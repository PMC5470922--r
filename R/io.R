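#' Describe an on-disk RGB-D sequence
#'
#' A sequence lives in three directories of PNG frames: 8-bit RGB color,
#' 16-bit grayscale depth in millimeters (0 = hole), and optionally 8-bit
#' ground-truth masks (binarized at 128). Frames are aligned one-to-one by
#' natural sort of their file names.
#'
#' Some public RGB-D benchmarks store depth PNGs with the top three bits
#' rotated to the other end of the 16-bit word; `depth_transform` undoes
#' that on read (`"rotl3"` / `"rotr3"`), and defaults to `"none"` so
#' sequences written by this package need no flag.
#'
#' @param color_dir,depth_dir,gt_dir Directories of PNG frames; `gt_dir` may
#'   be `NULL`.
#' @param pattern Regular expression selecting frame files.
#' @param depth_transform One of `"none"`, `"rotl3"`, `"rotr3"`.
#' @param max_range_mm Depth normalization range carried along for the
#'   segmenters.
#' @return A list of class `"sequence_spec"`.
#' @export
sequence_spec <- function(color_dir, depth_dir, gt_dir = NULL,
                          pattern = "\\.png$",
                          depth_transform = c("none", "rotl3", "rotr3"),
                          max_range_mm = 8000) {
  depth_transform <- match.arg(depth_transform)
  structure(list(color_dir = color_dir, depth_dir = depth_dir, gt_dir = gt_dir,
                 pattern = pattern, depth_transform = depth_transform,
                 max_range_mm = max_range_mm),
            class = "sequence_spec")
}

# natural sort: digit runs compare numerically ("frame_2" < "frame_10")
natural_sort <- function(x) {
  key <- vapply(x, function(s) {
    m <- gregexpr("\\d+", s)
    regmatches(s, m) <- lapply(regmatches(s, m),
                               function(d) sprintf("%020.0f", as.numeric(d)))
    s
  }, character(1))
  x[order(key)]
}

#' Apply or undo a 16-bit depth bit rotation
#'
#' `"rotl3"` rotates each 16-bit value left by three bits, `"rotr3"` right by
#' three; the two are mutual inverses, and `"none"` is the identity.
#'
#' @param x Integer vector/matrix of 16-bit values (0-65535).
#' @param type `"none"`, `"rotl3"` or `"rotr3"`.
#' @return Transformed values, same shape as `x`.
#' @examples
#' depth_bit_transform(0x8000L, "rotl3")  # 4
#' @export
depth_bit_transform <- function(x, type = c("none", "rotl3", "rotr3")) {
  type <- match.arg(type)
  if (any(x < 0 | x > 65535)) stop("values must be 16-bit (0-65535)")
  d <- dim(x)
  xi <- as.integer(x)
  out <- switch(type,
    none = xi,
    rotl3 = bitwOr(bitwAnd(bitwShiftL(xi, 3), 65535L), bitwShiftR(xi, 13)),
    rotr3 = bitwOr(bitwShiftR(xi, 3), bitwAnd(bitwShiftL(xi, 13), 65535L)))
  dim(out) <- d
  out
}

# ---- minimal 16-bit grayscale PNG encoder -------------------------------
# No installed package writes 16-bit PNG (png::writePNG is 8-bit only), so
# depth frames are encoded here: IHDR (bit depth 16, color type 0) + one
# zlib-compressed IDAT of filter-0 scanlines. R's memCompress(type = "gzip")
# emits a zlib stream (0x78 0x9c header + Adler-32 trailer), which is exactly
# the IDAT payload format. png::readPNG reads the result back bit-exactly.

.devibe_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(.devibe_env$crc_tab)) {
    tab <- integer(256)
    for (i in 0:255) {
      cr <- i
      for (k in 1:8)
        cr <- if (bitwAnd(cr, 1L) != 0L)
          bitwXor(-306674912L, bitwShiftR(cr, 1))  # 0xEDB88320, logical shift
        else bitwShiftR(cr, 1)
      tab[i + 1] <- cr
    }
    .devibe_env$crc_tab <- tab
  }
  .devibe_env$crc_tab
}

crc32_bytes <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  writeBin(bitwXor(crc, -1L), raw(), size = 4, endian = "big")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(writeBin(length(data), raw(), size = 4, endian = "big"), body,
    crc32_bytes(body))
}

write_png_gray16 <- function(values, path) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (any(values < 0 | values > 65535)) stop("values must be 16-bit (0-65535)")
  h <- nrow(values); w <- ncol(values)
  v <- as.integer(t(values))                      # row-major pixel order
  bytes <- as.raw(rbind(v %/% 256L, v %% 256L))   # big-endian 16-bit samples
  scan <- rbind(as.raw(0L), matrix(bytes, nrow = 2L * w))  # filter byte 0/row
  ihdr <- c(writeBin(c(w, h), raw(), size = 4, endian = "big"),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))      # depth 16, grayscale
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", memCompress(as.raw(scan), "gzip")), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

read_png_gray16 <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  round(v * 65535)
}

# -------------------------------------------------------------------------

#' Read an RGB-D sequence from disk
#'
#' @param spec A [sequence_spec()], or a color directory path (then
#'   `depth_dir`/`gt_dir`/etc. are taken from `...` via [sequence_spec()]).
#' @param ... Passed to [sequence_spec()] when `spec` is a path.
#' @return An `rgbd_sequence` with frame names taken from the color files.
#' @export
read_sequence <- function(spec, ...) {
  if (!inherits(spec, "sequence_spec")) spec <- sequence_spec(spec, ...)
  for (d in c(spec$color_dir, spec$depth_dir, spec$gt_dir))
    if (!dir.exists(d)) stop("directory does not exist: ", d)
  cf <- natural_sort(list.files(spec$color_dir, spec$pattern))
  df <- natural_sort(list.files(spec$depth_dir, spec$pattern))
  if (length(cf) == 0) stop("no frames match in ", spec$color_dir)
  if (length(cf) != length(df))
    stop(sprintf("frame count mismatch: %d color vs %d depth frames",
                 length(cf), length(df)))
  gf <- NULL
  if (!is.null(spec$gt_dir)) {
    gf <- natural_sort(list.files(spec$gt_dir, spec$pattern))
    if (length(gf) != length(cf))
      stop(sprintf("frame count mismatch: %d color vs %d ground-truth frames",
                   length(cf), length(gf)))
  }
  frames <- vector("list", length(cf))
  for (t in seq_along(cf)) {
    color <- read_color_png(file.path(spec$color_dir, cf[t]))
    depth <- read_png_gray16(file.path(spec$depth_dir, df[t]))
    depth <- depth_bit_transform(depth, spec$depth_transform)
    gt <- if (is.null(gf)) NULL else
      read_mask_png(file.path(spec$gt_dir, gf[t]))
    frames[[t]] <- frame_triplet(color, depth, gt)
  }
  rgbd_sequence(frames, frame_names = sub("\\.png$", "", cf))
}

read_color_png <- function(path) {
  v <- tryCatch(png::readPNG(path),
                error = function(e) stop("cannot read PNG file ", path, ": ",
                                         conditionMessage(e)))
  if (length(dim(v)) == 2L) v <- array(v, c(dim(v), 3L))
  if (dim(v)[3] > 3L) v <- v[, , 1:3, drop = FALSE]
  round(v * 255)
}

read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  round(v * 255) >= 128
}

#' Write an RGB-D sequence to disk
#'
#' Writes `color/`, `depth/` and (when ground truth is present) `gt/`
#' subdirectories of PNGs in exactly the layout [read_sequence()] expects:
#' 8-bit RGB color, 16-bit grayscale depth in millimeters, 8-bit masks.
#'
#' @param seq An `rgbd_sequence`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sequence <- function(seq, out_dir) {
  if (!inherits(seq, "rgbd_sequence")) stop("seq must be an rgbd_sequence")
  nm <- attr(seq, "frame_names")
  has_gt <- !is.null(seq[[1]]$gt)
  for (d in c("color", "depth", if (has_gt) "gt"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(seq)) {
    f <- seq[[t]]
    png::writePNG(f$color / 255, file.path(out_dir, "color", paste0(nm[t], ".png")))
    write_png_gray16(f$depth, file.path(out_dir, "depth", paste0(nm[t], ".png")))
    if (has_gt)
      png::writePNG((f$gt != 0) * 1.0, file.path(out_dir, "gt", paste0(nm[t], ".png")))
  }
  invisible(out_dir)
}

#' Write segmentation masks as PNGs
#'
#' One 8-bit single-channel PNG per frame, 0 = background, 255 = foreground,
#' named after the input frames.
#'
#' @param seg A `"segmentation"` object (or a list of logical masks).
#' @param out_dir Output directory (created if needed).
#' @param frame_names Optional names; defaults to the segmentation's.
#' @return Character vector of written paths.
#' @export
write_masks <- function(seg, out_dir, frame_names = NULL) {
  masks <- if (inherits(seg, "segmentation")) seg$masks else seg
  if (is.null(frame_names))
    frame_names <- if (inherits(seg, "segmentation")) seg$frame_names
                   else sprintf("frame_%04d", seq_along(masks))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, paste0(frame_names, ".png"))
  for (t in seq_along(masks))
    png::writePNG((masks[[t]] != 0) * 1.0, paths[t])
  paths
}

#' Read a directory of binary mask PNGs
#'
#' @param dir Directory of 8-bit mask PNGs (binarized at 128).
#' @param pattern Regular expression selecting files.
#' @return List of logical matrices, named by file, in natural-sort order.
#' @export
read_masks <- function(dir, pattern = "\\.png$") {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  files <- natural_sort(list.files(dir, pattern))
  if (length(files) == 0) stop("no masks match in ", dir)
  out <- lapply(files, function(f) read_mask_png(file.path(dir, f)))
  names(out) <- sub("\\.png$", "", files)
  out
}

#' Read algorithm parameters from a YAML configuration file
#'
#' The file may carry any subset of the [devb_params()] fields plus
#' `max_range_mm` and `depth_transform`; missing fields use the defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `params` ([devb_params()]), `max_range_mm`
#'   and `depth_transform`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pf <- intersect(names(cfg), names(formals(devb_params)))
  list(params = do.call(devb_params, cfg[pf]),
       max_range_mm = if (is.null(cfg$max_range_mm)) 8000 else cfg$max_range_mm,
       depth_transform = if (is.null(cfg$depth_transform)) "none" else cfg$depth_transform)
}
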