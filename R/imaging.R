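#' Fixed blue-to-red colormap
#'
#' A 256-entry lookup table running from cool blue (low coupling) through
#' green to warm red (high coupling), generated analytically so rendering
#' never depends on a plotting library's defaults and is bit-reproducible.
#'
#' @return 256 x 3 integer matrix (R, G, B in 0..255).
#' @export
blue_red_colormap <- function() {
  t <- (0:255) / 255
  clamp01 <- function(x) pmin(1, pmax(0, x))
  r <- clamp01(1.5 - abs(4 * t - 3))
  g <- clamp01(1.5 - abs(4 * t - 2))
  b <- clamp01(1.5 - abs(4 * t - 1))
  cbind(R = as.integer(round(255 * r)), G = as.integer(round(255 * g)),
        B = as.integer(round(255 * b)))
}

#' Render a connectivity matrix as a colour raster image
#'
#' Values are mapped to `[0, 1]` (PDC/DTF: identity with clamping; GC:
#' the fixed monotone map `1 - exp(-v)` since GC is unbounded), looked up in
#' the fixed blue-to-red colormap, and upscaled to `size x size` by nearest
#' neighbour so every matrix cell is a uniform block. The scaling is fixed
#' (never per-image min-max) so identical couplings render identically
#' across images - a prerequisite for between-class intensity differences to
#' survive into the classifier.
#'
#' @param cm a `connectivity_matrix` (already in canonical channel order,
#'   see [order_channels()]).
#' @param size output edge length in pixels (default 224).
#' @return object of class `connectivity_image`: integer `pixels`
#'   (`size x size x 3`, 0..255) plus metadata.
#' @export
render_image <- function(cm, size = 224) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  v <- cm$values
  if (any(!is.finite(v))) stop("NaN/Inf in connectivity values")
  scaling <- if (cm$method == "GC") "1-exp(-v)" else "clamp01"
  u <- if (cm$method == "GC") 1 - exp(-v) else pmin(1, pmax(0, v))
  idx <- matrix(as.integer(round(u * 255)) + 1L, nrow(v), ncol(v))
  m <- nrow(v)
  if (size < m) stop("size must be >= matrix dimension")
  lut <- blue_red_colormap()
  src <- floor((seq_len(size) - 0.5) * m / size) + 1L   # nearest neighbour
  big <- idx[src, src, drop = FALSE]
  pixels <- array(0L, c(size, size, 3L))
  for (ch in 1:3) pixels[, , ch] <- matrix(lut[big, ch], size, size)
  structure(list(pixels = pixels,
                 meta = list(method = cm$method, band = cm$band,
                             emotion = cm$meta$emotion %||% "",
                             subject = cm$meta$subject %||% "",
                             colormap = "blue-red-256", scaling = scaling,
                             matrix_dim = m)),
            class = "connectivity_image")
}

#' @export
print.connectivity_image <- function(x, ...) {
  cat(sprintf("<connectivity_image> %dx%d, %s/%s, emotion='%s'\n",
              dim(x$pixels)[1L], dim(x$pixels)[2L], x$meta$method,
              x$meta$band, x$meta$emotion))
  invisible(x)
}

#' Save / load a connectivity image as PNG
#'
#' Lossless PNG with the method, band, emotion, subject, colormap and
#' scaling metadata stored in text chunks; loading restores the pixels
#' bit-exactly and the metadata round-trips.
#'
#' @param img a `connectivity_image`.
#' @param path destination / source file path.
#' @return `path` invisibly (save); a `connectivity_image` (load).
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "connectivity_image"))
  write_png(img$pixels, path,
            text = img$meta[c("method", "band", "emotion", "subject",
                              "colormap", "scaling", "matrix_dim")])
  invisible(path)
}

#' @rdname save_image
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  p <- read_png(path)
  meta <- p$text
  meta$matrix_dim <- as.integer(meta$matrix_dim %||% NA)
  structure(list(pixels = p$pixels, meta = meta),
            class = "connectivity_image")
}
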