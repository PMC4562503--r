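# Minimal animated-GIF codec (GIF89a, 256-level grayscale palette).
# The encoder emits a valid LZW stream made of 9-bit literal codes with a
# clear code every 250 pixels, so the code width never grows; the decoder
# is a general LZW decoder.  Lossless for 8-bit grayscale frames.

u16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

# Pack integer codes (all the same bit width) LSB-first into raw bytes.
pack_codes <- function(codes, width) {
  bits <- bitwAnd(bitwShiftR(rep(codes, each = width),
                             rep(0:(width - 1L), length(codes))), 1L)
  pad <- (-length(bits)) %% 8L
  if (pad) bits <- c(bits, integer(pad))
  packBits(as.integer(bits), type = "raw")
}

# Split a raw vector into <=255-byte GIF data sub-blocks.
sub_blocks <- function(bytes) {
  n <- length(bytes)
  if (n == 0L) return(as.raw(0L))
  starts <- seq(1L, n, by = 255L)
  out <- lapply(starts, function(s) {
    chunk <- bytes[s:min(s + 254L, n)]
    c(as.raw(length(chunk)), chunk)
  })
  c(do.call(c, out), as.raw(0L))
}

encode_frame_lzw <- function(idx) {
  clear <- 256L
  eoi <- 257L
  chunks <- split(idx, ceiling(seq_along(idx) / 250L))
  codes <- c(clear,
             unlist(lapply(chunks, function(ch) c(ch, clear)),
                    use.names = FALSE))
  codes[length(codes)] <- eoi  # replace trailing clear
  pack_codes(codes, 9L)
}

#' Write frames as an animated grayscale GIF
#'
#' Frames are numeric matrices in `[0, 1]`, quantised to 256 grey levels;
#' values already on the 1/255 grid round-trip losslessly through
#' [read_gif()].
#'
#' @param frames List of numeric matrices with identical dimensions.
#' @param path Output path.
#' @param delay_cs Per-frame delay in centiseconds (scalar or per-frame).
#' @param loop Loop count for the animation (0 = forever) or `NA` for a
#'   single pass without a loop block.
#' @return `path`, invisibly.
#' @export
write_gif <- function(frames, path, delay_cs = 10, loop = 0L) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  dims <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("all frames must share the same dimensions")
  h <- dims[1L]; w <- dims[2L]
  delay_cs <- rep_len(as.integer(delay_cs), length(frames))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  writeBin(c(u16(w), u16(h), as.raw(0xF7), as.raw(0L), as.raw(0L)), con)
  writeBin(as.raw(rep(0:255, each = 3L)), con)  # grayscale palette
  if (!is.na(loop)) {
    writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
               as.raw(c(0x03, 0x01)), u16(as.integer(loop)), as.raw(0L)),
             con)
  }
  for (i in seq_along(frames)) {
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x00)), u16(delay_cs[i]),
               as.raw(c(0x00, 0x00))), con)
    writeBin(c(as.raw(0x2C), u16(0L), u16(0L), u16(w), u16(h),
               as.raw(0L), as.raw(8L)), con)
    idx <- as.integer(round(pmin(pmax(t(frames[[i]]), 0), 1) * 255))
    writeBin(sub_blocks(encode_frame_lzw(as.vector(idx))), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}

decode_lzw <- function(bytes, min_code_size) {
  clear <- bitwShiftL(1L, min_code_size)
  eoi <- clear + 1L
  bits <- as.integer(rawToBits(bytes))
  pos <- 1L
  width <- min_code_size + 1L
  weights <- bitwShiftL(1L, 0:11)
  dict <- vector("list", 4096L)
  reset <- function() {
    for (i in seq_len(clear)) dict[[i]] <<- i - 1L
    next_code <<- eoi + 1L
    width <<- min_code_size + 1L
  }
  next_code <- 0L
  reset()
  out <- vector("list", 4096L)
  n_out <- 0L
  prev <- NULL
  repeat {
    if (pos + width - 1L > length(bits)) break
    code <- sum(bits[pos:(pos + width - 1L)] * weights[1:width])
    pos <- pos + width
    if (code == clear) {
      reset()
      prev <- NULL
      next
    }
    if (code == eoi) break
    if (code < next_code && !is.null(dict[[code + 1L]])) {
      entry <- dict[[code + 1L]]
      if (!is.null(prev)) {
        dict[[next_code + 1L]] <- c(prev, entry[1L])
        next_code <- next_code + 1L
      }
    } else if (!is.null(prev)) {
      entry <- c(prev, prev[1L])
      dict[[next_code + 1L]] <- entry
      next_code <- next_code + 1L
    } else stop("corrupt LZW stream")
    n_out <- n_out + 1L
    out[[n_out]] <- entry
    prev <- entry
    if (next_code >= bitwShiftL(1L, width) && width < 12L)
      width <- width + 1L
  }
  unlist(out[seq_len(n_out)], use.names = FALSE)
}

#' Read an animated grayscale GIF written by [write_gif()]
#'
#' @param path File path.
#' @return List with `frames` (numeric matrices in `[0, 1]`) and
#'   `delay_cs` (per-frame delays).
#' @export
read_gif <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (rawToChar(bytes[1:6]) != "GIF89a") stop("not a GIF89a file")
  w <- as.integer(bytes[7]) + 256L * as.integer(bytes[8])
  h <- as.integer(bytes[9]) + 256L * as.integer(bytes[10])
  flags <- as.integer(bytes[11])
  pos <- 14L
  palette <- NULL
  if (bitwAnd(flags, 0x80L) > 0L) {
    gct_size <- 3L * bitwShiftL(2L, bitwAnd(flags, 7L))
    palette <- matrix(as.integer(bytes[pos:(pos + gct_size - 1L)]),
                      ncol = 3L, byrow = TRUE)
    pos <- pos + gct_size
  }
  frames <- list()
  delays <- integer(0)
  cur_delay <- 0L
  skip_blocks <- function(p) {
    while ((sz <- as.integer(bytes[p])) != 0L) p <- p + sz + 1L
    p + 1L
  }
  repeat {
    marker <- as.integer(bytes[pos])
    if (marker == 0x3BL || pos > length(bytes)) break
    if (marker == 0x21L) {               # extension
      label <- as.integer(bytes[pos + 1L])
      p <- pos + 2L
      if (label == 0xF9L) {
        sz <- as.integer(bytes[p])
        cur_delay <- as.integer(bytes[p + 2L]) +
          256L * as.integer(bytes[p + 3L])
      }
      pos <- skip_blocks(p)
    } else if (marker == 0x2CL) {        # image descriptor
      iw <- as.integer(bytes[pos + 5L]) + 256L * as.integer(bytes[pos + 6L])
      ih <- as.integer(bytes[pos + 7L]) + 256L * as.integer(bytes[pos + 8L])
      lflags <- as.integer(bytes[pos + 9L])
      p <- pos + 10L
      if (bitwAnd(lflags, 0x80L) > 0L)
        p <- p + 3L * bitwShiftL(2L, bitwAnd(lflags, 7L))
      mcs <- as.integer(bytes[p])
      p <- p + 1L
      data <- raw(0)
      while ((sz <- as.integer(bytes[p])) != 0L) {
        data <- c(data, bytes[(p + 1L):(p + sz)])
        p <- p + sz + 1L
      }
      pos <- p + 1L
      idx <- decode_lzw(data, mcs)
      if (length(idx) != iw * ih) stop("frame pixel count mismatch")
      grey <- palette[idx + 1L, 1L] / 255
      frames[[length(frames) + 1L]] <- t(matrix(grey, nrow = iw))
      delays <- c(delays, cur_delay)
    } else stop(sprintf("unexpected GIF block 0x%02X", marker))
  }
  list(frames = frames, delay_cs = delays)
}

#' Export a frame stack as an animated GIF
#'
#' @param frames List of numeric matrices in `[0, 1]` (or a
#'   `proxy_frames` object); at least two frames.
#' @param path Output path.
#' @param frame_rate Frames per second; the per-frame delay becomes
#'   `round(100 / frame_rate)` centiseconds.
#' @return `path`, invisibly.
#' @export
export_animation <- function(frames, path, frame_rate = 100) {
  if (inherits(frames, "proxy_frames")) frames <- frames$frames
  if (!is.list(frames) || length(frames) < 2L)
    stop("an animation needs at least two frames")
  write_gif(frames, path, delay_cs = max(1L, round(100 / frame_rate)))
}
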