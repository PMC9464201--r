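# Minimal uncompressed RIFF/AVI codec.
#
# No installed package handles AVI containers, so the package carries its own
# reader/writer for the uncompressed (BI_RGB) subset it emits: 8-bit paletted
# grayscale or 24-bit RGB device-independent bitmap frames in '00db' chunks,
# with a standard 'hdrl' header and 'idx1' index. Pixel data are quantized to
# 8 bits per channel at write time; after that the round trip is bit-exact.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
fourcc <- function(s) charToRaw(s)

riff_chunk <- function(id, payload) {
  pad <- if (length(payload) %% 2L == 1L) as.raw(0) else raw(0)
  c(fourcc(id), u32(length(payload)), payload, pad)
}
riff_list <- function(type, payload) riff_chunk("LIST", c(fourcc(type), payload))

#' Write a video clip to an uncompressed AVI file
#'
#' Frames are quantized to 8 bits per channel and stored without compression
#' (grayscale clips as paletted 8-bit DIBs, RGB clips as 24-bit DIBs), so a
#' subsequent [read_video()] recovers the written pixel values exactly.
#'
#' @param clip a [video_clip()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_video()]
#' @export
write_video <- function(clip, path) {
  stopifnot(inherits(clip, "video_clip"))
  rgb <- clip$channel_tag == "rgb"
  d <- dim(clip$frames)
  h <- d[1]; w <- d[2]; nt <- d[length(d)]
  bpp <- if (rgb) 3L else 1L
  stride <- as.integer(ceiling(w * bpp / 4) * 4)
  frame_bytes <- stride * h

  # stream format: BITMAPINFOHEADER (+ gray palette for 8-bit)
  strf <- c(u32(40L), u32(w), u32(h), u16(1L), u16(8L * bpp), u32(0L),
            u32(frame_bytes), u32(0L), u32(0L),
            u32(if (rgb) 0L else 256L), u32(0L))
  if (!rgb)
    strf <- c(strf, as.raw(rbind(0:255, 0:255, 0:255, 0L)))

  scale <- 1000L
  rate <- as.integer(round(clip$fps * scale))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0L), u16(0L), u16(0L),
            u32(0L), u32(scale), u32(rate), u32(0L), u32(nt),
            u32(frame_bytes), u32(-1L), u32(0L),
            u16(0L), u16(0L), u16(w), u16(h))
  avih <- c(u32(as.integer(round(1e6 / clip$fps))),
            u32(frame_bytes * as.integer(round(clip$fps))), u32(0L),
            u32(0x10L),  # AVIF_HASINDEX
            u32(nt), u32(0L), u32(1L), u32(frame_bytes),
            u32(w), u32(h), u32(0L), u32(0L), u32(0L), u32(0L))
  hdrl <- riff_list("hdrl", c(riff_chunk("avih", avih),
                              riff_list("strl", c(riff_chunk("strh", strh),
                                                  riff_chunk("strf", strf)))))

  q <- function(m) {
    v <- round(pmin(pmax(m, 0), 1) * 255)
    storage.mode(v) <- "integer"  # keep dims
    v
  }
  enc_frame <- function(i) {
    out <- matrix(as.raw(0), nrow = stride, ncol = h)
    if (rgb) {
      fr <- clip$frames[, , , i]
      # bottom-up rows, B G R byte order
      px <- array(0L, c(3L, w, h))
      px[1, , ] <- t(q(fr[h:1, , 3]))
      px[2, , ] <- t(q(fr[h:1, , 2]))
      px[3, , ] <- t(q(fr[h:1, , 1]))
      out[seq_len(3L * w), ] <- as.raw(px)
    } else {
      out[seq_len(w), ] <- as.raw(t(q(clip$frames[h:1, , i])))
    }
    as.vector(out)
  }

  frames_raw <- lapply(seq_len(nt), function(i) riff_chunk("00db", enc_frame(i)))
  movi <- riff_list("movi", do.call(c, frames_raw))

  # idx1 offsets count from the 'movi' fourcc position inside the LIST data
  sizes <- vapply(frames_raw, length, integer(1))
  offs <- 4L + c(0L, cumsum(sizes))[seq_len(nt)]
  idx <- do.call(c, lapply(seq_len(nt), function(i)
    c(fourcc("00db"), u32(0x10L), u32(offs[i]), u32(frame_bytes))))
  idx1 <- riff_chunk("idx1", idx)

  body <- c(fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

read_u32 <- function(r, at) {
  sum(as.integer(r[at:(at + 3)]) * c(1, 256, 65536, 16777216))
}
read_u16 <- function(r, at) sum(as.integer(r[at:(at + 1)]) * c(1, 256))

# walk a RIFF chunk sequence in r[from:to]; returns list of
# (id, type, data_from, data_to)
riff_walk <- function(r, from, to) {
  out <- list(); at <- from
  while (at + 7 <= to) {
    id <- rawToChar(r[at:(at + 3)])
    sz <- read_u32(r, at + 4)
    dat_from <- at + 8
    type <- if (id == "LIST" && sz >= 4) rawToChar(r[dat_from:(dat_from + 3)])
            else NA_character_
    out[[length(out) + 1L]] <- list(id = id, type = type,
                                    from = dat_from, to = dat_from + sz - 1)
    at <- dat_from + sz + (sz %% 2)
  }
  out
}

#' Read a video clip from an AVI file
#'
#' Supports the uncompressed AVI subset written by [write_video()] (8-bit
#' paletted or 24-bit BI_RGB frames). Intensities are normalized to
#' `[0, 1]` and the frame rate is taken from the stream header.
#'
#' @param path path to an AVI file.
#' @return a [video_clip()]; 24-bit files give an `"rgb"` clip, 8-bit files a
#'   `"grayscale"` clip.
#' @export
read_video <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop_aquacol(sprintf("cannot read video file '%s'", path),
                 "aquacol_io_error")
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 12 || rawToChar(r[1:4]) != "RIFF" ||
      rawToChar(r[9:12]) != "AVI ")
    stop_aquacol(sprintf("'%s' is not an AVI file", path), "aquacol_io_error")

  top <- riff_walk(r, 13L, length(r))
  hdrl <- Filter(function(ch) identical(ch$type, "hdrl"), top)
  movi <- Filter(function(ch) identical(ch$type, "movi"), top)
  if (length(hdrl) == 0 || length(movi) == 0)
    stop_aquacol("AVI is missing hdrl or movi lists", "aquacol_io_error")

  hd <- riff_walk(r, hdrl[[1]]$from + 4L, hdrl[[1]]$to)
  strl <- Filter(function(ch) identical(ch$type, "strl"), hd)
  if (length(strl) == 0) stop_aquacol("AVI has no stream list", "aquacol_io_error")
  st <- riff_walk(r, strl[[1]]$from + 4L, strl[[1]]$to)
  strh <- Filter(function(ch) ch$id == "strh", st)[[1]]
  strf <- Filter(function(ch) ch$id == "strf", st)[[1]]

  if (rawToChar(r[strh$from:(strh$from + 3)]) != "vids")
    stop_aquacol("first AVI stream is not video", "aquacol_io_error")
  scale <- read_u32(r, strh$from + 20)
  rate <- read_u32(r, strh$from + 24)
  fps <- if (scale > 0) rate / scale else 30

  w <- read_u32(r, strf$from + 4)
  h <- read_u32(r, strf$from + 8)
  bitcount <- read_u16(r, strf$from + 14)
  compression <- read_u32(r, strf$from + 16)
  if (compression != 0 || !(bitcount %in% c(8L, 24L)))
    stop_aquacol("only uncompressed 8-bit or 24-bit AVI frames are supported",
                 "aquacol_io_error")
  palette <- NULL
  if (bitcount == 8L) {
    pal_at <- strf$from + 40
    palette <- as.integer(r[pal_at + 4 * (0:255) + 2])  # red entry
  }

  chunks <- riff_walk(r, movi[[1]]$from + 4L, movi[[1]]$to)
  fr_chunks <- Filter(function(ch) grepl("^..d[bc]$", ch$id), chunks)
  if (length(fr_chunks) == 0)
    stop_aquacol("AVI contains no frames", "aquacol_io_error")
  nt <- length(fr_chunks)
  bpp <- bitcount %/% 8L
  stride <- as.integer(ceiling(w * bpp / 4) * 4)

  if (bpp == 1L) {
    frames <- array(0, c(h, w, nt))
    for (i in seq_len(nt)) {
      dat <- as.integer(r[fr_chunks[[i]]$from:(fr_chunks[[i]]$from + stride * h - 1)])
      m <- matrix(dat, nrow = stride)[seq_len(w), , drop = FALSE]
      frames[, , i] <- matrix(palette[t(m) + 1L], h, w)[h:1, , drop = FALSE] / 255
    }
    clip <- video_clip(frames, fps, "grayscale")
  } else {
    frames <- array(0, c(h, w, 3, nt))
    for (i in seq_len(nt)) {
      dat <- as.integer(r[fr_chunks[[i]]$from:(fr_chunks[[i]]$from + stride * h - 1)])
      m <- matrix(dat, nrow = stride)  # columns are bottom-up rows
      for (ch in 1:3) {
        plane <- m[seq(4 - ch, by = 3, length.out = w), , drop = FALSE]
        frames[, , ch, i] <- t(plane)[h:1, , drop = FALSE] / 255
      }
    }
    clip <- video_clip(frames, fps, "rgb")
  }
  clip
}
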