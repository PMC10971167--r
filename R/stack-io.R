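#' Construct a TimeLapseStack
#'
#' Builds and validates a \linkS4class{TimeLapseStack} from a raw count
#' array. A 3-D \code{[t, y, x]} array is promoted to \code{[t, z=1, y, x]}.
#'
#' @param pixels numeric array, \code{[t, z, y, x]} or \code{[t, y, x]}.
#' @param timestamps frame times in seconds, strictly increasing.
#' @param pixelSizeUm micrometres per pixel (default 0.22955, i.e. 229.55
#'   nm/pixel at 100x magnification).
#' @param bitDepth camera bit depth (default 12).
#' @param irradiationTimeS irradiation time in seconds (default 1 s).
#' @return a validated \linkS4class{TimeLapseStack}.
#' @export
#' @examples
#' stk <- TimeLapseStack(array(100, c(4, 8, 8)), timestamps = 0:3,
#'                       irradiationTimeS = 1)
#' stk
TimeLapseStack <- function(pixels, timestamps, pixelSizeUm = 0.22955,
                           bitDepth = 12L, irradiationTimeS = 1) {
  d <- dim(pixels)
  if (length(d) == 3L) {
    pixels <- array(pixels, dim = c(d[1L], 1L, d[2L], d[3L]))
  } else if (length(d) != 4L) {
    stop("pixels must have 3 (t, y, x) or 4 (t, z, y, x) dimensions, got ",
         length(d))
  }
  storage.mode(pixels) <- "double"
  new("TimeLapseStack", pixels = pixels, timestamps = as.numeric(timestamps),
      pixelSizeUm = pixelSizeUm, bitDepth = as.integer(bitDepth),
      irradiationTimeS = irradiationTimeS)
}

#' Construct a FrameSeries
#'
#' @param frames numeric \code{[t, y, x]} array.
#' @param timestamps frame times in seconds.
#' @param provenance processing tag (default \code{"raw-MIP"}).
#' @param irradiationTimeS irradiation time in seconds.
#' @return a validated \linkS4class{FrameSeries}.
#' @export
FrameSeries <- function(frames, timestamps, provenance = "raw-MIP",
                        irradiationTimeS = 1) {
  new("FrameSeries", frames = frames, timestamps = as.numeric(timestamps),
      provenance = provenance, irradiationTimeS = irradiationTimeS)
}

#' Build the two-rate acquisition timebase
#'
#' Frame times for the acquisition schedule of the assay: an initial fast
#' phase (1 fps) resolving the rapid recruitment, then a slow phase (0.2 fps)
#' covering the withdrawal. The first \code{nFast} inter-frame intervals
#' equal \code{fastDtS}, the remaining intervals equal \code{slowDtS};
#' timestamps start at 0.
#'
#' @param nFast number of fast intervals (capped at \code{totalFrames - 1}).
#' @param fastDtS fast-phase frame interval, seconds (> 0).
#' @param slowDtS slow-phase frame interval, seconds (> 0).
#' @param totalFrames total number of frames.
#' @return numeric vector of \code{totalFrames} strictly increasing
#'   timestamps starting at 0.
#' @export
#' @examples
#' buildTimebase(3, 1, 5, 5)   # 0 1 2 3 8
buildTimebase <- function(nFast, fastDtS, slowDtS, totalFrames) {
  if (fastDtS <= 0 || slowDtS <= 0)
    stop("frame intervals must be positive")
  if (nFast > totalFrames)
    stop("nFast (", nFast, ") exceeds totalFrames (", totalFrames, ")")
  nInt <- totalFrames - 1L
  nF <- min(nFast, nInt)
  c(0, cumsum(c(rep(fastDtS, nF), rep(slowDtS, nInt - nF))))
}

#' Default 10-minute analysis timebase
#'
#' 1 fps for the first 120 s, then 0.2 fps, 217 frames covering 0-600 s.
#' The kinetic analysis window defaults to the first 10 minutes after
#' irradiation; full-length (35 min) movies are supported by building a
#' longer timebase.
#'
#' @return numeric timestamp vector (see \code{\link{buildTimebase}}).
#' @export
defaultTimebase <- function() {
  buildTimebase(120L, 1, 5, 217L)
}

#' Maximum-intensity projection of a stack
#'
#' Projects a \linkS4class{TimeLapseStack} along z: each output pixel is the
#' maximum over the z planes of that time point. Timestamps and irradiation
#' time are carried over.
#'
#' @param stack a \linkS4class{TimeLapseStack}.
#' @return a \linkS4class{FrameSeries} with provenance \code{"raw-MIP"}.
#' @export
maxProject <- function(stack) {
  stopifnot(is(stack, "TimeLapseStack"))
  px <- stack@pixels
  d <- dim(px)
  if (d[2L] == 1L) {
    frames <- array(px, dim = d[-2L])
  } else {
    frames <- array(0, dim = d[-2L])
    for (z in seq_len(d[2L]))
      frames <- pmax(frames, array(px[, z, , ], dim = d[-2L]))
  }
  FrameSeries(frames, stack@timestamps, provenance = "raw-MIP",
              irradiationTimeS = stack@irradiationTimeS)
}

#' Read a time-lapse stack from TIFF plus sidecar metadata
#'
#' Reads a multi-page TIFF written by \code{\link{writeStack}} (or any
#' t-major, z-minor page ordering) into the canonical \code{[t, z, y, x]}
#' layout. Pixel values are stored as 16-bit integers scaled by 65535, which
#' is exact for 12-bit camera counts. Metadata (timestamps or a frame-rate
#' schedule, pixel size, bit depth, irradiation time, z-plane count) come
#' from a list or a YAML sidecar file.
#'
#' @param path TIFF file path.
#' @param metadata a named list, or path to a YAML file, with elements
#'   \code{timestamps} (seconds) or \code{schedule} (list with \code{nFast},
#'   \code{fastDtS}, \code{slowDtS}), and optionally \code{nZ},
#'   \code{pixelSizeUm}, \code{bitDepth}, \code{irradiationTimeS}.
#' @return a validated \linkS4class{TimeLapseStack}.
#' @export
readStack <- function(path, metadata) {
  if (!file.exists(path))
    stop("cannot read stack: file not found: ", path)
  if (is.character(metadata))
    metadata <- yaml::read_yaml(metadata)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) round(p * 65535))
  nZ <- as.integer(metadata$nZ %||% 1L)
  nPages <- length(pages)
  if (nPages %% nZ != 0L)
    stop("page count (", nPages, ") is not a multiple of nZ (", nZ, ")")
  nT <- nPages %/% nZ
  ts <- metadata$timestamps
  if (is.null(ts)) {
    sch <- metadata$schedule
    if (is.null(sch))
      stop("metadata must supply timestamps or a frame-rate schedule")
    ts <- buildTimebase(sch$nFast, sch$fastDtS, sch$slowDtS, nT)
  }
  ts <- as.numeric(ts)
  if (length(ts) != nT)
    stop("metadata supplies ", length(ts), " timestamps for ", nT, " frames")
  if (any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing")
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  px <- array(0, dim = c(nT, nZ, ny, nx))
  k <- 0L
  for (t in seq_len(nT)) {
    for (z in seq_len(nZ)) {
      k <- k + 1L
      px[t, z, , ] <- pages[[k]]
    }
  }
  TimeLapseStack(
    px, ts,
    pixelSizeUm = metadata$pixelSizeUm %||% 0.22955,
    bitDepth = as.integer(metadata$bitDepth %||% 12L),
    irradiationTimeS = metadata$irradiationTimeS %||% 1
  )
}

#' Write a time-lapse stack as TIFF plus YAML metadata
#'
#' Pages are written t-major, z-minor; counts are stored as 16-bit integers
#' (exact round trip for intensities up to 65535). A YAML sidecar carries
#' timestamps, pixel size, bit depth, z-plane count and irradiation time.
#'
#' @param stack a \linkS4class{TimeLapseStack}.
#' @param path output TIFF path.
#' @param metadataPath output YAML path (default: \code{path} with a
#'   \code{.yaml} extension).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, metadataPath = NULL) {
  stopifnot(is(stack, "TimeLapseStack"))
  if (is.null(metadataPath))
    metadataPath <- paste0(sub("\\.[^.]+$", "", path), ".yaml")
  d <- dim(stack@pixels)
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (t in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      k <- k + 1L
      pages[[k]] <- matrix(stack@pixels[t, z, , ], d[3L], d[4L]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(
    timestamps = as.numeric(stack@timestamps),
    nZ = d[2L],
    pixelSizeUm = stack@pixelSizeUm,
    bitDepth = as.integer(stack@bitDepth),
    irradiationTimeS = stack@irradiationTimeS
  ), metadataPath)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
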