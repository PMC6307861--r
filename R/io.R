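#' Read a TIFF stack as a Movie
#'
#' Multi-page grayscale TIFF; plane order is acquisition order. For 4D
#' data pass \code{nz} in \code{metadata} and consecutive pages are
#' regrouped into z-stacks per timepoint. Intensities are returned as
#' stored.
#'
#' @param path TIFF file.
#' @param metadata named list: \code{pixelSizeXY}, \code{frameInterval}
#'   (required), optional \code{nz}, \code{voxelSizeZ}, \code{channelLabel},
#'   \code{embryoPositionEL}.
#' @return a \code{\linkS4class{Movie}}.
#' @export
readMovie <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("missing file: ", path)
  plain <- try(tiff::readTIFF(path, all = TRUE), silent = TRUE)
  if (inherits(plain, "try-error") || !length(plain))
    stop("unreadable stack: ", path)
  raw <- try(suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE)),
             silent = TRUE)
  # integer TIFFs: the raw (as.is) planes are the plain ones times the
  # sample depth; float TIFFs fail that relation and are taken as stored
  planes <- plain
  if (!inherits(raw, "try-error")) {
    for (s in c(255, 65535)) {
      if (max(abs(raw[[1]] - plain[[1]] * s)) < 1e-3 * s) {
        planes <- raw
        break
      }
    }
  }
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental RGB
    p
  })
  shp <- vapply(planes, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shp)) != 1L)
    stop("inconsistent plane shapes in ", path)
  ps <- metadata$pixelSizeXY %||% 0.1
  if (!isTRUE(ps > 0)) stop("non-positive pixel size")
  nz <- metadata$nz
  if (!is.null(nz) && nz > 1L) {
    if (length(planes) %% nz != 0L)
      stop("page count not a multiple of nz")
    nT <- length(planes) %/% nz
    frames <- lapply(seq_len(nT), function(t) {
      sub <- planes[((t - 1L) * nz + 1L):(t * nz)]
      array(unlist(sub), c(dim(sub[[1]]), nz))
    })
  } else {
    frames <- planes
  }
  methods::new("Movie", frames = frames, pixelSizeXY = ps,
               voxelSizeZ = metadata$voxelSizeZ %||% NA_real_,
               frameInterval = metadata$frameInterval %||% 1,
               channelLabel = metadata$channelLabel %||% "",
               embryoPositionEL = metadata$embryoPositionEL %||% NA_real_)
}

#' Write a Movie to a multi-page 16-bit TIFF
#'
#' Intensities are rounded to integer camera counts (range 0..65535; the
#' convention of 16-bit scientific CMOS data). 3D frames are unrolled
#' into consecutive z-pages (read back with \code{nz} metadata).
#'
#' @param movie a \code{\linkS4class{Movie}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMovie <- function(movie, path) {
  planes <- list()
  for (fr in frames(movie)) {
    if (length(dim(fr)) == 3L) {
      for (z in seq_len(dim(fr)[3])) planes[[length(planes) + 1L]] <- fr[, , z]
    } else {
      planes[[length(planes) + 1L]] <- fr
    }
  }
  planes <- lapply(planes, function(p) {
    p <- round(p)
    if (min(p) < 0 || max(p) > 65535)
      stop("intensities outside the 16-bit range 0..65535")
    p / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read trajectories from CSV
#'
#' The format is a plain CSV with columns \code{id}, \code{frame},
#' \code{x}, \code{y} (um) and optional \code{intensity}, preceded by
#' comment header lines of the form \code{# key: value} carrying
#' \code{frame_interval} and \code{exposure}.
#'
#' @param path CSV file.
#' @return a \code{\linkS4class{TrackSet}}.
#' @export
readTracks <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  d <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                    collapse = "\n"))
  if (anyDuplicated(d[, c("id", "frame")]))
    stop("duplicate (id, frame) rows")
  d <- d[order(d$id, d$frame), ]
  rownames(d) <- NULL
  methods::new("TrackSet", data = d,
               frameInterval = meta$frame_interval %||% 0.01,
               exposure = meta$exposure %||% meta$frame_interval %||% 0.01)
}

#' Write trajectories to CSV
#'
#' Inverse of \code{\link{readTracks}}; floats are written with 17
#' significant digits so a round-trip is bit-identical.
#'
#' @param tracks a \code{\linkS4class{TrackSet}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTracks <- function(tracks, path) {
  d <- trackData(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_interval: %.17g", tracks@frameInterval),
               sprintf("# exposure: %.17g", tracks@exposure)), con)
  cols <- intersect(c("id", "frame", "x", "y", "intensity"), names(d))
  dd <- d[, cols, drop = FALSE]
  for (cl in cols)
    if (is.double(dd[[cl]])) dd[[cl]] <- sprintf("%.17g", dd[[cl]])
  utils::write.csv(dd, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write FRAP traces
#'
#' Wide CSV: one row per frame, columns \code{bleach.1..}, \code{control.1..},
#' \code{dark.1..}; comment headers carry \code{frame_interval} and
#' \code{n_pre}.
#'
#' @param path CSV file.
#' @return a \code{\linkS4class{FrapExperiment}}.
#' @export
readFrapTraces <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  d <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                    collapse = "\n"))
  pick <- function(prefix)
    as.matrix(d[, grep(paste0("^", prefix, "\\."), names(d)), drop = FALSE])
  methods::new("FrapExperiment", bleach = pick("bleach"),
               control = pick("control"), dark = pick("dark"),
               frameInterval = meta$frame_interval %||% 0.024,
               nPre = as.integer(meta$n_pre %||% 10L),
               measurementRadius = meta$measurement_radius %||% 0.3)
}

#' @rdname readFrapTraces
#' @param exp a \code{\linkS4class{FrapExperiment}}.
#' @export
writeFrapTraces <- function(exp, path) {
  name <- function(prefix, m)
    `colnames<-`(m, paste(prefix, seq_len(ncol(m)), sep = "."))
  d <- cbind(name("bleach", exp@bleach), name("control", exp@control),
             name("dark", exp@dark))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_interval: %.17g", exp@frameInterval),
               sprintf("# n_pre: %d", exp@nPre),
               sprintf("# measurement_radius: %.17g",
                       exp@measurementRadius)), con)
  dd <- as.data.frame(d)
  for (cl in names(dd)) dd[[cl]] <- sprintf("%.17g", dd[[cl]])
  utils::write.csv(dd, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
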