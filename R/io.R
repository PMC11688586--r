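#' Image, dataset and report input/output
#'
#' Grayscale PNG (8-bit) and TIFF (8- or 16-bit) images with intensities
#' scaled by the container maximum; the on-disk dataset layout
#' \code{<root>/low/<id>.png}, \code{<root>/high/<id>.png} plus
#' \code{<root>/manifest.csv}; metric reports as per-pair CSV and aggregate
#' JSON.
#'
#' @name cli_io
NULL

collapseGray <- function(img, path) {
  if (length(dim(img)) == 2L) return(img)
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    rgb <- img[, , seq_len(min(ch, 3L)), drop = FALSE]
    mx <- apply(rgb, c(1, 2), max); mn <- apply(rgb, c(1, 2), min)
    if (max(mx - mn) > 1e-6)
      stop("multi-channel non-gray input: ", path)
    return(rgb[, , 1L])
  }
  stop("unreadable image dimensions in ", path)
}

#' Read a grayscale image
#'
#' Intensities are scaled by the container's maximum (255 or 65535) to
#' [0, 1]; the declared bit depth is attached as attribute
#' \code{"bitDepth"} so the PSNR convention (MAX_I from the container, not
#' from observed maxima) is reproducible. RGB files whose channels agree
#' are collapsed to one channel.
#'
#' @param path a PNG or TIFF file.
#' @return numeric matrix in [0, 1] with attribute \code{bitDepth}.
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else stop("unsupported image format: ", path)
  m <- collapseGray(img, path)
  attributes(m) <- list(dim = dim(m), bitDepth = as.integer(depth))
  m
}

#' Write a grayscale image
#'
#' Quantizes to the requested bit depth in a lossless container: PNG for
#' 8-bit, TIFF for 8- or 16-bit. Out-of-range input is an error unless
#' \code{clip} is set.
#'
#' @param image numeric matrix in [0, 1].
#' @param path output path (.png or .tif/.tiff).
#' @param bitDepth 8 or 16.
#' @param clip clip out-of-range values instead of failing.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(image, path, bitDepth = 8L, clip = FALSE) {
  if (min(image) < 0 || max(image) > 1) {
    if (!clip) stop(sprintf("image intensities outside [0,1] (range %.4g..%.4g); set clip = TRUE to clip",
                            min(image), max(image)))
    image <- pmin(pmax(image, 0), 1)
  }
  ext <- tolower(tools::file_ext(path))
  mx <- 2^bitDepth - 1
  q <- round(image * mx) / mx
  if (ext == "png") {
    if (bitDepth != 8L) stop("PNG output supports bitDepth = 8; use TIFF for 16-bit")
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bitDepth))
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write a paired dataset to the standard layout
#'
#' \code{<root>/low/<id>.<ext>}, \code{<root>/high/<id>.<ext>} and
#' \code{<root>/manifest.csv} with columns id, registered, split, lowPath,
#' highPath.
#'
#' @param pairs list of \linkS4class{ImagePair}.
#' @param root dataset directory (created if missing).
#' @param split optional character vector of split labels per pair.
#' @param bitDepth 8 (PNG) or 16 (TIFF).
#' @return the manifest data.frame, invisibly.
#' @export
writeDataset <- function(pairs, root, split = NULL, bitDepth = 8L) {
  ext <- if (bitDepth == 8L) "png" else "tif"
  dir.create(file.path(root, "low"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(root, "high"), showWarnings = FALSE, recursive = TRUE)
  if (is.null(split)) split <- rep("unassigned", length(pairs))
  man <- data.frame(
    id = vapply(pairs, function(p) p@id, character(1)),
    registered = vapply(pairs, function(p) p@registered, logical(1)),
    split = split,
    lowPath = vapply(pairs, function(p) file.path("low", paste0(p@id, ".", ext)),
                     character(1)),
    highPath = vapply(pairs, function(p) file.path("high", paste0(p@id, ".", ext)),
                      character(1)))
  for (i in seq_along(pairs)) {
    writeGrayImage(pairs[[i]]@low, file.path(root, man$lowPath[i]), bitDepth)
    writeGrayImage(pairs[[i]]@high, file.path(root, man$highPath[i]), bitDepth)
  }
  write.csv(man, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read and validate a dataset manifest
#'
#' Checks identifier uniqueness, the existence of every referenced file and
#' the split labels.
#'
#' @param root dataset directory containing \code{manifest.csv}.
#' @return the manifest data.frame.
#' @export
readManifest <- function(root) {
  path <- file.path(root, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", root)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "registered", "split", "lowPath", "highPath")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(man$id)) stop("duplicate identifiers in manifest")
  bad <- setdiff(man$split, c("train", "val", "test", "unassigned"))
  if (length(bad)) stop("unknown split labels: ", paste(bad, collapse = ", "))
  missing <- !file.exists(file.path(root, man$lowPath)) |
    !file.exists(file.path(root, man$highPath))
  if (any(missing))
    stop("missing image files for: ", paste(man$id[missing], collapse = ", "))
  man
}

#' Read a paired dataset from disk
#'
#' @param root dataset directory.
#' @param split optional label to filter on (e.g. \code{"test"}).
#' @return list with \code{pairs} (list of \linkS4class{ImagePair}) and
#'   \code{manifest}.
#' @export
readDataset <- function(root, split = NULL) {
  man <- readManifest(root)
  if (!is.null(split)) man <- man[man$split %in% split, , drop = FALSE]
  pairs <- lapply(seq_len(nrow(man)), function(i)
    ImagePair(id = man$id[i],
              low = readGrayImage(file.path(root, man$lowPath[i])),
              high = readGrayImage(file.path(root, man$highPath[i])),
              registered = man$registered[i]))
  list(pairs = pairs, manifest = man)
}

#' Write / read a metric report
#'
#' Per-pair values go to \code{<prefix>.csv}; the aggregate means, pair
#' count and PSNR-cap flag go to \code{<prefix>.json}.
#'
#' @param report a \linkS4class{MetricReport}.
#' @param prefix output path prefix.
#' @export
writeMetricReport <- function(report, prefix) {
  write.csv(report@perPair, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(means = as.list(report@means), n = report@n,
                            psnrCapped = report@psnrCapped),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeMetricReport
#' @param cfg \linkS4class{MetricConfig} supplying the PSNR cap when the
#'   aggregate means are recomputed.
#' @export
readMetricReport <- function(prefix, cfg = MetricConfig()) {
  perPair <- read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  capped <- any(is.infinite(perPair$psnr))
  means <- c(ssi = mean(perPair$ssi), lncc = mean(perPair$lncc),
             psnr = mean(pmin(perPair$psnr, cfg@psnrCap)),
             lpips = mean(perPair$lpips))
  new("MetricReport", perPair = perPair, means = means,
      n = nrow(perPair), psnrCapped = capped)
}
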