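#' Read a single-channel greyscale image
#'
#' Reads 8- or 16-bit single-channel TIFF or PNG into a [GreyImage-class],
#' preserving integer grey levels exactly. Multi-channel or floating-point
#' images are rejected with a hint to convert to single-channel greyscale
#' first.
#'
#' @param path path to a \code{.tif}, \code{.tiff} or \code{.png} file.
#' @return a [GreyImage-class].
#' @export
readGreyImage <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
        if (length(dim(x)) == 3L)
            stop("multi-channel TIFF: convert to single-channel greyscale ",
                 "before reading")
        bits <- attr(x, "bits.per.sample")
        if (is.null(bits)) bits <- if (max(x) > 255) 16L else 8L
        if (!bits %in% c(8L, 16L))
            stop("unsupported TIFF bit depth (", bits, "); use 8 or 16 bit")
        greyImage(x, as.integer(bits))
    } else if (ext == "png") {
        x <- png::readPNG(path, info = TRUE)
        if (length(dim(x)) == 3L)
            stop("multi-channel PNG: convert to single-channel greyscale ",
                 "before reading")
        info <- attr(x, "info")
        bits <- if (!is.null(info) && !is.null(info$bit.depth))
            as.integer(info$bit.depth) else 8L
        if (!bits %in% c(8L, 16L))
            stop("unsupported PNG bit depth (", bits, "); use 8 or 16 bit")
        greyImage(round(x * (2^bits - 1)), bits)
    } else {
        stop("unsupported image format '.", ext, "': use TIFF or PNG")
    }
}

#' Write a binary mask or label image
#'
#' Binary (logical) masks are written as 8-bit images with foreground 255
#' and background 0; integer label images as 16-bit (error beyond 65535
#' labels). TIFF or PNG is chosen from the file extension; both are
#' lossless.
#'
#' @param mask logical matrix, integer label matrix, or a
#'   [SegmentationResult-class] (its label image is written).
#' @param path output path ending in \code{.tif}, \code{.tiff} or
#'   \code{.png}.
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
    if (is(mask, "SegmentationResult")) mask <- mask@labels
    stopifnot(is.matrix(mask))
    if (is.logical(mask)) {
        norm <- matrix(ifelse(mask, 1, 0), nrow(mask), ncol(mask))
        bits <- 8L
    } else {
        if (max(mask) > 65535L) stop("more than 65535 labels")
        norm <- mask / 65535
        bits <- 16L
    }
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff"))
        tiff::writeTIFF(norm, path, bits.per.sample = bits)
    else if (ext == "png")
        png::writePNG(norm, path)
    else stop("unsupported image format '.", ext, "': use TIFF or PNG")
    invisible(path)
}

# read a label image back as an integer matrix
.readLabels <- function(path) {
    img <- readGreyImage(path)
    px <- img@pixels
    # 8-bit 0/255 binary masks become a single labelled class per component
    if (img@bitDepth == 8L && all(px %in% c(0L, 255L)))
        .label8(px > 0L) else px
}

#' Run configuration for the command-line interface
#'
#' Bundles every CLI-exposed parameter with its default: dark polarity,
#' Beucher gradient, average-gradient statistic, cumulative projection mode,
#' object specification (0.5, 250, 3000), Gaussian radius 0 and seed 0. A
#' configuration round-trips losslessly through a plain-text
#' \code{key = value} file.
#'
#' @param polarity \code{"dark"} or \code{"bright"}.
#' @param gradient \code{"beucher"} or \code{"sobel"}.
#' @param statistic \code{"average"} or \code{"total"}.
#' @param mode \code{"cumulative"} or \code{"stack"}.
#' @param minCircularity,minArea,maxArea object specification values.
#' @param gaussRadius Gaussian preprocessing radius.
#' @param seed integer seed.
#' @return named list of class \code{"gradsegConfig"}.
#' @export
runConfig <- function(polarity = "dark", gradient = "beucher",
                      statistic = "average", mode = "cumulative",
                      minCircularity = 0.5, minArea = 250, maxArea = 3000,
                      gaussRadius = 0, seed = 0L) {
    cfg <- list(polarity = match.arg(polarity, c("dark", "bright")),
                gradient = match.arg(gradient, c("beucher", "sobel")),
                statistic = match.arg(statistic, c("average", "total")),
                mode = match.arg(mode, c("cumulative", "stack")),
                minCircularity = as.numeric(minCircularity),
                minArea = as.numeric(minArea),
                maxArea = as.numeric(maxArea),
                gaussRadius = as.numeric(gaussRadius),
                seed = as.integer(seed))
    # reuse the ObjectSpec validity rules for the spec-valued fields
    objectSpec(cfg$minCircularity, cfg$minArea, cfg$maxArea)
    if (cfg$gaussRadius < 0) stop("'gaussRadius' must be >= 0")
    class(cfg) <- "gradsegConfig"
    cfg
}

#' @rdname runConfig
#' @param cfg a configuration from [runConfig()].
#' @param path file path for the \code{key = value} text representation.
#' @export
writeRunConfig <- function(cfg, path) {
    stopifnot(inherits(cfg, "gradsegConfig"))
    lines <- vapply(names(cfg), function(k)
        sprintf("%s = %s", k, format(cfg[[k]], digits = 17)), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE,
                  value = TRUE)
    kv <- strsplit(lines, "\\s*=\\s*")
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, `[`, character(1), 2L)
    keys <- trimws(keys); vals <- trimws(vals)
    args <- as.list(vals)
    names(args) <- keys
    num <- c("minCircularity", "minArea", "maxArea", "gaussRadius", "seed")
    for (k in intersect(num, keys)) args[[k]] <- as.numeric(args[[k]])
    do.call(runConfig, args)
}
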