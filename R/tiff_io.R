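#' Write a multi-channel voxel stack as multi-page TIFF
#'
#' Pages are channel-major (all z-slices of channel 1, then channel 2, ...),
#' stored as 32-bit samples after scaling into `[0, 1]` by a power-of-two
#' intensity scale (so re-writing a read stack re-quantizes every value to
#' itself). Acquisition metadata
#' (voxel size, channel roles, intensity scale, physical origin) is written
#' to a JSON header sidecar `<path>.meta.json`; x/y resolution TIFF tags are
#' set as well.
#'
#' @param img A `voxel_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  d <- dim(img$channels[[1]])
  # power-of-two scale: re-writing a read stack re-quantizes every value to
  # itself, so write -> read round trips are stable
  scale <- 2^ceiling(log2(max(1, max(vapply(img$channels, max,
                                            numeric(1))))))
  pages <- list()
  for (ch in seq_along(img$channels))
    for (z in seq_len(d[3]))
      pages[[length(pages) + 1]] <- img$channels[[ch]][, , z] / scale
  pages <- lapply(pages, function(p) {
    attr(p, "x.resolution") <- 1 / img$voxel_size[["x"]]
    attr(p, "y.resolution") <- 1 / img$voxel_size[["y"]]
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "LZW")
  meta <- list(voxel_size = as.list(img$voxel_size),
               shape = list(y = d[1], x = d[2], z = d[3]),
               n_channels = length(img$channels),
               channel_roles = img$channel_roles,
               intensity_scale = scale,
               origin = img$origin)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-channel voxel stack written by [write_stack()]
#'
#' Voxel size and channel layout are taken from the JSON header sidecar; if
#' it is absent both `voxel_size` and `expected_channel_roles` must be
#' supplied, otherwise reading fails. When `expected_channel_roles` is given
#' it is checked against the stack's channel count.
#'
#' @param path TIFF path.
#' @param expected_channel_roles Character vector of channel roles the caller
#'   expects (e.g. `c("paint1", "paint2", "dapi")`).
#' @param voxel_size Optional override, named `c(z=, y=, x=)` µm.
#' @return A `voxel_image`.
#' @export
read_stack <- function(path, expected_channel_roles = NULL, voxel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 1) stop("empty TIFF: ", path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    vox <- unlist(meta$voxel_size)[c("z", "y", "x")]
    n_ch <- meta$n_channels
    roles <- meta$channel_roles
    scale <- meta$intensity_scale
    origin <- meta$origin
  } else {
    if (is.null(voxel_size))
      stop("no metadata sidecar for ", path,
           ": voxel_size override is required")
    if (is.null(expected_channel_roles))
      stop("no metadata sidecar for ", path,
           ": expected_channel_roles is required to infer the channel count")
    vox <- voxel_size[c("z", "y", "x")]
    n_ch <- length(expected_channel_roles)
    roles <- expected_channel_roles
    scale <- 1
    origin <- c(0, 0, 0)
  }
  if (!is.null(voxel_size)) vox <- voxel_size[c("z", "y", "x")]
  if (length(pages) %% n_ch != 0)
    stop("page count ", length(pages), " is not divisible by ", n_ch,
         " channels")
  if (!is.null(expected_channel_roles) &&
      length(expected_channel_roles) != n_ch)
    stop("channel mismatch: stack has ", n_ch, " channels, expected ",
         length(expected_channel_roles))
  nz <- length(pages) %/% n_ch
  d <- dim(pages[[1]])
  channels <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    arr <- array(0, dim = c(d[1], d[2], nz))
    for (z in seq_len(nz)) arr[, , z] <- pages[[(ch - 1) * nz + z]] * scale
    channels[[ch]] <- arr
  }
  structure(list(channels = channels, voxel_size = vox,
                 origin = as.numeric(origin), channel_roles = roles),
            class = "voxel_image")
}

#' Write / read the ground-truth sidecar of a synthetic nucleus
#'
#' Serializes the planted geometry and pair truth of a `nucleus_spec` to
#' JSON: per territory the centerline, tube radius, bead count, stage and
#' analytic morphometry; per pair the configuration, association profile,
#' edge distance and proximity category.
#'
#' @param nucleus A `nucleus_spec`.
#' @param path JSON output path.
#' @export
write_ground_truth <- function(nucleus, path) {
  terr <- lapply(nucleus$territories, function(t) list(
    chromosome_id = t$chromosome_id, homolog = t$homolog,
    centerline = unname(t$centerline), tube_radius = t$tube_radius,
    width = t$width, length = t$length, slenderness = t$slenderness,
    bead_count = t$bead_count, stage = t$stage))
  pairs <- lapply(nucleus$pair_truth, function(pt)
    pt[c("chromosome_id", "configuration", "profile", "paired_fraction",
         "edge_distance", "touching", "scale_D", "proximity",
         "alignment_state", "slenderness", "bead_count", "width", "length")])
  jsonlite::write_json(list(territories = terr, pairs = pairs,
                            nuclear_radius = nucleus$nuclear_radius,
                            clustered = nucleus$clustered),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
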