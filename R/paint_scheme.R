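#' Paint scheme: map chromosome coordinate intervals to fluorophore channels
#'
#' A paint scheme describes how a whole-chromosome FISH paint probe assigns
#' fluorophores along the chromosome. Each segment covers an interval of the
#' normalized chromosome coordinate (0 = left end, 1 = right end) and lists
#' one or more channels (multiple channels model double-labeled regions such
#' as the chromosome ends of multicolor paints). Intervals must be
#' non-overlapping; uncovered intervals are unpainted (emit no paint signal).
#'
#' @param chromosome_id Character label, e.g. `"chrII"`.
#' @param segments List of `list(interval = c(a, b), channels = ints)` with
#'   `0 <= a < b <= 1`.
#' @param pc_end Which chromosome end carries the meiotic pairing center:
#'   `"left"` (coordinate 0) or `"right"` (coordinate 1).
#' @return An object of class `paint_scheme`.
#' @export
paint_scheme <- function(chromosome_id, segments, pc_end = c("left", "right")) {
  pc_end <- match.arg(pc_end)
  stopifnot(is.character(chromosome_id), length(chromosome_id) == 1,
            is.list(segments), length(segments) >= 1)
  iv <- t(vapply(segments, function(s) {
    stopifnot(is.numeric(s$interval), length(s$interval) == 2,
              s$interval[1] >= 0, s$interval[2] <= 1,
              s$interval[1] < s$interval[2],
              length(s$channels) >= 1, all(s$channels >= 1))
    s$interval
  }, numeric(2)))
  o <- order(iv[, 1])
  segments <- segments[o]
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-12))
    stop("paint segments must not overlap")
  structure(list(chromosome_id = chromosome_id, segments = segments,
                 pc_end = pc_end),
            class = "paint_scheme")
}

#' Channels active at given chromosome coordinates
#'
#' @param paint A [paint_scheme()].
#' @param u Numeric vector of coordinates in `[0, 1]`.
#' @return A list (per coordinate) of integer channel vectors; empty where
#'   the coordinate is unpainted.
#' @export
channels_at <- function(paint, u) {
  lapply(u, function(ui) {
    for (s in paint$segments)
      if (ui >= s$interval[1] - 1e-12 && ui <= s$interval[2] + 1e-12)
        return(as.integer(s$channels))
    integer(0)
  })
}

#' All channels used by a paint scheme
#' @param paint A [paint_scheme()].
#' @export
paint_channels <- function(paint) {
  sort(unique(unlist(lapply(paint$segments, `[[`, "channels"))))
}

#' Preset paint schemes
#'
#' Ready-made schemes mirroring the multicolor paints used for C. elegans
#' chromosome territory scoring:
#' \describe{
#'   \item{`chrII_thirds`}{three dyes over thirds of chromosome II, with both
#'     terminal 5% double-labeled by the dye of the opposite end so the two
#'     ends are distinguishable (channels 1--3), PC at the left end.}
#'   \item{`chrI_halves`}{left half channel 1, right half channel 2.}
#'   \item{`chrII_halves`}{left half channel 3, right half channel 4.}
#'   \item{`chrX_halves`}{left half channel 3, right half channel 4.}
#' }
#' Channel indices refer to paint channels of the rendered stack; the DAPI
#' channel is always appended last.
#'
#' @param name One of the preset names above.
#' @export
paint_scheme_preset <- function(name = c("chrII_thirds", "chrI_halves",
                                         "chrII_halves", "chrX_halves")) {
  name <- match.arg(name)
  switch(name,
    chrII_thirds = paint_scheme("chrII", list(
      list(interval = c(0, 0.05), channels = c(1L, 3L)),
      list(interval = c(0.05, 1 / 3), channels = 1L),
      list(interval = c(1 / 3, 2 / 3), channels = 2L),
      list(interval = c(2 / 3, 0.95), channels = 3L),
      list(interval = c(0.95, 1), channels = c(3L, 1L))), pc_end = "left"),
    chrI_halves = paint_scheme("chrI", list(
      list(interval = c(0, 0.5), channels = 1L),
      list(interval = c(0.5, 1), channels = 2L)), pc_end = "left"),
    chrII_halves = paint_scheme("chrII", list(
      list(interval = c(0, 0.5), channels = 3L),
      list(interval = c(0.5, 1), channels = 4L)), pc_end = "left"),
    chrX_halves = paint_scheme("chrX", list(
      list(interval = c(0, 0.5), channels = 3L),
      list(interval = c(0.5, 1), channels = 4L)), pc_end = "left"))
}

#' @export
print.paint_scheme <- function(x, ...) {
  cat("<paint_scheme>", x$chromosome_id, "PC end:", x$pc_end, "\n")
  for (s in x$segments)
    cat(sprintf("  [%.3f, %.3f] -> ch %s\n", s$interval[1], s$interval[2],
                paste(s$channels, collapse = "+")))
  invisible(x)
}
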