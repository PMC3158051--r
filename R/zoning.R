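#' Zone scheme for gonad subdivision
#'
#' `standard`: premeiotic = first `premeiotic_rows` rows from the distal
#' tip (default 10; 15 covers the wider premeiotic window used for the
#' proximity analysis); transition zone detected from chromatin clustering
#' and chromosome-I alignment; pachytene = a `pachytene_length`-row window
#' (15--20) beginning `pachytene_offset` rows proximal to the transition
#' zone end. `syp1_six_zone`: one premeiotic zone plus five meiotic zones
#' whose widths follow the N/5 rule of [split_meiotic_zones()].
#'
#' @param kind `"standard"` or `"syp1_six_zone"`.
#' @param premeiotic_rows Rows in the premeiotic zone.
#' @param pachytene_offset Rows between the transition-zone end and the
#'   pachytene window (default 5).
#' @param pachytene_length Pachytene window length in rows (default 15).
#' @param tz_clustered_frac Minimum clustered fraction for a
#'   transition-zone row (default 0.5).
#' @param tz_full_frac Chromosome-I full-alignment fraction above which a
#'   row is no longer transition zone (default 0.9).
#' @export
zone_scheme <- function(kind = c("standard", "syp1_six_zone"),
                        premeiotic_rows = 10L, pachytene_offset = 5L,
                        pachytene_length = 15L, tz_clustered_frac = 0.5,
                        tz_full_frac = 0.9) {
  kind <- match.arg(kind)
  stopifnot(premeiotic_rows >= 1, pachytene_length >= 1)
  structure(list(kind = kind, premeiotic_rows = as.integer(premeiotic_rows),
                 pachytene_offset = as.integer(pachytene_offset),
                 pachytene_length = as.integer(pachytene_length),
                 tz_clustered_frac = tz_clustered_frac,
                 tz_full_frac = tz_full_frac),
            class = "zone_scheme")
}

#' Widths of the five meiotic zones (N/5 rule)
#'
#' The meiotic region of N nucleus rows is divided into five zones: N/5 is
#' rounded to the nearest integer n (half away from zero); zones 2--5 get n
#' rows each and zone 6 gets the remaining N - 4n rows.
#'
#' @param N Total meiotic rows (>= 5).
#' @return Integer vector of five widths summing to N.
#' @export
split_meiotic_zones <- function(N) {
  stopifnot(length(N) == 1, N >= 5)
  n <- floor(N / 5 + 0.5)
  last <- N - 4 * n
  if (last < 0) stop("degenerate gonad: N - 4n < 0 for N = ", N)
  as.integer(c(n, n, n, n, last))
}

#' Assign gonad zones to nuclei
#'
#' Standard scheme: the premeiotic zone is the first `premeiotic_rows`
#' rows; the transition zone is the maximal contiguous run of subsequent
#' rows in which at least `tz_clustered_frac` of nuclei have clustered
#' chromatin and fewer than `tz_full_frac` have fully aligned chromosome I
#' territories; pachytene is a fixed window beginning
#' `pachytene_offset` rows after the transition zone ends. Rows captured by
#' no zone are labeled `"unzoned"`.
#'
#' Six-zone scheme: rows before the first clustered row are premeiotic;
#' the remaining (meiotic) rows are divided into zones 2--6 by
#' [split_meiotic_zones()].
#'
#' @param nuclei Data frame with columns `nucleus_id`, `row` (1-based from
#'   the distal tip), `clustered` (logical) and `chrI_state` (one of
#'   [alignment_levels()]).
#' @param scheme A [zone_scheme()].
#' @return The input with a `zone` column appended; the transition-zone row
#'   span is attached as attribute `"tz_span"` (NULL when empty).
#' @export
assign_zones <- function(nuclei, scheme = zone_scheme()) {
  stopifnot(all(c("nucleus_id", "row", "clustered", "chrI_state") %in%
                  names(nuclei)))
  rows <- sort(unique(nuclei$row))
  if (!all(diff(rows) == 1))
    stop("nucleus rows must be contiguous")
  by_row <- function(r) {
    sub <- nuclei[nuclei$row == r, ]
    c(clustered = mean(sub$clustered),
      full = mean(sub$chrI_state == "full"))
  }
  stats_rows <- t(vapply(rows, by_row, numeric(2)))
  tz_candidate <- stats_rows[, "clustered"] >= scheme$tz_clustered_frac &
    stats_rows[, "full"] < scheme$tz_full_frac
  if (scheme$kind == "syp1_six_zone") {
    first_meiotic <- which(tz_candidate & rows > 1)[1]
    if (is.na(first_meiotic))
      stop("no meiotic (clustered) rows found for the six-zone scheme")
    start_row <- rows[first_meiotic]
    N <- max(rows) - start_row + 1
    widths <- split_meiotic_zones(N)
    bounds <- start_row + cumsum(c(0, widths))
    zone <- rep("premeiotic", nrow(nuclei))
    for (zi in 1:5) {
      sel <- nuclei$row >= bounds[zi] & nuclei$row < bounds[zi + 1]
      zone[sel] <- paste0("zone", zi + 1)
    }
    nuclei$zone <- zone
    attr(nuclei, "tz_span") <- NULL
    attr(nuclei, "meiotic_start") <- start_row
    return(nuclei)
  }
  pm <- scheme$premeiotic_rows
  cand <- tz_candidate & rows > pm
  # maximal contiguous candidate run (longest; earliest on ties)
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  true_runs <- which(r$values)
  tz <- NULL
  if (length(true_runs) > 0) {
    lens <- r$lengths[true_runs]
    pick <- true_runs[which.max(lens)]
    tz <- c(rows[starts[pick]], rows[ends[pick]])
  }
  zone <- rep("unzoned", nrow(nuclei))
  zone[nuclei$row <= pm] <- "premeiotic"
  if (!is.null(tz)) {
    zone[nuclei$row >= tz[1] & nuclei$row <= tz[2]] <- "transition"
    pa_start <- tz[2] + scheme$pachytene_offset
    pa_end <- pa_start + scheme$pachytene_length - 1
    zone[nuclei$row >= pa_start & nuclei$row <= pa_end &
           zone == "unzoned"] <- "pachytene"
  }
  nuclei$zone <- zone
  attr(nuclei, "tz_span") <- tz
  nuclei
}

#' Joint alignment-state matrix for two chromosomes
#'
#' Cross-tabulates per-nucleus alignment states of two chromosomes into the
#' nine-category matrix (unaligned / partial / full for each chromosome).
#'
#' @param statesA,statesB Character vectors of [alignment_levels()] per
#'   nucleus.
#' @export
joint_alignment_matrix <- function(statesA, statesB) {
  lv <- alignment_levels()
  stopifnot(all(statesA %in% lv), all(statesB %in% lv),
            length(statesA) == length(statesB))
  table(A = factor(statesA, levels = lv), B = factor(statesB, levels = lv))
}

#' Zone-level summary tables of morphometry and alignment
#'
#' Per zone (with transition-zone nuclei stratified into fully aligned,
#' "TZ Full", and not-fully aligned, "TZ NF"), chromosome and genotype:
#' mean and SD of painted-segment counts, percentage of highly extended
#' territories with its standard error, and the full-alignment percentage.
#' Empty strata are absent from the output rather than reported as zero.
#'
#' @param records Data frame joining per-territory morphometry with the
#'   per-pair alignment state and per-nucleus zone: columns
#'   `zone`, `genotype`, `chromosome_id`, `segment_count_k`,
#'   `highly_extended`, `alignment_state`.
#' @return List of data frames `segments`, `extension`, `alignment`.
#' @export
summarize_zone_metrics <- function(records) {
  req <- c("zone", "genotype", "chromosome_id", "segment_count_k",
           "highly_extended", "alignment_state")
  stopifnot(all(req %in% names(records)))
  records$stratum <- ifelse(
    records$zone == "transition",
    ifelse(records$alignment_state == "full", "TZ Full", "TZ NF"),
    records$zone)
  grp <- interaction(records$stratum, records$chromosome_id,
                     records$genotype, drop = TRUE)
  seg <- do.call(rbind, lapply(split(records, grp), function(g) data.frame(
    stratum = g$stratum[1], chromosome_id = g$chromosome_id[1],
    genotype = g$genotype[1], n = nrow(g),
    mean_k = mean(g$segment_count_k), sd_k = sd(g$segment_count_k),
    stringsAsFactors = FALSE)))
  ext <- do.call(rbind, lapply(split(records, grp), function(g) {
    p <- mean(g$highly_extended)
    data.frame(
      stratum = g$stratum[1], chromosome_id = g$chromosome_id[1],
      genotype = g$genotype[1], n = nrow(g),
      pct_highly_extended = 100 * p,
      sem = 100 * sqrt(p * (1 - p) / nrow(g)),
      stringsAsFactors = FALSE)
  }))
  ali <- do.call(rbind, lapply(split(records, grp), function(g) data.frame(
    stratum = g$stratum[1], chromosome_id = g$chromosome_id[1],
    genotype = g$genotype[1], n = nrow(g),
    pct_full_alignment = 100 * mean(g$alignment_state == "full"),
    stringsAsFactors = FALSE)))
  rownames(seg) <- rownames(ext) <- rownames(ali) <- NULL
  list(segments = seg, extension = ext, alignment = ali)
}
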