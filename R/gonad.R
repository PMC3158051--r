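# Whole-gonad synthesis: row-organized nuclei whose planted morphologies and
# pairing states follow the stereotyped distal-to-proximal progression
# (compact premeiotic ovoids -> clustered transition-zone nuclei with a
# mixture of alignment states and elongating territories -> mostly
# fully-aligned pachytene nuclei), with per-genotype modifications.

#' Per-genotype planting parameters
#'
#' Probabilities and morphology settings the gonad generator uses per zone
#' and chromosome. `config_probs` are sampling weights over configurations;
#' `p_extended` is the probability that a transition-zone territory is
#' planted highly extended (analytic slenderness above 6); `beads` gives
#' the planted bead-count range per zone.
#'
#' @param scenario One of `"wildtype"`, `"syp1"`, `"him8e1489"`,
#'   `"him8me4"`, `"meDf2"`.
#' @export
scenario_params <- function(scenario = c("wildtype", "syp1", "him8e1489",
                                         "him8me4", "meDf2")) {
  scenario <- match.arg(scenario)
  wt_tz <- c("no_contact" = 0.25, "V-PC" = 0.12, "Y-PC" = 0.10,
             "V-NPC" = 0.03, "X" = 0.03, "O" = 0.04, "no_alignment" = 0.03,
             "full" = 0.40)
  wt_pa <- c("full" = 0.95, "Y-PC" = 0.05)
  noalign_tz <- c("no_contact" = 0.70, "no_alignment" = 0.10,
                  "V-PC" = 0.10, "Y-PC" = 0.10)
  base <- list(
    premeiotic = list(config_probs = c("random" = 1), p_extended = 0,
                      beads = c(1L, 1L), slenderness = c(1.3, 2.2)),
    transition = list(config_probs = wt_tz, p_extended = 0.5,
                      beads = c(2L, 4L), slenderness_ext = c(6.5, 8.5),
                      slenderness_cmp = c(2, 4.5)),
    pachytene = list(config_probs = wt_pa, p_extended = 0.6,
                     beads = c(3L, 5L), slenderness_ext = c(7, 9),
                     slenderness_cmp = c(3, 5)))
  out <- list(genotype = scenario, zones = base, per_chromosome = list())
  if (scenario == "syp1") {
    # no synapsis: configurations shift from PC-end contact to asynaptic
    # full alignment along the meiotic zones, never stabilizing completely
    out$zones$meiotic <- list(
      zone2 = c("no_contact" = 0.40, "V-PC" = 0.25, "Y-PC" = 0.08,
                "V-NPC" = 0.05, "X" = 0.04, "O" = 0.04,
                "no_alignment" = 0.04, "full" = 0.10),
      zone3 = c("no_contact" = 0.28, "V-PC" = 0.28, "Y-PC" = 0.10,
                "V-NPC" = 0.05, "X" = 0.03, "O" = 0.04,
                "no_alignment" = 0.04, "full" = 0.18),
      zone4 = c("no_contact" = 0.20, "V-PC" = 0.27, "Y-PC" = 0.10,
                "V-NPC" = 0.04, "X" = 0.03, "O" = 0.04,
                "no_alignment" = 0.04, "full" = 0.28),
      zone5 = c("no_contact" = 0.15, "V-PC" = 0.25, "Y-PC" = 0.08,
                "V-NPC" = 0.04, "X" = 0.03, "O" = 0.04,
                "no_alignment" = 0.03, "full" = 0.38),
      zone6 = c("no_contact" = 0.15, "V-PC" = 0.22, "Y-PC" = 0.07,
                "V-NPC" = 0.03, "X" = 0.03, "O" = 0.04,
                "no_alignment" = 0.03, "full" = 0.43))
  }
  if (scenario %in% c("him8e1489", "him8me4", "meDf2")) {
    # X chromosomes fail to align in all three; elongation fails in
    # him-8(e1489) and (as full extension) in the PC-deletion
    x_ext <- if (scenario == "him8me4") 0.27 else 0.05
    out$per_chromosome$chrX <- list(
      transition = list(config_probs = noalign_tz, p_extended = x_ext,
                        beads = if (scenario == "him8e1489") c(1L, 2L)
                                else c(2L, 4L),
                        slenderness_ext = c(6.5, 8.5),
                        slenderness_cmp = c(1.5, 4)),
      pachytene = list(config_probs = noalign_tz, p_extended = x_ext,
                       beads = if (scenario == "him8e1489") c(1L, 2L)
                               else c(3L, 4L),
                       slenderness_ext = c(6.5, 8.5),
                       slenderness_cmp = c(1.5, 4.5)))
  }
  out
}

zone_of_row <- function(row, rows) {
  bounds <- cumsum(rows)
  nm <- names(rows)
  nm[which(row <= bounds)[1]]
}

sample_config <- function(probs) {
  sample(names(probs), 1, prob = probs)
}

#' Generate a ground-truthed synthetic gonad
#'
#' Lays out nuclei in rows from the distal tip and realizes each nucleus's
#' geometry with planted zones: compact unconstrained premeiotic nuclei,
#' clustered transition-zone nuclei with mixed chromosome-I alignment
#' states, and mostly fully aligned pachytene nuclei. For the `syp1`
#' scenario the meiotic region is planted with the six-zone configuration
#' gradient instead.
#'
#' @param scenario See [scenario_params()].
#' @param rows Named rows per zone. Standard scenarios:
#'   `c(premeiotic = 10, transition = 11, pachytene = 15)`. For `syp1`:
#'   `c(premeiotic = 8, meiotic = 27)`.
#' @param nuclei_per_row Nuclei per row (default 3).
#' @param paints List of [paint_scheme()] (one homolog pair is planted per
#'   scheme per nucleus).
#' @param nuclear_radius µm, default 2.
#' @param seed Integer seed.
#' @return A `gonad` object: `layout` data frame (nucleus_id, row,
#'   zone_planted, genotype, clustered, per-chromosome planted
#'   configuration and alignment state) and `nuclei` (list of
#'   `nucleus_spec`).
#' @export
generate_gonad <- function(scenario = "wildtype",
                           rows = NULL, nuclei_per_row = 3L,
                           paints = list(paint_scheme_preset("chrI_halves")),
                           nuclear_radius = 2, seed = 1L) {
  par <- scenario_params(scenario)
  if (is.null(rows))
    rows <- if (scenario == "syp1") c(premeiotic = 8L, meiotic = 27L)
            else c(premeiotic = 10L, transition = 11L, pachytene = 15L)
  if (any(rows < 1)) stop("each requested zone needs at least one row")
  if (nuclei_per_row < 1) stop("empty layout: no nuclei requested")
  n_rows <- sum(rows)
  meiotic_widths <- if (scenario == "syp1")
    split_meiotic_zones(rows[["meiotic"]]) else NULL
  layout <- list()
  nuclei <- list()
  with_seed(seed, {
    nid <- 0L
    for (row in seq_len(n_rows)) {
      zone <- zone_of_row(row, rows)
      zone_label <- zone
      if (scenario == "syp1" && zone == "meiotic") {
        mrow <- row - rows[["premeiotic"]]
        zi <- which(mrow <= cumsum(meiotic_widths))[1]
        zone_label <- paste0("zone", zi + 1)
      }
      for (j in seq_len(nuclei_per_row)) {
        nid <- nid + 1L
        nseed <- child_seed(seed, row, j)
        clustered <- zone_label %in%
          c("transition", "zone2", "zone3", "zone4", "zone5", "zone6")
        # syp-1 nuclei stay clustered through an extended region; taper off
        if (scenario == "syp1" && zone_label %in% c("zone5", "zone6"))
          clustered <- runif(1) < 0.6
        pairs <- list()
        pl_cfg <- character(length(paints))
        for (ci in seq_along(paints)) {
          p <- paints[[ci]]
          zp <- par$per_chromosome[[p$chromosome_id]][[zone]] %||%
            (if (scenario == "syp1" && zone == "meiotic")
               list(config_probs = par$zones$meiotic[[zone_label]],
                    p_extended = 0.5, beads = c(2L, 4L),
                    slenderness_ext = c(6.5, 8.5),
                    slenderness_cmp = c(2, 4.5))
             else par$zones[[zone]])
          cfg <- sample_config(zp$config_probs)
          pl_cfg[ci] <- cfg
          extended_zone <- !(zone == "premeiotic")
          ext <- extended_zone && runif(1) < zp$p_extended
          sl <- if (!extended_zone)
            runif(1, zp$slenderness[1], zp$slenderness[2])
          else if (ext) runif(1, zp$slenderness_ext[1], zp$slenderness_ext[2])
          else runif(1, zp$slenderness_cmp[1], zp$slenderness_cmp[2])
          pairs[[ci]] <- list(
            paint = p, configuration = cfg,
            stage = if (extended_zone) "extended" else "compact",
            target_slenderness = sl,
            bead_count = sample(zp$beads[1]:zp$beads[2], 1))
        }
        nuc <- generate_nucleus(pairs, nuclear_radius = nuclear_radius,
                                clustered = clustered, seed = nseed)
        nuclei[[nid]] <- nuc
        layout[[nid]] <- data.frame(
          nucleus_id = sprintf("n%04d", nid), row = row,
          zone_planted = zone_label, genotype = par$genotype,
          clustered = clustered,
          chromosome_id = vapply(paints, function(p) p$chromosome_id,
                                 character(1)),
          configuration_planted = pl_cfg,
          alignment_planted = vapply(nuc$pair_truth, function(pt)
            pt$alignment_state, character(1)),
          stringsAsFactors = FALSE)
      }
    }
  })
  structure(list(layout = do.call(rbind, layout), nuclei = nuclei,
                 scenario = scenario, rows = rows, seed = seed,
                 nuclei_per_row = nuclei_per_row),
            class = "gonad")
}

#' @export
print.gonad <- function(x, ...) {
  cat(sprintf("<gonad> %s: %d nuclei in %d rows (%s)\n", x$scenario,
              length(x$nuclei), sum(x$rows),
              paste(names(x$rows), x$rows, sep = "=", collapse = ", ")))
  invisible(x)
}
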