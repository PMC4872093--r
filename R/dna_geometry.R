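# DNA deformation geometry: helical axis, bend angle, groove widths,
# flipped-base detection.

bp_midpoints <- function(model, frame) {
  positions <- sort(unique(frame$position))
  mids <- t(vapply(positions, function(p) {
    top <- frame_residue(frame, p, "top")
    bot <- frame_residue(frame, p, "bottom")
    c1 <- rbind(
      if (!is.null(top)) atom_coords(model, top$chain, top$resno, top$ins,
                                     "C1'"),
      if (!is.null(bot)) atom_coords(model, bot$chain, bot$resno, bot$ins,
                                     "C1'"))
    if (is.null(c1) || nrow(c1) == 0) rep(NA_real_, 3) else colMeans(c1)
  }, numeric(3)))
  list(positions = positions, xyz = mids)
}

fit_line_direction <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, direction = sv$v[, 1])
}

#' Fit a smoothed helical axis
#'
#' One axis point per base-pair step, obtained by projecting the raw step
#' midpoint onto a least-squares 3D line fitted to the C1'-midpoints of a
#' window of base pairs around the step. Using C1' midpoints makes the fit
#' robust to a flipped-out base (whose sugar stays in the helix).
#'
#' @param model a `StructureModel`
#' @param frame a `TargetFrame`
#' @param window number of base pairs per line-fit window (default 5)
#' @return data.frame: step (index), pos_before, pos_after, x, y, z
#' @export
fit_helical_axis <- function(model, frame, window = 5) {
  bm <- bp_midpoints(model, frame)
  ok <- !is.na(bm$xyz[, 1])
  pos <- bm$positions[ok]; xyz <- bm$xyz[ok, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 8) stop("geometry error: duplex too short for axis fitting (< 8 bp)")
  half <- floor(window / 2)
  pts <- t(vapply(seq_len(n - 1), function(s) {
    lo <- max(1, s - half); hi <- min(n, s + half + 1)
    ln <- fit_line_direction(xyz[lo:hi, , drop = FALSE])
    raw <- (xyz[s, ] + xyz[s + 1, ]) / 2
    ln$center + sum((raw - ln$center) * ln$direction) * ln$direction
  }, numeric(3)))
  data.frame(step = seq_len(n - 1), pos_before = pos[-n], pos_after = pos[-1],
             x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

point_polyline_distance <- function(p, axis) {
  pts <- as.matrix(axis[, c("x", "y", "z")])
  if (nrow(pts) == 1) return(sqrt(sum((p - pts[1, ])^2)))
  dmin <- Inf
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    d <- sqrt(sum((p - (a + t * ab))^2))
    if (d < dmin) dmin <- d
  }
  dmin
}

#' DNA bend angle between two duplex arms
#'
#' Fits a least-squares line to the C1'-midpoints of each arm (both
#' oriented 5'->3' along increasing position) and returns the angle between
#' the two direction vectors, in degrees within \[0, 180\]. A straight
#' duplex gives 0.
#'
#' @param model a `StructureModel`
#' @param frame a `TargetFrame`
#' @param upstream,downstream length-2 position ranges (inclusive) defining
#'   the two arms; each must span at least 4 steps and they must not overlap
#' @return bend angle in degrees
#' @export
bend_angle <- function(model, frame, upstream, downstream) {
  if (max(upstream) >= min(downstream) && max(downstream) >= min(upstream))
    stop("parameter error: arm ranges overlap")
  bm <- bp_midpoints(model, frame)
  arm_dir <- function(rng) {
    sel <- bm$positions >= min(rng) & bm$positions <= max(rng) &
      !is.na(bm$xyz[, 1])
    if (sum(sel) < 5) stop("each arm needs at least 4 steps (5 base pairs)")
    xyz <- bm$xyz[sel, , drop = FALSE]
    ln <- fit_line_direction(xyz)
    # orient along increasing position
    proj <- xyz %*% ln$direction
    if (stats::cor(seq_along(proj), as.numeric(proj)) < 0)
      ln$direction <- -ln$direction
    ln$direction
  }
  d1 <- arm_dir(upstream); d2 <- arm_dir(downstream)
  acos(pmin(1, pmax(-1, sum(d1 * d2)))) * 180 / pi
}

# cross-strand register windows (steps across the groove) of the
# El Hassan / Calladine-style P-P convention
.MAJOR_REGISTER <- (-2):2
.MINOR_REGISTER <- 2:6
.P_RADIUS2 <- 5.8  # two phosphate-group radii, subtracted from P-P distances

#' Per-position major- and minor-groove widths
#'
#' Width at a top-strand position is the shortest cross-strand P-P distance
#' within the groove-specific register window (major: the partner phosphate
#' -2..+2 steps across; minor: +2..+6), minus 5.8 Angstrom for the two
#' phosphate radii. Positions within 3 steps of a duplex end, or with
#' missing phosphates, are reported NA.
#'
#' @param model a `StructureModel`
#' @param frame a `TargetFrame`
#' @return data.frame: position, major, minor (Angstrom)
#' @export
groove_widths <- function(model, frame) {
  positions <- sort(unique(frame$position))
  n <- length(positions)
  getP <- function(p, strand) {
    fr <- frame_residue(frame, p, strand)
    if (is.null(fr)) return(NULL)
    atom_coords(model, fr$chain, fr$resno, fr$ins, "P")
  }
  Ptop <- lapply(positions, getP, strand = "top")
  Pbot <- lapply(positions, getP, strand = "bottom")
  width <- function(i, register) {
    js <- i + register
    js <- js[js >= 1 & js <= n]
    if (is.null(Ptop[[i]]) || length(js) == 0) return(NA_real_)
    d <- vapply(js, function(j) {
      if (is.null(Pbot[[j]])) return(NA_real_)
      sqrt(sum((Ptop[[i]] - Pbot[[j]])^2))
    }, numeric(1))
    if (all(is.na(d))) return(NA_real_)
    min(d, na.rm = TRUE) - .P_RADIUS2
  }
  major <- vapply(seq_len(n), width, numeric(1), register = .MAJOR_REGISTER)
  minor <- vapply(seq_len(n), width, numeric(1), register = .MINOR_REGISTER)
  edge <- seq_len(n) <= 3 | seq_len(n) > n - 3
  major[edge] <- NA_real_; minor[edge] <- NA_real_
  data.frame(position = positions, major = major, minor = minor)
}

WC_PAIRING_ATOMS <- c(A = "N1", G = "N1", I = "N1",
                      C = "N3", T = "N3", U = "N3")

#' Detect flipped-out bases
#'
#' A base is flipped when the centroid of its base heavy atoms lies more
#' than `threshold` Angstrom from the local helical axis AND it makes no
#' Watson-Crick hydrogen bond (pairing-atom distance above
#' `pairing_cutoff`) to its frame partner. Bases without a partner must
#' satisfy only the displacement criterion.
#'
#' @param model a `StructureModel`
#' @param frame a `TargetFrame`
#' @param threshold displacement threshold in Angstrom (default 8)
#' @param pairing_cutoff Watson-Crick pairing distance cutoff in Angstrom
#'   (default 3.5)
#' @return data.frame: position, strand, displacement_A
#' @export
detect_flipped_bases <- function(model, frame, threshold = 8,
                                 pairing_cutoff = 3.5) {
  axis <- fit_helical_axis(model, frame)
  a <- model$atoms
  recs <- list()
  for (r in seq_len(nrow(frame))) {
    fr <- frame[r, ]
    sel <- a$chain == fr$chain & a$resno == fr$resno & a$ins == fr$ins &
      !a$elety %in% c("P", "C1'", "OP1", "OP2", "O1P", "O2P", "O3'", "O5'",
                      "O4'", "C2'", "C3'", "C4'", "C5'")
    if (!any(sel)) next
    ctr <- colMeans(a[sel, c("x", "y", "z")])
    disp <- point_polyline_distance(ctr, axis)
    if (disp <= threshold) next
    partner <- frame_residue(frame, fr$position,
                             if (fr$strand == "top") "bottom" else "top")
    paired <- FALSE
    if (!is.null(partner)) {
      p1 <- atom_coords(model, fr$chain, fr$resno, fr$ins,
                        WC_PAIRING_ATOMS[[fr$base]])
      p2 <- atom_coords(model, partner$chain, partner$resno, partner$ins,
                        WC_PAIRING_ATOMS[[partner$base]])
      if (!is.null(p1) && !is.null(p2))
        paired <- sqrt(sum((p1 - p2)^2)) <= pairing_cutoff
    }
    if (!paired)
      recs[[length(recs) + 1]] <- data.frame(
        position = fr$position, strand = fr$strand, displacement_A = disp,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    return(data.frame(position = integer(), strand = character(),
                      displacement_A = numeric(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Full duplex geometry summary
#'
#' @param model a `StructureModel`
#' @param frame a `TargetFrame`
#' @param upstream,downstream optional arm ranges for the bend angle
#' @return object of class `DuplexGeometry`: list with `axis`, `widths`,
#'   `flipped` and (if arms given) `bend_deg`
#' @export
duplex_geometry <- function(model, frame, upstream = NULL,
                            downstream = NULL) {
  g <- list(axis = fit_helical_axis(model, frame),
            widths = groove_widths(model, frame),
            flipped = detect_flipped_bases(model, frame))
  if (!is.null(upstream) && !is.null(downstream))
    g$bend_deg <- bend_angle(model, frame, upstream, downstream)
  class(g) <- "DuplexGeometry"
  g
}

#' @export
print.DuplexGeometry <- function(x, ...) {
  cat("DuplexGeometry:", nrow(x$axis), "axis steps")
  if (!is.null(x$bend_deg)) cat(", bend", round(x$bend_deg, 1), "deg")
  cat(",", nrow(x$flipped), "flipped base(s)\n")
  invisible(x)
}
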