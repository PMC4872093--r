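# Synthetic fixtures with planted ground truth: idealized B-form duplexes
# (optional kink / base flip / groove widening), pseudo protein contacts,
# multiple sequence alignments, and lag-phase kinetic traces.

# cylindrical backbone parameters of the idealized duplex (Angstrom / deg);
# chosen to reproduce B-form hallmarks: C1'-C1' pair distance 10.5, P-C1'
# ~4.6, cross-strand P-P register minima ~11.6 (minor) / ~15.4 (major)
.HELIX <- list(r_P = 8.91, az_P = 94.5, dz_P = 2.08,
               r_C1 = 5.25, az_C1 = 90, r_pair = 1.45)

# in-plane base-atom templates: (a, b) in the local residue frame, a along
# the axis->C1' direction, b perpendicular; pairing atom placed separately
.BASE_TEMPLATES <- list(
  A = rbind(N9 = c(4.8, 0.8), C8 = c(4.2, 2.1), N7 = c(2.9, 2.4),
            C5 = c(2.4, 1.1), C6 = c(1.2, 0.9), N6 = c(0.4, 1.9),
            C2 = c(2.6, -1.0), N3 = c(3.7, -0.9), C4 = c(3.5, 0.3)),
  G = rbind(N9 = c(4.8, 0.8), C8 = c(4.2, 2.1), N7 = c(2.9, 2.4),
            C5 = c(2.4, 1.1), C6 = c(1.2, 0.9), O6 = c(0.3, 1.9),
            C2 = c(2.6, -1.0), N2 = c(2.3, -2.3), N3 = c(3.7, -0.9),
            C4 = c(3.5, 0.3)),
  C = rbind(N1 = c(4.8, 0.8), C2 = c(3.9, -0.4), O2 = c(4.3, -1.5),
            C4 = c(2.4, 1.2), N4 = c(1.2, 1.9), C5 = c(3.1, 2.0),
            C6 = c(4.3, 1.9)),
  T = rbind(N1 = c(4.8, 0.8), C2 = c(3.9, -0.4), O2 = c(4.3, -1.5),
            C4 = c(2.4, 1.2), O4 = c(1.2, 1.9), C5 = c(3.1, 2.0),
            C7 = c(2.6, 3.2), C6 = c(4.3, 1.9)))

#' Specification of a synthetic duplex
#'
#' @param sequence top-strand sequence (A/C/G/T), length >= 4
#' @param rise rise per base-pair step in Angstrom (default 3.4)
#' @param twist twist per step in degrees (default 36)
#' @param kink optional `list(step, angle)`: rigid kink of `angle` degrees
#'   (in (0, 90]) at base-pair step `step`
#' @param flip optional `list(position, strand)`: base displaced out of the
#'   helix at that frame position
#' @param widen optional `list(positions, added)`: positions (frame labels)
#'   whose major-groove width is increased by `added` Angstrom
#' @param plus_one base-pair index assigned frame position +1 (default
#'   midpoint)
#' @return object of class `DuplexSpec`
#' @export
duplex_spec <- function(sequence, rise = 3.4, twist = 36, kink = NULL,
                        flip = NULL, widen = NULL, plus_one = NULL) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < 4) stop("duplex sequence must be >= 4 bp")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("duplex sequence must be A/C/G/T only")
  if (!is.null(kink)) {
    stopifnot(is.numeric(kink$angle), is.numeric(kink$step))
    if (kink$angle <= 0 || kink$angle > 90)
      stop("kink angle must be in (0, 90] degrees")
    if (kink$step < 1 || kink$step >= length(bases))
      stop("kink step outside duplex")
  }
  if (is.null(plus_one)) plus_one <- ceiling(length(bases) / 2)
  spec <- list(sequence = sequence, bases = bases, rise = rise,
               twist = twist, kink = kink, flip = flip, widen = widen,
               plus_one = plus_one)
  class(spec) <- "DuplexSpec"
  spec
}

bp_position_labels <- function(n, plus_one) {
  i <- seq_len(n)
  i - plus_one + as.integer(i >= plus_one)
}

position_to_index <- function(pos, n, plus_one) {
  labels <- bp_position_labels(n, plus_one)
  idx <- match(pos, labels)
  if (any(is.na(idx))) stop("position(s) outside duplex: ",
                            paste(pos[is.na(idx)], collapse = ","))
  idx
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Build an idealized duplex with planted deformations
#'
#' Generates a reduced-atom B-form duplex (P, C1', Watson-Crick pairing atom
#' and named base atoms per nucleotide) following the helical parameters of
#' the spec, then applies the requested groove widening, base flip and kink.
#' Top strand is chain A (residues 1..n, 5'->3' with increasing position),
#' bottom strand chain B (n..1, anti-parallel).
#'
#' @param spec a `DuplexSpec`
#' @return list with `model` (a `StructureModel`), `frame` (ground-truth
#'   `TargetFrame`) and `truth` (planted kink angle, flip, widening)
#' @export
make_duplex <- function(spec) {
  stopifnot(inherits(spec, "DuplexSpec"))
  n <- length(spec$bases)
  if (!is.null(spec$flip) && !is.null(spec$kink)) {
    fi <- position_to_index(spec$flip$position, n, spec$plus_one)
    if (fi %in% c(spec$kink$step, spec$kink$step + 1))
      stop("contradictory options: base flip at the kink step")
  }
  H <- .HELIX
  deg2rad <- pi / 180
  rows <- list(); bp_of_atom <- integer(0)
  add_atom <- function(chain, resno, resid, elety, xyz, i) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, elety = elety,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    bp_of_atom <<- c(bp_of_atom, i)
  }
  cyl <- function(r, az_deg, z) c(r * cos(az_deg * deg2rad),
                                  r * sin(az_deg * deg2rad), z)
  for (i in seq_len(n)) {
    z <- (i - 1) * spec$rise
    th <- (i - 1) * spec$twist
    b_top <- spec$bases[i]
    b_bot <- WC_PARTNER[[b_top]]
    for (strand in c("top", "bottom")) {
      s <- if (strand == "top") 1 else -1
      chain <- if (strand == "top") "A" else "B"
      resno <- if (strand == "top") i else n - i + 1
      b <- if (strand == "top") b_top else b_bot
      resid <- paste0("D", b)
      add_atom(chain, resno, resid, "P",
               cyl(H$r_P, th + s * H$az_P, z + s * H$dz_P), i)
      c1 <- cyl(H$r_C1, th + s * H$az_C1, z)
      add_atom(chain, resno, resid, "C1'", c1, i)
      # pairing atom on the pair pseudo-dyad (N1 purine / N3 pyrimidine)
      pa <- pairing_atom(b)
      add_atom(chain, resno, resid, pa,
               cyl(H$r_pair, th + (if (strand == "top") 0 else 180), z), i)
      # in-plane base atoms from the template (pairing atom excluded)
      e1 <- cyl(1, th + s * H$az_C1, 0)
      e2 <- s * c(-e1[2], e1[1], 0)  # mirrored for the bottom strand
      tmpl <- .BASE_TEMPLATES[[b]]
      tmpl <- tmpl[setdiff(rownames(tmpl), pa), , drop = FALSE]
      for (an in rownames(tmpl)) {
        xyz <- tmpl[an, 1] * e1 + tmpl[an, 2] * e2 + c(0, 0, z)
        add_atom(chain, resno, resid, an, xyz, i)
      }
    }
  }
  atoms <- do.call(rbind, rows)

  # groove widening: push the phosphates of the major-groove register pair
  # radially outward so that the register distance grows by exactly `added`
  truth_widen <- NULL
  if (!is.null(spec$widen)) {
    idx <- position_to_index(spec$widen$positions, n, spec$plus_one)
    added <- spec$widen$added
    ptop <- function(i) which(atoms$chain == "A" & atoms$resno == i &
                                atoms$elety == "P")
    pbot <- function(i) which(atoms$chain == "B" &
                                atoms$resno == n - i + 1 &
                                atoms$elety == "P")
    # representative register from the uniform helix
    i0 <- idx[1]
    ks <- (-2):2
    ks <- ks[i0 + ks >= 1 & i0 + ks <= n]
    d0 <- vapply(ks, function(k) {
      a <- unlist(atoms[ptop(i0), c("x", "y", "z")])
      b <- unlist(atoms[pbot(i0 + k), c("x", "y", "z")])
      sqrt(sum((a - b)^2))
    }, numeric(1))
    kstar <- ks[which.min(d0)]
    dmin <- min(d0)
    # solve the radial push delta for an exact +added at that register
    pushed_dist <- function(delta) {
      a <- unlist(atoms[ptop(i0), c("x", "y", "z")])
      b <- unlist(atoms[pbot(i0 + kstar), c("x", "y", "z")])
      ra <- sqrt(sum(a[1:2]^2)); rb <- sqrt(sum(b[1:2]^2))
      a[1:2] <- a[1:2] * (ra + delta) / ra
      b[1:2] <- b[1:2] * (rb + delta) / rb
      sqrt(sum((a - b)^2))
    }
    delta <- stats::uniroot(function(d) pushed_dist(d) - (dmin + added),
                            c(0, 3 * added + 1))$root
    push <- unique(c(unlist(lapply(idx, ptop)),
                     unlist(lapply(idx + kstar, function(j)
                       if (j >= 1 && j <= n) pbot(j) else integer(0)))))
    r <- sqrt(atoms$x[push]^2 + atoms$y[push]^2)
    atoms$x[push] <- atoms$x[push] * (r + delta) / r
    atoms$y[push] <- atoms$y[push] * (r + delta) / r
    truth_widen <- list(positions = spec$widen$positions, added = added,
                        register = kstar)
  }

  # base flip: rigid radial extrusion of the base atoms (P and C1' stay)
  truth_flip <- NULL
  if (!is.null(spec$flip)) {
    fi <- position_to_index(spec$flip$position, n, spec$plus_one)
    strand <- spec$flip$strand %||% "bottom"
    chain <- if (strand == "top") "A" else "B"
    resno <- if (strand == "top") fi else n - fi + 1
    sel <- which(atoms$chain == chain & atoms$resno == resno &
                   !atoms$elety %in% c("P", "C1'"))
    ctr <- colMeans(atoms[sel, c("x", "y", "z")])
    r_c <- sqrt(sum(ctr[1:2]^2))
    u <- c(ctr[1:2] / r_c, 0)
    target_r <- 10
    shift <- (target_r - r_c) * u
    atoms$x[sel] <- atoms$x[sel] + shift[1]
    atoms$y[sel] <- atoms$y[sel] + shift[2]
    truth_flip <- list(position = spec$flip$position, strand = strand,
                       axis_distance = target_r)
  }

  # kink: rotate everything downstream of the kink step about an in-plane
  # axis through the step midpoint
  truth_bend <- 0
  if (!is.null(spec$kink)) {
    s <- spec$kink$step
    ctr <- c(0, 0, (s - 0.5) * spec$rise)
    R <- rot_x(spec$kink$angle)
    sel <- which(bp_of_atom > s)
    xyz <- t(as.matrix(atoms[sel, c("x", "y", "z")]))
    xyz <- R %*% (xyz - ctr) + ctr
    atoms$x[sel] <- xyz[1, ]; atoms$y[sel] <- xyz[2, ]
    atoms$z[sel] <- xyz[3, ]
    truth_bend <- spec$kink$angle
  }

  atoms <- data.frame(serial = seq_len(nrow(atoms)), chain = atoms$chain,
                      resno = atoms$resno, ins = "", resid = atoms$resid,
                      elety = atoms$elety,
                      element = infer_element(atoms$elety),
                      alt = "", occ = 1,
                      x = atoms$x, y = atoms$y, z = atoms$z,
                      stringsAsFactors = FALSE)
  model <- new_structure_model("synthetic_duplex", atoms,
                               source = list(path = NA, format = "synthetic"))
  labels <- bp_position_labels(n, spec$plus_one)
  frame <- rbind(
    data.frame(position = labels, strand = "top", chain = "A",
               resno = seq_len(n), ins = "", base = spec$bases,
               stringsAsFactors = FALSE),
    data.frame(position = labels, strand = "bottom", chain = "B",
               resno = n - seq_len(n) + 1, ins = "",
               base = unname(WC_PARTNER[spec$bases]),
               stringsAsFactors = FALSE))
  frame <- structure(frame, class = c("TargetFrame", "data.frame"),
                     target = spec$sequence, plus_one = spec$plus_one)
  list(model = model, frame = frame,
       truth = list(bend_angle = truth_bend, kink = spec$kink,
                    flip = truth_flip, widen = truth_widen,
                    rise = spec$rise, twist = spec$twist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant pseudo protein contacts (and optional water bridges)
#'
#' Adds single-atom pseudo protein residues (chain E, plus an outboard CA)
#' placed along the outward normal from the named DNA base atom at the
#' requested distance (within 0.01 Angstrom). Rows with `via_water = TRUE`
#' instead place a water oxygen at `water_distance` from the DNA atom and
#' the protein atom at a further `distance` beyond it.
#'
#' @param duplex list returned by [make_duplex()]
#' @param plants data.frame with columns resname, resno, atom, position,
#'   strand, base_atom, distance, and optionally via_water (logical) and
#'   water_distance
#' @return list with `model` (augmented `StructureModel`), `frame`, and
#'   `truth` (the plant table; ground-truth contact list)
#' @export
plant_contacts <- function(duplex, plants) {
  model <- duplex$model; frame <- duplex$frame
  if (is.null(plants$via_water)) plants$via_water <- FALSE
  if (is.null(plants$water_distance)) plants$water_distance <- NA_real_
  if (any(plants$distance < 2.4))
    stop("steric error: requested contact distance < 2.4 Angstrom")
  atoms <- model$atoms
  nw <- 0
  for (r in seq_len(nrow(plants))) {
    p <- plants[r, ]
    fr <- frame_residue(frame, p$position, p$strand)
    if (is.null(fr)) stop("no frame residue at position ", p$position)
    tgt <- atom_coords(model, fr$chain, fr$resno, fr$ins, p$base_atom)
    if (is.null(tgt)) stop("base atom ", p$base_atom,
                           " absent at position ", p$position)
    # outward direction: away from the base-pair C1' midpoint
    top <- frame_residue(frame, p$position, "top")
    bot <- frame_residue(frame, p$position, "bottom")
    c1s <- rbind(atom_coords(model, top$chain, top$resno, top$ins, "C1'"),
                 if (!is.null(bot))
                   atom_coords(model, bot$chain, bot$resno, bot$ins, "C1'"))
    ctr <- colMeans(c1s)
    u <- tgt - ctr
    u[3] <- 0.25 * u[3]   # stay close to the base plane
    u <- u / sqrt(sum(u^2))
    if (isTRUE(p$via_water)) {
      nw <- nw + 1
      wat <- tgt + p$water_distance * u
      prot <- tgt + (p$water_distance + p$distance) * u
      atoms <- rbind(atoms,
        data.frame(serial = 0, chain = "W", resno = nw, ins = "",
                   resid = "HOH", kind = "water", elety = "O",
                   element = "O", alt = "", occ = 1, x = wat[1],
                   y = wat[2], z = wat[3], stringsAsFactors = FALSE))
    } else {
      prot <- tgt + p$distance * u
    }
    ca <- prot + 3.0 * u
    atoms <- rbind(atoms,
      data.frame(serial = 0, chain = "E", resno = p$resno, ins = "",
                 resid = p$resname, kind = residue_kind(p$resname),
                 elety = c(p$atom, "CA"), element = infer_element(
                   c(p$atom, "CA")), alt = "", occ = 1,
                 x = c(prot[1], ca[1]), y = c(prot[2], ca[2]),
                 z = c(prot[3], ca[3]), stringsAsFactors = FALSE))
  }
  atoms$serial <- seq_len(nrow(atoms))
  list(model = new_structure_model(model$id, atoms, model$source),
       frame = frame, truth = plants)
}

#' Plant a planar pseudo side-chain group mid-stack
#'
#' Places an arginine-like guanidinium group (NE, CZ, NH1, NH2, planar,
#' parallel to the base planes) centred between the base centroids of the
#' residues at two frame positions on one strand, optionally displaced
#' laterally.
#'
#' @param duplex list returned by [make_duplex()]
#' @param between length-2 vector of frame positions flanking the insertion
#' @param strand `"top"` or `"bottom"`
#' @param lateral lateral displacement in Angstrom (default 0)
#' @param resno residue number for the pseudo residue (default 999)
#' @return list with `model`, `frame`, `truth`
#' @export
plant_intercalator <- function(duplex, between, strand = "top", lateral = 0,
                               resno = 999) {
  model <- duplex$model; frame <- duplex$frame
  ctrs <- lapply(between, function(p) {
    fr <- frame_residue(frame, p, strand)
    a <- model$atoms
    sel <- a$chain == fr$chain & a$resno == fr$resno &
      !a$elety %in% c("P", "C1'")
    colMeans(a[sel, c("x", "y", "z")])
  })
  mid <- (ctrs[[1]] + ctrs[[2]]) / 2
  axis <- ctrs[[2]] - ctrs[[1]]
  # lateral displacement points radially out of the duplex
  rad <- c(mid[1], mid[2], 0)
  rad <- if (sqrt(sum(rad^2)) < 1e-6) c(1, 0, 0) else rad / sqrt(sum(rad^2))
  mid <- mid + lateral * rad
  lat <- c(-axis[2], axis[1], 0)
  lat <- if (sqrt(sum(lat^2)) < 1e-6) c(1, 0, 0) else lat / sqrt(sum(lat^2))
  perp <- c(lat[2] * axis[3] - lat[3] * axis[2],
            lat[3] * axis[1] - lat[1] * axis[3],
            lat[1] * axis[2] - lat[2] * axis[1])
  perp <- perp - c(0, 0, perp[3])  # keep the group parallel to base planes
  perp <- if (sqrt(sum(perp^2)) < 1e-6) c(0, 1, 0) else perp / sqrt(sum(perp^2))
  grp <- rbind(CZ = mid, NE = mid + 1.33 * lat,
               NH1 = mid - 1.15 * lat + 1.0 * perp,
               NH2 = mid - 1.15 * lat - 1.0 * perp)
  atoms <- rbind(model$atoms,
    data.frame(serial = 0, chain = "E", resno = resno, ins = "",
               resid = "ARG", kind = "protein", elety = rownames(grp),
               element = infer_element(rownames(grp)), alt = "", occ = 1,
               x = grp[, 1], y = grp[, 2], z = grp[, 3],
               stringsAsFactors = FALSE))
  atoms$serial <- seq_len(nrow(atoms))
  list(model = new_structure_model(model$id, atoms, model$source),
       frame = frame,
       truth = list(between = between, strand = strand, lateral = lateral,
                    resno = resno))
}

AMINO20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic alignment
#'
#' @param n_seq number of sequences (>= 20 when planting features)
#' @param length alignment length (columns)
#' @param conserved data.frame(column, residue): columns held at >= 95%
#'   of the planted residue
#' @param coupled list of `list(i, j, states)` where `states` is a
#'   data.frame(a, b, p) giving the joint residue distribution of the pair
#' @param anchors optional `list(labels, map)`: `labels` is a per-sequence
#'   target-base label vector, `map` a data.frame(column, label, residue)
#'   forcing the residue at `column` for sequences carrying `label`
#' @param background_rate substitution rate away from the per-column
#'   consensus in background columns (default 0.3)
#' @param conserved_rate substitution rate in conserved columns
#'   (default 0.02)
#' @param alphabet residue alphabet (default the 20 amino acids)
#' @param seed RNG seed
#' @return object of class `MsaSpec`
#' @export
msa_spec <- function(n_seq, length, conserved = NULL, coupled = NULL,
                     anchors = NULL, background_rate = 0.3,
                     conserved_rate = 0.02, alphabet = AMINO20, seed = 1) {
  if ((!is.null(conserved) || !is.null(coupled)) && n_seq < 20)
    stop("n_seq too small for the requested planted fidelity (need >= 20)")
  if (!is.null(conserved) && any(conserved$column > length))
    stop("conserved column index exceeds alignment length")
  for (cp in coupled) {
    if (cp$i > length || cp$j > length)
      stop("coupled column index exceeds alignment length")
    if (abs(sum(cp$states$p) - 1) > 1e-8)
      stop("coupled joint state table is not a distribution")
  }
  if (!is.null(anchors)) {
    stopifnot(length(anchors$labels) == n_seq)
    if (any(anchors$map$column > length))
      stop("anchor column index exceeds alignment length")
  }
  structure(list(n_seq = n_seq, length = length, conserved = conserved,
                 coupled = coupled, anchors = anchors,
                 background_rate = background_rate,
                 conserved_rate = conserved_rate, alphabet = alphabet,
                 seed = seed),
            class = "MsaSpec")
}

# deterministic allocation of n draws to probabilities (largest remainder)
allocate_counts <- function(p, n) {
  raw <- p * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt
}

#' Simulate an alignment with planted conservation, coupling and anchors
#'
#' Background columns carry a consensus residue substituted at
#' `background_rate` into a small per-column set of alternatives (as in real
#' alignments, columns are far from uniform over the full alphabet).
#' Conserved columns keep the planted residue in at least 95% of rows by
#' construction; coupled pairs realize their joint state table with exact
#' (largest-remainder) counts; anchor columns follow the label map exactly.
#'
#' @param spec an `MsaSpec`
#' @return list with `msa` (an `msa` object) and `truth` (planted features)
#' @export
simulate_msa <- function(spec) {
  stopifnot(inherits(spec, "MsaSpec"))
  set.seed(spec$seed)
  n <- spec$n_seq; L <- spec$length
  aln <- matrix("", n, L)
  role <- rep("background", L)
  for (j in seq_len(L)) {
    cons <- sample(spec$alphabet, 1)
    alts <- sample(setdiff(spec$alphabet, cons), 3)
    mut <- stats::runif(n) < spec$background_rate
    aln[, j] <- ifelse(mut, sample(alts, n, replace = TRUE), cons)
  }
  if (!is.null(spec$conserved)) for (r in seq_len(nrow(spec$conserved))) {
    j <- spec$conserved$column[r]; res <- spec$conserved$residue[r]
    n_mut <- floor(spec$conserved_rate * n)
    col <- rep(res, n)
    if (n_mut > 0) {
      rows <- sample(n, n_mut)
      col[rows] <- sample(setdiff(spec$alphabet, res), n_mut,
                          replace = TRUE)
    }
    aln[, j] <- col
    role[j] <- "conserved"
  }
  for (cp in spec$coupled) {
    cnt <- allocate_counts(cp$states$p, n)
    ord <- sample(n)
    states <- rep(seq_len(nrow(cp$states)), cnt)
    aln[ord, cp$i] <- cp$states$a[states]
    aln[ord, cp$j] <- cp$states$b[states]
    role[c(cp$i, cp$j)] <- "coupled"
  }
  if (!is.null(spec$anchors)) {
    for (r in seq_len(nrow(spec$anchors$map))) {
      m <- spec$anchors$map[r, ]
      rows <- spec$anchors$labels == m$label
      aln[rows, m$column] <- m$residue
      role[m$column] <- "anchor"
    }
  }
  ids <- sprintf("seq%03d", seq_len(n))
  rownames(aln) <- ids
  msa <- new_msa(ids, aln)
  list(msa = msa, truth = list(role = role, spec = spec))
}

#' Specification of synthetic triplex-displacement traces
#'
#' Traces follow the lag-phase displacement model (linear background of
#' gradient `m` up to the lag time, then an offset exponential of amplitude
#' `A` and rate `k`), with lag times T_app = d / k_true + C2 and i.i.d.
#' Gaussian noise on the signal.
#'
#' @param distances translocation distances d in bp
#' @param k_true true stepping rate in bp/s (> 0)
#' @param C2 lag-vs-distance intercept in s (default 5)
#' @param m background gradient, signal/s (default 0.001)
#' @param A exponential amplitude, signal units (default 1)
#' @param k apparent displacement rate constant, 1/s (default 0.2)
#' @param dt sampling interval in s (default 0.1, i.e. 10 Hz)
#' @param duration trace duration in s (default: max lag + 5/k + 5)
#' @param noise_sd Gaussian noise SD in signal units (default 0.02, 2% of
#'   the default amplitude)
#' @param seed RNG seed
#' @return object of class `TraceSpec`
#' @export
trace_spec <- function(distances, k_true, C2 = 5, m = 0.001, A = 1,
                       k = 0.2, dt = 0.1, duration = NULL, noise_sd = 0.02,
                       seed = 1) {
  if (k_true <= 0) stop("k_true must be > 0")
  t_app <- distances / k_true + C2
  if (is.null(duration)) duration <- max(t_app) + 5 / k + 5
  if (duration <= max(t_app))
    stop("duration must exceed the largest lag time")
  structure(list(distances = distances, k_true = k_true, C2 = C2, m = m,
                 A = A, k = k, dt = dt, duration = duration,
                 noise_sd = noise_sd, seed = seed),
            class = "TraceSpec")
}

#' Simulate triplex-displacement traces
#' @param spec a `TraceSpec`
#' @return list of `kinetic_trace` objects (data.frames time/signal with
#'   attributes `d` and `truth`)
#' @export
simulate_traces <- function(spec) {
  stopifnot(inherits(spec, "TraceSpec"))
  set.seed(spec$seed)
  lapply(spec$distances, function(d) {
    t_app <- d / spec$k_true + spec$C2
    t <- seq(0, spec$duration, by = spec$dt)
    y <- eq_displacement(t, spec$m, spec$A, spec$k, t_app)
    if (spec$noise_sd > 0) y <- y + stats::rnorm(length(t), 0, spec$noise_sd)
    tr <- data.frame(time = t, signal = y)
    structure(tr, class = c("kinetic_trace", "data.frame"), d = d,
              label = paste0("d", d),
              truth = list(m = spec$m, A = spec$A, k = spec$k,
                           T_app = t_app, C1 = spec$m * t_app))
  })
}

#' Write kinetic traces as two-column CSV files
#' @param traces list of `kinetic_trace`
#' @param dir output directory
#' @return character vector of file paths, invisibly
#' @export
write_traces_csv <- function(traces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(traces, function(tr) {
    p <- file.path(dir, paste0("trace_", attr(tr, "label"), ".csv"))
    utils::write.csv(data.frame(time_s = tr$time, signal = tr$signal), p,
                     row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a kinetic trace from a two-column CSV
#' @param path CSV with time and signal columns
#' @param d translocation distance in bp (metadata)
#' @return a `kinetic_trace`
#' @export
read_trace_csv <- function(path, d = NA_real_) {
  x <- utils::read.csv(path)
  tr <- data.frame(time = x[[1]], signal = x[[2]])
  structure(tr, class = c("kinetic_trace", "data.frame"), d = d,
            label = basename(path))
}
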