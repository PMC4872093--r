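# Protein-DNA hydrogen-bond contacts, water bridges, intercalation, and the
# schematic contact table.

# Hydrogen-bond chemistry dictionaries. The criterion is distance-only
# (donor/acceptor heavy atoms within the cutoff); the 2.84-Angstrom-class
# structures this targets carry no hydrogens, so no D-H...A angle is used by
# default. Histidine ring nitrogens are treated as ambivalent.

PROTEIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  TRP = "NE1", CYS = "SG")

PROTEIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

MAINCHAIN_DONOR <- "N"
MAINCHAIN_ACCEPTOR <- "O"

# per-base donor/acceptor atoms by moiety; W = Watson-Crick edge
BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4", T = "N3",
                    U = "N3")
BASE_ACCEPTORS <- list(A = c("N7", "N1", "N3"), G = c("N7", "O6", "N3"),
                       C = c("N3", "O2"), T = c("O4", "O2"),
                       U = c("O4", "O2"))
BACKBONE_ACCEPTORS <- c("OP1", "OP2", "O1P", "O2P", "O3'", "O5'", "O4'")

MAJOR_GROOVE_ATOMS <- list(A = c("N7", "N6"), G = c("N7", "O6"),
                           C = c("N4", "C5"), T = c("O4", "C7", "C5"),
                           U = "O4")
MINOR_GROOVE_ATOMS <- list(A = c("N3", "C2"), G = c("N3", "N2"),
                           C = "O2", T = "O2", U = "O2")

# planar side-chain groups eligible for intercalation
PLANAR_GROUPS <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

#' Hydrogen-bond chemistry dictionaries
#'
#' Returns the fixed donor/acceptor atom dictionaries for protein residues
#' and DNA bases, the per-base major- and minor-groove atom sets, and the
#' planar side-chain groups eligible for intercalation.
#' @return named list of dictionaries
#' @export
chemistry_dictionaries <- function() {
  list(protein_donors = PROTEIN_DONORS,
       protein_acceptors = PROTEIN_ACCEPTORS,
       mainchain_donor = MAINCHAIN_DONOR,
       mainchain_acceptor = MAINCHAIN_ACCEPTOR,
       base_donors = BASE_DONORS, base_acceptors = BASE_ACCEPTORS,
       backbone_acceptors = BACKBONE_ACCEPTORS,
       major_groove = MAJOR_GROOVE_ATOMS, minor_groove = MINOR_GROOVE_ATOMS,
       planar_groups = PLANAR_GROUPS)
}

protein_hb_atoms <- function(atoms) {
  res <- atoms$resid; ety <- atoms$elety
  donor <- mapply(function(r, e) e %in% PROTEIN_DONORS[[r]] ||
                    e == MAINCHAIN_DONOR, res, ety)
  acceptor <- mapply(function(r, e) e %in% PROTEIN_ACCEPTORS[[r]] ||
                       e == MAINCHAIN_ACCEPTOR, res, ety)
  part <- ifelse(ety %in% c("N", "CA", "C", "O", "OXT"),
                 "main chain", "side chain")
  data.frame(idx = seq_len(nrow(atoms)), donor = donor, acceptor = acceptor,
             part = part, stringsAsFactors = FALSE)[donor | acceptor, ,
                                                    drop = FALSE]
}

dna_hb_atoms <- function(atoms) {
  base <- base_letter(atoms$resid); ety <- atoms$elety
  donor <- mapply(function(b, e) !is.na(b) && e %in% BASE_DONORS[[b]],
                  base, ety)
  acceptor <- mapply(function(b, e) !is.na(b) &&
                       (e %in% BASE_ACCEPTORS[[b]] ||
                          e %in% BACKBONE_ACCEPTORS), base, ety)
  moiety <- ifelse(ety %in% c("OP1", "OP2", "O1P", "O2P", "P", "O5'", "O3'"),
                   "phosphate",
                   ifelse(grepl("'", ety), "sugar", "base"))
  groove <- mapply(function(b, e, m) {
    if (m != "base" || is.na(b)) return("n/a")
    if (e %in% MAJOR_GROOVE_ATOMS[[b]]) return("major")
    if (e %in% MINOR_GROOVE_ATOMS[[b]]) return("minor")
    "n/a"
  }, base, ety, moiety)
  data.frame(idx = seq_len(nrow(atoms)), donor = donor, acceptor = acceptor,
             moiety = moiety, groove = groove,
             stringsAsFactors = FALSE)[donor | acceptor, , drop = FALSE]
}

frame_atom_selection <- function(model, frame) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$ins)
  fkey <- paste(frame$chain, frame$resno, frame$ins)
  m <- match(key, fkey)
  list(sel = which(!is.na(m)), frame_row = m[!is.na(m)])
}

#' Detect protein-DNA hydrogen-bond contacts
#'
#' Every protein donor/acceptor atom within `cutoff` of a DNA
#' donor/acceptor atom of a frame-assigned nucleotide, with compatible
#' roles (donor against acceptor; ambivalent atoms match both), yields one
#' annotated contact record. A coarse bounding-box prefilter around the DNA
#' selection accelerates the scan; results are identical to an all-pairs
#' scan.
#'
#' @param model a `StructureModel`
#' @param frame a `TargetFrame`
#' @param cutoff distance cutoff in Angstrom (default 3.5)
#' @return data.frame of contact records sorted by position then residue
#'   number: chain, resno, resname, part, atom, position, strand, moiety,
#'   groove, distance_A, mediation, water
#' @export
detect_hbond_contacts <- function(model, frame, cutoff = 3.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- model$atoms
  prot <- which(a$kind == "protein")
  fsel <- frame_atom_selection(model, frame)
  dna <- fsel$sel[a$kind[fsel$sel] == "nucleotide"]
  dna_rows <- fsel$frame_row[a$kind[fsel$sel] == "nucleotide"]
  if (length(prot) == 0 || length(dna) == 0) return(empty_contacts())

  ph <- protein_hb_atoms(a[prot, , drop = FALSE]); ph$idx <- prot[ph$idx]
  dh <- dna_hb_atoms(a[dna, , drop = FALSE])
  dh$frame_row <- dna_rows[dh$idx]; dh$idx <- dna[dh$idx]
  if (nrow(ph) == 0 || nrow(dh) == 0) return(empty_contacts())

  # bounding-box prefilter on the protein side
  bb <- apply(a[dh$idx, c("x", "y", "z"), drop = FALSE], 2, range)
  px <- a[ph$idx, c("x", "y", "z"), drop = FALSE]
  inbox <- px$x >= bb[1, 1] - cutoff & px$x <= bb[2, 1] + cutoff &
    px$y >= bb[1, 2] - cutoff & px$y <= bb[2, 2] + cutoff &
    px$z >= bb[1, 3] - cutoff & px$z <= bb[2, 3] + cutoff
  ph <- ph[inbox, , drop = FALSE]
  if (nrow(ph) == 0) return(empty_contacts())

  P <- as.matrix(a[ph$idx, c("x", "y", "z")])
  D <- as.matrix(a[dh$idx, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(D^2), "+") - 2 * P %*% t(D)
  hits <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_contacts())

  recs <- lapply(seq_len(nrow(hits)), function(h) {
    i <- hits[h, 1]; j <- hits[h, 2]
    ok <- (ph$donor[i] && dh$acceptor[j]) || (ph$acceptor[i] && dh$donor[j])
    if (!ok) return(NULL)
    pi <- ph$idx[i]; di <- dh$idx[j]; fr <- frame[dh$frame_row[j], ]
    data.frame(chain = a$chain[pi], resno = a$resno[pi],
               resname = a$resid[pi], part = ph$part[i],
               atom = a$elety[pi], position = fr$position,
               strand = fr$strand, nt_atom = a$elety[di],
               moiety = dh$moiety[j], groove = dh$groove[j],
               distance_A = sqrt(max(d2[i, j], 0)),
               mediation = "direct", water = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) return(empty_contacts())
  out <- out[order(out$position, out$resno, out$atom, out$nt_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_contacts <- function() {
  data.frame(chain = character(), resno = integer(), resname = character(),
             part = character(), atom = character(), position = integer(),
             strand = character(), nt_atom = character(),
             moiety = character(), groove = character(),
             distance_A = numeric(), mediation = character(),
             water = character(), stringsAsFactors = FALSE)
}

#' Detect water-bridged protein-DNA contacts
#'
#' A water oxygen within `cutoff` of both a protein donor/acceptor atom and
#' a DNA base donor/acceptor atom of a frame-assigned nucleotide yields one
#' bridged record per (protein atom, water, base atom) combination.
#' `distance_A` reports the longer of the two legs; both legs are also
#' returned.
#'
#' @inheritParams detect_hbond_contacts
#' @return data.frame of contact records with `mediation = "water-bridged"`
#' @export
detect_water_bridges <- function(model, frame, cutoff = 3.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- model$atoms
  wat <- which(a$kind == "water" & a$elety %in% c("O", "OW", "OH2"))
  prot <- which(a$kind == "protein")
  fsel <- frame_atom_selection(model, frame)
  dna <- fsel$sel[a$kind[fsel$sel] == "nucleotide"]
  dna_rows <- fsel$frame_row[a$kind[fsel$sel] == "nucleotide"]
  if (length(wat) == 0 || length(prot) == 0 || length(dna) == 0)
    return(empty_contacts())
  ph <- protein_hb_atoms(a[prot, , drop = FALSE]); ph$idx <- prot[ph$idx]
  dh <- dna_hb_atoms(a[dna, , drop = FALSE])
  dh$frame_row <- dna_rows[dh$idx]; dh$idx <- dna[dh$idx]
  dh <- dh[dh$moiety == "base", , drop = FALSE]
  if (nrow(ph) == 0 || nrow(dh) == 0) return(empty_contacts())
  W <- as.matrix(a[wat, c("x", "y", "z"), drop = FALSE])
  P <- as.matrix(a[ph$idx, c("x", "y", "z")])
  D <- as.matrix(a[dh$idx, c("x", "y", "z")])
  dW_P <- sqrt(pmax(outer(rowSums(W^2), rowSums(P^2), "+") -
                      2 * W %*% t(P), 0))
  dW_D <- sqrt(pmax(outer(rowSums(W^2), rowSums(D^2), "+") -
                      2 * W %*% t(D), 0))
  recs <- list()
  for (w in seq_along(wat)) {
    pi <- which(dW_P[w, ] <= cutoff)
    di <- which(dW_D[w, ] <= cutoff)
    if (length(pi) == 0 || length(di) == 0) next
    for (i in pi) for (j in di) {
      ai <- ph$idx[i]; dj <- dh$idx[j]; fr <- frame[dh$frame_row[j], ]
      recs[[length(recs) + 1]] <- data.frame(
        chain = a$chain[ai], resno = a$resno[ai], resname = a$resid[ai],
        part = ph$part[i], atom = a$elety[ai], position = fr$position,
        strand = fr$strand, nt_atom = a$elety[dj], moiety = dh$moiety[j],
        groove = dh$groove[j],
        distance_A = max(dW_P[w, i], dW_D[w, j]),
        mediation = "water-bridged",
        water = paste0(a$chain[wat[w]], a$resno[wat[w]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) return(empty_contacts())
  out <- out[order(out$position, out$resno, out$atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect intercalating planar side chains
#'
#' A planar side-chain group (arginine guanidinium; His/Trp/Tyr/Phe ring)
#' whose centroid lies between the base planes of two consecutive stack
#' positions - within `dist_max` of both flanking base centroids and with
#' its plane inclined less than `angle_max` to their mean plane - is
#' reported. Flipped-out bases are removed from the stack before
#' consecutive positions are formed, so a residue filling the cavity left
#' by a flipped base is reported between the flanking positions.
#'
#' @param model a `StructureModel`
#' @param frame a `TargetFrame`
#' @param dist_max centroid-to-flank distance cutoff in Angstrom
#'   (default 4.5)
#' @param angle_max plane angle cutoff in degrees (default 30)
#' @param flip_threshold displacement used to drop flipped bases from the
#'   stack (default 8)
#' @return data.frame: chain, resno, resname, strand, pos_before, pos_after
#' @export
detect_intercalation <- function(model, frame, dist_max = 4.5,
                                 angle_max = 30, flip_threshold = 8) {
  a <- model$atoms
  axis <- tryCatch(fit_helical_axis(model, frame),
                   error = function(e) NULL)
  base_centroid <- function(fr) {
    sel <- a$chain == fr$chain & a$resno == fr$resno & a$ins == fr$ins &
      !a$elety %in% c("P", "C1'", "OP1", "OP2", "O1P", "O2P", "O3'", "O5'",
                      "O4'", "C2'", "C3'", "C4'", "C5'")
    if (!any(sel)) return(NULL)
    colMeans(a[sel, c("x", "y", "z")])
  }
  base_normal <- function(fr) {
    sel <- a$chain == fr$chain & a$resno == fr$resno & a$ins == fr$ins &
      !a$elety %in% c("P", "C1'", "OP1", "OP2", "O1P", "O2P", "O3'", "O5'",
                      "O4'", "C2'", "C3'", "C4'", "C5'")
    xyz <- as.matrix(a[sel, c("x", "y", "z")])
    if (nrow(xyz) < 3) return(NULL)
    sv <- svd(scale(xyz, scale = FALSE))
    sv$v[, 3]
  }
  recs <- list()
  for (strand in unique(frame$strand)) {
    fs <- frame[frame$strand == strand, , drop = FALSE]
    fs <- fs[order(fs$position), , drop = FALSE]
    cents <- lapply(seq_len(nrow(fs)), function(i) base_centroid(fs[i, ]))
    keep <- !vapply(cents, is.null, logical(1))
    if (!is.null(axis)) {
      disp <- vapply(seq_len(nrow(fs)), function(i) {
        if (is.null(cents[[i]])) return(NA_real_)
        point_polyline_distance(cents[[i]], axis)
      }, numeric(1))
      keep <- keep & (is.na(disp) | disp < flip_threshold)
    }
    fs <- fs[keep, , drop = FALSE]; cents <- cents[keep]
    if (nrow(fs) < 2) next
    for (i in seq_len(nrow(fs) - 1)) {
      c1 <- cents[[i]]; c2 <- cents[[i + 1]]
      n1 <- base_normal(fs[i, ]); n2 <- base_normal(fs[i + 1, ])
      nm <- if (!is.null(n1) && !is.null(n2)) {
        s <- if (sum(n1 * n2) < 0) -1 else 1
        v <- n1 + s * n2; v / sqrt(sum(v^2))
      } else NULL
      for (resname in names(PLANAR_GROUPS)) {
        cand <- a[a$kind == "protein" & a$resid == resname, , drop = FALSE]
        for (rn in unique(paste(cand$chain, cand$resno))) {
          sub <- cand[paste(cand$chain, cand$resno) == rn, , drop = FALSE]
          grp <- sub[sub$elety %in% PLANAR_GROUPS[[resname]], , drop = FALSE]
          if (nrow(grp) < 3) next
          g <- colMeans(grp[, c("x", "y", "z")])
          if (sqrt(sum((g - c1)^2)) > dist_max ||
              sqrt(sum((g - c2)^2)) > dist_max) next
          if (!is.null(nm)) {
            sv <- svd(scale(as.matrix(grp[, c("x", "y", "z")]),
                            scale = FALSE))
            gn <- sv$v[, 3]
            ang <- acos(pmin(1, abs(sum(gn * nm)))) * 180 / pi
            if (ang >= angle_max) next
          }
          recs[[length(recs) + 1]] <- data.frame(
            chain = grp$chain[1], resno = grp$resno[1], resname = resname,
            strand = strand, pos_before = fs$position[i],
            pos_after = fs$position[i + 1], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), strand = character(),
                      pos_before = integer(), pos_after = integer(),
                      stringsAsFactors = FALSE))
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Schematic contact table and per-position summary
#'
#' @param contacts contact records from [detect_hbond_contacts()] and/or
#'   [detect_water_bridges()]
#' @param frame a `TargetFrame`
#' @return list with `records` (the annotated rows) and `per_position`
#'   (position, base-specific contact count, backbone contact count)
#' @export
contact_schematic <- function(contacts, frame) {
  positions <- sort(unique(frame$position))
  per <- data.frame(position = positions,
                    n_base = vapply(positions, function(p)
                      sum(contacts$position == p & contacts$moiety == "base"),
                      numeric(1)),
                    n_backbone = vapply(positions, function(p)
                      sum(contacts$position == p &
                            contacts$moiety != "base"), numeric(1)))
  list(records = contacts, per_position = per)
}

#' Write contact records as TSV (fixed column order)
#' @param contacts contact record data.frame
#' @param path output path
#' @param enzyme enzyme label for the first column
#' @return `path`, invisibly
#' @export
write_contacts_tsv <- function(contacts, path, enzyme = "") {
  out <- cbind(enzyme = enzyme,
               contacts[, c("chain", "resno", "resname", "part", "atom",
                            "position", "strand", "moiety", "groove",
                            "distance_A", "mediation")])
  utils::write.table(format(out, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
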