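# Structure input/output and the target-position frame.

PROTEIN_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

NUCLEOTIDE_RESIDUES <- c("DA", "DT", "DG", "DC", "DU", "DI",
                         "A", "T", "G", "C", "U", "I")

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Classify a residue name
#'
#' Deterministic lookup of a residue name against fixed dictionaries of
#' standard amino acids (plus MSE/SEC/PYL), deoxy- and ribonucleotides, and
#' water names. Anything else is `"other"`.
#'
#' @param resid Character vector of residue names (e.g. `"ALA"`, `"DA"`).
#' @return Character vector, one of `"protein"`, `"nucleotide"`, `"water"`,
#'   `"other"`.
#' @export
residue_kind <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- rep("other", length(resid))
  out[resid %in% PROTEIN_RESIDUES] <- "protein"
  out[resid %in% NUCLEOTIDE_RESIDUES] <- "nucleotide"
  out[resid %in% WATER_RESIDUES] <- "water"
  out
}

#' One-letter base code of a nucleotide residue name
#' @param resid residue names (`"DA"`, `"DT"`, ...)
#' @return one-letter base (A/C/G/T/U/I), NA for non-nucleotides
#' @export
base_letter <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- ifelse(resid %in% NUCLEOTIDE_RESIDUES, sub("^D", "", resid),
                NA_character_)
  out
}

infer_element <- function(elety, elesy = NULL) {
  el <- if (!is.null(elesy)) toupper(trimws(elesy)) else
    rep("", length(elety))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    nm <- gsub("[0-9'*]", "", toupper(trimws(elety[miss])))
    # two-letter elements that actually occur in protein/DNA files
    two <- substr(nm, 1, 2)
    guess <- substr(nm, 1, 1)
    guess[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")] <-
      two[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")]
    el[miss] <- guess
  }
  el
}

new_structure_model <- function(id, atoms, source = list()) {
  atoms$kind <- residue_kind(atoms$resid)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(id = id, atoms = atoms, source = source),
            class = "StructureModel")
}

#' Build a structure model from an atom table
#'
#' @param atoms data.frame with at least chain, resno, resid, elety, x, y,
#'   z; serial/ins/alt/occ/element are filled with defaults when absent
#' @param id model identifier
#' @return a `StructureModel`
#' @export
as_structure_model <- function(atoms, id = "model") {
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$elety)
  new_structure_model(id, atoms, source = list(path = NA, format = "memory"))
}

#' @export
print.StructureModel <- function(x, ...) {
  res <- residue_table(x)
  cat("StructureModel", x$id, "\n")
  cat("  atoms:", nrow(x$atoms), " residues:", nrow(res),
      " chains:", paste(unique(x$atoms$chain), collapse = ","), "\n")
  cat("  kinds:", paste(names(table(res$kind)), table(res$kind),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Table of residues in a structure
#' @param model a `StructureModel`
#' @return data.frame with chain, resno, ins, resid, kind and atom count
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$ins, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             ins = a$ins[first], resid = a$resid[first],
             kind = a$kind[first],
             n_atoms = as.integer(table(key)[key[first]]),
             stringsAsFactors = FALSE)
}

# drop alternate conformers: per residue keep the alt-loc label with the
# highest occupancy (ties -> alphabetically first), plus unlabelled atoms
filter_altloc <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k & alt != "")
    occ <- tapply(atoms$occ[idx], alt[idx], sum)
    best <- names(occ)[order(-occ, names(occ))][1]
    keep[idx[alt[idx] != best]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Load a protein-DNA structure from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records (waters retained) into a flat atom table.
#' Alternate conformers are reduced to the highest-occupancy one per residue
#' (ties broken alphabetically by alt-loc label). Author residue numbering is
#' preserved.
#'
#' @param path file path
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension, default)
#' @return a `StructureModel`: list with `id`, `atoms` (data.frame: serial,
#'   chain, resno, ins, resid, kind, elety, element, alt, occ, x, y, z),
#'   `source`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    element = infer_element(at$elety, at$elesy),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    occ = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    stringsAsFactors = FALSE)
  atoms <- filter_altloc(atoms)
  id <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "", basename(path),
            ignore.case = TRUE)
  new_structure_model(id, atoms,
                      source = list(path = path, format = format))
}

#' Write a structure model as fixed-column PDB
#'
#' Waters and `"other"` residues are written as HETATM, everything else as
#' ATOM. Coordinates are written at 1e-3 Angstrom precision.
#'
#' @param model a `StructureModel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  rec <- ifelse(a$kind %in% c("water", "other"), "HETATM", "ATOM  ")
  nm <- a$elety
  # atom name column convention: 1-3 char names start in column 14
  nm <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
  lines <- sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000, nm, substr(a$alt, 1, 1),
                   a$resid, substr(a$chain, 1, 1), a$resno,
                   substr(a$ins, 1, 1), a$x, a$y, a$z, a$occ, 0,
                   a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           MSE = "M")

#' Extract a one-letter sequence from a chain
#'
#' Residues are ordered by author residue number; non-standard residues come
#' out as `X`. Numbering gaps are not padded; the missing residue numbers are
#' reported in the `"gaps"` attribute.
#'
#' @param model a `StructureModel`
#' @param chain chain identifier
#' @return character scalar with attribute `gaps` (integer vector of missing
#'   residue numbers)
#' @export
extract_sequence <- function(model, chain) {
  res <- residue_table(model)
  res <- res[res$chain == chain & res$kind != "water", , drop = FALSE]
  if (nrow(res) == 0) stop("no chain '", chain, "' in model ", model$id)
  res <- res[order(res$resno, res$ins), , drop = FALSE]
  one <- ifelse(res$kind == "protein",
                unname(AA321[res$resid]),
                base_letter(res$resid))
  one[is.na(one)] <- "X"
  gaps <- setdiff(seq(min(res$resno), max(res$resno)), res$resno)
  structure(paste(one, collapse = ""), gaps = as.integer(gaps))
}

# IUPAC nucleotide codes -> compatible bases
IUPAC_DNA <- list(A = "A", C = "C", G = "G", T = c("T", "U"),
                  U = c("T", "U"),
                  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

WC_PARTNER <- c(A = "T", T = "A", G = "C", C = "G", U = "A", I = "C")

pairing_atom <- function(base) ifelse(base %in% c("A", "G", "I"), "N1", "N3")

atom_coords <- function(model, chain, resno, ins, elety) {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$ins == ins &
               a$elety == elety)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Assign the target-position frame to DNA residues
#'
#' Positions on the recognition sequence follow the convention used for
#' Type ISP targets: the methylated T:A base pair is +1, downstream
#' positions are positive, upstream positions negative, and there is no
#' position 0 (-1 immediately precedes +1). The anchor residue is the
#' top-strand residue at +1; the target string is read with `plus_one` giving
#' the string index of the +1 base (default 2, as in CTnGAyG where the
#' methylated T is the second letter).
#'
#' Bottom-strand partners are assigned as the nucleotide whose Watson-Crick
#' pairing atom (purine N1 / pyrimidine N3) is nearest, subject to a
#' C1'-C1' distance of at most 12 Angstrom; residues whose pairing atoms are
#' absent or far (e.g. a flipped base) get their partner by frame arithmetic
#' from neighbouring positions.
#'
#' @param model a `StructureModel`
#' @param target top-strand target string, IUPAC codes allowed
#' @param anchor_chain,anchor_resno chain and author residue number of the
#'   top-strand +1 residue
#' @param anchor_ins insertion code of the anchor (default `""`)
#' @param plus_one index within `target` of the +1 base (default 2)
#' @param pairing_max maximum pairing-atom distance (Angstrom) for direct
#'   partner assignment; beyond it (a flipped or unpaired base) the partner
#'   comes from frame arithmetic (default 3.5)
#' @return a `TargetFrame`: data.frame with columns position, strand
#'   (`"top"`/`"bottom"`), chain, resno, ins, base
#' @export
assign_target_frame <- function(model, target, anchor_chain, anchor_resno,
                                anchor_ins = "", plus_one = 2,
                                pairing_max = 3.5) {
  tchars <- toupper(strsplit(target, "")[[1]])
  bad <- !tchars %in% names(IUPAC_DNA)
  if (any(bad)) stop("target contains non-IUPAC codes: ",
                     paste(tchars[bad], collapse = ","))
  res <- residue_table(model)
  nt <- res[res$kind == "nucleotide", , drop = FALSE]
  ai <- which(nt$chain == anchor_chain & nt$resno == anchor_resno &
                nt$ins == anchor_ins)
  if (length(ai) != 1) stop("anchor residue not found on a nucleotide chain")
  top <- nt[nt$chain == anchor_chain, , drop = FALSE]
  top <- top[order(top$resno, top$ins), , drop = FALSE]
  anchor_idx <- which(top$resno == anchor_resno & top$ins == anchor_ins)

  # string index i -> position label (no 0) and top-strand residue index
  idx <- seq_along(tchars)
  pos <- idx - plus_one + as.integer(idx >= plus_one)
  top_idx <- anchor_idx + (idx - plus_one)
  inside <- top_idx >= 1 & top_idx <= nrow(top)
  if (any(!inside)) {
    warning("target frame truncated: positions ",
            paste(pos[!inside], collapse = ","), " fall off the duplex")
    idx <- idx[inside]; pos <- pos[inside]; top_idx <- top_idx[inside]
  }

  top_res <- top[top_idx, , drop = FALSE]
  top_base <- base_letter(top_res$resid)
  mism <- mapply(function(b, code) !(b %in% IUPAC_DNA[[code]]),
                 top_base, tchars[idx])
  if (any(mism)) {
    stop("top-strand base conflicts with target string at position(s) ",
         paste(pos[mism], collapse = ","), ": found ",
         paste(top_base[mism], collapse = ","))
  }

  # candidate bottom-strand residues: nucleotides off the top chain
  cand <- nt[!(paste(nt$chain, nt$resno, nt$ins) %in%
                 paste(top_res$chain, top_res$resno, top_res$ins)) &
               nt$chain != anchor_chain, , drop = FALSE]
  bot <- data.frame(chain = NA_character_, resno = NA_integer_,
                    ins = NA_character_, resid = NA_character_,
                    stringsAsFactors = FALSE)[rep(1, length(pos)), ]
  if (nrow(cand) > 0) {
    cand_pair <- t(vapply(seq_len(nrow(cand)), function(j) {
      p <- atom_coords(model, cand$chain[j], cand$resno[j], cand$ins[j],
                       pairing_atom(base_letter(cand$resid[j])))
      if (is.null(p)) rep(NA_real_, 3) else p
    }, numeric(3)))
    cand_c1 <- t(vapply(seq_len(nrow(cand)), function(j) {
      p <- atom_coords(model, cand$chain[j], cand$resno[j], cand$ins[j], "C1'")
      if (is.null(p)) rep(NA_real_, 3) else p
    }, numeric(3)))
    for (i in seq_along(pos)) {
      tp <- atom_coords(model, top_res$chain[i], top_res$resno[i],
                        top_res$ins[i], pairing_atom(top_base[i]))
      tc <- atom_coords(model, top_res$chain[i], top_res$resno[i],
                        top_res$ins[i], "C1'")
      if (is.null(tp) || is.null(tc)) next
      dp <- sqrt(rowSums((cand_pair - rep(tp, each = nrow(cand)))^2))
      dc <- sqrt(rowSums((cand_c1 - rep(tc, each = nrow(cand)))^2))
      ok <- which(!is.na(dp) & !is.na(dc) & dc <= 12 & dp <= pairing_max)
      if (length(ok) > 0) {
        j <- ok[which.min(dp[ok])]
        bot[i, c("chain", "resno", "ins", "resid")] <-
          cand[j, c("chain", "resno", "ins", "resid")]
      }
    }
    # frame arithmetic for unassigned partners (flipped/unpaired bases):
    # bottom strand is anti-parallel, so resno steps opposite to position
    for (pass in 1:2) for (i in seq_along(pos)) {
      if (!is.na(bot$resno[i])) next
      for (nb in c(i - 1, i + 1)) {
        if (nb < 1 || nb > length(pos) || is.na(bot$resno[nb])) next
        guess <- bot$resno[nb] + (i - nb) *
          sign_or_one(bottom_direction(bot))
        hit <- which(cand$chain == bot$chain[nb] & cand$resno == guess)
        if (length(hit) > 0) {
          bot[i, c("chain", "resno", "ins", "resid")] <-
            cand[hit[1], c("chain", "resno", "ins", "resid")]
          break
        }
      }
    }
  }

  frame <- rbind(
    data.frame(position = pos, strand = "top", chain = top_res$chain,
               resno = top_res$resno, ins = top_res$ins, base = top_base,
               stringsAsFactors = FALSE),
    data.frame(position = pos, strand = "bottom", chain = bot$chain,
               resno = bot$resno, ins = bot$ins,
               base = base_letter(bot$resid), stringsAsFactors = FALSE))
  frame <- frame[!(frame$strand == "bottom" & is.na(frame$resno)), ,
                 drop = FALSE]
  rownames(frame) <- NULL
  plus1 <- frame[frame$position == 1 & frame$strand == "top", , drop = FALSE]
  if (nrow(plus1) == 1 && !plus1$base %in% c("T", "U"))
    warning("top-strand +1 base is ", plus1$base,
            "; the methylated position is expected to be T (T:A pair)")
  structure(frame, class = c("TargetFrame", "data.frame"),
            target = target, plus_one = plus_one)
}

# direction of bottom-strand resno with increasing position (+1 or -1)
bottom_direction <- function(bot) {
  ok <- which(!is.na(bot$resno))
  if (length(ok) < 2) return(NA_real_)
  d <- diff(bot$resno[ok]) / diff(ok)
  stats::median(d)
}

sign_or_one <- function(x) if (is.na(x) || x == 0) -1 else sign(x)

#' Look up the residue at a frame position
#' @param frame a `TargetFrame`
#' @param position position label (no 0)
#' @param strand `"top"` or `"bottom"`
#' @return one-row data.frame or NULL
#' @export
frame_residue <- function(frame, position, strand = "top") {
  r <- frame[frame$position == position & frame$strand == strand, ,
             drop = FALSE]
  if (nrow(r) == 0) NULL else r[1, ]
}

#' Structure summary as JSON
#' @param model a `StructureModel`
#' @param path optional output file
#' @return JSON string (invisibly if written to file)
#' @export
structure_summary_json <- function(model, path = NULL) {
  res <- residue_table(model)
  per_chain <- lapply(split(res, res$chain), function(r)
    list(n_residues = nrow(r), kinds = as.list(table(r$kind))))
  j <- jsonlite::toJSON(list(id = model$id, n_atoms = nrow(model$atoms),
                             chains = per_chain), auto_unbox = TRUE,
                        pretty = TRUE)
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}

#' Write chain sequences as FASTA
#' @param model a `StructureModel`
#' @param path output file
#' @param chains chains to write (default: all protein/nucleotide chains)
#' @return `path`, invisibly
#' @export
write_sequences_fasta <- function(model, path, chains = NULL) {
  res <- residue_table(model)
  res <- res[res$kind %in% c("protein", "nucleotide"), , drop = FALSE]
  if (is.null(chains)) chains <- unique(res$chain)
  lines <- unlist(lapply(chains, function(ch)
    c(paste0(">", model$id, "_", ch), as.character(extract_sequence(model, ch)))))
  writeLines(lines, path)
  invisible(path)
}
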