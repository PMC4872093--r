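# Superposition, inter-domain rotation and pairwise sequence identity.

#' Select atoms from a structure model
#'
#' @param model a `StructureModel`
#' @param chain optional chain id
#' @param resno optional residue numbers (vector, may be built with
#'   `ranges()`-style `c(1200:1239, 1297:1440)`)
#' @param elety optional atom names (e.g. `"CA"`)
#' @param kind optional residue kind
#' @return integer atom indices into `model$atoms`
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, elety = NULL,
                         kind = NULL) {
  a <- model$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(resno)) sel <- sel & a$resno %in% resno
  if (!is.null(elety)) sel <- sel & a$elety %in% elety
  if (!is.null(kind)) sel <- sel & a$kind %in% kind
  which(sel)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` over paired rows.
#'
#' @param mobile,reference n x 3 coordinate matrices, rows paired
#' @return object of class `Superposition`: list with `rotation` (3 x 3,
#'   determinant +1), `translation`, `rmsd`, `n_atoms`
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("degeneracy error: need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  if (svd(M)$d[2] < 1e-8) stop("degeneracy error: collinear atoms")
  H <- t(M) %*% R0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - R0)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd, n_atoms = n),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms, rmsd %.3f A\n", x$n_atoms,
              x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 matrix
#' @param sp a `Superposition`
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(xyz, sp) {
  t(sp$rotation %*% t(as.matrix(xyz)) + sp$translation)
}

#' Rotation angle of a rotation matrix, degrees
#' @param R 3 x 3 rotation matrix
#' @return angle in \[0, 180\]
#' @export
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

coords_at <- function(model, idx) {
  as.matrix(model$atoms[idx, c("x", "y", "z")])
}

#' Pair CA atoms of two chains by sequence alignment
#'
#' Global (Needleman-Wunsch, BLOSUM62, gap 10/0.5) alignment of the two
#' chain sequences; aligned residue pairs with CA atoms on both sides give
#' the paired coordinate sets. Residue-number pairing is wrong across
#' homologs with numbering offsets, which is why alignment pairing is the
#' cross-protein default.
#'
#' @param model_a,model_b `StructureModel`s
#' @param chain_a,chain_b chain ids
#' @param resno_a,resno_b optional residue-number restrictions applied
#'   after alignment (e.g. a domain range)
#' @param elety atom used for pairing (default `"CA"`)
#' @return list with matrices `a`, `b` and data.frame `pairs`
#' @export
pair_by_alignment <- function(model_a, chain_a, model_b, chain_b,
                              resno_a = NULL, resno_b = NULL,
                              elety = "CA") {
  res_a <- residue_table(model_a)
  res_a <- res_a[res_a$chain == chain_a & res_a$kind == "protein", ,
                 drop = FALSE]
  res_a <- res_a[order(res_a$resno), , drop = FALSE]
  res_b <- residue_table(model_b)
  res_b <- res_b[res_b$chain == chain_b & res_b$kind == "protein", ,
                 drop = FALSE]
  res_b <- res_b[order(res_b$resno), , drop = FALSE]
  seq_a <- as.character(extract_sequence(model_a, chain_a))
  seq_b <- as.character(extract_sequence(model_b, chain_b))
  aln <- Biostrings::pairwiseAlignment(
    gsub("X", "A", seq_a), gsub("X", "A", seq_b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0; ib <- 0; pairs <- list()
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1
    if (pb[k] != "-") ib <- ib + 1
    if (pa[k] != "-" && pb[k] != "-")
      pairs[[length(pairs) + 1]] <- c(ia, ib)
  }
  pairs <- do.call(rbind, pairs)
  pr <- data.frame(resno_a = res_a$resno[pairs[, 1]],
                   resno_b = res_b$resno[pairs[, 2]])
  if (!is.null(resno_a)) pr <- pr[pr$resno_a %in% resno_a, , drop = FALSE]
  if (!is.null(resno_b)) pr <- pr[pr$resno_b %in% resno_b, , drop = FALSE]
  geta <- function(model, chain, rn) {
    i <- select_atoms(model, chain = chain, resno = rn, elety = elety)
    if (length(i) == 0) NA else i[1]
  }
  ia <- vapply(pr$resno_a, function(rn) geta(model_a, chain_a, rn),
               numeric(1))
  ib <- vapply(pr$resno_b, function(rn) geta(model_b, chain_b, rn),
               numeric(1))
  ok <- !is.na(ia) & !is.na(ib)
  list(a = coords_at(model_a, ia[ok]), b = coords_at(model_b, ib[ok]),
       pairs = pr[ok, , drop = FALSE])
}

#' Superpose one model's selection onto another's
#'
#' @param mobile,reference `StructureModel`s
#' @param chain_mobile,chain_reference chain ids
#' @param resno_mobile,resno_reference optional residue-number selections
#' @param pairing `"alignment"` (default; for homologs) or `"number"`
#' @param elety atom name used (default CA)
#' @return a `Superposition`
#' @export
superpose_models <- function(mobile, reference, chain_mobile,
                             chain_reference, resno_mobile = NULL,
                             resno_reference = NULL,
                             pairing = c("alignment", "number"),
                             elety = "CA") {
  pairing <- match.arg(pairing)
  if (pairing == "alignment") {
    pr <- pair_by_alignment(mobile, chain_mobile, reference,
                            chain_reference, resno_mobile, resno_reference,
                            elety = elety)
    superpose(pr$a, pr$b)
  } else {
    rn <- intersect(
      model_resnos(mobile, chain_mobile, resno_mobile, elety),
      model_resnos(reference, chain_reference, resno_reference, elety))
    im <- vapply(rn, function(r)
      select_atoms(mobile, chain_mobile, r, elety)[1], numeric(1))
    ir <- vapply(rn, function(r)
      select_atoms(reference, chain_reference, r, elety)[1], numeric(1))
    superpose(coords_at(mobile, im), coords_at(reference, ir))
  }
}

model_resnos <- function(model, chain, resno = NULL, elety = "CA") {
  i <- select_atoms(model, chain = chain, resno = resno, elety = elety)
  sort(unique(model$atoms$resno[i]))
}

#' Inter-domain rotation between two structures
#'
#' Superposes model B onto model A over the reference selection, then
#' superposes the (already reference-aligned) mobile selections; the
#' rotation angle of that residual transform is the inter-domain rotation.
#'
#' @param model_a,model_b `StructureModel`s
#' @param chain_a,chain_b chain ids
#' @param ref_a,ref_b residue-number vectors of the reference domain
#' @param mob_a,mob_b residue-number vectors of the mobile domain
#' @param pairing `"alignment"` or `"number"`
#' @return angle in degrees, \[0, 180\]
#' @export
interdomain_rotation <- function(model_a, model_b, chain_a, chain_b,
                                 ref_a, ref_b, mob_a, mob_b,
                                 pairing = c("alignment", "number")) {
  pairing <- match.arg(pairing)
  get_pairs <- function(rn_a, rn_b) {
    if (pairing == "alignment") {
      pr <- pair_by_alignment(model_b, chain_b, model_a, chain_a,
                              resno_a = rn_b, resno_b = rn_a)
      list(b = pr$a, a = pr$b)
    } else {
      rn <- intersect(rn_a, rn_b)
      ia <- vapply(rn, function(r)
        select_atoms(model_a, chain_a, r, "CA")[1], numeric(1))
      ib <- vapply(rn, function(r)
        select_atoms(model_b, chain_b, r, "CA")[1], numeric(1))
      ok <- !is.na(ia) & !is.na(ib)
      list(a = coords_at(model_a, ia[ok]), b = coords_at(model_b, ib[ok]))
    }
  }
  ref <- get_pairs(ref_a, ref_b)
  if (nrow(ref$a) == 0) stop("selection error: empty reference selection")
  s1 <- superpose(ref$b, ref$a)
  mob <- get_pairs(mob_a, mob_b)
  if (nrow(mob$a) == 0) stop("selection error: empty mobile selection")
  s2 <- superpose(apply_superposition(mob$b, s1), mob$a)
  rotation_angle(s2$rotation)
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, extension
#' 0.5); identity is the fraction of identical aligned pairs over alignment
#' columns excluding end gaps, as a percentage.
#'
#' @param seq_a,seq_b amino-acid sequences (strings; `X` allowed)
#' @return percent identity
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  for (s in c(seq_a, seq_b)) {
    if (nchar(s) == 0) stop("empty sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(s)))
      stop("alphabet error: non-amino-acid symbols in sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    gsub("X", "A", toupper(seq_a)), gsub("X", "A", toupper(seq_b)),
    type = "global", substitutionMatrix = "BLOSUM62", gapOpening = 10,
    gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  non_gap_a <- which(pa != "-"); non_gap_b <- which(pb != "-")
  lo <- max(min(non_gap_a), min(non_gap_b))
  hi <- min(max(non_gap_a), max(non_gap_b))
  cols <- lo:hi
  100 * sum(pa[cols] == pb[cols]) / length(cols)
}

#' Named domain ranges of the two crystallized Type ISP enzymes
#'
#' TRD subdomain boundaries (core, jaw, guide) for LlaGI and LlaBIII, the
#' jaw helix that sits in the major groove, and the MTase-TRD window used
#' for coupling analysis (LlaGI numbering).
#'
#' @return data.frame: protein, domain, start, end
#' @export
isp_domains <- function() {
  data.frame(
    protein = c(rep("LlaGI", 6), rep("LlaBIII", 4)),
    domain = c("trd_core", "trd_core2", "trd_jaw", "trd_guide",
               "helix_H", "mtase_trd_window",
               "trd_core", "trd_core2", "trd_jaw", "trd_guide"),
    start = c(1200, 1297, 1240, 1440, 1286, 868,
              1205, 1291, 1245, 1448),
    end = c(1239, 1440, 1296, 1578, 1294, 1428,
            1244, 1448, 1288, 1578),
    stringsAsFactors = FALSE)
}

#' Residue numbers of a named domain
#' @param protein `"LlaGI"` or `"LlaBIII"`
#' @param domains domain names from [isp_domains()] (the two core segments
#'   can be requested together as `"trd_core"` + `"trd_core2"`)
#' @return integer vector of residue numbers
#' @export
domain_resnos <- function(protein, domains) {
  d <- isp_domains()
  d <- d[d$protein == protein & d$domain %in% domains, , drop = FALSE]
  if (nrow(d) == 0) stop("unknown domain for ", protein)
  unlist(mapply(seq, d$start, d$end, SIMPLIFY = FALSE))
}
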