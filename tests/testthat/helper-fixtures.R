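# Shared fixture builders used across the suite.

# duplex whose central bases spell out the CTnGAyG-class target, +1 at the
# embedded T
target_duplex <- function(...) {
  seqs <- paste0("ACGTACGT", "CTAGATG", "ACGTACGTA")
  make_duplex(duplex_spec(seqs, plus_one = 10, ...))
}

rigid_transform <- function(model, angles = c(0.4, 1.1, -0.7),
                            shift = c(12, -5, 31)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                             0, -sin(a), cos(a)), 3, 3)
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  R <- rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
  xyz <- t(R %*% t(as.matrix(model$atoms[, c("x", "y", "z")]))) +
    rep(shift, each = nrow(model$atoms))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# random single-atom pseudo-protein plants on a duplex, all with donor or
# acceptor atoms compatible with the base atom they target
random_plants <- function(frame, n, seed, dmin = 2.8, dmax = 4.5) {
  set.seed(seed)
  # acceptor base atoms get protein donors, donor base atoms get acceptors
  donors <- list(c("LYS", "NZ"), c("ARG", "NH1"), c("SER", "OG"),
                 c("ASN", "ND2"))
  acceptors <- list(c("ASP", "OD1"), c("GLU", "OE1"), c("GLN", "OE1"))
  base_acc <- list(A = c("N7", "N3"), G = c("N7", "O6", "N3"),
                   C = c("O2"), T = c("O4", "O2"))
  base_don <- list(A = "N6", G = "N2", C = "N4", T = character(0))
  rows <- lapply(seq_len(n), function(i) {
    fr <- frame[sample(nrow(frame), 1), ]
    use_donor <- runif(1) < 0.7
    if (use_donor) {
      ba <- base_acc[[fr$base]]
      pa <- donors[[sample(length(donors), 1)]]
    } else {
      ba <- base_don[[fr$base]]
      if (length(ba) == 0) {
        ba <- base_acc[[fr$base]]
        pa <- donors[[sample(length(donors), 1)]]
      } else pa <- acceptors[[sample(length(acceptors), 1)]]
    }
    data.frame(resname = pa[1], resno = 100 + i, atom = pa[2],
               position = fr$position, strand = fr$strand,
               base_atom = sample(ba, 1),
               distance = runif(1, dmin, dmax),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# brute-force all-pairs hydrogen-bond scan (independent oracle)
oracle_hbond_scan <- function(model, frame, cutoff = 3.5) {
  dict <- chemistry_dictionaries()
  a <- model$atoms
  recs <- list()
  for (i in which(a$kind == "protein")) {
    p_don <- a$elety[i] %in% dict$protein_donors[[a$resid[i]]] ||
      a$elety[i] == dict$mainchain_donor
    p_acc <- a$elety[i] %in% dict$protein_acceptors[[a$resid[i]]] ||
      a$elety[i] == dict$mainchain_acceptor
    if (!p_don && !p_acc) next
    for (r in seq_len(nrow(frame))) {
      fr <- frame[r, ]
      for (j in which(a$chain == fr$chain & a$resno == fr$resno &
                        a$ins == fr$ins)) {
        b <- base_letter(a$resid[j])
        d_don <- a$elety[j] %in% dict$base_donors[[b]]
        d_acc <- a$elety[j] %in% dict$base_acceptors[[b]] ||
          a$elety[j] %in% dict$backbone_acceptors
        if (!d_don && !d_acc) next
        if (!((p_don && d_acc) || (p_acc && d_don))) next
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
        if (d <= cutoff)
          recs[[length(recs) + 1]] <- data.frame(
            resno = a$resno[i], atom = a$elety[i], position = fr$position,
            strand = fr$strand, nt_atom = a$elety[j],
            distance_A = d, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) return(out)
  out[order(out$position, out$resno, out$atom, out$nt_atom), , drop = FALSE]
}

contact_key <- function(ct) {
  if (is.null(ct) || nrow(ct) == 0) return(character(0))
  sort(paste(ct$resno, ct$atom, ct$position, ct$strand, ct$nt_atom))
}

# synthetic two-domain CA-only protein pair with a planted hinge rotation
two_domain_models <- function(theta_deg, seed = 11) {
  set.seed(seed)
  walk <- function(n, start) {
    steps <- matrix(rnorm(3 * n), n, 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 3.8
    sweep(apply(steps, 2, cumsum), 2, -start)
  }
  dom1 <- walk(40, c(0, 0, 0))
  dom2 <- walk(40, c(30, 0, 0))
  mk <- function(xyz1, xyz2) {
    as_structure_model(data.frame(
      chain = "A", resno = c(1:40, 101:140), resid = "ALA", elety = "CA",
      x = c(xyz1[, 1], xyz2[, 1]), y = c(xyz1[, 2], xyz2[, 2]),
      z = c(xyz1[, 3], xyz2[, 3]), stringsAsFactors = FALSE))
  }
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  hinge <- c(30, 0, 0)
  dom2_rot <- t(R %*% (t(dom2) - hinge) + hinge)
  list(a = mk(dom1, dom2), b = mk(dom1, dom2_rot))
}
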