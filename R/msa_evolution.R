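# Alignment conservation, mutual-information coupling with average-product
# correction, per-residue coupling strength, top-fraction selection and
# contact-residue enrichment.

# BLOSUM62 amino-acid background frequencies (Henikoff & Henikoff)
BLOSUM62_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073)

new_msa <- function(ids, aln, ref = NULL) {
  stopifnot(is.matrix(aln), length(ids) == nrow(aln))
  structure(list(ids = ids, aln = aln, ref = ref), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", nrow(x$aln), "sequences x", ncol(x$aln), "columns")
  if (!is.null(x$ref)) cat(", reference", x$ref$id)
  cat("\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Aligned FASTA, Clustal or Stockholm. All rows must have equal length.
#'
#' @param path alignment file
#' @param format `"auto"` (default, by extension/content), `"fasta"`,
#'   `"clustal"` or `"stockholm"`
#' @return an `msa` object (list with `ids`, `aln` character matrix, `ref`)
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal",
                                      "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("missing input: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^CLUSTAL", first)) "clustal"
    else if (grepl("^# STOCKHOLM", first)) "stockholm"
    else "fasta"
  }
  ss <- if (format == "fasta") Biostrings::readAAStringSet(path)
  else Biostrings::readAAMultipleAlignment(path, format = format)@unmasked
  if (length(unique(Biostrings::width(ss))) != 1)
    stop("rows have unequal lengths; not an alignment")
  aln <- do.call(rbind, unname(strsplit(toupper(as.character(ss)), "")))
  aln[aln == "."] <- "-"
  ids <- sub("\\s.*", "", names(ss))
  dimnames(aln) <- list(ids, NULL)
  new_msa(ids, aln)
}

#' Write an alignment as aligned FASTA
#' @param msa an `msa`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_msa_fasta <- function(msa, path) {
  lines <- unlist(lapply(seq_along(msa$ids), function(i)
    c(paste0(">", msa$ids[i]), paste(msa$aln[i, ], collapse = ""))))
  writeLines(lines, path)
  invisible(path)
}

#' Attach a reference numbering to an alignment
#'
#' Columns where the reference row is ungapped are numbered consecutively
#' from `start`; gap columns of the reference get NA.
#'
#' @param msa an `msa`
#' @param id reference sequence id (must be a row of the alignment)
#' @param start residue number of the reference's first ungapped column
#' @return the `msa` with a `ref` component (`id`, `numbers`)
#' @export
set_reference <- function(msa, id, start = 1) {
  i <- match(id, msa$ids)
  if (is.na(i)) stop("reference id not found: ", id)
  row <- msa$aln[i, ]
  numbers <- rep(NA_integer_, length(row))
  numbers[row != "-"] <- as.integer(seq(start, length.out = sum(row != "-")))
  msa$ref <- list(id = id, numbers = numbers)
  msa
}

#' Position-based (Henikoff) sequence weights
#'
#' @param aln character matrix (rows sequences); gaps count as a symbol
#' @return numeric weights, normalized to mean 1
#' @export
henikoff_weights <- function(aln) {
  n <- nrow(aln)
  w <- numeric(n)
  for (j in seq_len(ncol(aln))) {
    col <- aln[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  w * n / sum(w)
}

#' Per-column conservation profile
#'
#' Raw score per column is the sequence-weighted relative entropy of the
#' column's amino-acid frequencies against the BLOSUM62 background (bits);
#' fully conserved columns score highest. The rescaled score follows the
#' flip-and-shift convention: multiplied by -1 and shifted by a constant
#' chosen so the minimum over defined columns is exactly 0. Columns with
#' more than `gap_max` gap fraction are flagged undefined.
#'
#' @param msa an `msa`
#' @param gap_max maximum tolerated gap fraction per column (default 0.5)
#' @return data.frame of class `ConservationProfile`: column, ref_residue,
#'   raw, rescaled, gap_frac, defined
#' @export
conservation_profile <- function(msa, gap_max = 0.5) {
  aln <- msa$aln
  if (nrow(aln) < 2) stop("need at least 2 sequences")
  w <- henikoff_weights(aln)
  bg <- BLOSUM62_BACKGROUND / sum(BLOSUM62_BACKGROUND)
  L <- ncol(aln)
  raw <- rep(NA_real_, L); gap_frac <- numeric(L)
  for (j in seq_len(L)) {
    col <- aln[, j]
    gap_frac[j] <- mean(col == "-")
    if (gap_frac[j] > gap_max) next
    keep <- col %in% names(bg)
    if (!any(keep)) next
    f <- tapply(w[keep], col[keep], sum)
    f <- f / sum(f)
    raw[j] <- sum(f * log2(f / bg[names(f)]))
  }
  defined <- !is.na(raw)
  rescaled <- rep(NA_real_, L)
  if (any(defined)) {
    offset <- max(raw[defined])
    rescaled[defined] <- -raw[defined] + offset
  }
  ref_res <- if (!is.null(msa$ref)) msa$ref$numbers else rep(NA_integer_, L)
  out <- data.frame(column = seq_len(L), ref_residue = ref_res, raw = raw,
                    rescaled = rescaled, gap_frac = gap_frac,
                    defined = defined)
  class(out) <- c("ConservationProfile", "data.frame")
  out
}

encode_alignment <- function(aln) {
  symbols <- c(AMINO20, "-")
  E <- matrix(match(aln, symbols), nrow(aln), ncol(aln))
  E[is.na(E)] <- 21  # unknowns treated with gaps
  E
}

#' Mutual-information coupling matrix with APC correction
#'
#' Pairwise coupling between alignment columns as mutual information (bits)
#' of sequence-weighted joint frequencies with a pseudocount, gaps as a
#' 21st symbol, followed by average-product correction
#' MIapc(i,j) = MI(i,j) - MI(i,.) MI(.,j) / MI(avg). Per-residue coupling
#' strength is the sum of positive corrected couplings of that residue over
#' the L strongest pairs (L = number of analysed columns). Columns with
#' more than `gap_max` gap fraction are excluded and flagged.
#'
#' @param msa an `msa`
#' @param window optional reference residue-number range (length-2) to
#'   restrict the analysis (requires [set_reference()])
#' @param pseudocount per-cell pseudocount for joint frequencies
#'   (default 0.5)
#' @param weights `"henikoff"` (default) or `"none"`
#' @param gap_max column gap-fraction threshold (default 0.5)
#' @return object of class `CouplingResult`: list with `mi`, `mi_apc`
#'   (symmetric matrices, zero diagonal), `strength` (data.frame: column,
#'   ref_residue, strength, rank), `columns`, `excluded`
#' @export
coupling_matrix <- function(msa, window = NULL, pseudocount = 0.5,
                            weights = c("henikoff", "none"),
                            gap_max = 0.5) {
  weights <- match.arg(weights)
  aln <- msa$aln
  cols <- seq_len(ncol(aln))
  if (!is.null(window)) {
    if (is.null(msa$ref)) stop("window requires a reference numbering")
    cols <- which(!is.na(msa$ref$numbers) &
                    msa$ref$numbers >= min(window) &
                    msa$ref$numbers <= max(window))
    if (length(cols) < 2) stop("range error: window maps to < 2 columns")
  }
  gap_frac <- colMeans(aln[, cols, drop = FALSE] == "-")
  excluded <- cols[gap_frac > gap_max]
  cols <- cols[gap_frac <= gap_max]
  L <- length(cols)
  if (L < 2) stop("fewer than 2 usable columns")
  n <- nrow(aln)
  w <- if (weights == "henikoff") henikoff_weights(aln) else rep(1, n)
  E <- encode_alignment(aln[, cols, drop = FALSE])
  # per-column one-hot blocks, weight-scaled on one side
  onehot <- lapply(seq_len(L), function(j) {
    O <- matrix(0, n, 21)
    O[cbind(seq_len(n), E[, j])] <- 1
    O
  })
  onehot_w <- lapply(onehot, function(O) O * w)
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    Oi <- onehot_w[[i]]
    for (j in (i + 1):L) {
      joint <- crossprod(Oi, onehot[[j]]) + pseudocount
      p <- joint / sum(joint)
      pi_ <- rowSums(p); pj <- colSums(p)
      t <- p * log2(p / outer(pi_, pj))
      mi[i, j] <- mi[j, i] <- sum(t[p > 0])
    }
  }
  row_mean <- rowSums(mi) / (L - 1)
  grand <- sum(mi) / (L * (L - 1))
  apc <- mi - outer(row_mean, row_mean) / grand
  diag(apc) <- 0
  # strength: positive corrected couplings among the top-L pairs
  ut <- which(upper.tri(apc), arr.ind = TRUE)
  ord <- order(apc[ut], decreasing = TRUE)
  top <- ut[ord[seq_len(min(L, nrow(ut)))], , drop = FALSE]
  strength <- numeric(L)
  for (r in seq_len(nrow(top))) {
    v <- apc[top[r, 1], top[r, 2]]
    if (v > 0) {
      strength[top[r, 1]] <- strength[top[r, 1]] + v
      strength[top[r, 2]] <- strength[top[r, 2]] + v
    }
  }
  ref_res <- if (!is.null(msa$ref)) msa$ref$numbers[cols] else
    rep(NA_integer_, L)
  strength_df <- data.frame(column = cols, ref_residue = ref_res,
                            strength = strength,
                            rank = rank(-strength, ties.method = "min"))
  dimnames(mi) <- dimnames(apc) <- list(cols, cols)
  structure(list(mi = mi, mi_apc = apc, strength = strength_df,
                 columns = cols, excluded = excluded),
            class = "CouplingResult")
}

#' @export
print.CouplingResult <- function(x, ...) {
  cat("CouplingResult over", length(x$columns), "columns;",
      length(x$excluded), "excluded (gaps)\n")
  invisible(x)
}

#' Select the top fraction of scored residues
#'
#' Picks `floor(fraction * n)` residues with the highest scores; ties at
#' the selection boundary are broken in favour of the lower residue number.
#'
#' @param scores named numeric vector (names = residue numbers)
#' @param fraction fraction in (0, 1]
#' @return sorted integer vector of selected residue numbers
#' @export
top_fraction <- function(scores, fraction = 0.1) {
  if (length(scores) == 0) stop("empty score vector")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  k <- floor(fraction * length(scores))
  ord <- order(-scores, as.numeric(names(scores)))
  sort(as.integer(names(scores)[ord][seq_len(k)]))
}

#' Enrichment of contact residues in a selected set
#'
#' Overlap between a selected residue set (e.g. a top coupling-strength
#' fraction) and a set of contact residues, with the hypergeometric upper
#' tail probability P(X >= overlap).
#'
#' @param selected integer vector of selected residue numbers
#' @param contacts integer vector of contact residue numbers
#' @param n_total total number of scored residues
#' @return list: overlap, n_selected, n_contacts, n_total, p_value
#' @export
contact_enrichment <- function(selected, contacts, n_total) {
  selected <- unique(selected); contacts <- unique(contacts)
  overlap <- length(intersect(selected, contacts))
  p <- stats::phyper(overlap - 1, length(contacts),
                     n_total - length(contacts), length(selected),
                     lower.tail = FALSE)
  list(overlap = overlap, n_selected = length(selected),
       n_contacts = length(contacts), n_total = n_total, p_value = p)
}

#' Write a per-column conservation/coupling TSV
#' @param profile a `ConservationProfile`
#' @param coupling optional `CouplingResult` to merge by column
#' @param path output file
#' @return `path`, invisibly
#' @export
write_column_scores_tsv <- function(profile, coupling = NULL, path) {
  out <- as.data.frame(profile)
  if (!is.null(coupling)) {
    m <- match(out$column, coupling$strength$column)
    out$ec_strength <- coupling$strength$strength[m]
    out$ec_rank <- coupling$strength$rank[m]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
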