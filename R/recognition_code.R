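# Anchor-residue mapping across homologs, residue <-> target-base
# association tabulation, and target prediction from anchor residues.

# Structural elements involved in target recognition (reference numbering).
# `astart`/`aend` are the anchor-containment windows, slightly wider than
# the printed element boundaries to absorb numbering offsets between
# homologs.
.RECOGNITION_ELEMENTS <- data.frame(
  element = c("Loop I", "Loop II", "Loop III", "Loop IV", "Loop V",
              "Loop VI", "helix H"),
  start = c(1017, 1053, 1115, 1223, 1324, 1365, 1286),
  end = c(1027, 1062, 1138, 1230, 1331, 1374, 1294),
  astart = c(1017, 1053, 1115, 1223, 1317, 1358, 1286),
  aend = c(1027, 1062, 1138, 1231, 1331, 1374, 1294),
  stringsAsFactors = FALSE)

.ANCHOR_RESIDUES <- c(1023, 1024, 1055, 1056, 1058, 1118, 1125, 1131,
                      1226, 1228, 1231, 1286, 1287, 1318, 1319, 1321,
                      1326, 1327, 1329, 1360, 1368, 1372, 1373)

#' Recognition elements and anchor residues
#'
#' The six loops and the jaw helix that carry the base-reading residues,
#' with the anchor residue numbers (reference numbering) observed or
#' predicted to read target bases. Every anchor lies in exactly one
#' element's containment window.
#'
#' @return list of class `RecognitionAnchors`: `elements` (data.frame) and
#'   `anchors` (integer vector)
#' @export
recognition_anchors <- function() {
  el <- .RECOGNITION_ELEMENTS
  hits <- vapply(.ANCHOR_RESIDUES, function(a)
    sum(a >= el$astart & a <= el$aend), numeric(1))
  stopifnot(all(hits == 1))
  structure(list(elements = el, anchors = .ANCHOR_RESIDUES),
            class = "RecognitionAnchors")
}

#' Element containing an anchor residue
#' @param resno anchor residue number(s)
#' @return character vector of element names (NA if outside all windows)
#' @export
anchor_element <- function(resno) {
  el <- .RECOGNITION_ELEMENTS
  vapply(resno, function(a) {
    i <- which(a >= el$astart & a <= el$aend)
    if (length(i) == 0) NA_character_ else el$element[i[1]]
  }, character(1))
}

#' Map anchor residues across an alignment
#'
#' For each sequence, the residue aligned to each reference-numbered anchor
#' column; gaps come out as NA. The reference sequence must be ungapped at
#' the anchor columns.
#'
#' @param msa an `msa` with a reference set ([set_reference()])
#' @param anchors integer anchor residue numbers (default: the full set)
#' @return data.frame: one row per sequence, columns `enzyme` then
#'   `A<resno>` per anchor
#' @export
map_anchor_residues <- function(msa, anchors = NULL) {
  if (is.null(msa$ref)) stop("alignment has no reference numbering")
  if (is.null(anchors)) anchors <- recognition_anchors()$anchors
  cols <- match(anchors, msa$ref$numbers)
  if (any(is.na(cols)))
    stop("anchor(s) outside the reference numbering: ",
         paste(anchors[is.na(cols)], collapse = ","))
  out <- data.frame(enzyme = msa$ids, stringsAsFactors = FALSE)
  for (k in seq_along(anchors)) {
    v <- msa$aln[, cols[k]]
    v[v == "-"] <- NA_character_
    out[[paste0("A", anchors[k])]] <- v
  }
  out
}

# target string position labels (no position 0)
TARGET_POSITIONS <- c(-1, 1, 2, 3, 4, 5, 6)

# oriented base pair written top:bottom
pair_of <- function(top) paste0(top, ":", WC_PARTNER[[top]])

# expand a target letter at a position into oriented base pairs + weights
expand_base <- function(letter) {
  letter <- toupper(letter)
  if (letter %in% c("N", "X") || is.na(letter)) return(NULL)
  bases <- IUPAC_DNA[[letter]]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(bases) == 0) return(NULL)
  data.frame(pair = vapply(bases, pair_of, character(1)),
             weight = 1 / length(bases), stringsAsFactors = FALSE)
}

#' Build enzyme/target entries from a target table and anchor residues
#'
#' @param targets data.frame with columns `enzyme` and `target` (string
#'   over positions -1..+6, IUPAC; `n` marks unspecified positions; shorter
#'   targets are right-padded as unspecified)
#' @param anchor_residues data.frame from [map_anchor_residues()] (or of
#'   the same shape)
#' @return data.frame of class `EnzymeTargetEntries` combining both
#' @export
enzyme_target_entries <- function(targets, anchor_residues) {
  m <- match(targets$enzyme, anchor_residues$enzyme)
  if (any(is.na(m))) stop("no anchor residues for: ",
                          paste(targets$enzyme[is.na(m)], collapse = ","))
  out <- cbind(targets, anchor_residues[m, -1, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("EnzymeTargetEntries", "data.frame")
  out
}

target_letter_at <- function(target, position) {
  i <- match(position, TARGET_POSITIONS)
  chars <- strsplit(target, "")[[1]]
  if (is.na(i) || i > length(chars)) NA_character_ else chars[i]
}

#' Derive the residue-to-base recognition code
#'
#' For every (target position, oriented base pair) observed and every
#' anchor, the association score is the product of the two conditional
#' purities P(residue | base pair) x P(base pair | residue), computed over
#' the enzymes that specify that position (degenerate target letters
#' contribute fractional weight to each compatible base pair). Entries
#' reaching `threshold` with weighted support of at least `min_support`
#' enzymes form the code.
#'
#' @param entries an `EnzymeTargetEntries` data.frame
#' @param threshold association score threshold (default 0.8)
#' @param min_support minimum weighted enzyme support (default 2)
#' @return data.frame of class `CodeTable`: position, pair, anchor,
#'   residue, score, support, predicted
#' @export
derive_code <- function(entries, threshold = 0.8, min_support = 2) {
  anchors <- grep("^A[0-9]+$", names(entries), value = TRUE)
  has_base <- vapply(seq_len(nrow(entries)), function(i)
    any(!vapply(TARGET_POSITIONS, function(p)
      is.null(expand_base(target_letter_at(entries$target[i], p))),
      logical(1))), logical(1))
  if (sum(has_base) < 3)
    stop("need >= 3 entries with specified bases")
  obs <- list()
  for (i in seq_len(nrow(entries))) {
    for (p in TARGET_POSITIONS) {
      ex <- expand_base(target_letter_at(entries$target[i], p))
      if (is.null(ex)) next
      for (r in seq_len(nrow(ex))) {
        for (a in anchors) {
          res <- entries[[a]][i]
          if (is.na(res)) next
          obs[[length(obs) + 1]] <- data.frame(
            enzyme = entries$enzyme[i], position = p, pair = ex$pair[r],
            weight = ex$weight[r], anchor = as.integer(sub("^A", "", a)),
            residue = res, stringsAsFactors = FALSE)
        }
      }
    }
  }
  obs <- do.call(rbind, obs)
  if (is.null(obs)) stop("no specified positions in entries")
  recs <- list()
  for (p in unique(obs$position)) {
    op <- obs[obs$position == p, , drop = FALSE]
    for (a in unique(op$anchor)) {
      oa <- op[op$anchor == a, , drop = FALSE]
      for (pr in unique(oa$pair)) {
        for (res in unique(oa$residue)) {
          both <- sum(oa$weight[oa$pair == pr & oa$residue == res])
          w_pair <- sum(oa$weight[oa$pair == pr])
          w_res <- sum(oa$weight[oa$residue == res])
          if (both == 0) next
          score <- (both / w_pair) * (both / w_res)
          recs[[length(recs) + 1]] <- data.frame(
            position = p, pair = pr, anchor = a, residue = res,
            score = score, support = both, predicted = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  code <- do.call(rbind, recs)
  code <- code[code$score >= threshold & code$support >= min_support, ,
               drop = FALSE]
  code <- code[order(code$position, code$pair, code$anchor), , drop = FALSE]
  rownames(code) <- NULL
  class(code) <- c("CodeTable", "data.frame")
  attr(code, "threshold") <- threshold
  attr(code, "min_support") <- min_support
  code
}

#' Add a hypothesis entry to a code table
#'
#' Stores a predicted (not data-supported) residue/base association,
#' flagged `predicted = TRUE`; such entries are never produced by
#' [derive_code()] and are excluded from support accounting.
#'
#' @param code a `CodeTable`
#' @param position target position
#' @param pair oriented base pair (e.g. `"G:C"`)
#' @param anchor anchor residue number
#' @param residue one-letter amino acid
#' @return the augmented `CodeTable`
#' @export
add_predicted_entry <- function(code, position, pair, anchor, residue) {
  row <- data.frame(position = position, pair = pair, anchor = anchor,
                    residue = residue, score = NA_real_, support = 0,
                    predicted = TRUE, stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(code), row)
  class(out) <- class(code)
  attributes(out)[c("threshold", "min_support")] <-
    attributes(code)[c("threshold", "min_support")]
  out
}

#' Predict a target from anchor residues
#'
#' For every coded position, the oriented base pair whose (non-predicted)
#' code entries best match the supplied residues wins; the confidence is
#' the summed matched association score. Positions with no match come out
#' unspecified with zero confidence.
#'
#' @param residues named character vector of anchor residues (names =
#'   `A<resno>` or plain residue numbers)
#' @param code a `CodeTable`
#' @return data.frame: position, pair (NA if unspecified), confidence
#' @export
predict_target <- function(residues, code) {
  code <- code[!code$predicted, , drop = FALSE]
  if (nrow(code) == 0) stop("code table is empty")
  nm <- sub("^A", "", names(residues))
  res_by_anchor <- stats::setNames(as.character(residues), nm)
  out <- list()
  for (p in sort(unique(code$position))) {
    cp <- code[code$position == p, , drop = FALSE]
    pairs <- unique(cp$pair)
    conf <- vapply(pairs, function(pr) {
      e <- cp[cp$pair == pr, , drop = FALSE]
      m <- res_by_anchor[as.character(e$anchor)]
      sum(e$score[!is.na(m) & m == e$residue])
    }, numeric(1))
    if (max(conf) <= 0) {
      out[[length(out) + 1]] <- data.frame(position = p,
                                           pair = NA_character_,
                                           confidence = 0)
    } else {
      best <- which.max(conf)
      out[[length(out) + 1]] <- data.frame(position = p,
                                           pair = pairs[best],
                                           confidence = conf[best])
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Synthetic enzyme/target entries with a planted recognition code
#'
#' Eleven pseudo-enzymes built around planted anchor-residue/base-pair
#' associations of the kind seen across Type ISP homologs: lysine at 1131
#' with C:G at -1 (asparagine otherwise), asparagine at 1228 with A:T at +4
#' versus lysine at 1226 with G:C, arginine at 1286 with G:C at +6 versus
#' arginine at 1327 with C:G, and histidine at 1368 with G:C at +3 versus
#' asparagine with A:T. Position +2 is left non-specific everywhere. Other
#' anchors carry label-independent filler residues drawn per enzyme.
#'
#' @param seed RNG seed
#' @param n_noise number of enzymes whose anchor residues are randomly
#'   relabelled (default 0)
#' @return an `EnzymeTargetEntries` data.frame (11 rows)
#' @export
synthetic_code_entries <- function(seed = 1, n_noise = 0) {
  set.seed(seed)
  planted <- list(
    list(position = -1, spec = c("C" = "K"), none = "N", anchor = 1131),
    list(position = 3, spec = c("G" = "H", "A" = "N"), none = "V",
         anchor = 1368),
    list(position = 4, spec = c("A" = "N"), none = "S", anchor = 1228),
    list(position = 4, spec = c("G" = "K"), none = "T", anchor = 1226),
    list(position = 6, spec = c("G" = "R"), none = "L", anchor = 1286),
    list(position = 6, spec = c("C" = "R"), none = "Q", anchor = 1327))
  # top-strand target letters per enzyme at -1,+1,+2,+3,+4,+5,+6
  targets <- rbind(
    c("C", "T", "n", "G", "A", "Y", "G"),
    c("n", "T", "n", "A", "G", "C", "C"),
    c("C", "T", "n", "G", "G", "T", "n"),
    c("C", "T", "n", "A", "A", "C", "G"),
    c("n", "T", "n", "G", "A", "T", "C"),
    c("C", "T", "n", "G", "G", "A", "G"),
    c("n", "T", "n", "A", "A", "G", "n"),
    c("C", "T", "n", "G", "A", "C", "G"),
    c("n", "T", "n", "A", "G", "T", "C"),
    c("C", "T", "n", "G", "G", "C", "G"),
    c("n", "T", "n", "A", "A", "A", "C"))
  enzymes <- sprintf("Enz%02d", seq_len(nrow(targets)))
  anchors <- recognition_anchors()$anchors
  ar <- data.frame(enzyme = enzymes, stringsAsFactors = FALSE)
  filler <- c("A", "G", "S", "T", "V", "L", "I", "P", "E", "D")
  # non-reading anchors carry one label-independent residue per column,
  # the pattern seen at positions an enzyme does not recognize
  for (k in seq_along(anchors)) ar[[paste0("A", anchors[k])]] <-
    filler[(k - 1) %% length(filler) + 1]
  for (pl in planted) {
    col <- paste0("A", pl$anchor)
    i <- match(pl$position, TARGET_POSITIONS)
    top <- targets[, i]
    res <- rep(pl$none, length(enzymes))
    for (b in names(pl$spec)) res[top == b] <- pl$spec[[b]]
    ar[[col]] <- res
  }
  if (n_noise > 0) {
    noisy <- sample(length(enzymes), n_noise)
    planted_cols <- unique(vapply(planted, function(pl)
      paste0("A", pl$anchor), character(1)))
    for (i in noisy) {
      col <- sample(planted_cols, 1)
      ar[i, col] <- sample(filler, 1)
    }
  }
  tg <- data.frame(enzyme = enzymes,
                   target = apply(targets, 1, paste, collapse = ""),
                   stringsAsFactors = FALSE)
  enzyme_target_entries(tg, ar)
}

#' Write a code table as TSV
#' @param code a `CodeTable`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_code_tsv <- function(code, path) {
  utils::write.table(as.data.frame(code), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
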