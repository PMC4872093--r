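test_that("every anchor residue lies in exactly one recognition element", {
  ra <- recognition_anchors()
  el <- ra$elements
  for (a in ra$anchors) {
    hits <- sum(a >= el$astart & a <= el$aend)
    expect_equal(hits, 1)
  }
  expect_identical(anchor_element(1131), "Loop III")
  expect_identical(anchor_element(1286), "helix H")
  expect_identical(anchor_element(1360), "Loop VI")
  expect_true(is.na(anchor_element(500)))
})

test_that("anchor mapping is the identity on the reference row", {
  # reference ungapped; a second sequence carries an insertion-driven gap
  ref <- strsplit(paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = ""),
                  "")[[1]]
  other <- ref
  other[10] <- "-"
  aln <- rbind(ref, other)
  m <- isprm:::new_msa(c("RefEnz", "OtherEnz"), aln)
  m <- set_reference(m, "RefEnz", start = 1100)
  anchors <- c(1105, 1109, 1131)
  got <- map_anchor_residues(m, anchors)
  expect_identical(got$A1105[1], ref[6])
  expect_identical(got$A1131[1], ref[32])
  expect_true(is.na(got$A1109[2]))   # gap comes out absent
  expect_identical(got$A1105[2], ref[6])
  expect_error(map_anchor_residues(m, 5000), "outside")
})

test_that("anchors still map correctly across planted insertions", {
  # insertion in another sequence adds a gap column to the reference
  ref <- c("K", "-", "L", "M", "N")
  other <- c("K", "W", "L", "M", "N")
  m <- isprm:::new_msa(c("r", "o"), rbind(ref, other))
  m <- set_reference(m, "r", start = 1)
  got <- map_anchor_residues(m, anchors = c(2, 3))
  expect_identical(got$A2[1], "L")
  expect_identical(got$A2[2], "L")
})

test_that("derive_code reports planted associations at full score", {
  entries <- synthetic_code_entries(seed = 1)
  code <- derive_code(entries)
  planted <- data.frame(
    position = c(-1, 3, 3, 4, 4, 6, 6),
    pair = c("C:G", "G:C", "A:T", "A:T", "G:C", "G:C", "C:G"),
    anchor = c(1131, 1368, 1368, 1228, 1226, 1286, 1327),
    residue = c("K", "H", "N", "N", "K", "R", "R"))
  for (i in seq_len(nrow(planted))) {
    hit <- code[code$position == planted$position[i] &
                  code$pair == planted$pair[i] &
                  code$anchor == planted$anchor[i] &
                  code$residue == planted$residue[i], ]
    expect_equal(nrow(hit), 1)
    expect_gte(hit$score, 0.8)
    expect_gte(hit$support, 2)
  }
  expect_error(derive_code(entries[1:2, ]), ">= 3 entries")
})

test_that("a constant residue at a varying position is not reported", {
  entries <- synthetic_code_entries(seed = 1)
  # anchor 1318 is constant filler; +3 varies G/A across enzymes
  at3 <- derive_code(entries)
  const <- at3[at3$position == 3 & at3$anchor == 1318, ]
  expect_equal(nrow(const), 0)
})

test_that("derive_code is invariant to entry order", {
  entries <- synthetic_code_entries(seed = 2)
  set.seed(3)
  shuffled <- entries[sample(nrow(entries)), ]
  c1 <- as.data.frame(derive_code(entries))
  c2 <- as.data.frame(derive_code(shuffled))
  key <- function(x) x[order(x$position, x$pair, x$anchor, x$residue), ]
  expect_equal(key(c1), key(c2), ignore_attr = TRUE)
})

test_that("a consistent extra enzyme never lowers an entry's score", {
  entries <- synthetic_code_entries(seed = 1)
  code <- derive_code(entries)
  extra <- entries[1, ]
  extra$enzyme <- "EnzXX"
  bigger <- derive_code(rbind(entries, extra))
  for (i in seq_len(nrow(code))) {
    m <- bigger[bigger$position == code$position[i] &
                  bigger$pair == code$pair[i] &
                  bigger$anchor == code$anchor[i] &
                  bigger$residue == code$residue[i], ]
    expect_equal(nrow(m), 1)
    expect_gte(m$score + 1e-12, code$score[i])
  }
})

test_that("planted associations survive relabelling noise across seeds", {
  for (seed in 1:10) {
    entries <- synthetic_code_entries(seed = seed, n_noise = 1)
    code <- derive_code(entries)
    hit <- code[code$position == -1 & code$pair == "C:G" &
                  code$anchor == 1131 & code$residue == "K", ]
    expect_equal(nrow(hit), 1)
    expect_gte(hit$score, 0.8)
  }
})

test_that("prediction is self-consistent and maps K1131 to C:G at -1", {
  entries <- synthetic_code_entries(seed = 1)
  code <- derive_code(entries)
  pred <- predict_target(c(A1131 = "K"), code)
  expect_identical(pred$pair[pred$position == -1], "C:G")
  # a training enzyme's own residues recover its own coded positions
  res <- unlist(entries[1, grep("^A", names(entries))])
  names(res) <- sub("^A", "", names(res))
  own <- predict_target(res, code)
  expect_identical(own$pair[own$position == -1], "C:G")
  expect_identical(own$pair[own$position == 4], "A:T")
  expect_identical(own$pair[own$position == 6], "G:C")
  # residues matching nothing -> unspecified, zero confidence
  none <- predict_target(c(A1131 = "Z", A1228 = "Z"), code)
  expect_true(all(is.na(none$pair)))
  expect_true(all(none$confidence == 0))
})

test_that("predicted (hypothesis) entries are flagged and never train", {
  entries <- synthetic_code_entries(seed = 1)
  code <- derive_code(entries)
  code2 <- add_predicted_entry(code, -1, "G:C", 1125, "R")
  expect_true(any(code2$predicted))
  p <- predict_target(c(A1125 = "R"), code2)
  expect_true(is.na(p$pair[p$position == -1]) ||
                p$pair[p$position == -1] != "G:C")
})

test_that("leave-one-out prediction recovers held-out bases", {
  entries <- synthetic_code_entries(seed = 1)
  n_ok <- 0; n_tot <- 0
  for (i in seq_len(nrow(entries))) {
    cd <- derive_code(entries[-i, ])
    res <- unlist(entries[i, grep("^A", names(entries))])
    names(res) <- sub("^A", "", names(res))
    pred <- predict_target(res, cd)
    for (p in pred$position[!is.na(pred$pair)]) {
      letter <- isprm:::target_letter_at(entries$target[i], p)
      ex <- isprm:::expand_base(letter)
      if (is.null(ex)) next
      n_tot <- n_tot + 1
      if (pred$pair[pred$position == p] %in% ex$pair) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.9)
})

test_that("code tables write as TSV", {
  code <- derive_code(synthetic_code_entries(seed = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_code_tsv(code, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), nrow(code))
})
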