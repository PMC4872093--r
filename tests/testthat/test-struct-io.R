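test_that("write-then-read round trip preserves atoms, names, coordinates", {
  d <- target_duplex()
  pc <- plant_contacts(d, data.frame(
    resname = "LYS", resno = 1131, atom = "NZ", position = -1,
    strand = "bottom", base_atom = "N7", distance = 3.4))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pc$model, f)
  m2 <- load_structure(f, format = "pdb")
  expect_equal(nrow(m2$atoms), nrow(pc$model$atoms))
  expect_equal(m2$atoms$elety, pc$model$atoms$elety)
  expect_equal(m2$atoms$resid, pc$model$atoms$resid)
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                      as.matrix(pc$model$atoms[, c("x", "y", "z")]))),
            1e-3)
})

test_that("unknown residue names classify as 'other' without error", {
  expect_identical(residue_kind(c("ALA", "DA", "HOH", "XYZ")),
                   c("protein", "nucleotide", "water", "other"))
  d <- target_duplex()
  m <- d$model
  m$atoms$resid[m$atoms$resno == 1 & m$atoms$chain == "A"] <- "UNK"
  m <- as_structure_model(m$atoms, m$id)
  res <- residue_table(m)
  expect_identical(res$kind[res$chain == "A" & res$resno == 1], "other")
})

test_that("alternate conformers reduce to the highest-occupancy one", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O  AGLY A   2       3.000   0.000   0.000  0.50  0.00           O",
    "ATOM      5  O  BGLY A   2       4.000   0.000   0.000  0.50  0.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- load_structure(f)
  n_atoms <- m$atoms[m$atoms$elety == "N", ]
  expect_equal(nrow(n_atoms), 1)
  expect_equal(n_atoms$x, 1.0)        # occupancy 0.6 conformer wins
  o_atoms <- m$atoms[m$atoms$elety == "O", ]
  expect_equal(nrow(o_atoms), 1)
  expect_equal(o_atoms$x, 3.0)        # tie broken alphabetically (A first)
})

test_that("sequences extract in residue order with gap reporting", {
  atoms <- data.frame(
    chain = "P", resno = c(1, 1, 2, 2, 5), resid = c("ALA", "ALA", "GLY",
                                                     "GLY", "XXX"),
    elety = c("N", "CA", "N", "CA", "CA"),
    x = 1:5, y = 0, z = 0, stringsAsFactors = FALSE)
  m <- as_structure_model(atoms)
  s <- extract_sequence(m, "P")
  expect_identical(as.character(s), "AGX")
  expect_identical(attr(s, "gaps"), c(3L, 4L))
  d <- target_duplex()
  expect_identical(substr(as.character(extract_sequence(d$model, "A")),
                          9, 15), "CTAGATG")
  expect_error(extract_sequence(d$model, "Z"), "no chain")
})

test_that("target frame reproduces generator ground truth and is a bijection", {
  d <- target_duplex()
  fr <- assign_target_frame(d$model, "CTNGAYG", "A", 10)
  gt <- as.data.frame(d$frame)
  gt <- gt[gt$position %in% fr$position, ]
  key <- function(x) x[order(x$strand, x$position),
                       c("position", "strand", "chain", "resno", "base")]
  expect_equal(key(as.data.frame(fr)), key(gt), ignore_attr = TRUE)
  top <- fr[fr$strand == "top", ]
  expect_false(any(duplicated(top$position)))
  expect_false(any(duplicated(paste(top$chain, top$resno, top$ins))))
  expect_false(0 %in% fr$position)
  expect_setequal(top$position, c(-1, 1:6))
})

test_that("target frame is invariant to rigid-body transformation", {
  d <- target_duplex()
  f1 <- assign_target_frame(d$model, "CTNGAYG", "A", 10)
  f2 <- assign_target_frame(rigid_transform(d$model), "CTNGAYG", "A", 10)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("frame truncates with a warning when positions fall off the end", {
  short <- make_duplex(duplex_spec("TAGATGAC", plus_one = 1))
  expect_warning(fr <- assign_target_frame(short$model, "CTNGAYG", "A", 1),
                 "truncated")
  expect_false(-1 %in% fr$position[fr$strand == "top"] &&
                 min(fr$position) < -1)
  expect_true(all(fr$position %in% c(-1, 1:6)))
})

test_that("base conflicts and bad anchors raise informative errors", {
  d <- target_duplex()
  expect_error(assign_target_frame(d$model, "GGGGGGG", "A", 10),
               "conflicts.*position")
  expect_error(assign_target_frame(d$model, "CTNGAYG", "A", 999),
               "anchor")
  expect_error(assign_target_frame(d$model, "CTQGAYG", "A", 10),
               "non-IUPAC")
})

test_that("flipped bases get their partner by frame arithmetic", {
  df <- target_duplex(flip = list(position = 1, strand = "bottom"))
  fr <- as.data.frame(assign_target_frame(df$model, "CTNGAYG", "A", 10))
  bot1 <- fr[fr$position == 1 & fr$strand == "bottom", ]
  expect_equal(bot1$resno, 15)
  expect_equal(bot1$base, "A")
})

test_that("structure summary and FASTA writers produce parseable output", {
  d <- target_duplex()
  j <- jsonlite::fromJSON(structure_summary_json(d$model))
  expect_equal(j$n_atoms, nrow(d$model$atoms))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_sequences_fasta(d$model, f)
  ss <- Biostrings::readBStringSet(f)
  expect_length(ss, 2)
})
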