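test_that("alignment readers handle FASTA, Clustal and Stockholm", {
  sp <- msa_spec(12, 8, seed = 3)
  m <- simulate_msa(sp)$msa
  f <- withr::local_tempfile(fileext = ".fasta")
  write_msa_fasta(m, f)
  m2 <- read_msa(f)
  expect_identical(m2$aln, m$aln)
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "s1   ACDE-G", "s2   ACDEFG", ""), cl)
  mc <- read_msa(cl)
  expect_identical(dim(mc$aln), c(2L, 6L))
  expect_identical(unname(mc$aln[1, 5]), "-")
  st <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACDE.G", "s2 ACDEFG", "//"), st)
  ms <- read_msa(st)
  expect_identical(unname(ms$aln[1, 5]), "-")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">b", "ACD"), bad)
  expect_error(read_msa(bad), "unequal")
})

test_that("reference numbering maps ungapped columns only", {
  aln <- rbind(c("A", "-", "C", "D"), c("A", "G", "C", "D"))
  rownames(aln) <- c("ref", "other")
  m <- isprm:::new_msa(c("ref", "other"), aln)
  m <- set_reference(m, "ref", start = 868)
  expect_identical(m$ref$numbers, c(868L, NA, 869L, 870L))
  expect_error(set_reference(m, "missing"), "not found")
})

test_that("conservation: conserved columns score highest, rescaled min is 0", {
  sp <- msa_spec(100, 30, conserved = data.frame(column = 5,
                                                 residue = "W"), seed = 4)
  m <- simulate_msa(sp)$msa
  pr <- conservation_profile(m)
  expect_equal(which.max(pr$raw), 5)
  expect_identical(min(pr$rescaled, na.rm = TRUE), 0)
  # rescaled is a flip-and-shift of raw
  expect_equal(pr$rescaled, -pr$raw + max(pr$raw, na.rm = TRUE))
  expect_error(conservation_profile(isprm:::new_msa(
    "one", matrix("A", 1, 3))), "2 sequences")
})

test_that("a uniform random column scores near the background", {
  set.seed(10)
  n <- 400
  aln <- cbind(matrix(sample(AMINO20, n * 4, replace = TRUE), n, 4),
               rep("W", n))
  m <- isprm:::new_msa(sprintf("s%d", 1:n), aln)
  pr <- conservation_profile(m)
  # analytic: uniform vs BLOSUM62 background has relative entropy
  # sum (1/20) log2((1/20)/bg); sampling noise is O(q/(2N ln 2))
  bg <- isprm:::BLOSUM62_BACKGROUND / sum(isprm:::BLOSUM62_BACKGROUND)
  expected <- sum(rep(1 / 20, 20) * log2((1 / 20) / bg))
  expect_equal(mean(pr$raw[1:4]), expected, tolerance = 0.25)
  expect_gt(pr$raw[5], max(pr$raw[1:4]))
})

test_that("all-gap and gap-heavy columns are flagged undefined", {
  aln <- rbind(c("A", "-", "C"), c("A", "-", "C"), c("A", "-", "G"))
  m <- isprm:::new_msa(c("a", "b", "c"), aln)
  pr <- conservation_profile(m)
  expect_false(pr$defined[2])
  expect_true(is.na(pr$raw[2]))
})

test_that("conservation is invariant to row order", {
  sp <- msa_spec(60, 15, seed = 8)
  m <- simulate_msa(sp)$msa
  set.seed(1)
  perm <- sample(nrow(m$aln))
  m2 <- isprm:::new_msa(m$ids[perm], m$aln[perm, ])
  expect_equal(conservation_profile(m)$raw, conservation_profile(m2)$raw)
})

test_that("two perfectly coupled uniform binary columns give exactly 1 bit", {
  sp <- msa_spec(100, 2, coupled = list(list(
    i = 1, j = 2, states = data.frame(a = c("A", "S"), b = c("L", "F"),
                                      p = c(0.5, 0.5)))), seed = 3)
  m <- simulate_msa(sp)$msa
  cr <- coupling_matrix(m, pseudocount = 0, weights = "none")
  expect_identical(cr$mi[1, 2], 1)
})

test_that("coupling matrices are symmetric, non-negative, zero-diagonal", {
  sp <- msa_spec(80, 12, coupled = list(list(
    i = 2, j = 7, states = data.frame(a = c("A", "S"), b = c("L", "F"),
                                      p = c(0.5, 0.5)))), seed = 5)
  cr <- coupling_matrix(simulate_msa(sp)$msa)
  expect_equal(cr$mi, t(cr$mi))
  expect_true(all(cr$mi >= 0))
  expect_true(all(diag(cr$mi) == 0))
  expect_equal(cr$mi_apc, t(cr$mi_apc))
  expect_true(all(cr$strength$strength >= 0))
})

test_that("independent columns stay below the permutation null", {
  sp <- msa_spec(150, 10, seed = 12)
  m <- simulate_msa(sp)$msa
  cr <- coupling_matrix(m, weights = "none")
  # permutation oracle: shuffle rows of each column independently
  set.seed(99)
  null_max <- replicate(30, {
    aln <- apply(m$aln, 2, sample)
    rownames(aln) <- m$ids
    mp <- isprm:::new_msa(m$ids, aln)
    max(coupling_matrix(mp, weights = "none")$mi_apc)
  })
  expect_lte(max(cr$mi_apc), stats::quantile(null_max, 0.99) * 1.5)
})

test_that("planted coupled pairs dominate the strongest couplings", {
  pairs <- lapply(1:10, function(p) list(
    i = 2 * p - 1, j = 2 * p,
    states = data.frame(a = c("A", "S", "L", "K"),
                        b = c("D", "E", "R", "G"), p = rep(0.25, 4))))
  sp <- msa_spec(200, 100, coupled = pairs, seed = 17)
  cr <- coupling_matrix(simulate_msa(sp)$msa)
  ut <- which(upper.tri(cr$mi_apc), arr.ind = TRUE)
  ord <- order(cr$mi_apc[ut], decreasing = TRUE)
  top15 <- ut[ord[1:15], , drop = FALSE]
  top_keys <- paste(pmin(top15[, 1], top15[, 2]),
                    pmax(top15[, 1], top15[, 2]))
  planted_keys <- paste(seq(1, 19, 2), seq(2, 20, 2))
  expect_true(all(planted_keys %in% top_keys))
  # planted columns dominate the top decile of coupling strength
  top10pct <- top_fraction(stats::setNames(cr$strength$strength,
                                           cr$strength$column), 0.10)
  expect_gte(mean(top10pct %in% 1:20), 0.8)
})

test_that("window restriction follows the reference numbering", {
  sp <- msa_spec(50, 30, seed = 20)
  m <- simulate_msa(sp)$msa
  m <- set_reference(m, m$ids[1], start = 868)
  cr <- coupling_matrix(m, window = c(870, 879))
  expect_length(cr$columns, 10)
  expect_error(coupling_matrix(m, window = c(5000, 5100)), "range error")
})

test_that("top-fraction selection sizes and tie-breaks are exact", {
  scores <- stats::setNames(stats::runif(561), 868:1428)
  expect_length(top_fraction(scores, 0.10), 56)
  expect_length(top_fraction(stats::setNames(stats::runif(10), 1:10),
                             0.10), 1)
  equal <- stats::setNames(rep(1, 20), 101:120)
  expect_identical(top_fraction(equal, 0.25), as.integer(101:105))
  expect_error(top_fraction(numeric(0), 0.1), "empty")
  expect_error(top_fraction(scores, 0), "fraction")
})

test_that("contact enrichment matches the exact combinatorial tail", {
  full <- contact_enrichment(1:17, 1:17, 561)
  expect_equal(full$overlap, 17)
  expect_lt(full$p_value, 1e-20)
  disjoint <- contact_enrichment(1:56, 500:516, 561)
  expect_equal(disjoint$overlap, 0)
  expect_equal(disjoint$p_value, 1, tolerance = 1e-9)
  # scenario sized like the enrichment analysis: 14 of 17 contacts in a
  # 56-residue top set of 561, against an explicit hypergeometric sum
  e <- contact_enrichment(c(1:14, 300:341), c(1:14, 400:402), 561)
  oracle <- sum(vapply(14:17, function(k)
    choose(17, k) * choose(561 - 17, 56 - k), numeric(1))) /
    choose(561, 56)
  expect_equal(e$p_value, oracle, tolerance = 1e-12)
})

test_that("column score TSV merges conservation and coupling", {
  sp <- msa_spec(40, 10, seed = 2)
  m <- simulate_msa(sp)$msa
  pr <- conservation_profile(m)
  cr <- coupling_matrix(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_column_scores_tsv(pr, cr, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("raw", "rescaled", "ec_strength", "ec_rank") %in%
                    names(tab)))
})
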