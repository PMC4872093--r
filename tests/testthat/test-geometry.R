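test_that("straight duplex gives a collinear axis and zero bend", {
  d <- target_duplex()
  ax <- fit_helical_axis(d$model, d$frame)
  xyz <- as.matrix(ax[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  v <- svd(sweep(xyz, 2, ctr))$v[, 1]
  resid <- sweep(xyz, 2, ctr) -
    sweep(xyz, 2, ctr) %*% v %*% t(v)
  expect_lt(max(sqrt(rowSums(resid^2))), 0.1)
  spacing <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(spacing > 2.5 & spacing < 4.5))
  pos <- sort(unique(d$frame$position))
  expect_lt(bend_angle(d$model, d$frame, range(pos[1:8]),
                       range(pos[17:24])), 1)
  expect_error(fit_helical_axis(
    make_duplex(duplex_spec("ACGTAC"))$model,
    make_duplex(duplex_spec("ACGTAC"))$frame), "too short")
})

test_that("planted kinks are recovered within 2 degrees", {
  seqs <- paste(rep("ACGT", 6), collapse = "")
  pos <- bp_positions <- sort(unique(make_duplex(duplex_spec(seqs))$frame$position))
  for (theta in c(10, 34, 60)) {
    dk <- make_duplex(duplex_spec(seqs, kink = list(step = 12,
                                                    angle = theta)))
    b <- bend_angle(dk$model, dk$frame, range(pos[1:8]),
                    range(pos[17:24]))
    expect_equal(b, theta, tolerance = 2 / theta)
  }
  dk <- make_duplex(duplex_spec(seqs, kink = list(step = 12, angle = 34)))
  b1 <- bend_angle(dk$model, dk$frame, range(pos[1:8]), range(pos[17:24]))
  b2 <- bend_angle(dk$model, dk$frame, range(pos[17:24]), range(pos[1:8]))
  expect_equal(b1, b2)
  expect_error(bend_angle(dk$model, dk$frame, c(-11, 1), c(-2, 13)),
               "overlap")
})

test_that("groove widths are uniform on the ideal helix", {
  d <- target_duplex()
  gw <- groove_widths(d$model, d$frame)
  mid <- gw[!is.na(gw$major) & !is.na(gw$minor), ]
  mid <- mid[4:(nrow(mid) - 4), ]
  expect_lt(stats::sd(mid$major), 0.3)
  expect_lt(stats::sd(mid$minor), 0.3)
  expect_true(all(mid$major > 0 & mid$minor > 0))
  expect_gt(mean(mid$major), mean(mid$minor))
  # ends flagged undefined
  expect_true(all(is.na(gw$major[1:3])))
})

test_that("planted groove widening is recovered within 0.3 A", {
  seqs <- paste(rep("ACGT", 6), collapse = "")
  d0 <- make_duplex(duplex_spec(seqs))
  dw <- make_duplex(duplex_spec(seqs,
                                widen = list(positions = c(-2, -1, 1, 2, 3),
                                             added = 2)))
  g0 <- groove_widths(d0$model, d0$frame)
  g1 <- groove_widths(dw$model, dw$frame)
  delta <- g1$major - g0$major
  target_rows <- g0$position %in% c(-2, -1, 1, 2, 3)
  flank_rows <- g0$position %in% c(-7, -6, -5, 6, 7, 8)
  rec <- mean(delta[target_rows]) - mean(delta[flank_rows])
  expect_equal(rec, 2, tolerance = 0.3 / 2)
})

test_that("register-based widths equal the brute-force oracle", {
  d <- target_duplex(widen = list(positions = c(-1, 1), added = 1.5))
  gw <- groove_widths(d$model, d$frame)
  # dumb double-loop oracle with the same register convention
  positions <- sort(unique(d$frame$position))
  n <- length(positions)
  getP <- function(p, strand) {
    fr <- frame_residue(d$frame, p, strand)
    a <- d$model$atoms
    i <- which(a$chain == fr$chain & a$resno == fr$resno &
                 a$elety == "P")
    c(a$x[i], a$y[i], a$z[i])
  }
  for (i in 4:(n - 3)) {
    for (reg in list(c(-2, 2), c(2, 6))) {
      best <- Inf
      for (k in reg[1]:reg[2]) {
        j <- i + k
        if (j < 1 || j > n) next
        dd <- sqrt(sum((getP(positions[i], "top") -
                          getP(positions[j], "bottom"))^2))
        if (dd < best) best <- dd
      }
      col <- if (identical(reg, c(-2, 2))) "major" else "minor"
      expect_equal(gw[[col]][i], best - 5.8, tolerance = 1e-9)
    }
  }
})

test_that("planted flips are detected exactly with no false positives", {
  for (seed in 1:20) {
    set.seed(seed)
    strand <- sample(c("top", "bottom"), 1)
    position <- sample(c(-3, -1, 1, 2, 4), 1)
    df <- target_duplex(flip = list(position = position, strand = strand))
    fl <- detect_flipped_bases(df$model, df$frame)
    expect_equal(nrow(fl), 1)
    expect_equal(fl$position, position)
    expect_equal(fl$strand, strand)
    expect_gte(fl$displacement_A, 8)
  }
  clean <- target_duplex()
  expect_equal(nrow(detect_flipped_bases(clean$model, clean$frame)), 0)
})

test_that("geometry outputs are invariant under rigid-body transforms", {
  d <- target_duplex(flip = list(position = 1, strand = "bottom"))
  m2 <- rigid_transform(d$model)
  pos <- sort(unique(d$frame$position))
  b1 <- bend_angle(d$model, d$frame, range(pos[1:8]), range(pos[17:24]))
  b2 <- bend_angle(m2, d$frame, range(pos[1:8]), range(pos[17:24]))
  expect_equal(b1, b2, tolerance = 1e-6)
  expect_equal(groove_widths(m2, d$frame), groove_widths(d$model, d$frame),
               tolerance = 1e-9)
  f1 <- detect_flipped_bases(d$model, d$frame)
  f2 <- detect_flipped_bases(m2, d$frame)
  expect_equal(f1[, c("position", "strand")], f2[, c("position", "strand")])
})

test_that("duplex geometry summary bundles axis, widths, flips and bend", {
  d <- target_duplex(flip = list(position = 1, strand = "bottom"))
  pos <- sort(unique(d$frame$position))
  g <- duplex_geometry(d$model, d$frame, upstream = range(pos[1:8]),
                       downstream = range(pos[17:24]))
  expect_s3_class(g, "DuplexGeometry")
  expect_equal(nrow(g$flipped), 1)
  expect_true(is.numeric(g$bend_deg))
})
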