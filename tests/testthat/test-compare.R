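# Gotoh global alignment oracle with the same scoring convention as the
# implementation (BLOSUM62, gap open 10, extension 0.5; a gap of length L
# costs 10 + 0.5 L; end gaps penalized)
oracle_global_align <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  go <- 10 + 0.5; ge <- 0.5
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(go + (i - 2) * ge)
  for (j in 2:(m + 1)) Iy[1, j] <- -(go + (j - 2) * ge)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                   Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - go, Ix[i - 1, j] - ge)
    Iy[i, j] <- max(M[i, j - 1] - go, Iy[i, j - 1] - ge)
  }
  best <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback for the identity
  path <- character(0)
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1],
                       Iy[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1) {
      s <- S[a[i - 1], b[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state_next <- which.max(prev)
      path <- c(if (a[i - 1] == b[j - 1]) "=" else "x", path)
      i <- i - 1; j <- j - 1; state <- state_next
    } else if (state == 2) {
      from_m <- abs(M[i - 1, j] - go - Ix[i, j]) < 1e-9
      path <- c("a", path)
      i <- i - 1
      state <- if (from_m) 1 else 2
    } else {
      from_m <- abs(M[i, j - 1] - go - Iy[i, j]) < 1e-9
      path <- c("b", path)
      j <- j - 1
      state <- if (from_m) 1 else 3
    }
  }
  # identity over columns excluding end gaps
  lead <- match(TRUE, path %in% c("=", "x"))
  tail_ <- length(path) - match(TRUE, rev(path) %in% c("=", "x")) + 1
  cols <- path[lead:tail_]
  list(score = best, identity = 100 * sum(cols == "=") / length(cols))
}

test_that("superposition recovers planted rigid transforms exactly", {
  set.seed(31)
  X <- matrix(rnorm(90), 30, 3) * 6
  s0 <- superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  th <- 70 * pi / 180
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  Y <- t(R %*% t(X)) + rep(c(5, -9, 2), each = 30)
  s1 <- superpose(Y, X)
  expect_lt(s1$rmsd, 1e-6)
  expect_equal(rotation_angle(s1$rotation), 70, tolerance = 1e-6)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-6)
  expect_equal(apply_superposition(Y, s1), X, tolerance = 1e-9)
  # rmsd symmetric in argument order
  set.seed(32)
  Z <- X + matrix(rnorm(90, sd = 0.6), 30, 3)
  expect_equal(superpose(X, Z)$rmsd, superpose(Z, X)$rmsd,
               tolerance = 1e-9)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "3 paired atoms")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line), "collinear")
})

test_that("RMSD agrees with the bio3d fitting oracle", {
  set.seed(33)
  X <- matrix(rnorm(75), 25, 3) * 4
  Y <- X + matrix(rnorm(75, sd = 0.8), 25, 3)
  ours <- superpose(Y, X)$rmsd
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(X)),
                           mobile = as.vector(t(Y)),
                           fixed.inds = 1:75, mobile.inds = 1:75)
  # bio3d::rmsd reports 3 decimals
  expect_equal(ours, bio3d::rmsd(as.vector(t(X)), fitted),
               tolerance = 1e-3)
})

test_that("inter-domain rotation recovers the planted hinge angle", {
  for (theta in c(25, 92)) {
    tm <- two_domain_models(theta)
    got <- interdomain_rotation(tm$a, tm$b, "A", "A",
                                ref_a = 1:40, ref_b = 1:40,
                                mob_a = 101:140, mob_b = 101:140,
                                pairing = "number")
    expect_equal(got, theta, tolerance = 0.5 / theta)
    # identical models -> 0
    expect_lt(interdomain_rotation(tm$a, tm$a, "A", "A", 1:40, 1:40,
                                   101:140, 101:140, pairing = "number"),
              1e-6)
    # invariant to a pre-applied rigid transform of either input
    got2 <- interdomain_rotation(tm$a, rigid_transform(tm$b), "A", "A",
                                 1:40, 1:40, 101:140, 101:140,
                                 pairing = "number")
    expect_equal(got2, got, tolerance = 1e-6)
  }
  tm <- two_domain_models(30)
  expect_error(interdomain_rotation(tm$a, tm$b, "A", "A", 900:950,
                                    900:950, 101:140, 101:140,
                                    pairing = "number"), "selection")
})

test_that("pairwise identity matches hand counts and is symmetric", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 100)
  expect_equal(pairwise_identity("ACDEFG", "ACDEFA"), 100 * 5 / 6,
               tolerance = 1e-9)
  expect_equal(pairwise_identity("MKWVNQ", "KWVNQ"),
               pairwise_identity("KWVNQ", "MKWVNQ"), tolerance = 1e-9)
  expect_error(pairwise_identity("AC-DE", "ACDE"), "alphabet")
  expect_error(pairwise_identity("", "ACDE"), "empty")
})

test_that("identity agrees with an exhaustive dynamic-programming oracle", {
  set.seed(44)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (rep in 1:10) {
    a <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    orc <- oracle_global_align(a, b)
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), orc$score, tolerance = 1e-9)
    expect_equal(pairwise_identity(a, b), orc$identity, tolerance = 1e-9)
  }
})

test_that("domain tables expose the TRD subdomains of both enzymes", {
  d <- isp_domains()
  expect_setequal(unique(d$protein), c("LlaGI", "LlaBIII"))
  core <- domain_resnos("LlaGI", c("trd_core", "trd_core2"))
  expect_true(all(c(1200, 1239, 1297, 1440) %in% core))
  expect_false(1250 %in% core)  # jaw is not core
  w <- domain_resnos("LlaGI", "mtase_trd_window")
  expect_length(w, 561)
  expect_error(domain_resnos("LlaGI", "nope"), "unknown domain")
})
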