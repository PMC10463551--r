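usalign_fixture <- function(tm1 = 0.8, tm2 = 0.6, row_a = "ACD-F",
                            row_b = "AC-EF") {
  marks <- strrep(":", nchar(row_a))   # parser ignores the marker row
  c("Name of Structure_1: models/modA.pdb:A",
    "Name of Structure_2: library/1ABC_B.pdb:B",
    "Length of Structure_1: 5 residues",
    "Length of Structure_2: 5 residues",
    "",
    "Aligned length= 3, RMSD=   1.20, Seq_ID=n_identical/n_aligned= 0.667",
    sprintf("TM-score= %.5f (normalized by length of Structure_1: L=5, d0=0.50)", tm1),
    sprintf("TM-score= %.5f (normalized by length of Structure_2: L=5, d0=0.50)", tm2),
    "",
    "(\":\" denotes residue pairs of d < 5.0 Angstrom, \".\" denotes other aligned residues)",
    row_a, marks, row_b)
}

test_that("US-align output parses to a hit with both normalizations", {
  hit <- parseUSalignOutput(usalign_fixture())
  expect_equal(hit@modelId, "modA")
  expect_equal(hit@chainId, "1ABC_B")
  expect_equal(hit@tmModel, 0.8)
  expect_equal(hit@tmTarget, 0.6)
  expect_equal(tmAvg(hit), 0.7)
  expect_equal(hit@rmsd, 1.2)
})

test_that("aligned-sequence columns decode to gap-aware residue pairs", {
  hit <- parseUSalignOutput(usalign_fixture(row_a = "ACD-F",
                                            row_b = "AC-EF"))
  expect_equal(hit@pairs$model_index, c(1L, 2L, 4L))
  expect_equal(hit@pairs$target_index, c(1L, 2L, 4L))
  expect_equal(hit@pairs$model_residue, c("A", "C", "F"))
  expect_equal(hit@pairs$target_residue, c("A", "C", "F"))
  # identity over aligned pairs only
  expect_equal(hit@seqIdentity, 100)
})

test_that("truncated or inconsistent US-align output is a parse error", {
  fx <- usalign_fixture()
  expect_error(parseUSalignOutput(fx[1:6]), "TM-score")
  expect_error(parseUSalignOutput(fx[1:10]), "truncated")
  expect_error(parseUSalignOutput(usalign_fixture(row_a = "ACDF",
                                                  row_b = "AC-EF")),
               "differ in length")
  expect_error(parseUSalignOutput(fx[-c(1, 2)]), "structure-name")
})

test_that("US-align writer round-trips through the parser", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    mi <- sort(sample(seq_len(n + 10), n))
    ti <- sort(sample(seq_len(n + 10), n))
    pairs <- data.frame(
      model_index = mi, target_index = ti,
      model_residue = sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                             n, replace = TRUE),
      target_residue = sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              n, replace = TRUE),
      stringsAsFactors = FALSE)
    hit <- alignmentHit(sprintf("m%02d", i), sprintf("c%02d_A", i),
                        runif(1, 0.3, 1), runif(1, 0.3, 1),
                        rmsd = runif(1, 0, 5), pairs = pairs)
    back <- parseUSalignOutput(writeUSalignOutput(hit))
    expect_equal(back@pairs, hit@pairs)
    expect_equal(back@tmModel, hit@tmModel, tolerance = 1e-4)
    expect_equal(back@tmTarget, hit@tmTarget, tolerance = 1e-4)
    expect_equal(back@modelId, hit@modelId)
  }
})

test_that("hits TSV interchange round-trips", {
  fx <- standard_fixture()
  hs <- makeHitSet("modT", fx$lib, ecCounts = c("1.1.1.1" = 3L),
                   nFeatureless = 2L, seed = 5L)
  f <- file.path(withr::local_tempdir(), "hits.tsv")
  writeHitsTable(hs$hits, f)
  back <- readHitsTable(f)
  expect_length(back, length(hs$hits))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]@chainId, hs$hits[[k]]@chainId)
    expect_equal(tmAvg(back[[k]]), tmAvg(hs$hits[[k]]), tolerance = 1e-9)
    expect_equal(back[[k]]@pairs, hs$hits[[k]]@pairs)
  }
})

test_that("hit filtering keeps the boundary, ranks, and is idempotent", {
  mk <- function(tm, id) alignmentHit("m", id, tm, tm)
  hits <- list(mk(0.65, "c1_A"), mk(0.70, "c2_A"), mk(0.90, "c3_A"))
  kept <- filterHits(hits, 0.7)
  expect_length(kept, 2L)
  expect_equal(vapply(kept, tmAvg, numeric(1)), c(0.90, 0.70))

  expect_length(filterHits(list(), 0.7), 0L)

  five <- list(mk(0.9, "e_A"), mk(0.75, "d_A"), mk(0.3, "a_A"),
               mk(0.75, "b_A"), mk(0.5, "c_A"))
  kept5 <- filterHits(five, 0.7)
  expect_equal(vapply(kept5, function(h) h@chainId, character(1)),
               c("e_A", "b_A", "d_A"))   # descending, lexicographic ties
  expect_equal(filterHits(kept5, 0.7), kept5)  # idempotent
})

test_that("tm_avg is symmetric under swapping model and target", {
  h <- alignmentHit("m", "c", 0.81, 0.57)
  h_swapped <- alignmentHit("c", "m", 0.57, 0.81)
  expect_equal(tmAvg(h), tmAvg(h_swapped))
})

test_that("Kabsch recovers exact superpositions and rejects degeneracy", {
  a <- makeToyStructure(12, seed = 2L)
  corr <- cbind(1:12, 1:12)

  fit <- kabschSuperpose(a, a, corr)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  # rigid motion is exactly inverted
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  b <- a %*% t(rot) + matrix(c(4, -2, 7), 12, 3, byrow = TRUE)
  fit2 <- kabschSuperpose(a, b, corr)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  moved <- b %*% t(fit2$rotation) +
    matrix(fit2$translation, 12, 3, byrow = TRUE)
  expect_equal(moved, a, tolerance = 1e-9)

  expect_error(kabschSuperpose(a, a, cbind(1:2, 1:2)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line, cbind(1:5, 1:5)), "degenerate")
})

test_that("Kabsch matches brute-force rigid-fit minimization on small toys", {
  # 4-point toy with one coordinate displaced by 1 A
  a <- matrix(c(0, 0, 0, 3.8, 0, 0, 3.8, 3.8, 0, 0, 3.8, 2), 4, 3,
              byrow = TRUE)
  b <- a
  b[4, 3] <- b[4, 3] + 1
  fit <- kabschSuperpose(a, b, cbind(1:4, 1:4))

  rmsd_of <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    m <- b %*% t(rz %*% ry %*% rx) + matrix(par[4:6], 4, 3, byrow = TRUE)
    sqrt(mean(rowSums((m - a)^2)))
  }
  set.seed(7)
  brute <- min(vapply(1:40, function(i) {
    optim(c(runif(3, -pi, pi), runif(3, -5, 5)), rmsd_of,
          method = "Nelder-Mead",
          control = list(maxit = 5000, reltol = 1e-14))$value
  }, numeric(1)))
  expect_equal(fit$rmsd, brute, tolerance = 1e-3)

  # independent oracle: bio3d's least-squares fit gives the same RMSD
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(a)), mobile = as.numeric(t(b)),
                        fixed.inds = 1:12, mobile.inds = 1:12)
  expect_equal(fit$rmsd,
               sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) -
                                  a)^2))),
               tolerance = 1e-6)
})

test_that("TM-score has unit self-identity and the standard d0", {
  a <- makeToyStructure(30, seed = 1L)
  expect_equal(tmScore(a, a, cbind(1:30, 1:30), 30), 1)
  expect_equal(tmD0(312), 1.24 * 297^(1 / 3) - 1.8, tolerance = 1e-9)
  expect_equal(tmD0(312), 6.473, tolerance = 1e-3)
  expect_equal(tmD0(10), 0.5)   # floor for short chains
  expect_error(tmScore(a, a, cbind(integer(), integer()), 30), "empty")
})

test_that("TM-score matches a brute-force superposition search on toys", {
  a <- makeToyStructure(20, seed = 5L)
  b <- perturbStructure(a, 0.4, seed = 6L)
  corr <- cbind(1:20, 1:20)
  engine <- tmScore(a, b, corr, 20)
  d0 <- tmD0(20)

  neg_tm <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    m <- b %*% t(rz %*% ry %*% rx) + matrix(par[4:6], 20, 3, byrow = TRUE)
    d <- sqrt(rowSums((m - a)^2))
    -sum(1 / (1 + (d / d0)^2)) / 20
  }
  set.seed(1)
  brute <- -min(vapply(1:30, function(i) {
    optim(c(runif(3, -pi, pi), runif(3, -30, 30)), neg_tm,
          method = "Nelder-Mead",
          control = list(maxit = 3000, reltol = 1e-12))$value
  }, numeric(1)))
  expect_equal(engine, brute, tolerance = 0.01)
  expect_gte(engine, brute - 0.01)   # engine must not fall short
})

test_that("Kabsch RMSD and TM-score are invariant under rigid motions", {
  a <- makeToyStructure(25, seed = 9L)
  b <- perturbStructure(a, 0.7, seed = 10L)
  corr <- cbind(1:25, 1:25)
  base_rmsd <- kabschSuperpose(a, b, corr)$rmsd
  base_tm <- tmScore(a, b, corr, 25)

  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rnorm(9), 3, 3)
    rot <- qr.Q(qr(m)); if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    b2 <- b %*% t(rot) + matrix(runif(3, -50, 50), 25, 3, byrow = TRUE)
    expect_equal(kabschSuperpose(a, b2, corr)$rmsd, base_rmsd,
                 tolerance = 1e-6)
    expect_equal(tmScore(a, b2, corr, 25), base_tm, tolerance = 1e-6)
  }
})

test_that("global sequence alignment reports pairs and identity", {
  al <- alignBySequence("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(nrow(al$pairs), 10L)
  expect_equal(al$identity, 100)

  al2 <- alignBySequence("ACDEF", "ACDF")
  expect_equal(nrow(al2$pairs), 4L)
  expect_equal(al2$identity, 100)   # identity over aligned columns only
  expect_equal(al2$pairs$a_index, c(1L, 2L, 3L, 5L))
  expect_equal(al2$pairs$b_index, 1:4)

  # unrelated random 50-mers: identity near background, far below related
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s1 <- paste(sample(aa, 50, replace = TRUE), collapse = "")
  s2 <- paste(sample(aa, 50, replace = TRUE), collapse = "")
  expect_lt(alignBySequence(s1, s2)$identity, 40)
})
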