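test_that("EC samples gather one count per label per retained hit chain", {
  fx <- standard_fixture()
  # concentrated sample: 10 EC-bearing hits plus 4 hits with no EC label
  hs <- makeHitSet("plp_like", fx$lib, ecCounts = c("4.3.3.6" = 10L),
                   nFeatureless = 4L, seed = 13L)
  s <- gatherECSample(filterHits(hs$hits, 0.7), fx$lib)
  expect_equal(sampleSize(s), 10L)
  expect_true(all(s@labels == "4.3.3.6"))

  expect_equal(sampleSize(gatherECSample(list(), fx$lib)), 0L)

  # hand-built: chains carrying {a}, {a, b}, {} -> P = {a: 2/3, b: 1/3}
  lib <- tiny_library(
    c(A_1 = "ACDEFGHIKL", B_1 = "ACDEFGHIKL", C_1 = "ACDEFGHIKL"),
    ec_labels = list(A_1 = list("1.1.1.1"),
                     B_1 = list("1.1.1.1", "2.3.1.1")))
  hits <- lapply(c("A_1", "B_1", "C_1"), function(id)
    identity_hit("m", id, "ACDEFGHIKL", "ACDEFGHIKL"))
  s2 <- gatherECSample(hits, lib)
  expect_equal(sampleSize(s2), 3L)
  p <- ecMass(sampleDistribution(s2))
  expect_equal(unname(p[c("1.1.1.1", "2.3.1.1")]), c(2 / 3, 1 / 3))
})

test_that("relative entropy matches closed-form values in bits", {
  # P concentrated on a label with Q(x) = 2^-9.5: exactly 9.5 bits
  q <- ecDistribution(c("4.3.3.6" = 2^-9.5, "1.1.1.1" = 1 - 2^-9.5),
                      nObservations = 1000L)
  p <- ecDistribution(c("4.3.3.6" = 1))
  re <- relativeEntropy(p, q)
  expect_equal(re$dkl_bits, 9.5, tolerance = 1e-12)
  expect_equal(unname(re$components["4.3.3.6"]), 9.5, tolerance = 1e-12)

  # P = Q: zero bits
  shared <- ecDistribution(c("1.1.1.1" = 0.6, "2.3.1.1" = 0.4))
  expect_equal(relativeEntropy(shared, shared)$dkl_bits, 0,
               tolerance = 1e-12)

  # two-term sum against direct evaluation
  p2 <- ecDistribution(c("1.1.1.1" = 0.75, "2.2.2.2" = 0.25))
  q4 <- ecDistribution(setNames(rep(0.25, 4),
                                c("1.1.1.1", "2.2.2.2", "3.3.3.3",
                                  "4.4.4.4")))
  re2 <- relativeEntropy(p2, q4)
  expect_equal(re2$dkl_bits, 0.75 * log2(3), tolerance = 1e-12)
  expect_equal(re2$dkl_bits, 1.1887, tolerance = 1e-4)
})

test_that("components always sum to the total", {
  set.seed(55)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    labs <- replicate(k, random_ec_label())
    while (anyDuplicated(labs)) labs <- replicate(k, random_ec_label())
    q <- ecDistribution(setNames(runif(k, 0.1, 1), labs),
                        nObservations = 100L)
    sub <- sample(k, sample(seq_len(k), 1))
    p <- ecDistribution(setNames(runif(length(sub), 0.1, 1), labs[sub]))
    re <- relativeEntropy(p, q)
    expect_equal(sum(re$components), re$dkl_bits, tolerance = 1e-9)
    # nonnegativity when P's support is within Q's support
    expect_gte(re$dkl_bits, -1e-12)
  }
})

test_that("labels absent from Q get the smoothing floor, not a crash", {
  q <- ecDistribution(c("1.1.1.1" = 9, "2.2.2.2" = 1), nObservations = 10L)
  p <- ecDistribution(c("7.7.7.7" = 1))
  re <- relativeEntropy(p, q)
  # floor = 1/(2*10); renormalized Q(7.7.7.7) = 0.05/1.05
  expect_equal(re$dkl_bits, -log2((1 / 20) / (1 + 1 / 20)),
               tolerance = 1e-12)

  q_hand <- ecDistribution(c("1.1.1.1" = 0.5, "2.2.2.2" = 0.5),
                           nObservations = NA_integer_)
  expect_error(relativeEntropy(p, q_hand), "qFloor")
  expect_silent(relativeEntropy(p, q_hand, qFloor = 1e-3))
})

test_that("moving P mass toward a rarer label never decreases D_KL", {
  q <- ecDistribution(c("1.1.1.1" = 0.7, "2.2.2.2" = 0.2,
                        "3.3.3.3" = 0.1))
  dkl_at <- function(w_rare) {
    p <- ecDistribution(c("1.1.1.1" = 1 - w_rare, "3.3.3.3" = w_rare))
    relativeEntropy(p, q)$dkl_bits
  }
  # beyond the crossing point P(rare) > Q(rare), D_KL rises monotonically
  vals <- vapply(seq(0.15, 0.95, by = 0.1), dkl_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("Monte-Carlo significance flags extreme deviations and is seeded", {
  q <- ecDistribution(c("1.1.1.1" = 0.99, "2.2.2.2" = 0.01),
                      nObservations = 1000L)
  s <- ecSample(rep("2.2.2.2", 50))
  sig <- significance(s, q, nDraws = 5000L, seed = 3L)
  expect_lt(sig$p_value, 1e-6)
  expect_gt(sig$z_score, 5)

  # determinism: identical seed, identical result; RNG state untouched
  set.seed(99); before <- .Random.seed
  sig2 <- significance(s, q, nDraws = 5000L, seed = 3L)
  expect_identical(sig, sig2)
  expect_identical(before, .Random.seed)

  expect_error(significance(ecSample(), q), "empty sample")
  q1 <- ecDistribution(c("1.1.1.1" = 1), nObservations = 10L)
  expect_error(significance(ecSample(rep("1.1.1.1", 5)), q1, 1000L, 1L),
               "degenerate null")
})

test_that("consensus rule: full label, prefix fallback, ties", {
  # single dominant full label
  lbl <- consensusLabel(c("4.3.3.6" = 9.5), 9.5)
  expect_s4_class(lbl, "ECNumber")
  expect_equal(formatEC(lbl), "4.3.3.6")

  # no full label reaches 50%, but one depth-3 prefix aggregates past it
  comp <- c("1.14.14.1" = 2.0, "1.14.14.2" = 1.5, "2.3.1.1" = 2.6)
  lbl2 <- consensusLabel(comp, 6.1)
  expect_equal(formatEC(lbl2), "1.14.14.*")

  # exact symmetric tie at every depth
  expect_identical(
    as.character(consensusLabel(c("1.1.1.1" = 1, "2.2.2.2" = 1), 2)),
    "NO_CONSENSUS")

  # majority below threshold everywhere (three-way split across classes)
  out <- consensusLabel(c("1.1.1.1" = 1, "2.2.2.2" = 1, "3.3.3.3" = 1), 3)
  expect_identical(as.character(out), "NO_CONSENSUS")

  expect_error(consensusLabel(numeric(), 1), "empty")
  expect_error(consensusLabel(c("1.1.1.1" = 1), 0), "positive")
})

test_that("consensus picks the most specific qualifying depth", {
  # the depth-3 prefix qualifies AND its depth-2/1 parents also would;
  # the most specific (depth 3) must win
  comp <- c("1.14.14.1" = 2.0, "1.14.14.2" = 1.6, "1.2.3.4" = 0.4,
            "6.1.1.1" = 2.0)
  lbl <- consensusLabel(comp, sum(comp))
  expect_equal(formatEC(lbl), "1.14.14.*")

  # partial labels participate at the depths they reach
  comp2 <- c("1.14.14.*" = 3.0, "2.3.1.1" = 2.0)
  expect_equal(formatEC(consensusLabel(comp2, 5)), "1.14.14.*")
})

test_that("annotateModel composes the verdicts", {
  fx <- standard_fixture()
  cfg <- pipelineConfig(seed = 11L, nDraws = 2000L)

  # concentrated on the rarest library label: enzyme, full-label consensus,
  # D_KL = -log2 Q(4.3.3.6) = log2(10)
  hs <- makeHitSet("enz", fx$lib, ecCounts = c("4.3.3.6" = 10L),
                   nFeatureless = 4L, seed = 3L)
  call <- annotateModel(filterHits(hs$hits, 0.7), fx$lib, fx$q, cfg)
  expect_equal(call@verdict, "ENZYME")
  expect_equal(call@assignedLabel, "4.3.3.6")
  expect_equal(call@dklBits, log2(10), tolerance = 1e-9)
  expect_equal(sum(call@components), call@dklBits, tolerance = 1e-9)
  expect_lte(call@pValue, cfg@alpha)

  # no hits at all
  none <- annotateModel(list(), fx$lib, fx$q, cfg, modelId = "empty")
  expect_equal(none@verdict, "NO_HITS")
  expect_true(is.na(none@assignedLabel))

  # hits carrying no EC labels: non-enzyme by construction
  hs2 <- makeHitSet("nohits_ec", fx$lib, nFeatureless = 6L, seed = 4L)
  call2 <- annotateModel(filterHits(hs2$hits, 0.7), fx$lib, fx$q, cfg)
  expect_equal(call2@verdict, "NOT_ENZYME")

  # identical inputs and seed reproduce the call bitwise
  call_again <- annotateModel(filterHits(hs$hits, 0.7), fx$lib, fx$q, cfg)
  expect_identical(call, call_again)
})

test_that("samples drawn from the background are mostly not called enzymes", {
  fx <- standard_fixture()
  cfg <- pipelineConfig(seed = 17L, nDraws = 2000L)
  set.seed(71)
  verdicts <- vapply(1:20, function(i) {
    lab <- sample(names(ecMass(fx$q)), 20, replace = TRUE,
                  prob = ecMass(fx$q))
    s <- ecSample(lab)
    sig <- significance(s, fx$q, nDraws = 2000L, seed = 100L + i)
    sig$p_value > cfg@alpha
  }, logical(1))
  expect_gt(mean(verdicts), 0.7)   # type-I errors stay the exception
})
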