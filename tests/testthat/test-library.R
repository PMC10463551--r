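test_that("flat-file parser extracts EC labels, features and sequence", {
  seq50 <- strrep("ACDEFGHIKL", 5)
  ft <- data.frame(category = c("BINDING", "ACT_SITE"),
                   position = c(13L, 2L),
                   residue_type = c("D", "C"),
                   ligand_label = c("HEME", ""),
                   stringsAsFactors = FALSE)
  lines <- writeUniprotFlatfile("Q00001", seq50,
                                ecLabels = c("4.3.3.6", "1.14.14.-"),
                                features = ft)
  entry <- parseUniprotFlatfile(lines)
  expect_equal(entry$sequence, seq50)
  expect_equal(vapply(entry$ec_labels, formatEC, character(1)),
               c("4.3.3.6", "1.14.14.*"))
  expect_equal(nrow(entry$features), 2L)
  bind <- entry$features[entry$features$category == "BINDING", ]
  expect_equal(bind$position, 13L)
  expect_equal(bind$ligand_label, "HEME")
  act <- entry$features[entry$features$category == "ACT_SITE", ]
  expect_equal(act$ligand_label, "")
})

test_that("flat-file entries without annotations parse to empty lists", {
  lines <- writeUniprotFlatfile("Q00002", strrep("MKT", 10))
  entry <- parseUniprotFlatfile(lines)
  expect_length(entry$ec_labels, 0)
  expect_equal(nrow(entry$features), 0L)
})

test_that("range features expand to one record per position", {
  entry <- parseUniprotFlatfile(c(
    "ID   RANGE_TEST  Reviewed;  30 AA.",
    "FT   BINDING         10..12",
    "FT                   /ligand=\"ATP\"",
    "SQ   SEQUENCE   30 AA;  0 MW;  0 CRC64;",
    paste0("     ", strrep("ACDEFGHIKL", 3)),
    "//"))
  expect_equal(entry$features$position, 10:12)
  expect_equal(entry$features$ligand_label, rep("ATP", 3))
  expect_equal(entry$features$residue_type,
               strsplit(strrep("ACDEFGHIKL", 3), "")[[1]][10:12])
})

test_that("truncated entries and malformed FT positions are parse errors", {
  expect_error(parseUniprotFlatfile(c("ID   X  Reviewed;  3 AA.",
                                      "SQ   SEQUENCE   3 AA;")),
               "terminator")
  expect_error(parseUniprotFlatfile(c(
    "ID   X  Reviewed;  30 AA.",
    "FT   BINDING         12..9",
    "//")), "line 2")
  expect_error(parseUniprotFlatfile(c(
    "ID   X  Reviewed;  30 AA.",
    "FT   ACT_SITE        abc",
    "//")), "malformed FT position")
})

test_that("feature mapping carries positions through a global alignment", {
  up <- paste(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 3),
              collapse = "")
  ft <- data.frame(category = "ACT_SITE", position = 15L,
                   residue_type = substr(up, 15, 15), ligand_label = "",
                   stringsAsFactors = FALSE)

  # identical sequences: identity mapping
  same <- mapFeaturesToChain(ft, up, up)
  expect_equal(same$features$position, 15L)
  expect_equal(same$dropped, 0L)

  # chain missing the first 10 residues: position 15 -> 5
  chain <- substr(up, 11, nchar(up))
  off <- mapFeaturesToChain(ft, up, chain)
  expect_equal(off$features$position, 5L)
  expect_equal(off$features$residue_type, substr(chain, 5, 5))

  # feature at a position deleted in the chain: dropped, count 1
  del_pos <- 25L
  ft2 <- data.frame(category = "BINDING", position = del_pos,
                    residue_type = substr(up, del_pos, del_pos),
                    ligand_label = "PLP", stringsAsFactors = FALSE)
  chain2 <- paste0(substr(up, 1, del_pos - 1),
                   substr(up, del_pos + 1, nchar(up)))
  expect_warning(dropped <- mapFeaturesToChain(ft2, up, chain2),
                 "dropped")
  expect_equal(nrow(dropped$features), 0L)
  expect_equal(dropped$dropped, 1L)
})

test_that("feature mapping is idempotent through an identity alignment", {
  fx <- standard_fixture()
  for (id in fx$manifest$chain_ids[1:4]) {
    ch <- libraryChain(fx$lib, id)
    if (!nrow(ch@features)) next
    again <- mapFeaturesToChain(ch@features, ch@sequence, ch@sequence)
    expect_equal(again$features$position, ch@features$position)
    expect_equal(again$dropped, 0L)
  }
})

test_that("buildLibrary assembles records and flags missing structures", {
  root <- withr::local_tempdir()
  m <- makeLibraryFixture(root, nChains = 4L,
                          ecProfile = c("1.1.1.1" = 1L, "2.7.1.1" = 1L),
                          seed = 3L)
  lib <- suppressMessages(buildLibrary(m$chain_list, m$mapping,
                                       m$flatfiles, m$structures,
                                       verbose = FALSE))
  expect_equal(nChains(lib), 4L)
  n_ec <- sum(vapply(m$chain_ids, function(id)
    length(libraryChain(lib, id)@ecLabels) > 0, logical(1)))
  expect_equal(n_ec, 2L)

  # chain listed without a structure file is a hard error naming it
  bad_list <- file.path(root, "bad_chains.txt")
  writeLines(c(m$chain_ids, "XXXX_A"), bad_list)
  expect_error(
    suppressMessages(buildLibrary(bad_list, m$mapping, m$flatfiles,
                                  m$structures, verbose = FALSE)),
    "XXXX_A")

  # empty chain list: empty library with a warning
  empty_list <- file.path(root, "empty.txt")
  writeLines(character(), empty_list)
  expect_warning(
    empty <- buildLibrary(empty_list, m$mapping, m$flatfiles,
                          m$structures, verbose = FALSE),
    "empty")
  expect_equal(nChains(empty), 0L)
})

test_that("background distribution normalizes label occurrences", {
  # label multiset {a, b, b, b} over three chains -> 0.25 / 0.75
  lib <- tiny_library(
    c(A_1 = "ACDEFGHIKLMNPQRSTVWY", B_1 = "ACDEFGHIKLMNPQRSTVWY",
      C_1 = "ACDEFGHIKLMNPQRSTVWY"),
    ec_labels = list(A_1 = list("1.1.1.1"),
                     B_1 = list("2.2.2.2", "2.2.2.2"),
                     C_1 = list("2.2.2.2")))
  q <- backgroundDistribution(lib)
  expect_equal(unname(ecMass(q)[c("1.1.1.1", "2.2.2.2")]), c(0.25, 0.75))

  # a single chain with two labels contributes one count each
  lib2 <- tiny_library(c(A_1 = "ACDEFGHIKL"),
                       ec_labels = list(A_1 = list("1.1.1.1", "2.2.2.2")))
  expect_equal(unname(ecMass(backgroundDistribution(lib2))), c(0.5, 0.5))

  # no EC-bearing chains: background undefined
  lib3 <- tiny_library(c(A_1 = "ACDEFGHIKL"))
  expect_error(backgroundDistribution(lib3), "background undefined")
})

test_that("fixture library background matches its planted EC profile", {
  fx <- standard_fixture()
  m <- ecMass(fx$q)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  expect_equal(unname(m[c("1.1.1.1", "2.3.1.1", "4.3.3.6")]),
               c(0.6, 0.3, 0.1))
  # support equals the set of distinct labels planted in the library
  planted <- unique(unlist(fx$manifest$ec_by_chain))
  expect_setequal(names(m), planted)
})

test_that("library manifest and feature table are written", {
  fx <- standard_fixture()
  out <- withr::local_tempdir()
  writeLibraryManifest(fx$lib, out)
  manifest <- jsonlite::read_json(file.path(out, "library_manifest.json"))
  expect_length(manifest, nChains(fx$lib))
  ft <- read.delim(file.path(out, "library_features.tsv"))
  expect_true(all(c("chain_id", "category", "chain_position",
                    "residue_type", "ligand_label") %in% names(ft)))
  expect_true(all(ft$category %in% c("ACT_SITE", "BINDING")))
})
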