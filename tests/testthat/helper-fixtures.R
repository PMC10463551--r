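# Shared synthetic fixtures, built once per test run.
#
# fixture_env caches the standard library fixture (12 chains, EC profile
# 6/3/1 over three labels, seeded features) plus its StructLibrary and
# background distribution, so individual test files don't rebuild it.

fixture_env <- new.env()

standard_fixture <- function() {
  if (is.null(fixture_env$lib)) {
    root <- file.path(tempdir(), "structec-fixture")
    manifest <- makeLibraryFixture(root, seed = 7L)
    lib <- suppressWarnings(suppressMessages(
      buildLibrary(manifest$chain_list, manifest$mapping,
                   manifest$flatfiles, manifest$structures,
                   verbose = FALSE)))
    fixture_env$manifest <- manifest
    fixture_env$lib <- lib
    fixture_env$q <- backgroundDistribution(lib)
  }
  list(manifest = fixture_env$manifest, lib = fixture_env$lib,
       q = fixture_env$q)
}

# Minimal in-code library: chains defined directly from sequences/labels/
# features, no files involved. features: list of data.frames (or NULL).
tiny_library <- function(sequences, ec_labels = NULL, features = NULL) {
  ids <- names(sequences)
  chains <- lapply(ids, function(id) {
    ft <- if (!is.null(features) && !is.null(features[[id]]))
      features[[id]] else structEC:::.emptyFeatures()
    ec <- if (!is.null(ec_labels) && !is.null(ec_labels[[id]]))
      ec_labels[[id]] else list()
    chainRecord(id, sequences[[id]], ecLabels = ec, features = ft)
  })
  names(chains) <- ids
  new("StructLibrary", chains = chains,
      droppedFeatures = setNames(integer(length(ids)), ids))
}

# Identity-alignment hit of a model sequence against a library chain.
identity_hit <- function(model_id, chain_id, model_seq, target_seq,
                         tm = 0.9) {
  n <- min(nchar(model_seq), nchar(target_seq))
  pairs <- data.frame(
    model_index = seq_len(n), target_index = seq_len(n),
    model_residue = strsplit(substr(model_seq, 1, n), "")[[1]],
    target_residue = strsplit(substr(target_seq, 1, n), "")[[1]],
    stringsAsFactors = FALSE)
  alignmentHit(model_id, chain_id, tm, tm, rmsd = 1, pairs = pairs)
}

random_ec_label <- function() {
  paste(sample(1:7, 1), sample(1:20, 1), sample(1:20, 1), sample(1:99, 1),
        sep = ".")
}

feature_row <- function(category, position, residue_type, ligand = "") {
  data.frame(category = category, position = position,
             residue_type = residue_type, ligand_label = ligand,
             stringsAsFactors = FALSE)
}

# Random small library + identity hits over a 15-residue model, for the
# feature-transfer property tests.
random_feature_fixture <- function(seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  model_seq <- paste(sample(aa, 15, replace = TRUE), collapse = "")
  n_chain <- sample(2:5, 1)
  seqs <- setNames(vapply(seq_len(n_chain), function(i)
    paste(sample(aa, 15, replace = TRUE), collapse = ""), character(1)),
    sprintf("T%02d_A", seq_len(n_chain)))
  fts <- lapply(seqs, function(s) {
    k <- sample(0:4, 1)
    if (k == 0) return(NULL)
    pos <- sample(1:15, k)
    feature_row(sample(c("ACT_SITE", "BINDING"), k, replace = TRUE),
                as.integer(pos), substring(s, pos, pos),
                sample(c("", "HEME", "ATP"), k, replace = TRUE))
  })
  lib <- tiny_library(seqs, features = fts)
  hits <- lapply(names(seqs), function(id)
    identity_hit("m", id, model_seq, seqs[[id]]))
  list(lib = lib, hits = hits)
}
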