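## Deterministic synthetic-fixture generator.
##
## Emits exactly the input formats the pipeline consumes — CA-trace PDB
## files, UniProtKB flat files, chain lists, mapping tables, hit TSVs — so
## the whole workflow builds and tests without any downloads. Everything is
## a pure function of its arguments and seed. Fixture sequences are sampled
## from uniform amino-acid frequencies: composition realism is irrelevant
## to the statistics under test.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.randomSequence <- function(n) {
    paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

#' Generate a toy CA trace
#'
#' An ideal poly-helix CA trace (radius 2.3 A, rise 1.5 A per residue, 100
#' degrees per turn step; consecutive CA-CA distances ~3.83 A, self-avoiding
#' by construction), placed in a seeded random rigid orientation so
#' different seeds give different traces.
#'
#' @param length number of residues (>= 3).
#' @param seed integer seed.
#' @return numeric matrix (length x 3) of CA coordinates.
#' @export
makeToyStructure <- function(length, seed = 1L) {
    stopifnot(length >= 3L)
    i <- seq_len(length)
    theta <- (i - 1) * 100 * pi / 180
    base <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    .withSeed(seed, {
        m <- matrix(stats::rnorm(9), 3, 3)
        qr_ <- qr(m)
        r <- qr.Q(qr_)
        if (det(r) < 0) r[, 1] <- -r[, 1]
        t_vec <- stats::runif(3, -20, 20)
    })
    sweep(base %*% t(r), 2, t_vec, `+`)
}

#' Perturb a structure with isotropic Gaussian noise
#'
#' @param coords numeric matrix (n x 3).
#' @param noiseSd per-coordinate standard deviation in Angstrom (0 returns
#'   the input unchanged).
#' @param seed integer seed.
#' @return perturbed coordinate matrix.
#' @export
perturbStructure <- function(coords, noiseSd, seed = 1L) {
    stopifnot(noiseSd >= 0)
    if (noiseSd == 0) return(coords)
    .withSeed(seed, {
        noise <- matrix(stats::rnorm(base::length(coords), sd = noiseSd),
                        nrow(coords), ncol(coords))
    })
    coords + noise
}

#' Write a UniProtKB flat-file entry (fixture writer)
#'
#' Emits the subset of flat-file syntax the parser consumes: ID/AC header,
#' DE \code{EC=} clauses, FT ACT_SITE/BINDING features with \code{/ligand}
#' qualifiers, and the SQ sequence block. [parseUniprotFlatfile()]
#' round-trips it.
#'
#' @param accession UniProt-style accession.
#' @param sequence canonical sequence.
#' @param ecLabels character vector of EC labels (may be empty).
#' @param features data.frame in UniProt numbering (columns as in
#'   [parseUniprotFlatfile()]); may be empty.
#' @param file output path; when \code{NULL} the lines are returned.
#' @return the text lines, invisibly when written to a file.
#' @export
writeUniprotFlatfile <- function(accession, sequence, ecLabels = character(),
                                 features = .emptyFeatures(), file = NULL) {
    lines <- c(
        sprintf("ID   %s_SYNTH              Reviewed;         %d AA.",
                accession, nchar(sequence)),
        sprintf("AC   %s;", accession),
        "DE   RecName: Full=Synthetic fixture protein;")
    for (ec in ecLabels)
        lines <- c(lines, sprintf("DE            EC=%s;", ec))
    if (nrow(features)) {
        for (k in seq_len(nrow(features))) {
            lines <- c(lines, sprintf("FT   %-15s %d",
                                      features$category[k],
                                      features$position[k]))
            if (nzchar(features$ligand_label[k]))
                lines <- c(lines, sprintf("FT                   /ligand=\"%s\"",
                                          features$ligand_label[k]))
        }
    }
    lines <- c(lines,
               sprintf("SQ   SEQUENCE   %d AA;  0 MW;  0000000000000000 CRC64;",
                       nchar(sequence)))
    seq_lines <- substring(sequence,
                           seq(1, nchar(sequence), 60),
                           pmin(seq(60, nchar(sequence) + 59, 60),
                                nchar(sequence)))
    lines <- c(lines, paste0("     ", seq_lines), "//")
    if (is.null(file)) return(lines)
    writeLines(lines, file)
    invisible(lines)
}

.FIXTURE_LIGANDS <- c("HEME", "PLP", "Zn(2+)", "ATP", "NAD(+)")

#' Generate a complete on-disk library fixture
#'
#' Writes everything [buildLibrary()] consumes under one root: per-chain
#' CA-trace PDB files, UniProtKB flat files with EC labels and seeded
#' ACT_SITE/BINDING features (residue types consistent with the chain
#' sequences), the chain list and the chain-to-UniProt mapping table.
#' EC labels are dealt to chains per \code{ecProfile} (one label per
#' EC-bearing chain, in profile order); chains beyond the profile total
#' carry no EC label. Identical seeds give byte-identical files.
#'
#' @param dir output root (created).
#' @param nChains number of chains; must be at least \code{sum(ecProfile)}.
#' @param ecProfile named integer vector, EC label -> number of chains
#'   carrying it.
#' @param featureDensity expected features per chain (Poisson).
#' @param chainLengthRange integer pair of min/max chain length (>= 20).
#' @param seed integer seed.
#' @return invisibly, a manifest list: \code{dir}, \code{chain_ids},
#'   \code{accessions}, \code{chain_list}, \code{mapping},
#'   \code{flatfiles}, \code{structures} (paths), \code{sequences},
#'   \code{ec_by_chain}, \code{features_by_chain}.
#' @export
makeLibraryFixture <- function(dir,
                               nChains = 12L,
                               ecProfile = c("1.1.1.1" = 6L, "2.3.1.1" = 3L,
                                             "4.3.3.6" = 1L),
                               featureDensity = 2,
                               chainLengthRange = c(40L, 80L),
                               seed = 1L) {
    stopifnot(chainLengthRange[1] >= 20L,
              chainLengthRange[2] >= chainLengthRange[1])
    labels <- rep(names(ecProfile), times = ecProfile)
    if (length(labels) > nChains)
        stop("makeLibraryFixture: ecProfile total exceeds nChains")
    dir.create(file.path(dir, "structures"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "flatfiles"), recursive = TRUE,
               showWarnings = FALSE)

    chain_ids <- sprintf("C%03d_A", seq_len(nChains))
    accessions <- sprintf("FXP%04d", seq_len(nChains))

    .withSeed(seed, {
        lens <- sample(seq(chainLengthRange[1], chainLengthRange[2]),
                       nChains, replace = TRUE)
        seqs <- vapply(lens, .randomSequence, character(1))
        nfeat <- stats::rpois(nChains, featureDensity)
        feat_list <- vector("list", nChains)
        for (i in seq_len(nChains)) {
            if (nfeat[i] == 0L || nChains == 0L) {
                feat_list[[i]] <- .emptyFeatures()
                next
            }
            pos <- sort(sample(seq_len(lens[i]), min(nfeat[i], lens[i])))
            category <- sample(c("ACT_SITE", "BINDING"), length(pos),
                               replace = TRUE)
            ligand <- ifelse(category == "BINDING",
                             sample(.FIXTURE_LIGANDS, length(pos),
                                    replace = TRUE), "")
            feat_list[[i]] <- data.frame(
                category = category, position = pos,
                residue_type = substring(seqs[i], pos, pos),
                ligand_label = ligand, stringsAsFactors = FALSE)
        }
    })

    ec_by_chain <- vector("list", nChains)
    for (i in seq_len(nChains))
        ec_by_chain[[i]] <- if (i <= length(labels)) labels[i] else character()

    for (i in seq_len(nChains)) {
        coords <- makeToyStructure(lens[i], seed = seed * 1000L + i)
        .writeCATrace(file.path(dir, "structures",
                                paste0(chain_ids[i], ".pdb")),
                      coords, seqs[i],
                      bfactor = rep(0, lens[i]))
        writeUniprotFlatfile(accessions[i], seqs[i],
                             ecLabels = ec_by_chain[[i]],
                             features = feat_list[[i]],
                             file = file.path(dir, "flatfiles",
                                              paste0(accessions[i], ".dat")))
    }

    chain_list <- file.path(dir, "chains.txt")
    writeLines(chain_ids, chain_list)
    mapping <- file.path(dir, "mapping.tsv")
    utils::write.table(
        data.frame(chain_id = chain_ids, uniprot_accession = accessions),
        mapping, sep = "\t", quote = FALSE, row.names = FALSE)

    names(ec_by_chain) <- chain_ids
    names(feat_list) <- chain_ids
    names(seqs) <- chain_ids
    invisible(list(dir = dir, chain_ids = chain_ids,
                   accessions = accessions,
                   chain_list = chain_list, mapping = mapping,
                   flatfiles = file.path(dir, "flatfiles"),
                   structures = file.path(dir, "structures"),
                   sequences = seqs, ec_by_chain = ec_by_chain,
                   features_by_chain = feat_list))
}

#' Generate a hit set for one model against a library fixture
#'
#' Writes a canonical hits TSV whose chains reference the given library:
#' for each EC label in \code{ecCounts}, that many hits against chains
#' carrying the label (chains are reused when fewer exist than requested),
#' plus \code{nFeatureless} hits against chains carrying no EC label.
#' Average TM-scores are seeded draws from \code{tmRange}; alignments are
#' identity correspondences between a seeded model sequence and each chain
#' sequence over their common length (so hit pairs are consistent with the
#' chain sequences, and model residues agree across hits).
#'
#' @param modelId model identifier.
#' @param library a [StructLibrary-class] built from the fixture.
#' @param ecCounts named integer vector, EC label -> number of hits whose
#'   chain carries it (may be empty).
#' @param tmRange numeric pair within (0, 1\] for the tm_avg draws.
#' @param nFeatureless number of extra hits against EC-less chains.
#' @param seed integer seed.
#' @param file output TSV path; when \code{NULL}, the hit list is returned
#'   without writing.
#' @param modelSequence model sequence; seeded random when \code{NULL}.
#' @return invisibly, list with \code{hits} (list of
#'   [AlignmentHit-class]), \code{model_sequence} and \code{file}.
#' @export
makeHitSet <- function(modelId, library, ecCounts = integer(),
                       tmRange = c(0.75, 0.95), nFeatureless = 0L,
                       seed = 1L, file = NULL, modelSequence = NULL) {
    stopifnot(is(library, "StructLibrary"),
              tmRange[1] > 0, tmRange[2] <= 1, tmRange[1] <= tmRange[2])
    chains <- library@chains
    ec_strings <- lapply(chains, function(ch)
        vapply(ch@ecLabels, formatEC, character(1)))

    pick <- character()
    for (lbl in names(ecCounts)) {
        want <- formatEC(parseEC(lbl))
        carrying <- names(chains)[vapply(ec_strings, function(e)
            want %in% e, logical(1))]
        if (!length(carrying))
            stop(sprintf("makeHitSet: no library chain carries EC %s", lbl))
        k <- ecCounts[[lbl]]
        pick <- c(pick, rep_len(carrying, k))
    }
    if (nFeatureless > 0L) {
        ecless <- names(chains)[vapply(ec_strings, length,
                                       integer(1)) == 0L]
        if (!length(ecless))
            stop("makeHitSet: no EC-less chains available for featureless hits")
        pick <- c(pick, rep_len(ecless, nFeatureless))
    }

    .withSeed(seed, {
        if (is.null(modelSequence)) {
            target_len <- if (length(chains))
                max(vapply(chains, function(ch) nchar(ch@sequence),
                           integer(1)))
            else 50L
            modelSequence <- .randomSequence(target_len)
        }
        tms <- stats::runif(length(pick), tmRange[1], tmRange[2])
    })

    hits <- vector("list", length(pick))
    for (k in seq_along(pick)) {
        ch <- chains[[pick[k]]]
        n <- min(nchar(modelSequence), nchar(ch@sequence))
        idx <- seq_len(n)
        pairs <- data.frame(
            model_index = idx, target_index = idx,
            model_residue = strsplit(substr(modelSequence, 1, n), "")[[1]],
            target_residue = strsplit(substr(ch@sequence, 1, n), "")[[1]],
            stringsAsFactors = FALSE)
        hits[[k]] <- alignmentHit(modelId, ch@chainId, tms[k], tms[k],
                                  rmsd = 1.0, pairs = pairs)
    }
    if (!is.null(file))
        writeHitsTable(hits, file)
    invisible(list(hits = hits, model_sequence = modelSequence,
                   file = file))
}

#' Generate a planted proteome fixture
#'
#' Builds per-model inputs for the command layer over a library fixture:
#' \code{nEnzyme} models whose hits concentrate on one EC label (planted
#' enzymes), \code{nNonEnzyme} models whose hits reference only EC-less
#' chains (planted non-enzymes), and \code{nNoHit} models whose hits all
#' sit below the TM-score threshold (planted no-hit models). Each model
#' also gets a CA-trace PDB with pLDDT-like B-factors and a JSON scores
#' file, all passing the quality gate.
#'
#' @param dir output root (created); hits under \code{hits/}, models under
#'   \code{models/}.
#' @param library a [StructLibrary-class] built from the fixture.
#' @param nEnzyme,nNonEnzyme,nNoHit planted class sizes.
#' @param enzymeEC EC label planted in the enzyme models' hits (must be
#'   carried by at least one library chain).
#' @param nHitsPerModel hits per model.
#' @param seed integer seed.
#' @return invisibly, data.frame with \code{model_id} and planted
#'   \code{truth} ("ENZYME", "NOT_ENZYME", "NO_HITS").
#' @export
makeProteomeFixture <- function(dir, library, nEnzyme = 8L,
                                nNonEnzyme = 8L, nNoHit = 4L,
                                enzymeEC = "4.3.3.6",
                                nHitsPerModel = 10L, seed = 1L) {
    dir.create(file.path(dir, "hits"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "models"), recursive = TRUE,
               showWarnings = FALSE)
    truth <- character(); ids <- character()
    total <- nEnzyme + nNonEnzyme + nNoHit
    classes <- rep(c("ENZYME", "NOT_ENZYME", "NO_HITS"),
                   c(nEnzyme, nNonEnzyme, nNoHit))
    for (i in seq_len(total)) {
        id <- sprintf("model%03d", i)
        cls <- classes[i]
        ec <- integer(); nfl <- 0L; rng <- c(0.75, 0.95)
        if (cls == "ENZYME") {
            ec <- stats::setNames(nHitsPerModel, enzymeEC)
        } else if (cls == "NOT_ENZYME") {
            nfl <- nHitsPerModel
        } else {
            nfl <- nHitsPerModel
            rng <- c(0.30, 0.60)
        }
        makeHitSet(id, library, ecCounts = ec, tmRange = rng,
                   nFeatureless = nfl, seed = seed * 100L + i,
                   file = file.path(dir, "hits", paste0(id, ".tsv")))
        len <- 40L
        coords <- makeToyStructure(len, seed = seed * 100L + i)
        .withSeed(seed * 100L + i, {
            mseq <- .randomSequence(len)
            plddt <- stats::runif(len, 75, 95)
        })
        .writeCATrace(file.path(dir, "models", paste0(id, ".pdb")),
                      coords, mseq, bfactor = plddt)
        jsonlite::write_json(list(ptm = 0.85),
                             file.path(dir, "models",
                                       paste0(id, "_scores.json")),
                             auto_unbox = TRUE, digits = NA)
        ids <- c(ids, id); truth <- c(truth, cls)
    }
    invisible(data.frame(model_id = ids, truth = truth,
                         stringsAsFactors = FALSE))
}
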