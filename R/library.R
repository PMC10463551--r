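## Annotated structural library: chain records, UniProt feature mapping,
## background EC distribution.

#' Construct a chain record
#'
#' Low-level constructor; [buildLibrary()] is the usual entry point.
#'
#' @param chainId chain identifier ("PDBID_CHAIN" style).
#' @param sequence one-letter amino-acid string.
#' @param uniprotAccession UniProt accession or \code{NA}.
#' @param ecLabels list of [ECNumber-class] (or EC strings, parsed here).
#' @param features data.frame in chain numbering (see
#'   [ChainRecord-class]); defaults to none.
#' @param coordinatesRef locator of the chain's structure file.
#' @return a [ChainRecord-class].
#' @export
chainRecord <- function(chainId, sequence, uniprotAccession = NA_character_,
                        ecLabels = list(), features = .emptyFeatures(),
                        coordinatesRef = NA_character_) {
    ecLabels <- lapply(ecLabels, function(e)
        if (is(e, "ECNumber")) e else parseEC(e))
    new("ChainRecord", chainId = chainId, sequence = sequence,
        uniprotAccession = uniprotAccession, ecLabels = ecLabels,
        features = features, coordinatesRef = coordinatesRef)
}

setMethod("show", "ChainRecord", function(object) {
    cat(sprintf("ChainRecord %s: %d aa, %d EC label(s), %d feature(s)\n",
                object@chainId, nchar(object@sequence),
                length(object@ecLabels), nrow(object@features)))
})

setMethod("show", "StructLibrary", function(object) {
    n <- length(object@chains)
    nec <- sum(vapply(object@chains,
                      function(ch) length(ch@ecLabels) > 0L, logical(1)))
    nft <- sum(vapply(object@chains,
                      function(ch) nrow(ch@features) > 0L, logical(1)))
    cat(sprintf(
        "StructLibrary: %d chain(s); %d with EC labels; %d with features; %d feature(s) dropped in mapping\n",
        n, nec, nft, sum(object@droppedFeatures)))
})

#' Number of chains in a library
#' @param x a [StructLibrary-class].
#' @return integer.
#' @export
nChains <- function(x) {
    stopifnot(is(x, "StructLibrary"))
    length(x@chains)
}

#' Retrieve a chain record by ID
#' @param x a [StructLibrary-class].
#' @param chainId chain identifier.
#' @return a [ChainRecord-class].
#' @export
libraryChain <- function(x, chainId) {
    stopifnot(is(x, "StructLibrary"))
    ch <- x@chains[[chainId]]
    if (is.null(ch))
        stop(sprintf("chain '%s' not in library", chainId))
    ch
}

#' Map UniProt-numbered residue features onto a chain sequence
#'
#' Aligns the UniProt canonical sequence to the chain sequence globally
#' (BLOSUM62, affine gaps) and carries each feature position through the
#' alignment into chain numbering. Features landing on alignment gaps, or
#' whose recorded residue type disagrees with the chain sequence at the
#' mapped position, are dropped with a warning. PDB chain numbering and
#' UniProt numbering routinely disagree (truncated constructs, tags,
#' engineered gaps), so author-provided numbering is never trusted.
#'
#' @param features data.frame in UniProt numbering (columns as in
#'   [parseUniprotFlatfile()]).
#' @param uniprotSequence canonical UniProt sequence.
#' @param chainSequence chain sequence (from the coordinate file).
#' @return list with \code{features} (data.frame re-indexed to chain
#'   numbering) and \code{dropped} (integer count).
#' @export
mapFeaturesToChain <- function(features, uniprotSequence, chainSequence) {
    stopifnot(nzchar(uniprotSequence), nzchar(chainSequence))
    if (!nrow(features))
        return(list(features = .emptyFeatures(), dropped = 0L))
    map <- .globalPositionMap(uniprotSequence, chainSequence)
    chain_pos <- map[features$position]
    chain_chr <- rep(NA_character_, length(chain_pos))
    ok <- !is.na(chain_pos)
    if (any(ok))
        chain_chr[ok] <- substring(chainSequence, chain_pos[ok],
                                   chain_pos[ok])
    keep <- ok & (is.na(features$residue_type) |
                  chain_chr == features$residue_type)
    dropped <- sum(!keep)
    if (dropped)
        warning(sprintf(
            "mapFeaturesToChain: dropped %d feature(s) (alignment gap or residue-type mismatch)",
            dropped))
    out <- features[keep, , drop = FALSE]
    out$position <- chain_pos[keep]
    out$residue_type <- chain_chr[keep]
    rownames(out) <- NULL
    list(features = out, dropped = dropped)
}

## Global alignment position map: for each position of seq a, the aligned
## position in seq b, or NA on a gap.
.globalPositionMap <- function(a, b) {
    pa <- .globalAlignment(a, b)
    arow <- strsplit(pa$aligned_a, "")[[1]]
    brow <- strsplit(pa$aligned_b, "")[[1]]
    ia <- cumsum(arow != "-")
    ib <- cumsum(brow != "-")
    map <- rep(NA_integer_, nchar(a))
    both <- arow != "-" & brow != "-"
    map[ia[both]] <- ib[both]
    map
}

## Needleman-Wunsch global alignment behind a small stable interface
## (Biostrings; BLOSUM62, gap open 10, extend 0.5).
.globalAlignment <- function(a, b) {
    subst <- .blosum62()
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(.maskNonstandard(a)),
        Biostrings::AAString(.maskNonstandard(b)),
        substitutionMatrix = subst, gapOpening = 10, gapExtension = 0.5,
        type = "global")
    list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
         aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

.blosum62 <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            e <- new.env()
            utils::data("BLOSUM62", package = "Biostrings", envir = e)
            cache <<- e$BLOSUM62
        }
        cache
    }
})

## BLOSUM62 in Biostrings covers the extended AA alphabet incl. X and *;
## replace anything outside it with X so alignment never fails.
.maskNonstandard <- function(s) {
    gsub("[^ACDEFGHIKLMNPQRSTVWYBZX*-]", "X", toupper(s))
}

#' Build the annotated structural library
#'
#' Assembles one [ChainRecord-class] per listed chain: the chain sequence is
#' read from its coordinate file, the matching UniProt flat file (if any)
#' contributes EC labels and ACT_SITE/BINDING features, and feature
#' positions are reconciled to chain numbering by global sequence alignment.
#' Chains without a UniProt mapping, or whose flat file is missing, get
#' empty annotation lists (with a warning for missing flat files).
#'
#' @param chainListFile plain-text file, one "PDBID_CHAIN" per line.
#' @param mappingFile TSV with header columns \code{chain_id},
#'   \code{uniprot_accession}; may cover only part of the chain list.
#' @param flatfileDir directory of UniProtKB flat files named
#'   \code{<accession>.dat} (\code{.txt} also accepted).
#' @param structureDir directory of per-chain coordinate files named
#'   \code{<chain_id>.pdb} (\code{.cif} also accepted). Every listed chain
#'   must resolve to a structure file; missing files are a hard error.
#' @param verbose emit a summary message (default TRUE).
#' @return a [StructLibrary-class].
#' @export
buildLibrary <- function(chainListFile, mappingFile, flatfileDir,
                         structureDir, verbose = TRUE) {
    chain_ids <- readLines(chainListFile, warn = FALSE)
    chain_ids <- trimws(chain_ids)
    chain_ids <- chain_ids[nzchar(chain_ids)]
    if (!length(chain_ids)) {
        warning("buildLibrary: empty chain list")
        return(new("StructLibrary", chains = list(),
                   droppedFeatures = integer()))
    }

    mapping <- utils::read.delim(mappingFile, stringsAsFactors = FALSE)
    if (!all(c("chain_id", "uniprot_accession") %in% names(mapping)))
        stop("buildLibrary: mapping table must have columns chain_id, uniprot_accession")

    struct_files <- vapply(chain_ids, function(id) {
        for (ext in c("pdb", "cif")) {
            f <- file.path(structureDir, paste0(id, ".", ext))
            if (file.exists(f)) return(f)
        }
        NA_character_
    }, character(1))
    if (anyNA(struct_files))
        stop(sprintf("buildLibrary: missing structure file(s) for: %s",
                     paste(chain_ids[is.na(struct_files)], collapse = ", ")))

    chains <- list()
    dropped <- integer()
    for (i in seq_along(chain_ids)) {
        id <- chain_ids[i]
        ca <- .readChainCA(struct_files[i])
        acc <- mapping$uniprot_accession[match(id, mapping$chain_id)]
        ec <- list(); ft <- .emptyFeatures(); ndrop <- 0L
        if (!is.na(acc) && nzchar(acc)) {
            ffile <- NULL
            for (ext in c("dat", "txt")) {
                f <- file.path(flatfileDir, paste0(acc, ".", ext))
                if (file.exists(f)) { ffile <- f; break }
            }
            if (is.null(ffile)) {
                warning(sprintf(
                    "buildLibrary: no flat file for accession %s (chain %s); empty annotations",
                    acc, id))
            } else {
                entry <- parseUniprotFlatfile(ffile)
                ec <- entry$ec_labels
                if (nrow(entry$features) && nzchar(entry$sequence)) {
                    mapped <- mapFeaturesToChain(entry$features,
                                                 entry$sequence, ca$sequence)
                    ft <- mapped$features
                    ndrop <- mapped$dropped
                }
            }
        } else {
            acc <- NA_character_
        }
        chains[[id]] <- chainRecord(id, ca$sequence, acc, ec, ft,
                                    struct_files[i])
        dropped[id] <- ndrop
    }
    lib <- new("StructLibrary", chains = chains, droppedFeatures = dropped)
    if (verbose) {
        nec <- sum(vapply(chains, function(ch) length(ch@ecLabels) > 0L,
                          logical(1)))
        nft <- sum(vapply(chains, function(ch) nrow(ch@features) > 0L,
                          logical(1)))
        message(sprintf(
            "buildLibrary: %d chain(s); %d with EC labels; %d with features; %d feature(s) dropped",
            length(chains), nec, nft, sum(dropped)))
    }
    lib
}

#' Construct an EC distribution
#'
#' Normalizes nonnegative weights (typically occurrence counts) over EC
#' labels into a probability distribution.
#'
#' @param weights named nonnegative numeric; names are EC label strings
#'   (normalized through [parseEC()]/[formatEC()]).
#' @param nObservations total label-occurrence count behind the weights;
#'   defaults to \code{sum(weights)} when the weights are integral counts,
#'   else \code{NA}.
#' @return an [ECDistribution-class].
#' @export
ecDistribution <- function(weights, nObservations = NULL) {
    if (is.null(names(weights)) || !length(weights))
        stop("ecDistribution: 'weights' must be a non-empty named vector")
    if (any(weights < 0))
        stop("ecDistribution: weights must be nonnegative")
    names(weights) <- vapply(names(weights),
                             function(s) formatEC(parseEC(s)), character(1))
    if (anyDuplicated(names(weights))) {
        weights <- tapply(weights, names(weights), sum)
        weights <- stats::setNames(as.numeric(weights), names(weights))
    }
    tot <- sum(weights)
    if (tot <= 0)
        stop("ecDistribution: total weight must be positive")
    if (is.null(nObservations)) {
        nObservations <- if (all(abs(weights - round(weights)) < 1e-9))
            as.integer(round(tot)) else NA_integer_
    }
    new("ECDistribution", mass = weights / tot,
        nObservations = as.integer(nObservations))
}

setMethod("show", "ECDistribution", function(object) {
    cat(sprintf("ECDistribution: %d label(s)", length(object@mass)))
    if (!is.na(object@nObservations))
        cat(sprintf(" from %d observation(s)", object@nObservations))
    cat("\n")
    top <- sort(object@mass, decreasing = TRUE)
    top <- utils::head(top, 5)
    for (i in seq_along(top))
        cat(sprintf("  %-14s %.4f\n", names(top)[i], top[i]))
})

#' Mass of an EC distribution
#' @param x an [ECDistribution-class].
#' @return named numeric probabilities.
#' @export
ecMass <- function(x) {
    stopifnot(is(x, "ECDistribution"))
    x@mass
}

#' Background EC distribution of a library
#'
#' The background Q of the annotation statistic: the frequency of each EC
#' label over all label occurrences in the library. A chain carrying two EC
#' labels contributes two counts. Chains without EC labels contribute
#' nothing (they are absent from the numerator and the denominator).
#'
#' @param library a [StructLibrary-class] with at least one EC-bearing chain.
#' @return an [ECDistribution-class].
#' @export
backgroundDistribution <- function(library) {
    stopifnot(is(library, "StructLibrary"))
    labels <- unlist(lapply(library@chains, function(ch)
        vapply(ch@ecLabels, formatEC, character(1))), use.names = FALSE)
    if (!length(labels))
        stop("backgroundDistribution: background undefined (no EC-bearing chains)")
    tab <- table(labels)
    ecDistribution(stats::setNames(as.numeric(tab), names(tab)),
                   nObservations = length(labels))
}

#' Write a library manifest and feature table
#'
#' Emits the library as a JSON manifest (chain IDs, accessions, EC labels,
#' sequence lengths, feature counts) plus a per-chain feature TSV
#' (\code{chain_id}, \code{category}, \code{chain_position},
#' \code{residue_type}, \code{ligand_label}).
#'
#' @param library a [StructLibrary-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeLibraryManifest <- function(library, dir) {
    stopifnot(is(library, "StructLibrary"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- lapply(library@chains, function(ch) list(
        chain_id = ch@chainId,
        uniprot_accession = ch@uniprotAccession,
        length = nchar(ch@sequence),
        ec_labels = vapply(ch@ecLabels, formatEC, character(1)),
        n_features = nrow(ch@features)))
    mpath <- file.path(dir, "library_manifest.json")
    jsonlite::write_json(unname(manifest), mpath, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    ft <- do.call(rbind, lapply(library@chains, function(ch) {
        if (!nrow(ch@features)) return(NULL)
        data.frame(chain_id = ch@chainId,
                   category = ch@features$category,
                   chain_position = ch@features$position,
                   residue_type = ch@features$residue_type,
                   ligand_label = ch@features$ligand_label,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(ft))
        ft <- data.frame(chain_id = character(), category = character(),
                         chain_position = integer(),
                         residue_type = character(),
                         ligand_label = character())
    utils::write.table(ft, file.path(dir, "library_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(mpath)
}
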