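## Residue-level feature transfer: ACT_SITE/BINDING evidence from retained
## hits accumulates on model residues through the alignment correspondences.
## The feature count tallies every feature element aligned onto a residue;
## the conservation count tallies the subset where model and target share
## the identical residue type.

#' Transfer residue features from hits onto a model
#'
#' For every aligned residue pair of every retained hit, each feature
#' element the target chain carries at the target position increments the
#' model residue's feature count and its category (ACT_SITE/BINDING) and
#' ligand tallies; the conservation count is additionally incremented when
#' the model and target residue types are identical. A target residue
#' carrying both an ACT_SITE and a BINDING record contributes two feature
#' elements. Hits whose chains carry no features contribute nothing.
#'
#' @param hits list of [AlignmentHit-class]; every hit's chain must exist
#'   in the library and its pair indices must fit the chain sequence.
#' @param library a [StructLibrary-class].
#' @param modelLength number of model residues; defaults to the largest
#'   model index seen across the hits.
#' @param modelId model identifier; defaults to the hits' model ID.
#' @return a [ResidueAnnotation-class].
#' @export
transferFeatures <- function(hits, library, modelLength = NULL,
                             modelId = NULL) {
    stopifnot(is(library, "StructLibrary"))
    if (is.null(modelId))
        modelId <- if (length(hits)) hits[[1]]@modelId else NA_character_
    if (is.null(modelLength)) {
        mx <- vapply(hits, function(h)
            if (nrow(h@pairs)) max(h@pairs$model_index) else 0L, numeric(1))
        modelLength <- if (length(mx)) as.integer(max(mx, 0)) else 0L
    }
    counts <- data.frame(
        residue_index = seq_len(modelLength),
        residue_type = rep(NA_character_, modelLength),
        feature_count = integer(modelLength),
        conservation_count = integer(modelLength),
        act_site_count = integer(modelLength),
        binding_count = integer(modelLength),
        stringsAsFactors = FALSE)
    lig <- list()

    for (h in hits) {
        ch <- libraryChain(library, h@chainId)
        p <- h@pairs
        if (!nrow(p)) next
        n_chain <- nchar(ch@sequence)
        if (any(p$target_index > n_chain) ||
            any(p$model_index > modelLength))
            stop(sprintf(
                "transferFeatures: pair index out of range in hit %s ~ %s",
                h@modelId, h@chainId))
        counts$residue_type[p$model_index] <- p$model_residue
        ft <- ch@features
        if (!nrow(ft)) next
        ## expand: one row per (feature element, aligned pair at its position)
        m <- match(ft$position, p$target_index)
        hitft <- ft[!is.na(m), , drop = FALSE]
        mi <- p$model_index[m[!is.na(m)]]
        if (!nrow(hitft)) next
        conserved <- p$model_residue[m[!is.na(m)]] == hitft$residue_type
        for (k in seq_len(nrow(hitft))) {
            i <- mi[k]
            counts$feature_count[i] <- counts$feature_count[i] + 1L
            if (conserved[k])
                counts$conservation_count[i] <-
                    counts$conservation_count[i] + 1L
            if (hitft$category[k] == "ACT_SITE")
                counts$act_site_count[i] <- counts$act_site_count[i] + 1L
            else
                counts$binding_count[i] <- counts$binding_count[i] + 1L
            if (nzchar(hitft$ligand_label[k])) {
                key <- paste0(i, "\r", hitft$ligand_label[k])
                lig[[key]] <- (lig[[key]] %||% 0L) + 1L
            }
        }
    }

    ligands <- if (length(lig)) {
        parts <- strsplit(names(lig), "\r", fixed = TRUE)
        data.frame(
            residue_index = as.integer(vapply(parts, `[`, "", 1L)),
            ligand_label = vapply(parts, `[`, "", 2L),
            count = as.integer(unlist(lig, use.names = FALSE)),
            stringsAsFactors = FALSE)
    } else {
        data.frame(residue_index = integer(), ligand_label = character(),
                   count = integer())
    }
    new("ResidueAnnotation", modelId = modelId, counts = counts,
        ligands = ligands)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top feature-bearing residues of a model
#'
#' Residues ranked by feature count (descending), conservation count as the
#' tie-break, then residue index; zero-count residues are suppressed.
#'
#' @param annotation a [ResidueAnnotation-class].
#' @param k number of residues to return (>= 1).
#' @return data.frame of the top rows of the per-residue count table, with
#'   a \code{top_ligand} column (most frequent ligand label at the residue,
#'   \code{NA} when none).
#' @export
topFeatureResidues <- function(annotation, k = 10L) {
    stopifnot(is(annotation, "ResidueAnnotation"), k >= 1L)
    ct <- annotation@counts
    ct <- ct[ct$feature_count > 0L, , drop = FALSE]
    if (!nrow(ct)) return(ct)
    ord <- order(-ct$feature_count, -ct$conservation_count,
                 ct$residue_index)
    ct <- ct[ord, , drop = FALSE]
    ct <- utils::head(ct, k)
    lg <- annotation@ligands
    ct$top_ligand <- vapply(ct$residue_index, function(i) {
        sub <- lg[lg$residue_index == i, , drop = FALSE]
        if (!nrow(sub)) return(NA_character_)
        sub$ligand_label[order(-sub$count, sub$ligand_label)][1]
    }, character(1))
    rownames(ct) <- NULL
    ct
}

#' Write the per-model residue feature table
#'
#' TSV with one row per model residue: counts by category plus the most
#' frequent ligand label.
#'
#' @param annotation a [ResidueAnnotation-class].
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeResidueTable <- function(annotation, file) {
    stopifnot(is(annotation, "ResidueAnnotation"))
    ct <- annotation@counts
    lg <- annotation@ligands
    ct$top_ligand <- vapply(ct$residue_index, function(i) {
        sub <- lg[lg$residue_index == i, , drop = FALSE]
        if (!nrow(sub)) return(NA_character_)
        sub$ligand_label[order(-sub$count, sub$ligand_label)][1]
    }, character(1))
    ct <- cbind(model_id = annotation@modelId, ct)
    utils::write.table(ct, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Re-emit a model PDB with feature counts in the B-factor column
#'
#' Writes the model CA trace with each residue's feature count as its
#' B-factor, for visualization in molecular viewers.
#'
#' @param annotation a [ResidueAnnotation-class].
#' @param modelFile the model coordinate file (CA trace source).
#' @param file output PDB path.
#' @return invisibly, \code{file}.
#' @export
writeFeatureColoredModel <- function(annotation, modelFile, file) {
    ca <- .readChainCA(modelFile)
    n <- nrow(ca$coords)
    fc <- numeric(n)
    ct <- annotation@counts
    idx <- ct$residue_index[ct$residue_index <= n]
    fc[idx] <- ct$feature_count[ct$residue_index <= n]
    .writeCATrace(file, ca$coords, ca$sequence, bfactor = fc)
}

setMethod("show", "ResidueAnnotation", function(object) {
    nf <- sum(object@counts$feature_count)
    nr <- sum(object@counts$feature_count > 0)
    cat(sprintf(
        "ResidueAnnotation %s: %d residue(s), %d feature element(s) on %d residue(s)\n",
        object@modelId, nrow(object@counts), nf, nr))
})
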