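## Structural-alignment hits: US-align output parsing, TM-score filtering,
## and a toy-scale sequential superposition/TM-score engine.
##
## Real-scale alignments are produced upstream (US-align, semi-nonsequential
## mode) and consumed here as parsed text; the built-in Kabsch/TM-score
## engine exists for verification at toy sizes and for the fixture
## generator, and searches sequential correspondences only.

#' Construct an alignment hit
#'
#' @param modelId,chainId identifiers of the aligned model and library chain.
#' @param tmModel,tmTarget TM-scores normalized by model / target length.
#' @param rmsd RMSD over aligned residues (Angstrom).
#' @param pairs data.frame of aligned residue pairs (columns
#'   \code{model_index}, \code{target_index}, \code{model_residue},
#'   \code{target_residue}).
#' @param seqIdentity percent identity over aligned pairs; recomputed from
#'   \code{pairs} when omitted.
#' @return an [AlignmentHit-class].
#' @export
alignmentHit <- function(modelId, chainId, tmModel, tmTarget, rmsd = NA_real_,
                         pairs = NULL, seqIdentity = NULL) {
    if (is.null(pairs))
        pairs <- data.frame(model_index = integer(), target_index = integer(),
                            model_residue = character(),
                            target_residue = character(),
                            stringsAsFactors = FALSE)
    if (is.null(seqIdentity))
        seqIdentity <- if (nrow(pairs))
            100 * mean(pairs$model_residue == pairs$target_residue)
        else NA_real_
    new("AlignmentHit", modelId = modelId, chainId = chainId,
        tmModel = as.numeric(tmModel), tmTarget = as.numeric(tmTarget),
        rmsd = as.numeric(rmsd), seqIdentity = as.numeric(seqIdentity),
        pairs = pairs)
}

#' Average TM-score of a hit
#'
#' The hit-ranking metric: the arithmetic mean of the TM-scores normalized
#' by each structure's length.
#'
#' @param hit an [AlignmentHit-class].
#' @return numeric in (0, 1\].
#' @export
tmAvg <- function(hit) {
    stopifnot(is(hit, "AlignmentHit"))
    (hit@tmModel + hit@tmTarget) / 2
}

setMethod("show", "AlignmentHit", function(object) {
    cat(sprintf(
        "AlignmentHit %s ~ %s: TM %.3f/%.3f (avg %.3f), %d pair(s), id %.1f%%\n",
        object@modelId, object@chainId, object@tmModel, object@tmTarget,
        tmAvg(object), nrow(object@pairs),
        if (is.na(object@seqIdentity)) NA_real_ else object@seqIdentity))
})

## ------------------------------------------------------------------------
## US-align text output
## ------------------------------------------------------------------------

.stripStructureName <- function(s) {
    s <- trimws(s)
    s <- sub(":[A-Za-z0-9]+$", "", s)          # trailing chain selector
    s <- basename(s)
    sub("\\.(pdb|cif|ent)$", "", s, ignore.case = TRUE)
}

#' Parse one US-align result
#'
#' Reads a single-pair US-align-style text result: the two structure-name
#' lines, the RMSD/identity line, the two \code{TM-score=} lines (each
#' stating which structure's length normalized it), and the three-row
#' aligned-sequence block. Residue pairs are reconstructed from the
#' alignment columns where both sequence rows are non-gap.
#'
#' @param x path to a result file, or a character vector of its lines.
#' @return an [AlignmentHit-class].
#' @export
parseUSalignOutput <- function(x) {
    lines <- .asLines(x)
    nm <- grep("^Name of Structure_[12]:", lines, value = TRUE)
    if (length(nm) < 2L)
        stop("parseUSalignOutput: missing structure-name lines")
    model_id <- .stripStructureName(sub("^Name of Structure_1:", "", nm[1]))
    chain_id <- .stripStructureName(sub("^Name of Structure_2:", "", nm[2]))

    tm_lines <- grep("^TM-score=", lines, value = TRUE)
    if (length(tm_lines) < 2L)
        stop(sprintf(
            "parseUSalignOutput: expected two TM-score lines, found %d",
            length(tm_lines)))
    tm_val <- as.numeric(sub("^TM-score=\\s*([0-9.]+).*$", "\\1", tm_lines))
    norm1 <- grepl("Structure_1", tm_lines)
    if (sum(norm1) != 1L)
        stop("parseUSalignOutput: cannot attribute TM-score normalizations")
    tm_model <- tm_val[norm1]
    tm_target <- tm_val[!norm1][1]

    rl <- grep("RMSD=", lines, value = TRUE)
    rmsd <- if (length(rl))
        as.numeric(sub(".*RMSD=\\s*([0-9.]+).*", "\\1", rl[1]))
    else NA_real_

    ## aligned block: the line after the denotes-legend, then the pair row,
    ## then the second sequence row
    legend <- grep("denotes", lines)
    if (!length(legend))
        stop("parseUSalignOutput: missing aligned-sequence block")
    i <- legend[length(legend)] + 1L
    if (i + 2L > length(lines))
        stop(sprintf("parseUSalignOutput: truncated aligned block at line %d", i))
    row_a <- lines[i]; row_b <- lines[i + 2L]
    if (nchar(row_a) != nchar(row_b))
        stop(sprintf(
            "parseUSalignOutput: alignment rows differ in length (%d vs %d) at line %d",
            nchar(row_a), nchar(row_b), i))
    pairs <- .pairsFromAlignedRows(row_a, row_b)
    alignmentHit(model_id, chain_id, tm_model, tm_target, rmsd, pairs)
}

.pairsFromAlignedRows <- function(row_a, row_b) {
    a <- strsplit(row_a, "")[[1]]
    b <- strsplit(row_b, "")[[1]]
    ia <- cumsum(a != "-")
    ib <- cumsum(b != "-")
    both <- a != "-" & b != "-"
    data.frame(model_index = ia[both], target_index = ib[both],
               model_residue = toupper(a[both]),
               target_residue = toupper(b[both]),
               stringsAsFactors = FALSE)
}

#' Write a US-align-style result (fixture writer)
#'
#' Emits the dialect [parseUSalignOutput()] consumes; used by the fixture
#' generator and for round-trip tests.
#'
#' @param hit an [AlignmentHit-class].
#' @param file output path; when \code{NULL} the lines are returned.
#' @param modelLength,targetLength lengths reported in the header; default
#'   to the maxima of the pair indices.
#' @return the text lines, invisibly when written to a file.
#' @export
writeUSalignOutput <- function(hit, file = NULL, modelLength = NULL,
                               targetLength = NULL) {
    stopifnot(is(hit, "AlignmentHit"))
    p <- hit@pairs
    if (is.null(modelLength))
        modelLength <- if (nrow(p)) max(p$model_index) else 0L
    if (is.null(targetLength))
        targetLength <- if (nrow(p)) max(p$target_index) else 0L
    rows <- .alignedRowsFromPairs(p)
    nid <- if (nrow(p)) sum(p$model_residue == p$target_residue) else 0L
    lines <- c(
        sprintf("Name of Structure_1: %s.pdb:A", hit@modelId),
        sprintf("Name of Structure_2: %s.pdb:A", hit@chainId),
        sprintf("Length of Structure_1: %d residues", modelLength),
        sprintf("Length of Structure_2: %d residues", targetLength),
        "",
        sprintf("Aligned length= %d, RMSD= %6.2f, Seq_ID=n_identical/n_aligned= %.3f",
                nrow(p), if (is.na(hit@rmsd)) 0 else hit@rmsd,
                if (nrow(p)) nid / nrow(p) else 0),
        sprintf("TM-score= %.5f (normalized by length of Structure_1: L=%d)",
                hit@tmModel, modelLength),
        sprintf("TM-score= %.5f (normalized by length of Structure_2: L=%d)",
                hit@tmTarget, targetLength),
        "",
        "(\":\" denotes residue pairs of d < 5.0 Angstrom, \".\" denotes other aligned residues)",
        rows$row_a, rows$marks, rows$row_b)
    if (is.null(file)) return(lines)
    writeLines(lines, file)
    invisible(lines)
}

## Rebuild gapped alignment rows from a (sequential) pair list: unaligned
## stretches before and between pairs are written against gaps as X, so
## absolute residue indices survive a round trip through the parser.
.alignedRowsFromPairs <- function(p) {
    if (!nrow(p))
        return(list(row_a = "", marks = "", row_b = ""))
    a <- character(); b <- character()
    prev_i <- 0L; prev_j <- 0L
    for (k in seq_len(nrow(p))) {
        di <- p$model_index[k] - prev_i - 1L
        dj <- p$target_index[k] - prev_j - 1L
        if (di > 0) { a <- c(a, rep("X", di)); b <- c(b, rep("-", di)) }
        if (dj > 0) { a <- c(a, rep("-", dj)); b <- c(b, rep("X", dj)) }
        a <- c(a, p$model_residue[k]); b <- c(b, p$target_residue[k])
        prev_i <- p$model_index[k]; prev_j <- p$target_index[k]
    }
    marks <- ifelse(a != "-" & b != "-", ":", " ")
    list(row_a = paste(a, collapse = ""),
         marks = paste(marks, collapse = ""),
         row_b = paste(b, collapse = ""))
}

## ------------------------------------------------------------------------
## Hit filtering and TSV interchange
## ------------------------------------------------------------------------

#' Filter and rank alignment hits
#'
#' Retains hits whose average TM-score is at or above the threshold (the
#' pipeline excludes hits strictly below it) and sorts them by descending
#' average TM-score, breaking ties lexicographically by chain ID.
#'
#' @param hits list of [AlignmentHit-class].
#' @param threshold retention threshold in (0, 1\]; default 0.7.
#' @return the retained hits, ranked.
#' @export
filterHits <- function(hits, threshold = 0.7) {
    stopifnot(threshold > 0, threshold <= 1)
    if (!length(hits)) return(list())
    avg <- vapply(hits, tmAvg, numeric(1))
    keep <- avg >= threshold
    hits <- hits[keep]; avg <- avg[keep]
    ids <- vapply(hits, function(h) h@chainId, character(1))
    hits[order(-avg, ids, method = "radix")]
}

#' Write hits to the canonical TSV interchange format
#'
#' One row per hit: identifiers, both TM-scores, their mean, RMSD, percent
#' identity and the two gapped alignment strings (from which residue pairs
#' are reconstructed on read).
#'
#' @param hits list of [AlignmentHit-class].
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeHitsTable <- function(hits, file) {
    df <- do.call(rbind, lapply(hits, function(h) {
        rows <- .alignedRowsFromPairs(h@pairs)
        data.frame(model_id = h@modelId, chain_id = h@chainId,
                   tm_model = h@tmModel, tm_target = h@tmTarget,
                   tm_avg = tmAvg(h), rmsd = h@rmsd,
                   identity = h@seqIdentity,
                   aln_model = rows$row_a, aln_target = rows$row_b,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(df))
        df <- data.frame(model_id = character(), chain_id = character(),
                         tm_model = numeric(), tm_target = numeric(),
                         tm_avg = numeric(), rmsd = numeric(),
                         identity = numeric(), aln_model = character(),
                         aln_target = character())
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read hits from the canonical TSV interchange format
#'
#' @param file path written by [writeHitsTable()] (or an equivalent
#'   upstream converter).
#' @return list of [AlignmentHit-class].
#' @export
readHitsTable <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE,
                            colClasses = "character")
    required <- c("model_id", "chain_id", "tm_model", "tm_target",
                  "rmsd", "aln_model", "aln_target")
    if (!all(required %in% names(df)))
        stop(sprintf("readHitsTable: %s lacks column(s): %s", file,
                     paste(setdiff(required, names(df)), collapse = ", ")))
    for (col in c("tm_model", "tm_target", "rmsd"))
        df[[col]] <- as.numeric(df[[col]])
    lapply(seq_len(nrow(df)), function(i) {
        pairs <- .pairsFromAlignedRows(df$aln_model[i], df$aln_target[i])
        alignmentHit(df$model_id[i], df$chain_id[i], df$tm_model[i],
                     df$tm_target[i], df$rmsd[i], pairs)
    })
}

## ------------------------------------------------------------------------
## Toy-scale superposition / TM-score engine
## ------------------------------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Computes the proper rotation and translation that superpose coordinate
#' set \code{b} onto \code{a} over a given correspondence, minimizing RMSD
#' (Kabsch algorithm via SVD, with the determinant correction that excludes
#' reflections).
#'
#' @param a,b numeric matrices (n x 3) of CA coordinates.
#' @param correspondence two-column matrix/data.frame of row indices
#'   (\code{a} index, \code{b} index); at least 3 pairs, not all collinear.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3;
#'   the superposed \code{b} is \code{b \%*\% t(rotation) + translation})
#'   and \code{rmsd}.
#' @export
kabschSuperpose <- function(a, b, correspondence) {
    corr <- as.matrix(correspondence)[, 1:2, drop = FALSE]
    if (nrow(corr) < 3L)
        stop("kabschSuperpose: at least 3 corresponding pairs required")
    pa <- a[corr[, 1], , drop = FALSE]
    pb <- b[corr[, 2], , drop = FALSE]
    ca <- colMeans(pa); cb <- colMeans(pb)
    xa <- sweep(pa, 2, ca); xb <- sweep(pb, 2, cb)
    h <- crossprod(xb, xa)                      # 3x3 covariance
    sv <- svd(h)
    if (sv$d[2] < 1e-10)
        stop("kabschSuperpose: degenerate (collinear) geometry")
    d <- sign(det(sv$v %*% t(sv$u)))
    r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    t_vec <- ca - as.numeric(r %*% cb)
    fitted <- xb %*% t(r)
    rmsd <- sqrt(mean(rowSums((fitted - xa)^2)))
    list(rotation = r, translation = t_vec, rmsd = rmsd)
}

#' TM-score normalization distance d0
#'
#' \code{d0 = 1.24 (L - 15)^(1/3) - 1.8}, floored at 0.5.
#'
#' @param normLength normalization length L.
#' @return numeric d0 in Angstrom.
#' @export
tmD0 <- function(normLength) {
    stopifnot(normLength >= 1)
    max(0.5, 1.24 * sign(normLength - 15) * abs(normLength - 15)^(1 / 3) - 1.8)
}

#' TM-score over a fixed correspondence
#'
#' Standard TM-score: \code{sum over aligned pairs of 1/(1 + (d_i/d0)^2)},
#' divided by the normalization length, maximized over rigid superpositions
#' by the usual iterative seed-fragment search (superpose on a seed subset,
#' rescore all pairs, re-superpose on the close pairs until stable; seeds
#' are contiguous fragments of decreasing length).
#'
#' @param a,b numeric matrices (n x 3) of CA coordinates.
#' @param correspondence two-column matrix/data.frame of aligned row index
#'   pairs; nonempty.
#' @param normLength normalization length (sets d0 and the denominator).
#' @return TM-score in (0, 1\].
#' @export
tmScore <- function(a, b, correspondence, normLength) {
    corr <- as.matrix(correspondence)[, 1:2, drop = FALSE]
    if (!nrow(corr))
        stop("tmScore: empty correspondence")
    stopifnot(normLength >= 1)
    d0 <- tmD0(normLength)
    pa <- a[corr[, 1], , drop = FALSE]
    pb <- b[corr[, 2], , drop = FALSE]
    n <- nrow(pa)
    if (n < 3L) {
        ## too few pairs for a unique superposition: best case is exact
        ## coincidence of the pairs; score them at distance 0
        return(min(1, n / normLength))
    }
    score_of <- function(sel) {
        fit <- tryCatch(kabschSuperpose(pa, pb, cbind(sel, sel)),
                        error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        moved <- pb %*% t(fit$rotation) +
            matrix(fit$translation, n, 3, byrow = TRUE)
        d <- sqrt(rowSums((moved - pa)^2))
        list(score = sum(1 / (1 + (d / d0)^2)) / normLength, d = d)
    }
    ## polish a candidate superposition by iteratively reweighted Kabsch
    ## (weights are the derivative-motivated TM terms), which maximizes the
    ## TM sum rather than minimizing plain RMSD
    polish <- function(d) {
        best_local <- 0
        for (iter in seq_len(50L)) {
            w <- 1 / (1 + (d / d0)^2)^2
            fit <- .weightedKabsch(pa, pb, w)
            if (is.null(fit)) break
            moved <- pb %*% t(fit$rotation) +
                matrix(fit$translation, n, 3, byrow = TRUE)
            d <- sqrt(rowSums((moved - pa)^2))
            sc <- sum(1 / (1 + (d / d0)^2)) / normLength
            if (sc <= best_local + 1e-12) break
            best_local <- sc
        }
        best_local
    }
    best <- 0
    frag_lens <- unique(pmax(4L, c(n, n %/% 2L, n %/% 4L)))
    for (fl in frag_lens) {
        if (fl > n) next
        starts <- unique(c(seq(1L, n - fl + 1L, by = max(1L, fl %/% 2L)),
                           n - fl + 1L))
        for (s in starts) {
            sel <- seq(s, s + fl - 1L)
            res <- score_of(sel)
            if (is.null(res)) next
            for (iter in seq_len(20L)) {
                cut <- d0
                repeat {
                    new_sel <- which(res$d < cut)
                    if (length(new_sel) >= 3L) break
                    cut <- cut + 0.5
                }
                if (identical(new_sel, sel)) break
                sel <- new_sel
                nxt <- score_of(sel)
                if (is.null(nxt)) break
                res <- nxt
            }
            best <- max(best, res$score, polish(res$d))
        }
    }
    min(1, best)
}

## Weighted Kabsch superposition over all rows (weights >= 0).
.weightedKabsch <- function(pa, pb, w) {
    w <- w / sum(w)
    ca <- colSums(pa * w); cb <- colSums(pb * w)
    xa <- sweep(pa, 2, ca); xb <- sweep(pb, 2, cb)
    h <- crossprod(xb * w, xa)
    sv <- tryCatch(svd(h), error = function(e) NULL)
    if (is.null(sv) || sv$d[2] < 1e-12) return(NULL)
    d <- sign(det(sv$v %*% t(sv$u)))
    r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    list(rotation = r, translation = ca - as.numeric(r %*% cb))
}

#' Global sequence alignment with identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gap penalties: open
#' 10, extend 0.5) between two amino-acid sequences. Identity is computed
#' over aligned (both non-gap) columns only.
#'
#' @param seqA,seqB nonempty amino-acid strings.
#' @return list with \code{pairs} (data.frame \code{a_index},
#'   \code{b_index}, \code{a_residue}, \code{b_residue}) and
#'   \code{identity} (percent over aligned columns).
#' @export
alignBySequence <- function(seqA, seqB) {
    stopifnot(nzchar(seqA), nzchar(seqB))
    al <- .globalAlignment(seqA, seqB)
    p <- .pairsFromAlignedRows(al$aligned_a, al$aligned_b)
    names(p) <- c("a_index", "b_index", "a_residue", "b_residue")
    identity <- if (nrow(p)) 100 * mean(p$a_residue == p$b_residue)
                else NA_real_
    list(pairs = p, identity = identity)
}
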