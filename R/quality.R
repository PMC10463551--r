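## Model-quality ingestion and the high-confidence gate.
##
## AlphaFold-style models carry per-residue pLDDT in the B-factor column;
## the whole-model pTM arrives in a JSON scores file. A model enters the
## alignment stage when either score clears its threshold (strictly).

#' Read per-residue pLDDT from a model coordinate file
#'
#' Takes the B-factor of each residue's CA atom (first atom of the residue
#' as fallback), in residue order. Values outside \[0, 100\] are clamped
#' with a warning.
#'
#' @param file PDB or mmCIF model file (single chain).
#' @return numeric vector of per-residue pLDDT values.
#' @export
readPlddtFromModel <- function(file) {
    ca <- .readChainCA(file)
    b <- ca$bfactor
    if (any(b < 0 | b > 100)) {
        warning(sprintf(
            "readPlddtFromModel: %d B-factor value(s) outside [0, 100] clamped in %s",
            sum(b < 0 | b > 100), basename(file)))
        b <- pmin(pmax(b, 0), 100)
    }
    b
}

#' Read the pTM score from a JSON scores file
#'
#' @param file JSON document; the top-level \code{"ptm"} key carries the
#'   score. A missing key yields \code{NA} (the gate then uses pLDDT only).
#' @return numeric pTM in \[0, 1\], or \code{NA} when unavailable.
#' @export
readPtm <- function(file) {
    doc <- tryCatch(jsonlite::read_json(file),
                    error = function(e) stop(sprintf(
                        "readPtm: cannot parse %s: %s", file,
                        conditionMessage(e))))
    if (is.null(doc$ptm))
        return(NA_real_)
    as.numeric(doc$ptm)
}

#' Assemble a model-quality record
#'
#' @param modelId model identifier.
#' @param ptm pTM score in \[0, 1\] or \code{NA}.
#' @param plddt per-residue pLDDT vector (may be empty when only pTM is
#'   known).
#' @return a [ModelQuality-class].
#' @export
modelQuality <- function(modelId, ptm = NA_real_, plddt = numeric()) {
    new("ModelQuality", modelId = modelId, ptm = as.numeric(ptm),
        plddt = as.numeric(plddt))
}

#' Mean pLDDT of a model
#' @param q a [ModelQuality-class].
#' @return numeric mean of per-residue values, \code{NA} when none.
#' @export
plddtMean <- function(q) {
    stopifnot(is(q, "ModelQuality"))
    if (!length(q@plddt)) NA_real_ else mean(q@plddt)
}

#' High-confidence model gate
#'
#' A model passes when pTM strictly exceeds \code{ptmThreshold} OR its mean
#' pLDDT strictly exceeds \code{plddtThreshold}. Values sitting exactly at a
#' threshold fail it. When one score is unavailable the other decides alone;
#' both unavailable is an error (and impossible for a valid
#' [ModelQuality-class]).
#'
#' @param q a [ModelQuality-class].
#' @param ptmThreshold default 0.7.
#' @param plddtThreshold default 70.
#' @return logical flag.
#' @examples
#' passesGate(modelQuality("m", ptm = 0.89, plddt = rep(89, 10)))  # TRUE
#' passesGate(modelQuality("m", ptm = 0.5, plddt = rep(60, 10)))   # FALSE
#' @export
passesGate <- function(q, ptmThreshold = 0.7, plddtThreshold = 70) {
    stopifnot(is(q, "ModelQuality"))
    pm <- plddtMean(q)
    if (is.na(q@ptm) && is.na(pm))
        stop("passesGate: neither pTM nor pLDDT available")
    (!is.na(q@ptm) && q@ptm > ptmThreshold) ||
        (!is.na(pm) && pm > plddtThreshold)
}

setMethod("show", "ModelQuality", function(object) {
    cat(sprintf("ModelQuality %s: pTM = %s, mean pLDDT = %s (%d residues)\n",
                object@modelId,
                if (is.na(object@ptm)) "NA" else sprintf("%.3f", object@ptm),
                if (!length(object@plddt)) "NA"
                else sprintf("%.1f", mean(object@plddt)),
                length(object@plddt)))
})
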