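#' @import methods
NULL

## -------------------------------------------------------------------------
## ECNumber
## -------------------------------------------------------------------------

#' EC number (possibly a hierarchical prefix)
#'
#' A four-level Enzyme Commission label. Unspecified trailing levels (written
#' \code{"*"} or \code{"-"} in source records) are stored as \code{NA};
#' \code{depth} counts the specified leading levels. \code{"1.14.14.*"} has
#' depth 3; a full label such as \code{"4.3.3.6"} has depth 4.
#'
#' @slot levels integer vector of length 4; \code{NA} marks an unspecified
#'   level. No specified level may follow an unspecified one.
#' @seealso [parseEC()], [ecPrefix()], [isPrefixOf()], [formatEC()]
#' @exportClass ECNumber
setClass("ECNumber", representation(levels = "integer"))

setValidity("ECNumber", function(object) {
    lv <- object@levels
    if (length(lv) != 4L)
        return("levels must have length 4")
    spec <- !is.na(lv)
    if (!any(spec))
        return("at least the top-level class must be specified")
    if (any(diff(spec) > 0L))
        return("a specified level must not follow an unspecified one")
    if (any(lv[spec] < 1L))
        return("specified levels must be positive integers")
    TRUE
})

## -------------------------------------------------------------------------
## ECDistribution
## -------------------------------------------------------------------------

#' Probability distribution over EC labels
#'
#' Normalized probability mass over (formatted) EC label strings. Used both
#' for the library background distribution Q and for a model's hit-sample
#' distribution P. \code{nObservations} records the total label-occurrence
#' count behind the distribution; it sets the smoothing floor
#' \code{1/(2*nObservations)} used when a sampled label is absent from Q.
#'
#' @slot mass named numeric; names are formatted EC labels, values sum to 1.
#' @slot nObservations integer; the count of label occurrences the
#'   distribution was estimated from (\code{NA} if constructed by hand).
#' @seealso [ecDistribution()], [backgroundDistribution()], [relativeEntropy()]
#' @exportClass ECDistribution
setClass("ECDistribution",
    representation(mass = "numeric", nObservations = "integer"))

setValidity("ECDistribution", function(object) {
    m <- object@mass
    if (length(m) == 0L)
        return("distribution must have at least one label")
    if (is.null(names(m)) || anyNA(names(m)) || any(names(m) == ""))
        return("all mass entries must be named by an EC label")
    if (anyDuplicated(names(m)))
        return("duplicate EC labels in mass")
    if (any(m < 0))
        return("probabilities must be nonnegative")
    if (abs(sum(m) - 1) > 1e-9)
        return(sprintf("probabilities must sum to 1 (got %.12f)", sum(m)))
    TRUE
})

## -------------------------------------------------------------------------
## ChainRecord / StructLibrary
## -------------------------------------------------------------------------

#' One annotated library chain
#'
#' A single-chain entry of the annotated structural library: its sequence,
#' EC labels gathered from the matched UniProt entry, and residue-level
#' ACT_SITE/BINDING features re-indexed to chain numbering.
#'
#' @slot chainId character, "PDBID_CHAIN"-style identifier.
#' @slot sequence character, one-letter amino-acid string.
#' @slot uniprotAccession character, \code{NA} when unmapped.
#' @slot ecLabels list of [ECNumber-class] objects (possibly empty).
#' @slot features data.frame with columns \code{category} ("ACT_SITE" or
#'   "BINDING"), \code{position} (1-based chain index), \code{residue_type}
#'   (one-letter code), \code{ligand_label} (empty string for ACT_SITE).
#' @slot coordinatesRef character path (or other locator) of the chain's
#'   structure file; may be \code{NA}.
#' @seealso [buildLibrary()], [chainRecord()]
#' @exportClass ChainRecord
setClass("ChainRecord", representation(
    chainId = "character",
    sequence = "character",
    uniprotAccession = "character",
    ecLabels = "list",
    features = "data.frame",
    coordinatesRef = "character"))

.featureColumns <- c("category", "position", "residue_type", "ligand_label")

setValidity("ChainRecord", function(object) {
    if (length(object@chainId) != 1L || is.na(object@chainId))
        return("chainId must be a single non-NA string")
    if (length(object@sequence) != 1L || is.na(object@sequence))
        return("sequence must be a single non-NA string")
    ft <- object@features
    if (!all(.featureColumns %in% names(ft)))
        return(sprintf("features must have columns %s",
                       paste(.featureColumns, collapse = ", ")))
    if (nrow(ft)) {
        if (!all(ft$category %in% c("ACT_SITE", "BINDING")))
            return("feature category must be ACT_SITE or BINDING")
        n <- nchar(object@sequence)
        if (any(ft$position < 1L) || any(ft$position > n))
            return("feature positions must lie within the chain sequence")
        chars <- substring(object@sequence, ft$position, ft$position)
        if (!all(chars == ft$residue_type))
            return("feature residue_type must match the chain sequence")
    }
    if (!all(vapply(object@ecLabels, is, logical(1), "ECNumber")))
        return("ecLabels must all be ECNumber objects")
    TRUE
})

#' Annotated structural library
#'
#' Container for the full annotated library: one [ChainRecord-class] per
#' chain, plus build-time bookkeeping (dropped-feature counts from the
#' UniProt-to-chain numbering reconciliation).
#'
#' @slot chains named list of [ChainRecord-class]; names are chain IDs.
#' @slot droppedFeatures named integer; per-chain count of UniProt features
#'   that could not be carried onto the chain sequence.
#' @seealso [buildLibrary()], [backgroundDistribution()]
#' @exportClass StructLibrary
setClass("StructLibrary", representation(
    chains = "list",
    droppedFeatures = "integer"))

setValidity("StructLibrary", function(object) {
    ch <- object@chains
    if (!all(vapply(ch, is, logical(1), "ChainRecord")))
        return("chains must all be ChainRecord objects")
    ids <- vapply(ch, function(x) x@chainId, character(1))
    if (length(ch) && !identical(names(ch), unname(ids)))
        return("chains must be named by their chainId")
    TRUE
})

## -------------------------------------------------------------------------
## ModelQuality
## -------------------------------------------------------------------------

#' AlphaFold-style model confidence scores
#'
#' Per-model confidence used by the quality gate: the whole-model pTM score
#' and per-residue pLDDT values (conventionally carried in the B-factor
#' column of the model coordinates).
#'
#' @slot modelId character.
#' @slot ptm numeric in \[0, 1\], \code{NA} when the scores file lacks it.
#' @slot plddt numeric vector of per-residue values in \[0, 100\]; may be
#'   empty when only pTM is available.
#' @seealso [modelQuality()], [passesGate()], [readPlddtFromModel()]
#' @exportClass ModelQuality
setClass("ModelQuality", representation(
    modelId = "character",
    ptm = "numeric",
    plddt = "numeric"))

setValidity("ModelQuality", function(object) {
    if (length(object@ptm) != 1L)
        return("ptm must be a single value (NA when unavailable)")
    if (!is.na(object@ptm) && (object@ptm < 0 || object@ptm > 1))
        return("ptm must lie in [0, 1]")
    pl <- object@plddt
    if (length(pl) && (anyNA(pl) || any(pl < 0) || any(pl > 100)))
        return("per-residue pLDDT values must lie in [0, 100]")
    if (is.na(object@ptm) && length(pl) == 0L)
        return("at least one of ptm / pLDDT must be available")
    TRUE
})

## -------------------------------------------------------------------------
## AlignmentHit
## -------------------------------------------------------------------------

#' One model-to-chain structural alignment
#'
#' Parsed result of a structural alignment between a model and a library
#' chain: TM-scores under both length normalizations, their mean (the hit
#' ranking metric), RMSD, percent identity over aligned residues, and the
#' residue-pair correspondence.
#'
#' @slot modelId character.
#' @slot chainId character.
#' @slot tmModel TM-score normalized by the model length, in (0, 1\].
#' @slot tmTarget TM-score normalized by the library-chain length, in (0, 1\].
#' @slot rmsd numeric, Angstrom.
#' @slot seqIdentity percent identity over aligned (both non-gap) columns.
#' @slot pairs data.frame with columns \code{model_index}, \code{target_index}
#'   (1-based), \code{model_residue}, \code{target_residue} (one-letter codes).
#' @seealso [parseUSalignOutput()], [filterHits()], [tmAvg()]
#' @exportClass AlignmentHit
setClass("AlignmentHit", representation(
    modelId = "character",
    chainId = "character",
    tmModel = "numeric",
    tmTarget = "numeric",
    rmsd = "numeric",
    seqIdentity = "numeric",
    pairs = "data.frame"))

.pairColumns <- c("model_index", "target_index", "model_residue",
                  "target_residue")

setValidity("AlignmentHit", function(object) {
    for (s in c("tmModel", "tmTarget"))
        if (length(slot(object, s)) != 1L)
            return(sprintf("%s must be a single value", s))
    if (object@tmModel <= 0 || object@tmModel > 1 ||
        object@tmTarget <= 0 || object@tmTarget > 1)
        return("TM-scores must lie in (0, 1]")
    p <- object@pairs
    if (!all(.pairColumns %in% names(p)))
        return(sprintf("pairs must have columns %s",
                       paste(.pairColumns, collapse = ", ")))
    if (nrow(p)) {
        if (any(p$model_index < 1L) || any(p$target_index < 1L))
            return("pair indices must be >= 1")
        aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]])
        if (!all(p$model_residue %in% aa) || !all(p$target_residue %in% aa))
            return("pair residues must be one-letter amino-acid codes or X")
    }
    TRUE
})

## -------------------------------------------------------------------------
## ECSample / EnzymeCall
## -------------------------------------------------------------------------

#' EC labels gathered from a model's retained hits
#'
#' The multiset of EC labels carried by the library chains of a model's
#' retained alignment hits (one count per label per chain), and the sample
#' distribution P derived from it.
#'
#' @slot labels character vector of formatted EC labels (with multiplicity);
#'   may be empty.
#' @seealso [gatherECSample()], [annotateModel()]
#' @exportClass ECSample
setClass("ECSample", representation(labels = "character"))

#' Enzyme annotation verdict for one model
#'
#' The full outcome of the relative-entropy annotation: the KL divergence in
#' bits with its per-label components, the Monte-Carlo z-score and one-sided
#' p-value, the verdict, and (for enzymes) the assigned consensus EC label.
#'
#' @slot modelId character.
#' @slot dklBits total relative entropy D(P||Q) in bits (NA when no sample).
#' @slot components named numeric; each label's summand P(x) log2(P(x)/Q(x)).
#' @slot zScore standardized statistic against the Monte-Carlo null.
#' @slot pValue one-sided upper-tail probability.
#' @slot verdict one of \code{"NO_HITS"}, \code{"NOT_ENZYME"}, \code{"ENZYME"}.
#' @slot assignedLabel formatted EC label or prefix, or \code{"NO_CONSENSUS"};
#'   \code{NA} unless the verdict is \code{"ENZYME"}.
#' @slot nHits number of retained hits behind the call.
#' @slot seed RNG seed used by the significance test.
#' @seealso [annotateModel()], [consensusLabel()]
#' @exportClass EnzymeCall
setClass("EnzymeCall", representation(
    modelId = "character",
    dklBits = "numeric",
    components = "numeric",
    zScore = "numeric",
    pValue = "numeric",
    verdict = "character",
    assignedLabel = "character",
    nHits = "integer",
    seed = "integer"))

setValidity("EnzymeCall", function(object) {
    if (!object@verdict %in% c("NO_HITS", "NOT_ENZYME", "ENZYME"))
        return("verdict must be NO_HITS, NOT_ENZYME or ENZYME")
    if (object@verdict == "ENZYME") {
        if (is.na(object@assignedLabel))
            return("ENZYME verdict requires an assigned label or NO_CONSENSUS")
        if (length(object@components) &&
            abs(sum(object@components) - object@dklBits) > 1e-9)
            return("components must sum to dklBits")
    } else if (!is.na(object@assignedLabel)) {
        return("assignedLabel must be NA unless verdict is ENZYME")
    }
    TRUE
})

## -------------------------------------------------------------------------
## ResidueAnnotation
## -------------------------------------------------------------------------

#' Residue-level feature evidence transferred onto a model
#'
#' Per-model-residue tallies of aligned library residues that carry
#' ACT_SITE/BINDING features (the feature count), of those with identical
#' residue type (the conservation count), split by category, plus a long
#' table of ligand-label tallies for BINDING evidence.
#'
#' @slot modelId character.
#' @slot counts data.frame, one row per model residue: \code{residue_index},
#'   \code{residue_type}, \code{feature_count}, \code{conservation_count},
#'   \code{act_site_count}, \code{binding_count}.
#' @slot ligands data.frame, long tally: \code{residue_index},
#'   \code{ligand_label}, \code{count}.
#' @seealso [transferFeatures()], [topFeatureResidues()]
#' @exportClass ResidueAnnotation
setClass("ResidueAnnotation", representation(
    modelId = "character",
    counts = "data.frame",
    ligands = "data.frame"))

setValidity("ResidueAnnotation", function(object) {
    cn <- c("residue_index", "residue_type", "feature_count",
            "conservation_count", "act_site_count", "binding_count")
    ct <- object@counts
    if (!all(cn %in% names(ct)))
        return(sprintf("counts must have columns %s",
                       paste(cn, collapse = ", ")))
    if (nrow(ct)) {
        if (any(ct$conservation_count > ct$feature_count))
            return("conservation_count must not exceed feature_count")
        if (any(ct$act_site_count + ct$binding_count != ct$feature_count))
            return("category tallies must sum to feature_count")
    }
    TRUE
})

## -------------------------------------------------------------------------
## PipelineConfig
## -------------------------------------------------------------------------

#' Pipeline thresholds and run parameters
#'
#' Holds the workflow cutoffs (model-quality gate, hit retention, consensus
#' majority, significance level), the Monte-Carlo draw count, the RNG seed,
#' and the input/output paths used by the command-layer functions.
#'
#' @slot ptmThreshold pass when pTM strictly exceeds this (default 0.7).
#' @slot plddtThreshold pass when mean pLDDT strictly exceeds this
#'   (default 70).
#' @slot tmAvgThreshold retain hits with average TM-score at or above this
#'   (default 0.7).
#' @slot majorityFraction consensus majority fraction (default 0.5).
#' @slot alpha significance level for the enzyme call (default 0.05).
#' @slot nDraws Monte-Carlo null sample count (default 10000).
#' @slot seed integer RNG seed.
#' @slot paths named character: optional \code{library}, \code{models},
#'   \code{hits}, \code{output} locations for the command layer.
#' @seealso [pipelineConfig()], [annotateModel()], [cmdAnnotate()]
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
    ptmThreshold = "numeric",
    plddtThreshold = "numeric",
    tmAvgThreshold = "numeric",
    majorityFraction = "numeric",
    alpha = "numeric",
    nDraws = "integer",
    seed = "integer",
    paths = "character"),
    prototype(
        ptmThreshold = 0.7,
        plddtThreshold = 70,
        tmAvgThreshold = 0.7,
        majorityFraction = 0.5,
        alpha = 0.05,
        nDraws = 10000L,
        seed = 1L,
        paths = character()))

setValidity("PipelineConfig", function(object) {
    if (object@ptmThreshold < 0 || object@ptmThreshold > 1)
        return("ptmThreshold must lie in [0, 1]")
    if (object@plddtThreshold < 0 || object@plddtThreshold > 100)
        return("plddtThreshold must lie in [0, 100]")
    if (object@tmAvgThreshold <= 0 || object@tmAvgThreshold > 1)
        return("tmAvgThreshold must lie in (0, 1]")
    if (object@majorityFraction <= 0 || object@majorityFraction > 1)
        return("majorityFraction must lie in (0, 1]")
    if (object@alpha <= 0 || object@alpha >= 1)
        return("alpha must lie in (0, 1)")
    if (object@nDraws < 1L)
        return("nDraws must be >= 1")
    TRUE
})
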