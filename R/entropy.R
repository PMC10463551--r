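## Enzyme/non-enzyme classification and consensus EC assignment.
##
## A model's retained hits yield a multiset of EC labels; its distribution P
## is compared to the library background Q through the relative entropy
## (Kullback-Leibler divergence, base-2 logs, in bits):
##
##     D(P||Q) = sum_x P(x) log2( P(x) / Q(x) )
##
## Significance comes from a Monte-Carlo null (samples of the same size
## drawn i.i.d. from Q); the consensus rule assigns the most specific EC
## label or prefix whose relative-entropy component holds a strict majority
## of the total.

#' Gather the EC-label sample of a model's retained hits
#'
#' Concatenates the EC labels of every retained hit's library chain, one
#' count per label per chain; chains without EC labels contribute nothing.
#' An empty sample is legal (the model is then called non-enzyme).
#'
#' @param hits list of [AlignmentHit-class], already filtered by average
#'   TM-score.
#' @param library a [StructLibrary-class].
#' @return an [ECSample-class].
#' @export
gatherECSample <- function(hits, library) {
    stopifnot(is(library, "StructLibrary"))
    labels <- unlist(lapply(hits, function(h) {
        ch <- libraryChain(library, h@chainId)
        vapply(ch@ecLabels, formatEC, character(1))
    }), use.names = FALSE)
    if (is.null(labels)) labels <- character()
    new("ECSample", labels = labels)
}

#' Construct an EC sample from label strings
#'
#' @param labels character vector of EC labels (with multiplicity;
#'   normalized through [parseEC()]). May be empty.
#' @return an [ECSample-class].
#' @export
ecSample <- function(labels = character()) {
    labels <- vapply(labels, function(s) formatEC(parseEC(s)), character(1),
                     USE.NAMES = FALSE)
    new("ECSample", labels = labels)
}

#' Size of an EC sample
#' @param x an [ECSample-class].
#' @return integer label count (with multiplicity).
#' @export
sampleSize <- function(x) {
    stopifnot(is(x, "ECSample"))
    length(x@labels)
}

#' Sample distribution P of an EC sample
#' @param x a nonempty [ECSample-class].
#' @return an [ECDistribution-class].
#' @export
sampleDistribution <- function(x) {
    stopifnot(is(x, "ECSample"))
    if (!length(x@labels))
        stop("sampleDistribution: empty sample")
    tab <- table(x@labels)
    ecDistribution(stats::setNames(as.numeric(tab), names(tab)),
                   nObservations = length(x@labels))
}

setMethod("show", "ECSample", function(object) {
    cat(sprintf("ECSample: %d label(s), %d distinct\n",
                length(object@labels), length(unique(object@labels))))
})

#' Relative entropy (KL divergence) of P against Q, in bits
#'
#' \code{D(P||Q) = sum_x P(x) log2(P(x)/Q(x))} over the support of P,
#' returned with its per-label components (the summands). Labels present in
#' P but absent from Q receive the smoothing floor probability
#' \code{1/(2 * nObservations(Q))}, and Q is renormalized for that
#' evaluation; the statistic is otherwise undefined at Q(x) = 0 and a novel
#' label in the hits must not crash the pipeline.
#'
#' @param p an [ECDistribution-class] (the sample distribution).
#' @param q an [ECDistribution-class] (the background).
#' @param qFloor override for the smoothing floor; required only when
#'   \code{q} was built by hand without an observation count and P has
#'   labels outside Q's support.
#' @return list with \code{dkl_bits} and \code{components} (named numeric;
#'   sums to \code{dkl_bits}).
#' @examples
#' p <- ecDistribution(c("4.3.3.6" = 1))
#' q <- ecDistribution(c("4.3.3.6" = 2^-9.5, "1.1.1.1" = 1 - 2^-9.5),
#'                     nObservations = 1000L)
#' relativeEntropy(p, q)$dkl_bits   # 9.5
#' @export
relativeEntropy <- function(p, q, qFloor = NULL) {
    stopifnot(is(p, "ECDistribution"), is(q, "ECDistribution"))
    pm <- p@mass
    qm <- q@mass
    novel <- setdiff(names(pm), names(qm))
    if (length(novel)) {
        if (is.null(qFloor)) {
            if (is.na(q@nObservations))
                stop("relativeEntropy: sample label(s) absent from Q and no floor available; supply qFloor")
            qFloor <- 1 / (2 * q@nObservations)
        }
        qm <- c(qm, stats::setNames(rep(qFloor, length(novel)), novel))
        qm <- qm / sum(qm)
    }
    qp <- qm[names(pm)]
    components <- pm * (log2(pm) - log2(qp))
    components[pm == 0] <- 0
    list(dkl_bits = sum(components), components = components)
}

#' Monte-Carlo significance of an observed EC sample
#'
#' Null model: draw \code{sampleSize(sample)} labels i.i.d. from Q,
#' compute the null relative entropy, repeat \code{nDraws} times. The
#' z-score standardizes the observed statistic against the null mean and
#' SD; the p-value is the one-sided upper tail of the standard normal at z.
#' Fully deterministic given \code{seed} (the caller's RNG state is left
#' untouched).
#'
#' @param sample a nonempty [ECSample-class].
#' @param q the background [ECDistribution-class].
#' @param nDraws number of null draws (>= 1000 recommended; default 10000).
#' @param seed integer RNG seed.
#' @return list with \code{z_score}, \code{p_value}, \code{null_mean},
#'   \code{null_sd}, \code{dkl_bits}.
#' @export
significance <- function(sample, q, nDraws = 10000L, seed = 1L) {
    stopifnot(is(sample, "ECSample"), is(q, "ECDistribution"))
    n <- sampleSize(sample)
    if (n == 0L)
        stop("significance: empty sample")
    if (nDraws < 1L)
        stop("significance: nDraws must be >= 1")
    obs <- relativeEntropy(sampleDistribution(sample), q)$dkl_bits
    null_dkl <- .nullDklDraws(q@mass, n, nDraws, seed)
    mu <- mean(null_dkl)
    sdv <- stats::sd(null_dkl)
    if (sdv == 0)
        stop("significance: degenerate null (zero SD)")
    z <- (obs - mu) / sdv
    list(z_score = z, p_value = stats::pnorm(z, lower.tail = FALSE),
         null_mean = mu, null_sd = sdv, dkl_bits = obs)
}

## Vectorized null: multinomial counts over Q's support, one column per
## draw; D(P_hat || Q) per column.
.nullDklDraws <- function(qmass, n, nDraws, seed) {
    .withSeed(seed, {
        counts <- stats::rmultinom(nDraws, size = n, prob = qmass)
    })
    phat <- counts / n
    plogp <- phat * log2(phat)
    plogp[counts == 0L] <- 0
    colSums(plogp) - colSums(phat * log2(qmass))
}

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

#' Consensus EC label from relative-entropy components
#'
#' Strict-majority consensus, most specific depth first. At depth 4, a
#' unique full label whose component reaches
#' \code{majorityFraction * dklBits} wins. Otherwise components aggregate by
#' prefix at depth 3, then 2, then 1; the first depth with a unique
#' qualifying prefix wins. When two labels qualify at the same depth (an
#' exact tie at the threshold, or jointly dominant negative-offset cases),
#' or no depth qualifies, the result is \code{"NO_CONSENSUS"}. When every
#' aggregate is negative at every depth (a sub-background sample) the
#' result is \code{"NO_CONSENSUS"} with attribute \code{diagnostic}.
#'
#' @param components named numeric; per-label relative-entropy components
#'   (names are EC label strings; partial labels participate only at depths
#'   they reach).
#' @param dklBits total relative entropy (must be positive).
#' @param majorityFraction majority threshold as a fraction of the total;
#'   default 0.5.
#' @return an [ECNumber-class], or the string \code{"NO_CONSENSUS"}.
#' @examples
#' consensusLabel(c("4.3.3.6" = 9.5), 9.5)                 # full label
#' consensusLabel(c("1.1.1.1" = 1, "2.2.2.2" = 1), 2)      # "NO_CONSENSUS"
#' @export
consensusLabel <- function(components, dklBits, majorityFraction = 0.5) {
    if (!length(components))
        stop("consensusLabel: empty components")
    if (is.na(dklBits) || dklBits <= 0)
        stop("consensusLabel: dklBits must be positive")
    thr <- majorityFraction * dklBits
    eps <- 1e-12
    any_positive <- FALSE
    for (depth in 4:1) {
        pref <- .labelPrefixAt(names(components), depth)
        ok <- !is.na(pref)
        if (!any(ok)) next
        agg <- tapply(components[ok], pref[ok], sum)
        if (any(agg > 0)) any_positive <- TRUE
        qual <- names(agg)[agg >= thr - eps]
        if (length(qual) == 1L)
            return(parseEC(qual))
        if (length(qual) > 1L)
            return("NO_CONSENSUS")
    }
    out <- "NO_CONSENSUS"
    if (!any_positive)
        attr(out, "diagnostic") <- "all aggregates nonpositive"
    out
}

#' Annotate one model from its retained hits
#'
#' The full per-model decision: \code{NO_HITS} when the retained hit list is
#' empty; \code{NOT_ENZYME} when the hits carry no EC labels or the
#' Monte-Carlo p-value exceeds \code{alpha}; otherwise \code{ENZYME}, with
#' the consensus label (full EC, prefix, or \code{"NO_CONSENSUS"}).
#'
#' @param hits list of [AlignmentHit-class], already filtered by average
#'   TM-score.
#' @param library a [StructLibrary-class].
#' @param q background [ECDistribution-class]; computed from the library
#'   when \code{NULL}.
#' @param config a [PipelineConfig-class]; supplies \code{alpha},
#'   \code{majorityFraction}, \code{nDraws} and \code{seed}.
#' @param modelId model identifier; defaults to the hits' model ID.
#' @return an [EnzymeCall-class].
#' @export
annotateModel <- function(hits, library, q = NULL,
                          config = pipelineConfig(), modelId = NULL) {
    stopifnot(is(library, "StructLibrary"), is(config, "PipelineConfig"))
    if (is.null(modelId))
        modelId <- if (length(hits)) hits[[1]]@modelId else NA_character_
    if (!length(hits))
        return(new("EnzymeCall", modelId = modelId, dklBits = NA_real_,
                   components = numeric(), zScore = NA_real_,
                   pValue = NA_real_, verdict = "NO_HITS",
                   assignedLabel = NA_character_, nHits = 0L,
                   seed = config@seed))
    sample <- gatherECSample(hits, library)
    if (sampleSize(sample) == 0L)
        return(new("EnzymeCall", modelId = modelId, dklBits = NA_real_,
                   components = numeric(), zScore = NA_real_,
                   pValue = NA_real_, verdict = "NOT_ENZYME",
                   assignedLabel = NA_character_,
                   nHits = length(hits), seed = config@seed))
    if (is.null(q))
        q <- backgroundDistribution(library)
    re <- relativeEntropy(sampleDistribution(sample), q)
    sig <- significance(sample, q, nDraws = config@nDraws,
                        seed = config@seed)
    if (sig$p_value > config@alpha)
        return(new("EnzymeCall", modelId = modelId, dklBits = re$dkl_bits,
                   components = re$components, zScore = sig$z_score,
                   pValue = sig$p_value, verdict = "NOT_ENZYME",
                   assignedLabel = NA_character_,
                   nHits = length(hits), seed = config@seed))
    lbl <- if (re$dkl_bits > 0)
        consensusLabel(re$components, re$dkl_bits, config@majorityFraction)
    else "NO_CONSENSUS"
    lbl_str <- if (is(lbl, "ECNumber")) formatEC(lbl) else "NO_CONSENSUS"
    new("EnzymeCall", modelId = modelId, dklBits = re$dkl_bits,
        components = re$components, zScore = sig$z_score,
        pValue = sig$p_value, verdict = "ENZYME",
        assignedLabel = lbl_str, nHits = length(hits), seed = config@seed)
}

setMethod("show", "EnzymeCall", function(object) {
    cat(sprintf("EnzymeCall %s: %s", object@modelId, object@verdict))
    if (object@verdict == "ENZYME")
        cat(sprintf(" [%s]", object@assignedLabel))
    if (!is.na(object@dklBits))
        cat(sprintf("  D_KL = %.3f bits, z = %.2f, p = %.3g",
                    object@dklBits, object@zScore, object@pValue))
    cat(sprintf("  (%d hit(s), seed %d)\n", object@nHits, object@seed))
})
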