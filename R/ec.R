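## EC label parsing, formatting and prefix algebra.
##
## EC labels arrive in several dialects: full four-level numbers
## ("1.14.14.82"), explicit prefixes ("1.14.14.*"), and provisional records
## where UniProt writes unassigned levels as "-" ("1.14.14.-") or "n"-tagged
## serials ("1.14.14.n3", a preliminary serial number). All depth-reducing
## markers fold into their prefix bucket so that prefix aggregation over hit
## sets is well defined.

#' Parse an EC string
#'
#' Accepts a dot-separated EC label with one to four components. Trailing
#' \code{"*"}, \code{"-"} or \code{"n<digits>"} components are treated as
#' unspecified and lower the depth. Input is whitespace-stripped and
#' case-insensitive.
#'
#' @param text a single EC string, e.g. \code{"1.14.14.82"} or
#'   \code{"1.14.14.*"}.
#' @return an [ECNumber-class].
#' @examples
#' parseEC("1.14.14.82")
#' ecDepth(parseEC("1.14.14.*"))   # 3
#' @export
parseEC <- function(text) {
    if (length(text) != 1L || !is.character(text) || is.na(text))
        stop("parseEC: 'text' must be a single EC string")
    raw <- tolower(gsub("\\s+", "", text))
    if (raw == "")
        stop("parseEC: empty EC string")
    parts <- strsplit(raw, ".", fixed = TRUE)[[1]]
    if (length(parts) == 0L || length(parts) > 4L)
        stop(sprintf("parseEC: '%s' has %d components (1-4 allowed)",
                     text, length(parts)))
    lv <- rep(NA_integer_, 4L)
    seen_unspec <- FALSE
    for (i in seq_along(parts)) {
        p <- parts[i]
        if (p %in% c("*", "-") || grepl("^n[0-9]*$", p)) {
            seen_unspec <- TRUE
        } else if (grepl("^[0-9]+$", p)) {
            if (seen_unspec)
                stop(sprintf(
                    "parseEC: '%s' has specified component '%s' after an unspecified one",
                    text, p))
            v <- suppressWarnings(as.integer(p))
            if (is.na(v) || v < 1L)
                stop(sprintf("parseEC: component '%s' in '%s' is not a positive integer",
                             p, text))
            lv[i] <- v
        } else {
            stop(sprintf("parseEC: non-numeric component '%s' in '%s'", p, text))
        }
    }
    new("ECNumber", levels = lv)
}

#' Depth of an EC label
#'
#' @param ec an [ECNumber-class].
#' @return integer count (1-4) of specified leading levels.
#' @export
ecDepth <- function(ec) {
    stopifnot(is(ec, "ECNumber"))
    sum(!is.na(ec@levels))
}

#' Format an EC label
#'
#' Full labels render as \code{"a.b.c.d"}; prefixes render with a single
#' trailing \code{".*"} (e.g. \code{"1.14.14.*"}), regardless of how the
#' unspecified levels were written in the source record.
#'
#' @param ec an [ECNumber-class].
#' @return a single character string.
#' @export
formatEC <- function(ec) {
    stopifnot(is(ec, "ECNumber"))
    d <- ecDepth(ec)
    spec <- paste(ec@levels[seq_len(d)], collapse = ".")
    if (d == 4L) spec else paste0(spec, ".*")
}

#' Truncate an EC label to a shallower depth
#'
#' @param ec an [ECNumber-class].
#' @param depth target depth, 1-4; must not exceed \code{ecDepth(ec)}.
#' @return an [ECNumber-class] of the requested depth.
#' @examples
#' formatEC(ecPrefix(parseEC("1.14.14.82"), 2))  # "1.14.*"
#' @export
ecPrefix <- function(ec, depth) {
    stopifnot(is(ec, "ECNumber"))
    if (length(depth) != 1L || is.na(depth) || depth < 1L || depth > 4L)
        stop("ecPrefix: 'depth' must be an integer in 1..4")
    depth <- as.integer(depth)
    if (depth > ecDepth(ec))
        stop(sprintf("ecPrefix: requested depth %d exceeds label depth %d (%s)",
                     depth, ecDepth(ec), formatEC(ec)))
    lv <- rep(NA_integer_, 4L)
    lv[seq_len(depth)] <- ec@levels[seq_len(depth)]
    new("ECNumber", levels = lv)
}

#' Test whether one EC label is a (non-strict) prefix of another
#'
#' @param a,b [ECNumber-class] objects.
#' @return \code{TRUE} iff \code{a}'s depth does not exceed \code{b}'s and
#'   the specified leading levels agree.
#' @examples
#' isPrefixOf(parseEC("1.14.*"), parseEC("1.14.14.82"))  # TRUE
#' @export
isPrefixOf <- function(a, b) {
    stopifnot(is(a, "ECNumber"), is(b, "ECNumber"))
    da <- ecDepth(a)
    if (da > ecDepth(b))
        return(FALSE)
    identical(a@levels[seq_len(da)], b@levels[seq_len(da)])
}

setMethod("show", "ECNumber", function(object) {
    cat("ECNumber:", formatEC(object),
        sprintf("(depth %d)\n", ecDepth(object)))
})

## internal: prefix string of a formatted label at a given depth, or NA when
## the label is shallower than `depth`
.labelPrefixAt <- function(labels, depth) {
    vapply(labels, function(s) {
        ec <- parseEC(s)
        if (ecDepth(ec) < depth) NA_character_
        else formatEC(ecPrefix(ec, depth))
    }, character(1), USE.NAMES = FALSE)
}
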