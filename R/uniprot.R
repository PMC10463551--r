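## UniProtKB flat-file ingestion.
##
## Only what the annotation layer needs is extracted: EC labels from DE
## "EC=" clauses, residue-level ACT_SITE / BINDING features (with /ligand
## qualifiers) from the FT block, and the canonical sequence from the SQ
## section. All other line types and FT categories are ignored.

#' Parse one UniProtKB flat-file entry
#'
#' Extracts EC labels (DE \code{EC=} clauses), ACT_SITE/BINDING residue
#' features and the canonical sequence from a single complete entry
#' (\code{ID ... //}). Range features (\code{a..b}) expand to one record per
#' position; \code{/ligand} qualifiers attach to the preceding BINDING
#' feature. Feature positions are in UniProt sequence numbering; the
#' recorded \code{residue_type} is read off the canonical sequence.
#'
#' @param x path to a flat file, or a character vector of its lines (a
#'   single string with embedded newlines is also accepted).
#' @return a list with elements \code{ec_labels} (list of
#'   [ECNumber-class]), \code{features} (data.frame with columns
#'   \code{category}, \code{position}, \code{residue_type},
#'   \code{ligand_label}) and \code{sequence} (character).
#' @examples
#' entry <- c("ID   TEST_ENTRY  Reviewed;  5 AA.",
#'            "DE            EC=4.3.3.6;",
#'            "FT   ACT_SITE        2",
#'            "SQ   SEQUENCE   5 AA;  1 MW;  X CRC64;",
#'            "     MKTAY", "//")
#' parseUniprotFlatfile(entry)$sequence
#' @export
parseUniprotFlatfile <- function(x) {
    lines <- .asLines(x)
    if (!length(lines))
        stop("parseUniprotFlatfile: empty input")
    term <- which(trimws(lines) == "//")
    if (!length(term))
        stop(sprintf(
            "parseUniprotFlatfile: truncated entry, no '//' terminator in %d lines",
            length(lines)))
    lines <- lines[seq_len(term[1])]

    ec_labels <- list()
    de <- grep("^DE\\s", lines)
    for (i in de) {
        m <- regmatches(lines[i],
                        gregexpr("EC=([0-9][0-9A-Za-z.*-]*)", lines[i]))[[1]]
        for (clause in m) {
            lbl <- sub("^EC=", "", clause)
            lbl <- sub(";$", "", lbl)
            ec_labels[[length(ec_labels) + 1L]] <- parseEC(lbl)
        }
    }

    ## SQ section: sequence lines follow the SQ header until //
    seq_str <- ""
    sq <- grep("^SQ\\s", lines)
    if (length(sq)) {
        body <- lines[seq(sq[1] + 1L, term[1] - 1L)]
        body <- body[grepl("^\\s", body)]
        seq_str <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }

    features <- .parseFTBlock(lines, seq_str)
    list(ec_labels = ec_labels, features = features, sequence = seq_str)
}

.asLines <- function(x) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
        return(readLines(x, warn = FALSE))
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

.emptyFeatures <- function() {
    data.frame(category = character(), position = integer(),
               residue_type = character(), ligand_label = character(),
               stringsAsFactors = FALSE)
}

## FT block scanner. UniProt FT syntax: a feature opens with
## "FT   <CATEGORY>  <location>" and qualifiers continue on "FT      /key=..."
## lines. Only ACT_SITE and BINDING are retained.
.parseFTBlock <- function(lines, seq_str) {
    ft <- grep("^FT\\s", lines)
    cat_out <- character(); pos_out <- integer()
    lig_out <- character()
    cur_cat <- NA_character_; cur_pos <- integer(); cur_lig <- ""

    flush <- function() {
        if (!is.na(cur_cat) && length(cur_pos)) {
            cat_out <<- c(cat_out, rep(cur_cat, length(cur_pos)))
            pos_out <<- c(pos_out, cur_pos)
            lig_out <<- c(lig_out, rep(cur_lig, length(cur_pos)))
        }
        cur_cat <<- NA_character_; cur_pos <<- integer(); cur_lig <<- ""
    }

    for (i in ft) {
        body <- sub("^FT\\s+", "", lines[i])
        if (startsWith(body, "/")) {
            m <- regmatches(body, regexec("^/ligand=\"([^\"]*)\"", body))[[1]]
            if (length(m) == 2L && !is.na(cur_cat) && cur_cat == "BINDING")
                cur_lig <- m[2]
            next
        }
        toks <- strsplit(trimws(body), "\\s+")[[1]]
        if (length(toks) < 2L) next
        category <- toks[1]
        flush()
        if (!category %in% c("ACT_SITE", "BINDING"))
            next
        loc <- toks[2]
        rng <- regmatches(loc, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", loc))[[1]]
        if (!length(rng))
            stop(sprintf(
                "parseUniprotFlatfile: malformed FT position '%s' at line %d",
                loc, i))
        from <- as.integer(rng[2])
        to <- if (rng[4] == "") from else as.integer(rng[4])
        if (is.na(from) || is.na(to) || to < from)
            stop(sprintf(
                "parseUniprotFlatfile: malformed FT position '%s' at line %d",
                loc, i))
        cur_cat <- category
        cur_pos <- seq.int(from, to)
    }
    flush()

    if (!length(cat_out))
        return(.emptyFeatures())

    keep <- rep(TRUE, length(pos_out))
    rtype <- rep(NA_character_, length(pos_out))
    if (nzchar(seq_str)) {
        n <- nchar(seq_str)
        out_of_range <- pos_out > n
        if (any(out_of_range)) {
            warning(sprintf(
                "parseUniprotFlatfile: dropping %d feature position(s) beyond sequence length %d",
                sum(out_of_range), n))
            keep <- !out_of_range
        }
        if (any(keep))
            rtype[keep] <- substring(seq_str, pos_out[keep],
                                     pos_out[keep])
    }
    data.frame(category = cat_out[keep], position = pos_out[keep],
               residue_type = rtype[keep],
               ligand_label = lig_out[keep],
               stringsAsFactors = FALSE)
}
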