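## Shared coordinate-file IO helpers (PDB / mmCIF via bio3d).

## Read the CA trace of a single-chain coordinate file. Falls back to the
## first atom of each residue when a residue has no CA record. Returns the
## one-letter sequence, an n x 3 coordinate matrix, residue numbers and the
## per-residue B-factor.
.readChainCA <- function(file) {
    if (!file.exists(file))
        stop(sprintf("coordinate file not found: %s", file))
    ext <- tolower(tools::file_ext(file))
    pdb <- if (ext %in% c("cif", "mmcif"))
        bio3d::read.cif(file, verbose = FALSE)
    else
        bio3d::read.pdb(file, verbose = FALSE)
    at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
    if (!nrow(at))
        stop(sprintf("no ATOM records in %s", file))
    ## one representative atom per residue: CA preferred
    key <- paste(at$chain, at$resno, at$insert, sep = "|")
    ord <- !duplicated(key)
    rep_idx <- integer(0)
    for (k in unique(key)) {
        rows <- which(key == k)
        ca <- rows[at$elety[rows] == "CA"]
        rep_idx <- c(rep_idx, if (length(ca)) ca[1] else rows[1])
    }
    at <- at[rep_idx, , drop = FALSE]
    seq1 <- suppressWarnings(bio3d::aa321(at$resid))
    seq1[is.na(seq1)] <- "X"
    list(sequence = paste(seq1, collapse = ""),
         coords = cbind(at$x, at$y, at$z),
         resno = at$resno,
         bfactor = at$b)
}

## Write a CA-only trace as a PDB file (fixtures and annotated re-emission).
.writeCATrace <- function(file, coords, sequence = NULL, bfactor = NULL,
                          chain = "A") {
    n <- nrow(coords)
    if (is.null(sequence)) sequence <- strrep("A", n)
    if (is.null(bfactor)) bfactor <- rep(0, n)
    aa3 <- bio3d::aa123(strsplit(sequence, "")[[1]])
    aa3[is.na(aa3)] <- "UNK"
    bio3d::write.pdb(pdb = NULL, file = file,
                     xyz = as.numeric(t(coords)),
                     type = rep("ATOM", n),
                     resno = seq_len(n), resid = aa3,
                     eleno = seq_len(n), elety = rep("CA", n),
                     chain = rep(chain, n),
                     o = rep(1, n), b = round(bfactor, 2))
    invisible(file)
}
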