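#' Read sequences from FASTA or FASTQ (plain or gzip)
#'
#' The format is auto-detected from the first record character (`>` FASTA,
#' `@` FASTQ); gzip is handled transparently. FASTQ qualities are retained on
#' the returned object (a `QualityScaledDNAStringSet`) but unused downstream.
#' Sequence identifiers are the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path input file.
#' @return a `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (FASTQ)
#'   in file order.
#' @export
readSequences <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    con <- gzfile(path, "r")
    first <- readLines(con, n = 1)
    close(con)
    if (length(first) == 0) stop("empty input: ", path)
    if (startsWith(first, ">")) {
        out <- Biostrings::readDNAStringSet(path, format = "fasta")
    } else if (startsWith(first, "@")) {
        # (suppressed warning: Biostrings drops metadata columns internally)
        out <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    } else {
        stop("cannot detect FASTA/FASTQ format of ", path)
    }
    names(out) <- sub("\\s.*$", "", names(out))
    if (anyDuplicated(names(out)))
        stop("duplicate sequence identifier in ", path)
    out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a `DNAStringSet` (or named character vector). For FASTQ output
#'   without attached qualities, a constant Q20 quality string is written.
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @param format `"fasta"` or `"fastq"`; default guessed from the file name
#'   (`.fq`/`.fastq` mean FASTQ).
#' @return invisibly, `path`.
#' @export
writeSequences <- function(x, path, format = NULL) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    if (is.null(format))
        format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
    compress <- grepl("\\.gz$", path)
    if (format == "fastq") {
        # written by hand: ultra-long records overflow the fixed line buffer
        # of the Biostrings FASTQ writer
        ids <- names(x)
        if (is.null(ids)) ids <- paste0("seq", seq_along(x))
        sq <- as.character(x)
        qual <- if (is(x, "QualityScaledXStringSet"))
            as.character(Biostrings::quality(x))
        else vapply(nchar(sq), function(w) strrep("5", w), "")
        lines <- as.vector(rbind(paste0("@", ids), sq, "+", qual))
        con <- if (compress) gzfile(path, "w") else file(path, "w")
        writeLines(lines, con)
        close(con)
    } else {
        Biostrings::writeXStringSet(x, path, format = format,
                                    compress = compress)
    }
    invisible(path)
}

#' Write overlap records as PAF
#'
#' Writes the 12 mandatory tab-separated PAF columns (0-based half-open
#' coordinates, `+`/`-` strand), one newline-terminated line per record, in
#' deterministic (`qname`, `tname`, `qstart`) order. Parameter-echo header
#' lines (`#`-prefixed) are written only on request, since strict PAF
#' consumers may reject comments.
#'
#' @param records PAF data.frame ([detectOverlaps()]).
#' @param path output file.
#' @param params optional [IvhParams-class]; when supplied together with
#'   `header = TRUE`, the full parameter set is echoed as `#` lines.
#' @param header write `#` comment headers (default `FALSE`).
#' @return invisibly, `path`.
#' @export
writePAF <- function(records, path, params = NULL, header = FALSE) {
    cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
              "tstart", "tend", "residue_matches", "block_len", "mapq")
    missing <- setdiff(cols, names(records))
    if (length(missing))
        stop("records lack PAF column(s): ", paste(missing, collapse = ", "))
    con <- file(path, "w")
    on.exit(close(con))
    if (header) {
        writeLines(sprintf("#ivhash %s", as.character(utils::packageVersion("ivhash"))), con)
        if (!is.null(params)) writeLines(paste0("#", paramHeader(params)), con)
    }
    rec <- records[order(records$qname, records$tname, records$qstart),
                   cols, drop = FALSE]
    if (nrow(rec) > 0)
        write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    invisible(path)
}

#' Read a PAF file
#'
#' Parses the 12 mandatory columns; `#` comment lines are skipped, extra
#' columns ignored.
#'
#' @param path PAF file.
#' @return data.frame with the 12 mandatory columns.
#' @export
readPAF <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
              "tstart", "tend", "residue_matches", "block_len", "mapq")
    if (length(lines) == 0) {
        out <- .emptyPaf()[, cols]
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(fields, length, 0L) < 12))
        stop("malformed PAF: fewer than 12 columns")
    m <- do.call(rbind, lapply(fields, `[`, 1:12))
    out <- data.frame(qname = m[, 1], qlen = as.integer(m[, 2]),
                      qstart = as.integer(m[, 3]), qend = as.integer(m[, 4]),
                      strand = m[, 5], tname = m[, 6],
                      tlen = as.integer(m[, 7]), tstart = as.integer(m[, 8]),
                      tend = as.integer(m[, 9]),
                      residue_matches = as.integer(m[, 10]),
                      block_len = as.integer(m[, 11]),
                      mapq = as.integer(m[, 12]), stringsAsFactors = FALSE)
    out
}

#' Write simulator ground truth as BED / TSV
#'
#' `writeLayoutBed()` writes the monomer/insertion layout as BED (0-based
#' half-open; name column `unit<u>.<type>[.<monomer>]`), `writeVariantsBed()`
#' the haplotype-B variant positions, and `writeOriginsTsv()` the per-read
#' truth table.
#'
#' @param sim a [HORSimulation-class] object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeLayoutBed <- function(sim, path) {
    lay <- horLayout(sim)
    name <- ifelse(lay$type == "monomer",
                   sprintf("unit%d.monomer%d%s", lay$unit, lay$monomer,
                           ifelse(lay$truncated, ".trunc", "")),
                   sprintf("unit%d.insertion", lay$unit))
    bed <- data.frame("hapA", lay$start, lay$end, name)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeLayoutBed
#' @export
writeVariantsBed <- function(sim, path) {
    v <- horVariants(sim)
    bed <- data.frame("hapB", v$pos, v$pos + 1L,
                      sprintf("%s>%s", v$ref, v$alt))
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeLayoutBed
#' @export
writeOriginsTsv <- function(sim, path) {
    write.table(horOrigins(sim), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}
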