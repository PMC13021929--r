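#' @importFrom utils read.delim write.table
NULL

# Internal: sorted-by-(chrom, start) check for GRanges, strand ignored.
.isPositionSorted <- function(gr) {
    if (length(gr) < 2L) return(TRUE)
    o <- order(as.character(seqnames(gr)), start(gr))
    identical(o, seq_along(gr))
}

.checkSorted <- function(gr, what) {
    if (!.isPositionSorted(gr))
        stop("'", what, "' must be sorted by (chrom, start)")
    invisible(TRUE)
}

# Internal: sort by (chrom lexicographic, start), the deterministic output
# order used for all interval outputs.
.positionSort <- function(gr) {
    gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

#' Read a BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open on disk; the returned
#' \link[GenomicRanges]{GRanges} uses the usual 1-based closed convention.
#' Columns beyond the third are optional (name, score, strand).
#'
#' @param path file path.
#' @return \link[GenomicRanges]{GRanges} with metadata columns \code{name}
#'   and \code{score} when present.
#' @seealso \code{\link{writeBed6}}
#' @export
readBed6 <- function(path) {
    raw <- readLines(path)
    raw <- raw[nzchar(raw)]
    if (!length(raw))
        return(GRanges())
    fields <- strsplit(raw, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
             ": fewer than 3 columns")
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
    if (length(bad))
        stop("malformed BED line ", bad[1L], " in ", path,
             ": bad coordinates")
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[`, "", 4L)
    if (all(nf >= 5L))
        mcols(gr)$score <- suppressWarnings(
            as.numeric(vapply(fields, `[`, "", 5L)))
    if (all(nf >= 6L)) {
        st <- vapply(fields, `[`, "", 6L)
        st[!st %in% c("+", "-")] <- "*"
        strand(gr) <- st
    }
    gr
}

#' Write a GRanges as BED6
#'
#' Coordinates are converted back to the 0-based half-open BED convention.
#' Rows are emitted in deterministic (chrom lexicographic, start) order.
#'
#' @param gr a \link[GenomicRanges]{GRanges}; metadata columns \code{name}
#'   and \code{score} are used when present.
#' @param path output path.
#' @param name,score optional overrides (vectors recycled to
#'   \code{length(gr)}).
#' @return the path, invisibly.
#' @export
writeBed6 <- function(gr, path, name = NULL, score = NULL) {
    if (is.null(name))
        name <- if ("name" %in% names(mcols(gr))) mcols(gr)$name else "."
    if (is.null(score))
        score <- if ("score" %in% names(mcols(gr))) mcols(gr)$score else 0
    df <- data.frame(
        chrom = as.character(seqnames(gr)),
        start = start(gr) - 1L,
        end = end(gr),
        name = rep_len(as.character(name), length(gr)),
        score = rep_len(score, length(gr)),
        strand = sub("\\*", ".", as.character(strand(gr))),
        stringsAsFactors = FALSE
    )
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene models from a BED-like TSV
#'
#' Expects at least 6 tab-separated columns (chrom, start, end, gene_id,
#' score, strand); every gene must be stranded.
#'
#' @param path file path.
#' @return \link[GenomicRanges]{GRanges} with a \code{gene_id} metadata
#'   column.
#' @export
readGeneModels <- function(path) {
    gr <- readBed6(path)
    if (!"name" %in% names(mcols(gr)))
        stop("gene models need a 4th (gene_id) column")
    if (any(as.character(strand(gr)) == "*"))
        stop("gene models must be stranded (+/-)")
    names(mcols(gr))[names(mcols(gr)) == "name"] <- "gene_id"
    mcols(gr)$score <- NULL
    gr
}

#' Read a differential-expression results table
#'
#' A TSV with header columns \code{gene_id}, \code{log2FoldChange} (log2
#' fold change upon silencing of the driver) and \code{padj}.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readDETable <- function(path) {
    de <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "log2FoldChange", "padj")
    miss <- setdiff(need, names(de))
    if (length(miss))
        stop("DE table lacks columns: ", paste(miss, collapse = ", "))
    de
}

#' Read a sample manifest
#'
#' TSV with header columns \code{sample_id}, \code{condition},
#' \code{replicate}, \code{path}; one row per sequencing library.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readManifest <- function(path) {
    m <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "replicate", "path")
    miss <- setdiff(need, names(m))
    if (length(miss))
        stop("manifest lacks columns: ", paste(miss, collapse = ", "))
    m
}

# Internal: write a data.frame as TSV with full numeric precision so that
# write/read round-trips are exact.
.writeTsv <- function(df, path) {
    num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
    out <- df
    for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path, width = 70L)
    invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path (wrapped or unwrapped, multi-record).
#' @return a named \link[Biostrings]{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
    Biostrings::readDNAStringSet(path)
}
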