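#' @importFrom stats quantile
NULL

#' Classify knockdown-defined target genes
#'
#' Turns a differential-expression table from a driver-silencing
#' experiment into induced / repressed / neither target calls. Because
#' the fold changes describe expression upon silencing, genes induced by
#' the driver go \emph{down} when it is silenced: induced means
#' \code{log2FoldChange <= -lfcCut}, repressed means
#' \code{log2FoldChange >= +lfcCut}, each additionally requiring
#' \code{padj < padjCut}. The fold-change boundary is included, the
#' adjusted-p boundary excluded.
#'
#' @param de data.frame with columns \code{gene_id},
#'   \code{log2FoldChange} (silenced vs control) and \code{padj}.
#' @param lfcCut absolute log2 fold-change cutoff (default 1).
#' @param padjCut adjusted-p cutoff (default 0.01).
#' @return data.frame with columns \code{gene_id} and
#'   \code{target_class} (\code{"induced"}, \code{"repressed"},
#'   \code{"neither"}); one row per input gene.
#' @examples
#' de <- data.frame(gene_id = c("A", "B", "C"),
#'                  log2FoldChange = c(-2, 1, 0.2),
#'                  padj = c(0.001, 0.009, 0.5))
#' classifyTargets(de)
#' @export
classifyTargets <- function(de, lfcCut = 1, padjCut = 0.01) {
    need <- c("gene_id", "log2FoldChange", "padj")
    miss <- setdiff(need, names(de))
    if (length(miss))
        stop("DE table lacks columns: ", paste(miss, collapse = ", "))
    dup <- de$gene_id[duplicated(de$gene_id)]
    if (length(dup))
        stop("duplicate gene_id in DE table: ",
             paste(unique(dup), collapse = ", "))
    bad <- is.na(de$log2FoldChange) | is.na(de$padj) |
        de$padj < 0 | de$padj > 1
    if (any(bad))
        stop("invalid DE record(s) (missing fields or padj outside ",
             "[0, 1]) for gene_id: ",
             paste(de$gene_id[bad], collapse = ", "))
    cls <- rep("neither", nrow(de))
    sig <- de$padj < padjCut
    cls[sig & de$log2FoldChange <= -lfcCut] <- "induced"
    cls[sig & de$log2FoldChange >= lfcCut] <- "repressed"
    data.frame(gene_id = de$gene_id, target_class = cls,
               stringsAsFactors = FALSE)
}

# TSS base position (1-based) of stranded gene models.
.tssPos <- function(genes) {
    ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

# TES base position (1-based).
.tesPos <- function(genes) {
    ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
}

#' Annotate sites to their nearest gene
#'
#' Each site is assigned to the same-chromosome gene whose TSS is nearest
#' to the site midpoint (distance magnitude only). Equidistant ties
#' resolve to the lexicographically smaller \code{gene_id}. Sites on a
#' chromosome with no gene get \code{NA} with a warning.
#'
#' @param sites \link[GenomicRanges]{GRanges}.
#' @param genes stranded \link[GenomicRanges]{GRanges} with a
#'   \code{gene_id} metadata column.
#' @return character vector of gene ids, parallel to \code{sites}.
#' @export
annotateNearestGene <- function(sites, genes) {
    if (!length(genes)) stop("empty gene set")
    if (!"gene_id" %in% names(mcols(genes)))
        stop("genes need a 'gene_id' metadata column")
    tss <- .tssPos(genes)
    gchrom <- as.character(seqnames(genes))
    gid <- mcols(genes)$gene_id
    mid <- (start(sites) + end(sites)) / 2
    schrom <- as.character(seqnames(sites))
    out <- rep(NA_character_, length(sites))
    for (chr in unique(schrom)) {
        gi <- which(gchrom == chr)
        si <- which(schrom == chr)
        if (!length(gi)) next
        # order candidate genes by gene_id so which.min takes the
        # lexicographically smaller id on distance ties
        gi <- gi[order(gid[gi])]
        for (i in si) {
            d <- abs(mid[i] - tss[gi])
            out[i] <- gid[gi[which.min(d)]]
        }
    }
    if (anyNA(out))
        warning(sum(is.na(out)),
                " site(s) on chromosome(s) without genes left unannotated")
    out
}

#' Partition genes into length tertiles
#'
#' Boundaries are the empirical 1/3 and 2/3 quantiles (type-7 linear
#' interpolation) of gene length. Genes shorter than the first boundary
#' are \code{"small"}, genes at or above the second are \code{"large"},
#' the rest \code{"medium"}. Boundaries are reported so they can be
#' compared against published, annotation-dependent values; they are
#' always recomputed, never assumed.
#'
#' @param genes \link[GenomicRanges]{GRanges} with a \code{gene_id}
#'   metadata column (at least 3 genes).
#' @return list with \code{classes} (character vector named by gene_id)
#'   and \code{boundaries} (numeric length-2, bp).
#' @export
partitionByLengthTertiles <- function(genes) {
    if (length(genes) < 3L) stop("need at least 3 genes")
    len <- width(genes)
    b <- unname(quantile(len, c(1, 2) / 3, type = 7))
    cls <- ifelse(len < b[1L], "small",
                  ifelse(len >= b[2L], "large", "medium"))
    names(cls) <- mcols(genes)$gene_id
    list(classes = cls, boundaries = b)
}
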