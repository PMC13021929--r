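#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Per-sample interval container for sequencing evidence
#'
#' Common container for one sample's aligned intervals together with its
#' experimental annotation. Two concrete subclasses exist:
#' \linkS4class{FragmentSet} for (unstranded) tagmentation fragments and
#' \linkS4class{ReadSet} for stranded nascent-transcription read 5' ends.
#'
#' @slot sampleId single sample identifier.
#' @slot condition experimental condition label (e.g. \code{"control"},
#'   \code{"LCE"}, \code{"HCE"}).
#' @slot replicate biological replicate number.
#' @slot intervals a \link[GenomicRanges]{GRanges} of the retained intervals.
#' @slot librarySize number of retained intervals; the CPM denominator.
#'
#' @name SampleIntervalSet-class
#' @aliases SampleIntervalSet
#' @exportClass SampleIntervalSet
setClass("SampleIntervalSet",
    representation(
        sampleId = "character",
        condition = "character",
        replicate = "integer",
        intervals = "GRanges",
        librarySize = "integer"
    )
)

setValidity("SampleIntervalSet", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        msg <- c(msg, "'sampleId' must be a single non-empty string")
    if (length(object@condition) != 1L)
        msg <- c(msg, "'condition' must be a single string")
    if (length(object@replicate) != 1L || is.na(object@replicate))
        msg <- c(msg, "'replicate' must be a single integer")
    if (length(object@librarySize) != 1L ||
        object@librarySize != length(object@intervals))
        msg <- c(msg, "'librarySize' must equal the number of intervals")
    if (length(msg)) msg else TRUE
})

#' CUT&Tag fragment set
#'
#' Fragments are unstranded intervals, one per sequenced tagmentation
#' fragment, already filtered to lengths below the maximum (see
#' \code{\link{loadFragments}}).
#'
#' @name FragmentSet-class
#' @aliases FragmentSet-class
#' @exportClass FragmentSet
setClass("FragmentSet", contains = "SampleIntervalSet")

#' Stranded read 5'-end set
#'
#' Nascent-transcription reads are reduced to their 5'-end positions:
#' every interval has width 1 and an explicit \code{+}/\code{-} strand.
#'
#' @name ReadSet-class
#' @aliases ReadSet-class
#' @exportClass ReadSet
setClass("ReadSet", contains = "SampleIntervalSet")

setValidity("ReadSet", function(object) {
    gr <- object@intervals
    msg <- character()
    if (length(gr) && !all(width(gr) == 1L))
        msg <- c(msg, "read 5'-end intervals must all have width 1")
    if (length(gr) && !all(as.character(strand(gr)) %in% c("+", "-")))
        msg <- c(msg, "every read must carry a '+' or '-' strand")
    if (length(msg)) msg else TRUE
})

#' @describeIn SampleIntervalSet-class constructor for fragment sets.
#' @param sampleId,condition,replicate sample annotation.
#' @param intervals a \link[GenomicRanges]{GRanges}.
#' @export
FragmentSet <- function(intervals, sampleId, condition = "control",
                        replicate = 1L) {
    new("FragmentSet", sampleId = as.character(sampleId),
        condition = as.character(condition),
        replicate = as.integer(replicate),
        intervals = intervals, librarySize = length(intervals))
}

#' @describeIn SampleIntervalSet-class constructor for stranded read sets.
#' @export
ReadSet <- function(intervals, sampleId, condition = "control",
                    replicate = 1L) {
    new("ReadSet", sampleId = as.character(sampleId),
        condition = as.character(condition),
        replicate = as.integer(replicate),
        intervals = intervals, librarySize = length(intervals))
}

#' @rdname SampleIntervalSet-class
#' @param object,x a \code{SampleIntervalSet}.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname SampleIntervalSet-class
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))
#' @rdname SampleIntervalSet-class
#' @export
setGeneric("sampleReplicate", function(x) standardGeneric("sampleReplicate"))
#' @rdname SampleIntervalSet-class
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @rdname SampleIntervalSet-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname SampleIntervalSet-class
#' @exportMethod sampleId
setMethod("sampleId", "SampleIntervalSet", function(x) x@sampleId)
#' @rdname SampleIntervalSet-class
#' @exportMethod sampleCondition
setMethod("sampleCondition", "SampleIntervalSet", function(x) x@condition)
#' @rdname SampleIntervalSet-class
#' @exportMethod sampleReplicate
setMethod("sampleReplicate", "SampleIntervalSet", function(x) x@replicate)
#' @rdname SampleIntervalSet-class
#' @exportMethod intervals
setMethod("intervals", "SampleIntervalSet", function(x) x@intervals)
#' @rdname SampleIntervalSet-class
#' @exportMethod librarySize
setMethod("librarySize", "SampleIntervalSet", function(x) x@librarySize)

setMethod("show", "SampleIntervalSet", function(object) {
    cat(class(object), " '", object@sampleId, "' (",
        object@condition, ", replicate ", object@replicate, "): ",
        object@librarySize, " intervals\n", sep = "")
})

#' Simulation configuration
#'
#' All tunables of the synthetic-data generator, with defaults chosen to
#' emulate a compact version of a two-condition drug-exposure study:
#' two small chromosomes, genes spanning three length strata, planted GGAA
#' response elements of every class, three biological replicates per
#' condition, and negative-binomial replicate noise.
#'
#' @slot seed integer seed governing every random draw.
#' @slot nChroms,chromLen genome shape (bp).
#' @slot nGenes number of genes, placed without overlap, lengths drawn in
#'   thirds from small/medium/large strata (bp ranges in
#'   \code{geneLenSmall}, \code{geneLenMedium}, \code{geneLenLarge}).
#' @slot geneLenSmall,geneLenMedium,geneLenLarge length ranges (bp).
#' @slot nMicrosat,nIsolated,nTandemPerClass planted element counts;
#'   tandem sites are planted for each cofactor class.
#' @slot microsatUnits range of (GGAA) unit counts for planted repeats.
#' @slot nInduced,nRepressed planted fusion-target genes per direction.
#' @slot nReplicates biological replicates per condition.
#' @slot groDepth expected nascent reads per replicate.
#' @slot fragDepth expected fragments per element per replicate at
#'   occupancy 1.
#' @slot bgFragsPerRep expected background fragments per replicate.
#' @slot dispersion negative-binomial dispersion phi (variance
#'   \eqn{\mu + \phi \mu^2}).
#' @slot fragLenMean,fragLenSd,maxFragmentLen fragment-length model (bp).
#' @slot pauseBoost multiplier on expected signal in the first 300 bp
#'   downstream of the TSS (promoter-proximal enrichment).
#' @slot kappaControl baseline attrition per kb (exponential decay of
#'   elongating signal with distance from the TSS).
#' @slot deltaKappaHCE added attrition per kb under the HCE-like preset.
#' @slot lfcInduced log2 initiation shift applied to induced targets under
#'   the LCE-like preset (repressed targets get the opposite sign).
#' @slot nullFraction fraction of elements with no occupancy shift.
#' @slot occShiftRange |delta log2 occupancy| range for shifted elements.
#' @slot antisense logical; plant treated-only antisense bursts at a
#'   subset of elements.
#' @slot pseudocount CPM pseudocount used downstream.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateGenome}}
#' @name SimConfig-class
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        seed = "integer",
        nChroms = "integer", chromLen = "integer",
        nGenes = "integer",
        geneLenSmall = "integer", geneLenMedium = "integer",
        geneLenLarge = "integer",
        nMicrosat = "integer", nIsolated = "integer",
        nTandemPerClass = "integer",
        microsatUnits = "integer",
        nInduced = "integer", nRepressed = "integer",
        nReplicates = "integer",
        groDepth = "numeric", fragDepth = "numeric",
        bgFragsPerRep = "numeric",
        dispersion = "numeric",
        fragLenMean = "numeric", fragLenSd = "numeric",
        maxFragmentLen = "integer",
        pauseBoost = "numeric",
        kappaControl = "numeric", deltaKappaHCE = "numeric",
        lfcInduced = "numeric",
        nullFraction = "numeric", occShiftRange = "numeric",
        antisense = "logical",
        pseudocount = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    pos <- c(nChroms = object@nChroms, chromLen = object@chromLen,
             nGenes = object@nGenes, nReplicates = object@nReplicates,
             groDepth = object@groDepth, fragDepth = object@fragDepth)
    bad <- names(pos)[pos <= 0]
    if (length(bad))
        msg <- c(msg, paste0("must be positive: ",
                             paste(bad, collapse = ", ")))
    if (object@dispersion < 0) msg <- c(msg, "'dispersion' must be >= 0")
    if (object@nullFraction < 0 || object@nullFraction > 1)
        msg <- c(msg, "'nullFraction' must lie in [0, 1]")
    if (length(object@occShiftRange) != 2L ||
        any(object@occShiftRange < 0) ||
        diff(object@occShiftRange) < 0)
        msg <- c(msg, "'occShiftRange' must be an increasing pair >= 0")
    if (length(object@microsatUnits) != 2L ||
        object@microsatUnits[1L] < 2L ||
        diff(object@microsatUnits) < 0)
        msg <- c(msg, "'microsatUnits' must be an increasing pair >= 2")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults define the study conditions the generator emulates; see
#' \linkS4class{SimConfig} for the meaning of each field.
#'
#' @param seed integer seed.
#' @param ... named overrides for any \linkS4class{SimConfig} slot.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(seed = 1L, ...) {
    args <- list(...)
    defaults <- list(
        seed = as.integer(seed),
        nChroms = 2L, chromLen = 800000L,
        nGenes = 48L,
        geneLenSmall = c(2000L, 6000L),
        geneLenMedium = c(8000L, 16000L),
        geneLenLarge = c(20000L, 35000L),
        nMicrosat = 100L, nIsolated = 100L, nTandemPerClass = 25L,
        microsatUnits = c(4L, 12L),
        nInduced = 10L, nRepressed = 10L,
        nReplicates = 3L,
        groDepth = 150000, fragDepth = 200, bgFragsPerRep = 40000,
        dispersion = 0.05,
        fragLenMean = 200, fragLenSd = 50, maxFragmentLen = 1000L,
        pauseBoost = 4,
        kappaControl = 0.02, deltaKappaHCE = 0.1,
        lfcInduced = -2,
        nullFraction = 1 / 3, occShiftRange = c(0.5, 2.5),
        antisense = FALSE,
        pseudocount = 1
    )
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
        stop("unknown SimConfig fields: ", paste(unknown, collapse = ", "))
    defaults[names(args)] <- args
    int_slots <- c("seed", "nChroms", "chromLen", "nGenes",
                   "geneLenSmall", "geneLenMedium", "geneLenLarge",
                   "nMicrosat", "nIsolated", "nTandemPerClass",
                   "microsatUnits", "nInduced", "nRepressed",
                   "nReplicates", "maxFragmentLen")
    for (s in int_slots) defaults[[s]] <- as.integer(defaults[[s]])
    do.call(new, c(list("SimConfig"), defaults))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: ", object@nChroms, " x ", object@chromLen,
        " bp genome, ", object@nGenes, " genes, ",
        object@nMicrosat + object@nIsolated + 4L * object@nTandemPerClass,
        " planted elements, ", object@nReplicates,
        " replicates/condition, seed ", object@seed, "\n", sep = "")
})

#' Planted simulation ground truth
#'
#' Per-gene initiation (\code{lambda}) and attrition (\code{kappa})
#' parameters, per-element occupancies, target labels, and the
#' configuration that produced them. Carried alongside simulated reads and
#' fragments so parameter-recovery tests can compare estimates against the
#' planted values.
#'
#' @slot genes \link[GenomicRanges]{GRanges} of gene models with metadata
#'   columns \code{gene_id}, \code{lambda_control}, \code{lambda_treated},
#'   \code{kappa_control}, \code{kappa_treated}, \code{target_class}.
#' @slot elements \link[GenomicRanges]{GRanges} of planted response
#'   elements with metadata columns \code{element_id},
#'   \code{element_class}, \code{unit_count}, \code{occupancy_control},
#'   \code{occupancy_treated}, \code{delta_log2_occupancy},
#'   \code{antisense}.
#' @slot preset which perturbation preset the treated condition encodes
#'   (\code{"lce"}, \code{"hce"} or \code{"null"}).
#' @slot config the generating \linkS4class{SimConfig}.
#'
#' @name SimTruth-class
#' @aliases SimTruth
#' @exportClass SimTruth
setClass("SimTruth",
    representation(
        genes = "GRanges",
        elements = "GRanges",
        preset = "character",
        config = "SimConfig"
    )
)

setValidity("SimTruth", function(object) {
    msg <- character()
    need_g <- c("gene_id", "lambda_control", "lambda_treated",
                "kappa_control", "kappa_treated", "target_class")
    if (!all(need_g %in% names(mcols(object@genes))))
        msg <- c(msg, "gene truth lacks required metadata columns")
    need_e <- c("element_id", "element_class", "occupancy_control",
                "occupancy_treated")
    if (!all(need_e %in% names(mcols(object@elements))))
        msg <- c(msg, "element truth lacks required metadata columns")
    lam <- mcols(object@genes)[["lambda_control"]]
    if (length(lam) && any(lam <= 0))
        msg <- c(msg, "initiation rates lambda must be positive")
    kap <- c(mcols(object@genes)[["kappa_control"]],
             mcols(object@genes)[["kappa_treated"]])
    if (length(kap) && any(kap < 0))
        msg <- c(msg, "attrition rates kappa must be non-negative")
    if (!object@preset %in% c("lce", "hce", "null"))
        msg <- c(msg, "'preset' must be one of lce/hce/null")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
    tc <- table(mcols(object@genes)$target_class)
    cat("SimTruth (", object@preset, " preset): ",
        length(object@genes), " genes (",
        paste(names(tc), as.integer(tc), sep = "=", collapse = ", "),
        "), ", length(object@elements), " elements\n", sep = "")
})

#' @rdname SimTruth-class
#' @param x a \code{SimTruth}.
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))
#' @rdname SimTruth-class
#' @export
setGeneric("truthElements", function(x) standardGeneric("truthElements"))
#' @rdname SimTruth-class
#' @exportMethod truthGenes
setMethod("truthGenes", "SimTruth", function(x) x@genes)
#' @rdname SimTruth-class
#' @exportMethod truthElements
setMethod("truthElements", "SimTruth", function(x) x@elements)
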