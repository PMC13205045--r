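#' Accessors for mitoPanels classes
#'
#' Small accessor generics: `mitoReference()` returns the
#' [ReferenceMito-class] behind an object, `refSequence()` its
#' [Biostrings::DNAString]; `cellBarcodes()` the cell identifiers;
#' `alleleCounts()` / `baseQualities()` one per-base sparse matrix of a
#' [MitoAlleleCounts-class]; `siteCoverage()` the per-position total read
#' depth (sum over the four bases); `presence()` the sparse logical
#' variant-by-cell matrix of a [MitoSNPMatrix-class]; `variantIDs()` its
#' variant names and `snpCounts()` its per-cell SNP counts;
#' `cellAnnotations()` the annotation table; `panelTriples()`,
#' `panelCoverage()` and `anchoring()` the components of an
#' [SNPPanelSet-class]; `traceMatches()` the per-cell matches of a
#' [TraceResult-class].
#'
#' @param x An object of the documented class.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mitoReference", function(x) standardGeneric("mitoReference"))
#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' @rdname accessors
#' @export
setGeneric("cellBarcodes", function(x) standardGeneric("cellBarcodes"))
#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x, base) standardGeneric("alleleCounts"))
#' @rdname accessors
#' @export
setGeneric("baseQualities", function(x, base) standardGeneric("baseQualities"))
#' @rdname accessors
#' @export
setGeneric("siteCoverage", function(x) standardGeneric("siteCoverage"))
#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
#' @rdname accessors
#' @export
setGeneric("variantIDs", function(x) standardGeneric("variantIDs"))
#' @rdname accessors
#' @export
setGeneric("snpCounts", function(x) standardGeneric("snpCounts"))
#' @rdname accessors
#' @export
setGeneric("cellAnnotations", function(x) standardGeneric("cellAnnotations"))
#' @rdname accessors
#' @export
setGeneric("panelTriples", function(x) standardGeneric("panelTriples"))
#' @rdname accessors
#' @export
setGeneric("panelCoverage", function(x) standardGeneric("panelCoverage"))
#' @rdname accessors
#' @export
setGeneric("anchoring", function(x) standardGeneric("anchoring"))
#' @rdname accessors
#' @export
setGeneric("traceMatches", function(x) standardGeneric("traceMatches"))

#' @rdname accessors
setMethod("mitoReference", "MitoAlleleCounts",
    function(x) metadata(x)$reference)
#' @rdname accessors
setMethod("mitoReference", "MitoSimTruth", function(x) x@reference)
#' @rdname accessors
setMethod("refSequence", "ReferenceMito", function(x) x@sequence)
#' @rdname accessors
setMethod("cellBarcodes", "MitoAlleleCounts", function(x) colnames(x))
#' @rdname accessors
setMethod("cellBarcodes", "MitoSNPMatrix", function(x) colnames(x))
#' @rdname accessors
setMethod("alleleCounts", "MitoAlleleCounts", function(x, base) {
    base <- match.arg(base, .BASES)
    assay(x, base)
})
#' @rdname accessors
setMethod("baseQualities", "MitoAlleleCounts", function(x, base) {
    base <- match.arg(base, .BASES)
    qn <- paste0("qual_", base)
    if (!qn %in% names(assays(x))) NULL else assay(x, qn)
})
#' @rdname accessors
setMethod("siteCoverage", "MitoAlleleCounts", function(x) {
    Reduce(`+`, lapply(.BASES, function(b) assay(x, b)))
})
#' @rdname accessors
setMethod("presence", "MitoSNPMatrix", function(x) assay(x, "presence"))
#' @rdname accessors
setMethod("presence", "ClusteredSNPMatrix", function(x) x@presence)
#' @rdname accessors
setMethod("variantIDs", "MitoSNPMatrix", function(x) rownames(x))
#' @rdname accessors
setMethod("snpCounts", "MitoSNPMatrix", function(x) {
    setNames(colSums(assay(x, "presence")), colnames(x))
})
#' @rdname accessors
setMethod("cellAnnotations", "MitoSNPMatrix",
    function(x) as.data.frame(colData(x)))
#' @rdname accessors
setMethod("panelTriples", "SNPPanelSet", function(x) x@triples)
#' @rdname accessors
setMethod("panelCoverage", "SNPPanelSet", function(x) x@coverage)
#' @rdname accessors
setMethod("anchoring", "SNPPanelSet", function(x) x@anchoring)
#' @rdname accessors
setMethod("traceMatches", "TraceResult", function(x) x@matches)

setMethod("show", "ReferenceMito", function(object) {
    cat("ReferenceMito ", object@name, ": ",
        length(object@sequence), " bp\n", sep = "")
})

setMethod("show", "SNPPanelSet", function(object) {
    cat("SNPPanelSet for cell type '", object@targetClass, "' (sample ",
        paste(object@sampleID, collapse = "+"), ")\n", sep = "")
    cat("  ", nrow(object@triples), " three-SNP combination(s); ",
        length(object@anchoring), "/", object@nTarget,
        " target cells anchored (coverage ",
        sprintf("%.3f", object@coverage), ")\n", sep = "")
    if (object@shortfall)
        cat("  note: requested coverage not reachable with the valid triples\n")
})

setMethod("show", "TraceResult", function(object) {
    cat("TraceResult: panel '", object@panel@targetClass,
        "' traced into sample '", object@querySample, "'\n", sep = "")
    cat("  ", length(object@matches), " of ", length(object@queryBarcodes),
        " query cells matched\n", sep = "")
    tc <- object@tagCounts
    cat("  reporter tag among matches: ", tc[1L], " tagged, ", tc[2L],
        " untagged, ", tc[3L], " unknown\n", sep = "")
})

setMethod("show", "MitoSimTruth", function(object) {
    cat("MitoSimTruth: ", length(object@parent), " cells over ",
        max(object@meta$generation), " generations; ",
        nrow(object@origin), " variants (",
        sum(object@origin$origin_node == "germline"), " germline)\n",
        sep = "")
})

setMethod("show", "ClusteredSNPMatrix", function(object) {
    cat("ClusteredSNPMatrix: ", ncol(object@presence), " cells x ",
        nrow(object@presence), " variants",
        if (is.null(object@linkage)) " (ordered)" else " (clustered)",
        "\n", sep = "")
})
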