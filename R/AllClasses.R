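#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Mitochondrial reference sequence
#'
#' Holds the mitochondrial reference genome that anchors the 1-based
#' coordinate system used throughout the package. Variant identifiers of the
#' form `"13080_G>A"` are interpreted against this sequence.
#'
#' @slot name Sequence name (for example `"chrM"`).
#' @slot sequence A [Biostrings::DNAString] over the alphabet `{A,C,G,T,N}`.
#'
#' @seealso [referenceMito()], [readMitoReference()]
#' @exportClass ReferenceMito
setClass("ReferenceMito",
    representation(name = "character", sequence = "DNAString"))

setValidity("ReferenceMito", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@sequence) < 1L)
        msg <- c(msg, "reference sequence must be non-empty")
    bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                   c("A", "C", "G", "T", "N"))
    if (length(bad))
        msg <- c(msg, paste0("reference contains characters outside {A,C,G,T,N}: ",
                             paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a mitochondrial reference
#'
#' @param name Sequence name.
#' @param sequence Character string or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}`.
#' @return A [ReferenceMito-class] object.
#' @examples
#' ref <- referenceMito("chrM", "ACGTACGTNN")
#' length(refSequence(ref))
#' @export
referenceMito <- function(name, sequence) {
    if (!is(sequence, "DNAString"))
        sequence <- DNAString(toupper(as.character(sequence)))
    new("ReferenceMito", name = name, sequence = sequence)
}

#' Read a mitochondrial reference from FASTA
#'
#' Reads the first record of a FASTA file as the mitochondrial reference.
#'
#' @param path Path to a FASTA file.
#' @return A [ReferenceMito-class] object.
#' @export
readMitoReference <- function(path) {
    if (!file.exists(path))
        stop("reference FASTA not found: ", path, call. = FALSE)
    ss <- readDNAStringSet(path)
    if (length(ss) < 1L)
        stop("reference FASTA is empty: ", path, call. = FALSE)
    referenceMito(sub("\\s.*$", "", names(ss)[1L]), ss[[1L]])
}

#' Per-cell mitochondrial allele counts
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one sparse assay of read counts per base (`"A"`, `"C"`, `"G"`,
#' `"T"`; rows are 1-based mitochondrial positions, columns are cell
#' barcodes) and, optionally, matching mean Phred base-quality assays
#' (`"qual_A"`, ...). Quality entries exist only where the corresponding
#' count is positive. The [ReferenceMito-class] lives in
#' `metadata(x)$reference` and fixes the number of rows.
#'
#' This mirrors the per-base count matrices emitted by mgatk/maegatk-style
#' single-cell mitochondrial genotyping, with strands collapsed.
#'
#' @seealso [MitoAlleleCounts()], [readAlleleCounts()], [callVariants()]
#' @exportClass MitoAlleleCounts
setClass("MitoAlleleCounts", contains = "SummarizedExperiment")

.BASES <- c("A", "C", "G", "T")

setValidity("MitoAlleleCounts", function(object) {
    msg <- character()
    an <- names(assays(object))
    if (!all(.BASES %in% an))
        return("assays must include counts for bases A, C, G and T")
    ref <- metadata(object)$reference
    if (is.null(ref) || !is(ref, "ReferenceMito"))
        return("metadata(x)$reference must be a ReferenceMito")
    if (nrow(object) != length(ref@sequence))
        msg <- c(msg, "number of rows must equal the reference length")
    bc <- colnames(object)
    if (ncol(object) > 0L) {
        if (is.null(bc) || anyNA(bc) || any(!nzchar(bc)))
            msg <- c(msg, "barcodes (colnames) must be non-empty strings")
        else if (anyDuplicated(bc))
            msg <- c(msg, "barcodes must be unique")
    }
    for (b in .BASES) {
        cnt <- assay(object, b)
        if (any(cnt@x < 0))
            msg <- c(msg, paste0("negative counts in base ", b))
        qn <- paste0("qual_", b)
        if (qn %in% an) {
            q <- drop0(assay(object, qn))
            if (any(q@x < 0) || any(q@x > 60))
                msg <- c(msg, paste0("qualities for base ", b,
                                     " outside [0, 60]"))
            # quality support must be a subset of the count support
            qs <- summary(q)
            cs <- summary(drop0(cnt))
            if (!all(paste(qs$i, qs$j) %in% paste(cs$i, cs$j)))
                msg <- c(msg, paste0("quality entries without counts for base ", b))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Binary SNP presence/absence matrix
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"presence"` is a sparse logical matrix of variants
#' (rows) by cells (columns): `presence[v, b]` is `TRUE` when the SNP call
#' for variant `v` was retained in cell `b`. `rowData` carries
#' `variant_id`, `position`, `ref` and `alt`; `colData` carries the joined
#' cell annotations (`sample_id`, `cell_type`, `cluster_id`,
#' `reporter_tag`).
#'
#' @seealso [buildSNPMatrix()], [filterCellsMinSNPs()], [discoverPanels()]
#' @exportClass MitoSNPMatrix
setClass("MitoSNPMatrix", contains = "SummarizedExperiment")

setValidity("MitoSNPMatrix", function(object) {
    msg <- character()
    if (!"presence" %in% names(assays(object)))
        return("assay 'presence' is required")
    p <- assay(object, "presence")
    if (!is(p, "lMatrix"))
        msg <- c(msg, "'presence' must be a sparse logical matrix")
    rd <- rowData(object)
    need <- c("variant_id", "position", "ref", "alt")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste0("rowData must contain ",
                             paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(rd$variant_id))
            msg <- c(msg, "variant_id values must be unique")
        if (any(rd$ref == rd$alt))
            msg <- c(msg, "ref and alt bases must differ")
    }
    cd <- colData(object)
    needc <- c("sample_id", "cell_type", "cluster_id", "reporter_tag")
    if (!all(needc %in% colnames(cd)))
        msg <- c(msg, paste0("colData must contain ",
                             paste(needc, collapse = ", ")))
    if (ncol(object) && anyDuplicated(colnames(object)))
        msg <- c(msg, "cell barcodes must be unique")
    if (length(msg)) msg else TRUE
})

#' A panel of unique three-SNP combinations for one cell class
#'
#' The result of panel discovery for one target cell type: an ordered list
#' of triples (each a primary/secondary/tertiary SNP combination carried by
#' at least `min_support` target cells and by no cell in the comparison
#' scope), the anchoring of each covered target cell to the first selected
#' triple it carries, and the fraction of target cells covered. When the
#' union of all valid triples cannot reach the requested coverage, the
#' best achievable panel is returned with `shortfall = TRUE`.
#'
#' @slot targetClass Target cell-type label.
#' @slot sampleID Sample identifier(s) the panel was discovered in.
#' @slot triples `data.frame` with columns `primary`, `secondary`,
#'   `tertiary`, `target_support`.
#' @slot anchoring Named integer vector mapping each anchored barcode to
#'   the index of its anchoring triple.
#' @slot coverage Fraction of target cells anchored.
#' @slot shortfall `TRUE` when the requested coverage was unreachable.
#' @slot nTarget Number of target cells at discovery time.
#' @slot params Discovery parameter snapshot.
#'
#' @seealso [greedySelectPanels()], [computeCoverage()], [verifyUniqueness()]
#' @exportClass SNPPanelSet
setClass("SNPPanelSet",
    representation(targetClass = "character", sampleID = "character",
                   triples = "data.frame", anchoring = "integer",
                   coverage = "numeric", shortfall = "logical",
                   nTarget = "integer", params = "list"))

setValidity("SNPPanelSet", function(object) {
    msg <- character()
    tr <- object@triples
    need <- c("primary", "secondary", "tertiary", "target_support")
    if (!all(need %in% colnames(tr)))
        msg <- c(msg, paste0("triples must have columns ",
                             paste(need, collapse = ", ")))
    else if (nrow(tr)) {
        same <- tr$primary == tr$secondary | tr$primary == tr$tertiary |
            tr$secondary == tr$tertiary
        if (any(same))
            msg <- c(msg, "the three SNPs of a triple must be distinct")
    }
    a <- object@anchoring
    if (length(a)) {
        if (is.null(names(a)) || anyDuplicated(names(a)))
            msg <- c(msg, "anchoring must be named by unique barcodes")
        if (any(a < 1L) || any(a > nrow(tr)))
            msg <- c(msg, "anchoring indices must point into 'triples'")
    }
    if (length(object@coverage) != 1L || is.na(object@coverage) ||
        object@coverage < 0 || object@coverage > 1)
        msg <- c(msg, "coverage must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Result of tracing a panel into a query sample
#'
#' Cells of a query sample that carry all three SNPs of at least one triple
#' of a reference [SNPPanelSet-class], with the matching triple indices per
#' cell and tabulations against cluster labels and the reporter tag.
#'
#' @slot panel The reference panel.
#' @slot querySample Query sample identifier.
#' @slot queryBarcodes All query cell barcodes that were searched.
#' @slot matches Named list: matched barcode -> integer indices of the
#'   triples it carries.
#' @slot clusterCounts Named integer vector of matched cells per cluster
#'   (including `"unassigned"` for unannotated matches).
#' @slot tagCounts Integer vector `c(tagged, untagged, unknown)` splitting
#'   matched cells by reporter tag.
#'
#' @seealso [tracePanels()], [clusterDistribution()], [tagConcordance()]
#' @exportClass TraceResult
setClass("TraceResult",
    representation(panel = "SNPPanelSet", querySample = "character",
                   queryBarcodes = "character", matches = "list",
                   clusterCounts = "integer", tagCounts = "integer"))

setValidity("TraceResult", function(object) {
    msg <- character()
    if (length(object@matches)) {
        if (is.null(names(object@matches)))
            msg <- c(msg, "matches must be named by barcode")
        else if (!all(names(object@matches) %in% object@queryBarcodes))
            msg <- c(msg, "matched barcodes must be query barcodes")
    }
    if (length(object@tagCounts) != 3L)
        msg <- c(msg, "tagCounts must have length 3 (tagged, untagged, unknown)")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated mtDNA lineage
#'
#' The full record of a forward simulation of mitochondrial heteroplasmy
#' drift along a binary cell-division tree: the tree itself (a parent map
#' over node identifiers that encode the root-to-node path, so ancestry is
#' a prefix test), each node's true per-variant heteroplasmy, the clade /
#' cell-type / reporter annotation of every node, and where each variant
#' arose.
#'
#' @slot parent Named character vector: node id -> parent id (`NA` for the
#'   founder).
#' @slot het List, one element per node: named numeric vector of true
#'   heteroplasmies (variants at h = 0 are omitted; 0 and 1 are absorbing).
#' @slot meta `DataFrame` with one row per node: `generation`, `clade`,
#'   `cell_type`, `reporter_tag`.
#' @slot origin `DataFrame` per variant: `variant_id`, `position`, `ref`,
#'   `alt`, `origin_node` (`"germline"` for founder variants),
#'   `origin_generation`.
#' @slot reference The simulated [ReferenceMito-class].
#' @slot config The [simConfig()] used.
#'
#' @seealso [simulateLineage()], [sampleCells()], [simulateReadout()]
#' @exportClass MitoSimTruth
setClass("MitoSimTruth",
    representation(parent = "character", het = "list", meta = "DataFrame",
                   origin = "DataFrame", reference = "ReferenceMito",
                   config = "list"))

setValidity("MitoSimTruth", function(object) {
    msg <- character()
    nodes <- names(object@parent)
    if (is.null(nodes) || anyDuplicated(nodes))
        msg <- c(msg, "parent map must be named by unique node ids")
    if (!identical(nodes, names(object@het)))
        msg <- c(msg, "het must be named identically to the parent map")
    if (!identical(nodes, rownames(object@meta)))
        msg <- c(msg, "meta rownames must equal the node ids")
    if (length(msg)) msg else TRUE
})

#' A reordered (and optionally clustered) binary SNP matrix
#'
#' The presence matrix of a [MitoSNPMatrix-class] with rows (variants) and
#' columns (cells) permuted for display — either by the descending
#' shared-SNP sort or by hierarchical clustering — plus, when clustering
#' was used, the agglomerative merge tree.
#'
#' @slot presence Sparse logical matrix, variants by cells, reordered.
#' @slot linkage `NULL`, or a `data.frame` with columns `step`, `left`,
#'   `right`, `height`, `size` describing the merges over cells (negative
#'   `left`/`right` index leaves, positive index earlier steps, as in
#'   [stats::hclust()]).
#'
#' @seealso [sortDescending()], [hierarchicalCluster()], [exportHeatmap()]
#' @exportClass ClusteredSNPMatrix
setClass("ClusteredSNPMatrix",
    representation(presence = "lMatrix", linkage = "ANY"))

setValidity("ClusteredSNPMatrix", function(object) {
    lk <- object@linkage
    if (!is.null(lk) && !is.data.frame(lk))
        return("linkage must be NULL or a data.frame")
    TRUE
})
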