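## Per-cell SNP calling from allele counts, and the binary presence/absence
## matrix that all downstream panel logic operates on.

#' SNP calling thresholds
#'
#' Parameters governing which per-cell variant observations become binary
#' SNP calls. The two headline thresholds are strict inequalities: a
#' variant allele frequency of *more than* 1% of the reads at the site,
#' and a mean base quality of *more than* 30, so boundary values are
#' excluded. `min_site_coverage` and `min_alt_reads` guard against single
#' stray reads at shallow sites passing the frequency rule; set them to
#' `0`/`1` to disable.
#'
#' @param min_vaf Variant allele frequency threshold; a call requires
#'   `alt/coverage > min_vaf`. Default `0.01`.
#' @param min_quality Mean Phred base-quality threshold; a call requires
#'   `mean_quality > min_quality`. Default `30`.
#' @param min_site_coverage Minimum total read depth at the site.
#'   Default `10`.
#' @param min_alt_reads Minimum alt-supporting reads. Default `2`.
#' @return A `CallingParams` object (validated list).
#' @export
callingParams <- function(min_vaf = 0.01, min_quality = 30,
                          min_site_coverage = 10, min_alt_reads = 2) {
    p <- list(min_vaf = min_vaf, min_quality = min_quality,
              min_site_coverage = min_site_coverage,
              min_alt_reads = min_alt_reads)
    if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                       is.na(x) || x < 0, logical(1L))))
        stop("all calling thresholds must be single non-negative numbers",
             call. = FALSE)
    if (p$min_vaf >= 1)
        stop("min_vaf must be < 1", call. = FALSE)
    structure(p, class = "CallingParams")
}

#' Call SNPs per cell from allele counts
#'
#' Emits one binary SNP call per (cell, position, alt base) whose
#' observation passes every threshold in `params`: site coverage at least
#' `min_site_coverage`, at least `min_alt_reads` alt-supporting reads,
#' variant allele frequency strictly above `min_vaf`, and mean base
#' quality strictly above `min_quality`. Each alt base at a position is an
#' independent variant, named `"{pos}_{ref}>{alt}"`. Positions whose
#' reference base is `N` are skipped and counted in the `diagnostics`
#' attribute. When the input carries no quality assays the quality filter
#' is inapplicable and `mean_quality` is reported as `NA`.
#'
#' @param acs A [MitoAlleleCounts-class] object.
#' @param params A [callingParams()] object.
#' @return A `data.frame` of calls sorted by (barcode, position, alt)
#'   with columns `variant_id`, `barcode`, `position`, `ref`, `alt`,
#'   `alt_count`, `coverage`, `vaf`, `mean_quality`, and an attribute
#'   `diagnostics` (list with `n_ref_N_skipped`).
#' @seealso [buildSNPMatrix()]
#' @export
callVariants <- function(acs, params = callingParams()) {
    stopifnot(is(acs, "MitoAlleleCounts"), inherits(params, "CallingParams"))
    cov <- drop0(siteCoverage(acs))
    refchar <- strsplit(as.character(refSequence(mitoReference(acs))), "")[[1]]
    bc <- colnames(acs)
    out <- list()
    n_skipped <- 0L
    for (b in .BASES) {
        s <- summary(drop0(assay(acs, b)))
        s <- s[s$x > 0, , drop = FALSE]
        if (!nrow(s)) next
        rb <- refchar[s$i]
        isN <- rb == "N"
        n_skipped <- n_skipped + sum(isN)
        s <- s[!isN & rb != b, , drop = FALSE]
        rb <- refchar[s$i]
        if (!nrow(s)) next
        cv <- cov[cbind(s$i, s$j)]
        q <- baseQualities(acs, b)
        mq <- if (is.null(q)) rep(NA_real_, nrow(s)) else q[cbind(s$i, s$j)]
        vaf <- s$x / cv
        keep <- cv >= params$min_site_coverage &
            s$x >= params$min_alt_reads &
            vaf > params$min_vaf &
            (is.na(mq) | mq > params$min_quality)
        if (!any(keep)) next
        s <- s[keep, , drop = FALSE]
        out[[b]] <- data.frame(
            variant_id = paste0(s$i, "_", rb[keep], ">", b),
            barcode = bc[s$j], position = s$i, ref = rb[keep], alt = b,
            alt_count = s$x, coverage = cv[keep], vaf = vaf[keep],
            mean_quality = mq[keep], stringsAsFactors = FALSE)
    }
    calls <- if (length(out)) do.call(rbind, out) else
        data.frame(variant_id = character(), barcode = character(),
                   position = integer(), ref = character(),
                   alt = character(), alt_count = numeric(),
                   coverage = numeric(), vaf = numeric(),
                   mean_quality = numeric())
    calls <- calls[order(calls$barcode, calls$position, calls$alt), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    attr(calls, "diagnostics") <- list(n_ref_N_skipped = n_skipped)
    calls
}

#' Parse variant identifiers
#'
#' Splits identifiers of the form `"13080_G>A"` into position, reference
#' and alternate base.
#'
#' @param variant_id Character vector of identifiers.
#' @return A `data.frame` with columns `position`, `ref`, `alt`.
#' @export
parseVariantID <- function(variant_id) {
    m <- regmatches(variant_id,
                    regexec("^([0-9]+)_([ACGT])>([ACGT])$", variant_id))
    bad <- lengths(m) != 4L
    if (any(bad))
        stop("malformed variant_id: ", variant_id[bad][1L], call. = FALSE)
    data.frame(position = as.integer(vapply(m, `[`, "", 2L)),
               ref = vapply(m, `[`, "", 3L),
               alt = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
}

#' Build the binary SNP presence/absence matrix
#'
#' Collects per-cell SNP calls into a sparse logical variants-by-cells
#' matrix. The variant universe is the union of called variants, ordered
#' by (position, alt base); cells are ordered by barcode. Cells present in
#' the calls but missing from `annotations` are retained with empty
#' annotation fields (a warning is raised): panel discovery only needs the
#' target-class labels.
#'
#' @param calls A calls `data.frame` from [callVariants()].
#' @param annotations Optional annotation `data.frame`
#'   ([readCellAnnotations()]).
#' @param barcodes Optional character vector of cells to include as
#'   columns even when they carry no calls (the union with called
#'   barcodes is used).
#' @return A [MitoSNPMatrix-class] object.
#' @export
buildSNPMatrix <- function(calls, annotations = NULL, barcodes = NULL) {
    vu <- unique(calls[, c("variant_id", "position", "ref", "alt")])
    vu <- vu[order(vu$position, vu$alt), , drop = FALSE]
    bc <- sort(unique(c(calls$barcode, barcodes)))
    p <- sparseMatrix(i = match(calls$variant_id, vu$variant_id),
                      j = match(calls$barcode, bc),
                      x = TRUE, dims = c(nrow(vu), length(bc)),
                      dimnames = list(vu$variant_id, bc))
    cd <- DataFrame(sample_id = rep(NA_character_, length(bc)),
                    cell_type = rep(NA_character_, length(bc)),
                    cluster_id = rep(NA_character_, length(bc)),
                    reporter_tag = rep(NA, length(bc)),
                    row.names = bc)
    if (!is.null(annotations)) {
        idx <- match(bc, annotations$barcode)
        if (anyNA(idx) && length(bc))
            warning(sum(is.na(idx)), " cell(s) have no annotation; ",
                    "retained with empty annotation fields")
        for (col in c("sample_id", "cell_type", "cluster_id"))
            cd[[col]] <- as.character(annotations[[col]])[idx]
        cd[["reporter_tag"]] <- annotations[["reporter_tag"]][idx]
    }
    rd <- DataFrame(variant_id = vu$variant_id, position = vu$position,
                    ref = vu$ref, alt = vu$alt, row.names = vu$variant_id)
    se <- SummarizedExperiment(assays = list(presence = as(p, "lMatrix")),
                               rowData = rd, colData = cd)
    new("MitoSNPMatrix", se)
}

#' Filter cells by minimum SNP count
#'
#' Retains cells carrying at least `k` SNPs (inclusive: a cell with
#' exactly `k` survives). Variant columns that become empty are kept by
#' default so the variant universe is unchanged.
#'
#' @param m A [MitoSNPMatrix-class] object.
#' @param k Minimum number of SNPs per cell (default `5`).
#' @param drop_empty Drop variants left with no carrier cell.
#' @return The filtered [MitoSNPMatrix-class].
#' @export
filterCellsMinSNPs <- function(m, k = 5L, drop_empty = FALSE) {
    stopifnot(is(m, "MitoSNPMatrix"), k >= 0L)
    keep <- colSums(assay(m, "presence")) >= k
    out <- m[, keep]
    if (drop_empty)
        out <- out[rowSums(assay(out, "presence")) > 0, ]
    new("MitoSNPMatrix", out)
}

#' Per-variant carrier fraction within a cell set
#'
#' For each variant, the fraction of the given cells that carry it
#' (denominator is the size of the cell set).
#'
#' @param m A [MitoSNPMatrix-class] object.
#' @param cells Character vector of barcodes (subset of
#'   `cellBarcodes(m)`); defaults to all cells.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
variantPrevalence <- function(m, cells = cellBarcodes(m)) {
    stopifnot(is(m, "MitoSNPMatrix"))
    if (length(cells) == 0L)
        stop("'cells' must be a non-empty subset of the matrix barcodes",
             call. = FALSE)
    if (!all(cells %in% cellBarcodes(m)))
        stop("unknown barcode(s) in 'cells'", call. = FALSE)
    rowSums(assay(m, "presence")[, cells, drop = FALSE]) / length(cells)
}

#' Read and write SNP calls and binary matrices
#'
#' Calls are serialized as a TSV with the columns of [callVariants()]'s
#' output. A [MitoSNPMatrix-class] is serialized as a directory holding
#' `presence.mtx` (Matrix Market pattern triplets, variants x cells),
#' `variants.tsv`, `barcodes.tsv` and `annotations.tsv`.
#'
#' @param calls A calls `data.frame`.
#' @param path File (calls) or directory (matrix).
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
writeVariantCalls <- function(calls, path) {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeVariantCalls
#' @export
readVariantCalls <- function(path) {
    if (!file.exists(path))
        stop("calls file not found: ", path, call. = FALSE)
    read.delim(path, header = TRUE, sep = "\t",
               colClasses = c(variant_id = "character",
                              barcode = "character", ref = "character",
                              alt = "character"))
}

#' @rdname writeVariantCalls
#' @param m A [MitoSNPMatrix-class] object.
#' @export
writeSNPMatrix <- function(m, path) {
    stopifnot(is(m, "MitoSNPMatrix"))
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    writeMM(as(drop0(assay(m, "presence") * 1), "nMatrix"),
            file.path(path, "presence.mtx"))
    write.table(as.data.frame(rowData(m)), file.path(path, "variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
    ann <- cellAnnotations(m)
    ann <- cbind(barcode = colnames(m), ann)
    write.table(ann, file.path(path, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeVariantCalls
#' @export
readSNPMatrix <- function(path) {
    p <- readMM(file.path(path, "presence.mtx"))
    vu <- read.delim(file.path(path, "variants.tsv"), sep = "\t",
                     colClasses = c(variant_id = "character",
                                    ref = "character", alt = "character"))
    bc <- readLines(file.path(path, "barcodes.tsv"))
    ann <- read.delim(file.path(path, "annotations.tsv"), sep = "\t",
                      colClasses = "character", na.strings = "NA")
    p <- as(as(p, "CsparseMatrix"), "lMatrix")
    dimnames(p) <- list(vu$variant_id, bc)
    rd <- DataFrame(vu, row.names = vu$variant_id)
    cd <- DataFrame(sample_id = ann$sample_id, cell_type = ann$cell_type,
                    cluster_id = ann$cluster_id,
                    reporter_tag = as.logical(ann$reporter_tag),
                    row.names = bc)
    new("MitoSNPMatrix",
        SummarizedExperiment(assays = list(presence = p), rowData = rd,
                             colData = cd))
}
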