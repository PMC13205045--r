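## Readers and writers for per-cell mitochondrial allele-count data.
## On-disk layout mirrors mgatk/maegatk-style output: one Matrix Market
## coordinate file per base (positions x cells), a barcode list, and the
## reference FASTA. Strand-split inputs (A.fwd.mtx / A.rev.mtx) are accepted
## and collapsed on read; qualities are combined as count-weighted means.

.asSparse <- function(m) as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")

#' Construct a MitoAlleleCounts object
#'
#' @param counts Named list with elements `"A"`, `"C"`, `"G"`, `"T"`, each
#'   a matrix (coerced to sparse) of read counts with one row per
#'   reference position and one column per cell; column names are the cell
#'   barcodes.
#' @param reference A [ReferenceMito-class] (its length fixes the row
#'   dimension).
#' @param qualities Optional named list like `counts` holding mean Phred
#'   base qualities; entries are kept only where the matching count is
#'   positive.
#' @param annotations Optional annotation `data.frame` as returned by
#'   [readCellAnnotations()]; joined onto the cells by barcode.
#' @return A [MitoAlleleCounts-class] object.
#' @examples
#' ref <- referenceMito("chrM", strrep("ACGT", 25))
#' cnt <- Matrix::sparseMatrix(i = 10, j = 1, x = 5, dims = c(100, 2),
#'                             dimnames = list(NULL, c("cell1", "cell2")))
#' acs <- MitoAlleleCounts(list(A = cnt, C = cnt * 0, G = cnt * 0, T = cnt * 0),
#'                         reference = ref)
#' coverageProfile(acs, 1)
#' @export
MitoAlleleCounts <- function(counts, reference, qualities = NULL,
                             annotations = NULL) {
    stopifnot(is(reference, "ReferenceMito"))
    if (!all(.BASES %in% names(counts)))
        stop("'counts' must have elements A, C, G and T", call. = FALSE)
    counts <- lapply(counts[.BASES], .asSparse)
    bc <- colnames(counts[["A"]])
    L <- length(reference@sequence)
    for (b in .BASES) {
        if (nrow(counts[[b]]) != L)
            stop("count matrix for base ", b, " has ", nrow(counts[[b]]),
                 " rows but the reference has ", L, " positions",
                 call. = FALSE)
        colnames(counts[[b]]) <- bc
        rownames(counts[[b]]) <- NULL
    }
    assays <- counts
    if (!is.null(qualities)) {
        for (b in intersect(names(qualities), .BASES)) {
            q <- .asSparse(qualities[[b]])
            if (!identical(dim(q), dim(counts[[b]])))
                stop("quality matrix for base ", b,
                     " does not match the count dimensions", call. = FALSE)
            q <- drop0(q * (counts[[b]] > 0))  # keep only where counts exist
            dimnames(q) <- dimnames(counts[[b]])
            assays[[paste0("qual_", b)]] <- q
        }
    }
    cd <- DataFrame(row.names = bc)
    if (!is.null(annotations) && length(bc)) {
        idx <- match(bc, annotations$barcode)
        for (col in setdiff(colnames(annotations), "barcode"))
            cd[[col]] <- annotations[[col]][idx]
    }
    se <- SummarizedExperiment(assays = assays, colData = cd)
    metadata(se)$reference <- reference
    new("MitoAlleleCounts", se)
}

.readOneBase <- function(dir, base, suffix = "mtx") {
    flat <- file.path(dir, paste0(base, ".", suffix))
    fwd <- file.path(dir, paste0(base, ".fwd.", suffix))
    rev <- file.path(dir, paste0(base, ".rev.", suffix))
    if (file.exists(flat))
        return(list(.asSparse(readMM(flat))))
    if (file.exists(fwd) && file.exists(rev))
        return(list(.asSparse(readMM(fwd)), .asSparse(readMM(rev))))
    NULL
}

#' Read per-cell mitochondrial allele counts
#'
#' Two on-disk layouts are supported. `"mtx_dir"` is a directory of four
#' Matrix Market coordinate files `A.mtx`, `C.mtx`, `G.mtx`, `T.mtx`
#' (rows = 1-based mitochondrial positions, columns = cells), a
#' `barcodes.tsv` (one barcode per line), a reference FASTA
#' (`reference.fasta`, or any single `.fa`/`.fasta` file), and optional
#' quality files `A.qual.mtx`, ... . Strand-split inputs
#' (`A.fwd.mtx`/`A.rev.mtx`, with `A.fwd.qual.mtx`/`A.rev.qual.mtx`) are
#' summed on read, qualities combined as a count-weighted mean.
#' `"long_tsv"` is a single tab-separated file with header
#' `barcode, pos, ref, base, count, mean_qual`; one row per observed
#' (cell, position, base), rows with `base == ref` carrying the
#' reference-supporting reads.
#'
#' @param path Directory (`"mtx_dir"`) or file (`"long_tsv"`).
#' @param format `"mtx_dir"` or `"long_tsv"`.
#' @param reference For `"long_tsv"` only: a [ReferenceMito-class] or path
#'   to a FASTA. When omitted, a reference is inferred from the `ref`
#'   column (unobserved positions become `N`).
#' @return A [MitoAlleleCounts-class] object.
#' @seealso [writeAlleleCounts()]
#' @export
readAlleleCounts <- function(path, format = c("mtx_dir", "long_tsv"),
                             reference = NULL) {
    format <- match.arg(format)
    if (format == "mtx_dir") .readMtxDir(path) else .readLongTSV(path, reference)
}

.readMtxDir <- function(dir) {
    if (!dir.exists(dir))
        stop("input directory not found: ", dir, call. = FALSE)
    bcf <- file.path(dir, "barcodes.tsv")
    if (!file.exists(bcf))
        stop("missing file: ", bcf, call. = FALSE)
    barcodes <- readLines(bcf)
    fa <- file.path(dir, "reference.fasta")
    if (!file.exists(fa)) {
        cand <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
        if (length(cand) != 1L)
            stop("missing file: reference FASTA in ", dir, call. = FALSE)
        fa <- cand
    }
    reference <- readMitoReference(fa)
    L <- length(reference@sequence)
    counts <- list(); quals <- list()
    for (b in .BASES) {
        parts <- .readOneBase(dir, b, "mtx")
        if (is.null(parts))
            stop("missing file: ", file.path(dir, paste0(b, ".mtx")),
                 call. = FALSE)
        for (p in parts) {
            if (ncol(p) != length(barcodes))
                stop("dimension mismatch: ", b, " matrix has ", ncol(p),
                     " columns but barcodes.tsv lists ", length(barcodes),
                     " barcodes", call. = FALSE)
            if (nrow(p) != L)
                stop("position out of range: ", b, " matrix has ", nrow(p),
                     " rows but the reference spans positions 1-", L,
                     call. = FALSE)
        }
        cnt <- Reduce(`+`, parts)
        qparts <- .readOneBase(dir, b, "qual.mtx")
        if (!is.null(qparts)) {
            if (length(qparts) != length(parts))
                stop("quality files for base ", b,
                     " do not match the strand layout of the counts",
                     call. = FALSE)
            # count-weighted mean across strands
            num <- Reduce(`+`, Map(`*`, qparts, parts))
            cs <- summary(drop0(cnt))
            quals[[b]] <- sparseMatrix(i = cs$i, j = cs$j,
                                       x = num[cbind(cs$i, cs$j)] / cs$x,
                                       dims = dim(cnt))
        }
        colnames(cnt) <- barcodes
        counts[[b]] <- cnt
    }
    if (length(quals)) for (b in names(quals)) colnames(quals[[b]]) <- barcodes
    MitoAlleleCounts(counts, reference,
                     qualities = if (length(quals)) quals else NULL)
}

.readLongTSV <- function(path, reference = NULL) {
    if (!file.exists(path))
        stop("input file not found: ", path, call. = FALSE)
    d <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c(barcode = "character", ref = "character",
                                   base = "character"))
    need <- c("barcode", "pos", "ref", "base", "count", "mean_qual")
    if (!all(need %in% colnames(d)))
        stop("long TSV must have header columns ",
             paste(need, collapse = ", "), call. = FALSE)
    if (is.character(reference))
        reference <- readMitoReference(reference)
    if (is.null(reference)) {
        L <- if (nrow(d)) max(d$pos) else 1L
        seq <- rep("N", L)
        seq[d$pos] <- d$ref
        reference <- referenceMito("chrM", paste(seq, collapse = ""))
    }
    L <- length(reference@sequence)
    bad <- which(d$pos < 1L | d$pos > L)
    if (length(bad))
        stop("position out of range at line ", bad[1L] + 1L, ": pos=",
             d$pos[bad[1L]], " (reference spans 1-", L, ")", call. = FALSE)
    key <- paste(d$barcode, d$pos, d$base)
    if (anyDuplicated(key))
        stop("duplicate (barcode, pos, base) row at line ",
             which(duplicated(key))[1L] + 1L, call. = FALSE)
    barcodes <- sort(unique(d$barcode))
    j <- match(d$barcode, barcodes)
    counts <- list(); quals <- list()
    for (b in .BASES) {
        sel <- d$base == b
        counts[[b]] <- sparseMatrix(i = d$pos[sel], j = j[sel],
                                    x = as.numeric(d$count[sel]),
                                    dims = c(L, length(barcodes)),
                                    dimnames = list(NULL, barcodes))
        quals[[b]] <- sparseMatrix(i = d$pos[sel], j = j[sel],
                                   x = as.numeric(d$mean_qual[sel]),
                                   dims = c(L, length(barcodes)),
                                   dimnames = list(NULL, barcodes))
    }
    MitoAlleleCounts(counts, reference, qualities = quals)
}

#' Write per-cell mitochondrial allele counts
#'
#' Inverse of [readAlleleCounts()]. Output is canonical and byte-stable:
#' barcodes are written in sorted order and Matrix Market triplets in
#' column-major order, so writing the same object twice produces identical
#' files.
#'
#' @param acs A [MitoAlleleCounts-class] object.
#' @param path Output directory (`"mtx_dir"`) or file (`"long_tsv"`).
#' @param format `"mtx_dir"` or `"long_tsv"`.
#' @return `path`, invisibly.
#' @export
writeAlleleCounts <- function(acs, path, format = c("mtx_dir", "long_tsv")) {
    format <- match.arg(format)
    stopifnot(is(acs, "MitoAlleleCounts"))
    bc <- if (is.null(colnames(acs))) character() else colnames(acs)
    ord <- order(bc)
    if (format == "mtx_dir") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        ref <- mitoReference(acs)
        ss <- DNAStringSet(ref@sequence)
        names(ss) <- ref@name
        writeXStringSet(ss, file.path(path, "reference.fasta"), width = 70L)
        writeLines(bc[ord], file.path(path, "barcodes.tsv"))
        for (b in .BASES) {
            writeMM(drop0(assay(acs, b)[, ord, drop = FALSE]),
                    file.path(path, paste0(b, ".mtx")))
            q <- baseQualities(acs, b)
            if (!is.null(q))
                writeMM(drop0(q[, ord, drop = FALSE]),
                        file.path(path, paste0(b, ".qual.mtx")))
        }
        return(invisible(path))
    }
    ref <- as.character(refSequence(mitoReference(acs)))
    rows <- list()
    for (b in .BASES) {
        cnt <- drop0(assay(acs, b))
        s <- summary(cnt)
        if (!nrow(s)) next
        q <- baseQualities(acs, b)
        mq <- if (is.null(q)) rep(NA_real_, nrow(s)) else q[cbind(s$i, s$j)]
        rows[[b]] <- data.frame(barcode = colnames(acs)[s$j], pos = s$i,
                                ref = substring(ref, s$i, s$i), base = b,
                                count = s$x, mean_qual = mq,
                                stringsAsFactors = FALSE)
    }
    d <- if (length(rows)) do.call(rbind, rows) else
        data.frame(barcode = character(), pos = integer(), ref = character(),
                   base = character(), count = numeric(),
                   mean_qual = numeric())
    d <- d[order(d$barcode, d$pos, d$base), , drop = FALSE]
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read or write cell annotations
#'
#' Cell annotations are a tab-separated table with header columns
#' `barcode`, `sample_id`, `cell_type`, `cluster_id` and an optional
#' `reporter_tag` (values `0`/`1`/`true`/`false`/`NA`). One row per
#' (barcode, sample); duplicates are rejected. The reporter tag is the
#' boolean stand-in for an upstream lineage label such as a recombinase
#' excision reporter.
#'
#' @param path Path to the TSV file.
#' @return `readCellAnnotations()`: a `data.frame` with columns `barcode`,
#'   `sample_id`, `cell_type`, `cluster_id`, `reporter_tag` (logical,
#'   `NA` = unknown).
#' @export
readCellAnnotations <- function(path) {
    if (!file.exists(path))
        stop("annotation file not found: ", path, call. = FALSE)
    d <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    na.strings = character())
    need <- c("barcode", "sample_id", "cell_type", "cluster_id")
    if (!all(need %in% colnames(d)))
        stop("annotations must have header columns ",
             paste(need, collapse = ", "), call. = FALSE)
    key <- paste(d$barcode, d$sample_id)
    if (anyDuplicated(key))
        stop("duplicate (barcode, sample_id) pair: ",
             key[which(duplicated(key))[1L]], call. = FALSE)
    tag <- rep(NA, nrow(d))
    if ("reporter_tag" %in% colnames(d)) {
        v <- tolower(d$reporter_tag)
        ok <- v %in% c("0", "1", "true", "false", "na", "")
        if (!all(ok))
            stop("invalid reporter_tag value: ", d$reporter_tag[!ok][1L],
                 call. = FALSE)
        tag <- ifelse(v %in% c("1", "true"), TRUE,
                      ifelse(v %in% c("0", "false"), FALSE, NA))
    }
    data.frame(barcode = d$barcode, sample_id = d$sample_id,
               cell_type = d$cell_type, cluster_id = d$cluster_id,
               reporter_tag = tag, stringsAsFactors = FALSE)
}

#' @rdname readCellAnnotations
#' @param annotations A `data.frame` as returned by
#'   [readCellAnnotations()].
#' @export
writeCellAnnotations <- function(annotations, path) {
    d <- annotations
    key <- paste(d$barcode, d$sample_id)
    if (anyDuplicated(key))
        stop("duplicate (barcode, sample_id) pair: ",
             key[which(duplicated(key))[1L]], call. = FALSE)
    if (!"reporter_tag" %in% colnames(d)) d$reporter_tag <- NA
    d$reporter_tag <- ifelse(is.na(d$reporter_tag), "NA",
                             ifelse(d$reporter_tag, "1", "0"))
    d <- d[order(d$sample_id, d$barcode),
           c("barcode", "sample_id", "cell_type", "cluster_id",
             "reporter_tag"), drop = FALSE]
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Fraction of the mitochondrial genome covered per cell
#'
#' For each cell, the fraction of reference positions whose total read
#' depth (summed over the four bases) is at least `min_depth`. Useful for
#' comparing capture protocols: mitochondria-optimized scATAC reaches
#' near-complete coverage of the mitochondrial genome, 3'-end transcript
#' enrichment covers only gene bodies.
#'
#' @param acs A [MitoAlleleCounts-class] object.
#' @param min_depth Minimum read depth (>= 1) for a position to count as
#'   covered.
#' @return Named numeric vector, one fraction in `[0, 1]` per cell.
#' @export
coverageProfile <- function(acs, min_depth = 1L) {
    stopifnot(is(acs, "MitoAlleleCounts"), min_depth >= 1L)
    cv <- drop0(siteCoverage(acs))
    s <- summary(cv)
    hit <- s$j[s$x >= min_depth]
    n <- tabulate(hit, nbins = ncol(cv))
    setNames(n / nrow(cv), colnames(acs))
}
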