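## Ordering and clustering of binary single-cell SNP profiles for
## clonal-structure heatmaps.

.presenceOf <- function(m) {
    if (is(m, "MitoSNPMatrix")) drop0(assay(m, "presence") * 1) > 0
    else if (is(m, "ClusteredSNPMatrix")) m@presence
    else stop("expected a MitoSNPMatrix or ClusteredSNPMatrix", call. = FALSE)
}

.variantOrder <- function(p) {
    prev <- rowMeans(p)
    pos <- parseVariantID(rownames(p))$position
    order(-prev, pos)
}

#' Sort cells and variants in descending shared-SNP order
#'
#' Variants are ordered by descending carrier prevalence (ties by
#' ascending genomic position). Each cell's presence row is then read as a
#' binary word over the ordered variants and cells are sorted by that word
#' in descending order (ties by ascending barcode), so cells sharing the
#' most prevalent SNPs collect at the top-left of the heatmap. This
#' formalizes the multi-column descending spreadsheet sort commonly used
#' for single-cell SNP heatmaps.
#'
#' @param m A [MitoSNPMatrix-class] (or an already ordered
#'   [ClusteredSNPMatrix-class], on which the operation is idempotent).
#' @return A [ClusteredSNPMatrix-class] (no linkage).
#' @export
sortDescending <- function(m) {
    p <- .presenceOf(m)
    if (ncol(p) == 0L)
        stop("the matrix has no cells", call. = FALSE)
    po <- p[.variantOrder(p), , drop = FALSE]
    words <- vapply(seq_len(ncol(po)), function(j)
        paste(as.integer(po[, j]), collapse = ""), "")
    cord <- order(words, colnames(po), method = "radix",
                  decreasing = c(TRUE, FALSE))
    new("ClusteredSNPMatrix", presence = po[, cord, drop = FALSE],
        linkage = NULL)
}

#' Pairwise Jaccard distance between cell SNP profiles
#'
#' `d(x, y) = 1 - |x & y| / |x | y|` on the cells' SNP sets, with
#' `d = 0` for two cells that both carry no SNPs (by convention).
#'
#' @param m A [MitoSNPMatrix-class] or [ClusteredSNPMatrix-class].
#' @return A symmetric numeric matrix of distances, cells by cells.
#' @export
jaccardDistance <- function(m) {
    p <- .presenceOf(m) * 1
    inter <- as.matrix(crossprod(p))
    sizes <- colSums(p)
    uni <- outer(sizes, sizes, `+`) - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0  # two empty profiles are identical by convention
    diag(d) <- 0
    dimnames(d) <- list(colnames(p), colnames(p))
    d
}

.subtreeLeaves <- function(merge, node) {
    if (node < 0) return(-node)
    c(.subtreeLeaves(merge, merge[node, 1L]),
      .subtreeLeaves(merge, merge[node, 2L]))
}

#' Hierarchical clustering of cells by shared SNPs
#'
#' Agglomerative clustering ([stats::hclust()]) of cells under the
#' Jaccard distance on their SNP sets. The leaf order is a recursive
#' traversal of the merge tree visiting the denser subtree (higher mean
#' SNPs per cell) first, ties broken by the lexicographically smallest
#' barcode, so equally dense subtrees are laid out deterministically.
#' Variants are ordered by descending prevalence as in
#' [sortDescending()].
#'
#' @param m A [MitoSNPMatrix-class] with at least two cells.
#' @param distance Distance measure; `"jaccard"` is the only option.
#' @param linkage_method `"average"` (default) or `"complete"`.
#' @return A [ClusteredSNPMatrix-class] whose `linkage` slot records the
#'   merges (`step`, `left`, `right`, `height`, `size`; negative
#'   left/right values index cells in the reordered matrix, positive
#'   values index earlier steps).
#' @export
hierarchicalCluster <- function(m, distance = "jaccard",
                                linkage_method = c("average", "complete")) {
    distance <- match.arg(distance, "jaccard")
    linkage_method <- match.arg(linkage_method)
    p <- .presenceOf(m)
    if (ncol(p) < 2L)
        stop("hierarchical clustering needs at least 2 cells; ",
             "use sortDescending() for a single cell", call. = FALSE)
    D <- jaccardDistance(m)
    hc <- hclust(as.dist(D), method = linkage_method)
    merge <- hc$merge
    nsnp <- colSums(p)
    bc <- colnames(p)
    visit <- function(node) {
        if (node < 0) return(-node)
        l <- .subtreeLeaves(merge, merge[node, 1L])
        r <- .subtreeLeaves(merge, merge[node, 2L])
        dl <- mean(nsnp[l]); dr <- mean(nsnp[r])
        first_left <- if (dl != dr) dl > dr else min(bc[l]) <= min(bc[r])
        if (first_left) c(visit(merge[node, 1L]), visit(merge[node, 2L]))
        else c(visit(merge[node, 2L]), visit(merge[node, 1L]))
    }
    cord <- if (nrow(merge)) visit(nrow(merge)) else 1L
    po <- p[.variantOrder(p), cord, drop = FALSE]
    # re-express leaf codes in the new cell order
    leafmap <- match(seq_along(cord), cord)
    sizes <- integer(nrow(merge))
    left <- right <- integer(nrow(merge))
    for (s in seq_len(nrow(merge))) {
        for (side in 1:2) {
            v <- merge[s, side]
            code <- if (v < 0) -leafmap[-v] else v
            if (side == 1L) left[s] <- code else right[s] <- code
        }
        sizes[s] <- length(.subtreeLeaves(merge, s))
    }
    linkage <- data.frame(step = seq_len(nrow(merge)), left = left,
                          right = right, height = hc$height, size = sizes)
    new("ClusteredSNPMatrix", presence = po, linkage = linkage)
}

#' Export an ordered SNP heatmap matrix (and linkage) as TSV
#'
#' `exportHeatmap()` writes the ordered 0/1 matrix with variants as rows
#' and cells as columns (first column `variant_id`, then one column per
#' barcode). `exportLinkage()` writes the merge list of a clustered
#' matrix. Rendering is left to general heatmap tools.
#'
#' @param cm A [ClusteredSNPMatrix-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportHeatmap <- function(cm, path) {
    stopifnot(is(cm, "ClusteredSNPMatrix"))
    p <- cm@presence
    d <- as.data.frame(as.matrix(p) * 1L)
    colnames(d) <- colnames(p)
    d <- cbind(variant_id = rownames(p), d)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname exportHeatmap
#' @export
exportLinkage <- function(cm, path) {
    stopifnot(is(cm, "ClusteredSNPMatrix"))
    if (is.null(cm@linkage))
        stop("this ClusteredSNPMatrix has no linkage (ordered, not clustered)",
             call. = FALSE)
    write.table(cm@linkage, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
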