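## Matching a reference panel against a query sample of the same
## individual, and tabulating the matched cells against cluster labels and
## the reporter tag. Matching is symmetric with discovery: a query cell
## matches a triple only when it carries all three SNPs (partial 2-of-3
## matches would void the uniqueness guarantee and are not offered).

#' Trace a panel into a query sample
#'
#' A query cell is matched when it carries all three SNPs of at least one
#' triple of the panel; every matching triple is recorded per cell, but
#' each cell counts once. The query matrix should come from the same
#' individual as the panel (not enforced — panels are individual-specific
#' and matches across individuals are meaningless).
#'
#' @param panel An [SNPPanelSet-class] object.
#' @param query A [MitoSNPMatrix-class] for the query sample. Panel SNPs
#'   absent from the query's variant universe simply never match.
#' @return A [TraceResult-class] object.
#' @export
tracePanels <- function(panel, query) {
    stopifnot(is(panel, "SNPPanelSet"), is(query, "MitoSNPMatrix"))
    ann <- cellAnnotations(query)
    qs <- sort(unique(ann$sample_id[!is.na(ann$sample_id)]))
    if (!length(qs)) qs <- NA_character_
    bc <- cellBarcodes(query)
    matches <- list()
    if (nrow(panel@triples) == 0L) {
        warning("panel has no triples; empty trace result")
    } else {
        p <- drop0(assay(query, "presence") * 1)
        vid <- rownames(query)
        for (r in seq_len(nrow(panel@triples))) {
            ids <- unlist(panel@triples[r, c("primary", "secondary",
                                             "tertiary")],
                          use.names = FALSE)
            if (!all(ids %in% vid)) next
            hit <- bc[.tripleCarriers(p, ids, bc)]
            for (b in hit) matches[[b]] <- c(matches[[b]], r)
        }
    }
    matched <- names(matches)
    cl <- ann$cluster_id[match(matched, rownames(ann))]
    cl[is.na(cl)] <- "unassigned"
    clusterCounts <- vapply(split(seq_along(cl), cl), length, integer(1L))
    tag <- ann$reporter_tag[match(matched, rownames(ann))]
    tagCounts <- c(tagged = sum(tag %in% TRUE),
                   untagged = sum(tag %in% FALSE),
                   unknown = sum(is.na(tag)))
    new("TraceResult", panel = panel, querySample = as.character(qs),
        queryBarcodes = bc, matches = matches,
        clusterCounts = clusterCounts, tagCounts = tagCounts)
}

#' Distribution of traced cells over clusters
#'
#' Tabulates the matched cells of a trace over the query's cluster labels:
#' per cluster, the number of matched cells, the cluster size among the
#' query cells, and the matched fraction. Matched cells without an
#' annotation are reported in an `"unassigned"` row.
#'
#' @param tr A [TraceResult-class] object.
#' @param annotations Annotation `data.frame` with columns `barcode` and
#'   `cluster_id` covering the query cells.
#' @return A `data.frame` with columns `cluster_id`, `matched`, `size`,
#'   `fraction`, sorted by cluster label (unassigned last).
#' @export
clusterDistribution <- function(tr, annotations) {
    stopifnot(is(tr, "TraceResult"))
    idx <- match(tr@queryBarcodes, annotations$barcode)
    cl <- as.character(annotations$cluster_id)[idx]
    cl[is.na(cl)] <- "unassigned"
    midx <- tr@queryBarcodes %in% names(tr@matches)
    clusters <- sort(unique(cl))
    clusters <- c(setdiff(clusters, "unassigned"),
                  intersect("unassigned", clusters))
    d <- data.frame(cluster_id = clusters,
                    matched = vapply(clusters, function(k)
                        sum(midx & cl == k), integer(1L)),
                    size = vapply(clusters, function(k) sum(cl == k),
                                  integer(1L)),
                    stringsAsFactors = FALSE)
    d$fraction <- ifelse(d$size > 0, d$matched / d$size, 0)
    rownames(d) <- NULL
    d
}

#' Reporter-tag concordance of traced cells
#'
#' Splits the matched cells of a trace by the boolean reporter tag in the
#' annotations: tagged, untagged, and tag-unknown. The tag stands in for
#' an upstream lineage label (for example a recombinase excision
#' reporter), so the tagged count measures how often SNP-based tracing
#' agrees with the orthogonal label.
#'
#' @inheritParams clusterDistribution
#' @param annotations Annotation `data.frame` with columns `barcode` and
#'   `reporter_tag`.
#' @return Named integer vector `c(tagged, untagged, unknown)`.
#' @export
tagConcordance <- function(tr, annotations) {
    stopifnot(is(tr, "TraceResult"))
    matched <- names(tr@matches)
    tag <- annotations$reporter_tag[match(matched, annotations$barcode)]
    c(tagged = sum(tag %in% TRUE), untagged = sum(tag %in% FALSE),
      unknown = sum(is.na(tag)))
}

#' Permutation test for cluster enrichment of traced cells
#'
#' Quantifies whether the matched cells concentrate in a set of expected
#' clusters (for example the clusters annotated as the panel's cell type
#' in the query sample). The null distribution is built by shuffling the
#' cluster labels over the annotated query cells with a seeded generator;
#' the p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, which cannot be zero.
#'
#' @inheritParams clusterDistribution
#' @param expected_clusters Character vector of cluster labels.
#' @param n_perm Number of permutations (default `1000`).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `observed` (fraction of matched, annotated cells in
#'   the expected clusters), `null_mean` and `p_value`.
#' @export
permutationTestEnrichment <- function(tr, annotations, expected_clusters,
                                      n_perm = 1000L, seed = NULL) {
    stopifnot(is(tr, "TraceResult"), n_perm >= 1L)
    idx <- match(tr@queryBarcodes, annotations$barcode)
    cl <- as.character(annotations$cluster_id)[idx]
    keep <- !is.na(cl)
    cl <- cl[keep]
    if (!any(expected_clusters %in% cl))
        stop("none of the expected clusters occur among the query cells",
             call. = FALSE)
    matched <- tr@queryBarcodes[keep] %in% names(tr@matches)
    if (!any(matched)) {
        warning("no matched annotated cells; p-value is 1")
        return(list(observed = NA_real_, null_mean = NA_real_, p_value = 1))
    }
    if (!is.null(seed)) set.seed(seed)
    observed <- mean(cl[matched] %in% expected_clusters)
    null <- vapply(seq_len(n_perm), function(i) {
        perm <- sample(cl)
        mean(perm[matched] %in% expected_clusters)
    }, numeric(1L))
    list(observed = observed, null_mean = mean(null),
         p_value = (1 + sum(null >= observed)) / (1 + n_perm))
}

#' Serialize a trace result to or from JSON
#'
#' The panel is embedded so a trace file is self-contained; key order is
#' stable so identical traces serialize to identical bytes.
#'
#' @param tr A [TraceResult-class] object.
#' @param path Output / input file path.
#' @return `writeTraceResult()` returns `path` invisibly;
#'   `readTraceResult()` the reconstructed [TraceResult-class].
#' @export
writeTraceResult <- function(tr, path) {
    stopifnot(is(tr, "TraceResult"))
    p <- tr@panel
    obj <- list(
        panel = list(target_class = p@targetClass,
                     sample_id = as.list(p@sampleID), params = p@params,
                     n_target = p@nTarget, triples = p@triples,
                     anchoring = as.list(p@anchoring),
                     coverage = p@coverage, shortfall = p@shortfall),
        query_sample = as.list(tr@querySample),
        query_barcodes = tr@queryBarcodes,
        matches = tr@matches,
        cluster_counts = as.list(tr@clusterCounts),
        tag_counts = as.list(tr@tagCounts))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
    invisible(path)
}

#' @rdname writeTraceResult
#' @export
readTraceResult <- function(path) {
    if (!file.exists(path))
        stop("trace file not found: ", path, call. = FALSE)
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    pj <- obj$panel
    triples <- as.data.frame(pj$triples, stringsAsFactors = FALSE)
    if (!nrow(triples))
        triples <- data.frame(primary = character(), secondary = character(),
                              tertiary = character(),
                              target_support = integer(),
                              stringsAsFactors = FALSE)
    triples$target_support <- as.integer(triples$target_support)
    anchoring <- setNames(as.integer(unlist(pj$anchoring)),
                          names(pj$anchoring))
    if (!length(anchoring)) anchoring <- setNames(integer(), character())
    panel <- new("SNPPanelSet", targetClass = pj$target_class,
                 sampleID = as.character(unlist(pj$sample_id)),
                 triples = triples, anchoring = anchoring,
                 coverage = as.numeric(pj$coverage),
                 shortfall = as.logical(pj$shortfall),
                 nTarget = as.integer(pj$n_target),
                 params = as.list(pj$params))
    matches <- lapply(obj$matches, as.integer)
    cc <- setNames(as.integer(unlist(obj$cluster_counts)),
                   names(obj$cluster_counts))
    if (!length(cc)) cc <- setNames(integer(), character())
    new("TraceResult", panel = panel,
        querySample = as.character(unlist(obj$query_sample)),
        queryBarcodes = as.character(obj$query_barcodes),
        matches = matches,
        clusterCounts = cc,
        tagCounts = setNames(as.integer(unlist(obj$tag_counts)),
                             c("tagged", "untagged", "unknown")))
}
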