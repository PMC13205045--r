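## Discovery of cell-type-unique three-SNP combinations and greedy panel
## assembly. A triple is valid for a target class when at least
## `min_support` target cells carry all three SNPs and no cell in the
## comparison scope (by default every other cell of the same individual)
## carries all three. Enumeration is target-driven: every valid triple is a
## 3-subset of some target cell's SNP set.

.csparseLists <- function(p) {
    p <- drop0(p)
    f <- factor(rep.int(seq_len(ncol(p)), diff(p@p)),
                levels = seq_len(ncol(p)))
    unname(split(p@i + 1L, f))
}

.targetScope <- function(m, target_class, scope = NULL) {
    ann <- cellAnnotations(m)
    bc <- cellBarcodes(m)
    target <- bc[!is.na(ann$cell_type) & ann$cell_type == target_class]
    if (length(target) == 0L)
        stop("no cells annotated with cell_type '", target_class, "'",
             call. = FALSE)
    if (is.null(scope)) {
        scope <- setdiff(bc, target)
    } else {
        if (!all(scope %in% bc))
            stop("comparison scope contains unknown barcodes", call. = FALSE)
        scope <- setdiff(scope, target)
    }
    list(target = target, scope = scope)
}

.tripleDF <- function(ids1, ids2, ids3, support, target_cells = list()) {
    d <- data.frame(snp1 = ids1, snp2 = ids2, snp3 = ids3,
                    target_support = as.integer(support),
                    stringsAsFactors = FALSE)
    perm <- order(d$snp1, d$snp2, d$snp3)
    d <- d[perm, , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "target_cells") <- if (length(target_cells)) target_cells[perm]
                               else list()
    d
}

#' Enumerate all valid three-SNP combinations for a target cell class
#'
#' Finds every unordered set of three SNPs that (a) is carried in full by
#' at least `min_support` target cells and (b) is carried in full by no
#' cell of the comparison scope. Candidates are generated from the target
#' cells' own SNP sets (per-cell 3-subsets, deduplicated), so the search
#' is exhaustive over combinations that can have target support without
#' ever scanning all variant triples; scope containment is tested on an
#' inverted variant-to-cells index.
#'
#' @param m A [MitoSNPMatrix-class] object.
#' @param target_class Cell-type label defining the target cells.
#' @param scope Barcodes of the comparison cells. Default: every non-target
#'   cell in `m` (all samples of the individual). Target cells are always
#'   excluded from the scope.
#' @param min_support Minimum number of target cells carrying the triple
#'   (default `1`).
#' @return A `data.frame` with columns `snp1`, `snp2`, `snp3` (variant ids
#'   in ascending position order within each triple) and `target_support`,
#'   sorted by the three ids. Attribute `target_cells` holds, per triple,
#'   the barcodes of the supporting target cells; attribute `params`
#'   records the discovery parameters. Zero rows (with a `diagnostics`
#'   attribute) when no target cell carries three or more SNPs.
#' @seealso [bruteForceTriples()] for the exhaustive reference search,
#'   [greedySelectPanels()] for panel assembly.
#' @export
enumerateValidTriples <- function(m, target_class, scope = NULL,
                                  min_support = 1L) {
    ts <- .targetScope(m, target_class, scope)
    p <- drop0(assay(m, "presence") * 1)
    tv <- .csparseLists(p[, ts$target, drop = FALSE])
    params <- list(target_class = target_class, min_support = min_support,
                   n_target = length(ts$target), n_scope = length(ts$scope))
    empty <- .tripleDF(character(), character(), character(), integer())
    attr(empty, "params") <- params
    if (all(lengths(tv) < 3L)) {
        attr(empty, "diagnostics") <- "no target cell carries >= 3 SNPs"
        return(empty)
    }
    sc <- .csparseLists(t(p[, ts$scope, drop = FALSE]))
    res <- .enumerate_triples_cpp(tv, sc, as.integer(min_support))
    if (!length(res$v1)) return(empty)
    vid <- rownames(m)
    out <- .tripleDF(vid[res$v1], vid[res$v2], vid[res$v3], res$support,
                     lapply(res$target_cells, function(ix) ts$target[ix]))
    attr(out, "params") <- params
    out
}

#' Exhaustive reference enumeration of valid triples
#'
#' Tests every one of the `choose(V, 3)` variant triples directly against
#' the target cells and the comparison scope. Independent of the
#' target-driven search in [enumerateValidTriples()] and intended as a
#' cross-check on small instances; refuses matrices with more than
#' `max_variants` variants.
#'
#' @inheritParams enumerateValidTriples
#' @param max_variants Refusal threshold (default `25`).
#' @return Same `data.frame` layout as [enumerateValidTriples()].
#' @export
bruteForceTriples <- function(m, target_class, scope = NULL,
                              min_support = 1L, max_variants = 25L) {
    if (nrow(m) > max_variants)
        stop("instance too large for the exhaustive search (",
             nrow(m), " > ", max_variants, " variants)", call. = FALSE)
    ts <- .targetScope(m, target_class, scope)
    p <- as.matrix(assay(m, "presence"))
    vid <- rownames(m)
    out <- list(); tc <- list()
    if (nrow(m) >= 3L) {
        for (trip in asplit(combn(nrow(m), 3L), 2L)) {
            carriers <- colSums(p[trip, , drop = FALSE]) == 3L
            supp <- names(carriers)[carriers]
            n_target <- sum(supp %in% ts$target)
            if (n_target < min_support) next
            if (any(supp %in% ts$scope)) next
            out[[length(out) + 1L]] <- c(vid[trip], n_target)
            tc[[length(tc) + 1L]] <- intersect(supp, ts$target)
        }
    }
    if (!length(out))
        return(.tripleDF(character(), character(), character(), integer()))
    mm <- do.call(rbind, out)
    .tripleDF(mm[, 1L], mm[, 2L], mm[, 3L], mm[, 4L], tc)
}

#' Order a triple into primary, secondary and tertiary SNPs
#'
#' The tertiary (anchoring) SNP is the member with the highest specificity
#' for the target class, `s(v) = prev_target(v) / (prev_target(v) +
#' prev_scope(v))` (`s = 1` when no scope cell carries `v`); ties go to
#' the member with the lower target prevalence, then the higher genomic
#' position. The remaining two are ordered primary before secondary by
#' descending target prevalence, ties by ascending position. The result
#' does not depend on the input order of the three ids.
#'
#' @param triple Character vector of three distinct variant ids.
#' @inheritParams enumerateValidTriples
#' @return A one-row `data.frame` with columns `primary`, `secondary`,
#'   `tertiary`.
#' @export
orderTriple <- function(triple, m, target_class, scope = NULL) {
    stopifnot(length(triple) == 3L, !anyDuplicated(triple))
    ts <- .targetScope(m, target_class, scope)
    pt <- variantPrevalence(m, ts$target)[triple]
    pn <- if (length(ts$scope)) variantPrevalence(m, ts$scope)[triple]
          else setNames(rep(0, 3L), triple)
    s <- ifelse(pn == 0, 1, pt / (pt + pn))
    pos <- parseVariantID(triple)$position
    ter <- order(-s, pt, -pos)[1L]
    rest <- setdiff(seq_len(3L), ter)
    rest <- rest[order(-pt[rest], pos[rest])]
    data.frame(primary = triple[rest[1L]], secondary = triple[rest[2L]],
               tertiary = triple[ter], stringsAsFactors = FALSE)
}

.tripleCarriers <- function(p, ids, cells) {
    # an id outside the matrix universe is carried by no cell
    if (!all(ids %in% rownames(p)))
        return(setNames(rep(FALSE, length(cells)), cells))
    colSums(p[ids, cells, drop = FALSE]) == 3L
}

#' Greedily assemble a panel covering the target class
#'
#' Classic greedy set cover over the valid triples: repeatedly select the
#' triple covering the most not-yet-anchored target cells, anchoring the
#' newly covered cells to it, until the covered fraction reaches
#' `target_coverage` or no triple adds coverage. When the union of all
#' valid triples cannot reach the requested coverage the best achievable
#' panel is returned with the shortfall flag set. Ties are broken by the
#' higher mean target prevalence of the triple's members, then by the
#' lexicographic order of the variant ids, so the result is deterministic.
#'
#' @param valid Output of [enumerateValidTriples()] (or
#'   [bruteForceTriples()]).
#' @inheritParams enumerateValidTriples
#' @param target_coverage Fraction of target cells the panel should mark
#'   (default `0.90`; the stop rule is `coverage >= target_coverage`).
#' @param sample_id Optional sample label stored in the panel; defaults to
#'   the sample ids of the target cells.
#' @return An [SNPPanelSet-class] object.
#' @export
greedySelectPanels <- function(valid, m, target_class, scope = NULL,
                               target_coverage = 0.90, sample_id = NULL) {
    ts <- .targetScope(m, target_class, scope)
    target <- ts$target
    if (is.null(sample_id)) {
        ann <- cellAnnotations(m)
        sample_id <- sort(unique(ann$sample_id[rownames(ann) %in% target]))
        sample_id <- sample_id[!is.na(sample_id)]
        if (!length(sample_id)) sample_id <- NA_character_
    }
    params <- list(target_coverage = target_coverage,
                   min_support = attr(valid, "params")$min_support,
                   n_target = length(target), n_scope = length(ts$scope))
    emptyPanel <- function(shortfall) {
        new("SNPPanelSet", targetClass = target_class,
            sampleID = as.character(sample_id),
            triples = data.frame(primary = character(),
                                 secondary = character(),
                                 tertiary = character(),
                                 target_support = integer(),
                                 stringsAsFactors = FALSE),
            anchoring = setNames(integer(), character()),
            coverage = 0, shortfall = shortfall,
            nTarget = length(target), params = params)
    }
    if (target_coverage <= 0) return(emptyPanel(FALSE))
    if (nrow(valid) == 0L) return(emptyPanel(TRUE))

    p <- drop0(assay(m, "presence") * 1)
    cover <- attr(valid, "target_cells")
    if (is.null(cover)) {
        ids <- as.matrix(valid[, c("snp1", "snp2", "snp3")])
        cover <- lapply(seq_len(nrow(valid)), function(r)
            target[.tripleCarriers(p, ids[r, ], target)])
    }
    prev_t <- variantPrevalence(m, target)
    mean_prev <- (prev_t[valid$snp1] + prev_t[valid$snp2] +
                  prev_t[valid$snp3]) / 3
    lexkey <- paste(valid$snp1, valid$snp2, valid$snp3)

    remaining <- target
    selected <- integer()
    anchor <- integer()
    repeat {
        if (length(anchor) / length(target) >= target_coverage) break
        gains <- vapply(cover, function(cells)
            sum(cells %in% remaining), integer(1L))
        gains[selected] <- 0L
        g <- max(gains)
        if (g == 0L) break
        cand <- which(gains == g)
        cand <- cand[order(-mean_prev[cand], lexkey[cand])]
        pick <- cand[1L]
        selected <- c(selected, pick)
        newly <- intersect(cover[[pick]], remaining)
        anchor <- c(anchor, setNames(rep(length(selected), length(newly)),
                                     newly))
        remaining <- setdiff(remaining, newly)
    }
    if (!length(selected)) return(emptyPanel(TRUE))
    coverage <- length(anchor) / length(target)
    triples <- do.call(rbind, lapply(selected, function(ix)
        orderTriple(unlist(valid[ix, c("snp1", "snp2", "snp3")],
                           use.names = FALSE),
                    m, target_class, scope)))
    triples$target_support <- valid$target_support[selected]
    rownames(triples) <- NULL
    new("SNPPanelSet", targetClass = target_class,
        sampleID = as.character(sample_id), triples = triples,
        anchoring = anchor, coverage = coverage,
        shortfall = coverage < target_coverage,
        nTarget = length(target), params = params)
}

#' Discover a panel for a target cell class
#'
#' Convenience wrapper: [enumerateValidTriples()] followed by
#' [greedySelectPanels()].
#'
#' @inheritParams greedySelectPanels
#' @inheritParams enumerateValidTriples
#' @return An [SNPPanelSet-class] object; the full valid-triple list is
#'   attached as attribute `valid_triples`.
#' @export
discoverPanels <- function(m, target_class, scope = NULL, min_support = 1L,
                           target_coverage = 0.90, sample_id = NULL) {
    valid <- enumerateValidTriples(m, target_class, scope, min_support)
    panel <- greedySelectPanels(valid, m, target_class, scope,
                                target_coverage, sample_id)
    attr(panel, "valid_triples") <- valid
    panel
}

#' Recompute the coverage of a panel
#'
#' Recomputes, from the matrix alone, the fraction of target cells that
#' carry all three SNPs of at least one triple of the panel. Must equal
#' the stored `panelCoverage()`.
#'
#' @param panel An [SNPPanelSet-class] object.
#' @param m A [MitoSNPMatrix-class] object.
#' @return A fraction in `[0, 1]`.
#' @export
computeCoverage <- function(panel, m) {
    ts <- .targetScope(m, panel@targetClass)
    if (nrow(panel@triples) == 0L) return(0)
    p <- drop0(assay(m, "presence") * 1)
    covered <- rep(FALSE, length(ts$target))
    for (r in seq_len(nrow(panel@triples))) {
        ids <- unlist(panel@triples[r, c("primary", "secondary", "tertiary")],
                      use.names = FALSE)
        covered <- covered | .tripleCarriers(p, ids, ts$target)
    }
    sum(covered) / length(ts$target)
}

#' Verify the uniqueness guarantee of a panel
#'
#' Checks that no cell of the comparison scope carries all three SNPs of
#' any triple in the panel — the defining property of a valid panel.
#'
#' @inheritParams computeCoverage
#' @param scope Comparison barcodes; default every non-target cell of `m`.
#' @return A list with `ok` (logical) and `violations` (`data.frame` with
#'   columns `barcode` and `triple`, the 1-based triple index).
#' @export
verifyUniqueness <- function(panel, m, scope = NULL) {
    ts <- .targetScope(m, panel@targetClass, scope)
    viol <- data.frame(barcode = character(), triple = integer(),
                       stringsAsFactors = FALSE)
    if (nrow(panel@triples) && length(ts$scope)) {
        p <- drop0(assay(m, "presence") * 1)
        for (r in seq_len(nrow(panel@triples))) {
            ids <- unlist(panel@triples[r, c("primary", "secondary",
                                             "tertiary")],
                          use.names = FALSE)
            hit <- .tripleCarriers(p, ids, ts$scope)
            if (any(hit))
                viol <- rbind(viol,
                              data.frame(barcode = ts$scope[hit], triple = r,
                                         stringsAsFactors = FALSE))
        }
    }
    list(ok = nrow(viol) == 0L, violations = viol)
}

#' Serialize a panel to or from JSON
#'
#' Panels are written as JSON with a stable key order
#' (`target_class`, `sample_id`, `params`, `triples`, `anchoring`,
#' `coverage`, `shortfall`), so identical panels serialize to identical
#' bytes.
#'
#' @param panel An [SNPPanelSet-class] object.
#' @param path Output / input file path.
#' @return `writePanelSet()` returns `path` invisibly; `readPanelSet()`
#'   the reconstructed [SNPPanelSet-class].
#' @export
writePanelSet <- function(panel, path) {
    stopifnot(is(panel, "SNPPanelSet"))
    obj <- list(
        target_class = panel@targetClass,
        sample_id = as.list(panel@sampleID),
        params = panel@params,
        n_target = panel@nTarget,
        triples = panel@triples,
        anchoring = as.list(panel@anchoring),
        coverage = panel@coverage,
        shortfall = panel@shortfall)
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, path)
    invisible(path)
}

#' @rdname writePanelSet
#' @export
readPanelSet <- function(path) {
    if (!file.exists(path))
        stop("panel file not found: ", path, call. = FALSE)
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    triples <- as.data.frame(obj$triples, stringsAsFactors = FALSE)
    if (!nrow(triples))
        triples <- data.frame(primary = character(), secondary = character(),
                              tertiary = character(),
                              target_support = integer(),
                              stringsAsFactors = FALSE)
    triples$target_support <- as.integer(triples$target_support)
    anchoring <- setNames(as.integer(unlist(obj$anchoring)),
                          names(obj$anchoring))
    if (!length(anchoring)) anchoring <- setNames(integer(), character())
    new("SNPPanelSet", targetClass = obj$target_class,
        sampleID = as.character(unlist(obj$sample_id)),
        triples = triples, anchoring = anchoring,
        coverage = as.numeric(obj$coverage),
        shortfall = as.logical(obj$shortfall),
        nTarget = as.integer(obj$n_target),
        params = as.list(obj$params))
}
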