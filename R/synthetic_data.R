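## Forward simulator of mitochondrial heteroplasmy drift along a
## cell-division tree, with a sequencing readout. Node identifiers encode
## the root-to-node path ("R" plus one bit per division), so ancestry is a
## prefix test and clade membership is read off the id. Only lineages
## ancestral to a sampled cell are materialized; because every branch
## evolves independently given its parent, the marginal law of the sampled
## cells is identical to simulating the complete tree.

.bitsSuffix <- function(k, width) {
    # k: 0-based node index within a generation; returns 'width' bits
    if (width == 0L) return(rep("", length(k)))
    vapply(k, function(x)
        paste(rev(as.integer(intToBits(x)[seq_len(width)])), collapse = ""),
        "")
}

#' Simulation configuration
#'
#' Parameters of the lineage/readout simulator. The defaults are a
#' two-timepoint "regeneration" study: eight clades fixed at generation 3
#' are assigned liver/spleen-style cell types, the cholangiocyte clade
#' carries the reporter tag, a pre-timepoint sample is taken at
#' generation 21 and a post-timepoint sample (with the hepatocyte clades
#' over-sampled threefold, emulating regenerative expansion) at
#' generation 24.
#'
#' Somatic variants arise at `mutation_rate` new variants per daughter
#' cell per division (Poisson), each at an unused genome position,
#' starting from a single molecule (`h = 1/copy_number`); heteroplasmy
#' then drifts by one binomial resampling of `copy_number` segregating
#' units per division. `copy_number` is an *effective* number of
#' segregating units: mitochondrial genomes segregate in nucleoid
#' packages, so the unit count driving drift sits at the low end of the
#' 100-1000 genome copies a cell carries.
#'
#' @param seed Integer seed; all stages derive their generators from it.
#' @param genome_length Mitochondrial genome length (default 16299, the
#'   mouse chrM).
#' @param copy_number Effective number of segregating mtDNA units per
#'   cell (default 100).
#' @param n_generations Number of cell divisions simulated (default 24).
#' @param mutation_rate Expected new somatic variants per daughter per
#'   division (default 1.2).
#' @param n_germline Founder homoplasmic variants shared by all cells
#'   (default 8).
#' @param clade_generation Generation whose nodes define the clades
#'   (default 3, i.e. eight clades).
#' @param clade_types Character vector of cell-type labels, one per clade
#'   (length `2^clade_generation`).
#' @param reporter_types Cell types whose clades carry the reporter tag.
#' @param sampling Named list of timepoints, each
#'   `list(generation=, n_cells=, expansion=)`; `expansion` is a named
#'   numeric vector of per-cell-type sampling weights (default 1).
#' @param readout List: `mean_coverage`, `dispersion` (negative binomial
#'   size), `error_rate` (per-read substitution probability, `< 0.25`),
#'   `dropout` (per cell-variant probability of losing all alt reads),
#'   `quality_mean`/`quality_sd` (mean Phred quality of reference- and
#'   variant-supporting read piles), `error_quality_mean`/
#'   `error_quality_sd` (quality of error-only piles, lower — this is
#'   what a quality filter exploits), `n_background_sites` (invariant
#'   positions included in the readout).
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L,
                      genome_length = 16299L,
                      copy_number = 100L,
                      n_generations = 24L,
                      mutation_rate = 1.2,
                      n_germline = 8L,
                      clade_generation = 3L,
                      clade_types = c("hepatocyte", "hepatocyte",
                                      "cholangiocyte", "B_cell", "T_cell",
                                      "endothelial", "macrophage", "NK"),
                      reporter_types = "cholangiocyte",
                      sampling = list(
                          pre = list(generation = 21L, n_cells = 250L,
                                     expansion = NULL),
                          post = list(generation = 24L, n_cells = 500L,
                                      expansion = c(hepatocyte = 3))),
                      readout = list()) {
    rd <- list(mean_coverage = 150, dispersion = 4, error_rate = 1e-3,
               dropout = 0.1, quality_mean = 37, quality_sd = 3,
               error_quality_mean = 25, error_quality_sd = 4,
               n_background_sites = 150L)
    rd[names(readout)] <- readout
    cfg <- list(seed = as.integer(seed), genome_length = genome_length,
                copy_number = copy_number, n_generations = n_generations,
                mutation_rate = mutation_rate, n_germline = n_germline,
                clade_generation = clade_generation,
                clade_types = clade_types, reporter_types = reporter_types,
                sampling = sampling, readout = rd)
    .validateSimConfig(cfg)
    structure(cfg, class = "SimConfig")
}

.validateSimConfig <- function(cfg) {
    with(cfg, {
        if (mutation_rate < 0) stop("mutation_rate must be >= 0",
                                    call. = FALSE)
        if (copy_number < 2) stop("copy_number must be >= 2", call. = FALSE)
        if (readout$error_rate < 0 || readout$error_rate >= 0.25)
            stop("error_rate must be in [0, 0.25)", call. = FALSE)
        if (readout$dropout < 0 || readout$dropout > 1)
            stop("dropout must be a probability", call. = FALSE)
        if (length(clade_types) != 2^clade_generation)
            stop("clade_types must have length 2^clade_generation",
                 call. = FALSE)
        if (n_germline >= genome_length)
            stop("more germline variants than genome positions",
                 call. = FALSE)
        for (tp in names(sampling)) {
            s <- sampling[[tp]]
            if (s$generation > n_generations)
                stop("sampling generation for '", tp,
                     "' exceeds n_generations", call. = FALSE)
            if (s$generation < clade_generation)
                stop("sampling generation for '", tp,
                     "' precedes the clade generation", call. = FALSE)
            if (s$generation - clade_generation > 30L)
                stop("sampling depth below the clades is limited to 30 ",
                     "divisions", call. = FALSE)
            if (!is.null(s$expansion) &&
                !all(names(s$expansion) %in% clade_types))
                stop("expansion names unknown cell type(s): ",
                     paste(setdiff(names(s$expansion), clade_types),
                           collapse = ", "), call. = FALSE)
        }
    })
    invisible(cfg)
}

#' Binomial heteroplasmy drift for one division
#'
#' Offspring heteroplasmy given a parent value: one binomial resampling
#' of the `N` segregating units, `h' = Binomial(N, h) / N`. `0` and `1`
#' are absorbing; the mean is conserved.
#'
#' @param h Numeric vector of parent heteroplasmies in `[0, 1]`.
#' @param N Number of segregating units.
#' @param n Number of draws per element of `h` (default 1, vectorized
#'   over `h`).
#' @return Numeric vector of offspring heteroplasmies.
#' @export
driftHeteroplasmy <- function(h, N, n = 1L) {
    if (n == 1L) rbinom(length(h), N, h) / N
    else rbinom(n * length(h), N, rep(h, each = n)) / N
}

.sampleTimepointNodes <- function(cfg, tp) {
    s <- cfg$sampling[[tp]]
    cg <- cfg$clade_generation
    clades <- paste0("R", .bitsSuffix(seq_len(2^cg) - 1L, cg))
    w <- setNames(rep(1, length(clades)), clades)
    if (!is.null(s$expansion))
        for (ct in names(s$expansion))
            w[cfg$clade_types == ct] <- s$expansion[[ct]]
    depth <- s$generation - cg
    clade_size <- 2^depth
    prob <- w * clade_size
    if (sum(prob) == 0)
        stop("all sampling weights are zero for timepoint '", tp, "'",
             call. = FALSE)
    n_c <- drop(rmultinom(1L, s$n_cells, prob / sum(prob)))
    # cap at clade size, pushing overflow to the other clades
    repeat {
        over <- n_c - clade_size
        if (all(over <= 0)) break
        excess <- sum(over[over > 0])
        n_c[over > 0] <- clade_size
        room <- clade_size - n_c
        open <- which(room > 0 & prob > 0)
        if (!length(open))
            stop("cannot place ", excess, " sampled cells for timepoint '",
                 tp, "'", call. = FALSE)
        add <- drop(rmultinom(1L, excess, prob[open] / sum(prob[open])))
        n_c[open] <- n_c[open] + pmin(add, room[open])
        if (sum(n_c) == s$n_cells) break
    }
    ids <- character()
    for (ci in seq_along(clades)) {
        if (n_c[ci] == 0L) next
        picks <- sample.int(clade_size, n_c[ci])
        ids <- c(ids, paste0(clades[ci], .bitsSuffix(picks - 1L, depth)))
    }
    sort(ids)
}

#' Simulate heteroplasmy drift along a cell-division tree
#'
#' Grows a binary division tree from one founder. The founder carries
#' `n_germline` homoplasmic (h = 1) variants; at every division each
#' daughter (i) redraws every segregating variant's heteroplasmy as
#' `Binomial(N, h)/N` independently and (ii) acquires
#' `Poisson(mutation_rate)` new variants, each at a uniformly chosen
#' unused genome position with a random alternate base, starting at
#' `h = 1/N`. Absorption at 0 and 1 is exact. The cells to be sampled at
#' each configured timepoint are chosen first (stratified over clades by
#' the expansion weights, uniformly within a clade) and only their
#' ancestral lineages are materialized.
#'
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [simConfig()] object.
#' @return A [MitoSimTruth-class] object.
#' @export
simulateLineage <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    L <- cfg$genome_length
    refseq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    reference <- referenceMito("chrM_sim", paste(refseq, collapse = ""))
    pool <- seq_len(L)

    newVariants <- function(k) {
        if (k > length(pool))
            stop("more variants requested than unused genome positions; ",
                 "lower mutation_rate or the sampled depth", call. = FALSE)
        idx <- sample.int(length(pool), k)
        pos <- pool[idx]
        pool <<- pool[-idx]
        alt <- vapply(refseq[pos], function(r)
            sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
        paste0(pos, "_", refseq[pos], ">", alt)
    }

    germ <- if (cfg$n_germline > 0L) newVariants(cfg$n_germline)
            else character()
    origin <- data.frame(variant_id = germ,
                         origin_node = rep("germline", length(germ)),
                         origin_generation = rep(0L, length(germ)),
                         stringsAsFactors = FALSE)

    # choose the sampled nodes, then the induced ancestral node set
    sampled <- lapply(names(cfg$sampling), function(tp)
        .sampleTimepointNodes(cfg, tp))
    names(sampled) <- names(cfg$sampling)
    nodes <- "R"
    for (ids in sampled)
        for (id in ids)
            nodes <- c(nodes, substring(id, 1L, 2:nchar(id)))
    nodes <- sort(unique(nodes))
    gen_of <- nchar(nodes) - 1L

    het <- vector("list", length(nodes))
    names(het) <- nodes
    het[["R"]] <- setNames(rep(1, length(germ)), germ)
    N <- cfg$copy_number
    for (g in seq_len(max(gen_of))) {
        for (id in nodes[gen_of == g]) {           # sorted: deterministic
            hp <- het[[substring(id, 1L, nchar(id) - 1L)]]
            h <- driftHeteroplasmy(hp, N)
            names(h) <- names(hp)
            h <- h[h > 0]
            k <- rpois(1L, cfg$mutation_rate)
            if (k > 0L) {
                nv <- newVariants(k)
                origin <- rbind(origin, data.frame(
                    variant_id = nv, origin_node = id,
                    origin_generation = g, stringsAsFactors = FALSE))
                h <- c(h, setNames(rep(1 / N, k), nv))
            }
            het[[id]] <- h
        }
    }

    cg <- cfg$clade_generation
    clades <- paste0("R", .bitsSuffix(seq_len(2^cg) - 1L, cg))
    clade_of <- ifelse(gen_of >= cg, substring(nodes, 1L, cg + 1L),
                       NA_character_)
    type_of <- cfg$clade_types[match(clade_of, clades)]
    tp_of <- rep(NA_character_, length(nodes))
    for (tp in names(sampled))
        tp_of[nodes %in% sampled[[tp]]] <- tp
    meta <- DataFrame(generation = gen_of, clade = clade_of,
                      cell_type = type_of,
                      reporter_tag = !is.na(type_of) &
                          type_of %in% cfg$reporter_types,
                      timepoint = tp_of, row.names = nodes)
    vinfo <- parseVariantID(origin$variant_id)
    origin <- DataFrame(variant_id = origin$variant_id,
                        position = vinfo$position, ref = vinfo$ref,
                        alt = vinfo$alt, origin_node = origin$origin_node,
                        origin_generation = origin$origin_generation,
                        row.names = origin$variant_id)
    new("MitoSimTruth", parent = setNames(
            ifelse(nodes == "R", NA_character_,
                   substring(nodes, 1L, nchar(nodes) - 1L)), nodes),
        het = het, meta = meta, origin = origin, reference = reference,
        config = unclass(cfg))
}

#' Extract the sampled cells and their annotations
#'
#' Returns, per timepoint, the sampled cell barcodes and a cell
#' annotation table (`sample_id` = timepoint name, `cell_type` from the
#' clade, `cluster_id` = clade node id, `reporter_tag`).
#'
#' @param truth A [MitoSimTruth-class] object.
#' @param timepoints Which timepoints (default: all configured).
#' @return Named list per timepoint with elements `barcodes` and
#'   `annotations`.
#' @export
sampleCells <- function(truth, timepoints = NULL) {
    stopifnot(is(truth, "MitoSimTruth"))
    m <- truth@meta
    if (is.null(timepoints))
        timepoints <- names(truth@config$sampling)
    out <- lapply(timepoints, function(tp) {
        sel <- !is.na(m$timepoint) & m$timepoint == tp
        if (!any(sel))
            stop("no sampled cells for timepoint '", tp, "'", call. = FALSE)
        bc <- rownames(m)[sel]
        list(barcodes = bc,
             annotations = data.frame(
                 barcode = bc, sample_id = tp,
                 cell_type = m$cell_type[sel],
                 cluster_id = m$clade[sel],
                 reporter_tag = m$reporter_tag[sel],
                 stringsAsFactors = FALSE))
    })
    names(out) <- timepoints
    out
}

#' Simulate a sequencing readout of sampled cells
#'
#' Per cell and assayed position, total coverage is negative binomial
#' (`mean_coverage`, `dispersion`). A variant with true heteroplasmy `h`
#' yields alt reads `Binomial(cov, h(1-e) + (1-h)e/3)`; each other
#' non-reference base accrues error reads `Binomial(cov, e/3)`; the
#' remainder supports the reference. With probability `dropout` a cell's
#' alt reads for a variant are zeroed. Mean base qualities are clipped
#' normals: reference- and true-variant piles from
#' `quality_mean`/`quality_sd`, error-only piles from the lower
#' `error_quality_mean`/`error_quality_sd` (so a quality filter behaves
#' as it does on real data). Assayed positions are those carrying a
#' variant in at least one requested cell plus `n_background_sites`
#' invariant positions; unassayed positions would contribute nothing
#' callable. Deterministic under the configuration seed.
#'
#' @param truth A [MitoSimTruth-class] object.
#' @param cells Character vector of cell barcodes (typically the union of
#'   timepoint samples from [sampleCells()]).
#' @param cfg The [simConfig()]; defaults to the truth's.
#' @return List with `counts` (a [MitoAlleleCounts-class]) and
#'   `annotations` (the cells' annotation `data.frame`).
#' @export
simulateReadout <- function(truth, cells, cfg = NULL) {
    stopifnot(is(truth, "MitoSimTruth"))
    if (is.null(cfg)) cfg <- truth@config
    cfg <- unclass(cfg)
    rd <- cfg$readout
    set.seed(cfg$seed + 1L)
    stopifnot(all(cells %in% names(truth@het)))
    het <- truth@het[cells]
    refseq <- strsplit(as.character(refSequence(truth@reference)), "")[[1]]
    L <- length(refseq)

    alive <- unique(unlist(lapply(het, names), use.names = FALSE))
    vpos <- if (length(alive)) parseVariantID(alive)$position else integer()
    bg_pool <- setdiff(seq_len(L), vpos)
    n_bg <- min(rd$n_background_sites, length(bg_pool))
    positions <- sort(unique(c(vpos, sample(bg_pool, n_bg))))
    np <- length(positions)
    pos_index <- integer(L)
    pos_index[positions] <- seq_len(np)
    posref <- refseq[positions]

    eps <- rd$error_rate
    trip <- list()                       # per base: i, j, x, qual flag
    for (b in c(.BASES)) trip[[b]] <-
        list(i = list(), j = list(), x = list(), err = list())
    for (ci in seq_along(cells)) {
        h <- het[[ci]]
        cov <- rnbinom(np, size = rd$dispersion, mu = rd$mean_coverage)
        altmat <- matrix(0, nrow = np, ncol = 4L,
                         dimnames = list(NULL, .BASES))
        istrue <- matrix(FALSE, nrow = np, ncol = 4L,
                         dimnames = list(NULL, .BASES))
        if (length(h)) {
            vi <- parseVariantID(names(h))
            pidx <- pos_index[vi$position]
            p_alt <- h * (1 - eps) + (1 - h) * eps / 3
            alt <- rbinom(length(h), cov[pidx], p_alt)
            if (rd$dropout > 0)
                alt[rbinom(length(h), 1L, rd$dropout) == 1L] <- 0L
            for (k in seq_along(h)) {
                altmat[pidx[k], vi$alt[k]] <- alt[k]
                istrue[pidx[k], vi$alt[k]] <- TRUE
            }
        }
        if (eps > 0) {
            for (b in .BASES) {
                sel <- posref != b & !istrue[, b]
                altmat[sel, b] <- altmat[sel, b] +
                    rbinom(sum(sel), cov[sel], eps / 3)
            }
        }
        refcount <- pmax(cov - rowSums(altmat), 0)
        for (b in .BASES) {
            isref <- posref == b
            cnt <- ifelse(isref, refcount, altmat[, b])
            nz <- which(cnt > 0)
            if (!length(nz)) next
            trip[[b]]$i[[length(trip[[b]]$i) + 1L]] <- positions[nz]
            trip[[b]]$j[[length(trip[[b]]$j) + 1L]] <-
                rep.int(ci, length(nz))
            trip[[b]]$x[[length(trip[[b]]$x) + 1L]] <- cnt[nz]
            trip[[b]]$err[[length(trip[[b]]$err) + 1L]] <-
                !isref[nz] & !istrue[nz, b]
        }
    }
    counts <- list(); quals <- list()
    for (b in .BASES) {
        i <- unlist(trip[[b]]$i); j <- unlist(trip[[b]]$j)
        x <- unlist(trip[[b]]$x); err <- unlist(trip[[b]]$err)
        if (is.null(i)) { i <- integer(); j <- integer()
                          x <- numeric(); err <- logical() }
        counts[[b]] <- sparseMatrix(i = i, j = j, x = x, dims = c(L,
                          length(cells)),
                          dimnames = list(NULL, cells))
        qm <- ifelse(err, rd$error_quality_mean, rd$quality_mean)
        qs <- ifelse(err, rd$error_quality_sd, rd$quality_sd)
        q <- round(pmin(pmax(rnorm(length(x), qm, qs), 0), 60), 3L)
        quals[[b]] <- sparseMatrix(i = i, j = j, x = q, dims = c(L,
                          length(cells)),
                          dimnames = list(NULL, cells))
    }
    meta <- truth@meta[cells, ]
    ann <- data.frame(barcode = cells, sample_id = meta$timepoint,
                      cell_type = meta$cell_type,
                      cluster_id = meta$clade,
                      reporter_tag = meta$reporter_tag,
                      stringsAsFactors = FALSE)
    acs <- MitoAlleleCounts(counts, truth@reference, qualities = quals,
                            annotations = ann)
    list(counts = acs, annotations = ann)
}

#' Simulate a complete dataset
#'
#' [simulateLineage()], [sampleCells()] and [simulateReadout()] in one
#' call.
#'
#' @param cfg A [simConfig()] object.
#' @return List with `truth`, `samples` (per-timepoint barcodes and
#'   annotations), `counts` and `annotations` (all timepoints combined).
#' @export
simulateDataset <- function(cfg = simConfig()) {
    truth <- simulateLineage(cfg)
    samples <- sampleCells(truth)
    cells <- unlist(lapply(samples, `[[`, "barcodes"), use.names = FALSE)
    ro <- simulateReadout(truth, cells, cfg)
    list(truth = truth, samples = samples, counts = ro$counts,
         annotations = ro$annotations)
}

#' Score a trace against the simulated ground truth
#'
#' Precision is the fraction of matched query cells that truly descend
#' from a clade of the panel's target cell type; recall is the fraction
#' of true-descendant query cells that were matched. Ancestry is exact
#' (node ids encode paths).
#'
#' @param tr A [TraceResult-class] from [tracePanels()].
#' @param truth The [MitoSimTruth-class] the query cells came from.
#' @return List with `precision` (`NA` when nothing matched), `recall`,
#'   and the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluateTracing <- function(tr, truth) {
    stopifnot(is(tr, "TraceResult"), is(truth, "MitoSimTruth"))
    m <- truth@meta
    stopifnot(all(tr@queryBarcodes %in% rownames(m)))
    target_clades <- unique(m$clade[!is.na(m$cell_type) &
                                    m$cell_type == tr@panel@targetClass])
    is_desc <- vapply(tr@queryBarcodes, function(b)
        any(vapply(target_clades, function(cl) startsWith(b, cl),
                   logical(1L))), logical(1L))
    matched <- tr@queryBarcodes %in% names(tr@matches)
    tp <- sum(matched & is_desc); fp <- sum(matched & !is_desc)
    fn <- sum(!matched & is_desc); tn <- sum(!matched & !is_desc)
    list(precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
         tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Serialize simulated ground truth
#'
#' The lineage tree is written as a parent-map TSV (`node`, `parent`,
#' `generation`, `clade`, `cell_type`, `reporter_tag`, `timepoint`) and
#' the rest (config, variant origins, per-cell heteroplasmies) as JSON.
#'
#' @param truth A [MitoSimTruth-class] object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeSimTruth <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- truth@meta
    tree <- data.frame(node = rownames(m), parent = truth@parent,
                       as.data.frame(m), stringsAsFactors = FALSE)
    write.table(tree, file.path(dir, "tree.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    obj <- list(config = truth@config,
                reference = list(name = truth@reference@name,
                                 sequence = as.character(
                                     refSequence(truth@reference))),
                origin = as.data.frame(truth@origin),
                het = lapply(truth@het, as.list))  # keep variant names
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA),
               file.path(dir, "truth.json"))
    invisible(dir)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(dir) {
    tree <- read.delim(file.path(dir, "tree.tsv"), sep = "\t",
                       colClasses = "character", na.strings = "NA")
    obj <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    nodes <- tree$node
    meta <- DataFrame(generation = as.integer(tree$generation),
                      clade = tree$clade, cell_type = tree$cell_type,
                      reporter_tag = as.logical(tree$reporter_tag),
                      timepoint = tree$timepoint, row.names = nodes)
    het <- lapply(obj$het, function(h) {
        v <- unlist(h)
        if (is.null(v)) setNames(numeric(), character()) else v
    })[nodes]
    names(het) <- nodes
    og <- as.data.frame(obj$origin)
    origin <- DataFrame(variant_id = og$variant_id,
                        position = as.integer(og$position), ref = og$ref,
                        alt = og$alt, origin_node = og$origin_node,
                        origin_generation = as.integer(og$origin_generation),
                        row.names = og$variant_id)
    new("MitoSimTruth",
        parent = setNames(tree$parent, nodes), het = het, meta = meta,
        origin = origin,
        reference = referenceMito(obj$reference$name,
                                  obj$reference$sequence),
        config = obj$config)
}
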