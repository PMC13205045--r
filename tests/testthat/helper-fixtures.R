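# Fixtures are built in code; nothing is read from disk.

# short variant ids used throughout the toy fixtures
.VAR <- c(a = "10_A>G", b = "20_C>T", c = "30_G>A", d = "40_T>C",
          e = "50_A>C", f = "60_C>G")

varid <- function(letters) unname(.VAR[letters])

# Build a MitoSNPMatrix directly from per-cell SNP letter sets.
makeSNPMatrix <- function(profiles, cell_type, sample_id = "s1",
                          cluster_id = NULL, reporter_tag = NA) {
    bc <- names(profiles)
    calls <- do.call(rbind, lapply(bc, function(b) {
        ids <- varid(profiles[[b]])
        if (!length(ids)) return(NULL)
        v <- parseVariantID(ids)
        data.frame(variant_id = ids, barcode = b, position = v$position,
                   ref = v$ref, alt = v$alt, alt_count = 5L, coverage = 100L,
                   vaf = 0.05, mean_quality = 37, stringsAsFactors = FALSE)
    }))
    ann <- data.frame(barcode = bc, sample_id = sample_id,
                      cell_type = cell_type,
                      cluster_id = if (is.null(cluster_id)) cell_type
                                   else cluster_id,
                      reporter_tag = reporter_tag,
                      stringsAsFactors = FALSE)
    buildSNPMatrix(calls, annotations = ann, barcodes = bc)
}

# The 4-cell worked example: two target cells sharing {a,b} with private
# third SNPs, two non-target cells that each carry only part of any triple.
toyFixture <- function() {
    makeSNPMatrix(
        profiles = list(T1 = c("a", "b", "c"), T2 = c("a", "b", "d"),
                        N1 = c("a", "b"), N2 = c("c", "d")),
        cell_type = c("target", "target", "other", "other"))
}

toyQuery <- function() {
    makeSNPMatrix(
        profiles = list(P1 = c("a", "b", "c", "e"), P2 = c("a", "d"),
                        P3 = c("b", "c")),
        cell_type = c("other", "other", "other"), sample_id = "query")
}

# Random binary SNP instance for oracle-equivalence and property tests.
randomInstance <- function(seed, max_cells = 30L, max_vars = 12L) {
    set.seed(seed)
    n_cells <- sample(4:max_cells, 1L)
    n_vars <- sample(4:max_vars, 1L)
    density <- runif(1L, 0.1, 0.6)
    pos <- sort(sample(500L, n_vars))
    ref <- sample(c("A", "C", "G", "T"), n_vars, replace = TRUE)
    alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    vid <- paste0(pos, "_", ref, ">", alt)
    bc <- sprintf("cell%02d", seq_len(n_cells))
    pres <- matrix(runif(n_vars * n_cells) < density, n_vars, n_cells)
    idx <- which(pres, arr.ind = TRUE)
    n_target <- sample(2:(n_cells - 1L), 1L)
    types <- c(rep("target", n_target), rep("other", n_cells - n_target))
    calls <- data.frame(variant_id = vid[idx[, 1L]], barcode = bc[idx[, 2L]],
                        position = pos[idx[, 1L]], ref = ref[idx[, 1L]],
                        alt = alt[idx[, 1L]], alt_count = 5L,
                        coverage = 100L, vaf = 0.05, mean_quality = 37,
                        stringsAsFactors = FALSE)
    ann <- data.frame(barcode = bc, sample_id = "s1", cell_type = types,
                      cluster_id = types, reporter_tag = NA,
                      stringsAsFactors = FALSE)
    buildSNPMatrix(calls, annotations = ann, barcodes = bc)
}

tripleKeys <- function(d) {
    if (nrow(d) == 0L) return(character())
    apply(d[, c("snp1", "snp2", "snp3")], 1L, function(r)
        paste(sort(r), collapse = "|"))
}

# Random allele-count object for round-trip property tests.
randomACS <- function(seed, L = 80L, n_cells = 3L, with_qual = TRUE) {
    set.seed(seed)
    ref <- referenceMito("chrM",
                         paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = ""))
    bc <- sprintf("bc%02d", seq_len(n_cells))
    counts <- list(); quals <- list()
    for (b in c("A", "C", "G", "T")) {
        nnz <- sample(5:20, 1L)
        i <- sample(L, nnz); j <- sample(n_cells, nnz, replace = TRUE)
        counts[[b]] <- Matrix::sparseMatrix(
            i = i, j = j, x = rpois(nnz, 8) + 1, dims = c(L, n_cells),
            dimnames = list(NULL, bc))
        q <- counts[[b]]
        q@x <- round(runif(length(q@x), 10, 45), 3L)
        quals[[b]] <- q
    }
    MitoAlleleCounts(counts, ref,
                     qualities = if (with_qual) quals else NULL)
}

# Allele counts with one engineered site, for threshold tests.
# ref G at position 100; alt A with the given counts/quality.
siteACS <- function(alt_count, coverage, qual, L = 200L) {
    seqs <- rep("G", L)
    ref <- referenceMito("chrM", paste(seqs, collapse = ""))
    mk <- function(x) Matrix::sparseMatrix(i = integer(), j = integer(),
                                           x = numeric(), dims = c(L, 1L),
                                           dimnames = list(NULL, "cell1"))
    counts <- list(A = mk(), C = mk(), G = mk(), T = mk())
    counts$A[100L, 1L] <- alt_count
    counts$G[100L, 1L] <- coverage - alt_count
    quals <- list(A = mk(), C = mk(), G = mk(), T = mk())
    quals$A[100L, 1L] <- qual
    quals$G[100L, 1L] <- 37
    MitoAlleleCounts(counts, ref, qualities = quals)
}

# Small simulation setup used by several suites.
smallSimConfig <- function(seed, n_pre = 50L, n_post = 70L,
                           readout = list()) {
    rd <- list(mean_coverage = 100, n_background_sites = 40L)
    rd[names(readout)] <- readout
    simConfig(seed = seed, n_generations = 10L, clade_generation = 2L,
              clade_types = c("hepatocyte", "cholangiocyte", "B_cell",
                              "T_cell"),
              mutation_rate = 1, n_germline = 4L,
              sampling = list(
                  pre = list(generation = 8L, n_cells = n_pre,
                             expansion = NULL),
                  post = list(generation = 10L, n_cells = n_post,
                              expansion = c(hepatocyte = 2))),
              readout = rd)
}

# Hand-built two-generation ground truth with chosen heteroplasmies.
handTruth <- function(h_by_cell, cell_type = NULL, timepoint = NULL) {
    cells <- names(h_by_cell)
    nodes <- c("R", cells)
    het <- c(list(R = setNames(numeric(), character())), h_by_cell)
    names(het) <- nodes
    vid <- unique(unlist(lapply(h_by_cell, names), use.names = FALSE))
    v <- parseVariantID(vid)
    L <- 300L
    refseq <- rep("T", L)
    refseq[v$position] <- v$ref
    if (is.null(cell_type))
        cell_type <- setNames(rep("typeA", length(cells)), cells)
    if (is.null(timepoint))
        timepoint <- setNames(rep("pre", length(cells)), cells)
    meta <- S4Vectors::DataFrame(
        generation = nchar(nodes) - 1L,
        clade = c(NA, substring(cells, 1L, 2L)),
        cell_type = c(NA, cell_type[cells]),
        reporter_tag = c(NA, rep(FALSE, length(cells))),
        timepoint = c(NA, timepoint[cells]), row.names = nodes)
    origin <- S4Vectors::DataFrame(
        variant_id = vid, position = v$position, ref = v$ref, alt = v$alt,
        origin_node = "germline", origin_generation = 0L,
        row.names = vid)
    cfg <- unclass(simConfig(seed = 1L, genome_length = L,
                             clade_generation = 1L,
                             clade_types = c("typeA", "typeB"),
                             n_generations = 4L,
                             sampling = list(pre = list(generation = 2L,
                                                        n_cells = 2L,
                                                        expansion = NULL))))
    new("MitoSimTruth",
        parent = setNames(c(NA_character_,
                            substring(cells, 1L, nchar(cells) - 1L)), nodes),
        het = het, meta = meta, origin = origin,
        reference = referenceMito("chrM_sim", paste(refseq, collapse = "")),
        config = cfg)
}
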