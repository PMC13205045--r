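test_that("with no somatic mutation every cell carries only germline h=1", {
    cfg <- simConfig(seed = 11, n_generations = 6L, clade_generation = 2L,
                     clade_types = c("a", "b", "c", "d"),
                     mutation_rate = 0, n_germline = 2L,
                     sampling = list(pre = list(generation = 6L,
                                                n_cells = 20L,
                                                expansion = NULL)))
    truth <- simulateLineage(cfg)
    expect_equal(nrow(truth@origin), 2L)
    for (h in truth@het) {
        expect_equal(length(h), 2L)
        expect_true(all(h == 1))
    }
})

test_that("absorbing states and subtree privacy hold exactly", {
    cfg <- smallSimConfig(23)
    truth <- simulateLineage(cfg)
    par <- truth@parent
    for (node in names(par)) {
        p <- par[[node]]
        if (is.na(p)) next
        hp <- truth@het[[p]]
        hc <- truth@het[[node]]
        # h = 1 in the parent stays 1 in the child
        ones <- names(hp)[hp == 1]
        expect_true(all(hc[ones] == 1))
        # h = 0 (absent) in the parent stays absent, except new mutations
        new_here <- truth@origin$variant_id[truth@origin$origin_node == node]
        expect_true(all(names(hc) %in% c(names(hp), new_here)))
    }
    # a somatic variant never appears outside the subtree of its origin
    som <- truth@origin[truth@origin$origin_node != "germline", ]
    carriers <- lapply(names(truth@het), function(n)
        names(truth@het[[n]]))
    names(carriers) <- names(truth@het)
    for (i in seq_len(nrow(som))) {
        v <- som$variant_id[i]
        org <- som$origin_node[i]
        has <- names(carriers)[vapply(carriers, function(x) v %in% x,
                                      logical(1L))]
        expect_true(all(startsWith(has, org)))
    }
})

test_that("drift conserves the mean and inflates the variance", {
    set.seed(77)
    draws <- driftHeteroplasmy(rep(0.3, 10000L), 500L)
    se <- sqrt(0.3 * 0.7 / 500) / sqrt(10000L)
    expect_lt(abs(mean(draws) - 0.3), 3 * se)
    # variance grows along lineages for intermediate heteroplasmy
    set.seed(78)
    h <- rep(0.3, 4000L)
    var_at <- numeric(12L)
    for (g in 1:12) {
        h <- driftHeteroplasmy(h, 100L)
        var_at[g] <- var(h)
    }
    expect_gt(var_at[8L], var_at[2L])
    expect_gt(var_at[12L], var_at[4L])
})

test_that("identical configs give byte-identical serialized output", {
    run <- function() {
        sim <- simulateDataset(smallSimConfig(31, n_pre = 20L,
                                              n_post = 25L))
        d <- tempfile()
        dir.create(d)
        writeAlleleCounts(sim$counts, file.path(d, "counts"), "mtx_dir")
        writeCellAnnotations(sim$annotations, file.path(d, "ann.tsv"))
        writeSimTruth(sim$truth, file.path(d, "truth"))
        d
    }
    d1 <- run(); d2 <- run()
    files <- list.files(d1, recursive = TRUE)
    expect_true(length(files) >= 7L)
    for (fn in files)
        expect_identical(readBin(file.path(d1, fn), "raw", 1e7),
                         readBin(file.path(d2, fn), "raw", 1e7))
})

test_that("ground truth round-trips through its serialized form", {
    truth <- simulateLineage(smallSimConfig(41, n_pre = 15L, n_post = 15L))
    d <- tempfile()
    writeSimTruth(truth, d)
    back <- readSimTruth(d)
    expect_identical(back@parent, truth@parent)
    expect_equal(back@het, truth@het)
    expect_identical(as.data.frame(back@meta), as.data.frame(truth@meta))
    expect_identical(back@origin$variant_id, truth@origin$variant_id)
    expect_identical(as.character(refSequence(back@reference)),
                     as.character(refSequence(truth@reference)))
})

test_that("timepoint sampling follows the multinomial expectation", {
    cfg <- simConfig(seed = 53, n_generations = 12L, clade_generation = 2L,
                     clade_types = c("target", "o1", "o2", "o3"),
                     mutation_rate = 0.2, n_germline = 2L,
                     sampling = list(
                         pre = list(generation = 10L, n_cells = 300L,
                                    expansion = NULL),
                         post = list(generation = 12L, n_cells = 1000L,
                                     expansion = c(target = 3))),
        readout = list(n_background_sites = 10L))
    truth <- simulateLineage(cfg)
    s <- sampleCells(truth)
    # proportional sampling at the pre timepoint: ~1/4 per clade
    pre_frac <- mean(s$pre$annotations$cell_type == "target")
    se_pre <- sqrt(0.25 * 0.75 / 300)
    expect_lt(abs(pre_frac - 0.25), 3 * se_pre)
    # weighted sampling: expected fraction w*s / sum(w*s) = 3/6 = 0.5
    post_frac <- mean(s$post$annotations$cell_type == "target")
    se_post <- sqrt(0.5 * 0.5 / 1000)
    expect_lt(abs(post_frac - 0.5), 3 * se_post)
    # expansion factor 0 removes a clade from the sample entirely
    cfg0 <- simConfig(seed = 54, n_generations = 8L, clade_generation = 2L,
                      clade_types = c("target", "o1", "o2", "o3"),
                      mutation_rate = 0.2, n_germline = 2L,
                      sampling = list(
                          post = list(generation = 8L, n_cells = 50L,
                                      expansion = c(target = 0))))
    s0 <- sampleCells(simulateLineage(cfg0))
    expect_false("target" %in% s0$post$annotations$cell_type)
})

test_that("the readout reproduces heteroplasmy without noise", {
    h <- list(R0 = c("10_T>A" = 1, "50_T>C" = 0.5),
              R1 = c("10_T>A" = 1))
    truth <- handTruth(h)
    cfg <- unclass(simConfig(seed = 3))
    cfg$genome_length <- 300L
    cfg$readout <- list(mean_coverage = 400, dispersion = 1e6,
                        error_rate = 0, dropout = 0,
                        quality_mean = 37, quality_sd = 0,
                        error_quality_mean = 25, error_quality_sd = 0,
                        n_background_sites = 5L)
    ro <- simulateReadout(truth, c("R0", "R1"), cfg)
    acs <- ro$counts
    cov <- siteCoverage(acs)
    # h = 1, no error: VAF exactly 1 at the site
    expect_equal(as.numeric(alleleCounts(acs, "A")[10, "R0"]),
                 as.numeric(cov[10, "R0"]))
    expect_gt(as.numeric(cov[10, "R0"]), 0)
    # h = 0, no error: zero alt reads anywhere off the true variants
    expect_equal(as.numeric(alleleCounts(acs, "C")[50, "R1"]), 0)
    expect_equal(sum(alleleCounts(acs, "G")), 0)
    # h = 0.5: mean observed VAF within 3 SE of 0.5
    vaf <- as.numeric(alleleCounts(acs, "C")[50, "R0"]) /
        as.numeric(cov[50, "R0"])
    expect_lt(abs(vaf - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("the mean observed VAF tracks h across many cells", {
    h <- rep(list(c("30_T>G" = 0.5)), 2L)
    names(h) <- c("R0", "R1")
    truth <- handTruth(h)
    cfg <- unclass(simConfig(seed = 5))
    cfg$genome_length <- 300L
    cfg$readout <- list(mean_coverage = 200, dispersion = 1e6,
                        error_rate = 0, dropout = 0,
                        quality_mean = 37, quality_sd = 0,
                        error_quality_mean = 25, error_quality_sd = 0,
                        n_background_sites = 0L)
    # replicate the readout across seeds to average 100 draws
    vafs <- vapply(1:50, function(s) {
        cfg$seed <- s
        ro <- simulateReadout(truth, c("R0", "R1"), cfg)
        cnt <- alleleCounts(ro$counts, "G")[30, ]
        cov <- siteCoverage(ro$counts)[30, ]
        mean(as.numeric(cnt) / as.numeric(cov))
    }, numeric(1L))
    se <- sqrt(0.25 / 200) / sqrt(100)
    expect_lt(abs(mean(vafs) - 0.5), 3 * se)
})

test_that("with clean deep reads, calling recovers the truth exactly", {
    cfg <- smallSimConfig(67, n_pre = 30L, n_post = 30L,
                          readout = list(mean_coverage = 2000,
                                         dispersion = 1e6,
                                         error_rate = 0, dropout = 0,
                                         quality_sd = 0))
    sim <- simulateDataset(cfg)
    calls <- callVariants(sim$counts)
    key_called <- paste(calls$barcode, calls$variant_id)
    truth <- sim$truth
    cells <- colnames(sim$counts)
    for (b in cells) {
        h <- truth@het[[b]]
        # every variant above the VAF threshold must be called
        expect_true(all(paste(b, names(h)[h > 0.015]) %in% key_called))
    }
    # and nothing outside the truth may be called
    key_true <- unlist(lapply(cells, function(b)
        paste(b, names(truth@het[[b]]))))
    expect_true(all(key_called %in% key_true))
})

test_that("tracing metrics match a hand-built confusion table", {
    h <- list("R00" = c("10_T>A" = 1), "R01" = c("10_T>A" = 1),
              "R10" = c("20_T>C" = 1), "R11" = c("20_T>C" = 1))
    types <- setNames(c("chol", "chol", "hep", "hep"), names(h))
    truth <- handTruth(h, cell_type = types)
    panel <- new("SNPPanelSet", targetClass = "chol", sampleID = "pre",
                 triples = data.frame(primary = "10_T>A",
                                      secondary = "20_T>C",
                                      tertiary = "30_T>G",
                                      target_support = 1L),
                 anchoring = setNames(integer(), character()),
                 coverage = 0, shortfall = FALSE, nTarget = 2L,
                 params = list())
    mk_tr <- function(matches) new(
        "TraceResult", panel = panel, querySample = "q",
        queryBarcodes = names(h), matches = matches,
        clusterCounts = setNames(integer(), character()),
        tagCounts = c(tagged = 0L, untagged = 0L,
                      unknown = as.integer(length(matches))))
    # one true descendant matched, one false match
    ev <- evaluateTracing(mk_tr(list(R00 = 1L, R10 = 1L)), truth)
    expect_equal(ev$precision, 0.5)
    expect_equal(ev$recall, 0.5)
    expect_equal(ev[c("tp", "fp", "fn", "tn")],
                 list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
    # nothing matched: precision undefined, recall zero
    ev0 <- evaluateTracing(mk_tr(list()), truth)
    expect_true(is.na(ev0$precision))
    expect_equal(ev0$recall, 0)
    # everything matched correctly: precision 1
    ev1 <- evaluateTracing(mk_tr(list(R00 = 1L, R01 = 1L)), truth)
    expect_equal(ev1$precision, 1)
    expect_equal(ev1$recall, 1)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(copy_number = 1L), "copy_number")
    expect_error(simConfig(readout = list(error_rate = 0.3)), "error_rate")
    expect_error(simConfig(clade_generation = 2L), "clade_types")
    expect_error(simConfig(
        sampling = list(pre = list(generation = 30L, n_cells = 10L,
                                   expansion = NULL))), "n_generations")
    expect_error(simConfig(
        sampling = list(pre = list(generation = 21L, n_cells = 10L,
                                   expansion = c(platelet = 2)))),
        "platelet")
    # position exhaustion: tiny genome cannot host the requested variants
    cfg <- simConfig(seed = 2, genome_length = 40L, n_generations = 8L,
                     clade_generation = 2L,
                     clade_types = c("a", "b", "c", "d"),
                     mutation_rate = 5, n_germline = 2L,
                     sampling = list(pre = list(generation = 8L,
                                                n_cells = 40L,
                                                expansion = NULL)),
                     readout = list(n_background_sites = 0L))
    expect_error(simulateLineage(cfg), "unused genome positions")
})
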