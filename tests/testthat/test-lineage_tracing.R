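test_that("tracing matches exactly the cells carrying a full triple", {
    ref <- toyFixture()
    panel <- discoverPanels(ref, "target")
    query <- toyQuery()
    tr <- tracePanels(panel, query)
    expect_equal(names(traceMatches(tr)), "P1")
    # P1 carries {a,b,c} = one of the two triples
    tri <- panelTriples(panel)[traceMatches(tr)$P1, ]
    expect_setequal(unlist(tri[c("primary", "secondary", "tertiary")]),
                    varid(c("a", "b", "c")))
    # containment soundness for every reported match
    for (b in names(traceMatches(tr)))
        for (ix in traceMatches(tr)[[b]]) {
            ids <- unlist(panelTriples(panel)[ix, c("primary", "secondary",
                                                    "tertiary")])
            expect_true(all(presence(query)[ids, b]))
        }
})

test_that("a cell carrying several triples is listed once with all indices", {
    ref <- toyFixture()
    panel <- discoverPanels(ref, "target")
    query <- makeSNPMatrix(
        profiles = list(Q1 = c("a", "b", "c", "d"), Q2 = "e"),
        cell_type = c("other", "other"), sample_id = "query")
    tr <- tracePanels(panel, query)
    expect_equal(length(traceMatches(tr)), 1L)
    expect_setequal(traceMatches(tr)$Q1, c(1L, 2L))
})

test_that("tracing degenerate cases behave", {
    ref <- toyFixture()
    panel <- discoverPanels(ref, "target")
    # no shared variants with the panel
    far <- makeSNPMatrix(profiles = list(Z1 = "f"), cell_type = "other",
                         sample_id = "query")
    expect_equal(length(traceMatches(tracePanels(panel, far))), 0L)
    # empty panel warns and matches nothing
    pe <- greedySelectPanels(enumerateValidTriples(ref, "target")[0, ],
                             ref, "target")
    expect_warning(tre <- tracePanels(pe, toyQuery()), "no triples")
    expect_equal(length(traceMatches(tre)), 0L)
    # self-trace recovers at least the anchored cells
    trs <- tracePanels(panel, ref)
    expect_true(all(names(anchoring(panel)) %in% names(traceMatches(trs))))
})

test_that("cluster distribution tabulates matched cells per cluster", {
    profiles <- c(lapply(sprintf("m%d", 1:3), function(i) c("a", "b", "c")),
                  lapply(sprintf("u%d", 1:7), function(i) "e"))
    names(profiles) <- c(sprintf("m%d", 1:3), sprintf("u%d", 1:7))
    query <- makeSNPMatrix(profiles, cell_type = rep("other", 10L),
                           cluster_id = rep("A", 10L), sample_id = "query")
    ref <- toyFixture()
    panel <- discoverPanels(ref, "target")
    tr <- tracePanels(panel, query)
    ann <- cbind(barcode = cellBarcodes(query), cellAnnotations(query))
    d <- clusterDistribution(tr, ann)
    expect_equal(d[d$cluster_id == "A", c("matched", "size", "fraction")],
                 data.frame(matched = 3L, size = 10L, fraction = 0.3),
                 ignore_attr = TRUE)
    # no matches: an all-zero table
    far <- makeSNPMatrix(profiles = list(Z1 = "f"), cell_type = "other",
                         cluster_id = "B", sample_id = "query")
    trf <- tracePanels(panel, far)
    df <- clusterDistribution(trf, cbind(barcode = "Z1",
                                         cellAnnotations(far)))
    expect_equal(df$matched, 0L)
    # matches without annotations fall into the unassigned row
    du <- clusterDistribution(tr, data.frame(barcode = "nobody",
                                             cluster_id = "C"))
    expect_equal(du$cluster_id[du$matched == 3L], "unassigned")
})

test_that("tag concordance splits matched cells by reporter state", {
    profiles <- lapply(setNames(nm = sprintf("m%d", 1:5)),
                       function(i) c("a", "b", "c"))
    query <- makeSNPMatrix(profiles, cell_type = rep("other", 5L),
                           sample_id = "query",
                           reporter_tag = c(TRUE, TRUE, FALSE, NA, TRUE))
    ref <- toyFixture()
    panel <- discoverPanels(ref, "target")
    tr <- tracePanels(panel, query)
    ann <- cbind(barcode = cellBarcodes(query), cellAnnotations(query))
    expect_equal(tagConcordance(tr, ann),
                 c(tagged = 3L, untagged = 1L, unknown = 1L))
    # no tags recorded anywhere
    ann$reporter_tag <- NA
    expect_equal(tagConcordance(tr, ann),
                 c(tagged = 0L, untagged = 0L, unknown = 5L))
    # no matches at all
    far <- makeSNPMatrix(profiles = list(Z1 = "f"), cell_type = "other")
    trf <- tracePanels(panel, far)
    expect_equal(tagConcordance(trf, ann),
                 c(tagged = 0L, untagged = 0L, unknown = 0L))
})

.enrichmentFixture <- function(rep_seed, n, m, n_clusters = 8L) {
    set.seed(rep_seed)
    cl <- sample(paste0("cl", seq_len(n_clusters)), n, TRUE)
    ann <- data.frame(barcode = paste0("c", seq_len(n)), cluster_id = cl,
                      sample_id = "s", cell_type = NA, reporter_tag = NA)
    matched <- sample(ann$barcode, m)
    panel <- new("SNPPanelSet", targetClass = "t", sampleID = "s",
                 triples = data.frame(primary = "1_A>C",
                                      secondary = "2_A>C",
                                      tertiary = "3_A>C",
                                      target_support = 1L),
                 anchoring = setNames(integer(), character()),
                 coverage = 0, shortfall = FALSE, nTarget = 1L,
                 params = list())
    tr <- new("TraceResult", panel = panel, querySample = "s",
              queryBarcodes = ann$barcode,
              matches = setNames(lapply(matched, function(x) 1L), matched),
              clusterCounts = setNames(integer(), character()),
              tagCounts = c(tagged = 0L, untagged = 0L,
                            unknown = as.integer(m)))
    list(tr = tr, ann = ann, matched = matched)
}

test_that("total enrichment in a minority cluster gives a small p", {
    fx <- .enrichmentFixture(5, n = 100, m = 0L)
    # put all matches inside cl1 cells
    in1 <- fx$ann$barcode[fx$ann$cluster_id == "cl1"][1:8]
    fx$tr@matches <- setNames(lapply(in1, function(x) 1L), in1)
    enr <- permutationTestEnrichment(fx$tr, fx$ann, "cl1",
                                     n_perm = 1000L, seed = 99L)
    expect_equal(enr$observed, 1)
    expect_lt(enr$p_value, 0.05)
    # identical seed, identical result
    enr2 <- permutationTestEnrichment(fx$tr, fx$ann, "cl1",
                                      n_perm = 1000L, seed = 99L)
    expect_identical(enr, enr2)
})

test_that("degenerate enrichment inputs behave", {
    fx <- .enrichmentFixture(6, n = 60, m = 10L)
    all_cl <- unique(fx$ann$cluster_id)
    enr <- permutationTestEnrichment(fx$tr, fx$ann, all_cl,
                                     n_perm = 200L, seed = 1L)
    expect_equal(enr$observed, 1)
    expect_equal(enr$null_mean, 1)
    expect_equal(enr$p_value, 1)
    expect_error(permutationTestEnrichment(fx$tr, fx$ann, "no_cluster",
                                           n_perm = 10L), "expected")
    fx0 <- .enrichmentFixture(7, n = 60, m = 10L)
    fx0$tr@matches <- list()
    expect_warning(
        enr0 <- permutationTestEnrichment(fx0$tr, fx0$ann, "cl1",
                                          n_perm = 10L, seed = 1L),
        "no matched")
    expect_equal(enr0$p_value, 1)
})

test_that("the permutation p-value is uniform under a true null", {
    ps <- vapply(1:200, function(s) {
        fx <- .enrichmentFixture(s, n = 400, m = 100L)
        permutationTestEnrichment(fx$tr, fx$ann,
                                  c("cl1", "cl2", "cl3"),
                                  n_perm = 199L, seed = s + 1L)$p_value
    }, numeric(1L))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("trace results serialize to stable bytes and round-trip", {
    panel <- discoverPanels(toyFixture(), "target")
    tr <- tracePanels(panel, toyQuery())
    f1 <- tempfile(); f2 <- tempfile()
    writeTraceResult(tr, f1)
    writeTraceResult(tracePanels(panel, toyQuery()), f2)
    expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
    back <- readTraceResult(f1)
    expect_identical(traceMatches(back), traceMatches(tr))
    expect_identical(back@queryBarcodes, tr@queryBarcodes)
    expect_identical(back@tagCounts, tr@tagCounts)
    expect_identical(panelTriples(back@panel), panelTriples(tr@panel))
})
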