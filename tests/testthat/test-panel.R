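test_that("representative sampling covers structure and avoids duplicates", {
    set.seed(89)
    g <- matrix(rbinom(60 * 8, 2, .5), 60, 8)
    g[, 2] <- g[, 1]    # exact duplicate pair
    gm <- makeGM(g, breed = "B1")
    picks <- representativeSamples(gm, 4, seed = 1)
    expect_length(picks, 4)
    expect_false(all(c("s001", "s002") %in% picks))
    # requesting everything returns everything
    expect_setequal(representativeSamples(gm, 8, seed = 1), sampleIds(gm))
    # a breed made of two drifted subclusters gets both represented
    mdl <- breedModel(n_snps = 400, n_chr = 4, breed_names = c("P", "Q"),
                      sample_sizes = c(12, 12), drift = c(.35, .35),
                      n_planted = 0, missing_rate = 0)
    hit <- 0
    for (s in 1:10) {
        sim <- simulateBreeds(mdl, seed = 100 + s)
        sub <- GenotypeData(genoMatrix(sim$gm), markerMap(sim$gm),
            data.frame(sample_id = sampleIds(sim$gm), breed = "ONE"))
        ids <- representativeSamples(sub, 6, similarity_threshold = 0.78,
                                     seed = s)
        from_p <- grepl("^P_", ids); from_q <- grepl("^Q_", ids)
        if (any(from_p) && any(from_q)) hit <- hit + 1
    }
    expect_gte(hit, 9)
})

test_that("panel QC applies the MAF boundary and the LD/missing contracts", {
    set.seed(97)
    n <- 50
    g <- matrix(rbinom(40 * n, 2, 0.5), 40, n)
    # plant exact MAF values just each side of the threshold (0.29 / 0.31)
    g[1, ] <- c(rep(2L, 13), rep(1L, 3), rep(0L, n - 16))   # maf 0.29
    g[2, ] <- c(rep(2L, 15), rep(1L, 1), rep(0L, n - 16))   # maf 0.31
    g[3, 1] <- NA                                            # missing call
    gm <- makeGM(g, breed = "B1")
    out <- panelQC(gm, maf = 0.3, r2 = 0.2)
    expect_false("m0001" %in% markerMap(out)$marker)
    expect_true("m0002" %in% markerMap(out)$marker)
    expect_false("m0003" %in% markerMap(out)$marker)
    expect_false(anyNA(genoMatrix(out)))
    r2 <- oracleAllR2(genoMatrix(out))
    diag(r2) <- 0
    expect_true(all(r2 <= 0.2 | is.na(r2)))
})

test_that("Fst preselection ranks, unions and tracks provenance", {
    mdl <- breedModel(n_snps = 300, n_chr = 6,
                      breed_names = c("F", "X", "Y"),
                      sample_sizes = c(20, 20, 20), drift = c(.2, .2, .2),
                      n_planted = 0, missing_rate = 0)
    sim <- simulateBreeds(mdl, seed = 13)
    g <- genoMatrix(sim$gm)
    # plant a fixed difference: focal all alt, others all ref
    g[7, ] <- ifelse(breeds(sim$gm) == "F", 2L, 0L)
    gm <- GenotypeData(g, markerMap(sim$gm),
        data.frame(sample_id = sampleIds(sim$gm), breed = breeds(sim$gm)))
    pre <- fstPreselect(gm, "F", top_frac = 0.05)
    planted_row <- pre[pre$marker == markerMap(gm)$marker[7], ]
    expect_equal(nrow(planted_row), 1L)
    expect_equal(sort(strsplit(planted_row$fst_pairs, ",")[[1]]),
                 c("F-X", "F-Y"))
    # per-pair count is exactly ceil(top_frac * m); union bounded
    expect_lte(nrow(pre), 2 * ceiling(0.05 * nrow(gm)))
    one_pair <- fstPreselect(gm[, breeds(gm) != "Y"], "F", top_frac = 0.05)
    expect_equal(nrow(one_pair), ceiling(0.05 * nrow(gm)))
})

test_that("CDA selection finds a separating variable and respects coding", {
    set.seed(101)
    n_per <- 20
    br <- rep(c("F", "X", "Y", "Z"), each = n_per)
    m <- 12
    g <- matrix(rbinom(m * length(br), 2, 0.5), m, length(br))
    g[5, ] <- ifelse(br == "F", 2L, 0L)   # fully separating variable
    gm <- makeGM(g, breed = br)
    sel <- cdaSelect(gm, "F")
    expect_true("m0005" %in% sel$marker)
    # flipping that SNP's allele coding must not change the selection
    g2 <- g; g2[5, ] <- 2L - g2[5, ]
    sel2 <- cdaSelect(makeGM(g2, breed = br), "F")
    expect_setequal(sel$marker, sel2$marker)
    # focal identical in distribution to the rest: nothing selected
    g3 <- matrix(rbinom(m * length(br), 2, 0.5), m, length(br))
    sel3 <- cdaSelect(makeGM(g3, breed = br), "F")
    expect_equal(nrow(sel3), 0L)
    # single-SNP chromosomes pass through
    gm4 <- makeGM(g, breed = br, chr = c(rep("1", m - 1), "2"))
    sel4 <- cdaSelect(gm4, "F")
    expect_true("m0012" %in% sel4$marker)
    expect_match(sel4$cda_function[sel4$marker == "m0012"], "passthrough")
})

test_that("buildPanel is deterministic, nested and provenance-complete", {
    fx <- simulateBreedFixture(seed = 1,
        model = breedModel(n_snps = 1500, n_chr = 10,
            breed_names = c("FOCAL", sprintf("BR%02d", 2:6)),
            sample_sizes = c(40, rep(30, 5)),
            drift = c(0.35, runif(5, 0.15, 0.25)), n_planted = 12))
    cfg <- list(train_per_breed = 15, n_validation = 4, val_focal_n = 8,
                val_other_range = c(6, 10), outliers = fx$truth$outliers)
    bp1 <- buildPanel(fx$gm, "FOCAL", split_config = cfg, seed = 3)
    bp2 <- buildPanel(fx$gm, "FOCAL", split_config = cfg, seed = 3)
    expect_identical(panelTable(bp1$panel), panelTable(bp2$panel))
    tab <- panelTable(bp1$panel)
    expect_gt(nrow(tab), 0)
    expect_true(all(nzchar(tab$fst_pairs)))
    expect_true(all(nzchar(tab$cda_function)))
    expect_false(anyDuplicated(tab$marker) > 0)
    # training and validation sets are disjoint
    tr_ids <- sampleIds(bp1$split$training)
    for (v in bp1$split$validation)
        expect_length(intersect(tr_ids, sampleIds(v)), 0)
    # pipeline shrinks the marker set at every stage
    gq <- panelQC(bp1$split$training)
    pre <- fstPreselect(gq, "FOCAL")
    expect_lt(nrow(tab), nrow(pre))
    expect_lt(nrow(pre), nrow(gq))
    expect_lt(nrow(gq), nrow(fx$gm))
})

test_that("binary classification separates classes and validates input", {
    set.seed(103)
    br <- rep(c("F", "X"), each = 15)
    g <- matrix(rbinom(20 * 30, 2, .5), 20, 30)
    g[3, ] <- ifelse(br == "F", 2L, 0L)
    gm <- makeGM(g, breed = br)
    pan <- new("Panel", snps = data.frame(
        marker = c("m0003", "m0007"), chr = "1", pos = c(300L, 700L),
        a1 = "A", a2 = "G", fst_pairs = "F-X", cda_function = "chr1:LD1",
        cda_score = 1), focal = "F")
    rep1 <- classifyBinary(pan, gm, gm)
    expect_equal(rep1@accuracy, 1)
    expect_equal(sum(rep1@confusion), 30)
    gm_onecl <- gm[, br == "F"]
    expect_error(classifyBinary(pan, gm_onecl, gm), "both classes")
})

test_that("aggregate genotypes follow the product approximation", {
    br <- rep(c("F", "X"), each = 10)
    # chromosome 1: three SNPs with focal alt frequencies 0.9, 0.8, 0.95
    freqs_f <- c(0.9, 0.8, 0.95)
    g <- rbind(
        matrix(rbinom(3 * 20, 2, rep(c(freqs_f), 20) *
                      rep(ifelse(br == "F", 1, 0.3), each = 3)), 3),
        ifelse(br == "F", 2L, 0L))
    gm <- makeGM(g, breed = br, chr = c("1", "1", "1", "2"))
    pan <- new("Panel", snps = data.frame(
        marker = sprintf("m%04d", 1:4), chr = c("1", "1", "1", "2"),
        pos = 1:4 * 100000L, a1 = "A", a2 = "G", fst_pairs = "F-X",
        cda_function = "x", cda_score = 1), focal = "F")
    agg <- aggregateGenotypes(pan, gm, "F")
    # single-SNP chromosome reported with a dash
    expect_equal(agg$aggregate[agg$chr == "2"], "-")
    expect_true(is.na(agg$freq_focal[agg$chr == "2"]))
    # product arithmetic on the observed focal frequencies
    gf <- genoMatrix(gm)[1:3, br == "F"]
    p_obs <- rowMeans(gf) / 2
    use_alt <- p_obs >= 0.5
    want <- prod(ifelse(use_alt, p_obs, 1 - p_obs))
    expect_equal(agg$freq_focal[agg$chr == "1"], want, tolerance = 1e-12)
    # a focal breed monomorphic at every chromosome SNP has frequency 1
    g2 <- rbind(ifelse(br == "F", 2L, 0L), ifelse(br == "F", 2L, 1L))
    gm2 <- makeGM(g2, breed = br, chr = c("1", "1"))
    pan2 <- new("Panel", snps = data.frame(
        marker = c("m0001", "m0002"), chr = "1", pos = c(1e5L, 2e5L),
        a1 = "A", a2 = "G", fst_pairs = "F-X", cda_function = "x",
        cda_score = 1), focal = "F")
    agg2 <- aggregateGenotypes(pan2, gm2, "F")
    expect_equal(agg2$freq_focal, 1)
})

test_that("clustering validation isolates a separable focal breed", {
    set.seed(107)
    br <- rep(c("F", "X", "Y"), each = 10)
    g <- matrix(rbinom(15 * 30, 2, .5), 15, 30)
    g[1:4, ] <- matrix(rep(ifelse(br == "F", 2L, 0L), each = 4), 4)
    gm <- makeGM(g, breed = br)
    pan <- new("Panel", snps = data.frame(
        marker = sprintf("m%04d", 1:4), chr = "1", pos = 1:4 * 1e5L,
        a1 = "A", a2 = "G", fst_pairs = "F-X", cda_function = "x",
        cda_score = 1), focal = "F")
    repc <- validatePanelClustering(pan, gm)
    expect_true(repc@focalSeparated)
    # all-identical samples: single cluster, flagged as non-separable
    g0 <- matrix(1L, 5, 10)
    gm0 <- makeGM(g0, breed = rep(c("F", "X"), each = 5))
    pan0 <- new("Panel", snps = data.frame(
        marker = sprintf("m%04d", 1:5), chr = "1", pos = 1:5 * 1e5L,
        a1 = "A", a2 = "G", fst_pairs = "F-X", cda_function = "x",
        cda_score = 1), focal = "F")
    rep0 <- validatePanelClustering(pan0, gm0)
    expect_false(rep0@focalSeparated)
})
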