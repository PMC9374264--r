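test_that("hand-written ped/map fixture parses into the expected codes", {
    tmp <- withr::local_tempdir()
    writeLines(c("1\tsnpA\t0\t100", "1\tsnpB\t0\t200", "1\tsnpC\t0\t300"),
               file.path(tmp, "fix.map"))
    writeLines(c("B1 x 0 0 0 -9 A A A G G G",
                 "B1 y 0 0 0 -9 A G 0 0 G G"),
               file.path(tmp, "fix.ped"))
    gm <- readGenotypes(file.path(tmp, "fix.ped"))
    expect_equal(dim(genoMatrix(gm)), c(3L, 2L))
    # alleles assigned alphabetically: a2 = G
    expect_equal(unname(genoMatrix(gm)[, "x"]), c(0L, 1L, 2L))
    expect_equal(unname(genoMatrix(gm)[, "y"]), c(1L, NA, 2L))
    expect_equal(unname(breeds(gm)), c("B1", "B1"))
})

test_that("malformed ped lines and marker-count mismatches are named", {
    tmp <- withr::local_tempdir()
    writeLines(c("1\tsnpA\t0\t100", "1\tsnpB\t0\t200"),
               file.path(tmp, "bad.map"))
    writeLines(c("B1 x 0 0 0 -9 A A G G",
                 "B1 y 0 0 0 -9 A A G"),
               file.path(tmp, "bad.ped"))
    expect_error(readGenotypes(file.path(tmp, "bad.ped")), "line 2")
})

test_that("write/read round trips are lossless", {
    set.seed(41)
    g <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 20, 3)
    # guarantee both alleles observed so .ped orientation is recoverable
    g[, 1] <- 1L
    gm <- makeGM(g, breed = c("B1", "B1", "B2"))
    tmp <- withr::local_tempdir()
    writeGenotypes(gm, file.path(tmp, "rt"), "plink")
    back <- readGenotypes(file.path(tmp, "rt.ped"))
    expect_identical(genoMatrix(back), genoMatrix(gm))
    expect_identical(breeds(back), breeds(gm))
    writeGenotypes(gm, file.path(tmp, "rt2"), "vcf")
    back2 <- readGenotypes(file.path(tmp, "rt2.vcf"), breed = breeds(gm))
    expect_identical(genoMatrix(back2), genoMatrix(gm))
    expect_identical(markerMap(back2), markerMap(gm))
    # missing encodings in the emitted text
    ped_txt <- readLines(file.path(tmp, "rt.ped"))
    vcf_txt <- readLines(file.path(tmp, "rt2.vcf"))
    expect_true(any(grepl(" 0 0", ped_txt)))
    expect_true(any(grepl("\\./\\.", vcf_txt)))
})

test_that("empty marker set still writes valid header-only outputs", {
    gm <- makeGM(matrix(integer(0), 0, 2))
    tmp <- withr::local_tempdir()
    expect_silent(writeGenotypes(gm, file.path(tmp, "empty"), "vcf"))
    txt <- readLines(file.path(tmp, "empty.vcf"))
    expect_match(txt[1], "VCFv4.2")
    expect_length(grep("^#", txt), length(txt))
})

test_that("multi-allelic VCF records are dropped with a warning", {
    tmp <- withr::local_tempdir()
    writeLines(c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tx\ty",
        "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
        "1\t200\tsnpB\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t1/2",
        "1\t300\tsnpC\tA\tG\t.\tPASS\t.\tGT\t1/1\t./."),
        file.path(tmp, "multi.vcf"))
    expect_warning(gm <- readGenotypes(file.path(tmp, "multi.vcf")),
                   "multi-allelic")
    expect_equal(nrow(gm), 2L)
    expect_setequal(markerMap(gm)$marker, c("snpA", "snpC"))
})

test_that("merging is idempotent, flips swapped alleles, rejects disjoint", {
    set.seed(7)
    g <- matrix(sample(0:2, 40, replace = TRUE), 10, 4)
    g[1, ] <- c(0L, 1L, 2L, 1L)
    gm <- makeGM(g, breed = "B1")
    self <- mergeGenotypes(gm, {
        x <- makeGM(g, breed = "B2")
        # rename samples to avoid id clash
        GenotypeData(genoMatrix(x), markerMap(x),
            data.frame(sample_id = paste0("t", 1:4), breed = "B2"))
    })
    expect_identical(markerMap(self)$marker, markerMap(gm)$marker)
    expect_identical(genoMatrix(self)[, 1:4], genoMatrix(gm))
    # swapped a1/a2 at one SNP flips that SNP's codes for b's samples
    mp <- markerMap(gm)
    mp$a1[1] <- "G"; mp$a2[1] <- "A"
    gswap <- g; gswap[1, ] <- 2L - gswap[1, ]
    b <- GenotypeData(gswap, mp,
        data.frame(sample_id = paste0("t", 1:4), breed = "B2"))
    merged <- mergeGenotypes(gm, b)
    expect_identical(unname(genoMatrix(merged)[1, 5:8]), unname(g[1, ]))
    # disjoint marker sets error
    other <- makeGM(matrix(0L, 3, 2), pos = c(11L, 22L, 33L))
    mp2 <- markerMap(other); mp2$marker <- paste0("z", 1:3)
    disj <- GenotypeData(genoMatrix(other), mp2,
        data.frame(sample_id = c("u1", "u2"), breed = "B9"))
    expect_error(mergeGenotypes(gm, disj), "no shared markers")
})

test_that("qcFilter applies every pass in order with correct counts", {
    set.seed(11)
    n <- 100
    g <- matrix(rbinom(20 * n, 2, 0.5), 20, n)
    chr <- rep("1", 20)
    chr[4:5] <- "X"                      # 2 sex-chromosome SNPs
    g[7, seq_len(11)] <- NA              # 89% call rate -> removed
    g[10, ] <- 0L; g[11, ] <- 0L; g[12, ] <- c(1L, rep(0L, n - 1))  # low MAF
    g[, 2] <- g[, 1]                     # duplicate sample pair
    gm <- makeGM(g, chr = chr)
    res <- qcFilter(gm)
    log <- qcLog(res$report)
    expect_equal(log$n_removed[log$reason == "sex-chromosome"], 2L)
    expect_equal(log$n_removed[log$reason == "call-rate" &
                               log$unit == "marker"], 1L)
    expect_equal(log$n_removed[log$reason == "maf"], 3L)
    expect_equal(log$n_removed[log$reason == "duplicate-ibs"], 1L)
    # the earlier duplicate is the one kept
    expect_true("s001" %in% sampleIds(res$gm))
    expect_false("s002" %in% sampleIds(res$gm))
    # idempotence
    res2 <- qcFilter(res$gm)
    expect_identical(genoMatrix(res2$gm), genoMatrix(res$gm))
})

test_that("LD pruning matches the exhaustive pairwise oracle", {
    # two identical columns -> one retained
    g <- rbind(c(0L, 1L, 2L, 0L, 1L), c(0L, 1L, 2L, 0L, 1L))
    gm <- makeGM(g)
    expect_length(ldPrune(gm, 0.3, window_snps = 2, step_snps = 1), 1L)
    # independent columns all retained; planted structure obeys the contract
    set.seed(13)
    base <- matrix(rbinom(10 * 40, 2, 0.5), 10, 40)
    base[2, ] <- base[1, ]                         # perfect LD pair
    base[5, ] <- ifelse(runif(40) < .9, base[4, ], 2L - base[4, ])
    gm2 <- makeGM(base)
    kept <- ldPrune(gm2, 0.3, window_snps = 10, step_snps = 5)
    r2 <- oracleAllR2(base[match(kept, markerMap(gm2)$marker), ,
                           drop = FALSE])
    diag(r2) <- 0
    expect_true(all(r2 < 0.3 | is.na(r2)))
    expect_false("m0002" %in% kept)   # later twin of the perfect-LD pair
    expect_true("m0001" %in% kept)
})

test_that("dropIncompleteMarkers keeps exactly the fully genotyped markers", {
    set.seed(17)
    g <- matrix(rbinom(20 * 10, 2, .5), 20, 10)
    miss <- sample(20, 7)
    for (k in miss) g[k, sample(10, 1)] <- NA
    gm <- makeGM(g)
    out <- dropIncompleteMarkers(gm)
    expect_equal(nrow(out), 13L)
    expect_false(anyNA(genoMatrix(out)))
    # no missing anywhere -> identity
    gm2 <- makeGM(matrix(1L, 4, 3))
    expect_identical(genoMatrix(dropIncompleteMarkers(gm2)), genoMatrix(gm2))
})
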