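test_that("LD decay binning matches direct r2 arithmetic", {
    # duplicated SNP columns: r2 = 1 before adjustment
    g <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L), c(0L, 1L, 2L, 0L, 1L, 2L))
    gm <- makeGM(g, pos = c(1e6L, 2e6L))
    b <- ldDecayBins(gm, bin_edges = c(0.001, 0.5))
    expect_equal(b$r2_adj, 1 - 1 / 6)
    expect_equal(b$n_pairs, 1)
    # hand two-locus table equals the covariance-formula oracle
    g2 <- rbind(c(0L, 1L, 2L, 2L, 0L, 1L, 1L, 2L),
                c(1L, 1L, 2L, 0L, 0L, 2L, 1L, 2L))
    r2_hand <- cov(g2[1, ], g2[2, ])^2 / (var(g2[1, ]) * var(g2[2, ]))
    gm2 <- makeGM(g2, pos = c(1e6L, 2e6L))
    b2 <- ldDecayBins(gm2, bin_edges = c(0.001, 0.5))
    expect_equal(b2$r2_adj + 1 / 8, r2_hand, tolerance = 1e-12)
    # independent simulated SNPs: mean adjusted r2 ~ 0 (raw mean ~ 1/n)
    set.seed(43)
    n <- 100
    gi <- matrix(rbinom(150 * n, 2, .5), 150, n)
    gmi <- makeGM(gi, pos = seq_len(150) * 100000L)
    bi <- suppressWarnings(ldDecayBins(gmi))
    m_adj <- weighted.mean(bi$r2_adj, bi$n_pairs)
    expect_lt(abs(m_adj), 0.01)
})

test_that("Sved-Feldman inversion and limits are exact", {
    bins <- data.frame(c_mean = 0.01, r2_adj = 0.2, n_pairs = 10,
                       t = 1 / 0.02)
    ns <- historicalNe(bins)
    expect_equal(neTable(ns)$ne, (1 / 0.2 - 1) / (4 * 0.01))  # 100
    # r2 -> 1 limit collapses Ne to 0+
    bins2 <- data.frame(c_mean = 0.01, r2_adj = 0.999999, n_pairs = 10,
                        t = 50)
    expect_lt(neTable(historicalNe(bins2))$ne, 1e-3)
    # out-of-range bins are skipped with a warning
    bins3 <- rbind(bins, data.frame(c_mean = 0.02, r2_adj = -0.01,
                                    n_pairs = 5, t = 25))
    expect_warning(out <- historicalNe(bins3), "skipped")
    expect_equal(nrow(neTable(out)), 1L)
})

test_that("linear extrapolation recovers exact and noisy intercepts", {
    t <- seq(2, 60, by = 2)
    exact <- new("NeSeries",
                 bins = data.frame(t = t, ne = 40 + 2 * t, c_mean = 1 / (2 * t),
                                   r2_adj = 0.1, n_pairs = 10),
                 fit = list())
    f <- neFit(extrapolateNe(exact, 54))
    expect_equal(f$intercept, 40, tolerance = 1e-9)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
    const <- new("NeSeries",
                 bins = data.frame(t = t, ne = 75, c_mean = 1 / (2 * t),
                                   r2_adj = .1, n_pairs = 10),
                 fit = list())
    fc <- neFit(extrapolateNe(const, 54))
    expect_equal(fc$slope, 0, tolerance = 1e-9)
    expect_equal(fc$ne_now, 75, tolerance = 1e-9)
    # noisy series: intercept within ~2 SE of truth in most replicates
    set.seed(47)
    cover <- 0
    for (r in 1:50) {
        y <- 40 + 2 * t + rnorm(length(t), 0, 5)
        s <- new("NeSeries", bins = data.frame(t = t, ne = y,
                     c_mean = 1 / (2 * t), r2_adj = .1, n_pairs = 10),
                 fit = list())
        fit <- lm(y ~ t)
        se <- summary(fit)$coefficients[1, 2]
        if (abs(neFit(extrapolateNe(s, 60))$intercept - 40) < 2.6 * se)
            cover <- cover + 1
    }
    expect_gte(cover, 45)
})

test_that("generation counts follow the complete/maximum definitions", {
    ped <- Pedigree(
        id = c("f1", "f2", "g1", "g2", "h", "x"),
        sire = c("0", "0", "f1", "0", "g1", "h"),
        dam = c("0", "0", "f2", "0", "g2", "0"))
    gc <- generationCounts(ped)
    rownames(gc) <- gc$id
    expect_equal(unlist(gc["f1", c("complete", "maximum")]),
                 c(complete = 0L, maximum = 0L))
    expect_equal(unlist(gc["g1", c("complete", "maximum")]),
                 c(complete = 1L, maximum = 1L))
    # one parent with a 3-deep known line, the other unknown -> (0, 3)
    expect_equal(unlist(gc["x", c("complete", "maximum")]),
                 c(complete = 0L, maximum = 3L))
})

test_that("pedigree Ne follows 1/(2*dF) and flags degenerate trends", {
    # mean F by generation (0, 0.0125, 0.025): dF = 0.0125 -> Ne = 40
    ped <- Pedigree(id = sprintf("i%02d", 1:9),
                    sire = c(rep("0", 3), "i01", "i01", "i01",
                             "i04", "i04", "i04"),
                    dam = c(rep("0", 3), "i02", "i02", "i02",
                            "i05", "i05", "i05"))
    counts <- generationCounts(ped)
    f <- setNames(rep(c(0, 0.0125, 0.025), each = 3), counts$id)
    res <- pedigreeNe(ped, inbreeding = f, counts = counts)
    expect_equal(res$delta_f, 0.0125, tolerance = 1e-9)
    expect_equal(res$ne, 40, tolerance = 1e-9)
    expect_error(pedigreeNe(ped, inbreeding = setNames(rep(0, 9), counts$id),
                            counts = counts), "non-positive")
    # a deep full-sib line pushes dF high and Ne toward its 2-boundary
    line <- Pedigree(
        id = c("a", "b", paste0(rep(c("c", "d"), 6), rep(1:6, each = 2))),
        sire = c("0", "0", "a", "a", rep(paste0("c", 1:5), each = 2)),
        dam = c("0", "0", "b", "b", rep(paste0("d", 1:5), each = 2)))
    res2 <- pedigreeNe(line)
    expect_lt(res2$ne, 5)
    expect_gt(res2$ne, 2)
})

test_that("random-mating pedigrees give Ne near census size", {
    set.seed(53)
    ratio <- numeric(30)
    N <- 24; G <- 7
    for (r in 1:30) {
        id <- character(0); sire <- character(0); dam <- character(0)
        prev <- sprintf("g0_%02d", 1:N)
        id <- prev; sire <- rep("0", N); dam <- rep("0", N)
        for (g in 1:G) {
            cur <- sprintf("g%d_%02d", g, 1:N)
            id <- c(id, cur)
            sire <- c(sire, sample(prev, N, replace = TRUE))
            dd <- sample(prev, N, replace = TRUE)
            clash <- dd == sire[(length(sire) - N + 1):length(sire)]
            while (any(clash)) {
                dd[clash] <- sample(prev, sum(clash), replace = TRUE)
                clash <- dd == sire[(length(sire) - N + 1):length(sire)]
            }
            dam <- c(dam, dd)
            prev <- cur
        }
        ped <- Pedigree(id, sire, dam)
        ratio[r] <- pedigreeNe(ped)$ne / N
    }
    expect_lt(abs(mean(ratio) - 1), 0.25)
})

test_that("census Ne formula is exact and bounded", {
    expect_equal(censusNe(10, 150), 37.5)
    expect_equal(censusNe(40, 40), 80)
    for (s in c(1, 5, 80)) for (d in c(3, 50, 200))
        expect_lte(censusNe(s, d), 4 * min(s, d))
    expect_error(censusNe(0, 10))
})

test_that("Ne series is invariant to relabeling and coding flips", {
    set.seed(59)
    g <- matrix(rbinom(60 * 40, 2, .5), 60, 40)
    gm <- makeGM(g, pos = seq_len(60) * 500000L)
    b1 <- suppressWarnings(ldDecayBins(gm))
    b2 <- suppressWarnings(ldDecayBins(makeGM(2L - g,
                                              pos = seq_len(60) * 500000L)))
    b3 <- suppressWarnings(ldDecayBins(gm[, sample(40)]))
    expect_equal(b1$r2_adj, b2$r2_adj, tolerance = 1e-12)
    expect_equal(b1$r2_adj, b3$r2_adj, tolerance = 1e-12)
})
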