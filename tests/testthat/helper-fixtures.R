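# Fixture builders and independent oracles used across the suite.

# Build a GenotypeData from a markers x samples matrix with minimal metadata.
makeGM <- function(geno, chr = "1", pos = NULL, breed = "B1",
                   a1 = "A", a2 = "G") {
    m <- nrow(geno); n <- ncol(geno)
    if (is.null(pos)) pos <- seq_len(m) * 100000L
    chr <- rep_len(chr, m)
    GenotypeData(geno,
        data.frame(marker = sprintf("m%04d", seq_len(m)), chr = chr,
                   pos = as.integer(pos), a1 = rep_len(a1, m),
                   a2 = rep_len(a2, m), stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                   breed = rep_len(breed, n), stringsAsFactors = FALSE))
}

# ---- brute-force ROH oracle -------------------------------------------------
# Independent re-derivation: explicit window loops for eligibility, then
# direct enumeration of maximal qualifying runs.
oracleROH <- function(g, pos, params) {
    m <- length(g)
    W <- params$scan_window_snps
    if (m < W) return(data.frame(start_bp = integer(0), end_bp = integer(0),
                                 n_snps = integer(0), length_kb = numeric(0)))
    is_hom_window <- function(w) {
        win <- g[w:(w + W - 1)]
        sum(win == 1, na.rm = TRUE) <= params$max_het_per_window &&
            sum(is.na(win)) <= params$max_missing_per_window
    }
    hw <- vapply(seq_len(m - W + 1), is_hom_window, logical(1))
    elig <- logical(m)
    for (i in seq_len(m)) {
        ws <- seq(max(1, i - W + 1), min(i, m - W + 1))
        elig[i] <- mean(hw[ws]) >= params$scan_threshold
    }
    segs <- list()
    i <- 1
    while (i <= m) {
        if (!elig[i]) { i <- i + 1; next }
        j <- i
        while (j < m && elig[j + 1] &&
               (pos[j + 1] - pos[j]) <= params$max_gap_kb * 1000) j <- j + 1
        ns <- j - i + 1
        len_kb <- (pos[j] - pos[i]) / 1000
        if (ns >= params$min_snps && len_kb >= params$min_length_kb &&
            len_kb / ns <= params$min_density_kb_per_snp)
            segs[[length(segs) + 1]] <- data.frame(
                start_bp = pos[i], end_bp = pos[j], n_snps = ns,
                length_kb = len_kb)
        i <- j + 1
    }
    if (length(segs)) do.call(rbind, segs) else
        data.frame(start_bp = integer(0), end_bp = integer(0),
                   n_snps = integer(0), length_kb = numeric(0))
}

# ---- double-loop GRM oracles ------------------------------------------------
oracleVanRaden <- function(g, p = 0.5) {
    n <- ncol(g)
    G <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        s <- 0; cnt <- 0
        for (k in seq_len(nrow(g))) {
            if (is.na(g[k, i]) || is.na(g[k, j])) next
            s <- s + (g[k, i] - 2 * p) * (g[k, j] - 2 * p) /
                (2 * p * (1 - p))
            cnt <- cnt + 1
        }
        G[i, j] <- s / cnt
    }
    G
}

oracleAllelicSimilarity <- function(g) {
    n <- ncol(g)
    S <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        s <- 0; cnt <- 0
        for (k in seq_len(nrow(g))) {
            gi <- g[k, i]; gj <- g[k, j]
            if (is.na(gi) || is.na(gj)) next
            s <- s + (gi * gj + (2 - gi) * (2 - gj)) / 4
            cnt <- cnt + 1
        }
        S[i, j] <- s / cnt
    }
    S
}

# ---- single-SNP Weir & Cockerham oracle (scalar, from-scratch) --------------
oracleWCSnp <- function(gA, gB) {
    n1 <- sum(!is.na(gA)); n2 <- sum(!is.na(gB))
    p1 <- mean(gA, na.rm = TRUE) / 2; p2 <- mean(gB, na.rm = TRUE) / 2
    h1 <- mean(gA == 1, na.rm = TRUE); h2 <- mean(gB == 1, na.rm = TRUE)
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
    a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
}

# ---- Tajima's D oracle from per-site alt-allele counts ----------------------
# n = number of sequences; counts = alt copies per segregating site.
oracleTajimaD <- function(counts, n) {
    S <- length(counts)
    th_pi <- sum(2 * counts * (n - counts) / (n * (n - 1)))
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (th_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# All pairwise dosage r^2 (pairwise-complete), brute force.
oracleAllR2 <- function(g) {
    m <- nrow(g)
    r2 <- matrix(NA_real_, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
        ok <- !is.na(g[i, ]) & !is.na(g[j, ])
        r2[i, j] <- suppressWarnings(cor(g[i, ok], g[j, ok]))^2
    }
    r2
}
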