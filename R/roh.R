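#' @include AllClasses.R accessors.R
NULL

#' Minimum number of SNPs constituting a run of homozygosity
#'
#' The Lencz/Purfield threshold limiting the expected number of spurious
#' all-homozygous stretches to \code{alpha} across the dataset:
#' \deqn{floor( \ln(\alpha / (n_{snps} n_{ind})) / \ln(1 - het) )}
#' where \code{mean_het} is the average proportion of heterozygous animals
#' per SNP.
#'
#' @param alpha type-I rate.
#' @param mean_het mean across-SNP heterozygote frequency, in (0, 1).
#' @param n_snps,n_individuals dataset dimensions.
#' @return integer minimum SNP count.
#' @examples
#' minRohSnps(0.05, 0.2895, 44315, 176)  # 55
#' @export
minRohSnps <- function(alpha, mean_het, n_snps, n_individuals) {
    stopifnot(alpha > 0, n_snps >= 1, n_individuals >= 1)
    if (mean_het <= 0 || mean_het >= 1)
        stop("mean_het must be in (0, 1)")
    as.integer(floor(log(alpha / (n_snps * n_individuals)) /
                     log(1 - mean_het)))
}

#' Parameters for the sliding-window ROH scan
#'
#' Defaults are the rare-breed scan settings: 55-SNP scanning window, at most
#' one heterozygous and two missing calls per window, scanning threshold
#' 0.05, minimum run of 55 SNPs and 1 Mb, maximum inter-SNP gap 1 Mb, and a
#' minimum density of one SNP per 500 kb.
#'
#' @param scan_window_snps scanning window size in SNPs.
#' @param scan_threshold minimum fraction of overlapping homozygous windows
#'   for a SNP to be ROH-eligible.
#' @param max_het_per_window,max_missing_per_window per-window allowances.
#' @param min_snps minimum SNPs per emitted run.
#' @param min_length_kb minimum run length.
#' @param max_gap_kb maximum gap between consecutive SNPs inside a run.
#' @param min_density_kb_per_snp maximum kb per SNP within a run.
#' @return list of class \code{"ROHParams"}.
#' @export
rohParams <- function(scan_window_snps = 55, scan_threshold = 0.05,
                      max_het_per_window = 1, max_missing_per_window = 2,
                      min_snps = 55, min_length_kb = 1000,
                      max_gap_kb = 1000, min_density_kb_per_snp = 500) {
    stopifnot(scan_window_snps >= 1, scan_threshold > 0, scan_threshold <= 1,
              min_snps >= 1, min_length_kb > 0, max_gap_kb > 0,
              min_density_kb_per_snp > 0)
    structure(list(scan_window_snps = scan_window_snps,
                   scan_threshold = scan_threshold,
                   max_het_per_window = max_het_per_window,
                   max_missing_per_window = max_missing_per_window,
                   min_snps = min_snps, min_length_kb = min_length_kb,
                   max_gap_kb = max_gap_kb,
                   min_density_kb_per_snp = min_density_kb_per_snp),
              class = "ROHParams")
}

## PLINK-style ROH eligibility + maximal-run extraction for one sample/chr.
## Returns a data.frame of segments (possibly empty).
.rohOneChr <- function(g, pos, params) {
    m <- length(g)
    W <- params$scan_window_snps
    het <- !is.na(g) & g == 1L
    mis <- is.na(g)
    nW <- m - W + 1
    cs_h <- c(0, cumsum(het)); cs_m <- c(0, cumsum(mis))
    wh <- cs_h[(W + 1):(m + 1)] - cs_h[1:nW]
    wm <- cs_m[(W + 1):(m + 1)] - cs_m[1:nW]
    hom_win <- wh <= params$max_het_per_window &
               wm <= params$max_missing_per_window
    ## windows overlapping SNP i: w in [max(1, i-W+1), min(i, nW)]
    cs_w <- c(0, cumsum(hom_win))
    lo <- pmax(1, seq_len(m) - W + 1)
    hi <- pmin(seq_len(m), nW)
    n_overlap <- hi - lo + 1
    n_hom <- cs_w[hi + 1] - cs_w[lo]
    eligible <- n_hom / n_overlap >= params$scan_threshold
    ## maximal runs of eligible SNPs, split at large physical gaps
    r <- rle(eligible)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    segs <- list()
    for (k in which(r$values)) {
        i0 <- starts[k]; i1 <- ends[k]
        run <- i0:i1
        gap_bp <- diff(pos[run])
        brk <- which(gap_bp > params$max_gap_kb * 1000)
        piece_start <- c(run[1], run[brk + 1])
        piece_end <- c(run[brk], run[length(run)])
        for (p in seq_along(piece_start)) {
            a <- piece_start[p]; b <- piece_end[p]
            ns <- b - a + 1
            len_kb <- (pos[b] - pos[a]) / 1000
            if (ns < params$min_snps) next
            if (len_kb < params$min_length_kb) next
            if (len_kb / ns > params$min_density_kb_per_snp) next
            segs[[length(segs) + 1]] <- data.frame(
                start_bp = pos[a], end_bp = pos[b], n_snps = ns,
                length_kb = len_kb)
        }
    }
    if (length(segs)) do.call(rbind, segs) else
        data.frame(start_bp = integer(0), end_bp = integer(0),
                   n_snps = integer(0), length_kb = numeric(0))
}

#' Detect runs of homozygosity with a PLINK-style sliding-window scan
#'
#' A window of \code{scan_window_snps} SNPs is homozygous when it contains at
#' most the allowed heterozygous and missing calls; each SNP's hit rate is
#' the fraction of overlapping windows that are homozygous, and SNPs at or
#' above \code{scan_threshold} are ROH-eligible. Maximal eligible runs are
#' split at physical gaps above \code{max_gap_kb} and emitted when they meet
#' the minimum SNP count, minimum length and density constraints.
#' Chromosomes shorter than the scanning window are skipped with a warning.
#'
#' @param gm an autosomal \linkS4class{GenotypeData}.
#' @param params a \code{\link{rohParams}} list.
#' @return a \linkS4class{ROHSet}.
#' @export
detectROH <- function(gm, params = rohParams()) {
    stopifnot(inherits(params, "ROHParams"))
    map <- markerMap(gm)
    g <- genoMatrix(gm)
    chrs <- unique(map$chr)
    skipped <- character(0)
    segs <- list()
    for (ch in chrs) {
        idx <- which(map$chr == ch)
        if (length(idx) < params$scan_window_snps) {
            skipped <- c(skipped, ch)
            next
        }
        pos <- map$pos[idx]
        for (s in seq_len(ncol(g))) {
            seg <- .rohOneChr(g[idx, s], pos, params)
            if (nrow(seg)) {
                seg$sample <- colnames(g)[s]
                seg$chr <- ch
                segs[[length(segs) + 1]] <- seg
            }
        }
    }
    if (length(skipped))
        warning("chromosome(s) skipped (fewer SNPs than scan window): ",
                paste(skipped, collapse = ", "))
    segments <- if (length(segs)) {
        x <- do.call(rbind, segs)
        x[, c("sample", "chr", "start_bp", "end_bp", "n_snps", "length_kb")]
    } else {
        data.frame(sample = character(0), chr = character(0),
                   start_bp = integer(0), end_bp = integer(0),
                   n_snps = integer(0), length_kb = numeric(0))
    }
    new("ROHSet", segments = segments, samples = colnames(g),
        params = unclass(params))
}

#' Total autosomal length covered by SNPs, in kb
#'
#' Sum over chromosomes of (last SNP position - first SNP position).
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @export
autosomeLengthKb <- function(gm) {
    map <- markerMap(gm)
    sum(vapply(split(map$pos, map$chr),
               function(p) (max(p) - min(p)) / 1000, numeric(1)))
}

#' ROH-based inbreeding coefficient
#'
#' \eqn{F_{ROH} = L_{ROH} / L_{AUTO}} per sample, where \eqn{L_{ROH}} is the
#' total autosomal ROH length and \eqn{L_{AUTO}} the SNP-covered autosome
#' length (see \code{\link{autosomeLengthKb}}).
#'
#' @param rohset a \linkS4class{ROHSet}.
#' @param l_auto_kb total autosome length in kb.
#' @return named numeric vector of per-sample \eqn{F_{ROH}}.
#' @export
froh <- function(rohset, l_auto_kb) {
    stopifnot(l_auto_kb > 0)
    rohTotalKb(rohset) / l_auto_kb
}
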