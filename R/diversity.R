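#' @include AllClasses.R accessors.R
NULL

## Tajima (1989) normalizing constants for n sequences
.tajimaConstants <- function(n) {
    stopifnot(n >= 4)
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
         e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

## per-site heterozygosity 2*nA*na/(n*(n-1)) and segregating flag,
## from a markers x samples call matrix; n = non-missing allele count
.siteStats <- function(g) {
    nonmiss <- rowSums(!is.na(g))
    nAll <- 2 * nonmiss
    nAlt <- rowSums(g, na.rm = TRUE)
    nRef <- nAll - nAlt
    pi_site <- ifelse(nAll >= 2, 2 * nAlt * nRef / (nAll * (nAll - 1)), 0)
    seg <- nAlt > 0 & nRef > 0
    list(pi = pi_site, seg = seg)
}

.windowTable <- function(gm, window_bp) {
    if (window_bp <= 0) stop("window_bp must be positive")
    map <- markerMap(gm)
    g <- genoMatrix(gm)
    st <- .siteStats(g)
    out <- list()
    for (ch in unique(map$chr)) {
        idx <- which(map$chr == ch)
        maxpos <- max(map$pos[idx])
        starts <- seq(1, maxpos, by = window_bp)
        win <- findInterval(map$pos[idx], starts)
        for (w in seq_along(starts)) {
            inw <- idx[win == w]
            out[[length(out) + 1]] <- data.frame(
                chr = ch, window_start = starts[w],
                window_end = starts[w] + window_bp - 1,
                n_snps = sum(st$seg[inw]),
                pi_sum = sum(st$pi[inw]),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity is \eqn{2 n_A n_a / (n (n-1))} with n the non-missing
#' allele count at the site; window diversity is the per-window sum divided by
#' the window length in bp (fixed tiles anchored at position 1).
#'
#' @param gm a \linkS4class{GenotypeData} with at least one sample.
#' @param window_bp window size in base pairs (default 1 Mb).
#' @return data.frame with chr, window_start, window_end, n_snps
#'   (segregating sites) and pi (per-bp diversity).
#' @export
windowedPi <- function(gm, window_bp = 1e6) {
    stopifnot(ncol(gm) >= 1)
    tab <- .windowTable(gm, window_bp)
    tab$pi <- tab$pi_sum / window_bp
    tab$pi_sum <- NULL
    tab
}

#' Windowed Tajima's D
#'
#' D contrasts the pairwise-diversity estimator of theta with Watterson's
#' \eqn{S/a_1} using the 1989 normalizing constants computed from
#' \eqn{n = 2 \times} samples. Windows without segregating sites report
#' \code{NA}, never zero.
#'
#' @inheritParams windowedPi
#' @return data.frame with chr, window_start, window_end, n_snps, tajima_d.
#' @export
windowedTajimaD <- function(gm, window_bp = 1e6) {
    n <- 2 * ncol(gm)
    if (n < 4) stop("Tajima's D needs at least 4 sampled chromosomes")
    k <- .tajimaConstants(n)
    tab <- .windowTable(gm, window_bp)
    S <- tab$n_snps
    denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
    tab$tajima_d <- ifelse(S > 0, (tab$pi_sum - S / k$a1) / denom, NA_real_)
    tab$pi_sum <- NULL
    tab
}

#' Significance limits for Tajima's D under the beta approximation
#'
#' Tajima's D is bounded between \eqn{D_{min}} (all sites singletons) and
#' \eqn{D_{max}} (all sites at half frequency); the null distribution is
#' approximated by a generalized beta on that interval with mean 0 and
#' variance 1, from which two-sided confidence limits are drawn.
#'
#' @param n_samples number of sampled sequences (chromosomes), at least 4.
#' @param alpha two-sided type-I error rate in (0, 1).
#' @return numeric vector \code{c(lower, upper)}.
#' @export
tajimaDLimits <- function(n_samples, alpha = 0.05) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
    n <- n_samples
    k <- .tajimaConstants(n)
    dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
    dmax <- (n / (2 * (n - 1)) - 1 / k$a1) / sqrt(k$e2)
    ## generalized beta with E[D]=0, V[D]=1 on [dmin, dmax]
    aa <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
    bb <- (1 + dmin * dmax) * dmin / (dmax - dmin)
    q <- stats::qbeta(c(alpha / 2, 1 - alpha / 2), bb, aa)
    lims <- dmin + q * (dmax - dmin)
    stats::setNames(lims, c("lower", "upper"))
}
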