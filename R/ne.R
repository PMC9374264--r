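#' @include AllClasses.R accessors.R
NULL

#' Bin pairwise LD by recombination distance
#'
#' Within-chromosome pairwise genotype-dosage r^2 (pairwise-complete
#' observations) is computed for all marker pairs; physical distance maps to
#' recombination fraction c through a uniform linear genetic map (capped at
#' 0.5 Morgans); the sample-size adjustment \eqn{r^2_{adj} = r^2 - 1/n}
#' removes the finite-sample expectation for unphased data. Pairs are then
#' averaged within distance bins.
#'
#' @param gm a \linkS4class{GenotypeData} with >= 2 SNPs per chromosome.
#' @param cm_per_mb uniform genetic-map density.
#' @param bin_edges recombination-fraction bin edges (Morgans); default 50
#'   log-spaced bins over (5e-4, 0.5).
#' @return data.frame of bins: c_mean, r2_adj, n_pairs, t (= 1/(2c)).
#' @export
ldDecayBins <- function(gm, cm_per_mb = 1.0, bin_edges = NULL) {
    if (is.null(bin_edges))
        bin_edges <- exp(seq(log(5e-4), log(0.5), length.out = 51))
    map <- markerMap(gm)
    g <- genoMatrix(gm)
    n <- ncol(g)
    nb <- length(bin_edges) - 1
    sum_c <- sum_r2 <- cnt <- numeric(nb)
    for (ch in unique(map$chr)) {
        idx <- which(map$chr == ch)
        if (length(idx) < 2) next
        r2 <- suppressWarnings(
            stats::cor(t(g[idx, , drop = FALSE]),
                       use = "pairwise.complete.obs"))^2
        pos <- map$pos[idx]
        d_bp <- abs(outer(pos, pos, "-"))
        cc <- pmin(d_bp * cm_per_mb / 1e8, 0.5)
        ut <- upper.tri(r2)
        rv <- r2[ut]; cv <- cc[ut]
        ok <- !is.na(rv)
        b <- findInterval(cv[ok], bin_edges, rightmost.closed = TRUE)
        inb <- b >= 1 & b <= nb
        b <- b[inb]; rvv <- rv[ok][inb]; cvv <- cv[ok][inb]
        sum_c <- sum_c + as.numeric(.binSum(cvv, b, nb))
        sum_r2 <- sum_r2 + as.numeric(.binSum(rvv, b, nb))
        cnt <- cnt + as.numeric(.binSum(rep(1, length(b)), b, nb))
    }
    keep <- cnt >= 1
    if (!all(keep))
        warning(sum(!keep), " empty LD bin(s) dropped")
    c_mean <- (sum_c / cnt)[keep]
    data.frame(c_mean = c_mean,
               r2_adj = (sum_r2 / cnt)[keep] - 1 / n,
               n_pairs = cnt[keep],
               t = 1 / (2 * c_mean))
}

## grouped sum over integer bins 1..nb
.binSum <- function(x, b, nb) {
    out <- numeric(nb)
    s <- tapply(x, factor(b, levels = seq_len(nb)), sum)
    out[!is.na(s)] <- s[!is.na(s)]
    out
}

#' Historical effective population size from binned LD decay
#'
#' Inverts the Sved & Feldman drift-recombination expectation
#' \eqn{E[r^2] = 1/(1 + 4 N_e c)} per bin:
#' \eqn{N_e(t) = (1/r^2_{adj} - \alpha) / (4c)} reported at
#' \eqn{t = 1/(2c)} generations ago. Bins with \eqn{r^2_{adj}} outside (0, 1)
#' are skipped with a warning.
#'
#' @param bins data.frame from \code{\link{ldDecayBins}}.
#' @param alpha_const the mapping constant (1 for the pure drift mapping).
#' @return a \linkS4class{NeSeries}.
#' @export
historicalNe <- function(bins, alpha_const = 1.0) {
    bad <- bins$r2_adj <= 0 | bins$r2_adj >= 1
    if (any(bad))
        warning(sum(bad), " bin(s) with r2_adj outside (0,1) skipped")
    b <- bins[!bad, , drop = FALSE]
    b$ne <- (1 / b$r2_adj - alpha_const) / (4 * b$c_mean)
    new("NeSeries",
        bins = b[order(b$t), c("t", "ne", "c_mean", "r2_adj", "n_pairs")],
        fit = list())
}

#' Extrapolate current Ne by a linear fit over recent generations
#'
#' Ordinary least squares of Ne on generations-ago t over the bins with
#' \code{t <= recent_generations}; the current size is the intercept (t = 0).
#' A non-positive intercept is returned with a warning.
#'
#' @param series a \linkS4class{NeSeries}.
#' @param recent_generations upper limit of the fitting window.
#' @return the series with its \code{fit} slot filled (slope, intercept,
#'   r_squared, ne_now, recent_generations).
#' @export
extrapolateNe <- function(series, recent_generations) {
    b <- neTable(series)
    w <- b[b$t <= recent_generations, , drop = FALSE]
    if (nrow(w) < 3) stop("need >= 3 bins within the recent window")
    fit <- stats::lm(ne ~ t, data = w)
    ne_now <- unname(stats::coef(fit)[1])
    if (ne_now <= 0)
        warning("extrapolated current Ne is non-positive")
    tss <- sum((w$ne - mean(w$ne))^2)
    r2 <- if (tss < 1e-12) NA_real_ else
        1 - sum(stats::residuals(fit)^2) / tss
    series@fit <- list(slope = unname(stats::coef(fit)[2]),
                       intercept = ne_now,
                       r_squared = r2,
                       ne_now = ne_now,
                       recent_generations = recent_generations)
    series
}

#' Linear-fit summary of an extrapolated NeSeries
#' @param x a NeSeries after \code{\link{extrapolateNe}}.
#' @export
setGeneric("neFit", function(x) standardGeneric("neFit"))
#' @rdname neFit
#' @export
setMethod("neFit", "NeSeries", function(x) x@fit)

#' Complete and maximum generation counts per individual
#'
#' The complete-generation count is the depth to which every ancestor is
#' known (0 when either parent is unknown); the maximum-generation count is
#' the longest known ancestor chain. Founders score (0, 0).
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return data.frame with id, complete, maximum.
#' @export
generationCounts <- function(ped) {
    df <- pedTable(ped)
    n <- nrow(df)
    si <- match(df$sire, df$id); di <- match(df$dam, df$id)
    comp <- maxg <- integer(n)
    for (i in seq_len(n)) {
        s <- si[i]; d <- di[i]
        comp[i] <- if (!is.na(s) && !is.na(d))
            1L + min(comp[s], comp[d]) else 0L
        mg <- 0L
        if (!is.na(s)) mg <- max(mg, 1L + maxg[s])
        if (!is.na(d)) mg <- max(mg, 1L + maxg[d])
        maxg[i] <- mg
    }
    data.frame(id = df$id, complete = comp, maximum = maxg,
               stringsAsFactors = FALSE)
}

#' Pedigree-based effective population size from complete generations
#'
#' The per-generation rate of inbreeding is estimated as the regression
#' slope of individual inbreeding on complete-generation number;
#' \eqn{N_e = 1/(2\Delta F)}. A non-positive slope leaves Ne undefined
#' (error).
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param inbreeding named per-individual inbreeding coefficients
#'   (default computed via \code{\link{pedigreeInbreeding}}).
#' @param counts generation counts (default \code{\link{generationCounts}}).
#' @return list with delta_f and ne.
#' @export
pedigreeNe <- function(ped, inbreeding = pedigreeInbreeding(ped),
                       counts = generationCounts(ped)) {
    f <- inbreeding[counts$id]
    gc <- counts$complete
    if (length(unique(gc)) < 2)
        stop("need >= 2 distinct complete-generation classes")
    slope <- unname(stats::coef(stats::lm(f ~ gc))[2])
    if (is.na(slope) || slope <= 0)
        stop("non-positive inbreeding trend; pedigree Ne undefined")
    list(delta_f = slope, ne = 1 / (2 * slope))
}

#' Effective size from breeding census counts
#'
#' \eqn{N_e = 4 N_s N_d / (N_s + N_d)}: the unequal-sex-ratio formula under
#' random mating, non-overlapping generations and Poisson family sizes.
#'
#' @param n_sires,n_dams positive breeding-animal counts.
#' @export
censusNe <- function(n_sires, n_dams) {
    stopifnot(n_sires > 0, n_dams > 0)
    4 * n_sires * n_dams / (n_sires + n_dams)
}
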