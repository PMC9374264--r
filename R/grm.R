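#' @include AllClasses.R accessors.R
NULL

#' Genomic relationship matrix, VanRaden method 2
#'
#' Marker-wise averaging of \eqn{z_i z_j / (2 p (1-p))} with
#' \eqn{z = g - 2p} and a fixed base-population allele frequency
#' (default 0.5, the correction used when the true base frequencies are
#' unknown). Missing calls are excluded pairwise, with per-pair
#' renormalization over the usable markers. Inbreeding is read off the
#' diagonal as \eqn{F_i = G_{ii} - 1} (see \code{\link{inbreeding}}).
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param base_freq base-population allele frequency: scalar or per-marker
#'   vector in (0, 1).
#' @return a \linkS4class{GRM} with method "vanraden".
#' @export
grmVanRaden <- function(gm, base_freq = 0.5) {
    g <- genoMatrix(gm)
    p <- rep_len(base_freq, nrow(g))
    stopifnot(all(p > 0 & p < 1))
    obs <- !is.na(g)
    if (any(rowSums(obs) == 0)) stop("marker with no observed calls")
    z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
    z[!obs] <- 0
    num <- crossprod(z)
    cnt <- crossprod(obs * 1)
    G <- num / cnt
    G[cnt == 0] <- NA
    dimnames(G) <- list(colnames(g), colnames(g))
    new("GRM", mat = G, method = "vanraden")
}

#' Genomic relationship matrix by allelic similarity
#'
#' The Nejati-Javaremi similarity: per marker, the fraction of the four
#' cross-individual allele pairings that match, averaged over markers
#' (\eqn{S_{ij} = E[(g_i g_j + (2-g_i)(2-g_j))/4]}). Self-similarity is 0.5
#' at a heterozygous locus and 1 at a homozygous one, so
#' \eqn{F_i = 2 S_{ii} - 1} equals the proportion of homozygous loci.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @return a \linkS4class{GRM} with method "allelic_similarity".
#' @export
grmAllelicSimilarity <- function(gm) {
    g <- genoMatrix(gm)
    obs <- !is.na(g)
    if (any(rowSums(obs) == 0)) stop("marker with no observed calls")
    x <- g; x[!obs] <- 0
    y <- 2 - g; y[!obs] <- 0
    num <- (crossprod(x) + crossprod(y)) / 4
    cnt <- crossprod(obs * 1)
    S <- num / cnt
    S[cnt == 0] <- NA
    dimnames(S) <- list(colnames(g), colnames(g))
    new("GRM", mat = S, method = "allelic_similarity")
}

#' Pedigree inbreeding coefficients (Wright / Meuwissen-Luo)
#'
#' Builds the numerator relationship matrix by the tabular method over the
#' topologically ordered pedigree; unknown parents are treated as unrelated,
#' non-inbred founders. \eqn{F_i = A_{ii} - 1}.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return named numeric vector of inbreeding coefficients, one per
#'   individual, in the pedigree's (sorted) order.
#' @export
pedigreeInbreeding <- function(ped) {
    df <- pedTable(ped)
    n <- nrow(df)
    A <- matrix(0, n, n, dimnames = list(df$id, df$id))
    si <- match(df$sire, df$id)   # NA for unknown
    di <- match(df$dam, df$id)
    for (i in seq_len(n)) {
        s <- si[i]; d <- di[i]
        if (i > 1) {
            for (j in seq_len(i - 1)) {
                aij <- 0
                if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
                if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
                A[i, j] <- A[j, i] <- aij
            }
        }
        A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    }
    stats::setNames(diag(A) - 1, df$id)
}
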