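#' @include AllClasses.R accessors.R genotype-io.R
NULL

#' Pairwise identity-by-state distances
#'
#' Per pair, IBS similarity is the mean over pairwise-complete markers of
#' the shared-allele fraction (0, 0.5 or 1 per marker); the distance is
#' 1 - IBS. Pairs with no shared markers get \code{NA}.
#'
#' @param gm a \linkS4class{GenotypeData} with >= 2 samples.
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibsDistance <- function(gm) {
    stopifnot(ncol(gm) >= 2)
    d <- 1 - .ibsSimilarity(genoMatrix(gm))
    diag(d) <- 0
    d
}

#' Principal components of a genomic relationship matrix
#'
#' Eigen-decomposition of the (symmetric) relationship matrix; sample
#' coordinates are the eigenvectors scaled by the square roots of their
#' (non-negative) eigenvalues, in decreasing eigenvalue order.
#'
#' @param grm a \linkS4class{GRM} or symmetric numeric matrix.
#' @param n_components number of components to return.
#' @return samples x components coordinate matrix; eigenvalues in
#'   \code{attr(, "values")}.
#' @export
grmPCA <- function(grm, n_components = 2) {
    m <- if (is(grm, "GRM")) grmMatrix(grm) else grm
    if (any(!is.finite(m))) stop("non-finite entries in relationship matrix")
    e <- eigen(m, symmetric = TRUE)
    k <- min(n_components, ncol(m))
    co <- e$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    rownames(co) <- rownames(m)
    colnames(co) <- paste0("PC", seq_len(k))
    attr(co, "values") <- e$values
    co
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the deficit transferred to the adjacent edge, which
#' preserves pairwise path lengths.
#'
#' @param d symmetric distance matrix with labelled rows.
#' @return an \pkg{ape} \code{phylo} tree (unrooted).
#' @export
njTree <- function(d) {
    if (!isSymmetric(unname(as.matrix(d)), tol = 1e-8))
        stop("distance matrix must be symmetric")
    tr <- ape::nj(as.dist(d))
    neg <- which(tr$edge.length < 0)
    for (e in neg) {
        deficit <- tr$edge.length[e]
        node <- tr$edge[e, 2]
        ## move the deficit onto edges leaving the child node
        out <- which(tr$edge[, 1] == node)
        if (length(out)) tr$edge.length[out] <- tr$edge.length[out] + deficit
        tr$edge.length[e] <- 0
    }
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
}

#' Bootstrap neighbor-joining consensus tree over markers
#'
#' Markers are resampled with replacement \code{n_boot} times; an NJ tree is
#' built from the IBS distances of each replicate; the majority-rule (>50\%)
#' consensus is computed, annotated with percent support per internal node,
#' and rooted on the outgroup samples.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param n_boot number of bootstrap replicates.
#' @param outgroup_label breed label used for rooting.
#' @param seed integer RNG seed.
#' @return a rooted \code{phylo} consensus tree whose \code{node.label}
#'   carries percent support.
#' @export
bootstrapNjConsensus <- function(gm, n_boot = 100, outgroup_label, seed = 1) {
    stopifnot(n_boot >= 1)
    if (!outgroup_label %in% breeds(gm))
        stop("outgroup breed not present: ", outgroup_label)
    set.seed(seed)
    g <- genoMatrix(gm)
    m <- nrow(g)
    trees <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
        idx <- sample.int(m, m, replace = TRUE)
        d <- 1 - .ibsSimilarity(g[idx, , drop = FALSE])
        diag(d) <- 0
        trees[[b]] <- njTree(d)
    }
    class(trees) <- "multiPhylo"
    cons <- ape::consensus(trees, p = 0.5)
    sup <- ape::prop.clades(cons, trees, rooted = FALSE)
    sup[is.na(sup)] <- 0
    cons$node.label <- round(100 * sup / n_boot)
    og <- sampleIds(gm)[breeds(gm) == outgroup_label]
    rooted <- tryCatch(ape::root(cons, outgroup = og, resolve.root = TRUE,
                                 edgelabel = TRUE),
                       error = function(e) ape::root(cons, outgroup = og[1],
                                                     resolve.root = TRUE,
                                                     edgelabel = TRUE))
    rooted
}

#' Per-SNP Weir & Cockerham Fst between two populations
#'
#' Computes the 1984 variance components a (between populations),
#' b (between individuals within populations) and c (within individuals)
#' from genotype counts; per-SNP theta = a/(a+b+c) and the genome mean is the
#' ratio of summed components. SNPs monomorphic in both populations (zero
#' total variance) are undefined and excluded from the mean.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param pop_a,pop_b breed labels, each with >= 2 samples.
#' @return list with \code{per_snp} (marker, chr, pos, fst), \code{mean}
#'   (ratio-of-sums), and \code{pops}.
#' @export
pairwiseFst <- function(gm, pop_a, pop_b) {
    br <- breeds(gm)
    ga <- genoMatrix(gm)[, br == pop_a, drop = FALSE]
    gb <- genoMatrix(gm)[, br == pop_b, drop = FALSE]
    if (ncol(ga) < 2 || ncol(gb) < 2)
        stop("both populations need >= 2 samples")
    comp <- .wcComponents(ga, gb)
    tot <- comp$a + comp$b + comp$c
    theta <- ifelse(abs(tot) > 0, comp$a / tot, NA_real_)
    map <- markerMap(gm)
    ok <- !is.na(theta)
    list(per_snp = data.frame(marker = map$marker, chr = map$chr,
                              pos = map$pos, fst = theta,
                              stringsAsFactors = FALSE),
         mean = sum(comp$a[ok]) / sum(tot[ok]),
         pops = c(pop_a, pop_b))
}

## W&C (1984) two-population variance components per marker
.wcComponents <- function(ga, gb) {
    n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
    p1 <- rowMeans(ga, na.rm = TRUE) / 2
    p2 <- rowMeans(gb, na.rm = TRUE) / 2
    h1 <- rowMeans(ga == 1L, na.rm = TRUE)
    h2 <- rowMeans(gb == 1L, na.rm = TRUE)
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
    bad <- n1 < 1 | n2 < 1 | nbar <= 1
    a[bad] <- b[bad] <- cc[bad] <- NA_real_
    list(a = a, b = b, c = cc)
}
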