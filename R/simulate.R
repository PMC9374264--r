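#' @include AllClasses.R accessors.R
NULL

#' Multi-breed drift model specification
#'
#' Describes a set of breeds that diverged from a common ancestral population
#' by pure drift: breed-specific allele frequencies are Beta-distributed
#' around the ancestral frequency with breed drift coefficient F
#' (Balding-Nichols). A configurable number of "planted" distinctive markers
#' get a frequency gap of at least \code{planted_gap} between the focal breed
#' and every other breed, providing known truth for panel-selection tests.
#'
#' Defaults emulate a rare-breed study design: 14 breeds on 18 autosomes,
#' one numerically dominant focal sample (the breed under study is heavily
#' sampled), stronger drift in the focal breed, ~1\% missing calls.
#'
#' @param n_snps total marker count, spread evenly over \code{n_chr}
#'   autosomes at \code{spacing_bp} intervals.
#' @param n_chr number of autosomes.
#' @param breed_names character vector; the first entry is the focal breed.
#' @param sample_sizes integer vector per breed.
#' @param drift per-breed drift coefficient F in [0, 1).
#' @param spacing_bp physical distance between adjacent markers.
#' @param missing_rate overall genotype missingness rate; injected as a
#'   mixture of near-complete markers and a small fraction of failing
#'   assays with heavy missingness, the pattern commercial arrays show.
#' @param n_planted number of planted distinctive markers (0 disables).
#' @param planted_gap minimum focal-vs-other allele frequency gap at planted
#'   markers.
#' @param ancestral_range range the ancestral frequencies are drawn from.
#' @return a list of class \code{"BreedModel"}.
#' @export
breedModel <- function(n_snps = 5000, n_chr = 18,
                       breed_names = c("FOCAL", sprintf("BR%02d", 2:13),
                                       "WILD"),
                       sample_sizes = c(60, rep(30, 13)),
                       drift = c(0.35, stats::runif(13, 0.15, 0.25)),
                       spacing_bp = 40000, missing_rate = 0.01,
                       n_planted = 40, planted_gap = 0.6,
                       ancestral_range = c(0.1, 0.9)) {
    stopifnot(length(breed_names) == length(sample_sizes),
              length(drift) == length(breed_names),
              all(drift >= 0), all(drift < 1), all(sample_sizes >= 1))
    structure(list(
        n_snps = n_snps, n_chr = n_chr, breed_names = breed_names,
        sample_sizes = sample_sizes, drift = drift, spacing_bp = spacing_bp,
        missing_rate = missing_rate, n_planted = n_planted,
        planted_gap = planted_gap, ancestral_range = ancestral_range),
        class = "BreedModel")
}

.simMap <- function(n_snps, n_chr, spacing_bp) {
    per <- rep(n_snps %/% n_chr, n_chr)
    if (n_snps %% n_chr) per[seq_len(n_snps %% n_chr)] <-
        per[seq_len(n_snps %% n_chr)] + 1
    chr <- rep(as.character(seq_len(n_chr)), per)
    pos <- unlist(lapply(per, function(m) seq_len(m) * spacing_bp))
    data.frame(marker = sprintf("snp%05d", seq_len(n_snps)), chr = chr,
               pos = as.integer(pos), a1 = "A", a2 = "G",
               stringsAsFactors = FALSE)
}

#' Simulate multi-breed genotypes under the Balding-Nichols drift model
#'
#' Breed k's frequency at each marker is drawn from
#' Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k) around the ancestral frequency p
#' (F_k = 0 reproduces p exactly); genotypes are Binomial(2, freq) with
#' uniform missingness injected afterwards.
#'
#' @param model a \code{\link{breedModel}}.
#' @param seed integer RNG seed (full reproducibility).
#' @return list with \code{gm} (\linkS4class{GenotypeData}) and \code{truth}:
#'   realized per-breed allele frequencies (breeds x markers), one-hot
#'   admixture matrix \code{q}, planted marker ids.
#' @export
simulateBreeds <- function(model = breedModel(), seed = 1) {
    stopifnot(inherits(model, "BreedModel"))
    if (any(model$drift >= 1)) stop("drift F must be < 1")
    set.seed(seed)
    m <- model$n_snps
    K <- length(model$breed_names)
    map <- .simMap(m, model$n_chr, model$spacing_bp)
    p <- stats::runif(m, model$ancestral_range[1], model$ancestral_range[2])
    freqs <- matrix(NA_real_, K, m,
                    dimnames = list(model$breed_names, map$marker))
    for (k in seq_len(K)) {
        Fk <- model$drift[k]
        freqs[k, ] <- if (Fk == 0) p else
            stats::rbeta(m, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
    }
    planted <- character(0)
    if (model$n_planted > 0) {
        idx <- unique(round(seq(1, m, length.out = model$n_planted)))
        hi <- seq_along(idx) %% 2 == 1   # alternate direction
        for (s in seq_along(idx)) {
            j <- idx[s]
            others <- stats::runif(K - 1, 0.25, 0.37)  # keeps pooled MAF >= .3
            if (hi[s]) {
                freqs[1, j] <- max(others) + model$planted_gap
                freqs[-1, j] <- others
            } else {
                freqs[1, j] <- 1 - (max(others) + model$planted_gap)
                freqs[-1, j] <- 1 - others
            }
        }
        freqs[freqs > 0.995] <- 0.995
        freqs[freqs < 0.005] <- 0.005
        planted <- map$marker[idx]
    }
    n <- sum(model$sample_sizes)
    breed_of <- rep(model$breed_names, model$sample_sizes)
    ids <- sprintf("%s_%03d", breed_of,
                   unlist(lapply(model$sample_sizes, seq_len)))
    geno <- matrix(NA_integer_, m, n)
    for (k in seq_len(K)) {
        cols <- which(breed_of == model$breed_names[k])
        geno[, cols] <- stats::rbinom(m * length(cols), 2,
                                      rep(freqs[k, ], length(cols)))
    }
    if (model$missing_rate > 0) {
        ## array missingness concentrates on failing assays: a small
        ## fraction of markers carries most of the missing calls, the rest
        ## are near-complete; overall rate ~= missing_rate
        base <- min(1e-4, model$missing_rate)
        bad_frac <- max(0, (model$missing_rate - base) / (0.275 - base))
        rates <- rep(base, m)
        bad <- stats::runif(m) < bad_frac
        rates[bad] <- stats::runif(sum(bad), 0.15, 0.4)
        geno[matrix(stats::runif(length(geno)), m, n) < rates] <- NA_integer_
    }
    q <- matrix(0, n, K, dimnames = list(ids, model$breed_names))
    q[cbind(seq_len(n), match(breed_of, model$breed_names))] <- 1
    gm <- GenotypeData(geno, map,
        data.frame(sample_id = ids, breed = breed_of,
                   stringsAsFactors = FALSE))
    list(gm = gm, truth = list(freqs = freqs, q = q, planted = planted,
                               ancestral = p))
}

#' Default multi-breed fixture with planted outliers
#'
#' Runs \code{\link{simulateBreeds}} under the default \code{\link{breedModel}}
#' and converts the last \code{n_outliers} focal-labelled samples into
#' planted outliers: their genotypes are redrawn from the second breed's
#' allele frequencies, emulating mislabelled animals that should fall outside
#' the focal cluster in validation.
#'
#' @param seed integer RNG seed.
#' @param n_outliers number of planted outliers (focal-labelled).
#' @param model optional \code{\link{breedModel}} override.
#' @return list with \code{gm}, \code{truth} (as \code{simulateBreeds}, plus
#'   \code{outliers}: the planted-outlier sample ids).
#' @export
simulateBreedFixture <- function(seed = 1, n_outliers = 2, model = NULL) {
    if (is.null(model)) {
        set.seed(seed)
        model <- breedModel()
    }
    sim <- simulateBreeds(model, seed = seed)
    out_ids <- character(0)
    if (n_outliers > 0) {
        focal <- model$breed_names[1]
        donor <- model$breed_names[2]
        foc_ids <- sampleIds(sim$gm)[breeds(sim$gm) == focal]
        out_ids <- utils::tail(foc_ids, n_outliers)
        f <- sim$truth$freqs[donor, ]
        g <- genoMatrix(sim$gm)
        for (id in out_ids)
            g[, id] <- stats::rbinom(length(f), 2, f)
        sim$gm <- GenotypeData(g, markerMap(sim$gm),
            data.frame(sample_id = sampleIds(sim$gm),
                       breed = breeds(sim$gm), stringsAsFactors = FALSE))
    }
    sim$truth$outliers <- out_ids
    sim
}

## one meiosis: recombine two haplotype vectors along Morgan positions
.meiosis <- function(h1, h2, posM) {
    L <- posM[length(posM)] - posM[1]
    start <- sample.int(2, 1)
    k <- if (L > 0) stats::rpois(1, L) else 0
    if (k == 0) return(if (start == 1) h1 else h2)
    xo <- sort(stats::runif(k, 0, L))
    seg <- findInterval(posM - posM[1], xo)
    phase <- (seg + start) %% 2
    ifelse(phase == 1, h1, h2)
}

#' Forward Wright-Fisher simulation of diploid genotypes
#'
#' Discrete generations, random mating (selfing allowed), crossover
#' recombination at \code{cm_per_mb} along each chromosome. Founder allele
#' frequencies are uniform in \code{init_freq_range}. The final generation is
#' sampled and returned; the realized LD carries the drift signature of the
#' chosen \code{ne}, supporting recovery tests of the LD-based Ne estimators.
#'
#' @param ne diploid population size (constant).
#' @param n_generations generations to run.
#' @param n_chr,snps_per_chr,spacing_bp marker map layout.
#' @param cm_per_mb uniform recombination rate (0 = complete linkage).
#' @param sample_n individuals sampled from the final generation.
#' @param init_freq_range founder allele-frequency range.
#' @param init_freq_dist "uniform" founder frequencies, or "neutral" for the
#'   drift-mutation equilibrium spectrum (density proportional to 1/p over
#'   the range), which keeps the site-frequency spectrum neutral-like.
#' @param seed integer RNG seed.
#' @return a \linkS4class{GenotypeData} (breed label "WF").
#' @export
simulateWF <- function(ne, n_generations, n_chr = 4, snps_per_chr = 120,
                       spacing_bp = 1e6, cm_per_mb = 1.0, sample_n = ne,
                       init_freq_range = c(0.1, 0.9),
                       init_freq_dist = c("uniform", "neutral"), seed = 1) {
    stopifnot(ne >= 2, cm_per_mb >= 0)
    init_freq_dist <- match.arg(init_freq_dist)
    if (sample_n > ne) stop("sample_n cannot exceed ne")
    set.seed(seed)
    m <- n_chr * snps_per_chr
    map <- .simMap(m, n_chr, spacing_bp)
    posM <- map$pos * cm_per_mb / 1e8   # Morgans
    chr_idx <- split(seq_len(m), map$chr)
    p0 <- if (init_freq_dist == "uniform") {
        stats::runif(m, init_freq_range[1], init_freq_range[2])
    } else {
        lo <- max(init_freq_range[1], 1 / (2 * ne))
        p <- lo * (init_freq_range[2] / lo)^stats::runif(m)
        flip <- stats::runif(m) < 0.5   # random derived-allele polarity
        ifelse(flip, 1 - p, p)
    }
    H <- matrix(stats::rbinom(2 * ne * m, 1, rep(p0, each = 2 * ne)),
                nrow = 2 * ne)
    for (g in seq_len(n_generations)) {
        H2 <- matrix(0L, 2 * ne, m)
        sires <- sample.int(ne, ne, replace = TRUE)
        dams <- sample.int(ne, ne, replace = TRUE)
        for (i in seq_len(ne)) {
            for (idx in chr_idx) {
                pm <- posM[idx]
                s <- sires[i]
                H2[2 * i - 1, idx] <-
                    .meiosis(H[2 * s - 1, idx], H[2 * s, idx], pm)
                d <- dams[i]
                H2[2 * i, idx] <-
                    .meiosis(H[2 * d - 1, idx], H[2 * d, idx], pm)
            }
        }
        H <- H2
    }
    take <- seq_len(sample_n)
    geno <- t(H[2 * take - 1, , drop = FALSE] + H[2 * take, , drop = FALSE])
    GenotypeData(geno, map,
        data.frame(sample_id = sprintf("WF_%03d", take), breed = "WF",
                   stringsAsFactors = FALSE))
}

#' Gene-drop simulation through a pedigree
#'
#' Founders are drawn in Hardy-Weinberg proportions at the supplied allele
#' frequencies; every non-founder inherits one recombinant gamete per parent.
#' Supports testing of pedigree inbreeding against genotype homozygosity.
#'
#' @param ped a \linkS4class{Pedigree} or data.frame with id/sire/dam.
#' @param founder_freqs per-marker allele frequencies (defines marker count).
#' @param spacing_bp,cm_per_mb single-chromosome map layout.
#' @param seed integer RNG seed.
#' @return list with \code{ped} (Pedigree) and \code{gm} (GenotypeData,
#'   breed "PED", samples in pedigree order).
#' @export
simulatePedigreeGenedrop <- function(ped, founder_freqs, spacing_bp = 1e6,
                                     cm_per_mb = 1.0, seed = 1) {
    if (!is(ped, "Pedigree"))
        ped <- Pedigree(ped$id, ped$sire, ped$dam)
    set.seed(seed)
    df <- pedTable(ped)
    m <- length(founder_freqs)
    map <- .simMap(m, 1, spacing_bp)
    posM <- map$pos * cm_per_mb / 1e8
    n <- nrow(df)
    hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
    rownames(hap1) <- rownames(hap2) <- df$id
    for (i in seq_len(n)) {
        for (side in 1:2) {
            par <- if (side == 1) df$sire[i] else df$dam[i]
            gam <- if (is.na(par)) {
                stats::rbinom(m, 1, founder_freqs)
            } else {
                .meiosis(hap1[par, ], hap2[par, ], posM)
            }
            if (side == 1) hap1[i, ] <- gam else hap2[i, ] <- gam
        }
    }
    geno <- t(hap1 + hap2)
    gm <- GenotypeData(geno, map,
        data.frame(sample_id = df$id, breed = "PED",
                   stringsAsFactors = FALSE))
    list(ped = ped, gm = gm)
}

#' Simulate admixed genotypes from ancestral allele frequencies
#'
#' Each of an individual's two allele copies at each marker draws its
#' ancestry from \code{q} and then its allele from the chosen ancestry's
#' frequency — the standard unsupervised-admixture generative model.
#'
#' @param freqs K x markers matrix of ancestral allele frequencies.
#' @param q ancestry proportions: length-K vector (shared by all samples) or
#'   an n x K matrix. Rows must be non-negative and sum to 1.
#' @param n number of individuals (ignored when \code{q} is a matrix).
#' @param map optional marker map; defaults to one chromosome at 40 kb
#'   spacing.
#' @param breed breed label for the simulated samples.
#' @param seed integer RNG seed.
#' @return a \linkS4class{GenotypeData}.
#' @export
simulateAdmixed <- function(freqs, q, n = NULL, map = NULL,
                            breed = "ADMIXED", seed = 1) {
    set.seed(seed)
    K <- nrow(freqs); m <- ncol(freqs)
    if (is.null(dim(q))) {
        if (length(q) != K) stop("q must have one entry per ancestry")
        if (is.null(n)) stop("supply n when q is a vector")
        q <- matrix(q, n, K, byrow = TRUE)
    }
    if (any(q < 0)) stop("q entries must be non-negative")
    if (any(abs(rowSums(q) - 1) > 1e-9)) stop("q rows must sum to 1")
    n <- nrow(q)
    if (is.null(map)) map <- .simMap(m, 1, 40000)
    cum <- t(apply(q, 1, cumsum))
    draw_copy <- function() {
        u <- matrix(stats::runif(n * m), n, m)
        anc <- matrix(1L, n, m)
        for (k in seq_len(K - 1))
            anc <- anc + (u > cum[, k])
        pf <- matrix(freqs[cbind(as.vector(anc), rep(seq_len(m), each = n))],
                     n, m)
        matrix(stats::rbinom(n * m, 1, pf), n, m)
    }
    geno <- t(draw_copy() + draw_copy())
    GenotypeData(geno, map,
        data.frame(sample_id = sprintf("%s_%03d", breed, seq_len(n)),
                   breed = breed, stringsAsFactors = FALSE))
}
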