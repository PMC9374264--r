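#' @include AllClasses.R accessors.R genotype-io.R relatedness.R
NULL

#' Select representative samples per breed by MDS coverage
#'
#' Within each breed, IBS similarity is computed from a random marker
#' subsample and the samples are grouped by single-linkage at the similarity
#' threshold; picks are allocated across groups proportionally to group size
#' and chosen inside each group by maximin spread on the principal
#' coordinates (the first pick is the sample closest to the group centroid).
#' Near-duplicate candidates (similarity > 0.99 to an already-picked sample)
#' are deferred, so at most one of an identical pair is selected. Requesting
#' at least the breed size returns every sample.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param per_breed_n representatives to pick per breed.
#' @param similarity_threshold IBS similarity grouping threshold.
#' @param dims principal-coordinate dimensions.
#' @param markers_sampled markers randomly subsampled for the similarity.
#' @param seed integer RNG seed.
#' @param exclude sample ids never selected (e.g. known outliers).
#' @return character vector of selected sample ids.
#' @export
representativeSamples <- function(gm, per_breed_n,
                                  similarity_threshold = 0.75, dims = 3,
                                  markers_sampled = 3000, seed = 1,
                                  exclude = character(0)) {
    set.seed(seed)
    g <- genoMatrix(gm)
    midx <- if (nrow(g) > markers_sampled)
        sort(sample.int(nrow(g), markers_sampled)) else seq_len(nrow(g))
    picks <- character(0)
    for (br in unique(breeds(gm))) {
        ids <- setdiff(sampleIds(gm)[breeds(gm) == br], exclude)
        if (!length(ids)) next
        if (length(ids) <= per_breed_n) {
            if (length(ids) < per_breed_n)
                warning("breed ", br, ": only ", length(ids),
                        " samples available")
            picks <- c(picks, ids)
            next
        }
        sim <- .ibsSimilarity(g[midx, ids, drop = FALSE])
        co <- stats::cmdscale(as.dist(1 - sim),
                              k = min(dims, length(ids) - 1))
        ## single-linkage groups at the similarity threshold
        adj <- sim >= similarity_threshold
        grp <- .components(adj)
        sizes <- table(grp)
        alloc <- .proportionalAlloc(as.integer(sizes), per_breed_n)
        names(alloc) <- names(sizes)
        for (gname in names(sizes)) {
            members <- ids[grp == gname]
            want <- alloc[[gname]]
            if (!want) next
            cm <- co[grp == gname, , drop = FALSE]
            centroid <- colMeans(cm)
            sel <- integer(0)
            d0 <- sqrt(rowSums(sweep(cm, 2, centroid)^2))
            cand <- order(d0)
            while (length(sel) < want && length(cand)) {
                nxt <- NA_integer_
                for (cidx in cand) {
                    dup <- length(sel) &&
                        any(sim[ids %in% members[sel],
                                ids == members[cidx]] > 0.99)
                    if (!dup) { nxt <- cidx; break }
                }
                if (is.na(nxt)) nxt <- cand[1]   # only near-dups left
                sel <- c(sel, nxt)
                cand <- setdiff(cand, nxt)
                if (length(cand) > 1 && length(sel) < want) {
                    ## maximin: re-rank remaining by distance to picks
                    dmin <- apply(cm[cand, , drop = FALSE], 1, function(x)
                        min(sqrt(colSums((t(cm[sel, , drop = FALSE]) - x)^2))))
                    cand <- cand[order(-dmin)]
                }
            }
            picks <- c(picks, members[sel])
        }
    }
    picks
}

## connected components of a logical adjacency matrix (single linkage)
.components <- function(adj) {
    n <- nrow(adj)
    grp <- rep(NA_integer_, n)
    cur <- 0L
    for (i in seq_len(n)) {
        if (!is.na(grp[i])) next
        cur <- cur + 1L
        queue <- i
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (!is.na(grp[v])) next
            grp[v] <- cur
            queue <- c(queue, which(adj[v, ] & is.na(grp)))
        }
    }
    as.character(grp)
}

## largest-remainder allocation of n picks proportional to sizes (>=0 each,
## never exceeding a group's size)
.proportionalAlloc <- function(sizes, n) {
    n <- min(n, sum(sizes))
    quota <- n * sizes / sum(sizes)
    alloc <- floor(quota)
    rem <- n - sum(alloc)
    if (rem > 0) {
        ord <- order(-(quota - alloc))
        for (i in ord) {
            if (rem == 0) break
            if (alloc[i] < sizes[i]) { alloc[i] <- alloc[i] + 1; rem <- rem - 1 }
        }
    }
    while (rem > 0) {        # spill over group caps
        i <- which(alloc < sizes)[1]
        alloc[i] <- alloc[i] + 1; rem <- rem - 1
    }
    alloc
}

#' Quality control of the panel training set
#'
#' Applies, in order: sample and marker call-rate filters, the high-MAF
#' retention filter (markers must segregate broadly across the pooled
#' training set), strong LD pruning, and removal of any marker with a
#' missing call.
#'
#' @param gm_train training \linkS4class{GenotypeData}.
#' @param maf minimum pooled minor allele frequency.
#' @param r2,window,step LD-pruning parameters.
#' @param call_rate marker and sample call-rate threshold.
#' @return the filtered \linkS4class{GenotypeData}.
#' @export
panelQC <- function(gm_train, maf = 0.3, r2 = 0.2, window = 50, step = 5,
                    call_rate = 0.90) {
    qc <- qcFilter(gm_train, marker_call_rate = call_rate,
                   sample_call_rate = call_rate, maf = maf,
                   drop_sex = TRUE, drop_unmapped = TRUE, dup_ibs = 1)
    gm <- qc$gm
    keep <- ldPrune(gm, r2_threshold = r2, window_snps = window,
                    step_snps = step)
    gm <- dropIncompleteMarkers(gm[keep, ])
    if (nrow(gm) == 0) stop("no markers survive panel QC")
    gm
}

#' Preselect SNPs by pairwise Fst against the focal breed
#'
#' For each (focal, other-breed) pair, per-SNP Weir-Cockerham Fst is ranked
#' and the top fraction retained (ties broken by Fst, then genomic order);
#' the union across pairs is returned with per-SNP provenance naming the
#' comparisons that selected it.
#'
#' @param gm_train training \linkS4class{GenotypeData}.
#' @param focal_breed the breed the panel must distinguish.
#' @param top_frac fraction of SNPs kept per pairwise comparison.
#' @return data.frame: marker, chr, pos, fst_pairs (comma-separated),
#'   max_fst.
#' @export
fstPreselect <- function(gm_train, focal_breed, top_frac = 0.05) {
    br <- unique(breeds(gm_train))
    if (!focal_breed %in% br) stop("focal breed absent from training set")
    others <- setdiff(br, focal_breed)
    if (!length(others)) stop("need at least one non-focal breed")
    map <- markerMap(gm_train)
    n_top <- ceiling(top_frac * nrow(map))
    prov <- list(); maxfst <- stats::setNames(rep(-Inf, nrow(map)), map$marker)
    for (ob in others) {
        fst <- pairwiseFst(gm_train, focal_breed, ob)$per_snp
        ok <- which(!is.na(fst$fst))
        if (!length(ok)) {
            warning("Fst undefined for every SNP in pair ", focal_breed,
                    "-", ob, "; pair skipped")
            next
        }
        ord <- ok[order(-fst$fst[ok], .chrOrder(fst$chr[ok]), fst$pos[ok])]
        top <- ord[seq_len(min(n_top, length(ord)))]
        pair <- paste0(focal_breed, "-", ob)
        for (j in top) {
            mk <- fst$marker[j]
            prov[[mk]] <- c(prov[[mk]], pair)
            maxfst[mk] <- max(maxfst[mk], fst$fst[j])
        }
    }
    sel <- names(prov)
    idx <- match(sel, map$marker)
    o <- order(.chrOrder(map$chr[idx]), map$pos[idx])
    data.frame(marker = sel[o], chr = map$chr[idx][o], pos = map$pos[idx][o],
               fst_pairs = vapply(prov[sel[o]], paste, "", collapse = ","),
               max_fst = unname(maxfst[sel[o]]),
               stringsAsFactors = FALSE, row.names = NULL)
}

## canonical discriminant analysis of dosages vs breed, one chromosome.
## Returns per-variable standardized coefficients for each canonical
## function on which the focal centroid is separated from every other
## centroid by > sep_sd pooled within-class SDs (lda scores have unit
## within-class variance).
.cdaChromosome <- function(X, classes, focal, sep_sd) {
    keep <- which(apply(X, 2, stats::var) > 0)
    if (length(keep) < 2) return(NULL)
    X <- X[, keep, drop = FALSE]
    fit <- tryCatch(
        suppressWarnings(MASS::lda(X, grouping = classes, tol = 1e-9)),
        error = function(e) NULL)
    if (is.null(fit)) {
        ## zero within-class variance (perfect discriminators) defeats
        ## MASS::lda; fall back to a deterministic ridge-regularized CDA
        fit <- .ridgeCDA(X, classes)
    } else {
        fit <- list(scaling = fit$scaling,
                    means = fit$means[, colnames(X), drop = FALSE])
    }
    sc <- fit$scaling
    centroids <- fit$means %*% sc
    fi <- which(rownames(centroids) == focal)
    ## standardize by total SD: pooled within-class SD is exactly zero for a
    ## perfectly separating variable, which would invert the intended ranking
    tot_sd <- apply(X, 2, stats::sd)
    out <- list()
    for (j in seq_len(ncol(sc))) {
        gap <- min(abs(centroids[-fi, j] - centroids[fi, j]))
        if (gap <= sep_sd) next
        out[[paste0("LD", j)]] <- abs(sc[, j]) * tot_sd
    }
    out
}

## canonical discriminant directions from eigen(solve(W + ridge, B));
## scaled to (near-)unit pooled within-class variance, like MASS::lda
.ridgeCDA <- function(X, classes) {
    mu <- colMeans(X)
    groups <- split(seq_len(nrow(X)), classes)
    p <- ncol(X)
    W <- matrix(0, p, p); B <- matrix(0, p, p)
    for (ix in groups) {
        Xi <- X[ix, , drop = FALSE]
        mi <- colMeans(Xi)
        W <- W + crossprod(sweep(Xi, 2, mi))
        B <- B + length(ix) * tcrossprod(mi - mu)
    }
    W <- W / (nrow(X) - length(groups))
    B <- B / (length(groups) - 1)
    lam <- 1e-6 * (mean(diag(W)) + 1e-8)
    Wr <- W + diag(lam, p)
    e <- eigen(solve(Wr, B))
    k <- min(length(groups) - 1, p)
    sc <- Re(e$vectors[, seq_len(k), drop = FALSE])
    ## normalize each direction to unit within-class variance
    for (j in seq_len(k)) {
        s <- sqrt(drop(crossprod(sc[, j], Wr %*% sc[, j])))
        sc[, j] <- sc[, j] / s
        ## deterministic sign: largest-magnitude element positive
        i0 <- which.max(abs(sc[, j]))
        if (sc[i0, j] < 0) sc[, j] <- -sc[, j]
    }
    rownames(sc) <- colnames(X)
    colnames(sc) <- paste0("LD", seq_len(k))
    means <- do.call(rbind, lapply(groups, function(ix)
        colMeans(X[ix, , drop = FALSE])))
    list(scaling = sc, means = means)
}


#' Select panel SNPs by per-chromosome canonical discriminant analysis
#'
#' On each chromosome, a multi-class canonical discriminant analysis of
#' genotype dosages against breed is fitted; canonical functions whose focal
#' centroid sits more than \code{sep_sd} pooled within-class SDs from every
#' other centroid are deemed focal-separating. On those functions, SNPs with
#' extreme standardized coefficients (raw coefficients scaled by each
#' variable's total SD; the pooled within-class SD would degenerate to zero
#' for a perfect discriminator) are selected: magnitude above
#' mean + \code{sd_multiplier} x SD of the function's coefficient magnitudes.
#' Magnitudes are used so selection is invariant to allele
#' coding. Single-SNP chromosomes bypass the analysis and pass through.
#'
#' @param gm training \linkS4class{GenotypeData} restricted to preselected
#'   SNPs.
#' @param focal_breed focal breed label.
#' @param sd_multiplier extremeness multiplier (default 2).
#' @param sep_sd centroid-separation rule in within-class SDs (default 3).
#' @return data.frame: marker, cda_function, cda_score.
#' @export
cdaSelect <- function(gm, focal_breed, sd_multiplier = 2.0, sep_sd = 3.0) {
    map <- markerMap(gm)
    classes <- factor(breeds(gm))
    D <- dosages(gm)
    out <- list()
    for (ch in unique(map$chr)) {
        mk <- map$marker[map$chr == ch]
        if (length(mk) == 1) {   # pass-through: CDA needs >= 2 variables
            out[[length(out) + 1]] <- data.frame(
                marker = mk, cda_function = paste0("chr", ch, ":passthrough"),
                cda_score = NA_real_, stringsAsFactors = FALSE)
            next
        }
        sel <- .cdaChromosome(D[, mk, drop = FALSE], classes, focal_breed,
                              sep_sd)
        if (is.null(sel) || !length(sel)) next
        for (fn in names(sel)) {
            sc <- sel[[fn]]
            thr <- mean(sc) + sd_multiplier * stats::sd(sc)
            hit <- names(sc)[sc > thr]
            if (length(hit))
                out[[length(out) + 1]] <- data.frame(
                    marker = hit, cda_function = paste0("chr", ch, ":", fn),
                    cda_score = unname(sc[hit]), stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(marker = character(0), cda_function = character(0),
                          cda_score = numeric(0)))
    res <- do.call(rbind, out)
    ## one row per marker; keep the strongest score
    res <- res[order(res$marker, -ifelse(is.na(res$cda_score), Inf,
                                         res$cda_score)), ]
    res[!duplicated(res$marker), , drop = FALSE]
}

#' Build a breed-distinctive SNP panel end-to-end
#'
#' Orchestrates the full selection pipeline: representative training samples
#' per breed, training-set QC (high-MAF retention, strong LD pruning,
#' missing-call removal), pairwise-Fst preselection against the focal breed,
#' and per-chromosome canonical discriminant selection. Also assembles
#' held-out validation sets (disjoint from training; known outliers are
#' excluded from training and appended to the last validation sets).
#'
#' @param gm_full the full multi-breed \linkS4class{GenotypeData}.
#' @param focal_breed the breed the panel must distinguish.
#' @param split_config list of design knobs: \code{train_per_breed} (20),
#'   \code{n_validation} (16), \code{val_focal_n} (10),
#'   \code{val_other_range} (c(6, 14)), \code{outliers} (sample ids treated
#'   as mislabelled focal animals).
#' @param seed integer RNG seed; the whole pipeline is deterministic given
#'   the seed.
#' @param maf,r2,top_frac,sd_multiplier,sep_sd stage parameters (see the
#'   stage functions).
#' @return list with \code{panel} (\linkS4class{Panel}) and \code{split}
#'   (training GenotypeData, list of validation GenotypeData, outlier ids).
#' @export
buildPanel <- function(gm_full, focal_breed, split_config = list(),
                       seed = 1, maf = 0.3, r2 = 0.2, top_frac = 0.05,
                       sd_multiplier = 2.0, sep_sd = 3.0) {
    cfg <- utils::modifyList(list(train_per_breed = 20, n_validation = 16,
                                  val_focal_n = 10,
                                  val_other_range = c(6, 14),
                                  outliers = character(0)), split_config)
    if (!focal_breed %in% breeds(gm_full)) stop("focal breed not present")
    set.seed(seed)
    train_ids <- representativeSamples(gm_full, cfg$train_per_breed,
                                       seed = seed, exclude = cfg$outliers)
    gm_train <- gm_full[, train_ids]
    ## held-out pool per breed
    pool <- setdiff(sampleIds(gm_full), c(train_ids, cfg$outliers))
    br_pool <- split(pool, breeds(gm_full)[match(pool, sampleIds(gm_full))])
    validation <- vector("list", cfg$n_validation)
    for (v in seq_len(cfg$n_validation)) {
        ids <- character(0)
        for (br in names(br_pool)) {
            avail <- br_pool[[br]]
            want <- if (br == focal_breed) cfg$val_focal_n else
                sample(seq(cfg$val_other_range[1], cfg$val_other_range[2]), 1)
            ids <- c(ids, sample(avail, min(want, length(avail))))
        }
        ## the last sets carry the planted outliers, one each
        n_out <- length(cfg$outliers)
        if (n_out && v > cfg$n_validation - n_out)
            ids <- c(ids, cfg$outliers[v - (cfg$n_validation - n_out)])
        validation[[v]] <- gm_full[, ids]
    }
    gm_qc <- panelQC(gm_train, maf = maf, r2 = r2)
    pre <- fstPreselect(gm_qc, focal_breed, top_frac = top_frac)
    cda <- cdaSelect(gm_qc[pre$marker, ], focal_breed,
                     sd_multiplier = sd_multiplier, sep_sd = sep_sd)
    map <- markerMap(gm_qc)
    idx <- match(cda$marker, map$marker)
    snps <- data.frame(marker = cda$marker, chr = map$chr[idx],
                       pos = map$pos[idx], a1 = map$a1[idx],
                       a2 = map$a2[idx],
                       fst_pairs = pre$fst_pairs[match(cda$marker,
                                                       pre$marker)],
                       cda_function = cda$cda_function,
                       cda_score = cda$cda_score,
                       stringsAsFactors = FALSE, row.names = NULL)
    if (nrow(snps) == 0)
        stop("no SNPs selected; the focal breed may not be separable ",
             "under the current thresholds")
    snps <- snps[order(.chrOrder(snps$chr), snps$pos), , drop = FALSE]
    rownames(snps) <- NULL
    list(panel = new("Panel", snps = snps, focal = focal_breed),
         split = list(training = gm_train, validation = validation,
                      outliers = cfg$outliers))
}
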