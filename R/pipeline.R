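#' @include AllClasses.R accessors.R genotype-io.R diversity.R roh.R grm.R
#' @include ne.R relatedness.R admixture.R panel.R panel-validate.R
NULL

#' Genomic characterization of one breed
#'
#' Runs the within-breed characterization stack: quality control, windowed
#' nucleotide diversity and Tajima's D with significance limits, ROH
#' detection and \eqn{F_{ROH}}, both GRM-based inbreeding estimators,
#' pedigree inbreeding, LD-based historical Ne with linear extrapolation,
#' and (when a pedigree is supplied) pedigree-based Ne. The inbreeding
#' summary mirrors a methods-by-statistics table (mean, SE, min, max).
#'
#' @param gm a \linkS4class{GenotypeData} (one breed, or filtered to one).
#' @param ped optional \linkS4class{Pedigree} for the same animals.
#' @param config list of overrides: \code{qc} (args to \code{qcFilter};
#'   \code{maf = 0} skips the MAF edit for the diversity stage as frequency
#'   filtering biases diversity), \code{window_bp}, \code{roh}
#'   (\code{rohParams} args), \code{cm_per_mb}, \code{recent_generations}.
#' @return list: qc report, diversity table, Tajima limits, rohset, froh,
#'   inbreeding summary data.frame, ne series (extrapolated), pedigree_ne.
#' @export
runCharacterize <- function(gm, ped = NULL, config = list()) {
    cfg <- utils::modifyList(list(
        qc = list(), window_bp = 1e6, roh = list(), cm_per_mb = 1.0,
        recent_generations = 54), config)
    ## diversity uses QC without the MAF edit; inbreeding/Ne use the full QC
    qc_div <- do.call(qcFilter,
                      c(list(gm), utils::modifyList(cfg$qc, list(maf = 0))))
    qc_full <- do.call(qcFilter, c(list(gm), cfg$qc))
    gmd <- qc_div$gm; gmi <- qc_full$gm
    pi_tab <- windowedPi(gmd, cfg$window_bp)
    td_tab <- windowedTajimaD(gmd, cfg$window_bp)
    limits <- tajimaDLimits(2 * ncol(gmd))
    roh <- detectROH(gmd, do.call(rohParams, cfg$roh))
    f_roh <- froh(roh, autosomeLengthKb(gmd))
    g_vr <- grmVanRaden(gmi)
    g_as <- grmAllelicSimilarity(gmi)
    f_list <- list(VanRaden = inbreeding(g_vr),
                   AllelicSimilarity = inbreeding(g_as),
                   ROH = f_roh)
    ped_ne <- NULL
    if (!is.null(ped)) {
        f_ped <- pedigreeInbreeding(ped)
        f_list <- c(list(Pedigree = f_ped), f_list)
        ped_ne <- tryCatch(pedigreeNe(ped), error = function(e) NULL)
    }
    summ <- do.call(rbind, lapply(names(f_list), function(nm) {
        x <- f_list[[nm]]
        data.frame(method = nm, mean = mean(x),
                   se = stats::sd(x) / sqrt(length(x)),
                   min = min(x), max = max(x), stringsAsFactors = FALSE)
    }))
    ne <- tryCatch(suppressWarnings({
        bins <- ldDecayBins(gmi, cm_per_mb = cfg$cm_per_mb)
        extrapolateNe(historicalNe(bins), cfg$recent_generations)
    }), error = function(e) NULL)
    list(qc = qc_full$report, diversity = pi_tab, tajima = td_tab,
         tajima_limits = limits, roh = roh, froh = f_roh,
         inbreeding_summary = summ, ne = ne, pedigree_ne = ped_ne)
}

#' Between-breed relatedness analyses
#'
#' Representative sampling of an over-represented focal breed, LD pruning
#' and missing-call removal, then the three relatedness views: bootstrap NJ
#' consensus tree on IBS distances, per-pair Fst against the focal breed,
#' and unsupervised admixture with cross-validated K plus a breed-level
#' summary.
#'
#' @param gm the multi-breed \linkS4class{GenotypeData}.
#' @param config list of overrides: \code{focal}, \code{focal_n} (33),
#'   \code{outgroup}, \code{r2} (0.3), \code{n_boot} (100), \code{K_range},
#'   \code{folds} (5), \code{seed}.
#' @return list: pruned GenotypeData, consensus tree, fst table, cv table,
#'   best-K QMatrix, admixture summary.
#' @export
runRelatedness <- function(gm, config = list()) {
    cfg <- utils::modifyList(list(
        focal = breeds(gm)[1], focal_n = 33, outgroup = NULL, r2 = 0.3,
        n_boot = 100, K_range = seq_len(min(6, length(unique(breeds(gm))))),
        folds = 5, seed = 1), config)
    if (length(unique(breeds(gm))) < 2)
        stop("relatedness analyses need more than one breed")
    keep_focal <- representativeSamples(gm[, breeds(gm) == cfg$focal],
                                        cfg$focal_n, seed = cfg$seed)
    keep_ids <- union(keep_focal,
                      sampleIds(gm)[breeds(gm) != cfg$focal])
    gmr <- gm[, sampleIds(gm) %in% keep_ids]
    pruned <- ldPrune(gmr, r2_threshold = cfg$r2)
    gmr <- dropIncompleteMarkers(gmr[pruned, ])
    outg <- if (is.null(cfg$outgroup))
        utils::tail(unique(breeds(gmr)), 1) else cfg$outgroup
    tree <- bootstrapNjConsensus(gmr, n_boot = cfg$n_boot,
                                 outgroup_label = outg, seed = cfg$seed)
    others <- setdiff(unique(breeds(gmr)), cfg$focal)
    fst <- do.call(rbind, lapply(others, function(ob) {
        data.frame(pop_a = cfg$focal, pop_b = ob,
                   mean_fst = pairwiseFst(gmr, cfg$focal, ob)$mean)
    }))
    cv <- admixtureCV(gmr, K_range = cfg$K_range, folds = cfg$folds,
                      seed = cfg$seed)
    bestK <- cv$K[which.min(cv$cv_error)]
    qm <- admixtureEM(gmr, bestK, seed = cfg$seed, n_init = 2)
    summ <- admixtureSummary(qm, breeds(gmr))
    list(gm = gmr, tree = tree, fst = fst, cv = cv, qmatrix = qm,
         admixture_summary = summ)
}

#' Panel selection with full validation
#'
#' Builds the distinctive-SNP panel (\code{\link{buildPanel}}), validates it
#' by hierarchical clustering on the panel GRM and by binary canonical
#' discriminant classification on every held-out validation set, and
#' produces the per-chromosome aggregate-genotype table.
#'
#' @param gm the multi-breed \linkS4class{GenotypeData}.
#' @param focal_breed the breed the panel must distinguish.
#' @param config passed to \code{\link{buildPanel}} as \code{split_config};
#'   plus optional \code{seed}.
#' @return list: panel, split, clustering reports, classification reports,
#'   pooled accuracy, aggregate table.
#' @export
runPanel <- function(gm, focal_breed, config = list()) {
    seed <- if (is.null(config$seed)) 1 else config$seed
    config$seed <- NULL
    bp <- buildPanel(gm, focal_breed, split_config = config, seed = seed)
    clus <- lapply(bp$split$validation, function(v)
        validatePanelClustering(bp$panel, v,
                                outlier_ids = bp$split$outliers))
    clas <- lapply(bp$split$validation, function(v)
        classifyBinary(bp$panel, bp$split$training, v,
                       outlier_ids = bp$split$outliers))
    n_ok <- sum(vapply(clas, function(r) sum(diag(r@confusion)), numeric(1)))
    n_all <- sum(vapply(clas, function(r) sum(r@confusion), numeric(1)))
    agg <- aggregateGenotypes(bp$panel, gm, focal_breed)
    list(panel = bp$panel, split = bp$split, clustering = clus,
         classification = clas, pooled_accuracy = n_ok / n_all,
         aggregate = agg)
}
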