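#' @include AllClasses.R accessors.R panel.R grm.R relatedness.R
NULL

## within-cluster sum of squares of coords under an assignment
.withinInertia <- function(coords, cl) {
    sum(vapply(split(seq_len(nrow(coords)), cl), function(ix) {
        cm <- coords[ix, , drop = FALSE]
        sum(sweep(cm, 2, colMeans(cm))^2)
    }, numeric(1)))
}

#' Validate a panel by hierarchical clustering on its GRM
#'
#' The VanRaden relationship matrix restricted to the panel SNPs is
#' decomposed into principal components; Ward-linkage hierarchical
#' clustering on the leading coordinates is cut at the cluster count with
#' the largest relative within-inertia drop. The report records whether the
#' focal samples (outliers excluded) form one cluster containing no
#' non-focal sample, and where each planted outlier lands.
#'
#' @param panel a \linkS4class{Panel}.
#' @param validation_gm a validation \linkS4class{GenotypeData} (>= 3
#'   samples).
#' @param outlier_ids focal-labelled samples known to be mislabelled.
#' @param n_pcs principal components used (default 2: the leading
#'   components carry the panel's focal-separation signal, later ones mainly
#'   unrelated between-breed structure that dilutes the clustering).
#' @param max_k largest cluster count examined.
#' @return a \linkS4class{ValidationReport} (method "clustering").
#' @export
validatePanelClustering <- function(panel, validation_gm,
                                    outlier_ids = character(0),
                                    n_pcs = 2, max_k = 8) {
    if (ncol(validation_gm) < 3) stop("validation set needs >= 3 samples")
    snps <- intersect(panelTable(panel)$marker,
                      markerMap(validation_gm)$marker)
    if (!length(snps)) stop("no panel SNPs present in validation set")
    gm <- validation_gm[snps, ]
    G <- grmVanRaden(gm)
    co <- grmPCA(G, n_components = min(n_pcs, ncol(gm) - 1))
    if (all(stats::dist(co) < 1e-10)) {
        rep <- data.frame(sample = sampleIds(gm), breed = breeds(gm),
                          cluster = 1L)
        return(new("ValidationReport", method = "clustering",
                   assignments = rep, focalSeparated = FALSE,
                   outliers = data.frame(), confusion = table(NULL),
                   accuracy = NA_real_))
    }
    hc <- stats::hclust(stats::dist(co), method = "ward.D2")
    ks <- seq(2, min(max_k, ncol(gm) - 1))
    W1 <- .withinInertia(co, rep(1, nrow(co)))
    W <- c(W1, vapply(ks, function(k)
        .withinInertia(co, stats::cutree(hc, k)), numeric(1)))
    drops <- (W[-length(W)] - W[-1]) / W[-length(W)]
    drops[W[-length(W)] <= 1e-9 * W1] <- -Inf   # inertia already negligible
    k_best <- ks[which.max(drops)]
    cl <- stats::cutree(hc, k_best)
    br <- breeds(gm)
    ids <- sampleIds(gm)
    is_out <- ids %in% outlier_ids
    focal_cl <- unique(cl[br == panel@focal & !is_out])
    pure <- length(focal_cl) == 1 &&
        !any(cl == focal_cl & !(br == panel@focal & !is_out))
    out_tab <- if (any(is_out)) {
        data.frame(sample = ids[is_out], cluster = cl[is_out],
                   outside_focal_cluster =
                       !(cl[is_out] %in% focal_cl) || length(focal_cl) != 1)
    } else data.frame()
    new("ValidationReport", method = "clustering",
        assignments = data.frame(sample = ids, breed = br, cluster = cl,
                                 stringsAsFactors = FALSE),
        focalSeparated = pure, outliers = out_tab,
        confusion = table(NULL), accuracy = NA_real_)
}

#' Binary focal-vs-other classification with the panel
#'
#' A two-class linear discriminant on panel-SNP dosages is fitted to the
#' training samples (focal breed vs all others) and applied to the test
#' samples. Missing dosages are imputed to the training mean. Planted
#' outliers, being mislabelled focal animals, are expected on the non-focal
#' side.
#'
#' @param panel a \linkS4class{Panel}.
#' @param gm_train,gm_test training and test \linkS4class{GenotypeData}.
#' @param outlier_ids test samples whose expected class is non-focal despite
#'   their focal label.
#' @return a \linkS4class{ValidationReport} (method "classification") with
#'   confusion counts and accuracy.
#' @export
classifyBinary <- function(panel, gm_train, gm_test,
                           outlier_ids = character(0)) {
    snps <- panelTable(panel)$marker
    tr_sn <- intersect(snps, markerMap(gm_train)$marker)
    te_sn <- intersect(tr_sn, markerMap(gm_test)$marker)
    if (!length(te_sn)) stop("no panel SNPs shared by training and test")
    Xtr <- dosages(gm_train[te_sn, ])
    ytr <- factor(ifelse(breeds(gm_train) == panel@focal, "focal", "other"),
                  levels = c("focal", "other"))
    if (nlevels(droplevels(ytr)) < 2)
        stop("training set must contain both classes")
    mu <- colMeans(Xtr, na.rm = TRUE)
    imp <- function(X) {
        for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
        X
    }
    Xtr <- imp(Xtr)
    keep <- apply(Xtr, 2, stats::var) > 0
    Xk <- Xtr[, keep, drop = FALSE]
    Xte <- imp(dosages(gm_test[te_sn, ]))[, keep, drop = FALSE]
    fit <- tryCatch(
        suppressWarnings(MASS::lda(Xk, grouping = ytr, tol = 1e-9)),
        error = function(e) NULL)
    pred <- if (!is.null(fit)) {
        stats::predict(fit, Xte)$class
    } else {
        ## perfect discriminators have zero within-class variance, which
        ## MASS::lda rejects; use a ridge-regularized Fisher direction
        mu_f <- colMeans(Xk[ytr == "focal", , drop = FALSE])
        mu_o <- colMeans(Xk[ytr == "other", , drop = FALSE])
        W <- (crossprod(sweep(Xk[ytr == "focal", , drop = FALSE], 2, mu_f)) +
              crossprod(sweep(Xk[ytr == "other", , drop = FALSE], 2, mu_o))) /
             (nrow(Xk) - 2)
        W <- W + diag(1e-6 * (mean(diag(W)) + 1e-8), ncol(Xk))
        w <- solve(W, mu_f - mu_o)
        thr <- drop(crossprod(w, (mu_f + mu_o) / 2))
        factor(ifelse(Xte %*% w > thr, "focal", "other"),
               levels = c("focal", "other"))
    }
    truth <- factor(ifelse(breeds(gm_test) == panel@focal &
                           !(sampleIds(gm_test) %in% outlier_ids),
                           "focal", "other"), levels = c("focal", "other"))
    conf <- table(truth = truth, predicted = pred)
    acc <- mean(pred == truth)
    out_tab <- if (any(sampleIds(gm_test) %in% outlier_ids)) {
        oi <- sampleIds(gm_test) %in% outlier_ids
        data.frame(sample = sampleIds(gm_test)[oi],
                   predicted = as.character(pred)[oi],
                   outside_focal_cluster = as.character(pred)[oi] != "focal")
    } else data.frame()
    new("ValidationReport", method = "classification",
        assignments = data.frame(sample = sampleIds(gm_test),
                                 breed = breeds(gm_test),
                                 predicted = as.character(pred),
                                 truth = as.character(truth),
                                 stringsAsFactors = FALSE),
        focalSeparated = NA, outliers = out_tab, confusion = conf,
        accuracy = acc)
}

#' Aggregate panel genotypes per chromosome
#'
#' For each chromosome with more than one panel SNP, the focal breed's most
#' frequent allele at each SNP forms an aggregate allele combination; its
#' frequency per breed is approximated as the product of per-SNP allele
#' frequencies (linkage-equilibrium approximation; flagged as approximate).
#' Single-SNP chromosomes are reported with a dash, without an aggregate.
#'
#' @param panel a \linkS4class{Panel}.
#' @param gm a \linkS4class{GenotypeData} containing the panel SNPs.
#' @param focal_breed focal breed label.
#' @return data.frame: chr, block_size, aggregate, freq_focal,
#'   freq_others_max.
#' @export
aggregateGenotypes <- function(panel, gm, focal_breed) {
    ptab <- panelTable(panel)
    snps <- intersect(ptab$marker, markerMap(gm)$marker)
    gm <- gm[snps, ]
    map <- markerMap(gm)
    g <- genoMatrix(gm)
    br <- breeds(gm)
    ub <- unique(br)
    freq_a2 <- sapply(ub, function(b)
        rowMeans(g[, br == b, drop = FALSE], na.rm = TRUE) / 2)
    if (is.null(dim(freq_a2))) freq_a2 <- matrix(freq_a2, nrow = 1,
                                                 dimnames = list(snps, ub))
    rows <- list()
    for (ch in unique(map$chr)) {
        idx <- which(map$chr == ch)
        if (length(idx) == 1) {
            rows[[length(rows) + 1]] <- data.frame(
                chr = ch, block_size = 1L, aggregate = "-",
                freq_focal = NA_real_, freq_others_max = NA_real_,
                stringsAsFactors = FALSE)
            next
        }
        pf <- freq_a2[idx, focal_breed]
        use_a2 <- pf >= 0.5
        alle <- ifelse(use_a2, map$a2[idx], map$a1[idx])
        per_breed <- vapply(ub, function(b) {
            p <- freq_a2[idx, b]
            prod(ifelse(use_a2, p, 1 - p))
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
            chr = ch, block_size = length(idx),
            aggregate = paste(alle, collapse = ""),
            freq_focal = unname(per_breed[focal_breed]),
            freq_others_max = max(per_breed[setdiff(ub, focal_breed)]),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "note") <-
        "frequencies are linkage-equilibrium products (approximate)"
    out
}
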