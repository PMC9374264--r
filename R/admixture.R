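#' @include AllClasses.R accessors.R
NULL

## binomial log-likelihood of genotypes under P = Q F (ignoring the
## constant choose(2, g) term); obs entries only
.admixLoglik <- function(g0, twoMinus, P, obs) {
    sum((g0 * log(P) + twoMinus * log(1 - P))[obs])
}

#' Maximum-likelihood unsupervised admixture by EM
#'
#' Fits the K-ancestry binomial mixture
#' \deqn{\ell = \sum_{i,m} g_{im} \log(\sum_k q_{ik} f_{km}) +
#'       (2-g_{im}) \log(1 - \sum_k q_{ik} f_{km})}
#' by block EM updates of the ancestry proportions q and ancestral
#' frequencies f, with frequencies clamped to [1e-6, 1-1e-6]. Missing
#' genotypes are ignored in both likelihood and updates. Several random
#' initializations can be run, keeping the best likelihood.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param K number of ancestral populations (>= 1).
#' @param seed integer RNG seed.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter EM iteration cap (warning on non-convergence).
#' @param n_init random restarts.
#' @return a \linkS4class{QMatrix}.
#' @export
admixtureEM <- function(gm, K, seed = 1, tol = 1e-6, max_iter = 2000,
                        n_init = 1) {
    stopifnot(K >= 1)
    set.seed(seed)
    g <- dosages(gm)           # samples x markers
    n <- nrow(g); m <- ncol(g)
    obs <- !is.na(g)
    g0 <- g; g0[!obs] <- 0
    twoMinus <- (2 - g); twoMinus[!obs] <- 0
    Mi <- rowSums(obs)
    pooled <- colMeans(g, na.rm = TRUE) / 2
    clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
    if (K == 1) {
        f <- clamp(matrix(pooled, 1, m))
        P <- matrix(f, n, m, byrow = TRUE)
        ll <- .admixLoglik(g0, twoMinus, P, obs)
        return(new("QMatrix", Q = matrix(1, n, 1,
                       dimnames = list(rownames(g), "K1")),
                   F = f, loglik = ll, converged = TRUE,
                   cv = data.frame()))
    }
    best <- NULL
    for (init in seq_len(n_init)) {
        q <- matrix(stats::rgamma(n * K, 1), n, K)
        q <- q / rowSums(q)
        f <- clamp(matrix(rep(pooled, each = K), K, m) +
                   matrix(stats::runif(K * m, -0.1, 0.1), K, m))
        ll_old <- -Inf; converged <- FALSE
        for (it in seq_len(max_iter)) {
            P <- q %*% f
            P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
            U <- (g0 / P) * obs
            V <- (twoMinus / (1 - P)) * obs
            qnum <- matrix(0, n, K)
            fnum <- fden <- matrix(0, K, m)
            for (k in seq_len(K)) {
                u_k <- U %*% f[k, ]          # n x 1
                v_k <- V %*% (1 - f[k, ])
                qnum[, k] <- q[, k] * (u_k + v_k)
                tu <- crossprod(U, q[, k])   # m x 1
                tv <- crossprod(V, q[, k])
                fnum[k, ] <- f[k, ] * tu
                fden[k, ] <- fnum[k, ] + (1 - f[k, ]) * tv
            }
            q <- qnum / (2 * Mi)
            q <- q / rowSums(q)              # guard against rounding
            f <- clamp(fnum / pmax(fden, 1e-12))
            ll <- .admixLoglik(g0, twoMinus,
                               pmin(pmax(q %*% f, 1e-9), 1 - 1e-9), obs)
            if (is.finite(ll_old) &&
                abs(ll - ll_old) < tol * (abs(ll) + 1)) {
                converged <- TRUE
                ll_old <- ll
                break
            }
            ll_old <- ll
        }
        if (is.null(best) || ll_old > best$ll)
            best <- list(q = q, f = f, ll = ll_old, converged = converged)
    }
    if (!best$converged)
        warning("admixture EM did not converge in ", max_iter, " iterations")
    dimnames(best$q) <- list(rownames(g), paste0("K", seq_len(K)))
    new("QMatrix", Q = best$q, F = best$f, loglik = best$ll,
        converged = best$converged, cv = data.frame())
}

#' Cross-validated choice of the number of ancestral populations
#'
#' Observed genotype entries are partitioned into \code{folds} masks; for
#' each fold the model is fitted with the masked entries hidden and the
#' masked genotypes are scored by their binomial prediction deviance
#' \eqn{-2[g \log \hat p + (2-g) \log(1-\hat p)]} under
#' \eqn{\hat p = \sum_k q_{ik} f_{km}}. The per-K error is the mean masked
#' deviance across folds; the K with the smallest error is preferred.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param K_range candidate K values.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer RNG seed (controls both masks and EM starts).
#' @param ... passed to \code{\link{admixtureEM}}.
#' @return data.frame with K and cv_error.
#' @export
admixtureCV <- function(gm, K_range = 1:5, folds = 5, seed = 1, ...) {
    if (folds < 2) stop("folds must be >= 2")
    set.seed(seed)
    g <- dosages(gm)
    obs_idx <- which(!is.na(g))
    fold_of <- sample(rep_len(seq_len(folds), length(obs_idx)))
    out <- data.frame(K = K_range, cv_error = NA_real_)
    for (ki in seq_along(K_range)) {
        K <- K_range[ki]
        dev <- numeric(folds)
        for (fd in seq_len(folds)) {
            masked <- obs_idx[fold_of == fd]
            gtrain <- g
            gtrain[masked] <- NA
            gmf <- GenotypeData(t(gtrain), markerMap(gm),
                data.frame(sample_id = sampleIds(gm), breed = breeds(gm),
                           stringsAsFactors = FALSE))
            fit <- suppressWarnings(
                admixtureEM(gmf, K, seed = seed + 1000 * fd + K, ...))
            P <- pmin(pmax(qMatrix(fit) %*% fit@F, 1e-9), 1 - 1e-9)
            gv <- g[masked]
            pv <- P[masked]
            dev[fd] <- mean(-2 * (gv * log(pv) + (2 - gv) * log(1 - pv)))
        }
        out$cv_error[ki] <- mean(dev)
    }
    out
}

#' Breed-by-cluster mean admixture proportions
#'
#' Averages the Q matrix within breeds and names clusters a posteriori by
#' the breed with the highest mean membership; when two breeds share a
#' maximal cluster the labels are suffixed and a warning raised.
#'
#' @param q a \linkS4class{QMatrix} (or plain Q matrix).
#' @param breed_labels per-sample breed labels aligned with Q rows.
#' @return breed x cluster matrix of mean percentages (rows sum to 100).
#' @export
admixtureSummary <- function(q, breed_labels) {
    Q <- if (is(q, "QMatrix")) qMatrix(q) else q
    stopifnot(nrow(Q) == length(breed_labels))
    means <- do.call(rbind, lapply(split(seq_len(nrow(Q)), breed_labels),
        function(ix) colMeans(Q[ix, , drop = FALSE])))
    cl_names <- rownames(means)[apply(means, 2, which.max)]
    if (anyDuplicated(cl_names)) {
        warning("ambiguous cluster naming; labels suffixed")
        cl_names <- make.unique(cl_names)
    }
    colnames(means) <- cl_names
    100 * means
}
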