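#' @include AllClasses.R
NULL

#' Accessors for GenotypeData and derived objects
#'
#' \code{genoMatrix} returns the markers x samples integer call matrix;
#' \code{dosages} its transpose (samples x markers), the orientation most
#' statistics use; \code{markerMap} the marker map as a data.frame;
#' \code{breeds} the per-sample breed labels; \code{sampleIds} the sample ids.
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @return See individual descriptions.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))
#' @rdname genotype-accessors
#' @export
setMethod("genoMatrix", "GenotypeData", function(x) assay(x, "geno"))

#' @rdname genotype-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname genotype-accessors
#' @export
setMethod("dosages", "GenotypeData", function(x) t(assay(x, "geno")))

#' @rdname genotype-accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname genotype-accessors
#' @export
setMethod("markerMap", "GenotypeData", function(x) {
    as.data.frame(rowData(x), row.names = NULL)
})

#' @rdname genotype-accessors
#' @export
setGeneric("breeds", function(x) standardGeneric("breeds"))
#' @rdname genotype-accessors
#' @export
setMethod("breeds", "GenotypeData", function(x) {
    b <- colData(x)$breed
    names(b) <- colnames(x)
    as.character(b)
})

#' @rdname genotype-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname genotype-accessors
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

#' Per-sample inbreeding coefficients
#'
#' For a \linkS4class{GRM} built with the VanRaden method this is
#' \eqn{G_{ii} - 1}; for the allelic-similarity method \eqn{2 S_{ii} - 1}
#' (the proportion of homozygous loci).
#'
#' @param x a GRM object.
#' @return named numeric vector of inbreeding coefficients.
#' @export
setGeneric("inbreeding", function(x) standardGeneric("inbreeding"))

#' @rdname inbreeding
#' @export
setMethod("inbreeding", "GRM", function(x) {
    d <- diag(x@mat)
    if (x@method == "vanraden") d - 1 else 2 * d - 1
})

#' Relationship matrix of a GRM object
#' @param x a GRM object.
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))
#' @rdname grmMatrix
#' @export
setMethod("grmMatrix", "GRM", function(x) x@mat)

#' ROH segments table
#' @param x a ROHSet object.
#' @return data.frame mirroring PLINK .hom columns (sample, chr, start_bp,
#'   end_bp, n_snps, length_kb).
#' @export
setGeneric("rohSegments", function(x) standardGeneric("rohSegments"))
#' @rdname rohSegments
#' @export
setMethod("rohSegments", "ROHSet", function(x) x@segments)

#' Total ROH length per sample, in kb
#' @param x a ROHSet object.
#' @export
setGeneric("rohTotalKb", function(x) standardGeneric("rohTotalKb"))
#' @rdname rohTotalKb
#' @export
setMethod("rohTotalKb", "ROHSet", function(x) {
    tot <- setNames(numeric(length(x@samples)), x@samples)
    if (nrow(x@segments)) {
        agg <- tapply(x@segments$length_kb, x@segments$sample, sum)
        tot[names(agg)] <- agg
    }
    tot
})

#' Pedigree records
#' @param x a Pedigree object.
#' @export
setGeneric("pedTable", function(x) standardGeneric("pedTable"))
#' @rdname pedTable
#' @export
setMethod("pedTable", "Pedigree", function(x) x@df)

#' Ne trajectory table
#' @param x a NeSeries object.
#' @export
setGeneric("neTable", function(x) standardGeneric("neTable"))
#' @rdname neTable
#' @export
setMethod("neTable", "NeSeries", function(x) x@bins)

#' Admixture proportions
#' @param x a QMatrix object.
#' @export
setGeneric("qMatrix", function(x) standardGeneric("qMatrix"))
#' @rdname qMatrix
#' @export
setMethod("qMatrix", "QMatrix", function(x) x@Q)

#' Panel SNP table
#' @param x a Panel object.
#' @export
setGeneric("panelTable", function(x) standardGeneric("panelTable"))
#' @rdname panelTable
#' @export
setMethod("panelTable", "Panel", function(x) x@snps)

#' QC report log
#' @param x a QCReport object.
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))
#' @rdname qcLog
#' @export
setMethod("qcLog", "QCReport", function(x) x@log)

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "markers x", ncol(object), "samples\n")
    b <- table(breeds(object))
    cat("breeds:", paste(sprintf("%s(%d)", names(b), b), collapse = ", "), "\n")
    miss <- mean(is.na(assay(object, "geno")))
    cat(sprintf("missingness: %.2f%%\n", 100 * miss))
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport:", object@before$n_markers, "->", object@after$n_markers,
        "markers;", object@before$n_samples, "->", object@after$n_samples,
        "samples\n")
    if (nrow(object@log)) print(object@log, row.names = FALSE)
})

setMethod("show", "ROHSet", function(object) {
    cat("ROHSet:", nrow(object@segments), "segments in",
        length(object@samples), "samples\n")
})

setMethod("show", "GRM", function(object) {
    cat("GRM (", object@method, "): ", nrow(object@mat), " x ",
        ncol(object@mat), "\n", sep = "")
})

setMethod("show", "Pedigree", function(object) {
    cat("Pedigree:", nrow(object@df), "individuals,",
        sum(is.na(object@df$sire) & is.na(object@df$dam)), "founders\n")
})

setMethod("show", "NeSeries", function(object) {
    cat("NeSeries:", nrow(object@bins), "bins")
    if (length(object@fit))
        cat(sprintf("; Ne(now) = %.1f (R^2 = %.3f over t <= %d)",
                    object@fit$ne_now, object@fit$r_squared,
                    object@fit$recent_generations))
    cat("\n")
})

setMethod("show", "QMatrix", function(object) {
    cat("QMatrix:", nrow(object@Q), "samples x", ncol(object@Q),
        "clusters; logLik =", format(object@loglik), "\n")
})

setMethod("show", "Panel", function(object) {
    cat("Panel:", nrow(object@snps), "SNPs distinguishing '", object@focal,
        "' across", length(unique(object@snps$chr)), "chromosomes\n")
})

setMethod("show", "ValidationReport", function(object) {
    cat("ValidationReport (", object@method, ")\n", sep = "")
    if (object@method == "classification")
        cat(sprintf("accuracy: %.3f\n", object@accuracy))
    else
        cat("focal cluster pure:", object@focalSeparated, "\n")
})
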