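#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GenotypeData: SNP genotypes with marker map and breed labels
#'
#' A \linkS4class{SummarizedExperiment} holding biallelic SNP genotypes.
#' Rows are markers, columns are samples. The single assay \code{"geno"}
#' stores the count of the \code{a2} allele per call (0, 1, 2) with \code{NA}
#' for missing. \code{rowData} carries the marker map (\code{marker},
#' \code{chr}, \code{pos}, \code{a1}, \code{a2}); \code{colData} carries
#' \code{sample_id} and \code{breed}.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

.validGenotypeData <- function(object) {
    msg <- character()
    g <- assay(object, "geno")
    rd <- rowData(object)
    cd <- colData(object)
    need <- c("marker", "chr", "pos", "a1", "a2")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
    if (!"breed" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'breed' column")
    if (nrow(rd) > 0 && "marker" %in% colnames(rd) &&
        anyDuplicated(rd$marker))
        msg <- c(msg, "marker ids must be unique")
    bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
    if (any(bad))
        msg <- c(msg, "genotype calls must be 0, 1, 2 or NA")
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param geno integer matrix, markers x samples, entries 0/1/2/NA counting
#'   copies of the \code{a2} allele.
#' @param map data.frame with columns \code{marker}, \code{chr}, \code{pos},
#'   \code{a1}, \code{a2}. Markers are sorted by (chr, pos) on construction.
#' @param samples data.frame with columns \code{sample_id} and \code{breed},
#'   one row per column of \code{geno}.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' gm <- GenotypeData(
#'     geno = matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3),
#'     map = data.frame(marker = c("s1", "s2", "s3"), chr = "1",
#'                      pos = c(100L, 200L, 300L), a1 = "A", a2 = "G"),
#'     samples = data.frame(sample_id = c("x", "y"), breed = "B1"))
#' @export
GenotypeData <- function(geno, map, samples) {
    stopifnot(nrow(geno) == nrow(map), ncol(geno) == nrow(samples))
    o <- order(.chrOrder(map$chr), map$pos)
    map <- map[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
    storage.mode(geno) <- "integer"
    rownames(geno) <- map$marker
    colnames(geno) <- samples$sample_id
    se <- SummarizedExperiment(
        assays = list(geno = geno),
        rowData = DataFrame(map, row.names = map$marker),
        colData = DataFrame(samples, row.names = samples$sample_id))
    new("GenotypeData", se)
}

## autosome numbers first in numeric order, then other labels alphabetically
.chrOrder <- function(chr) {
    chr <- as.character(chr)
    n <- suppressWarnings(as.numeric(chr))
    ord <- ifelse(is.na(n), 1e6 + as.integer(factor(chr)), n)
    ord
}

#' QCReport: append-only log of genotype quality-control passes
#'
#' @slot log data.frame with columns \code{step}, \code{unit}
#'   ("marker"/"sample"), \code{reason}, \code{n_removed}.
#' @slot before,after named lists with \code{n_markers}, \code{n_samples}.
#' @export
setClass("QCReport", representation(
    log = "data.frame", before = "list", after = "list"))

#' ROHSet: runs of homozygosity per sample
#'
#' @slot segments data.frame with columns \code{sample}, \code{chr},
#'   \code{start_bp}, \code{end_bp}, \code{n_snps}, \code{length_kb}.
#' @slot samples character, every sample scanned (including those without ROH).
#' @slot params list of scan parameters used.
#' @export
setClass("ROHSet", representation(
    segments = "data.frame", samples = "character", params = "list"))

#' GRM: genomic relationship matrix
#'
#' @slot mat symmetric numeric matrix with sample ids as dimnames.
#' @slot method "vanraden" or "allelic_similarity".
#' @export
setClass("GRM", representation(mat = "matrix", method = "character"))

setValidity("GRM", function(object) {
    if (!isSymmetric(unname(object@mat), tol = 1e-8))
        return("relationship matrix must be symmetric")
    TRUE
})

#' Pedigree: (id, sire, dam) records
#'
#' Unknown parents are coded \code{NA} (or "0" on input). The pedigree must be
#' acyclic; construction reorders records so parents precede offspring.
#'
#' @slot df data.frame with columns \code{id}, \code{sire}, \code{dam}.
#' @export
setClass("Pedigree", representation(df = "data.frame"))

#' Construct a Pedigree
#'
#' @param id,sire,dam character vectors; "0", "" and NA denote unknown
#'   parents. Parents appearing only as sire/dam are added as founders.
#' @export
Pedigree <- function(id, sire, dam) {
    id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
    sire[sire %in% c("0", "")] <- NA
    dam[dam %in% c("0", "")] <- NA
    if (anyDuplicated(id)) stop("duplicated individual ids in pedigree")
    extra <- setdiff(c(sire, dam), c(id, NA))
    if (length(extra)) {
        id <- c(extra, id)
        sire <- c(rep(NA_character_, length(extra)), sire)
        dam <- c(rep(NA_character_, length(extra)), dam)
    }
    df <- .topoSortPedigree(data.frame(
        id = id, sire = sire, dam = dam, stringsAsFactors = FALSE))
    new("Pedigree", df = df)
}

## Kahn topological sort; names a cycle on failure
.topoSortPedigree <- function(df) {
    n <- nrow(df)
    idx <- seq_len(n)
    names(idx) <- df$id
    placed <- rep(FALSE, n)
    out <- integer(0)
    repeat {
        ready <- which(!placed &
            (is.na(df$sire) | df$sire %in% df$id[placed]) &
            (is.na(df$dam) | df$dam %in% df$id[placed]))
        if (!length(ready)) break
        placed[ready] <- TRUE
        out <- c(out, ready)
    }
    if (length(out) < n)
        stop("pedigree contains a cycle involving: ",
             paste(df$id[!placed], collapse = ", "))
    df[out, , drop = FALSE]
}

#' NeSeries: LD-based historical effective population size trajectory
#'
#' @slot bins data.frame with columns \code{t} (generations ago), \code{ne},
#'   \code{c_mean} (Morgans), \code{r2_adj}, \code{n_pairs}.
#' @slot fit list (slope, intercept, r_squared, ne_now, recent_generations)
#'   or empty before extrapolation.
#' @export
setClass("NeSeries", representation(bins = "data.frame", fit = "list"))

#' QMatrix: admixture proportions and ancestral allele frequencies
#'
#' @slot Q samples x K matrix of ancestry proportions (rows sum to 1).
#' @slot F K x markers matrix of ancestral allele frequencies.
#' @slot loglik final log-likelihood.
#' @slot converged logical.
#' @slot cv data.frame of cross-validation errors per K (possibly empty).
#' @export
setClass("QMatrix", representation(
    Q = "matrix", F = "matrix", loglik = "numeric",
    converged = "logical", cv = "data.frame"))

setValidity("QMatrix", function(object) {
    if (nrow(object@Q) && any(abs(rowSums(object@Q) - 1) > 1e-6))
        return("admixture rows must sum to 1")
    TRUE
})

#' Panel: breed-distinctive SNP set with selection provenance
#'
#' @slot snps data.frame with columns \code{marker}, \code{chr}, \code{pos},
#'   \code{a1}, \code{a2}, \code{fst_pairs} (comma-separated pairwise
#'   comparisons that preselected the SNP), \code{cda_function},
#'   \code{cda_score}.
#' @slot focal the focal breed the panel distinguishes.
#' @export
setClass("Panel", representation(snps = "data.frame", focal = "character"))

#' ValidationReport: outcome of a panel validation analysis
#'
#' @slot method "clustering" or "classification".
#' @slot assignments per-sample data.frame (sample, breed, cluster/predicted).
#' @slot focalSeparated logical; TRUE when the focal samples form one pure
#'   cluster (clustering method).
#' @slot outliers data.frame of planted-outlier placements.
#' @slot confusion 2x2 table (classification method).
#' @slot accuracy numeric in [0,1] (classification method).
#' @export
setClass("ValidationReport", representation(
    method = "character", assignments = "data.frame",
    focalSeparated = "logical", outliers = "data.frame",
    confusion = "table", accuracy = "numeric"))
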