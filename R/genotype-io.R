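#' @include AllClasses.R accessors.R
NULL

#' Read SNP genotypes from PLINK text or VCF files
#'
#' PLINK input is a \code{.ped}/\code{.map} pair (pass the common prefix or
#' the \code{.ped} path); the PLINK family id is taken as the breed label.
#' VCF input (uncompressed, GT field) is read through \pkg{vcfR}; breed labels
#' are supplied via \code{breed} (recycled if length 1) since VCF carries none.
#' Calls count copies of the \code{a2} allele. For PLINK input, observed
#' alleles at each marker are assigned alphabetically (a1 < a2); for VCF,
#' a1 = REF and a2 = ALT. Multi-allelic VCF records are dropped with a
#' warning. Markers are sorted by (chromosome, position).
#'
#' @param path file path: PLINK prefix, \code{.ped} file, or \code{.vcf} file.
#' @param breed optional breed labels for VCF input.
#' @return A \linkS4class{GenotypeData} object.
#' @export
readGenotypes <- function(path, breed = NULL) {
    if (grepl("\\.vcf$", path)) return(.readVcf(path, breed))
    prefix <- sub("\\.ped$", "", path)
    ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
    if (!file.exists(ped) || !file.exists(map))
        stop("need both ", ped, " and ", map)
    mp <- utils::read.table(map, header = FALSE, colClasses = "character")
    if (ncol(mp) != 4) stop("malformed .map: expected 4 columns")
    mp <- data.frame(marker = mp[[2]], chr = mp[[1]],
                     pos = as.integer(mp[[4]]), stringsAsFactors = FALSE)
    lines <- readLines(ped)
    lines <- lines[nzchar(lines)]
    m <- nrow(mp); n <- length(lines)
    a1m <- matrix("0", m, n); a2m <- matrix("0", m, n)
    fid <- iid <- character(n)
    for (i in seq_len(n)) {
        f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
        if (length(f) != 6 + 2 * m)
            stop("malformed .ped line ", i, ": expected ", 6 + 2 * m,
                 " fields, got ", length(f))
        fid[i] <- f[1]; iid[i] <- f[2]
        al <- f[-(1:6)]
        a1m[, i] <- al[seq(1, 2 * m, 2)]
        a2m[, i] <- al[seq(2, 2 * m, 2)]
    }
    geno <- matrix(NA_integer_, m, n)
    A1 <- A2 <- character(m)
    for (j in seq_len(m)) {
        obs <- c(a1m[j, ], a2m[j, ])
        miss <- a1m[j, ] == "0" | a2m[j, ] == "0"
        alleles <- sort(unique(obs[obs != "0"]))
        if (length(alleles) > 2)
            stop("marker ", mp$marker[j], " has >2 alleles in .ped")
        if (length(alleles) == 0) alleles <- c("0", "0")
        if (length(alleles) == 1) alleles <- c("0", alleles)
        A1[j] <- alleles[1]; A2[j] <- alleles[2]
        g <- (a1m[j, ] == alleles[2]) + (a2m[j, ] == alleles[2])
        g[miss] <- NA_integer_
        geno[j, ] <- g
    }
    GenotypeData(geno,
        data.frame(marker = mp$marker, chr = mp$chr, pos = mp$pos,
                   a1 = A1, a2 = A2, stringsAsFactors = FALSE),
        data.frame(sample_id = iid, breed = fid, stringsAsFactors = FALSE))
}

.readVcf <- function(path, breed = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi)) {
        warning(sum(multi), " multi-allelic VCF record(s) dropped")
        v <- v[!multi, ]
        fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- function(x) {
        x <- gsub("\\|", "/", x)
        out <- rep(NA_integer_, length(x))
        out[x == "0/0"] <- 0L
        out[x %in% c("0/1", "1/0")] <- 1L
        out[x == "1/1"] <- 2L
        out
    }
    geno <- matrix(code(gt), nrow = nrow(gt))
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
        paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    samp <- colnames(gt)
    if (is.null(breed)) breed <- "unknown"
    GenotypeData(geno,
        data.frame(marker = ids, chr = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]),
                   a1 = fix[, "REF"], a2 = fix[, "ALT"],
                   stringsAsFactors = FALSE),
        data.frame(sample_id = samp, breed = rep_len(breed, length(samp)),
                   stringsAsFactors = FALSE))
}

#' Write genotypes in PLINK text or VCF form
#'
#' PLINK output encodes missing calls as \code{0 0}; VCF 4.2 output carries a
#' GT-only FORMAT with \code{./.} for missing, REF = a1, ALT = a2. Round-trips
#' through \code{\link{readGenotypes}} are lossless for biallelic data with
#' alphabetical allele orientation (PLINK) or any orientation (VCF).
#'
#' @param gm a \linkS4class{GenotypeData} object.
#' @param prefix output path prefix (extension added).
#' @param format "plink" or "vcf".
#' @return invisibly, the paths written.
#' @export
writeGenotypes <- function(gm, prefix, format = c("plink", "vcf")) {
    format <- match.arg(format)
    map <- markerMap(gm)
    g <- genoMatrix(gm)
    if (format == "plink") {
        mapfile <- paste0(prefix, ".map"); pedfile <- paste0(prefix, ".ped")
        utils::write.table(
            data.frame(map$chr, map$marker, 0, map$pos),
            mapfile, quote = FALSE, row.names = FALSE, col.names = FALSE,
            sep = "\t")
        br <- breeds(gm)
        con <- file(pedfile, "w")
        on.exit(close(con))
        for (i in seq_len(ncol(g))) {
            gi <- g[, i]
            al1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, map$a2, map$a1))
            al2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, map$a2, map$a1))
            writeLines(paste(c(br[i], colnames(g)[i], 0, 0, 0, -9,
                               rbind(al1, al2)), collapse = " "), con)
        }
        return(invisible(c(pedfile, mapfile)))
    }
    vcffile <- paste0(prefix, ".vcf")
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(g)), collapse = "\t"))
    gtchr <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
    gtchr[is.na(g)] <- "./."
    body <- if (nrow(g)) {
        paste(map$chr, map$pos, map$marker,
              ifelse(map$a1 == "0", "N", map$a1),
              ifelse(map$a2 == "0", "N", map$a2),
              ".", "PASS", ".", "GT",
              apply(gtchr, 1, paste, collapse = "\t"), sep = "\t")
    } else character(0)
    writeLines(c(hdr, body), vcffile)
    invisible(vcffile)
}

#' Merge two genotype datasets on their shared markers
#'
#' Markers are intersected; where the second dataset's allele labels are
#' swapped relative to the first, its codes are flipped (0 <-> 2). Markers
#' with irreconcilable allele labels are dropped with a warning. An unknown
#' allele label "0" (monomorphic marker) matches anything.
#'
#' @param a,b \linkS4class{GenotypeData} objects. \code{a}'s map wins.
#' @return A merged \linkS4class{GenotypeData}.
#' @export
mergeGenotypes <- function(a, b) {
    shared <- intersect(markerMap(a)$marker, markerMap(b)$marker)
    if (!length(shared)) stop("no shared markers between datasets")
    a2 <- a[shared, ]; b2 <- b[shared, ]
    ma <- markerMap(a2); mb <- markerMap(b2)
    stopifnot(identical(ma$marker, mb$marker))
    same <- (ma$a1 == mb$a1 | ma$a1 == "0" | mb$a1 == "0") &
            (ma$a2 == mb$a2 | ma$a2 == "0" | mb$a2 == "0")
    swap <- !same & (ma$a1 == mb$a2 | ma$a1 == "0" | mb$a2 == "0") &
            (ma$a2 == mb$a1 | ma$a2 == "0" | mb$a1 == "0")
    bad <- !same & !swap
    gb <- genoMatrix(b2)
    gb[swap, ] <- 2L - gb[swap, ]
    if (any(bad))
        warning(sum(bad), " marker(s) with irreconcilable alleles dropped: ",
                paste(utils::head(ma$marker[bad], 5), collapse = ", "))
    keep <- !bad
    geno <- cbind(genoMatrix(a2)[keep, , drop = FALSE],
                  gb[keep, , drop = FALSE])
    samples <- rbind(
        data.frame(sample_id = sampleIds(a2), breed = breeds(a2)),
        data.frame(sample_id = sampleIds(b2), breed = breeds(b2)))
    if (anyDuplicated(samples$sample_id))
        stop("duplicate sample ids across datasets")
    GenotypeData(geno, ma[keep, , drop = FALSE], samples)
}

#' Quality-control filtering of a genotype dataset
#'
#' Filters are applied in a fixed order: sex-chromosome and unmapped markers,
#' marker call rate, minor allele frequency, sample call rate, then duplicate
#' samples by pairwise IBS (the earlier sample in input order is kept). MAF is
#' computed on non-missing calls. Every pass is appended to the returned
#' \linkS4class{QCReport}.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param marker_call_rate,sample_call_rate minimum call-rate thresholds.
#' @param maf minimum minor allele frequency (set 0 to skip).
#' @param drop_sex,drop_unmapped drop markers on sex chromosomes (X/Y/XY/MT)
#'   or without map position (chromosome "0" or position <= 0).
#' @param dup_ibs IBS similarity above which a sample pair is called duplicate.
#' @return list with elements \code{gm} (filtered data) and \code{report}.
#' @export
qcFilter <- function(gm, marker_call_rate = 0.90, sample_call_rate = 0.90,
                     maf = 0.02, drop_sex = TRUE, drop_unmapped = TRUE,
                     dup_ibs = 0.98) {
    stopifnot(marker_call_rate >= 0, marker_call_rate <= 1,
              sample_call_rate >= 0, sample_call_rate <= 1,
              maf >= 0, maf <= 0.5, dup_ibs >= 0, dup_ibs <= 1)
    before <- list(n_markers = nrow(gm), n_samples = ncol(gm))
    log <- data.frame(step = integer(), unit = character(),
                      reason = character(), n_removed = integer())
    step <- 0L
    addlog <- function(unit, reason, n) {
        step <<- step + 1L
        log <<- rbind(log, data.frame(step = step, unit = unit,
                                      reason = reason, n_removed = n))
    }
    map <- markerMap(gm)
    if (drop_sex) {
        sex <- toupper(map$chr) %in% c("X", "Y", "XY", "M", "MT")
        addlog("marker", "sex-chromosome", sum(sex))
        gm <- gm[!sex, ]; map <- markerMap(gm)
    }
    if (drop_unmapped) {
        unm <- map$chr %in% c("0", "") | is.na(map$chr) |
               is.na(map$pos) | map$pos <= 0
        addlog("marker", "unmapped", sum(unm))
        gm <- gm[!unm, ]
    }
    g <- genoMatrix(gm)
    cr <- rowMeans(!is.na(g))
    low <- cr < marker_call_rate
    addlog("marker", "call-rate", sum(low))
    gm <- gm[!low, ]
    if (maf > 0) {
        g <- genoMatrix(gm)
        p <- rowMeans(g, na.rm = TRUE) / 2
        mafv <- pmin(p, 1 - p)
        lowm <- is.na(mafv) | mafv < maf
        addlog("marker", "maf", sum(lowm))
        gm <- gm[!lowm, ]
    }
    g <- genoMatrix(gm)
    scr <- colMeans(!is.na(g))
    lows <- scr < sample_call_rate
    addlog("sample", "call-rate", sum(lows))
    gm <- gm[, !lows]
    if (ncol(gm) == 0) stop("all samples removed by QC")
    if (ncol(gm) >= 2) {
        ibs <- .ibsSimilarity(genoMatrix(gm))
        n <- ncol(gm)
        dup <- logical(n)
        for (j in 2:n) {
            if (any(ibs[j, seq_len(j - 1)][!dup[seq_len(j - 1)]] > dup_ibs,
                    na.rm = TRUE))
                dup[j] <- TRUE
        }
        addlog("sample", "duplicate-ibs", sum(dup))
        gm <- gm[, !dup]
    }
    if (ncol(gm) == 0) stop("all samples removed by QC")
    report <- new("QCReport", log = log, before = before,
                  after = list(n_markers = nrow(gm), n_samples = ncol(gm)))
    list(gm = gm, report = report)
}

## pairwise IBS similarity from a markers x samples call matrix:
## per pair, mean over pairwise-complete markers of (2 - |gi - gj|) / 2
.ibsSimilarity <- function(g) {
    A <- (!is.na(g)) * 1
    X <- g; X[is.na(X)] <- 0
    ## indicator matrices per genotype class
    I0 <- (g == 0L) & !is.na(g); I1 <- (g == 1L) & !is.na(g)
    I2 <- (g == 2L) & !is.na(g)
    I0 <- I0 * 1; I1 <- I1 * 1; I2 <- I2 * 1
    n01 <- crossprod(I0, I1) + crossprod(I1, I0) +
           crossprod(I1, I2) + crossprod(I2, I1)      # |diff| = 1 counts
    n02 <- crossprod(I0, I2) + crossprod(I2, I0)      # |diff| = 2 counts
    npairs <- crossprod(A)                            # complete-pair counts
    sim <- 1 - (n01 + 2 * n02) / (2 * npairs)
    sim[npairs == 0] <- NA
    dimnames(sim) <- list(colnames(g), colnames(g))
    sim
}

#' LD pruning by sliding-window pairwise r-squared
#'
#' Within each window of \code{window_snps} markers (windows never span
#' chromosomes, shifted by \code{step_snps}), one SNP of any pair with
#' dosage-correlation r^2 above the threshold is removed greedily — always the
#' later-positioned SNP. r^2 is the squared Pearson correlation of genotype
#' dosages on pairwise-complete observations.
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @param r2_threshold r^2 above which a pair is thinned.
#' @param window_snps,step_snps window size and shift in SNPs.
#' @return character vector of retained marker ids (map order).
#' @export
ldPrune <- function(gm, r2_threshold, window_snps = 50, step_snps = 5) {
    stopifnot(r2_threshold > 0, window_snps >= step_snps, step_snps >= 1)
    map <- markerMap(gm)
    g <- genoMatrix(gm)
    keep <- rep(TRUE, nrow(map))
    for (ch in unique(map$chr)) {
        idx <- which(map$chr == ch)
        m <- length(idx)
        starts <- seq(1, max(1, m), by = step_snps)
        for (s in starts) {
            w <- idx[s:min(s + window_snps - 1, m)]
            w <- w[keep[w]]
            if (length(w) < 2) next
            r2 <- suppressWarnings(
                stats::cor(t(g[w, , drop = FALSE]),
                           use = "pairwise.complete.obs"))^2
            k <- length(w)
            live <- rep(TRUE, k)
            for (i in seq_len(k - 1)) {
                if (!live[i]) next
                for (j in seq(i + 1, k)) {
                    if (!live[j]) next
                    if (!is.na(r2[i, j]) && r2[i, j] > r2_threshold)
                        live[j] <- FALSE
                }
            }
            keep[w[!live]] <- FALSE
        }
    }
    map$marker[keep]
}

#' Drop every marker with at least one missing call
#'
#' @param gm a \linkS4class{GenotypeData}.
#' @return the subset of \code{gm} with fully genotyped markers.
#' @export
dropIncompleteMarkers <- function(gm) {
    gm[rowSums(is.na(genoMatrix(gm))) == 0, ]
}
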