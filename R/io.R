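#' Read a UMI count matrix
#'
#' Reads a 10x-style Matrix Market triplet directory (\code{matrix.mtx} plus
#' \code{features.tsv}/\code{genes.tsv} and \code{barcodes.tsv}, plain or
#' gzipped) or a dense TSV with gene rows and cell columns, and returns a
#' \linkS4class{SingleCellExperiment} holding the gene x cell counts.
#' Duplicate gene symbols are disambiguated deterministically by suffixing
#' \code{.1}, \code{.2}, ... in file order.
#'
#' @param path directory containing the MTX triplet, or a dense TSV file.
#' @param metadata optional per-cell metadata \code{data.frame} with a
#'   \code{cell_id} column (see \code{\link{readCellMetadata}}); attached as
#'   \code{colData} after matching on cell id.
#' @return a \code{SingleCellExperiment} with a \code{counts} assay
#'   (sparse, non-negative integer).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sce <- generateAtlas(simConfig(nCellsFovea = 30, nCellsPeriphery = 30,
#'                                nGenes = 400, nCellsSpeciesB = 20))$sce
#' writeCounts(sce, dir)
#' sce2 <- readCounts(dir)
#' stopifnot(identical(dim(sce2), dim(sce)))
#' @export
readCounts <- function(path, metadata = NULL) {
    if (dir.exists(path)) {
        sce <- .readMtxDir(path)
    } else if (file.exists(path)) {
        sce <- .readDenseTsv(path)
    } else stop("path does not exist: ", path)
    if (!is.null(metadata)) sce <- attachMetadata(sce, metadata)
    sce
}

.firstExisting <- function(dir, names) {
    for (nm in names) {
        p <- file.path(dir, nm)
        if (file.exists(p)) return(p)
    }
    NULL
}

.readMtxDir <- function(dir) {
    mtx <- .firstExisting(dir, c("matrix.mtx", "matrix.mtx.gz"))
    feat <- .firstExisting(dir, c("features.tsv", "features.tsv.gz",
                                  "genes.tsv", "genes.tsv.gz"))
    bc <- .firstExisting(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
    if (is.null(mtx) || is.null(feat) || is.null(bc))
        stop("format error: directory must contain matrix.mtx, ",
             "features.tsv/genes.tsv and barcodes.tsv (optionally gzipped)")
    m <- Matrix::readMM(mtx)
    ## normalize pattern/symmetric MM variants to general numeric sparse
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (any(m@x != round(m@x)) || any(m@x < 0))
        stop("validation error: counts must be non-negative integers")
    ft <- read.table(feat, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, quote = "", comment.char = "")
    genes <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
    bcs <- read.table(bc, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(bcs))
        stop("format error: matrix dimensions do not match annotation files")
    dimnames(m) <- list(make.unique(genes, sep = "."), bcs)
    if (anyDuplicated(bcs)) stop("validation error: duplicate cell barcodes")
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

.readDenseTsv <- function(path) {
    tab <- read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                      check.names = FALSE, stringsAsFactors = FALSE)
    genes <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m) || any(m != round(m)) || any(m < 0))
        stop("validation error: counts must be non-negative integers")
    rownames(m) <- make.unique(genes, sep = ".")
    m <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a count matrix
#'
#' Writes the \code{counts} assay either as a Matrix Market triplet directory
#' (\code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}) or as a
#' dense TSV (gene rows, cell columns). \code{readCounts} round-trips both.
#'
#' @param sce a \code{SingleCellExperiment} (or a counts matrix with
#'   dimnames).
#' @param path output directory (\code{format = "mtx"}) or file
#'   (\code{format = "tsv"}).
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(sce, path, format = c("mtx", "tsv")) {
    format <- match.arg(format)
    m <- if (methods::is(sce, "SummarizedExperiment"))
        SummarizedExperiment::assay(sce, "counts") else sce
    if (format == "mtx") {
        if (!dir.exists(path)) dir.create(path, recursive = TRUE)
        Matrix::writeMM(as(m, "CsparseMatrix"), file.path(path, "matrix.mtx"))
        write.table(data.frame(id = rownames(m), symbol = rownames(m)),
                    file.path(path, "features.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        write.table(data.frame(colnames(m)), file.path(path, "barcodes.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    } else {
        tab <- data.frame(gene = rownames(m), as.matrix(m),
                          check.names = FALSE)
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read per-cell metadata
#'
#' TSV with required columns \code{cell_id}, \code{donor}, \code{region},
#' \code{enrichment}, \code{batch}, \code{species}. \code{region} must be
#' \code{fovea} or \code{periphery}; \code{enrichment} one of \code{none},
#' \code{CD73_depleted}, \code{CD90_enriched}.
#'
#' @param path TSV file with a header row.
#' @return data.frame with one row per cell.
#' @export
readCellMetadata <- function(path) {
    meta <- read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    need <- c("cell_id", "donor", "region", "enrichment", "batch", "species")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("metadata is missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in metadata")
    bad <- setdiff(unique(meta$region), c("fovea", "periphery"))
    if (length(bad))
        stop("unknown region label(s): ", paste(bad, collapse = ", "))
    if (any(!nzchar(meta$species))) stop("species must be non-empty")
    meta
}

#' Attach per-cell metadata to a SingleCellExperiment
#'
#' @param sce a \code{SingleCellExperiment}.
#' @param meta data.frame with a \code{cell_id} column covering every cell.
#' @return \code{sce} with \code{colData} filled from \code{meta}.
#' @export
attachMetadata <- function(sce, meta) {
    idx <- match(colnames(sce), meta$cell_id)
    if (anyNA(idx))
        stop("metadata is missing ", sum(is.na(idx)), " cell id(s)")
    cd <- meta[idx, setdiff(colnames(meta), "cell_id"), drop = FALSE]
    rownames(cd) <- colnames(sce)
    SummarizedExperiment::colData(sce) <- S4Vectors::DataFrame(cd)
    sce
}

#' Merge count matrices from multiple samples
#'
#' Concatenates cells across samples after namespacing cell ids as
#' \code{<sample>_<barcode>}. The gene axis becomes the union of the samples'
#' gene sets, with genes absent from a sample filled with zero counts, so the
#' total UMI count is conserved.
#'
#' @param sces list of \code{SingleCellExperiment}s (each with a
#'   \code{counts} assay and, optionally, \code{colData}).
#' @param sampleNames character, one name per sample; defaults to the list
#'   names or \code{sample1, sample2, ...}.
#' @return a merged \code{SingleCellExperiment}; \code{colData} gains a
#'   \code{sample} column.
#' @export
mergeSamples <- function(sces, sampleNames = NULL) {
    stopifnot(length(sces) >= 1)
    if (is.null(sampleNames)) {
        sampleNames <- names(sces)
        if (is.null(sampleNames))
            sampleNames <- paste0("sample", seq_along(sces))
    }
    stopifnot(length(sampleNames) == length(sces))
    genes <- Reduce(union, lapply(sces, rownames))
    mats <- vector("list", length(sces))
    cds <- vector("list", length(sces))
    for (i in seq_along(sces)) {
        m <- SummarizedExperiment::assay(sces[[i]], "counts")
        colnames(m) <- paste(sampleNames[i], colnames(m), sep = "_")
        full <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                     dims = c(length(genes), ncol(m)),
                                     dimnames = list(genes, colnames(m)))
        full[rownames(m), ] <- m
        mats[[i]] <- full
        cd <- as.data.frame(SummarizedExperiment::colData(sces[[i]]))
        if (!nrow(cd)) cd <- data.frame(row.names = colnames(m))
        cd$sample <- sampleNames[i]
        rownames(cd) <- colnames(m)
        cds[[i]] <- cd
    }
    ids <- unlist(lapply(mats, colnames))
    if (anyDuplicated(ids))
        stop("cell ids collide after prefixing with sample names")
    merged <- do.call(cbind, mats)
    allcols <- Reduce(union, lapply(cds, colnames))
    cds <- lapply(cds, function(cd) {
        for (cc in setdiff(allcols, colnames(cd))) cd[[cc]] <- NA
        cd[, allcols, drop = FALSE]
    })
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = merged),
        colData = S4Vectors::DataFrame(do.call(rbind, cds)))
}

#' Read a (gene, group) list
#'
#' Two-column TSV, header optional (detected when the first row is
#' \code{gene}/\code{group}-like). Rows are deduplicated on the (gene, group)
#' pair preserving first-seen order. An optional third column named
#' \code{override} (logical) marks genes forced into downstream screens for
#' clinical interest.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{gene}, \code{group} and, if present
#'   in the file, \code{override}.
#' @export
readGeneList <- function(path) {
    tab <- tryCatch(
        read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
        error = function(e) stop("empty or unreadable gene list: ", path))
    if (!nrow(tab)) stop("empty gene list: ", path)
    if (ncol(tab) < 2) stop("gene list must have two columns (gene, group)")
    if (tolower(tab[1, 1]) == "gene") {
        hdr <- tolower(as.character(tab[1, ]))
        tab <- tab[-1, , drop = FALSE]
        colnames(tab) <- hdr
    } else colnames(tab)[1:2] <- c("gene", "group")
    if (!nrow(tab)) stop("empty gene list: ", path)
    out <- tab[!duplicated(tab[, c("gene", "group")]), , drop = FALSE]
    rownames(out) <- NULL
    if ("override" %in% colnames(out))
        out$override <- as.logical(out$override)
    out[, intersect(c("gene", "group", "override"), colnames(out)),
        drop = FALSE]
}

#' Read a 1:1 ortholog table
#'
#' Two-column TSV of gene pairs (species A, species B). Pairs in which either
#' gene appears more than once are rejected: only one-to-one relations are
#' retained for cross-species mapping.
#'
#' @param path TSV file, header optional.
#' @return data.frame with columns \code{species_a}, \code{species_b}.
#' @export
readOrthologTable <- function(path) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (tolower(tab[1, 1]) %in% c("species_a", "gene_a", "human"))
        tab <- tab[-1, , drop = FALSE]
    if (ncol(tab) < 2) stop("ortholog table must have two columns")
    colnames(tab)[1:2] <- c("species_a", "species_b")
    if (anyDuplicated(tab$species_a) || anyDuplicated(tab$species_b))
        stop("ortholog table is not 1:1: a gene appears in multiple pairs")
    rownames(tab) <- NULL
    tab[, 1:2]
}
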