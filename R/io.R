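#' Write a count matrix as a 10x-style MTX triplet
#'
#' Emits `matrix.mtx` (MatrixMarket integer coordinate, 1-based indices),
#' `features.tsv` (gene id, gene name, feature type, plus the
#' `mito`/`ribo`/`sex` flag columns when present), `barcodes.tsv` and
#' `metadata.tsv` (barcode, sample, region and any `true_*` ground-truth
#' columns).  The triplet round-trips losslessly through [read_10x()].
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_10x <- function(sce, path) {
  stopifnot(is(sce, "SummarizedExperiment"))
  m <- counts(sce)
  if (nrow(m) == 0 || ncol(m) == 0) stop("refusing to write an empty matrix")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(m, "CsparseMatrix"), file.path(path, "matrix.mtx"))
  rd <- as.data.frame(rowData(sce))
  feat <- data.frame(id = rownames(sce), name = rownames(sce),
                     type = "Gene Expression")
  for (fl in intersect(c("mito", "ribo", "sex"), colnames(rd)))
    feat[[fl]] <- rd[[fl]]
  write.table(feat, file.path(path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(sce), file.path(path, "barcodes.tsv"))
  cd <- as.data.frame(colData(sce))
  keep <- intersect(c("sample", "donor", "region",
                      grep("^true_", colnames(cd), value = TRUE)),
                    colnames(cd))
  meta <- cbind(data.frame(barcode = colnames(sce)), cd[, keep, drop = FALSE])
  write.table(meta, file.path(path, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 10x-style MTX triplet
#'
#' Counterpart of [write_10x()]; also accepts plain triplets without the
#' metadata TSV or the flag columns.
#'
#' @param path directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `metadata.tsv`.
#' @return a `SingleCellExperiment`.
#' @export
read_10x <- function(path) {
  m <- as(Matrix::readMM(file.path(path, "matrix.mtx")), "CsparseMatrix")
  feat <- read.delim(file.path(path, "features.tsv"), header = FALSE,
                     stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  stopifnot(nrow(feat) == nrow(m), length(barcodes) == ncol(m))
  dimnames(m) <- list(feat[[1]], barcodes)
  rd <- DataFrame(gene = feat[[1]], row.names = feat[[1]])
  if (ncol(feat) >= 6) {
    rd$mito <- as.logical(feat[[4]])
    rd$ribo <- as.logical(feat[[5]])
    rd$sex <- as.logical(feat[[6]])
  } else {
    rd$mito <- startsWith(feat[[1]], "MT-")
    rd$ribo <- startsWith(feat[[1]], "RPS") | startsWith(feat[[1]], "RPL")
    rd$sex <- rep(FALSE, nrow(feat))
  }
  cd <- DataFrame(row.names = barcodes)
  mf <- file.path(path, "metadata.tsv")
  if (file.exists(mf)) {
    meta <- read.delim(mf, stringsAsFactors = FALSE)
    rownames(meta) <- meta$barcode
    meta <- meta[barcodes, setdiff(colnames(meta), "barcode"), drop = FALSE]
    cd <- DataFrame(meta, row.names = barcodes, check.names = FALSE)
  }
  SingleCellExperiment(assays = list(counts = m), colData = cd, rowData = rd)
}

#' Read a one-gene-per-line text file
#'
#' Used for explicit gene panels such as an ion-channel (GO:0005216-style)
#' list.  Blank lines and lines starting with `#` are skipped.
#'
#' @param file path to the gene list.
#' @return character vector of gene names.
#' @export
read_gene_list <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read gene sets in GMT format
#'
#' Each line is `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param file path to a `.gmt` file.
#' @return named list `term -> character vector of genes`.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}
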