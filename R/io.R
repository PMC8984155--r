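#' @importClassesFrom Matrix dgCMatrix
#' @importFrom Matrix readMM writeMM Diagonal colSums rowSums t sparseMatrix
#' @importFrom SingleCellExperiment SingleCellExperiment logcounts logcounts<-
#' @importFrom SummarizedExperiment assay assayNames colData colData<- assays assays<-
#' @importFrom S4Vectors DataFrame
NULL

#' Load a cell-by-gene expression matrix
#'
#' Reads either the 10X-style sparse triple (Matrix Market file plus barcode
#' and feature sidecars, genes as rows and cells as columns) or a dense
#' delimited table (cells as rows, header row of gene names, first column the
#' cell identifier). Returns a \linkS4class{SingleCellExperiment} with the
#' matrix in the assay named by \code{layer}.
#'
#' Duplicate gene symbols are collapsed by keeping the first occurrence, with
#' a warning. Absent sparse entries are zeros; negative values are rejected.
#'
#' @param matrix_path path to the .mtx file or the dense delimited table.
#' @param cells_path path to the barcodes file (one cell id per line);
#'   required for MTX input.
#' @param features_path path to the features file (gene id in the first
#'   column); required for MTX input.
#' @param layer which layer the values represent: raw \code{"counts"} or
#'   already-\code{"normalized"} expression.
#' @return \linkS4class{SingleCellExperiment} (genes x cells).
#' @export
loadExpression <- function(matrix_path, cells_path = NULL, features_path = NULL,
                           layer = c("counts", "normalized")) {
  layer <- match.arg(layer)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(cells_path) || is.null(features_path)) {
      stop("MTX input requires 'cells_path' and 'features_path' sidecars")
    }
    m <- as(readMM(matrix_path), "CsparseMatrix")
    barcodes <- read.delim(cells_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
    features <- read.delim(features_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
    if (length(features) != nrow(m)) {
      stop(sprintf("format error: matrix declares %d genes but features sidecar has %d",
                   nrow(m), length(features)))
    }
    if (length(barcodes) != ncol(m)) {
      stop(sprintf("format error: matrix declares %d cells but barcodes sidecar has %d",
                   ncol(m), length(barcodes)))
    }
    rownames(m) <- features
    colnames(m) <- barcodes
  } else {
    df <- read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE,
                     sep = if (grepl("\\.csv$", matrix_path)) "," else "\t")
    cells <- df[[1L]]
    m <- Matrix::t(as(as.matrix(df[, -1L, drop = FALSE]), "CsparseMatrix"))
    colnames(m) <- cells
  }
  if (anyNA(m@x)) stop("validation error: missing values in expression matrix")
  if (any(m@x < 0)) stop("validation error: negative expression values")
  if (anyDuplicated(colnames(m))) stop("validation error: duplicate cell identifiers")
  if (anyDuplicated(rownames(m))) {
    warning("duplicate gene identifiers collapsed (keeping first occurrence)")
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
  }
  assays <- setNames(list(m), if (layer == "counts") "counts" else "normalized")
  sce <- SingleCellExperiment(assays = assays)
  if (layer == "normalized") logcounts(sce) <- m
  sce
}

#' Attach per-cell metadata (cell type, sample, pathological state)
#'
#' @param sce \linkS4class{SingleCellExperiment}.
#' @param metadata data.frame (or path to a TSV) with columns
#'   \code{cell_id}, \code{cell_type}, \code{sample_id}, \code{state}.
#' @param state_order optional ordered vector of state labels (e.g.
#'   \code{c("NBM","MGUS","SMM","MM")}); states are ordered factors then.
#' @return the experiment with populated \code{colData}, subset to annotated
#'   cells in metadata order.
#' @export
addCellMetadata <- function(sce, metadata, state_order = NULL) {
  if (is.character(metadata)) metadata <- readResultTable(metadata)
  req <- c("cell_id", "cell_type", "sample_id", "state")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols)) {
    stop("format error: metadata missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$cell_id)) {
    stop("validation error: duplicate cell_id in metadata")
  }
  absent <- setdiff(metadata$cell_id, colnames(sce))
  if (length(absent)) {
    stop("validation error: metadata cells absent from expression matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  sce <- sce[, metadata$cell_id]
  st <- metadata$state
  if (!is.null(state_order)) {
    bad <- setdiff(unique(st), state_order)
    if (length(bad)) stop("validation error: states not in state_order: ",
                          paste(bad, collapse = ", "))
    st <- factor(st, levels = state_order, ordered = TRUE)
  }
  colData(sce) <- DataFrame(cell_id = metadata$cell_id,
                            cell_type = metadata$cell_type,
                            sample_id = metadata$sample_id,
                            state = st,
                            row.names = metadata$cell_id)
  sce
}

#' Quality-control filter for cells, then genes
#'
#' Keeps cells with mitochondrial fraction below \code{max_mito_fraction} and
#' a detected-gene count strictly between \code{min_genes} and
#' \code{max_genes}; then keeps genes detected in at least \code{min_cells}
#' of the remaining cells (gene detection is recomputed after the cell
#' filter, so the order is fixed: cells first, then genes).
#'
#' @param sce \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes used
#'   to compute the per-cell mitochondrial count fraction.
#' @param max_mito_fraction keep cells with mito fraction strictly below this.
#' @param min_genes,max_genes keep cells with detected-gene count strictly
#'   inside (min_genes, max_genes).
#' @param min_cells keep genes detected in at least this many surviving cells.
#' @return filtered experiment.
#' @export
qcFilterCells <- function(sce, mito_prefix = "MT-", max_mito_fraction = 0.20,
                          min_genes = 200, max_genes = 2500, min_cells = 3) {
  if (!"counts" %in% assayNames(sce)) stop("QC requires a 'counts' assay")
  counts <- assay(sce, "counts")
  .checkFraction(max_mito_fraction, "max_mito_fraction")
  mito <- startsWith(rownames(counts), mito_prefix)
  tot <- Matrix::colSums(counts)
  mito_frac <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1)
  } else rep(0, ncol(counts))
  n_detected <- Matrix::colSums(counts > 0)
  keep_cells <- mito_frac < max_mito_fraction &
    n_detected > min_genes & n_detected < max_genes
  if (!any(keep_cells)) stop("empty after QC: all cells removed")
  out <- sce[, keep_cells]
  keep_genes <- Matrix::rowSums(assay(out, "counts") > 0) >= min_cells
  out[keep_genes, ]
}

#' Library-size normalize counts and log-transform
#'
#' Scales each cell to \code{scale_factor} total counts and applies
#' \code{log1p}, storing the result in \code{logcounts}. Cells with zero
#' total counts stay all-zero.
#'
#' @param sce experiment with a \code{counts} assay.
#' @param scale_factor target library size (default 10,000).
#' @return the experiment with a \code{logcounts} assay added.
#' @export
logNormalize <- function(sce, scale_factor = 1e4) {
  counts <- assay(sce, "counts")
  lib <- Matrix::colSums(counts)
  sf <- ifelse(lib > 0, scale_factor / lib, 0)
  norm <- counts %*% Diagonal(x = sf)
  dimnames(norm) <- dimnames(counts)
  logcounts(sce) <- log1p(norm)
  sce
}

# logcounts if present, otherwise a "normalized" assay, otherwise normalize
.normalizedAssay <- function(sce) {
  if ("logcounts" %in% assayNames(sce)) return(assay(sce, "logcounts"))
  if ("normalized" %in% assayNames(sce)) return(assay(sce, "normalized"))
  if ("counts" %in% assayNames(sce)) return(logcounts(logNormalize(sce)))
  stop("no usable assay found (need logcounts, normalized or counts)")
}

#' Load a ligand-receptor pair table
#'
#' Expects a delimited table with columns \code{pair_id}, \code{partner_a},
#' \code{partner_b}, \code{a_is_receptor}, \code{b_is_receptor} (the receptor
#' flags may be "True"/"False" strings or logicals). The partner flagged as
#' the receptor defines the target (regulated) side; the other partner is the
#' ligand on the source (regulatory) side. Pairs with no \code{True} flag (or
#' both \code{True}) are ambiguous: partner_b is taken as the receptor and
#' the row flagged, with a warning.
#'
#' @param path file path, or a data.frame with the same columns.
#' @return data.frame: pair_id, ligand, receptor, ambiguous.
#' @export
loadLRPairs <- function(path) {
  df <- if (is.data.frame(path)) path else {
    readResultTable(path)
  }
  req <- c("pair_id", "partner_a", "partner_b", "a_is_receptor", "b_is_receptor")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("format error: LR pair table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  to_logical <- function(x) {
    if (is.logical(x)) return(x)
    tolower(trimws(as.character(x))) %in% c("true", "t", "1")
  }
  a_rec <- to_logical(df$a_is_receptor)
  b_rec <- to_logical(df$b_is_receptor)
  if (any(df$partner_a == df$partner_b)) {
    stop("validation error: pair with identical partners: ",
         paste(df$pair_id[df$partner_a == df$partner_b], collapse = ", "))
  }
  if (anyDuplicated(df$pair_id)) stop("validation error: duplicate pair_id")
  ambiguous <- (a_rec & b_rec) | (!a_rec & !b_rec)
  if (any(ambiguous)) {
    warning(sum(ambiguous), " pair(s) without a unique 'True' receptor flag; ",
            "partner_b treated as receptor")
  }
  receptor <- ifelse(!ambiguous & a_rec, df$partner_a, df$partner_b)
  ligand <- ifelse(receptor == df$partner_b, df$partner_a, df$partner_b)
  data.frame(pair_id = df$pair_id, ligand = ligand, receptor = receptor,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Flag ligand-receptor pairs active in an expression matrix
#'
#' Pairs whose partners are absent from the matrix are retained but flagged
#' inactive; downstream detection skips them with a reason code.
#'
#' @param pairs data.frame from \code{loadLRPairs}.
#' @param sce expression experiment.
#' @return \code{pairs} with an added logical column \code{active}.
#' @export
markActivePairs <- function(pairs, sce) {
  genes <- rownames(sce)
  pairs$active <- pairs$ligand %in% genes & pairs$receptor %in% genes
  pairs
}

#' Load a protein-protein interaction edge table
#'
#' @param path TSV with columns \code{gene_u}, \code{gene_v},
#'   \code{combined_score} (score in [0, 1]), or an equivalent data.frame.
#' @return validated data.frame.
#' @export
loadPPIEdges <- function(path) {
  df <- if (is.data.frame(path)) path else readResultTable(path)
  req <- c("gene_u", "gene_v", "combined_score")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("format error: PPI table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$gene_u == df$gene_v)) stop("validation error: PPI self-loop")
  if (any(df$combined_score < 0 | df$combined_score > 1)) {
    stop("validation error: combined_score outside [0, 1]")
  }
  df
}

#' Load a survival table
#'
#' @param path TSV with columns \code{sample_id}, \code{time} (months) and
#'   \code{event} (0 censored / 1 event), or an equivalent data.frame.
#' @return validated data.frame.
#' @export
loadSurvival <- function(path) {
  df <- if (is.data.frame(path)) path else readResultTable(path)
  req <- c("sample_id", "time", "event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("format error: survival table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$time < 0)) stop("validation error: negative survival time")
  if (!all(df$event %in% c(0, 1))) stop("validation error: event must be 0/1")
  df
}

#' Load risk-score coefficients into a RiskModel
#'
#' @param path TSV with columns \code{gene} and \code{beta}, or an
#'   equivalent data.frame.
#' @return \linkS4class{RiskModel}.
#' @export
loadRiskCoefficients <- function(path) {
  df <- if (is.data.frame(path)) path else readResultTable(path)
  if (!all(c("gene", "beta") %in% names(df))) {
    stop("format error: coefficient table needs columns 'gene' and 'beta'")
  }
  if (anyNA(df$beta)) {
    stop("validation error: missing beta values (fill in the coefficient template)")
  }
  new("RiskModel", coefficients = setNames(as.numeric(df$beta), df$gene),
      geneOrder = df$gene)
}
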