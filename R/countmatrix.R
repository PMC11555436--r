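#' Single-cell count matrix container
#'
#' A lightweight S3 record holding one or more gene x cell expression layers
#' (sparse `Matrix::dgCMatrix`) together with per-cell metadata. The `counts`
#' layer holds raw non-negative integer counts; downstream stages add derived
#' layers such as `lognorm` (log1p of counts-per-10K), `spliced`, `unspliced`
#' or `moments`.
#'
#' @param values gene x cell matrix (coerced to sparse); rows are genes.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param cell_meta data.frame of per-cell annotations (`species`, `stage`,
#'   `class` are the conventional columns; `class` may be `NA`).
#' @param layer_tag name of the layer `values` represents; one of
#'   `"counts"`, `"lognorm"`, `"spliced"`, `"unspliced"`, `"moments"`.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values), cell_meta = NULL,
                         layer_tag = "counts") {
  layer_tag <- match.arg(layer_tag,
                         c("counts", "lognorm", "spliced", "unspliced", "moments"))
  values <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids))
    stop(sprintf("dimension mismatch on gene axis: matrix has %d rows, %d gene ids given",
                 nrow(values), length(gene_ids)), call. = FALSE)
  if (ncol(values) != length(cell_ids))
    stop(sprintf("dimension mismatch on cell axis: matrix has %d columns, %d cell ids given",
                 ncol(values), length(cell_ids)), call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ", paste(unique(gene_ids[duplicated(gene_ids)])[1:min(3, sum(duplicated(gene_ids)))],
                                       collapse = ", "), call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ", paste(unique(cell_ids[duplicated(cell_ids)])[1:min(3, sum(duplicated(cell_ids)))],
                                       collapse = ", "), call. = FALSE)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(species = NA_character_, stage = NA_character_,
                            class = NA_character_)[rep(1, length(cell_ids)), , drop = FALSE]
    rownames(cell_meta) <- cell_ids
  }
  if (nrow(cell_meta) == 1L && length(cell_ids) > 1L)
    cell_meta <- cell_meta[rep(1L, length(cell_ids)), , drop = FALSE]
  if (nrow(cell_meta) != length(cell_ids))
    stop("cell_meta has ", nrow(cell_meta), " rows for ", length(cell_ids), " cells",
         call. = FALSE)
  rownames(cell_meta) <- cell_ids
  if (layer_tag %in% c("counts", "spliced", "unspliced")) {
    v <- values@x
    if (length(v) && (any(v < 0) || any(abs(v - round(v)) > 1e-8)))
      stop(layer_tag, " layer must be non-negative integer-valued", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(layers = stats::setNames(list(values), layer_tag),
                 gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, layer_tag = layer_tag),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells; layers: %s\n",
              length(x$gene_ids), length(x$cell_ids),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) c(length(x$gene_ids), length(x$cell_ids))

#' Get a layer of a CountMatrix
#' @param m CountMatrix.
#' @param tag layer name; defaults to the primary layer.
#' @return sparse gene x cell matrix.
#' @export
cm_layer <- function(m, tag = m$layer_tag) {
  if (!tag %in% names(m$layers))
    stop("layer '", tag, "' not present (have: ",
         paste(names(m$layers), collapse = ", "), ")", call. = FALSE)
  m$layers[[tag]]
}

#' Add or replace a layer
#' @param m CountMatrix.
#' @param tag layer name.
#' @param values gene x cell matrix with matching dimensions.
#' @export
cm_set_layer <- function(m, tag, values) {
  values <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!identical(dim(values), c(length(m$gene_ids), length(m$cell_ids))))
    stop("layer '", tag, "' dimensions do not match the container", call. = FALSE)
  dimnames(values) <- list(m$gene_ids, m$cell_ids)
  m$layers[[tag]] <- values
  m
}

#' Subset a CountMatrix by genes and/or cells
#' @param m CountMatrix.
#' @param genes gene ids or indices (default all).
#' @param cells cell ids or indices (default all).
#' @export
cm_subset <- function(m, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(m$cell_ids) else cells
  if (is.character(gi)) gi <- match(gi, m$gene_ids)
  if (is.character(ci)) ci <- match(ci, m$cell_ids)
  if (anyNA(gi)) stop("unknown gene ids in subset", call. = FALSE)
  if (anyNA(ci)) stop("unknown cell ids in subset", call. = FALSE)
  m$layers <- lapply(m$layers, function(L) L[gi, ci, drop = FALSE])
  m$gene_ids <- m$gene_ids[gi]
  m$cell_ids <- m$cell_ids[ci]
  m$cell_meta <- m$cell_meta[ci, , drop = FALSE]
  m
}
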