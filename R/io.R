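#' Read a sparse count matrix in MatrixMarket layout
#'
#' Reads the CellRanger-style triplet: an `.mtx` file with genes as rows
#' (1-based indices on disk), a gene annotation table and a cell (barcode)
#' annotation table. Annotation tables are header-less TSV whose first column
#' is the identifier; extra cell columns are kept as metadata (conventional
#' order: species, stage, class).
#'
#' @param path_matrix path to the MatrixMarket file.
#' @param path_genes path to the gene table (first column = gene id).
#' @param path_cells path to the cell table (first column = cell id).
#' @param layer_tag layer name for the values read (default `"counts"`).
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path_matrix, path_genes, path_cells,
                              layer_tag = "counts") {
  for (p in c(path_matrix, path_genes, path_cells))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  values <- Matrix::readMM(path_matrix)
  genes <- utils::read.table(path_genes, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
  cells <- utils::read.table(path_cells, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "")
  if (nrow(values) != nrow(genes))
    stop(sprintf("dimension mismatch on gene axis: matrix has %d rows but gene table has %d",
                 nrow(values), nrow(genes)), call. = FALSE)
  if (ncol(values) != nrow(cells))
    stop(sprintf("dimension mismatch on cell axis: matrix has %d columns but cell table has %d",
                 ncol(values), nrow(cells)), call. = FALSE)
  meta <- NULL
  if (ncol(cells) > 1) {
    meta <- cells[, -1, drop = FALSE]
    nm <- c("species", "stage", "class")
    colnames(meta) <- c(nm[seq_len(min(ncol(meta), 3))],
                        if (ncol(meta) > 3) paste0("V", 4:ncol(meta)))
  }
  count_matrix(values, gene_ids = genes[[1]], cell_ids = cells[[1]],
               cell_meta = meta, layer_tag = layer_tag)
}

#' Write a CountMatrix layer as MatrixMarket triplet
#' @param m CountMatrix.
#' @param dir output directory (created if absent).
#' @param prefix file prefix; writes `<prefix>.mtx`, `<prefix>.genes.tsv`,
#'   `<prefix>.cells.tsv`.
#' @param tag layer to write.
#' @export
write_count_matrix <- function(m, dir, prefix = m$layer_tag, tag = m$layer_tag) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(cm_layer(m, tag), file.path(dir, paste0(prefix, ".mtx")))
  utils::write.table(data.frame(m$gene_ids),
                     file.path(dir, paste0(prefix, ".genes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- m$cell_meta
  utils::write.table(cbind(data.frame(cell = m$cell_ids), meta),
                     file.path(dir, paste0(prefix, ".cells.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file.path(dir, paste0(prefix, ".mtx")))
}

#' Read a regulon set from a GMT-like file
#'
#' Each line is `name<TAB>regulator<TAB>target1<TAB>target2...`. Names follow
#' the `"TF (N)"` convention where N is the target count. Every regulon must
#' keep at least `min_targets` targets; the regulator is never a member of its
#' own target set.
#'
#' @param path file path.
#' @param min_targets minimum target-set size (default 8).
#' @return a `RegulonSet`: list with `entries`, each
#'   `list(name, regulator, targets)`.
#' @export
read_regulons <- function(path, min_targets = 8) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed regulon line: ", ln, call. = FALSE)
    regulon(regulator = f[2], targets = f[-(1:2)], name = f[1],
            min_targets = min_targets)
  })
  regulon_set(entries)
}

#' Construct a single regulon
#' @param regulator regulator gene id.
#' @param targets character vector of target gene ids.
#' @param name optional display name; default `"regulator (N)"`.
#' @param min_targets minimum target-set size; a smaller set is a validation
#'   error (the minimum module size rule, default 8).
#' @export
regulon <- function(regulator, targets, name = NULL, min_targets = 8) {
  targets <- unique(setdiff(as.character(targets), regulator))
  if (length(targets) < min_targets)
    stop(sprintf("regulon '%s' has %d targets; minimum module size is %d",
                 if (is.null(name)) regulator else name, length(targets),
                 min_targets), call. = FALSE)
  if (is.null(name)) name <- sprintf("%s (%d)", regulator, length(targets))
  list(name = name, regulator = regulator, targets = targets)
}

#' Bundle regulons into a RegulonSet
#' @param entries list of [regulon()] records.
#' @export
regulon_set <- function(entries) {
  nms <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate regulon names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  structure(list(entries = entries), class = "RegulonSet")
}

#' @export
print.RegulonSet <- function(x, ...) {
  cat(sprintf("RegulonSet: %d regulons\n", length(x$entries)))
  invisible(x)
}

#' @export
length.RegulonSet <- function(x) length(x$entries)

#' Write a RegulonSet to a GMT-like file
#' @param rs RegulonSet.
#' @param path output path.
#' @export
write_regulons <- function(rs, path) {
  lines <- vapply(rs$entries, function(e)
    paste(c(e$name, e$regulator, sort(e$targets)), collapse = "\t"), "")
  writeLines(lines[order(lines)], path)
  invisible(path)
}

#' Write a table as TSV with a provenance comment line
#'
#' All per-stage tabular outputs use this writer: a `#` comment line recording
#' the seed and parameters, then a header and tab-separated rows.
#'
#' @param obj data.frame.
#' @param path output path.
#' @param seed seed used by the producing stage (or NA).
#' @param params named list of stage parameters recorded in the comment.
#' @export
write_table <- function(obj, path, seed = NA, params = list()) {
  pstr <- if (length(params))
    paste(vapply(names(params), function(k)
      paste0(k, "=", paste(format(params[[k]]), collapse = ",")), ""),
      collapse = " ")
  else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#seed=%s %s", format(seed), pstr), con)
  utils::write.table(obj, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path file path.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write an ortholog map
#'
#' TSV with columns `cluster_id`, `species`, `gene`: each cluster contains
#' exactly one gene per covered species (one-to-one orthology).
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_ortholog_map <- function(path) {
  df <- read_table(path)
  validate_ortholog_map(df)
}

#' Validate an ortholog map table
#' @param df data.frame with columns cluster_id, species, gene.
#' @export
validate_ortholog_map <- function(df) {
  need <- c("cluster_id", "species", "gene")
  if (!all(need %in% colnames(df)))
    stop("ortholog map needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  key <- paste(df$species, df$gene)
  if (anyDuplicated(key))
    stop("ortholog map: a gene appears in more than one cluster", call. = FALSE)
  cs <- paste(df$cluster_id, df$species)
  if (anyDuplicated(cs))
    stop("ortholog map: a cluster has >1 gene for one species (not one-to-one)",
         call. = FALSE)
  df
}

#' Read an orthogroup table
#'
#' TSV with columns `orthogroup_id`, `species`, `gene`; copy numbers per
#' species may exceed one.
#' @param path file path.
#' @export
read_orthogroups <- function(path) {
  df <- read_table(path)
  need <- c("orthogroup_id", "species", "gene")
  if (!all(need %in% colnames(df)))
    stop("orthogroup table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
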