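#' CPC matrix container
#'
#' A `cpc_matrix` holds an absolute protein abundance table in cell protein
#' copy (CPC) units: a numeric protein-by-cell-line matrix where `NA` marks
#' an undetected (absent) entry, plus a tissue-of-origin label for every
#' cell line. CPC is a dimensionless copies-per-cell count, so all present
#' values must be non-negative.
#'
#' @param values numeric matrix, rows = proteins (rownames are protein
#'   ids), columns = cell lines (colnames are cell-line ids). `NA` = not
#'   detected.
#' @param tissues named character vector mapping each cell-line id to its
#'   tissue label.
#' @return an object of class `cpc_matrix` with elements `cpc` (the
#'   matrix) and `tissue` (the label vector, ordered as the columns).
#' @export
cpc_matrix <- function(values, tissues) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_cpcnet("values must be a numeric matrix", class = "cpcnet_format_error")
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop_cpcnet("protein ids (rownames) must be present and unique",
                class = "cpcnet_format_error")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_cpcnet("cell-line ids (colnames) must be present and unique",
                class = "cpcnet_format_error")
  if (any(values < 0, na.rm = TRUE))
    stop_cpcnet("negative CPC value", class = "cpcnet_format_error")
  missing_tissue <- setdiff(colnames(values), names(tissues))
  if (length(missing_tissue))
    stop_cpcnet("cell lines without tissue label: ",
                paste(missing_tissue, collapse = ", "),
                class = "cpcnet_format_error")
  structure(list(cpc = values,
                 tissue = unname(tissues[colnames(values)])),
            names = c("cpc", "tissue"),
            class = "cpc_matrix")
}

#' @export
print.cpc_matrix <- function(x, ...) {
  cat(sprintf("<cpc_matrix> %d proteins x %d cell lines (%d tissues), %.1f%% detected\n",
              nrow(x$cpc), ncol(x$cpc), length(unique(x$tissue)),
              100 * mean(!is.na(x$cpc))))
  invisible(x)
}

#' @export
dim.cpc_matrix <- function(x) dim(x$cpc)

tissue_of <- function(m) stats::setNames(m$tissue, colnames(m$cpc))

# Detection indicator: present AND > 0 (absent entries and measured zeros
# both count as undetected).
detected <- function(m) !is.na(m$cpc) & m$cpc > 0

#' Read a CPC abundance table with its tissue annotation
#'
#' Reads a protein-by-cell-line table (TSV, CSV or XLSX; dialect chosen by
#' file extension) whose first column holds protein ids and whose header
#' row holds cell-line ids, together with a two-column
#' (`cell_line`, `tissue`) annotation file. Empty cells are recorded as
#' absent (`NA`), not as zero.
#'
#' @param path abundance table path (`.tsv`, `.csv` or `.xlsx`; XLSX
#'   requires the readxl package).
#' @param tissue_path two-column TSV mapping every cell line to a tissue.
#' @return a [cpc_matrix()].
#' @export
read_cpc_table <- function(path, tissue_path) {
  if (!file.exists(path))
    stop_cpcnet("no such file: ", path, class = "cpcnet_format_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_cpcnet("reading XLSX requires the readxl package",
                  class = "cpcnet_format_error")
    df <- as.data.frame(readxl::read_excel(path), check.names = FALSE)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path)
  }
  if (ncol(df) < 2)
    stop_cpcnet("abundance table needs a protein id column plus >=1 cell line",
                class = "cpcnet_format_error")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_cpcnet("duplicate protein ids in ", path, class = "cpcnet_format_error")
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  tis <- read_tsv(tissue_path)
  cpc_matrix(vals, stats::setNames(as.character(tis[[2]]),
                                   as.character(tis[[1]])))
}

#' Write a CPC matrix (abundance table + tissue file)
#'
#' Inverse of [read_cpc_table()]: absent entries become empty TSV fields.
#'
#' @param m a [cpc_matrix()].
#' @param path abundance TSV path.
#' @param tissue_path tissue annotation TSV path.
#' @return `path`, invisibly.
#' @export
write_cpc_table <- function(m, path, tissue_path) {
  df <- data.frame(protein_id = rownames(m$cpc), m$cpc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(data.frame(cell_line = colnames(m$cpc), tissue = m$tissue),
            tissue_path)
  invisible(path)
}

#' Read a pathway membership map
#'
#' A pathway map is a many-to-many (`pathway_id`, `protein_id`) pair list
#' in the style of a KEGG gene-to-pathway mapping; proteins with at least
#' one membership define the metabolic subset of the proteome.
#'
#' @param path two-column TSV.
#' @return data frame with columns `pathway_id`, `protein_id` (unique pairs).
#' @export
read_pathway_map <- function(path) {
  df <- read_tsv(path)
  names(df)[1:2] <- c("pathway_id", "protein_id")
  df <- unique(df[, c("pathway_id", "protein_id")])
  df[order(df$pathway_id, df$protein_id), , drop = FALSE]
}

metabolic_proteins <- function(pathway_map) unique(pathway_map$protein_id)
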