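#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor pt pnorm rnorm rpois runif sd var setNames
#' @importFrom utils read.delim write.table head
NULL

#' CellMatrix: single-cell counts with per-cell study metadata
#'
#' A thin wrapper around [SingleCellExperiment::SingleCellExperiment] that
#' enforces the metadata contract of a paired perturbation study: every cell
#' carries `sample_id`, `patient_id`, `timepoint` (`"pre"` or `"post"`) and
#' `cell_type`, with optional `cell_subtype` and `clonotype_id` columns.
#' Each (patient, timepoint) combination maps to exactly one sample.
#'
#' Counts are stored genes x cells (the on-disk CellRanger MTX convention).
#' Counts must be non-negative; they are ordinarily integers, but fractional
#' values are permitted so that noiseless expected-count matrices from the
#' simulator's debug mode remain representable.
#'
#' @slot .Data inherits all slots from `SingleCellExperiment`.
#' @export
setClass("CellMatrix", contains = "SingleCellExperiment")

.validCellMatrix <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (min(m) < 0) msg <- c(msg, "counts must be non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "patient_id", "timepoint", "cell_type")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (!all(cd$timepoint %in% c("pre", "post")))
      msg <- c(msg, "timepoint must be 'pre' or 'post'")
    key <- paste(cd$patient_id, cd$timepoint)
    tab <- unique(data.frame(key = key, sample = cd$sample_id))
    if (anyDuplicated(tab$key))
      msg <- c(msg, "each (patient_id, timepoint) must map to exactly one sample_id")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate cell barcodes")
  if (length(msg)) msg else TRUE
}
setValidity("CellMatrix", .validCellMatrix)

#' Construct a CellMatrix
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse), non-negative.
#'   Row names are gene symbols, column names cell barcodes.
#' @param meta data.frame of per-cell metadata with one row per cell, in cell
#'   order, containing at least `cell_id`, `sample_id`, `patient_id`,
#'   `timepoint`, `cell_type`.
#' @return a `CellMatrix`
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' meta <- data.frame(cell_id = paste0("c", 1:4),
#'                    sample_id = rep(c("s1", "s2"), each = 2),
#'                    patient_id = "p1",
#'                    timepoint = rep(c("pre", "post"), each = 2),
#'                    cell_type = "T")
#' cm <- CellMatrix(m, meta)
#' @export
CellMatrix <- function(counts, meta) {
  if (!is.data.frame(meta)) meta <- as.data.frame(meta)
  need <- c("cell_id", "sample_id", "patient_id", "timepoint", "cell_type")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("cell metadata is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- meta$cell_id
  if (anyDuplicated(meta$cell_id))
    stop("duplicate cell barcodes in metadata", call. = FALSE)
  extra <- setdiff(colnames(counts), meta$cell_id)
  if (length(extra))
    stop("cells present in counts but absent from metadata: ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(counts), meta$cell_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(meta[setdiff(colnames(meta), "cell_id")],
                             row.names = meta$cell_id)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  new("CellMatrix", sce)
}

#' PseudoBulkTable: per-sample aggregated expression for one cell type
#'
#' A [SummarizedExperiment::SummarizedExperiment] (genes x samples) holding
#' log2(CPM + 1) pseudo-bulk values for a single cell type, with per-sample
#' `patient_id` and the binary treatment indicator `Z` (0 = pre, 1 = post)
#' in `colData`. The cell type lives in `metadata(x)$cell_type`.
#'
#' @export
setClass("PseudoBulkTable", contains = "SummarizedExperiment")

.validPseudoBulk <- function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("patient_id", "Z") %in% colnames(cd)))
    msg <- c(msg, "colData must contain patient_id and Z")
  else {
    if (!all(cd$Z %in% c(0L, 1L))) msg <- c(msg, "Z must be 0/1")
    if (anyDuplicated(paste(cd$patient_id, cd$Z)))
      msg <- c(msg, "each patient contributes at most one pre and one post sample")
  }
  v <- SummarizedExperiment::assay(object, 1L)
  if (length(v) && min(v) < 0) msg <- c(msg, "values must be non-negative")
  if (is.null(S4Vectors::metadata(object)$cell_type))
    msg <- c(msg, "metadata(x)$cell_type is required")
  if (length(msg)) msg else TRUE
}
setValidity("PseudoBulkTable", .validPseudoBulk)

#' GEModule: a gene expression module tied to one LR mediator
#'
#' A set of co-regulated differentially expressed genes within one cell type,
#' associated with one ligand-receptor pair. Sender-side modules (GEM X)
#' collect causal genes from the treatment-targeted cell type; receiver-side
#' modules (GEM Y) collect effect genes.
#'
#' @slot gem_id module identifier, deterministic per network
#' @slot side `"sender"` or `"receiver"`
#' @slot cell_type cell type the members belong to
#' @slot members gene symbols
#' @slot ligand ligand gene symbol
#' @slot receptor receptor, subunits joined by `_`
#' @export
setClass("GEModule", representation(
  gem_id = "character", side = "character", cell_type = "character",
  members = "character", ligand = "character", receptor = "character"))

setValidity("GEModule", function(object) {
  msg <- character()
  if (!length(object@members)) msg <- c(msg, "members must be nonempty")
  if (!object@side %in% c("sender", "receiver"))
    msg <- c(msg, "side must be 'sender' or 'receiver'")
  if (length(msg)) msg else TRUE
})

#' CCCNetwork: the assembled cell-cell communication network
#'
#' One row (channel) per (sender type, receiver type, ligand, receptor) with
#' its sender/receiver gene expression modules and per-channel summary
#' statistics. Channels are kept in a deterministic order (sorted by sender
#' type, receiver type, ligand, receptor).
#'
#' @slot channels data.frame with columns `sender_type`, `receiver_type`,
#'   `ligand`, `receptor`, `sender_gem_id`, `receiver_gem_id`, `n_pairs`,
#'   `median_p_cit`, and list-columns `sender_members`, `receiver_members`.
#' @export
setClass("CCCNetwork", representation(channels = "data.frame"))

setValidity("CCCNetwork", function(object) {
  ch <- object@channels
  need <- c("sender_type", "receiver_type", "ligand", "receptor",
            "sender_gem_id", "receiver_gem_id", "n_pairs", "median_p_cit",
            "sender_members", "receiver_members")
  miss <- setdiff(need, colnames(ch))
  if (length(miss))
    return(paste0("channels is missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(ch)) {
    bad <- ch$n_pairs > lengths(ch$sender_members) * lengths(ch$receiver_members)
    if (any(bad)) return("n_pairs exceeds |sender members| x |receiver members|")
  }
  TRUE
})
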