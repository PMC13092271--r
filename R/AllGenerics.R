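#' Per-cell metadata of a CellMatrix
#'
#' @param x a `CellMatrix`
#' @return data.frame with one row per cell (`cell_id` restored as a column)
#' @export
setGeneric("cellMeta", function(x) standardGeneric("cellMeta"))

#' @rdname cellMeta
setMethod("cellMeta", "CellMatrix", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(cell_id = colnames(x), cd, row.names = NULL)
})

#' Treatment indicator of a pseudo-bulk table
#'
#' @param x a `PseudoBulkTable`
#' @return integer vector of 0/1 (0 = pre, 1 = post), one per sample
#' @export
setGeneric("treatmentZ", function(x) standardGeneric("treatmentZ"))

#' @rdname treatmentZ
setMethod("treatmentZ", "PseudoBulkTable", function(x)
  as.integer(SummarizedExperiment::colData(x)$Z))

#' Cell type of a pseudo-bulk table
#' @param x a `PseudoBulkTable`
#' @return character scalar
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname cellType
setMethod("cellType", "PseudoBulkTable", function(x)
  S4Vectors::metadata(x)$cell_type)

#' Samples-by-genes value matrix of a pseudo-bulk table
#'
#' Statistical stages of the pipeline operate on samples as observations;
#' this accessor transposes the genes-by-samples assay accordingly.
#'
#' @param x a `PseudoBulkTable`
#' @return numeric matrix, samples x genes, log2(CPM + 1) scale
#' @export
setGeneric("pbMatrix", function(x) standardGeneric("pbMatrix"))

#' @rdname pbMatrix
setMethod("pbMatrix", "PseudoBulkTable", function(x)
  t(as.matrix(SummarizedExperiment::assay(x, 1L))))

#' Channel table of a CCC network
#' @param x a `CCCNetwork`
#' @return data.frame of channels (see [CCCNetwork-class])
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname channels
setMethod("channels", "CCCNetwork", function(x) x@channels)

#' @rdname channels
#' @aliases length,CCCNetwork-method
#' @export
setMethod("length", "CCCNetwork", function(x) nrow(x@channels))

#' Module member genes
#' @param x a `GEModule`
#' @return character vector of gene symbols
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname members
setMethod("members", "GEModule", function(x) x@members)

setMethod("show", "CellMatrix", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CellMatrix:", nrow(object), "genes x", ncol(object), "cells\n")
  cat("  patients:", length(unique(cd$patient_id)),
      " samples:", length(unique(cd$sample_id)), "\n")
  cat("  cell types:", paste(sort(unique(cd$cell_type)), collapse = ", "), "\n")
  cat("  timepoints:", paste(names(table(cd$timepoint)),
                             table(cd$timepoint), collapse = "  "), "\n")
})

setMethod("show", "PseudoBulkTable", function(object) {
  cat("PseudoBulkTable (", cellType(object), "): ",
      nrow(object), " genes x ", ncol(object), " samples, ",
      sum(treatmentZ(object) == 0), " pre / ",
      sum(treatmentZ(object) == 1), " post\n", sep = "")
})

setMethod("show", "GEModule", function(object) {
  cat("GEModule ", object@gem_id, " [", object@side, ", ", object@cell_type,
      "] ", object@ligand, "-", object@receptor, ": ",
      length(object@members), " genes\n", sep = "")
})

setMethod("show", "CCCNetwork", function(object) {
  cat("CCCNetwork with", nrow(object@channels), "channel(s)\n")
  if (nrow(object@channels)) {
    ch <- object@channels
    for (i in seq_len(min(10, nrow(ch))))
      cat(sprintf("  %s -> %s via %s-%s (%d X x %d Y genes, %d pairs)\n",
                  ch$sender_type[i], ch$receiver_type[i], ch$ligand[i],
                  ch$receptor[i], length(ch$sender_members[[i]]),
                  length(ch$receiver_members[[i]]), ch$n_pairs[i]))
    if (nrow(ch) > 10) cat("  ...\n")
  }
})
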