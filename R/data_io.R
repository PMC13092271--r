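#' Read a single-cell count matrix with cell metadata
#'
#' Reads either a CellRanger-style Matrix Market directory (`matrix.mtx` plus
#' `genes.tsv`/`features.tsv` and `barcodes.tsv`) or a dense delimited table
#' (genes in rows, cells in columns, gene symbols in the first column), and
#' joins per-cell metadata.
#'
#' The metadata table must contain `cell_id`, `sample_id`, `patient_id`,
#' `timepoint`, `cell_type`; `cell_subtype` and `clonotype_id` are optional.
#' Column order is free, column names are strict. Cells present in the counts
#' but absent from the metadata are rejected with an error; metadata rows for
#' absent cells are dropped.
#'
#' Gene identity is by symbol, case-sensitive; duplicated symbols are
#' suffix-disambiguated (`make.unique`) with a warning.
#'
#' @param path directory containing `matrix.mtx` + companion TSVs, or a dense
#'   `.csv`/`.tsv` file
#' @param meta_path path to the cell metadata table (TSV or CSV)
#' @return a [CellMatrix]
#' @export
readCellMatrix <- function(path, meta_path) {
  # metadata fields are identifiers: read everything as character so that
  # symbols like "T" survive (read.delim would parse them as logical)
  meta <- .readTable(meta_path, colClasses = "character")
  need <- c("cell_id", "sample_id", "patient_id", "timepoint", "cell_type")
  for (col in need)
    if (!col %in% colnames(meta))
      stop("cell metadata is missing required column(s): ", col, call. = FALSE)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path, call. = FALSE)
    counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    gf <- file.path(path, c("genes.tsv", "features.tsv"))
    gf <- gf[file.exists(gf)][1]
    if (is.na(gf)) stop("no genes.tsv/features.tsv in ", path, call. = FALSE)
    genes <- utils::read.delim(gf, header = FALSE, stringsAsFactors = FALSE)
    sym <- genes[[min(2L, ncol(genes))]]
    bc <- utils::read.delim(file.path(path, "barcodes.tsv"), header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
    if (length(sym) != nrow(counts) || length(bc) != ncol(counts))
      stop("gene/barcode annotation does not match matrix dimensions",
           call. = FALSE)
    rownames(counts) <- .uniqueSymbols(sym)
    colnames(counts) <- bc
  } else {
    tab <- .readTable(path)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- .uniqueSymbols(as.character(tab[[1]]))
    counts <- methods::as(methods::as(Matrix::Matrix(counts), "generalMatrix"),
                          "CsparseMatrix")
  }
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell barcodes in counts", call. = FALSE)
  CellMatrix(counts, meta)
}

.uniqueSymbols <- function(sym) {
  if (anyDuplicated(sym)) {
    warning(sum(duplicated(sym)), " duplicated gene symbol(s) ",
            "suffix-disambiguated", call. = FALSE)
    sym <- make.unique(sym)
  }
  sym
}

# delimiter by extension, falling back to a sniff of the header line
.readTable <- function(path, colClasses = NA) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (sep == "\t" && !grepl("\t", first) && grepl(",", first)) sep <- ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = colClasses)
}

#' Write a CellMatrix as Matrix Market + TSV companions
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `meta.tsv` into `dir`.
#'
#' @param x a [CellMatrix]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
writeCellMatrix <- function(x, dir) {
  stopifnot(is(x, "CellMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(x, "counts")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  writeResultTable(cellMeta(x), file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read and merge ligand-receptor databases
#'
#' Each file must provide columns `ligand`, `receptor` and `source`.
#' Multi-subunit receptor complexes are encoded as subunits joined by `_`
#' (a `/` separator is accepted on read and normalized to `_`). Rows with a
#' blank ligand or receptor are dropped with a warning. Files are unioned and
#' deduplicated on (ligand, receptor), keeping the first source encountered.
#'
#' @param paths character vector of CSV/TSV files
#' @return data.frame with columns `ligand`, `receptor`, `source`
#' @seealso [receptorSubunits()]
#' @export
readLRDatabase <- function(paths) {
  tabs <- lapply(paths, function(p) {
    tab <- .readTable(p)
    miss <- setdiff(c("ligand", "receptor", "source"), colnames(tab))
    if (length(miss))
      stop("LR database ", p, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    tab[, c("ligand", "receptor", "source")]
  })
  db <- do.call(rbind, tabs)
  db$ligand <- trimws(as.character(db$ligand))
  db$receptor <- gsub("/", "_", trimws(as.character(db$receptor)), fixed = TRUE)
  blank <- !nzchar(db$ligand) | !nzchar(db$receptor) |
    is.na(db$ligand) | is.na(db$receptor)
  if (any(blank)) {
    warning(sum(blank), " LR row(s) with blank ligand/receptor dropped",
            call. = FALSE)
    db <- db[!blank, , drop = FALSE]
  }
  db <- db[!duplicated(paste(db$ligand, db$receptor, sep = "\r")), ,
           drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Split a receptor complex into its subunits
#'
#' @param receptor character vector of receptor strings, subunits joined by `_`
#' @return list of character vectors of subunit symbols
#' @examples
#' receptorSubunits("ITGAL_ITGB2")
#' @export
receptorSubunits <- function(receptor) strsplit(receptor, "_", fixed = TRUE)

#' Write / read a result table (TSV)
#'
#' Tab-separated with a header row. Doubles are written with 17 significant
#' digits so that write-then-read round-trips are lossless for strings and
#' integers and exact to machine precision for floats.
#'
#' @param x data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
writeResultTable <- function(x, path) {
  out <- as.data.frame(x)
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)

#' Write / read a CCC network as JSON
#'
#' The export lists one record per channel: sender and receiver cell type,
#' ligand, receptor, GEM member genes on both sides, and per-channel
#' statistics. `readNetwork(writeNetwork(x))` reproduces `x` exactly.
#'
#' @param network a [CCCNetwork]
#' @param path output `.json` file
#' @return `path`, invisibly
#' @export
writeNetwork <- function(network, path) {
  stopifnot(is(network, "CCCNetwork"))
  ch <- channels(network)
  recs <- lapply(seq_len(nrow(ch)), function(i) list(
    sender_type = ch$sender_type[i],
    receiver_type = ch$receiver_type[i],
    ligand = ch$ligand[i],
    receptor = ch$receptor[i],
    sender_gem_id = ch$sender_gem_id[i],
    receiver_gem_id = ch$receiver_gem_id[i],
    sender_members = as.list(ch$sender_members[[i]]),
    receiver_members = as.list(ch$receiver_members[[i]]),
    n_pairs = ch$n_pairs[i],
    median_p_cit = ch$median_p_cit[i]))
  jsonlite::write_json(list(channels = recs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recs <- obj$channels
  ch <- .emptyChannels()
  if (length(recs)) {
    ch <- data.frame(
      sender_type = vapply(recs, `[[`, "", "sender_type"),
      receiver_type = vapply(recs, `[[`, "", "receiver_type"),
      ligand = vapply(recs, `[[`, "", "ligand"),
      receptor = vapply(recs, `[[`, "", "receptor"),
      sender_gem_id = vapply(recs, `[[`, "", "sender_gem_id"),
      receiver_gem_id = vapply(recs, `[[`, "", "receiver_gem_id"),
      n_pairs = vapply(recs, function(r) as.integer(r$n_pairs), 1L),
      median_p_cit = vapply(recs, function(r) as.numeric(r$median_p_cit), 1),
      stringsAsFactors = FALSE)
    ch$sender_members <- lapply(recs, function(r)
      as.character(unlist(r$sender_members)))
    ch$receiver_members <- lapply(recs, function(r)
      as.character(unlist(r$receiver_members)))
  }
  new("CCCNetwork", channels = ch)
}

.emptyChannels <- function() {
  ch <- data.frame(sender_type = character(), receiver_type = character(),
                   ligand = character(), receptor = character(),
                   sender_gem_id = character(), receiver_gem_id = character(),
                   n_pairs = integer(), median_p_cit = numeric(),
                   stringsAsFactors = FALSE)
  ch$sender_members <- list()
  ch$receiver_members <- list()
  ch
}
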