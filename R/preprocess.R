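#' Quality-control parameters
#'
#' Boundary semantics follow the usual droplet QC reading of "fewer than" /
#' "more than": removals are strict, so cells with exactly `min_genes`
#' detected genes (or exactly `max_umi` UMIs) are kept, and cells with a
#' mitochondrial fraction strictly greater than `max_mito_frac` are removed.
#'
#' @param min_genes,max_genes retained range of detected genes per cell
#' @param min_umi,max_umi retained range of total UMIs per cell
#' @param max_mito_frac maximum tolerated mitochondrial UMI fraction
#' @return a `QCParams` list
#' @export
qcParams <- function(min_genes = 500L, max_genes = 5000L,
                     min_umi = 400L, max_umi = 25000L,
                     max_mito_frac = 0.20) {
  stopifnot(min_genes < max_genes, min_umi < max_umi,
            max_mito_frac >= 0, max_mito_frac <= 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umi = min_umi, max_umi = max_umi,
                 max_mito_frac = max_mito_frac), class = "QCParams")
}

#' Filter cells on detected genes, total UMIs and mitochondrial fraction
#'
#' Retains cells with `min_genes <= detected genes <= max_genes`,
#' `min_umi <= total UMIs <= max_umi` and mitochondrial UMI fraction
#' `<= max_mito_frac`. Per-criterion removal counts are reported via
#' `message()`.
#'
#' @param x a [CellMatrix]
#' @param params a [qcParams()] list
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes
#' @return the filtered [CellMatrix]
#' @export
qcFilter <- function(x, params = qcParams(), mito_prefix = "MT-") {
  stopifnot(is(x, "CellMatrix"), inherits(params, "QCParams"))
  m <- SummarizedExperiment::assay(x, "counts")
  detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mito <- startsWith(rownames(m), mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(m[mito, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(m))
  fail <- list(
    low_genes = detected < params$min_genes,
    high_genes = detected > params$max_genes,
    low_umi = total < params$min_umi,
    high_umi = total > params$max_umi,
    high_mito = mito_frac > params$max_mito_frac)
  removed <- vapply(fail, sum, 1)
  keep <- !Reduce(`|`, fail)
  message("qcFilter: removed ", sum(!keep), "/", ncol(m), " cells (",
          paste(names(removed), removed, sep = "=", collapse = ", "), ")")
  if (!any(keep))
    stop("all cells removed by QC: ",
         paste(names(removed), removed, sep = "=", collapse = ", "),
         call. = FALSE)
  x[, keep]
}

#' Build a per-cell-type pseudo-bulk table
#'
#' For each sample, counts of cells of `cell_type` are summed gene-wise
#' (sums preserve count statistics), scaled to counts per million, then
#' log2(x + 1)-transformed. Samples containing no cell of the type are
#' dropped with a warning. Length normalization is deliberately absent:
#' UMI counts have no length bias, so "TPM" here is CPM.
#'
#' @param x a [CellMatrix]
#' @param cell_type cell type to aggregate
#' @return a [PseudoBulkTable] (genes x samples, log2(CPM + 1))
#' @export
pseudobulk <- function(x, cell_type) {
  stopifnot(is(x, "CellMatrix"))
  cd <- SummarizedExperiment::colData(x)
  sel <- cd$cell_type == cell_type
  if (!any(sel)) stop("no cells of type '", cell_type, "'", call. = FALSE)
  m <- SummarizedExperiment::assay(x, "counts")[, sel, drop = FALSE]
  smp <- as.character(cd$sample_id[sel])
  all_samples <- unique(as.character(cd$sample_id))
  agg <- vapply(unique(smp), function(s)
    Matrix::rowSums(m[, smp == s, drop = FALSE]), numeric(nrow(m)))
  if (is.null(dim(agg)))
    agg <- matrix(agg, nrow = nrow(m),
                  dimnames = list(rownames(m), unique(smp)))
  dropped <- setdiff(all_samples, colnames(agg))
  if (length(dropped))
    warning(length(dropped), " sample(s) with no '", cell_type,
            "' cells dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  total <- colSums(agg)
  cpm <- sweep(agg, 2, pmax(total, 1), "/") * 1e6
  vals <- log2(cpm + 1)
  info <- unique(data.frame(sample_id = as.character(cd$sample_id),
                            patient_id = as.character(cd$patient_id),
                            timepoint = as.character(cd$timepoint),
                            stringsAsFactors = FALSE))
  info <- info[match(colnames(vals), info$sample_id), ]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logTPM = vals),
    colData = S4Vectors::DataFrame(
      patient_id = info$patient_id,
      Z = as.integer(info$timepoint == "post"),
      row.names = info$sample_id),
    metadata = list(cell_type = cell_type))
  new("PseudoBulkTable", se)
}

#' Paired differential expression on pseudo-bulk values
#'
#' For each gene, a paired t-test on the per-patient (post - pre) difference
#' of log2(CPM + 1) values. Only patients with both timepoints enter the
#' test. `log2fc` is the mean post minus mean pre over those patients (values
#' are already on the log2 scale). A gene is `significant` when
#' `p_value < alpha` and `|log2fc| > lfc_min`.
#'
#' Genes with zero counts in every sample are excluded (undefined
#' statistics). Zero-variance nonzero differences leave t undefined; such
#' genes are flagged `degenerate`, assigned the smallest representable
#' p-value, and reported via `message()` so that noiseless fixtures behave
#' predictably. P-values are raw by default (`bh = TRUE` applies
#' Benjamini-Hochberg before the significance call).
#'
#' @param pb a [PseudoBulkTable]
#' @param alpha significance level on the (possibly adjusted) p-value
#' @param lfc_min minimum absolute log2 fold-change
#' @param bh apply Benjamini-Hochberg correction
#' @return data.frame with columns `gene`, `cell_type`, `log2fc`, `t_stat`,
#'   `p_value`, `n_pairs`, `significant`, `degenerate`
#' @export
pairedDEG <- function(pb, alpha = 0.05, lfc_min = 0.5, bh = FALSE) {
  stopifnot(is(pb, "PseudoBulkTable"))
  v <- pbMatrix(pb)                      # samples x genes
  cd <- SummarizedExperiment::colData(pb)
  pre <- rownames(v)[cd$Z == 0]; post <- rownames(v)[cd$Z == 1]
  pat <- setNames(as.character(cd$patient_id), rownames(v))
  common <- intersect(pat[pre], pat[post])
  if (length(common) < 2)
    stop("paired DEG testing needs >= 2 patients with both timepoints",
         call. = FALSE)
  pre <- pre[match(common, pat[pre])]
  post <- post[match(common, pat[post])]
  keep <- colSums(v) > 0
  vp <- v[pre, keep, drop = FALSE]; vq <- v[post, keep, drop = FALSE]
  d <- vq - vp
  n <- length(common)
  mu <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, mu)^2) / (n - 1))
  tt <- mu / (s / sqrt(n))
  p <- 2 * pt(-abs(tt), df = n - 1)
  degen <- s == 0 & mu != 0
  if (any(degen)) {
    p[degen] <- .Machine$double.xmin
    tt[degen] <- sign(mu[degen]) * Inf
    message("pairedDEG: ", sum(degen),
            " gene(s) with zero-variance nonzero differences; ",
            "p set to the floor value")
  }
  p[s == 0 & mu == 0] <- 1
  tt[s == 0 & mu == 0] <- 0
  p_used <- if (bh) stats::p.adjust(p, "BH") else p
  data.frame(gene = colnames(d), cell_type = cellType(pb),
             log2fc = mu, t_stat = tt, p_value = p, n_pairs = n,
             significant = p_used < alpha & abs(mu) > lfc_min,
             degenerate = degen, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify patients by T-cell clonal expansion
#'
#' A patient is labelled `E` (expanded) when more than 50 clonotypes are each
#' carried by more than 2 cells (i.e. at least 3 cells), `NE` otherwise, and
#' `unknown` when the patient has no clonotype data.
#'
#' @param meta per-cell metadata data.frame with `patient_id` and
#'   `clonotype_id` (NA/empty for cells without TCR data)
#' @param min_clonotypes expansion calls require strictly more than this many
#'   qualifying clonotypes
#' @param min_cells a clonotype qualifies when carried by strictly more than
#'   this many cells
#' @return named character vector, patient_id -> `"E"`/`"NE"`/`"unknown"`
#' @export
classifyExpansion <- function(meta, min_clonotypes = 50L, min_cells = 2L) {
  stopifnot(all(c("patient_id", "clonotype_id") %in% colnames(meta)))
  pats <- unique(as.character(meta$patient_id))
  out <- setNames(rep("unknown", length(pats)), pats)
  has <- !is.na(meta$clonotype_id) & nzchar(as.character(meta$clonotype_id))
  for (p in pats) {
    cl <- meta$clonotype_id[has & meta$patient_id == p]
    if (!length(cl)) next
    n_exp <- sum(table(cl) > min_cells)
    out[p] <- if (n_exp > min_clonotypes) "E" else "NE"
  }
  out
}
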