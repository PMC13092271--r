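# small in-code fixtures shared across test files

# 3-gene x 4-cell toy matrix: 2 patients, paired pre/post, one cell type
toyCellMatrix <- function() {
  m <- matrix(c(1, 0, 2, 4,
                0, 3, 1, 0,
                5, 2, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), paste0("c", 1:4)))
  meta <- data.frame(
    cell_id = paste0("c", 1:4),
    sample_id = c("p1_pre", "p1_post", "p2_pre", "p2_post"),
    patient_id = c("p1", "p1", "p2", "p2"),
    timepoint = c("pre", "post", "pre", "post"),
    cell_type = "T", stringsAsFactors = FALSE)
  CellMatrix(m, meta)
}

# pseudo-bulk table built directly from a samples x genes value matrix
makePB <- function(values, patient_id, Z, cell_type = "T",
                   sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- paste0(patient_id, "_", ifelse(Z == 1, "post", "pre"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logTPM = t(values)),
    colData = S4Vectors::DataFrame(patient_id = patient_id,
                                   Z = as.integer(Z),
                                   row.names = sample_id),
    metadata = list(cell_type = cell_type))
  new("PseudoBulkTable", se)
}

# vectors with exact sample correlation structure: columns of Q are centered
# and orthonormal, so population correlations equal sample correlations
orthoBasis <- function(n, k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(cbind(1, matrix(rnorm(n * k), n, k))))[, -1, drop = FALSE]
}
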