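#' Pipeline configuration
#'
#' Thresholds default to the conventional screening values used throughout
#' the package: raw p < 0.05 at the DEG, IV and exclusion stages, |log2FC| >
#' 0.5 for DEG calls, 0.3 for the single-cell co-expression requirement and
#' for the direct-co-expression guard.
#'
#' @param sender_cell_type the treatment-targeted cell type (source of X
#'   genes)
#' @param receiver_cell_types non-targeted cell types (sources of Y genes)
#' @param alpha_deg,fc_min DEG thresholds ([pairedDEG()])
#' @param alpha_iv,alpha_excl IV-stage thresholds ([screenPairs()])
#' @param alpha_cit,rho_min CIT-stage thresholds ([screenLR()])
#' @param rho_max direct-co-expression guard ([filterDirectCoexpression()])
#' @param qc a [qcParams()] list, or `NULL` to skip cell QC (e.g. for
#'   synthetic data whose gene panel is smaller than droplet QC assumes)
#' @param mito_prefix mitochondrial gene prefix for QC
#' @param strict_n3 use the plain 1/sqrt(n-3) Fisher-z null sd
#' @param gem_filter_mode `"residual"` or `"literal"`
#' @param bh_correction apply Benjamini-Hochberg at the DEG and IV stages
#' @return a `PipelineConfig` list
#' @export
pipelineConfig <- function(sender_cell_type, receiver_cell_types,
                           alpha_deg = 0.05, fc_min = 0.5,
                           alpha_iv = 0.05, alpha_excl = 0.05,
                           alpha_cit = 0.05, rho_min = 0.3, rho_max = 0.3,
                           qc = NULL, mito_prefix = "MT-",
                           strict_n3 = FALSE,
                           gem_filter_mode = c("residual", "literal"),
                           bh_correction = FALSE) {
  for (a in c(alpha_deg, alpha_iv, alpha_excl, alpha_cit))
    if (a <= 0 || a >= 1) stop("alpha thresholds must be in (0,1)",
                               call. = FALSE)
  structure(list(
    sender_cell_type = sender_cell_type,
    receiver_cell_types = receiver_cell_types,
    alpha_deg = alpha_deg, fc_min = fc_min,
    alpha_iv = alpha_iv, alpha_excl = alpha_excl,
    alpha_cit = alpha_cit, rho_min = rho_min, rho_max = rho_max,
    qc = qc, mito_prefix = mito_prefix, strict_n3 = strict_n3,
    gem_filter_mode = match.arg(gem_filter_mode),
    bh_correction = bh_correction), class = "PipelineConfig")
}

#' Run the full causal CCC pipeline
#'
#' Executes QC (optional) -> per-cell-type pseudo-bulk -> paired DEG ->
#' instrumental-variable screening (sender x each receiver) -> Fisher-z LR
#' mediation screening -> direct-co-expression filtering -> GEM grouping ->
#' network assembly. Every intermediate table is returned, and written to
#' `outdir` (TSV; network as JSON; run manifest with per-stage counts) when
#' given.
#'
#' @param cells a [CellMatrix]
#' @param lr_db LR database data.frame ([readLRDatabase()])
#' @param config a [pipelineConfig()]
#' @param outdir optional output directory
#' @return list with `deg` (named list of [pairedDEG()] tables), `iv`,
#'   `cit`, `filtered` (data.frames), `gems` (list), `network`
#'   ([CCCNetwork-class]) and `manifest` (per-stage counts)
#' @export
runPipeline <- function(cells, lr_db, config, outdir = NULL) {
  stopifnot(is(cells, "CellMatrix"), inherits(config, "PipelineConfig"))
  stage <- "qc"
  res <- tryCatch({
    if (!is.null(config$qc))
      cells <- qcFilter(cells, config$qc, config$mito_prefix)
    stage <- "pseudobulk"
    types <- c(config$sender_cell_type, config$receiver_cell_types)
    pb <- lapply(setNames(types, types), function(ty) pseudobulk(cells, ty))
    stage <- "deg"
    deg <- lapply(pb, pairedDEG, alpha = config$alpha_deg,
                  lfc_min = config$fc_min, bh = config$bh_correction)
    stage <- "iv"
    sender <- config$sender_cell_type
    iv <- do.call(rbind, lapply(config$receiver_cell_types, function(ty)
      screenPairs(deg[[sender]], deg[[ty]], pb[[sender]], pb[[ty]],
                  alpha_iv = config$alpha_iv, alpha_excl = config$alpha_excl,
                  bh = config$bh_correction)))
    stage <- "cit"
    cit <- do.call(rbind, lapply(config$receiver_cell_types, function(ty) {
      iv_ty <- iv[iv$receiver_type == ty, , drop = FALSE]
      if (!nrow(iv_ty[iv_ty$passes, ])) return(NULL)
      screenLR(iv_ty, lr_db, pb[[sender]], pb[[ty]], cells,
               alpha_cit = config$alpha_cit, rho_min = config$rho_min,
               strict_n3 = config$strict_n3)
    }))
    if (is.null(cit)) cit <- screenLR(iv[0, ], lr_db,
                                      pb[[sender]],
                                      pb[[config$receiver_cell_types[1]]],
                                      cells)
    stage <- "gem_filter"
    med <- cit[cit$mediates, , drop = FALSE]
    filtered <- do.call(rbind, lapply(config$receiver_cell_types, function(ty) {
      m_ty <- med[med$receiver_type == ty, , drop = FALSE]
      if (!nrow(m_ty)) return(m_ty)
      filterDirectCoexpression(m_ty, pb[[sender]], pb[[ty]],
                               rho_max = config$rho_max,
                               mode = config$gem_filter_mode)
    }))
    stage <- "network"
    gems <- groupGEMs(filtered)
    network <- buildNetwork(gems)
    manifest <- list(
      n_cells = ncol(cells),
      n_deg = vapply(deg, function(d) sum(d$significant), 1L),
      n_pairs_tested = nrow(iv),
      n_pairs_iv_pass = sum(iv$passes),
      n_triples_tested = nrow(cit),
      n_triples_mediating = sum(cit$mediates),
      n_triples_filtered = nrow(filtered),
      n_xy_pairs_in_network = length(unique(
        paste(filtered$x_gene, filtered$y_gene))),
      n_channels = length(network),
      thresholds = config[c("alpha_deg", "fc_min", "alpha_iv", "alpha_excl",
                            "alpha_cit", "rho_min", "rho_max",
                            "gem_filter_mode")])
    list(pseudobulk = pb, deg = deg, iv = iv, cit = cit, filtered = filtered,
         gems = gems, network = network, manifest = manifest)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(outdir)) .writePipeline(res, outdir)
  res
}

.writePipeline <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  deg_all <- do.call(rbind, res$deg)
  writeResultTable(deg_all, file.path(outdir, "deg.tsv"))
  writeResultTable(res$iv, file.path(outdir, "iv_pairs.tsv"))
  writeResultTable(res$cit, file.path(outdir, "cit_results.tsv"))
  gems <- res$gems
  gtab <- do.call(rbind, lapply(gems, function(g) data.frame(
    gem_id = c(g$sender@gem_id, g$receiver@gem_id),
    side = c("sender", "receiver"),
    cell_type = c(g$sender_type, g$receiver_type),
    lr = paste(g$ligand, g$receptor, sep = "-"),
    members = c(paste(g$sender@members, collapse = ","),
                paste(g$receiver@members, collapse = ",")),
    stringsAsFactors = FALSE)))
  if (is.null(gtab)) gtab <- data.frame(gem_id = character(),
                                        side = character(),
                                        cell_type = character(),
                                        lr = character(),
                                        members = character())
  writeResultTable(gtab, file.path(outdir, "gems.tsv"))
  writeNetwork(res$network, file.path(outdir, "network.json"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
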