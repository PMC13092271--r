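#' Simulation configuration for paired perturbation single-cell data
#'
#' Builds the configuration of the synthetic tumor-microenvironment generator.
#' The generator emulates a paired pre/post-treatment design in which a
#' therapy directly targets one sender cell type: treatment activates a latent
#' sender pathway, the pathway drives a gene expression module (GEM X) and
#' ligand secretion, the population ligand level engages a receptor on
#' receiver cells, and receptor engagement drives a receiver pathway, the
#' receptor itself, and GEM Y. Patient-level confounders, confounded decoy
#' gene pairs (correlated only through the patient effect) and causally inert
#' decoy ligand-receptor pairs are planted alongside.
#'
#' Two preset scales are provided. `"smoke"`: 8 patients, 50 cells per sample
#' per cell type, 1 planted channel. `"full"`: 31 patients (a paired-biopsy
#' cohort size typical of window-of-opportunity immunotherapy trials),
#' 200 cells per sample per type, 5 planted channels, 50 decoy LR pairs and
#' 20 confounded decoy gene pairs over a background of 800 inert genes.
#' Background genes dominate the per-cell library (as in a real
#' transcriptome), so treatment-responsive modules shift totals - and hence
#' the CPM values of unaffected genes - only mildly.
#'
#' Effect sizes are on the natural-log scale of expression means. Defaults
#' place the planted channels in a regime where treatment-responsive genes
#' have an expected log2 fold-change near 1 and ligand/module co-expression
#' is detectable at the single-cell level, while decoys remain non-trivial;
#' the methods vignette motivates each value.
#'
#' @param scale `"smoke"` or `"full"` preset
#' @param ... named overrides of any configuration field
#' @return a `SimConfig` list with fields: `n_patients`, `cells_per_type`,
#'   `sender_type`, `receiver_types`, `n_channels`, `genes_per_gem`,
#'   `n_decoy_lr`, `n_confounded`, `n_background`, `a0`, `a1` (treatment
#'   effect on the sender pathway), `lambda` (pathway to GEM X loading),
#'   `lambda_ligand`, `theta` (signal to GEM Y loading), `receptor_loading`,
#'   `gem_y_conf` (patient-confounder loading on GEM Y), `conf_z`, `conf_u_x`,
#'   `conf_u_y` (decoy-pair loadings), `sigma_u`, `sigma_eps`,
#'   `gene_noise_x`, `gene_noise_y`, `base_mean`, `cross_mean`,
#'   `bg_mean_range`, `libsize_sd`, `nb_dispersion`, `debug_deterministic`,
#'   `seed`
#' @export
simConfig <- function(scale = c("smoke", "full"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    n_patients = 8L, cells_per_type = 50L,
    sender_type = "Tcell", receiver_types = "myeloid",
    n_channels = 1L, genes_per_gem = 5L,
    n_decoy_lr = 5L, n_confounded = 3L, n_background = 150L,
    a0 = 0, a1 = 1, lambda = 0.7, lambda_ligand = 0.7, theta = 1,
    receptor_loading = 1, gem_y_conf = 0.3,
    conf_z = 0.7, conf_u_x = 1, conf_u_y = 1,
    sigma_u = 0.3, sigma_eps = 0.15,
    gene_noise_x = 0.1, gene_noise_y = 0.25,
    base_mean = 25, cross_mean = 0.05, bg_mean_range = c(1, 30),
    libsize_sd = 0.3, nb_dispersion = 0,
    debug_deterministic = FALSE, seed = 1L)
  if (scale == "full") {
    cfg$n_patients <- 31L
    cfg$cells_per_type <- 200L
    cfg$n_channels <- 5L
    cfg$n_decoy_lr <- 50L
    cfg$n_confounded <- 20L
    cfg$n_background <- 800L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$n_patients < 4) stop("n_patients must be >= 4", call. = FALSE)
  if (!length(cfg$receiver_types))
    stop("at least one receiver cell type is required", call. = FALSE)
  sc <- c("sigma_u", "sigma_eps", "gene_noise_x", "gene_noise_y",
          "libsize_sd", "nb_dispersion", "base_mean", "cross_mean")
  for (f in sc) if (any(cfg[[f]] < 0))
    stop(f, " must be non-negative", call. = FALSE)
  structure(cfg, class = "SimConfig")
}

# one stream per patient, derived from the master seed by a fixed offset so
# that changing n_patients never reshuffles earlier patients
.streamSeed <- function(seed, i)
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)

#' Simulate a paired perturbation single-cell dataset with ground truth
#'
#' Generative model, per patient i with latent confounder
#' u_i ~ N(0, sigma_u^2) shared by both timepoints and all cell types, and
#' treatment z = 0 (pre) / 1 (post):
#'
#' * Sender pathway, per channel k and sample: A = a0 + a1 z + u_i + eps,
#'   eps ~ N(0, sigma_eps^2).
#' * Sender cells: each GEM X gene has mean `base_mean * exp(lambda * A + xi)`
#'   with per-gene per-sample noise xi ~ N(0, gene_noise_x^2); the ligand has
#'   mean `base_mean * exp(lambda_ligand * A)`.
#' * Receiver cells: the signal acts through the population (pseudo-bulk)
#'   ligand level, proportional on the log scale to `lambda_ligand * A`; the
#'   receptor and each GEM Y gene have mean
#'   `base_mean * exp(loading * lambda_ligand * A + gem_y_conf * u_i + xi)`
#'   (receptor: `receptor_loading`, no confounder term; GEM Y: `theta`,
#'   xi ~ N(0, gene_noise_y^2)).
#' * Confounded decoy pairs: sender X' has mean
#'   `base_mean * exp(conf_z * z + conf_u_x * u_i + xi)`; receiver Y' has mean
#'   `base_mean * exp(conf_u_y * u_i + xi)` - no treatment path to Y', so the
#'   X'-Y' correlation is purely confounded.
#' * Decoy LR pairs: ligand (sender) and receptor (receiver) expressed
#'   constitutively at `base_mean`, causally inert.
#' * Background genes: constant per-gene means drawn log-uniformly from
#'   `bg_mean_range`; five mitochondrial (`MT-`) background genes are
#'   included for QC exercises.
#'
#' Counts are Poisson with per-cell lognormal library-size factors
#' (negative binomial when `nb_dispersion > 0`). Genes outside a compartment
#' are expressed at `cross_mean`. With `debug_deterministic = TRUE`, library
#' factors are fixed at 1 and counts are replaced by their expectations
#' (fractional values), giving a noiseless limit when the sigma fields are 0.
#'
#' @param config a `SimConfig` from [simConfig()]
#' @return list with elements `cells` (a [CellMatrix]) and `truth`
#'   (a `GroundTruth` list: `channels` data.frame with list-columns
#'   `gem_x`/`gem_y`, `confounded`, `decoy_lr`, and `lr_database` - the
#'   planted-plus-decoy LR table to feed the screening stage)
#' @export
simulateTME <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  K <- cfg$n_channels; G <- cfg$genes_per_gem
  panel <- .genePanel(cfg)
  genes <- panel$genes
  nG <- length(genes)

  set.seed(.streamSeed(cfg$seed, 0L))
  bg_mean <- exp(runif(length(panel$bg), log(cfg$bg_mean_range[1]),
                       log(cfg$bg_mean_range[2])))

  types <- c(cfg$sender_type, cfg$receiver_types)
  n_cells <- cfg$cells_per_type
  blocks <- list(); metas <- list(); b <- 0L
  for (i in seq_len(cfg$n_patients)) {
    set.seed(.streamSeed(cfg$seed, i))
    u <- rnorm(1, 0, cfg$sigma_u)
    pid <- sprintf("P%02d", i)
    for (tp in c("pre", "post")) {
      z <- as.integer(tp == "post")
      sid <- paste0(pid, "_", tp)
      eps <- rnorm(K, 0, cfg$sigma_eps)
      A <- cfg$a0 + cfg$a1 * z + u + eps
      for (ty in types) {
        mu <- .sampleMeans(cfg, panel, bg_mean, A, z, u,
                           sender = (ty == cfg$sender_type))
        cnt <- .drawCounts(cfg, mu, n_cells)
        rownames(cnt) <- genes
        colnames(cnt) <- sprintf("%s_%s_%03d", sid, ty, seq_len(n_cells))
        b <- b + 1L
        blocks[[b]] <- cnt
        metas[[b]] <- data.frame(
          cell_id = colnames(cnt), sample_id = sid, patient_id = pid,
          timepoint = tp, cell_type = ty, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- methods::as(Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE),
                        "CsparseMatrix")
  meta <- do.call(rbind, metas)
  cells <- CellMatrix(counts, meta)

  truth <- list(channels = panel$channels, confounded = panel$confounded,
                decoy_lr = panel$decoy_lr,
                lr_database = rbind(
                  data.frame(ligand = panel$channels$ligand,
                             receptor = panel$channels$receptor,
                             source = "planted", stringsAsFactors = FALSE),
                  panel$decoy_lr))
  class(truth) <- "GroundTruth"
  list(cells = cells, truth = truth)
}

.genePanel <- function(cfg) {
  K <- cfg$n_channels; G <- cfg$genes_per_gem
  ch <- data.frame(
    sender_type = cfg$sender_type,
    receiver_type = rep(cfg$receiver_types, length.out = max(K, 1))[seq_len(K)],
    ligand = sprintf("LIG%d", seq_len(K)),
    receptor = sprintf("REC%d", seq_len(K)),
    stringsAsFactors = FALSE)
  ch$gem_x <- lapply(seq_len(K), function(k) sprintf("GX%d.%d", k, seq_len(G)))
  ch$gem_y <- lapply(seq_len(K), function(k) sprintf("GY%d.%d", k, seq_len(G)))
  confounded <- data.frame(
    x_gene = sprintf("CFX.%d", seq_len(cfg$n_confounded)),
    y_gene = sprintf("CFY.%d", seq_len(cfg$n_confounded)),
    stringsAsFactors = FALSE)
  if (!cfg$n_confounded) confounded <- confounded[0, ]
  decoy_lr <- data.frame(
    ligand = sprintf("DLIG.%d", seq_len(cfg$n_decoy_lr)),
    receptor = sprintf("DREC.%d", seq_len(cfg$n_decoy_lr)),
    source = "decoy", stringsAsFactors = FALSE)
  if (!cfg$n_decoy_lr) decoy_lr <- decoy_lr[0, ]
  bg <- c(sprintf("BG.%d", seq_len(cfg$n_background)), sprintf("MT-%d", 1:5))
  genes <- c(unlist(ch$gem_x), ch$ligand, unlist(ch$gem_y), ch$receptor,
             confounded$x_gene, confounded$y_gene,
             decoy_lr$ligand, decoy_lr$receptor, bg)
  list(genes = genes, channels = ch, confounded = confounded,
       decoy_lr = decoy_lr, bg = bg)
}

# expected expression per gene for one (sample, cell type); A is the
# per-channel sender pathway activity vector for this sample
.sampleMeans <- function(cfg, panel, bg_mean, A, z, u, sender) {
  K <- cfg$n_channels; G <- cfg$genes_per_gem
  base <- cfg$base_mean; cross <- cfg$cross_mean
  n_cf <- nrow(panel$confounded); n_dl <- nrow(panel$decoy_lr)
  sig <- cfg$lambda_ligand * A          # log population ligand level, per channel
  gx <- gy <- lig <- rec <- numeric(0)
  if (K) {
    if (sender) {
      xi <- rnorm(K * G, 0, cfg$gene_noise_x)
      gx <- base * exp(rep(cfg$lambda * A, each = G) + xi)
      lig <- base * exp(sig)
      gy <- rep(cross, K * G); rec <- rep(cross, K)
    } else {
      xi <- rnorm(K * G, 0, cfg$gene_noise_y)
      gy <- base * exp(rep(cfg$theta * sig, each = G) + cfg$gem_y_conf * u + xi)
      rec <- base * exp(cfg$receptor_loading * sig)
      gx <- rep(cross, K * G); lig <- rep(cross, K)
    }
  }
  if (n_cf) {
    if (sender) {
      cfx <- base * exp(cfg$conf_z * z + cfg$conf_u_x * u +
                          rnorm(n_cf, 0, cfg$gene_noise_x))
      cfy <- rep(cross, n_cf)
    } else {
      cfx <- rep(cross, n_cf)
      cfy <- base * exp(cfg$conf_u_y * u + rnorm(n_cf, 0, cfg$gene_noise_y))
    }
  } else cfx <- cfy <- numeric(0)
  if (n_dl) {
    dl <- if (sender) rep(base, n_dl) else rep(cross, n_dl)
    dr <- if (sender) rep(cross, n_dl) else rep(base, n_dl)
  } else dl <- dr <- numeric(0)
  c(gx, lig, gy, rec, cfx, cfy, dl, dr, bg_mean)
}

.drawCounts <- function(cfg, mu, n_cells) {
  nG <- length(mu)
  if (cfg$debug_deterministic)
    return(matrix(rep(mu, n_cells), nG, n_cells))
  lib <- exp(rnorm(n_cells, -cfg$libsize_sd^2 / 2, cfg$libsize_sd))
  lam <- mu %o% lib
  if (cfg$nb_dispersion > 0)
    matrix(stats::rnbinom(nG * n_cells, mu = lam,
                          size = 1 / cfg$nb_dispersion), nG, n_cells)
  else
    matrix(rpois(nG * n_cells, lam), nG, n_cells)
}

#' Write a simulated dataset to disk
#'
#' Writes the count matrix as Matrix Market with companion TSVs (see
#' [writeCellMatrix()]) plus `ground_truth.json`.
#'
#' @param sim result of [simulateTME()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
writeSimulation <- function(sim, dir) {
  writeCellMatrix(sim$cells, dir)
  tr <- sim$truth
  ch <- tr$channels
  obj <- list(
    channels = lapply(seq_len(nrow(ch)), function(i) list(
      sender_type = ch$sender_type[i], receiver_type = ch$receiver_type[i],
      ligand = ch$ligand[i], receptor = ch$receptor[i],
      gem_x = as.list(ch$gem_x[[i]]), gem_y = as.list(ch$gem_y[[i]]))),
    confounded = tr$confounded, decoy_lr = tr$decoy_lr)
  jsonlite::write_json(obj, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
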