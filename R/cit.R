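#' Fisher-z conditional independence test
#'
#' Tests X independent of Y given the conditioning set M via the partial
#' correlation r of X and Y given M (computed as the correlation of OLS
#' residuals of X and Y on `[1, M]`), Fisher-transformed to
#' `w = 0.5 * log((1 + r) / (1 - r))`. Under the null the transformed
#' statistic has mean 0 and standard deviation
#' `sigma = 1 / sqrt(n - |M| - 3)` (the standard Fisher-z CIT convention;
#' `strict_n3 = TRUE` uses `1 / sqrt(n - 3)` regardless of the conditioning
#' size). The z-score is `w / sigma` and
#' `p = 2 * (1 - pnorm(|z|))`.
#'
#' `|r| = 1` saturates the transform; the test then returns `p = 0` with a
#' `saturated` flag. Zero-variance inputs are an error.
#'
#' @param X,Y numeric vectors of length n
#' @param M conditioning variables: `NULL` (marginal test), a vector, or a
#'   matrix with n rows
#' @param strict_n3 use the plain `1/sqrt(n - 3)` null standard deviation
#' @return list with `r_partial`, `w`, `sigma`, `z_score`, `p_value`, `n`,
#'   `cond_size`, `saturated`
#' @export
fisherZTest <- function(X, Y, M = NULL, strict_n3 = FALSE) {
  n <- length(X)
  stopifnot(length(Y) == n)
  if (!is.null(M)) {
    M <- as.matrix(M)
    stopifnot(nrow(M) == n)
  }
  q <- if (is.null(M)) 0L else ncol(M)
  if (n < q + 4)
    stop("need n >= |conditioning set| + 4 samples", call. = FALSE)
  if (sd(X) == 0 || sd(Y) == 0)
    stop("zero-variance input to fisherZTest", call. = FALSE)
  if (q == 0) {
    r <- cor(X, Y)
  } else {
    fit <- stats::lm.fit(cbind(1, M), cbind(X, Y))
    rx <- fit$residuals[, 1]; ry <- fit$residuals[, 2]
    vx <- sum(rx^2); vy <- sum(ry^2)
    if (vx < .Machine$double.eps * sum((X - mean(X))^2) ||
        vy < .Machine$double.eps * sum((Y - mean(Y))^2))
      stop("conditioning set explains X or Y exactly; partial correlation ",
           "undefined", call. = FALSE)
    r <- sum(rx * ry) / sqrt(vx * vy)
  }
  r <- max(min(r, 1), -1)
  df_sigma <- if (strict_n3) n - 3 else n - q - 3
  sigma <- 1 / sqrt(df_sigma)
  saturated <- abs(r) >= 1 - .Machine$double.eps
  if (saturated) {
    w <- sign(r) * Inf; z <- sign(r) * Inf; p <- 0
  } else {
    w <- 0.5 * log((1 + r) / (1 - r))
    z <- w / sigma
    p <- 2 * (1 - pnorm(abs(z)))
  }
  list(r_partial = r, w = w, sigma = sigma, z_score = z, p_value = p,
       n = n, cond_size = q, saturated = saturated)
}

# first-order partial correlation by the recursive formula; used as the
# independent cross-check of the residual-regression route
.partialCorRecursive <- function(X, Y, M) {
  rxy <- cor(X, Y); rxm <- cor(X, M); rym <- cor(Y, M)
  (rxy - rxm * rym) / sqrt((1 - rxm^2) * (1 - rym^2))
}

#' Single-cell co-expression of two genes within a cell type
#'
#' Pearson correlation across single cells of `cell_type` (pooled over all
#' samples) on per-cell log2(CPM + 1) normalized expression. When `gene_a`
#' or `gene_b` names several genes (a receptor complex), the per-cell
#' normalized values are combined by the subunit-wise minimum
#' (limiting-subunit logic).
#'
#' Zero variance in either profile returns 0 with a `"degenerate"` attribute
#' (which fails any co-expression threshold).
#'
#' @param x a [CellMatrix]
#' @param gene_a,gene_b gene symbol(s)
#' @param cell_type cells to use
#' @param min_cells minimum number of cells required
#' @return correlation (numeric scalar)
#' @export
coexpression <- function(x, gene_a, gene_b, cell_type, min_cells = 10L) {
  stopifnot(is(x, "CellMatrix"))
  miss <- setdiff(c(gene_a, gene_b), rownames(x))
  if (length(miss))
    stop("gene(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  norm <- .normalizedCells(x, cell_type, unique(c(gene_a, gene_b)))
  if (ncol(norm) < min_cells)
    stop("fewer than ", min_cells, " cells of type '", cell_type, "'",
         call. = FALSE)
  a <- .combineSubunits(norm, gene_a)
  b <- .combineSubunits(norm, gene_b)
  if (sd(a) == 0 || sd(b) == 0) {
    r <- 0
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  cor(a, b)
}

# per-cell log2(CPM + 1) over the full transcriptome, restricted to `genes`
.normalizedCells <- function(x, cell_type, genes) {
  cd <- SummarizedExperiment::colData(x)
  sel <- cd$cell_type == cell_type
  if (!any(sel)) stop("no cells of type '", cell_type, "'", call. = FALSE)
  m <- SummarizedExperiment::assay(x, "counts")[, sel, drop = FALSE]
  total <- Matrix::colSums(m)
  sub <- as.matrix(m[genes, , drop = FALSE])
  log2(sweep(sub, 2, pmax(total, 1), "/") * 1e6 + 1)
}

.combineSubunits <- function(norm, genes) {
  if (length(genes) == 1L) return(norm[genes, ])
  do.call(pmin, lapply(genes, function(g) norm[g, ]))
}

#' Screen ligand-receptor pairs as mediators of IV-passing gene pairs
#'
#' For each IV-passing (X, Y) pair and each LR pair, the conditioning
#' variable is the per-sample product of the sender pseudo-bulk ligand value
#' and the receiver pseudo-bulk receptor value (complex receptors: the
#' subunit-wise minimum of receiver pseudo-bulk values). The Fisher-z test
#' ([fisherZTest()]) is run on the sample-aligned pseudo-bulk X, Y given M;
#' an LR pair `mediates` the X-Y relation when
#'
#' * the marginal (unconditioned) X-Y dependence is significant
#'   (`p < alpha_marginal`) - so "independence given M" reflects mediation,
#'   not absent association;
#' * the conditional test fails to reject independence
#'   (`p_value > alpha_cit`, strictly);
#' * the ligand co-expresses with X in sender cells and the receptor with Y
#'   in receiver cells at the single-cell level
#'   ([coexpression()] `>= rho_min`).
#'
#' LR pairs whose ligand is not measured in the sender pseudo-bulk or whose
#' receptor subunits are not all measured in the receiver pseudo-bulk are
#' skipped with a message.
#'
#' @param iv_results a [screenPairs()] table (only rows with `passes` are
#'   screened)
#' @param lr_db LR database data.frame from [readLRDatabase()] (columns
#'   `ligand`, `receptor`, `source`)
#' @param pb_sender,pb_receiver [PseudoBulkTable]s
#' @param cells the [CellMatrix] (for single-cell co-expression)
#' @param alpha_cit retention level of the conditional test
#' @param rho_min minimum single-cell co-expression
#' @param alpha_marginal level of the marginal-dependence prerequisite
#' @param strict_n3 passed to [fisherZTest()]
#' @return data.frame with columns `x_gene`, `y_gene`, `ligand`, `receptor`,
#'   `r_partial`, `w`, `z_score`, `p_value`, `p_marginal`,
#'   `coexpr_ligand_x`, `coexpr_receptor_y`, `mediates`
#' @export
screenLR <- function(iv_results, lr_db, pb_sender, pb_receiver, cells,
                     alpha_cit = 0.05, rho_min = 0.3, alpha_marginal = 0.05,
                     strict_n3 = FALSE) {
  if (!nrow(lr_db)) stop("empty LR database", call. = FALSE)
  iv <- iv_results[iv_results$passes, , drop = FALSE]
  empty <- data.frame(x_gene = character(), y_gene = character(),
                      sender_type = character(), receiver_type = character(),
                      ligand = character(), receptor = character(),
                      r_partial = numeric(), w = numeric(),
                      z_score = numeric(), p_value = numeric(),
                      p_marginal = numeric(), coexpr_ligand_x = numeric(),
                      coexpr_receptor_y = numeric(), mediates = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(iv)) return(empty)
  al <- .alignSamples(pb_sender, pb_receiver)
  n <- length(al$samples)
  sender_type <- cellType(pb_sender); receiver_type <- cellType(pb_receiver)

  subunits <- receptorSubunits(lr_db$receptor)
  measurable <- lr_db$ligand %in% colnames(al$sender) &
    vapply(subunits, function(s) all(s %in% colnames(al$receiver)), TRUE)
  if (any(!measurable))
    message("screenLR: skipping ", sum(!measurable),
            " LR pair(s) with unmeasured ligand/receptor")
  lr <- lr_db[measurable, , drop = FALSE]
  subunits <- subunits[measurable]
  if (!nrow(lr)) return(empty)

  # per-sample conditioning variables, one column per LR pair
  Mmat <- vapply(seq_len(nrow(lr)), function(k) {
    rec <- al$receiver[, subunits[[k]], drop = FALSE]
    al$sender[, lr$ligand[k]] * apply(rec, 1, min)
  }, numeric(n))

  xs <- unique(iv$x_gene); ys <- unique(iv$y_gene)
  Xm <- al$sender[, xs, drop = FALSE]; Ym <- al$receiver[, ys, drop = FALSE]
  r_xy <- cor(Xm, Ym)
  ok_m <- apply(Mmat, 2, sd) > 0
  r_xm <- matrix(0, length(xs), nrow(lr)); r_ym <- matrix(0, length(ys), nrow(lr))
  r_xm[, ok_m] <- cor(Xm, Mmat[, ok_m, drop = FALSE])
  r_ym[, ok_m] <- cor(Ym, Mmat[, ok_m, drop = FALSE])
  dimnames(r_xm) <- list(xs, NULL); dimnames(r_ym) <- list(ys, NULL)

  # single-cell co-expression, computed once per unique (gene, partner) pair
  lig_cor <- .coexprGrid(cells, sender_type,
                         lapply(lr$ligand, identity), xs)
  rec_cor <- .coexprGrid(cells, receiver_type, subunits, ys)

  pairs <- iv[, c("x_gene", "y_gene")]
  grid <- expand.grid(pi = seq_len(nrow(pairs)), k = seq_len(nrow(lr)))
  xi <- match(pairs$x_gene[grid$pi], xs)
  yi <- match(pairs$y_gene[grid$pi], ys)
  rxy <- r_xy[cbind(xi, yi)]
  rxm <- r_xm[cbind(xi, grid$k)]
  rym <- r_ym[cbind(yi, grid$k)]
  denom <- sqrt(pmax((1 - rxm^2) * (1 - rym^2), 0))
  rp <- ifelse(denom > 0, (rxy - rxm * rym) / denom, rxy)
  rp <- pmax(pmin(rp, 1), -1)
  sigma <- 1 / sqrt(if (strict_n3) n - 3 else n - 4)
  sat <- abs(rp) >= 1 - .Machine$double.eps
  w <- ifelse(sat, sign(rp) * Inf, 0.5 * log((1 + rp) / (1 - rp)))
  z <- w / sigma
  p <- ifelse(sat, 0, 2 * (1 - pnorm(abs(z))))
  # marginal dependence, Fisher-z with empty conditioning set
  w0 <- 0.5 * log((1 + pmax(pmin(rxy, 1 - 1e-15), -1 + 1e-15)) /
                    (1 - pmax(pmin(rxy, 1 - 1e-15), -1 + 1e-15)))
  p0 <- 2 * (1 - pnorm(abs(w0) * sqrt(n - 3)))
  cx <- lig_cor[cbind(grid$k, xi)]
  cy <- rec_cor[cbind(grid$k, yi)]
  out <- data.frame(
    x_gene = pairs$x_gene[grid$pi], y_gene = pairs$y_gene[grid$pi],
    sender_type = sender_type, receiver_type = receiver_type,
    ligand = lr$ligand[grid$k], receptor = lr$receptor[grid$k],
    r_partial = rp, w = w, z_score = z, p_value = p, p_marginal = p0,
    coexpr_ligand_x = cx, coexpr_receptor_y = cy,
    mediates = p0 < alpha_marginal & p > alpha_cit &
      cx >= rho_min & cy >= rho_min,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# correlation grid between LR-side profiles (list of subunit sets, min-
# combined) and target genes, on per-cell normalized values of one cell type
.coexprGrid <- function(cells, cell_type, side_genes, targets) {
  all_genes <- unique(c(unlist(side_genes), targets))
  norm <- .normalizedCells(cells, cell_type, all_genes)
  tmat <- t(norm[targets, , drop = FALSE])
  side <- vapply(side_genes, function(g) .combineSubunits(norm, g),
                 numeric(ncol(norm)))
  keep_s <- apply(side, 2, sd) > 0
  keep_t <- apply(tmat, 2, sd) > 0
  out <- matrix(0, length(side_genes), length(targets),
                dimnames = list(NULL, targets))
  if (any(keep_s) && any(keep_t))
    out[keep_s, keep_t] <- cor(side[, keep_s, drop = FALSE],
                               tmat[, keep_t, drop = FALSE])
  out
}
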