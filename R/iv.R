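#' Two-stage least squares with a single binary instrument
#'
#' First stage: `X` is regressed on `[1, Z]`, giving fitted values
#' `Xhat = P_Z X` (projection onto the instrument with intercept). Second
#' stage: `Y = beta0 + beta1 * Xhat + u`. Standard errors follow the 2SLS
#' convention: residuals are computed with the *original* `X`
#' (`u = Y - beta0 - beta1 * X`), not the fitted `Xhat`, which is what
#' standard IV regression software reports; the two-sided p-value for
#' `beta1` uses the t distribution with `n - 2` degrees of freedom.
#'
#' With a single binary instrument and intercepts in both stages, `beta1`
#' equals the Wald estimator
#' `(mean(Y | Z=1) - mean(Y | Z=0)) / (mean(X | Z=1) - mean(X | Z=0))`.
#'
#' @param Z binary instrument (0/1), the treatment indicator
#' @param X exposure (sender-gene pseudo-bulk values)
#' @param Y outcome (receiver-gene pseudo-bulk values)
#' @param weak_tol relative tolerance on the first-stage covariance below
#'   which the instrument is declared weak (error)
#' @return list with `delta_hat` (first-stage slope), `beta0`, `beta1`,
#'   `se_beta1`, `p_beta1`, `n`
#' @export
fit2SLS <- function(Z, X, Y, weak_tol = 1e-8) {
  n <- length(Z)
  stopifnot(length(X) == n, length(Y) == n)
  if (n < 4) stop("2SLS needs at least 4 samples", call. = FALSE)
  if (length(unique(Z)) < 2)
    stop("weak instrument: Z is constant", call. = FALSE)
  zc <- Z - mean(Z); xc <- X - mean(X); yc <- Y - mean(Y)
  szz <- sum(zc^2); szx <- sum(zc * xc); szy <- sum(zc * yc)
  scale <- sqrt(szz * sum(xc^2))
  if (scale == 0 || abs(szx) < weak_tol * max(scale, 1))
    stop("weak instrument: first-stage covariance of Z and X is ~0",
         call. = FALSE)
  delta <- szx / szz
  xhat_c <- delta * zc                      # centered fitted values
  sxhat <- sum(xhat_c^2)
  beta1 <- sum(xhat_c * yc) / sxhat         # == szy / szx
  beta0 <- mean(Y) - beta1 * mean(X)
  u <- Y - beta0 - beta1 * X                # original X, 2SLS convention
  sigma2 <- sum(u^2) / (n - 2)
  se <- sqrt(sigma2 / sxhat)
  tstat <- beta1 / se
  list(delta_hat = delta, beta0 = beta0, beta1 = beta1, se_beta1 = se,
       p_beta1 = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Exclusion-restriction residual check
#'
#' Regresses `Y` on `[1, X]` by OLS, takes the residuals `e`, and returns the
#' two-sided p-value of the Pearson correlation between `Z` and `e` (t test
#' with `n - 2` df). A *large* p-value supports the exclusion restriction
#' (the instrument reaches `Y` only through `X`); a small one indicates a
#' direct or confounded path from `Z` to `Y`.
#'
#' Zero-variance residuals (perfect mediation by `X`) return `p = 1` with a
#' `degenerate` flag.
#'
#' @inheritParams fit2SLS
#' @return list with `r` (correlation of Z and the residuals), `p_exclusion`,
#'   `degenerate`
#' @export
exclusionTest <- function(Z, X, Y) {
  n <- length(Z)
  stopifnot(length(X) == n, length(Y) == n)
  xc <- X - mean(X); yc <- Y - mean(Y); zc <- Z - mean(Z)
  sxx <- sum(xc^2)
  b <- if (sxx > 0) sum(xc * yc) / sxx else 0
  e <- yc - b * xc
  se2 <- sum(e^2)
  if (se2 < .Machine$double.eps * max(sum(yc^2), 1))
    return(list(r = 0, p_exclusion = 1, degenerate = TRUE))
  r <- sum(zc * e) / sqrt(sum(zc^2) * se2)
  r <- max(min(r, 1), -1)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p_exclusion = 2 * pt(-abs(tstat), df = n - 2),
       degenerate = FALSE)
}

#' Screen sender x receiver DEG pairs with the treatment instrument
#'
#' For every pair (X gene, Y gene) in the cross product of significant sender
#' DEGs and significant receiver DEGs, fits 2SLS ([fit2SLS()]) and the
#' exclusion-restriction check ([exclusionTest()]) on sample-aligned
#' pseudo-bulk values. The direction is fixed: X genes come from the
#' treatment-targeted sender cell type, Y genes from a non-targeted receiver
#' type. A pair `passes` when `p_beta1 <= alpha_iv` and
#' `p_exclusion > alpha_excl` (failure to reject exogeneity retains the
#' pair). All fitted pairs are returned; filter on `passes` downstream.
#' No multiplicity correction is applied across the cross product by default
#' (`bh = TRUE` adjusts `p_beta1` for the pass call).
#'
#' Sender and receiver tables are inner-joined on sample id; samples present
#' on one side only are dropped with a warning. Pairs whose first stage is
#' degenerate (weak instrument) are skipped with a message.
#'
#' @param sender_degs,receiver_degs [pairedDEG()] tables
#' @param pb_sender,pb_receiver [PseudoBulkTable]s of the two cell types
#' @param alpha_iv significance level on the 2SLS slope
#' @param alpha_excl level of the exclusion-restriction check
#' @param bh apply Benjamini-Hochberg to `p_beta1` before the pass call
#' @return data.frame with columns `x_gene`, `y_gene`, `sender_type`,
#'   `receiver_type`, `delta_hat`, `beta0`, `beta1`, `se_beta1`, `p_beta1`,
#'   `p_exclusion`, `n`, `passes`
#' @export
screenPairs <- function(sender_degs, receiver_degs, pb_sender, pb_receiver,
                        alpha_iv = 0.05, alpha_excl = 0.05, bh = FALSE) {
  xs <- sender_degs$gene[sender_degs$significant]
  ys <- receiver_degs$gene[receiver_degs$significant]
  empty <- data.frame(x_gene = character(), y_gene = character(),
                      sender_type = character(), receiver_type = character(),
                      delta_hat = numeric(), beta0 = numeric(),
                      beta1 = numeric(), se_beta1 = numeric(),
                      p_beta1 = numeric(), p_exclusion = numeric(),
                      n = integer(), passes = logical(),
                      stringsAsFactors = FALSE)
  if (!length(xs) || !length(ys)) return(empty)
  al <- .alignSamples(pb_sender, pb_receiver)
  if (length(al$samples) < 4)
    stop("fewer than 4 aligned samples between sender and receiver tables",
         call. = FALSE)
  Z <- al$Z
  Xm <- al$sender[, xs, drop = FALSE]
  Ym <- al$receiver[, ys, drop = FALSE]
  n <- length(Z)
  zc <- Z - mean(Z); szz <- sum(zc^2)
  Xc <- sweep(Xm, 2, colMeans(Xm)); Yc <- sweep(Ym, 2, colMeans(Ym))
  szx <- drop(crossprod(zc, Xc)); szy <- drop(crossprod(zc, Yc))
  sxx <- colSums(Xc^2); syy <- colSums(Yc^2); sxy <- crossprod(Xc, Yc)
  weak <- abs(szx) < 1e-8 * pmax(sqrt(szz * sxx), 1)
  if (any(weak)) {
    message("screenPairs: skipping ", sum(weak),
            " sender gene(s) with a weak first stage")
    if (all(weak)) return(empty)
    xs <- xs[!weak]
    Xc <- Xc[, !weak, drop = FALSE]; szx <- szx[!weak]
    sxx <- sxx[!weak]; sxy <- sxy[!weak, , drop = FALSE]
  }
  grid <- expand.grid(xi = seq_along(xs), yi = seq_along(ys))
  b1 <- szy[grid$yi] / szx[grid$xi]
  # 2SLS residual sum with original X: SSR = Syy - 2 b1 Sxy + b1^2 Sxx
  ssr <- syy[grid$yi] - 2 * b1 * sxy[cbind(grid$xi, grid$yi)] +
    b1^2 * sxx[grid$xi]
  ssr <- pmax(ssr, 0)
  sxhat <- (szx[grid$xi]^2) / szz
  se <- sqrt(ssr / (n - 2) / sxhat)
  tstat <- b1 / se
  p_b1 <- 2 * pt(-abs(tstat), df = n - 2)
  # exclusion: residuals of Y on X, correlated with Z
  b_ols <- sxy[cbind(grid$xi, grid$yi)] / sxx[grid$xi]
  sse <- pmax(syy[grid$yi] - b_ols * sxy[cbind(grid$xi, grid$yi)], 0)
  sze <- szy[grid$yi] - b_ols * szx[grid$xi]
  degen <- sse < .Machine$double.eps * pmax(syy[grid$yi], 1)
  r_ex <- ifelse(degen, 0, sze / sqrt(szz * pmax(sse, .Machine$double.xmin)))
  r_ex <- pmax(pmin(r_ex, 1), -1)
  t_ex <- r_ex * sqrt((n - 2) / pmax(1 - r_ex^2, .Machine$double.eps))
  p_ex <- ifelse(degen, 1, 2 * pt(-abs(t_ex), df = n - 2))
  p_pass <- if (bh) stats::p.adjust(p_b1, "BH") else p_b1
  out <- data.frame(
    x_gene = xs[grid$xi], y_gene = ys[grid$yi],
    sender_type = cellType(pb_sender), receiver_type = cellType(pb_receiver),
    delta_hat = szx[grid$xi] / szz,
    beta0 = NA_real_, beta1 = b1, se_beta1 = se, p_beta1 = p_b1,
    p_exclusion = p_ex, n = n,
    passes = p_pass <= alpha_iv & p_ex > alpha_excl,
    stringsAsFactors = FALSE)
  out$beta0 <- colMeans(Ym)[grid$yi] - b1 * colMeans(Xm)[grid$xi]
  rownames(out) <- NULL
  out
}

# inner-join the two pseudo-bulk tables on sample id
.alignSamples <- function(pb_sender, pb_receiver) {
  vs <- pbMatrix(pb_sender); vr <- pbMatrix(pb_receiver)
  common <- intersect(rownames(vs), rownames(vr))
  dropped <- setdiff(union(rownames(vs), rownames(vr)), common)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " sample(s) absent from one side: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  zs <- setNames(treatmentZ(pb_sender), rownames(vs))
  list(samples = common,
       sender = vs[common, , drop = FALSE],
       receiver = vr[common, , drop = FALSE],
       Z = as.numeric(zs[common]))
}
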