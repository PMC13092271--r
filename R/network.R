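#' Filter mediating triples on direct co-expression
#'
#' Guards against "mediation" that is really direct co-expression: a triple
#' (X, Y, LR) is retained only when none of five comparisons shows a strong
#' association. In the default `"residual"` mode the comparisons are made on
#' the post-conditioning scale (partial correlations given the LR product
#' M), which is the scale on which mediation leaves no signal behind:
#'
#' 1. X vs Y given M (the post-conditioning association);
#' 2. X vs ligand given M (catches X duplicating the ligand signal);
#' 3. X vs M after removing M - exactly 0 by least-squares orthogonality,
#'    evaluated and logged for completeness;
#' 4. receptor vs Y given M (catches Y duplicating the receptor);
#' 5. M vs Y after removing M - exactly 0, as in 3.
#'
#' The `"literal"` mode applies the `< rho_max` threshold to the raw
#' pseudo-bulk correlations of all five comparisons instead. Note that under
#' genuine mediation the raw X-M and M-Y correlations are necessarily large
#' (the mediated share of the X-Y correlation is bounded by their product),
#' so the literal mode is expected to empty out strongly mediated channels;
#' it is provided for comparability, not as the default.
#'
#' Each comparison's failure count is reported via `message()`. Degenerate
#' comparisons (zero-variance residuals, e.g. the ligand fully determined by
#' M) count as passing.
#'
#' @param triples [screenLR()] rows to filter (typically those with
#'   `mediates = TRUE`)
#' @param pb_sender,pb_receiver [PseudoBulkTable]s
#' @param rho_max retention threshold on each |correlation|
#' @param mode `"residual"` (default) or `"literal"`
#' @return the retained rows of `triples`
#' @export
filterDirectCoexpression <- function(triples, pb_sender, pb_receiver,
                                     rho_max = 0.3,
                                     mode = c("residual", "literal")) {
  mode <- match.arg(mode)
  if (!nrow(triples)) return(triples)
  al <- .alignSamples(pb_sender, pb_receiver)
  comps <- c("x_vs_y", "x_vs_ligand", "x_vs_m", "receptor_vs_y", "m_vs_y")
  fails <- setNames(numeric(5), comps)
  keep <- logical(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    tr <- triples[i, ]
    X <- al$sender[, tr$x_gene]
    Y <- al$receiver[, tr$y_gene]
    L <- al$sender[, tr$ligand]
    sub <- receptorSubunits(tr$receptor)[[1]]
    R <- apply(al$receiver[, sub, drop = FALSE], 1, min)
    M <- L * R
    cc <- if (mode == "literal")
      c(x_vs_y = .safeCor(X, Y), x_vs_ligand = .safeCor(X, L),
        x_vs_m = .safeCor(X, M), receptor_vs_y = .safeCor(R, Y),
        m_vs_y = .safeCor(M, Y))
    else {
      rx <- .residOn(X, M); ry <- .residOn(Y, M)
      rl <- .residOn(L, M); rr <- .residOn(R, M)
      c(x_vs_y = .safeCor(rx, ry), x_vs_ligand = .safeCor(rx, rl),
        x_vs_m = .safeCor(rx, M), receptor_vs_y = .safeCor(rr, ry),
        m_vs_y = .safeCor(M, ry))
    }
    bad <- abs(cc) >= rho_max
    fails[bad] <- fails[bad] + 1
    keep[i] <- !any(bad)
  }
  message("filterDirectCoexpression (", mode, "): retained ", sum(keep), "/",
          nrow(triples), " triple(s); failures: ",
          paste(names(fails), fails, sep = "=", collapse = ", "))
  triples[keep, , drop = FALSE]
}

.residOn <- function(v, M) {
  f <- stats::lm.fit(cbind(1, M), v)
  f$residuals
}

# correlation that treats zero-variance inputs as showing no association
.safeCor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Group mediating triples into gene expression module pairs
#'
#' Partitions triples by (sender type, receiver type, ligand, receptor).
#' Within each group the sender GEM is the union of X genes and the receiver
#' GEM the union of Y genes; `n_pairs` counts distinct (X, Y) pairs
#' (duplicates collapse). Groups are ordered and GEM ids assigned
#' deterministically, sorted by (sender_type, receiver_type, ligand,
#' receptor): `GEM_<cell type>_<k>` on each side.
#'
#' @param triples filtered [screenLR()] rows
#' @return list of GEM pairs; each element has `sender` and `receiver`
#'   ([GEModule-class]), `ligand`, `receptor`, `sender_type`,
#'   `receiver_type`, `n_pairs`, `median_p_cit`
#' @export
groupGEMs <- function(triples) {
  if (!nrow(triples)) return(list())
  key <- paste(triples$sender_type, triples$receiver_type,
               triples$ligand, triples$receptor, sep = "\r")
  groups <- split(seq_len(nrow(triples)), key)
  groups <- groups[order(names(groups))]
  lapply(seq_along(groups), function(k) {
    tr <- triples[groups[[k]], , drop = FALSE]
    # deterministic: sort before collapsing duplicate (X, Y) pairs so the
    # retained row does not depend on input order
    tr <- tr[order(tr$x_gene, tr$y_gene, tr$p_value), , drop = FALSE]
    dup <- duplicated(paste(tr$x_gene, tr$y_gene, sep = "\r"))
    tr <- tr[!dup, , drop = FALSE]
    list(
      sender = new("GEModule",
                   gem_id = sprintf("GEM_%s_%d", tr$sender_type[1], k),
                   side = "sender", cell_type = tr$sender_type[1],
                   members = sort(unique(tr$x_gene)),
                   ligand = tr$ligand[1], receptor = tr$receptor[1]),
      receiver = new("GEModule",
                     gem_id = sprintf("GEM_%s_%d", tr$receiver_type[1], k),
                     side = "receiver", cell_type = tr$receiver_type[1],
                     members = sort(unique(tr$y_gene)),
                     ligand = tr$ligand[1], receptor = tr$receptor[1]),
      ligand = tr$ligand[1], receptor = tr$receptor[1],
      sender_type = tr$sender_type[1], receiver_type = tr$receiver_type[1],
      n_pairs = nrow(tr),
      median_p_cit = stats::median(tr$p_value))
  })
}

#' Assemble a CCC network from GEM pairs
#'
#' @param gem_pairs output of [groupGEMs()]
#' @return a [CCCNetwork-class] with deterministically ordered channels
#' @export
buildNetwork <- function(gem_pairs) {
  if (!length(gem_pairs)) return(new("CCCNetwork", channels = .emptyChannels()))
  ch <- data.frame(
    sender_type = vapply(gem_pairs, `[[`, "", "sender_type"),
    receiver_type = vapply(gem_pairs, `[[`, "", "receiver_type"),
    ligand = vapply(gem_pairs, `[[`, "", "ligand"),
    receptor = vapply(gem_pairs, `[[`, "", "receptor"),
    sender_gem_id = vapply(gem_pairs, function(g) g$sender@gem_id, ""),
    receiver_gem_id = vapply(gem_pairs, function(g) g$receiver@gem_id, ""),
    n_pairs = vapply(gem_pairs, function(g) as.integer(g$n_pairs), 1L),
    median_p_cit = vapply(gem_pairs, `[[`, 1, "median_p_cit"),
    stringsAsFactors = FALSE)
  ch$sender_members <- lapply(gem_pairs, function(g) g$sender@members)
  ch$receiver_members <- lapply(gem_pairs, function(g) g$receiver@members)
  ord <- order(ch$sender_type, ch$receiver_type, ch$ligand, ch$receptor)
  ch <- ch[ord, , drop = FALSE]
  rownames(ch) <- NULL
  new("CCCNetwork", channels = ch)
}
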