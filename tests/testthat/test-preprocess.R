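test_that("qcFilter applies the droplet QC boundary semantics exactly", {
  # 600 genes so the default min_genes = 500 boundary is exercisable
  nG <- 600
  genes <- c(sprintf("G%03d", seq_len(nG - 5)), paste0("MT-", 1:5))
  mkcell <- function(n_detected, mito_umis = 0, umi_per_gene = 2) {
    v <- numeric(nG)
    v[seq_len(n_detected)] <- umi_per_gene
    v[nG - 4:0] <- 0
    if (mito_umis > 0) v[nG] <- mito_umis
    v
  }
  cells <- cbind(
    ok        = mkcell(500),               # exactly 500 genes: kept
    few_genes = mkcell(499),               # fewer than 500: removed
    low_umi   = { v <- mkcell(500, umi_per_gene = 0); v[1:399] <- 1; v },
    mito21    = { v <- mkcell(500); v[nG] <- round(sum(v) * 0.21 / 0.79); v },
    mito20    = { v <- mkcell(500); v[nG] <- sum(v) * 0.25; v })
  # mito20: mito/total = 0.25x/(x + 0.25x) = 0.20 exactly: kept
  rownames(cells) <- genes
  meta <- data.frame(cell_id = colnames(cells), sample_id = "s1",
                     patient_id = "p1", timepoint = "pre", cell_type = "T")
  cm <- CellMatrix(cells, meta)
  kept <- suppressMessages(qcFilter(cm, qcParams()))
  expect_setequal(colnames(kept), c("ok", "mito20"))
  expect_error(suppressMessages(
    qcFilter(cm, qcParams(min_umi = 10^6 - 1, max_umi = 10^6))),
    "all cells removed")
})

test_that("pseudobulk does CPM then log2(x+1), summing counts per sample", {
  # one sample, two genes with counts [1, 3]
  m <- matrix(c(1, 0, 0, 3), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  meta <- data.frame(cell_id = c("c1", "c2"), sample_id = "s1",
                     patient_id = "p1", timepoint = "pre", cell_type = "T")
  pb <- pseudobulk(CellMatrix(m, meta), "T")
  v <- pbMatrix(pb)
  expect_equal(unname(v["s1", c("g1", "g2")]),
               c(log2(250000 + 1), log2(750000 + 1)), tolerance = 1e-12)
  # additivity: counts [1,0] and [0,1] sum to [1,1] before scaling
  m2 <- matrix(c(1, 0, 0, 1), nrow = 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  v2 <- pbMatrix(pseudobulk(CellMatrix(m2, meta), "T"))
  expect_equal(unname(v2["s1", ]), rep(log2(5e5 + 1), 2), tolerance = 1e-12)
  # an all-zero sample yields a row of zeros
  m3 <- matrix(0, 2, 2, dimnames = dimnames(m2))
  expect_equal(unname(pbMatrix(pseudobulk(CellMatrix(m3, meta), "T"))["s1", ]),
               c(0, 0))
  expect_error(pseudobulk(CellMatrix(m, meta), "B"), "no cells")
})

test_that("pairedDEG matches the textbook paired t-test", {
  # per-patient post-pre differences 1, 2, 3
  pre <- c(1, 1, 1); post <- c(2, 3, 4)
  vals <- matrix(c(pre, post), ncol = 1,
                 dimnames = list(NULL, "g1"))
  pb <- makePB(vals, patient_id = rep(c("a", "b", "c"), 2),
               Z = rep(c(0, 1), each = 3))
  d <- pairedDEG(pb)
  t_oracle <- 2 / (1 / sqrt(3))                 # mean 2, sd 1, n 3
  # exact t tail for df = 2: P(T > t) = (1 - t/sqrt(2 + t^2)) / 2
  p_oracle <- 1 - t_oracle / sqrt(2 + t_oracle^2)
  expect_equal(d$t_stat, t_oracle, tolerance = 1e-10)
  expect_equal(d$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(d$log2fc, 2)
  expect_identical(d$n_pairs, 3L)
})

test_that("pairedDEG degenerate and null cases behave as documented", {
  vals <- cbind(same = rep(1, 6),
                shift = c(1, 1, 1, 2, 2, 2))     # zero-variance diffs of 1
  pb <- makePB(vals, patient_id = rep(c("a", "b", "c"), 2),
               Z = rep(c(0, 1), each = 3))
  d <- suppressMessages(pairedDEG(pb))
  same <- d[d$gene == "same", ]; shift <- d[d$gene == "shift", ]
  expect_equal(same$log2fc, 0)
  expect_false(same$significant)
  expect_true(shift$degenerate)
  expect_equal(shift$p_value, .Machine$double.xmin)
  expect_true(shift$significant)
  # fewer than 2 complete pairs errors
  pb1 <- makePB(cbind(g = c(1, 2)), patient_id = c("a", "a"), Z = c(0, 1))
  expect_error(pairedDEG(pb1), ">= 2 patients")
})

test_that("pairedDEG is invariant to sample/gene order and flips with labels", {
  set.seed(42)
  n <- 6
  vals <- matrix(rnorm(2 * n * 5, mean = 5), ncol = 5,
                 dimnames = list(NULL, paste0("g", 1:5)))
  pats <- rep(paste0("p", 1:n), 2)
  Z <- rep(c(0, 1), each = n)
  pb <- makePB(vals, pats, Z)
  d <- pairedDEG(pb)
  perm <- sample(2 * n); gperm <- sample(5)
  pb2 <- makePB(vals[perm, gperm], pats[perm], Z[perm])
  d2 <- pairedDEG(pb2)
  d2 <- d2[match(d$gene, d2$gene), ]
  expect_equal(d$log2fc, d2$log2fc, tolerance = 1e-12)
  expect_equal(d$p_value, d2$p_value, tolerance = 1e-12)
  # swapping pre/post flips the sign of log2fc, p unchanged
  pb3 <- makePB(vals, pats, 1 - Z,
                sample_id = paste0(pats, "_", ifelse(Z == 1, "post", "pre")))
  d3 <- pairedDEG(pb3)
  expect_equal(d3$log2fc, -d$log2fc, tolerance = 1e-12)
  expect_equal(d3$p_value, d$p_value, tolerance = 1e-12)
})

test_that("clonal expansion classification follows the >50/>2 rule", {
  mk <- function(patient, n_clono, cells_each) {
    data.frame(patient_id = patient,
               clonotype_id = rep(sprintf("%s_cl%d", patient,
                                          seq_len(n_clono)),
                                  each = cells_each))
  }
  meta <- rbind(mk("pE", 51, 3),          # 51 clonotypes on 3 cells: E
                mk("pNE", 50, 3),         # 50 such clonotypes: NE
                mk("pNE2", 60, 2),        # 60 clonotypes but only 2 cells: NE
                data.frame(patient_id = "pU", clonotype_id = NA))
  lab <- classifyExpansion(meta)
  expect_identical(lab[["pE"]], "E")
  expect_identical(lab[["pNE"]], "NE")
  expect_identical(lab[["pNE2"]], "NE")
  expect_identical(lab[["pU"]], "unknown")
})
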