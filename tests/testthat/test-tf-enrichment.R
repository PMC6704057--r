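make_reads <- function(ns) {
  out <- lapply(seq_along(ns), function(i) paste0("s", i, "_r", seq_len(ns[i])))
  names(out) <- paste0("s", seq_along(ns))
  out
}

test_that("read-count equalisation enforces the minimum-count rule", {
  eq <- equalize_read_counts(make_reads(c(100, 80, 95)), seed = 1)
  expect_equal(unname(lengths(eq)), c(80, 80, 80))
  # every retained read existed in its original sample (subset, no duplicates)
  orig <- make_reads(c(100, 80, 95))
  for (s in names(eq)) {
    expect_true(all(eq[[s]] %in% orig[[s]]))
    expect_false(anyDuplicated(eq[[s]]) > 0)
  }
  expect_identical(eq$s2, orig$s2)
  expect_identical(equalize_read_counts(make_reads(50), seed = 1), make_reads(50))
  expect_identical(eq, equalize_read_counts(make_reads(c(100, 80, 95)), seed = 1))
  expect_false(identical(eq, equalize_read_counts(make_reads(c(100, 80, 95)), seed = 2)))
  expect_error(equalize_read_counts(list(a = character())), "at least one read")
})

test_that("FASTQ equalisation subsamples files to a common depth", {
  skip_if_not_installed("Biostrings")
  write_fq <- function(path, n) {
    recs <- unlist(lapply(seq_len(n), function(i)
      c(paste0("@read", i), "ACGTACGT", "+", "IIIIIIII")))
    writeLines(recs, path)
  }
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  o1 <- withr::local_tempfile(fileext = ".fastq")
  o2 <- withr::local_tempfile(fileext = ".fastq")
  write_fq(f1, 30); write_fq(f2, 18)
  suppressWarnings(equalize_fastq(c(f1, f2), c(o1, o2), seed = 1))
  n_out <- vapply(c(o1, o2), function(f) length(readLines(f)) / 4, numeric(1))
  expect_equal(unname(n_out), c(18, 18))
})

test_that("DEG filter applies FDR and pseudocounted fold-change gates", {
  tbl <- data.frame(
    gene = c("boundary", "fdr_fail", "flat_zero", "strong_down", "weak"),
    fpkm_1 = c(1.6, 50, 0, 1, 5.0),
    fpkm_2 = c(1.0, 1, 0, 4, 5.2),
    q_value = c(0.01, 0.06, 0.01, 0.05, 0.01))
  degs <- filter_degs(tbl)
  # log2((1.6+1)/(1.0+1)) is exactly log2(1.3): boundary is inclusive
  expect_true("boundary" %in% degs$gene)
  expect_false("fdr_fail" %in% degs$gene)   # q above 0.05, any fold change
  expect_false("flat_zero" %in% degs$gene)  # (0,0) -> fold change 0
  expect_true("strong_down" %in% degs$gene) # downregulation counts via |.|
  expect_lt(degs$log2_fc[degs$gene == "strong_down"], 0)
  expect_false("weak" %in% degs$gene)
  # row-order invariance and idempotence on the passing set
  shuffled <- tbl[c(4, 2, 5, 1, 3), ]
  expect_equal(filter_degs(shuffled), degs)
  expect_error(filter_degs(transform(tbl, fpkm_1 = -fpkm_1)), ">= 0")
})

test_that("homolog remapping expands, drops, and collapses symbols", {
  lib <- gene_set_library(list(TF = c("A", "B")))
  expect_equal(map_homologs(lib, data.frame(source = "A", target = "a"))$sets,
               list(TF = "a"))  # unmapped B dropped
  two <- map_homologs(lib, data.frame(source = c("A", "A"), target = c("a1", "a2")))
  expect_setequal(two$sets$TF, c("a1", "a2"))
  ident <- map_homologs(lib, data.frame(source = c("A", "B"), target = c("A", "B")))
  expect_equal(ident$sets, lib$sets)
  expect_error(map_homologs(lib, data.frame(source = character(),
                                            target = character())), "non-empty")
})

test_that("universe restriction intersects library and DEGs symmetrically", {
  lib <- gene_set_library(list(TF1 = c("g1", "g2", "gZ"), TF2 = c("gY", "gW")))
  expect_warning(res <- restrict_universe(lib, c("g1", "g2", "g3"),
                                          degs = c("g1", "gX")),
                 "outside the annotation")
  expect_equal(res$degs, "g1")                       # gX not annotated
  expect_false("TF2" %in% names(res$library$sets))   # fully outside
  expect_setequal(res$library$universe, c("g1", "g2"))
  # annotation superset: nothing changes
  all_lib <- gene_set_library(list(TF = c("g1", "g2")))
  res2 <- restrict_universe(all_lib, paste0("g", 1:10), degs = "g1")
  expect_equal(res2$library$sets, all_lib$sets)
  suppressWarnings(expect_error(restrict_universe(lib, "unrelated", degs = "g1"),
                                "empty"))
})

test_that("Fisher p-values match exhaustive hypergeometric summation", {
  # worked example: N=20, m=5, n=6, k=4 -> 540/38760
  lib <- gene_set_library(list(TFA = paste0("g", 1:5)),
                          universe = paste0("g", 1:20))
  degs <- paste0("g", c(1:4, 10, 11))
  res <- fisher_enrichment(degs, lib)
  expect_equal(res$k, 4)
  expect_equal(res$p_value, 540 / 38760, tolerance = 1e-12)
  expect_equal(res$p_value, hyper_tail_oracle(4, 5, 6, 20), tolerance = 1e-14)

  # exhaustive agreement across small universes
  for (N in c(6, 13, 20, 41, 60)) {
    for (m in unique(c(1, 2, N %/% 3, N %/% 2, N - 1))) {
      for (n in unique(c(1, N %/% 4, N %/% 2, N))) {
        for (k in unique(c(0, 1, min(m, n) %/% 2, min(m, n)))) {
          expect_equal(phyper(k - 1, m, N - m, n, lower.tail = FALSE),
                       hyper_tail_oracle(k, m, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("Fisher right tail behaves at its extremes and is monotone in k", {
  lib <- gene_set_library(list(TFA = paste0("g", 1:5)),
                          universe = paste0("g", 1:20))
  # zero overlap: P(X >= 0) = 1
  expect_equal(fisher_enrichment(paste0("g", 10:15), lib)$p_value, 1)
  # DEGs = universe: overlap is certain, p = 1 for every TF
  expect_equal(fisher_enrichment(paste0("g", 1:20), lib)$p_value, 1)
  p_k <- phyper(0:5 - 1, 5, 15, 6, lower.tail = FALSE)
  expect_true(all(diff(p_k) <= 0))
  expect_error(fisher_enrichment("not_in_universe", lib), "subset")
})

test_that("ranking is by descending -log10 p with alphabetical ties", {
  res <- tibble::tibble(tf = c("Zeb", "Abc", "Mid"),
                        neg_log10_p = c(1.2, 1.2, 2.0))
  ranked <- rank_tfs(res)
  expect_equal(ranked$tf, c("Mid", "Abc", "Zeb"))
  expect_equal(ranked$rank, 1:3)
  expect_error(rank_tfs(res[0, ]), "no enrichment results")
})

test_that("GMT round-trip preserves the library", {
  lib <- gene_set_library(list(TFA = c("g1", "g2"), TFB = c("g3", "g4", "g5")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  back <- read_gmt(path)
  expect_equal(back$sets, lib$sets)
})

test_that("a planted 4x enrichment signal is detected at rank 1", {
  sim <- simulate_enrichment_data(seed = 5)
  res <- fisher_enrichment(sim$degs, sim$library)
  expect_equal(res$tf[1], sim$spiked_tf)
  expect_identical(sim, simulate_enrichment_data(seed = 5))
  ps <- planted_signal_study(n_reps = 20, seed = 500)
  expect_gte(ps$top_rate, 0.95)
})
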