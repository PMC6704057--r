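#' Gene-set library (TF -> target genes)
#'
#' @param sets Named list of character vectors: transcription-factor name to
#'   target gene symbols. Empty sets are dropped with a warning.
#' @param universe Optional character vector of annotatable gene symbols; by
#'   default the union of all target sets.
#'
#' @return A `memflex_library` list with elements `sets` and `universe`.
#' @export
#' @examples
#' gene_set_library(list(TFA = c("g1", "g2"), TFB = c("g2", "g3")))
gene_set_library <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s)", call. = FALSE)
    sets <- sets[!empty]
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  structure(list(sets = sets, universe = unique(as.character(universe))),
            class = "memflex_library")
}

#' @export
print.memflex_library <- function(x, ...) {
  cat(sprintf("<memflex_library> %d gene set(s), universe of %d symbols\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a gene-set library from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   member genes).
#'
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path) {
  gene_set_library(fgsea::gmtPathways(path))
}

#' Write a gene-set library to a GMT file
#'
#' @param library A [gene_set_library()].
#' @param path Output path; the description column is left empty.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$sets), function(nm)
    paste(c(nm, "", library$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Equalise read counts across samples by random subsampling
#'
#' Sequencing depth affects how many genes are detectable, so samples are
#' brought to a common depth before alignment: reads are randomly removed
#' (without replacement) from every sample with more reads than the
#' shallowest one, leaving each sample with exactly the minimum original
#' count.
#'
#' @param samples Named list of per-sample read identifier vectors.
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG untouched.
#'
#' @return Named list of subsampled read identifier vectors, all the same
#'   length.
#' @export
#' @examples
#' reads <- list(a = paste0("r", 1:100), b = paste0("r", 1:80))
#' lengths(equalize_read_counts(reads, seed = 1))
equalize_read_counts <- function(samples, seed = 1) {
  stopifnot(is.list(samples))
  if (any(lengths(samples) == 0L))
    stop("all samples must contain at least one read", call. = FALSE)
  target <- min(lengths(samples))
  withr::with_seed(seed, {
    lapply(samples, function(r)
      if (length(r) > target) r[sort(sample.int(length(r), target))] else r)
  })
}

#' Equalise FASTQ files to a common read count
#'
#' Applies [equalize_read_counts()]' subsampling rule directly to FASTQ files
#' (plain or gzipped), writing one subsampled FASTQ per input. Requires
#' \pkg{Biostrings}.
#'
#' @param files Character vector of input FASTQ paths.
#' @param out_files Output paths, same length as `files`.
#' @param seed Integer seed.
#'
#' @return Invisibly, the per-file retained read counts.
#' @export
equalize_fastq <- function(files, out_files, seed = 1) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("equalize_fastq requires the Biostrings package", call. = FALSE)
  stopifnot(length(files) == length(out_files))
  reads <- lapply(files, Biostrings::readQualityScaledDNAStringSet)
  if (any(lengths(reads) == 0L)) stop("empty FASTQ input", call. = FALSE)
  target <- min(lengths(reads))
  withr::with_seed(seed, {
    for (i in seq_along(reads)) {
      keep <- if (length(reads[[i]]) > target)
        sort(sample.int(length(reads[[i]]), target)) else seq_along(reads[[i]])
      Biostrings::writeQualityScaledXStringSet(reads[[i]][keep], out_files[i])
    }
  })
  invisible(setNames(rep(target, length(files)), out_files))
}

#' Filter differentially expressed genes
#'
#' A gene is a DEG when it is significant at the FDR level and its
#' pseudocounted fold change is large enough:
#' `q_value <= fdr` and `|log2((FPKM1 + 1) / (FPKM2 + 1))| >= log2(min_fold)`
#' (both boundaries inclusive). The +1 pseudocount stabilises ratios for
#' lowly expressed genes.
#'
#' @param table Data frame with columns `gene`, `fpkm_1`, `fpkm_2`,
#'   `q_value`.
#' @param fdr FDR threshold (default 0.05).
#' @param min_fold Minimum fold change as a ratio (default 1.3).
#'
#' @return Tibble of passing genes: `gene`, `log2_fc` (signed), `q_value`.
#' @export
#' @examples
#' tbl <- data.frame(gene = c("a", "b"), fpkm_1 = c(1.6, 9),
#'                   fpkm_2 = c(1.0, 9.1), q_value = c(0.01, 0.01))
#' filter_degs(tbl)
filter_degs <- function(table, fdr = 0.05, min_fold = 1.3) {
  req <- c("gene", "fpkm_1", "fpkm_2", "q_value")
  if (!all(req %in% names(table)))
    stop("expression table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(table$fpkm_1 < 0 | table$fpkm_2 < 0))
    stop("FPKM values must be >= 0", call. = FALSE)
  if (anyDuplicated(table$gene))
    stop("gene symbols must be unique", call. = FALSE)
  lfc <- log2((table$fpkm_1 + 1) / (table$fpkm_2 + 1))
  pass <- table$q_value <= fdr & abs(lfc) >= log2(min_fold) - 1e-12
  tibble::tibble(gene = as.character(table$gene)[pass],
                 log2_fc = lfc[pass],
                 q_value = table$q_value[pass]) |>
    dplyr::arrange(.data$gene)
}

#' Remap a gene-set library through a homolog table
#'
#' Replaces every target symbol by all of its homologs in another species
#' (one-to-many mappings expand the set); symbols without a homolog are
#' dropped, and duplicates collapse. Sets left empty are removed.
#'
#' @param library A [gene_set_library()].
#' @param homologs Data frame with columns `source`, `target` mapping source
#'   symbols to homolog symbols.
#'
#' @return A remapped [gene_set_library()]; its universe is remapped the same
#'   way.
#' @export
#' @examples
#' lib <- gene_set_library(list(TF = c("A", "B")))
#' map_homologs(lib, data.frame(source = "A", target = "a"))
map_homologs <- function(library, homologs) {
  stopifnot(inherits(library, "memflex_library"))
  if (!all(c("source", "target") %in% names(homologs)) || nrow(homologs) == 0L)
    stop("homolog table must be non-empty with columns 'source' and 'target'",
         call. = FALSE)
  remap <- function(symbols)
    unique(homologs$target[homologs$source %in% symbols])
  sets <- lapply(library$sets, remap)
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L)
    stop("no gene set survived homolog remapping", call. = FALSE)
  gene_set_library(sets, universe = remap(library$universe))
}

#' Restrict library and DEGs to an annotated universe
#'
#' Symbols absent from the genome annotation can never be called
#' differentially expressed, and DEGs outside the library can never overlap a
#' set; both are removed so that the enrichment universe contains only
#' symbols observable on both sides. The resulting universe (annotation
#' intersected with the library-covered symbols) is fixed for all tests and
#' recorded on the returned library.
#'
#' @param library A [gene_set_library()].
#' @param annotation Character vector of annotated gene symbols.
#' @param degs Character vector of DEG symbols.
#'
#' @return List: `library` (restricted, universe updated), `degs`
#'   (restricted).
#' @export
#' @examples
#' lib <- gene_set_library(list(TF = c("g1", "g2", "gZ")))
#' restrict_universe(lib, annotation = c("g1", "g2", "g3"), degs = c("g1", "gX"))
restrict_universe <- function(library, annotation, degs) {
  stopifnot(inherits(library, "memflex_library"))
  annotation <- unique(as.character(annotation))
  sets <- lapply(library$sets, function(s) intersect(s, annotation))
  gone <- lengths(sets) == 0L
  if (any(gone))
    warning(sum(gone), " gene set(s) fell entirely outside the annotation",
            call. = FALSE)
  sets <- sets[!gone]
  universe <- intersect(intersect(library$universe, annotation),
                        unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0L)
    stop("restricted universe is empty", call. = FALSE)
  list(library = gene_set_library(sets, universe = universe),
       degs = intersect(unique(as.character(degs)), universe))
}

#' Right-tailed Fisher enrichment of TF target sets in a DEG list
#'
#' For each transcription factor, tests whether its target set overlaps the
#' DEG list more than expected by chance in a fixed gene universe: with
#' universe size `N`, set size `m`, DEG count `n` and overlap `k`, the
#' right-tailed Fisher p-value is `P(X >= k)` for
#' `X ~ hypergeometric(N, m, n)`. Results carry `-log10(p)` and are ranked by
#' it (see [rank_tfs()]).
#'
#' @param degs Character vector of DEG symbols; must be a subset of the
#'   universe (see [restrict_universe()]).
#' @param library A preprocessed [gene_set_library()].
#' @param adjust Also add a Benjamini-Hochberg adjusted p column
#'   (`p_adjusted`)? Ranking always uses the raw p-value. Default `FALSE`.
#'
#' @return Tibble: `tf`, `k`, `m`, `n`, `N`, `p_value`, `neg_log10_p`,
#'   `rank` (and `p_adjusted` if requested), ordered by rank.
#' @export
#' @examples
#' lib <- gene_set_library(list(TFA = paste0("g", 1:5), TFB = paste0("g", 4:12)),
#'                         universe = paste0("g", 1:20))
#' fisher_enrichment(paste0("g", 1:6), lib)
fisher_enrichment <- function(degs, library, adjust = FALSE) {
  stopifnot(inherits(library, "memflex_library"))
  degs <- unique(as.character(degs))
  if (!all(degs %in% library$universe))
    stop("DEG set must be a subset of the library universe; ",
         "run restrict_universe() first", call. = FALSE)
  N <- length(library$universe)
  n <- length(degs)
  res <- tibble::tibble(
    tf = names(library$sets),
    k = vapply(library$sets, function(s) length(intersect(s, degs)),
               integer(1), USE.NAMES = FALSE),
    m = unname(lengths(library$sets)),
    n = n, N = N)
  res$p_value <- phyper(res$k - 1, res$m, N - res$m, n, lower.tail = FALSE)
  res$neg_log10_p <- -log10(res$p_value)
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rank_tfs(res)
}

#' Rank enrichment results
#'
#' Orders transcription factors by decreasing `-log10(p)`; ties are broken
#' alphabetically by TF name. Ranks are assigned 1..T.
#'
#' @param results Tibble from [fisher_enrichment()] (needs `tf`,
#'   `neg_log10_p`).
#'
#' @return The same tibble, ordered, with a contiguous `rank` column.
#' @export
rank_tfs <- function(results) {
  if (nrow(results) == 0L) stop("no enrichment results to rank", call. = FALSE)
  out <- results[order(-results$neg_log10_p, results$tf), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Simulate a DEG table and TF library with one planted signal
#'
#' Builds a synthetic enrichment problem: a universe of `n_genes` symbols, a
#' library of `n_tfs` random target sets of size `set_size`, and a DEG list
#' of `n_degs` genes drawn without replacement in which targets of the first
#' ("spiked") TF are enriched `spike_fold`-fold over background.
#'
#' @param n_genes Universe size (default 2000).
#' @param n_tfs Number of TFs (default 20); the spiked one is `TF01`.
#' @param set_size Targets per TF (default 100).
#' @param n_degs DEG list size (default 150).
#' @param spike_fold Sampling-weight ratio of spiked targets vs background
#'   (default 4).
#' @param seed Integer seed.
#'
#' @return List: `library`, `degs`, `spiked_tf`.
#' @export
#' @examples
#' sim <- simulate_enrichment_data(seed = 1)
#' fisher_enrichment(sim$degs, sim$library)[1, ]
simulate_enrichment_data <- function(n_genes = 2000, n_tfs = 20, set_size = 100,
                                     n_degs = 150, spike_fold = 4, seed = 1) {
  stopifnot(n_degs <= n_genes, set_size <= n_genes, n_tfs >= 1)
  universe <- sprintf("g%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_tfs), function(i) sample(universe, set_size))
    names(sets) <- sprintf("TF%02d", seq_len(n_tfs))
    w <- rep(1, n_genes)
    w[universe %in% sets[[1L]]] <- spike_fold
    degs <- sample(universe, n_degs, prob = w)
    list(library = gene_set_library(sets, universe = universe),
         degs = degs, spiked_tf = names(sets)[1L])
  })
}

#' Monte-Carlo check that a planted enrichment signal is detected
#'
#' Repeatedly simulates an enrichment problem with one spiked TF
#' ([simulate_enrichment_data()]) and records how often that TF is ranked
#' first by [fisher_enrichment()].
#'
#' @param n_reps Number of replicates (default 100).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param ... Passed to [simulate_enrichment_data()].
#'
#' @return List: `top_rate` (fraction of replicates with the spiked TF at
#'   rank 1), `ranks` (integer vector of spiked-TF ranks).
#' @export
planted_signal_study <- function(n_reps = 100, seed = 1, ...) {
  ranks <- vapply(seq_len(n_reps), function(r) {
    sim <- simulate_enrichment_data(seed = seed + r, ...)
    res <- fisher_enrichment(sim$degs, sim$library)
    res$rank[res$tf == sim$spiked_tf]
  }, integer(1))
  list(top_rate = mean(ranks == 1L), ranks = ranks)
}
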