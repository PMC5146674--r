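# Formula-level microbial community metrics on OTU count tables:
# alpha diversity, Good's coverage, rarefaction, three-way OTU sharing,
# domain ratios and rank-level abundance tables.

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus")

#' OTU count table
#'
#' Taxa-by-samples matrix of non-negative integer read counts, with
#' optional semicolon-separated taxonomy lineages
#' (`domain;phylum;class;order;family;genus`) per taxon.
#'
#' @param counts integer matrix, taxa in rows (rownames required),
#'   samples in columns (colnames required).
#' @param taxonomy optional character vector of lineages, one per taxon
#'   (named or in row order).
#' @return Object of class `otu_counts`.
#' @export
otu_counts <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have taxon rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) taxonomy <- taxonomy[rownames(counts)]
    if (length(taxonomy) != nrow(counts)) {
      stop("taxonomy must have one lineage per taxon")
    }
    taxonomy <- unname(taxonomy)
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "otu_counts")
}

#' @export
print.otu_counts <- function(x, ...) {
  cat(sprintf("<otu_counts> %d taxa x %d samples (%s taxonomy)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with"))
  cat("  sample totals:",
      paste(colnames(x$counts), colSums(x$counts), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# lineage field at a rank, "unclassified" when absent/blank
lineage_at_rank <- function(taxonomy, rank) {
  i <- match(rank, TAXONOMIC_RANKS)
  if (is.na(i)) stop("unknown rank: ", rank, " (use one of ",
                     paste(TAXONOMIC_RANKS, collapse = ", "), ")")
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  vapply(parts, function(p) {
    v <- if (length(p) >= i) trimws(p[i]) else ""
    if (nzchar(v)) v else "unclassified"
  }, character(1))
}

#' Alpha diversity and coverage per sample
#'
#' Observed OTUs, bias-corrected Chao1 richness
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, Shannon index
#' `H = -sum p_i log_b p_i`, Gini-Simpson index `D = 1 - sum p_i^2`,
#' and Good's coverage `100 (1 - F1 / N)`, where F1/F2 are singleton and
#' doubleton counts and N the sample total.
#'
#' @param x an [otu_counts] table.
#' @param shannon_base logarithm base for H: 2 (default) or `exp(1)`.
#' @param chao1_bias_corrected if `FALSE`, uses the classic
#'   `S_obs + F1^2 / (2 F2)` estimator (infinite when F2 = 0 with
#'   singletons present).
#' @return data.frame with one row per sample: `sample`, `reads`,
#'   `observed_otus`, `chao1`, `shannon`, `simpson`,
#'   `goods_coverage_pct`.
#' @examples
#' tab <- otu_counts(matrix(c(5L, 5L, 5L, 5L), 4,
#'                   dimnames = list(paste0("t", 1:4), "s1")))
#' alpha_diversity(tab) # H = 2 bits, D = 0.75
#' @export
alpha_diversity <- function(x, shannon_base = 2,
                            chao1_bias_corrected = TRUE) {
  stopifnot(inherits(x, "otu_counts"))
  res <- lapply(colnames(x$counts), function(s) {
    n <- x$counts[, s]
    N <- sum(n)
    if (N < 1) stop("sample '", s, "' is empty")
    p <- n[n > 0] / N
    f1 <- sum(n == 1L)
    f2 <- sum(n == 2L)
    s_obs <- sum(n > 0L)
    chao1 <- if (chao1_bias_corrected) {
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    } else {
      if (f2 == 0 && f1 > 0) Inf else if (f1 == 0) s_obs
      else s_obs + f1^2 / (2 * f2)
    }
    data.frame(
      sample = s, reads = N, observed_otus = s_obs, chao1 = chao1,
      shannon = -sum(p * log(p, base = shannon_base)),
      simpson = 1 - sum(p^2),
      goods_coverage_pct = 100 * (1 - f1 / N),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples every sample to exactly `depth` reads without replacement
#' (multivariate hypergeometric). Samples shallower than `depth` are
#' dropped with a warning. Fully seeded and reproducible.
#'
#' @param x an [otu_counts] table.
#' @param depth target reads per sample (>= 1).
#' @param seed integer RNG seed.
#' @return A rarefied [otu_counts] table (same taxa, possibly fewer
#'   samples).
#' @export
rarefy_counts <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "otu_counts"), depth >= 1)
  totals <- colSums(x$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth)
  if (any(!keep)) {
    warning("dropping sample(s) shallower than depth ", depth, ": ",
            paste(colnames(x$counts)[!keep], collapse = ", "))
  }
  counts <- x$counts[, keep, drop = FALSE]
  set.seed(seed)
  rar <- apply(counts, 2, function(n) {
    if (sum(n) == depth) return(as.integer(n))
    pool <- rep.int(seq_along(n), n)
    tabulate(sample(pool, depth), nbins = length(n))
  })
  dimnames(rar) <- dimnames(counts)
  otu_counts(rar, x$taxonomy)
}

#' Three-sample OTU sharing (Venn regions)
#'
#' Exact set algebra over the OTU identifier sets of three samples:
#' the seven Venn regions, the union size, and each region as a
#' percentage of the union (one decimal).
#'
#' @param a,b,c character vectors of OTU identifiers (non-empty).
#' @param labels names for the three samples.
#' @return data.frame with columns `region`, `otus`, `percent_of_union`;
#'   attribute `union` holds the union size.
#' @examples
#' v <- venn3(letters[1:4], letters[3:6], letters[4:8])
#' attr(v, "union")
#' @export
venn3 <- function(a, b, c, labels = c("A", "B", "C")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  if (!length(a) || !length(b) || !length(c)) {
    stop("all three OTU sets must be non-empty")
  }
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  region <- c(
    paste0(labels[1], " only"), paste0(labels[2], " only"),
    paste0(labels[3], " only"),
    paste(labels[1], labels[2], sep = "&"),
    paste(labels[1], labels[3], sep = "&"),
    paste(labels[2], labels[3], sep = "&"),
    paste(labels, collapse = "&")
  )
  otus <- c(
    sum(in_a & !in_b & !in_c), sum(!in_a & in_b & !in_c),
    sum(!in_a & !in_b & in_c),
    sum(in_a & in_b & !in_c), sum(in_a & !in_b & in_c),
    sum(!in_a & in_b & in_c), sum(in_a & in_b & in_c)
  )
  structure(
    data.frame(region = region, otus = otus,
               percent_of_union = round(100 * otus / length(u), 1),
               stringsAsFactors = FALSE),
    union = length(u)
  )
}

#' Shared-core fraction of three samples
#'
#' Percentage of the union's OTUs present in all three samples, at one
#' decimal (e.g. 580 shared of 9,400 observed is 6.2%).
#'
#' @inheritParams venn3
#' @return Percent of the union shared by all three.
#' @export
core_fraction <- function(a, b, c) {
  v <- venn3(a, b, c)
  v$percent_of_union[nrow(v)]
}

#' Domain ratio per sample
#'
#' Ratio of summed reads of one domain over another, e.g. Archaea to
#' Bacteria. A zero denominator yields `Inf`.
#'
#' @param x an [otu_counts] table with taxonomy.
#' @param numerator,denominator domain names (lineage field 1).
#' @return Named numeric vector, one ratio per sample.
#' @export
domain_ratio <- function(x, numerator = "Archaea",
                         denominator = "Bacteria") {
  stopifnot(inherits(x, "otu_counts"))
  if (is.null(x$taxonomy)) stop("table has no taxonomy lineages")
  dom <- lineage_at_rank(x$taxonomy, "domain")
  num <- colSums(x$counts[dom == numerator, , drop = FALSE])
  den <- colSums(x$counts[dom == denominator, , drop = FALSE])
  ifelse(den == 0, Inf, num / den)
}

#' Rank-level relative abundance table with minor taxa pooled
#'
#' Aggregates counts to a taxonomic rank, converts to per-sample
#' relative abundances (percent), and pools taxa representing less than
#' `threshold_pct` of the total sequence reads (across all samples)
#' into an `"others"` row. Columns sum to 100; rows are sorted
#' lexicographically with `"others"` last.
#'
#' @param x an [otu_counts] table with taxonomy.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @param threshold_pct pooling threshold (percent of total reads).
#' @return Matrix of percentages, rank taxa x samples.
#' @export
abundance_table <- function(x, rank = "phylum", threshold_pct = 1) {
  stopifnot(inherits(x, "otu_counts"))
  if (is.null(x$taxonomy)) stop("table has no taxonomy lineages")
  grp <- lineage_at_rank(x$taxonomy, rank)
  agg <- rowsum(x$counts, grp)
  overall <- rowSums(agg) / sum(agg) * 100
  minor <- overall < threshold_pct
  if (any(minor)) {
    pooled <- colSums(agg[minor, , drop = FALSE])
    agg <- agg[!minor, , drop = FALSE]
    agg <- rbind(agg, others = pooled)
  }
  pct <- sweep(agg, 2, colSums(agg), "/") * 100
  ord <- order(rownames(pct) == "others", rownames(pct))
  pct[ord, , drop = FALSE]
}
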