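make_table <- function(counts_by_sample, taxonomy = NULL) {
  m <- do.call(cbind, counts_by_sample)
  rownames(m) <- sprintf("t%03d", seq_len(nrow(m)))
  otu_counts(m, taxonomy)
}

test_that("alpha diversity matches closed forms on degenerate tables", {
  tab <- make_table(list(s1 = c(5L, 5L, 5L, 5L)))
  d <- alpha_diversity(tab, shannon_base = 2)
  expect_equal(d$shannon, 2)       # uniform over 4 taxa, base 2
  expect_equal(d$simpson, 0.75)
  expect_equal(d$observed_otus, 4)
  mono <- alpha_diversity(make_table(list(s1 = c(10L, 0L, 0L))))
  expect_equal(mono$shannon, 0)
  expect_equal(mono$simpson, 0)
  expect_equal(mono$goods_coverage_pct, 100)
  expect_error(alpha_diversity(make_table(list(s1 = c(0L, 0L)))), "empty")
})

test_that("all five indices equal an independent naive evaluation", {
  set.seed(21)
  for (i in 1:10) {
    n <- as.integer(rpois(30, lambda = sample(c(0.5, 2, 20), 1)))
    if (sum(n) == 0) n[1] <- 1L
    tab <- make_table(list(s = n))
    d <- alpha_diversity(tab, shannon_base = 2)
    o <- naive_diversity(n, base = 2)
    expect_equal(d$observed_otus, o$observed, tolerance = 1e-9)
    expect_equal(d$chao1, o$chao1, tolerance = 1e-9)
    expect_equal(d$shannon, o$shannon, tolerance = 1e-9)
    expect_equal(d$simpson, o$simpson, tolerance = 1e-9)
    expect_equal(d$goods_coverage_pct, o$coverage, tolerance = 1e-9)
  }
})

test_that("shannon and simpson agree with vegan's implementations", {
  skip_if_not_installed("vegan")
  set.seed(5)
  n <- as.integer(rpois(40, 8)) + 0L
  n[1] <- n[1] + 1L
  tab <- make_table(list(s = n))
  d2 <- alpha_diversity(tab, shannon_base = 2)
  de <- alpha_diversity(tab, shannon_base = exp(1))
  expect_equal(de$shannon, unname(vegan::diversity(n, "shannon")))
  expect_equal(d2$shannon,
               unname(vegan::diversity(n, "shannon", base = 2)))
  expect_equal(d2$simpson, unname(vegan::diversity(n, "simpson")))
})

test_that("chao1 dominates observed richness and collapses without singletons", {
  set.seed(8)
  for (i in 1:10) {
    n <- as.integer(rpois(50, 1.2))
    if (sum(n) == 0) n[1] <- 3L
    d <- alpha_diversity(make_table(list(s = n)))
    expect_gte(d$chao1, d$observed_otus)
  }
  no_singletons <- make_table(list(s = c(4L, 7L, 2L)))
  d <- alpha_diversity(no_singletons)
  expect_equal(d$chao1, d$observed_otus)
  # classic estimator differs when requested
  with_f1f2 <- make_table(list(s = c(1L, 1L, 1L, 2L, 5L)))
  bc <- alpha_diversity(with_f1f2)$chao1
  cl <- alpha_diversity(with_f1f2, chao1_bias_corrected = FALSE)$chao1
  expect_equal(bc, 5 + 3 * 2 / (2 * 2))
  expect_equal(cl, 5 + 9 / 2)
})

test_that("shannon obeys the change-of-base identity", {
  set.seed(13)
  n <- as.integer(rpois(25, 6)) + 1L
  tab <- make_table(list(s = n))
  h2 <- alpha_diversity(tab, shannon_base = 2)$shannon
  he <- alpha_diversity(tab, shannon_base = exp(1))$shannon
  expect_equal(h2, he / log(2))
})

test_that("rarefaction subsamples to exact depth, reproducibly", {
  set.seed(1)
  m <- matrix(as.integer(rpois(60, 30)), nrow = 20,
              dimnames = list(sprintf("t%02d", 1:20), c("a", "b", "c")))
  tab <- otu_counts(m)
  r1 <- rarefy_counts(tab, 100, seed = 7)
  r2 <- rarefy_counts(tab, 100, seed = 7)
  expect_identical(r1$counts, r2$counts)          # seeded determinism
  expect_true(all(colSums(r1$counts) == 100))
  expect_true(all(r1$counts <= m))                # without replacement
  # depth equal to the total is the identity
  ident <- rarefy_counts(tab, min(colSums(m)), seed = 1)
  keep <- colSums(m) == min(colSums(m))
  if (any(keep)) {
    expect_identical(ident$counts[, colnames(m)[keep], drop = FALSE],
                     m[, keep, drop = FALSE])
  }
  # shallow samples are dropped with a warning
  m2 <- m; m2[, "a"] <- 0L; m2[1, "a"] <- 5L
  expect_warning(rd <- rarefy_counts(otu_counts(m2), 100, seed = 1),
                 "dropping")
  expect_false("a" %in% colnames(rd$counts))
})

test_that("rarefied counts follow the hypergeometric expectation", {
  tab <- otu_counts(matrix(c(50L, 50L), 2,
                           dimnames = list(c("A", "B"), "s")))
  draws <- vapply(1:1000, function(s)
    rarefy_counts(tab, 10, seed = s)$counts["A", "s"], numeric(1))
  # E = 5, var = 10*0.25*(90/99); mean of 1000 draws within 4 sigma
  se <- sqrt(10 * 0.25 * 90 / 99 / 1000)
  expect_lt(abs(mean(draws) - 5), 4 * se)
})

test_that("expected richness after rarefaction is monotone in depth", {
  set.seed(2)
  n <- as.integer(rpois(40, 3))
  n[n == 0] <- 0L
  if (sum(n) < 60) n[1] <- n[1] + 60L
  N <- sum(n)
  exp_rich <- function(d)
    sum(1 - exp(lchoose(N - n[n > 0], d) - lchoose(N, d)))
  depths <- c(5, 10, 20, 40, 60)
  expect_true(all(diff(vapply(depths, exp_rich, numeric(1))) >= 0))
  # empirical mean at one depth matches the analytic expectation
  tab <- make_table(list(s = n))
  obs <- vapply(1:300, function(s) {
    sum(rarefy_counts(tab, 20, seed = s)$counts > 0)
  }, numeric(1))
  expect_lt(abs(mean(obs) - exp_rich(20)), 4 * sd(obs) / sqrt(300))
})

test_that("three-way OTU sharing matches brute-force membership", {
  sets <- make_venn_sets(300, 200, 100, 50, 40, 30, 25)
  v <- venn3(sets$a, sets$b, sets$c)
  expect_equal(v$otus, c(300, 200, 100, 50, 40, 30, 25))
  expect_equal(attr(v, "union"), 745)
  expect_equal(sum(v$otus), attr(v, "union"))
  # brute-force oracle over all elements
  u <- unique(c(sets$a, sets$b, sets$c))
  member <- cbind(u %in% sets$a, u %in% sets$b, u %in% sets$c)
  expect_equal(v$otus[7], sum(rowSums(member) == 3))
  # disjoint sets share nothing
  vd <- venn3(c("x1", "x2"), c("y1"), c("z1", "z2"))
  expect_equal(vd$otus[4:7], c(0, 0, 0, 0))
  expect_error(venn3(character(0), "a", "b"), "non-empty")
})

test_that("domain ratios sum reads by lineage domain", {
  tax <- c(t001 = "Archaea;Euryarchaeota", t002 = "Bacteria;Proteobacteria",
           t003 = "Bacteria;Firmicutes")
  tab <- make_table(list(s1 = c(30L, 50L, 20L), s2 = c(0L, 10L, 10L)),
                    taxonomy = tax)
  r <- domain_ratio(tab)
  expect_equal(unname(r["s1"]), 30 / 70)
  expect_equal(unname(r["s2"]), 0)
  all_arch <- make_table(list(s = c(5L, 5L, 5L)),
                         taxonomy = setNames(rep("Archaea;X", 3),
                                             sprintf("t%03d", 1:3)))
  expect_equal(unname(domain_ratio(all_arch)), Inf)
  expect_error(domain_ratio(make_table(list(s = c(1L, 2L, 3L)))),
               "no taxonomy")
})

test_that("abundance tables pool minor taxa into others and sum to 100", {
  tax <- c(t001 = "Bacteria;Proteobacteria;", t002 = "Bacteria;Firmicutes;",
           t003 = "Bacteria;Chloroflexi;")
  tab <- make_table(list(s = c(120L, 79L, 1L)), taxonomy = tax)
  ab <- abundance_table(tab, rank = "phylum", threshold_pct = 1)
  expect_equal(unname(ab["others", "s"]), 0.5)
  expect_equal(unname(colSums(ab)), 100, tolerance = 1e-9)
  one <- make_table(list(s = c(10L)),
                    taxonomy = c(t001 = "Bacteria;Proteobacteria"))
  ab1 <- abundance_table(one, "phylum")
  expect_false("others" %in% rownames(ab1))
  expect_error(abundance_table(tab, rank = "species"), "unknown rank")
  # random tables always normalize per sample
  set.seed(4)
  big <- make_table(list(s1 = as.integer(rpois(20, 40)) + 1L,
                         s2 = as.integer(rpois(20, 40)) + 1L),
                    taxonomy = setNames(
                      paste0("Bacteria;P", sample(1:6, 20, TRUE)),
                      sprintf("t%03d", 1:20)))
  expect_equal(unname(colSums(abundance_table(big, "phylum"))), c(100, 100),
               tolerance = 1e-9)
})
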