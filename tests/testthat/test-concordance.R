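test_that("pairing inner-joins per compartment and reports unmatched genes", {
  transcripts <- tibble::tibble(
    gene_id = c("A", "B", "C"), gene_name = c("a", "b", "c"),
    ntpm = c(5, 0, 20),
    rna_category = as_expression_category(c("Medium", "Not detected", "High"))
  )
  buckets <- list(glomeruli = tibble::tibble(
    gene_id = c("B", "C", "D"), gene_name = c("b", "c", "d"),
    level = c("Low", "High", "Medium")
  ))
  pairs <- pair_records(transcripts, buckets)
  expect_equal(sort(pairs$glomeruli$gene_id), c("B", "C"))
  un <- attr(pairs, "unmatched")$glomeruli
  expect_equal(un$transcript_only, 1L)
  expect_equal(un$protein_only, 1L)

  # the same gene in two compartments yields two pairs
  buckets2 <- list(
    glomeruli = tibble::tibble(gene_id = "A", gene_name = "a", level = "Low"),
    tubules = tibble::tibble(gene_id = "A", gene_name = "a", level = "High")
  )
  pairs2 <- pair_records(transcripts, buckets2)
  expect_equal(nrow(pairs2$glomeruli), 1L)
  expect_equal(nrow(pairs2$tubules), 1L)

  empty <- list(glomeruli = tibble::tibble(
    gene_id = "Z", gene_name = "z", level = "Low"))
  expect_warning(pair_records(transcripts, empty), "empty")
  expect_error(pair_records(transcripts, empty, strict = TRUE), "empty")
})

test_that("discordance classes follow the extreme-discordance rules", {
  expect_equal(classify_pair("Medium", "Medium"), "concordant")
  expect_equal(classify_pair("High", "Not detected"),
               "protein_null_rna_detected")
  expect_equal(classify_pair("Not detected", "High"),
               "rna_null_protein_detected")
  expect_equal(classify_pair("Low", "High"), "discordant_other")
  # exhaustively: classes are consistent with the category pair
  lev <- expression_levels()
  grid <- expand.grid(rna = lev, protein = lev, stringsAsFactors = FALSE)
  cls <- classify_pair(grid$rna, grid$protein)
  expect_equal(cls[grid$rna == grid$protein], rep("concordant", 4))
  expect_equal(sum(cls == "protein_null_rna_detected"), 3L)
  expect_equal(sum(cls == "rna_null_protein_detected"), 3L)
  expect_equal(sum(cls == "discordant_other"), 6L)
})

test_that("contingency matrix equals a brute-force double-loop tabulation", {
  lev <- expression_levels()
  # all cells once
  grid <- expand.grid(rna = lev, protein = lev, stringsAsFactors = FALSE)
  pairs16 <- make_pairs(grid$rna, grid$protein)
  m16 <- unclass(build_contingency(pairs16))
  attr(m16, "compartment") <- NULL
  expect_equal(m16,
               matrix(1L, 4, 4, dimnames = list(rna = lev, protein = lev)))

  # all mass in one cell
  pairs4 <- make_pairs(rep("High", 4), rep("High", 4))
  m4 <- build_contingency(pairs4)
  expect_equal(m4["High", "High"], 4L)
  expect_equal(sum(m4), 4L)

  set.seed(3)
  rna <- sample(lev, 500, replace = TRUE)
  prot <- sample(lev, 500, replace = TRUE)
  m <- build_contingency(make_pairs(rna, prot))
  oracle <- matrix(0L, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    oracle[i, j] <- sum(rna == lev[i] & prot == lev[j])
  }
  expect_equal(unclass(m), oracle, ignore_attr = TRUE)

  expect_error(build_contingency(make_pairs(character(0), character(0))),
               "zero pairs")
})

test_that("concordance summary counts and percentages are conserved", {
  lev <- expression_levels()
  # identity-only matrix
  ident <- make_pairs(rep(lev, 3), rep(lev, 3))
  cc <- summarize_concordance(build_contingency(ident))
  expect_equal(cc$concordant, 12L)
  expect_equal(cc$discordant, 0L)
  expect_equal(cc$pct$concordant, 100)

  # all-ones matrix: hand-counted extreme-discordance cells
  grid <- expand.grid(rna = lev, protein = lev, stringsAsFactors = FALSE)
  cc16 <- summarize_concordance(build_contingency(
    make_pairs(grid$rna, grid$protein)))
  expect_equal(cc16$concordant, 4L)
  expect_equal(cc16$discordant, 12L)
  expect_equal(cc16$protein_null_rna_detected, 3L)
  expect_equal(cc16$rna_null_protein_detected, 3L)

  # conservation on random pair sets: trace + class tallies
  set.seed(8)
  for (i in 1:10) {
    pairs <- make_pairs(sample(lev, 300, TRUE), sample(lev, 300, TRUE))
    m <- build_contingency(pairs)
    cc <- summarize_concordance(m)
    expect_equal(cc$concordant + cc$discordant, cc$total)
    expect_equal(cc$concordant, sum(diag(unclass(m))))
    tab <- table(pairs$discordance_class)
    expect_equal(sum(tab), cc$total)
    expect_equal(unname(tab["concordant"]), cc$concordant,
                 ignore_attr = TRUE)
  }
})

test_that("chi-square matches the independent oracle and the 2x2 closed form", {
  set.seed(21)
  for (i in 1:50) {
    m <- random_table(4, 4)
    mine <- chi_square_independence(m)
    oracle <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(mine$statistic, unname(oracle$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)
    expect_equal(mine$degrees_of_freedom,
                 as.integer(unname(oracle$parameter)))
    # symmetry under transposition
    expect_equal(chi_square_independence(t(m))$statistic, mine$statistic,
                 tolerance = 1e-12)
  }
  for (i in 1:20) {
    m <- random_table(2, 2)
    n <- sum(m)
    closed <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      (prod(rowSums(m)) * prod(colSums(m)))
    expect_equal(chi_square_independence(m)$statistic, closed,
                 tolerance = 1e-12)
  }
})

test_that("chi-square drops zero margins, flags small expecteds, rejects degenerate tables", {
  # observed equals the outer product of its margins -> statistic 0, p 1
  m <- outer(c(2, 3, 5), c(1, 4, 5))
  res <- chi_square_independence(m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  with_zero <- rbind(c(10, 20, 0), c(20, 10, 0), c(0, 0, 0))
  res0 <- chi_square_independence(with_zero)
  expect_equal(res0$degrees_of_freedom, 1L)
  expect_equal(res0$statistic,
               chi_square_independence(with_zero[1:2, 1:2])$statistic)

  small <- rbind(c(2, 1), c(1, 2))
  expect_true(chi_square_independence(small)$validity_warning)

  expect_error(chi_square_independence(rbind(c(1, 2, 3))), "single")
  expect_error(chi_square_independence(cbind(c(0, 0), c(3, 4))), "single")
})

test_that("pair table export round-trips classifications and matches the summary", {
  set.seed(5)
  lev <- expression_levels()
  pairs <- make_pairs(sample(lev, 1000, TRUE), sample(lev, 1000, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  emit_pair_table(pairs, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 1000L)
  expect_equal(sort(names(table(back$discordance_class))),
               sort(names(table(pairs$discordance_class))))
  cc <- summarize_concordance(build_contingency(pairs))
  expect_equal(sum(back$discordance_class == "concordant"), cc$concordant)
  expect_equal(
    sum(back$discordance_class == "protein_null_rna_detected"),
    cc$protein_null_rna_detected)
  # re-deriving the class from the re-read categories is the identity
  expect_equal(classify_pair(back$rna_category, back$protein_category),
               back$discordance_class)
})

test_that("with zero latent correlation the concordant fraction matches the product of marginals", {
  q <- c(0.537, 0.186, 0.201, 0.076)
  p0 <- 0.1867
  expected <- p0 * q[1] + (1 - p0) / 3 * sum(q[2:4])
  fracs <- vapply(1:50, function(s) {
    sim <- generate_synthetic_data(
      generator_config(n_genes = 2000, rho = 0, seed = s))
    tr <- sim$truth
    el <- tr$in_rna & tr$in_ihc & tr$reliability_glomeruli != "Uncertain"
    tert <- compute_tertiles(tr$ntpm[tr$in_rna])
    rna_cat <- categorize_transcript(tr$ntpm[el], tert)
    mean(as.character(rna_cat) == tr$protein_glomeruli[el])
  }, numeric(1))
  mc_se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * mc_se)
})
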