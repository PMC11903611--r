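test_that("validation thresholds enforce their invariants", {
  th <- validation_thresholds()
  expect_equal(th$ntpm_detect, 0)
  expect_equal(th$spectral_min, 1)
  expect_error(validation_thresholds(ntpm_detect = -1), "non-negative")
  expect_error(validation_thresholds(ntpm_detect = 2, ntpm_strict = 1),
               "strict")
})

test_that("MS validation counts matched, below-threshold and absent genes separately", {
  pairs <- make_pairs(
    rna = c("High", "Medium", "Low", "Not detected", "High"),
    protein = c("Not detected", "Not detected", "Not detected", "High",
                "High"),
    ntpm = c(24.6, 5, 0.4, 0, 50),
    gene_name = c("COL6A1", "GEN2", "GEN3", "GEN4", "GEN5")
  )
  ms <- tibble::tibble(
    gene_name = c("COL6A1", "GEN2"),
    compartment = c("glomeruli", "glomeruli"),
    mean_spectral_count = c(82, 0.4)
  )
  v <- validate_protein_nulls(pairs, ms)
  expect_equal(v$n_detect, 3L)        # three protein-null pairs, all nTPM > 0
  expect_equal(v$n_strict, 2L)        # 24.6 and 5 are >= 1; 0.4 is not
  expect_equal(v$n_ms, 1L)            # COL6A1 at 82 counts
  expect_equal(v$n_below, 1L)         # GEN2 present at 0.4 < 1
  expect_equal(v$n_unmatched, 1L)     # GEN3 absent from the MS table
  expect_equal(v$validated$gene_name, "COL6A1")
  expect_equal(v$validated$mean_spectral_count, 82)
})

test_that("tubular pairs are matched against the tubulointerstitial MS compartment", {
  pairs <- make_pairs("High", "Not detected", compartment = "tubules",
                      ntpm = 436.6, gene_name = "HSP90AA1")
  ms <- tibble::tibble(gene_name = "HSP90AA1",
                       compartment = "tubulointerstitium",
                       mean_spectral_count = 97)
  expect_equal(validate_protein_nulls(pairs, ms)$n_ms, 1L)
  # an MS table lacking the mapped compartment degrades to missing
  ms_wrong <- tibble::tibble(gene_name = "HSP90AA1",
                             compartment = "glomeruli",
                             mean_spectral_count = 97)
  expect_warning(v <- validate_protein_nulls(pairs, ms_wrong), "missing")
  expect_true(is.na(v$n_ms))
})

test_that("external RNA validation applies detection and strict TPM bounds", {
  pairs <- make_pairs(
    rna = rep("Not detected", 3),
    protein = c("High", "Low", "Medium"),
    ntpm = c(0, 0, 0),
    gene_name = c("GA", "GB", "GC")
  )
  ext <- tibble::tibble(
    gene_name = c("GA", "GB"), compartment = "glomeruli",
    tpm = c(0.3, 2.0)
  )
  v <- validate_rna_nulls(pairs, ext)
  expect_equal(v$n_total, 3L)
  expect_equal(v$n_tpm_detect, 2L)  # 0.3 and 2.0 are > 0
  expect_equal(v$n_tpm_strict, 1L)  # only 2.0 is >= 1
  expect_equal(v$n_unmatched, 1L)   # GC absent from the external table
})

test_that("raising any threshold never increases its validated count", {
  set.seed(31)
  lev <- expression_levels()
  pairs <- make_pairs(
    rna = sample(lev, 400, TRUE), protein = sample(lev, 400, TRUE),
    ntpm = NULL
  )
  pairs$ntpm[pairs$rna_category != "Not detected"] <-
    rlnorm(sum(pairs$rna_category != "Not detected"), 1, 1.5)
  ms <- tibble::tibble(gene_name = pairs$gene_name,
                       compartment = "glomeruli",
                       mean_spectral_count = rnbinom(400, 0.5, mu = 3))
  ext <- tibble::tibble(gene_name = pairs$gene_name,
                        compartment = "glomeruli",
                        tpm = pairs$ntpm * exp(rnorm(400, 0, 0.5)))
  sweep_vals <- c(0.5, 1, 2, 4, 8)
  n_ms <- vapply(sweep_vals, function(s) {
    validate_protein_nulls(pairs, ms,
      validation_thresholds(spectral_min = s))$n_ms
  }, integer(1))
  n_strict <- vapply(sweep_vals, function(s) {
    validate_protein_nulls(pairs, ms,
      validation_thresholds(ntpm_strict = s))$n_strict
  }, integer(1))
  n_tpm <- vapply(sweep_vals, function(s) {
    validate_rna_nulls(pairs, ext,
      validation_thresholds(tpm_strict = s))$n_tpm_strict
  }, integer(1))
  expect_true(all(diff(n_ms) <= 0))
  expect_true(all(diff(n_strict) <= 0))
  expect_true(all(diff(n_tpm) <= 0))

  # join is symmetric in input row order
  v1 <- validate_protein_nulls(pairs, ms)
  v2 <- validate_protein_nulls(pairs, ms[sample(nrow(ms)), ])
  expect_equal(v1[c("n_detect", "n_strict", "n_ms", "n_unmatched")],
               v2[c("n_detect", "n_strict", "n_ms", "n_unmatched")])
})

test_that("assembled summaries enforce nesting and percentage denominators", {
  pairs <- make_pairs(
    rna = c(rep("High", 6), rep("Not detected", 2), "Low", "Medium"),
    protein = c(rep("Not detected", 4), "High", "High", "Low", "Medium",
                "Low", "Medium")
  )
  ms <- tibble::tibble(gene_name = pairs$gene_name[1:2],
                       compartment = "glomeruli",
                       mean_spectral_count = c(5, 12))
  ext <- tibble::tibble(gene_name = pairs$gene_name[7],
                        compartment = "glomeruli", tpm = 0.5)
  cc <- summarize_concordance(build_contingency(pairs))
  pv <- validate_protein_nulls(pairs, ms)
  rv <- validate_rna_nulls(pairs, ext)
  summ <- assemble_summary(list(glomeruli = cc), list(glomeruli = pv),
                           list(glomeruli = rv))
  counts <- summ$compartments$glomeruli$counts
  expect_equal(counts$total, 10)
  expect_true(counts$protein_null_ms_validated <=
                counts$protein_null_rna_detected)
  # percentages use the compartment total as denominator
  expect_equal(summ$compartments$glomeruli$pct$protein_null_ms_validated,
               pct_of(counts$protein_null_ms_validated, 10))

  # planting an impossible nested count trips the consistency checker
  pv_bad <- pv
  pv_bad$n_ms <- pv$n_detect + 5L
  expect_error(
    assemble_summary(list(glomeruli = cc), list(glomeruli = pv_bad),
                     list(glomeruli = rv)),
    "internal-consistency"
  )
  # validation computed on a different pair set is rejected
  pv_off <- pv
  pv_off$n_detect <- pv$n_detect + 1L
  expect_error(
    assemble_summary(list(glomeruli = cc), list(glomeruli = pv_off),
                     list(glomeruli = rv)),
    "same pair set"
  )
})

test_that("zero validated genes render as 0 (0.00%), not as missing", {
  pairs <- make_pairs(c("High", "Low"), c("Not detected", "Low"))
  ms <- tibble::tibble(gene_name = "OTHER", compartment = "glomeruli",
                       mean_spectral_count = 9)
  cc <- summarize_concordance(build_contingency(pairs))
  pv <- validate_protein_nulls(pairs, ms)
  rv <- validate_rna_nulls(pairs, NULL)
  summ <- assemble_summary(list(glomeruli = cc), list(glomeruli = pv),
                           list(glomeruli = rv))
  expect_equal(
    format_count_pct(summ$compartments$glomeruli$counts$protein_null_ms_validated,
                     summ$compartments$glomeruli$counts$total),
    "0 (0.00%)")
})
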