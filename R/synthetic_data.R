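#' Configuration for the synthetic kidney expression generator
#'
#' The generator draws, per gene, a latent standard-normal transcript score
#' and one latent protein score per compartment, correlated with the
#' transcript score at `rho`. Transcript abundance is zero-inflated through
#' latent thresholding (the lowest `p_zero_rna` quantile of the transcript
#' score maps to nTPM = 0, so non-detection co-occurs across platforms when
#' `rho > 0`) and lognormal above it; protein categories arise from
#' cutpoints on the protein score placed at the cumulative
#' `protein_marginals`. Mass-spectrometry spectral counts and external
#' RNA-seq TPMs are generated from the same latents so that cross-platform
#' validation has planted positives and negatives.
#'
#' Defaults emulate whole-kidney bulk RNA-seq and glomerular IHC marginal
#' structure: about 18.7% undetected transcripts, positive-nTPM tertile
#' boundaries near 3 and 13 nTPM, a protein category split of roughly
#' 54/19/20/8% and 15% Uncertain antibody calls.
#'
#' @param n_genes number of genes (>= 10).
#' @param rho latent mRNA-protein correlation in `[-1, 1]`.
#' @param p_zero_rna probability of nTPM = 0.
#' @param protein_marginals four probabilities over the ordinal scale
#'   (Not detected, Low, Medium, High), summing to 1.
#' @param reliability_probs four probabilities over (Enhanced, Supported,
#'   Approved, Uncertain), summing to 1.
#' @param lognormal_mu,lognormal_sigma log-scale parameters of positive
#'   nTPM.
#' @param ms_mean_link scale linking the protein latent to the log mean
#'   spectral count.
#' @param ms_dispersion negative-binomial size of spectral counts.
#' @param ms_null_zero_prob probability that an IHC-Not-detected gene is
#'   forced to a zero spectral count (plants MS-silent protein nulls next
#'   to MS-validated ones).
#' @param overlap_frac fraction of genes present in both the RNA and IHC
#'   tables; the remainder is split between RNA-only and IHC-only genes.
#' @param tpm_noise_sd log-scale noise between nTPM and external TPM.
#' @param plant_ext_prob probability that an RNA-undetected gene receives a
#'   positive external TPM (plants externally rescued RNA nulls).
#' @param plant_tpm_meanlog,plant_tpm_sdlog lognormal parameters of the
#'   planted external TPM values (defaults keep most below 1 TPM).
#' @param cutpoint_mode `"theoretical"` (default) places the Low/Medium/High
#'   protein cutpoints at normal quantiles of the cumulative marginals;
#'   `"empirical_tertiles"` places them at the empirical within-compartment
#'   quantiles of the detected-protein latents, which aligns protein
#'   categories exactly with rank-based transcript tertiles in the
#'   perfect-correlation limit.
#' @param decoy_cell_type_frac fraction of IHC genes receiving an extra row
#'   for a non-compartment cell type (exercises the cell-type filter).
#' @param decoy_tissue_frac fraction of IHC genes receiving an extra
#'   non-kidney tissue row (exercises the tissue filter).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_genes = 20000,
                             rho = 0.6,
                             p_zero_rna = 0.1867,
                             protein_marginals = c(0.537, 0.186, 0.201, 0.076),
                             reliability_probs = c(0.25, 0.30, 0.30, 0.15),
                             lognormal_mu = 1.843,
                             lognormal_sigma = 1.729,
                             ms_mean_link = 1.5,
                             ms_dispersion = 0.5,
                             ms_null_zero_prob = 0.5,
                             overlap_frac = 0.553,
                             tpm_noise_sd = 0.3,
                             plant_ext_prob = 0.8,
                             plant_tpm_meanlog = -1.5,
                             plant_tpm_sdlog = 1,
                             cutpoint_mode = c("theoretical",
                                               "empirical_tertiles"),
                             decoy_cell_type_frac = 0.05,
                             decoy_tissue_frac = 0.02,
                             seed = 1L) {
  check_probs <- function(p, what, len) {
    if (length(p) != len || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-8) {
      stop(what, " must be ", len, " probabilities summing to 1",
           call. = FALSE)
    }
  }
  if (n_genes < 10) stop("n_genes must be at least 10", call. = FALSE)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (p_zero_rna < 0 || p_zero_rna >= 1) {
    stop("p_zero_rna must lie in [0, 1)", call. = FALSE)
  }
  check_probs(protein_marginals, "protein_marginals", 4L)
  check_probs(reliability_probs, "reliability_probs", 4L)
  if (overlap_frac < 0 || overlap_frac > 1) {
    stop("overlap_frac must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_genes = as.integer(n_genes), rho = rho, p_zero_rna = p_zero_rna,
      protein_marginals = protein_marginals,
      reliability_probs = reliability_probs,
      lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
      ms_mean_link = ms_mean_link, ms_dispersion = ms_dispersion,
      ms_null_zero_prob = ms_null_zero_prob,
      overlap_frac = overlap_frac, tpm_noise_sd = tpm_noise_sd,
      plant_ext_prob = plant_ext_prob,
      plant_tpm_meanlog = plant_tpm_meanlog,
      plant_tpm_sdlog = plant_tpm_sdlog,
      cutpoint_mode = match.arg(cutpoint_mode),
      decoy_cell_type_frac = decoy_cell_type_frac,
      decoy_tissue_frac = decoy_tissue_frac,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

.reliability_labels <- c("Enhanced", "Supported", "Approved", "Uncertain")
.decoy_cell_types <- setdiff(.kidney_cell_types,
                             c("cells in glomeruli", "cells in tubules"))

#' Generate synthetic kidney expression tables with ground truth
#'
#' Produces the four input tables of the pipeline (whole-kidney RNA,
#' compartment IHC, compartment mass spectrometry, external compartment
#' RNA-seq) in the exact dialects the readers parse, plus a per-gene ground
#' truth table from which every downstream summary count can be re-tallied
#' directly. The IHC table additionally carries decoy rows (non-kidney
#' tissue, non-compartment cell types) that the filters must remove.
#'
#' @param config a [generator_config()].
#' @return list with tibbles `rna`, `ihc`, `ms`, `external_rna`, `truth`
#'   and the `config` used. `truth` has one row per gene with its nTPM,
#'   table memberships, per-compartment protein category, reliability,
#'   spectral count and external TPM.
#' @export
generate_synthetic_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(config$seed)

  n <- config$n_genes
  gene_id <- sprintf("SYNG%07d", seq_len(n))
  gene_name <- sprintf("GENE%d", seq_len(n))
  lev <- expression_levels()

  # latent scores: one transcript score, one protein score per compartment
  z_r <- stats::rnorm(n)
  resid_scale <- sqrt(1 - config$rho^2)
  z_p <- list(
    glomeruli = config$rho * z_r + resid_scale * stats::rnorm(n),
    tubules = config$rho * z_r + resid_scale * stats::rnorm(n)
  )

  # zero-inflated lognormal nTPM via latent thresholding
  u <- stats::pnorm(z_r)
  zero <- u < config$p_zero_rna
  ntpm <- numeric(n)
  if (config$p_zero_rna < 1) {
    u_pos <- (u[!zero] - config$p_zero_rna) / (1 - config$p_zero_rna)
    u_pos <- pmin(pmax(u_pos, 1e-12), 1 - 1e-12)
    ntpm[!zero] <- exp(config$lognormal_mu +
                         config$lognormal_sigma * stats::qnorm(u_pos))
  }

  # protein categories from cutpoints at the cumulative marginals
  cum <- pmin(pmax(cumsum(config$protein_marginals)[1:3], 1e-12), 1 - 1e-12)
  cuts <- stats::qnorm(cum)
  protein_cat <- lapply(z_p, function(z) {
    if (config$cutpoint_mode == "empirical_tertiles") {
      detected <- z[z >= cuts[1L]]
      rel <- (cum[2:3] - cum[1L]) / (1 - cum[1L])
      c12 <- stats::quantile(detected, rel, type = 7, names = FALSE)
      lev[findInterval(z, c(cuts[1L], c12)) + 1L]
    } else {
      lev[findInterval(z, cuts) + 1L]
    }
  })
  reliability <- lapply(z_p, function(z) {
    sample(.reliability_labels, n, replace = TRUE,
           prob = config$reliability_probs)
  })

  # spectral counts: NB around the protein latent; some IHC-null genes are
  # forced MS-silent so both validated and unvalidated nulls exist
  ms_count <- lapply(names(z_p), function(comp) {
    mu_ms <- exp(config$ms_mean_link * z_p[[comp]])
    cnt <- stats::rnbinom(n, size = config$ms_dispersion, mu = mu_ms)
    nulls <- protein_cat[[comp]] == lev[1L]
    forced <- nulls & stats::runif(n) < config$ms_null_zero_prob
    cnt[forced] <- 0L
    as.numeric(cnt)
  })
  names(ms_count) <- names(z_p)

  # external TPM tracks nTPM with noise; a planted subset of RNA-null genes
  # gains positive external TPM
  ext_tpm <- lapply(names(z_p), function(comp) {
    tpm <- ntpm * exp(stats::rnorm(n, 0, config$tpm_noise_sd))
    planted <- zero & stats::runif(n) < config$plant_ext_prob
    tpm[planted] <- stats::rlnorm(sum(planted), config$plant_tpm_meanlog,
                                  config$plant_tpm_sdlog)
    tpm
  })
  names(ext_tpm) <- names(z_p)

  # table membership: overlap set in both tables, remainder split one-sided
  perm <- sample.int(n)
  n_both <- round(config$overlap_frac * n)
  rest <- if (n_both > 0L) perm[-seq_len(n_both)] else perm
  in_rna <- in_ihc <- logical(n)
  in_rna[perm[seq_len(n_both)]] <- TRUE
  in_ihc[perm[seq_len(n_both)]] <- TRUE
  if (length(rest) > 0L) {
    rna_only <- rest[seq_along(rest) %% 2L == 1L]
    ihc_only <- rest[seq_along(rest) %% 2L == 0L]
    in_rna[rna_only] <- TRUE
    in_ihc[ihc_only] <- TRUE
  }

  truth <- tibble::tibble(
    gene_id = gene_id, gene_name = gene_name, ntpm = ntpm,
    in_rna = in_rna, in_ihc = in_ihc,
    protein_glomeruli = protein_cat$glomeruli,
    protein_tubules = protein_cat$tubules,
    reliability_glomeruli = reliability$glomeruli,
    reliability_tubules = reliability$tubules,
    ms_glomeruli = ms_count$glomeruli,
    ms_tubulointerstitium = ms_count$tubules,
    ext_glomeruli = ext_tpm$glomeruli,
    ext_tubules = ext_tpm$tubules
  )

  rna <- tibble::tibble(
    Gene = gene_id[in_rna], `Gene name` = gene_name[in_rna],
    Tissue = "kidney", nTPM = ntpm[in_rna]
  )

  ihc_main <- dplyr::bind_rows(lapply(
    c(glomeruli = "cells in glomeruli", tubules = "cells in tubules"),
    function(ct) {
      comp <- if (ct == "cells in glomeruli") "glomeruli" else "tubules"
      tibble::tibble(
        Gene = gene_id[in_ihc], `Gene name` = gene_name[in_ihc],
        Tissue = "kidney", `Cell type` = ct,
        Level = protein_cat[[comp]][in_ihc],
        Reliability = reliability[[comp]][in_ihc]
      )
    }
  ))
  ihc_idx <- which(in_ihc)
  decoy_ct <- ihc_idx[stats::runif(length(ihc_idx)) <
                        config$decoy_cell_type_frac]
  decoy_ts <- ihc_idx[stats::runif(length(ihc_idx)) <
                        config$decoy_tissue_frac]
  decoys <- dplyr::bind_rows(
    tibble::tibble(
      Gene = gene_id[decoy_ct], `Gene name` = gene_name[decoy_ct],
      Tissue = "kidney",
      `Cell type` = sample(.decoy_cell_types, length(decoy_ct),
                           replace = TRUE),
      Level = sample(lev, length(decoy_ct), replace = TRUE),
      Reliability = sample(.reliability_labels, length(decoy_ct),
                           replace = TRUE,
                           prob = config$reliability_probs)
    ),
    tibble::tibble(
      Gene = gene_id[decoy_ts], `Gene name` = gene_name[decoy_ts],
      Tissue = "liver", `Cell type` = "hepatocytes",
      Level = sample(lev, length(decoy_ts), replace = TRUE),
      Reliability = sample(.reliability_labels, length(decoy_ts),
                           replace = TRUE,
                           prob = config$reliability_probs)
    )
  )
  ihc <- dplyr::bind_rows(ihc_main, decoys)
  ihc <- ihc[order(ihc$Gene, ihc$`Cell type`, ihc$Tissue), , drop = FALSE]

  ms <- dplyr::bind_rows(
    tibble::tibble(gene_name = gene_name, compartment = "glomeruli",
                   mean_spectral_count = ms_count$glomeruli),
    tibble::tibble(gene_name = gene_name, compartment = "tubulointerstitium",
                   mean_spectral_count = ms_count$tubules)
  )
  ms <- ms[ms$mean_spectral_count > 0, , drop = FALSE]

  external_rna <- dplyr::bind_rows(
    tibble::tibble(gene_name = gene_name, compartment = "glomeruli",
                   tpm = ext_tpm$glomeruli),
    tibble::tibble(gene_name = gene_name, compartment = "tubules",
                   tpm = ext_tpm$tubules)
  )

  list(rna = rna, ihc = ihc, ms = ms, external_rna = external_rna,
       truth = truth, config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits the four pipeline input tables plus `truth.tsv` into a directory,
#' in the dialects [read_protein_table()] and [read_quant_table()] parse.
#' Output is byte-identical for identical configs.
#'
#' @param sim result of [generate_synthetic_data()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (`protein`, `rna`, `ms`,
#'   `external_rna`, `truth`).
#' @export
write_synthetic_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    protein = file.path(dir, "ihc_normal_tissue.tsv"),
    rna = file.path(dir, "rna_consensus.tsv"),
    ms = file.path(dir, "ms_spectral_counts.tsv"),
    external_rna = file.path(dir, "external_rna.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$ihc, paths$protein)
  readr::write_tsv(sim$rna, paths$rna)
  readr::write_tsv(sim$ms, paths$ms)
  readr::write_tsv(sim$external_rna, paths$external_rna)
  readr::write_tsv(sim$truth, paths$truth)
  paths
}

#' Check a pipeline summary against generator ground truth
#'
#' Re-tallies every summary count directly from the ground-truth table —
#' using the tertile thresholds the pipeline itself published, so the check
#' does not depend on distributional assumptions — and reports any
#' disagreement. When the per-compartment pair tables are supplied, the
#' discordance class of every paired gene is also compared, so a single
#' flipped truth value is reported with its gene and field.
#'
#' @param summary a `concordance_summary` from the pipeline.
#' @param truth ground-truth tibble from [generate_synthetic_data()].
#' @param tertiles the `tertile_thresholds` the pipeline computed.
#' @param thresholds the [validation_thresholds()] the pipeline used.
#' @param pairs optional per-compartment list of paired-record tibbles.
#' @return tibble of discrepancies (`compartment`, `field`, `gene_id`,
#'   `pipeline`, `truth`); zero rows on success.
#' @export
truth_check <- function(summary, truth, tertiles,
                        thresholds = validation_thresholds(),
                        pairs = NULL) {
  stopifnot(inherits(summary, "concordance_summary"),
            inherits(tertiles, "tertile_thresholds"))
  lev <- expression_levels()
  # direct vectorized tally, independent of the pipeline's join/tabulate path
  rna_cat <- ifelse(truth$ntpm == 0, lev[1L],
             ifelse(truth$ntpm <= tertiles$t1, lev[2L],
             ifelse(truth$ntpm <= tertiles$t2, lev[3L], lev[4L])))
  ms_col <- c(glomeruli = "ms_glomeruli", tubules = "ms_tubulointerstitium")
  ext_col <- c(glomeruli = "ext_glomeruli", tubules = "ext_tubules")

  disc <- list()
  note <- function(comp, field, pipeline, truth_val, gene = NA_character_) {
    disc[[length(disc) + 1L]] <<- tibble::tibble(
      compartment = comp, field = field, gene_id = gene,
      pipeline = as.numeric(pipeline), truth = as.numeric(truth_val)
    )
  }

  for (comp in names(summary$compartments)) {
    prot <- truth[[paste0("protein_", comp)]]
    rel <- truth[[paste0("reliability_", comp)]]
    eligible <- truth$in_rna & truth$in_ihc & rel != "Uncertain"
    p_null <- eligible & prot == lev[1L] & rna_cat != lev[1L] &
      truth$ntpm > thresholds$ntpm_detect
    r_null <- eligible & rna_cat == lev[1L] & prot != lev[1L]
    ms_val <- truth[[ms_col[[comp]]]]
    ext_val <- truth[[ext_col[[comp]]]]
    expected <- list(
      total = sum(eligible),
      concordant = sum(eligible & rna_cat == prot),
      discordant = sum(eligible & rna_cat != prot),
      protein_null_rna_detected = sum(p_null),
      protein_null_ntpm_strict = sum(p_null &
                                       truth$ntpm >= thresholds$ntpm_strict),
      protein_null_ms_validated = sum(p_null &
                                        ms_val >= thresholds$spectral_min),
      rna_null_protein_detected = sum(r_null),
      rna_null_ext_detected = sum(r_null & ext_val > thresholds$tpm_detect),
      rna_null_ext_strict = sum(r_null & ext_val >= thresholds$tpm_strict)
    )
    got <- summary$compartments[[comp]]$counts
    for (field in names(expected)) {
      g <- got[[field]]
      if (is.na(g) || g != expected[[field]]) {
        note(comp, field, g, expected[[field]])
      }
    }
    if (!is.null(pairs[[comp]])) {
      pp <- pairs[[comp]]
      idx <- match(pp$gene_id, truth$gene_id)
      true_class <- classify_pair(rna_cat[idx], prot[idx])
      bad <- which(as.character(pp$discordance_class) != true_class)
      for (b in bad) {
        note(comp, paste0("discordance_class:", true_class[b]),
             NA_real_, NA_real_, gene = pp$gene_id[b])
      }
    }
  }
  if (length(disc) == 0L) {
    tibble::tibble(compartment = character(), field = character(),
                   gene_id = character(), pipeline = numeric(),
                   truth = numeric())
  } else {
    dplyr::bind_rows(disc)
  }
}
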