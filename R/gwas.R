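# Per-variant time-to-event GWAS, inverse-variance fixed-effects
# meta-analysis, greedy LD pruning and power-adjusted replication.

#' Per-variant Cox GWAS of prognosis
#'
#' Cox regression of the post-onset primary event on each dosage column
#' (additive genetic model) plus adjustment covariates, restricted to onset
#' cases.  Equivalent to calling [cox_fit()] per variant and reporting the
#' dosage coefficient; a shared compiled driver reuses the risk-set ordering
#' across variants.
#'
#' @param cohort a `cohort_table`.
#' @param covariates adjustment columns (default age and sex).
#' @param variants optional variant indices to scan (default all).
#' @param ties tie handling, as in [cox_fit()].
#' @return a `summary_stats` data frame (prognosis scale: log-hazard per
#'   allele).
#' @export
per_variant_cox <- function(cohort, covariates = c("age", "sex"),
                            variants = NULL, ties = c("efron", "breslow")) {
  stopifnot(inherits(cohort, "cohort_table"))
  ties <- match.arg(ties)
  out <- build_summary_stats(cohort, "prognosis", covariates, ties)
  if (!is.null(variants)) out <- out[variants, , drop = FALSE]
  out
}

#' Per-variant Cox scan over an explicit dosage matrix
#'
#' Lower-level interface to the batched per-variant Cox driver, for dosage
#' matrices that do not live in a `cohort_table` (reference panels,
#' economized scans).  Monomorphic columns are flagged non-estimable.
#'
#' @param time,event survival outcome as in [cox_fit()].
#' @param genotypes integer dosage matrix (individuals x variants).
#' @param covariates optional adjustment matrix.
#' @param ties tie handling.
#' @return data frame with one row per column: `beta`, `se`, `pvalue`,
#'   `eaf`, `n`, `estimable`.
#' @export
cox_gwas <- function(time, event, genotypes, covariates = NULL,
                     ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  n <- length(time)
  if (nrow(genotypes) != n) stop("genotypes rows must match time length")
  cm <- if (!is.null(covariates)) as_covariate_matrix(covariates, n) else NULL
  res <- cox_gwas_cpp(as.numeric(time), as.integer(event), genotypes, cm,
                      ties == "efron", 25L, 1e-8, 1e-10)
  data.frame(beta = res[, "beta"], se = res[, "se"],
             pvalue = wald_p(res[, "beta"], res[, "se"]),
             eaf = colMeans(genotypes) / 2, n = n,
             estimable = res[, "estimable"] == 1 & res[, "converged"] == 1)
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-study estimates with weights `1/se^2`.  At least two studies
#' are required; single-study records are rejected.
#'
#' @param beta per-study estimates.
#' @param se per-study standard errors (> 0).
#' @return class `meta_result`: pooled `beta`, `se`, `z`, `p`, Cochran's `q`
#'   with `df` and `q_p`, and normalized per-study `weights`.
#' @export
fixed_effect_meta <- function(beta, se) {
  keep <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[keep]
  se <- se[keep]
  k <- length(beta)
  if (k < 2) stop("meta-analysis requires at least 2 studies")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - pooled)^2)
  structure(list(beta = pooled, se = pooled_se, z = pooled / pooled_se,
                 p = wald_p(pooled, pooled_se), q = q, df = k - 1L,
                 q_p = pchisq(q, k - 1, lower.tail = FALSE),
                 n_studies = k, weights = w / sum(w)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis of %d studies\n", x$n_studies))
  cat(sprintf("  pooled beta %.4f (se %.4f), z = %.2f, p = %.3g\n",
              x$beta, x$se, x$z, x$p))
  cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n", x$q, x$df, x$q_p))
  invisible(x)
}

#' Meta-analyze per-variant summary statistics across studies
#'
#' Applies [fixed_effect_meta()] variant-by-variant over a list of
#' `summary_stats` tables.  Only variants estimable in at least two studies
#' are reported.
#'
#' @param tables list of `summary_stats` data frames.
#' @return `summary_stats` with additional columns `n_studies`, `q_stat`,
#'   `q_p`; `n` is the summed sample size and `eaf` the sample-size-weighted
#'   mean frequency.
#' @export
meta_summary_stats <- function(tables) {
  if (length(tables) < 2) stop("meta-analysis requires at least 2 studies")
  all_rows <- do.call(rbind, lapply(tables, function(t)
    t[t$estimable & is.finite(t$se) & t$se > 0, , drop = FALSE]))
  counts <- table(all_rows$variant_id)
  ids <- names(counts)[counts >= 2]
  template <- tables[[1]]
  out <- template[match(ids, template$variant_id), , drop = FALSE]
  metas <- lapply(ids, function(id) {
    rows <- all_rows[all_rows$variant_id == id, ]
    m <- fixed_effect_meta(rows$beta, rows$se)
    c(beta = m$beta, se = m$se, p = m$p, q = m$q, q_p = m$q_p,
      k = m$n_studies, n = sum(rows$n),
      eaf = weighted.mean(rows$eaf, rows$n))
  })
  mm <- do.call(rbind, metas)
  out$beta <- mm[, "beta"]
  out$se <- mm[, "se"]
  out$pvalue <- mm[, "p"]
  out$n <- mm[, "n"]
  out$eaf <- mm[, "eaf"]
  out$estimable <- TRUE
  out$n_studies <- as.integer(mm[, "k"])
  out$q_stat <- mm[, "q"]
  out$q_p <- mm[, "q_p"]
  out <- out[order(match(out$variant_id, template$variant_id)), ]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Greedy LD pruning
#'
#' PLINK-style greedy pruning: candidates are visited in ascending p-value
#' order (ties broken by chromosome then position) and accepted if their
#' squared dosage correlation with every already-accepted variant on the
#' same chromosome within `window_kb` is below `r2_max`.
#'
#' @param stats a `summary_stats`-like data frame with `variant_id`,
#'   `chrom`, `pos`, `pvalue`.
#' @param ref_genotypes reference dosage matrix with columns named by
#'   variant id, covering all candidates.
#' @param r2_max squared-correlation threshold (default 0.001).
#' @param window_kb window in kilobases (default 10,000 kb = 10 Mb).
#' @return the retained rows of `stats`, ordered by p-value.
#' @export
ld_prune <- function(stats, ref_genotypes, r2_max = 0.001,
                     window_kb = 10000) {
  need <- c("variant_id", "chrom", "pos", "pvalue")
  miss <- setdiff(need, names(stats))
  if (length(miss) > 0)
    stop(sprintf("stats is missing column(s): %s", paste(miss, collapse = ", ")))
  absent <- setdiff(stats$variant_id, colnames(ref_genotypes))
  if (length(absent) > 0)
    stop(sprintf("reference genotypes missing variant(s): %s",
                 paste(head(absent, 5), collapse = ", ")))
  o <- order(stats$pvalue, stats$chrom, stats$pos)
  stats <- stats[o, , drop = FALSE]
  keep <- logical(nrow(stats))
  win <- window_kb * 1000
  for (i in seq_len(nrow(stats))) {
    acc <- which(keep & stats$chrom == stats$chrom[i] &
                   abs(stats$pos - stats$pos[i]) <= win)
    ok <- TRUE
    gi <- ref_genotypes[, stats$variant_id[i]]
    for (j in acc) {
      gj <- ref_genotypes[, stats$variant_id[j]]
      if (sd(gi) == 0 || sd(gj) == 0) next
      if (cor(gi, gj)^2 >= r2_max) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Power-adjusted replication of discovery variants
#'
#' Compares the observed number of discovery variants replicating in an
#' outcome GWAS at level `alpha` with the number expected given the outcome
#' standard errors, treating the discovery effect sizes as true:
#' `expected = sum_i Phi(|b_i|/s_i - z) + Phi(-|b_i|/s_i - z)` with
#' `z = z_(1-alpha/2)`.  Replication is counted both with the pinned
#' direction-consistency requirement (`observed`) and without it
#' (`observed_any_direction`).
#'
#' @param discovery data frame with `variant_id`, `beta` (and alleles if
#'   available).
#' @param outcome data frame with `variant_id`, `beta`, `se` (`pvalue`
#'   optional; recomputed from the Wald ratio if absent).
#' @param alpha replication significance level.
#' @return list with counts, rates and the per-variant table.  Unmatched
#'   discovery variants are listed and excluded with a warning.
#' @export
power_adjusted_replication <- function(discovery, outcome, alpha = 0.05) {
  m <- match(discovery$variant_id, outcome$variant_id)
  un <- which(is.na(m))
  if (length(un) > 0) {
    warning(sprintf("excluding %d unmatched variant(s): %s", length(un),
                    paste(head(discovery$variant_id[un], 5), collapse = ", ")))
    discovery <- discovery[-un, , drop = FALSE]
    m <- m[!is.na(m)]
  }
  out <- outcome[m, , drop = FALSE]
  flip <- rep(FALSE, nrow(out))
  if (all(c("effect_allele", "other_allele") %in% names(discovery)) &&
      all(c("effect_allele", "other_allele") %in% names(out))) {
    flip <- out$effect_allele == discovery$other_allele &
      out$other_allele == discovery$effect_allele
  }
  b_out <- ifelse(flip, -out$beta, out$beta)
  p_out <- out$pvalue %||% wald_p(b_out, out$se)
  if (is.null(out$pvalue)) p_out <- wald_p(b_out, out$se)
  z <- qnorm(1 - alpha / 2)
  snr <- abs(discovery$beta) / out$se
  power <- pnorm(snr - z) + pnorm(-snr - z)
  tab <- data.frame(variant_id = discovery$variant_id,
                    beta_disc = discovery$beta, beta_out = b_out,
                    se_out = out$se, p_out = p_out, power = power,
                    replicated = p_out < alpha &
                      sign(b_out) == sign(discovery$beta),
                    replicated_any = p_out < alpha)
  list(n = nrow(tab),
       observed = sum(tab$replicated),
       observed_any_direction = sum(tab$replicated_any),
       expected = sum(power),
       observed_rate = mean(tab$replicated),
       expected_rate = mean(power),
       table = tab)
}

#' Suggestive association hits
#'
#' Filters a (meta-analyzed) summary-statistics table at the suggestive
#' threshold and LD-prunes the survivors.
#'
#' @param stats `summary_stats` table.
#' @param ref_genotypes reference dosages for pruning.
#' @param threshold p-value threshold (default 5e-6).
#' @param r2_max,window_kb pruning parameters, as in [ld_prune()].
#' @return retained rows with `ci_low`/`ci_high` columns added.
#' @export
suggestive_hits <- function(stats, ref_genotypes, threshold = 5e-6,
                            r2_max = 0.001, window_kb = 10000) {
  cand <- stats[stats$estimable %||% TRUE & stats$pvalue < threshold, ,
                drop = FALSE]
  if (nrow(cand) == 0) {
    cand$ci_low <- cand$ci_high <- numeric(0)
    return(cand)
  }
  out <- ld_prune(cand, ref_genotypes, r2_max, window_kb)
  z <- z975()
  out$ci_low <- out$beta - z * out$se
  out$ci_high <- out$beta + z * out$se
  out
}
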