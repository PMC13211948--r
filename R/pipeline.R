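# End-to-end pipeline: observational paradox recapitulation, multi-study
# prognosis GWAS with meta-analysis and bias assessment, and bias-corrected
# Mendelian randomization, driven by one configuration object with one
# global seed fanned out per stage.

#' Pipeline configuration
#'
#' Thresholds default to the standard values used throughout the package:
#' instrument significance 5e-8, suggestive significance 5e-6, LD pruning
#' r2 < 0.001 in 10,000 kb windows, Bonferroni base 0.05.
#'
#' @param sim a [simulation_config()] describing each simulated study.
#' @param n_studies number of studies to simulate for the meta-analysis.
#' @param stages stages to run, in dependency order; subset of
#'   `observational`, `gwas`, `bias`, `mr`.
#' @param bias_methods subset of `cwbls`, `dudbridge`, `cwls`,
#'   `slope_hunter`, `mr_slope`.
#' @param mr_methods subset of `ivw`, `egger`, `weighted_median`,
#'   `weighted_mode`.
#' @param instrument_p,suggestive_p,r2_max,window_kb,bonferroni_base
#'   thresholds.
#' @param subgroups run stratum-wise MR and the interaction test.
#' @param seed global seed; stage seeds are derived deterministically.
#' @return class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            n_studies = 3L,
                            stages = c("observational", "gwas", "bias",
                                       "mr"),
                            bias_methods = c("cwbls", "dudbridge", "cwls",
                                             "slope_hunter", "mr_slope"),
                            mr_methods = c("ivw", "egger",
                                           "weighted_median",
                                           "weighted_mode"),
                            instrument_p = 5e-8, suggestive_p = 5e-6,
                            r2_max = 0.001, window_kb = 10000,
                            bonferroni_base = 0.05, subgroups = TRUE,
                            seed = 1L) {
  stopifnot(inherits(sim, "simulation_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, n_studies = as.integer(n_studies),
                 stages = stages, bias_methods = bias_methods,
                 mr_methods = mr_methods, instrument_p = instrument_p,
                 suggestive_p = suggestive_p, r2_max = r2_max,
                 window_kb = window_kb, bonferroni_base = bonferroni_base,
                 subgroups = subgroups, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(simulation_config,
                 x$sim[intersect(names(x$sim),
                                 names(formals(simulation_config)))])
  # an explicit effect vector in the file overrides the rebuilt defaults
  for (f in c("maf", "variant_effects", "onset_variant_effects"))
    if (!is.null(x$sim[[f]])) sim[[f]] <- rep_len(x$sim[[f]], sim$n_variants)
  do.call(pipeline_config,
          c(list(sim = sim),
            x[intersect(names(x), setdiff(names(formals(pipeline_config)),
                                          "sim"))]))
}

write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on simulated studies
#' and writes per-stage TSVs, a machine-readable `manifest.yaml` (config,
#' seed, versions, per-stage status and row counts) and a human-readable
#' `summary.txt` whose every number is traceable to a TSV cell.  A stage
#' failure is recorded in the manifest and dependent stages are skipped;
#' partial outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the report bundle, invisibly: per-stage results plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "colliderMR",
                   version = as.character(packageVersion("colliderMR")),
                   seed = config$seed,
                   created = format(Sys.time(), tz = "UTC"),
                   stages = list())
  bundle <- list()
  summary_lines <- character(0)
  say <- function(...) summary_lines <<- c(summary_lines, sprintf(...))
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(res))
      failed <<- TRUE
      return(NULL)
    }
    manifest$stages[[name]] <<- c(list(status = "ok"), res$meta %||% list())
    res$value
  }

  # --- simulate the studies (always needed) -------------------------------
  cohorts <- run_stage("simulate", function() {
    cs <- lapply(seq_len(config$n_studies), function(k) {
      cfg <- config$sim
      cfg$seed <- stage_seed(config$seed, 100L + k)
      simulate_cohort(cfg)
    })
    list(value = cs,
         meta = list(n_studies = length(cs),
                     n_individuals = sum(vapply(cs, nrow, numeric(1))),
                     n_cases = sum(vapply(cs, function(x) sum(x$onset),
                                          numeric(1)))))
  })

  if ("observational" %in% config$stages) {
    obs <- run_stage("observational", function() {
      co <- cohorts[[1]]
      cat_all <- bmi_category(co$exposure_raw)
      res <- list()
      for (scope in c("population", "cases")) {
        sub <- if (scope == "cases") co[co$onset == 1L, ] else co
        cats <- droplevels(bmi_category(sub$exposure_raw))
        keep <- levels(cats)[table(cats) >= 10]
        if (!"normal" %in% keep) stop("no normal-BMI reference group")
        sub <- sub[cats %in% keep, ]
        cats <- factor(as.character(bmi_category(sub$exposure_raw)),
                       levels = c("normal", setdiff(keep, "normal")))
        D <- stats::model.matrix(~cats)[, -1, drop = FALSE]
        colnames(D) <- sub("^cats", "", colnames(D))
        tt <- if (scope == "cases") sub$time else sub$time_pop
        ee <- if (scope == "cases") as.integer(sub$event == "primary")
              else sub$event_pop
        fit <- cox_fit(tt, ee, cbind(D, age = sub$age, sex = sub$sex))
        tab <- fit_summary_table(fit)
        tab <- tab[tab$term %in% colnames(D), ]
        tab$scope <- scope
        tab$reference <- "normal"
        res[[scope]] <- tab
      }
      category_hr <- do.call(rbind, res)
      cases <- co[co$onset == 1L, ]
      ev <- as.integer(cases$event == "primary")
      unadj <- cox_fit(cases$time, ev,
                       cbind(exposure = cases$exposure, age = cases$age,
                             sex = cases$sex))
      adj <- cox_fit(cases$time, ev,
                     cbind(exposure = cases$exposure,
                           competitor = cases$competitor, age = cases$age,
                           sex = cases$sex))
      continuous <- rbind(
        cbind(fit_summary_table(unadj), model = "age_sex"),
        cbind(fit_summary_table(adj), model = "age_sex_competitor"))
      spline <- rcs_cox_curve(cases$time, ev, cases$exposure_raw,
                              covariates = cbind(age = cases$age,
                                                 sex = cases$sex))
      fg <- fine_gray_fit(cases$time, cases$event,
                          cbind(exposure = cases$exposure, age = cases$age,
                                sex = cases$sex))
      ph <- schoenfeld_scaled(unadj, cases$time, ev,
                              cbind(exposure = cases$exposure,
                                    age = cases$age, sex = cases$sex))
      write_tsv(category_hr, out_dir, "obs_category_hr.tsv")
      write_tsv(continuous, out_dir, "obs_continuous_hr.tsv")
      write_tsv(spline, out_dir, "obs_spline_curve.tsv")
      write_tsv(fit_summary_table(fg), out_dir, "obs_fine_gray.tsv")
      write_tsv(data.frame(term = names(ph$p), p = ph$p), out_dir,
                "obs_schoenfeld.tsv")
      ow_case <- category_hr$hr[category_hr$scope == "cases" &
                                  category_hr$term == "overweight"]
      ow_pop <- category_hr$hr[category_hr$scope == "population" &
                                 category_hr$term == "overweight"]
      say("observational: overweight-vs-normal HR %.3f in cases, %.3f in population (obs_category_hr.tsv)",
          ow_case, ow_pop)
      say("observational: case-only exposure HR/SD %.3f (age+sex), %.3f (+competitor) (obs_continuous_hr.tsv)",
          exp(unadj$coefficients["exposure"]),
          exp(adj$coefficients["exposure"]))
      list(value = list(category_hr = category_hr, continuous = continuous,
                        spline = spline, fine_gray = fg, schoenfeld = ph),
           meta = list(n_cases = nrow(cases)))
    })
    bundle$observational <- obs
  }

  stats <- NULL
  if (any(c("gwas", "bias", "mr") %in% config$stages)) {
    stats <- run_stage("gwas", function() {
      per_study <- lapply(cohorts, function(co) {
        list(incidence = build_summary_stats(co, "incidence"),
             prognosis = build_summary_stats(co, "prognosis"),
             exposure = build_summary_stats(co, "exposure"))
      })
      meta <- list(
        incidence = meta_summary_stats(lapply(per_study, `[[`,
                                              "incidence")),
        prognosis = meta_summary_stats(lapply(per_study, `[[`,
                                              "prognosis")),
        exposure = meta_summary_stats(lapply(per_study, `[[`, "exposure")))
      ref <- attr(cohorts[[1]], "genotypes")
      colnames(ref) <- attr(cohorts[[1]], "variants")$variant_id
      hits <- suggestive_hits(meta$prognosis, ref, config$suggestive_p,
                              config$r2_max, config$window_kb)
      disc <- meta$incidence[meta$incidence$pvalue < 1e-4, , drop = FALSE]
      rep_res <- if (nrow(disc) >= 1)
        power_adjusted_replication(disc, meta$prognosis)
      else NULL
      for (nm in names(meta))
        write_summary_stats(meta[[nm]],
                            file.path(out_dir,
                                      paste0("meta_", nm, ".tsv")))
      write_tsv(hits, out_dir, "suggestive_hits.tsv")
      if (!is.null(rep_res)) {
        write_tsv(rep_res$table, out_dir, "replication.tsv")
        say("gwas: %d/%d incidence signals replicate in prognosis (%.1f expected) (replication.tsv)",
            rep_res$observed, rep_res$n, rep_res$expected)
      }
      say("gwas: %d suggestive prognosis hits at p < %g (suggestive_hits.tsv)",
          nrow(hits), config$suggestive_p)
      list(value = list(per_study = per_study, meta = meta, hits = hits,
                        replication = rep_res, ref = ref),
           meta = list(n_variants = nrow(meta$prognosis),
                       n_suggestive = nrow(hits)))
    })
    bundle$gwas <- stats
  }

  adjustments <- NULL
  if ("bias" %in% config$stages && !is.null(stats)) {
    adjustments <- run_stage("bias", function() {
      inc <- stats$meta$incidence
      prog <- stats$meta$prognosis
      expo <- stats$meta$exposure
      adjs <- list()
      for (mth in config$bias_methods) {
        adjs[[mth]] <- switch(
          mth,
          cwbls = cwbls_bivariate(expo, inc, prog,
                                  p_threshold = config$instrument_p)$adjustment,
          dudbridge = dudbridge_adjust(inc, prog),
          cwls = cwls_adjust(inc, prog),
          slope_hunter = slope_hunter(inc, prog,
                                      seed = stage_seed(config$seed, 300L)),
          mr_slope = mr_slope_adjust(inc, prog,
                                     p_threshold = config$instrument_p))
      }
      slopes <- do.call(rbind, lapply(adjs, function(a)
        data.frame(method = a$method, b = a$b, se_b = a$se_b,
                   correction_factor = a$correction_factor,
                   n_variants = a$n_variants, stringsAsFactors = FALSE)))
      write_tsv(slopes, out_dir, "bias_slopes.tsv")
      for (mth in names(adjs))
        write_bias_adjustment(adjs[[mth]],
                              file.path(out_dir,
                                        paste0("bias_", mth, ".yaml")),
                              file.path(out_dir,
                                        paste0("adjusted_", mth, ".tsv")))
      say("bias: slopes per method in bias_slopes.tsv (%s)",
          paste(sprintf("%s=%.3f", slopes$method, slopes$b),
                collapse = ", "))
      list(value = adjs, meta = list(methods = names(adjs)))
    })
    bundle$bias <- adjustments
  }

  if ("mr" %in% config$stages && !is.null(stats)) {
    mr_res <- run_stage("mr", function() {
      expo <- stats$meta$exposure
      instruments <- select_instruments(expo, config$instrument_p,
                                        stats$ref, config$r2_max,
                                        config$window_kb)
      outcomes <- list(unadjusted = stats$meta$prognosis)
      for (mth in names(adjustments %||% list()))
        outcomes[[mth]] <- adjustments[[mth]]$adjusted
      rows <- list()
      for (onm in names(outcomes)) {
        inst <- harmonize(instruments, outcomes[[onm]],
                          p_threshold = config$instrument_p)
        tab <- mr_all(inst, config$mr_methods,
                      seed = stage_seed(config$seed, 400L))
        tab$outcome <- onm
        tab$subgroup <- "all"
        rows[[onm]] <- tab
      }
      # instrument validity: exposure effects among cases vs everyone
      co1 <- cohorts[[1]]
      sub <- co1[co1$onset == 1L, ]
      attr(sub, "genotypes") <-
        attr(co1, "genotypes")[co1$onset == 1L, , drop = FALSE]
      attr(sub, "variants") <- attr(co1, "variants")
      class(sub) <- class(co1)
      expo_cases <- build_summary_stats(sub, "exposure")
      val <- instrument_validity_het(
        instruments, expo_cases[expo_cases$variant_id %in%
                                  instruments$variant_id, ],
        config$bonferroni_base)
      write_tsv(val$table, out_dir, "instrument_validity.tsv")
      say("mr: instrument %s in cases (%d/%d variants flagged at p < %.3g) (instrument_validity.tsv)",
          if (val$valid) "valid" else "heterogeneous", val$n_flagged,
          nrow(val$table), val$threshold)
      inter <- NULL
      if (config$subgroups &&
          any(!is.na(cohorts[[1]]$stratum))) {
        sub_est <- list()
        for (sg in c("reduced", "preserved")) {
          progs <- lapply(cohorts, function(co) {
            keep <- co$onset == 1L & !is.na(co$stratum) & co$stratum == sg
            sub <- co
            sub$onset[!keep] <- 0L
            build_summary_stats(sub, "prognosis")
          })
          meta_sg <- meta_summary_stats(progs)
          inst <- harmonize(instruments, meta_sg,
                            p_threshold = config$instrument_p)
          est <- mr_ivw(inst)
          sub_est[[sg]] <- est
          rows[[paste0("subgroup_", sg)]] <-
            data.frame(method = "ivw", beta = est$beta, se = est$se,
                       hr = exp(est$beta), ci_low = exp(est$ci_low),
                       ci_high = exp(est$ci_high), p = est$p,
                       n_variants = est$n_variants,
                       outcome = "unadjusted", subgroup = sg,
                       stringsAsFactors = FALSE)
        }
        inter <- interaction_z(sub_est$reduced, sub_est$preserved)
        write_tsv(data.frame(z = inter$z, p = inter$p), out_dir,
                  "mr_interaction.tsv")
      }
      results <- do.call(rbind, rows)
      rownames(results) <- NULL
      write_tsv(results, out_dir, "mr_results.tsv")
      ivw_row <- function(onm) results[results$method == "ivw" &
                                         results$outcome == onm &
                                         results$subgroup == "all", ]
      say("mr: IVW HR/SD %.3f unadjusted%s (mr_results.tsv)",
          ivw_row("unadjusted")$hr,
          if ("cwbls" %in% results$outcome)
            sprintf(", %.3f CWBLS-adjusted", ivw_row("cwbls")$hr) else "")
      if (!is.null(inter))
        say("mr: stratum interaction p = %.3f (mr_interaction.tsv)",
            inter$p)
      list(value = list(results = results, interaction = inter,
                        instruments = instruments),
           meta = list(n_instruments = nrow(instruments)))
    })
    bundle$mr <- mr_res
  }

  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  manifest$config <- cfg
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  bundle$manifest <- manifest
  invisible(bundle)
}
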