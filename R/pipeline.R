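#' Pipeline run configuration
#'
#' Bundles the cohort, gaze and analysis settings of one reproducible run.
#' Round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param cohort arguments for [cohort_config()] (a list).
#' @param gaze arguments for [gaze_sim_config()] (a list).
#' @param effects arguments for [standard_outcomes()] (a list).
#' @param weight_tables list of per-score settings, each with
#'   \code{n_significant} and \code{seed}; three tables mirror a
#'   three-score design.
#' @param family_size FDR family size for the association table.
#' @param interaction_family_size FDR family size for the interaction
#'   table (the one-inflated outcome has no interaction test).
#' @param n_pcs principal components adjusted for.
#' @param gaze_tasks simulate and process raw gaze recordings for the
#'   oculomotor outcomes (slow; when FALSE all outcomes are simulated
#'   directly at the cohort level).
#' @param seed master seed; all stage seeds derive from it.
#' @export
run_config <- function(cohort = list(n_subjects = 200), gaze = list(),
                       effects = list(),
                       weight_tables = list(
                         list(n_significant = 29, seed = 101),
                         list(n_significant = 36, seed = 102),
                         list(n_significant = 37, seed = 103)),
                       family_size = 28, interaction_family_size = 27,
                       n_pcs = 6, gaze_tasks = FALSE, seed = 1L) {
  structure(list(cohort = cohort, gaze = gaze, effects = effects,
                 weight_tables = weight_tables, family_size = family_size,
                 interaction_family_size = interaction_family_size,
                 n_pcs = n_pcs, gaze_tasks = gaze_tasks,
                 seed = as.integer(seed)), class = "run_config")
}

#' @rdname run_config
#' @param config a run_config.
#' @param path YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Association table for one polygenic score over an outcome battery
#'
#' One row per outcome: linear outcomes through [fit_linear_model()] (log
#' transform per the configured list), the one-inflated outcome through
#' [oibeta()] whose logistic-part PRS odds ratio, Wald CI and p-value fill
#' the row. Raw p-values are FDR-adjusted within the family.
#'
#' @param data analysis frame (outcomes, \code{age_c}, \code{age_c2},
#'   \code{sex}, PCs and the PRS column).
#' @param outcomes outcome column names.
#' @param prs_col PRS column name.
#' @param log_outcomes outcomes analysed on the natural log scale.
#' @param oibeta_outcomes outcomes fitted with the one-inflated beta model.
#' @param family_size FDR family size.
#' @param n_pcs principal components adjusted for.
#' @return data frame: outcome, model, estimate, ci_lo, ci_hi, p_raw,
#'   p_fdr, n_used. For \code{model == "oibeta"} the estimate is the odds
#'   ratio per SD of PRS; otherwise the linear coefficient.
#' @export
assoc_table <- function(data, outcomes, prs_col = "prs_z",
                        log_outcomes = log_transformed_outcomes(),
                        oibeta_outcomes = "antisaccade_correction_rate",
                        family_size = 28, n_pcs = 6) {
  rows <- lapply(outcomes, function(oc) {
    if (oc %in% oibeta_outcomes) {
      ## rates reported in percent are mapped onto (0, 1]
      if (max(data[[oc]], na.rm = TRUE) > 1)
        data[[oc]] <- data[[oc]] / 100
      fml <- stats::as.formula(paste(
        oc, "~", paste(c(prs_col, "age_c", "age_c2", "sex",
                         if (n_pcs > 0) paste0("PC", seq_len(n_pcs))),
                       collapse = " + ")))
      fit <- oibeta(fml, data)
      sm <- summary(fit)
      data.frame(outcome = oc, model = "oibeta",
                 estimate = sm$odds_ratios[prs_col, "OR"],
                 ci_lo = sm$odds_ratios[prs_col, "2.5 %"],
                 ci_hi = sm$odds_ratios[prs_col, "97.5 %"],
                 p_raw = sm$logistic[prs_col, "Pr(>|z|)"],
                 n_used = fit$nobs, stringsAsFactors = FALSE)
    } else {
      r <- fit_linear_model(oc, data, log_transform = oc %in% log_outcomes,
                            n_pcs = n_pcs, prs_col = prs_col)$result
      data.frame(outcome = oc, model = "linear", estimate = r$b,
                 ci_lo = r$ci_lo, ci_hi = r$ci_hi, p_raw = r$p_raw,
                 n_used = r$n_used, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw, m = max(family_size, nrow(out)))
  out
}

#' Interaction-test table for one polygenic score
#'
#' Nested-model F tests of the PRS x age and PRS x age^2 terms for every
#' continuous outcome, FDR-adjusted within the family.
#'
#' @inheritParams assoc_table
#' @export
interaction_table <- function(data, outcomes, prs_col = "prs_z",
                              log_outcomes = log_transformed_outcomes(),
                              family_size = 27, n_pcs = 6) {
  rows <- lapply(outcomes, function(oc)
    test_interaction(oc, data, log_transform = oc %in% log_outcomes,
                     n_pcs = n_pcs, prs_col = prs_col))
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw, m = max(family_size, nrow(out)))
  out
}

## per-subject oculomotor processing for the gaze-task branch
.measure_subject_gaze <- function(gsim, seed, outdir = NULL, id = NULL) {
  sess <- list()
  for (tk in c("fixation", "spem", "prosaccade", "antisaccade")) {
    sess[[tk]] <- simulate_gaze_session(tk, gsim,
                                        seed = seed + match(tk, c(
                                          "fixation", "spem", "prosaccade",
                                          "antisaccade")))
    if (!is.null(outdir))
      write_gaze_tsv(sess[[tk]]$recording,
                     file.path(outdir, sprintf("%s_%s_gaze.tsv", id, tk)),
                     file.path(outdir, sprintf("%s_%s_messages.tsv", id,
                                               tk)))
  }
  aggregate_subject(
    fixation = summarize_fixation_task(sess$fixation$recording),
    spem = summarize_spem_task(sess$spem$recording),
    pro = process_saccade_session(sess$prosaccade$recording,
                                  task_spec("prosaccade")),
    anti = process_saccade_session(sess$antisaccade$recording,
                                   task_spec("antisaccade")))
}

#' Run the full synthetic study pipeline
#'
#' Simulate genotypes, apply quality control, build the polygenic scores
#' from the configured weight tables, compute genetic principal components,
#' simulate covariates and outcomes with the planted effect structure,
#' optionally simulate and process raw gaze recordings for the oculomotor
#' outcomes, fit the association and interaction tables per score, and
#' write every artifact plus a provenance record to \code{outdir}.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory artifacts (prs, cohort,
#'   associations, interactions, power, paths).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "genotypes"
  res <- tryCatch({
    ccfg <- do.call(cohort_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$cohort))
    geno <- simulate_genotypes(ccfg)
    write_dosage_tsv(geno$dosages, file.path(outdir, "genotypes.tsv"))

    stage <- "qc"
    qc <- qc_filter(geno$dosages)
    utils::write.table(qc$report, file.path(outdir, "qc_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "prs"
    prs_list <- list()
    for (i in seq_along(config$weight_tables)) {
      wt_cfg <- config$weight_tables[[i]]
      wt <- simulate_weight_table(geno$variants, wt_cfg$n_significant,
                                  seed = wt_cfg$seed)
      write_weight_tsv(wt, file.path(outdir,
                                     sprintf("weights_%d.tsv", i)))
      gw <- select_genome_wide_significant(wt)
      gw <- gw[gw$variant_id %in% colnames(qc$genotypes), , drop = FALSE]
      prs_list[[i]] <- compute_prs(qc$genotypes, gw, geno$variants)
      utils::write.table(prs_list[[i]],
                         file.path(outdir, sprintf("prs_%d.tsv", i)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    pcs <- compute_pcs(qc$genotypes,
                       k = min(config$n_pcs, nrow(qc$genotypes) - 1))
    utils::write.table(data.frame(subject_id = rownames(pcs), pcs),
                       file.path(outdir, "genetic_pcs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

    stage <- "cohort"
    effects <- do.call(standard_outcomes, config$effects)
    prs_z <- prs_list[[1]]$z
    if (length(prs_z) != ccfg$n_subjects) {
      ## QC dropped samples; rebuild the cohort at the retained size
      ccfg$n_subjects <- length(prs_z)
    }
    cohort <- simulate_covariates_outcomes(ccfg, effects, prs_z)
    cohort$subject_id <- prs_list[[1]]$subject_id
    for (i in seq_along(prs_list))
      cohort[[sprintf("prs%d_z", i)]] <- prs_list[[i]]$z

    if (isTRUE(config$gaze_tasks)) {
      stage <- "gaze"
      gdir <- file.path(outdir, "gaze")
      dir.create(gdir, showWarnings = FALSE)
      gcfg <- do.call(gaze_sim_config, config$gaze)
      oc <- lapply(seq_len(nrow(cohort)), function(i)
        .measure_subject_gaze(gcfg, seed = config$seed * 1000L + i,
                              outdir = gdir, id = cohort$subject_id[i]))
      oc <- do.call(rbind, oc)
      ocu_cols <- intersect(names(oc), names(cohort))
      for (cn in ocu_cols) cohort[[cn]] <- oc[[cn]]
      ## carry the trial-count bookkeeping for the report
      for (cn in grep("^n_", names(oc), value = TRUE))
        cohort[[cn]] <- oc[[cn]]
      utils::write.table(
        data.frame(subject_id = cohort$subject_id, oc),
        file.path(outdir, "oculomotor_summary.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE, na = "")
    }
    write_cohort_tsv(cohort, file.path(outdir, "cohort.tsv"))

    stage <- "associations"
    outcomes <- names(effects)
    assoc <- list(); inter <- list()
    for (i in seq_along(prs_list)) {
      prs_col <- sprintf("prs%d_z", i)
      a <- assoc_table(cohort, outcomes, prs_col = prs_col,
                       family_size = config$family_size,
                       n_pcs = config$n_pcs)
      a$prs <- i
      assoc[[i]] <- a
      lin <- setdiff(outcomes, "antisaccade_correction_rate")
      b <- interaction_table(cohort, lin, prs_col = prs_col,
                             family_size = config$interaction_family_size,
                             n_pcs = config$n_pcs)
      b$prs <- i
      inter[[i]] <- b
    }
    assoc <- do.call(rbind, assoc)
    inter <- do.call(rbind, inter)
    utils::write.table(assoc, file.path(outdir, "associations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(inter, file.path(outdir, "interactions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "power"
    n_eff <- stats::median(assoc$n_used)
    pw <- data.frame(f2 = c(0.0010, 0.0015, 0.0020))
    pw$power <- power_f_test(pw$f2, n = n_eff)
    pw$n <- n_eff
    utils::write.table(pw, file.path(outdir, "power.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)

    stage <- "provenance"
    prov <- list(package = "oculoprs",
                 version = as.character(utils::packageVersion("oculoprs")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 seed = config$seed,
                 config_hash = sum(utf8ToInt(paste(
                   deparse(unclass(config)), collapse = ""))),
                 config = unclass(config))
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(config = config, cohort = cohort, prs = prs_list,
         associations = assoc, interactions = inter, power = pw,
         qc_report = qc$report, outdir = outdir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  write_report(res, file.path(outdir, "report.md"))
  invisible(res)
}

#' Write a human-readable run report
#'
#' Markdown report with a descriptive-statistics table, the association and
#' interaction tables, the planted-versus-recovered effect comparison and
#' the trial-exclusion bookkeeping. Absent outcomes are printed as blank
#' fields, never zero.
#'
#' @param run the list returned by [run_pipeline()].
#' @param path output file.
#' @export
write_report <- function(run, path) {
  if (is.null(run$associations)) stop("run artifacts incomplete")
  co <- run$cohort
  fm <- function(x) ifelse(is.na(x), "", formatC(x, digits = 3,
                                                 format = "g"))
  lines <- c("# Synthetic study run report", "",
             sprintf("Seed: %d; subjects: %d", run$config$seed, nrow(co)),
             "", "## Descriptive statistics", "",
             "| outcome | n | mean | sd | median | IQR |",
             "|---|---|---|---|---|---|")
  effects <- do.call(standard_outcomes, run$config$effects)
  for (oc in names(effects)) {
    v <- co[[oc]]
    ok <- !is.na(v)
    lines <- c(lines, sprintf(
      "| %s | %d | %s | %s | %s | %s |", oc, sum(ok), fm(mean(v[ok])),
      fm(stats::sd(v[ok])), fm(stats::median(v[ok])), fm(stats::IQR(v[ok]))))
  }
  pa <- run$associations
  lines <- c(lines, "", "## Associations (per score, FDR within family)",
             "", "| PRS | outcome | estimate | 95% CI | p | FDR p |",
             "|---|---|---|---|---|---|",
             sprintf("| %d | %s | %s | (%s, %s) | %s | %s |", pa$prs,
                     pa$outcome, fm(pa$estimate), fm(pa$ci_lo),
                     fm(pa$ci_hi), fm(pa$p_raw), fm(pa$p_fdr)))
  pi <- run$interactions
  lines <- c(lines, "", "## Age-interaction tests", "",
             "| PRS | outcome | F | p | FDR p |", "|---|---|---|---|---|",
             sprintf("| %d | %s | %s | %s | %s |", pi$prs, pi$outcome,
                     fm(pi$F_value), fm(pi$p_raw), fm(pi$p_fdr)))
  planted <- c(corsi_forward =
                 if (is.null(run$config$effects$beta_corsi)) -0.038 else
                   run$config$effects$beta_corsi)
  rec <- pa[pa$prs == 1 & pa$outcome == "corsi_forward", ]
  lines <- c(lines, "", "## Planted versus recovered effects", "",
             sprintf(paste0("- corsi_forward: planted b = %s, recovered ",
                            "b = %s (%s, %s)"), fm(planted[1]),
                     fm(rec$estimate), fm(rec$ci_lo), fm(rec$ci_hi)))
  if ("n_valid_correct_anti" %in% names(co)) {
    lines <- c(lines, "", "## Trial-filter bookkeeping", "",
               sprintf(paste0("- subjects below the 7 valid-and-correct ",
                              "antisaccade trial floor: %d"),
                       sum(co$n_valid_correct_anti < 7, na.rm = TRUE)),
               sprintf("- subjects below the 5 direction-error floor: %d",
                       sum(co$n_errors_anti < 5, na.rm = TRUE)))
  }
  n_uniform <- mean(pa$p_raw < 0.05)
  lines <- c(lines, "",
             sprintf("Raw p < 0.05 fraction across all rows: %s",
                     fm(n_uniform)),
             sprintf("FDR-significant rows: %d", sum(pa$p_fdr < 0.05)))
  writeLines(lines, path)
  invisible(path)
}
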