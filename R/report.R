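#' Seasonality analysis per phenophase and time interval
#'
#' For each (phenophase, interval) cell: fits and ranks the ten circular
#' models, picks the uniformity test implied by the best-fit modality
#' (Rayleigh for uniform/unimodal, Hermans-Rasson for bimodal), runs it,
#' and summarizes mean vector length, mean angle, concentration, component
#' weight and mean date. The mean angle and mean date are omitted when the
#' uniformity test is not significant at `alpha`. Cells with fewer than 5
#' records are reported as insufficient and not fitted.
#'
#' @param records Cleaned records data frame.
#' @param scheme An [interval_scheme()].
#' @param phases Phenophases to analyse.
#' @param alpha Significance threshold for reporting mean direction.
#' @param n_sim Monte Carlo simulations for the Hermans-Rasson p-value.
#' @param seed Integer seed (Hermans-Rasson nulls).
#' @param convention Angle encoding convention for mean dates.
#' @return Data frame, one row per phase-interval, mirroring a seasonality
#'   results table: best model, distribution class, test used, statistic,
#'   p, r, mean angle, kappa, lambda, mean date (day/month), n.
#' @export
run_seasonality <- function(records, scheme = default_intervals(),
                            phases = c("flowering", "fruiting"),
                            alpha = 0.05, n_sim = 999, seed = 1L,
                            convention = "month_arc") {
  rows <- list()
  for (phase in phases) {
    months <- months_by_interval(records, scheme, phase)
    for (i in seq_len(nrow(scheme))) {
      lab <- scheme$label[i]
      iv_lab <- sprintf("%d-%d", scheme$first_year[i], scheme$last_year[i])
      m <- months[[lab]]
      base <- data.frame(phase = phase, interval = lab, years = iv_lab,
                         n = length(m), stringsAsFactors = FALSE)
      if (length(m) < 5) {
        rows[[length(rows) + 1]] <- cbind(base, data.frame(
          status = if (length(m) == 0) "no data" else "insufficient (n < 5)",
          best_model = NA_character_, distribution = NA_character_,
          test = NA_character_, statistic = NA_real_, p_value = NA_real_,
          r = NA_real_, mean_angle = NA_real_, kappa = NA_real_,
          lambda = NA_real_, mean_date = NA_character_,
          stringsAsFactors = FALSE))
        next
      }
      ang <- month_to_angle(m)
      sel <- select_model(ang)
      best <- sel$best
      test <- choose_uniformity_test(best)
      res <- if (test == "rayleigh") {
        rayleigh_test(ang)
      } else {
        hermans_rasson_test(ang, n_sim = n_sim, seed = seed + i)
      }
      cs <- circ_summary(ang, convention = convention)
      signif <- res$p_value < alpha
      fmt_date <- function(a) {
        d <- angle_to_date(a, convention)
        sprintf("%02d/%02d", d$day, d$month)
      }
      mean_date <- if (!signif || best$modality == "uniform") {
        NA_character_
      } else if (best$modality %in% c("bimodal_axial", "bimodal_nonaxial")) {
        paste(fmt_date(best$params$q1), fmt_date(best$params$q2))
      } else {
        fmt_date(best$params$q1)
      }
      rows[[length(rows) + 1]] <- cbind(base, data.frame(
        status = "ok",
        best_model = best$model, distribution = best$modality,
        test = test, statistic = res$statistic, p_value = res$p_value,
        r = cs$r,
        mean_angle = if (signif) {
          if (best$modality == "uniform") NA_real_ else best$params$q1
        } else NA_real_,
        kappa = if (best$modality == "uniform") NA_real_ else best$params$k1,
        lambda = if (best$modality == "uniform") NA_real_ else best$params$l1,
        mean_date = mean_date, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full phenology pipeline and write all reports
#'
#' Cleans the records, then produces: the cleaning report, the seasonality
#' table, pairwise Watson U2 interval comparisons per phenophase, the
#' month-by-interval contingency residuals, and (when a climate table is
#' supplied) the collinearity screen, full and backward-selected
#' regressions, and the one-way climate ANOVA across intervals. All outputs
#' are written as delimited text (plus a JSON manifest recording seeds and
#' configuration) and returned invisibly; a rerun with the same seed is
#' byte-identical. A failing stage is recorded in the manifest and the
#' remaining stages still run.
#'
#' @param records Raw records data frame (see [parse_records()]).
#' @param out_dir Output directory, created if needed.
#' @param climate Optional [climate_table()] for the regression/ANOVA
#'   stages.
#' @param scheme An [interval_scheme()].
#' @param seed Integer seed for all stochastic stages.
#' @param alpha Significance threshold used in reports.
#' @param n_sim Hermans-Rasson Monte Carlo simulations.
#' @param n_perm Watson U2 permutations.
#' @param normalize Passed to [clean_records()].
#' @return Invisibly, a list with every computed report and the manifest.
#' @export
run_full <- function(records, out_dir, climate = NULL,
                     scheme = default_intervals(), seed = 1L,
                     alpha = 0.05, n_sim = 999, n_perm = 999,
                     normalize = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenocirc")),
    seed = seed, alpha = alpha, n_sim = n_sim, n_perm = n_perm,
    scheme = as.data.frame(unclass(scheme)), failed_stages = character(0))
  out <- list()
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stages <<- c(manifest$failed_stages,
                                   paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }
  cl <- stage("clean", clean_records(records, normalize = normalize))
  if (is.null(cl)) stop("cleaning failed; nothing to analyse", call. = FALSE)
  out$cleaning_report <- as.data.frame(unclass(cl$report))
  wr(out$cleaning_report, "cleaning_report.tsv")
  wr(cl$records, "cleaned_records.tsv")
  out$seasonality <- stage("seasonality",
    run_seasonality(cl$records, scheme, alpha = alpha, n_sim = n_sim,
                    seed = seed))
  if (!is.null(out$seasonality)) wr(out$seasonality, "seasonality.tsv")
  for (phase in c("flowering", "fruiting")) {
    months <- months_by_interval(cl$records, scheme, phase)
    if (sum(vapply(months, length, integer(1)) > 0) >= 2) {
      cmp <- stage(paste0("compare_", phase),
        interval_comparison_matrix(months, n_perm = n_perm,
                                   seed = seed, alpha = alpha))
      out[[paste0("comparison_", phase)]] <- cmp
      if (!is.null(cmp)) wr(cmp$pairs, paste0("comparison_", phase, ".tsv"))
    }
    counts <- vapply(months, function(m) tabulate(m, 12L), integer(12))
    if (is.matrix(counts) && sum(counts) > 0) {
      ct <- stage(paste0("contingency_", phase),
                  contingency_residuals(counts))
      out[[paste0("contingency_", phase)]] <- ct
      if (!is.null(ct)) {
        wr(as.data.frame(ct$residuals), paste0("contingency_", phase, ".tsv"))
      }
    }
  }
  if (!is.null(climate)) {
    for (phase in c("flowering", "fruiting")) {
      sub <- phenophase_subset(cl$records, phase)
      sub <- sub[sub$year <= max(climate$year), , drop = FALSE]
      if (nrow(sub) < 20) next
      des <- stage(paste0("design_", phase),
                   build_lagged_design(sub, climate, match = "nearest"))
      if (is.null(des)) next
      out[[paste0("collinearity_", phase)]] <-
        stage(paste0("collinearity_", phase), collinearity_screen(des))
      full <- stage(paste0("regression_full_", phase), fit_full_model(des))
      if (!is.null(full)) {
        wr(full$terms, paste0("regression_full_", phase, ".tsv"))
        fin <- stage(paste0("regression_final_", phase),
                     backward_select(full))
        out[[paste0("regression_full_", phase)]] <- full
        out[[paste0("regression_final_", phase)]] <- fin
        if (!is.null(fin)) wr(fin$terms, paste0("regression_final_", phase,
                                                ".tsv"))
      }
    }
    av <- stage("climate_anova", {
      do.call(rbind, lapply(c("tmean", "trange", "precip"), function(v) {
        a <- climate_anova(climate, scheme, v)
        data.frame(variable = v, f = a$f, df1 = a$df[1], df2 = a$df[2],
                   p_value = a$p_value)
      }))
    })
    out$climate_anova <- av
    if (!is.null(av)) wr(av, "climate_anova.tsv")
  }
  out$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
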