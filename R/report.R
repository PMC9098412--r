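#' Descriptive statistics per group x test x sex
#'
#' Mirrors the layout of a cohort descriptives table: for every enrollment
#' group x test x sex cell, the number of schools and children, mean/SD age,
#' mean/SD raw score and (when present) mean/SD delta z-score. Cells with a
#' single child report an absent (NA) SD; empty cells are simply absent.
#'
#' @param table Annotated observation table (with `group`, `age_years`,
#'   `raw_value`; optionally `delta`).
#' @return A tibble, one row per non-empty cell.
#' @export
summarize_descriptives <- function(table) {
  has_delta <- "delta" %in% names(table)
  sd_or_na <- function(x) if (length(x) < 2) NA_real_ else sd(x)
  out <- table |>
    dplyr::group_by(.data$group, .data$test, .data$sex) |>
    dplyr::summarise(
      n_schools = dplyr::n_distinct(.data$school_id),
      n_children = dplyr::n_distinct(.data$child_id),
      mean_age = mean(.data$age_years),
      sd_age = sd_or_na(.data$age_years),
      mean_score = mean(.data$raw_value),
      sd_score = sd_or_na(.data$raw_value),
      mean_delta = if (has_delta) mean(.data$delta) else NA_real_,
      sd_delta = if (has_delta) sd_or_na(.data$delta) else NA_real_,
      .groups = "drop"
    )
  out
}

#' Delta z-score versus age figure
#'
#' Observed child-mean delta z-scores binned by age (points, by sex) with
#' the zero reference line that represents keyage-expected performance, one
#' panel per test.
#'
#' @param deltas Delta records with `age_years`, `sex`, `test`, `delta`.
#' @param bin_width Age bin width in years (default one month).
#' @return A ggplot object.
#' @export
plot_delta_age <- function(deltas, bin_width = 1 / 12) {
  binned <- deltas |>
    dplyr::mutate(age_bin = bin_width * (floor(.data$age_years / bin_width) + 0.5)) |>
    dplyr::group_by(.data$test, .data$sex, .data$age_bin) |>
    dplyr::summarise(delta = mean(.data$delta), .groups = "drop")
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$age_bin, y = .data$delta,
                                       shape = .data$sex)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(girl = 1, boy = 16)) +
    ggplot2::facet_wrap(~test, nrow = 1) +
    ggplot2::labs(x = "Age at test (years)", y = "Delta z-score") +
    ggplot2::theme_bw()
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full enrollment-timing pipeline
#'
#' Orchestrates ingest (or synthetic generation), cohort classification and
#' exclusions, pace transformation, two-stage standardization with outlier
#' removal, the keyage reference fit, prediction and delta formation for the
#' non-keyage groups, the OTK and YTK delta models (optionally with
#' parsimonious random-structure selection and the post-hoc nested
#' parameterization), and writes the artifact bundle: descriptives table,
#' fixed-effect and variance-component tables, delta table, exclusion
#' ledger, selection trace, effective run configuration, and (optionally)
#' the delta-versus-age figure. Every stage is logged with counts. Reruns
#' with the same configuration and seed are deterministic.
#'
#' @param input Path to an observation CSV ([read_observations()] schema),
#'   or `NULL` to simulate from `synth`.
#' @param synth A [synth_config()] used when `input` is `NULL`.
#' @param out_dir Output directory for the artifact bundle (created).
#' @param seed Integer seed (synthetic generation).
#' @param cutoff_month_day Enrollment cutoff.
#' @param outlier_k Stage-1 SD multiple.
#' @param outlier_scope `"observation"` or `"child"` (see [stage1_filter()]).
#' @param by_sex Stage-2 reference statistics per test x sex instead of
#'   pooled.
#' @param age_center Centering origin for age.
#' @param select Run random-structure selection for the group models.
#' @param posthoc Also fit the nested per-test parameterization.
#' @param figures Write the delta-versus-age figure (PDF).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all in-memory artifacts (`descriptives`,
#'   `reference`, `otk`, `ytk`, `deltas`, `ledger`, `selection`, `files`).
#' @export
run_pipeline <- function(input = NULL, synth = synth_config(), out_dir,
                         seed = 1, cutoff_month_day = "09-30",
                         outlier_k = 3, outlier_scope = "observation",
                         by_sex = FALSE, age_center = 8.5,
                         select = FALSE, posthoc = TRUE,
                         figures = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(input)) {
    table <- read_observations(input)
    say("ingest: ", nrow(table), " rows from ", input)
  } else {
    gen <- generate_cohort(synth, seed = seed)
    table <- gen$table
    say("simulate: ", nrow(table), " rows, ",
        length(unique(table$child_id)), " children (seed ", seed, ")")
  }

  table <- annotate_cohort(table, cutoff_month_day)
  excl <- apply_exclusions(table)
  table <- excl$table
  say("exclusions: ", -excl$ledger$children[excl$ledger$stage == "age"],
      " children by age, ",
      -excl$ledger$children[excl$ledger$stage == "health"], " by health")

  table <- add_pace(table)
  st1 <- stage1_filter(table, k = outlier_k, scope = outlier_scope)
  table <- st1$table
  ledger <- append_outlier_stage(excl$ledger, st1$n_removed_children,
                                 st1$n_removed_rows)
  say("stage-1 filter (k = ", outlier_k, "): ", st1$n_removed_rows,
      " rows removed")

  keyage <- table[table$group == "keyage", , drop = FALSE]
  ref <- reference_stats(keyage, by_sex = by_sex)
  table <- stage2_standardize(table, ref)
  keyage <- table[table$group == "keyage", , drop = FALSE]

  say("reference fit: ", length(unique(keyage$child_id)), " keyage children")
  reference <- fit_keyage_reference(keyage, ref, age_center = age_center)

  nonkey <- table[table$group %in% c("otk", "ytk"), , drop = FALSE]
  preds <- predict_expected(reference, nonkey)
  deltas <- compute_deltas(nonkey, preds)
  say("deltas: ", nrow(deltas), " rows (",
      sum(deltas$group == "otk"), " otk, ", sum(deltas$group == "ytk"), " ytk)")

  fits <- list()
  selection <- list()
  for (g in c("otk", "ytk")) {
    dg <- deltas[deltas$group == g, , drop = FALSE]
    if (length(unique(dg$child_id)) < 20) {
      say("group ", g, ": too few children, skipped")
      next
    }
    spec <- fitness_model_spec(paste0(g, "_delta"))
    if (select) {
      sel <- select_random_structure(dg, spec, age_center = age_center)
      selection[[g]] <- sel$trace
      fits[[g]] <- sel$fit
      say("group ", g, ": selection over ", nrow(sel$trace),
          " comparisons, ", sel$fit$n_cov_par, " covariance parameters kept")
    } else {
      fits[[g]] <- fit_group_model(dg, g, age_center = age_center)
    }
    if (posthoc) {
      fits[[paste0(g, "_nested")]] <-
        posthoc_nested_fit(dg, g, age_center = age_center)
    }
    say("group ", g, ": deviance ", format(fits[[g]]$deviance, digits = 8))
  }

  # ---- artifact bundle ----
  files <- character()
  desc <- summarize_descriptives(
    dplyr::bind_rows(keyage, dplyr::mutate(deltas, z2 = .data$observed)))
  f <- file.path(out_dir, "descriptives.tsv")
  .write_tsv(dplyr::mutate(desc, dplyr::across(dplyr::where(is.numeric),
                                               ~round(.x, 6))), f)
  files <- c(files, f)

  fx <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    dplyr::mutate(fits[[nm]]$fixed, model = nm, .before = 1)
  }))
  files <- c(files, .write_tsv(fx, file.path(out_dir, "fixed_effects.tsv")))

  vc <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    dplyr::mutate(fits[[nm]]$vc, model = nm, .before = 1)
  }))
  files <- c(files, .write_tsv(vc, file.path(out_dir, "variance_components.tsv")))

  keep_cols <- c("child_id", "school_id", "assessment_year", "sex", "test",
                 "group", "age_years", "observed", "predicted", "delta")
  files <- c(files, .write_tsv(deltas[, keep_cols],
                               file.path(out_dir, "deltas.tsv")))

  f <- file.path(out_dir, "exclusion_ledger.json")
  jsonlite::write_json(ledger, f, dataframe = "rows", pretty = TRUE)
  files <- c(files, f)

  f <- file.path(out_dir, "selection_trace.json")
  jsonlite::write_json(selection, f, dataframe = "rows", pretty = TRUE,
                       auto_unbox = TRUE)
  files <- c(files, f)

  f <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(
    list(input = input, seed = seed, cutoff_month_day = cutoff_month_day,
         outlier_k = outlier_k, outlier_scope = outlier_scope,
         by_sex = by_sex, age_center = age_center, select = select),
    f, auto_unbox = TRUE, pretty = TRUE, null = "null")
  files <- c(files, f)

  if (figures) {
    p <- plot_delta_age(deltas)
    f <- file.path(out_dir, "delta_vs_age.pdf")
    ggplot2::ggsave(f, p, width = 11, height = 3.2)
    files <- c(files, f)
  }
  say("wrote ", length(files), " artifacts to ", out_dir)

  invisible(list(descriptives = desc, reference = reference, deltas = deltas,
                 fits = fits, ledger = ledger, selection = selection,
                 files = files))
}
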