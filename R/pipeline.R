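#' @noRd
read_json_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  config
}

config_from_list <- function(cfg) {
  keep <- intersect(names(cfg), names(formals(analysis_config)))
  do.call(analysis_config, cfg[keep])
}

write_manifest <- function(out_dir, seed, config, inputs, outputs) {
  manifest <- list(
    package = "glycopk",
    version = as.character(utils::packageVersion("glycopk")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    input_md5 = as.list(tools::md5sum(inputs)),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a synthetic study and write its input files
#'
#' Runs [generate_study()] and writes the tables an analysis run consumes:
#' `profiles.csv`, `concentrations.csv`, `doses.csv` (group, nominal dose,
#' route), `standard_profile.csv` (dose-adjustment profile),
#' `standards_observed.csv` (spiked-standard replicates), `truth.csv`,
#' `true_concentrations.csv` and a `manifest.json`. Reruns with the same seed
#' produce identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Optional JSON file path or list overriding simulation
#'   settings: any argument of [study_design()], [pk_parameters()] or
#'   [noise_model()] by name.
#' @param seed Random seed; overrides `config$seed`.
#' @param registry A `glyco_registry`.
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(out_dir, config = NULL, seed = NULL,
                         registry = default_registry()) {
  cfg <- read_json_config(config)
  take <- function(fun, extra = list()) {
    keep <- intersect(names(cfg), names(formals(fun)))
    do.call(fun, c(cfg[keep], extra))
  }
  design <- take(study_design)
  params <- take(pk_parameters)
  noise <- take(noise_model)
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  study <- generate_study(design, params, noise, registry)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    profiles = file.path(out_dir, "profiles.csv"),
    concentrations = file.path(out_dir, "concentrations.csv"),
    doses = file.path(out_dir, "doses.csv"),
    standard_profile = file.path(out_dir, "standard_profile.csv"),
    standards_observed = file.path(out_dir, "standards_observed.csv"),
    truth = file.path(out_dir, "truth.csv"),
    true_concentrations = file.path(out_dir, "true_concentrations.csv"))
  readr::write_csv(study$profiles, paths["profiles"])
  readr::write_csv(study$concentrations, paths["concentrations"])
  readr::write_csv(tibble::tibble(group = study$dose$group,
                                  nominal_dose_mg_per_kg = study$dose$nominal_dose_mg_per_kg,
                                  route = study$dose$route),
                   paths["doses"])
  readr::write_csv(dplyr::mutate(study$dose$standard_profile,
                                 group = study$dose$group, .before = 1),
                   paths["standard_profile"])
  readr::write_csv(study$standards, paths["standards_observed"])
  readr::write_csv(study$truth, paths["truth"])
  readr::write_csv(study$true_concentrations, paths["true_concentrations"])
  write_manifest(out_dir, noise$seed, cfg, character(0), paths)
  invisible(paths)
}

#' Run the glycoform-resolved PK pipeline on input tables
#'
#' Reads profiles, concentrations and dose tables, then per experimental
#' group: splits totals into glycoform concentrations, runs NCA
#' ([nca_study()]), normalizes clearances to the reference glycoform, and
#' compares glycoform clearances against the reference with paired t tests
#' under BH FDR control. When two groups with different routes share a
#' formulation and observed standards are supplied, serum profiles are
#' additionally compared between routes at `serum_comparison_time_h` with the
#' spiked-standard batch-effect control.
#'
#' Writes `nca_results.csv`, `normalized_clearance.csv`,
#' `normalized_summary.csv`, `comparisons.csv`, `traits.csv`, optionally
#' `serum_comparison.csv`, and `manifest.json`.
#'
#' @param profiles,concentrations,doses,standard_profile Paths to the input
#'   CSVs (formats of [cmd_simulate()]); `doses` needs one row per group.
#' @param out_dir Output directory.
#' @param config Optional JSON path or list with [analysis_config()] fields.
#' @param standards Optional path to observed spiked-standard replicates
#'   (`sample_id`, `group`, `glycoform`, `fraction` — or without `group` for a
#'   single shared batch).
#' @param registry A `glyco_registry`.
#' @return Invisibly, a list with the computed tables.
#' @export
cmd_run <- function(profiles, concentrations, doses, standard_profile,
                    out_dir, config = NULL, standards = NULL,
                    registry = default_registry()) {
  cfg_list <- read_json_config(config)
  config <- config_from_list(cfg_list)
  prof <- read_profiles(profiles, registry)
  conc <- read_concentrations(concentrations, lloq_ng_ml = config$lloq_ng_ml)
  dose_tab <- readr::read_csv(doses, show_col_types = FALSE, progress = FALSE)
  std_prof <- readr::read_csv(standard_profile, show_col_types = FALSE,
                              progress = FALSE)
  std_obs <- if (!is.null(standards))
    readr::read_csv(standards, show_col_types = FALSE, progress = FALSE) else NULL

  groups <- unique(conc$group)
  missing_dose <- setdiff(groups, dose_tab$group)
  if (length(missing_dose) > 0) {
    stop("no dose specified for group(s): ",
         paste(missing_dose, collapse = ", "), call. = FALSE)
  }
  res <- lapply(groups, function(g) {
    drow <- dose_tab[dose_tab$group == g, ]
    sp <- std_prof[std_prof$group == g, c("glycoform", "fraction")]
    if (nrow(sp) == 0) stop("no standard profile for group ", g, call. = FALSE)
    ds <- dose_spec(g, drow$nominal_dose_mg_per_kg, drow$route, sp)
    nca_study(prof[prof$group == g, ], conc[conc$group == g, ], ds,
              config, quiet = TRUE)
  })
  nca_results <- dplyr::bind_rows(res)
  normalized <- normalize_to_reference(nca_results, config$reference_glycoform)
  norm_summary <- summarize_normalized(normalized)
  comparisons <- compare_glycoforms(nca_results,
                                    reference = config$reference_glycoform,
                                    fdr = config$fdr)
  traits <- dplyr::bind_rows(lapply(split(prof, prof$sample_id), function(s) {
    cbind(s[1, c("sample_id", "animal_id", "group", "route", "time_h")],
          compute_traits(setNames(s$fraction, s$glycoform), registry))
  }))

  serum_cmp <- NULL
  routes <- unique(dose_tab$route[dose_tab$group %in% groups])
  if (!is.null(std_obs) && length(groups) == 2 && length(routes) == 2) {
    t0 <- config$serum_comparison_time_h
    pick <- function(g) {
      p <- prof[prof$group == g, ]
      p[abs(p$time_h - t0) < 1e-9, c("sample_id", "glycoform", "fraction")]
    }
    std_pick <- function(g) {
      if ("group" %in% names(std_obs)) std_obs[std_obs$group == g, ] else std_obs
    }
    a <- groups[1]; b <- groups[2]
    sa <- pick(a); sb <- pick(b)
    if (nrow(sa) > 0 && nrow(sb) > 0) {
      serum_cmp <- compare_serum_profiles(sa, sb, std_pick(a), std_pick(b),
                                          fdr = config$fdr)
      serum_cmp <- dplyr::mutate(serum_cmp, group_a = a, group_b = b,
                                 time_h = t0, .before = 1)
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- list(nca_results = nca_results, normalized_clearance = normalized,
               normalized_summary = norm_summary, comparisons = comparisons,
               traits = traits)
  if (!is.null(serum_cmp)) outs$serum_comparison <- serum_cmp
  paths <- character(0)
  for (nm in names(outs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(outs[[nm]], p)
    paths <- c(paths, p)
  }
  inputs <- c(profiles, concentrations, doses, standard_profile,
              if (!is.null(standards)) standards)
  write_manifest(out_dir, seed = NULL, config = cfg_list,
                 inputs = inputs, outputs = paths)
  invisible(outs)
}

fmt_pm <- function(mean, sd, stars = "") {
  ifelse(is.na(mean), "-",
         ifelse(is.na(sd),
                paste0(formatC(mean, format = "f", digits = 2), stars),
                paste0(formatC(mean, format = "f", digits = 2), " ± ",
                       formatC(sd, format = "f", digits = 2), stars)))
}

#' Render a plain-text report from a completed run directory
#'
#' Produces a markdown report with a wide clearance table (glycoform x group,
#' mean ± SD with significance stars against the reference), the
#' reference-normalized clearance summary, and the serum-profile comparison.
#' No value is recomputed: everything is read from the run's result tables,
#' so regenerating the report is idempotent.
#'
#' @param out_dir A directory written by [cmd_run()].
#' @param file Output file (default `report.md` inside `out_dir`).
#' @return Invisibly, the report text.
#' @export
cmd_report <- function(out_dir, file = file.path(out_dir, "report.md")) {
  need <- file.path(out_dir, c("nca_results.csv", "normalized_summary.csv",
                               "comparisons.csv"))
  absent <- need[!file.exists(need)]
  if (length(absent) > 0) {
    stop("incomplete run directory; missing: ",
         paste(basename(absent), collapse = ", "), call. = FALSE)
  }
  nca <- readr::read_csv(need[1], show_col_types = FALSE, progress = FALSE)
  norm <- readr::read_csv(need[2], show_col_types = FALSE, progress = FALSE)
  cmp <- readr::read_csv(need[3], show_col_types = FALSE, progress = FALSE)

  # mean +/- SD clearance per glycoform x group, stars from the comparisons
  summ <- dplyr::summarise(
    dplyr::group_by(nca, .data$group, .data$glycoform, .data$clearance_label),
    mean = mean(.data$clearance_ml_day_kg, na.rm = TRUE),
    sd = sd(.data$clearance_ml_day_kg, na.rm = TRUE), .groups = "drop")
  summ <- dplyr::left_join(summ, cmp[c("group", "glycoform", "stars")],
                           by = c("group", "glycoform"))
  summ$stars[is.na(summ$stars)] <- ""
  summ$cell <- fmt_pm(summ$mean, summ$sd, summ$stars)
  summ$col <- paste0(summ$group, " ", summ$clearance_label, " (mL/day/kg)")
  wide <- tidyr::pivot_wider(summ[c("glycoform", "col", "cell")],
                             names_from = "col", values_from = "cell")
  wide <- wide[order(wide$glycoform != "Total", wide$glycoform), ]

  lines <- c("# Glycoform-resolved PK report", "",
             "## Clearance per glycoform (mean ± SD)", "",
             "For SC groups, CL/F — apparent clearance as a function of",
             "bioavailability following SC administration — is reported.", "",
             md_table(wide), "",
             "Stars mark FDR-significant paired contrasts against the reference",
             "glycoform (* significant; ** p < 0.01; *** p < 0.001; **** p < 0.0001).",
             "", "## Clearance normalized to the reference glycoform", "",
             md_table(dplyr::mutate(norm, dplyr::across(dplyr::where(is.numeric),
                                                        ~ round(.x, 4)))))

  ser_path <- file.path(out_dir, "serum_comparison.csv")
  lines <- c(lines, "", "## Serum profile comparison", "")
  if (file.exists(ser_path)) {
    ser <- readr::read_csv(ser_path, show_col_types = FALSE, progress = FALSE)
    sig <- ser[!is.na(ser$flag) & ser$flag != "ns", ]
    if (nrow(sig) == 0) {
      lines <- c(lines, "None significant.")
    } else {
      lines <- c(lines, md_table(dplyr::mutate(sig, dplyr::across(
        dplyr::where(is.numeric), ~ signif(.x, 4)))))
    }
  } else {
    lines <- c(lines, "Not performed (requires two routes and observed standards).")
  }
  text <- paste(lines, collapse = "\n")
  writeLines(text, file)
  invisible(text)
}

md_table <- function(df) {
  df <- as.data.frame(lapply(df, as.character), check.names = FALSE)
  df[is.na(df)] <- "-"
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
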