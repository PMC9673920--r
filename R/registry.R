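#' Construct a glycoform attribute registry
#'
#' A registry maps short glycan codes (G0F, Man5, ...) to the structural
#' attributes that drive derived glycosylation traits and the simulation's
#' clearance multipliers: number of antennae (0 for oligomannose), number of
#' terminal galactoses, number of sialic acids, core fucosylation, and
#' oligomannose class membership.
#'
#' Structural invariants are enforced: `n_galactose <= n_antennae` for
#' complex/hybrid types, `n_sialic <= n_galactose`, and oligomannose implies
#' zero antennae and no core fucose.
#'
#' @param x A data frame with columns `name`, `n_antennae`, `n_galactose`,
#'   `n_sialic`, `core_fucose`, `oligomannose`.
#' @return A tibble of class `glyco_registry`.
#' @seealso [default_registry()], [load_registry()]
#' @export
glyco_registry <- function(x) {
  required <- c("name", "n_antennae", "n_galactose", "n_sialic",
                "core_fucose", "oligomannose")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[required]
  x$name <- as.character(x$name)
  for (col in c("n_antennae", "n_galactose", "n_sialic")) {
    x[[col]] <- as.integer(x[[col]])
    if (anyNA(x[[col]]) && nrow(x) > 0) {
      stop("registry column '", col, "' contains non-integer values", call. = FALSE)
    }
  }
  for (col in c("core_fucose", "oligomannose")) {
    x[[col]] <- parse_flag(x[[col]], col)
  }
  dup <- x$name[duplicated(x$name)]
  if (length(dup) > 0) {
    stop("duplicate glycoform name(s) in registry: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- x$name[!x$oligomannose & x$n_galactose > x$n_antennae]
  if (length(bad) > 0) {
    stop("n_galactose exceeds n_antennae for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- x$name[x$n_sialic > x$n_galactose]
  if (length(bad) > 0) {
    stop("n_sialic exceeds n_galactose for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- x$name[x$oligomannose & (x$n_antennae != 0L | x$core_fucose)]
  if (length(bad) > 0) {
    stop("oligomannose glycoforms must have 0 antennae and no core fucose: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("glyco_registry", class(x))
  x
}

# strict logical parser used for registry flag columns; reports offending rows
parse_flag <- function(v, col) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes")] <- TRUE
  out[s %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && length(s) > 0) {
    lines <- which(is.na(out))
    stop("non-boolean value in registry column '", col, "' at data row(s) ",
         paste(lines, collapse = ", "), call. = FALSE)
  }
  as.logical(out)
}

#' Built-in default glycoform registry
#'
#' Covers the glycoforms quantified in typical CHO-produced, oligomannose-rich
#' and galactosylated/sialylated IgG1 preparations: Man5, G0, G0F, G0F-N, G1,
#' G1F, G2F, G2FS1, G2S2, G2FS2, H6N4F1S2, G1S-N and G1FS-N.
#'
#' `H6N4F1S2` is a minor glycan identified only by monosaccharide composition;
#' its attributes (diantennary, digalactosylated, disialylated, fucosylated)
#' are inferred from that composition and should be treated as provisional.
#'
#' @return A `glyco_registry` tibble.
#' @export
default_registry <- function() {
  glyco_registry(tibble::tribble(
    ~name,        ~n_antennae, ~n_galactose, ~n_sialic, ~core_fucose, ~oligomannose,
    "Man5",       0L,          0L,           0L,        FALSE,        TRUE,
    "G0",         2L,          0L,           0L,        FALSE,        FALSE,
    "G0F",        2L,          0L,           0L,        TRUE,         FALSE,
    "G0F-N",      1L,          0L,           0L,        TRUE,         FALSE,
    "G1",         2L,          1L,           0L,        FALSE,        FALSE,
    "G1F",        2L,          1L,           0L,        TRUE,         FALSE,
    "G2F",        2L,          2L,           0L,        TRUE,         FALSE,
    "G2FS1",      2L,          2L,           1L,        TRUE,         FALSE,
    "G2S2",       2L,          2L,           2L,        FALSE,        FALSE,
    "G2FS2",      2L,          2L,           2L,        TRUE,         FALSE,
    "H6N4F1S2",   2L,          2L,           2L,        TRUE,         FALSE,
    "G1S-N",      1L,          1L,           1L,        FALSE,        FALSE,
    "G1FS-N",     1L,          1L,           1L,        TRUE,         FALSE
  ))
}

#' Read a glycoform registry from a delimited file
#'
#' @param path CSV file with header columns `name`, `n_antennae`,
#'   `n_galactose`, `n_sialic`, `core_fucose`, `oligomannose`.
#' @return A `glyco_registry`. An empty file (header only) yields an empty
#'   registry with a warning.
#' @export
load_registry <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    warning("registry file '", path, "' contains no glycoforms", call. = FALSE)
  }
  glyco_registry(df)
}

#' @rdname load_registry
#' @param registry A `glyco_registry`.
#' @export
write_registry <- function(registry, path) {
  readr::write_csv(registry, path)
  invisible(path)
}

#' Look up glycoform attributes
#'
#' @param registry A `glyco_registry`.
#' @param names Character vector of glycoform codes; every code must resolve.
#' @return The registry rows for `names`, in the same order.
#' @export
registry_lookup <- function(registry, names) {
  idx <- match(names, registry$name)
  if (anyNA(idx)) {
    stop("glycoform(s) not in registry: ",
         paste(unique(names[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  registry[idx, ]
}

sample_key <- function(df) {
  if ("sample_id" %in% names(df)) {
    as.character(df$sample_id)
  } else {
    paste(df$animal_id, df$group, df$time_h, sep = "|")
  }
}

#' Read per-sample glycoform profiles
#'
#' Reads tidy long-format profile tables: one row per (sample, glycoform)
#' with columns `animal_id`, `group`, `route`, `time_h`, `glycoform`,
#' `fraction` and an optional `sample_id`. Fractions may be on the unit scale
#' (per-sample sums near 1) or percent scale (sums near 100); percent-scale
#' samples are rescaled, and every sample is renormalized to sum exactly 1.
#' Per-sample sums outside \[0.95, 1.05\] (or \[95, 105\]) raise an error
#' naming the sample, as such profiles indicate missing or duplicated
#' glycoforms rather than rounding.
#'
#' @param path CSV file.
#' @param registry A `glyco_registry`; every glycoform in the table must
#'   resolve.
#' @return A tibble with columns `sample_id`, `animal_id`, `group`, `route`,
#'   `time_h`, `glycoform`, `fraction`.
#' @export
read_profiles <- function(path, registry = default_registry()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_sample_profiles(df, registry)
}

#' @rdname read_profiles
#' @param df A data frame already in the long profile format.
#' @export
as_sample_profiles <- function(df, registry = default_registry()) {
  required <- c("animal_id", "group", "route", "time_h", "glycoform", "fraction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("profile table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  registry_lookup(registry, unique(df$glycoform))
  if (any(df$fraction < 0)) stop("negative glycoform fractions", call. = FALSE)
  df$sample_id <- sample_key(df)
  dup <- duplicated(df[c("sample_id", "glycoform")])
  if (any(dup)) {
    stop("duplicate glycoform rows within sample(s): ",
         paste(unique(df$sample_id[dup]), collapse = ", "), call. = FALSE)
  }
  sums <- tapply(df$fraction, df$sample_id, sum)
  scale <- numeric(length(sums))
  unit <- sums >= 0.95 & sums <= 1.05
  pct <- sums >= 95 & sums <= 105
  if (any(!unit & !pct)) {
    stop("profile fractions sum outside [0.95, 1.05] (or [95, 105]) for sample(s): ",
         paste(names(sums)[!unit & !pct], collapse = ", "), call. = FALSE)
  }
  # renormalize each sample to sum exactly 1 (handles percent scale too)
  df$fraction <- df$fraction / as.numeric(sums[df$sample_id])
  df[c("sample_id", "animal_id", "group", "route", "time_h",
       "glycoform", "fraction")]
}

#' @rdname read_profiles
#' @param profiles A profile tibble as returned by `read_profiles()`.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' Read total antibody concentration series
#'
#' Reads tidy long-format concentration tables with columns `animal_id`,
#' `group`, `time_h`, `conc_ug_ml` and an optional logical `bloq`. Rows are
#' sorted by time within animal; concentrations below the ELISA lower limit
#' of quantitation are flagged BLOQ (retained in storage, excluded from NCA
#' downstream).
#'
#' @param path CSV file.
#' @param lloq_ng_ml ELISA lower limit of quantitation in ng/mL (default 7).
#' @return A tibble with columns `animal_id`, `group`, `time_h`,
#'   `conc_ug_ml`, `bloq`.
#' @export
read_concentrations <- function(path, lloq_ng_ml = 7) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_concentration_series(df, lloq_ng_ml = lloq_ng_ml)
}

#' @rdname read_concentrations
#' @param df A data frame already in the long concentration format.
#' @export
as_concentration_series <- function(df, lloq_ng_ml = 7) {
  required <- c("animal_id", "group", "time_h", "conc_ug_ml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("concentration table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (any(df$conc_ug_ml < 0, na.rm = TRUE)) {
    stop("negative concentration value(s)", call. = FALSE)
  }
  key <- paste(df$animal_id, df$group, df$time_h, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (animal, time) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (!"bloq" %in% names(df)) df$bloq <- FALSE
  df$bloq <- isTRUE_vec(df$bloq) | df$conc_ug_ml < lloq_ng_ml / 1000
  df <- df[order(df$animal_id, df$group, df$time_h), ]
  df <- df[c("animal_id", "group", "time_h", "conc_ug_ml", "bloq")]
  tibble::as_tibble(df)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  s <- tolower(trimws(as.character(x)))
  s %in% c("true", "t", "1", "yes")
}

#' @rdname read_concentrations
#' @param concentrations A concentration tibble.
#' @export
write_concentrations <- function(concentrations, path) {
  readr::write_csv(concentrations, path)
  invisible(path)
}

#' Dose specification for one experimental group
#'
#' Carries the nominal dose, the administration route, and the glycoform
#' profile measured in serum spiked with the dosing material (the spiked
#' standard). The standard profile defines the glycoform-specific dose
#' fractions used for dose adjustment in [nca_study()]: each glycoform's dose
#' is the nominal dose times its fraction in the standard.
#'
#' @param group Group label (e.g. `"CHO-mAb1-IV"`).
#' @param nominal_dose_mg_per_kg Nominal dose in mg/kg; must be positive.
#' @param route `"IV"` or `"SC"`.
#' @param standard_profile A data frame with columns `glycoform`, `fraction`
#'   summing to 1 within 5% (renormalized to 1 exactly).
#' @return A list of class `dose_spec`.
#' @export
dose_spec <- function(group, nominal_dose_mg_per_kg, route, standard_profile) {
  stopifnot(is.numeric(nominal_dose_mg_per_kg), nominal_dose_mg_per_kg > 0)
  route <- match.arg(route, c("IV", "SC"))
  sp <- tibble::as_tibble(standard_profile)[c("glycoform", "fraction")]
  s <- sum(sp$fraction)
  if (any(sp$fraction < 0) || abs(s - 1) > 0.05) {
    stop("standard profile fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  sp$fraction <- sp$fraction / s
  structure(list(group = as.character(group),
                 nominal_dose_mg_per_kg = nominal_dose_mg_per_kg,
                 route = route,
                 standard_profile = sp),
            class = "dose_spec")
}
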