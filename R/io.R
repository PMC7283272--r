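#' Read a delimited table with schema checking and metadata comments
#'
#' Reads a comma- or tab-separated file (separator autodetected from the
#' header line). Leading comment lines of the form `#key=value` are parsed
#' into a metadata list. Required columns are matched by name,
#' order-insensitively; unknown extra columns are kept with a warning;
#' missing required columns or non-numeric cells in numeric columns are
#' errors naming the offending column (and row).
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @param numeric_cols columns that must parse as numeric when present
#'   (default: all required columns); also counts as known schema, so
#'   optional numeric columns do not trigger the unknown-column warning.
#' @return data frame of records, with the metadata list attached as
#'   attribute `"metadata"`.
#' @export
read_table <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) {
    stop("no data rows in ", path, call. = FALSE)
  }
  metadata <- list()
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      num <- suppressWarnings(as.numeric(val))
      metadata[[key]] <- if (!is.na(num)) num else val
    }
  }
  sep <- if (grepl("\t", body[1], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), union(required, numeric_cols))
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & nzchar(trimws(df[[col]])))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "', row ", bad[1],
           " of ", path, call. = FALSE)
    }
    df[[col]] <- vals
  }
  attr(df, "metadata") <- metadata
  df
}

#' Read a time-course file
#'
#' Delimited text with columns `time_s`, `product_uM`; condition metadata in
#' `#key=value` header lines (recognized keys: `enzyme_conc`, `dna_conc`,
#' `nucleotide_id`, `nucleotide_conc`, `context_tag`, `temperature`,
#' `label`).
#'
#' @param path file path.
#' @return A [time_course()].
#' @export
read_timecourse <- function(path) {
  df <- read_table(path, required = c("time_s", "product_uM"))
  m <- attr(df, "metadata")
  pick <- function(key, default) if (!is.null(m[[key]])) m[[key]] else default
  time_course(
    df$time_s, df$product_uM,
    enzyme_conc = pick("enzyme_conc", NA_real_),
    dna_conc = pick("dna_conc", NA_real_),
    nucleotide_id = pick("nucleotide_id", NA_character_),
    nucleotide_conc = pick("nucleotide_conc", NA_real_),
    context_tag = as.character(pick("context_tag", "none")),
    temperature = pick("temperature", NA_real_),
    label = as.character(pick("label", ""))
  )
}

#' Read a titration file
#'
#' Delimited text with columns `conc_uM`, `k_obs_s` and optionally
#' `se_kobs`, `amplitude_uM`, `se_amp`; metadata keys `nucleotide_id` and
#' `context_tag` in `#key=value` header lines.
#'
#' @param path file path.
#' @return A [titration_series()].
#' @export
read_titration <- function(path) {
  df <- read_table(path, required = c("conc_uM", "k_obs_s"),
                   numeric_cols = c("conc_uM", "k_obs_s", "se_kobs",
                                    "amplitude_uM", "se_amp"))
  m <- attr(df, "metadata")
  pick <- function(key, default) if (!is.null(m[[key]])) m[[key]] else default
  titration_series(
    df$conc_uM, df$k_obs_s,
    amplitude = if ("amplitude_uM" %in% names(df)) df$amplitude_uM else NULL,
    se_kobs = if ("se_kobs" %in% names(df)) df$se_kobs else NULL,
    se_amp = if ("se_amp" %in% names(df)) df$se_amp else NULL,
    nucleotide_id = as.character(pick("nucleotide_id", NA_character_)),
    context_tag = as.character(pick("context_tag", "none"))
  )
}

#' Read melt curves from a long-format file
#'
#' Delimited text with columns `well`, `temperature_C`, `rfu`; one
#' [melt_curve()] per well.
#'
#' @param path file path.
#' @return named list of [melt_curve()] objects, one per well.
#' @export
read_meltcurves <- function(path) {
  df <- read_table(path, required = c("well", "temperature_C", "rfu"),
                   numeric_cols = c("temperature_C", "rfu"))
  wells <- unique(df$well)
  out <- lapply(wells, function(w) {
    d <- df[df$well == w, ]
    d <- d[order(d$temperature_C), ]
    melt_curve(d$temperature_C, d$rfu, well_id = w)
  })
  names(out) <- wells
  out
}

# display formatting: 2 significant figures for efficiencies, scientific
# notation below 1e-3, locale-independent
format_efficiency <- function(x) {
  ifelse(abs(x) < 1e-3,
         formatC(signif(x, 2), format = "e", digits = 1),
         formatC(signif(x, 2), format = "fg"))
}

format_fold <- function(x) formatC(round(x, 1), format = "fg")

#' Write a kinetics summary report
#'
#' Emits a summary table shaped like a per-context kinetics table: one row
#' per fitted titration with `k_pol`, `K_d`, their one-SD errors, the
#' incorporation efficiency and the fold difference to the reference
#' context. Two files are written: the display report at `path` with
#' efficiencies rounded to 2 significant figures and folds to 1 decimal, and
#' a full-precision machine-readable companion at `path` with `_full`
#' inserted before the extension.
#'
#' @param params list of `kinetic_parameters` (results of
#'   [fit_titration()]); non-empty, all from the same nucleotide or not --
#'   rows are written as given.
#' @param path output CSV path.
#' @param reference context tag used for the fold-difference column; default
#'   the first entry's context.
#' @return invisibly, the display data frame. The full-precision companion
#'   path is attached as attribute `"full_path"`.
#' @export
write_kinetics_report <- function(params, path, reference = NULL) {
  if (length(params) == 0) stop("empty parameter list", call. = FALSE)
  stopifnot(all(vapply(params, inherits, TRUE, "kinetic_parameters")))
  ctx <- vapply(params, `[[`, "", "context_tag")
  if (is.null(reference)) reference <- ctx[1]
  effs <- vapply(params, `[[`, 0, "efficiency")
  names(effs) <- ctx
  folds <- fold_difference_table(effs, reference)
  full <- data.frame(
    nucleotide_id = vapply(params, `[[`, "", "nucleotide_id"),
    context_tag = ctx,
    k_pol = vapply(params, `[[`, 0, "k_pol"),
    se_kpol = vapply(params, `[[`, 0, "se_kpol"),
    K_d = vapply(params, `[[`, 0, "K_d"),
    se_Kd = vapply(params, `[[`, 0, "se_Kd"),
    efficiency = effs,
    fold_vs_reference = as.numeric(folds),
    branch = vapply(params, `[[`, "", "branch"),
    form = vapply(params, `[[`, "", "form"),
    row.names = NULL
  )
  display <- full
  display$efficiency <- format_efficiency(full$efficiency)
  display$fold_vs_reference <- format_fold(full$fold_vs_reference)
  full_path <- sub("(\\.[^.]+)?$", "_full\\1", path)
  utils::write.csv(display, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(full, full_path, row.names = FALSE, quote = FALSE)
  attr(display, "full_path") <- full_path
  invisible(display)
}

#' Default analysis configuration
#'
#' @return named list of all recognized configuration options with their
#'   defaults: `stage` (`"titration"`), `form`, `branch`, `alpha`,
#'   `reference_context`, `smooth_window`, `min_prominence`,
#'   `search_range`, `sign_convention`, `cycle_counts`, `seed`.
#' @export
default_config <- function() {
  list(
    stage = "titration",
    form = "quadratic",
    branch = "auto",
    alpha = 0.05,
    reference_context = "PreC",
    smooth_window = 7,
    min_prominence = 0.1,
    search_range = c(25, 90),
    sign_convention = "negative",
    cycle_counts = c(basal = 3, oligomycin = 6, fccp = 3, rot_aa = 3),
    seed = 1
  )
}

#' Read and validate an analysis configuration
#'
#' YAML configuration; unknown keys are rejected with a message naming them,
#' known keys override the defaults of [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, user)
}

#' Run the titration pipeline over a directory
#'
#' Reads every `*.csv`/`*.tsv` titration file in `input_dir`, fits each with
#' [fit_titration()] under the configured form/branch, and writes a
#' kinetics report (display + full precision) to `out`. Per-file failures
#' are collected and reported at the end rather than aborting the run; the
#' result records them so a caller (or the CLI) can exit non-zero.
#' Deterministic given the same inputs and configuration: reruns produce
#' byte-identical machine-readable output.
#'
#' @param input_dir directory of titration files.
#' @param out output report path (CSV).
#' @param config configuration list from [read_config()] /
#'   [default_config()].
#' @return list with `parameters` (successful fits), `failures` (named list
#'   of fit failures or read errors), `report` (display data frame).
#' @export
run_pipeline <- function(input_dir, out, config = default_config()) {
  files <- list.files(input_dir, pattern = "\\.(csv|tsv)$",
                      full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0) {
    stop("no titration files (*.csv, *.tsv) in ", input_dir, call. = FALSE)
  }
  params <- list()
  failures <- list()
  for (f in files) {
    res <- tryCatch({
      series <- read_titration(f)
      fit_titration(series, form = config$form, branch = config$branch,
                    alpha = config$alpha)
    }, error = function(e) fit_failure("run_pipeline", conditionMessage(e)))
    if (is_fit_failure(res)) {
      failures[[basename(f)]] <- res
    } else {
      params[[length(params) + 1]] <- res
    }
  }
  if (length(params) == 0) {
    stop("all input files failed to fit", call. = FALSE)
  }
  ref <- config$reference_context
  ctx <- vapply(params, `[[`, "", "context_tag")
  if (!ref %in% ctx) ref <- ctx[1]
  report <- write_kinetics_report(params, out, reference = ref)
  if (length(failures)) {
    warning(length(failures), " file(s) failed: ",
            paste(names(failures), collapse = ", "), call. = FALSE)
  }
  list(parameters = params, failures = failures, report = report)
}
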