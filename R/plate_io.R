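# Plate-reader table I/O: long one-row-per-well CSV/TSV is the canonical
# format. Concentrations are carried internally in micromolar; an optional
# `unit` column (uM/nM/mM) is converted on read.

WELL_COLUMNS <- c("model_id", "drug_a", "drug_b", "conc_a", "conc_b",
                  "replicate", "signal", "role")
WELL_ROLES <- c("treatment", "negative_control", "positive_control")

unit_factor <- function(unit) {
  u <- tolower(trimws(unit))
  u[u == ""] <- "um"
  f <- c(um = 1, "µm" = 1, nm = 1e-3, mm = 1e3)[u]
  if (anyNA(f))
    stop("unknown concentration unit(s): ",
         paste(unique(unit[is.na(f)]), collapse = ", "), call. = FALSE)
  unname(f)
}

#' Read a long-format plate-reader table
#'
#' Reads a one-row-per-well CSV or TSV table of raw viability signals and
#' validates it: required columns, non-negative signals and concentrations,
#' consistent control rows (zero doses), and at least two negative and two
#' positive control wells per `(model_id, drug_a, drug_b)` group. An
#' optional `unit` column (uM, nM, mM) is converted to micromolar. An
#' optional `plate` column identifies plates for per-plate control
#' aggregation; absent, one plate per group is assumed.
#'
#' @param path Path to the table.
#' @param sep Field separator; default inferred from the file extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return A `data.frame` of validated well records, row order preserved,
#'   concentrations in micromolar, with class `well_table`.
#' @export
#' @examples
#' path <- system.file("extdata", "example_plate.csv",
#'                     package = "comboscreen")
#' wells <- read_plate_table(path)
#' head(wells, 3)
read_plate_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          na.strings = c("NA", ""))
  validate_well_table(df, where = path)
}

#' Validate a data frame of well records
#'
#' @param df Data frame with the columns of a well table.
#' @param where Label used in error messages.
#' @return The validated `well_table` (concentrations converted to uM).
#' @export
validate_well_table <- function(df, where = "well table") {
  missing_cols <- setdiff(WELL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("schema error in ", where, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$drug_b[is.na(df$drug_b)] <- ""
  df$conc_a <- as.numeric(df$conc_a)
  df$conc_b <- as.numeric(df$conc_b)
  df$signal <- as.numeric(df$signal)
  df$replicate <- as.integer(df$replicate)
  if ("unit" %in% names(df)) {
    f <- unit_factor(ifelse(is.na(df$unit), "um", df$unit))
    df$conc_a <- df$conc_a * f
    df$conc_b <- df$conc_b * f
    df$unit <- NULL
  }
  bad <- which(!df$role %in% WELL_ROLES)
  if (length(bad))
    stop("validation error in ", where, ": unknown role at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$signal) | df$signal < 0)
  if (length(bad))
    stop("validation error in ", where, ": negative or missing signal at ",
         "row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(df$conc_a) | df$conc_a < 0 |
               is.na(df$conc_b) | df$conc_b < 0)
  if (length(bad))
    stop("validation error in ", where, ": negative or missing ",
         "concentration at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  is_ctrl <- df$role != "treatment"
  bad <- which(is_ctrl & (df$conc_a != 0 | df$conc_b != 0))
  if (length(bad))
    stop("validation error in ", where, ": control wells must have zero ",
         "doses, row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  treat <- !is_ctrl
  if (any(treat) && all(df$conc_a[treat] == 0 & df$conc_b[treat] == 0))
    stop("validation error in ", where, ": no nonzero dose in any ",
         "treatment well", call. = FALSE)
  bad <- which(treat & df$conc_a == 0 & df$conc_b == 0)
  if (length(bad))
    stop("validation error in ", where, ": treatment wells need a nonzero ",
         "dose, row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  if (!"plate" %in% names(df)) df$plate <- 1L
  grp <- interaction(df$model_id, df$drug_a, df$drug_b, df$plate, drop = TRUE)
  for (g in levels(grp)) {
    rows <- df[grp == g, ]
    n_neg <- sum(rows$role == "negative_control")
    n_pos <- sum(rows$role == "positive_control")
    if (n_neg < 2 || n_pos < 2)
      stop("validation error in ", where, ": group '", g, "' has ", n_neg,
           " negative and ", n_pos, " positive control wells ",
           "(>= 2 of each required)", call. = FALSE)
  }
  class(df) <- c("well_table", "data.frame")
  df
}

#' Write a well table (or any result table) to CSV
#'
#' Plain UTF-8 CSV with '.' decimal separator and LF line endings, written
#' at full double precision so read/write round-trips are exact.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the command, configuration, seed, package version, input file
#' hashes (MD5) and a timestamp, so a run can be identified and repeated.
#'
#' @param path Output path for the manifest JSON.
#' @param command Character label of the pipeline stage.
#' @param config A `screen_config`.
#' @param inputs Character vector of input file paths to hash.
#' @param seed Integer seed used for the run.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character(),
                           seed = config$rng_seed) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command,
    config = unclass(config),
    config_hash = unname(tools::md5sum(textConnectionHash(config))),
    input_hashes = hashes,
    seed = seed,
    version = as.character(utils::packageVersion("comboscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# hash the config via a temp file; tools::md5sum only hashes files
textConnectionHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  tf
}
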