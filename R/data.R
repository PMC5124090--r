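#' Observed data for one region
#'
#' Container for the three observation streams the IPM joins: an annual
#' abundance-index series (with possible missing years), individual nest
#' records, and capture histories from constant-effort ringing sites.
#'
#' @param region Region label.
#' @param years Ordered vector of calendar years (length `T`).
#' @param counts Numeric vector of length `T`; `NA` marks a year with no
#'   survey (the latent state is still propagated, which imputes it).
#' @param nests Data frame with columns `region, year, brood, egg_days,
#'   egg_survived, chick_days, chick_survived` (flags 0/1; exposure days
#'   include the failure day).
#' @param histories Data frame with columns `region, first_year,
#'   encounter_string`; each string has one 0/1 character per study year.
#' @return An object of class `ipm_data`.
#' @export
ipm_data <- function(region, years, counts, nests, histories) {
  years <- check_count(years, "years")
  tt <- length(years)
  if (tt < 3) abort("An IPM needs at least 3 study years.")
  if (any(diff(years) != 1L)) abort("`years` must be consecutive calendar years.")
  if (length(counts) != tt) abort("`counts` must have one value per year.")
  if (all(is.na(counts))) abort("At least one count must be observed.")
  if (any(!is.na(counts) & counts <= 0)) {
    abort("Observed counts must be positive; flag missing years as NA, not zero.")
  }
  nests <- as_tibble(nests)
  validate_nests(nests)
  if (nrow(nests) && !all(nests$year %in% years[-tt])) {
    abort("Nest seasons must fall inside the study years (excluding the final year).")
  }
  histories <- as_tibble(histories)
  encounter_matrix(histories, tt) # validates
  structure(
    list(region = region, years = years, counts = counts,
         nests = nests, histories = histories),
    class = "ipm_data"
  )
}

#' @export
print.ipm_data <- function(x, ...) {
  cat("<ipm_data> region '", x$region, "': ", length(x$years), " years (",
      x$years[1], "-", x$years[length(x$years)], ")\n", sep = "")
  cat("  counts: ", sum(!is.na(x$counts)), " observed, ",
      sum(is.na(x$counts)), " missing\n", sep = "")
  cat("  nests: ", nrow(x$nests), " records | histories: ",
      nrow(x$histories), " individuals\n", sep = "")
  invisible(x)
}

#' Read the three observation streams from CSV
#'
#' `read_counts_csv()` expects columns `region,year,count` (empty `count`
#' fields mark missing years); `read_nests_csv()` the nest-record dialect;
#' `read_histories_csv()` columns `region,first_year,encounter_string`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_counts_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    region = readr::col_character(),
    year = readr::col_integer(),
    count = readr::col_double()
  ))
}

#' @rdname read_counts_csv
#' @export
read_nests_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    region = readr::col_character(),
    year = readr::col_integer(),
    brood = readr::col_integer(),
    egg_days = readr::col_integer(),
    egg_survived = readr::col_integer(),
    chick_days = readr::col_integer(),
    chick_survived = readr::col_integer()
  ))
}

#' @rdname read_counts_csv
#' @export
read_histories_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    region = readr::col_character(),
    first_year = readr::col_integer(),
    encounter_string = readr::col_character()
  ))
}

#' Read MARK-style .inp capture histories
#'
#' Parses encounter-history lines of the form `011010 12;` (history then a
#' frequency, terminated by `;`), tolerating `/* ... */` comments. Each
#' history is replicated by its frequency.
#'
#' @param path File path.
#' @param years Study years the encounter columns correspond to.
#' @param region Region label to attach.
#' @return A tibble in the `histories` dialect.
#' @export
read_inp_histories <- function(path, years, region = NA_character_) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt)
  stmts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  rows <- purrr::map(stmts, function(s) {
    parts <- strsplit(s, "[[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 1) return(NULL)
    hist <- parts[1]
    freq <- if (length(parts) >= 2) as.integer(parts[2]) else 1L
    if (grepl("[^01]", hist)) abort(sprintf("Invalid encounter string '%s' in %s.", hist, path))
    if (nchar(hist) != length(years)) {
      abort(sprintf("Encounter string '%s' does not span %d years.", hist, length(years)))
    }
    first <- regexpr("1", hist)[1]
    tibble(region = region, first_year = years[first],
           encounter_string = rep(hist, freq))
  })
  list_rbind(rows)
}

#' Write a simulated scenario to disk
#'
#' Emits `counts.csv`, `nests.csv` and `histories.csv` in the package's CSV
#' dialects, plus `truth.yaml` recording every generating parameter (the
#' preset, the drawn yearly rates and the latent trajectory).
#'
#' @param scenario An `ipm_scenario` from [simulate_region()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "ipm_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- scenario$data
  counts <- tibble(region = d$region, year = d$years, count = d$counts)
  readr::write_csv(counts, file.path(dir, "counts.csv"), na = "")
  readr::write_csv(d$nests, file.path(dir, "nests.csv"))
  readr::write_csv(d$histories, file.path(dir, "histories.csv"))
  p <- scenario$truth
  truth <- list(
    region = d$region,
    preset = unclass(scenario$preset),
    params = list(
      phi_ad = p$phi_ad, brood_size = p$brood_size,
      phi_egg_daily = p$phi_egg_daily, phi_chick_daily = p$phi_chick_daily,
      rho = p$rho, sigma_obs = p$sigma_obs, p_recapture = p$p_recapture,
      ep = p$ep, yp = p$yp
    ),
    latent = as.list(scenario$latent),
    extinct = scenario$extinct,
    seed = scenario$seed
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a scenario directory back into an `ipm_data` object
#'
#' @param dir Directory written by [write_scenario()] (or hand-assembled
#'   CSVs in the same dialect).
#' @return An [ipm_data()] object; if `truth.yaml` is present it is attached
#'   as the `truth` attribute.
#' @export
read_scenario <- function(dir) {
  counts <- read_counts_csv(file.path(dir, "counts.csv"))
  nests <- read_nests_csv(file.path(dir, "nests.csv"))
  histories <- read_histories_csv(file.path(dir, "histories.csv"))
  counts <- arrange(counts, .data$year)
  dat <- ipm_data(region = counts$region[1], years = counts$year,
                  counts = counts$count, nests = nests,
                  histories = histories)
  tf <- file.path(dir, "truth.yaml")
  if (file.exists(tf)) attr(dat, "truth") <- yaml::read_yaml(tf)
  dat
}
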