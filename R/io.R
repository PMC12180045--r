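#' Read a stratified intake table
#'
#' Reads a comma-separated UTF-8 table of stratum-level mean dietary
#' intakes keyed by country, year, age group, sex, education and residence,
#' optionally with an uncertainty-draw index. Any column not among the key
#' columns, \code{energy_basis} or \code{draw} is treated as a food-group
#' intake column. When \code{energy_basis} is absent it is filled from the
#' age-specific schedule via \code{\link{energy_basis_for_age_group}}.
#' Missing values are empty fields; sentinel codes are not interpreted.
#'
#' @param path Path to a CSV file with a single header row.
#' @return A data frame of typed stratum records with attribute
#'   \code{"component_cols"} naming the intake columns.
#' @export
read_stratum_table <- function(path) {
  tab <- read_csv_strict(path)
  mandatory <- c("country", "year", "age_group", "sex", "education",
                 "residence")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing))
    stop("stratum table missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  comp_cols <- setdiff(names(tab), c(mandatory, "energy_basis", "draw"))
  if (!length(comp_cols)) stop("stratum table has no intake columns")
  for (cc in comp_cols) {
    tab[[cc]] <- as.numeric(tab[[cc]])
    if (any(tab[[cc]] < 0, na.rm = TRUE))
      stop("negative intake in column '", cc, "'")
  }
  tab$year <- as.integer(tab$year)
  if (is.null(tab$energy_basis)) {
    tab$energy_basis <- energy_basis_for_age_group(tab$age_group)
  } else {
    tab$energy_basis <- as.numeric(tab$energy_basis)
    fill <- is.na(tab$energy_basis)
    if (any(fill))
      tab$energy_basis[fill] <- energy_basis_for_age_group(tab$age_group[fill])
    if (any(tab$energy_basis <= 0)) stop("energy_basis must be > 0")
  }
  if (!is.null(tab$draw)) tab$draw <- as.integer(tab$draw)
  attr(tab, "component_cols") <- comp_cols
  tab
}

#' Read a participant table
#'
#' Reads a comma-separated participant-level table with survey design
#' columns (\code{weight}, \code{stratum}, \code{psu}), two 24-hour diet
#' recalls per food group (\code{diet_<component>_r1} / \code{_r2}),
#' biomarkers, covariates and mortality follow-up. The two recalls are
#' averaged into a single \code{diet_<component>} intake; a record with
#' only one recall uses that recall alone and gets
#' \code{single_recall = TRUE}. Records missing the kidney markers needed
#' for staging get \code{staging_ineligible = TRUE} rather than being
#' dropped.
#'
#' @param path Path to a CSV file.
#' @return A data frame of participant records with attribute
#'   \code{"diet_cols"} naming the averaged intake columns.
#' @export
read_participant_table <- function(path) {
  tab <- read_csv_strict(path)
  mandatory <- c("id", "cycle", "weight", "stratum", "psu")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing))
    stop("participant table missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate participant id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  tab$weight <- as.numeric(tab$weight)
  if (any(is.na(tab$weight)) || any(tab$weight <= 0))
    stop("survey weights must be positive")
  r1 <- grep("^diet_.*_r1$", names(tab), value = TRUE)
  comps <- sub("^diet_(.*)_r1$", "\\1", r1)
  tab$single_recall <- FALSE
  for (comp in comps) {
    c1 <- tab[[paste0("diet_", comp, "_r1")]]
    c2 <- tab[[paste0("diet_", comp, "_r2")]]
    if (is.null(c2)) c2 <- rep(NA_real_, nrow(tab))
    c1 <- as.numeric(c1); c2 <- as.numeric(c2)
    tab[[paste0("diet_", comp)]] <- rowMeans(cbind(c1, c2), na.rm = TRUE)
    tab$single_recall <- tab$single_recall | xor(is.na(c1), is.na(c2))
  }
  kidney <- intersect(c("egfr", "acr"), names(tab))
  tab$staging_ineligible <- if (length(kidney) < 2) rep(TRUE, nrow(tab))
    else is.na(tab$egfr) | is.na(tab$acr)
  attr(tab, "diet_cols") <- paste0("diet_", comps)
  tab
}

#' Read a burden table
#'
#' Reads a comma-separated table of disease-burden values keyed by disease,
#' measure (incidence, prevalence, mortality, DALYs), year, age group and
#' sex. Keys must be unique and values nonnegative.
#'
#' @param path Path to a CSV file.
#' @return A data frame of burden records.
#' @export
read_burden_table <- function(path) {
  tab <- read_csv_strict(path)
  mandatory <- c("disease", "measure", "year", "age_group", "sex", "value")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing))
    stop("burden table missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  ok <- c("incidence", "prevalence", "mortality", "dalys")
  bad <- setdiff(unique(tab$measure), ok)
  if (length(bad))
    stop("unknown measure(s): ", paste(bad, collapse = ", "))
  tab$value <- as.numeric(tab$value)
  if (any(is.na(tab$value)) || any(tab$value < 0))
    stop("burden values must be nonnegative")
  key <- do.call(paste, c(tab[c("disease", "measure", "year", "age_group",
                                "sex")], sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate burden key(s)")
  tab$year <- as.integer(tab$year)
  tab
}

#' Write a table as CSV
#'
#' Comma-separated UTF-8 with one header row, empty fields for missing
#' values, full double precision (reads back to 1e-12 relative tolerance
#' or better).
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(tab, path) {
  num <- vapply(tab, is.numeric, TRUE) & !vapply(tab, is.integer, TRUE)
  out <- tab
  for (j in which(num))
    out[[j]] <- ifelse(is.na(tab[[j]]), "",
                       formatC(tab[[j]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  check.names = FALSE, fileEncoding = "UTF-8")
}
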