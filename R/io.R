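#' Read and write the pipeline's CSV dialects
#'
#' Plain-CSV interchange formats, one reader/writer pair per input kind.
#' Empty cells in the survey indicator columns are read as missing.
#'
#' * survey microdata: `region_id,age,sex,urbanicity,weight,asthma,copd,`
#'   `heart_disease,diabetes,less_than_hs`
#' * regions: `region_id,stratum,population,female_fraction,urban_fraction`
#'   (extra columns such as `name`/`province` pass through)
#' * supplied / normalized prevalence:
#'   `scope,stratum,factor,urbanicity,value[,provenance]`
#' * pregnancy inputs: `stratum,live_births,fetal_losses,induced_abortions,`
#'   `female_population`
#' * pollutant surface: `cell_id,region_id,pollutant,year,concentration`
#'   `[,area_weight]`
#'
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_survey_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "age", "sex", "urbanicity", "weight", "asthma",
            "copd", "heart_disease", "diabetes", "less_than_hs")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("survey CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' @rdname pipeline_io
#' @export
read_regions_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "stratum", "population", "female_fraction",
            "urban_fraction")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("regions CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' @rdname pipeline_io
#' @export
read_prevalence_csv <- function(path) {
  prevalence_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                   na.strings = c("NA", "")))
}

#' @rdname pipeline_io
#' @param table A [prevalence_table()].
#' @export
write_prevalence_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_pregnancy_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
read_surface_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "region_id", "pollutant", "year", "concentration")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("surface CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Write a synthetic world to a directory of CSV files
#'
#' Emits the same CSV dialects the pipeline reads (`regions.csv`,
#' `survey.csv`, `supplied_prevalence.csv`, `pregnancy_inputs.csv`,
#' `surface.csv`) plus `truth.csv` (the true prevalences) and
#' `truth_totals.csv` (true regional susceptibility percents) for
#' recovery tests.
#'
#' @param world A `synthetic_world` from [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(world$survey, file.path(dir, "survey.csv"),
                   row.names = FALSE, na = "")
  write_prevalence_csv(world$supplied,
                       file.path(dir, "supplied_prevalence.csv"))
  utils::write.csv(world$pregnancy_inputs,
                   file.path(dir, "pregnancy_inputs.csv"), row.names = FALSE)
  utils::write.csv(world$surface, file.path(dir, "surface.csv"),
                   row.names = FALSE)
  write_prevalence_csv(world$truth$prevalence, file.path(dir, "truth.csv"))
  utils::write.csv(world$truth$totals, file.path(dir, "truth_totals.csv"),
                   row.names = FALSE)
  invisible(dir)
}
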