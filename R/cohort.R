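# Cohort container and IO ----------------------------------------------------
#
# A cohort is a long-format table of pig-level hair cortisol concentration
# (HCC) observations: one row per pig, identified by (farm_id, batch_id,
# pig_id), with hcc in pg/mg. Identifiers are opaque strings; batch labels
# ("1"/"2") are categories, never quantities.

#' Assay detection floor of the cortisol ELISA, pg/mg of hair
#'
#' Concentrations below this limit are technically unreliable; the reader
#' accepts them with a warning rather than censoring, because field data sets
#' report minima well above it.
#' @keywords internal
HCC_DETECTION_LIMIT <- 0.13

#' Construct a validated pig cohort
#'
#' @param df data.frame with columns `farm_id`, `batch_id`, `pig_id`, `hcc`.
#' @param check validate invariants (positive finite HCC, unique pig keys,
#'   every (farm, batch) cell holding at least two pigs).
#' @param allow_nonpositive accept non-positive HCC values with a warning
#'   instead of an error. Used by the additive-Gaussian synthetic generator,
#'   whose noise model can cross zero; real assay data must be positive.
#' @return `hcc_cohort` object: the data.frame with normalized character
#'   identifiers and `farm_ids` / `batch_ids` attributes (sorted unique ids).
#' @export
new_cohort <- function(df, check = TRUE, allow_nonpositive = FALSE) {
  required <- c("farm_id", "batch_id", "pig_id", "hcc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$farm_id <- as.character(df$farm_id)
  df$batch_id <- as.character(df$batch_id)
  df$pig_id <- as.character(df$pig_id)
  if (!is.numeric(df$hcc)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$hcc))))
    stop("non-numeric hcc value(s) at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  df$hcc <- as.numeric(df$hcc)
  rownames(df) <- NULL

  if (check) {
    bad <- which(!is.finite(df$hcc))
    if (length(bad) > 0) {
      stop("non-finite hcc value(s) at row(s): ",
           paste(head(bad, 5L), collapse = ", "))
    }
    nonpos <- which(df$hcc <= 0)
    if (length(nonpos) > 0) {
      if (allow_nonpositive) {
        warning(length(nonpos), " non-positive hcc value(s) retained ",
                "(synthetic additive noise can cross zero)")
      } else {
        stop("non-positive hcc value(s) at row(s): ",
             paste(head(nonpos, 5L), collapse = ", "))
      }
    }
    below <- which(df$hcc > 0 & df$hcc < HCC_DETECTION_LIMIT)
    if (length(below) > 0) {
      warning(length(below), " hcc value(s) below the assay detection limit (",
              HCC_DETECTION_LIMIT, " pg/mg) at row(s): ",
              paste(head(below, 5L), collapse = ", "))
    }
    key <- paste(df$farm_id, df$batch_id, df$pig_id, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      stop("duplicate (farm_id, batch_id, pig_id) at row(s): ",
           paste(head(dup, 5L), collapse = ", "))
    }
    cell <- table(df$farm_id, df$batch_id)
    one <- which(cell == 1L, arr.ind = TRUE)
    if (nrow(one) > 0) {
      stop("cell with a single pig (SD undefined): farm ",
           rownames(cell)[one[1, 1]], ", batch ", colnames(cell)[one[1, 2]])
    }
  }

  structure(df,
            farm_ids = sort(unique(df$farm_id)),
            batch_ids = sort(unique(df$batch_id)),
            class = c("hcc_cohort", "data.frame"))
}

#' @export
print.hcc_cohort <- function(x, ...) {
  cat("HCC cohort: ", nrow(x), " pigs, ",
      length(attr(x, "farm_ids")), " farms, ",
      length(attr(x, "batch_ids")), " batches per farm (labels: ",
      paste(attr(x, "batch_ids"), collapse = ", "), ")\n", sep = "")
  cat("hcc (pg/mg): mean ", format(mean(x$hcc), digits = 4),
      ", sd ", format(sd(x$hcc), digits = 4),
      ", range [", format(min(x$hcc), digits = 4), ", ",
      format(max(x$hcc), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Read a pig-level HCC table from CSV
#'
#' @param path CSV file with a header row. Any extra columns are ignored.
#' @param schema named character vector mapping the canonical names
#'   `farm_id`, `batch_id`, `pig_id`, `hcc` to the column names actually used
#'   in the file.
#' @param delim field delimiter (default comma).
#' @inheritParams new_cohort
#' @return an [new_cohort()] object, row order preserved.
#' @export
read_cohort <- function(path,
                        schema = c(farm_id = "farm_id", batch_id = "batch_id",
                                   pig_id = "pig_id", hcc = "hcc_pg_mg"),
                        delim = ",", check = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  canonical <- c("farm_id", "batch_id", "pig_id", "hcc")
  full <- setNames(canonical, canonical)
  full[names(schema)] <- schema
  raw <- read.csv(path, sep = delim, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(full), names(raw))
  if (length(missing_cols) > 0) {
    stop("input lacks mapped column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(farm_id = raw[[full[["farm_id"]]]],
                   batch_id = raw[[full[["batch_id"]]]],
                   pig_id = raw[[full[["pig_id"]]]],
                   stringsAsFactors = FALSE)
  hcc_raw <- raw[[full[["hcc"]]]]
  hcc <- suppressWarnings(as.numeric(hcc_raw))
  bad <- which(is.na(hcc) & !is.na(hcc_raw))
  if (length(bad) > 0) {
    stop("non-numeric hcc value at row ", bad[1], ": '", hcc_raw[bad[1]], "'")
  }
  nonpos <- which(hcc <= 0)
  if (check && length(nonpos) > 0) {
    stop("non-positive hcc value at row ", nonpos[1], ": ", hcc[nonpos[1]])
  }
  df$hcc <- hcc
  new_cohort(df, check = check)
}

#' Write a cohort to the canonical CSV layout
#'
#' Columns `farm_id,batch_id,pig_id,hcc_pg_mg`; reading the file back with
#' [read_cohort()] reproduces the cohort exactly.
#' @param cohort an `hcc_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  out <- data.frame(farm_id = cohort$farm_id, batch_id = cohort$batch_id,
                    pig_id = cohort$pig_id,
                    hcc_pg_mg = format(cohort$hcc, digits = 15, trim = TRUE,
                                       scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-(farm, batch) descriptive summaries
#'
#' The batch is the unit of all downstream analyses: its mean and SD feed the
#' farm typology and the subsample study. SD uses the sample convention
#' (denominator n - 1) throughout.
#'
#' @param cohort an `hcc_cohort`.
#' @return data.frame of class `hcc_batch_summaries` with columns `farm_id`,
#'   `batch_id`, `n`, `mean`, `sd`, `cv`, ordered by (farm, batch).
#' @export
batch_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  key <- interaction(cohort$farm_id, cohort$batch_id, drop = TRUE, sep = "\r")
  n <- tapply(cohort$hcc, key, length)
  small <- which(n < 2L)
  if (length(small) > 0) {
    cell <- strsplit(names(n)[small[1]], "\r", fixed = TRUE)[[1]]
    stop("cell with fewer than 2 pigs: farm ", cell[1], ", batch ", cell[2])
  }
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  out <- data.frame(
    farm_id = vapply(parts, `[`, "", 1L),
    batch_id = vapply(parts, `[`, "", 2L),
    n = as.integer(n),
    mean = as.numeric(tapply(cohort$hcc, key, mean)),
    sd = as.numeric(tapply(cohort$hcc, key, sd)),
    stringsAsFactors = FALSE)
  out$cv <- out$sd / out$mean
  out <- out[order(out$farm_id, out$batch_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hcc_batch_summaries", "data.frame")
  out
}

# Farm metadata ---------------------------------------------------------------

#' Declared dictionary of the 17 farm-management and herd-health variables
#'
#' Categorical levels follow the modalities reported by farmers and
#' veterinarians: piglet procedures (yes/no), ages at social regrouping in
#' days (recorded as classes), regrouping criteria, housing types per rearing
#' period, minimal floor-space classes (m^2 per pig) and per-batch health
#' disorder flags.
#' @return named list mapping variable name to its allowed character levels.
#' @export
farm_metadata_dictionary <- function() {
  housing <- c("indoors", "indoors_outdoor_access", "outdoors")
  modality <- c("litter", "parity", "weight", "sex", "none")
  list(
    castration = c("yes", "no"),
    tail_docking = c("yes", "no"),
    teeth_grinding = c("yes", "no"),
    iron_administration = c("yes", "no"),
    early_socialization = c("yes", "no"),
    age_at_weaning = c("21", "28", "42"),
    age_regrouping_fattening = c("none", "63", "70", "77", "84"),
    regrouping_modality_suckling = modality,
    regrouping_modality_weaning = modality,
    regrouping_modality_fattening = modality,
    housing_suckling = housing,
    housing_post_weaning = housing,
    housing_fattening = housing,
    floor_space_post_weaning = c("<0.3", "0.3-0.4", ">0.4"),
    floor_space_fattening = c("<0.7", "0.7-0.9", "0.9-1.5", ">1.5"),
    health_disorder_batch1 = c("yes", "no"),
    health_disorder_batch2 = c("yes", "no")
  )
}

#' Read farm metadata (management practices and herd health)
#'
#' @param path CSV keyed by `farm_id`, one row per farm, holding any subset of
#'   the variables in [farm_metadata_dictionary()].
#' @param cohort optional `hcc_cohort`; farms present in the metadata but not
#'   in the cohort raise a warning, never an error.
#' @param dictionary category dictionary; values outside it are kept verbatim
#'   and listed in the validation report.
#' @return data.frame of class `hcc_farm_metadata` with a `validation`
#'   attribute: character vector of notes (missing variables, unknown levels,
#'   missing values), empty when the file is fully conforming.
#' @export
read_farm_metadata <- function(path, cohort = NULL,
                               dictionary = farm_metadata_dictionary()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  if (!"farm_id" %in% names(raw)) stop("metadata lacks a farm_id column")
  notes <- character(0)
  absent <- setdiff(names(dictionary), names(raw))
  for (v in absent) notes <- c(notes, paste0("missing variable: ", v))
  for (v in intersect(names(dictionary), names(raw))) {
    vals <- raw[[v]]
    vals[vals == ""] <- NA_character_
    raw[[v]] <- vals
    n_na <- sum(is.na(vals))
    if (n_na > 0) {
      notes <- c(notes, paste0("variable ", v, ": ", n_na, " missing value(s)"))
    }
    unknown <- setdiff(vals[!is.na(vals)], dictionary[[v]])
    for (u in unknown) {
      notes <- c(notes,
                 paste0("variable ", v, ": level '", u,
                        "' outside the declared dictionary (kept verbatim)"))
    }
  }
  if (!is.null(cohort)) {
    extra <- setdiff(raw$farm_id, attr(cohort, "farm_ids"))
    if (length(extra) > 0) {
      warning("metadata covers farm(s) absent from the cohort: ",
              paste(extra, collapse = ", "))
    }
  }
  structure(raw, validation = notes,
            class = c("hcc_farm_metadata", "data.frame"))
}
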