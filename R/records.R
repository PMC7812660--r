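# Occurrence-record data model: controlled vocabularies, CSV ingestion with
# per-row validation, and the recoding rules that map raw field annotations
# (Renvall decay stages, woody-debris measurements, stand descriptors) onto
# the analysis categories used downstream.

#' Controlled vocabularies for occurrence records
#'
#' Levels for the categorical fields of an occurrence record. Site-type
#' groups follow the Estonian forest-site classification by soil nutrient
#' and moisture regime (nine natural groups plus drained-peatland and
#' reclaimed stands); dataset identifiers distinguish historical data (I),
#' systematic surveys (IIa--IId) and casual collections (IIIa--IIIb).
#'
#' @name record_vocabulary
#' @keywords internal
NULL

dataset_levels <- c("I", "IIa", "IIb", "IIc", "IId", "IIIa", "IIIb")
decay_levels <- c("I", "II", "III", "IV", "V")
fraction_levels <- c("coarse_fallen", "snag_stump", "fwd", "live_tree")
tree_class_levels <- c("picea", "pinus", "deciduous")
age_class_levels <- c("old", "other", "early_successional")
special_habitat_levels <- c("park", "wooded_meadow", "bog_forest",
                            "heath_forest")
site_type_levels <- c("alvar", "dry_boreal", "heath", "boreal",
                      "meso_eutrophic", "eutrophic", "swamp", "bog",
                      "floodplain", "drained_peatland", "reclaimed")

# canonical column order of a validated record table
record_columns <- c("species_id", "dataset_id", "year", "plot_id",
                    "site_type_group", "tree_class", "age_class",
                    "host_taxon", "substrate_fraction", "decay_raw",
                    "special_habitat")

#' Schema configuration for reading occurrence records
#'
#' Describes how a CSV maps onto the canonical record fields and which
#' vocabularies to validate against. `columns` renames CSV headers to
#' canonical names (e.g. `list(species_id = "taxon")`); unlisted fields are
#' expected under their canonical names. `host_vocabulary = NULL` accepts
#' any non-empty host string; supplying a character vector turns unknown
#' hosts into row rejections (the aggregate-taxon granularity, e.g.
#' `"Betula spp."`, is fixed by this list).
#'
#' @param columns named list mapping canonical field -> CSV column name.
#' @param current_year latest acceptable record year.
#' @param site_type_groups valid site-type group tokens.
#' @param host_vocabulary optional controlled list of host taxa.
#' @return a list of class `record_schema`.
#' @export
record_schema <- function(columns = list(), current_year = 2019,
                          site_type_groups = site_type_levels,
                          host_vocabulary = NULL) {
  stopifnot(is.list(columns), current_year >= 1800)
  bad <- setdiff(names(columns), record_columns)
  if (length(bad))
    stop("unknown canonical field(s) in column mapping: ",
         paste(bad, collapse = ", "))
  structure(list(columns = columns, current_year = current_year,
                 site_type_groups = site_type_groups,
                 host_vocabulary = host_vocabulary),
            class = "record_schema")
}

blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  x
}

#' Read and validate occurrence records from CSV
#'
#' Every row either becomes a validated record or is logged as a rejection
#' with its row number and a reason; nothing is silently coerced. A missing
#' required column (`species_id`, `dataset_id`, `year`) is a hard failure.
#'
#' Validation rules: `dataset_id`, `site_type_group`, `tree_class`,
#' `age_class`, `substrate_fraction`, `decay_raw` and `special_habitat`
#' must be known vocabulary tokens when present; `year` must be an integer
#' in `[1800, current_year]`; live trees carry no decay stage.
#'
#' @param file path or connection to a CSV with a header row.
#' @param schema a [record_schema()].
#' @return list of class `record_set`: `records` (canonical data frame),
#'   `n_accepted`, `n_rejected`, `rejections` (data frame with `row`,
#'   `reason`).
#' @export
read_records <- function(file, schema = record_schema()) {
  stopifnot(inherits(schema, "record_schema"))
  raw <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  # apply column mapping
  for (canon in names(schema$columns)) {
    src <- schema$columns[[canon]]
    if (!src %in% names(raw))
      stop("mapped column '", src, "' (for ", canon, ") not found in CSV")
    names(raw)[names(raw) == src] <- canon
  }
  required <- c("species_id", "dataset_id", "year")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("required column(s) missing: ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(record_columns, names(raw)))
    raw[[col]] <- rep(NA_character_, nrow(raw))
  raw <- raw[record_columns]
  n <- nrow(raw)
  if (n == 0L)
    return(structure(list(records = empty_records(), n_accepted = 0L,
                          n_rejected = 0L,
                          rejections = data.frame(row = integer(),
                                                  reason = character())),
                     class = "record_set"))
  for (col in record_columns) raw[[col]] <- blank_to_na(raw[[col]])

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason <<- ifelse(bad & is.na(reason), why, reason)

  flag(is.na(raw$species_id), "missing species_id")
  flag(!is.na(raw$dataset_id) & !raw$dataset_id %in% dataset_levels,
       "unknown dataset_id")
  flag(is.na(raw$dataset_id), "missing dataset_id")
  yr <- suppressWarnings(as.integer(raw$year))
  flag(is.na(yr), "missing or non-integer year")
  flag(!is.na(yr) & (yr < 1800 | yr > schema$current_year),
       "year out of range")
  flag(!is.na(raw$site_type_group) &
         !raw$site_type_group %in% schema$site_type_groups,
       "unknown site-type group")
  flag(!is.na(raw$tree_class) & !raw$tree_class %in% tree_class_levels,
       "unknown tree class")
  flag(!is.na(raw$age_class) & !raw$age_class %in% age_class_levels,
       "unknown age class")
  flag(!is.na(raw$substrate_fraction) &
         !raw$substrate_fraction %in% fraction_levels,
       "unknown substrate fraction")
  flag(!is.na(raw$decay_raw) & !raw$decay_raw %in% decay_levels,
       "unknown decay stage")
  flag(!is.na(raw$special_habitat) &
         !raw$special_habitat %in% special_habitat_levels,
       "unknown special habitat")
  if (!is.null(schema$host_vocabulary))
    flag(!is.na(raw$host_taxon) &
           !raw$host_taxon %in% schema$host_vocabulary,
         "unknown host taxon")
  # live trees have no decay stage by definition
  flag(!is.na(raw$substrate_fraction) &
         raw$substrate_fraction == "live_tree" & !is.na(raw$decay_raw),
       "decay stage given for live tree")

  ok <- is.na(reason)
  records <- raw[ok, , drop = FALSE]
  records$year <- yr[ok]
  rownames(records) <- NULL
  rejections <- data.frame(row = which(!ok), reason = reason[!ok],
                           stringsAsFactors = FALSE)
  structure(list(records = records, n_accepted = sum(ok),
                 n_rejected = sum(!ok), rejections = rejections),
            class = "record_set")
}

empty_records <- function() {
  df <- as.data.frame(stats::setNames(
    replicate(length(record_columns), character(0), simplify = FALSE),
    record_columns), stringsAsFactors = FALSE)
  df$year <- integer(0)
  df[record_columns]
}

#' @export
print.record_set <- function(x, ...) {
  cat("Occurrence record set: ", x$n_accepted, " accepted, ",
      x$n_rejected, " rejected\n", sep = "")
  if (x$n_rejected > 0) {
    tab <- sort(table(x$rejections$reason), decreasing = TRUE)
    for (i in seq_along(tab))
      cat("  - ", names(tab)[i], ": ", tab[[i]], "\n", sep = "")
  }
  invisible(x)
}

#' Write occurrence records to CSV
#'
#' Writes the canonical column layout produced by [read_records()]; reading
#' the file back yields an identical record table (round-trip property).
#'
#' @param records canonical record data frame.
#' @param file output path.
#' @export
write_records <- function(records, file) {
  stopifnot(all(record_columns %in% names(records)))
  utils::write.csv(records[record_columns], file, row.names = FALSE,
                   na = "")
  invisible(file)
}

#' Write a rejection log
#'
#' @param record_set result of [read_records()].
#' @param file output path for the plain-text log.
#' @export
write_rejection_log <- function(record_set, file) {
  stopifnot(inherits(record_set, "record_set"))
  lines <- sprintf("row %d: %s", record_set$rejections$row,
                   record_set$rejections$reason)
  writeLines(c(sprintf("# %d accepted, %d rejected",
                       record_set$n_accepted, record_set$n_rejected), lines),
             file)
  invisible(file)
}

#' Recode Renvall decay stages to a three-class scale
#'
#' Stages I--II become `early`, III `medium`, IV--V `late`. Free-text
#' annotations of the wood as extremely decayed (without a measured stage)
#' are mapped to `late` via `extremely_decayed`. Missing stages propagate
#' as `NA` -- never guessed.
#'
#' @param decay_raw character vector of stages `"I"`..`"V"` (or `NA`).
#' @param extremely_decayed logical vector; `TRUE` forces `late` when the
#'   stage itself is missing.
#' @return character vector in `{"early","medium","late"}` or `NA`.
#' @export
recode_decay <- function(decay_raw, extremely_decayed = FALSE) {
  decay_raw <- as.character(decay_raw)
  known <- is.na(decay_raw) | decay_raw %in% decay_levels
  if (!all(known))
    stop("unknown decay stage: ",
         paste(unique(decay_raw[!known]), collapse = ", "))
  out <- c(I = "early", II = "early", III = "medium",
           IV = "late", V = "late")[decay_raw]
  out <- unname(out)
  extremely_decayed <- rep_len(extremely_decayed, length(out))
  out[is.na(out) & extremely_decayed] <- "late"
  out
}

#' Classify a woody-substrate item into a fraction
#'
#' Live trees form their own class; any dead item under 10 cm diameter at
#' the basidiome location is fine woody debris (FWD) whether fallen or
#' standing; dead standing stems and stumps of at least 10 cm are snags or
#' stumps; the remaining fallen items are coarse fallen wood. The 10 cm
#' boundary itself goes to the coarse classes, since FWD is strictly
#' "under 10 cm".
#'
#' @param diameter_cm diameter at the basidiome location (cm).
#' @param standing is the item standing dead wood?
#' @param live is it a live tree?
#' @param stump is it a stump?
#' @return character vector of substrate fractions.
#' @export
classify_substrate_fraction <- function(diameter_cm, standing = FALSE,
                                        live = FALSE, stump = FALSE) {
  if (any(!is.na(diameter_cm) & diameter_cm < 0))
    stop("negative diameter")
  n <- max(length(diameter_cm), length(standing), length(live),
           length(stump))
  diameter_cm <- rep_len(diameter_cm, n)
  standing <- rep_len(standing, n)
  live <- rep_len(live, n)
  stump <- rep_len(stump, n)
  out <- ifelse(live, "live_tree",
         ifelse(diameter_cm < 10, "fwd",
         ifelse(stump | standing, "snag_stump", "coarse_fallen")))
  out
}

#' Build habitat keys from stand descriptors
#'
#' A habitat type is either the triple site-type group x tree-species
#' composition x stand-age class (joined with `"|"`), or a pooled special
#' habitat (park, wooded meadow, bog forest, heath forest) represented by
#' a single label. Exactly one of the two forms must be supplied per
#' record; a natural stand missing part of its triple is an error, as is a
#' record carrying both forms.
#'
#' @param site_type_group,tree_class,age_class the stand triple.
#' @param special_habitat pooled special-habitat label.
#' @return character vector of habitat keys.
#' @seealso [habitat_keys()] for the record-table wrapper.
#' @export
habitat_key <- function(site_type_group = NA, tree_class = NA,
                        age_class = NA, special_habitat = NA) {
  n <- max(length(site_type_group), length(tree_class), length(age_class),
           length(special_habitat))
  site_type_group <- rep_len(as.character(site_type_group), n)
  tree_class <- rep_len(as.character(tree_class), n)
  age_class <- rep_len(as.character(age_class), n)
  special_habitat <- rep_len(as.character(special_habitat), n)
  has_special <- !is.na(special_habitat)
  has_any_triple <- !is.na(site_type_group) | !is.na(tree_class) |
    !is.na(age_class)
  if (any(has_special & has_any_triple))
    stop("record has both a stand triple and a special habitat")
  triple_complete <- !is.na(site_type_group) & !is.na(tree_class) &
    !is.na(age_class)
  if (any(!has_special & !triple_complete))
    stop("incomplete stand triple without a special habitat (rows ",
         paste(utils::head(which(!has_special & !triple_complete), 5),
               collapse = ", "), ")")
  ifelse(has_special, special_habitat,
         paste(site_type_group, tree_class, age_class, sep = "|"))
}

#' @rdname habitat_key
#' @param records canonical record data frame.
#' @export
habitat_keys <- function(records) {
  habitat_key(records$site_type_group, records$tree_class,
              records$age_class, records$special_habitat)
}

#' Is a habitat key an early-successional stand?
#'
#' Early-successional (post clear-cut) stands are flagged so they can be
#' excluded from assemblage analyses restricted to stands over 20 years.
#'
#' @param key habitat key vector.
#' @export
is_early_successional <- function(key) {
  grepl("\\|early_successional$", key)
}

#' Band a record count for reporting
#'
#' Counts strictly above the threshold are censored to `">threshold"`, as
#' in checklist tables that print `">100"` for abundant species; counts at
#' or below it are reported exactly.
#'
#' @param n non-negative integer vector.
#' @param threshold censoring threshold (default 100).
#' @return character vector.
#' @export
band_count <- function(n, threshold = 100) {
  stopifnot(all(n >= 0), threshold >= 1)
  ifelse(n > threshold, paste0(">", threshold), as.character(n))
}
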