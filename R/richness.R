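# Species-pool accounting: frequency tallies, the Chao1 richness estimator,
# checklist-reconciliation ledgers, the regional-extinction rule, and
# turnover between checklist snapshots.

#' Tally species record frequencies
#'
#' Counts records per species and derives the frequency summary feeding
#' the Chao estimator: observed richness, singletons (species recorded
#' exactly once) and doubletons (exactly twice).
#'
#' @param records canonical record data frame, or a character vector of
#'   species identifiers (one element per record).
#' @return list of class `richness_summary` with `S_obs`, `f1`, `f2` and
#'   the per-species `counts` (named integer vector, sorted by name).
#' @export
tally_frequencies <- function(records) {
  species <- if (is.data.frame(records)) records$species_id else records
  species <- species[!is.na(species)]
  if (length(species)) {
    counts <- table(species)
    counts <- stats::setNames(as.integer(counts), names(counts))
    counts <- counts[order(names(counts))]
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  structure(list(S_obs = length(counts),
                 f1 = sum(counts == 1L),
                 f2 = sum(counts == 2L),
                 counts = counts,
                 S_chao = NA_real_,
                 estimator_variant = NA_character_),
            class = "richness_summary")
}

#' Chao1 species-richness estimate
#'
#' Nonparametric lower-bound estimate of total richness from singletons and
#' doubletons. The classic form is `S_obs + f1^2 / (2 f2)`; when there are
#' no doubletons it falls back to the bias-corrected term
#' `S_obs + f1 (f1 - 1) / 2`. The bias-corrected variant is
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`. The raw (unrounded) estimate is
#' returned; round only in reports.
#'
#' @param S_obs observed species count.
#' @param f1 number of singletons.
#' @param f2 number of doubletons.
#' @param variant `"classic"` (default) or `"bias_corrected"`.
#' @return the richness estimate (numeric scalar, `>= S_obs`).
#' @examples
#' chao1(221, 17, 6)   # 245.08, reported as 245
#' @export
chao1 <- function(S_obs, f1, f2, variant = c("classic", "bias_corrected")) {
  variant <- match.arg(variant)
  if (S_obs < 0 || f1 < 0 || f2 < 0) stop("inputs must be non-negative")
  if (f1 + f2 > S_obs) stop("f1 + f2 cannot exceed S_obs")
  if (variant == "classic") {
    if (f2 > 0) S_obs + f1^2 / (2 * f2)
    else S_obs + f1 * (f1 - 1) / 2
  } else {
    S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' Add a Chao estimate to a richness summary
#'
#' @param summary a [tally_frequencies()] result.
#' @param variant passed to [chao1()].
#' @return the summary with `S_chao` and `estimator_variant` filled in.
#' @export
estimate_richness <- function(summary, variant = "classic") {
  stopifnot(inherits(summary, "richness_summary"))
  summary$S_chao <- chao1(summary$S_obs, summary$f1, summary$f2, variant)
  summary$estimator_variant <- variant
  summary
}

#' @export
print.richness_summary <- function(x, ...) {
  cat("Richness summary: S_obs = ", x$S_obs, ", singletons f1 = ", x$f1,
      ", doubletons f2 = ", x$f2, "\n", sep = "")
  if (!is.na(x$S_chao))
    cat("  Chao (", x$estimator_variant, ") estimate: ",
        round(x$S_chao), " (raw ", format(x$S_chao, digits = 5), ")\n",
        sep = "")
  invisible(x)
}

ledger_actions <- c("accept", "merge_into", "exclude_unsupported",
                    "exclude_misidentified", "add_new", "split_from")

#' Apply a checklist-reconciliation ledger
#'
#' Reconciles a historical checklist against current taxonomy: taxa merged
#' into others or excluded (unsupported or misidentified material) are
#' removed, new or split-off taxa are added, and every change is traceable
#' to one ledger entry. The name count obeys
#' `|accepted| = |base| - merges - exclusions + additions`.
#'
#' A ledger is a data frame with columns `name`, `action` (one of
#' `accept`, `merge_into`, `exclude_unsupported`, `exclude_misidentified`,
#' `add_new`, `split_from`) and optional `target` (merge target or split
#' source) and `note`. With `strict = TRUE` (default) an entry referencing
#' an unknown name, or adding an existing one, is an error; with
#' `strict = FALSE` such entries become logged no-ops, which makes
#' application idempotent.
#'
#' @param base_names character vector of unique checklist names.
#' @param ledger ledger data frame (see Details).
#' @param strict error on inapplicable entries (default) instead of
#'   skipping them.
#' @return list with `accepted` (sorted name vector) and `report` (one row
#'   per ledger entry: `name`, `action`, `applied`, `note`).
#' @export
apply_ledger <- function(base_names, ledger, strict = TRUE) {
  if (anyDuplicated(base_names)) stop("base_names must be unique")
  if (is.null(ledger) || nrow(ledger) == 0)
    return(list(accepted = sort(base_names),
                report = data.frame(name = character(),
                                    action = character(),
                                    applied = logical(),
                                    note = character())))
  stopifnot(all(c("name", "action") %in% names(ledger)))
  bad <- setdiff(ledger$action, ledger_actions)
  if (length(bad)) stop("unknown ledger action(s): ",
                        paste(unique(bad), collapse = ", "))
  current <- base_names
  applied <- logical(nrow(ledger))
  note <- rep("", nrow(ledger))
  removing <- c("merge_into", "exclude_unsupported", "exclude_misidentified")
  for (i in seq_len(nrow(ledger))) {
    nm <- ledger$name[i]
    act <- ledger$action[i]
    if (act %in% c("accept")) {
      applied[i] <- nm %in% current
      if (!applied[i] && strict) stop("ledger references unknown name: ", nm)
      next
    }
    if (act %in% removing) {
      if (!nm %in% current) {
        if (strict) stop("ledger references unknown name: ", nm)
        note[i] <- "already absent"
        next
      }
      current <- setdiff(current, nm)
      applied[i] <- TRUE
    } else {  # add_new / split_from
      if (nm %in% current) {
        if (strict) stop("cannot add existing name: ", nm)
        note[i] <- "already present"
        next
      }
      current <- c(current, nm)
      applied[i] <- TRUE
    }
  }
  # merge targets must exist among accepted names after application
  if ("target" %in% names(ledger)) {
    mt <- ledger$target[ledger$action == "merge_into" & applied]
    mt <- mt[!is.na(mt) & nzchar(mt)]
    missing <- setdiff(mt, current)
    if (length(missing))
      stop("merge target(s) not among accepted names: ",
           paste(missing, collapse = ", "))
  }
  list(accepted = sort(current),
       report = data.frame(name = ledger$name, action = ledger$action,
                           applied = applied, note = note,
                           stringsAsFactors = FALSE))
}

#' Read a reconciliation ledger from CSV
#'
#' @param file CSV with columns `name`, `action` and optional `target`,
#'   `note`.
#' @export
read_ledger <- function(file) {
  led <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("name", "action") %in% names(led)))
  led
}

#' Flag species as regionally extinct
#'
#' A species is flagged when the gap between its last record and the
#' current year strictly exceeds the horizon -- the "no records for more
#' than 50 years" checklist rule.
#'
#' @param last_year named numeric vector: last record year per species.
#' @param current_year reference year.
#' @param horizon gap in years (default 50, strict inequality).
#' @return character vector of flagged species names.
#' @export
flag_regionally_extinct <- function(last_year, current_year, horizon = 50) {
  stopifnot(all(last_year <= current_year))
  names(last_year)[current_year - last_year > horizon]
}

#' Species with no record after a cutoff year
#'
#' @param records canonical record data frame (needs `species_id`, `year`).
#' @param cutoff_year species whose latest record year is `<= cutoff_year`
#'   are returned.
#' @return sorted character vector of species names.
#' @export
records_since <- function(records, cutoff_year) {
  last <- tapply(records$year, records$species_id, max)
  sort(names(last)[last <= cutoff_year])
}

#' Turnover between two checklist snapshots
#'
#' Losses are names present only in the old list, gains only in the new;
#' the turnover percentage is `100 * (|losses| + |gains|) / (2 * S_ref)`
#' with `S_ref` the old-list size -- i.e. the average of the loss and gain
#' rates. The raw loss/gain lists are kept so alternative denominators can
#' be recomputed.
#'
#' @param old_accepted,new_accepted character vectors of unique names.
#' @return list of class `turnover_report`: `losses`, `gains`, `S_ref`,
#'   `turnover_pct`.
#' @export
turnover <- function(old_accepted, new_accepted) {
  if (anyDuplicated(old_accepted) || anyDuplicated(new_accepted))
    stop("name lists must be unique")
  losses <- sort(setdiff(old_accepted, new_accepted))
  gains <- sort(setdiff(new_accepted, old_accepted))
  S_ref <- length(old_accepted)
  structure(list(losses = losses, gains = gains, S_ref = S_ref,
                 turnover_pct = 100 * (length(losses) + length(gains)) /
                   (2 * S_ref)),
            class = "turnover_report")
}

#' @export
print.turnover_report <- function(x, ...) {
  cat("Checklist turnover: ", length(x$losses), " losses, ",
      length(x$gains), " gains against a reference pool of ", x$S_ref,
      " -> ", format(x$turnover_pct, digits = 3), "%\n", sep = "")
  invisible(x)
}
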