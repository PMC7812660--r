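# End-to-end orchestration: a single validated config drives the stages
# records -> checklist -> substrate -> assemblage, with seeded
# reproducibility, one structured log line per stage, and a manifest of
# every output file with content hashes (identical config + seeds give
# identical hashes).

known_config_keys <- list(
  top = c("synthetic", "input", "stages", "parameters"),
  synthetic = c("S", "theta", "specialist_fraction", "habitat_sd",
                "tree_affinity", "pool_seed", "survey_seed",
                "plots_per_habitat", "per_species_cap", "per_plot_cap",
                "casual_effort"),
  input = c("records", "ledger"),
  stages = c("checklist", "substrate", "assemblage"),
  parameters = c("chao_variant", "current_year", "extinction_horizon",
                 "band_threshold", "min_systematic_records",
                 "nmds_starts", "nmds_seed", "mrpp_B", "mrpp_seed")
)

check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Load and validate a pipeline configuration
#'
#' A config (YAML file or list) names either a `synthetic` generation
#' block or an `input` block with a records CSV, optional stage toggles,
#' and parameters. Unknown keys anywhere are rejected, and every random
#' stage must carry an explicit seed: `pool_seed`/`survey_seed` for the
#' synthetic block, `nmds_seed`/`mrpp_seed` when the assemblage stage is
#' enabled.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  check_keys(config, known_config_keys$top, "top level")
  has_syn <- !is.null(config$synthetic)
  has_in <- !is.null(config$input)
  if (has_syn == has_in)
    stop("config must name exactly one of 'synthetic' or 'input'")
  if (has_syn) {
    check_keys(config$synthetic, known_config_keys$synthetic, "synthetic")
    if (is.null(config$synthetic$pool_seed) ||
        is.null(config$synthetic$survey_seed))
      stop("synthetic block requires explicit pool_seed and survey_seed")
  } else {
    check_keys(config$input, known_config_keys$input, "input")
    if (is.null(config$input$records))
      stop("input block requires a records path")
  }
  config$stages <- utils::modifyList(
    list(checklist = TRUE, substrate = TRUE, assemblage = TRUE),
    if (is.null(config$stages)) list() else config$stages)
  check_keys(config$stages, known_config_keys$stages, "stages")
  config$parameters <- utils::modifyList(
    list(chao_variant = "classic", current_year = 2019,
         extinction_horizon = 50, band_threshold = 100,
         min_systematic_records = 25, nmds_starts = 10, mrpp_B = 999),
    if (is.null(config$parameters)) list() else config$parameters)
  check_keys(config$parameters, known_config_keys$parameters, "parameters")
  if (isTRUE(config$stages$assemblage) &&
      (is.null(config$parameters$nmds_seed) ||
         is.null(config$parameters$mrpp_seed)))
    stop("assemblage stage requires explicit nmds_seed and mrpp_seed")
  structure(config, class = c("pipeline_config", "list"))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full analysis pipeline
#'
#' Executes the stages records -> checklist -> substrate -> assemblage
#' from a validated config, writing every output under `out_dir` and a
#' `manifest.json` listing each file with its MD5 hash. Identical config
#' and seeds produce byte-identical outputs. On a stage failure the
#' partial outputs are kept, the manifest carries a failure marker, and
#' the returned status is non-zero.
#'
#' @param config a [pipeline_config()], a list, or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return list with `status` (0 on success), `manifest` (data frame of
#'   file names and hashes) and `outputs` (named paths), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name) outputs[[name]] <<- file.path(out_dir, name)
  status <- 0L
  failed_stage <- NULL
  par <- config$parameters

  result <- tryCatch({
    # --- records stage -------------------------------------------------
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      pool <- sample_species_pool(
        S = syn$S %||% 200, theta = syn$theta %||% 0.99999,
        specialist_fraction = syn$specialist_fraction %||% 0.15,
        habitat_sd = syn$habitat_sd %||% 0.75,
        tree_affinity = syn$tree_affinity %||% 3, seed = syn$pool_seed)
      design <- survey_design(
        plots_per_habitat = syn$plots_per_habitat %||% 2,
        per_species_cap = syn$per_species_cap %||% 10,
        per_plot_cap = syn$per_plot_cap %||% 150,
        casual_effort = syn$casual_effort %||% 500)
      records <- simulate_survey(pool, design, seed = syn$survey_seed)
      write_records(records, emit("records.csv"))
      write_json_file(ground_truth(pool), emit("truth.json"))
      stage_log("records", "simulated ", nrow(records), " records of ",
                length(unique(records$species_id)), " species")
    } else {
      rs <- read_records(config$input$records)
      records <- rs$records
      write_records(records, emit("records.csv"))
      write_rejection_log(rs, emit("rejections.log"))
      stage_log("records", "read ", rs$n_accepted, " records (",
                rs$n_rejected, " rejected)")
    }

    # --- checklist stage ----------------------------------------------
    if (isTRUE(config$stages$checklist)) {
      freq <- tally_frequencies(records)
      freq <- estimate_richness(freq, par$chao_variant)
      utils::write.csv(data.frame(species_id = names(freq$counts),
                                  n_records = unname(freq$counts)),
                       emit("frequencies.csv"), row.names = FALSE)
      extinct <- flag_regionally_extinct(
        tapply(records$year, records$species_id, max),
        par$current_year, par$extinction_horizon)
      richness <- list(S_obs = freq$S_obs, f1 = freq$f1, f2 = freq$f2,
                       S_chao = freq$S_chao,
                       estimator_variant = freq$estimator_variant,
                       regionally_extinct = as.list(sort(extinct)))
      if (!is.null(config$input$ledger)) {
        led <- read_ledger(config$input$ledger)
        app <- apply_ledger(names(freq$counts), led)
        writeLines(app$accepted, emit("accepted_names.txt"))
        richness$n_accepted_after_ledger <- length(app$accepted)
      }
      write_json_file(richness, emit("richness.json"))
      stage_log("checklist", "S_obs = ", freq$S_obs, ", f1 = ", freq$f1,
                ", f2 = ", freq$f2, ", Chao = ", round(freq$S_chao, 2))
    }

    # --- substrate stage ----------------------------------------------
    if (isTRUE(config$stages$substrate)) {
      host_tab <- build_association_table(records, "host_taxon")
      utils::write.csv(as.data.frame(host_tab$counts),
                       emit("association_host.csv"))
      cls <- classify_associations(host_tab)
      utils::write.csv(cls, emit("classification_host.csv"),
                       row.names = FALSE)
      utils::write.csv(host_range_summary(host_tab),
                       emit("host_range.csv"), row.names = FALSE)
      # category summary in the checklist-table shape: species counts per
      # host with regular/specialist sub-counts, record counts banded
      summ <- data.frame(
        category = colnames(host_tab$counts),
        n_species = colSums(host_tab$counts > 0),
        n_regular = as.integer(tapply(cls$regular, cls$category, sum)),
        n_specialist = as.integer(tapply(cls$specialist, cls$category, sum)),
        n_records = band_count(host_tab$category_totals,
                               par$band_threshold))
      utils::write.csv(summ, emit("substrate_summary.csv"),
                       row.names = FALSE)
      pa <- host_similarity_input(host_tab)
      if (sum(colSums(pa) > 0) >= 3) {
        dend <- suppressWarnings(cluster_hosts(pa))
        write_newick(dend, emit("host_dendrogram.nwk"))
      }
      stage_log("substrate", nrow(host_tab$counts), " species x ",
                ncol(host_tab$counts), " hosts; ",
                sum(cls$specialist), " specialist associations")
    }

    # --- assemblage stage ---------------------------------------------
    if (isTRUE(config$stages$assemblage)) {
      hm <- build_habitat_matrix(records)
      hm012 <- three_class_recode(hm)
      filt <- filter_single_habitat_species(hm012)
      assemblages <- t(filt$matrix)  # habitats x species
      assemblages <- assemblages[rowSums(assemblages) > 0, , drop = FALSE]
      D <- bray_curtis(assemblages)
      ord <- nmds(D, k = 2, n_starts = par$nmds_starts,
                  seed = par$nmds_seed)
      utils::write.csv(as.data.frame(ord$points),
                       emit("nmds_coordinates.csv"))
      write_json_file(list(stress = ord$stress, n_starts = ord$n_starts,
                           best_start = ord$best_start,
                           converged = ord$converged, seed = ord$seed,
                           n_sites = nrow(ord$points),
                           n_species = ncol(assemblages),
                           n_species_removed = length(filt$removed)),
                      emit("nmds_meta.json"))
      # MRPP per environmental variable parsed from the habitat keys
      env <- do.call(rbind, strsplit(rownames(assemblages), "|",
                                     fixed = TRUE))
      env <- as.data.frame(env, stringsAsFactors = FALSE)
      names(env) <- c("site_type_group", "tree_class", "age_class")
      mrpp_out <- list()
      for (v in names(env)) {
        g <- env[[v]]
        keep <- g %in% names(which(table(g) >= 2))
        if (length(unique(g[keep])) < 2) next
        Dv <- stats::as.dist(as.matrix(D)[keep, keep])
        mrpp_out[[v]] <- mrpp(Dv, g[keep], B = par$mrpp_B,
                              seed = par$mrpp_seed)
      }
      m_tests <- length(mrpp_out)
      mrpp_json <- lapply(mrpp_out, function(r)
        list(delta_obs = r$delta_obs, expected_delta = r$expected_delta,
             A = r$A, p_raw = r$p_raw,
             p_adjusted = bonferroni(r$p_raw, m_tests),
             B = r$B, exhaustive = r$exhaustive))
      write_json_file(mrpp_json, emit("mrpp.json"))
      # habitat set overlaps by site-type group
      lists <- split(colnames(assemblages)[col(assemblages)[assemblages > 0]],
                     env$site_type_group[row(assemblages)[assemblages > 0]])
      lists <- lapply(lists, unique)
      combos <- c(lapply(names(lists), identity),
                  if (length(lists) >= 2) list(names(lists)))
      ov <- overlap_counts(lists, combos)
      utils::write.csv(ov, emit("overlap.csv"), row.names = FALSE)
      stage_log("assemblage", nrow(assemblages), " assemblages, stress ",
                round(ord$stress, 3), ", ", m_tests, " MRPP tests")
    }

    # --- species table -------------------------------------------------
    utils::write.csv(
      export_species_table(records,
                           band_threshold = par$band_threshold,
                           min_systematic = par$min_systematic_records),
      emit("species_table.csv"), row.names = FALSE)
    NULL
  }, error = function(e) e)

  if (inherits(result, "error")) {
    status <- 1L
    failed_stage <- conditionMessage(result)
    warning("pipeline failed: ", failed_stage, call. = FALSE)
  }
  files <- sort(basename(unlist(outputs)))
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  write_json_file(list(status = status, failure = failed_stage,
                       files = manifest),
                  file.path(out_dir, "manifest.json"))
  invisible(list(status = status, manifest = manifest, outputs = outputs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round_half_up <- function(x) floor(x + 0.5)

pct_block <- function(values, levels) {
  known <- values[!is.na(values)]
  if (!length(known)) return(stats::setNames(rep(NA_real_, length(levels)),
                                             levels))
  tab <- table(factor(known, levels = levels))
  stats::setNames(round_half_up(100 * as.vector(tab) / length(known)),
                  levels)
}

#' Export a checklist-style species table
#'
#' One row per species: record counts per source group (I historical, II
#' systematic, III casual), banded above `band_threshold`; and for species
#' with at least `min_systematic` systematic records, integer-percentage
#' breakdowns of the systematic sample by stand-age class, substrate
#' fraction and decay class (half-up rounding, so each block sums to 100
#' within rounding).
#'
#' @param records canonical record data frame.
#' @param band_threshold censoring threshold for count columns.
#' @param min_systematic minimum systematic records for percentage blocks.
#' @return data frame, one row per species (sorted by name).
#' @export
export_species_table <- function(records, band_threshold = 100,
                                 min_systematic = 25) {
  source_group <- ifelse(records$dataset_id == "I", "I",
                  ifelse(records$dataset_id %in% c("IIa", "IIb", "IIc",
                                                   "IId"), "II", "III"))
  species <- sort(unique(records$species_id))
  rows <- lapply(species, function(sp) {
    rec <- records[records$species_id == sp, , drop = FALSE]
    grp <- source_group[records$species_id == sp]
    counts <- vapply(c("I", "II", "III"), function(g) sum(grp == g),
                     integer(1))
    sys <- rec[grp == "II", , drop = FALSE]
    row <- data.frame(species_id = sp,
                      n_I = band_count(counts[["I"]], band_threshold),
                      n_II = band_count(counts[["II"]], band_threshold),
                      n_III = band_count(counts[["III"]], band_threshold),
                      stringsAsFactors = FALSE)
    blocks <- if (nrow(sys) >= min_systematic) {
      c(stats::setNames(pct_block(sys$age_class, age_class_levels),
                        paste0("pct_age_", age_class_levels)),
        stats::setNames(pct_block(sys$substrate_fraction, fraction_levels),
                        paste0("pct_frac_", fraction_levels)),
        stats::setNames(pct_block(recode_decay(sys$decay_raw),
                                  c("early", "medium", "late")),
                        paste0("pct_decay_", c("early", "medium", "late"))))
    } else {
      nm <- c(paste0("pct_age_", age_class_levels),
              paste0("pct_frac_", fraction_levels),
              paste0("pct_decay_", c("early", "medium", "late")))
      stats::setNames(rep(NA_real_, length(nm)), nm)
    }
    cbind(row, as.data.frame(as.list(blocks)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
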