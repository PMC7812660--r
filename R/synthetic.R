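# Seeded synthetic occurrence-record generator. Emulates the statistical
# structure a regional fungarium synthesis assumes: a log-series species
# abundance distribution, habitat- and host-structured preferences with a
# phylogenetic block structure among hosts (conifers / soft deciduous /
# hardwoods), fixed-effort plot surveys with per-species and per-plot record
# caps, and a casual-collection stream with detectability bias. Ground truth
# (which species were constructed as specialists, which host belongs to
# which block) is recorded so downstream recovery can be tested.

#' Default host taxa grouped into phylogenetic blocks
#'
#' Conifers, common soft-wooded deciduous trees, and hardwood/understorey
#' species -- the three clusters a host-assemblage dendrogram of a
#' hemiboreal polypore biota is expected to separate.
#'
#' @export
default_host_blocks <- list(
  conifer = c("Picea abies", "Pinus sylvestris", "Juniperus communis"),
  soft_deciduous = c("Populus tremula", "Betula spp.", "Alnus glutinosa",
                     "Alnus incana", "Salix spp."),
  hardwood = c("Quercus robur", "Fraxinus excelsior", "Ulmus spp.",
               "Tilia cordata", "Acer platanoides")
)

#' Default habitat keys for simulated surveys
#'
#' Twelve stand triples (site-type group | tree-species composition | age
#' class) spanning fertile and poor soils and all three tree classes.
#'
#' @export
default_habitats <- c(
  "meso_eutrophic|picea|old", "meso_eutrophic|picea|other",
  "swamp|picea|old", "eutrophic|picea|old",
  "dry_boreal|pinus|old", "dry_boreal|pinus|other",
  "heath|pinus|other", "bog|pinus|old",
  "eutrophic|deciduous|old", "eutrophic|deciduous|other",
  "floodplain|deciduous|old", "drained_peatland|deciduous|other"
)

# draw S abundances from a log-series distribution P(n) proportional to
# theta^n / n, truncated at n_max (negligible tail mass for theta < 1)
rlogseries <- function(S, theta, n_max = 20000L) {
  stopifnot(theta > 0, theta < 1)
  n <- seq_len(n_max)
  pmf <- theta^n / n
  sample(n, S, replace = TRUE, prob = pmf)
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Sample a synthetic species pool
#'
#' Builds `S` species profiles: relative abundances from a log-series
#' species-abundance distribution with parameter `theta` (many singletons,
#' as regional fungal data show), per-habitat affinity multipliers,
#' host preferences with the block structure of `host_blocks`, decay- and
#' substrate-fraction profiles, and a detectability multiplier for the
#' casual stream. A fraction `specialist_fraction` of species is
#' constructed as single-host or single-habitat specialists and flagged in
#' the ground truth.
#'
#' @param S number of species (>= 2).
#' @param theta log-series parameter in (0, 1); larger values flatten the
#'   abundance distribution. The default 0.99999 yields roughly 5--10\%
#'   singletons at default survey effort.
#' @param habitats character vector of habitat keys.
#' @param host_blocks named list of host taxa per phylogenetic block.
#' @param specialist_fraction fraction of species constructed as
#'   specialists (`round(S * specialist_fraction)` species, alternating
#'   host- and habitat-specialists).
#' @param habitat_sd log-normal sd of per-site-type preferences for
#'   non-specialists; habitats sharing a site-type group get correlated
#'   assemblages.
#' @param tree_affinity affinity multiplier for habitats whose tree-class
#'   composition matches the species' host block (conifer-block species
#'   prefer Picea/Pinus stands, the deciduous blocks prefer deciduous
#'   stands), creating the tree-composition gradient. Set
#'   `tree_affinity = 1` together with `habitat_sd = 0` for fully
#'   structureless assemblages (e.g. permutation-test calibration).
#' @param cross_block_weight host-preference weight of out-of-block hosts
#'   relative to in-block hosts for non-specialists.
#' @param seed integer seed; identical seeds give identical pools.
#' @return list of class `species_pool`.
#' @export
sample_species_pool <- function(S = 200, theta = 0.99999,
                                habitats = default_habitats,
                                host_blocks = default_host_blocks,
                                specialist_fraction = 0.15,
                                habitat_sd = 0.75,
                                tree_affinity = 3,
                                cross_block_weight = 0.08,
                                seed = 1) {
  if (S < 2) stop("S must be at least 2")
  stopifnot(theta > 0, length(habitats) >= 1, specialist_fraction >= 0,
            specialist_fraction <= 1)
  set.seed(seed)
  hosts <- unlist(host_blocks, use.names = FALSE)
  host_block <- rep(names(host_blocks), lengths(host_blocks))
  H <- length(habitats); nh <- length(hosts)
  species <- sprintf("sp%03d", seq_len(S))

  abundance <- rlogseries(S, theta)
  abundance <- abundance / sum(abundance)

  block <- sample(names(host_blocks), S, replace = TRUE)

  # host preference: in-block hosts weighted 1, others cross_block_weight
  host_pref <- matrix(cross_block_weight, S, nh,
                      dimnames = list(species, hosts))
  for (b in names(host_blocks))
    host_pref[block == b, host_block == b] <- 1
  # mild within-block variation so hosts differ in composition
  host_pref <- host_pref * matrix(exp(stats::rnorm(S * nh, 0, 0.4)), S, nh)

  # habitat affinity = per-site-type preference x tree-class match, so
  # assemblages are organised along the soil and tree-composition
  # gradients rather than varying independently per habitat key
  parts <- strsplit(habitats, "|", fixed = TRUE)
  site_of <- vapply(parts, `[`, "", 1)   # special habitats are their own type
  tree_of <- vapply(parts, function(p) if (length(p) >= 2) p[2]
                    else NA_character_, "")
  site_types <- unique(site_of)
  site_pref <- matrix(exp(stats::rnorm(S * length(site_types), 0,
                                       habitat_sd)),
                      S, length(site_types),
                      dimnames = list(species, site_types))
  tree_match <- matrix(FALSE, S, H)
  conifer_sp <- block == "conifer"
  tree_match[conifer_sp, !is.na(tree_of) &
               tree_of %in% c("picea", "pinus")] <- TRUE
  tree_match[!conifer_sp, !is.na(tree_of) & tree_of == "deciduous"] <- TRUE
  habitat_affinity <- site_pref[, site_of, drop = FALSE] *
    ifelse(tree_match, tree_affinity, 1)
  dimnames(habitat_affinity) <- list(species, habitats)

  # constructed specialists (ground truth), alternating host / habitat
  n_spec <- round(S * specialist_fraction)
  spec_ids <- if (n_spec > 0) sample(S, n_spec) else integer(0)
  spec_kind <- rep(c("host", "habitat"), length.out = n_spec)
  spec_target <- rep(NA_character_, S)
  for (i in seq_along(spec_ids)) {
    s <- spec_ids[i]
    if (spec_kind[i] == "host") {
      # a specialist is near-exclusive on one in-block host by construction
      focal <- sample(which(host_block == block[s]), 1)
      pref <- rep(0.005 / (nh - 1), nh)
      pref[focal] <- 0.995
      host_pref[s, ] <- pref
      spec_target[s] <- hosts[focal]
    } else {
      focal <- sample(H, 1)
      aff <- numeric(H)
      aff[focal] <- 1
      habitat_affinity[s, ] <- aff
      spec_target[s] <- habitats[focal]
    }
  }
  specialist <- seq_len(S) %in% spec_ids
  kind <- rep(NA_character_, S)
  kind[spec_ids] <- spec_kind

  host_pref <- host_pref / rowSums(host_pref)

  decay_profile <- rdirichlet1(S, c(2, 3, 2))
  colnames(decay_profile) <- c("early", "medium", "late")
  fraction_profile <- rdirichlet1(S, c(5, 2.5, 2.5, 0.3))
  colnames(fraction_profile) <- c("coarse_fallen", "snag_stump", "fwd",
                                  "live_tree")
  rownames(decay_profile) <- rownames(fraction_profile) <- species

  structure(list(species = species, abundance = abundance,
                 habitat_affinity = habitat_affinity,
                 host_preference = host_pref,
                 decay_profile = decay_profile,
                 fraction_profile = fraction_profile,
                 detectability = stats::runif(S, 0.2, 1),
                 block = block, specialist = specialist,
                 specialist_kind = kind, specialist_target = spec_target,
                 habitats = habitats, hosts = hosts,
                 host_block = stats::setNames(host_block, hosts),
                 seed = seed),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Synthetic species pool: ", length(x$species), " species, ",
      length(x$habitats), " habitats, ", length(x$hosts), " hosts\n",
      sep = "")
  cat("  constructed specialists: ", sum(x$specialist), " (",
      sum(x$specialist_kind == "host", na.rm = TRUE), " host, ",
      sum(x$specialist_kind == "habitat", na.rm = TRUE), " habitat)\n",
      sep = "")
  invisible(x)
}

#' Survey design for the simulator
#'
#' Fixed-effort plot surveys: per species within a plot only the first
#' `per_species_cap` records are retained (their substrates described in
#' detail), and a plot yields at most `per_plot_cap` records in total --
#' the caps of the field protocol the simulator emulates (10 and 150).
#' A casual-collection stream of expected size `casual_effort` is drawn
#' with species detectability bias, without plot membership.
#'
#' @param plots data frame with columns `plot_id`, `habitat` (habitat
#'   keys), or `NULL` to lay out `plots_per_habitat` plots in each habitat.
#' @param habitats habitat keys used when `plots` is `NULL`.
#' @param plots_per_habitat number of plots per habitat key.
#' @param per_species_cap,per_plot_cap the record caps.
#' @param casual_effort expected number of casual records.
#' @param years calendar years records are drawn from.
#' @return list of class `survey_design`.
#' @export
survey_design <- function(plots = NULL, habitats = default_habitats,
                          plots_per_habitat = 2, per_species_cap = 10,
                          per_plot_cap = 150, casual_effort = 500,
                          years = 2005:2019) {
  stopifnot(per_species_cap >= 1, per_plot_cap >= 1, casual_effort >= 0)
  if (is.null(plots)) {
    plots <- data.frame(
      plot_id = sprintf("plot%02d", seq_len(length(habitats) *
                                              plots_per_habitat)),
      habitat = rep(habitats, each = plots_per_habitat),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("plot_id", "habitat") %in% names(plots)))
  structure(list(plots = plots, per_species_cap = per_species_cap,
                 per_plot_cap = per_plot_cap, casual_effort = casual_effort,
                 years = years),
            class = "survey_design")
}

# sample one categorical column per record, grouped by species for speed
sample_by_species <- function(species_idx, prob_matrix, levels) {
  out <- character(length(species_idx))
  for (s in unique(species_idx)) {
    i <- species_idx == s
    p <- prob_matrix[s, ]
    if (sum(p) <= 0) p <- rep(1, length(p))
    out[i] <- sample(levels, sum(i), replace = TRUE, prob = p)
  }
  out
}

decay_to_raw <- function(decay_class) {
  n <- length(decay_class)
  raw <- character(n)
  e <- decay_class == "early"
  m <- decay_class == "medium"
  l <- decay_class == "late"
  raw[e] <- sample(c("I", "II"), sum(e), replace = TRUE)
  raw[m] <- "III"
  raw[l] <- sample(c("IV", "V"), sum(l), replace = TRUE)
  raw
}

#' Simulate an occurrence-record survey
#'
#' Draws records plot by plot: species are drawn proportional to
#' `abundance * habitat_affinity(plot habitat)` in a seeded random order,
#' and the per-species cap truncates that order (mirroring a protocol that
#' describes only the first records of each species); the plot cap bounds
#' the total. Each accepted record is assigned a host, substrate fraction
#' and decay stage from the species' profiles (live trees get no decay
#' stage). The casual stream draws species with probability additionally
#' weighted by detectability and assigns each record a habitat weighted by
#' the species' affinities.
#'
#' @param pool a [sample_species_pool()] result.
#' @param design a [survey_design()].
#' @param seed integer seed; identical seed and inputs give identical
#'   record tables.
#' @return canonical occurrence-record data frame (see [read_records()]),
#'   systematic records under dataset `IIb`, casual ones under `IIIa`.
#' @export
simulate_survey <- function(pool, design, seed = 1) {
  stopifnot(inherits(pool, "species_pool"), inherits(design, "survey_design"))
  set.seed(seed)
  S <- length(pool$species)
  chunks <- list()
  for (p in seq_len(nrow(design$plots))) {
    hab <- design$plots$habitat[p]
    if (!hab %in% pool$habitats)
      stop("plot habitat not in pool: ", hab)
    w <- pool$abundance * pool$habitat_affinity[, hab]
    if (sum(w) <= 0) next
    draws <- sample(S, size = design$per_plot_cap * 3, replace = TRUE,
                    prob = w)
    nth <- stats::ave(seq_along(draws), draws, FUN = seq_along)
    keep <- draws[nth <= design$per_species_cap]
    keep <- utils::head(keep, design$per_plot_cap)
    if (!length(keep)) next
    n <- length(keep)
    frac <- sample_by_species(keep, pool$fraction_profile,
                              colnames(pool$fraction_profile))
    dec <- sample_by_species(keep, pool$decay_profile,
                             colnames(pool$decay_profile))
    parts <- strsplit(hab, "|", fixed = TRUE)[[1]]
    chunks[[length(chunks) + 1L]] <- data.frame(
      species_id = pool$species[keep],
      dataset_id = "IIb",
      year = sample(design$years, n, replace = TRUE),
      plot_id = design$plots$plot_id[p],
      site_type_group = parts[1], tree_class = parts[2],
      age_class = parts[3],
      host_taxon = sample_by_species(keep, pool$host_preference,
                                     pool$hosts),
      substrate_fraction = frac,
      decay_raw = ifelse(frac == "live_tree", NA_character_,
                         decay_to_raw(dec)),
      special_habitat = NA_character_,
      stringsAsFactors = FALSE)
  }
  n_casual <- if (design$casual_effort > 0)
    stats::rpois(1, design$casual_effort) else 0L
  if (n_casual > 0) {
    w <- pool$abundance * pool$detectability
    keep <- sample(S, n_casual, replace = TRUE, prob = w)
    frac <- sample_by_species(keep, pool$fraction_profile,
                              colnames(pool$fraction_profile))
    dec <- sample_by_species(keep, pool$decay_profile,
                             colnames(pool$decay_profile))
    hab <- sample_by_species(keep, pool$habitat_affinity, pool$habitats)
    parts <- do.call(rbind, strsplit(hab, "|", fixed = TRUE))
    chunks[[length(chunks) + 1L]] <- data.frame(
      species_id = pool$species[keep],
      dataset_id = "IIIa",
      year = sample(design$years, n_casual, replace = TRUE),
      plot_id = NA_character_,
      site_type_group = parts[, 1], tree_class = parts[, 2],
      age_class = parts[, 3],
      host_taxon = sample_by_species(keep, pool$host_preference,
                                     pool$hosts),
      substrate_fraction = frac,
      decay_raw = ifelse(frac == "live_tree", NA_character_,
                         decay_to_raw(dec)),
      special_habitat = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(chunks)) return(empty_records())
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out[record_columns]
}

#' Ground truth of a synthetic pool
#'
#' Machine-readable truth tables for recovery tests: per-species specialist
#' flags with kind and target, host-block membership of every species, and
#' the host-to-block map itself.
#'
#' @param pool a [sample_species_pool()] result.
#' @return list with `specialists`, `species_blocks`, `host_blocks`.
#' @export
ground_truth <- function(pool) {
  stopifnot(inherits(pool, "species_pool"))
  list(
    specialists = data.frame(species_id = pool$species[pool$specialist],
                             kind = pool$specialist_kind[pool$specialist],
                             target = pool$specialist_target[pool$specialist],
                             stringsAsFactors = FALSE),
    species_blocks = data.frame(species_id = pool$species,
                                block = pool$block,
                                stringsAsFactors = FALSE),
    host_blocks = data.frame(host = pool$hosts,
                             block = unname(pool$host_block),
                             stringsAsFactors = FALSE)
  )
}
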