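# Species x substrate-category association tables and the rule-based
# regular/specialist classification of substrate use, host-range summaries,
# and host-tree assemblage clustering.

#' Build a species x substrate-category association table
#'
#' Cross-tabulates records by species and one substrate axis: host taxon,
#' substrate fraction, or decay class (decay stages recoded via
#' [recode_decay()]). Records lacking the axis annotation are excluded
#' from the counts but retained in the per-species totals, so percentage
#' rules are evaluated against a species' full record count.
#'
#' @param records canonical record data frame.
#' @param axis `"host_taxon"`, `"substrate_fraction"` or `"decay_class"`.
#' @return list of class `association_table`: `counts` (species x category
#'   integer matrix, categories in lexicographic order), `species_totals`
#'   (all records per species), `category_totals`, `n_missing_axis`,
#'   `axis`.
#' @export
build_association_table <- function(records,
                                    axis = c("host_taxon",
                                             "substrate_fraction",
                                             "decay_class")) {
  axis <- match.arg(axis)
  values <- switch(axis,
                   host_taxon = records$host_taxon,
                   substrate_fraction = records$substrate_fraction,
                   decay_class = recode_decay(records$decay_raw))
  if (all(is.na(values)))
    stop("axis '", axis, "' is missing from every record")
  species_totals <- table(records$species_id)
  species_totals <- stats::setNames(as.integer(species_totals),
                                    names(species_totals))
  species_totals <- species_totals[order(names(species_totals))]
  has <- !is.na(values) & !is.na(records$species_id)
  counts <- table(factor(records$species_id[has],
                         levels = names(species_totals)),
                  factor(values[has], levels = sort(unique(values[has]))))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, species_totals = species_totals,
                 category_totals = colSums(counts),
                 n_missing_axis = sum(!has), axis = axis),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat("Association table (axis: ", x$axis, "): ", nrow(x$counts),
      " species x ", ncol(x$counts), " categories; ", x$n_missing_axis,
      " records without axis annotation\n", sep = "")
  invisible(x)
}

#' Classify a species as a regular occupant of a substrate category
#'
#' A species occurs regularly on a category when any of three rules holds:
#' (a) at least 5\% of its records are on the category and its regional
#' total is at least 40 records; (b) more than one record on the category
#' while the total is under 40; or (c) its records make up at least 5\% of
#' all records in that category. The rules form a plain OR; the reported
#' rule is the first matching in the order a, b, c (a reporting
#' convention, not a precedence).
#'
#' @param n_cat records of the species on the category.
#' @param n_species_total the species' total record count.
#' @param n_cat_total all records in the category (0 skips rule c).
#' @return data frame with logical `regular` and character `rule` in
#'   `{"a_share5_total40", "b_gt1_total_lt40", "c_cat_share5", "none"}`.
#' @export
classify_regular <- function(n_cat, n_species_total, n_cat_total) {
  n <- max(length(n_cat), length(n_species_total), length(n_cat_total))
  n_cat <- rep_len(n_cat, n)
  n_species_total <- rep_len(n_species_total, n)
  n_cat_total <- rep_len(n_cat_total, n)
  if (any(n_cat > n_species_total)) stop("n_cat exceeds species total")
  if (any(n_cat > n_cat_total)) stop("n_cat exceeds category total")
  a <- n_species_total >= 40 & n_cat / n_species_total >= 0.05
  b <- n_species_total < 40 & n_cat > 1
  c_ <- n_cat_total > 0 & n_cat / n_cat_total >= 0.05
  rule <- rep("none", n)
  rule[c_] <- "c_cat_share5"
  rule[b] <- "b_gt1_total_lt40"
  rule[a] <- "a_share5_total40"
  data.frame(regular = a | b | c_, rule = rule, stringsAsFactors = FALSE)
}

#' Classify a species as a substrate specialist
#'
#' Specialists are the subset of regular species with more than two
#' records on the category which form either at least 90\% of all the
#' species' records, or all of them when the total is 3--9 records.
#'
#' @param n_cat records of the species on the category.
#' @param n_species_total the species' total record count.
#' @param regular logical: is the species regular on the category?
#' @return logical vector.
#' @export
classify_specialist <- function(n_cat, n_species_total, regular) {
  n <- max(length(n_cat), length(n_species_total), length(regular))
  n_cat <- rep_len(n_cat, n)
  n_species_total <- rep_len(n_species_total, n)
  regular <- rep_len(regular, n)
  share <- ifelse(n_species_total > 0, n_cat / n_species_total, 0)
  regular & n_cat > 2 &
    (share >= 0.90 |
       (n_species_total >= 3 & n_species_total <= 9 &
          n_cat == n_species_total))
}

#' Classify every species x category association of a table
#'
#' Applies [classify_regular()] and [classify_specialist()] to every cell
#' of an association table.
#'
#' @param table an [build_association_table()] result.
#' @return long data frame: `species_id`, `category`, `n_cat`,
#'   `n_species_total`, `n_cat_total`, `regular`, `rule`, `specialist`.
#' @export
classify_associations <- function(table) {
  stopifnot(inherits(table, "association_table"))
  cn <- colnames(table$counts)
  rn <- rownames(table$counts)
  out <- data.frame(
    species_id = rep(rn, times = length(cn)),
    category = rep(cn, each = length(rn)),
    n_cat = as.vector(table$counts),
    n_species_total = rep(unname(table$species_totals[rn]),
                          times = length(cn)),
    n_cat_total = rep(unname(table$category_totals[cn]), each = length(rn)),
    stringsAsFactors = FALSE)
  cls <- classify_regular(out$n_cat, out$n_species_total, out$n_cat_total)
  out$regular <- cls$regular
  out$rule <- cls$rule
  out$specialist <- classify_specialist(out$n_cat, out$n_species_total,
                                        cls$regular)
  out
}

#' Host-range summary of well-recorded species
#'
#' For species recorded more than `min_records` times (strictly), counts
#' the host taxa they have been found on and bins them into the classes
#' 1--2, 3--7 and 8-or-more host species.
#'
#' @param table a host-axis [build_association_table()] result.
#' @param min_records inclusion threshold (strict `>`; default 10).
#' @return data frame `species_id`, `n_records`, `n_hosts`, `host_class`;
#'   species with no host annotation at all get `NA` class.
#' @export
host_range_summary <- function(table, min_records = 10) {
  stopifnot(inherits(table, "association_table"),
            table$axis == "host_taxon")
  keep <- names(table$species_totals)[table$species_totals > min_records]
  n_hosts <- rowSums(table$counts[keep, , drop = FALSE] > 0)
  cls <- ifelse(n_hosts == 0, NA_character_,
         ifelse(n_hosts <= 2, "1-2",
         ifelse(n_hosts <= 7, "3-7", ">=8")))
  data.frame(species_id = keep,
             n_records = unname(table$species_totals[keep]),
             n_hosts = unname(n_hosts), host_class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Presence/absence matrix of regular host--species pairs
#'
#' Restricts a host-association table to the regular pairs used for host
#' clustering: cell (species, host) is 1 when the records there are at
#' least 5\% of the species' total records or at least 5\% of the host's
#' total records. Presence/absence of merely incidental associations would
#' over-emphasise atypical substrates.
#'
#' @param table a host-axis [build_association_table()] result.
#' @param share threshold share (default 0.05).
#' @return binary species x host matrix.
#' @export
host_similarity_input <- function(table, share = 0.05) {
  stopifnot(inherits(table, "association_table"))
  sp_tot <- table$species_totals[rownames(table$counts)]
  cat_tot <- table$category_totals
  by_species <- table$counts >= share * matrix(sp_tot, nrow(table$counts),
                                               ncol(table$counts))
  by_host <- table$counts >= share * matrix(cat_tot, nrow(table$counts),
                                            ncol(table$counts),
                                            byrow = TRUE)
  pa <- (by_species | by_host) & table$counts > 0
  storage.mode(pa) <- "integer"
  pa
}

#' Cluster host trees by their polypore assemblages
#'
#' Average-linkage (UPGMA) clustering of host taxa on Bray-Curtis
#' dissimilarities of presence/absence species composition. Hosts with no
#' present species are excluded with a warning.
#'
#' @param pa_matrix binary species x host matrix, e.g. from
#'   [host_similarity_input()].
#' @return an `upgma_dendrogram` (see [upgma()]).
#' @export
cluster_hosts <- function(pa_matrix) {
  empty <- colSums(pa_matrix) == 0
  if (any(empty)) {
    warning("excluding host(s) with no present species: ",
            paste(colnames(pa_matrix)[empty], collapse = ", "))
    pa_matrix <- pa_matrix[, !empty, drop = FALSE]
  }
  if (ncol(pa_matrix) < 3)
    stop("need at least 3 hosts with at least one present species")
  D <- bray_curtis(t(pa_matrix))
  upgma(D)
}
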