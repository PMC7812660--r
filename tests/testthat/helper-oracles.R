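# Independent oracles and small fixture builders shared across tests.

# plain Rand index between two partitions (pair-counting agreement)
rand_index <- function(a, b) {
  n <- length(a)
  s <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
  s / choose(n, 2)
}

# Bray-Curtis by a naive double loop over sample pairs
naive_bray <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(abs(X[i, ] - X[j, ])) / sum(X[i, ] + X[j, ])
  D
}

# exact monotone least-squares fit by enumerating all ordered partitions
# into level blocks (2^(n-1) for length n); feasible for n <= 8
brute_force_isotonic <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(w[idx] * y[idx]) / sum(w[idx])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# write a records CSV from a data frame of (partial) canonical columns
write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# small valid record table builder; unspecified descriptor fields stay NA
make_records <- function(species, dataset = "IIb", year = 2015,
                         host = NA, fraction = NA, decay = NA,
                         site = "meso_eutrophic", tree = "picea",
                         age = "old", plot = "p1") {
  n <- length(species)
  data.frame(species_id = species,
             dataset_id = rep_len(dataset, n),
             year = rep_len(year, n),
             plot_id = rep_len(plot, n),
             site_type_group = rep_len(site, n),
             tree_class = rep_len(tree, n),
             age_class = rep_len(age, n),
             host_taxon = rep_len(host, n),
             substrate_fraction = rep_len(fraction, n),
             decay_raw = rep_len(decay, n),
             special_habitat = NA_character_,
             stringsAsFactors = FALSE)
}
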