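# In-code fixtures shared across test files.

# Minimal spot table: `cells` is a data.frame with sample_id, isotype,
# glycan_id and a list-column `nets` of replicate net signals; background
# is a flat 100 RFU so foreground = net + 100.
write_spot_fixture <- function(cells, path = tempfile(fileext = ".tsv"),
                               background = 100) {
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    nets <- cells$nets[[i]]
    data.frame(sample_id = cells$sample_id[i], isotype = cells$isotype[i],
               glycan_id = cells$glycan_id[i],
               replicate = seq_along(nets),
               foreground = nets + background, background = background,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Reactivity matrix wrapper around a plain values matrix.
make_rm <- function(values, group = NULL, isotype = "IgG", library = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("g%03d", seq_len(ncol(values)))
  }
  samples <- data.frame(sample_id = rownames(values),
                        group = if (is.null(group)) NA_character_ else group,
                        stringsAsFactors = FALSE)
  structure(list(values = values, samples = samples, isotype = isotype,
                 library = library),
            class = "reactivity_matrix")
}

# Independent clustering oracle: agglomerate by exhaustively re-scanning
# the ORIGINAL distance matrix, tracking explicit member lists (different
# representation from the implementation's running cluster-distance
# matrix). Ties break on the lowest (i, j) pair in creation order.
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    m <- length(members)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- max(D[members[[i]], members[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merge[s, ] <- sort(c(codes[best[1]], codes[best[2]]))
    height[s] <- best_d
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    codes[best[1]] <- s
    members <- members[-best[2]]
    codes <- codes[-best[2]]
  }
  list(merge = merge, height = height)
}

# Small otu_table with a planted two-species genus.
make_otu_fixture <- function(counts, lineages, samples) {
  taxonomy <- data.frame(otu_id = rownames(counts), lineage = lineages,
                         stringsAsFactors = FALSE)
  new_otu_table(counts, taxonomy, samples)
}
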