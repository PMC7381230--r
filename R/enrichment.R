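#' Read OTU count, taxonomy and sample-sheet tables
#'
#' @param counts_path TSV of counts, rows = OTUs (first column `otu_id`),
#'   remaining columns = samples.
#' @param taxonomy_path TSV with columns `otu_id` and `lineage`
#'   (semicolon-delimited, rank-prefixed `d:/p:/c:/o:/f:/g:/s:`, possibly
#'   truncated).
#' @param samples_path TSV with columns `sample_id`, `fraction`
#'   (`unsorted`, `AAL_pos`, `IgG_pos`), `serum_group` (`ctrl`, `UC`,
#'   `CD`, `none`) and `matched_unsorted_id` (empty for unsorted samples).
#' @return An `otu_table`: list with `counts` (integer matrix OTU x
#'   sample), `taxonomy`, `samples`.
#' @export
read_otu_tables <- function(counts_path, taxonomy_path, samples_path) {
  ctab <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  stopifnot("otu_id" %in% names(ctab))
  counts <- as.matrix(ctab[, setdiff(names(ctab), "otu_id"), drop = FALSE])
  rownames(counts) <- ctab$otu_id
  storage.mode(counts) <- "integer"
  taxonomy <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  stopifnot(all(c("otu_id", "lineage") %in% names(taxonomy)))
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               na.strings = c("NA", ""))
  stopifnot(all(c("sample_id", "fraction", "serum_group") %in% names(samples)))
  new_otu_table(counts, taxonomy, samples)
}

#' Construct an `otu_table` from in-memory pieces
#'
#' @param counts Non-negative integer matrix, rows OTUs, columns samples.
#' @param taxonomy Data frame `otu_id`, `lineage`.
#' @param samples Data frame `sample_id`, `fraction`, `serum_group`,
#'   `matched_unsorted_id`.
#' @return An `otu_table`.
#' @export
new_otu_table <- function(counts, taxonomy, samples) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            setequal(rownames(counts), taxonomy$otu_id),
            setequal(colnames(counts), samples$sample_id))
  counts <- counts[taxonomy$otu_id, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, taxonomy = taxonomy, samples = samples),
            class = "otu_table")
}

#' Per-sample relative abundance (percent of total bacteria)
#'
#' @param counts Count matrix (rows taxa, columns samples), or an
#'   `otu_table`.
#' @return Matrix of percentages; every column sums to 100.
#' @export
relative_abundance <- function(counts) {
  if (inherits(counts, "otu_table")) counts <- counts$counts
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop(sprintf("all-zero sample(s): %s",
                 paste(colnames(counts)[totals == 0], collapse = ", ")),
         call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 100
}

rank_prefixes <- c(domain = "d", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s")

# Lineage string -> named character vector of assigned ranks.
parse_lineage <- function(lineage) {
  fields <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  fields <- fields[nzchar(fields)]
  pre <- sub(":.*$", "", fields)
  val <- sub("^[a-z]:", "", fields)
  names(val) <- names(rank_prefixes)[match(pre, rank_prefixes)]
  val[!is.na(names(val))]
}

# Aggregation key of one lineage at `rank`: "g:Bacteroides" when assigned,
# else "<lowest assigned>;g:unclassified" (e.g. "f:Lachnospiraceae;
# g:unclassified"), mirroring how unknown genera are reported under their
# family.
taxon_key <- function(lineage, rank) {
  parsed <- parse_lineage(lineage)
  prefix <- rank_prefixes[[rank]]
  if (rank %in% names(parsed)) {
    return(paste0(prefix, ":", parsed[[rank]]))
  }
  ranks <- names(rank_prefixes)
  upto <- ranks[seq_len(match(rank, ranks) - 1)]
  assigned <- intersect(rev(upto), names(parsed))
  lowest <- if (length(assigned) > 0) {
    paste0(rank_prefixes[[assigned[1]]], ":", parsed[[assigned[1]]])
  } else {
    "unassigned"
  }
  paste0(lowest, ";", prefix, ":unclassified")
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Counts of OTUs sharing the rank label are summed. OTUs unassigned at
#' that rank are grouped under their lowest assigned rank with an
#' `unclassified` placeholder (e.g. `f:Lachnospiraceae;g:unclassified`).
#' Per-sample totals are conserved exactly.
#'
#' @param otu An `otu_table`.
#' @param rank One of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return List with `counts` (taxa x samples) and `keys` (data frame
#'   mapping `otu_id` to its aggregation key).
#' @export
aggregate_taxa <- function(otu, rank = "genus") {
  stopifnot(inherits(otu, "otu_table"),
            rank %in% names(rank_prefixes))
  keys <- vapply(otu$taxonomy$lineage, taxon_key, "", rank = rank,
                 USE.NAMES = FALSE)
  agg <- rowsum(otu$counts, group = keys)
  list(counts = agg,
       keys = data.frame(otu_id = otu$taxonomy$otu_id, key = keys,
                         stringsAsFactors = FALSE))
}

#' Fold enrichment of a taxon in a sorted fraction
#'
#' Ratio of the taxon's relative abundance in the sorted fraction to its
#' relative abundance in the matched unsorted sample, with an additive
#' pseudo-proportion applied to both so the ratio stays finite when the
#' taxon is absent from the unsorted sample.
#'
#' @param sorted_pct,unsorted_pct Percentages (vectorised over taxa).
#' @param pseudo Pseudo-percentage added to numerator and denominator; see
#'   [pseudo_percent()] for the default policy.
#' @return Ratios; taxa absent from both fractions return exactly 1.
#' @export
fold_enrichment <- function(sorted_pct, unsorted_pct, pseudo) {
  stopifnot(pseudo > 0, all(sorted_pct >= 0), all(unsorted_pct >= 0))
  (sorted_pct + pseudo) / (unsorted_pct + pseudo)
}

#' Default pseudo-percentage for fold enrichment
#'
#' One read in the smaller of the two libraries, on the percentage scale:
#' `100 / min(depth_sorted, depth_unsorted)`.
#'
#' @param depth_sorted,depth_unsorted Total read counts of the pair.
#' @return Pseudo-percentage.
#' @export
pseudo_percent <- function(depth_sorted, depth_unsorted) {
  100 / min(depth_sorted, depth_unsorted)
}

#' Alpha diversity as observed OTU richness
#'
#' Number of OTUs with at least one read in the sample.
#'
#' @param otu An `otu_table` or a count matrix.
#' @param sample Sample id(s); default all samples.
#' @return Named integer vector of richness values.
#' @export
alpha_richness <- function(otu, sample = NULL) {
  counts <- if (inherits(otu, "otu_table")) otu$counts else otu
  if (!is.null(sample)) {
    stopifnot(all(sample %in% colnames(counts)))
    counts <- counts[, sample, drop = FALSE]
  }
  colSums(counts >= 1)
}

#' Fold-enrichment table for one sorted fraction
#'
#' For every sorted sample of the given fraction, computes per-taxon fold
#' enrichment against its matched unsorted sample at the chosen rank, with
#' the per-pair default pseudocount.
#'
#' @param otu An `otu_table`.
#' @param fraction `"AAL_pos"` or `"IgG_pos"`.
#' @param rank Aggregation rank (default `"genus"`).
#' @param serum_group Optional filter on the serum group of the sorted
#'   samples.
#' @return Matrix taxa x sorted samples of fold enrichments; relative
#'   abundances attached as attributes `"sorted_pct"`, `"unsorted_pct"`.
#' @export
fraction_folds <- function(otu, fraction, rank = "genus",
                           serum_group = NULL) {
  stopifnot(inherits(otu, "otu_table"))
  agg <- aggregate_taxa(otu, rank)$counts
  smp <- otu$samples
  sorted <- smp[smp$fraction == fraction, , drop = FALSE]
  if (!is.null(serum_group)) {
    sorted <- sorted[sorted$serum_group %in% serum_group, , drop = FALSE]
  }
  if (nrow(sorted) == 0) {
    stop(sprintf("no sorted samples for fraction %s", fraction),
         call. = FALSE)
  }
  if (anyNA(sorted$matched_unsorted_id)) {
    stop("sorted sample(s) without matched_unsorted_id", call. = FALSE)
  }
  pct <- relative_abundance(agg)
  folds <- sapply(seq_len(nrow(sorted)), function(i) {
    sid <- sorted$sample_id[i]
    uid <- sorted$matched_unsorted_id[i]
    stopifnot(uid %in% colnames(agg))
    pseudo <- pseudo_percent(sum(agg[, sid]), sum(agg[, uid]))
    fold_enrichment(pct[, sid], pct[, uid], pseudo)
  })
  folds <- matrix(folds, nrow = nrow(agg),
                  dimnames = list(rownames(agg), sorted$sample_id))
  attr(folds, "sorted_pct") <- pct[, sorted$sample_id, drop = FALSE]
  attr(folds, "unsorted_pct") <- pct[, sorted$matched_unsorted_id,
                                     drop = FALSE]
  folds
}

#' Flag taxa enriched beyond a threshold across replicate sorted samples
#'
#' A taxon is flagged per replicate when its fold enrichment meets the
#' threshold (`>=` when `inclusive`, the "at least" phrasing; `>`
#' otherwise), and the per-replicate flags are combined by majority: the
#' taxon passes when at least half of the replicates pass.
#'
#' @param folds Taxa x replicates fold-enrichment matrix (or a vector).
#' @param threshold Fold threshold (default 1.5).
#' @param inclusive Use `>=` (default TRUE).
#' @return Named logical vector over taxa.
#' @export
flag_enriched <- function(folds, threshold = 1.5, inclusive = TRUE) {
  if (is.null(dim(folds))) folds <- matrix(folds, ncol = 1,
                                           dimnames = list(names(folds), NULL))
  pass <- if (inclusive) folds >= threshold else folds > threshold
  rowMeans(pass) >= 0.5
}

#' Intersect lectin- and IgG-enriched taxa with CD preference
#'
#' Implements the candidate screen: a taxon is a candidate when (a) it is
#' lectin-enriched (majority of AAL-positive replicates at `>=`
#' threshold), (b) some serum group's median IgG-capture enrichment
#' exceeds the threshold (strict `>`, the "more than" phrasing), and (c)
#' it is CD-preferential: the CD group's median IgG enrichment exceeds the
#' control group's. The candidate set is a subset of both the (a) and (b)
#' sets by construction.
#'
#' @param aal_folds Taxa x replicates AAL fold-enrichment matrix.
#' @param igg_folds_by_group Named list (`ctrl`, `UC`, `CD`) of taxa x
#'   samples IgG fold-enrichment matrices over the same taxa.
#' @param threshold Fold threshold (default 1.5).
#' @return A `candidate_set` data frame with per-criterion provenance:
#'   `taxon`, `aal_enriched`, `aal_median_fold`, per-group median folds,
#'   `igg_enriched`, `cd_preferential`, `candidate`.
#' @export
candidate_intersection <- function(aal_folds, igg_folds_by_group,
                                   threshold = 1.5) {
  req <- c("ctrl", "UC", "CD")
  missing <- setdiff(req, names(igg_folds_by_group))
  if (length(missing) > 0) {
    stop(sprintf("missing IgG enrichment for group(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(dim(aal_folds))) {
    aal_folds <- matrix(aal_folds, ncol = 1,
                        dimnames = list(names(aal_folds), NULL))
  }
  taxa <- rownames(aal_folds)
  for (g in req) {
    stopifnot(identical(rownames(igg_folds_by_group[[g]]), taxa))
  }
  aal_set <- flag_enriched(aal_folds, threshold, inclusive = TRUE)
  med <- sapply(req, function(g) {
    apply(igg_folds_by_group[[g]], 1, stats::median)
  })
  igg_set <- apply(med > threshold, 1, any)
  cd_pref <- med[, "CD"] > med[, "ctrl"]
  candidate <- aal_set & igg_set & cd_pref
  stopifnot(all(candidate <= aal_set), all(candidate <= igg_set))
  out <- data.frame(taxon = taxa, aal_enriched = aal_set,
                    aal_median_fold = apply(aal_folds, 1, stats::median),
                    igg_median_fold_ctrl = med[, "ctrl"],
                    igg_median_fold_UC = med[, "UC"],
                    igg_median_fold_CD = med[, "CD"],
                    igg_enriched = igg_set, cd_preferential = cd_pref,
                    candidate = candidate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Full sorted-fraction candidate analysis from an OTU table
#'
#' Convenience wrapper: aggregates at `rank`, computes AAL and per-group
#' IgG fold enrichments against matched unsorted samples, and intersects
#' them with [candidate_intersection()].
#'
#' @param otu An `otu_table` containing `AAL_pos` samples and `IgG_pos`
#'   samples for serum groups ctrl, UC and CD.
#' @param rank Aggregation rank (default `"genus"`).
#' @param threshold Fold threshold (default 1.5).
#' @return A `candidate_set` (see [candidate_intersection()]).
#' @export
sorted_fraction_candidates <- function(otu, rank = "genus",
                                       threshold = 1.5) {
  aal <- fraction_folds(otu, "AAL_pos", rank = rank)
  igg <- lapply(c(ctrl = "ctrl", UC = "UC", CD = "CD"), function(g) {
    fraction_folds(otu, "IgG_pos", rank = rank, serum_group = g)
  })
  candidate_intersection(aal, igg, threshold = threshold)
}
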