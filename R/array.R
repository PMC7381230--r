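#' Read a spot-level glycan-array export
#'
#' Expects a tab-separated file emulating a scanner export with header
#' columns `sample_id`, `isotype`, `glycan_id`, `replicate`, `foreground`,
#' `background` (extra columns are ignored). `foreground`/`background` are
#' per-spot mean fluorescence: the spot is read as a 110 um circle and the
#' background as the surrounding 330 um annulus, both upstream of this
#' function.
#'
#' @param path Path to the TSV file.
#' @return Data frame of validated spot records; rows with non-numeric RFU
#'   are dropped with a warning. The number of rejected rows is attached as
#'   attribute `"n_rejected"`.
#' @export
read_spot_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("sample_id", "isotype", "glycan_id", "replicate",
           "foreground", "background")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("spot table missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab <- tab[req]
  fg <- suppressWarnings(as.numeric(tab$foreground))
  bg <- suppressWarnings(as.numeric(tab$background))
  rep_idx <- suppressWarnings(as.integer(tab$replicate))
  ok <- !is.na(fg) & !is.na(bg) & !is.na(rep_idx)
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    warning(sprintf("%d spot row(s) with non-numeric values rejected", n_rej),
            call. = FALSE)
  }
  out <- data.frame(sample_id = tab$sample_id[ok], isotype = tab$isotype[ok],
                    glycan_id = tab$glycan_id[ok], replicate = rep_idx[ok],
                    foreground = fg[ok], background = bg[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Net spot signal
#'
#' Background-subtracted spot intensity: `foreground - background`. Negative
#' values are permitted at the spot level; clamping happens only after
#' replicate averaging.
#'
#' @param foreground,background Per-spot mean RFU (vectorised).
#' @return Net RFU, possibly negative.
#' @export
net_signal <- function(foreground, background) {
  foreground - background
}

#' Average replicate spots with non-positive clamping
#'
#' Arithmetic mean of the replicate net signals; a non-positive mean is set
#' to `clamp_value` (default 1, so the downstream log2 is defined and the
#' floor of the reactivity scale is 0). Positive sub-1 means are returned
#' as-is here; they are floored at the log2 step of
#' [build_reactivity_matrix()].
#'
#' @param nets Numeric vector of replicate net signals (length >= 1).
#' @param clamp_value Replacement for non-positive means (default 1).
#' @param expected_replicates If non-`NULL`, warn when the replicate count
#'   differs (arrays are printed in quadruplicate by convention).
#' @return Scalar aggregated RFU.
#' @export
aggregate_replicates <- function(nets, clamp_value = 1,
                                 expected_replicates = NULL) {
  if (length(nets) < 1L) {
    stop("no replicates to aggregate", call. = FALSE)
  }
  if (!is.null(expected_replicates) && length(nets) != expected_replicates) {
    warning(sprintf("expected %d replicates, got %d", expected_replicates,
                    length(nets)), call. = FALSE)
  }
  m <- mean(nets)
  if (m <= 0) clamp_value else m
}

#' Build the samples x glycans log2 reactivity matrix
#'
#' For each (sample, glycan) of the requested isotype the replicate net
#' signals are averaged, non-positive means are clamped to `clamp_value`,
#' and the cell is `log2(max(mean, clamp_value))` so every cell is
#' non-negative. The matrix is complete by construction: any (sample,
#' glycan) without replicates is a fatal error listing the offenders.
#'
#' @param spots Spot data frame as from [read_spot_table()].
#' @param samples Sample metadata data frame with columns `sample_id`,
#'   `group` (levels `ctrl`, `UC`, `CD`) and optionally
#'   `igg_concentration`.
#' @param isotype Which channel to build (`"IgG"` or `"IgM"`).
#' @param clamp_value Clamp constant (default 1).
#' @param expected_replicates Warn once if any cell deviates (default 4).
#' @param library Optional classified library from [partition_library()];
#'   attached as glycan metadata and used to fix column order.
#' @return A `reactivity_matrix`: list with `values` (samples x glycans
#'   matrix of log2 RFU), `samples`, `isotype`, `library`.
#' @export
build_reactivity_matrix <- function(spots, samples, isotype = "IgG",
                                    clamp_value = 1, expected_replicates = 4,
                                    library = NULL) {
  stopifnot(is.data.frame(spots), is.data.frame(samples),
            "sample_id" %in% names(samples))
  sp <- spots[spots$isotype == isotype, , drop = FALSE]
  sample_ids <- samples$sample_id
  glycan_ids <- if (!is.null(library)) library$glycan_id
                else sort(unique(sp$glycan_id))
  sp <- sp[sp$sample_id %in% sample_ids, , drop = FALSE]
  fs <- factor(sp$sample_id, levels = sample_ids)
  fg <- factor(sp$glycan_id, levels = glycan_ids)
  net <- net_signal(sp$foreground, sp$background)
  counts <- table(fs, fg)
  if (any(counts == 0)) {
    idx <- which(counts == 0, arr.ind = TRUE)
    miss <- paste(sample_ids[idx[, 1]], glycan_ids[idx[, 2]], sep = ":")
    stop(sprintf("no replicates for %d (sample, glycan) cell(s): %s",
                 length(miss),
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(expected_replicates) && any(counts != expected_replicates)) {
    warning(sprintf("%d cell(s) deviate from the expected %d replicates",
                    sum(counts != expected_replicates), expected_replicates),
            call. = FALSE)
  }
  agg <- tapply(net, list(fs, fg), mean)
  agg[agg <= 0] <- clamp_value
  vals <- log2(pmax(agg, clamp_value))
  dimnames(vals) <- list(sample_ids, glycan_ids)
  structure(
    list(values = vals, samples = samples, isotype = isotype,
         library = library),
    class = "reactivity_matrix"
  )
}

#' @export
print.reactivity_matrix <- function(x, ...) {
  cat(sprintf("reactivity_matrix: %d samples x %d glycans (%s, log2 RFU)\n",
              nrow(x$values), ncol(x$values), x$isotype))
  if (!is.null(x$samples$group)) {
    cat("groups:", paste(sprintf("%s=%d", names(table(x$samples$group)),
                                 table(x$samples$group)), collapse = " "), "\n")
  }
  invisible(x)
}
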