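#' Parse an oligosaccharide composition label
#'
#' Composition labels count monosaccharides: hexose (H), N-acetylhexosamine
#' (N), fucose (F) and sialic acid / N-acetylneuraminic acid (S), e.g.
#' `"H4N2F3"`. A trailing parenthetical is treated as a trivial-name alias
#' (`"H2F1 (3-FL)"`), slash-separated labels denote ambiguous alternatives
#' (`"H6N4F4/H7N5F2"`), and the literal `"unknown"` (any case) marks a
#' structure whose composition was not determined.
#'
#' @param label A single non-empty character string.
#' @return A `composition_set`: list with `alternatives` (list of named
#'   integer vectors with elements `H`, `N`, `F`, `S`, de-duplicated),
#'   `alias` (character or `NA`), `unknown` (logical) and `source_label`.
#' @examples
#' parse_composition("H4N2F3")
#' parse_composition("H2F1 (3-FL)")
#' parse_composition("H6N4F4/H7N5F2")
#' @export
parse_composition <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(trimws(label))) {
    stop("composition label must be a single non-empty string", call. = FALSE)
  }
  raw <- trimws(label)
  alias <- NA_character_
  m <- regmatches(raw, regexec("^(.*?)\\s*\\(([^)]*)\\)\\s*$", raw))[[1]]
  body <- raw
  if (length(m) == 3L) {
    body <- m[2L]
    alias <- m[3L]
  }
  if (tolower(body) == "unknown") {
    return(new_composition_set(list(), alias, TRUE, label))
  }
  parts <- strsplit(body, "/", fixed = TRUE)[[1L]]
  if (grepl("^/|/$|//", body) ||
      length(parts) == 0L || any(!nzchar(trimws(parts)))) {
    stop(sprintf("malformed composition label '%s': empty alternative", label),
         call. = FALSE)
  }
  offset <- 1L
  alts <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    alts[[i]] <- parse_counts(trimws(parts[i]), offset, label)
    offset <- offset + nchar(parts[i]) + 1L
  }
  alts <- alts[!duplicated(vapply(alts, paste, "", collapse = ","))]
  new_composition_set(alts, alias, FALSE, label)
}

new_composition_set <- function(alternatives, alias, unknown, source_label) {
  structure(
    list(alternatives = alternatives, alias = alias, unknown = unknown,
         source_label = source_label),
    class = "composition_set"
  )
}

# One alternative: letters in {H,N,F,S}, each followed by a positive integer,
# no letter repeated. `offset` locates tokens within the original label for
# error messages.
parse_counts <- function(part, offset, label) {
  counts <- c(H = 0L, N = 0L, F = 0L, S = 0L)
  n <- nchar(part)
  if (n == 0L) {
    stop(sprintf("malformed composition label '%s': empty alternative", label),
         call. = FALSE)
  }
  pos <- 1L
  seen <- character()
  while (pos <= n) {
    ch <- substr(part, pos, pos)
    if (!ch %in% c("H", "N", "F", "S")) {
      stop(sprintf(
        "malformed token '%s' at position %d in composition label '%s'",
        ch, offset + pos - 1L, label), call. = FALSE)
    }
    if (ch %in% seen) {
      stop(sprintf(
        "duplicate monosaccharide letter '%s' at position %d in '%s'",
        ch, offset + pos - 1L, label), call. = FALSE)
    }
    digits <- regmatches(substr(part, pos + 1L, n),
                         regexpr("^[0-9]+", substr(part, pos + 1L, n)))
    if (length(digits) == 0L) {
      stop(sprintf(
        "malformed token '%s' at position %d in composition label '%s': letter without a count",
        ch, offset + pos - 1L, label), call. = FALSE)
    }
    value <- as.integer(digits)
    if (is.na(value) || value < 1L) {
      stop(sprintf(
        "malformed token '%s%s' at position %d in composition label '%s': count must be a positive integer",
        ch, digits, offset + pos - 1L, label), call. = FALSE)
    }
    counts[ch] <- value
    seen <- c(seen, ch)
    pos <- pos + 1L + nchar(digits)
  }
  counts
}

#' Render a composition count vector back to its canonical label
#'
#' Letters appear in H, N, F, S order; zero counts are omitted. Rendering
#' then re-parsing yields identical counts (round-trip contract).
#'
#' @param counts Named integer vector with elements `H`, `N`, `F`, `S`.
#' @return Canonical label, e.g. `"H4N2F3"`.
#' @export
render_composition <- function(counts) {
  counts <- counts[c("H", "N", "F", "S")]
  if (any(is.na(counts)) || any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with at least one positive entry",
         call. = FALSE)
  }
  keep <- counts > 0
  paste0(names(counts)[keep], counts[keep], collapse = "")
}

class_of_counts <- function(ct) {
  has_f <- ct[["F"]] > 0
  has_s <- ct[["S"]] > 0
  if (has_f && has_s) "fucosylated_sialylated"
  else if (has_f) "fucosylated_only"
  else if (has_s) "sialylated_only"
  else "undecorated"
}

#' Decoration class of a glycan
#'
#' Classifies a parsed composition by its fucose/sialic-acid decoration:
#' `undecorated` (F = 0, S = 0), `fucosylated_only` (F > 0, S = 0),
#' `sialylated_only` (S > 0, F = 0) or `fucosylated_sialylated` (both).
#' Ambiguous (slash) labels get the class only when every alternative
#' agrees, else `ambiguous`; the unknown marker maps to `unknown`.
#'
#' @param comp A `composition_set` from [parse_composition()].
#' @return One of `"undecorated"`, `"fucosylated_only"`,
#'   `"sialylated_only"`, `"fucosylated_sialylated"`, `"unknown"`,
#'   `"ambiguous"`.
#' @export
decoration_class <- function(comp) {
  stopifnot(inherits(comp, "composition_set"))
  if (comp$unknown) return("unknown")
  cls <- unique(vapply(comp$alternatives, class_of_counts, ""))
  if (length(cls) == 1L) cls else "ambiguous"
}

fucose_band_of <- function(f) {
  if (f == 0) "F0" else if (f == 1) "F1" else if (f <= 4) "F2to4" else "F_gt4"
}

sialic_band_of <- function(s) {
  if (s == 0) "S0" else if (s == 1) "S1" else if (s == 2) "S2" else "S_gt2"
}

#' Fucosylation and sialylation bands of a glycan
#'
#' Bands follow the field's figure conventions: mono-fucosylated F1, di- to
#' tetra-fucosylated F2to4, mono-sialylated S1, di-sialylated S2; F0/S0 for
#' undecorated and separate F_gt4/S_gt2 bands for heavier decoration (never
#' merged into F2to4/S2). Ambiguous labels get a band only when all
#' alternatives fall in the same band.
#'
#' @param comp A `composition_set`.
#' @return List with `fucose_band` and `sialic_band` character scalars.
#' @export
decoration_bands <- function(comp) {
  stopifnot(inherits(comp, "composition_set"))
  if (comp$unknown) {
    return(list(fucose_band = "unknown", sialic_band = "unknown"))
  }
  fb <- unique(vapply(comp$alternatives,
                      function(ct) fucose_band_of(ct[["F"]]), ""))
  sb <- unique(vapply(comp$alternatives,
                      function(ct) sialic_band_of(ct[["S"]]), ""))
  list(fucose_band = if (length(fb) == 1L) fb else "ambiguous",
       sialic_band = if (length(sb) == 1L) sb else "ambiguous")
}

#' Classify every glycan of an array library
#'
#' Parses each composition label and attaches decoration class and bands.
#' Unparseable labels are not fatal: they are classified `unknown` and a
#' warning lists them.
#'
#' @param labels Character vector of composition labels.
#' @param ids Glycan identifiers (default `g001`, `g002`, ...).
#' @return Data frame with one row per glycan: `glycan_id`,
#'   `composition_label`, `class`, `fucose_band`, `sialic_band`. The
#'   per-class summary counts are attached as attribute `"class_counts"`.
#' @export
partition_library <- function(labels, ids = NULL) {
  n <- length(labels)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  cls <- character(n)
  fb <- character(n)
  sb <- character(n)
  bad <- character(0)
  for (i in seq_len(n)) {
    comp <- tryCatch(parse_composition(labels[i]), error = function(e) NULL)
    if (is.null(comp)) {
      bad <- c(bad, labels[i])
      cls[i] <- "unknown"
      fb[i] <- "unknown"
      sb[i] <- "unknown"
    } else {
      cls[i] <- decoration_class(comp)
      bands <- decoration_bands(comp)
      fb[i] <- bands$fucose_band
      sb[i] <- bands$sialic_band
    }
  }
  if (length(bad) > 0) {
    warning(sprintf("%d unparseable composition label(s) classified unknown: %s",
                    length(bad), paste(utils::head(bad, 5), collapse = ", ")),
            call. = FALSE)
  }
  out <- data.frame(glycan_id = ids, composition_label = labels,
                    class = cls, fucose_band = fb, sialic_band = sb,
                    stringsAsFactors = FALSE)
  attr(out, "class_counts") <- table(factor(
    cls, levels = c("undecorated", "fucosylated_only", "sialylated_only",
                    "fucosylated_sialylated", "unknown", "ambiguous")))
  out
}

#' Read and classify a library composition file
#'
#' @param path TSV with header columns `glycan_id` and `composition_label`.
#' @return As [partition_library()].
#' @export
read_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("glycan_id", "composition_label")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("library file missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  partition_library(tab$composition_label, ids = tab$glycan_id)
}
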