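#' Configuration for a synthetic glycan-array study
#'
#' Defaults emulate the design of the serology study the pipeline targets:
#' a ~220-feature oligosaccharide library with hexose/HexNAc/fucose/sialic
#' compositions, serum groups of 20 controls, 17 UC and 23 CD, a planted
#' CD-specific log2 elevation on the di- to tetra-fucosylated (F2to4)
#' subgroup, and an IgM channel coupled to IgG within each serum.
#'
#' @param n_glycans Library size (default 220).
#' @param class_mix Named proportions of composition classes generated
#'   (`undecorated`, `fucosylated_f1`, `fucosylated_f2to4`, `sialylated`,
#'   `fucosylated_sialylated`); must sum to 1. The default mix is a
#'   configurable stand-in, not a published library composition.
#' @param group_sizes Named sizes for `ctrl`, `UC`, `CD` (default
#'   20/17/23); each >= 2.
#' @param target_band Fucose band receiving the planted CD shift (default
#'   `"F2to4"`).
#' @param delta Planted log2 shift for CD samples on the target subgroup
#'   (default 1.5, >= 0).
#' @param baseline_mean,baseline_sd Per-glycan baseline log2 RFU
#'   distribution (default Normal(7, 1.2)).
#' @param sample_offset_sd SD of the per-serum reactivity offset
#'   (default 0.5); emulates serum-wide scale differences.
#' @param noise_sd Per-cell log2 noise SD (default 1).
#' @param replicates Spots printed per glycan (default 4).
#' @param background_meanlog,background_sdlog Lognormal per-spot background
#'   RFU (default meanlog log(100), sdlog 0.3).
#' @param spot_noise_sd Additive RFU noise per spot measurement
#'   (default 5).
#' @param rho Isotype coupling in `[0, 1]` (default 0.8): the IgM channel
#'   shares the glycan baseline and mixes a fraction `rho` of the IgG
#'   per-cell deviations.
#' @param isotypes Channels to simulate (default IgG and IgM).
#' @param seed RNG seed.
#' @return Validated `array_sim_config` list.
#' @export
array_sim_config <- function(n_glycans = 220,
                             class_mix = c(undecorated = 0.20,
                                           fucosylated_f1 = 0.25,
                                           fucosylated_f2to4 = 0.25,
                                           sialylated = 0.20,
                                           fucosylated_sialylated = 0.10),
                             group_sizes = c(ctrl = 20, UC = 17, CD = 23),
                             target_band = "F2to4",
                             delta = 1.5,
                             baseline_mean = 7, baseline_sd = 1.2,
                             sample_offset_sd = 0.5,
                             noise_sd = 1,
                             replicates = 4,
                             background_meanlog = log(100),
                             background_sdlog = 0.3,
                             spot_noise_sd = 5,
                             rho = 0.8,
                             isotypes = c("IgG", "IgM"),
                             seed = 1) {
  cfg <- list(n_glycans = n_glycans, class_mix = class_mix,
              group_sizes = group_sizes, target_band = target_band,
              delta = delta, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              sample_offset_sd = sample_offset_sd, noise_sd = noise_sd,
              replicates = replicates,
              background_meanlog = background_meanlog,
              background_sdlog = background_sdlog,
              spot_noise_sd = spot_noise_sd, rho = rho,
              isotypes = isotypes, seed = seed)
  problems <- character(0)
  if (n_glycans < 1) problems <- c(problems, "n_glycans must be >= 1")
  if (abs(sum(class_mix) - 1) > 1e-8) {
    problems <- c(problems, "class_mix must sum to 1")
  }
  if (!setequal(names(group_sizes), c("ctrl", "UC", "CD")) ||
      any(group_sizes < 2)) {
    problems <- c(problems, "group_sizes needs ctrl/UC/CD each >= 2")
  }
  if (delta < 0) problems <- c(problems, "delta must be >= 0")
  if (rho < 0 || rho > 1) problems <- c(problems, "rho must be in [0, 1]")
  if (replicates < 1) problems <- c(problems, "replicates must be >= 1")
  if (any(c(baseline_sd, sample_offset_sd, noise_sd, spot_noise_sd,
            background_sdlog) < 0)) {
    problems <- c(problems, "all SD parameters must be >= 0")
  }
  if (length(problems) > 0) {
    stop(paste(c("invalid array simulation config:", problems),
               collapse = "\n  "), call. = FALSE)
  }
  structure(cfg, class = "array_sim_config")
}

# Draw one composition count vector for a class label.
random_composition <- function(cls) {
  h <- sample(2:9, 1)
  n <- max(h - 2L, 0L)
  f <- switch(cls,
              undecorated = 0L, sialylated = 0L,
              fucosylated_f1 = 1L,
              fucosylated_f2to4 = sample(2:4, 1),
              fucosylated_sialylated = sample(1:4, 1))
  s <- switch(cls,
              undecorated = 0L, fucosylated_f1 = 0L,
              fucosylated_f2to4 = 0L,
              sialylated = sample(1:2, 1),
              fucosylated_sialylated = sample(1:2, 1))
  c(H = h, N = n, F = f, S = s)
}

#' Simulate a glycan-array serology study
#'
#' Generates a spot-level scanner export plus metadata and ground truth.
#' Per glycan g a baseline `b_g ~ Normal(mean, sd)`; per sample i a serum
#' offset; CD samples get the planted `delta` added on every glycan of the
#' target fucose band; per-cell Normal noise on the log2 scale. The IgM
#' channel shares `b_g` and the planted effect, with per-cell deviations
#' mixed as `rho * e + sqrt(1 - rho^2) * u`. Spot foreground is
#' `2^level + background + noise` replicated `replicates` times; the
#' reported background is the same per-spot background plus independent
#' measurement noise, so background subtraction is unbiased. Deterministic
#' under the config seed.
#'
#' @param config An [array_sim_config()].
#' @return List: `spots` (data frame as read by [read_spot_table()]),
#'   `samples` (metadata with `group` and `igg_concentration`), `library`
#'   (`glycan_id`, `composition_label`), `truth` (planted glycan ids,
#'   delta, config echo).
#' @export
simulate_array_study <- function(config = array_sim_config()) {
  stopifnot(inherits(config, "array_sim_config"))
  set.seed(config$seed)
  n_g <- config$n_glycans
  cls <- sample(names(config$class_mix), n_g, replace = TRUE,
                prob = config$class_mix)
  counts <- t(vapply(cls, random_composition, c(H = 0L, N = 0L, F = 0L,
                                                S = 0L)))
  labels <- apply(counts, 1, render_composition)
  glycan_ids <- sprintf("g%03d", seq_len(n_g))
  target <- vapply(counts[, "F"], fucose_band_of, "") == config$target_band

  groups <- rep(names(config$group_sizes), config$group_sizes)
  n_s <- length(groups)
  sample_ids <- sprintf("s%02d_%s", seq_len(n_s), groups)
  samples <- data.frame(sample_id = sample_ids, group = groups,
                        igg_concentration = stats::rlnorm(n_s, log(10), 0.25),
                        stringsAsFactors = FALSE)

  b <- stats::rnorm(n_g, config$baseline_mean, config$baseline_sd)
  planted <- outer(groups == "CD", target) * config$delta
  base_level <- matrix(b, n_s, n_g, byrow = TRUE) + planted

  levels_by_iso <- list()
  if ("IgG" %in% config$isotypes || "IgM" %in% config$isotypes) {
    o_g <- stats::rnorm(n_s, 0, config$sample_offset_sd)
    e <- matrix(stats::rnorm(n_s * n_g, 0, config$noise_sd), n_s, n_g)
    if ("IgG" %in% config$isotypes) {
      levels_by_iso[["IgG"]] <- base_level + o_g + e
    }
    if ("IgM" %in% config$isotypes) {
      o_m <- stats::rnorm(n_s, 0, config$sample_offset_sd)
      u <- matrix(stats::rnorm(n_s * n_g, 0, config$noise_sd), n_s, n_g)
      levels_by_iso[["IgM"]] <- base_level + o_m +
        config$rho * e + sqrt(1 - config$rho^2) * u
    }
  }

  spot_frames <- lapply(names(levels_by_iso), function(iso) {
    lv <- levels_by_iso[[iso]]
    n_cells <- length(lv)
    reps <- config$replicates
    signal <- rep(as.vector(2^lv), times = reps)
    n_spots <- n_cells * reps
    bg_spot <- stats::rlnorm(n_spots, config$background_meanlog,
                             config$background_sdlog)
    fg <- pmax(signal + bg_spot +
                 stats::rnorm(n_spots, 0, config$spot_noise_sd), 0)
    bg <- pmax(bg_spot + stats::rnorm(n_spots, 0, config$spot_noise_sd), 0)
    data.frame(
      sample_id = rep(rep(sample_ids, times = n_g), times = reps),
      isotype = iso,
      glycan_id = rep(rep(glycan_ids, each = n_s), times = reps),
      replicate = rep(seq_len(reps), each = n_cells),
      foreground = fg, background = bg, stringsAsFactors = FALSE)
  })
  spots <- do.call(rbind, spot_frames)

  truth <- list(affected_glycans = glycan_ids[target],
                delta = config$delta,
                target_band = config$target_band,
                true_levels_igg = if ("IgG" %in% config$isotypes)
                  levels_by_iso[["IgG"]] else NULL,
                seed = config$seed,
                config = config)
  list(spots = spots, samples = samples,
       library = data.frame(glycan_id = glycan_ids,
                            composition_label = labels,
                            stringsAsFactors = FALSE),
       truth = truth)
}

default_sort_taxa <- function() {
  lin <- function(f, g = NULL, s = NULL,
                  o = "o:Unspecified", p = "p:Bacillota") {
    parts <- c("d:Bacteria", p, "c:Unspecified", o, paste0("f:", f))
    if (!is.null(g)) parts <- c(parts, paste0("g:", g))
    if (!is.null(s)) parts <- c(parts, paste0("s:", s))
    paste(parts, collapse = ";")
  }
  bac <- function(s) {
    paste("d:Bacteria", "p:Bacteroidota", "c:Bacteroidia", "o:Bacteroidales",
          "f:Bacteroidaceae", "g:Bacteroides", paste0("s:Bacteroides ", s),
          sep = ";")
  }
  lineages <- c(
    bac("stercoris"), bac("vulgatus"), bac("thetaiotaomicron"),
    lin("Peptoniphilaceae", "Peptoniphilus"),
    lin("Paenibacillaceae", "Paenibacillus"),
    lin("Lachnospiraceae", "Agathobacter"),
    lin("Lachnospiraceae", "Anaerostipes"),
    lin("Enterobacteriaceae", "Escherichia", p = "p:Pseudomonadota"),
    lin("Enterococcaceae", "Enterococcus"),
    lin("Eubacteriaceae", "Eubacterium"),
    lin("Erysipelotrichaceae", "Holdemania"),
    lin("Eggerthellaceae", "Slackia", p = "p:Actinomycetota"),
    lin("Morganellaceae", "Proteus", p = "p:Pseudomonadota"),
    lin("Oscillospiraceae", "Ruminococcus"),
    lin("Oscillospiraceae", "Ruminococcus"),
    lin("Tannerellaceae", "Parabacteroides", p = "p:Bacteroidota"),
    lin("Oscillospiraceae", "Ruthenibacterium"),
    lin("Lachnospiraceae", "Lachnospira"),
    lin("Bifidobacteriaceae", "Bifidobacterium", p = "p:Actinomycetota"),
    lin("Oscillospiraceae", "Faecalibacterium"),
    lin("Lachnospiraceae", "Blautia"),
    lin("Lachnospiraceae", "Roseburia"),
    lin("Lachnospiraceae"),
    lin("Ruminococcaceae"),
    lin("Muribaculaceae", p = "p:Bacteroidota")
  )
  data.frame(otu_id = sprintf("otu%02d", seq_along(lineages)),
             lineage = lineages,
             planted = grepl("g:Bacteroides;", paste0(lineages, ";")),
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic sorted-fraction sequencing study
#'
#' Defaults emulate the sorting design the pipeline targets: a gut-like
#' community with one planted multi-species *Bacteroides* genus bound by
#' both the fucose lectin and CD-serum IgG, 6 IgG-sorted samples per serum
#' group plus 3 lectin-sorted replicates, each with a matched unsorted
#' sample at the same read depth.
#'
#' @param taxa Data frame `otu_id`, `lineage`, `planted`; default a
#'   25-OTU gut-like community with a planted 3-species *Bacteroides*
#'   genus.
#' @param dirichlet_alpha Dirichlet concentration per OTU (scalar or
#'   vector, default 5).
#' @param capture_lo,capture_hi Capture probabilities for unbound vs bound
#'   taxa (defaults 0.2 and 0.6, ratio 3); in (0, 1] with `capture_hi >=
#'   capture_lo` (equality gives the uniform-capture null).
#' @param depth Reads per sample (default 2e4).
#' @param igg_sorted_per_group IgG-sorted samples per serum group
#'   (default 6).
#' @param aal_replicates Lectin-sorted replicates (default 3).
#' @param seed RNG seed.
#' @return Validated `sort_sim_config` list.
#' @export
sort_sim_config <- function(taxa = default_sort_taxa(),
                            dirichlet_alpha = 5,
                            capture_lo = 0.2, capture_hi = 0.6,
                            depth = 2e4,
                            igg_sorted_per_group = 6,
                            aal_replicates = 3,
                            seed = 1) {
  problems <- character(0)
  if (!all(c("otu_id", "lineage", "planted") %in% names(taxa))) {
    problems <- c(problems, "taxa needs otu_id, lineage, planted columns")
  } else if (!any(taxa$planted)) {
    problems <- c(problems, "at least one planted taxon required")
  }
  if (any(c(capture_lo, capture_hi) <= 0) ||
      any(c(capture_lo, capture_hi) > 1)) {
    problems <- c(problems, "capture probabilities must be in (0, 1]")
  } else if (capture_hi < capture_lo) {
    # equality is allowed: uniform capture is the null (no planted binding)
    problems <- c(problems, "capture_hi must be >= capture_lo")
  }
  if (depth <= 0) problems <- c(problems, "depth must be > 0")
  if (any(dirichlet_alpha <= 0)) {
    problems <- c(problems, "dirichlet_alpha must be > 0")
  }
  if (length(problems) > 0) {
    stop(paste(c("invalid sort simulation config:", problems),
               collapse = "\n  "), call. = FALSE)
  }
  alpha <- rep_len(dirichlet_alpha, nrow(taxa))
  structure(list(taxa = taxa, dirichlet_alpha = alpha,
                 capture_lo = capture_lo, capture_hi = capture_hi,
                 depth = depth, igg_sorted_per_group = igg_sorted_per_group,
                 aal_replicates = aal_replicates, seed = seed),
            class = "sort_sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a sorted-fraction 16S study
#'
#' One true community `pi ~ Dirichlet(alpha)` per study. Unsorted samples
#' are `Multinomial(depth, pi)`. A sorted sample captures taxon t with
#' probability `p_t` (lectin: high for planted taxa; IgG: high for planted
#' taxa under CD sera only), so its composition is `pi_t * p_t`
#' renormalized, sampled multinomially at the same depth. Every sorted
#' sample has its own matched unsorted sample.
#'
#' @param config A [sort_sim_config()].
#' @return List: `otu` (an `otu_table`), `truth` (planted genus key and
#'   OTUs, true proportions, capture vectors, expected folds, config
#'   echo).
#' @export
simulate_sort_study <- function(config = sort_sim_config()) {
  stopifnot(inherits(config, "sort_sim_config"))
  set.seed(config$seed)
  taxa <- config$taxa
  n_t <- nrow(taxa)
  pi <- rdirichlet1(config$dirichlet_alpha)
  p_bound <- ifelse(taxa$planted, config$capture_hi, config$capture_lo)
  p_flat <- rep(config$capture_lo, n_t)

  cols <- list()
  sheet <- list()
  add_pair <- function(sid, fraction, serum_group, capture) {
    sorted_prob <- pi * capture / sum(pi * capture)
    uid <- paste0(sid, "_uns")
    cols[[sid]] <<- stats::rmultinom(1, config$depth, sorted_prob)[, 1]
    cols[[uid]] <<- stats::rmultinom(1, config$depth, pi)[, 1]
    sheet[[sid]] <<- data.frame(sample_id = sid, fraction = fraction,
                                serum_group = serum_group,
                                matched_unsorted_id = uid,
                                stringsAsFactors = FALSE)
    sheet[[uid]] <<- data.frame(sample_id = uid, fraction = "unsorted",
                                serum_group = serum_group,
                                matched_unsorted_id = NA_character_,
                                stringsAsFactors = FALSE)
  }
  for (r in seq_len(config$aal_replicates)) {
    add_pair(sprintf("aal%d", r), "AAL_pos", "none", p_bound)
  }
  for (g in c("ctrl", "UC", "CD")) {
    capture <- if (g == "CD") p_bound else p_flat
    for (r in seq_len(config$igg_sorted_per_group)) {
      add_pair(sprintf("igg_%s%d", g, r), "IgG_pos", g, capture)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- taxa$otu_id
  storage.mode(counts) <- "integer"
  samples <- do.call(rbind, sheet)
  rownames(samples) <- NULL
  otu <- new_otu_table(counts, taxa[, c("otu_id", "lineage")], samples)

  planted_key <- unique(vapply(taxa$lineage[taxa$planted], taxon_key, "",
                               rank = "genus", USE.NAMES = FALSE))
  truth <- list(planted_genus_keys = planted_key,
                planted_otus = taxa$otu_id[taxa$planted],
                true_proportions = stats::setNames(pi, taxa$otu_id),
                capture_bound = p_bound, capture_uniform = p_flat,
                expected_fold_bound = config$capture_hi /
                  sum(pi * p_bound),
                seed = config$seed, config = config)
  list(otu = otu, truth = truth)
}

#' Simulate a qPCR Ct table from true target proportions
#'
#' With perfect efficiency (doubling per cycle) the total-bacteria
#' amplicon exits at `ct_base` and the target at
#' `ct_base - log2(p) + Normal(0, noise_sd)`, so the expected `2^-dCt`
#' equals the true proportion `p`.
#'
#' @param proportions Named numeric vector in (0, 1]: true target
#'   fractions per sample.
#' @param noise_sd Ct noise SD on the target channel (default 0.1).
#' @param ct_base Reference Ct (default 15).
#' @param target Target name (default `"genus_target"`).
#' @param seed RNG seed.
#' @return List: `ct` (data frame `sample_id`, `target`, `Ct`,
#'   `plate_id`), `truth` (the proportions and parameters).
#' @export
simulate_qpcr <- function(proportions, noise_sd = 0.1, ct_base = 15,
                          target = "genus_target", seed = 1) {
  if (any(proportions <= 0) || any(proportions > 1)) {
    stop("proportions must be in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  ids <- if (is.null(names(proportions)))
    sprintf("q%02d", seq_along(proportions)) else names(proportions)
  ct <- rbind(
    data.frame(sample_id = ids, target = "total_bacteria",
               Ct = rep(ct_base, length(ids)), plate_id = "p1",
               stringsAsFactors = FALSE),
    data.frame(sample_id = ids, target = target,
               Ct = ct_base - log2(proportions) +
                 stats::rnorm(length(ids), 0, noise_sd),
               plate_id = "p1", stringsAsFactors = FALSE))
  list(ct = ct, truth = list(proportions = stats::setNames(proportions, ids),
                             noise_sd = noise_sd, ct_base = ct_base,
                             seed = seed))
}

#' Write a complete synthetic study to disk
#'
#' Emits every input the pipeline consumes as plain TSV plus a
#' machine-readable truth JSON: spot table, sample metadata, OTU counts,
#' taxonomy, sample sheet, qPCR Ct table, truth. Filenames are fixed;
#' reruns with the same configs are byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param array_config An [array_sim_config()].
#' @param sort_config A [sort_sim_config()].
#' @param qpcr_noise_sd Ct noise for the qPCR table (default 0.1).
#' @return Invisibly, named vector of the 7 file paths.
#' @export
write_fixtures <- function(dir, array_config = array_sim_config(),
                           sort_config = sort_sim_config(),
                           qpcr_noise_sd = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- simulate_array_study(array_config)
  srt <- simulate_sort_study(sort_config)

  pct <- relative_abundance(aggregate_taxa(srt$otu, "genus")$counts)
  planted_pct <- colSums(pct[srt$truth$planted_genus_keys, , drop = FALSE])
  qp <- simulate_qpcr(pmin(pmax(planted_pct / 100, 1e-6), 1),
                      noise_sd = qpcr_noise_sd,
                      seed = sort_config$seed + 1L)

  tsv <- function(x, name) {
    path <- file.path(dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  counts_df <- data.frame(otu_id = rownames(srt$otu$counts),
                          srt$otu$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  truth <- list(
    array = arr$truth[c("affected_glycans", "delta", "target_band", "seed")],
    sort = srt$truth[c("planted_genus_keys", "planted_otus",
                       "true_proportions", "expected_fold_bound", "seed")],
    qpcr = qp$truth)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(
    spot_table = tsv(arr$spots, "spot_table.tsv"),
    sample_metadata = tsv(arr$samples, "sample_metadata.tsv"),
    otu_counts = tsv(counts_df, "otu_counts.tsv"),
    taxonomy = tsv(srt$otu$taxonomy, "taxonomy.tsv"),
    sample_sheet = tsv(srt$otu$samples, "sample_sheet.tsv"),
    qpcr_ct = tsv(qp$ct, "qpcr_ct.tsv"),
    truth = truth_path)
  invisible(files)
}
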