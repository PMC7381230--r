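test_that("composition labels parse to the expected counts", {
  cases <- list(
    list(label = "H4N2F3", counts = c(H = 4L, N = 2L, F = 3L, S = 0L)),
    list(label = "H3N1S1", counts = c(H = 3L, N = 1L, F = 0L, S = 1L)),
    list(label = "H7N5",   counts = c(H = 7L, N = 5L, F = 0L, S = 0L)),
    list(label = "F1H2",   counts = c(H = 2L, N = 0L, F = 1L, S = 0L)),
    list(label = "H10N8F4", counts = c(H = 10L, N = 8L, F = 4L, S = 0L))
  )
  for (cs in cases) {
    comp <- parse_composition(cs$label)
    expect_length(comp$alternatives, 1L)
    expect_identical(comp$alternatives[[1]], cs$counts, label = cs$label)
    expect_false(comp$unknown)
  }
})

test_that("aliases are stripped and retained, never classified on", {
  comp <- parse_composition("H2F1 (3-FL)")
  expect_identical(comp$alternatives[[1]], c(H = 2L, N = 0L, F = 1L, S = 0L))
  expect_identical(comp$alias, "3-FL")
  comp2 <- parse_composition("H3N1S1 (LSTb)")
  expect_identical(comp2$alias, "LSTb")
  expect_identical(decoration_class(comp2), "sialylated_only")
  # alias with spaces and digits
  expect_identical(parse_composition("H3N1F1 (LNnFP V)")$alias, "LNnFP V")
})

test_that("slash labels give de-duplicated alternatives; unknown is marked", {
  comp <- parse_composition("H6N4F4/H7N5F2")
  expect_length(comp$alternatives, 2L)
  expect_identical(comp$alternatives[[1]], c(H = 6L, N = 4L, F = 4L, S = 0L))
  expect_identical(comp$alternatives[[2]], c(H = 7L, N = 5L, F = 2L, S = 0L))
  expect_length(parse_composition("H2F1/H2F1")$alternatives, 1L)
  unk <- parse_composition("unknown")
  expect_true(unk$unknown)
  expect_length(unk$alternatives, 0L)
  expect_true(parse_composition("Unknown")$unknown)
})

test_that("malformed labels fail naming the offending token and position", {
  expect_error(parse_composition("H0N2"), "H0.*position 1")
  expect_error(parse_composition("X3"), "'X' at position 1")
  expect_error(parse_composition("H2X3"), "'X' at position 3")
  expect_error(parse_composition("H2N"), "position 3.*without a count")
  expect_error(parse_composition("3H2"), "'3' at position 1")
  expect_error(parse_composition("H2H3"), "duplicate.*'H'")
  expect_error(parse_composition(""), "non-empty")
  expect_error(parse_composition("H2/"), "empty alternative")
  # position is relative to the full label across alternatives
  expect_error(parse_composition("H2F1/H0"), "position 6")
})

test_that("render/parse round-trips over random grammar-valid compositions", {
  set.seed(42)
  for (i in 1:200) {
    counts <- c(H = sample(0:12, 1), N = sample(0:9, 1),
                F = sample(0:6, 1), S = sample(0:4, 1))
    if (sum(counts) == 0) counts["H"] <- 1L
    label <- render_composition(counts)
    reparsed <- parse_composition(label)$alternatives[[1]]
    expect_identical(as.integer(reparsed), as.integer(counts))
  }
})

test_that("decoration class follows the fucose/sialic partition rules", {
  expect_identical(decoration_class(parse_composition("H5N3")),
                   "undecorated")
  expect_identical(decoration_class(parse_composition("H4N2F2S1")),
                   "fucosylated_sialylated")
  expect_identical(decoration_class(parse_composition("H4N2F3")),
                   "fucosylated_only")
  expect_identical(decoration_class(parse_composition("H6N4S1")),
                   "sialylated_only")
  # alternatives agreeing on the class keep it; disagreeing -> ambiguous
  expect_identical(decoration_class(parse_composition("H6N4F4/H7N5F2")),
                   "fucosylated_only")
  expect_identical(decoration_class(parse_composition("H5N3/H5N3F1")),
                   "ambiguous")
  expect_identical(decoration_class(parse_composition("unknown")), "unknown")
})

test_that("decoration bands honor the F1/F2to4 and S1/S2 conventions", {
  b <- decoration_bands(parse_composition("H4N2F3"))
  expect_identical(b$fucose_band, "F2to4")
  expect_identical(b$sialic_band, "S0")
  b <- decoration_bands(parse_composition("H3N1S1"))
  expect_identical(b$fucose_band, "F0")
  expect_identical(b$sialic_band, "S1")
  # heavier decoration stays in its own band, never merged
  expect_identical(decoration_bands(parse_composition("H9N7F5"))$fucose_band,
                   "F_gt4")
  expect_identical(decoration_bands(parse_composition("H5N3S3"))$sialic_band,
                   "S_gt2")
  # alternatives within the same band agree; across bands -> ambiguous
  expect_identical(decoration_bands(parse_composition("H6N4F4/H7N5F2"))$fucose_band,
                   "F2to4")
  expect_identical(decoration_bands(parse_composition("H6N4F1/H7N5F2"))$fucose_band,
                   "ambiguous")
})

test_that("band membership implies a fucosylated decoration class", {
  set.seed(7)
  for (i in 1:100) {
    counts <- c(H = sample(1:9, 1), N = sample(0:7, 1),
                F = sample(0:6, 1), S = sample(0:3, 1))
    comp <- parse_composition(render_composition(counts))
    fb <- decoration_bands(comp)$fucose_band
    if (fb %in% c("F1", "F2to4")) {
      expect_true(decoration_class(comp) %in%
                    c("fucosylated_only", "fucosylated_sialylated"))
    }
  }
})

test_that("partition_library covers every glycan exactly once", {
  labels <- c("H5N3", "H4N2F1", "H3N1S1")
  part <- partition_library(labels)
  expect_identical(nrow(part), 3L)
  counts <- attr(part, "class_counts")
  expect_identical(as.integer(counts[c("undecorated", "fucosylated_only",
                                       "sialylated_only")]),
                   c(1L, 1L, 1L))
  expect_identical(sum(counts), 3L)
  # empty library
  empty <- partition_library(character(0))
  expect_identical(nrow(empty), 0L)
  expect_identical(sum(attr(empty, "class_counts")), 0L)
  # unparseable entries are classified unknown with a warning, not dropped
  expect_warning(mixed <- partition_library(c("H2F1", "garbage!")),
                 "unparseable")
  expect_identical(nrow(mixed), 2L)
  expect_identical(mixed$class[2], "unknown")
})

test_that("partition is exhaustive over random libraries", {
  set.seed(11)
  labels <- replicate(300, {
    counts <- c(H = sample(1:9, 1), N = sample(0:7, 1),
                F = sample(0:5, 1), S = sample(0:3, 1))
    render_composition(counts)
  })
  part <- partition_library(labels)
  expect_identical(sum(attr(part, "class_counts")), length(labels))
  expect_false(anyDuplicated(part$glycan_id) > 0)
})
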