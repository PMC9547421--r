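test_that("default rule table encodes the subtype consensus definitions", {
  rules <- default_rule_table()
  names_ <- vapply(rules, `[[`, character(1), "name")
  expect_equal(names_, c("RING-M", "RING-D", "RING-H2", "RING-HC", "IBR"))
  h2 <- rules[[match("RING-H2", names_)]]
  expect_equal(h2$allowed[[4]], "H")
  expect_equal(h2$allowed[[5]], "H")
  hc <- rules[[match("RING-HC", names_)]]
  expect_equal(hc$allowed[[4]], "H")
  expect_equal(hc$allowed[[5]], "C")
  m <- rules[[match("RING-M", names_)]]
  expect_equal(m$allowed[[1]], "M")
  expect_equal(m$allowed[[2]], "R")
  expect_equal(vapply(m$spacers, `[`, integer(1), 1),
               c(2L, 14L, 1L, 2L, 2L, 10L, 2L))
  expect_equal(vapply(m$spacers, `[`, integer(1), 2),
               c(2L, 14L, 1L, 2L, 2L, 10L, 2L))
  ibr <- rules[[match("IBR", names_)]]
  expect_true(ibr$accessory)
  expect_length(ibr$allowed, 9L)
})

test_that("rule tables survive a JSON round-trip", {
  rules <- default_rule_table()
  f <- withr::local_tempfile(fileext = ".json")
  write_rule_table(rules, f)
  back <- read_rule_table(f)
  expect_equal(back, rules)
})

test_that("the RING-M exemplar yields exactly one hit at the planted ligands", {
  ex <- make_ring_protein("RING-M", spacers = c(2, 14, 1, 2, 2, 10, 2),
                          flank_lengths = c(0, 0), seed = 1, filler = "A")
  expect_equal(nchar(ex$record$sequence), 41L)
  rules <- default_rule_table()
  hits <- scan_rule(ex$record$sequence, rules[[1]])
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$positions, c(0L, 3L, 18L, 20L, 23L, 26L, 37L, 40L))
  expect_equal(hits[[1]]$residues,
               c("M", "R", "C", "H", "C", "C", "C", "C"))
  expect_equal(hits[[1]]$start, 0L)
  expect_equal(hits[[1]]$end, 41L)
})

test_that("a sequence without His cannot satisfy the H2/HC rules", {
  seq <- paste0("CAAC", strrep("A", 12), "CAAAAAAAAAACAACAAAAC")
  rules <- default_rule_table()
  names_ <- vapply(rules, `[[`, character(1), "name")
  expect_length(scan_rule(seq, rules[[match("RING-H2", names_)]]), 0L)
  expect_length(scan_rule(seq, rules[[match("RING-HC", names_)]]), 0L)
})

test_that("two non-overlapping planted domains give two ordered hits", {
  a <- make_ring_protein("RING-H2", flank_lengths = c(0, 30), seed = 2)
  b <- make_ring_protein("RING-H2", flank_lengths = c(30, 0), seed = 3)
  seq <- paste0(a$record$sequence, b$record$sequence)
  rules <- default_rule_table()
  hits <- scan_rule(seq, rules[[3]])
  expect_length(hits, 2L)
  expect_true(hits[[1]]$start < hits[[2]]$start)
})

test_that("scanner agrees with the exhaustive assignment oracle", {
  rules <- default_rule_table()
  set.seed(20)
  # biased alphabet so ligand-rich sequences occur; X included deliberately
  alph <- c(ringzf:::AA_STANDARD, "X", rep(c("C", "H"), 4))
  for (i in 1:40) {
    seq <- paste(sample(alph, sample(40:120, 1), replace = TRUE),
                 collapse = "")
    for (rule in rules) {
      got <- scan_rule(seq, rule)
      exp <- oracle_scan_rule(seq, rule)
      expect_equal(length(got), length(exp),
                   info = paste("rule", rule$name, "seq", seq))
      for (k in seq_along(got))
        expect_equal(got[[k]]$positions, exp[[k]],
                     info = paste("rule", rule$name, "seq", seq))
    }
  }
})

test_that("every reported hit satisfies its rule's constraints", {
  rules <- default_rule_table()
  # planted exemplars guarantee one sound hit per rule
  for (rule in rules) {
    ex <- make_ring_protein(rule$name, flank_lengths = c(10, 10),
                            seed = 21)
    hits <- scan_rule(ex$record$sequence, rule)
    expect_gte(length(hits), 1L)
    for (h in hits) expect_true(assert_hit_sound(h, rule))
  }
  set.seed(21)
  alph <- c(ringzf:::AA_STANDARD, rep(c("C", "H", "M", "R"), 3))
  for (i in 1:30) {
    seq <- paste(sample(alph, 150, replace = TRUE), collapse = "")
    for (rule in rules) {
      for (h in scan_rule(seq, rule))
        expect_true(assert_hit_sound(h, rule))
    }
  }
})

test_that("priority resolves the RING-M / RING-HC ambiguity", {
  ex <- make_ring_protein("RING-M", spacers = c(2, 14, 1, 2, 2, 10, 2),
                          flank_lengths = c(3, 3), seed = 4)
  hits <- scan_all(ex$record$sequence)
  core <- Filter(function(h) !h$accessory, hits)
  expect_length(core, 1L)
  expect_equal(core[[1]]$subtype, "RING-M")
})

test_that("accessory IBR hits coexist with core RING hits", {
  hc <- make_ring_protein("RING-HC", flank_lengths = c(2, 2), seed = 5)
  ibr <- make_ring_protein("IBR", flank_lengths = c(2, 2), seed = 6)
  seq <- paste0(hc$record$sequence, ibr$record$sequence)
  hits <- scan_all(seq)
  labs <- vapply(hits, `[[`, character(1), "subtype")
  expect_true("RING-HC" %in% labs)
  expect_true("IBR" %in% labs)
})

test_that("decoy proteins produce no hits", {
  ps <- make_protein_set(c(), n_decoys = 10, seed = 9)
  for (s in ps$records$sequence) expect_length(scan_all(s), 0L)
})

test_that("the HCa/HCb spacer criterion splits as configured", {
  mk_hit <- function(spacers) {
    pos <- cumsum(c(0L, spacers + 1L))
    list(start = 0L, end = pos[8] + 1L, positions = pos,
         residues = c("C", "C", "C", "H", "C", "C", "C", "C"),
         spacers = spacers, subtype = "RING-HC", rule_name = "RING-HC",
         accessory = FALSE)
  }
  expect_equal(split_hc(mk_hit(c(2, 9, 1, 2, 2, 20, 2))), "RING-HCa")
  expect_equal(split_hc(mk_hit(c(2, 9, 1, 2, 2, 4, 2))), "RING-HCb")
  expect_equal(split_hc(mk_hit(c(2, 20, 1, 2, 2, 4, 2)),
                        criterion = list(spacer_index = 1L,
                                         threshold = 15L)), "RING-HCa")
  bad <- mk_hit(c(2, 9, 1, 2, 2, 4, 2)); bad$rule_name <- "RING-H2"
  expect_error(split_hc(bad), "only to RING-HC")
})

test_that("classification recovers planted subtypes and spans exactly", {
  ps <- make_protein_set(c("RING-H2" = 10, "RING-HCa" = 8, "RING-HCb" = 5,
                           "RING-D" = 2, "RING-M" = 2), n_decoys = 4,
                         seed = 11)
  cl <- classify_proteome(ps$records)
  m <- merge(cl$assignments, ps$truth, by = "protein_id")
  expect_equal(nrow(m), 27L)
  expect_equal(m$subtype.x, m$subtype.y)
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
  decoys <- cl$assignments[grepl("decoy", cl$assignments$protein_id), ]
  expect_true(all(decoys$subtype == "unclassified"))
  expect_equal(cl$census$total, 27L)
})

test_that("multi-domain proteins keep one census entry and are reported", {
  parts <- lapply(1:3, function(i)
    make_ring_protein("RING-H2", flank_lengths = c(30, 30), seed = i))
  seq <- paste(vapply(parts, function(p) p$record$sequence, character(1)),
               collapse = "")
  recs <- data.frame(id = "multi", sequence = seq, source_note = "")
  cl <- classify_proteome(recs)
  expect_equal(cl$census$total, 1L)
  expect_equal(cl$multi_domain$n_core_domains, 3L)
  expect_equal(cl$assignments$start, parts[[1]]$truth$start)
})

test_that("census percentages use half-up rounding at one decimal", {
  expect_equal(census_percentage(59, 75), 78.7)
  expect_equal(census_percentage(129, 138), 93.5)
  expect_equal(census_percentage(26, 28), 92.9)
  expect_equal(census_percentage(22, 138), 15.9)
  expect_equal(census_percentage(47, 138), 34.1)
  expect_equal(census_percentage(112, 138), 81.2)
  expect_equal(census_percentage(1, 16), 6.3)  # 6.25 rounds up, not to even
  expect_error(census_percentage(1, 0), "positive")
  expect_error(census_percentage(5, 4), "count")
})

test_that("census counts and percentages recompute from each other", {
  ps <- make_protein_set(c("RING-H2" = 7, "RING-HCa" = 6, "RING-M" = 1),
                         n_decoys = 2, seed = 13)
  cl <- classify_proteome(ps$records)
  cen <- cl$census
  expect_equal(sum(cen$counts), cen$total)
  for (nm in names(cen$counts))
    expect_equal(cen$percentages[[nm]],
                 census_percentage(cen$counts[[nm]], cen$denominator))
})
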