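# CA taxonomy decision tree, annotations, breakdowns and size filter.
# chrA has 200 bins with the centromere at bin 80; q arm = bins 81..200.

grid_t <- tiny_grid()
cons_t <- consensus_from_genome(tiny_genome(), grid_t)

seg <- function(chrom, from, to, cn1 = 1L, w1 = 1L, cn2 = 1L, w2 = 0L) {
  data.frame(chrom = chrom, from = from, to = to, cn1 = cn1, w1 = w1,
             cn2 = cn2, w2 = w2)
}

test_that("whole-chromosome deviations classify as chromosome gain/loss", {
  track <- make_track(seg("chrA", 1, 200, cn1 = 0L, w1 = 0L))
  calls <- classify_cell(track, cons_t, grid_t)
  expect_equal(calls$class, "chromosome_loss")
  expect_equal(calls$delta, -1L)
  expect_equal(calls$hap, "H1")
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 40e6)

  track2 <- make_track(seg("chrB", 1, 150, cn2 = 2L, w2 = 0L))
  calls2 <- classify_cell(track2, cons_t, grid_t)
  expect_equal(calls2$class, "chromosome_gain")
  expect_equal(calls2$hap, "H2")
})

test_that("an isolated gain over >90% of an arm is terminal with whole-arm flag", {
  # q arm of chrA is bins 81..200; 91..200 covers 110/120 bins (91.7%)
  track <- make_track(rbind(seg("chrA", 1, 90),
                            seg("chrA", 91, 200, cn1 = 2L, w1 = 2L)))
  calls <- classify_cell(track, cons_t, grid_t)
  expect_equal(calls$class, "terminal_gain")
  expect_match(calls$annotations, "whole_arm")
  expect_equal(calls$strand_config, "same")
})

test_that("isolated interior runs are interstitial; telomeric runs terminal", {
  track <- make_track(rbind(seg("chrA", 1, 29),
                            seg("chrA", 30, 40, cn1 = 2L, w1 = 2L),
                            seg("chrA", 41, 200)))
  calls <- classify_cell(track, cons_t, grid_t)
  expect_equal(calls$class, "interstitial_gain")
  expect_equal(calls$n_breakpoints, 2L)

  track2 <- make_track(rbind(seg("chrA", 1, 150),
                             seg("chrA", 151, 200, cn2 = 0L, w2 = 0L)))
  calls2 <- classify_cell(track2, cons_t, grid_t)
  expect_equal(calls2$class, "terminal_loss")
  expect_equal(calls2$hap, "H2")
})

test_that("telomere-anchored alternating runs are terminal multi-step", {
  track <- make_track(rbind(seg("chrA", 1, 149),
                            seg("chrA", 150, 180, cn1 = 2L, w1 = 2L),
                            seg("chrA", 181, 200, cn1 = 0L, w1 = 0L)))
  calls <- classify_cell(track, cons_t, grid_t)
  expect_equal(calls$class, "terminal_multistep")
  expect_equal(calls$hap, "H1")
  expect_equal(calls$start, 149 * 2e5)
  expect_equal(calls$end, 40e6)
})

test_that("copy-number oscillation between two states is chromothripsis", {
  pieces <- lapply(0:11, function(k) {
    seg("chrA", 100 + 8 * k, 107 + 8 * k,
        cn1 = ifelse(k %% 2 == 0, 0L, 1L), w1 = ifelse(k %% 2 == 0, 0L, 1L))
  })
  track <- make_track(do.call(rbind, c(list(seg("chrA", 1, 99)), pieces,
                                       list(seg("chrA", 196, 200)))))
  calls <- classify_cell(track, cons_t, grid_t)
  expect_equal(calls$class, "chromothripsis")
  expect_equal(calls$hap, "H1")
  expect_gte(calls$n_breakpoints, 5L)
})

test_that("scattered runs with more than two breakpoints are complex", {
  track <- make_track(rbind(seg("chrA", 1, 29),
                            seg("chrA", 30, 40, cn1 = 2L, w1 = 2L),
                            seg("chrA", 41, 119),
                            seg("chrA", 120, 140, cn1 = 0L, w1 = 0L),
                            seg("chrA", 141, 200)))
  calls <- classify_cell(track, cons_t, grid_t)
  expect_equal(calls$class, "complex")
  expect_equal(calls$n_breakpoints, 4L)
  # both runs on one haplotype: the call carries that haplotype
  expect_equal(calls$hap, "H1")
})

test_that("opposite-strand terminal gains are annotated as inverted duplications", {
  # host homologue H1 templated on W; gained copy on C -> opposite
  inv <- make_track(rbind(seg("chrA", 1, 150),
                          seg("chrA", 151, 200, cn1 = 2L, w1 = 1L)))
  calls <- classify_cell(inv, cons_t, grid_t)
  expect_equal(calls$class, "terminal_gain")
  expect_equal(calls$strand_config, "opposite")
  expect_match(calls$annotations, "inverted_duplication")

  # tandem (same-strand) gain is not annotated
  tan <- make_track(rbind(seg("chrA", 1, 150),
                          seg("chrA", 151, 200, cn1 = 2L, w1 = 2L)))
  calls2 <- classify_cell(tan, cons_t, grid_t)
  expect_equal(calls2$class, "terminal_gain")
  expect_false(grepl("inverted_duplication", calls2$annotations))
})

test_that("balanced two-copy gains carry the isoacentric signature", {
  bal <- make_track(rbind(seg("chrA", 1, 150),
                          seg("chrA", 151, 200, cn1 = 3L, w1 = 2L)))
  calls <- classify_cell(bal, cons_t, grid_t)
  iso <- detect_isoacentric_signature(calls, bal)
  expect_equal(iso$n_total, 1L)
  expect_equal(iso$n_balanced, 1L)
  expect_match(iso$calls$annotations, "isoacentric_signature")
  expect_match(iso$calls$annotations, "amplification")

  # both extra copies on the template strand: amplification but not isoacentric
  same <- make_track(rbind(seg("chrA", 1, 150),
                           seg("chrA", 151, 200, cn1 = 3L, w1 = 3L)))
  calls2 <- classify_cell(same, cons_t, grid_t)
  iso2 <- detect_isoacentric_signature(calls2, same)
  expect_equal(iso2$n_total, 1L)
  expect_equal(iso2$n_balanced, 0L)
})

test_that("on-breakpoint annotation marks calls near a supplied locus", {
  track <- make_track(rbind(seg("chrA", 1, 150),
                            seg("chrA", 151, 200, cn1 = 0L, w1 = 0L)))
  calls <- classify_cell(track, cons_t, grid_t, locus = "chrA:30100000")
  expect_match(calls$annotations, "on_breakpoint")
  calls2 <- classify_cell(track, cons_t, grid_t, locus = "chrA:10000000")
  expect_false(grepl("on_breakpoint", calls2$annotations))
})

test_that("class breakdown reports counts and one-decimal percentages", {
  calls <- bind_calls(make_calls("terminal_gain", 3), make_calls("terminal_loss", 1))
  bd <- class_breakdown(calls)
  expect_equal(bd$total, 4L)
  expect_equal(bd$classes[class == "terminal_gain"]$pct, 75.0)
  single <- class_breakdown(make_calls("chromosome_loss", 1))
  expect_equal(single$classes$pct, 100.0)
  empty <- class_breakdown(make_calls("terminal_gain", 0))
  expect_equal(empty$total, 0L)
})

test_that("the minimum-size filter drops sub-bin calls only", {
  small <- make_calls("interstitial_loss", 1, start = 0, end = 150000)
  big <- make_calls("interstitial_loss", 1, start = 0, end = 250000)
  calls <- bind_calls(small, big)
  kept <- filter_min_size(calls)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$end, 250000)
  expect_equal(nrow(filter_min_size(calls, 0)), 2L)
})

test_that("classification is deterministic given track, consensus and config", {
  qs <- quick_sim(3, event_rate = 1, seed = 21, events_per_cell = "fixed")
  cons <- consensus_from_genome(qs$genome, qs$grid)
  tr <- segment_population(qs$sim$counts, qs$grid, cons)
  c1 <- classify_population(tr, cons, qs$grid)
  c2 <- classify_population(tr, cons, qs$grid)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  # every call interval is consistent with its class's positional definition
  genome <- qs$genome
  for (i in seq_len(nrow(c1))) {
    len <- genome$length[match(c1$chrom[i], genome$chrom)]
    if (c1$class[i] %in% c("chromosome_gain", "chromosome_loss"))
      expect_true(c1$start[i] == 0 && c1$end[i] == len)
    if (c1$class[i] %in% c("terminal_gain", "terminal_loss", "terminal_multistep"))
      expect_true(c1$start[i] == 0 || c1$end[i] == len)
    if (c1$class[i] %in% c("interstitial_gain", "interstitial_loss"))
      expect_true(c1$start[i] > 0 && c1$end[i] < len)
  }
})
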