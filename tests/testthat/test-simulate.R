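test_that("family simulation is seed-deterministic and seed-sensitive", {
  f1 <- simulate_family(family_sim_config(seed = 1))
  f2 <- simulate_family(family_sim_config(seed = 1))
  f3 <- simulate_family(family_sim_config(seed = 2))
  expect_identical(f1$ancestor$residues, f2$ancestor$residues)
  expect_identical(lapply(f1$descendants, `[[`, "residues"),
                   lapply(f2$descendants, `[[`, "residues"))
  expect_false(identical(f1$ancestor$residues, f3$ancestor$residues))
})

test_that("zero rates reproduce the ancestor; planted structure validates", {
  fam <- simulate_family(family_sim_config(seed = 4, p_sub_srs = 0,
                                           p_sub_nonsrs = 0))
  for (d in fam$descendants) {
    expect_identical(d$residues, fam$ancestor$residues)
  }
  expect_equal(nrow(fam$edit_log), 0L)
  # generated records and annotations survive the readers' validation
  dir <- withr::local_tempdir()
  write_fasta(c(list(ancestor = fam$ancestor), fam$descendants),
              file.path(dir, "fam.fasta"))
  recs <- read_fasta(file.path(dir, "fam.fasta"))
  expect_length(recs, 1 + fam$config$n_sequences)
  write_srs_annotations(list(fam$annotation), file.path(dir, "srs.tsv"))
  back <- read_srs_annotations(file.path(dir, "srs.tsv"), recs)
  expect_equal(back$ancestor$intervals, fam$annotation$intervals)
})

test_that("region-specific rates produce the expected identity contrast", {
  # mutate everything outside the SRS regions, nothing inside
  fam <- simulate_family(family_sim_config(seed = 10, n_sequences = 3,
                                           p_sub_srs = 0,
                                           p_sub_nonsrs = 1))
  widths <- sum(srs_widths(fam$annotation))
  len <- fam$config$length
  for (d in names(fam$descendants)) {
    # sequences are collinear by construction; use the known column map so
    # the check isolates the simulator from the aligner
    aln <- alignment_from_gapped("ancestor", d, fam$ancestor$residues,
                                 fam$descendants[[d]]$residues)
    prof <- srs_identity(aln, fam$annotation,
                         fam$descendant_annotations[[d]])
    expect_equal(prof$total_srs, 100)
    # outside SRS only the two invariant motif residues match
    expect_equal(prof$full_length, 100 * (widths + 2) / len)
  }
})

test_that("the edit log records exactly the observed differences", {
  fam <- simulate_family(family_sim_config(seed = 15, n_sequences = 2))
  anc <- strsplit(fam$ancestor$residues, "")[[1]]
  for (d in names(fam$descendants)) {
    des <- strsplit(fam$descendants[[d]]$residues, "")[[1]]
    diffs <- which(anc != des)
    logged <- fam$edit_log[fam$edit_log$sequence_id == d, ]
    expect_equal(sort(logged$position), diffs)
    expect_equal(logged$ref[order(logged$position)], anc[diffs])
    expect_equal(logged$new[order(logged$position)], des[diffs])
  }
})

test_that("screen simulation is deterministic and passes the IS invariant", {
  s1 <- simulate_screen(screen_sim_config(seed = 7))
  s2 <- simulate_screen(screen_sim_config(seed = 7))
  expect_identical(s1$peaks, s2$peaks)
  expect_silent(validate_peak_table(s1$peaks))
  expect_false(identical(
    s1$peaks$area, simulate_screen(screen_sim_config(seed = 8))$peaks$area
  ))
})

test_that("a noiseless screen recovers true titers and fold changes exactly", {
  sim <- simulate_screen(screen_sim_config(seed = 1, cv = 0))
  yields <- relative_yield(sim$peaks)
  curves <- lapply(split(sim$calibration, sim$calibration$compound),
                   fit_standard_curve)
  titers <- absolute_titer(yields, curves)
  truth <- sim$truth
  merged <- merge(as.data.frame(titers), as.data.frame(truth),
                  by = c("strain", "compound"))
  expect_equal(merged$titer_mg_per_L, merged$true_titer_mg_per_L,
               tolerance = 1e-8)
  fc <- fold_change(titers, "A99I", "WT", "2", value = "titer_mg_per_L")
  true_fc <- truth$true_fold_change_vs_ref[truth$strain == "A99I" &
                                             truth$compound == "2"]
  expect_equal(fc, true_fc, tolerance = 1e-8)
})

test_that("planted truth of a known fold change is recovered noiselessly", {
  cfg <- screen_sim_config(
    seed = 2, cv = 0,
    strains = list("native" = c("1" = 10, "2" = 10),
                   "variant" = c("1" = 4, "2" = 56))
  )
  sim <- simulate_screen(cfg)
  yields <- relative_yield(sim$peaks)
  expect_equal(fold_change(yields, "variant", "native", "2"), 5.6,
               tolerance = 1e-10)
})
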