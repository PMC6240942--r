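test_that("hotspot candidates sit at fixed offsets downstream of the E", {
  rec <- planted_record()
  hit <- find_exxr(rec, search_start = 357)
  hot <- srs5_hotspots(rec, hit)
  expect_equal(hot$position, c(362L, 366L))
  expect_equal(hot$rule, rep("hotspot_srs5", 2))
  expect_equal(hot$variant_text,
               paste0(residue_at(rec, c(362, 366)), c(362, 366), "X"))
  expect_match(hot$provenance[1], "ExxR@357 \\+ 5")

  expect_equal(nrow(srs5_hotspots(rec, hit, offsets = integer())), 0L)

  # replacement panel expands each offset
  panel <- srs5_hotspots(rec, hit, offsets = 5L,
                         replacements = c("V", "F", "E"))
  expect_equal(nrow(panel), 3L)
  expect_equal(panel$variant_text,
               paste0(residue_at(rec, 362), "362", c("V", "F", "E")))
})

test_that("offsets beyond the sequence end are skipped with a warning", {
  rec <- protein_record("short", "AAEKLRAA")
  hit <- find_exxr(rec)
  expect_warning(hot <- srs5_hotspots(rec, hit, offsets = c(2L, 50L)),
                 "skipped")
  expect_equal(hot$position, 5L)
})

test_that("reciprocal candidates are empty when donor equals target", {
  fam <- simulate_family(family_sim_config(seed = 2, n_sequences = 1))
  t <- fam$descendants$desc1
  out <- reciprocal_candidates(t, t, fam$descendant_annotations$desc1,
                               global_align(t, t))
  expect_equal(nrow(out), 0L)
})

test_that("reciprocal candidates recover exactly the planted SRS differences", {
  fam <- simulate_family(family_sim_config(seed = 8, n_sequences = 1,
                                           p_sub_srs = 0.1,
                                           p_sub_nonsrs = 0.08))
  target <- fam$descendants$desc1
  donor <- fam$ancestor
  out <- reciprocal_candidates(
    target, donor, fam$descendant_annotations$desc1,
    global_align(target, donor), donor_srs = fam$annotation
  )
  planted <- fam$edit_log[fam$edit_log$in_srs, ]
  expect_equal(sort(out$position), sort(planted$position))
  expect_setequal(out$variant_text,
                  paste0(planted$new, planted$position, planted$ref))
  expect_true(all(out$rule == "reciprocal"))
})

test_that("a planted SRS6 indel surfaces as one left-anchored segment swap", {
  fam <- simulate_family(family_sim_config(seed = 12, n_sequences = 1,
                                           p_sub_srs = 0.08,
                                           p_sub_nonsrs = 0.06,
                                           indel_prob = 1,
                                           indel_length = 2L))
  target <- fam$ancestor        # carries the segment the descendant lost
  donor <- fam$descendants$desc1
  out <- reciprocal_candidates(target, donor, fam$annotation,
                               global_align(target, donor),
                               donor_srs = fam$descendant_annotations$desc1)
  swaps <- out[out$rule == "indel_swap", ]
  expect_equal(nrow(swaps), 1L)
  spec <- parse_variant(swaps$variant_text)
  # anchored swap: reference segment = anchor + the two deleted residues
  expect_equal(nchar(spec$edits$ref) - nchar(spec$edits$new), 2L)
  edited <- apply_variant(target, spec)
  expect_equal(record_length(edited), record_length(target) - 2L)
})

test_that("applying all reciprocal substitutions transfers the donor's SRS residues", {
  for (seed in c(31, 32)) {
    fam <- simulate_family(family_sim_config(seed = seed, n_sequences = 2,
                                             p_sub_srs = 0.12,
                                             p_sub_nonsrs = 0.1))
    target <- fam$descendants$desc1
    donor <- fam$descendants$desc2
    ann <- fam$descendant_annotations$desc1
    out <- reciprocal_candidates(target, donor, ann,
                                 global_align(target, donor))
    if (nrow(out) == 0L) next
    edited <- Reduce(function(r, v) apply_variant(r, v),
                     out$variant_text, accumulate = FALSE, init = target)
    # closure: every SRS residue of the edited target equals the donor's
    iv <- ann$intervals
    for (i in 1:6) {
      expect_equal(
        substr(edited$residues, iv$start[i], iv$end[i]),
        substr(donor$residues, iv$start[i], iv$end[i]),
        info = paste("seed", seed, SRS_LABELS[i])
      )
    }
  }
})

test_that("equivalent positions map through the alignment or report a miss", {
  rec <- planted_record("self")
  same <- map_equivalent_position(rec, rec, 123L)
  expect_true(same$found)
  expect_equal(same$query_position, 123L)
  expect_equal(same$query_residue, same$homolog_residue)

  # a query gap under the homolog position is an explicit miss
  qry <- protein_record("q", "MKW")
  hom <- protein_record("h", "MAKW")
  aln <- alignment_from_gapped("q", "h", "M-KW", "MAKW")
  m <- map_equivalent_position(qry, hom, 2L, aln)
  expect_false(m$found)
  expect_equal(m$homolog_residue, "A")

  expect_error(map_equivalent_position(qry, hom, 99L, aln), "out of range")
})
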