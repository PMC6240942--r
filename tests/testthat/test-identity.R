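make_annotated_pair <- function(seed, len = 100,
                                starts = c(10L, 25L, 40L, 55L, 70L, 85L),
                                ends = c(13L, 28L, 43L, 58L, 73L, 88L),
                                mutate_at = integer()) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- sample(aa, len, replace = TRUE)
  a <- protein_record("a", paste(res, collapse = ""))
  res_b <- res
  for (p in mutate_at) res_b[p] <- setdiff(aa, res[p])[1]
  b <- protein_record("b", paste(res_b, collapse = ""))
  list(a = a, b = b,
       ann_a = srs_annotation("a", starts, ends),
       ann_b = srs_annotation("b", starts, ends))
}

test_that("identical sequences give 100% in every field", {
  p <- make_annotated_pair(1)
  aln <- global_align(p$a, p$b)
  prof <- srs_identity(aln, p$ann_a, p$ann_b)
  expect_equal(unname(prof$per_srs), rep(100, 6))
  expect_equal(prof$total_srs, 100)
  expect_equal(prof$full_length, 100)
})

test_that("pooled SRS identity counts mismatching columns directly", {
  # 24 SRS residues (6 x 4); mutate 2 inside SRS1 -> SRS1 = 2/4 = 50%,
  # pooled = 22/24
  p <- make_annotated_pair(2, mutate_at = c(10L, 11L))
  prof <- srs_identity(global_align(p$a, p$b), p$ann_a, p$ann_b)
  expect_equal(unname(prof$per_srs["SRS1"]), 50)
  expect_equal(prof$total_srs, 100 * 22 / 24)
  expect_equal(prof$full_length, 98)
})

test_that("identity is symmetric and reflexive across random families", {
  fam <- simulate_family(family_sim_config(seed = 21, n_sequences = 2))
  recs <- c(list(ancestor = fam$ancestor), fam$descendants)
  anns <- c(list(ancestor = fam$annotation), fam$descendant_annotations)
  for (pair in list(c("ancestor", "desc1"), c("desc1", "desc2"))) {
    f <- srs_identity(global_align(recs[[pair[1]]], recs[[pair[2]]]),
                      anns[[pair[1]]], anns[[pair[2]]])
    r <- srs_identity(global_align(recs[[pair[2]]], recs[[pair[1]]]),
                      anns[[pair[2]]], anns[[pair[1]]])
    expect_equal(unname(f$per_srs), unname(r$per_srs), tolerance = 1e-12)
    expect_equal(f$total_srs, r$total_srs)
    expect_equal(f$full_length, r$full_length)
  }
  self <- srs_identity(global_align(fam$ancestor, fam$ancestor),
                       fam$annotation, fam$annotation)
  expect_equal(unname(self$per_srs), rep(100, 6))
})

test_that("gap columns count as mismatches in the denominator", {
  # equal SRS content but one extra non-SRS residue in a: full-length
  # identity must dip below 100 while SRS stays 100
  p <- make_annotated_pair(3)
  a_plus <- protein_record("a", paste0(p$a$residues, "W"))
  aln <- global_align(a_plus, p$b)
  prof <- srs_identity(aln, srs_annotation("a", p$ann_a$intervals$start,
                                           p$ann_a$intervals$end),
                       p$ann_b)
  expect_equal(prof$total_srs, 100)
  expect_equal(prof$full_length, 100 * 100 / 101)
})

test_that("identity_matrix validates ids, respects pair order, stays symmetric", {
  fam <- simulate_family(family_sim_config(seed = 4, n_sequences = 3))
  recs <- c(list(ancestor = fam$ancestor), fam$descendants)
  anns <- c(list(ancestor = fam$annotation), fam$descendant_annotations)
  tab <- identity_matrix(recs, anns,
                         list(c("desc1", "desc2"), c("desc2", "desc1"),
                              c("desc3", "desc3")))
  expect_equal(nrow(tab), 3L)
  expect_equal(unlist(tab[1, SRS_LABELS]), unlist(tab[2, SRS_LABELS]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tab$full_length[3], 100)
  expect_error(identity_matrix(recs, anns, list(c("desc1", "nope"))),
               "nope")
})

test_that("higher SRS substitution rates never raise expected SRS identity", {
  rates <- c(0.05, 0.15, 0.30)
  mean_ident <- vapply(rates, function(r) {
    vals <- vapply(1:6, function(s) {
      fam <- simulate_family(family_sim_config(
        seed = 100 + s, n_sequences = 1, p_sub_srs = r,
        p_sub_nonsrs = 0.1
      ))
      prof <- srs_identity(
        global_align(fam$ancestor, fam$descendants$desc1),
        fam$annotation, fam$descendant_annotations$desc1
      )
      prof$total_srs
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  # binomial SE for 78 SRS columns x 6 seeds, widened by alignment noise
  n_cols <- 78 * 6
  tol <- 300 * sqrt(0.25 / n_cols)  # 3 SE in percentage points
  expect_gt(mean_ident[1], mean_ident[2] - tol)
  expect_gt(mean_ident[2], mean_ident[3] - tol)
  expect_gt(mean_ident[1], mean_ident[3])  # widest gap must be clean
})

test_that("identity report writes integer TSV and unrounded JSON", {
  fam <- simulate_family(family_sim_config(seed = 6, n_sequences = 2))
  recs <- c(list(ancestor = fam$ancestor), fam$descendants)
  anns <- c(list(ancestor = fam$annotation), fam$descendant_annotations)
  tab <- identity_matrix(recs, anns, list(c("desc1", "desc2")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_identity_report(tab, tsv, js)
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(back$SRS1, round(tab$SRS1))
  unrounded <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(unrounded$full_length, tab$full_length, tolerance = 1e-9)
})
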