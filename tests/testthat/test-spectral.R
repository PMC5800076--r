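test_that("site maps skip reference gaps and shift positions", {
  # reference has a missing codon in column 2 (the "M-KV" pattern)
  m <- matrix(c(15L, NA, 2L, 9L,
                15L, 3L, 2L, 9L), 2, 4, byrow = TRUE,
              dimnames = list(c("ref", "other"), NULL))
  sm <- build_site_map(codon_alignment(m), "ref")
  expect_equal(sm$column, c(1, 3, 4))
  expect_equal(sm$position, c(1, 2, 3))
  expect_equal(site_map_column(sm, 2), 3)
  expect_true(is.na(site_map_column(sm, 99)))
  # ungapped reference: identity map
  aln2 <- random_codon_aln(c("r", "s"), 6, seed = 2, p_missing = 0)
  sm2 <- build_site_map(aln2, "r")
  expect_equal(sm2$column, 1:6)
  expect_equal(sm2$position, 1:6)
  expect_error(build_site_map(aln2, "nope"), "absent")
})

test_that("planted residues are recovered through the site map", {
  # plant a known codon at reference position 3 behind a reference gap
  ct <- codon_table()
  thr_codon <- ct$index[ct$codon == "ACA"] # encodes T
  m <- matrix(sample.int(61, 10, replace = TRUE), 2, 5,
              dimnames = list(c("bovine", "sp1"), NULL))
  m[1, 2] <- NA
  m[2, 4] <- thr_codon
  sm <- build_site_map(codon_alignment(m), "bovine")
  col <- site_map_column(sm, 3)
  expect_equal(col, 4)
  expect_equal(ct$aa[m[2, col]], "T")
})

test_that("the site-86 VS/UVS rule partitions records as stated", {
  tt <- trait_table(data.frame(
    species_id = c("bat", "lemur", "seal", "mole", "shrew", "whale"),
    activity_pattern = "nocturnal",
    site86_residue = c("F", "F", "Y", "Y", "Q", NA),
    sws1_active = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    is_primate = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)))
  out <- classify_vs_uvs(tt)
  got <- setNames(as.character(out$vs_uvs), out$species_id)
  expect_equal(unname(got[c("bat", "lemur", "seal", "mole", "shrew", "whale")]),
               c("UVS", "unclassified", "VS", "excluded", "unclassified",
                 "unclassified"))
  # every VS residue maps to VS
  for (r in c("Y", "S", "V", "C", "L")) {
    tt2 <- trait_table(data.frame(species_id = "x",
                                  activity_pattern = "diurnal",
                                  site86_residue = r))
    expect_equal(as.character(classify_vs_uvs(tt2)$vs_uvs), "VS")
  }
  # the classification is a partition of the input
  expect_equal(sum(table(out$vs_uvs)), nrow(tt))
})

test_that("site-93 segregation tables conserve record counts", {
  tt <- trait_table(data.frame(
    species_id = paste0("s", 1:6),
    activity_pattern = c("nocturnal", "nocturnal", "diurnal", "cathemeral",
                         "unknown", "nocturnal"),
    site93_residue = c("T", "T", "P", "T", "P", NA)))
  seg <- site93_segregation(tt)
  expect_equal(unname(seg$table["T", "nocturnal"]), 2)
  expect_equal(unname(seg$table["P", "diurnal"]), 1)
  expect_equal(sum(seg$table), 3) # marginals = filtered record count
  expect_equal(unname(seg$excluded["cathemeral"]), 1)
  expect_equal(unname(seg$excluded["unknown_activity"]), 1)
  expect_equal(unname(seg$excluded["missing_residue"]), 1)
  expect_equal(seg$concordance, 1)

  sub <- site93_segregation(tt[tt$activity_pattern == "unknown", ])
  expect_equal(sum(sub$table), 0) # the unknown-activity record is dropped
  expect_equal(unname(sub$excluded["unknown_activity"]), 1)
})

test_that("an empty trait table yields an empty segregation, not an error", {
  tt <- trait_table(data.frame(species_id = character(),
                               activity_pattern = character()))
  seg <- site93_segregation(tt)
  expect_equal(sum(seg$table), 0)
  expect_true(is.na(seg$concordance))
})
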