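test_that("study table loads with the expected structure and key records", {
  tab <- load_study_table()
  expect_equal(nrow(tab), 41L)
  expect_equal(as.vector(table(tab$land_use)), c(11L, 11L, 19L))

  schools <- tab[tab$description == "Surface soil in schools in Beijing", ]
  expect_equal(schools$total_pahs, 1989.0)
  expect_equal(schools$bapeq, 286.6)

  jinghai <- tab[grepl("Jinghai", tab$description), ]
  expect_equal(jinghai$total_pahs, 142.0)

  expect_true(all(tab$total_pahs > 0))
  expect_true(all(tab$bapeq >= 0))
})

test_that("contamination classification follows the soil thresholds", {
  expect_equal(as.character(classify_contamination(1989.0)),
               "heavily_contaminated")
  expect_equal(as.character(classify_contamination(142.0)),
               "not_contaminated")
  expect_equal(as.character(classify_contamination(602.5)), "contaminated")
  # boundary convention: [0,200) / [200,600) / [600,1000] / (1000,Inf)
  expect_equal(as.character(classify_contamination(c(0, 199.99, 200, 599.9,
                                                     600, 1000, 1000.01))),
               c("not_contaminated", "not_contaminated",
                 "weakly_contaminated", "weakly_contaminated",
                 "contaminated", "contaminated", "heavily_contaminated"))
  expect_error(classify_contamination(-1), "non-negative")
  expect_error(classify_contamination(NaN), "finite")
})

test_that("classification is monotone and matches every printed label", {
  tab <- load_study_table()
  computed <- classify_contamination(tab$total_pahs)
  expect_equal(as.character(computed), as.character(tab$contamination_level))

  totals <- sort(c(tab$total_pahs, 0, 200, 600, 1000, 5000))
  levels_int <- as.integer(classify_contamination(totals))
  expect_true(all(diff(levels_int) >= 0))
})

test_that("group summaries equal the brute-force oracle", {
  tab <- load_study_table()
  for (lu in levels(tab$land_use)) {
    rec <- tab[tab$land_use == lu, ]
    for (field in c("total_pahs", "bapeq")) {
      expect_equal(summarize_group(rec, field, "mean"),
                   sum(rec[[field]]) / nrow(rec), tolerance = 1e-9)
      expect_equal(summarize_group(rec, field, "min"), min(rec[[field]]))
      expect_equal(summarize_group(rec, field, "max"), max(rec[[field]]))
    }
  }
  expect_error(summarize_group(tab[0, ], "bapeq", "mean"), "non-empty")
})

test_that("per-level counts are computed from totals, not printed labels", {
  tab <- load_study_table()
  # force a label/total mismatch: counts must follow the total
  rec <- tab[1, ]
  rec$total_pahs <- 1500
  rec$contamination_level <- factor("not_contaminated",
                                    levels = contamination_levels(),
                                    ordered = TRUE)
  counts <- count_by_level(rec)
  expect_equal(unname(counts["heavily_contaminated"]), 1L)
  expect_equal(sum(counts), 1L)

  empty <- count_by_level(tab[0, ])
  expect_equal(sum(empty), 0L)
  expect_named(empty, contamination_levels())
})

test_that("concentration CSV round-trips and validates", {
  catal <- default_catalog()
  x <- matrix(seq_len(48), nrow = 3,
              dimnames = list(paste0("s", 1:3), catal$abbreviation))
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(as_concentration_matrix(x), path)
  back <- read_concentration_table(path)
  expect_equal(unname(back), unname(x * 1.0))
  expect_equal(colnames(back), catal$abbreviation)

  # permuted columns are reordered to the canonical order
  df <- utils::read.csv(path, check.names = FALSE)
  df <- df[, c("sample_id", rev(catal$abbreviation))]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_equal(read_concentration_table(path2), back)

  # missing compound column is a schema error naming the column
  df3 <- df[, setdiff(names(df), "BaP")]
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df3, path3, row.names = FALSE)
  expect_error(read_concentration_table(path3), "BaP")

  # negative cells are rejected with their position
  df4 <- utils::read.csv(path, check.names = FALSE)
  df4$Naph[2] <- -5
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df4, path4, row.names = FALSE)
  expect_error(read_concentration_table(path4), "row 2.*Naph")
})

test_that("below-MDL substitution halves the detection limit and flags", {
  catal <- default_catalog(mdl = 2)
  x <- matrix(5, nrow = 2, ncol = 16,
              dimnames = list(NULL, catal$abbreviation))
  x[1, "BaP"] <- 0
  x[2, "Naph"] <- 1.5
  out <- substitute_below_mdl(x, catal)
  expect_equal(out[1, "BaP"], 1.0)
  expect_equal(out[2, "Naph"], 1.0)
  flags <- attr(out, "below_mdl")
  expect_true(flags[1, "BaP"])
  expect_true(flags[2, "Naph"])
  expect_equal(sum(flags), 2L)

  # all values at or above MDL: identity transform
  x2 <- matrix(3, nrow = 1, ncol = 16,
               dimnames = list(NULL, catal$abbreviation))
  out2 <- substitute_below_mdl(x2, catal)
  expect_equal(unname(out2)[1, ], rep(3, 16))
  expect_false(any(attr(out2, "below_mdl")))
})

test_that("catalog invariants hold and CSV overrides merge", {
  catal <- default_catalog()
  expect_equal(nrow(catal), 16L)
  expect_equal(catal$tef[catal$abbreviation == "BaP"], 1)
  expect_equal(catal$tef[catal$abbreviation == "DBahA"], 1)
  expect_equal(catal$tef[catal$abbreviation == "Naph"], 0.001)
  expect_true(all(catal$ring_count %in% 2:6))

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("abbreviation,mdl,error_fraction", "BaP,0.5,0.2"), path)
  over <- read_catalog(path)
  expect_equal(over$mdl[over$abbreviation == "BaP"], 0.5)
  expect_equal(over$error_fraction[over$abbreviation == "BaP"], 0.2)
  expect_equal(over$mdl[over$abbreviation == "Naph"], 1.0)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("abbreviation,mdl", "Nope,1"), path2)
  expect_error(read_catalog(path2), "Nope")
})
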