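test_that("a database round-trips through the four CSV tables", {
  db <- make_db(
    cases = data.frame(case_id = paste0("c", 1:5),
                       sex = c("women", "men", "men", "unknown", "women")),
    drugs = data.frame(case_id = c("c1", "c2", "c2"),
                       generic_name = c("Ipilimumab ", "nivolumab",
                                        "nivolumab"),
                       involvement = c("suspect", "concomitant", "suspect"),
                       admin_start_date = as.Date(c("2015-03-01", NA,
                                                    "2016-07-15"))),
    events = data.frame(case_id = c("c1", "c3"),
                        pt_name = c("hypopituitarism", "nausea"),
                        onset_date = as.Date(c("2015-05-01", NA))))
  dir <- withr::local_tempdir()
  write_database(db, dir)
  db2 <- load_database(list(demo = file.path(dir, "demo.csv"),
                            drug = file.path(dir, "drug.csv"),
                            reac = file.path(dir, "reac.csv")))
  expect_equal(db2$n_reports, 5)
  expect_equal(nrow(db2$drugs), 3)
  expect_equal(nrow(db2$events), 2)
  expect_equal(sort(unique(db2$cases$sex)), c("men", "unknown", "women"))
  # names are normalized on load
  expect_true("ipilimumab" %in% db2$drugs$generic_name)
  expect_equal(db2$drugs$admin_start_date[db2$drugs$involvement == "suspect" &
                                            db2$drugs$generic_name ==
                                            "ipilimumab"],
               as.Date("2015-03-01"))
})

test_that("out-of-vocabulary sex falls back to unknown with a warning", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(case_id = c("a", "b"), sex = c("female", "hermit"),
                       report_quarter = NA),
            file.path(dir, "demo.csv"), row.names = FALSE)
  write.csv(data.frame(case_id = "a", generic_name = "x",
                       involvement = "suspect", admin_start_date = ""),
            file.path(dir, "drug.csv"), row.names = FALSE)
  write.csv(data.frame(case_id = "a", pt_name = "nausea", onset_date = "",
                       outcome = ""),
            file.path(dir, "reac.csv"), row.names = FALSE)
  paths <- list(demo = file.path(dir, "demo.csv"),
                drug = file.path(dir, "drug.csv"),
                reac = file.path(dir, "reac.csv"))
  expect_warning(db <- load_database(paths), "outside the vocabulary")
  expect_equal(db$cases$sex, c("women", "unknown"))
})

test_that("missing tables and missing columns are fatal and named", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(case_id = "a", sex = "female"),
            file.path(dir, "demo.csv"), row.names = FALSE)
  paths <- list(demo = file.path(dir, "demo.csv"),
                drug = file.path(dir, "drug.csv"),
                reac = file.path(dir, "reac.csv"))
  expect_error(load_database(paths), "drug")
  write.csv(data.frame(case_id = "a", generic_name = "x"),
            file.path(dir, "drug.csv"), row.names = FALSE)
  write.csv(data.frame(case_id = "a", pt_name = "nausea"),
            file.path(dir, "reac.csv"), row.names = FALSE)
  expect_error(load_database(paths), "involvement")
})

test_that("referential integrity is enforced", {
  expect_error(
    make_db(cases = data.frame(case_id = "c1", sex = "women"),
            drugs = data.frame(case_id = "c9", generic_name = "x",
                               involvement = "suspect")),
    "referential-integrity")
  expect_error(
    make_db(cases = data.frame(case_id = "c1", sex = "women"),
            events = data.frame(case_id = "c9", pt_name = "nausea")),
    "referential-integrity")
  expect_error(
    make_db(cases = data.frame(case_id = c("c1", "c1"),
                               sex = c("women", "men"))),
    "duplicate")
})

test_that("rows with unparseable case identifiers are dropped and counted", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(case_id = c("a", "", "b"),
                       sex = c("female", "male", "male")),
            file.path(dir, "demo.csv"), row.names = FALSE)
  write.csv(data.frame(case_id = c("a", ""), generic_name = c("x", "y"),
                       involvement = "suspect"),
            file.path(dir, "drug.csv"), row.names = FALSE)
  write.csv(data.frame(case_id = "b", pt_name = "nausea"),
            file.path(dir, "reac.csv"), row.names = FALSE)
  expect_warning(
    db <- load_database(list(demo = file.path(dir, "demo.csv"),
                             drug = file.path(dir, "drug.csv"),
                             reac = file.path(dir, "reac.csv"))),
    "unparseable")
  expect_equal(db$n_reports, 2)
  expect_equal(unname(attr(db, "dropped_rows")), c(1L, 1L, 0L))
})

test_that("partial dates parse as missing without dropping the row", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(case_id = "a", sex = "female"),
            file.path(dir, "demo.csv"), row.names = FALSE)
  write.csv(data.frame(case_id = "a", generic_name = "x",
                       involvement = "suspect",
                       admin_start_date = "2016-07"),
            file.path(dir, "drug.csv"), row.names = FALSE)
  write.csv(data.frame(case_id = "a", pt_name = "nausea",
                       onset_date = "2016-09-03"),
            file.path(dir, "reac.csv"), row.names = FALSE)
  db <- load_database(list(demo = file.path(dir, "demo.csv"),
                           drug = file.path(dir, "drug.csv"),
                           reac = file.path(dir, "reac.csv")))
  expect_equal(nrow(db$drugs), 1)
  expect_true(is.na(db$drugs$admin_start_date))
  expect_equal(db$events$onset_date, as.Date("2016-09-03"))
})

test_that("restrict_to_suspect filters mentions, keeps cases, is idempotent", {
  db <- make_db(
    cases = data.frame(case_id = paste0("c", 1:4),
                       sex = rep("women", 4)),
    drugs = data.frame(case_id = c("c1", "c1", "c2", "c3", "c4"),
                       generic_name = "d",
                       involvement = c("suspect", "concomitant", "suspect",
                                       "suspect", "interaction")))
  r1 <- restrict_to_suspect(db)
  expect_equal(nrow(r1$drugs), 3)
  expect_equal(r1$n_reports, db$n_reports)
  expect_identical(restrict_to_suspect(r1)$drugs, r1$drugs)
  # a database with no suspect mentions keeps all its cases
  db2 <- make_db(cases = data.frame(case_id = "c1", sex = "men"),
                 drugs = data.frame(case_id = "c1", generic_name = "d",
                                    involvement = "concomitant"))
  r2 <- restrict_to_suspect(db2)
  expect_equal(nrow(r2$drugs), 0)
  expect_equal(r2$n_reports, 1)
})

test_that("flag_event_group deduplicates within a case and counts by hand", {
  # two distinct PTs of the same HLT flag the case exactly once
  db <- make_db(
    cases = data.frame(case_id = c("c1", "c2"), sex = c("women", "men")),
    events = data.frame(case_id = c("c1", "c1", "c2"),
                        pt_name = c("hypopituitarism", "hypophysitis",
                                    "diabetes insipidus")))
  f <- flag_event_group(db, toy_map, "anterior pituitary hypofunction")
  expect_equal(sum(f), 1)
  expect_true(f[["c1"]])
  expect_false(f[["c2"]])

  # 10-case database with exactly 3 flagged cases, counted by hand
  db10 <- make_db(
    cases = data.frame(case_id = paste0("c", 1:10),
                       sex = rep(c("women", "men"), 5)),
    events = data.frame(
      case_id = c("c1", "c2", "c2", "c5", "c7", "c7"),
      pt_name = c("hypopituitarism", "hypophysitis", "hypopituitarism",
                  "nausea", "hypophysitis", "diabetes insipidus")))
  f10 <- flag_event_group(db10, toy_map, "anterior pituitary hypofunction")
  expect_equal(sum(f10), 3)
  expect_equal(names(f10)[f10], c("c1", "c2", "c7"))
})

test_that("flag_event_group depends only on the set of a case's PTs", {
  db1 <- make_db(
    cases = data.frame(case_id = "c1", sex = "women"),
    events = data.frame(case_id = "c1", pt_name = "hypopituitarism"))
  db2 <- make_db(
    cases = data.frame(case_id = "c1", sex = "women"),
    events = data.frame(case_id = rep("c1", 3),
                        pt_name = rep("hypopituitarism", 3)))
  expect_identical(
    flag_event_group(db1, toy_map, "anterior pituitary hypofunction"),
    flag_event_group(db2, toy_map, "anterior pituitary hypofunction"))
})

test_that("unmapped PTs are detectable and absent HLTs are config errors", {
  expect_true(is.na(pt_to_hlt(toy_map, "vertigo")))
  expect_equal(pt_to_hlt(toy_map, "hypophysitis"),
               "anterior pituitary hypofunction")
  db <- toy_8case_db()
  expect_error(flag_event_group(db, toy_map, "no such hlt"),
               class = "srsignal_config_error")
  expect_error(term_map(c("pt1", "pt1"), c("hltA", "hltB")), "exactly one")
})

test_that("drug-name matching is normalized and synonym-aware", {
  db <- make_db(
    cases = data.frame(case_id = c("c1", "c2"), sex = c("women", "men")),
    drugs = data.frame(case_id = c("c1", "c2"),
                       generic_name = c("  Yervoy ", "ipilimumab"),
                       involvement = "suspect"))
  syn <- c(Yervoy = "ipilimumab")
  f <- flag_drug_exposure(db, "IPILIMUMAB", synonyms = syn)
  expect_true(all(f))
  expect_equal(sum(flag_drug_exposure(db, "ipilimumab")), 1)
})
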