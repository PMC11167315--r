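write_conf_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".conf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a config is parsed with all tier mappings attached", {
  path <- write_conf_text(c(
    "schema: mini2016", "dialect: inline_xml", "",
    "[Phone]", "extract: PHONE", "tier0: PII", "tier1: PhoneFax",
    "tier2: Phone", "",
    "[Fax]", "extract: FAX", "tier0: PII", "tier1: PhoneFax",
    "tier2: Fax"
  ))
  cfg <- read_schema_config(path)
  expect_s3_class(cfg, "pii_schema")
  expect_equal(nrow(cfg$rules), 2)
  expect_equal(unique(cfg$rules$tier1), "PhoneFax")
})

test_that("missing tier keys, duplicate natives and malformed lines error", {
  incomplete <- write_conf_text(c(
    "schema: x", "dialect: brat", "",
    "[Name]", "extract: NAME", "tier0: PII"
  ))
  expect_error(read_schema_config(incomplete), "tier1",
               class = "piieval_config_error")

  dup <- write_conf_text(c(
    "schema: x", "dialect: brat", "",
    "[Name]", "extract: N1", "tier0: PII", "tier1: Names", "tier2: Patient",
    "",
    "[Name]", "extract: N2", "tier0: PII", "tier1: Names", "tier2: Patient"
  ))
  expect_error(read_schema_config(dup), "Duplicate native",
               class = "piieval_config_error")

  bad <- write_conf_text(c("schema: x", "dialect: brat", "not a key value"))
  expect_error(read_schema_config(bad), "line 3",
               class = "piieval_config_error")

  expect_error(
    pii_schema("x", "brat",
               tibble::tibble(native_name = "A", extract = "A",
                              tier0 = "NotPII", tier1 = "u", tier2 = "u")),
    class = "piieval_config_error"
  )
})

test_that("mapping follows the tier contract", {
  cfg2016 <- read_schema_config("i2b2-2014-2016")
  cfg2006 <- read_schema_config("i2b2-2006")
  expect_equal(map_scoring_category(cfg2016, "Fax", "tier1"), "PhoneFax")
  expect_equal(map_scoring_category(cfg2006, "Doctor", "tier0"), "PII")
  expect_equal(map_scoring_category(cfg2006, "Doctor", "native"), "Doctor")
  reset_unmapped_warnings()
  expect_warning(
    out <- map_scoring_category(cfg2006, "NoSuchCategory", "tier2"),
    class = "piieval_unmapped_warning"
  )
  expect_equal(out, "unmapped")
  # warned once per name only
  expect_no_warning(map_scoring_category(cfg2006, "NoSuchCategory", "tier2"))
})

test_that("scoring category listing dedupes, sorts and drops unmapped", {
  cfg <- pii_schema("x", "brat", tibble::tibble(
    native_name = c("A", "B", "C", "D"), extract = c("A", "B", "C", "D"),
    tier0 = "PII", tier1 = c("X", "X", "Y", "unmapped"),
    tier2 = c("a", "b", "c", "unmapped")
  ))
  expect_equal(scoring_categories(cfg, "tier1"), c("X", "Y"))
  expect_equal(scoring_categories(read_schema_config("i2b2-2006"), "tier0"),
               "PII")
})

test_that("schema round-trips through serialisation unchanged", {
  for (id in shipped_schemas()$schema_id) {
    cfg <- read_schema_config(id)
    path <- withr::local_tempfile(fileext = ".conf")
    write_schema_config(cfg, path)
    expect_equal(read_schema_config(path), cfg, info = id)
  }
})

test_that("tier monotonicity holds across all shipped configs", {
  for (id in shipped_schemas()$schema_id) {
    cfg <- read_schema_config(id)
    r <- cfg$rules[cfg$rules$tier2 != "unmapped", ]
    by_t2 <- split(r$tier1, r$tier2)
    for (t2 in names(by_t2)) {
      expect_length(unique(by_t2[[t2]]), 1)
    }
    expect_true(all(cfg$rules$tier0 == "PII"), info = id)
  }
})

test_that("shipped schemas resolve by id and by path", {
  sch <- shipped_schemas()
  byid <- read_schema_config("musc")
  bypath <- read_schema_config(sch$path[sch$schema_id == "musc"])
  expect_equal(byid, bypath)
})
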