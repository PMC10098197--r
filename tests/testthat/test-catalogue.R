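test_that("the bundled catalogue resolves to 14 dose-determining substances in 9 classes", {
  dd <- vapply(CAT$products$productId,
               function(p) resolve_dose_determining(CAT, p)$substance,
               character(1))
  ref <- substance_reference <- unique(default_ddd_registry()$substance)
  expect_length(setdiff(dd, "trimethoprim") |> unique(), 14)
  classes <- unique(CAT$substances$amClass[
    match(setdiff(unique(dd), "trimethoprim"), CAT$substances$substance)])
  expect_length(classes, 9)
})

test_that("a catalogue written to files loads back equivalently", {
  dir <- withr::local_tempdir()
  fx <- reference_dataset()
  paths <- write_dataset(dir, fx$catalogue, fx$herds, fx$events)
  cat2 <- load_catalogue(paths["products"], paths["ddd"], paths["cia_map"],
                         substanceFile = paths["substances"])
  expect_equal(nrow(cat2$products), nrow(CAT$products))
  expect_equal(
    lookup_ddd(cat2, "ceftiofur", "CATTLE", "PARENTERAL")$dddKg,
    lookup_ddd(CAT, "ceftiofur", "CATTLE", "PARENTERAL")$dddKg
  )
})

test_that("catalogue loading rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  fx <- reference_dataset()
  paths <- write_dataset(dir, fx$catalogue, fx$herds, fx$events)

  empty <- file.path(dir, "empty_products.csv")
  writeLines(paste(c("productId", "tradeName", "formulation", "unitSize",
                     "substance", "concentration", "concentrationUnit",
                     "role"), collapse = ","), empty)
  expect_error(load_catalogue(empty, paths["ddd"], paths["cia_map"]),
               "no products")

  foo <- file.path(dir, "foo_products.csv")
  readr::write_csv(tibble::tibble(
    productId = "PX", tradeName = "X", formulation = "PARENTERAL",
    unitSize = 10, substance = "foo", concentration = 100,
    concentrationUnit = "mg/mL", role = "DOSE_DETERMINING"
  ), foo)
  expect_error(load_catalogue(foo, paths["ddd"], paths["cia_map"]), "foo")

  dup <- file.path(dir, "dup_products.csv")
  readr::write_csv(tibble::tibble(
    productId = c("PX", "PX"), tradeName = c("X", "Y"),
    formulation = "PARENTERAL", unitSize = c(10, 20),
    substance = "enrofloxacin", concentration = 100,
    concentrationUnit = "mg/mL", role = "DOSE_DETERMINING"
  ), dup)
  expect_error(load_catalogue(dup, paths["ddd"], paths["cia_map"]),
               "duplicate productId")
})

test_that("combination rules pick trimethoprim and the beta-lactam partner", {
  expect_equal(resolve_dose_determining(CAT, "P15")$substance, "trimethoprim")
  expect_equal(resolve_dose_determining(CAT, "P16")$substance, "amoxicillin")
  expect_equal(resolve_dose_determining(CAT, "P05")$substance, "enrofloxacin")
})

test_that("resolution is idempotent and never returns a co-formulated partner", {
  partners <- c("clavulanic acid", "sulbactam", "tazobactam")
  for (p in CAT$products$productId) {
    r1 <- resolve_dose_determining(CAT, p)
    expect_equal(r1$role, "DOSE_DETERMINING")
    expect_false(r1$substance %in% partners)
    # the sulphonamide partner of a trimethoprim combination never wins
    comp <- CAT$components[CAT$components$productId == p, ]
    if (nrow(comp) > 1 && "trimethoprim" %in% comp$substance) {
      expect_equal(r1$substance, "trimethoprim")
    }
    expect_identical(resolve_dose_determining(CAT, p), r1)
  }
})

test_that("an unruled multi-component product is an ambiguous combination", {
  rows <- tibble::tibble(
    productId = c("PZ", "PZ"), tradeName = "Z", formulation = "PARENTERAL",
    unitSize = 30, substance = c("enrofloxacin", "gentamicin"),
    concentration = c(100, 40), concentrationUnit = "mg/mL",
    role = NA_character_
  )
  expect_error(
    build_catalogue(rows, default_ddd_registry(), default_cia_map(),
                    default_substances()),
    "ambiguous combination"
  )
})

test_that("active masses are concentration times quantity, per component", {
  m <- total_active_mass(CAT, "P05", 60)
  expect_equal(m$massMg, 6000)
  expect_equal(m$role, "DOSE_DETERMINING")

  m0 <- total_active_mass(CAT, "P05", 0)
  expect_equal(m0$massMg, 0)

  combo <- total_active_mass(CAT, "P15", 10)
  expect_equal(combo$massMg[combo$substance == "trimethoprim"], 800)
  expect_equal(combo$role[combo$substance == "trimethoprim"],
               "DOSE_DETERMINING")
  expect_equal(combo$massMg[combo$substance == "sulphadiazine"], 4000)
  expect_equal(combo$role[combo$substance == "sulphadiazine"],
               "CO_FORMULATED")

  expect_error(total_active_mass(CAT, "P05", -1), "non-negative")
})

test_that("active mass is linear in quantity for every product", {
  set.seed(7)
  for (p in CAT$products$productId) {
    q <- runif(1, 0.1, 50)
    expect_equal(total_active_mass(CAT, p, 2 * q)$massMg,
                 2 * total_active_mass(CAT, p, q)$massMg)
  }
})

test_that("IU-denominated concentrations convert via the configured factor", {
  m <- total_active_mass(CAT, "P12", 1)
  expect_equal(m$massMg, 400000 / 1598)
  cat_no_iu <- default_catalogue(iu_per_mg = NA)
  expect_error(total_active_mass(cat_no_iu, "P12", 1), "IU")
})

test_that("WHO categorization follows the class map", {
  expect_equal(who_category(CAT, "enrofloxacin"), "HPCIA")
  expect_equal(who_category(CAT, "ceftriaxone"), "HPCIA")
  expect_equal(who_category(CAT, "gentamicin"), "HIGH_PRIORITY_CIA")
  expect_equal(who_category(CAT, "amoxicillin"), "HIGH_PRIORITY_CIA")
  expect_equal(who_category(CAT, "oxytetracycline"), "HIGHLY_IMPORTANT")
  expect_equal(who_category(CAT, "procaine penicillin"), "HIGHLY_IMPORTANT")

  crippled <- CAT
  crippled$cia_map <- crippled$cia_map[crippled$cia_map$amClass != "quinolones", ]
  expect_error(who_category(crippled, "enrofloxacin"), "absent from category map")
})

test_that("DDD lookup prefers the most specific record and errors when absent", {
  expect_equal(lookup_ddd(CAT, "ceftiofur", "CATTLE", "PARENTERAL")$dddKg, 0.625)
  enro <- lookup_ddd(CAT, "enrofloxacin", "CATTLE", "PARENTERAL")$dddKg
  expect_lt(abs(enro - 5.26), 0.01)
  expect_equal(lookup_ddd(CAT, "ceftiofur", "CATTLE", "PARENTERAL")$source,
               "BACKCALC")
  expect_error(lookup_ddd(CAT, "colistin", "CATTLE", "PARENTERAL"),
               "no DDD record")
  expect_error(lookup_ddd(CAT, "enrofloxacin", "CATTLE", "ORAL"),
               "no DDD record")

  specific <- CAT
  specific$ddd <- dplyr::bind_rows(
    tibble::tibble(substance = "ceftiofur", species = "CATTLE",
                   route = "PARENTERAL", dddKg = 1.0, source = "ESVAC"),
    CAT$ddd
  )
  expect_equal(lookup_ddd(specific, "ceftiofur", "CATTLE", "PARENTERAL")$dddKg, 1.0)
  expect_equal(lookup_ddd(specific, "ceftiofur", "BUFFALO", "PARENTERAL")$dddKg,
               0.625)
})

test_that("substance synonyms normalize to canonical names", {
  expect_equal(normalize_substance("Procaine Penicillin"),
               "procaine benzylpenicillin")
  expect_equal(normalize_substance("Cephalexin"), "cefalexin")
  expect_equal(normalize_substance(" ENROFLOXACIN "), "enrofloxacin")
})
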