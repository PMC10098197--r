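# Catalogue of antimicrobial products, active substances, the DDDkg registry
# (defined daily dose in mg per kg bodyweight per day) and the WHO
# critical-importance category map.

WHO_CATEGORIES <- c("HPCIA", "HIGH_PRIORITY_CIA", "HIGHLY_IMPORTANT",
                    "IMPORTANT", "UNCLASSIFIED")
FORMULATIONS <- c("PARENTERAL", "INTRAMAMMARY", "ORAL")
SPECIES <- c("CATTLE", "BUFFALO", "BOVINE_ANY")
COMPONENT_ROLES <- c("DOSE_DETERMINING", "CO_FORMULATED")
DDD_SOURCES <- c("ESVAC", "LABEL", "BACKCALC")
CONCENTRATION_UNITS <- c("mg/mL", "mg/unit", "IU/mL")

# beta-lactam classes eligible as the dose-determining partner of an
# inhibitor or penicillin-salt pairing
BETA_LACTAM_CLASSES <- c("penicillins", "aminopenicillins",
                         "cephalosporins-1st-gen", "cephalosporins-3rd-gen")

SUBSTANCE_SYNONYMS <- c(
  "procaine penicillin"       = "procaine benzylpenicillin",
  "benzylpenicillin procaine" = "procaine benzylpenicillin",
  "penicillin g procaine"     = "procaine benzylpenicillin",
  "cephalexin"                = "cefalexin",
  "sulfadiazine"              = "sulphadiazine"
)

#' Normalize an active-substance name
#'
#' Lower-cases, trims, and maps known synonyms (e.g. "procaine penicillin" and
#' "procaine benzylpenicillin" are the same substance) onto canonical names.
#'
#' @param x character vector of substance names.
#' @return character vector of canonical lower-case names.
#' @export
normalize_substance <- function(x) {
  x <- tolower(trimws(x))
  hit <- x %in% names(SUBSTANCE_SYNONYMS)
  x[hit] <- SUBSTANCE_SYNONYMS[x[hit]]
  x
}

#' Default active-substance table
#'
#' The 14 substances observed in the surveillance design this package models,
#' spanning 9 antimicrobial classes, plus co-formulation partners
#' (trimethoprim, clavulanic acid) needed by the combination-drug rules.
#'
#' @return tibble with columns `substance`, `amClass`.
#' @export
default_substances <- function() {
  tibble::tribble(
    ~substance,                  ~amClass,
    "ceftriaxone",               "cephalosporins-3rd-gen",
    "ceftiofur",                 "cephalosporins-3rd-gen",
    "cefoperazone",              "cephalosporins-3rd-gen",
    "ceftizoxime",               "cephalosporins-3rd-gen",
    "enrofloxacin",              "quinolones",
    "levofloxacin",              "quinolones",
    "gentamicin",                "aminoglycosides",
    "amoxicillin",               "aminopenicillins",
    "ampicillin",                "aminopenicillins",
    "oxytetracycline",           "tetracyclines",
    "cefalexin",                 "cephalosporins-1st-gen",
    "procaine benzylpenicillin", "penicillins",
    "sulphadiazine",             "sulphonamides",
    "metronidazole",             "nitroimidazole",
    "trimethoprim",              "diaminopyrimidines",
    "clavulanic acid",           "beta-lactamase-inhibitors"
  )
}

#' Default WHO critical-importance category map
#'
#' Maps antimicrobial class to WHO category. Quinolones and 3rd-generation
#' cephalosporins are highest-priority critically important (HPCIA);
#' aminopenicillins and aminoglycosides are high-priority CIA; the remaining
#' classes fall outside the CIA group. The map is replaceable by file
#' (`cia_map.csv`) to use an alternative edition of the WHO list.
#'
#' @return tibble with columns `amClass`, `whoCategory`.
#' @export
default_cia_map <- function() {
  tibble::tribble(
    ~amClass,                    ~whoCategory,
    "cephalosporins-3rd-gen",    "HPCIA",
    "quinolones",                "HPCIA",
    "aminopenicillins",          "HIGH_PRIORITY_CIA",
    "aminoglycosides",           "HIGH_PRIORITY_CIA",
    "tetracyclines",             "HIGHLY_IMPORTANT",
    "cephalosporins-1st-gen",    "HIGHLY_IMPORTANT",
    "penicillins",               "HIGHLY_IMPORTANT",
    "sulphonamides",             "HIGHLY_IMPORTANT",
    "diaminopyrimidines",        "HIGHLY_IMPORTANT",
    "nitroimidazole",            "IMPORTANT",
    "beta-lactamase-inhibitors", "UNCLASSIFIED"
  )
}

#' Default DDDkg registry
#'
#' Recommended daily doses (mg/kg/day) per substance for adult bovines,
#' parenteral route. Values are back-calculated from the reference dataset's
#' median used daily doses and dosing ratios (source `BACKCALC`); an ESVAC- or
#' label-sourced registry can be dropped in via `ddd.csv` without code change.
#'
#' @return tibble with columns `substance`, `species`, `route`, `dddKg`, `source`.
#' @export
default_ddd_registry <- function() {
  base <- tibble::tibble(
    substance = c("ceftriaxone", "ceftiofur", "cefoperazone", "ceftizoxime",
                  "enrofloxacin", "levofloxacin", "gentamicin", "amoxicillin",
                  "ampicillin", "oxytetracycline", "cefalexin",
                  "procaine benzylpenicillin", "sulphadiazine", "metronidazole"),
    species = "BOVINE_ANY",
    route = "PARENTERAL",
    dddKg = c(7.50 / 1.07, 1.25 / 2.00, 11.25 / 1.00, 7.50 / 1.50,
              5.00 / 0.95, 4.00 / 0.90, 1.80 / 0.19, 7.50 / 0.90,
              4.50 / 0.52, 3.25 / 0.38, 6.75 / 0.54, 3.25 / 0.35,
              3.00 / 0.23, 1.25 / 0.25),
    source = "BACKCALC"
  )
  dplyr::bind_rows(
    base,
    tibble::tibble(substance = "trimethoprim", species = "BOVINE_ANY",
                   route = "PARENTERAL", dddKg = 4.0, source = "LABEL")
  )
}

#' Default drug-product catalogue rows
#'
#' One plausible commercial product per substance (parenteral multi-dose
#' vials; procaine benzylpenicillin denominated in IU/mL), one
#' trimethoprim–sulphonamide combination, one amoxicillin–clavulanate
#' combination, and one intramammary syringe product, in the `products.csv`
#' dialect (one row per component).
#'
#' @return tibble in the `products.csv` schema.
#' @export
default_products <- function() {
  tibble::tribble(
    ~productId, ~tradeName,      ~formulation,   ~unitSize, ~substance,                  ~concentration, ~concentrationUnit, ~role,
    "P01", "Ceftrivet",          "PARENTERAL",   10,  "ceftriaxone",               100,    "mg/mL",   "DOSE_DETERMINING",
    "P02", "Ceftiocare",         "PARENTERAL",   10,  "ceftiofur",                 50,     "mg/mL",   "DOSE_DETERMINING",
    "P03", "Perazodel",          "PARENTERAL",   10,  "cefoperazone",              100,    "mg/mL",   "DOSE_DETERMINING",
    "P04", "Zoximvet",           "PARENTERAL",   10,  "ceftizoxime",               100,    "mg/mL",   "DOSE_DETERMINING",
    "P05", "Enrodac",            "PARENTERAL",   30,  "enrofloxacin",              100,    "mg/mL",   "DOSE_DETERMINING",
    "P06", "Levotas",            "PARENTERAL",   30,  "levofloxacin",              100,    "mg/mL",   "DOSE_DETERMINING",
    "P07", "Gentasure",          "PARENTERAL",   30,  "gentamicin",                40,     "mg/mL",   "DOSE_DETERMINING",
    "P08", "Amoxirum",           "PARENTERAL",   30,  "amoxicillin",               150,    "mg/mL",   "DOSE_DETERMINING",
    "P09", "Ampisure",           "PARENTERAL",   30,  "ampicillin",                100,    "mg/mL",   "DOSE_DETERMINING",
    "P10", "Oxyvet LA",          "PARENTERAL",   50,  "oxytetracycline",           50,     "mg/mL",   "DOSE_DETERMINING",
    "P11", "Cefaward",           "PARENTERAL",   30,  "cefalexin",                 100,    "mg/mL",   "DOSE_DETERMINING",
    "P12", "Penzo Forte",        "PARENTERAL",   30,  "procaine benzylpenicillin", 400000, "IU/mL",   "DOSE_DETERMINING",
    "P13", "Sulphamax",          "PARENTERAL",   50,  "sulphadiazine",             200,    "mg/mL",   "DOSE_DETERMINING",
    "P14", "Metrozole",          "PARENTERAL",   100, "metronidazole",             50,     "mg/mL",   "DOSE_DETERMINING",
    "P15", "Trisulfin",          "PARENTERAL",   30,  "trimethoprim",              80,     "mg/mL",   NA,
    "P15", "Trisulfin",          "PARENTERAL",   30,  "sulphadiazine",             400,    "mg/mL",   NA,
    "P16", "Clavamox Inj",       "PARENTERAL",   30,  "amoxicillin",               140,    "mg/mL",   NA,
    "P16", "Clavamox Inj",       "PARENTERAL",   30,  "clavulanic acid",           35,     "mg/mL",   NA,
    "P17", "Mastiject",          "INTRAMAMMARY", 1,   "cefoperazone",              200,    "mg/unit", "DOSE_DETERMINING"
  )
}

new_catalogue <- function(products, components, substances, ddd, cia_map,
                          iu_per_mg = 1598) {
  structure(
    list(products = products, components = components,
         substances = substances, ddd = ddd, cia_map = cia_map,
         iu_per_mg = iu_per_mg),
    class = "amu_catalogue"
  )
}

#' @export
print.amu_catalogue <- function(x, ...) {
  cat("<amu_catalogue>\n")
  cat("  products:  ", nrow(x$products), "\n")
  cat("  substances:", nrow(x$substances), "\n")
  cat("  DDD records:", nrow(x$ddd), "\n")
  cat("  classes mapped to WHO categories:", nrow(x$cia_map), "\n")
  invisible(x)
}

validate_catalogue <- function(cat) {
  if (nrow(cat$products) == 0) amu_stop("no products in catalogue")
  dup <- cat$products$productId[duplicated(cat$products$productId)]
  if (length(dup)) amu_stop("duplicate productId: ", paste(unique(dup), collapse = ", "))
  unknown <- setdiff(cat$components$substance, cat$substances$substance)
  if (length(unknown)) {
    amu_stop("component substance missing from substance table: ",
             paste(unknown, collapse = ", "))
  }
  if (any(cat$components$concentration <= 0)) {
    amu_stop("component concentrations must be > 0")
  }
  if (any(cat$products$unitSize <= 0)) amu_stop("unitSize must be > 0")
  if (any(cat$ddd$dddKg <= 0)) amu_stop("dddKg must be > 0")
  bad_cat <- setdiff(cat$cia_map$whoCategory, WHO_CATEGORIES)
  if (length(bad_cat)) {
    amu_stop("unknown whoCategory in map: ", paste(bad_cat, collapse = ", "))
  }
  invisible(cat)
}

#' Build the bundled default catalogue
#'
#' @param iu_per_mg IU-to-mg conversion factor for IU-denominated
#'   concentrations (default 1598 IU per mg, benzylpenicillin).
#' @return an `amu_catalogue`.
#' @examples
#' cat <- default_catalogue()
#' lookup_ddd(cat, "ceftiofur", "CATTLE", "PARENTERAL")
#' @export
default_catalogue <- function(iu_per_mg = 1598) {
  build_catalogue(default_products(), default_ddd_registry(),
                  default_cia_map(), default_substances(), iu_per_mg)
}

build_catalogue <- function(product_rows, ddd, cia_map, substances,
                            iu_per_mg = 1598) {
  product_rows$substance <- normalize_substance(product_rows$substance)
  substances$substance <- normalize_substance(substances$substance)
  ddd$substance <- normalize_substance(ddd$substance)
  ddd$species <- match_enum(ddd$species, SPECIES, "species")
  ddd$route <- match_enum(ddd$route, FORMULATIONS, "route")
  if (!all(ddd$source %in% DDD_SOURCES)) {
    amu_stop("ddd source must be one of ", paste(DDD_SOURCES, collapse = ", "))
  }
  products <- product_rows |>
    dplyr::distinct(.data$productId, .data$tradeName, .data$formulation,
                    .data$unitSize)
  products$formulation <- match_enum(products$formulation, FORMULATIONS,
                                     "formulation")
  components <- product_rows |>
    dplyr::select("productId", "substance", "concentration",
                  "concentrationUnit", "role")
  if (!all(components$concentrationUnit %in% CONCENTRATION_UNITS)) {
    amu_stop("concentrationUnit must be one of ",
             paste(CONCENTRATION_UNITS, collapse = ", "))
  }
  components$role[is.na(components$role) | components$role == ""] <- NA_character_
  ok_role <- is.na(components$role) | components$role %in% COMPONENT_ROLES
  if (!all(ok_role)) {
    amu_stop("component role must be one of ",
             paste(COMPONENT_ROLES, collapse = ", "))
  }
  cat <- new_catalogue(products, components, substances, ddd, cia_map,
                       iu_per_mg)
  validate_catalogue(cat)
  # resolving every product exercises the combination rules up front; flag
  # (not error) dose-determining substances that lack any DDD record
  dd_subs <- vapply(products$productId, function(p) {
    resolve_dose_determining(cat, p)$substance
  }, character(1))
  no_ddd <- setdiff(unique(dd_subs), ddd$substance)
  if (length(no_ddd)) {
    amu_warn("dose-determining substances without a DDD record: ",
             paste(no_ddd, collapse = ", "))
  }
  cat
}

#' Load a catalogue from delimited-text files
#'
#' @param productFile path to `products.csv` (one row per product component:
#'   productId, tradeName, formulation, unitSize, substance, concentration,
#'   concentrationUnit, role).
#' @param dddFile path to `ddd.csv` (substance, species, route,
#'   dddKg_mg_per_kg_day, source).
#' @param ciaFile path to `cia_map.csv` (amClass, whoCategory).
#' @param substanceFile optional path to a substance table (substance,
#'   amClass); defaults to the bundled [default_substances()].
#' @param iu_per_mg IU-to-mg conversion factor.
#' @return an `amu_catalogue`.
#' @export
load_catalogue <- function(productFile, dddFile, ciaFile,
                           substanceFile = NULL, iu_per_mg = 1598) {
  products <- read_schema_csv(
    productFile,
    c("productId", "tradeName", "formulation", "unitSize", "substance",
      "concentration", "concentrationUnit", "role"),
    readr::cols(
      productId = "c", tradeName = "c", formulation = "c", unitSize = "d",
      substance = "c", concentration = "d", concentrationUnit = "c",
      role = "c"
    )
  )
  if (nrow(products) == 0) amu_stop("no products")
  ddd <- read_schema_csv(
    dddFile,
    c("substance", "species", "route", "dddKg_mg_per_kg_day", "source"),
    readr::cols(substance = "c", species = "c", route = "c",
                dddKg_mg_per_kg_day = "d", source = "c")
  ) |>
    dplyr::rename(dddKg = "dddKg_mg_per_kg_day")
  cia <- read_schema_csv(ciaFile, c("amClass", "whoCategory"),
                         readr::cols(amClass = "c", whoCategory = "c"))
  substances <- if (is.null(substanceFile)) {
    default_substances()
  } else {
    read_schema_csv(substanceFile, c("substance", "amClass"),
                    readr::cols(substance = "c", amClass = "c"))
  }
  build_catalogue(products, ddd, cia, substances, iu_per_mg)
}

read_schema_csv <- function(path, required, col_types) {
  if (!file.exists(path)) amu_stop("file not found: ", path)
  out <- tryCatch(
    readr::read_csv(path, col_types = col_types, progress = FALSE),
    error = function(e) amu_stop("parse error in ", path, ": ", conditionMessage(e))
  )
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    amu_stop(path, " is missing required columns: ",
             paste(missing, collapse = ", "))
  }
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    amu_stop("parse error in ", path, " at row ", prob$row[1], ": ",
             prob$expected[1], " expected, got '", prob$actual[1], "'")
  }
  out
}

catalogue_product <- function(catalogue, productId) {
  p <- catalogue$products[catalogue$products$productId == productId, ]
  if (nrow(p) == 0) amu_stop("unknown product: ", productId)
  p
}

substance_class <- function(catalogue, substance) {
  i <- match(substance, catalogue$substances$substance)
  if (anyNA(i)) {
    amu_stop("unknown substance: ",
             paste(substance[is.na(i)], collapse = ", "))
  }
  catalogue$substances$amClass[i]
}

#' Resolve the dose-determining component of a product
#'
#' Single-component products resolve to their only component. For fixed
#' combinations, the field convention is to treat the pairing as a single
#' active substance: a beta-lactam paired with a beta-lactamase inhibitor
#' (clavulanic acid, sulbactam, tazobactam) resolves to the beta-lactam, and a
#' trimethoprim–sulphonamide pairing resolves to the minor substance,
#' trimethoprim. Components explicitly annotated with a role in the catalogue
#' file take precedence over the rules. Any other multi-component product is
#' an ambiguous combination and errors.
#'
#' @param catalogue an `amu_catalogue`.
#' @param productId product identifier.
#' @return one-row tibble: the dose-determining component (substance,
#'   concentration, concentrationUnit).
#' @export
resolve_dose_determining <- function(catalogue, productId) {
  comp <- catalogue$components[catalogue$components$productId == productId, ]
  if (nrow(comp) == 0) amu_stop("unknown product: ", productId)
  if (nrow(comp) == 1) return(dplyr::mutate(comp, role = "DOSE_DETERMINING"))
  annotated <- which(comp$role %in% "DOSE_DETERMINING")
  if (length(annotated) == 1) return(comp[annotated, ])
  if (length(annotated) > 1) {
    amu_stop("product ", productId, ": more than one DOSE_DETERMINING component")
  }
  cls <- substance_class(catalogue, comp$substance)
  tmp <- which(cls == "diaminopyrimidines")
  if (length(tmp) == 1 && any(cls == "sulphonamides")) {
    out <- comp[tmp, ]
    out$role <- "DOSE_DETERMINING"
    return(out)
  }
  beta <- which(cls %in% BETA_LACTAM_CLASSES)
  inhib <- which(cls == "beta-lactamase-inhibitors")
  if (length(beta) == 1 && length(inhib) == nrow(comp) - 1) {
    out <- comp[beta, ]
    out$role <- "DOSE_DETERMINING"
    return(out)
  }
  amu_stop("product ", productId, ": ambiguous combination; annotate the ",
           "DOSE_DETERMINING component in the catalogue")
}

# concentration in mg per dispensed unit (mL or syringe), applying the IU factor
concentration_mg <- function(concentration, unit, iu_per_mg) {
  if (any(unit == "IU/mL")) {
    if (is.null(iu_per_mg) || is.na(iu_per_mg) || iu_per_mg <= 0) {
      amu_stop("IU-denominated concentration but no IU-to-mg factor configured")
    }
  }
  ifelse(unit == "IU/mL", concentration / iu_per_mg, concentration)
}

#' Total active-ingredient mass dispensed from a product
#'
#' Multiplies the administered quantity (mL for liquids, dispensing units for
#' syringes) by each component's concentration. The dose-determining
#' component is flagged; co-formulated partner masses are recorded for
#' mass-conservation audit but do not enter the dose metrics.
#'
#' @param catalogue an `amu_catalogue`.
#' @param productId product identifier.
#' @param quantityUsed quantity administered (mL or units), `>= 0`.
#' @return tibble with columns `substance`, `massMg`, `role`.
#' @examples
#' total_active_mass(default_catalogue(), "P05", 60) # 6000 mg enrofloxacin
#' @export
total_active_mass <- function(catalogue, productId, quantityUsed) {
  if (length(quantityUsed) != 1 || is.na(quantityUsed) || quantityUsed < 0) {
    amu_stop("quantityUsed must be a single non-negative number")
  }
  comp <- catalogue$components[catalogue$components$productId == productId, ]
  if (nrow(comp) == 0) amu_stop("unknown product: ", productId)
  dd <- resolve_dose_determining(catalogue, productId)
  tibble::tibble(
    substance = comp$substance,
    massMg = concentration_mg(comp$concentration, comp$concentrationUnit,
                              catalogue$iu_per_mg) * quantityUsed,
    role = ifelse(comp$substance == dd$substance, "DOSE_DETERMINING",
                  "CO_FORMULATED")
  )
}

#' WHO critical-importance category of a substance
#'
#' @param catalogue an `amu_catalogue` (the lookup goes through the
#'   substance's antimicrobial class and the catalogue's category map).
#' @param substance substance name (synonyms accepted).
#' @return one of `"HPCIA"`, `"HIGH_PRIORITY_CIA"`, `"HIGHLY_IMPORTANT"`,
#'   `"IMPORTANT"`, `"UNCLASSIFIED"`.
#' @examples
#' who_category(default_catalogue(), "enrofloxacin")
#' @export
who_category <- function(catalogue, substance) {
  cls <- substance_class(catalogue, normalize_substance(substance))
  i <- match(cls, catalogue$cia_map$amClass)
  if (anyNA(i)) {
    amu_stop("antimicrobial class absent from category map: ",
             paste(unique(cls[is.na(i)]), collapse = ", "))
  }
  catalogue$cia_map$whoCategory[i]
}

#' Look up the recommended daily dose (DDDkg) for a substance
#'
#' Returns the most specific match: exact species and route first, then the
#' species-agnostic `BOVINE_ANY` record for the route.
#'
#' @param catalogue an `amu_catalogue`.
#' @param substance substance name.
#' @param species `"CATTLE"`, `"BUFFALO"` or `"BOVINE_ANY"`.
#' @param route `"PARENTERAL"`, `"INTRAMAMMARY"` or `"ORAL"`.
#' @return one-row tibble with `dddKg` (mg/kg/day) and `source`.
#' @export
lookup_ddd <- function(catalogue, substance, species, route) {
  substance <- normalize_substance(substance)
  species <- match_enum(species, SPECIES, "species")
  route <- match_enum(route, FORMULATIONS, "route")
  reg <- catalogue$ddd
  hit <- reg[reg$substance == substance & reg$species == species &
               reg$route == route, ]
  if (nrow(hit) == 0) {
    hit <- reg[reg$substance == substance & reg$species == "BOVINE_ANY" &
                 reg$route == route, ]
  }
  if (nrow(hit) == 0) {
    amu_stop("no DDD record for ", substance, " / ", species, " / ", route)
  }
  hit[1, c("substance", "species", "route", "dddKg", "source")]
}
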