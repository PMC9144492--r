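#' Read a solvent catalog
#'
#' Loads a table of candidate solvents with their molar masses, commercial
#' availability flags and (optionally) the eight raw environmental-impact
#' component scores used by [ei_total()].  Columns carrying a `_x10` or
#' `_x1e5` header suffix are understood to be on the scaled display
#' convention of PARIS-III-style reports (human ingestion toxicity
#' multiplied by 10, aquatic toxicity by 1e5) and are de-scaled to raw
#' scores at load time.
#'
#' Expected columns: `name`, `cas`, `molar_mass_g_mol`, `available`, and the
#' EI components `htping`, `htpinh`, `ttp`, `atp`, `gwp`, `odp`, `pcop`,
#' `ar` (the first and fourth optionally as `htping_x10` / `atp_x1e5`).
#' EI columns may be missing entirely (records without an EI are legal and
#' handled downstream), but a row with some EI components and holes in
#' others is rejected.
#'
#' @param path Path to a CSV or JSON file.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return A tibble with one row per solvent: `name`, `cas`, `molar_mass`
#'   (g/mol), `available` (logical), the eight raw EI component columns
#'   (`NA` when the record carries no EI), plus any extra columns present
#'   in the file (e.g. model parameters).
#' @export
#' @examples
#' path <- system.file("extdata", "solvents.csv", package = "greensolv")
#' read_solvent_catalog(path)
read_solvent_catalog <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  raw <- read_table_file(path, format)
  required <- c("name", "cas", "molar_mass_g_mol", "available")
  check_columns(raw, required, path)

  scaled <- detect_scaled_ei(names(raw))
  out <- tibble(
    name = as.character(raw$name),
    cas = as.character(raw$cas),
    molar_mass = parse_numeric_column(raw$molar_mass_g_mol, "molar_mass_g_mol"),
    available = parse_logical_column(raw$available, "available")
  )
  for (comp in EI_COMPONENTS) {
    col <- scaled$source[[comp]]
    if (is.null(col)) {
      out[[comp]] <- NA_real_
    } else {
      out[[comp]] <- parse_numeric_column(raw[[col]], col) / scaled$factor[[comp]]
    }
  }
  extra <- setdiff(names(raw), c(required, unlist(scaled$source)))
  for (col in extra) out[[col]] <- raw[[col]]
  validate_solvent_catalog(out)
  out
}

#' Write a solvent catalog
#'
#' Inverse of [read_solvent_catalog()].  With `scaled = TRUE` the HTPIng and
#' ATP columns are written back on the display convention (`htping_x10`,
#' `atp_x1e5`), so a scaled write followed by a read is the identity on raw
#' scores.
#'
#' @param catalog A solvent tibble as returned by [read_solvent_catalog()].
#' @param path Output file path.
#' @param scaled Write HTPIng/ATP on the x10 / x1e5 display scale?
#' @return `path`, invisibly.
#' @export
write_solvent_catalog <- function(catalog, path, scaled = FALSE) {
  validate_solvent_catalog(catalog)
  out <- catalog
  names(out)[names(out) == "molar_mass"] <- "molar_mass_g_mol"
  if (scaled) {
    out$htping <- out$htping * 10
    out$atp <- out$atp * 1e5
    names(out)[names(out) == "htping"] <- "htping_x10"
    names(out)[names(out) == "atp"] <- "atp_x1e5"
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a solute catalog
#'
#' Solutes are characterised by their melting temperature and enthalpy of
#' fusion; the enthalpy unit tag is mandatory in the file (`kJ/mol` or
#' `kcal/mol`) and is never inferred.  Enthalpies are converted to kJ/mol
#' on load (the stored tag is kept for provenance).
#'
#' Expected columns: `name`, `cas`, `tm_K`, `hfus`, `hfus_unit`.
#'
#' @inheritParams read_solvent_catalog
#' @return A tibble: `name`, `cas`, `tm` (K), `hfus` (kJ/mol, converted),
#'   `hfus_unit` (the tag as given in the file).
#' @export
read_solute_catalog <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  raw <- read_table_file(path, format)
  check_columns(raw, c("name", "cas", "tm_K", "hfus", "hfus_unit"), path)
  hfus <- parse_numeric_column(raw$hfus, "hfus")
  unit <- as.character(raw$hfus_unit)
  out <- tibble(
    name = as.character(raw$name),
    cas = as.character(raw$cas),
    tm = parse_numeric_column(raw$tm_K, "tm_K"),
    hfus = purrr::map2_dbl(hfus, unit, convert_fusion_enthalpy),
    hfus_unit = unit
  )
  validate_solute_catalog(out)
  out
}

#' Write a solute catalog
#'
#' Enthalpies are written in kJ/mol with an explicit unit tag, so a
#' write/read round trip is the identity.
#'
#' @inheritParams write_solvent_catalog
#' @param catalog A solute tibble as returned by [read_solute_catalog()].
#' @export
write_solute_catalog <- function(catalog, path) {
  validate_solute_catalog(catalog)
  out <- tibble(
    name = catalog$name, cas = catalog$cas, tm_K = catalog$tm,
    hfus = catalog$hfus, hfus_unit = "kJ/mol"
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read shake-flask measurement records
#'
#' Reads wide-format measurement tables (`x_rep1 .. x_repN` replicate
#' columns) into a tidy tibble with one row per (solute, organic solvent,
#' solute-free organic fraction, temperature) and replicate solubilities in
#' a list column, alongside their mean and standard deviation.
#'
#' Expected columns: `solute`, `organic_solvent`, `x2_star`, `T_K`,
#' `x_rep1` .. `x_repN` (N >= 1; trailing replicates may be NA for
#' unbalanced designs, but each row needs at least one value).
#'
#' @inheritParams read_solvent_catalog
#' @return A tibble: `solute`, `organic_solvent`, `organic_fraction`,
#'   `temperature`, `replicates` (list of numeric vectors), `x_mean`,
#'   `x_sd` (`NA` for single replicates).
#' @export
read_measurements <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  raw <- read_table_file(path, format)
  check_columns(raw, c("solute", "organic_solvent", "x2_star", "T_K"), path)
  rep_cols <- grep("^x_rep[0-9]+$", names(raw), value = TRUE)
  if (length(rep_cols) == 0) {
    abort(sprintf("no replicate columns (x_rep1..) found in '%s'", path))
  }
  rep_cols <- rep_cols[order(as.integer(sub("^x_rep", "", rep_cols)))]
  reps <- purrr::map(rep_cols, function(col) parse_numeric_column(raw[[col]], col, allow_na = TRUE))
  rep_mat <- do.call(cbind, reps)
  rep_list <- apply(rep_mat, 1, function(r) r[!is.na(r)], simplify = FALSE)

  out <- tibble(
    solute = as.character(raw$solute),
    organic_solvent = as.character(raw$organic_solvent),
    organic_fraction = parse_numeric_column(raw$x2_star, "x2_star"),
    temperature = parse_numeric_column(raw$T_K, "T_K"),
    replicates = rep_list,
    x_mean = purrr::map_dbl(rep_list, mean),
    x_sd = purrr::map_dbl(rep_list, function(r) if (length(r) > 1) stats::sd(r) else NA_real_)
  )
  validate_measurements(out)
  out
}

#' Write measurement records in the wide replicate format
#'
#' @inheritParams write_solvent_catalog
#' @param measurements A tibble as returned by [read_measurements()] or
#'   [generate_measured_profiles()].
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  nrep <- max(lengths(measurements$replicates))
  wide <- tibble(
    solute = measurements$solute,
    organic_solvent = measurements$organic_solvent,
    x2_star = measurements$organic_fraction,
    T_K = measurements$temperature
  )
  for (k in seq_len(nrep)) {
    wide[[paste0("x_rep", k)]] <- purrr::map_dbl(
      measurements$replicates,
      function(r) if (length(r) >= k) r[[k]] else NA_real_
    )
  }
  readr::write_csv(wide, path)
  invisible(path)
}

#' Convert an enthalpy of fusion to kJ/mol
#'
#' `kcal/mol` values are multiplied by exactly 4.184; `kJ/mol` values pass
#' through unchanged.  The unit tag must always be given explicitly.
#'
#' @param value Enthalpy of fusion, positive.
#' @param unit `"kJ/mol"` or `"kcal/mol"`.
#' @return The enthalpy in kJ/mol.
#' @export
#' @examples
#' convert_fusion_enthalpy(20.9, "kcal/mol") # 87.4456
convert_fusion_enthalpy <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) || value <= 0) {
    abort("fusion enthalpy must be a single positive number")
  }
  switch(unit,
    "kJ/mol" = value,
    "kcal/mol" = value * 4.184,
    abort(sprintf("unknown enthalpy unit tag '%s' (use 'kJ/mol' or 'kcal/mol')", unit))
  )
}

#' Solute-free organic mole fraction
#'
#' The composition coordinate of a water--organic binary solvent: the
#' organic amount over the total solvent amount, dissolved solute excluded
#' from the basis.
#'
#' @param moles_organic,moles_water Amounts (mol), both non-negative and
#'   not both zero.
#' @return The solute-free fraction in `[0, 1]`.
#' @export
solute_free_fraction <- function(moles_organic, moles_water) {
  stopifnot(is.numeric(moles_organic), is.numeric(moles_water))
  if (any(moles_organic < 0) || any(moles_water < 0)) {
    abort("amounts must be non-negative")
  }
  total <- moles_organic + moles_water
  if (any(total == 0)) abort("organic and water amounts cannot both be zero")
  moles_organic / total
}

#' Bundled example solvents
#'
#' The four solvents of the worked examples (water, DMSO, DMF and
#' 4-formylmorpholine) with their molar masses and raw EI component scores
#' (water's component-level breakdown is not tabulated anywhere public;
#' only its composite EI of 0.02 is known, so its component columns are
#' `NA` and mixture work uses the composite via [ei_aqueous_mixture()]).
#'
#' @return A solvent catalog tibble; see [read_solvent_catalog()].
#' @export
example_solvents <- function() {
  read_solvent_catalog(system.file("extdata", "solvents.csv", package = "greensolv"))
}

#' Bundled example solutes
#'
#' Fusion data for benzamide, salicylamide and ethenzamide (melting
#' temperature and enthalpy of fusion).  The primary literature prints the
#' enthalpies with a kcal/mol tag, but their magnitudes (20.9, 28.4,
#' 20.4) match the kJ/mol values compiled for these amides, and only the
#' kJ/mol reading yields sensible ideal solubilities (a 87 kJ/mol fusion
#' enthalpy would put benzamide's ideal solubility near 4e-10).  The
#' bundled records therefore declare kJ/mol; use
#' [convert_fusion_enthalpy()] if you prefer the literal reading.
#'
#' @return A solute catalog tibble; see [read_solute_catalog()].
#' @export
example_solutes <- function() {
  read_solute_catalog(system.file("extdata", "solutes.csv", package = "greensolv"))
}

# ---- internal helpers -------------------------------------------------------

read_table_file <- function(path, format) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
}

check_columns <- function(raw, required, path) {
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("schema error in '%s': missing mandatory column(s) %s",
                  path, paste0("'", missing, "'", collapse = ", ")))
  }
}

# Map each EI component to its source column and de-scaling factor, honouring
# the _x10 / _x1e5 display-scale header suffixes.
detect_scaled_ei <- function(cols) {
  source <- list()
  factor <- list()
  for (comp in EI_COMPONENTS) {
    hits <- cols[cols == comp | grepl(paste0("^", comp, "_x[0-9e]+$"), cols)]
    if (length(hits) > 1) {
      abort(sprintf("EI component '%s' appears in multiple columns: %s",
                    comp, paste(hits, collapse = ", ")))
    }
    if (length(hits) == 1) {
      source[[comp]] <- hits
      suffix <- sub(paste0("^", comp), "", hits)
      factor[[comp]] <- if (suffix == "") 1
        else if (suffix == "_x10") 10
        else if (suffix == "_x1e5") 1e5
        else abort(sprintf("unrecognised scaling suffix in column '%s'", hits))
    }
  }
  list(source = source, factor = factor)
}

parse_numeric_column <- function(x, col, allow_na = FALSE) {
  if (is.numeric(x)) return(as.double(x))
  out <- suppressWarnings(as.double(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "")
  if (length(bad) > 0) {
    abort(sprintf("parse error in column '%s', row %d: '%s' is not numeric",
                  col, bad[1], x[bad[1]]))
  }
  if (!allow_na && anyNA(out) && !all(is.na(out))) {
    # mixed NA/value columns are only legal for EI blocks, checked later
  }
  out
}

parse_logical_column <- function(x, col) {
  if (is.logical(x)) return(x)
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("parse error in column '%s', row %d: '%s' is not logical",
                  col, bad[1], as.character(x)[bad[1]]))
  }
  out
}

validate_solvent_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  need <- c("name", "molar_mass", "available")
  missing <- setdiff(need, names(catalog))
  if (length(missing) > 0) {
    abort(sprintf("solvent catalog lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(catalog$molar_mass) | catalog$molar_mass <= 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid molar_mass in row %d (must be > 0)", bad[1]))
  }
  comp_present <- intersect(EI_COMPONENTS, names(catalog))
  if (length(comp_present) > 0) {
    comps <- as.matrix(catalog[comp_present])
    n_na <- rowSums(is.na(comps))
    partial <- which(n_na > 0 & n_na < length(comp_present))
    if (length(partial) > 0) {
      abort(sprintf("row %d has a partial EI block (all eight components or none)",
                    partial[1]))
    }
    neg <- which(apply(comps, 1, function(r) any(!is.na(r) & r < 0)))
    if (length(neg) > 0) abort(sprintf("negative EI component in row %d", neg[1]))
  }
  invisible(catalog)
}

validate_solute_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  missing <- setdiff(c("name", "tm", "hfus"), names(catalog))
  if (length(missing) > 0) {
    abort(sprintf("solute catalog lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(catalog$tm) | catalog$tm <= 0)) abort("melting temperature must be > 0 K")
  if (any(!is.finite(catalog$hfus) | catalog$hfus <= 0)) abort("fusion enthalpy must be > 0")
  invisible(catalog)
}

validate_measurements <- function(m) {
  stopifnot(is.data.frame(m))
  need <- c("solute", "organic_solvent", "organic_fraction", "temperature", "replicates")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0) {
    abort(sprintf("measurement table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(m$organic_fraction < 0 | m$organic_fraction > 1)) {
    abort("organic_fraction must lie in [0, 1]")
  }
  if (any(lengths(m$replicates) < 1)) abort("each record needs at least one replicate")
  ok <- purrr::map_lgl(m$replicates, function(r) all(r > 0 & r < 1))
  if (!all(ok)) abort(sprintf("replicate solubilities must lie in (0, 1); row %d violates",
                              which(!ok)[1]))
  invisible(m)
}

# Look up one solute row by name from a solute catalog (or pass a one-row
# tibble/list through).  Used by the solver-facing functions.
as_solute <- function(solute, catalog = NULL) {
  if (is.character(solute)) {
    if (is.null(catalog)) catalog <- example_solutes()
    hit <- catalog[catalog$name == solute, , drop = FALSE]
    if (nrow(hit) != 1) abort(sprintf("solute '%s' not found in catalog", solute))
    return(as.list(hit))
  }
  solute <- as.list(solute)
  if (is.null(solute$tm) || is.null(solute$hfus)) {
    abort("a solute needs 'tm' (K) and 'hfus' (kJ/mol) fields")
  }
  if (is.null(solute$name)) solute$name <- "solute"
  solute
}
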