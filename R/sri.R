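# Spectral reflectance index registry: each index is a named record with a
# formula over band symbols R350..R2500, evaluated column-wise on a spectra
# table. Two-band families (normalized difference, simple ratio) are built by
# constructors; multi-band indices carry an explicit expression string.

sri_name2 <- function(prefix, a, b) sprintf("%s (%d;%d)", prefix, a, b)

sri_record <- function(name, kind, wavelengths, expression, provenance = "") {
  stopifnot(kind %in% c("normalized_difference", "ratio", "expression"))
  wavelengths <- as.integer(wavelengths)
  if (any(wavelengths < 350L | wavelengths > 2500L)) {
    abort(sprintf("index `%s` references a wavelength outside [350, 2500]", name),
          class = "spectrait_format_error")
  }
  tibble(name = name, kind = kind, wavelengths = list(wavelengths),
         expression = expression, provenance = provenance)
}

#' Generic two-band spectral index constructors
#'
#' `sri_ndsi()` builds a normalized-difference index
#' \eqn{(R_a - R_b)/(R_a + R_b)} and `sri_sr()` a simple ratio
#' \eqn{R_a / R_b}, the two families from which most published spectral
#' reflectance indices derive (NDSI/NDWI/NDTI and SR/CI/RBI/WI
#' respectively). Use them to extend a registry beyond the built-in set.
#'
#' @param a,b Integer wavelengths in nm within \[350, 2500\].
#' @param name Registry name; defaults to `"NDSI (a;b)"` / `"SR (a;b)"`.
#' @param provenance Free-text provenance note.
#' @return A one-row registry tibble, row-bindable onto [sri_registry()].
#' @export
#' @examples
#' dplyr::bind_rows(sri_registry(), sri_ndsi(1100, 1200))
sri_ndsi <- function(a, b, name = sri_name2("NDSI", a, b), provenance = "") {
  sri_record(name, "normalized_difference", c(a, b),
             sprintf("(R%d - R%d) / (R%d + R%d)", a, b, a, b), provenance)
}

#' @rdname sri_ndsi
#' @export
sri_sr <- function(a, b, name = sri_name2("SR", a, b), provenance = "") {
  sri_record(name, "ratio", c(a, b), sprintf("R%d / R%d", a, b), provenance)
}

sri_expr <- function(name, expression, provenance = "") {
  wl <- sort(unique(as.integer(sub("^R", "",
    regmatches(expression, gregexpr("R[0-9]+", expression))[[1L]]))))
  sri_record(name, "expression", wl, expression, provenance)
}

#' Built-in registry of spectral reflectance indices
#'
#' All indices used in the motivating wheat phenotyping comparison:
#' near-infrared water indices (NWI-3, WI, WI2, NDWI pairs), chlorophyll and
#' red-edge indices (MTCI, MCARI, TCARI variants, DATT, PRI, SIPI, RE),
#' structural/soil-adjusted indices (SAVI, WDVI, BI, NRI), and the generic
#' normalized-difference (NDSI/NDTI) and ratio (SR/CI/RBI) pairs at their
#' published wavelengths. Indices whose defining papers print only a name
#' and wavelengths are instantiated from their standard literature forms;
#' the `provenance` column records the source of each formula.
#'
#' @return A registry tibble with columns `name`, `kind`, `wavelengths`
#'   (list of integer nm), `expression` and `provenance`.
#' @export
#' @examples
#' reg <- sri_registry()
#' reg[reg$name == "NWI-3", ]
sri_registry <- function() {
  nd <- function(prefix, a, b, prov = "normalized difference at published bands")
    sri_ndsi(a, b, name = sri_name2(prefix, a, b), provenance = prov)
  rt <- function(prefix, a, b, prov = "simple ratio at published bands")
    sri_sr(a, b, name = sri_name2(prefix, a, b), provenance = prov)
  out <- dplyr::bind_rows(
    sri_expr("NWI-3", "(R970 - R920) / (R970 + R920)",
             "normalized water index 3"),
    sri_expr("WI2", "R970 / R900", "water index variant R970/R900"),
    rt("WI", 950, 900, "water index, Penuelas-style band ratio"),
    rt("WI", 900, 970, "water index, inverse orientation"),
    rt("WI", 970, 900, "water index, same form as WI2"),
    sri_expr("MTCI (800;750;670)", "(R800 - R750) / (R750 - R670)",
             "MERIS terrestrial chlorophyll index"),
    sri_expr("SAVI (807;736)", "1.5 * (R807 - R736) / (R807 + R736 + 0.5)",
             "soil-adjusted vegetation index, L = 0.5"),
    sri_expr("SAVI 2 (800;670)", "1.5 * (R800 - R670) / (R800 + R670 + 0.5)",
             "soil-adjusted vegetation index at classical red/NIR bands"),
    sri_expr("TCARI (700;600;550;850;670)",
             "3 * ((R700 - R600) - (0.2 * (R700 - R550)) * (R700 / (R850 + R670)))",
             "transformed chlorophyll absorption ratio, five-band variant"),
    sri_expr("TCARI (700;670;550)",
             "3 * ((R700 - R670) - 0.2 * (R700 - R550) * (R700 / R670))",
             "transformed chlorophyll absorption ratio, Haboudane form"),
    sri_expr("MCARI (700;670;550)",
             "((R700 - R670) - 0.2 * (R700 - R550)) * (R700 / R670)",
             "modified chlorophyll absorption ratio, Daughtry form"),
    nd("PRI", 550, 531, "photochemical reflectance index orientation"),
    nd("PRI", 512, 531, "photochemical reflectance index, 512 nm variant"),
    sri_expr("PRI * CI (570;530;760;700)",
             "((R570 - R530) / (R570 + R530)) * (R760 / R700 - 1)",
             "PRI scaled by the red-edge chlorophyll index, Garrity form"),
    nd("NRI", 1510, 660, "nitrogen reflectance index"),
    sri_expr("SIPI (800;440;680)", "(R800 - R440) / (R800 - R680)",
             "structure-insensitive pigment index, Penuelas form"),
    sri_expr("Datt (850;710;680)", "(R850 - R710) / (R850 - R680)",
             "Datt chlorophyll index"),
    sri_expr("WDVI (830;660)", "R830 - 1.06 * R660",
             "weighted difference vegetation index, soil-line slope 1.06"),
    sri_expr("BI (460;660)", "sqrt((R460^2 + R660^2) / 2)",
             "euclidean brightness index"),
    sri_expr("RE (670;780)",
             "700 + 40 * (((R670 + R780) / 2 - R700) / (R740 - R700))",
             "red-edge inflection position by linear interpolation"),
    sri_expr("AI (740;887;691;698)", "(R740 - R887) / (R691 - R698)",
             "aphid index, Mirik form"),
    nd("NDSI", 403, 830), nd("NDSI", 543, 548), nd("NDSI", 933, 948),
    nd("NDSI", 410, 550), nd("NDSI", 1060, 1118), nd("NDSI", 940, 1122),
    nd("NDSI", 442, 438), nd("NDSI", 503, 483),
    nd("NDWI", 970, 920, "normalized difference water index"),
    nd("NDWI", 970, 850, "normalized difference water index"),
    nd("NDWI", 870, 1260, "normalized difference water index"),
    nd("NDTI", 1650, 2215, "normalized difference tillage index"),
    rt("SR", 550, 670), rt("SR", 690, 655), rt("SR", 960, 950),
    rt("SR", 440, 685),
    rt("CI", 415, 695, "colouration index band ratio"),
    rt("RBI", 695, 445, "red/blue ratio index")
  )
  if (anyDuplicated(out$name)) abort("registry names must be unique")
  class(out) <- unique(c("sri_registry", class(out)))
  out
}

canon_sri <- function(x) gsub("[[:space:]]", "", tolower(x))

#' Look up an index definition by name
#'
#' Matching ignores case and whitespace, so `"SAVI 2 (800;670)"` and
#' `"savi2(800;670)"` resolve to the same record.
#'
#' @param registry A registry tibble (see [sri_registry()]).
#' @param name Index name to resolve.
#' @return The matching one-row registry tibble; error if absent.
#' @export
sri_lookup <- function(registry, name) {
  hit <- which(canon_sri(registry$name) == canon_sri(name))
  if (length(hit) == 0L) {
    # fall back to the base name ("MTCI" for "MTCI (800;750;670)") when it
    # identifies a single registry entry
    base <- function(x) canon_sri(sub("\\s*\\(.*$", "", x))
    hit <- which(base(registry$name) == base(name))
    if (length(hit) > 1L) {
      abort(sprintf("index name `%s` is ambiguous; candidates: %s", name,
                    paste(registry$name[hit], collapse = ", ")),
            class = "spectrait_lookup_error")
    }
  }
  if (length(hit) == 0L) {
    abort(sprintf("no index named `%s` in the registry", name),
          class = "spectrait_lookup_error")
  }
  registry[hit[1L], ]
}

# Evaluate one index expression against a band environment. Returns a vector
# over observations; non-finite results (zero denominators) become NA so
# downstream screening can proceed.
eval_index <- function(definition, band_env, available) {
  need <- definition$wavelengths[[1L]]
  missing_nm <- setdiff(need, available)
  if (length(missing_nm) > 0L) {
    abort(sprintf("index `%s` needs band(s) %s nm, absent from the spectra grid",
                  definition$name, paste(missing_nm, collapse = ", ")),
          class = "spectrait_band_error")
  }
  v <- eval(parse(text = definition$expression)[[1L]], envir = band_env)
  v[!is.finite(v)] <- NA_real_
  v
}

#' Compute one spectral index
#'
#' @param spectra Spectra tibble (any number of rows).
#' @param definition One-row registry tibble, or an index name resolved
#'   against `registry`.
#' @param registry Registry used when `definition` is a name.
#' @return Numeric vector, one value per observation; `NA` where the
#'   formula is undefined (zero denominator).
#' @export
#' @examples
#' s <- tibble::tibble(observation_id = "p", `920` = 0.3, `970` = 0.3)
#' compute_index(s, "NWI-3")
compute_index <- function(spectra, definition, registry = sri_registry()) {
  if (is.character(definition)) definition <- sri_lookup(registry, definition)
  spectra <- as_tibble(spectra)
  bands <- band_cols(spectra)
  band_env <- new.env(parent = baseenv())
  for (b in bands) assign(paste0("R", b), spectra[[b]], envir = band_env)
  eval_index(definition, band_env, as.integer(bands))
}

#' Compute every registry index over a spectra table
#'
#' @param spectra Spectra tibble.
#' @param registry Registry tibble; defaults to the built-in set.
#' @return Tibble with `observation_id` followed by one column per index, in
#'   registry order. An index whose bands were trimmed from the grid yields
#'   an all-`NA` column with a warning rather than a failure.
#' @export
compute_indices <- function(spectra, registry = sri_registry()) {
  spectra <- as_tibble(spectra)
  bands <- band_cols(spectra)
  band_env <- new.env(parent = baseenv())
  for (b in bands) assign(paste0("R", b), spectra[[b]], envir = band_env)
  available <- as.integer(bands)
  n <- nrow(spectra)
  cols <- lapply(seq_len(nrow(registry)), function(i) {
    tryCatch(eval_index(registry[i, ], band_env, available),
             spectrait_band_error = function(e) {
               warn(sprintf("index `%s` skipped: %s", registry$name[i],
                            conditionMessage(e)))
               rep(NA_real_, n)
             })
  })
  names(cols) <- registry$name
  dplyr::bind_cols(spectra["observation_id"], as_tibble(cols))
}

#' Export or import an index registry as delimited text
#'
#' One record per line: `name`, `kind`, semicolon-joined `wavelengths`,
#' `expression`, `provenance`, written as CSV so registries can be shared
#' and extended outside R.
#'
#' @param registry Registry tibble.
#' @param path File path.
#' @return `write_registry()` returns `registry` invisibly; `read_registry()`
#'   the re-assembled registry tibble.
#' @export
write_registry <- function(registry, path) {
  flat <- dplyr::mutate(as_tibble(registry),
    wavelengths = vapply(.data$wavelengths, paste, "", collapse = ";"))
  readr::write_csv(flat, path)
  invisible(registry)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- dplyr::mutate(flat,
    wavelengths = lapply(strsplit(as.character(.data$wavelengths), ";"), as.integer))
  class(out) <- unique(c("sri_registry", class(out)))
  out
}
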