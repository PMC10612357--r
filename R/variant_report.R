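extdata_table <- function(file) {
  path <- system.file("extdata", file, package = "kinstab")
  if (path == "") ks_stop(paste0("packaged table not found: ", file),
                          "missing_data")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged reference tables for MAPK1/MAPK3 wild type and variants
#'
#' Reference measurements for the cancer-associated MAPK1 and MAPK3 missense
#' variants profiled by this pipeline, shipped as plain CSV so other kinase
#' or variant sets can replace them:
#' `mapk_variant_groups()` -- CD-site classification (group I: residue
#' interacting with the common docking site; II: residue in the CD-site;
#' III: elsewhere); `mapk_kinetics_table()` -- Michaelis-Menten and
#' temperature-dependence parameters of the phosphorylated enzymes;
#' `mapk_tm_table()` -- apparent melting temperatures (one row per detected
#' transition; biphasic melts have several rows); `mapk_stability_table()`
#' -- two-state equilibrium unfolding parameters (rows whose published fits
#' were three-state are not included).
#'
#' @return A data frame.
#' @export
mapk_variant_groups <- function() extdata_table("variant_groups.csv")

#' @rdname mapk_variant_groups
#' @export
mapk_kinetics_table <- function() extdata_table("kinetics_parameters.csv")

#' @rdname mapk_variant_groups
#' @export
mapk_tm_table <- function() extdata_table("melting_temperatures.csv")

#' @rdname mapk_variant_groups
#' @export
mapk_stability_table <- function() extdata_table("stability_two_state.csv")

# sequence lengths bounding valid substitution positions
protein_lengths <- c(MAPK1 = 360L, MAPK3 = 379L)

#' Parse a missense substitution label
#'
#' Splits a label such as `"E81K"` into wild-type residue, position and
#' mutant residue, validating the position against the protein length
#' (MAPK1: 360 residues, MAPK3: 379).
#'
#' @param substitution Text, letter-integer-letter.
#' @param protein `"MAPK1"` or `"MAPK3"` (optional: enables the position
#'   bound check).
#'
#' @return A list with `wt`, `position`, `mut`.
#' @export
parse_substitution <- function(substitution, protein = NULL) {
  if (!is.character(substitution) || length(substitution) != 1L ||
      !grepl("^[A-Z][0-9]+[A-Z]$", substitution)) {
    ks_stop(sprintf("malformed substitution '%s': expected e.g. 'E81K'",
                    paste(substitution, collapse = ",")), "parse_error")
  }
  pos <- as.integer(gsub("[A-Z]", "", substitution))
  if (!is.null(protein)) {
    protein <- match.arg(protein, names(protein_lengths))
    if (pos < 1L || pos > protein_lengths[[protein]]) {
      ks_stop(sprintf("position %d outside %s sequence (1-%d)",
                      pos, protein, protein_lengths[[protein]]),
              "parse_error")
    }
  }
  list(wt = substr(substitution, 1L, 1L), position = pos,
       mut = substr(substitution, nchar(substitution), nchar(substitution)))
}

#' Classify a variant by its relation to the common docking site
#'
#' Looks the substitution up in the packaged group table (or a user-supplied
#' one with columns `protein`, `substitution`, `group`): group I variants
#' carry a mutation in a residue interacting with the CD-site, group II in
#' the CD-site itself, group III elsewhere in the protein.
#'
#' @param protein `"MAPK1"` or `"MAPK3"`.
#' @param substitution Substitution label, e.g. `"E81K"`.
#' @param group_table Lookup table; defaults to [mapk_variant_groups()].
#'
#' @return `"I"`, `"II"`, `"III"`, or `"Unclassified"` for a variant absent
#'   from the table.
#' @export
#'
#' @examples
#' classify_variant("MAPK1", "E81K")  # "I"
#' classify_variant("MAPK1", "P319S") # "II"
classify_variant <- function(protein, substitution,
                             group_table = mapk_variant_groups()) {
  protein <- match.arg(protein, names(protein_lengths))
  parse_substitution(substitution, protein)
  hit <- group_table$protein == protein &
    group_table$substitution == substitution
  if (!any(hit)) return("Unclassified")
  group_table$group[which(hit)[1L]]
}

#' Assemble a per-variant measurement record
#'
#' Collects the measured quantities a wild-type comparison needs: apparent
#' melting temperatures of the non-phosphorylated (NP) and phosphorylated
#' (P) forms, catalytic efficiency, temperature of maximal activity and
#' activation energy of the active enzyme, plus the judgement flags
#' (tertiary-structure change, three-state unfolding) which are recorded
#' inputs, not inferred.
#'
#' @param protein `"MAPK1"` or `"MAPK3"`.
#' @param substitution Substitution label, or `"WT"` for the wild type.
#' @param tm_NP,tm_P Apparent Tm in degrees C.
#' @param efficiency Catalytic efficiency kcat/Km, 1/s/uM.
#' @param tmax Temperature of maximal activity, degrees C.
#' @param Ea Arrhenius activation energy, kcal/mol.
#' @param tertiary_change_NP,tertiary_change_P Logical flags from near-UV CD
#'   comparison with the wild type.
#' @param three_state_NP,three_state_P Logical flags: unfolding required the
#'   three-state model.
#' @param group CD-site group; default from [classify_variant()].
#'
#' @return An object of class `kinstab_variant_record`.
#' @export
variant_record <- function(protein, substitution,
                           tm_NP = NA_real_, tm_P = NA_real_,
                           efficiency = NA_real_, tmax = NA_real_,
                           Ea = NA_real_,
                           tertiary_change_NP = NA, tertiary_change_P = NA,
                           three_state_NP = NA, three_state_P = NA,
                           group = NULL) {
  protein <- match.arg(protein, names(protein_lengths))
  if (!identical(substitution, "WT")) {
    parse_substitution(substitution, protein)
    if (is.null(group)) group <- classify_variant(protein, substitution)
  } else {
    group <- group %||% NA_character_
  }
  structure(
    list(protein = protein, substitution = substitution, group = group,
         tm_NP = tm_NP, tm_P = tm_P, efficiency = efficiency,
         tmax = tmax, Ea = Ea,
         tertiary_change_NP = tertiary_change_NP,
         tertiary_change_P = tertiary_change_P,
         three_state_NP = three_state_NP, three_state_P = three_state_P),
    class = "kinstab_variant_record"
  )
}

#' Compare a variant record to the wild type
#'
#' Builds one row of the comparison ledger: temperature deltas are
#' variant minus wild type; the efficiency ratio is variant efficiency over
#' wild-type efficiency. Swapping the arguments negates every delta and
#' inverts the ratio.
#'
#' @param variant,wildtype [variant_record()] objects for the same protein.
#'
#' @return A `kinstab_comparison_row` with `delta_tm_NP`, `delta_tm_P`
#'   (degrees C), `efficiency_ratio`, `delta_tmax` (degrees C), `delta_Ea`
#'   (kcal/mol) and the copied judgement flags.
#' @export
compare_to_wildtype <- function(variant, wildtype) {
  for (r in list(variant, wildtype)) {
    if (!inherits(r, "kinstab_variant_record")) {
      ks_stop("arguments must be kinstab_variant_record objects",
              "invalid_input")
    }
  }
  if (variant$protein != wildtype$protein) {
    ks_stop("variant and wild type belong to different proteins",
            "invalid_input")
  }
  need <- c("tm_NP", "tm_P", "efficiency", "tmax", "Ea")
  missing_v <- need[vapply(need, function(f) is.na(variant[[f]]), logical(1))]
  missing_w <- need[vapply(need, function(f) is.na(wildtype[[f]]), logical(1))]
  if (length(missing_v) || length(missing_w)) {
    ks_stop(paste0(
      "incomplete record; missing ",
      if (length(missing_v)) paste0("variant: ",
                                    paste(missing_v, collapse = ", ")),
      if (length(missing_v) && length(missing_w)) "; ",
      if (length(missing_w)) paste0("wild type: ",
                                    paste(missing_w, collapse = ", "))),
      "incomplete_record")
  }
  if (wildtype$efficiency <= 0) {
    ks_stop("wild-type efficiency must be positive", "invalid_input")
  }
  structure(
    list(protein = variant$protein, substitution = variant$substitution,
         group = variant$group,
         delta_tm_NP = variant$tm_NP - wildtype$tm_NP,
         delta_tm_P = variant$tm_P - wildtype$tm_P,
         efficiency_ratio = variant$efficiency / wildtype$efficiency,
         delta_tmax = variant$tmax - wildtype$tmax,
         delta_Ea = variant$Ea - wildtype$Ea,
         tertiary_change_NP = variant$tertiary_change_NP,
         tertiary_change_P = variant$tertiary_change_P,
         three_state_NP = variant$three_state_NP,
         three_state_P = variant$three_state_P),
    class = "kinstab_comparison_row"
  )
}

first_tm <- function(tm_table, protein, variant, state) {
  hit <- tm_table$protein == protein & tm_table$variant == variant &
    tm_table$phospho_state == state
  if (!any(hit)) NA_real_ else tm_table$tm_C[which(hit)[1L]]
}

record_from_tables <- function(protein, variant,
                               kin = mapk_kinetics_table(),
                               tm = mapk_tm_table()) {
  krow <- kin[kin$protein == protein & kin$variant == variant, ]
  variant_record(
    protein,
    if (variant == "WT") "WT" else variant,
    tm_NP = first_tm(tm, protein, variant, "NP"),
    tm_P = first_tm(tm, protein, variant, "P"),
    efficiency = if (nrow(krow)) krow$efficiency_per_s_uM[1L] else NA_real_,
    tmax = if (nrow(krow)) krow$Tmax_C[1L] else NA_real_,
    Ea = if (nrow(krow)) krow$Ea_kcal_mol[1L] else NA_real_
  )
}

#' Build the full variant-vs-wild-type comparison ledger
#'
#' Assembles one [compare_to_wildtype()] row per variant from the packaged
#' reference tables (or user-supplied replacements with the same columns).
#' The efficiency ratio uses the tables' efficiency column, i.e. the
#' reported kcat/Km values.
#'
#' @param protein `"MAPK1"`, `"MAPK3"` or `"both"` (default).
#' @param kinetics_table,tm_table Data frames shaped like
#'   [mapk_kinetics_table()] and [mapk_tm_table()].
#'
#' @return A list of `kinstab_comparison_row`, in table order.
#' @export
build_comparison_table <- function(protein = c("both", "MAPK1", "MAPK3"),
                                   kinetics_table = mapk_kinetics_table(),
                                   tm_table = mapk_tm_table()) {
  protein <- match.arg(protein)
  prots <- if (protein == "both") c("MAPK1", "MAPK3") else protein
  rows <- list()
  for (p in prots) {
    wt <- record_from_tables(p, "WT", kinetics_table, tm_table)
    vars <- unique(kinetics_table$variant[kinetics_table$protein == p])
    vars <- setdiff(vars, "WT")
    for (v in vars) {
      vr <- record_from_tables(p, v, kinetics_table, tm_table)
      rows[[paste(p, v, sep = ".")]] <- compare_to_wildtype(vr, wt)
    }
  }
  rows
}

format_ratio <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (abs(v) < 1e-2) format(signif(v, 3), scientific = TRUE)
    else format(signif(v, 3))
  }, character(1))
}

#' Render the comparison ledger
#'
#' Deterministic tabular output of comparison rows, in input order.
#' Temperature deltas are printed to 0.1 degrees C, energy deltas to 0.01
#' kcal/mol, and efficiency ratios to 3 significant figures (scientific
#' notation below 1e-2).
#'
#' @param rows A nonempty list of `kinstab_comparison_row`.
#' @param format `"data.frame"` (default), `"csv"` (character vector of CSV
#'   lines) or `"text"` (fixed-width lines).
#'
#' @return Depends on `format`; see above.
#' @export
render_report <- function(rows, format = c("data.frame", "csv", "text")) {
  format <- match.arg(format)
  if (inherits(rows, "kinstab_comparison_row")) rows <- list(rows)
  if (length(rows) == 0L) ks_stop("no rows to report", "empty_report")
  if (!all(vapply(rows, inherits, logical(1), "kinstab_comparison_row"))) {
    ks_stop("rows must be kinstab_comparison_row objects", "invalid_input")
  }
  df <- data.frame(
    protein = vapply(rows, `[[`, character(1), "protein"),
    substitution = vapply(rows, `[[`, character(1), "substitution"),
    group = vapply(rows, function(r) as.character(r$group %||% NA), character(1)),
    delta_tm_NP = sprintf("%.1f", vapply(rows, `[[`, numeric(1), "delta_tm_NP")),
    delta_tm_P = sprintf("%.1f", vapply(rows, `[[`, numeric(1), "delta_tm_P")),
    efficiency_ratio = format_ratio(vapply(rows, `[[`, numeric(1),
                                           "efficiency_ratio")),
    delta_tmax = sprintf("%.1f", vapply(rows, `[[`, numeric(1), "delta_tmax")),
    delta_Ea = sprintf("%.2f", vapply(rows, `[[`, numeric(1), "delta_Ea")),
    stringsAsFactors = FALSE
  )
  switch(format,
    data.frame = df,
    csv = c(paste(names(df), collapse = ","),
            apply(df, 1L, paste, collapse = ",")),
    text = {
      widths <- pmax(nchar(names(df)),
                     apply(nchar(as.matrix(df)), 2L, max))
      fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths),
                                      collapse = "  ")
      c(fmt_row(names(df)), apply(df, 1L, fmt_row))
    }
  )
}

#' @export
print.kinstab_comparison_row <- function(x, ...) {
  cat(sprintf(
    "<comparison_row> %s %s: dTm(NP) %.1f, dTm(P) %.1f, eff ratio %s, dTmax %.1f, dEa %.2f\n",
    x$protein, x$substitution, x$delta_tm_NP, x$delta_tm_P,
    format_ratio(x$efficiency_ratio), x$delta_tmax, x$delta_Ea))
  invisible(x)
}
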