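#' Normalize species intensities to their class internal standard
#'
#' Each lipid species' counts-per-second are divided by the
#' counts-per-second of its class' deuterated internal standard within the
#' same injection, absorbing injection-to-injection differences in
#' extraction efficiency and spray. The result is a dimensionless
#' lipid/standard ratio per injection.
#'
#' @param raw Raw intensity table (`injection_id`, `animal_id`, `group`,
#'   `tissue`, `analyte`, `cps`), e.g. `generate_dataset(...)$raw` or a
#'   table read from TSV.
#' @param panel A [lipid_panel()] mapping species to classes and classes to
#'   standard labels.
#' @return Tibble of per-injection ratios (`injection_id`, `animal_id`,
#'   `group`, `tissue`, `species`, `lipid_class`, `value`).
#' @export
normalize_to_standard <- function(raw, panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  need <- c("injection_id", "animal_id", "group", "tissue", "analyte", "cps")
  if (!all(need %in% names(raw))) {
    abort_input("raw table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(raw$cps < 0)) abort_input("counts per second must be >= 0")

  species_map <- tibble::tibble(
    analyte = panel$species$canonical_label,
    lipid_class = panel$species$lipid_class
  )
  std_map <- tibble::tibble(
    analyte = unname(panel$standards),
    lipid_class = names(panel$standards)
  )

  std <- dplyr::inner_join(raw, std_map, by = "analyte")
  std <- std[, c("injection_id", "lipid_class", "cps")]
  names(std)[names(std) == "cps"] <- "standard_cps"

  sp <- dplyr::inner_join(raw, species_map, by = "analyte")
  if (nrow(sp) == 0) abort_input("raw table contains no panel species")

  out <- dplyr::left_join(sp, std, by = c("injection_id", "lipid_class"))
  miss <- which(is.na(out$standard_cps))
  if (length(miss) > 0) {
    abort_input("injection '", out$injection_id[miss[1]],
                "' is missing the internal standard for class ",
                out$lipid_class[miss[1]])
  }
  zero <- which(out$standard_cps == 0)
  if (length(zero) > 0) {
    abort_input("internal standard for class ", out$lipid_class[zero[1]],
                " has zero counts in injection '", out$injection_id[zero[1]], "'")
  }
  out$value <- out$cps / out$standard_cps
  out$species <- out$analyte
  tibble::as_tibble(out[, c("injection_id", "animal_id", "group", "tissue",
                            "species", "lipid_class", "value")])
}

#' Average technical duplicates into per-animal values
#'
#' After standard normalization, the lipid/standard ratios of an animal's
#' technical injections are collapsed by their arithmetic mean, yielding
#' one value per animal and species. Idempotent: applying it to an
#' already collapsed table is the identity.
#'
#' @param ratios Per-injection ratio table from [normalize_to_standard()]
#'   (an `injection_id` column is optional for already collapsed input).
#' @return Normalized table with one row per animal and species
#'   (`animal_id`, `group`, `tissue`, `species`, `lipid_class`, `value`).
#' @export
average_duplicates <- function(ratios) {
  need <- c("animal_id", "group", "tissue", "species", "lipid_class", "value")
  if (!all(need %in% names(ratios))) {
    abort_input("ratio table must have columns: ", paste(need, collapse = ", "))
  }
  out <- dplyr::summarise(
    dplyr::group_by(ratios, .data$animal_id, .data$group, .data$tissue,
                    .data$species, .data$lipid_class),
    value = mean(.data$value), .groups = "drop"
  )
  dplyr::arrange(out, .data$animal_id, .data$species)
}

#' Matrix-effect QC from internal-standard signals
#'
#' Co-extracted sample components can suppress or enhance a standard's
#' signal differently in the two groups (a matrix effect). The QC metric is,
#' per lipid class, the absolute percent change of the mean standard signal
#' between treated and control injections; the report carries the per-class
#' values plus their maximum and mean.
#'
#' @inheritParams normalize_to_standard
#' @return A list of class `matrix_effect_report` with elements `per_class`
#'   (tibble `lipid_class`, `percent_change`), `max_percent`, `mean_percent`.
#' @export
matrix_effect_qc <- function(raw, panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  if (!all(c("control", "treated") %in% raw$group)) {
    abort_input("matrix-effect QC needs both groups present, got: ",
                paste(unique(raw$group), collapse = ", "))
  }
  std_map <- tibble::tibble(
    analyte = unname(panel$standards),
    lipid_class = names(panel$standards)
  )
  std <- dplyr::inner_join(raw, std_map, by = "analyte")
  if (nrow(std) == 0) abort_input("raw table contains no internal standards")
  by_class <- dplyr::summarise(
    dplyr::group_by(std, .data$lipid_class),
    percent_change = abs(
      mean(.data$cps[.data$group == "treated"]) /
        mean(.data$cps[.data$group == "control"]) - 1
    ) * 100,
    .groups = "drop"
  )
  structure(
    list(per_class = by_class,
         max_percent = max(by_class$percent_change),
         mean_percent = mean(by_class$percent_change)),
    class = "matrix_effect_report"
  )
}

#' @export
print.matrix_effect_report <- function(x, ...) {
  cat(sprintf("<matrix_effect_report> max %.2f%%, mean %.2f%% across %d classes\n",
              x$max_percent, x$mean_percent, nrow(x$per_class)))
  invisible(x)
}

#' Re-express species as fractions of their lipid-class total ("/tot")
#'
#' Divides each species value by the per-animal sum over all panel species
#' of its class, so the fractions of one animal and class sum to exactly 1.
#' This reveals shifts in the distribution of species within a class
#' independently of any change of the class total.
#'
#' @param norm Per-animal normalized table from [average_duplicates()].
#' @param panel A [lipid_panel()] (defines class membership for the totals).
#' @return Table of the same shape with `value` replaced by the class
#'   fraction.
#' @export
class_fraction_normalize <- function(norm, panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  keep <- norm$species %in% panel$species$canonical_label
  out <- dplyr::group_by(norm[keep, ], .data$animal_id, .data$tissue,
                         .data$lipid_class)
  out <- dplyr::mutate(out, .class_total = sum(.data$value))
  out <- dplyr::ungroup(out)
  zero <- which(out$.class_total == 0)
  if (length(zero) > 0) {
    abort_input("class total is zero for animal '", out$animal_id[zero[1]],
                "', class ", out$lipid_class[zero[1]],
                "; fractions are undefined")
  }
  out$value <- out$value / out$.class_total
  out$.class_total <- NULL
  out
}
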