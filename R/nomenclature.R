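#' Lipid classes recognized by the shorthand parser
#'
#' The panel covers the six MRM lipid classes of the workflow (diacyl- and
#' ether/plasmalogen phosphatidylcholine, lyso-phosphatidylcholine,
#' sphingomyelin, triacylglyceride, acyl-/acetyl-carnitine) plus total and
#' free cholesterol, which are measured as two standalone analytes outside
#' acyl nomenclature.
#'
#' @return Character vector of class identifiers.
#' @export
lipid_classes <- function() {
  c("PC_AA", "PC_AE", "LYSO_PC", "SM", "TAG", "CARNITINE",
    "CHOLESTEROL_TOTAL", "CHOLESTEROL_FREE")
}

abort_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# One regex per label dialect; groups = (carbons, double bonds[, OH]).
.species_patterns <- list(
  PC_AA   = "^PC ?aa C0*([0-9]+):0*([0-9]+)$",
  PC_AE   = "^PC ?ae C0*([0-9]+):0*([0-9]+)$",
  LYSO_PC = "^[Ll]yso[- ]?PC C0*([0-9]+):0*([0-9]+)$",
  SM      = "^SM C0*([0-9]+):0*([0-9]+)$",
  TAG     = "^TAG ?0*([0-9]+):0*([0-9]+)$",
  CARNITINE = "^C0*([0-9]+)(?::0*([0-9]+))?( OH)?$"
)

#' Parse lipid shorthand labels
#'
#' Accepts the shorthand dialect used throughout the workflow:
#' `"PC aa C36:4"`, `"PC ae C40:0"`, `"lyso-PC C22:6"`, `"SM C24:0"`,
#' `"TAG 48:0"` (no `C` prefix, as printed for triacylglycerides), carnitines
#' `"C0"` (free carnitine), `"C2"` (acetylcarnitine), `"C10"`, `"C3 OH"`
#' (hydroxylated), and `"Cholesterol total"` / `"Cholesterol free"`. Leading
#' zeros (e.g. `"C03 OH"`) are accepted and normalized away in the canonical
#' label.
#'
#' @param labels Character vector of species labels.
#' @return A tibble with one row per label: `raw_label`, `canonical_label`,
#'   `lipid_class`, `carbons` (total acyl-chain carbons; 0 for free
#'   carnitine and for cholesterol), `double_bonds`, `hydroxylated`.
#' @examples
#' parse_species(c("PC aa C36:4", "C03 OH", "TAG 48:0"))
#' @export
parse_species <- function(labels) {
  if (!is.character(labels) || length(labels) == 0) {
    abort_input("'labels' must be a non-empty character vector")
  }
  if (anyNA(labels) || any(!nzchar(trimws(labels)))) {
    abort_input("species labels must be non-empty strings")
  }
  labels <- trimws(labels)
  n <- length(labels)
  cls <- rep(NA_character_, n)
  carbons <- integer(n)
  db <- integer(n)
  oh <- logical(n)

  chol <- stringr::str_match(labels, "^Cholesterol \\(?(total|free)\\)?$")
  hit <- !is.na(chol[, 1])
  cls[hit] <- ifelse(chol[hit, 2] == "total", "CHOLESTEROL_TOTAL", "CHOLESTEROL_FREE")

  for (k in names(.species_patterns)) {
    todo <- is.na(cls)
    if (!any(todo)) break
    m <- stringr::str_match(labels[todo], .species_patterns[[k]])
    got <- !is.na(m[, 1])
    idx <- which(todo)[got]
    cls[idx] <- k
    carbons[idx] <- as.integer(m[got, 2])
    db[idx] <- ifelse(is.na(m[got, 3]), 0L, suppressWarnings(as.integer(m[got, 3])))
    db[idx][is.na(db[idx])] <- 0L
    if (k == "CARNITINE") oh[idx] <- !is.na(m[got, 4])
  }

  bad <- which(is.na(cls))
  if (length(bad) > 0) {
    abort_input("unparseable lipid label: '", labels[bad[1]], "'")
  }
  impossible <- which(db > carbons)
  if (length(impossible) > 0) {
    abort_input("invalid lipid label '", labels[impossible[1]],
                "': double bonds (", db[impossible[1]],
                ") exceed acyl carbons (", carbons[impossible[1]], ")")
  }
  tibble::tibble(
    raw_label = labels,
    canonical_label = format_species(cls, carbons, db, oh),
    lipid_class = cls,
    carbons = carbons,
    double_bonds = db,
    hydroxylated = oh
  )
}

#' Format a species back into its canonical shorthand label
#'
#' Inverse of [parse_species()]: `format_species` applied to parsed fields
#' reproduces the canonical label, so parse-then-format is the identity on
#' canonical labels.
#'
#' @param lipid_class,carbons,double_bonds,hydroxylated Parallel vectors of
#'   species fields (as returned by [parse_species()]).
#' @return Character vector of canonical labels.
#' @export
format_species <- function(lipid_class, carbons, double_bonds, hydroxylated = FALSE) {
  n <- max(length(lipid_class), length(carbons),
           length(double_bonds), length(hydroxylated))
  lipid_class <- rep_len(lipid_class, n)
  carbons <- rep_len(carbons, n)
  double_bonds <- rep_len(double_bonds, n)
  hydroxylated <- rep_len(hydroxylated, n)
  out <- character(n)
  cd <- paste0(carbons, ":", double_bonds)
  out[lipid_class == "PC_AA"] <- paste0("PC aa C", cd[lipid_class == "PC_AA"])
  out[lipid_class == "PC_AE"] <- paste0("PC ae C", cd[lipid_class == "PC_AE"])
  out[lipid_class == "LYSO_PC"] <- paste0("lyso-PC C", cd[lipid_class == "LYSO_PC"])
  out[lipid_class == "SM"] <- paste0("SM C", cd[lipid_class == "SM"])
  out[lipid_class == "TAG"] <- paste0("TAG ", cd[lipid_class == "TAG"])
  carn <- lipid_class == "CARNITINE"
  out[carn] <- paste0(
    "C", carbons[carn],
    ifelse(double_bonds[carn] > 0, paste0(":", double_bonds[carn]), ""),
    ifelse(hydroxylated[carn], " OH", "")
  )
  out[lipid_class == "CHOLESTEROL_TOTAL"] <- "Cholesterol total"
  out[lipid_class == "CHOLESTEROL_FREE"] <- "Cholesterol free"
  if (any(!nzchar(out))) abort_input("unknown lipid class in format_species()")
  out
}

#' Expand species-range notation into individual species
#'
#' Figure-legend style ranges come in three shapes: a double-bond range
#' `"C36:0-5"` (carbons fixed, double bonds stepped by 1), a carbon range
#' `"C30-42:2"` (double bonds fixed, carbons stepped by `carbon_step`,
#' default 2 — total acyl carbons of di-/tri-acyl lipids are enumerated in
#' even steps), or a single species `"C44:0"`.
#'
#' @param range_spec A range string, e.g. `"C36:0-5"`.
#' @param lipid_class Class identifier the expanded species belong to.
#' @param carbon_step Step for carbon ranges (default 2).
#' @return Tibble of species as from [parse_species()].
#' @examples
#' expand_range("C36:0-5", "PC_AE")
#' @export
expand_range <- function(range_spec, lipid_class, carbon_step = 2) {
  stopifnot(is.character(range_spec), length(range_spec) == 1)
  lipid_class <- match.arg(lipid_class, lipid_classes())
  spec <- trimws(range_spec)

  m <- stringr::str_match(spec, "^C([0-9]+):([0-9]+)-([0-9]+)$")
  if (!is.na(m[1, 1])) {
    lo <- as.integer(m[1, 3]); hi <- as.integer(m[1, 4])
    if (lo > hi) abort_input("empty range '", spec, "': ", lo, " > ", hi)
    return(parse_species(format_species(lipid_class, as.integer(m[1, 2]), lo:hi)))
  }
  m <- stringr::str_match(spec, "^C([0-9]+)-([0-9]+):([0-9]+)$")
  if (!is.na(m[1, 1])) {
    lo <- as.integer(m[1, 2]); hi <- as.integer(m[1, 3])
    if (lo > hi) abort_input("empty range '", spec, "': ", lo, " > ", hi)
    return(parse_species(format_species(
      lipid_class, seq(lo, hi, by = carbon_step), as.integer(m[1, 4])
    )))
  }
  m <- stringr::str_match(spec, "^C([0-9]+):([0-9]+)$")
  if (!is.na(m[1, 1])) {
    return(parse_species(format_species(
      lipid_class, as.integer(m[1, 2]), as.integer(m[1, 3])
    )))
  }
  abort_input("unparseable range specification: '", spec, "'")
}

#' Expand a list of range specifications and check for duplicates
#'
#' @param range_specs Character vector of range strings.
#' @inheritParams expand_range
#' @return Tibble of distinct species; errors if two ranges overlap.
#' @export
expand_ranges <- function(range_specs, lipid_class, carbon_step = 2) {
  out <- dplyr::bind_rows(lapply(range_specs, expand_range,
                                 lipid_class = lipid_class,
                                 carbon_step = carbon_step))
  dup <- duplicated(out$canonical_label)
  if (any(dup)) {
    abort_input("ranges overlap: species '", out$canonical_label[which(dup)[1]],
                "' produced more than once")
  }
  out
}

# PC ae chain-length legend ranges; their union is the full 39-species roster.
.pc_ae_chain_ranges <- c("C30:0-2", "C32:1-2", "C34:0-3", "C36:0-5",
                         "C38:0-6", "C40:0-6", "C42:0-5", "C44:3-6")
# PC aa chain-length legend ranges (40 species; the panel adds 3 more).
.pc_aa_chain_ranges <- c("C30:0-2", "C32:0-3", "C34:1-4", "C36:0-6",
                         "C38:0-6", "C40:0-6", "C42:0-6", "C44:0")

.default_rosters <- function() {
  list(
    PC_AA = c(expand_ranges(.pc_aa_chain_ranges, "PC_AA")$canonical_label,
              "PC aa C26:0", "PC aa C28:0", "PC aa C28:1"),
    PC_AE = expand_ranges(.pc_ae_chain_ranges, "PC_AE")$canonical_label,
    LYSO_PC = paste0("lyso-PC C", c(
      "6:0", "8:0", "12:0", "14:0", "15:0", "16:0", "16:1", "17:0", "18:0",
      "18:1", "18:2", "18:3", "20:0", "20:3", "20:4", "22:5", "22:6",
      "24:0", "26:0", "26:1", "28:0", "28:1")),
    SM = paste0("SM C", c(
      "14:0", "16:0", "16:1", "18:0", "18:1", "18:2", "20:0", "20:1",
      "20:2", "22:0", "22:1", "24:0", "24:1", "26:0", "26:1")),
    TAG = paste0("TAG ", c(
      "44:0", "46:0", "46:1", "48:0", "48:1", "48:2", "50:0", "50:1",
      "50:2", "50:3", "52:1", "52:2", "52:3", "54:2", "54:3", "54:4",
      "56:3")),
    CARNITINE = c(
      "C0", "C2", "C3", "C3 OH", "C3:1", "C4", "C4 OH", "C4:1",
      "C5", "C5 OH", "C5:1", "C6", "C6 OH", "C6:1", "C7", "C8", "C8:1",
      "C9", "C10", "C10:1", "C10:2", "C11", "C12", "C12:1", "C12 OH",
      "C12:1 OH", "C13", "C14", "C14:1", "C14:2", "C14 OH", "C16",
      "C16:1", "C16:2", "C16 OH", "C16:1 OH", "C18", "C18:1", "C18:2",
      "C18 OH", "C18:1 OH"),
    CHOLESTEROL_TOTAL = "Cholesterol total",
    CHOLESTEROL_FREE = "Cholesterol free"
  )
}

# Class sizes of the measured panel; custom rosters must keep them.
.declared_sizes <- c(PC_AA = 43L, PC_AE = 39L, LYSO_PC = 22L, SM = 15L,
                     TAG = 17L, CARNITINE = 41L,
                     CHOLESTEROL_TOTAL = 1L, CHOLESTEROL_FREE = 1L)

.default_standards <- c(
  PC_AA = "06:0 PC (DHPC)",
  PC_AE = "PC ae standard (Splash Lipidomix)",
  LYSO_PC = "19:0 Lyso PC",
  SM = "06:0 SM (d18:1/6:0)",
  TAG = "TAG standard (Splash Lipidomix)",
  CARNITINE = "octanoyl-L-carnitine d3",
  CHOLESTEROL_TOTAL = "cholesterol-d7 (total)",
  CHOLESTEROL_FREE = "cholesterol-d7 (free)"
)

#' Construct an analyte panel
#'
#' A panel couples a species roster with one internal-standard label per
#' lipid class; analyte intensities are only interpretable as
#' analyte/standard ratios, so every class present among the species must
#' name exactly one standard.
#'
#' @param species Character vector of species labels (any accepted dialect)
#'   or a tibble from [parse_species()].
#' @param standards Named character vector, `lipid_class -> standard label`.
#' @return An object of class `lipid_panel`: a list with elements `species`
#'   (parsed tibble) and `standards`.
#' @export
lipid_panel <- function(species, standards) {
  if (is.character(species)) species <- parse_species(species)
  stopifnot(is.data.frame(species))
  dup <- duplicated(species$canonical_label)
  if (any(dup)) {
    abort_input("duplicate species label in panel: '",
                species$canonical_label[which(dup)[1]], "'")
  }
  if (is.null(names(standards)) || any(!nzchar(names(standards)))) {
    abort_input("'standards' must be a named vector (lipid_class -> label)")
  }
  missing_std <- setdiff(unique(species$lipid_class), names(standards))
  if (length(missing_std) > 0) {
    abort_input("no internal standard declared for class ", missing_std[1])
  }
  if (anyDuplicated(standards[unique(species$lipid_class)])) {
    abort_input("internal standard labels must be distinct across classes")
  }
  structure(
    list(species = species, standards = standards[unique(species$lipid_class)]),
    class = "lipid_panel"
  )
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat("<lipid_panel>", nrow(x$species), "species in",
      length(unique(x$species$lipid_class)), "classes\n")
  counts <- table(x$species$lipid_class)
  for (cl in names(counts)) {
    cat(sprintf("  %-18s %3d species, standard: %s\n",
                cl, counts[[cl]], x$standards[[cl]]))
  }
  invisible(x)
}

#' Build the default measurement panel
#'
#' The default panel mirrors the class sizes of the measured analyte set:
#' 43 PC aa, 39 PC ae (the exact chain-length-legend expansion), 22
#' lyso-PC, 15 SM, 17 TAG and 41 carnitine species, plus total and free
#' cholesterol as standalone analytes. Only the PC ae roster (and 40 of the
#' 43 PC aa species) is fully enumerated by the source legends; the
#' remaining rosters are synthetic stand-ins of the declared sizes that
#' include every species label reported individually.
#'
#' @param rosters Optional named list replacing the roster of one or more
#'   classes; a replacement must keep the declared class size.
#' @param standards Optional named character vector overriding default
#'   internal-standard labels.
#' @return A [lipid_panel()].
#' @examples
#' panel <- build_default_panel()
#' table(panel$species$lipid_class)
#' @export
build_default_panel <- function(rosters = NULL, standards = NULL) {
  base <- .default_rosters()
  if (!is.null(rosters)) {
    unknown <- setdiff(names(rosters), names(base))
    if (length(unknown) > 0) abort_input("unknown lipid class in rosters: ", unknown[1])
    for (cl in names(rosters)) {
      if (length(rosters[[cl]]) != .declared_sizes[[cl]]) {
        abort_input("roster for ", cl, " has ", length(rosters[[cl]]),
                    " species but the declared panel size is ",
                    .declared_sizes[[cl]])
      }
      base[[cl]] <- rosters[[cl]]
    }
  }
  std <- .default_standards
  if (!is.null(standards)) std[names(standards)] <- standards
  lipid_panel(unlist(base, use.names = FALSE), std)
}

#' Read / write a panel as TSV
#'
#' The on-disk format has one row per species with columns `label`, `class`
#' and `standard_label` (the standard of the species' class, repeated).
#'
#' @param path File path.
#' @return `read_panel` returns a [lipid_panel()]; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort_input("panel file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "class", "standard_label")
  if (!all(need %in% names(tab))) {
    abort_input("panel file must have columns: ", paste(need, collapse = ", "))
  }
  parsed <- parse_species(tab$label)
  mism <- which(parsed$lipid_class != tab$class)
  if (length(mism) > 0) {
    abort_input("panel file class '", tab$class[mism[1]], "' does not match label '",
                tab$label[mism[1]], "' (parsed as ", parsed$lipid_class[mism[1]], ")")
  }
  std <- tapply(tab$standard_label, tab$class, function(x) unique(x))
  if (any(lengths(std) != 1)) {
    abort_input("class ", names(std)[lengths(std) != 1][1],
                " declares more than one standard")
  }
  lipid_panel(parsed, vapply(std, identity, character(1)))
}

#' @rdname read_panel
#' @param panel A [lipid_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "lipid_panel"))
  tab <- data.frame(
    label = panel$species$canonical_label,
    class = panel$species$lipid_class,
    standard_label = unname(panel$standards[panel$species$lipid_class])
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
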