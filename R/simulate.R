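#' Configure a synthetic MRM experiment
#'
#' The generator emulates a two-group targeted shotgun-lipidomics design:
#' `n_per_group` animals per group, each injected `n_tech_reps` times, with
#' every injection measuring every panel species and every class internal
#' standard. Intensities are multiplicative: a per-species lognormal
#' baseline, a per-animal lognormal biological factor (`noise_cv`), the
#' group fold change for spiked species, and a per-injection lognormal
#' technical factor (`tech_cv`). Standards carry technical noise only, plus
#' an optional group-dependent matrix drift (a relative shift of the
#' standard signal in treated samples) so the matrix-effect QC has a known
#' truth to recover. All lognormal factors have mean 1, so group ratios are
#' centred on the true fold change.
#'
#' @param panel A [lipid_panel()]; defaults to [build_default_panel()].
#' @param n_per_group Animals per group (default 6).
#' @param n_tech_reps Technical injections per animal (default 2).
#' @param baseline_log_mean,baseline_log_sd Log-scale location/spread of
#'   species baseline intensities, in log counts-per-second.
#' @param noise_cv Biological coefficient of variation across animals.
#' @param tech_cv Technical coefficient of variation across injections.
#' @param standard_intensity Internal-standard signal, counts per second.
#' @param matrix_drift Relative shift of standard signal in the treated
#'   group (0.013 = 1.3%).
#' @param effects Named numeric vector or list, species label -> true fold
#'   change (treated/control). Unnamed species have fold change 1.
#' @param tissue Tissue label attached to every row (label only; tissues
#'   are independent simulations).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(panel = build_default_panel(),
                              n_per_group = 6L,
                              n_tech_reps = 2L,
                              baseline_log_mean = log(2000),
                              baseline_log_sd = 1,
                              noise_cv = 0.10,
                              tech_cv = 0.04,
                              standard_intensity = 5000,
                              matrix_drift = 0.013,
                              effects = NULL,
                              tissue = "brain",
                              seed = 1L) {
  stopifnot(inherits(panel, "lipid_panel"))
  if (n_per_group < 2) abort_input("n_per_group must be >= 2")
  if (n_tech_reps < 1) abort_input("n_tech_reps must be >= 1")
  if (noise_cv < 0 || tech_cv < 0) abort_input("coefficients of variation must be >= 0")
  if (standard_intensity <= 0) abort_input("standard_intensity must be > 0")
  if (matrix_drift < 0) abort_input("matrix_drift must be >= 0")
  effects <- unlist(effects)
  if (length(effects) > 0) {
    if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
      abort_input("'effects' must be named by species label")
    }
    unknown <- setdiff(names(effects), panel$species$canonical_label)
    if (length(unknown) > 0) {
      abort_input("effect declared for unknown species: '", unknown[1], "'")
    }
    if (any(effects <= 0)) abort_input("fold changes must be > 0")
  }
  structure(
    list(panel = panel, n_per_group = as.integer(n_per_group),
         n_tech_reps = as.integer(n_tech_reps),
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         noise_cv = noise_cv, tech_cv = tech_cv,
         standard_intensity = standard_intensity,
         matrix_drift = matrix_drift,
         effects = effects, tissue = tissue, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# lognormal multiplicative factors with mean 1 and coefficient of variation cv
.lnorm_factor <- function(n, cv) {
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic raw MRM intensity table with known ground truth
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset` with elements:
#'   \describe{
#'     \item{raw}{Tibble of rows (`injection_id`, `animal_id`, `group`,
#'       `tissue`, `analyte`, `cps`): every injection contains every panel
#'       species and every class standard exactly once.}
#'     \item{truth}{Ground truth: the effects map, noise and drift
#'       parameters, and the seed.}
#'   }
#' @examples
#' ds <- generate_dataset(simulation_config(seed = 7))
#' head(ds$raw)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- config$panel
  species <- panel$species$canonical_label
  classes <- unique(panel$species$lipid_class)
  set.seed(config$seed)

  fc <- stats::setNames(rep(1, length(species)), species)
  if (length(config$effects) > 0) fc[names(config$effects)] <- config$effects

  baseline <- stats::setNames(
    exp(stats::rnorm(length(species), config$baseline_log_mean, config$baseline_log_sd)),
    species
  )

  animals <- tibble::tibble(
    animal_id = c(sprintf("ctrl_%02d", seq_len(config$n_per_group)),
                  sprintf("trt_%02d", seq_len(config$n_per_group))),
    group = rep(c("control", "treated"), each = config$n_per_group)
  )

  bio <- tidyr::expand_grid(animal_id = animals$animal_id, analyte = species)
  bio$bio_factor <- .lnorm_factor(nrow(bio), config$noise_cv)

  injections <- tidyr::expand_grid(animals, rep = seq_len(config$n_tech_reps))
  injections$injection_id <- sprintf("%s_inj%d", injections$animal_id, injections$rep)

  sp_rows <- tidyr::expand_grid(
    injections[, c("injection_id", "animal_id", "group")],
    analyte = species
  )
  sp_rows <- dplyr::left_join(sp_rows, bio, by = c("animal_id", "analyte"))
  sp_rows$cps <- unname(
    baseline[sp_rows$analyte] * sp_rows$bio_factor *
      ifelse(sp_rows$group == "treated", fc[sp_rows$analyte], 1) *
      .lnorm_factor(nrow(sp_rows), config$tech_cv)
  )
  sp_rows$bio_factor <- NULL

  std_rows <- tidyr::expand_grid(
    injections[, c("injection_id", "animal_id", "group")],
    analyte = unname(panel$standards[classes])
  )
  std_rows$cps <- config$standard_intensity *
    .lnorm_factor(nrow(std_rows), config$tech_cv) *
    ifelse(std_rows$group == "treated", 1 + config$matrix_drift, 1)

  raw <- dplyr::bind_rows(sp_rows, std_rows)
  raw$tissue <- config$tissue
  raw <- dplyr::arrange(
    raw[, c("injection_id", "animal_id", "group", "tissue", "analyte", "cps")],
    .data$injection_id, .data$analyte
  )

  truth <- list(
    effects = as.list(fc[fc != 1]),
    noise_cv = config$noise_cv,
    tech_cv = config$tech_cv,
    matrix_drift = config$matrix_drift,
    standard_intensity = config$standard_intensity,
    n_per_group = config$n_per_group,
    n_tech_reps = config$n_tech_reps,
    tissue = config$tissue,
    seed = config$seed
  )
  structure(list(raw = raw, truth = truth), class = "synthetic_dataset")
}

#' Write / read a synthetic dataset fixture
#'
#' Writes `raw_intensities.tsv` (the intensity table) and `truth.json` (the
#' ground-truth sidecar) into `dir`; `read_fixture` reverses the operation.
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `write_fixture` returns the two file paths invisibly;
#'   `read_fixture` returns a `synthetic_dataset`.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort_input("cannot create output directory: ", dir)
  raw_path <- file.path(dir, "raw_intensities.tsv")
  truth_path <- file.path(dir, "truth.json")
  tab <- as.data.frame(dataset$raw)
  tab$cps <- sprintf("%.15g", tab$cps)
  utils::write.table(tab, raw_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, truth_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(raw = raw_path, truth = truth_path))
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  raw_path <- file.path(dir, "raw_intensities.tsv")
  truth_path <- file.path(dir, "truth.json")
  if (!file.exists(raw_path)) abort_input("fixture file not found: ", raw_path)
  raw <- tibble::as_tibble(
    utils::read.delim(raw_path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c(cps = "numeric"))
  )
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  structure(list(raw = raw, truth = truth), class = "synthetic_dataset")
}
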