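#' Human-equivalent dose by body-surface-area scaling
#'
#' Converts an animal dose to its human-equivalent dose (HED) with the
#' standard body-surface-area correction factors (Km): HED = animal dose x
#' Km(animal) / Km(human). The defaults are the conventional mouse (3) and
#' human (37) factors, under which a 10 mg/kg mouse dose corresponds to
#' 0.81 mg/kg in humans.
#'
#' @param animal_dose Dose in mg/kg body weight.
#' @param animal_km,human_km Body-surface-area Km factors (> 0).
#' @return List with `hed` (unrounded, mg/kg) and `hed_rounded` (2 dp).
#' @examples
#' human_equivalent_dose(10)    # mouse -> human: 0.81 mg/kg
#' @export
human_equivalent_dose <- function(animal_dose, animal_km = 3, human_km = 37) {
  if (!is.numeric(animal_dose) || length(animal_dose) != 1 || animal_dose <= 0) {
    abort_input("animal_dose must be a single positive number (mg/kg)")
  }
  if (animal_km <= 0 || human_km <= 0) {
    abort_input("Km factors must be > 0")
  }
  hed <- animal_dose * animal_km / human_km
  list(hed = hed, hed_rounded = round(hed, 2))
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Standard qPCR relative quantification: per sample, dCt = Ct(target) -
#' Ct(reference); ddCt = dCt - mean dCt of the control group; relative
#' expression = 2^(-ddCt). The control-group mean relative expression is
#' 100% by construction; the treated group is reported as percent of
#' control with a two-sample Student t-test on per-sample relative
#' expressions. Invariant to adding a constant to all Cts of a sample
#' (plate shifts cancel in dCt).
#'
#' @param ct_table Long table with columns `sample`, `group`, `gene`, `ct`.
#' @param target_gene Gene of interest.
#' @param reference_gene Housekeeping gene (e.g. `"Gapdh"`).
#' @param control_group Group label defining the baseline (default
#'   `"control"`).
#' @return List of class `qpcr_result`: `gene`, `per_sample` tibble
#'   (`sample`, `group`, `dct`, `ddct`, `rel_expr`), `percent_of_control`,
#'   `p`.
#' @export
ddct_relative_expression <- function(ct_table, target_gene,
                                     reference_gene = "Gapdh",
                                     control_group = "control") {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ct_table))) {
    abort_input("ct_table must have columns: ", paste(need, collapse = ", "))
  }
  tgt <- ct_table[ct_table$gene == target_gene, ]
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (nrow(tgt) == 0) abort_input("no Ct values for target gene '", target_gene, "'")
  samples <- unique(ct_table$sample)
  for (s in samples) {
    if (!s %in% tgt$sample) abort_input("sample '", s, "' is missing a ", target_gene, " Ct")
    if (!s %in% ref$sample) abort_input("sample '", s, "' is missing a ", reference_gene, " Ct")
  }
  per <- dplyr::inner_join(
    tgt[, c("sample", "group", "ct")],
    ref[, c("sample", "ct")],
    by = "sample", suffix = c("_target", "_reference")
  )
  per$dct <- per$ct_target - per$ct_reference
  ctrl_dct <- per$dct[per$group == control_group]
  if (length(ctrl_dct) == 0) {
    abort_input("no samples in control group '", control_group, "'")
  }
  per$ddct <- per$dct - mean(ctrl_dct)
  per$rel_expr <- 2^(-per$ddct)

  ctrl <- per$rel_expr[per$group == control_group]
  trt <- per$rel_expr[per$group != control_group]
  pct <- if (length(trt) > 0) 100 * (mean(trt) / mean(ctrl)) else NA_real_
  p <- if (length(trt) > 0) two_sample_t_p(trt, ctrl) else NA_real_
  structure(
    list(
      gene = target_gene,
      per_sample = tibble::as_tibble(
        per[, c("sample", "group", "dct", "ddct", "rel_expr")]
      ),
      percent_of_control = pct,
      p = p
    ),
    class = "qpcr_result"
  )
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("<qpcr_result> %s: %.1f%% of control (p = %.3g, n = %d)\n",
              x$gene, x$percent_of_control, x$p, nrow(x$per_sample)))
  invisible(x)
}
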