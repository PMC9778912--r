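#' Default saturation and chain-length profile bins
#'
#' The phosphatidylcholine profile bins, as data rather than code: for each
#' of PC aa and PC ae, a `saturation` axis (one bin per double-bond count,
#' each a carbon range at fixed saturation) and a `chain_length` axis (one
#' bin per total carbon count, each a double-bond range at fixed length).
#' The PC ae chain-length bins enumerate the complete 39-species roster.
#'
#' @return Nested named list: `class -> axis -> bin_label -> range specs`
#'   (strings accepted by [expand_range()]).
#' @export
default_profile_bins <- function() {
  list(
    PC_AA = list(
      saturation = list(
        ":0" = "C20-48:0", ":1" = "C28-42:1", ":2" = "C30-42:2",
        ":3" = "C32-40:3", ":4" = "C34-42:4", ":5" = "C36-42:5",
        ":6" = "C36-42:6"
      ),
      chain_length = list(
        "30:X" = "C30:0-2", "32:X" = "C32:0-3", "34:X" = "C34:1-4",
        "36:X" = "C36:0-6", "38:X" = "C38:0-6", "40:X" = "C40:0-6",
        "42:X" = "C42:0-6", "44:X" = "C44:0"
      )
    ),
    PC_AE = list(
      saturation = list(
        ":0" = "C30-42:0", ":1" = "C30-42:1", ":2" = "C30-42:2",
        ":3" = "C34-44:3", ":4" = "C36-44:4", ":5" = "C36-44:5",
        ":6" = "C38-44:6"
      ),
      chain_length = list(
        "30:X" = "C30:0-2", "32:X" = "C32:1-2", "34:X" = "C34:0-3",
        "36:X" = "C36:0-5", "38:X" = "C38:0-6", "40:X" = "C40:0-6",
        "42:X" = "C42:0-5", "44:X" = "C44:3-6"
      )
    )
  )
}

#' Read profile bins from a JSON config
#'
#' @param path JSON file with the structure of [default_profile_bins()].
#' @return Nested bin list.
#' @export
read_profile_bins <- function(path) {
  if (!file.exists(path)) abort_input("bins file not found: ", path)
  bins <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(bins, function(cl) lapply(cl, function(ax) lapply(ax, unlist)))
}

# expand a bin's range specs into canonical labels, with disjointness check
.expand_bins <- function(bins, lipid_class) {
  members <- lapply(bins, function(specs) {
    expand_ranges(unlist(specs), lipid_class)$canonical_label
  })
  all_members <- unlist(members, use.names = FALSE)
  dup <- all_members[duplicated(all_members)]
  if (length(dup) > 0) {
    abort_input("species '", dup[1], "' is claimed by two bins of one axis")
  }
  members
}

#' Aggregate species effects into a saturation or chain-length profile
#'
#' Each bin's member-species values are summed per animal (so the bin
#' behaves like a sub-class total), then the treated mean is expressed as a
#' percent of the control mean with a one-sample t-test against 100%, as in
#' [class_summary()]. Members are matched against the species present in
#' `norm`; bins with no present member are dropped with a warning.
#' `method = "mean_fc"` instead averages the member species' fold changes.
#'
#' @param norm Per-animal normalized table.
#' @param panel A [lipid_panel()].
#' @param lipid_class Class to profile (`"PC_AA"` or `"PC_AE"` with default
#'   bins; any class with custom bins).
#' @param axis `"saturation"` or `"chain_length"`.
#' @param bins Named list `bin_label -> range specs`; default = the
#'   [default_profile_bins()] entry for the class and axis.
#' @param method `"sum"` (default, per-animal bin totals) or `"mean_fc"`.
#' @return Tibble with one row per tissue and bin: `axis`, `lipid_class`,
#'   `bin_label`, `n_species`, `percent_of_control`, `p_one_sample`.
#' @export
aggregate_profile <- function(norm, panel, lipid_class,
                              axis = c("saturation", "chain_length"),
                              bins = NULL, method = c("sum", "mean_fc")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  stopifnot(inherits(panel, "lipid_panel"))
  lipid_class <- match.arg(lipid_class, lipid_classes())
  if (is.null(bins)) {
    defaults <- default_profile_bins()
    if (!lipid_class %in% names(defaults)) {
      abort_input("no default bins for class ", lipid_class,
                  "; supply 'bins' explicitly")
    }
    bins <- defaults[[lipid_class]][[axis]]
  }
  members <- .expand_bins(bins, lipid_class)
  present <- unique(norm$species[norm$lipid_class == lipid_class])

  res <- lapply(names(members), function(lbl) {
    mem <- intersect(members[[lbl]], present)
    if (length(mem) == 0) {
      warning("profile bin '", lbl, "' has no member species in the data; omitted",
              call. = FALSE)
      return(NULL)
    }
    sub <- norm[norm$species %in% mem, ]
    if (method == "sum") {
      totals <- dplyr::summarise(
        dplyr::group_by(sub, .data$tissue, .data$animal_id, .data$group),
        total = sum(.data$value), .groups = "drop"
      )
      by_tissue <- lapply(split(totals, totals$tissue), function(tt) {
        ctrl <- tt$total[tt$group == "control"]
        trt <- tt$total[tt$group == "treated"]
        if (mean(ctrl) == 0) abort_input("control total is zero in bin '", lbl, "'")
        tibble::tibble(
          tissue = tt$tissue[1], axis = axis, lipid_class = lipid_class,
          bin_label = lbl, n_species = length(mem),
          percent_of_control = 100 * (mean(trt) / mean(ctrl)),
          p_one_sample = one_sample_t_p(100 * (trt / mean(ctrl)), mu = 100)
        )
      })
      dplyr::bind_rows(by_tissue)
    } else {
      st <- species_stats(sub)
      agg <- dplyr::summarise(
        dplyr::group_by(st, .data$tissue),
        percent_of_control = 100 * mean(.data$fc), .groups = "drop"
      )
      tibble::tibble(
        tissue = agg$tissue, axis = axis, lipid_class = lipid_class,
        bin_label = lbl, n_species = length(mem),
        percent_of_control = agg$percent_of_control,
        p_one_sample = NA_real_
      )
    }
  })
  dplyr::bind_rows(res)
}

#' Saturated-TAG share of the triacylglyceride pool
#'
#' Per animal, the share of fully saturated TAG species (zero double bonds)
#' in the total TAG signal; reported as the treated-group share in percent
#' of the control-group share, with a two-sample Student t-test on the
#' per-animal shares.
#'
#' @param norm Per-animal normalized table containing TAG species.
#' @param panel A [lipid_panel()].
#' @return Tibble with one row per tissue: `percent_of_control`, `p`,
#'   `mean_share_control`, `mean_share_treated`.
#' @export
tag_saturation_share <- function(norm, panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  info <- panel$species[panel$species$lipid_class == "TAG", ]
  if (nrow(info) == 0) abort_input("panel contains no TAG species")
  sub <- norm[norm$species %in% info$canonical_label, ]
  if (nrow(sub) == 0) abort_input("normalized table contains no TAG species")
  sat <- info$canonical_label[info$double_bonds == 0]

  shares <- dplyr::summarise(
    dplyr::group_by(sub, .data$tissue, .data$animal_id, .data$group),
    total = sum(.data$value),
    sat_total = sum(.data$value[.data$species %in% sat]),
    .groups = "drop"
  )
  if (any(shares$total == 0)) {
    abort_input("TAG total is zero for animal '",
                shares$animal_id[which(shares$total == 0)[1]], "'")
  }
  shares$share <- shares$sat_total / shares$total

  dplyr::bind_rows(lapply(split(shares, shares$tissue), function(tt) {
    ctrl <- tt$share[tt$group == "control"]
    trt <- tt$share[tt$group == "treated"]
    p <- two_sample_t_p(trt, ctrl)
    tibble::tibble(
      tissue = tt$tissue[1],
      percent_of_control = 100 * (mean(trt) / mean(ctrl)),
      p = p,
      mean_share_control = mean(ctrl),
      mean_share_treated = mean(trt)
    )
  }))
}
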