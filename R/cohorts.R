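#' Vaginal pH category schemes
#'
#' Two binning schemes for measured vaginal pH: a three-category scheme
#' (4-5, 5-6, >=6) used for *L. iners* protein analyses, and a
#' two-category scheme (4-5, >=5) used for *L. crispatus* analyses, where
#' sample sizes are smaller. Bins are half-open on the left label's upper
#' edge (`"4-5"` means `[4, 5)`, so pH 5.0 falls in `"5-6"`); the top bin
#' is closed at the strip maximum of 9.
#'
#' @param name `"ph3_iners"` or `"ph2_crispatus"`.
#' @return A list with `name`, `boundaries` (lower bin edges) and
#'   `labels`, of class `"ph_scheme"`.
#' @export
ph_scheme <- function(name = c("ph3_iners", "ph2_crispatus")) {
  name <- match.arg(name)
  sch <- if (name == "ph3_iners") {
    list(name = name, boundaries = c(4, 5, 6),
         labels = c("4-5", "5-6", ">=6"))
  } else {
    list(name = name, boundaries = c(4, 5), labels = c("4-5", ">=5"))
  }
  class(sch) <- "ph_scheme"
  sch
}

#' Assign pH readings to categories
#'
#' @param ph Numeric vector of pH values on the 0.5 grid.
#' @param scheme A [ph_scheme()].
#' @return Character vector of category labels (a factor's levels follow
#'   `scheme$labels`). Readings below the lowest boundary are mapped to
#'   the lowest bin with a warning; none occur in the study's observed
#'   range of 4-7.
#' @export
ph_category <- function(ph, scheme = ph_scheme("ph3_iners")) {
  stopifnot(inherits(scheme, "ph_scheme"))
  idx <- findInterval(ph, scheme$boundaries)
  if (any(idx < 1)) {
    warning("pH value(s) below ", scheme$boundaries[1],
            " mapped to the lowest category", call. = FALSE)
    idx[idx < 1] <- 1
  }
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Per-group analysis cohort for a species
#'
#' Comparative protein analyses only include samples with a positive 16S
#' result for the species, within each microbiota group. Groups with no
#' positive members are reported with n = 0 (and are skipped by pairwise
#' testing downstream).
#'
#' @param species `"L_iners"` or `"L_crispatus"`.
#' @param samples A validated sample table.
#' @return A list with `species`, `groups` (named list mapping each VMB
#'   group to its member sample ids), `n_per_group`, and `n_total`.
#' @export
analysis_cohort <- function(species, samples) {
  species <- match.arg(species, SPECIES)
  pos <- sample_positive(samples, species)
  groups <- lapply(stats::setNames(VMB_GROUPS, VMB_GROUPS), function(g) {
    ids <- samples$sample_id[samples$vmb_group == g]
    sort(ids[pos[ids]])
  })
  n <- vapply(groups, length, integer(1))
  list(species = species, groups = groups, n_per_group = n,
       n_total = sum(n))
}

#' Split a cohort into taxon-abundance strata
#'
#' High/low strata of 16S S/B abundance, either by median split within
#' the supplied samples (high = strictly above the median; ties at the
#' median go low) or by a fixed threshold (high = strictly above it,
#' e.g. the study's `> 70` rule for high *L. iners* abundance).
#'
#' @param samples A validated sample table (already restricted to the
#'   analysis cohort of interest).
#' @param species Taxon whose S/B ratio defines the strata.
#' @param mode `"median_split"` or `"fixed_threshold"`.
#' @param threshold S/B cut-point for `"fixed_threshold"`.
#' @return A list with `high` and `low` (character vectors of sample
#'   ids) and `cutoff` (the S/B value used).
#' @export
abundance_strata <- function(samples, species,
                             mode = c("median_split", "fixed_threshold"),
                             threshold = 70) {
  mode <- match.arg(mode)
  if (nrow(samples) == 0) stop("empty sample set", call. = FALSE)
  sb <- sample_sb(samples, match.arg(species, SPECIES))
  cutoff <- if (mode == "median_split") stats::median(sb) else threshold
  list(
    high = sort(names(sb)[sb > cutoff]),
    low = sort(names(sb)[sb <= cutoff]),
    cutoff = cutoff
  )
}
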