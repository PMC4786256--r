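#' Post-identification inclusion filter for identified proteins
#'
#' A protein is retained when it has at least one unique peptide and at
#' least two peptides overall (unique or shared). Proteins supported by a
#' single unique peptide are rescued only when their per-protein ANOVA
#' p-value across microbiota groups is below 0.05 (strictly) *and* a
#' series of at least 4 continuous fragment ions was confirmed by manual
#' spectrum inspection (carried here as the boolean `fragment_series_ok`,
#' since raw spectra are outside this package's scope). A single-unique-
#' peptide record lacking either piece of rescue evidence fails,
#' conservatively.
#'
#' @param protein One-row data frame (or list) with fields
#'   `peptide_count`, `unique_peptides`, `anova_p`, `fragment_series_ok`.
#' @return A list with `pass` (logical) and `reason` (character): `"ok"`
#'   when passing, otherwise the first failed clause among
#'   `"no-unique-peptide"`, `"fewer-than-two-peptides"`,
#'   `"insufficient-evidence-metadata"`, `"anova-p-not-significant"`,
#'   `"fragment-series-not-confirmed"`.
#' @examples
#' passes_inclusion(list(peptide_count = 12, unique_peptides = 10,
#'                       anova_p = NA, fragment_series_ok = NA))
#' @export
passes_inclusion <- function(protein) {
  u <- protein$unique_peptides
  n <- protein$peptide_count
  stopifnot(length(u) == 1, length(n) == 1, u <= n)
  if (u < 1) {
    return(list(pass = FALSE, reason = "no-unique-peptide"))
  }
  if (n < 2) {
    return(list(pass = FALSE, reason = "fewer-than-two-peptides"))
  }
  if (u >= 2) {
    return(list(pass = TRUE, reason = "ok"))
  }
  # rescue path for exactly one unique peptide
  p <- protein$anova_p
  flag <- protein$fragment_series_ok
  if (is.null(p) || is.null(flag) || is.na(p) || is.na(flag)) {
    return(list(pass = FALSE, reason = "insufficient-evidence-metadata"))
  }
  if (!(p < 0.05)) {
    return(list(pass = FALSE, reason = "anova-p-not-significant"))
  }
  if (!isTRUE(flag)) {
    return(list(pass = FALSE, reason = "fragment-series-not-confirmed"))
  }
  list(pass = TRUE, reason = "ok")
}

#' Partition a protein table by the inclusion filter
#'
#' Applies [passes_inclusion()] to every record, preserving input order.
#'
#' @param proteins A validated protein table.
#' @return A list with `included` (protein table), `excluded` (protein
#'   table with an extra `reason` column), and `reasons` (character
#'   vector over all inputs, `"ok"` for included records).
#' @export
filter_proteins <- function(proteins) {
  n <- nrow(proteins)
  if (is.null(n) || n == 0) {
    empty <- proteins[integer(0), , drop = FALSE]
    excluded <- empty
    excluded$reason <- character(0)
    return(list(included = empty, excluded = excluded,
                reasons = character(0)))
  }
  verdicts <- lapply(seq_len(n), function(i) {
    passes_inclusion(proteins[i, , drop = FALSE])
  })
  pass <- vapply(verdicts, `[[`, logical(1), "pass")
  reasons <- vapply(verdicts, `[[`, character(1), "reason")
  excluded <- proteins[!pass, , drop = FALSE]
  excluded$reason <- reasons[!pass]
  list(
    included = proteins[pass, , drop = FALSE],
    excluded = excluded,
    reasons = reasons
  )
}
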