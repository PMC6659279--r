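# The two desaturation summaries of a composition profile.
#
# Delta-9 desaturation index: the ratio of the five MUFAs producible by the
# delta-9 desaturase pathway to their three saturated precursors,
#
#   D9-DI = (wt%14:1ω5 + wt%16:1ω7 + wt%16:1ω9 + wt%18:1ω9 + wt%18:1ω7) /
#           (wt%14:0 + wt%16:0 + wt%18:0)
#
# PUFAs are mostly dietary and are deliberately excluded. The double bond
# index, by contrast, sums over every FA: DBI = sum(x * wt%) / 100 with x
# the number of double bonds, so it folds dietary PUFAs back in.

.di_numerator_fas <- c("14:1ω5", "16:1ω7", "16:1ω9", "18:1ω9", "18:1ω7")
.di_denominator_fas <- c("14:0", "16:0", "18:0")

#' Fatty acids entering the desaturation index
#'
#' @return Character vector of the eight canonical labels used by
#'   [delta9_desaturation_index()]: five delta-9 pathway MUFAs (numerator)
#'   and their three SFA precursors (denominator).
#' @export
di_formula_fas <- function() c(.di_numerator_fas, .di_denominator_fas)

.profile_weight <- function(profile, labels, warn_missing = FALSE) {
  w <- profile$weights[labels]
  missing <- labels[is.na(w)]
  if (warn_missing && length(missing)) {
    warning(sprintf("%s: FAs absent from profile treated as wt%% 0: %s",
                    profile$species, paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  w[is.na(w)] <- 0
  w
}

#' Delta-9 desaturation index
#'
#' Ratio of the five delta-9-pathway monounsaturated fatty acids' wt% to
#' the wt% of their three saturated precursors. A proxy for endogenous
#' stearoyl-CoA (delta-9) desaturase activity: polyunsaturated FAs, being
#' largely dietary, never enter the formula. Formula FAs absent from the
#' profile count as 0 (with a warning, since source tables omit trace FAs
#' inconsistently).
#'
#' @param profile An [fa_profile()].
#' @param warn_missing Warn when a formula FA is absent (default `TRUE`).
#' @return Non-negative numeric scalar.
#' @examples
#' p <- fa_profile("x", c("16:1w7" = 10, "18:1w9" = 20, "16:0" = 15, "18:0" = 5))
#' delta9_desaturation_index(p, warn_missing = FALSE)  # 30 / 20
#' @export
delta9_desaturation_index <- function(profile, warn_missing = TRUE) {
  stopifnot(inherits(profile, "fa_profile"))
  num <- sum(.profile_weight(profile, .di_numerator_fas, warn_missing))
  den <- sum(.profile_weight(profile, .di_denominator_fas, warn_missing))
  if (den <= 0) {
    stop(sprintf("%s: desaturation index undefined, saturated-FA denominator is 0",
                 profile$species), call. = FALSE)
  }
  num / den
}

#' Double bond index
#'
#' Sum over all fatty acids of (number of double bonds x wt%) / 100.
#' Saturated FAs contribute 0; monounsaturated and polyunsaturated FAs all
#' contribute, so the DBI reflects total unsaturation including dietary
#' PUFAs. Every label in the profile must parse; unparseable labels are an
#' error, never skipped.
#'
#' @param profile An [fa_profile()].
#' @return Non-negative numeric scalar.
#' @examples
#' double_bond_index(fa_profile("x", c("18:1w9" = 50, "16:0" = 50)))  # 0.5
#' @export
double_bond_index <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  if (!length(profile$weights)) return(0)
  db <- vapply(names(profile$weights),
               function(l) parse_fa_label(l)$double_bonds, integer(1L))
  sum(db * profile$weights) / 100
}

#' Compute both indices for a list of profiles
#'
#' @param profiles List of [fa_profile()] objects.
#' @param renormalize If `TRUE`, rescale each profile's wt% to total 100
#'   before computing. Default `FALSE`: both indices are ratios or weighted
#'   sums of the raw wt% as published.
#' @param tolerance Passed to [validate_profile()].
#' @return `data.frame` with columns `species`, `section`, `delta9_di`,
#'   `dbi`, `n_fas_used`, `warnings` (semicolon-joined; empty when clean).
#' @export
compute_indices <- function(profiles, renormalize = FALSE, tolerance = 5) {
  stopifnot(is.list(profiles), all(vapply(profiles, inherits, logical(1L),
                                          "fa_profile")))
  rows <- lapply(profiles, function(p) {
    warns <- validate_profile(p, tolerance = tolerance)
    if (renormalize && sum(p$weights) > 0) {
      p$weights <- p$weights * (100 / sum(p$weights))
    }
    missing <- setdiff(di_formula_fas(), names(p$weights))
    if (length(missing)) {
      warns <- c(warns, sprintf("formula FAs treated as 0: %s",
                                paste(missing, collapse = ", ")))
    }
    data.frame(
      species = p$species,
      section = p$section,
      delta9_di = delta9_desaturation_index(p, warn_missing = FALSE),
      dbi = double_bond_index(p),
      n_fas_used = length(p$weights),
      warnings = paste(warns, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read fatty-acid composition profiles from CSV
#'
#' Expected layout: one row per species, a `species` column, an optional
#' `section` column (`outer`, `whole`, `white_adipose`), and one column per
#' fatty-acid label holding wt%. Empty cells count as absent (0 for the
#' index formulas).
#'
#' @param path CSV file path.
#' @return List of [fa_profile()] objects.
#' @export
read_fa_profiles <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("fatty-acid CSV not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) {
    stop(sprintf("%s: missing required column 'species'", path), call. = FALSE)
  }
  has_section <- "section" %in% names(df)
  fa_cols <- setdiff(names(df), c("species", "section"))
  if (!length(fa_cols)) {
    stop(sprintf("%s: no fatty-acid columns found", path), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    w <- suppressWarnings(as.numeric(df[i, fa_cols]))
    names(w) <- fa_cols
    w <- w[!is.na(w)]
    section <- if (has_section && nzchar(df$section[i])) df$section[i] else "unknown"
    fa_profile(df$species[i], w, section = section)
  })
}

#' Write an index table to CSV
#'
#' @param indices Output of [compute_indices()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_indices <- function(indices, path) {
  utils::write.csv(indices, path, row.names = FALSE)
  invisible(path)
}
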