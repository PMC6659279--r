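# Fatty-acid nomenclature: canonical form is "C:D" for saturated FAs and
# "C:DwN" internally rendered with the omega glyph, e.g. "16:1ω7".
# Several dialects circulate in the composition literature and all are
# accepted on input: "16:1w7", "16:1n-7", "16:1(n-7)", "16:1ω7".

.omega_dialects <- c(
  "ω" = "ω",   # omega glyph
  "w"      = "ω",   # ascii substitute
  "n-"     = "ω",   # n-minus notation
  "n"      = "ω"    # bare n (rare)
)

#' Parse a fatty-acid label
#'
#' Parses shorthand fatty-acid nomenclature (`"16:1w7"`, `"22:6n-3"`,
#' `"16:0"`, `"16:1(n-7)"`, or the omega glyph itself) into its components:
#' chain length, number of double bonds, and the omega position of the first
#' double bond counted from the methyl end.
#'
#' @param label Character scalar, e.g. `"18:1w9"`.
#' @param dialects Named character vector mapping accepted omega-prefix
#'   dialects to the canonical omega glyph. Extend to accept local notation;
#'   unknown prefixes are an error, never silently dropped.
#'
#' @return An object of class `"fatty_acid"`: a list with elements
#'   `carbons`, `double_bonds`, `omega_position` (`NA` for saturated FAs)
#'   and `label` (the canonical form).
#'
#' @examples
#' parse_fa_label("18:1w9")
#' parse_fa_label("22:6n-3")$label   # canonicalised
#' parse_fa_label("16:0")
#' @export
parse_fa_label <- function(label, dialects = .omega_dialects) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(trimws(label))) {
    stop("fatty-acid label must be a single non-empty string", call. = FALSE)
  }
  raw <- trimws(label)
  x <- gsub("[()]", "", raw)
  if (!grepl(":", x, fixed = TRUE)) {
    stop(sprintf("malformed fatty-acid label '%s': no ':' separator", raw),
         call. = FALSE)
  }
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    stop(sprintf("malformed fatty-acid label '%s': expected one ':'", raw),
         call. = FALSE)
  }
  carbons <- suppressWarnings(as.integer(parts[1L]))
  if (is.na(carbons) || !grepl("^[0-9]+$", parts[1L])) {
    stop(sprintf("malformed fatty-acid label '%s': chain length '%s' is not a number",
                 raw, parts[1L]), call. = FALSE)
  }
  rest <- parts[2L]
  # split double-bond count from an optional omega suffix
  m <- regexpr("^[0-9]+", rest)
  if (m == -1L) {
    stop(sprintf("malformed fatty-acid label '%s': double-bond count '%s' is not a number",
                 raw, rest), call. = FALSE)
  }
  db_str <- regmatches(rest, m)
  double_bonds <- as.integer(db_str)
  suffix <- substring(rest, nchar(db_str) + 1L)
  omega <- NA_integer_
  if (nzchar(suffix)) {
    prefixes <- names(dialects)[order(-nchar(names(dialects)))]
    hit <- NULL
    for (p in prefixes) {
      if (startsWith(suffix, p)) { hit <- p; break }
    }
    if (is.null(hit)) {
      stop(sprintf("malformed fatty-acid label '%s': unknown omega dialect '%s'",
                   raw, suffix), call. = FALSE)
    }
    pos_str <- substring(suffix, nchar(hit) + 1L)
    if (!grepl("^[0-9]+$", pos_str)) {
      stop(sprintf("malformed fatty-acid label '%s': omega position '%s' is not a number",
                   raw, pos_str), call. = FALSE)
    }
    omega <- as.integer(pos_str)
  }
  if (carbons < 2L) {
    stop(sprintf("fatty-acid label '%s': chain length must be >= 2", raw),
         call. = FALSE)
  }
  if (double_bonds > 0L && is.na(omega)) {
    # unsaturated with unstated position: allowed on input (e.g. "16:1"),
    # but then there is no omega class
    omega <- NA_integer_
  }
  if (double_bonds == 0L && !is.na(omega)) {
    stop(sprintf("fatty-acid label '%s': saturated FA cannot carry an omega position",
                 raw), call. = FALSE)
  }
  canon <- if (is.na(omega)) {
    sprintf("%d:%d", carbons, double_bonds)
  } else {
    sprintf("%d:%dω%d", carbons, double_bonds, omega)
  }
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         omega_position = omega, label = canon),
    class = "fatty_acid"
  )
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(sprintf("<fatty_acid> %s  (C%d, %d double bond%s%s)\n",
              x$label, x$carbons, x$double_bonds,
              if (x$double_bonds == 1L) "" else "s",
              if (is.na(x$omega_position)) ""
              else sprintf(", ω%d", x$omega_position)))
  invisible(x)
}

#' Canonicalise a vector of fatty-acid labels
#'
#' @param labels Character vector of labels in any accepted dialect.
#' @return Character vector of canonical labels.
#' @export
canonical_fa_label <- function(labels) {
  vapply(labels, function(l) parse_fa_label(l)$label, character(1L),
         USE.NAMES = FALSE)
}

#' Construct a fatty-acid composition profile
#'
#' A profile holds the percent-by-weight (wt%) composition of one species'
#' adipose tissue or blubber sample: a named numeric vector of wt% keyed by
#' canonical fatty-acid label, together with the species name and the tissue
#' section the sample came from.
#'
#' @param species Taxon name.
#' @param weights Named numeric vector: names are fatty-acid labels (any
#'   accepted dialect), values wt% in `[0, 100]`.
#' @param section One of `"outer"`, `"whole"`, `"white_adipose"`,
#'   `"unknown"`. Outer-layer blubber is the section least influenced by
#'   diet; terrestrial samples are white adipose tissue.
#'
#' @return An object of class `"fa_profile"`.
#' @examples
#' fa_profile("Phoca vitulina", c("16:0" = 15, "16:1w7" = 12, "18:1w9" = 25))
#' @export
fa_profile <- function(species, weights,
                       section = c("unknown", "outer", "whole", "white_adipose")) {
  section <- match.arg(section)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("profile weights must be a fully named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("profile weights must all be finite", call. = FALSE)
  }
  if (any(weights < 0)) {
    bad <- names(weights)[weights < 0]
    stop(sprintf("negative wt%% for %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  canon <- canonical_fa_label(names(weights))
  if (anyDuplicated(canon)) {
    dup <- unique(canon[duplicated(canon)])
    stop(sprintf("duplicate fatty-acid labels after canonicalisation: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  w <- as.numeric(weights)
  names(w) <- canon
  structure(list(species = species, section = section, weights = w),
            class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("<fa_profile> %s [%s]: %d FAs, total wt%% = %.2f\n",
              x$species, x$section, length(x$weights), sum(x$weights)))
  invisible(x)
}

#' Validate a composition profile
#'
#' Checks that the wt% total is plausibly a full composition (100 within a
#' tolerance band; trace FAs are often unreported so small shortfalls are
#' expected) and reports what it finds as character warnings rather than
#' failing, so batch loaders can collect them.
#'
#' @param profile An [fa_profile()].
#' @param tolerance Permitted deviation of the wt% total from 100
#'   (percentage points; default 5).
#' @return Character vector of warning messages (length 0 when clean).
#'   Negative weights and duplicate labels are structural errors and are
#'   raised, not returned (the `fa_profile` constructor already enforces
#'   both; this re-checks in case the object was hand-edited).
#' @export
validate_profile <- function(profile, tolerance = 5) {
  stopifnot(inherits(profile, "fa_profile"))
  w <- profile$weights
  if (any(w < 0)) {
    stop(sprintf("negative wt%% for %s", paste(names(w)[w < 0], collapse = ", ")),
         call. = FALSE)
  }
  canon <- canonical_fa_label(names(w))
  if (anyDuplicated(canon)) {
    stop(sprintf("duplicate fatty-acid labels after canonicalisation: %s",
                 paste(unique(canon[duplicated(canon)]), collapse = ", ")),
         call. = FALSE)
  }
  warnings <- character(0L)
  total <- sum(w)
  if (abs(total - 100) > tolerance) {
    warnings <- c(warnings,
                  sprintf("%s: wt%% total %.3f outside 100 ± %g",
                          profile$species, total, tolerance))
  }
  warnings
}
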