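# The study's concrete analyses: named model sets for the desaturation and
# double-bond indices (environment x latitude, full mammal dataset) and for
# the semi-aquatic hair-density subset, plus per-environment summaries, the
# pinniped blubber-section subanalysis and per-FA latitude regressions.

.environments <- c("fully_aquatic", "semi_aquatic", "terrestrial")
.sections <- c("outer", "whole", "white_adipose", "unknown")

.suite_formulas <- list(
  interaction       = ~ latitude * environment,
  additive          = ~ latitude + environment,
  latitude_only     = ~ latitude,
  environment_only  = ~ environment,
  hair_density_only = ~ log_hair_density,
  latitude_x_hair   = ~ latitude * log_hair_density,
  latitude_plus_hair = ~ latitude + log_hair_density,
  null              = ~ 1
)

#' Model specification for the trait suites
#'
#' @param name One of `"interaction"`, `"additive"`, `"latitude_only"`,
#'   `"environment_only"`, `"hair_density_only"`, `"latitude_x_hair"`,
#'   `"latitude_plus_hair"`, `"null"`.
#' @param reference_level Baseline environment for dummy coding. The
#'   default `"fully_aquatic"` makes the environment contrasts directly
#'   comparable with fully-aquatic-vs-terrestrial and
#'   fully-aquatic-vs-semi-aquatic intercept differences.
#' @return Object of class `"model_spec"`: list with `name`, `formula`,
#'   `terms`, `reference_level`.
#' @export
model_spec <- function(name, reference_level = "fully_aquatic") {
  name <- match.arg(name, names(.suite_formulas))
  reference_level <- match.arg(reference_level, .environments)
  f <- .suite_formulas[[name]]
  structure(list(name = name, formula = f,
                 terms = attr(stats::terms(f), "term.labels"),
                 reference_level = reference_level),
            class = "model_spec")
}

#' The two named five-model suites
#'
#' `mammal_suite()`: interaction, additive, latitude-only,
#' environment-only and null models for the full dataset.
#' `hair_suite()`: latitude + hair density combinations for the
#' semi-aquatic subset.
#'
#' @param reference_level Passed to [model_spec()].
#' @return Named list of `"model_spec"` objects.
#' @export
mammal_suite <- function(reference_level = "fully_aquatic") {
  nm <- c("interaction", "additive", "latitude_only", "environment_only", "null")
  stats::setNames(lapply(nm, model_spec, reference_level = reference_level), nm)
}

#' @rdname mammal_suite
#' @export
hair_suite <- function(reference_level = "fully_aquatic") {
  nm <- c("latitude_plus_hair", "latitude_x_hair", "hair_density_only",
          "latitude_only", "null")
  stats::setNames(lapply(nm, model_spec, reference_level = reference_level), nm)
}

#' Load the species trait table
#'
#' Reads and validates a CSV with one row per species. Required columns:
#' `species`, `environment` (`terrestrial` / `semi_aquatic` /
#' `fully_aquatic`), `latitude` (degrees). Optional: `hair_density` (hairs
#' per mm^2; a `hair_density_secondary` column, when present, is added to
#' it — total hair density is what enters the models), `blubber_section`,
#' `pinniped` (logical), `delta9_di`, `dbi`. `log_hair_density` is derived
#' by natural log where hair density is present.
#'
#' @param path CSV file path.
#' @param latitude_mode `"absolute"` (default; latitude as a thermal proxy
#'   regardless of hemisphere) or `"signed"`.
#' @return data.frame of validated records, `environment` a factor.
#' @export
load_species_table <- function(path, latitude_mode = c("absolute", "signed")) {
  latitude_mode <- match.arg(latitude_mode)
  if (!file.exists(path)) {
    stop(sprintf("species table not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "environment", "latitude")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  validate_species_records(df, context = path)
  df$latitude <- as.numeric(df$latitude)
  if (latitude_mode == "absolute") df$latitude <- abs(df$latitude)
  df$environment <- factor(df$environment, levels = .environments)
  if ("hair_density_secondary" %in% names(df)) {
    sec <- as.numeric(df$hair_density_secondary)
    df$hair_density <- ifelse(is.na(sec), df$hair_density,
                              df$hair_density + sec)
  }
  if ("hair_density" %in% names(df)) {
    df$log_hair_density <- ifelse(is.na(df$hair_density) | df$hair_density <= 0,
                                  NA_real_, log(df$hair_density))
  }
  if (!"blubber_section" %in% names(df)) df$blubber_section <- "unknown"
  df$blubber_section[is.na(df$blubber_section) |
                       !nzchar(df$blubber_section)] <- "unknown"
  if ("pinniped" %in% names(df)) df$pinniped <- as.logical(df$pinniped)
  df
}

# shared validation, usable on freshly simulated tables too
validate_species_records <- function(df, context = "species table") {
  bad_env <- which(!df$environment %in% .environments)
  if (length(bad_env)) {
    stop(sprintf("%s: unknown environment '%s' at row %d",
                 context, df$environment[bad_env[1L]], bad_env[1L]),
         call. = FALSE)
  }
  bad_sp <- which(is.na(df$species) | !nzchar(trimws(df$species)))
  if (length(bad_sp)) {
    stop(sprintf("%s: missing species name at row %d", context, bad_sp[1L]),
         call. = FALSE)
  }
  lat <- suppressWarnings(as.numeric(df$latitude))
  bad_lat <- which(is.na(lat) | abs(lat) > 90)
  if (length(bad_lat)) {
    stop(sprintf("%s: latitude out of [-90, 90] (or non-numeric) at row %d",
                 context, bad_lat[1L]), call. = FALSE)
  }
  if ("hair_density" %in% names(df)) {
    hd <- suppressWarnings(as.numeric(df$hair_density))
    bad_hd <- which(!is.na(df$hair_density) & (is.na(hd) | hd <= 0))
    if (length(bad_hd)) {
      stop(sprintf("%s: hair density must be positive at row %d",
                   context, bad_hd[1L]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a design matrix for a model specification
#'
#' Intercept column of ones; environment dummy-coded against the spec's
#' reference level (two contrast columns for three levels); interaction
#' terms are elementwise products of latitude with each environment dummy,
#' alongside all marginal terms. Records incomplete for the requested terms
#' are dropped with a message.
#'
#' @param records data.frame from [load_species_table()] or
#'   [simulate_traits()].
#' @param spec A [model_spec()].
#' @return List with `X` (matrix, rownames = species), `columns`,
#'   `rows_used` (integer indices into `records`).
#' @export
build_design_matrix <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- all.vars(spec$formula)
  miss_col <- setdiff(vars, names(records))
  if (length(miss_col)) {
    stop(sprintf("records lack columns needed by model '%s': %s",
                 spec$name, paste(miss_col, collapse = ", ")), call. = FALSE)
  }
  if ("environment" %in% vars) {
    env <- factor(as.character(records$environment),
                  levels = c(spec$reference_level,
                             setdiff(.environments, spec$reference_level)))
    empty <- levels(env)[!levels(env) %in% env]
    if (length(empty)) {
      stop(sprintf("environment level(s) with no records: %s",
                   paste(empty, collapse = ", ")), call. = FALSE)
    }
    records$environment <- env
  }
  complete <- if (length(vars)) {
    stats::complete.cases(records[vars])
  } else rep(TRUE, nrow(records))
  if (!all(complete)) {
    message(sprintf("model '%s': dropping %d record(s) incomplete for terms %s",
                    spec$name, sum(!complete), paste(vars, collapse = ", ")))
  }
  use <- records[complete, , drop = FALSE]
  X <- stats::model.matrix(spec$formula, data = use)
  rownames(X) <- use$species
  list(X = X, columns = colnames(X), rows_used = which(complete))
}

#' Run a model suite across random tree resolutions
#'
#' Prunes the tree to the records' species, restricts to records complete
#' for every variable any suite member uses (so all models share the same
#' response), and fits each model by lambda-ML PGLS on each of `n_iter`
#' random polytomy resolutions — the same resolved trees for every model,
#' so AICc differences are never topology artefacts. Models are ranked by
#' across-iteration mean AICc; the effect size r of each model is computed
#' against the intercept-only fit on the same resolution. When the suite
#' contains the interaction model, per-environment latitude slopes (the
#' marginal slope for each environment, with delta-method intervals) are
#' extracted from it.
#'
#' @param records Species trait table (data.frame).
#' @param tree [ape::phylo] containing at least the records' species.
#' @param response `"delta9_di"` or `"dbi"` (any numeric column name is
#'   accepted).
#' @param suite Named list of [model_spec()]s, e.g. [mammal_suite()].
#' @param n_iter Random polytomy resolutions (study design: 1000).
#' @param seed Master seed.
#' @param level Confidence level.
#' @return List of class `"suite_result"`: `comparison`
#'   (`"model_comparison"` on mean AICc), `models` (per-model aggregate
#'   summaries), `slopes` (per-environment latitude slopes, or `NULL`),
#'   `iterations` (long data.frame: iteration, model, aicc, lambda, r),
#'   `n`, `response`.
#' @export
run_model_suite <- function(records, tree, response = c("delta9_di", "dbi"),
                            suite = mammal_suite(), n_iter = 1000L, seed = 1L,
                            level = 0.95) {
  response <- if (is.character(response)) response[1L] else response
  if (!response %in% names(records)) {
    stop(sprintf("records have no response column '%s'", response),
         call. = FALSE)
  }
  stopifnot(length(suite) >= 1L, !is.null(names(suite)))
  vars <- unique(unlist(lapply(suite, function(s) all.vars(s$formula))))
  keep <- stats::complete.cases(records[c(response, vars)])
  if (!all(keep)) {
    message(sprintf("dropping %d record(s) incomplete for {%s}",
                    sum(!keep), paste(c(response, vars), collapse = ", ")))
  }
  records <- records[keep, , drop = FALSE]
  tree <- prune_to_taxa(tree, records$species)
  # align record order to tree tip order
  ord <- match(normalize_taxon(tree$tip.label), normalize_taxon(records$species))
  records <- records[ord, , drop = FALSE]
  y <- stats::setNames(records[[response]], tree$tip.label)

  designs <- lapply(suite, function(s) {
    d <- build_design_matrix(records, s)
    if (length(d$rows_used) != nrow(records)) {
      stop(sprintf("model '%s' would drop records after suite-wide filtering",
                   s$name), call. = FALSE)
    }
    rownames(d$X) <- tree$tip.label
    d
  })
  null_X <- matrix(1, nrow(records), 1L,
                   dimnames = list(tree$tip.label, "(Intercept)"))

  seeds <- derive_seeds(seed, n_iter)
  binary <- is_binary_rooted(tree)
  model_names <- names(suite)
  per_iter <- vector("list", n_iter)
  fits_by_model <- stats::setNames(
    lapply(model_names, function(m) vector("list", n_iter)), model_names)
  slope_rows <- vector("list", n_iter)
  has_interaction <- "interaction" %in% model_names

  for (i in seq_len(n_iter)) {
    if (binary && i > 1L) {
      per_iter[[i]] <- transform(per_iter[[1L]], iteration = i, seed = seeds[i])
      for (m in model_names) fits_by_model[[m]][[i]] <- fits_by_model[[m]][[1L]]
      if (has_interaction) {
        slope_rows[[i]] <- transform(slope_rows[[1L]], iteration = i)
      }
      next
    }
    tr <- resolve_polytomies(tree, seeds[i])
    V0 <- vcv_from_tree(tr)[tree$tip.label, tree$tip.label]
    null_fit <- fit_lambda_ml(y, null_X, V0 = V0, level = level)
    rows <- lapply(model_names, function(m) {
      fit <- if (identical(designs[[m]]$columns, "(Intercept)")) null_fit
             else fit_lambda_ml(y, designs[[m]]$X, V0 = V0, level = level)
      fit$r <- if (identical(fit, null_fit)) NA_real_
               else effect_size(fit, null_fit)
      fits_by_model[[m]][[i]] <<- fit
      data.frame(iteration = i, seed = seeds[i], model = m, aicc = fit$aicc,
                 lambda = fit$lambda, r = fit$r, stringsAsFactors = FALSE)
    })
    per_iter[[i]] <- do.call(rbind, rows)
    if (has_interaction) {
      sl <- environment_slopes(fits_by_model[["interaction"]][[i]],
                               suite[["interaction"]], level = level)
      sl$iteration <- i
      slope_rows[[i]] <- sl
    }
  }

  iterations <- do.call(rbind, per_iter)
  model_summ <- lapply(model_names, function(m) {
    fs <- fits_by_model[[m]]
    list(
      name = m,
      aicc = mean(vapply(fs, `[[`, numeric(1L), "aicc")),
      aicc_median = stats::median(vapply(fs, `[[`, numeric(1L), "aicc")),
      lambda = mean(vapply(fs, `[[`, numeric(1L), "lambda")),
      r = mean(vapply(fs, function(f) f$r, numeric(1L))),
      beta = colMeans(do.call(rbind, lapply(fs, `[[`, "beta"))),
      ci_low = colMeans(do.call(rbind, lapply(fs, `[[`, "ci_low"))),
      ci_high = colMeans(do.call(rbind, lapply(fs, `[[`, "ci_high"))),
      k = fs[[1L]]$k,
      n = fs[[1L]]$n
    )
  })
  names(model_summ) <- model_names
  comparison <- compare_models(model_summ)

  slopes <- NULL
  if (has_interaction) {
    all_slopes <- do.call(rbind, slope_rows)
    slopes <- do.call(rbind, lapply(split(all_slopes, all_slopes$environment),
                                    function(d) {
      data.frame(environment = d$environment[1L],
                 slope = mean(d$slope), low = mean(d$low), high = mean(d$high),
                 stringsAsFactors = FALSE)
    }))
    slopes$significant <- slopes$low > 0 | slopes$high < 0
    rownames(slopes) <- NULL
  }

  structure(list(comparison = comparison, models = model_summ,
                 slopes = slopes, iterations = iterations,
                 n = model_summ[[1L]]$n, response = response,
                 n_iter = n_iter, seed = seed),
            class = "suite_result")
}

#' @export
print.suite_result <- function(x, ...) {
  cat(sprintf("<suite_result> response = %s, n = %d, %d iterations\n",
              x$response, x$n, x$n_iter))
  print(x$comparison)
  if (!is.null(x$slopes)) {
    cat("per-environment latitude slopes (interaction model):\n")
    print(transform(x$slopes, slope = round(slope, 4), low = round(low, 4),
                    high = round(high, 4)))
  }
  invisible(x)
}

#' Per-environment latitude slopes from an interaction fit
#'
#' For the model `~ latitude * environment` with reference level `ref`,
#' the latitude slope in environment `e` is `beta_latitude` (for `ref`)
#' or `beta_latitude + beta_latitude:environment_e`; the combined standard
#' error uses the coefficient covariance.
#'
#' @param fit `"pgls_fit"` of the interaction design.
#' @param spec The interaction [model_spec()] used to build the design.
#' @param level Confidence level.
#' @return data.frame: environment, slope, se, low, high, significant.
#' @export
environment_slopes <- function(fit, spec, level = 0.95) {
  stopifnot(inherits(fit, "pgls_fit"))
  ref <- spec$reference_level
  envs <- c(ref, setdiff(.environments, ref))
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - fit$p)
  V <- fit$vcov
  rows <- lapply(envs, function(e) {
    c1 <- "latitude"
    c2 <- paste0("latitude:environment", e)
    if (e == ref || !c2 %in% names(fit$beta)) {
      slope <- fit$beta[[c1]]
      se <- fit$se[[c1]]
    } else {
      slope <- fit$beta[[c1]] + fit$beta[[c2]]
      se <- sqrt(V[c1, c1] + V[c2, c2] + 2 * V[c1, c2])
    }
    data.frame(environment = e, slope = slope, se = se,
               low = slope - tq * se, high = slope + tq * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$low > 0 | out$high < 0
  rownames(out) <- NULL
  out
}

#' Per-environment summary of an index
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' count per environment. Empty groups are omitted with a warning; a
#' single-record group reports `NA` SD.
#'
#' @param records Species trait table.
#' @param field Column to summarise (`"delta9_di"` or `"dbi"`).
#' @return data.frame: environment, mean, sd, n.
#' @export
group_summary <- function(records, field = c("delta9_di", "dbi")) {
  field <- if (is.character(field)) field[1L] else field
  stopifnot(field %in% names(records))
  vals <- split(records[[field]], factor(as.character(records$environment),
                                         levels = .environments))
  rows <- lapply(names(vals), function(e) {
    v <- vals[[e]][!is.na(vals[[e]])]
    if (!length(v)) {
      warning(sprintf("no records for environment '%s'; omitted", e),
              call. = FALSE)
      return(NULL)
    }
    data.frame(environment = e, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pinniped blubber-section subanalysis
#'
#' Marine-mammal blubber is stratified: the outer layer is richer in MUFAs
#' and less diet-influenced than whole-core samples. To check whether the
#' section sampled distorts the latitude relationship, this fits separate
#' latitude-only lambda-ML PGLS models to the pinniped records whose
#' profiles came from the outer layer and from whole blubber cores.
#'
#' @param records Species trait table with a logical `pinniped` column and
#'   `blubber_section` values; only sections `"outer"` and `"whole"`
#'   enter.
#' @param tree [ape::phylo] containing the pinniped species.
#' @param n_iter,seed,level As in [multi_tree_pgls()].
#' @param min_n Smallest group size accepted (default 3).
#' @return Named list (`outer`, `whole`) of lists: `fit`
#'   (`"multi_pgls"`), `slope`, `low`, `high`, `significant`, `n`.
#' @export
blubber_section_subanalysis <- function(records, tree, n_iter = 1000L,
                                        seed = 1L, level = 0.95, min_n = 3L) {
  if (!"pinniped" %in% names(records)) {
    stop("records need a logical 'pinniped' column", call. = FALSE)
  }
  pin <- records[isTRUE_vec(records$pinniped) &
                   records$blubber_section %in% c("outer", "whole"), ,
                 drop = FALSE]
  out <- lapply(c(outer = "outer", whole = "whole"), function(sec) {
    grp <- pin[pin$blubber_section == sec, , drop = FALSE]
    if (nrow(grp) < min_n) {
      stop(sprintf("blubber section '%s' has only %d pinniped record(s); need >= %d",
                   sec, nrow(grp), min_n), call. = FALSE)
    }
    tr <- prune_to_taxa(tree, grp$species)
    ord <- match(normalize_taxon(tr$tip.label), normalize_taxon(grp$species))
    grp <- grp[ord, , drop = FALSE]
    y <- stats::setNames(grp$delta9_di, tr$tip.label)
    X <- cbind("(Intercept)" = 1, latitude = grp$latitude)
    rownames(X) <- tr$tip.label
    fit <- multi_tree_pgls(y, X, tr, n_iter = n_iter, seed = seed,
                           level = level)
    list(fit = fit, n = nrow(grp),
         slope = unname(fit$beta["latitude"]),
         low = unname(fit$ci_low["latitude"]),
         high = unname(fit$ci_high["latitude"]),
         significant = unname(fit$ci_low["latitude"] > 0 |
                                fit$ci_high["latitude"] < 0))
  })
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Per-fatty-acid regressions on latitude
#'
#' Ordinary (non-phylogenetic) least-squares regression of each formula
#' FA's wt% on latitude, used to see which individual FAs drive a
#' latitude trend in the desaturation index. Species lacking an FA are
#' excluded from that FA's regression.
#'
#' @param profiles List of [fa_profile()] objects.
#' @param records Species trait table supplying latitude (matched by
#'   species name).
#' @param fas Canonical FA labels to test (default: the eight
#'   desaturation-index FAs).
#' @param alpha Significance level for the flag (default 0.01).
#' @return data.frame: fa, n, slope, p_value, significant, constant.
#' @export
fa_vs_latitude_regressions <- function(profiles, records,
                                       fas = di_formula_fas(), alpha = 0.01) {
  sp <- vapply(profiles, `[[`, character(1L), "species")
  lat <- records$latitude[match(normalize_taxon(sp),
                                normalize_taxon(records$species))]
  rows <- lapply(fas, function(fa) {
    wt <- vapply(profiles, function(p) {
      w <- p$weights[fa]
      if (is.na(w)) NA_real_ else unname(w)
    }, numeric(1L))
    ok <- !is.na(wt) & !is.na(lat)
    if (sum(ok) < 3L) {
      stop(sprintf("FA %s present in only %d species; need >= 3", fa, sum(ok)),
           call. = FALSE)
    }
    if (stats::sd(wt[ok]) == 0) {
      return(data.frame(fa = fa, n = sum(ok), slope = 0, p_value = NA_real_,
                        significant = FALSE, constant = TRUE,
                        stringsAsFactors = FALSE))
    }
    m <- stats::lm(wt[ok] ~ lat[ok])
    cf <- summary(m)$coefficients
    data.frame(fa = fa, n = sum(ok), slope = cf[2L, 1L],
               p_value = cf[2L, 4L], significant = cf[2L, 4L] < alpha,
               constant = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
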