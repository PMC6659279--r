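# Seeded generators for every input the pipeline consumes: ultrametric
# Yule trees (optionally with polytomies), trait tables drawn from the
# PGLS generative model (fixed effects + lambda-scaled Brownian
# residuals), and fatty-acid composition profiles constructed to hit
# prescribed index values exactly.

#' Simulation configuration
#'
#' Defaults mirror the composition of the study dataset: 54 species split
#' 15 terrestrial / 25 semi-aquatic / 14 fully-aquatic, latitudes spanning
#' 0-80 degrees, log-normal hair densities for the furred species (median
#' ~100 hairs per mm^2, spanning roughly 10-1000), and a lambda-scaled
#' Brownian residual around the fixed effects.
#'
#' @param seed Master seed; every generator output is bit-reproducible
#'   from it.
#' @param n_tips Number of species / tree tips.
#' @param birth_rate Speciation rate of the Yule (pure-birth) tree.
#' @param true_beta Named coefficient vector on the design of `spec`
#'   (names must match the design-matrix columns).
#' @param true_lambda Pagel's lambda of the residual, in `[0, 1]`.
#' @param sigma2 Brownian residual rate.
#' @param latitude_range Degrees, default `c(0, 80)`.
#' @param env_proportions Length-3 probabilities (terrestrial,
#'   semi-aquatic, fully-aquatic); default `15/54, 25/54, 14/54`.
#' @param polytomy_fraction Share of internal edges collapsed into
#'   polytomies (0 = strictly binary).
#' @param hair_density_lognormal `c(meanlog, sdlog)` of the hair-density
#'   distribution.
#' @param clade_bias If `TRUE` (default) environments are assigned to
#'   clade-contiguous blocks of tips, giving the phylogenetically
#'   clustered predictors a lambda-aware method must cope with; `FALSE`
#'   assigns them i.i.d.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_tips = 54L, birth_rate = 1,
                       true_beta = NULL, true_lambda = 0.5, sigma2 = 1,
                       latitude_range = c(0, 80),
                       env_proportions = c(terrestrial = 15 / 54,
                                           semi_aquatic = 25 / 54,
                                           fully_aquatic = 14 / 54),
                       polytomy_fraction = 0,
                       hair_density_lognormal = c(meanlog = log(100), sdlog = 1.2),
                       clade_bias = TRUE) {
  stopifnot(n_tips >= 3L, birth_rate > 0, sigma2 >= 0,
            true_lambda >= 0, true_lambda <= 1,
            length(env_proportions) == 3L,
            abs(sum(env_proportions) - 1) < 1e-8,
            polytomy_fraction >= 0, polytomy_fraction < 1)
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 birth_rate = birth_rate, true_beta = true_beta,
                 true_lambda = true_lambda, sigma2 = sigma2,
                 latitude_range = latitude_range,
                 env_proportions = env_proportions,
                 polytomy_fraction = polytomy_fraction,
                 hair_density_lognormal = hair_density_lognormal,
                 clade_bias = clade_bias),
            class = "sim_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with `n_tips` tips via [ape::rphylo()]. When
#' `polytomy_fraction > 0`, that share of internal edges is collapsed: a
#' collapsed edge's length is pushed down onto its child's daughter edges
#' before removal, so the tree stays ultrametric with the same tip depths,
#' and the zero-length edges are then merged into genuine multifurcations.
#'
#' @param config A [sim_config()].
#' @return [ape::phylo], ultrametric; binary iff `polytomy_fraction = 0`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    tree <- ape::rphylo(config$n_tips, birth = config$birth_rate, death = 0)
    tree$tip.label <- sprintf("sp%03d", seq_len(config$n_tips))
    if (config$polytomy_fraction > 0) {
      ntip <- length(tree$tip.label)
      internal_child <- tree$edge[, 2L] > ntip
      idx <- which(internal_child)
      n_collapse <- floor(config$polytomy_fraction * length(idx))
      if (n_collapse > 0L) {
        chosen <- sample(idx, n_collapse)
        for (e in chosen) {
          v <- tree$edge[e, 2L]
          len <- tree$edge.length[e]
          kids <- which(tree$edge[, 1L] == v)
          tree$edge.length[kids] <- tree$edge.length[kids] + len
          tree$edge.length[e] <- 0
        }
        tree <- ape::di2multi(tree, tol = 1e-12)
      }
    }
    tree
  })
}

#' Simulate species trait records under the PGLS generative model
#'
#' Assigns environments (clade-biased blocks by default), draws latitudes
#' uniformly on the configured range and hair densities log-normally, then
#' draws the response `y = X beta + e` with
#' `e ~ MVN(0, sigma2 * V(lambda))` via Cholesky factorisation of the
#' lambda-transformed Brownian covariance. The generating values are
#' attached as `attr(records, "truth")` for recovery tests.
#'
#' @param tree Binary [ape::phylo] (resolve polytomies first).
#' @param config A [sim_config()] supplying `true_beta`, `true_lambda`,
#'   `sigma2` and the covariate distributions.
#' @param spec [model_spec()] defining the design `true_beta` lives on.
#' @param response Column name for the simulated response (default
#'   `"delta9_di"`).
#' @return data.frame of species records with a `truth` attribute.
#' @export
simulate_traits <- function(tree, config, spec = model_spec("interaction"),
                            response = "delta9_di") {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "model_spec"))
  if (!is_binary_rooted(tree)) {
    stop("tree must be binary; resolve polytomies first", call. = FALSE)
  }
  n <- length(tree$tip.label)
  with_local_seed(config$seed + 1L, {
    # clade-contiguous environment blocks: tips in cladewise order
    tip_order <- tree$tip.label[.tip_sequence(tree)]
    counts <- .apportion(config$env_proportions, n)
    env_by_tip <- rep(names(config$env_proportions), counts)
    if (!config$clade_bias) env_by_tip <- sample(env_by_tip)
    env <- stats::setNames(env_by_tip, tip_order)[tree$tip.label]
    lat <- stats::runif(n, config$latitude_range[1L], config$latitude_range[2L])
    hd <- stats::rlnorm(n, config$hair_density_lognormal[[1L]],
                        config$hair_density_lognormal[[2L]])
    hd[env == "fully_aquatic"] <- NA  # bare-skinned: no pelage to count
    records <- data.frame(
      species = tree$tip.label,
      environment = factor(unname(env), levels = names(.env_levels())),
      latitude = lat,
      hair_density = hd,
      log_hair_density = ifelse(is.na(hd), NA_real_, log(hd)),
      blubber_section = ifelse(env == "terrestrial", "white_adipose", "outer"),
      pinniped = unname(env) == "semi_aquatic",
      stringsAsFactors = FALSE
    )
    d <- build_design_matrix(records, spec)
    if (length(d$rows_used) != n) {
      stop("simulated records incomplete for the generating model's terms",
           call. = FALSE)
    }
    X <- d$X
    beta <- config$true_beta
    if (is.null(beta)) beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    if (is.null(names(beta)) || !setequal(names(beta), colnames(X))) {
      stop(sprintf("true_beta names must match design columns: %s",
                   paste(colnames(X), collapse = ", ")), call. = FALSE)
    }
    beta <- beta[colnames(X)]
    mu <- as.vector(X %*% beta)
    eps <- if (config$sigma2 > 0) {
      Vl <- apply_lambda(vcv_from_tree(tree), config$true_lambda)
      as.vector(t(chol(config$sigma2 * Vl)) %*% stats::rnorm(n))
    } else rep(0, n)
    records[[response]] <- mu + eps
    attr(records, "truth") <- list(beta = beta, lambda = config$true_lambda,
                                   sigma2 = config$sigma2, spec = spec$name,
                                   columns = colnames(X), response = response)
    records
  })
}

.env_levels <- function() {
  stats::setNames(1:3, c("fully_aquatic", "semi_aquatic", "terrestrial"))
}

# tips in the order they appear along a cladewise edge traversal
.tip_sequence <- function(tree) {
  edge <- stats::reorder(tree, "cladewise")$edge
  tips <- edge[edge[, 2L] <= length(tree$tip.label), 2L]
  tips
}

# integer apportionment of n among proportions (largest remainder)
.apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# fixed 12-FA panel: the 8 desaturation-index FAs plus 4 dietary PUFAs
.sim_panel <- list(
  sfa  = c("14:0", "16:0", "18:0"),
  mufa = c("14:1ω5", "16:1ω7", "16:1ω9", "18:1ω9", "18:1ω7"),
  pufa = stats::setNames(c(2L, 4L, 5L, 6L),
                         c("18:2ω6", "20:4ω6", "20:5ω3", "22:6ω3"))
)

#' Simulate fatty-acid composition profiles with prescribed indices
#'
#' For each record, constructs wt% over a fixed 12-FA panel (the eight
#' desaturation-index FAs plus four dietary PUFAs) so that the recomputed
#' desaturation index equals the record's `delta9_di` exactly and the
#' double bond index equals its `dbi`, with Dirichlet noise distributing
#' mass within the SFA, MUFA and PUFA groups. Weights total exactly 100.
#'
#' The construction solves, for SFA mass `s`, MUFA mass `m = di * s` and
#' PUFA mass `P` with mean double bonds `xbar`:
#' `s (1 + di) + P = 100` and `m + xbar P = 100 dbi`. Feasibility requires
#' `di / (1 + di) <= dbi < 6`; outside that region the call errors with
#' the feasible interval.
#'
#' @param records data.frame with `species`, `delta9_di`, `dbi` and
#'   (optionally) `blubber_section` columns.
#' @param config A [sim_config()] (supplies the seed).
#' @param dirichlet_alpha Concentration of the within-group mass split.
#' @return List of [fa_profile()] objects.
#' @export
simulate_fa_profiles <- function(records, config, dirichlet_alpha = 5) {
  stopifnot(inherits(config, "sim_config"),
            all(c("delta9_di", "dbi") %in% names(records)))
  panel <- .sim_panel
  xs <- unname(panel$pufa)
  with_local_seed(config$seed + 2L, {
    lapply(seq_len(nrow(records)), function(i) {
      di <- records$delta9_di[i]
      dbi <- records$dbi[i]
      if (is.na(di) || is.na(dbi) || di < 0) {
        stop(sprintf("row %d: need non-negative delta9_di and dbi", i),
             call. = FALSE)
      }
      lo <- di / (1 + di)
      if (dbi < lo - 1e-12 || dbi >= 6) {
        stop(sprintf("row %d (%s): (delta9_di = %.3f, dbi = %.3f) infeasible; dbi must lie in [%.3f, 6)",
                     i, records$species[i], di, dbi, lo), call. = FALSE)
      }
      # PUFA mix and its mean double-bond count
      w <- stats::rgamma(length(xs), dirichlet_alpha)
      w <- w / sum(w)
      xbar <- sum(w * xs)
      if (dbi >= xbar) {         # heavy unsaturation: tilt mix toward DHA
        target <- (dbi + 6) / 2
        t <- (target - xbar) / (6 - xbar)
        w <- (1 - t) * w; w[length(w)] <- w[length(w)] + t
        xbar <- sum(w * xs)
      }
      if (abs(dbi - lo) < 1e-12) {
        s <- 100 / (1 + di); P <- 0
      } else {
        s <- 100 * (dbi - xbar) / (di - xbar * (1 + di))
        P <- 100 - s * (1 + di)
      }
      m <- di * s
      split_mass <- function(total, k) {
        if (total <= 0) return(rep(0, k))
        g <- stats::rgamma(k, dirichlet_alpha)
        total * g / sum(g)
      }
      weights <- c(
        stats::setNames(split_mass(s, 3L), panel$sfa),
        stats::setNames(split_mass(m, 5L), panel$mufa),
        stats::setNames(P * w, names(panel$pufa))
      )
      section <- if ("blubber_section" %in% names(records)) {
        sec <- records$blubber_section[i]
        if (sec %in% c("outer", "whole", "white_adipose")) sec else "unknown"
      } else "unknown"
      fa_profile(records$species[i], weights, section = section)
    })
  })
}
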