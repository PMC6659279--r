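# shared fixtures, all built in code

# the hand-evaluated reference profile: DI = 37/20 = 1.85
reference_profile <- function(extra = c("20:5w3" = 8, "22:6w3" = 12)) {
  fa_profile("testsp", c(
    "14:1w5" = 2, "16:1w7" = 10, "16:1w9" = 1, "18:1w9" = 20, "18:1w7" = 4,
    "14:0" = 3, "16:0" = 15, "18:0" = 2, extra
  ))
}

# small random ultrametric tree with unique labels
random_tree <- function(n, seed) {
  with_seed(seed, {
    tr <- ape::rcoal(n)
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    tr
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# explicit-inverse GLS oracle (deliberately naive: direct solve(V))
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  sigma2 <- as.numeric(t(r) %*% Vi %*% r) / n
  lnL <- -n / 2 * log(2 * pi * sigma2) - determinant(V)$modulus[1] / 2 - n / 2
  list(beta = as.vector(beta), sigma2 = sigma2, lnL = lnL)
}

# interaction-model coefficients with a semi-aquatic-only latitude effect
strong_interaction_beta <- function(slope = 0.06) {
  c("(Intercept)" = 2.3, latitude = 0,
    environmentsemi_aquatic = -1, environmentterrestrial = -1,
    "latitude:environmentsemi_aquatic" = slope,
    "latitude:environmentterrestrial" = 0)
}

# simulate one study-shaped dataset and return records + tree
simulate_study <- function(seed, n_tips = 54, lambda = 0.5, sigma2 = 0.4,
                           beta = strong_interaction_beta(),
                           polytomy_fraction = 0,
                           spec = model_spec("interaction")) {
  cfg <- sim_config(seed = seed, n_tips = n_tips, true_beta = beta,
                    true_lambda = lambda, sigma2 = sigma2,
                    polytomy_fraction = polytomy_fraction)
  tree <- simulate_tree(cfg)
  bin <- resolve_polytomies(tree, seed)
  records <- simulate_traits(bin, cfg, spec)
  list(records = records, tree = tree, binary = bin, config = cfg)
}
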