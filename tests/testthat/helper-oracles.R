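# Independent brute-force oracles used to validate the analytic
# implementations on tiny instances, plus small hand-built study fixtures.

# Impurity by the definition: double loop over rows against the mean.
oracle_impurity <- function(m) {
  m <- as.matrix(m)
  ctr <- colMeans(m)
  tot <- 0
  for (i in seq_len(nrow(m))) tot <- tot + sum((m[i, ] - ctr)^2)
  tot
}

# Exhaustive best split: try every covariate, every observed threshold,
# score left/right impurity directly.
oracle_best_split <- function(Y, X, min_bucket) {
  best <- NULL
  for (j in seq_along(X)) {
    x <- X[[j]]
    obs <- which(!is.na(x))
    vals <- sort(unique(x[obs]))
    if (length(vals) < 2) next
    thr <- (vals[-1] + vals[-length(vals)]) / 2
    for (tt in thr) {
      l <- obs[x[obs] < tt]
      r <- obs[x[obs] >= tt]
      if (length(l) < min_bucket || length(r) < min_bucket) next
      dec <- oracle_impurity(Y[obs, , drop = FALSE]) -
        oracle_impurity(Y[l, , drop = FALSE]) -
        oracle_impurity(Y[r, , drop = FALSE])
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(var = names(X)[j], threshold = tt, decrease = dec)
      }
    }
  }
  best
}

# PERMANOVA pseudo-F straight from the definition.
oracle_permanova_F <- function(D, labels) {
  Dm <- as.matrix(D)^2
  N <- nrow(Dm)
  labs <- unique(labels)
  ss_t <- sum(Dm) / (2 * N)
  ss_w <- 0
  for (l in labs) {
    idx <- which(labels == l)
    ss_w <- ss_w + sum(Dm[idx, idx]) / (2 * length(idx))
  }
  a <- length(labs)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (N - a))
}

# Exact permutation p-value by enumerating every relabelling.
oracle_permanova_exact <- function(D, labels) {
  n <- length(labels)
  perms <- NULL
  rec <- function(left, acc) {
    if (length(left) == 0) {
      perms[[length(perms) + 1L]] <<- acc
      return()
    }
    for (i in seq_along(left)) rec(left[-i], c(acc, left[i]))
  }
  rec(seq_len(n), integer(0))
  f_obs <- oracle_permanova_F(D, labels)
  fs <- vapply(perms, function(p) oracle_permanova_F(D, labels[p]),
               numeric(1))
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12))
}

# Subsample-enumeration oracles for the incidence diversity estimators.
# qD interpolation: mean, over all subsets of t units, of the plug-in
# entropy computed with the expected incidence total u_t = t U / T.
oracle_hill_shannon <- function(pres, t) {
  # pres: units x groups 0/1 matrix
  Tn <- nrow(pres)
  U <- sum(pres)
  u_t <- t * U / Tn
  subs <- utils::combn(Tn, t, simplify = FALSE)
  hs <- vapply(subs, function(s) {
    y <- colSums(pres[s, , drop = FALSE])
    y <- y[y > 0]
    -sum((y / u_t) * log(y / u_t))
  }, numeric(1))
  exp(mean(hs))
}

# Coverage: leave-one-out subsample expectation matching the incidence
# rarefaction form: for each group and each unit containing it, the chance
# that t units drawn from the remaining T-1 miss the group, weighted Y/U.
oracle_coverage <- function(pres, t) {
  Tn <- nrow(pres)
  U <- sum(pres)
  uncov <- 0
  for (j in seq_len(ncol(pres))) {
    units <- which(pres[, j] > 0)
    if (length(units) == 0) next
    for (u in units) {
      rest <- setdiff(seq_len(Tn), u)
      subs <- utils::combn(rest, t, simplify = FALSE)
      miss <- mean(vapply(subs, function(s) all(pres[s, j] == 0),
                          logical(1)))
      uncov <- uncov + miss / U
    }
  }
  1 - uncov
}

# Imputation precedence: the donor level that should win for each
# presence pattern of (stomach, year, group) donor pools.
oracle_imputation_level <- function(has_stomach, has_year, has_group) {
  if (has_stomach) "imputed_stomach"
  else if (has_year) "imputed_year"
  else if (has_group) "imputed_group"
  else NA_character_
}

# --- tiny fixture builders -------------------------------------------------

mini_stomachs <- function(n, year = 2010, ...) {
  tibble::tibble(stomach_id = sprintf("s%02d", seq_len(n)),
                 year = rep(year, length.out = n), ...)
}

mini_prey <- function(stomach_id, family, broad_group, n_each = 1,
                      taxon_id = tolower(family), genus = NA_character_,
                      species = NA_character_,
                      measurement_kind = "unmeasured",
                      measured_value_mm = NA_real_) {
  d <- tibble::tibble(stomach_id = stomach_id, family = family,
                      broad_group = broad_group, taxon_id = taxon_id,
                      genus = genus, species = species,
                      measurement_kind = measurement_kind,
                      measured_value_mm = measured_value_mm)
  d <- d[rep(seq_len(nrow(d)), n_each), ]
  d$prey_id <- sprintf("p%03d", seq_len(nrow(d)))
  d$is_bait <- FALSE
  d
}

# A small regression/energy set for hand-computed energetics tests.
mini_regressions <- function() {
  validate_regressions(tibble::tibble(
    scope_level = c("family", "family", "family", "predator", "predator"),
    scope_value = c("Myctophidae", "Myctophidae", "Gonatidae", "tuna",
                    "tuna"),
    kind = c("hardpart_to_length", "length_to_mass", "length_to_mass",
             "ol_to_fl", "fl_to_mass"),
    form = c("linear", "power", "power", "linear", "power"),
    a = c(0, 0.01, 0.02, 0, 2e-5),
    b = c(10, 3, 2.5, 4, 3),
    input_unit = c("mm", "mm", "mm", "cm", "cm"),
    output_unit = c("mm", "g", "g", "cm", "kg")))
}
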