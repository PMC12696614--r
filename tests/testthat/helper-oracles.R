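# Independent oracles and small fixtures, deliberately written along
# different code paths than the package internals.

# Mann-Kendall by explicit double loop; tie variance from sorted runs.
mk_brute <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i])
    }
  }
  ties <- rle(sort(x))$lengths
  tie_term <- 0
  for (t in ties) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  if (var_s == 0) z <- 0
  list(s = s, var_s = var_s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# LMG by full permutation enumeration of orderings, sequential R^2 via lm().
lmg_brute <- function(y, x) {
  x <- as.matrix(x)
  p <- ncol(x)
  perms <- gtools_permutations(p)
  r2_of <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(stats::lm(y ~ x[, cols, drop = FALSE]))$r.squared
  }
  shares <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    order_k <- perms[r, ]
    before <- integer(0)
    for (k in order_k) {
      shares[k] <- shares[k] + r2_of(c(before, k)) - r2_of(before)
      before <- c(before, k)
    }
  }
  stats::setNames(shares / nrow(perms), colnames(x))
}

# all permutations of 1..p (tiny p only)
gtools_permutations <- function(p) {
  if (p == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(p - 1)
  out <- NULL
  for (k in seq_len(p)) {
    rest <- setdiff(seq_len(p), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

tiny_grid <- function(nlat = 3, nlon = 4, years = 1982:2001) {
  grid_spec(seq(0, by = 3, length.out = nlat),
            seq(0, by = 3, length.out = nlon), years)
}

# wide driver table with iid uniform positive predictors, one cell
random_cell_drivers <- function(n = 39, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * 10, 0.5, 1.5), n, 10)
    colnames(m) <- canonical_predictors()
    m
  })
}

# single-row greenness map fixture for voting tests
make_greenness <- function(categories, lats = 0,
                           lons = seq(0, by = 3, length.out = length(categories))) {
  structure(
    tibble::tibble(
      lat = lats, lon = lons,
      category = factor(categories, levels = vegdry:::greenness_levels())
    ),
    class = c("vd_greenness", class(tibble::tibble()))
  )
}

# single-row attribution map fixture for voting tests
mk_att <- function(dominants) {
  tibble::tibble(
    lat = 0, lon = seq_along(dominants) * 3 - 3,
    status = ifelse(is.na(dominants), "no_satisfactory_model", "attributed"),
    dominant = dominants
  )
}
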