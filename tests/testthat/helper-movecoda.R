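# Shared fixture builders. Everything is generated in code; no files.

# All permutations of a vector (used for brute-force basis invariance).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Random strictly positive five-part compositions closed to 1440.
random_compositions <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(exp(stats::rnorm(n * 5, sd = 0.8)), ncol = 5,
              dimnames = list(NULL, movement_parts()))
  close_composition(x, total = 1440)
}

# Numeric vector with exact sample mean and SD (for effect-size checks
# against printed group statistics).
vector_with_stats <- function(n, mean, sd) {
  base <- seq_len(n)
  as.numeric(scale(base)) * sd + mean
}

# Participant-level records with a planted linear outcome on the ILR
# coordinates of the canonical SED-first basis: y = beta'z + 0.5*I(female)
# + 0.05*(age - 11) + noise.
make_records <- function(n = 200, beta = c(0.5, -0.3, 0.2, -0.4),
                         noise_sd = 0.1, seed = 99) {
  set.seed(seed)
  basis <- pivot_basis("SED")
  mu <- ilr_transform(c(SED = 342, LPA = 351, MPA = 40, VPA = 14, Sleep = 693),
                      basis)
  z <- MASS::mvrnorm(n, mu = mu, Sigma = diag(c(0.18, 0.18, 0.4, 0.55)^2))
  comp <- ilr_inverse(z, basis, total = 1440)
  rec <- tibble::tibble(
    participant_id = sprintf("T%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = stats::runif(n, 8, 15),
    ethnicity = sample(c("White", "Black", "Asian", "NotReported"), n,
                       replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    month = sample(1:12, n, replace = TRUE)
  )
  rec <- dplyr::bind_cols(rec, tibble::as_tibble(comp))
  rec$y <- drop(z %*% beta) + 0.5 * (rec$sex == "female") +
    0.05 * (rec$age - 11) + stats::rnorm(n, 0, noise_sd)
  rec
}

# Rotated pivot-coefficient truths implied by beta in the canonical basis,
# derived independently through CLR space.
rotated_truths <- function(beta) {
  ref <- pivot_basis("SED")
  clr <- drop(t(ref$contrast) %*% beta)
  names(clr) <- ref$part_order
  vapply(movement_parts(), function(b) {
    bb <- pivot_basis(b)
    sum(bb$contrast[1, ] * clr[bb$part_order])
  }, numeric(1))
}
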