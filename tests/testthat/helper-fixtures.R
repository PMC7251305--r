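# Shared fixtures: tiny dictionaries, published worked-example tables,
# and convenience constructors. All numeric tables below are keyed in
# from the printed sources used by the worked-example tests.

toy_dicts <- function() {
  dictionary_set(
    pos_words = c("happy", "agree", "hug"),
    neg_words = c("sad", "disagree", "abandon"),
    abs_words = c("year", "hour", "soul")
  )
}

# build an `mtm` from a probability matrix (NA rows = undefined);
# pseudo-counts make defined rows detectable by rowSums(counts) > 0
mtm_from_probs <- function(probs, subject_id = "fixture", role = "patient",
                           n_per_row = 1000L) {
  probs <- as.matrix(probs)
  counts <- round(probs * n_per_row)
  counts[is.na(probs)] <- 0L
  structure(
    list(k = nrow(probs), counts = counts, probs = probs,
         subject_id = subject_id, role = role),
    class = "mtm"
  )
}

# George's individual transition matrix (6 defined rows over 8 states;
# states 5 and 6 were pruned and their rows are undefined)
george_probs <- function() {
  m <- matrix(NA_real_, 8, 8, dimnames = list(1:8, 1:8))
  m[1, c(1:4, 7, 8)] <- c(0.237, 0.042, 0.203, 0.025, 0.195, 0.297)
  m[2, c(1:4, 7, 8)] <- c(0.025, 0.125, 0.325, 0.125, 0.325, 0.075)
  m[3, c(1:4, 7, 8)] <- c(0.159, 0.057, 0.248, 0.038, 0.217, 0.280)
  m[4, c(1:4, 7, 8)] <- c(0.121, 0.030, 0.212, 0.091, 0.121, 0.424)
  m[7, c(1:4, 7, 8)] <- c(0.139, 0.062, 0.206, 0.026, 0.289, 0.278)
  m[8, c(1:4, 7, 8)] <- c(0.129, 0.031, 0.133, 0.043, 0.246, 0.418)
  m[c(1:4, 7, 8), 5:6] <- 0 # no transitions into the pruned states
  m
}

# George's patient-to-therapist dyad matrix
george_p2t_probs <- function() {
  m <- matrix(NA_real_, 8, 8, dimnames = list(1:8, 1:8))
  m[1, c(1:4, 7, 8)] <- c(0.066, 0.246, 0.016, 0.131, 0.361, 0.180)
  m[2, c(1:4, 7, 8)] <- c(0.103, 0.069, 0.138, 0.052, 0.284, 0.353)
  m[3, c(1:4, 7, 8)] <- c(0.014, 0.264, 0.000, 0.125, 0.389, 0.208)
  m[4, c(1:4, 7, 8)] <- c(0.133, 0.084, 0.120, 0.120, 0.229, 0.313)
  m[7, c(1:4, 7, 8)] <- c(0.084, 0.113, 0.122, 0.084, 0.303, 0.294)
  m[8, c(1:4, 7, 8)] <- c(0.061, 0.187, 0.075, 0.140, 0.299, 0.238)
  m[c(1:4, 7, 8), 5:6] <- 0
  m
}

# published per-subject full-model coefficients (beta distance, beta
# composite frequency, R, R^2, adjusted R^2, beta ratio), by role
published_fits <- function() {
  pat <- tibble::tribble(
    ~subject_id, ~beta_dist, ~beta_comp, ~r, ~r2, ~adj_r2, ~beta_ratio,
    "George",    -0.295, 0.709, 0.864, 0.746, 0.717, 2.403,
    "Primo",     -0.373, 0.697, 0.896, 0.803, 0.781, 1.869,
    "Secondolo", -0.405, 0.663, 0.896, 0.803, 0.781, 1.637,
    "Terzio",    -0.149, 0.806, 0.872, 0.761, 0.734, 5.409,
    "Jan",       -0.369, 0.673, 0.873, 0.762, 0.735, 1.823,
    "Lisa",      -0.476, 0.645, 0.928, 0.861, 0.845, 1.355,
    "Margareth", -0.452, 0.676, 0.941, 0.885, 0.872, 1.495,
    "Sarah",     -0.220, 0.763, 0.869, 0.754, 0.727, 3.468
  )
  ther <- tibble::tribble(
    ~subject_id, ~beta_dist, ~beta_comp, ~r, ~r2, ~adj_r2, ~beta_ratio,
    "George",     0.271, 1.006, 0.888, 0.789, 0.754,  3.712,
    "Primo",     -0.036, 0.827, 0.845, 0.714, 0.667, 22.972,
    "Secondolo",  0.057, 0.915, 0.890, 0.793, 0.758, 16.052,
    "Terzio",    -0.025, 0.784, 0.798, 0.638, 0.577, 31.360,
    "Jan",       -0.069, 0.892, 0.927, 0.859, 0.835, 12.927,
    "Lisa",      -0.056, 0.750, 0.782, 0.612, 0.547, 13.393,
    "Margareth",  0.109, 0.875, 0.831, 0.690, 0.639,  8.027,
    "Sarah",      0.031, 0.877, 0.862, 0.743, 0.700, 28.290
  )
  pat$role <- "patient"; ther$role <- "therapist"
  pat$mode <- "full"; ther$mode <- "full"
  list(patient = pat, therapist = ther, both = rbind(pat, ther))
}

# a length-6 vector with exactly the published poor-poor DeltaCorr class
# moments (mean 0.105, sample sd 0.100)
published_delta_values <- function() {
  0.105 + 0.100 * as.numeric(scale(1:6))
}

# small separated 3-blob standardized fixture for clustering tests
three_blob_fixture <- function(n_per = 40L, sd = 0.1, seed = 42L) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0), 3, byrow = TRUE)
  z <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(n_per * 3, 0, sd), n_per, 3), 2, centers[i, ], "+")
  }))
  list(z = z, truth = rep(1:3, each = n_per), centers = centers)
}

# independent linear-solve oracle for the stationary distribution
stationary_oracle <- function(P) {
  k <- nrow(P)
  A <- rbind(t(diag(k) - P), rep(1, k))
  b <- c(rep(0, k), 1)
  qr.solve(A, b)
}
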