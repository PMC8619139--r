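# Brute-force maximum-weight one-to-one assignment over a candidate pair
# table: the independent oracle for the modified-cosine peak assignment.
# Exhaustive recursion (use / skip each candidate), feasible for the small
# spectra it is applied to.
brute_force_assignment <- function(cand) {
  n <- nrow(cand)
  if (n == 0L) return(0)
  rec <- function(i, used_a, used_b) {
    if (i > n) return(0)
    best <- rec(i + 1L, used_a, used_b)  # skip candidate i
    ia <- cand$index_a[i]; ib <- cand$index_b[i]
    if (!(ia %in% used_a) && !(ib %in% used_b))
      best <- max(best, cand$weight[i] + rec(i + 1L, c(used_a, ia), c(used_b, ib)))
    best
  }
  rec(1L, integer(0), integer(0))
}

# Oracle modified cosine: brute-force assignment normalized like the
# implementation, but sharing no code path with greedy_assign.
oracle_modified_cosine <- function(a, b, frag_tol = 0.02) {
  cand <- photonet::match_peaks(a, b, frag_tol)
  norm_a <- sqrt(sum(a$peaks[, 2]))
  norm_b <- sqrt(sum(b$peaks[, 2]))
  if (norm_a == 0 || norm_b == 0) return(0)
  min(brute_force_assignment(cand) / (norm_a * norm_b), 1)
}

# Random related spectrum pair with <= max_peaks peaks each: b copies some of
# a's peaks, shifts others by the precursor mass difference, and adds fresh
# ones -- the structure analog pairs actually have.
random_spectrum_pair <- function(max_peaks = 6L) {
  na <- sample(2:max_peaks, 1L)
  mza <- sort(stats::runif(na, 100, 500))
  while (any(diff(mza) < 0.05)) mza <- sort(stats::runif(na, 100, 500))
  ia <- stats::rlnorm(na, log(50), 1)
  delta <- sample(c(0, 14.0157, 15.9949, 162.0528), 1L)
  pa <- max(mza) + stats::runif(1, 20, 120)
  n_copy <- sample(0:na, 1L)
  copied <- sort(sample(seq_len(na), n_copy))
  shifted <- setdiff(seq_len(na), copied)
  shifted <- shifted[stats::runif(length(shifted)) < 0.7]
  mzb <- c(mza[copied], mza[shifted] + delta)
  ib <- c(ia[copied], ia[shifted]) * stats::rlnorm(length(mzb), 0, 0.2)
  n_new <- sample(0:(max_peaks - length(mzb)), 1L)
  if (n_new > 0L) {
    mzb <- c(mzb, stats::runif(n_new, 100, 500))
    ib <- c(ib, stats::rlnorm(n_new, log(50), 1))
  }
  o <- order(mzb)
  mzb <- mzb[o]; ib <- ib[o]
  keep <- if (length(mzb) > 0L) c(TRUE, diff(mzb) > 1e-6) else logical(0)
  list(a = photonet::fragment_spectrum("a", pa, peaks = cbind(mza, ia)),
       b = photonet::fragment_spectrum("b", pa + delta,
                                       peaks = cbind(mzb[keep], ib[keep])))
}

# Noise-free Hill viability at the standard dose ladder.
hill_viability <- function(conc, ec50, h = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ec50)^h)
}

dose_ladder <- c(37.5, 18.75, 7.5, 3.75, 1.875, 0.375)

# Small deterministic generator config for fast tests.
small_config <- function(seed = 1L) {
  plan <- data.frame(
    family = c("A", "B", "C"),
    size = c(5L, 4L, 3L),
    extract = c("xanthophyllus", "rubrophyllus", "callisteus"),
    chromophore = c(TRUE, TRUE, FALSE),
    specific = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  generator_config(seed = seed, family_plan = plan)
}
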