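#' Simulate a synovial-fluid-like binned metabolite cohort
#'
#' Generates a labelled bin matrix with the statistical structure the
#' downstream analysis assumes: a small two-class cohort (default 10 OA vs
#' 14 RA, mirroring the MTBLS564 synovial-fluid study design) over a few
#' hundred bins, of three kinds:
#'
#' * **perfect** bins: the two class-conditional distributions are uniforms
#'   on disjoint intervals whose supports, after min-max scaling of the bin,
#'   are separated by at least `gap` — so a single-threshold decision stump
#'   attains MCC exactly 1.
#' * **informative** bins: Gaussian class distributions whose means differ
#'   by `effect_size * noise_sd`, with overlapping sample supports. A draw
#'   whose class supports happen not to overlap is redrawn, since
#'   non-overlap is the defining property reserved for perfect bins.
#' * **null** bins: identical Gaussian distributions in both classes.
#'
#' Each bin's direction (which class is elevated) is random. All intensities
#' are made positive by a single global shift, which preserves every
#' distributional shape and all downstream scale-invariant statistics.
#'
#' @param n_OA,n_RA class sample sizes (defaults 10 and 14).
#' @param n_bins total number of bins (default 200).
#' @param n_perfect number of perfectly separating bins (default 4).
#' @param n_informative number of moderately informative bins (default 50).
#' @param effect_size class-mean separation of informative bins, in units
#'   of `noise_sd` (default 2).
#' @param gap minimum normalized gap between the class supports of perfect
#'   bins, on the bin's min-max scale; must lie in (0, 1) (default 0.5).
#' @param noise_sd within-class standard deviation (default 1).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#' @return a list of class `simulated_cohort` with elements `matrix` (a
#'   [bin_matrix()]), `truth` (data.frame `bin_id`, `role`, `direction`)
#'   and `config`.
#' @examples
#' sim <- simulate_cohort(seed = 1)
#' table(sim$truth$role)
#' @export
simulate_cohort <- function(n_OA = 10, n_RA = 14, n_bins = 200,
                            n_perfect = 4, n_informative = 50,
                            effect_size = 2, gap = 0.5, noise_sd = 1,
                            seed = 1) {
  if (n_perfect + n_informative > n_bins) {
    stop("n_perfect + n_informative must not exceed n_bins")
  }
  if (gap <= 0 || gap >= 1) stop("gap must lie strictly between 0 and 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_OA < 1 || n_RA < 1) stop("both classes need at least one sample")
  n <- n_OA + n_RA
  labels <- rep(c("OA", "RA"), c(n_OA, n_RA))
  is_ra <- labels == "RA"

  set.seed(seed)

  roles <- rep("null", n_bins)
  if (n_perfect > 0) roles[seq_len(n_perfect)] <- "perfect"
  if (n_informative > 0) roles[n_perfect + seq_len(n_informative)] <- "informative"

  values <- matrix(0, n, n_bins)
  direction <- character(n_bins)
  width <- (1 - gap) / 2  # support width of each class interval on [0,1]
  for (j in seq_len(n_bins)) {
    up <- stats::runif(1) < 0.5  # TRUE: RA elevated
    direction[j] <- if (up) "RA" else "OA"
    if (roles[j] == "perfect") {
      lo <- stats::runif(n, 0, width)
      hi <- stats::runif(n, 1 - width, 1)
      x <- ifelse(xor(is_ra, !up), hi, lo)
      # arbitrary positive scale so raw intensities are not already in [0,1]
      x <- x * stats::runif(1, 5, 50)
    } else if (roles[j] == "informative") {
      mu <- stats::runif(1, 5, 15)
      delta <- effect_size * noise_sd
      repeat {
        x <- stats::rnorm(n, mu + ifelse(xor(is_ra, !up), delta, 0), noise_sd)
        # enforce overlapping class supports; disjoint supports are the
        # defining property of perfect bins only
        if (max(x[!xor(is_ra, !up)]) > min(x[xor(is_ra, !up)])) break
      }
    } else {
      mu <- stats::runif(1, 5, 15)
      x <- stats::rnorm(n, mu, noise_sd)
      direction[j] <- "none"
    }
    values[, j] <- x
  }
  shift <- min(values)
  if (shift <= 0) values <- values + abs(shift) + 0.01

  bin_id <- sprintf("%s_bin_%03d [%0.4f]", roles, seq_len(n_bins),
                    seq(0.5, 9.5, length.out = n_bins))
  colnames(values) <- bin_id
  m <- bin_matrix(values, labels = labels)
  truth <- data.frame(bin_id = bin_id, role = roles, direction = direction,
                      stringsAsFactors = FALSE)
  structure(list(matrix = m, truth = truth,
                 config = list(n_OA = n_OA, n_RA = n_RA, n_bins = n_bins,
                               n_perfect = n_perfect,
                               n_informative = n_informative,
                               effect_size = effect_size, gap = gap,
                               noise_sd = noise_sd, seed = seed)),
            class = "simulated_cohort")
}

#' Inject within-block correlation among null bins
#'
#' Rewrites consecutive blocks of null bins as a shared-factor Gaussian
#' model so that, in expectation, pairs within a block correlate at `rho`,
#' emulating within-pathway metabolite correlation. Per-bin means and
#' standard deviations, the labels and all planted (perfect/informative)
#' bins are untouched.
#'
#' @param cohort a `simulated_cohort` from [simulate_cohort()].
#' @param rho target pairwise correlation within a block, in `[0, 1]`.
#' @param block_size number of consecutive null bins per block (>= 2).
#' @param seed integer seed (default: derived from the cohort's seed).
#' @return the modified `simulated_cohort`.
#' @export
inject_correlation <- function(cohort, rho, block_size, seed = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (block_size < 2) stop("block_size must be at least 2")
  if (rho == 0) return(cohort)
  if (is.null(seed)) seed <- cohort$config$seed + 10000L
  set.seed(seed)
  idx_null <- which(cohort$truth$role == "null")
  n <- nrow(cohort$matrix$values)
  blocks <- split(idx_null, ceiling(seq_along(idx_null) / block_size))
  for (blk in blocks) {
    if (length(blk) < 2) next
    z <- stats::rnorm(n)  # shared factor
    for (j in blk) {
      mu <- mean(cohort$matrix$values[, j])
      sdj <- stats::sd(cohort$matrix$values[, j])
      eps <- stats::rnorm(n)
      x <- sqrt(rho) * z + sqrt(1 - rho) * eps
      cohort$matrix$values[, j] <- mu + sdj * x
    }
  }
  cohort
}
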